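test_that("Fitch length matches exhaustive enumeration on the fixtures", {
  fx <- chelicerate_rgc_fixture()
  chars <- fx$characters
  all_zero <- setNames(rep("0", length(fx$tree$tip.label)),
                       fx$tree$tip.label)
  expect_equal(fitch_length(fx$tree, all_zero)$length, 0L)
  for (cn in colnames(chars)) {
    ch <- setNames(chars[[cn]], rownames(chars))
    oracle <- enumerate_mprs(fx$tree, ch)
    expect_equal(fitch_length(fx$tree, ch)$length, oracle$min_length)
  }
  expect_equal(fitch_length(fx$tree,
                            setNames(chars$promenade,
                                     rownames(chars)))$length, 2L)
  expect_equal(fitch_length(fx$tree,
                            setNames(chars$book_lungs,
                                     rownames(chars)))$length, 2L)
  expect_error(fitch_length(fx$tree, all_zero[-1]), "without character")
})

test_that("courtship-dance histories realise both equally parsimonious scenarios", {
  fx <- chelicerate_rgc_fixture()
  prom <- setNames(fx$characters$promenade, rownames(fx$characters))
  arachnopulmonata <- c("Scorpiones", "Pseudoscorpiones", "Araneae",
                        "Amblypygi", "Uropygi", "Schizomida")
  panscorpiones <- c("Pseudoscorpiones", "Scorpiones")
  pedipalpi <- c("Amblypygi", "Uropygi", "Schizomida")
  acc <- acctran(fx$tree, prom, outgroup = fx$outgroup)
  del <- deltran(fx$tree, prom, outgroup = fx$outgroup)
  expect_equal(acc$length, 2L)
  expect_equal(del$length, 2L)
  expect_equal(acc$length, acc$fitch_length)
  key <- function(tips, from, to)
    sprintf("%s:%s>%s", paste(sort(tips), collapse = ","), from, to)
  expect_setequal(history_keys(acc),
                  c(key(arachnopulmonata, "0", "1"),
                    key("Araneae", "1", "0")))
  expect_setequal(history_keys(del),
                  c(key(panscorpiones, "0", "1"),
                    key(pedipalpi, "0", "1")))
  # book lungs: early gain with a pseudoscorpion reversal
  bl <- setNames(fx$characters$book_lungs, rownames(fx$characters))
  acc_bl <- acctran(fx$tree, bl, outgroup = fx$outgroup)
  expect_setequal(history_keys(acc_bl),
                  c(key(arachnopulmonata, "0", "1"),
                    key("Pseudoscorpiones", "1", "0")))
  # both reproductive-behaviour characters admit exactly the two scenarios
  for (cn in c("promenade", "brood_care")) {
    ch <- setNames(fx$characters[[cn]], rownames(fx$characters))
    oracle <- enumerate_mprs(fx$tree, ch)
    expect_equal(oracle$min_length, 2L)
    expect_equal(oracle$n_minimal, 2L)
    mpr_keys <- lapply(seq_len(2), function(r)
      mpr_change_keys(oracle, r, ch))
    a <- acctran(fx$tree, ch, outgroup = fx$outgroup)
    d <- deltran(fx$tree, ch, outgroup = fx$outgroup)
    expect_true(any(vapply(mpr_keys, identical, logical(1),
                           y = history_keys(a))))
    expect_true(any(vapply(mpr_keys, identical, logical(1),
                           y = history_keys(d))))
    expect_false(identical(history_keys(a), history_keys(d)))
  }
})

test_that("ACCTRAN/DELTRAN always attain the Fitch minimum", {
  set.seed(31)
  for (i in 1:25) {
    ntaxa <- sample(5:10, 1)
    tr <- ape::rtree(ntaxa)
    alphabet <- as.character(seq_len(sample(2:3, 1)) - 1)
    ch <- setNames(sample(c(alphabet, "?"), ntaxa, replace = TRUE,
                          prob = c(rep(0.45, length(alphabet)), 0.1)),
                   tr$tip.label)
    if (all(ch == "?")) ch[1] <- "0"
    if (length(unique(ch[ch != "?"])) < 2) ch[1:2] <- alphabet[1:2]
    oracle <- enumerate_mprs(tr, ch, alphabet)
    fl <- fitch_length(tr, ch)$length
    expect_equal(fl, oracle$min_length)
    acc <- acctran(tr, ch)
    del <- deltran(tr, ch)
    expect_equal(acc$length, oracle$min_length)
    expect_equal(del$length, oracle$min_length)
    # each history is a genuine MPR
    all_keys <- lapply(seq_len(oracle$n_minimal), function(r)
      mpr_change_keys(oracle, r, ch))
    expect_true(any(vapply(all_keys, identical, logical(1),
                           y = history_keys(acc))))
    expect_true(any(vapply(all_keys, identical, logical(1),
                           y = history_keys(del))))
  }
})

test_that("LCA reconciliation matches the brute-force oracle", {
  st <- read_newick("((a,b),c);")
  gt <- read_newick("((a1,b1),(a2,b2));")
  map <- c(a1 = "a", b1 = "b", a2 = "a", b2 = "b")
  rec <- lca_reconcile(gt, st, map)
  expect_equal(rec$n_duplications, 1L)
  expect_equal(sum(rec$events$event == "speciation"), 2L)
  # congruent single-copy tree: no duplications
  cong <- lca_reconcile(read_newick("((a1,b1),c1);"), st,
                        c(a1 = "a", b1 = "b", c1 = "c"))
  expect_equal(cong$n_duplications, 0L)
  expect_error(lca_reconcile(gt, st, map[-1]), "unmapped")
  expect_error(lca_reconcile(gt, st, c(map[-4], b2 = "zz")), "absent")
  # random gene trees against the oracle
  set.seed(91)
  species <- paste0("s", 1:5)
  st2 <- ape::rtree(5); st2$tip.label <- species
  for (i in 1:30) {
    gt2 <- ape::rtree(12)
    map2 <- setNames(sample(species, 12, replace = TRUE), gt2$tip.label)
    rec2 <- lca_reconcile(gt2, st2, map2)
    oracle <- brute_reconcile(gt2, st2, map2)
    expect_equal(rec2$events$event, oracle$event)
    expect_equal(rec2$events$species_node, oracle$species_node)
  }
})

test_that("shared duplications are separated from lineage-specific ones", {
  dir <- system.file("extdata", package = "lbagrid")
  gt <- read_newick(paste(readLines(file.path(dir,
                                              "dac_ohnologs_synthetic.nwk")),
                          collapse = ""))
  st <- read_newick(paste(readLines(file.path(dir,
                                              "ohnolog_species_synthetic.nwk")),
                          collapse = ""))
  map <- setNames(sub("_dac[0-9]*$", "", gt$tip.label), gt$tip.label)
  rec <- lca_reconcile(gt, st, map)
  expect_equal(rec$n_duplications, 1L)
  expect_equal(shared_duplication(rec, c("spider", "scorpion",
                                         "pseudoscorpion")), "shared")
  # in-paralogs: duplication inside one lineage
  st3 <- read_newick("((a,b),c);")
  rec3 <- lca_reconcile(read_newick("((a1,a2),b1);"), st3,
                        c(a1 = "a", a2 = "a", b1 = "b"))
  expect_equal(shared_duplication(rec3, c("a", "b")), "lineage_specific")
  expect_equal(shared_duplication(rec3, c("b", "c")), "absent")
  expect_error(shared_duplication(rec3, character()), "empty")
})

test_that("paralog screening merges alleles and fragments, splits paralogs", {
  same <- strrep("ACDEFGHIKLMNPQRSTVWY", 8)           # 160 aa
  expect_equal(paralog_screen(c(x = same, y = same))$copy_count, 1L)
  five_subs <- paste0(strrep("ACDEFGHIKLMNPQRSTVWY", 7),
                      "WWWWWGHIKLMNPQRSTVWY")
  expect_equal(paralog_screen(c(x = same, y = five_subs))$copy_count, 2L)
  # two non-overlapping fragments that each overlap a third with >= 2 subs
  frag1 <- paste0(strrep("A", 150), strrep("-", 150))
  frag2 <- paste0(strrep("-", 150), strrep("C", 150))
  third <- paste0(strrep("A", 75), strrep("W", 150), strrep("C", 75))
  res <- paralog_screen(c(f1 = frag1, f2 = frag2, t = third))
  expect_equal(res$copy_count, 2L)
  # order invariance
  res2 <- paralog_screen(c(t = third, f2 = frag2, f1 = frag1))
  expect_equal(res2$copy_count, res$copy_count)
  expect_equal(paralog_screen(character())$copy_count, 0L)
  # overlap must exceed 100 aa to call paralogy
  short_a <- paste0(strrep("A", 90), strrep("-", 110))
  short_b <- paste0(strrep("C", 90), strrep("-", 110))
  expect_equal(paralog_screen(c(a = short_a, b = short_b))$copy_count, 1L)
})

test_that("motif filtering requires every motif as an exact substring", {
  both <- "MSTELEKEFAAKIWFQNRRMK"
  one <- "MSTELEKEFAAKIWAQNRRMK"
  expect_equal(motif_filter(c(both, one)), both)
  expect_equal(motif_filter(c(both, one), character()), c(both, one))
  expect_length(motif_filter(one), 0L)
})

test_that("duplication tallies flag rows shared between clades", {
  counts <- rbind(dac = c(pseudo = 2, scorpion = 2, mite = 1),
                  hth = c(pseudo = 2, scorpion = 1, mite = 1),
                  exd = c(pseudo = 1, scorpion = 1, mite = 1))
  tal <- duplication_tally(counts, focal_species = "pseudo",
                           reference_species = c("scorpion"))
  expect_equal(unname(tal$shared), c(TRUE, FALSE, FALSE))
  all_ones <- matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                              c("pseudo", "scorpion")))
  expect_false(any(duplication_tally(all_ones, "pseudo",
                                     "scorpion")$shared))
  expect_error(duplication_tally(counts, "nope", "scorpion"), "unknown")
})
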