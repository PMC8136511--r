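test_that("pruning likelihood matches exhaustive-state enumeration", {
  set.seed(101)
  for (i in 1:12) {
    ntaxa <- sample(3:5, 1)
    tr <- random_blen_tree(ntaxa, seed = 200 + i)
    gamma <- if (i %% 2) NULL else 0.6
    m <- aa_model(sample(c("Poisson", "LG"), 1), gamma_shape = gamma,
                  n_cat = 3)
    lc <- simulate_alignment(tr, m, 4, seed = 300 + i)
    if (i %% 3 == 0) lc$seqs[1, 1] <- "-"  # exercise ambiguity handling
    expect_equal(tree_loglik(tr, lc, m)$log_likelihood,
                 exhaustive_loglik(tr, lc, m), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting and leaf order", {
  tr <- random_blen_tree(6, seed = 42)
  m <- aa_model("LG", gamma_shape = 0.8)
  lc <- simulate_alignment(tr, m, 80, seed = 5)
  base <- tree_loglik(tr, lc, m)$log_likelihood
  rerooted <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_equal(tree_loglik(rerooted, lc, m)$log_likelihood, base,
               tolerance = 1e-6)
  perm <- aa_locus(lc$id, lc$seqs[sample(nrow(lc$seqs)), ])
  expect_equal(tree_loglik(tr, perm, m)$log_likelihood, base,
               tolerance = 1e-10)
  expect_equal(sum(tree_loglik(tr, lc, m)$site_loglik), base,
               tolerance = 1e-8)
})

test_that("degenerate branch lengths hit their closed forms", {
  m <- aa_model("Poisson")
  same <- tree_loglik(read_newick("(A:0,B:0);"),
                      aa_locus("s", c(A = "AR", B = "AR")), m)
  expect_equal(same$log_likelihood, 2 * log(1 / 20), tolerance = 1e-10)
  expect_warning(
    diff_fit <- tree_loglik(read_newick("(A:0,B:0);"),
                            aa_locus("d", c(A = "A", B = "R")), m),
    "floored")
  expect_equal(diff_fit$site_loglik, -745)
})

test_that("branch-length optimisation matches the closed-form 2-taxon MLE", {
  m <- aa_model("Poisson")
  a <- rep("A", 1000)
  b <- c(rep("A", 525), rep("C", 475))   # p = 0.475
  fit <- optimize_branch_lengths(read_newick("(A:0.3,B:0.3);"),
                                 aa_locus("p", rbind(A = a, B = b)), m)
  expect_equal(sum(fit$tree$edge.length),
               -(19 / 20) * log(1 - 20 * 0.475 / 19), tolerance = 1e-4)
  ident <- optimize_branch_lengths(read_newick("(A:0.2,B:0.2);"),
                                   aa_locus("i", rbind(A = a, B = a)), m)
  expect_true(all(ident$tree$edge.length <= 1e-6))
  # ascent property on a larger tree
  tr <- random_blen_tree(7, seed = 8)
  lc <- simulate_alignment(tr, m, 200, seed = 9)
  start <- tree_loglik(tr, lc, m)$log_likelihood
  opt <- optimize_branch_lengths(tr, lc, m)
  expect_gte(opt$log_likelihood, start)
  expect_true(opt$converged)
})

test_that("BIC model selection behaves at the edges and recovers the truth", {
  tr <- random_blen_tree(5, seed = 77)
  m <- aa_model("WAG")
  lc <- simulate_alignment(tr, m, 60, seed = 78)
  single <- select_model(lc, tr, data.frame(name = "JTT", gamma = FALSE))
  expect_equal(single$fit$model$name, "JTT")
  # one site: the gamma shape cannot justify its parameter
  one_site <- aa_locus("o", lc$seqs[, 1, drop = FALSE])
  sel <- select_model(one_site, tr,
                      data.frame(name = "LG", gamma = c(TRUE, FALSE)))
  expect_null(sel$fit$model$gamma_shape)
  # simulation recovery: LG+G data prefer LG+G in most replicates
  hits <- 0L
  for (r in 1:5) {
    trr <- random_blen_tree(8, seed = 500 + r, min_len = 0.05,
                            max_len = 0.5)
    sim <- simulate_alignment(trr, aa_model("LG", gamma_shape = 0.5), 2000,
                              seed = 600 + r)
    res <- select_model(sim, trr)
    best <- res$table[which.min(res$table$bic), ]
    hits <- hits + (best$name == "LG" && best$gamma)
  }
  expect_gte(hits, 3L)
})

test_that("Poisson-corrected distances follow the closed form", {
  expect_equal(ml_pairwise_distance("ACDE", "ACDE"), 0, ignore_attr = TRUE)
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste(c(rep("A", 525), rep("C", 475)), collapse = "")
  expect_equal(as.numeric(ml_pairwise_distance(a, b)),
               -(19 / 20) * log(1 - 20 * 0.475 / 19), tolerance = 1e-12)
  sat <- ml_pairwise_distance(paste(rep("A", 100), collapse = ""),
                              paste(c(rep("A", 4), rep("C", 96)),
                                    collapse = ""))
  expect_equal(as.numeric(sat), 20)
  expect_true(attr(sat, "saturated"))
  expect_error(ml_pairwise_distance("A-", "-A"), "unambiguous")
})

test_that("neighbor joining recovers additive distances exactly", {
  true <- read_newick("((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(true)
  nj <- nj_tree(D[c("A", "C", "B", "D"), c("A", "C", "B", "D")])
  expect_true(ape::all.equal.phylo(ape::unroot(true), nj,
                                   use.edge.length = TRUE))
  # 3 taxa: closed-form star lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  star <- nj_tree(D3)
  lens <- setNames(star$edge.length, star$tip.label[star$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "3 taxa")
  D3b <- D3; D3b[1, 2] <- 9
  expect_error(nj_tree(D3b), "symmetric")
})

test_that("NNI search equals exhaustive evaluation on quartets", {
  m <- aa_model("Poisson")
  q <- felsenstein_zone_quartet(p_long = 0.4, p_short = 0.1,
                                internal = 0.15, n_sites = 600, seed = 31)
  topos <- list("((A:0.1,C:0.1):0.1,B:0.1,D:0.1);",
                "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);",
                "((A:0.1,D:0.1):0.1,B:0.1,C:0.1);")
  ex <- vapply(topos, function(t)
    optimize_branch_lengths(read_newick(t), q$locus, m)$log_likelihood,
    numeric(1))
  found <- nni_search(read_newick(topos[[2]]), q$locus, m)
  expect_equal(found$fit$log_likelihood, max(ex), tolerance = 1e-2)
  # an already-optimal start is returned unchanged
  again <- nni_search(found$tree, q$locus, m)
  expect_equal(tree_splits(again$tree), tree_splits(found$tree))
  expect_gte(found$fit$log_likelihood,
             optimize_branch_lengths(read_newick(topos[[2]]), q$locus,
                                     m)$log_likelihood - 1e-9)
})

test_that("NNI search recovers the true topology on clean data", {
  m <- aa_model("Poisson")
  hits <- 0L
  for (r in 1:6) {
    set.seed(900 + r)
    tr <- ape::rtree(8, rooted = FALSE)
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    lc <- simulate_alignment(tr, m, 1000, seed = 950 + r)
    found <- nni_search(nj_tree(ml_distance_matrix(lc)), lc, m)
    hits <- hits + setequal(tree_splits(found$tree), tree_splits(tr))
  }
  expect_gte(hits, 5L)
})

test_that("site bootstrap is reproducible and calibrated", {
  m <- aa_model("Poisson")
  set.seed(4)
  tr <- read_newick(
    "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.5,(E:0.1,F:0.1):0.5);")
  lc <- simulate_alignment(tr, m, 400, seed = 12)
  one <- bootstrap_support(lc, m, n_reps = 1, seed = 2)
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  b1 <- bootstrap_support(lc, m, n_reps = 20, seed = 6)
  b2 <- bootstrap_support(lc, m, n_reps = 20, seed = 6)
  expect_identical(b1$node.label, b2$node.label)
  # long internal branches: every split strongly supported
  b3 <- bootstrap_support(lc, m, n_reps = 50, seed = 6)
  sup3 <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(sup3[!is.na(sup3)] >= 90))
})

test_that("newick I/O round trips and surfaces parse errors", {
  tr <- read_newick("((A:1,B:2)90:0.5,C:1);")
  expect_equal(node_supports(tr)[2], 90)
  set.seed(19)
  big <- ape::rtree(50)
  back <- read_newick(write_newick(big))
  expect_true(ape::all.equal.phylo(big, back, use.edge.length = TRUE))
  expect_error(read_newick("((A,B);"), "parse")
  expect_error(read_newick("((A:1,A:2):1,B:1);"), "duplicate")
})
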