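toy_hypotheses <- function() {
  h1 <- "((O1:0.1,O2:0.1):0.1,((S1:0.1,S2:0.1):0.1,(P1:0.1,P2:0.1):0.1):0.1,(X1:0.1,X2:0.1):0.1);"
  h2 <- "((O1:0.1,O2:0.1):0.1,(S1:0.1,S2:0.1):0.1,((P1:0.1,P2:0.1):0.1,(X1:0.1,X2:0.1):0.1):0.1);"
  hypothesis_pair("P+S", h1, "P+X", h2)
}

test_that("constraint pruning contracts degree-2 nodes", {
  hyp <- toy_hypotheses()
  m <- aa_model("Poisson")
  full <- simulate_alignment(hyp$tree_1, m, 60, seed = 1)
  fit <- gene_loglik_on_topology(full, hyp$tree_1,
                                 data.frame(name = "LG", gamma = FALSE))
  expect_s3_class(fit, "likelihood_result")
  expect_equal(sort(fit$tree$tip.label), sort(hyp$tree_1$tip.label))
  # drop one taxon: pruned topology loses one leaf, stays unrooted binary
  part <- aa_locus("p", full$seqs[-1, ])
  fit2 <- gene_loglik_on_topology(part, hyp$tree_1,
                                  data.frame(name = "LG", gamma = FALSE))
  expect_equal(length(fit2$tree$tip.label), 7L)
  expect_equal(fit2$tree$Nnode, 5L)  # binary unrooted: n - 2 internals
  # too few taxa left: skipped with a reason
  tiny <- aa_locus("t", full$seqs[1:3, ])
  sk <- gene_loglik_on_topology(tiny, hyp$tree_1)
  expect_s3_class(sk, "skipped_locus")
})

test_that("deltaGLS is zero at indistinguishable hypotheses and antisymmetric", {
  hyp <- toy_hypotheses()
  m1 <- data.frame(name = "Poisson", gamma = FALSE)
  lc <- simulate_alignment(hyp$tree_1, aa_model("Poisson"), 80, seed = 2)
  d12 <- delta_gls(lc, hyp, m1)
  swapped <- hypothesis_pair(hyp$label_2, hyp$tree_2,
                             hyp$label_1, hyp$tree_1)
  d21 <- delta_gls(lc, swapped, m1)
  expect_equal(as.numeric(d12), -as.numeric(d21), tolerance = 1e-6)
  # a locus without the discriminating taxa sees identical topologies
  blind <- aa_locus("b", lc$seqs[c("O1", "O2", "S1", "S2", "P1"), ])
  expect_identical(delta_gls(blind, hyp, m1), 0)
  # undefined when a side is unresolvable
  tiny <- aa_locus("t", lc$seqs[1:3, ])
  expect_true(is.na(delta_gls(tiny, hyp, m1)))
})

test_that("deltaGLS distributions favour the generating topology", {
  hyp <- toy_hypotheses()
  m1 <- data.frame(name = "Poisson", gamma = FALSE)
  wins <- 0L
  vals <- numeric(10)
  for (r in 1:10) {
    lc <- simulate_alignment(hyp$tree_1, aa_model("Poisson"), 500,
                             seed = 100 + r)
    vals[r] <- delta_gls(lc, hyp, m1)
  }
  expect_gte(sum(vals > 0), 9L)
})

test_that("dgls_summary applies the stated tie rule", {
  s <- dgls_summary(c(2, -1, 0))
  expect_equal(unname(s$proportion), c(0.5, 0.5))
  expect_equal(s$n_neutral, 1L)
  expect_equal(s$n_defined, 3L)
  all_pos <- dgls_summary(c(1, 2, 3))
  expect_equal(unname(all_pos$proportion), c(1, 0))
  expect_error(dgls_summary(c(NA_real_, NA_real_)), "no defined")
})

test_that("sister classification names single, composite and failed cases", {
  groups <- list(Scorp = c("sc1", "sc2"), Acar = c("ac1", "ac2"),
                 Opil = c("op1"))
  og <- c("out1", "out2")
  tr <- read_newick(paste0("((out1,out2),((ac1,ac2),(op1,((sc1,sc2),",
                           "(ps1,ps2)))));"))
  res <- classify_sister(tr, c("ps1", "ps2"), groups, og)
  expect_true(res$focal_monophyletic)
  expect_equal(res$category, "Scorp")
  expect_equal(res$sister, c("sc1", "sc2"))
  # composite: sister = scorpions + harvestman exactly
  tr2 <- read_newick(paste0("((out1,out2),((ac1,ac2),((op1,(sc1,sc2)),",
                            "(ps1,ps2))));"))
  expect_equal(classify_sister(tr2, c("ps1", "ps2"), groups, og)$category,
               "Opil+Scorp")
  # split focal clade
  tr3 <- read_newick(paste0("((out1,out2),((ps1,(ac1,ac2)),(op1,((sc1,sc2),",
                            "ps2))));"))
  expect_equal(classify_sister(tr3, c("ps1", "ps2"), groups, og)$category,
               "non-monophyletic")
  # a single focal leaf present is unresolvable
  tr4 <- read_newick("((out1,out2),((ac1,ac2),(op1,((sc1,sc2),ps1))));")
  expect_equal(classify_sister(tr4, c("ps1", "ps2"), groups, og)$category,
               "unresolved")
  # sister set not coverable by named groups
  tr5 <- read_newick(paste0("((out1,out2),(ac2,((op1,ac1),((sc1,sc2),",
                            "(ps1,ps2)))));"))
  res5 <- classify_sister(tr5, c("ps1", "ps2"), groups, og)
  expect_equal(res5$category, "Scorp")
  tr6 <- read_newick(paste0("((out1,out2),(ac2,(((op1,ac1),(sc1,sc2)),",
                            "(ps1,ps2))));"))
  expect_equal(classify_sister(tr6, c("ps1", "ps2"), groups, og)$category,
               "other")
})

test_that("classification is invariant to leaf order and rerooting", {
  groups <- list(Scorp = c("sc1", "sc2"), Acar = c("ac1", "ac2"),
                 Opil = c("op1"))
  og <- c("out1", "out2")
  base <- paste0("((out1,out2),((ac1,ac2),(op1,((sc1,sc2),(ps1,ps2)))));")
  tr <- read_newick(base)
  res <- classify_sister(tr, c("ps1", "ps2"), groups, og)
  rot <- ape::rotateConstr(tr, sample(tr$tip.label))
  res_rot <- classify_sister(rot, c("ps1", "ps2"), groups, og)
  expect_equal(res_rot$category, res$category)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "ac1",
                        resolve.root = TRUE)
  res_rr <- classify_sister(rerooted, c("ps1", "ps2"), groups, og)
  expect_equal(res_rr$category, res$category)
  # nested hypotheses: a scorpion sister counts towards the larger clade
  expect_true(placement_matches(res, c("Scorp")))
  expect_true(placement_matches(res, c("Scorp", "Tetrapulmonata")))
  expect_false(placement_matches(res, c("Acar")))
})

test_that("hypothesis support reads node labels or flags absence", {
  tr <- read_newick("((out1,out2),((a,b)97,(c,d)55)88);")
  s <- hypothesis_support(tr, c("a", "b"), c("out1", "out2"))
  expect_equal(as.numeric(s), 97)
  expect_true(attr(s, "recovered"))
  missing <- hypothesis_support(tr, c("a", "c"), c("out1", "out2"))
  expect_equal(as.numeric(missing), 0)
  expect_false(attr(missing, "recovered"))
})

test_that("sensitivity grids join losslessly onto the plan", {
  plan <- build_matrix_grid(paste0("G", 1:6), paste0("T", 0:-6))
  plan$method <- "partitioned_ml"
  fake <- function(cat) structure(list(category = cat, support = 90,
                                       focal_monophyletic = TRUE,
                                       sister = character(), flags = NULL),
                                  class = "placement_result")
  keys <- grid_key(plan$family, plan$subset, plan$method)
  results <- setNames(lapply(seq_along(keys), function(i) fake("Scorp")),
                      keys)
  grid <- sensitivity_grid(plan, results)
  expect_equal(nrow(grid$table), 42L)
  expect_length(grid$missing, 0L)
  empty <- sensitivity_grid(plan, list())
  expect_equal(sum(is.na(empty$table$category)), 42L)
  expect_length(empty$missing, 42L)
  expect_error(sensitivity_grid(plan, setNames(list(fake("x")), "bad.key")),
               "unknown cell")
})
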