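# End-to-end sensitivity experiments on the synthetic LBA scenario:
# replicate simulation, tree inference with a deliberately LBA-susceptible
# method (Fitch parsimony), sister-group classification, and assembly of
# occupancy-by-pruning grids.  Inference runs on a reduced representative
# taxon set (a few tips per clade) to keep grid-scale runs tractable.

#' Representative taxa of an LBA scenario
#'
#' The complete focal clade (the clade under study is never thinned), plus
#' two tips each from the sister, attractor and outgroup clades and one per
#' "other" clade; the focal representation shrinks along the pruning series
#' as basal subgroups are removed.
#'
#' @param scenario result of \code{\link{lba_scenario}}.
#' @return character vector of tip names.
#' @export
lba_representatives <- function(scenario) {
  g <- scenario$groups
  basal <- grep("^FocalBasal", names(g), value = TRUE)
  c(unlist(g[basal], use.names = FALSE),
    g$FocalDerived,
    g$Sister[1:2], g$Attractor[1:2], g$Outgroup[1:2],
    g$OtherA[1], g$OtherB[1])
}

lba_group_defs <- function(scenario) {
  g <- scenario$groups
  basal <- grep("^FocalBasal", names(g), value = TRUE)
  list(Focal = c(unlist(g[basal], use.names = FALSE), g$FocalDerived),
       Sister = g$Sister, Attractor = g$Attractor,
       OtherA = g$OtherA, OtherB = g$OtherB)
}

classify_lba_tree <- function(tree, scenario) {
  defs <- lba_group_defs(scenario)
  classify_sister(tree,
                  focal_def = defs$Focal,
                  group_defs = defs[names(defs) != "Focal"],
                  outgroup_def = scenario$groups$Outgroup)
}

simulate_reduced_replicate <- function(scenario, config_args, reps, seed) {
  tr <- ape::keep.tip(scenario$tree, reps)
  cfg <- do.call(scenario_config,
                 c(list(tree = tr, seed = seed), config_args))
  simulate_locus_set(cfg)
}

#' Misplacement rates across the pruning series
#'
#' For each replicate, simulates a locus set on the representative taxa of
#' the scenario's true tree, then for each requested taxon subset restricts
#' the loci to the subset's surviving representatives, concatenates, infers
#' a tree by Fitch parsimony, and classifies the sister group of the focal
#' clade.  The classic LBA signature is an attractor-sister call on the
#' pruned-most subset and a true-sister call on the unpruned one.
#'
#' @param scenario result of \code{\link{lba_scenario}}.
#' @param n_reps number of simulation replicates.
#' @param seed integer seed.
#' @param subsets subset labels to analyse (default: unpruned and
#'   pruned-most).
#' @param model simulation model.
#' @param n_loci,sites_range,rate_shape,dropout generator conditions
#'   (defaults follow \code{\link{scenario_config}}).
#' @return data frame with one row per replicate x subset: \code{rep},
#'   \code{subset}, \code{category}, \code{focal_monophyletic}.
#' @export
lba_misplacement_rates <- function(scenario, n_reps = 50L, seed = 42L,
                                   subsets = NULL,
                                   model = aa_model("LG"),
                                   n_loci = 300L,
                                   sites_range = c(150L, 400L),
                                   rate_shape = 1, dropout = 0.25) {
  series <- scenario$series
  if (is.null(subsets))
    subsets <- c(series$label[1], series$label[nrow(series)])
  taxa_sets <- attr(series, "taxa")
  reps_all <- lba_representatives(scenario)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_reps)
  out <- vector("list", n_reps * length(subsets))
  k <- 0
  cfg_args <- list(model = model, n_loci = n_loci,
                   sites_range = sites_range, rate_shape = rate_shape,
                   dropout = dropout)
  for (r in seq_len(n_reps)) {
    sim <- simulate_reduced_replicate(scenario, cfg_args, reps_all,
                                      rep_seeds[r])
    for (lab in subsets) {
      keep <- intersect(reps_all, taxa_sets[[lab]])
      loci <- prune_taxa(sim$loci, keep)
      loci <- Filter(function(lc) !isTRUE(attr(lc, "untreeable")), loci)
      sm <- concatenate_loci(loci)
      inferred <- parsimony_tree(aa_locus("concat", sm$alignment))$tree
      res <- classify_lba_tree(inferred, scenario)
      k <- k + 1
      out[[k]] <- data.frame(rep = r, subset = lab,
                             category = res$category,
                             focal_monophyletic =
                               isTRUE(res$focal_monophyletic))
    }
  }
  do.call(rbind, out)
}

#' Occupancy-by-pruning sensitivity grid on synthetic data
#'
#' Runs the full supermatrix pipeline for one simulated replicate: loci are
#' filtered into occupancy families (occupancy measured against the
#' replicate's representative taxon set), each family is pruned along the
#' scenario's taxon series, concatenated, analysed by Fitch parsimony, and
#' the focal clade's sister group is classified per cell.
#'
#' @inheritParams lba_misplacement_rates
#' @param thresholds occupancy thresholds defining the families.
#' @return a \code{\link{sensitivity_grid}} result; the table has one row
#'   per (family, subset) cell.
#' @export
lba_sensitivity_grid <- function(scenario, seed = 42L,
                                 thresholds = c(0.80, 0.75, 0.70, 0.65,
                                                0.60, 0.55),
                                 model = aa_model("LG"), n_loci = 300L,
                                 sites_range = c(150L, 400L),
                                 rate_shape = 1, dropout = 0.25) {
  fams <- occupancy_families(thresholds)
  series <- scenario$series
  taxa_sets <- attr(series, "taxa")
  reps_all <- lba_representatives(scenario)
  cfg_args <- list(model = model, n_loci = n_loci,
                   sites_range = sites_range, rate_shape = rate_shape,
                   dropout = dropout)
  sim <- simulate_reduced_replicate(scenario, cfg_args, reps_all, seed)
  plan <- build_matrix_grid(fams, series)
  plan$method <- "parsimony"
  results <- list()
  for (i in seq_len(nrow(fams))) {
    filt <- filter_by_occupancy(sim$loci, fams$threshold[i], reps_all)
    for (lab in series$label) {
      keep <- intersect(reps_all, taxa_sets[[lab]])
      loci <- prune_taxa(filt$loci, keep)
      loci <- Filter(function(lc) !isTRUE(attr(lc, "untreeable")), loci)
      if (!length(loci)) next
      sm <- concatenate_loci(loci)
      inferred <- parsimony_tree(aa_locus("concat", sm$alignment))$tree
      key <- grid_key(fams$family[i], lab, "parsimony")
      results[[key]] <- classify_lba_tree(inferred, scenario)
    }
  }
  sensitivity_grid(plan, results)
}

#' Simulate loci under a hypothesis topology and score deltaGLS
#'
#' Convenience driver for signal experiments: simulates \code{n_loci} on the
#' scenario's (reduced, unpruned) true tree and computes deltaGLS between
#' the true placement (focal + sister) and the attractor placement (focal
#' moved next to the attractor clade) for every locus.
#'
#' @inheritParams lba_misplacement_rates
#' @param model_candidates per-gene model candidates for
#'   \code{\link{delta_gls}}.
#' @return list with \code{values} (per-locus deltaGLS, \code{NA} where
#'   undefined), \code{hypotheses}, and the simulated \code{loci}.
#' @export
lba_dgls_experiment <- function(scenario, n_loci = 200L, seed = 42L,
                                model = aa_model("LG"),
                                sites_range = c(150L, 400L),
                                rate_shape = 1, dropout = 0.25,
                                model_candidates = data.frame(name = "LG",
                                                              gamma = FALSE)) {
  # gene-level signal needs clade membership, not every breaker tip: one
  # representative per basal subgroup keeps per-gene fits small
  g <- scenario$groups
  basal <- grep("^FocalBasal", names(g), value = TRUE)
  reps_all <- c(vapply(g[basal], `[`, character(1), 1), g$FocalDerived,
                g$Sister[1:2], g$Attractor[1:2], g$Outgroup[1:2],
                g$OtherA[1], g$OtherB[1])
  true_tree <- ape::keep.tip(scenario$tree, reps_all)
  alt_tree <- attractor_hypothesis_tree(true_tree, scenario)
  hyp <- hypothesis_pair("focal+sister", true_tree,
                         "focal+attractor", alt_tree)
  cfg <- scenario_config(true_tree, model, n_loci = n_loci,
                         sites_range = sites_range, rate_shape = rate_shape,
                         dropout = dropout, seed = seed)
  sim <- simulate_locus_set(cfg)
  vals <- vapply(sim$loci, function(lc)
    as.numeric(delta_gls(lc, hyp, model_candidates)), numeric(1))
  list(values = vals, hypotheses = hyp, loci = sim$loci, truth = sim$truth)
}

# Alternative placement: the focal clade regrafted as sister to the
# attractor clade (branch lengths seeded at the true tree's scale).
attractor_hypothesis_tree <- function(true_tree, scenario) {
  defs <- lba_group_defs(scenario)
  focal <- intersect(defs$Focal, true_tree$tip.label)
  attr_tips <- intersect(defs$Attractor, true_tree$tip.label)
  pruned <- ape::drop.tip(true_tree, focal)
  focal_sub <- ape::keep.tip(true_tree, focal)
  focal_sub$root.edge <- 0.05
  node <- if (length(attr_tips) > 1) ape::getMRCA(pruned, attr_tips)
          else match(attr_tips, pruned$tip.label)
  e <- which(pruned$edge[, 2] == node)
  # graft halfway along the attractor stem so the result stays binary
  out <- ape::bind.tree(pruned, focal_sub, where = node,
                        position = pruned$edge.length[e] / 2)
  ape::unroot(out)
}
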