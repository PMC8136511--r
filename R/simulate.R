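# Forward simulation of amino-acid alignments and clade-structured
# long-branch-attraction (LBA) scenarios: a focal clade with basally
# branching short-branch subgroups and a fast-evolving derived subgroup, a
# short-branch true sister clade, an unrelated fast-evolving attractor
# clade, and outgroups.  Long branches arise purely from branch-length
# multipliers; gaps arise only from taxon dropout.

#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' down each branch with the transition matrices \eqn{P(t \cdot r_c)}, where
#' the discrete-gamma category \eqn{c} of each site is drawn with equal
#' weights.
#'
#' @param tree \code{phylo} with finite branch lengths.
#' @param model an \code{aa_model}.
#' @param n_sites number of columns (\eqn{\ge 1}).
#' @param seed integer seed.
#' @param rate overall rate multiplier applied to all branches.
#' @param id locus id of the returned alignment.
#' @return an \code{aa_locus} over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 42L, rate = 1,
                               id = "locus") {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  ncat <- model$n_categories
  cat_of <- sample.int(ncat, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                               prob = model$frequencies)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    t_e <- tr$edge.length[e] * rate
    # stack per-category cumulative transition rows: row (c-1)*20 + i
    cum <- do.call(rbind, lapply(seq_len(ncat), function(c)
      t(apply(transition_matrix(model, t_e * model$rates[c]), 1, cumsum))))
    rowid <- (cat_of - 1L) * 20L + states[u, ]
    u01 <- runif(n_sites)
    states[v, ] <- rowSums(cum[rowid, , drop = FALSE] < u01) + 1L
  }
  seqs <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                 nrow = ntip, dimnames = list(tr$tip.label, NULL))
  aa_locus(id, seqs)
}

#' Scenario configuration for locus-set simulation
#'
#' @param tree the true tree (a \code{phylo} with branch lengths).
#' @param model simulation model (an \code{aa_model}).
#' @param n_loci number of loci.
#' @param sites_range integer (min, max) of per-locus lengths (drawn
#'   uniformly).
#' @param rate_shape gamma shape of the across-locus rate multiplier
#'   distribution (mean 1).
#' @param dropout per-locus, per-taxon probability of dropping a taxon's row.
#' @param seed integer seed.
#' @return list of class \code{scenario_config}.
#' @export
scenario_config <- function(tree, model, n_loci = 300L,
                            sites_range = c(150L, 400L), rate_shape = 1,
                            dropout = 0.25, seed = 42L) {
  stopifnot(dropout >= 0, dropout <= 1, rate_shape > 0, n_loci >= 1,
            length(sites_range) == 2, sites_range[1] <= sites_range[2])
  structure(list(tree = tree, model = model, n_loci = as.integer(n_loci),
                 sites_range = as.integer(sites_range),
                 rate_shape = rate_shape, dropout = dropout,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a locus set with rate variation and taxon dropout
#'
#' Draws a per-locus rate multiplier from a mean-1 gamma distribution with
#' shape \code{rate_shape}, simulates each locus on the true tree, and
#' independently drops each taxon's row with probability \code{dropout}
#' (dropout masks rows only; the truth tree is untouched).  Identical seeds
#' give identical locus sets.
#'
#' @param config a \code{scenario_config}.
#' @return list with \code{loci}, \code{tree} (the truth), and \code{truth}
#'   (data frame: locus, rate multiplier, n_sites, dropped taxa as a
#'   comma-joined string).
#' @export
simulate_locus_set <- function(config) {
  set.seed(config$seed)
  ntaxa <- length(config$tree$tip.label)
  exp_left <- ntaxa * (1 - config$dropout)
  if (exp_left < 4)
    warning("dropout leaves fewer than 4 taxa per locus in expectation")
  mult <- rgamma(config$n_loci, shape = config$rate_shape,
                 rate = config$rate_shape)
  nsites <- sample.int(config$sites_range[2] - config$sites_range[1] + 1L,
                       config$n_loci, replace = TRUE) +
            config$sites_range[1] - 1L
  locus_seeds <- sample.int(.Machine$integer.max - 1L, config$n_loci)
  loci <- vector("list", config$n_loci)
  dropped <- character(config$n_loci)
  ids <- sprintf("locus%04d", seq_len(config$n_loci))
  for (i in seq_len(config$n_loci)) {
    lc <- simulate_alignment(config$tree, config$model, nsites[i],
                             seed = locus_seeds[i], rate = mult[i],
                             id = ids[i])
    set.seed(locus_seeds[i] + 1L)
    drop <- rownames(lc$seqs)[runif(ntaxa) < config$dropout]
    if (length(drop) >= ntaxa - 1) drop <- drop[seq_len(ntaxa - 2)]
    if (length(drop))
      lc <- aa_locus(lc$id, lc$seqs[setdiff(rownames(lc$seqs), drop), ,
                                    drop = FALSE])
    loci[[i]] <- lc
    dropped[i] <- paste(drop, collapse = ",")
  }
  list(loci = loci, tree = config$tree,
       truth = data.frame(locus = ids, rate_multiplier = mult,
                          n_sites = nsites, dropped = dropped))
}

#' Build a clade-structured LBA scenario
#'
#' Constructs the true tree of a long-branch-attraction scenario: a focal
#' clade with \code{k_basal} basally branching short-branch subgroups and a
#' fast-evolving derived subgroup, a short-branch true sister clade, a
#' fast-evolving attractor clade elsewhere in the tree, and outgroup/other
#' clades.  "Long" lineages get their stem and tip branches multiplied by
#' \code{long_mult}.  Also emits the registry, the pruning series removing
#' the basal focal subgroups one at a time, and the corresponding pruned
#' true trees.
#'
#' @param k_basal number of basal short-branch focal subgroups (\eqn{\ge 1}).
#' @param tips_per_basal tips per basal subgroup.
#' @param n_derived long-branch derived focal tips.
#' @param n_sister,n_attractor,n_outgroup,n_other tips in the sister,
#'   attractor, outgroup and each of the two "other" clades.
#' @param base_len short internal/stem branch length.
#' @param tip_len short tip branch length.
#' @param long_mult branch-length multiplier for long lineages.
#' @return list with \code{tree}, \code{registry} (a
#'   \code{taxon_registry}), \code{steps}, \code{series} (from
#'   \code{\link{pruning_series}}), \code{pruned_trees} (one per subset) and
#'   the clade definitions \code{groups} (named list of tip vectors).
#' @export
lba_scenario <- function(k_basal = 3L, tips_per_basal = 2L, n_derived = 2L,
                         n_sister = 4L, n_attractor = 4L, n_outgroup = 4L,
                         n_other = 2L, base_len = 0.05, tip_len = 0.06,
                         long_mult = 6) {
  if (k_basal < 1) stop("k_basal must be >= 1")
  tipset <- function(prefix, n) sprintf("%s_%d", prefix, seq_len(n))
  cherry <- function(tips, len) {
    if (length(tips) == 1) return(sprintf("%s:%g", tips, len))
    paste0("(", paste(sprintf("%s:%g", tips, len), collapse = ","),
           "):", len)
  }
  basal_names <- lapply(seq_len(k_basal),
                        function(i) tipset(sprintf("FocalBasal%d", i),
                                           tips_per_basal))
  derived <- tipset("FocalDerived", n_derived)
  sister <- tipset("Sister", n_sister)
  attractor <- tipset("Attractor", n_attractor)
  outgroup <- tipset("Outgroup", n_outgroup)
  otherA <- tipset("OtherA", n_other)
  otherB <- tipset("OtherB", n_other)
  # focal subtree: derived (long) nested inside successively more basal
  # short-branch subgroups; FocalBasal1 is basal-most (pruned first)
  sub <- cherry(derived, tip_len * long_mult)
  for (i in rev(seq_len(k_basal)))
    sub <- paste0("(", cherry(basal_names[[i]], tip_len), ",", sub, "):",
                  base_len)
  focal <- sub
  nwk <- paste0(
    "((((", focal, ",", cherry(sister, tip_len), "):", base_len, ",",
    cherry(otherB, tip_len), "):", base_len, ",(",
    cherry(attractor, tip_len * long_mult), ",", cherry(otherA, tip_len),
    "):", base_len, "):", base_len, ",", cherry(outgroup, tip_len), ");")
  # cherry() writes the subgroup stems at the same length as the tips, so
  # the attractor and focal-derived stems are already long
  tree <- read_newick(nwk)
  groups <- c(setNames(basal_names, paste0("FocalBasal", seq_len(k_basal))),
              list(FocalDerived = derived, Sister = sister,
                   Attractor = attractor, Outgroup = outgroup,
                   OtherA = otherA, OtherB = otherB))
  focal_tips <- c(unlist(basal_names), derived)
  reg <- taxon_registry(
    name = unlist(groups, use.names = FALSE),
    group = rep(c(rep("Focal", k_basal), "Focal", "Sister", "Attractor",
                  "Outgroup", "OtherA", "OtherB"),
                lengths(groups)),
    subgroup = rep(c(paste0("Basal", seq_len(k_basal)), "Derived", "", "",
                     "", "", ""), lengths(groups)),
    role = rep(c(rep("ingroup", k_basal), "ingroup", "ingroup", "ingroup",
                 "outgroup", "ingroup", "ingroup"), lengths(groups)))
  steps <- lapply(seq_len(k_basal), function(i)
    pruning_step(i, paste0("Basal", i), tips_per_basal))
  series <- pruning_series(reg, steps, "Focal")
  taxa_sets <- attr(series, "taxa")
  pruned_trees <- lapply(taxa_sets, function(tx) ape::keep.tip(tree, tx))
  list(tree = tree, registry = reg, steps = steps, series = series,
       pruned_trees = pruned_trees, groups = groups,
       focal_tips = focal_tips)
}

#' Write a simulated locus set to disk
#'
#' Emits per-locus FASTA files, the true tree as Newick, the truth table as
#' TSV, and (when a registry is supplied) the taxon registry TSV consumed by
#' the design layer.
#'
#' @param sim result of \code{\link{simulate_locus_set}}.
#' @param dir output directory (created if needed).
#' @param registry optional \code{taxon_registry} to write alongside.
#' @export
write_locus_set <- function(sim, dir, registry = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in sim$loci)
    write_locus_fasta(lc, file.path(dir, paste0(lc$id, ".fasta")))
  writeLines(write_newick(sim$tree), file.path(dir, "true_tree.nwk"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(registry))
    write.table(registry, file.path(dir, "registry.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Felsenstein-zone quartet
#'
#' Simulates an alignment on the unrooted quartet
#' \code{((A:short,C:long),(B:short,D:long))} with internal branch
#' \code{internal}: the true tree pairs each long branch with a short one,
#' the regime in which parsimony is statistically inconsistent and groups
#' the two long branches (C, D).
#'
#' @param p_long,p_short,internal branch lengths (> 0).
#' @param n_sites alignment length.
#' @param seed integer seed.
#' @param model simulation model (default Poisson).
#' @return list with \code{locus} (an \code{aa_locus}) and \code{tree}
#'   (the true quartet).
#' @export
felsenstein_zone_quartet <- function(p_long = 1.2, p_short = 0.05,
                                     internal = 0.02, n_sites = 1000L,
                                     seed = 42L, model = aa_model("Poisson")) {
  stopifnot(p_long > 0, p_short > 0, internal > 0)
  tree <- read_newick(sprintf("((A:%g,C:%g):%g,B:%g,D:%g);",
                              p_short, p_long, internal, p_short, p_long))
  list(locus = simulate_alignment(tree, model, n_sites, seed = seed,
                                  id = "quartet"),
       tree = tree)
}
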