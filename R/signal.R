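# Phylogenetic-signal dissection: gene-wise log-likelihoods on competing
# constraint topologies (deltaGLS), sister-group classification of inferred
# trees relative to a focal clade, hypothesis-support read-off, and assembly
# of the occupancy x pruning sensitivity grid.

#' A pair of competing placement hypotheses
#'
#' Each hypothesis is a full constraint topology (Newick string or
#' \code{phylo}).  The two topologies must differ.
#'
#' @param label_1,label_2 hypothesis labels.
#' @param tree_1,tree_2 constraint topologies.
#' @export
hypothesis_pair <- function(label_1, tree_1, label_2, tree_2) {
  t1 <- if (is.character(tree_1)) read_newick(tree_1) else tree_1
  t2 <- if (is.character(tree_2)) read_newick(tree_2) else tree_2
  if (identical(sort(t1$tip.label), sort(t2$tip.label)) &&
      setequal(tree_splits(t1), tree_splits(t2)))
    stop("the two hypotheses are topologically identical")
  structure(list(label_1 = label_1, tree_1 = t1,
                 label_2 = label_2, tree_2 = t2),
            class = "hypothesis_pair")
}

#' Gene log-likelihood on a constraint topology
#'
#' Restricts the constraint tree to the taxa present in the locus
#' (suppressing degree-2 nodes and summing branch lengths), selects a model
#' for the gene by BIC over \code{model_candidates}, and re-optimises branch
#' lengths on the pruned topology.
#'
#' @param locus an \code{aa_locus}.
#' @param constraint_tree a \code{phylo} covering (at least) the locus taxa.
#' @param model_candidates passed to \code{\link{select_model}}; a
#'   single-row data frame skips the model competition.
#' @return a \code{likelihood_result}, or \code{NULL} (with attribute
#'   \code{reason}) when fewer than four constraint taxa remain.
#' @export
gene_loglik_on_topology <- function(locus, constraint_tree,
                                    model_candidates = data.frame(
                                      name = "LG", gamma = TRUE)) {
  shared <- intersect(constraint_tree$tip.label, locus_taxa(locus))
  if (length(shared) < 4)
    return(structure(list(), class = "skipped_locus",
                     reason = paste0("only ", length(shared),
                                     " constraint taxa present")))
  sub <- ape::keep.tip(constraint_tree, shared)
  sub <- ape::unroot(sub)
  lc <- aa_locus(locus$id, locus$seqs[shared, , drop = FALSE])
  if (nrow(model_candidates) == 1) {
    nm <- as.character(model_candidates$name[1])
    if (isTRUE(model_candidates$gamma[1])) fit_gamma_model(sub, lc, nm)
    else optimize_branch_lengths(sub, lc, aa_model(nm))
  } else {
    select_model(lc, sub, model_candidates)$fit
  }
}

#' Gene-wise log-likelihood difference between two hypotheses
#'
#' \eqn{\Delta GLS = \ln L(gene \mid T_1) - \ln L(gene \mid T_2)}; positive
#' values favour the first hypothesis.  The statistic is antisymmetric under
#' swapping the hypotheses and exactly zero when they coincide topologically
#' for the locus.
#'
#' @param locus an \code{aa_locus}.
#' @param hypotheses a \code{hypothesis_pair}.
#' @param model_candidates as in \code{\link{gene_loglik_on_topology}}.
#' @return signed numeric, or \code{NA} (attribute \code{reason}) when
#'   either side is skipped.
#' @export
delta_gls <- function(locus, hypotheses,
                      model_candidates = data.frame(name = "LG",
                                                    gamma = TRUE)) {
  # when the two hypotheses are indistinguishable for this locus (the taxa
  # that separate them are absent), the statistic is exactly zero
  s1 <- intersect(hypotheses$tree_1$tip.label, locus_taxa(locus))
  s2 <- intersect(hypotheses$tree_2$tip.label, locus_taxa(locus))
  if (length(s1) >= 4 && setequal(s1, s2)) {
    p1 <- ape::keep.tip(hypotheses$tree_1, s1)
    p2 <- ape::keep.tip(hypotheses$tree_2, s2)
    if (setequal(tree_splits(p1), tree_splits(p2))) return(0)
  }
  f1 <- gene_loglik_on_topology(locus, hypotheses$tree_1, model_candidates)
  f2 <- gene_loglik_on_topology(locus, hypotheses$tree_2, model_candidates)
  if (inherits(f1, "skipped_locus") || inherits(f2, "skipped_locus"))
    return(structure(NA_real_, reason = "constraint unresolvable for locus"))
  f1$log_likelihood - f2$log_likelihood
}

#' Summarise deltaGLS values over loci
#'
#' @param values numeric vector of per-locus deltaGLS (NAs = undefined loci,
#'   dropped).
#' @param labels optional hypothesis labels (length 2).
#' @return list with the proportions of non-neutral loci favouring each
#'   hypothesis (summing to 1), the neutral count (exact zeros), and
#'   magnitude quantiles.
#' @export
dgls_summary <- function(values, labels = c("T1", "T2")) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined deltaGLS values")
  pos <- sum(v > 0); neg <- sum(v < 0); zero <- sum(v == 0)
  nz <- pos + neg
  props <- if (nz) c(pos, neg) / nz else c(NA_real_, NA_real_)
  list(n_defined = length(v),
       proportion = setNames(props, labels),
       n_neutral = zero,
       magnitude_quantiles = stats::quantile(abs(v),
                                             c(0.25, 0.5, 0.75, 0.9)))
}

#' Classify the sister group of a focal clade
#'
#' Roots the tree on the outgroup (the outgroup clade when monophyletic,
#' otherwise the first outgroup leaf, flagged), checks monophyly of the
#' focal leaves, and names the sister group: a single group label when the
#' sister leaf set is exactly that group's members on the tree, a composite
#' \code{"A+B"} label when exactly covered by a union of groups, otherwise
#' \code{"other"}.
#'
#' @param tree a \code{phylo}.
#' @param focal_def character vector of focal-clade leaves (or a group name
#'   resolved through \code{group_defs}).
#' @param group_defs named list: group label -> member leaves.
#' @param outgroup_def character vector of outgroup leaves.
#' @return list of class \code{placement_result}: \code{focal_monophyletic},
#'   \code{category}, \code{sister} (leaf set), \code{support} (label at the
#'   focal+sister node if present), \code{flags}.
#' @export
classify_sister <- function(tree, focal_def, group_defs, outgroup_def) {
  if (length(focal_def) == 1 && focal_def %in% names(group_defs))
    focal_def <- group_defs[[focal_def]]
  tips <- tree$tip.label
  focal <- intersect(focal_def, tips)
  og <- intersect(outgroup_def, tips)
  if (!length(og)) stop("tree contains no outgroup leaf")
  if (!length(focal)) stop("tree contains no focal leaf")
  flags <- character()
  if (length(focal) < 2)
    return(structure(list(focal_monophyletic = NA, category = "unresolved",
                          sister = character(), support = NA_real_,
                          flags = "fewer than 2 focal leaves present"),
                     class = "placement_result"))
  rooted <- root_on_outgroup(tree, og)
  tree <- rooted$tree
  flags <- c(flags, rooted$flags)
  desc <- node_descendants(tree)
  ntip <- length(tree$tip.label)
  if (length(focal) == ntip)
    stop("focal clade spans the whole tree")
  # focal monophyly: some node's tip set equals the focal set
  focal_node <- find_clade_node(tree, focal, desc)
  if (is.na(focal_node))
    return(structure(list(focal_monophyletic = FALSE,
                          category = "non-monophyletic",
                          sister = character(), support = NA_real_,
                          flags = flags),
                     class = "placement_result"))
  parent <- tree$edge[tree$edge[, 2] == focal_node, 1]
  if (!length(parent))  # focal clade is the whole ingroup at the root
    return(structure(list(focal_monophyletic = TRUE, category = "other",
                          sister = setdiff(tree$tip.label, focal),
                          support = NA_real_,
                          flags = c(flags, "focal clade at root")),
                     class = "placement_result"))
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], focal_node)
  sister <- sort(unique(unlist(desc[sibs])))
  grp_on_tree <- lapply(group_defs, intersect, y = tree$tip.label)
  covering <- names(grp_on_tree)[vapply(grp_on_tree, function(g)
    length(g) > 0 && any(g %in% sister), logical(1))]
  covered <- sort(unique(unlist(grp_on_tree[covering])))
  category <- if (length(covering) && setequal(covered, sister)) {
    paste(sort(covering), collapse = "+")
  } else "other"
  support <- NA_real_
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[parent - ntip]
    support <- suppressWarnings(as.numeric(lab))
  }
  structure(list(focal_monophyletic = TRUE, category = category,
                 sister = sister, support = support, flags = flags),
            class = "placement_result")
}

root_on_outgroup <- function(tree, og) {
  flags <- character()
  tree <- ape::unroot(tree)
  mono <- length(og) == 1 ||
    ape::is.monophyletic(tree, og)
  if (mono) {
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE,
                      edgelabel = TRUE)
  } else {
    flags <- "outgroup non-monophyletic; rooted on first outgroup leaf"
    tree <- ape::root(tree, outgroup = og[1], resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  list(tree = tree, flags = flags)
}

node_descendants <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(tr$edge))
  for (i in seq_along(tr$tip.label)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1]]] <- c(desc[[tr$edge[e, 1]]], desc[[tr$edge[e, 2]]])
  # map back: reorder preserves node numbering
  desc
}

find_clade_node <- function(tree, tipset, desc = node_descendants(tree)) {
  ntip <- length(tree$tip.label)
  for (v in (ntip + 1):(ntip + tree$Nnode))
    if (setequal(desc[[v]], tipset)) return(v)
  NA_integer_
}

#' Support for a hypothesised clade
#'
#' Looks up the support label of the node whose descendant leaf set equals
#' \code{clade_leafset} under outgroup rooting; absent clades return
#' \code{0} with the flag \code{"not recovered"}.
#'
#' @param tree a \code{phylo} with numeric internal-node labels.
#' @param clade_leafset character vector of leaves.
#' @param outgroup_def outgroup leaves used for rooting.
#' @return numeric support, with attribute \code{recovered}.
#' @export
hypothesis_support <- function(tree, clade_leafset, outgroup_def) {
  og <- intersect(outgroup_def, tree$tip.label)
  tree <- root_on_outgroup(tree, og)$tree
  node <- find_clade_node(tree, intersect(clade_leafset, tree$tip.label))
  if (is.na(node))
    return(structure(0, recovered = FALSE))
  ntip <- length(tree$tip.label)
  lab <- if (is.null(tree$node.label)) NA_character_
         else tree$node.label[node - ntip]
  structure(suppressWarnings(as.numeric(lab)), recovered = TRUE)
}

#' Assemble a sensitivity grid
#'
#' Joins per-cell placement results onto an analysis plan, producing the
#' long table behind occupancy-by-pruning sensitivity plots.
#'
#' @param plan data frame of cells (\code{family}, \code{subset},
#'   \code{method}, optional \code{tertile}), e.g. from
#'   \code{\link{enumerate_analyses}}.
#' @param results named list of \code{placement_result}, keyed by
#'   \code{family.subset.method[.tertile]} (see \code{\link{grid_key}}).
#' @return list with \code{table} (one row per plan cell: the key columns
#'   plus \code{category} and \code{support}) and \code{missing} (keys
#'   without results).  Results keyed outside the plan are an error.
#' @export
sensitivity_grid <- function(plan, results) {
  if (is.null(plan$tertile)) plan$tertile <- NA_character_
  keys <- grid_key(plan$family, plan$subset, plan$method, plan$tertile)
  unknown <- setdiff(names(results), keys)
  if (length(unknown))
    stop("results for unknown cell(s): ", paste(unknown, collapse = ", "))
  category <- rep(NA_character_, length(keys))
  support <- rep(NA_real_, length(keys))
  for (i in seq_along(keys)) {
    r <- results[[keys[i]]]
    if (!is.null(r)) {
      category[i] <- r$category
      support[i] <- r$support
    }
  }
  tab <- cbind(plan, category = category, support = support)
  rownames(tab) <- NULL
  list(table = tab, missing = keys[!keys %in% names(results)])
}

#' Does a placement support a (possibly nested) hypothesis?
#'
#' A placement counts towards a hypothesis whenever the groups named in its
#' category are a subset of the hypothesis' partner groups, so a sister
#' assignment to a nested group also counts towards the enclosing
#' hypothesis (e.g. a scorpion sister group counts towards an
#' arachnopulmonate one).
#'
#' @param result a \code{placement_result}.
#' @param partner_groups character vector of group labels defining the
#'   hypothesis.
#' @export
placement_matches <- function(result, partner_groups) {
  if (result$category %in% c("other", "non-monophyletic", "unresolved"))
    return(FALSE)
  all(strsplit(result$category, "+", fixed = TRUE)[[1]] %in% partner_groups)
}

#' @rdname sensitivity_grid
#' @param family,subset,method,tertile cell coordinates.
#' @export
grid_key <- function(family, subset, method, tertile = NA_character_) {
  k <- paste(family, subset, method, sep = ".")
  tertile <- rep_len(tertile, length(k))
  ifelse(is.na(tertile) | tertile == "", k, paste(k, tertile, sep = "."))
}
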