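# R interface to the pruning-likelihood engine, plus distance/NJ/NNI tree
# search and nonparametric site bootstrap.  Trees are ape "phylo" objects.

MIN_BRLEN <- 1e-8
MAX_BRLEN <- 20

# Align a phylo with an alignment and package everything for the C++ core.
engine_inputs <- function(tree, locus) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  seqs <- if (inherits(locus, "aa_locus")) locus$seqs else locus
  miss <- setdiff(tree$tip.label, rownames(seqs))
  if (length(miss))
    stop("tree leaves missing from alignment: ", paste(miss, collapse = ", "))
  if (!ncol(seqs)) stop("alignment has no sites")
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- locus_states(seqs[tr$tip.label, , drop = FALSE])
  pat <- compress_patterns(states)
  lens <- tr$edge.length
  if (is.null(lens)) lens <- rep(0.1, nrow(tr$edge))
  lens[is.na(lens) | lens < 0] <- 0
  list(tree = tr, edge = tr$edge, ntip = length(tr$tip.label),
       states = pat$states, weights = pat$weights, index = pat$index,
       lengths = lens)
}

likelihood_result <- function(tree, model, fit, index) {
  structure(list(tree = tree,
                 log_likelihood = fit$loglik,
                 site_loglik = fit$site_loglik[index],
                 model = model,
                 n_floored = fit$n_floored,
                 converged = if (is.null(fit$converged)) NA else fit$converged,
                 sweeps = if (is.null(fit$sweeps)) NA_integer_ else fit$sweeps),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("log-likelihood %.4f under %s (%d sites)\n",
              x$log_likelihood, model_label(x$model), length(x$site_loglik)))
  invisible(x)
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree under an
#' \code{aa_model}, summing per-site log-likelihoods averaged over the
#' discrete-gamma categories with equal weights.  Gaps and other ambiguous
#' residues contribute a partial likelihood of 1 for every state.  Sites with
#' zero likelihood (possible only at zero-length branches) are floored at
#' -745 with a warning.
#'
#' @param tree a \code{phylo}; its tips must all appear in the alignment.
#' @param locus an \code{aa_locus} (or character matrix of residues).
#' @param model an \code{aa_model}.
#' @return a \code{likelihood_result} with \code{log_likelihood},
#'   \code{site_loglik}, \code{tree} and \code{model}.
#' @export
tree_loglik <- function(tree, locus, model) {
  inp <- engine_inputs(tree, locus)
  fit <- cpp_tree_loglik(inp$edge, inp$ntip, inp$states, inp$weights,
                         model$eigen$E, model$eigen$Einv, model$eigen$lambda,
                         as.numeric(model$frequencies), model$rates,
                         inp$lengths)
  if (fit$n_floored > 0)
    warning(fit$n_floored,
            " site pattern(s) had zero likelihood; floored at -745")
  likelihood_result(inp$tree, model, fit, inp$index)
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise maximisation of the log-likelihood over branch lengths
#' (bracketed scalar search per branch), sweeping until the improvement
#' drops below \code{tol} or \code{max_sweeps} is reached.  The
#' log-likelihood is non-decreasing across sweeps; lengths are constrained
#' to \eqn{[10^{-8}, 20]}.
#'
#' @inheritParams tree_loglik
#' @param max_sweeps maximum number of sweeps over all branches.
#' @param tol minimum log-likelihood gain per sweep to continue.
#' @return a \code{likelihood_result}; \code{$tree} carries the optimised
#'   lengths and \code{$converged} reports whether the sweep loop terminated
#'   by tolerance.
#' @export
optimize_branch_lengths <- function(tree, locus, model, max_sweeps = 50L,
                                    tol = 1e-4) {
  inp <- engine_inputs(tree, locus)
  fit <- cpp_optimize_bl(inp$edge, inp$ntip, inp$states, inp$weights,
                         model$eigen$E, model$eigen$Einv, model$eigen$lambda,
                         as.numeric(model$frequencies), model$rates,
                         inp$lengths, MIN_BRLEN, MAX_BRLEN,
                         as.integer(max_sweeps), tol)
  tr <- inp$tree
  tr$edge.length <- as.numeric(fit$lengths)
  if (!fit$converged)
    warning("branch-length optimisation did not converge in ", max_sweeps,
            " sweeps; returning best fit so far")
  likelihood_result(tr, model, fit, inp$index)
}

# Re-optimise the gamma shape at fixed branch lengths (bracketed search on
# log-alpha), alternating with branch-length sweeps.
fit_gamma_model <- function(tree, locus, name, n_cat = 4L, rounds = 2L) {
  alpha <- 1
  fit <- optimize_branch_lengths(tree, locus,
                                 aa_model(name, gamma_shape = alpha, n_cat))
  for (r in seq_len(rounds)) {
    obj <- function(la) {
      m <- aa_model(name, gamma_shape = exp(la), n_cat)
      tree_loglik(fit$tree, locus, m)$log_likelihood
    }
    opt <- optimize(obj, c(log(0.02), log(100)), maximum = TRUE, tol = 1e-3)
    alpha <- exp(opt$maximum)
    fit <- optimize_branch_lengths(fit$tree, locus,
                                   aa_model(name, gamma_shape = alpha, n_cat))
  }
  fit
}

#' Select a substitution model by BIC
#'
#' Fits each candidate (branch lengths optimised; gamma shape estimated for
#' "+G" candidates) and returns the fit minimising
#' \eqn{BIC = -2 \ln L + p \ln n}, where \eqn{p} counts the branch lengths
#' plus one for the gamma shape and \eqn{n} is the number of sites.  Ties are
#' broken by candidate order.
#'
#' @param locus an \code{aa_locus}.
#' @param tree topology on which candidates are scored.
#' @param candidates data frame with columns \code{name} and \code{gamma}
#'   (logical); the default crosses LG/WAG/JTT with \{+G4, uniform\}.
#' @return list with \code{fit} (the winning \code{likelihood_result}),
#'   \code{table} (per-candidate lnL, parameters, BIC).
#' @export
select_model <- function(locus, tree,
                         candidates = expand.grid(
                           name = c("LG", "WAG", "JTT"),
                           gamma = c(TRUE, FALSE),
                           stringsAsFactors = FALSE)) {
  if (!nrow(candidates)) stop("candidates must be non-empty")
  n_sites <- if (inherits(locus, "aa_locus")) locus$nsites else ncol(locus)
  n_branch <- nrow(ape::reorder.phylo(tree, "postorder")$edge)
  fits <- vector("list", nrow(candidates))
  bic <- lnl <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    nm <- as.character(candidates$name[i])
    if (isTRUE(candidates$gamma[i])) {
      fits[[i]] <- fit_gamma_model(tree, locus, nm)
      p <- n_branch + 1
    } else {
      fits[[i]] <- optimize_branch_lengths(tree, locus, aa_model(nm))
      p <- n_branch
    }
    lnl[i] <- fits[[i]]$log_likelihood
    bic[i] <- -2 * lnl[i] + p * log(n_sites)
  }
  best <- which.min(bic)  # which.min takes the first among ties
  list(fit = fits[[best]],
       table = data.frame(name = candidates$name, gamma = candidates$gamma,
                          loglik = lnl, bic = bic))
}

#' Poisson-corrected pairwise distance
#'
#' Maximum-likelihood distance between two aligned amino-acid sequences under
#' the 20-state equal-rates model: \eqn{d = -\frac{19}{20}\ln(1 -
#' \frac{20p}{19})} on the mismatch proportion \eqn{p} over mutually
#' unambiguous columns.  Saturated pairs (\eqn{p \ge 19/20}) are capped at 20
#' and flagged.
#'
#' @param seq_a,seq_b equal-length character vectors of residues (or
#'   1-row matrices / strings of equal length).
#' @return distance (attribute \code{saturated} when capped).
#' @export
ml_pairwise_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1) strsplit(seq_a, "")[[1]] else as.vector(seq_a)
  b <- if (length(seq_b) == 1) strsplit(seq_b, "")[[1]] else as.vector(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- is_unambiguous(a) & is_unambiguous(b)
  if (!any(ok)) stop("no mutually unambiguous columns")
  p <- mean(a[ok] != b[ok])
  if (p >= 19 / 20)
    return(structure(MAX_BRLEN, saturated = TRUE))
  structure(-(19 / 20) * log(1 - 20 * p / 19), saturated = FALSE)
}

#' All pairwise Poisson-corrected distances of a locus
#' @param locus an \code{aa_locus}.
#' @return symmetric distance matrix.
#' @export
ml_distance_matrix <- function(locus) {
  m <- locus$seqs
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- ml_pairwise_distance(m[i, ], m[j, ])
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix; negative branch
#' lengths are clamped to zero (attribute \code{clamped}).
#'
#' @param distance_matrix symmetric matrix over at least 3 taxa.
#' @return unrooted \code{phylo}.
#' @export
nj_tree <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- any(neg)
  tr
}

#' Hill-climbing NNI search under maximum likelihood
#'
#' From a starting tree, repeatedly evaluates all nearest-neighbour
#' interchanges (candidates ranked by likelihood at current branch lengths),
#' fully re-optimises branch lengths for the best candidate, and accepts it
#' if it improves the log-likelihood by more than \code{tol}; terminates
#' otherwise.  The final log-likelihood is never below the starting one.
#'
#' @param start_tree \code{phylo} over the alignment's taxa.
#' @param locus an \code{aa_locus}.
#' @param model an \code{aa_model}.
#' @param tol minimum improvement to accept a swap.
#' @return list with \code{tree} and \code{fit} (a \code{likelihood_result}).
#' @export
nni_search <- function(start_tree, locus, model, tol = 1e-3) {
  cur <- optimize_branch_lengths(start_tree, locus, model)
  repeat {
    nbs <- phangorn::nni(cur$tree)
    if (!length(nbs)) break
    quick <- vapply(nbs, function(nb) {
      nb$edge.length <- rep(0.1, nrow(nb$edge))
      # score candidates cheaply: flat lengths, single sweep
      suppressWarnings(
        optimize_branch_lengths(nb, locus, model,
                                max_sweeps = 1L)$log_likelihood)
    }, numeric(1))
    best <- which.max(quick)
    cand <- optimize_branch_lengths(nbs[[best]], locus, model)
    if (cand$log_likelihood > cur$log_likelihood + tol) cur <- cand
    else break
  }
  list(tree = cur$tree, fit = cur)
}

# Canonical bipartition keys of a tree's internal edges (splits are
# represented by the tip-label side not containing the first label
# alphabetically, joined sorted).
tree_splits <- function(tree) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  tips <- sort(tr$tip.label)
  anchor <- tips[1]
  ntip <- length(tr$tip.label)
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  internal <- tr$edge[, 2] > ntip
  keys <- vapply(which(internal), function(e) {
    s <- desc[[tr$edge[e, 2]]]
    if (anchor %in% s) s <- setdiff(tips, s)
    if (length(s) < 2 || length(s) > ntip - 2) return(NA_character_)
    paste(sort(s), collapse = "|")
  }, character(1))
  stats::na.omit(unique(keys))
}

#' Nonparametric site bootstrap with NJ + NNI replicates
#'
#' Resamples alignment columns with replacement, re-estimates a tree for each
#' replicate (neighbor joining on Poisson-corrected distances followed by NNI
#' hill climbing), and labels each internal node of the point-estimate tree
#' with the percentage of replicates containing its bipartition.
#'
#' @param locus an \code{aa_locus}.
#' @param model an \code{aa_model}.
#' @param n_reps number of bootstrap replicates (\eqn{\ge 1}).
#' @param seed integer seed; identical seeds give identical supports.
#' @param point_tree optional point-estimate tree; by default it is inferred
#'   from the full alignment with the same NJ + NNI procedure.
#' @return the point-estimate \code{phylo} with \code{node.label} holding
#'   rounded percentage supports.
#' @export
bootstrap_support <- function(locus, model, n_reps = 100L, seed = 42L,
                              point_tree = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  infer <- function(lc) nni_search(nj_tree(ml_distance_matrix(lc)), lc,
                                   model)$tree
  if (is.null(point_tree)) point_tree <- infer(locus)
  set.seed(seed)
  keys <- tree_splits(point_tree)
  hits <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(locus$nsites, locus$nsites, replace = TRUE)
    rep_locus <- aa_locus(locus$id, locus$seqs[, cols, drop = FALSE])
    rep_keys <- tree_splits(infer(rep_locus))
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  support <- round(100 * hits / n_reps)
  tr <- ape::reorder.phylo(ape::unroot(point_tree), "postorder")
  ntip <- length(tr$tip.label)
  labs <- rep("", tr$Nnode)
  own <- tree_splits(tr)
  # map each internal node to its split key
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1]]] <- c(desc[[tr$edge[e, 1]]], desc[[tr$edge[e, 2]]])
  tips <- sort(tr$tip.label); anchor <- tips[1]
  for (v in (ntip + 1):(ntip + tr$Nnode)) {
    s <- desc[[v]]
    if (anchor %in% s) s <- setdiff(tips, s)
    key <- paste(sort(s), collapse = "|")
    if (key %in% names(support)) labs[v - ntip] <- as.character(support[key])
  }
  tr$node.label <- labs
  tr
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser that treat numeric internal
#' node labels as support values and validate leaf-name uniqueness.
#'
#' @param text Newick string (\code{read_newick}) .
#' @param tree a \code{phylo} (\code{write_newick}).
#' @return \code{read_newick}: a \code{phylo}; \code{write_newick}: a Newick
#'   string.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) {
    open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    stop("Newick parse error",
         if (open != close) sprintf(": unbalanced parentheses (%d '(' vs %d ')')",
                                    open, close) else "")
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' Node support values of a tree
#'
#' Numeric internal-node labels interpreted as supports; non-numeric labels
#' give \code{NA}.
#' @param tree a \code{phylo}.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}
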