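# Fitch parsimony on amino-acid alignments, with state sets packed into
# integer bitmasks (20 residue bits; ambiguity = all bits) so that scoring
# is vectorised over site patterns.  Used as the deliberately
# LBA-susceptible inference method in sensitivity experiments.

aa_bitmask <- function(seqs) {
  idx <- matrix(aa_index(seqs), nrow = nrow(seqs))
  m <- matrix(0L, nrow(seqs), ncol(seqs), dimnames = list(rownames(seqs),
                                                          NULL))
  full <- bitwShiftL(1L, 20L) - 1L
  m[] <- ifelse(idx < 0L, full, bitwShiftL(1L, idx))
  m
}

# Compress identical bitmask columns, returning masks + weights.
compress_masks <- function(masks) {
  key <- column_keys(masks)
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(masks = masks[, u, drop = FALSE],
       weights = tabulate(idx, nbins = sum(u)))
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of substitutions needed on the tree, summed over sites
#' (Fitch downpass per column, vectorised over site patterns).  Unrooted
#' trees are rooted on their first tip before scoring so every internal node
#' is binary.
#'
#' @param tree a \code{phylo} whose tips appear in the alignment.
#' @param locus an \code{aa_locus} (or a precomputed structure from
#'   \code{parsimony_data}).
#' @return integer parsimony score.
#' @export
parsimony_score <- function(tree, locus) {
  dat <- if (inherits(locus, "parsimony_data")) locus
         else parsimony_data(locus)
  tr <- binary_rooted(tree)
  miss <- setdiff(tr$tip.label, rownames(dat$masks))
  if (length(miss))
    stop("tips missing from alignment: ", paste(miss, collapse = ", "))
  tr <- ape::reorder.phylo(tr, "postorder")
  cpp_fitch_score(tr$edge, length(tr$tip.label),
                  dat$masks[tr$tip.label, , drop = FALSE],
                  as.numeric(dat$weights))
}

#' Precompute pattern-compressed parsimony data for repeated scoring
#' @param locus an \code{aa_locus}.
#' @export
parsimony_data <- function(locus) {
  cm <- compress_masks(aa_bitmask(locus$seqs))
  rownames(cm$masks) <- rownames(locus$seqs)
  structure(cm, class = "parsimony_data")
}

binary_rooted <- function(tree) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  tree
}

#' Parsimony tree search (NJ start + NNI hill climbing)
#'
#' Starts from neighbor joining on Poisson-corrected distances and accepts
#' nearest-neighbour interchanges while they lower the Fitch score.
#'
#' @param locus an \code{aa_locus} with \eqn{\ge 4} taxa.
#' @return list with \code{tree} (unrooted \code{phylo}) and \code{score}.
#' @export
parsimony_tree <- function(locus) {
  if (nrow(locus$seqs) < 4) stop("need at least 4 taxa")
  dat <- parsimony_data(locus)
  cur <- ape::unroot(nj_tree(ml_distance_matrix(locus)))
  cur_score <- parsimony_score(cur, dat)
  repeat {
    nbs <- phangorn::nni(cur)
    sc <- vapply(nbs, parsimony_score, numeric(1), locus = dat)
    if (min(sc) < cur_score) {
      best <- which.min(sc)
      cur <- nbs[[best]]
      cur_score <- sc[best]
    } else break
  }
  list(tree = cur, score = cur_score)
}
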