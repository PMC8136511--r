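# Supermatrix assembly: occupancy profiling and thresholding, taxon pruning,
# concatenation with 1-based inclusive partition spans, and evolutionary-rate
# binning of loci by mean pairwise sequence identity (MPSI).

# A taxon is "present" in a locus only if it has at least one unambiguous
# residue; all-gap / all-X padding rows do not count towards occupancy.
present_taxa <- function(locus) {
  keep <- apply(locus$seqs, 1, function(r) any(is_unambiguous(r)))
  rownames(locus$seqs)[keep]
}

#' Gene occupancy of a locus
#'
#' Fraction of the full taxon set represented in the locus by at least one
#' unambiguous residue.
#'
#' @param locus an \code{aa_locus}.
#' @param full_taxon_set character vector of all terminals in the study.
#' @return fraction in \eqn{[0, 1]}.
#' @export
locus_occupancy <- function(locus, full_taxon_set) {
  if (!length(full_taxon_set)) stop("full_taxon_set must be non-empty")
  length(intersect(present_taxa(locus), full_taxon_set)) /
    length(full_taxon_set)
}

#' Filter loci by gene occupancy
#'
#' Retains loci whose occupancy is at least \code{threshold}; used to build
#' occupancy families of supermatrices (denser thresholds retain fewer loci).
#'
#' @param loci list of \code{aa_locus}.
#' @param threshold occupancy threshold in \eqn{(0, 1]}.
#' @param full_taxon_set character vector of all terminals.
#' @return list with \code{loci} (retained) and \code{profile}, a list holding
#'   per-locus occupancy, per-taxon coverage and the threshold used.
#' @export
filter_by_occupancy <- function(loci, threshold, full_taxon_set) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  occ <- vapply(loci, locus_occupancy, numeric(1),
                full_taxon_set = full_taxon_set)
  names(occ) <- vapply(loci, `[[`, character(1), "id")
  keep <- occ >= threshold
  pres <- lapply(loci, present_taxa)
  cov <- vapply(full_taxon_set, function(tx)
    mean(vapply(pres, function(p) tx %in% p, logical(1))), numeric(1))
  list(loci = loci[keep],
       profile = list(locus_occupancy = occ,
                      taxon_coverage = cov,
                      threshold = threshold,
                      n_retained = sum(keep)))
}

#' Restrict loci to a taxon subset
#'
#' Drops rows outside \code{keep_set} from every locus.  Occupancy filtering
#' is deliberately \emph{not} re-applied: pruning follows matrix construction,
#' so the locus count of each occupancy family is preserved.  Loci left with
#' fewer than four taxa are flagged \code{untreeable} (attribute) but kept.
#'
#' @param loci list of \code{aa_locus}.
#' @param keep_set taxa to retain (must be a subset of the union of locus
#'   taxa).
#' @return list of pruned \code{aa_locus}; each has attribute
#'   \code{untreeable} set to \code{TRUE} when fewer than 4 rows remain.
#' @export
prune_taxa <- function(loci, keep_set) {
  if (!length(keep_set)) stop("keep_set must be non-empty")
  all_taxa <- unique(unlist(lapply(loci, locus_taxa)))
  extra <- setdiff(keep_set, all_taxa)
  if (length(extra))
    stop("keep_set contains unknown taxa: ", paste(extra, collapse = ", "))
  lapply(loci, function(lc) {
    rows <- intersect(rownames(lc$seqs), keep_set)
    out <- aa_locus(lc$id, lc$seqs[rows, , drop = FALSE])
    attr(out, "untreeable") <- length(rows) < 4
    out
  })
}

#' Concatenate loci into a supermatrix
#'
#' Builds one alignment over the union taxon set, padding taxa absent from a
#' locus with \code{'-'} across its span, and records 1-based inclusive
#' partition coordinates that tile the matrix without gap or overlap.
#'
#' @param loci non-empty list of \code{aa_locus}.
#' @return object of class \code{supermatrix}: \code{alignment} (character
#'   matrix), \code{partitions} (data frame \code{locus}, \code{start},
#'   \code{end}) and \code{taxa}.
#' @export
concatenate_loci <- function(loci) {
  if (!length(loci)) stop("need at least one locus")
  taxa <- unique(unlist(lapply(loci, locus_taxa)))
  lens <- vapply(loci, `[[`, numeric(1), "nsites")
  total <- sum(lens)
  aln <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  end <- cumsum(lens)
  start <- end - lens + 1
  for (i in seq_along(loci)) {
    rows <- rownames(loci[[i]]$seqs)
    aln[rows, start[i]:end[i]] <- loci[[i]]$seqs
  }
  structure(list(alignment = aln,
                 partitions = data.frame(
                   locus = vapply(loci, `[[`, character(1), "id"),
                   start = as.integer(start), end = as.integer(end)),
                 taxa = taxa),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", nrow(x$alignment), "taxa x", ncol(x$alignment),
      "sites in", nrow(x$partitions), "partitions\n")
  invisible(x)
}

#' Extract one partition of a supermatrix as a locus
#' @param sm a \code{supermatrix}.
#' @param locus_id partition (locus) identifier.
#' @export
supermatrix_slice <- function(sm, locus_id) {
  i <- match(locus_id, sm$partitions$locus)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  aa_locus(locus_id,
           sm$alignment[, sm$partitions$start[i]:sm$partitions$end[i],
                        drop = FALSE])
}

#' Write a supermatrix with its partition file
#'
#' Writes concatenated FASTA and relaxed PHYLIP plus a plain partition file
#' (\code{MODEL, locus = start-end}, one per line).
#'
#' @param sm a \code{supermatrix}.
#' @param prefix output path prefix.
#' @param model model string written into the partition file.
#' @export
write_supermatrix <- function(sm, prefix, model = "LG") {
  seqs <- apply(sm$alignment, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)),
             paste0(prefix, ".fasta"))
  writeLines(c(paste(nrow(sm$alignment), ncol(sm$alignment)),
               paste(names(seqs), seqs)),
             paste0(prefix, ".phy"))
  writeLines(sprintf("%s, %s = %d-%d", model, sm$partitions$locus,
                     sm$partitions$start, sm$partitions$end),
             paste0(prefix, ".partitions"))
  invisible(prefix)
}

#' Mean pairwise sequence identity (MPSI) of a locus
#'
#' For every unordered pair of rows, the proportion of identical residues
#' among columns where both rows carry an unambiguous residue; pairs with no
#' comparable column are excluded.  The mean over pairs is returned as a
#' percentage.  High identity indicates a slowly evolving locus.
#'
#' @param locus an \code{aa_locus} with at least two rows.
#' @return percentage in \eqn{[0, 100]}, or \code{NA} if no pair of rows has
#'   any mutually unambiguous column.
#' @export
mpsi <- function(locus) {
  m <- locus$seqs
  if (nrow(m) < 2) stop("MPSI needs at least two sequences")
  ok <- matrix(is_unambiguous(m), nrow(m))
  pairs <- combn(nrow(m), 2)
  vals <- apply(pairs, 2, function(ij) {
    both <- ok[ij[1], ] & ok[ij[2], ]
    if (!any(both)) return(NA_real_)
    mean(m[ij[1], both] == m[ij[2], both])
  })
  if (all(is.na(vals))) return(NA_real_)
  100 * mean(vals, na.rm = TRUE)
}

#' Bin loci into evolutionary-rate tertiles by MPSI
#'
#' Loci are ranked by MPSI in decreasing order (highest identity = slowest)
#' and split into \code{slow}, \code{intermediate} and \code{fast} bins whose
#' sizes differ by at most one; remainders go to the slower bins first, and
#' MPSI ties are broken lexicographically by locus id.
#'
#' @param loci list of at least three \code{aa_locus} with defined MPSI.
#' @return data frame with columns \code{locus}, \code{mpsi},
#'   \code{tertile} (factor slow/intermediate/fast).
#' @export
rate_tertiles <- function(loci) {
  ids <- vapply(loci, `[[`, character(1), "id")
  vals <- vapply(loci, mpsi, numeric(1))
  keep <- !is.na(vals)
  if (sum(keep) < 3) stop("need at least 3 loci with defined MPSI")
  ids <- ids[keep]; vals <- vals[keep]
  ord <- order(-vals, ids)
  n <- length(ord)
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra >= 1) sizes[1] <- sizes[1] + 1
  if (extra == 2) sizes[2] <- sizes[2] + 1
  lab <- rep(c("slow", "intermediate", "fast"), times = sizes)
  out <- data.frame(locus = ids[ord], mpsi = vals[ord],
                    tertile = factor(lab, levels = c("slow", "intermediate",
                                                     "fast")))
  rownames(out) <- NULL
  out
}
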