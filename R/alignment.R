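# Per-locus amino-acid alignments.  A locus is stored as a character matrix
# (rows = taxa, columns = sites) of single upper-case residues, with '-' for
# gaps and 'X' for unknown residues.

#' Create a locus alignment
#'
#' @param id locus identifier.
#' @param seqs either a character matrix (rows named by taxon, one residue
#'   per cell) or a named character vector of equal-length strings.
#' @return an object of class \code{aa_locus} with elements \code{id},
#'   \code{seqs} (character matrix) and \code{nsites}.
#' @export
aa_locus <- function(id, seqs) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    n <- nchar(seqs)
    if (length(unique(n)) > 1)
      stop("locus '", id, "': unequal row lengths (",
           paste(unique(n), collapse = ", "), ")")
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  seqs <- toupper(as.matrix(seqs))
  if (nrow(seqs) < 1) stop("locus '", id, "': no sequences")
  if (is.null(rownames(seqs))) stop("locus '", id, "': rows must be named")
  if (anyDuplicated(rownames(seqs)))
    stop("locus '", id, "': duplicate taxon names")
  bad <- setdiff(unique(as.vector(seqs)), c(AA_ALPHABET, "-", "X", "?", "*",
                                            "B", "Z", "J", "U", "O"))
  if (length(bad))
    stop("locus '", id, "': unexpected characters: ",
         paste(bad, collapse = " "))
  structure(list(id = as.character(id), seqs = seqs, nsites = ncol(seqs)),
            class = "aa_locus")
}

#' @export
print.aa_locus <- function(x, ...) {
  cat("Locus", x$id, ":", nrow(x$seqs), "taxa x", x$nsites, "sites\n")
  invisible(x)
}

locus_taxa <- function(locus) rownames(locus$seqs)

#' Read per-locus FASTA alignments from a directory
#'
#' One FASTA file per locus; the locus id is the file name without extension.
#' Files are read in sorted filename order and sequences are upper-cased.
#' A file whose rows differ in length is rejected with an error naming the
#' file.
#'
#' @param directory path containing \code{.fa}/\code{.fasta}/\code{.faa}
#'   files.
#' @return list of \code{aa_locus} (empty, with a warning, if no FASTA files
#'   are found).
#' @export
read_loci <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.(fa|fasta|faa)$",
                           full.names = TRUE))
  if (!length(files)) {
    warning("no FASTA files found in ", directory)
    return(list())
  }
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    id <- sub("\\.(fa|fasta|faa)$", "", basename(files[i]))
    seqs <- ape::read.FASTA(files[i], type = "AA")
    chr <- lapply(as.character(seqs), toupper)
    n <- lengths(chr)
    if (length(unique(n)) > 1)
      stop("ragged alignment in ", basename(files[i]), ": row lengths ",
           paste(unique(n), collapse = ", "))
    m <- do.call(rbind, chr)
    rownames(m) <- names(seqs)
    out[[i]] <- aa_locus(id, m)
  }
  out
}

#' Write a locus (or any taxon-by-site matrix) as FASTA
#' @param locus an \code{aa_locus}.
#' @param file output path.
#' @export
write_locus_fasta <- function(locus, file) {
  seqs <- apply(locus$seqs, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), file)
  invisible(file)
}

# Integer state matrix (0..19, -1 ambiguous) plus site-pattern compression.
# Pattern compression is purely an efficiency device: identical columns share
# one likelihood evaluation, weighted by multiplicity.
locus_states <- function(seqs) {
  m <- matrix(aa_index(seqs), nrow = nrow(seqs),
              dimnames = list(rownames(seqs), NULL))
  storage.mode(m) <- "integer"
  m
}

column_keys <- function(m) {
  do.call(paste, c(lapply(seq_len(nrow(m)), function(i) m[i, ]), sep = ","))
}

compress_patterns <- function(states) {
  key <- column_keys(states)
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}
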