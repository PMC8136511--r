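# Rare-genomic-change analyses: Fitch parsimony on discrete characters with
# ACCTRAN/DELTRAN resolutions of equally parsimonious histories, LCA
# gene-tree/species-tree reconciliation classifying shared versus
# lineage-specific duplications, paralog/allele screening of candidate
# peptides, and duplication tally matrices.

check_character <- function(tree, character) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  miss <- setdiff(names(character), tree$tip.label)
  if (length(miss))
    stop("character scores tips absent from tree: ",
         paste(miss, collapse = ", "))
  unscored <- setdiff(tree$tip.label, names(character))
  if (length(unscored))
    stop("tips without character scores: ", paste(unscored, collapse = ", "))
  invisible(TRUE)
}

char_alphabet <- function(character) {
  sort(unique(as.character(character[!character %in% "?"])))
}

#' Fitch parsimony length of a discrete character
#'
#' Standard Fitch downpass for an unordered character on a rooted binary
#' tree; \code{"?"} tips carry the full state set.  The length is the
#' number of empty-intersection unions.
#'
#' @param tree rooted binary \code{phylo}.
#' @param character named vector of tip states (character or integer;
#'   \code{"?"} = missing).
#' @return list with \code{length} and \code{state_sets} (downpass sets per
#'   node, as a list of character vectors).
#' @export
fitch_length <- function(tree, character) {
  character <- setNames(as.character(character), names(character))
  check_character(tree, character)
  alpha <- char_alphabet(character)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    s <- character[[tr$tip.label[i]]]
    sets[[i]] <- if (s == "?") alpha else s
  }
  len <- 0L
  touched <- logical(nnode)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (!touched[u]) {
      sets[[u]] <- sets[[v]]
      touched[u] <- TRUE
    } else {
      inter <- intersect(sets[[u]], sets[[v]])
      if (length(inter)) sets[[u]] <- inter
      else {
        sets[[u]] <- union(sets[[u]], sets[[v]])
        len <- len + 1L
      }
    }
  }
  list(length = len, state_sets = sets)
}

# Sankoff minimum-change costs: C[v, s] = minimum number of changes in the
# subtree of v given state s at v.
sankoff_costs <- function(tree, character, alpha) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  k <- length(alpha)
  C <- matrix(0, nnode, k, dimnames = list(NULL, alpha))
  for (i in seq_len(ntip)) {
    s <- character[[tr$tip.label[i]]]
    if (s != "?") C[i, alpha != s] <- Inf
  }
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (u <= ntip) next
    contrib <- vapply(seq_len(k), function(s)
      min(C[v, ] + (alpha != alpha[s])), numeric(1))
    C[u, ] <- C[u, ] + contrib
  }
  list(C = C, tree = tr, ntip = ntip)
}

resolve_history <- function(tree, character, mode, outgroup = NULL) {
  character <- setNames(as.character(character), names(character))
  check_character(tree, character)
  alpha <- char_alphabet(character)
  sk <- sankoff_costs(tree, character, alpha)
  tr <- sk$tree; C <- sk$C; ntip <- sk$ntip
  nnode <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]
  # root state: minimum subtree cost; ties resolved towards the state
  # observed in the declared outgroup tips, then by alphabet order
  root_candidates <- which(C[root, ] == min(C[root, ]))
  root_state <- alpha[root_candidates[1]]
  if (length(root_candidates) > 1 && !is.null(outgroup)) {
    og_states <- unique(character[intersect(outgroup, names(character))])
    og_states <- setdiff(og_states, "?")
    hit <- alpha[root_candidates] %in% og_states
    if (any(hit)) root_state <- alpha[root_candidates][hit][1]
  }
  state <- character(nnode)
  state[root] <- root_state
  # preorder traceback; at ties between keeping and changing state,
  # ACCTRAN changes as early (rootward) as possible, DELTRAN keeps the
  # parental state as long as possible
  for (e in rev(seq_len(nrow(tr$edge)))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    ps <- state[u]
    total <- C[v, ] + (alpha != ps)
    cand <- alpha[total == min(total)]
    if (length(cand) == 1) state[v] <- cand
    else if (mode == "deltran")
      state[v] <- if (ps %in% cand) ps else cand[1]
    else  # acctran
      state[v] <- if (any(cand != ps)) cand[cand != ps][1] else ps
  }
  changes <- data.frame(node = integer(), from = character(),
                        to = character())
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (state[u] != state[v])
      changes <- rbind(changes,
                       data.frame(node = v, from = state[u], to = state[v]))
  }
  desc <- node_descendants(tr)
  changes$clade <- vapply(changes$node, function(v)
    paste(sort(desc[[v]]), collapse = ","), character(1))
  structure(list(states = setNames(state, c(tr$tip.label,
                                            rep(NA, nnode - ntip))),
                 tree = tr,
                 changes = changes,
                 length = nrow(changes),
                 mode = mode,
                 fitch_length = fitch_length(tree, character)$length),
            class = "character_history")
}

#' ACCTRAN and DELTRAN character histories
#'
#' Among the minimum-length reconstructions of an unordered character,
#' \code{acctran} places state changes as close to the root as possible
#' (gains early, reversals later) while \code{deltran} delays changes
#' tipward.  Both are obtained by a minimum-cost downpass with a preorder
#' traceback whose tie-breaking prefers, respectively, changing away from
#' or retaining the parental state; both histories always attain the Fitch
#' minimum length.  The root state is the minimum-cost state, with ties
#' resolved towards the state observed in the declared outgroup.
#'
#' @param tree rooted binary \code{phylo}.
#' @param character named vector of tip states (\code{"?"} allowed).
#' @param outgroup tips whose observed state breaks root-state ties.
#' @return a \code{character_history}: per-node \code{states},
#'   \code{changes} (data frame: child \code{node}, \code{from}, \code{to},
#'   \code{clade} = sorted tip set below the change), \code{length} and the
#'   \code{fitch_length} it equals.
#' @export
acctran <- function(tree, character, outgroup = NULL)
  resolve_history(tree, character, "acctran", outgroup)

#' @rdname acctran
#' @export
deltran <- function(tree, character, outgroup = NULL)
  resolve_history(tree, character, "deltran", outgroup)

#' @export
print.character_history <- function(x, ...) {
  cat(toupper(x$mode), "history:", x$length, "change(s)\n")
  if (nrow(x$changes))
    for (i in seq_len(nrow(x$changes)))
      cat(sprintf("  %s -> %s on the branch to {%s}\n", x$changes$from[i],
                  x$changes$to[i], x$changes$clade[i]))
  invisible(x)
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of the species below it; an internal node is a duplication
#' exactly when its mapping equals the mapping of one of its children.
#'
#' @param gene_tree rooted binary \code{phylo}.
#' @param species_tree rooted \code{phylo}.
#' @param leaf_to_species named character vector mapping every gene-tree
#'   leaf to a species-tree tip.
#' @return list of class \code{reconciliation}: \code{events} (data frame:
#'   gene node, mapped species node, event), \code{n_duplications},
#'   \code{duplications} (per duplication, the species below the mapped
#'   node and the gene leaves involved).
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_to_species) {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!ape::is.binary(gene_tree)) stop("gene tree must be binary")
  miss <- setdiff(gene_tree$tip.label, names(leaf_to_species))
  if (length(miss))
    stop("unmapped gene leaves: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(leaf_to_species[gene_tree$tip.label]),
                 species_tree$tip.label)
  if (length(bad))
    stop("species absent from species tree: ", paste(bad, collapse = ", "))
  sdesc <- node_descendants(species_tree)
  # LCA of a species set = the node with the smallest tip set containing it
  lca_of <- function(spp) {
    sizes <- lengths(sdesc)
    ok <- vapply(seq_along(sdesc), function(v) all(spp %in% sdesc[[v]]),
                 logical(1))
    which(ok)[which.min(sizes[ok])]
  }
  gt <- ape::reorder.phylo(gene_tree, "postorder")
  ntip <- length(gt$tip.label)
  nnode <- max(gt$edge)
  below <- vector("list", nnode)   # species below each gene node
  map <- integer(nnode)
  for (i in seq_len(ntip)) {
    below[[i]] <- unname(leaf_to_species[gt$tip.label[i]])
    map[i] <- lca_of(below[[i]])
  }
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  # postorder guarantees below[[v]] is complete when edge (u, v) is seen
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
    below[[u]] <- unique(c(below[[u]], below[[v]]))
  }
  for (u in (ntip + 1):nnode) map[u] <- lca_of(below[[u]])
  internal <- (ntip + 1):nnode
  event <- vapply(internal, function(v) {
    ch <- kids[[as.character(v)]]
    if (any(map[ch] == map[v])) "duplication" else "speciation"
  }, character(1))
  gdesc <- node_descendants(gt)
  dups <- lapply(internal[event == "duplication"], function(v)
    list(gene_node = v, species_node = map[v],
         species = sort(unique(sdesc[[map[v]]])),
         species_below = sort(unique(below[[v]])),
         gene_leaves = sort(gdesc[[v]]),
         child_species = lapply(kids[[as.character(v)]],
                                function(c2) sort(unique(below[[c2]])))))
  structure(list(tree = gt, species_tree = species_tree,
                 events = data.frame(gene_node = internal,
                                     species_node = map[internal],
                                     event = event),
                 map = map,
                 n_duplications = sum(event == "duplication"),
                 duplications = dups),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Reconciliation:", x$n_duplications, "duplication(s),",
      sum(x$events$event == "speciation"), "speciation(s)\n")
  invisible(x)
}

#' Classify a duplication as shared by a clade or lineage-specific
#'
#' A duplication is \code{"shared"} by the clade when its mapped species
#' node is the clade's MRCA or an ancestor of it \emph{and} both child
#' subtrees of the duplication contain genes from at least one clade
#' member; it is \code{"lineage_specific"} when mapped strictly below the
#' clade's MRCA or involving a single member; otherwise \code{"absent"}
#' (no clade member involved).
#'
#' @param reconciliation a \code{reconciliation}.
#' @param clade_species_set non-empty subset of species-tree leaves.
#' @return character vector (one entry per duplication).
#' @export
shared_duplication <- function(reconciliation, clade_species_set) {
  if (!length(clade_species_set)) stop("clade species set is empty")
  sp_tree <- reconciliation$species_tree
  bad <- setdiff(clade_species_set, sp_tree$tip.label)
  if (length(bad))
    stop("species not in species tree: ", paste(bad, collapse = ", "))
  sdesc <- node_descendants(sp_tree)
  mrca <- if (length(clade_species_set) == 1)
    match(clade_species_set, sp_tree$tip.label)
  else ape::getMRCA(sp_tree, clade_species_set)
  mrca_set <- sdesc[[mrca]]
  vapply(reconciliation$duplications, function(d) {
    members_in <- intersect(d$species_below, clade_species_set)
    if (!length(members_in)) return("absent")
    at_or_above <- all(mrca_set %in% d$species)
    both_children <- all(vapply(d$child_species, function(cs)
      any(cs %in% clade_species_set), logical(1)))
    if (at_or_above && both_children) "shared"
    else "lineage_specific"
  }, character(1))
}

#' Screen candidate peptides into copies, alleles and fragments
#'
#' Pairs of pre-aligned candidate sequences are called paralogs when their
#' overlap (columns where both carry an unambiguous residue) exceeds 100
#' amino acids \emph{and} shows at least two substitutions; pairs failing
#' this test (near-identical alleles, short overlaps, or non-overlapping
#' fragments of one copy) are merged.  The copy count is the number of
#' connected components after merging, which is invariant to input order.
#'
#' @param candidates named character vector of aligned peptide strings (same
#'   coordinate system; \code{'-'} for gaps), or a character matrix.
#' @param min_overlap overlap required to call paralogy (default
#'   \code{> 100} aa).
#' @param min_subs substitutions within the overlap required (default
#'   \eqn{\ge 2}).
#' @return list with \code{copy_count}, \code{components} (membership
#'   vector) and \code{pairs} (per-pair overlap, substitutions, call).
#' @export
paralog_screen <- function(candidates, min_overlap = 100L, min_subs = 2L) {
  if (!length(candidates))
    return(list(copy_count = 0L, components = integer(),
                pairs = data.frame()))
  m <- if (is.matrix(candidates)) candidates
       else do.call(rbind, strsplit(toupper(candidates), ""))
  if (is.null(rownames(m)))
    rownames(m) <- paste0("seq", seq_len(nrow(m)))
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- NULL
  if (n > 1) {
    idx <- combn(n, 2)
    ok <- matrix(is_unambiguous(m), n)
    pairs <- data.frame(a = rownames(m)[idx[1, ]], b = rownames(m)[idx[2, ]],
                        overlap = 0L, substitutions = 0L, call = "")
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      both <- ok[i, ] & ok[j, ]
      ov <- sum(both)
      subs <- sum(m[i, both] != m[j, both])
      paralog <- ov > min_overlap && subs >= min_subs
      pairs$overlap[k] <- ov
      pairs$substitutions[k] <- subs
      pairs$call[k] <- if (paralog) "paralogs"
                       else if (ov == 0) "non-overlapping fragments"
                       else "allele/fragment"
      if (!paralog) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  names(comp) <- rownames(m)
  list(copy_count = length(unique(comp)), components = comp, pairs = pairs)
}

#' Retain peptides containing all required motifs
#'
#' @param peptides character vector.
#' @param required_motifs motifs that must each occur as an exact substring
#'   (default: the homeodomain helix-3 signature pair).
#' @return the retained subset.
#' @export
motif_filter <- function(peptides, required_motifs = c("ELEKEF", "KIWFQN")) {
  if (!length(required_motifs)) return(peptides)
  keep <- rep(TRUE, length(peptides))
  for (mot in required_motifs)
    keep <- keep & grepl(mot, peptides, fixed = TRUE)
  peptides[keep]
}

#' Duplication tally matrix with shared-by-clade flags
#'
#' @param counts gene/family-by-species matrix of copy counts (non-negative
#'   integers).
#' @param focal_species,reference_species column subsets; a row is flagged
#'   \code{shared} when it has \eqn{\ge 2} copies in at least one focal
#'   species and \eqn{\ge 2} copies in at least one reference species.
#' @return list with \code{tally} (the matrix) and \code{shared} (logical
#'   per row).
#' @export
duplication_tally <- function(counts, focal_species, reference_species) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  miss <- setdiff(c(focal_species, reference_species), colnames(counts))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  shared <- apply(counts, 1, function(r)
    any(r[focal_species] >= 2) && any(r[reference_species] >= 2))
  list(tally = counts, shared = shared)
}

#' Reference order-level chelicerate fixtures
#'
#' The order-level arachnopulmonate tree and three binary characters (the
#' promenade-a-deux courtship dance, book lungs, and the
#' whole-genome-duplication signature) shipped as plain-text files; used by
#' the ancestral-state examples.  Pseudoscorpiones is coded present for the
#' promenade (retention in one superfamily).
#'
#' @return list with \code{tree} (rooted \code{phylo}) and
#'   \code{characters} (data frame, tips x characters).
#' @export
chelicerate_rgc_fixture <- function() {
  dir <- system.file("extdata", package = "lbagrid")
  tree <- read_newick(paste(readLines(file.path(dir,
                                                "arachnopulmonata_orders.nwk")),
                            collapse = ""))
  chars <- read.delim(file.path(dir, "arachnopulmonata_characters.tsv"),
                      row.names = 1, colClasses = "character")
  list(tree = tree, characters = chars,
       outgroup = c("Xiphosura", "Opiliones", "Parasitiformes",
                    "Acariformes"))
}
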