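# Independent oracles used to freeze expected values: exhaustive-state
# likelihood enumeration, exhaustive most-parsimonious-reconstruction (MPR)
# enumeration, a brute-force reconciliation checker, and a quadrature oracle
# for the discrete-gamma means.  All deliberately avoid the code paths they
# check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Likelihood by summing over every assignment of states to interior nodes.
exhaustive_loglik <- function(tree, locus, model) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- (ntip + 1):nnode
  states <- matrix(match(locus$seqs[tr$tip.label, , drop = FALSE], AA20),
                   ntip)
  pi <- as.numeric(model$frequencies)
  total <- 0
  g <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  for (s in seq_len(ncol(states))) {
    sitelik <- 0
    for (cat in seq_len(model$n_categories)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        transition_matrix(model, tr$edge.length[e] * model$rates[cat]))
      prob <- pi[g[, match(root, internals)]]
      for (e in seq_len(nrow(tr$edge))) {
        u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
        su <- if (u <= ntip) rep(states[u, s], nrow(g))
              else g[, match(u, internals)]
        if (v <= ntip) {
          sv <- states[v, s]
          if (is.na(sv)) next  # fully ambiguous tip: sums out to 1
          prob <- prob * P[[e]][cbind(su, sv)]
        } else {
          prob <- prob * P[[e]][cbind(su, g[, match(v, internals)])]
        }
      }
      sitelik <- sitelik + sum(prob) / model$n_categories
    }
    total <- total + log(sitelik)
  }
  total
}

# All minimum-length reconstructions of a discrete character by enumerating
# interior-state assignments (tips fixed; "?" tips excluded from change
# counting by trying all their states too).
enumerate_mprs <- function(tree, character, alphabet = NULL) {
  character <- setNames(as.character(character), names(character))
  if (is.null(alphabet))
    alphabet <- sort(unique(character[character != "?"]))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  internals <- (ntip + 1):nnode
  tipstate <- character[tr$tip.label]
  free_tips <- which(tipstate == "?")
  vary <- c(internals, free_tips)
  g <- as.matrix(expand.grid(rep(list(alphabet), length(vary)),
                             stringsAsFactors = FALSE))
  state_of <- function(v, row) {
    if (v %in% vary) g[row, match(v, vary)] else tipstate[v]
  }
  lens <- vapply(seq_len(nrow(g)), function(row) {
    ch <- 0L
    for (e in seq_len(nrow(tr$edge)))
      if (state_of(tr$edge[e, 1], row) != state_of(tr$edge[e, 2], row))
        ch <- ch + 1L
    ch
  }, integer(1))
  keep <- lens == min(lens)
  list(min_length = min(lens),
       n_minimal = sum(keep),
       assignments = g[keep, , drop = FALSE],
       nodes = vary,
       tree = tr)
}

# Change keys of one MPR assignment row: "tips:from>to" per changed edge,
# sorted; comparable with history_keys() of an acctran/deltran result.
mpr_change_keys <- function(mpr, row, character) {
  tr <- mpr$tree
  character <- setNames(as.character(character), names(character))
  tipstate <- character[tr$tip.label]
  state_of <- function(v) {
    if (v %in% mpr$nodes) mpr$assignments[row, match(v, mpr$nodes)]
    else tipstate[v]
  }
  desc <- lbagrid_desc(tr)
  keys <- character()
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (state_of(u) != state_of(v))
      keys <- c(keys, sprintf("%s:%s>%s",
                              paste(sort(desc[[v]]), collapse = ","),
                              state_of(u), state_of(v)))
  }
  sort(keys)
}

# tip sets below each node (duplicated small helper, independent of package
# internals)
lbagrid_desc <- function(tr) {
  tr <- ape::reorder.phylo(tr, "postorder")
  desc <- vector("list", max(tr$edge))
  for (i in seq_along(tr$tip.label)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1]]] <- c(desc[[tr$edge[e, 1]]], desc[[tr$edge[e, 2]]])
  desc
}

# history -> canonical set of "tip,tip,...:from>to" change keys
history_keys <- function(history) {
  if (!nrow(history$changes)) return(character())
  sort(sprintf("%s:%s>%s", history$changes$clade, history$changes$from,
               history$changes$to))
}

# Brute-force reconciliation: recompute the LCA map with pairwise MRCAs and
# re-derive events from the child-mapping condition.
brute_reconcile <- function(gene_tree, species_tree, map) {
  gt <- ape::reorder.phylo(gene_tree, "postorder")
  ntip <- length(gt$tip.label)
  nnode <- max(gt$edge)
  desc <- lbagrid_desc(gt)
  lca_species <- function(spp) {
    spp <- unique(spp)
    if (length(spp) == 1) return(match(spp, species_tree$tip.label))
    ape::getMRCA(species_tree, spp)
  }
  node_map <- integer(nnode)
  for (v in seq_len(nnode))
    node_map[v] <- lca_species(unname(map[desc[[v]]]))
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  internal <- (ntip + 1):nnode
  event <- vapply(internal, function(v) {
    ch <- kids[[as.character(v)]]
    if (any(node_map[ch] == node_map[v])) "duplication" else "speciation"
  }, character(1))
  data.frame(gene_node = internal, species_node = node_map[internal],
             event = event)
}

# Discrete-gamma category means by numerical quadrature.
gamma_rates_quadrature <- function(alpha, k) {
  qs <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  qs[k + 1] <- Inf
  vapply(seq_len(k), function(i)
    k * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  qs[i], qs[i + 1], rel.tol = 1e-10)$value,
    numeric(1))
}

# Random utilities -----------------------------------------------------------

random_locus <- function(ntaxa, nsites, seed, gap_prob = 0) {
  set.seed(seed)
  m <- matrix(sample(AA20, ntaxa * nsites, replace = TRUE), ntaxa,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  if (gap_prob > 0)
    m[runif(length(m)) < gap_prob] <- "-"
  aa_locus(paste0("rand", seed), m)
}

random_blen_tree <- function(ntaxa, seed, min_len = 0.02, max_len = 0.9) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}
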