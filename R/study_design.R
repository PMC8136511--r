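# Study-design accounting: the taxon registry, the sequential taxon-pruning
# series, the occupancy-family x taxon-subset matrix grid, and enumeration of
# the full analysis plan.

#' Create a taxon registry
#'
#' @param name unique terminal identifiers.
#' @param group order-level clade label (must be non-empty for ingroup
#'   records).
#' @param subgroup within-order label (may be \code{""}).
#' @param role \code{"ingroup"} or \code{"outgroup"}.
#' @return data frame of class \code{taxon_registry}.
#' @export
taxon_registry <- function(name, group, subgroup = "", role = "ingroup") {
  df <- data.frame(name = trimws(as.character(name)),
                   group = trimws(as.character(group)),
                   subgroup = trimws(as.character(subgroup)),
                   role = as.character(role))
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate terminal name(s): ", paste(unique(dup), collapse = ", "))
  if (!all(df$role %in% c("ingroup", "outgroup")))
    stop("role must be 'ingroup' or 'outgroup'")
  empty <- df$role == "ingroup" & df$group == ""
  if (any(empty))
    stop("ingroup records need a non-empty group: ",
         paste(df$name[empty], collapse = ", "))
  class(df) <- c("taxon_registry", "data.frame")
  df
}

#' Read a taxon registry from TSV
#'
#' Expects a header \code{name<TAB>group<TAB>subgroup<TAB>role}.
#' @param file path to the TSV file.
#' @export
read_taxon_registry <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "group", "subgroup", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  taxon_registry(df$name, df$group, df$subgroup, df$role)
}

#' Census of a taxon registry
#'
#' @param registry a \code{taxon_registry}.
#' @return list with \code{groups} (data frame of group, count, ordered by
#'   group label), \code{ingroup}, \code{outgroup}, \code{total}.
#' @export
taxon_census <- function(registry) {
  if (!nrow(registry)) stop("registry must be non-empty")
  tab <- table(registry$group)
  groups <- data.frame(group = names(tab), count = as.integer(tab))
  groups <- groups[order(groups$group), , drop = FALSE]
  rownames(groups) <- NULL
  list(groups = groups,
       ingroup = sum(registry$role == "ingroup"),
       outgroup = sum(registry$role == "outgroup"),
       total = nrow(registry))
}

#' Define one pruning step
#'
#' @param index 1-based position in the pruning sequence.
#' @param removed_subgroups subgroup labels removed at this step (a step may
#'   remove several subgroups at once).
#' @param removed_count optional expected number of terminals removed; a
#'   mismatch at application time is an error.
#' @export
pruning_step <- function(index, removed_subgroups, removed_count = NA_integer_) {
  structure(list(index = as.integer(index),
                 removed_subgroups = trimws(as.character(removed_subgroups)),
                 removed_count = as.integer(removed_count)),
            class = "pruning_step")
}

#' Apply a sequential pruning series to the focal group
#'
#' Starting from the full registry (subset \code{T0}), each step removes the
#' terminals of the named subgroups of \code{focal_group}, producing nested
#' subsets \code{T-1}, \code{T-2}, ...  Non-focal terminals are never touched.
#' Subgroup labels are matched case-sensitively after whitespace trimming.
#'
#' @param registry a \code{taxon_registry}.
#' @param steps list of \code{pruning_step} with consecutive indices from 1
#'   and pairwise-disjoint subgroup sets.
#' @param focal_group group label whose subgroups are pruned.
#' @return data frame with one row per subset: \code{label}, \code{n_taxa},
#'   \code{n_focal}; the retained taxa of each subset are in the list
#'   attribute \code{"taxa"}.
#' @export
pruning_series <- function(registry, steps, focal_group) {
  idx <- vapply(steps, `[[`, integer(1), "index")
  if (length(idx) && !identical(idx, seq_along(idx)))
    stop("step indices must be consecutive from 1")
  subs <- lapply(steps, `[[`, "removed_subgroups")
  allsubs <- unlist(subs)
  if (anyDuplicated(allsubs))
    stop("subgroups removed in more than one step: ",
         paste(unique(allsubs[duplicated(allsubs)]), collapse = ", "))
  focal <- registry[registry$group == focal_group, , drop = FALSE]
  unknown <- setdiff(allsubs, focal$subgroup)
  if (length(unknown))
    stop("unknown subgroup(s) under ", focal_group, ": ",
         paste(unknown, collapse = ", "))
  keep <- registry$name
  labels <- "T0"
  taxa_sets <- list(keep)
  for (k in seq_along(steps)) {
    drop <- focal$name[focal$subgroup %in% steps[[k]]$removed_subgroups]
    expected <- steps[[k]]$removed_count
    if (!is.na(expected) && length(drop) != expected)
      stop("step ", k, " removes ", length(drop),
           " terminals but removed_count = ", expected)
    keep <- setdiff(keep, drop)
    labels <- c(labels, paste0("T-", k))
    taxa_sets <- c(taxa_sets, list(keep))
  }
  n_focal <- vapply(taxa_sets, function(tx)
    sum(tx %in% focal$name), integer(1))
  out <- data.frame(label = labels,
                    n_taxa = lengths(taxa_sets),
                    n_focal = n_focal)
  attr(out, "taxa") <- setNames(taxa_sets, labels)
  out
}

#' Occupancy family labels
#'
#' Families are labelled \code{G1}, \code{G2}, ... in order of decreasing
#' occupancy threshold, so \code{G1} is the densest (and shortest) matrix and
#' the last family the longest.
#'
#' @param thresholds occupancy thresholds in \eqn{(0, 1]}.
#' @return data frame \code{family}, \code{threshold}.
#' @export
occupancy_families <- function(thresholds = c(0.80, 0.75, 0.70, 0.65, 0.60,
                                              0.55)) {
  th <- sort(unique(thresholds), decreasing = TRUE)
  data.frame(family = paste0("G", seq_along(th)), threshold = th)
}

#' Cross occupancy families with taxon subsets
#'
#' @param families character vector of family labels (or the data frame from
#'   \code{\link{occupancy_families}}).
#' @param subsets character vector of subset labels (or the data frame from
#'   \code{\link{pruning_series}}).
#' @return data frame of cells in row-major order (family outer, subset
#'   inner).
#' @export
build_matrix_grid <- function(families, subsets) {
  if (is.data.frame(families)) families <- families$family
  if (is.data.frame(subsets)) subsets <- subsets$label
  if (!length(families) || !length(subsets))
    stop("both families and subsets must be non-empty")
  data.frame(family = rep(families, each = length(subsets)),
             subset = rep(subsets, times = length(families)))
}

#' Enumerate a full analysis plan
#'
#' Each element of \code{plan_spec} declares one analysis family as a list
#' with a \code{method} label and the grid dimensions it spans:
#' \code{families}, \code{subsets}, and optional \code{tertiles}.  The flat
#' plan is the concatenation of the per-family grids; duplicate cells
#' (same family, subset, method, tertile) are rejected.
#'
#' @param plan_spec list of analysis-family declarations.
#' @return list with \code{plan} (data frame \code{family}, \code{subset},
#'   \code{method}, \code{tertile}) and \code{n_analyses}.
#' @export
enumerate_analyses <- function(plan_spec) {
  if (!length(plan_spec))
    return(list(plan = data.frame(family = character(), subset = character(),
                                  method = character(), tertile = character()),
                n_analyses = 0L))
  parts <- lapply(plan_spec, function(fam) {
    stopifnot(!is.null(fam$method), length(fam$families) > 0,
              length(fam$subsets) > 0)
    tert <- if (is.null(fam$tertiles)) NA_character_ else fam$tertiles
    g <- expand.grid(tertile = tert, subset = fam$subsets,
                     family = fam$families, stringsAsFactors = FALSE)
    data.frame(family = g$family, subset = g$subset, method = fam$method,
               tertile = g$tertile)
  })
  plan <- do.call(rbind, parts)
  key <- do.call(paste, c(plan, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate analysis cell(s) in plan: ",
         paste(unique(gsub("\r", " / ", key[duplicated(key)])),
               collapse = "; "))
  rownames(plan) <- NULL
  list(plan = plan, n_analyses = nrow(plan))
}

#' The chelicerate study design
#'
#' Reference registry and pruning series matching the study this package
#' emulates: 117 chelicerate ingroup terminals across 11 orders plus 15
#' outgroups, with the pseudoscorpion superfamilies as the focal pruning
#' series (six steps ending with the 12 Cheliferoidea exemplars).  Terminal
#' names are synthetic placeholders (\code{<Group>_<i>}); group-level counts
#' follow the published sampling design.
#'
#' @return list with \code{registry}, \code{steps} (list of
#'   \code{pruning_step}) and \code{focal_group}.
#' @export
chelicerate_design <- function() {
  ingroup <- c(Pseudoscorpiones = 40, Scorpiones = 12, Araneae = 17,
               Pedipalpi = 4, Opiliones = 13, Ricinulei = 5, Xiphosura = 3,
               Solifugae = 2, Parasitiformes = 9, Acariformes = 10,
               Pycnogonida = 2)
  outgroup <- c(Onychophora = 3, Myriapoda = 4, Pancrustacea = 8)
  pseudo_subgroups <- c(Chthonioidea = 6, Feaelloidea = 2, Neobisioidea = 10,
                        Garypoidea = 5, Garypinoidea = 3, Cheridoidea = 1,
                        Sternophoroidea = 1, Cheliferoidea = 12)
  mk <- function(group, n) sprintf("%s_%02d", group, seq_len(n))
  name <- c(unlist(lapply(names(ingroup), function(g) mk(g, ingroup[[g]]))),
            unlist(lapply(names(outgroup), function(g) mk(g, outgroup[[g]]))))
  group <- c(rep(names(ingroup), ingroup), rep(names(outgroup), outgroup))
  role <- rep(c("ingroup", "outgroup"), c(sum(ingroup), sum(outgroup)))
  subgroup <- rep("", length(name))
  ps <- rep(names(pseudo_subgroups), pseudo_subgroups)
  subgroup[group == "Pseudoscorpiones"] <- ps
  reg <- taxon_registry(name, group, subgroup, role)
  steps <- list(
    pruning_step(1, "Chthonioidea", 6),
    pruning_step(2, "Feaelloidea", 2),
    pruning_step(3, "Neobisioidea", 10),
    pruning_step(4, "Garypoidea", 5),
    pruning_step(5, "Garypinoidea", 3),
    # one pruning event removing two minor superfamilies together
    pruning_step(6, c("Cheridoidea", "Sternophoroidea"), 2))
  list(registry = reg, steps = steps, focal_group = "Pseudoscorpiones")
}

#' The chelicerate analysis plan
#'
#' The full enumeration of analyses in the emulated design: partitioned ML
#' and coalescent summary (ASTRAL-style) runs over the 6 x 7 grid, the
#' site-heterogeneous C20 runs on the densest and largest families, C60 on
#' the densest, and rate-tertile ML + summary runs on the two mid-occupancy
#' families.
#'
#' @return the result of \code{\link{enumerate_analyses}} (189 analyses).
#' @export
chelicerate_plan <- function() {
  fams <- occupancy_families()$family     # G1..G6
  subs <- paste0("T", c(0, -1, -2, -3, -4, -5, -6))
  tert <- c("slow", "intermediate", "fast")
  enumerate_analyses(list(
    list(method = "partitioned_ml", families = fams, subsets = subs),
    list(method = "astral", families = fams, subsets = subs),
    list(method = "pmsf_c20", families = c("G1", "G6"), subsets = subs),
    list(method = "pmsf_c60", families = "G1", subsets = subs),
    list(method = "rate_tertile_ml", families = c("G2", "G3"),
         subsets = subs, tertiles = tert),
    list(method = "rate_tertile_astral", families = c("G2", "G3"),
         subsets = subs, tertiles = tert)))
}
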