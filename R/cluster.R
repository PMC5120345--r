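#' Extract single-species monophyletic clusters from a tree
#'
#' Scans the internal edges of an (annotated) tree for maximal groups of
#' leaves whose contained reference sequences belong to a single species
#' and whose subtending edge has bootstrap support at or above
#' `min_support`. Both sides of every internal bipartition are considered,
#' plus the full leaf set (support 100 by convention), so a single-species
#' tree yields one cluster containing all leaves. Candidate groups are
#' accepted greedily from largest to smallest, keeping disjoint groups;
#' query leaves outside every accepted group are reported `UNRESOLVED`.
#'
#' Trees without support annotation pass the support filter (support is
#' taken as 100).
#'
#' @param tree a `phylo`, typically from [bootstrap_support()].
#' @param refs a [seq_panel()] of reference sequences (species labelled);
#'   reference ids must be tree leaves.
#' @param min_support minimal support percentage (default 99).
#' @return data.frame with one row per leaf: `id`, `cluster_id` (NA when
#'   unresolved), `species_call` (`"UNRESOLVED"` outside clusters),
#'   `support`, `is_reference`.
#' @export
extract_clusters <- function(tree, refs, min_support = 99) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  ref_ids <- intersect(refs$id, tips)
  if (length(ref_ids) == 0) stop("no reference sequences among tree leaves")
  ref_sp <- setNames(refs$species, refs$id)[ref_ids]
  n <- length(tips)

  sets <- list(seq_len(n))
  support <- 100
  if (n >= 4 && tree$Nnode > 1) {
    pp <- ape::prop.part(tree)
    idx <- match(attr(pp, "labels"), tips)
    sup <- split_support(tree)
    if (length(sup) != length(pp)) sup <- rep(NA_real_, length(pp))
    for (i in seq_along(pp)) {
      s <- sort(idx[pp[[i]]])
      if (length(s) < 2 || length(s) > n - 2) next
      sets <- c(sets, list(s), list(setdiff(seq_len(n), s)))
      si <- if (is.na(sup[i])) 100 else sup[i]
      support <- c(support, si, si)
    }
  }

  keep_sp <- character(0)
  keep_sets <- list()
  keep_sup <- numeric(0)
  ord <- order(-vapply(sets, length, integer(1)))
  taken <- logical(n)
  for (i in ord) {
    s <- sets[[i]]
    if (support[i] < min_support) next
    ids <- tips[s]
    rs <- unique(ref_sp[intersect(ids, ref_ids)])
    if (length(rs) != 1) next
    if (any(taken[s])) next
    taken[s] <- TRUE
    keep_sets <- c(keep_sets, list(s))
    keep_sp <- c(keep_sp, rs)
    keep_sup <- c(keep_sup, support[i])
  }

  out <- data.frame(id = tips, cluster_id = NA_character_,
                    species_call = "UNRESOLVED", support = NA_real_,
                    is_reference = tips %in% ref_ids,
                    stringsAsFactors = FALSE)
  if (length(keep_sets)) {
    o <- order(-vapply(keep_sets, length, integer(1)))
    for (k in seq_along(o)) {
      s <- keep_sets[[o[k]]]
      out$cluster_id[s] <- paste0("C", k)
      out$species_call[s] <- keep_sp[o[k]]
      out$support[s] <- keep_sup[o[k]]
    }
  }
  out
}

#' Assign query sequences to species by best identity against a panel
#'
#' A local stand-in for web-based best-hit identification: the identity of
#' a query against each reference is the fraction of matching sites among
#' comparable sites (pairwise deletion of `N`/gap positions, consistent
#' with the distance computation). The query takes the species of its
#' best-identity reference when that identity reaches `min_identity`
#' (default 0.99, per the "99-100% identical" assignment convention), and
#' `"UNASSIGNED"` otherwise. Exact ties go to the earliest reference in
#' panel order and are flagged.
#'
#' @param query a [seq_panel()] of one or more query sequences.
#' @param refs a [seq_panel()] of labelled references (same marker, aligned
#'   with the queries).
#' @param min_identity assignment threshold in `[0, 1]`.
#' @return data.frame with one row per query: `id`, `species`, `identity`,
#'   `best_ref`, `tie`.
#' @export
assign_by_identity <- function(query, refs, min_identity = 0.99) {
  stopifnot(inherits(query, "seq_panel"))
  if (is.null(refs) || nrow(refs) == 0) stop("empty reference panel")
  if (query$marker[1] != refs$marker[1])
    stop("query and reference markers differ")
  codes <- .seq_codes(c(query$residues, refs$residues))
  qc <- codes[, seq_len(nrow(query)), drop = FALSE]
  rc <- codes[, nrow(query) + seq_len(nrow(refs)), drop = FALSE]
  cnt <- .ident_counts_cpp(qc, rc)
  idm <- cnt$matches / cnt$comparable
  idm[cnt$comparable == 0] <- NA_real_

  best <- vapply(seq_len(nrow(idm)), function(i) {
    x <- idm[i, ]
    if (all(is.na(x))) return(c(NA_real_, NA_real_, 0))
    m <- max(x, na.rm = TRUE)
    hits <- which(!is.na(x) & x >= m - 1e-12)
    c(m, hits[1], length(hits) > 1)
  }, numeric(3))
  identity <- best[1, ]
  ref_i <- best[2, ]
  species <- ifelse(!is.na(identity) & identity >= min_identity,
                    refs$species[ref_i], "UNASSIGNED")
  data.frame(id = query$id, species = species, identity = identity,
             best_ref = refs$id[ref_i], tie = as.logical(best[3, ]),
             stringsAsFactors = FALSE)
}

#' Barcoding-gap summary of a distance matrix
#'
#' Splits the pairwise K2P distances into within-species and
#' between-species pairs according to the supplied labels and reports both
#' ranges as percentage distances (100 * d). Ids labelled `"UNKNOWN"` are
#' excluded. A barcoding gap exists when `intra_max < inter_min`.
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @param labels species per id: either a named character vector (names =
#'   sequence ids) or a vector aligned with `dm$labels`.
#' @return Object of class `gap_summary`: list with `intra_min`,
#'   `intra_max`, `inter_min`, `inter_max` (percent), `n_intra_pairs`,
#'   `n_inter_pairs`, `gap` (logical).
#' @export
barcoding_gap <- function(dm, labels) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (!is.null(names(labels))) labels <- labels[dm$labels]
  labels <- as.character(labels)
  if (length(labels) != length(dm$labels))
    stop("labels must cover every sequence in the matrix")
  keep <- !is.na(labels) & labels != "UNKNOWN"
  if (!any(keep)) stop("all ids are UNKNOWN")
  d <- dm$d[keep, keep, drop = FALSE]
  sp <- labels[keep]
  if (length(unique(sp)) < 2) stop("need at least 2 labelled species")
  same <- outer(sp, sp, "==")
  ut <- upper.tri(d)
  intra <- 100 * d[ut & same]
  inter <- 100 * d[ut & !same]
  if (length(intra) == 0)
    stop("no intraspecific pairs (need >= 2 members in some species)")
  structure(list(intra_min = min(intra), intra_max = max(intra),
                 inter_min = min(inter), inter_max = max(inter),
                 n_intra_pairs = length(intra),
                 n_inter_pairs = length(inter),
                 gap = max(intra) < min(inter)),
            class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("Barcoding gap summary (%% K2P distance)\n"))
  cat(sprintf("  intra-species: %.2f - %.2f  (%d pairs)\n",
              x$intra_min, x$intra_max, x$n_intra_pairs))
  cat(sprintf("  inter-species: %.2f - %.2f  (%d pairs)\n",
              x$inter_min, x$inter_max, x$n_inter_pairs))
  cat("  gap present:", x$gap, "\n")
  invisible(x)
}
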