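#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the Q-criterion. When two pairs
#' minimize the criterion equally the smallest pair in the current node
#' ordering is joined; negative branch lengths are clamped to zero with the
#' deficit moved to the sibling branch. Two taxa yield a single edge split
#' evenly; the output is the usual unrooted tree with a trifurcating root
#' node.
#'
#' @param dm a `k2p_dist` from [distance_matrix()], a symmetric numeric
#'   matrix with dimnames, or a [stats::dist] object.
#' @return An unrooted `ape::phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
neighbor_joining <- function(dm) {
  d <- .dist_input(dm)
  ape::read.tree(text = .nj_newick_cpp(d, rownames(d)))
}

.dist_input <- function(dm) {
  if (inherits(dm, "k2p_dist")) d <- dm$d
  else if (inherits(dm, "dist")) d <- as.matrix(dm)
  else if (is.matrix(dm)) d <- dm
  else stop("expected a k2p_dist, matrix or dist object")
  if (nrow(d) != ncol(d) || any(!is.finite(d)))
    stop("distance matrix must be square with finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

# canonical bipartition keys of the internal edges of a tree, relative to a
# reference tip ordering; the side not containing the first reference tip,
# as a sorted comma-separated index string. Element i corresponds to
# internal node (Ntip + i); the root key is NA (no subtending edge).
.tree_splits <- function(tree, ref_tips) {
  pp <- ape::prop.part(tree)
  idx <- match(attr(pp, "labels"), ref_tips)
  n <- length(ref_tips)
  vapply(seq_along(pp), function(i) {
    s <- idx[pp[[i]]]
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    if (length(s) < 2 || length(s) > n - 2) return(NA_character_)
    paste(sort(s), collapse = ",")
  }, character(1))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ/K2P tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times, rebuilds the tree
#' per replicate and annotates each internal edge of the reference tree
#' with the percentage of replicate trees containing the same bipartition.
#' A replicate in which any pairwise K2P distance is undefined (saturation)
#' is discarded and counted; a warning is raised when more than 10% of
#' replicates are discarded. Fully reproducible for a fixed seed.
#'
#' @param records aligned [seq_panel()] (>= 3 sequences for internal edges).
#' @param replicates number of bootstrap replicates (>= 1; default 1000).
#' @param seed integer RNG seed.
#' @return `ape::phylo` tree whose `node.label` holds per-internal-edge
#'   support percentages (empty at the root); the numeric vector is also
#'   attached as attribute `"support"` and the discarded-replicate count as
#'   `"discarded"`.
#' @export
bootstrap_support <- function(records, replicates = 1000, seed = 1) {
  stopifnot(inherits(records, "seq_panel"), replicates >= 1)
  codes <- .seq_codes(records$residues)
  L <- nrow(codes)
  n <- ncol(codes)
  dm <- distance_matrix(records)
  ref <- neighbor_joining(dm)
  keys <- .tree_splits(ref, ref$tip.label)
  hits <- setNames(numeric(length(keys)), keys)
  discarded <- 0L

  set.seed(seed)
  for (r in seq_len(replicates)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), L)
    cnt <- .pair_counts_cpp(codes, as.numeric(w))
    ns <- cnt$n_sites
    diag(ns) <- 1
    if (any(ns == 0)) { discarded <- discarded + 1L; next }
    d <- .k2p(cnt$transitions / ns, cnt$transversions / ns)
    diag(d) <- 0
    if (any(!is.finite(d))) { discarded <- discarded + 1L; next }
    dimnames(d) <- list(records$id, records$id)
    rep_tree <- ape::read.tree(text = .nj_newick_cpp(d, records$id))
    rk <- .tree_splits(rep_tree, ref$tip.label)
    found <- keys[!is.na(keys) & keys %in% rk]
    hits[found] <- hits[found] + 1
  }
  used <- replicates - discarded
  if (used == 0) stop("all bootstrap replicates discarded (saturation)")
  if (discarded > 0.1 * replicates)
    warning(discarded, " of ", replicates,
            " bootstrap replicates discarded (undefined distances)")
  support <- ifelse(is.na(keys), NA_real_, 100 * hits / used)
  ref$node.label <- ifelse(is.na(support), "",
                           formatC(support, format = "fg", digits = 4))
  attr(ref, "support") <- support
  attr(ref, "discarded") <- discarded
  ref
}

#' Per-internal-node support values of an annotated tree
#'
#' @param tree a `phylo` from [bootstrap_support()] (or any tree with
#'   numeric node labels).
#' @return Numeric vector, one entry per internal node (NA where a node has
#'   no subtending internal edge or no label).
#' @export
split_support <- function(tree) {
  sup <- attr(tree, "support")
  if (!is.null(sup)) return(sup)
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}
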