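#' Pairwise substitution tally between two aligned sequences
#'
#' Counts comparable sites between two aligned sequences of the same marker
#' under pairwise deletion (a site is dropped when either sequence carries
#' `N` or `-`), and returns the transition proportion P (`A<->G`, `C<->T`)
#' and transversion proportion Q among the retained sites. These are the
#' two quantities entering the Kimura 2-parameter distance.
#'
#' @param a,b single sequences: either residue strings or one-row
#'   [seq_panel()] subsets.
#' @return Object of class `pairwise_substitution`: list with `n_sites`,
#'   `P`, `Q`.
#' @export
count_substitutions <- function(a, b) {
  ra <- .residues1(a)
  rb <- .residues1(b)
  if (nchar(ra) != nchar(rb))
    stop("sequences have unequal lengths (", nchar(ra), " vs ", nchar(rb),
         "); inputs must be aligned")
  ma <- .marker1(a); mb <- .marker1(b)
  if (!is.null(ma) && !is.null(mb) && ma != mb)
    stop("sequences are from different markers (", ma, " vs ", mb, ")")
  ca <- .seq_codes(ra)[, 1]
  cb <- .seq_codes(rb)[, 1]
  ok <- ca < 4L & cb < 4L
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  da <- ca[ok]; db <- cb[ok]
  ts <- sum(bitwXor(da, db) == 2L)
  tv <- sum(da != db) - ts
  structure(list(n_sites = n, P = ts / n, Q = tv / n),
            class = "pairwise_substitution")
}

.residues1 <- function(x) {
  if (is.character(x) && length(x) == 1) return(toupper(x))
  if (is.data.frame(x) && nrow(x) == 1 && "residues" %in% names(x))
    return(x$residues)
  if (is.list(x) && !is.null(x$residues)) return(toupper(x$residues))
  stop("expected a single sequence (residue string or one-row seq_panel)")
}

.marker1 <- function(x) {
  if (is.data.frame(x) && "marker" %in% names(x)) return(x$marker[1])
  if (is.list(x) && !is.null(x$marker)) return(x$marker)
  NULL
}

# vectorized K2P core; NaN where the logs are undefined (saturation)
.k2p <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  d[w1 <= 0 | w2 <= 0] <- NaN
  d + 0 # turn IEEE -0 (identical sequences) into +0
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, in substitutions per site,
#' where P and Q are the transition and transversion proportions among
#' compared sites. Saturated pairs (non-positive log arguments) raise an
#' error rather than returning infinity.
#'
#' @param sub a `pairwise_substitution` from [count_substitutions()], or a
#'   list with elements `P` and `Q`.
#' @return Non-negative distance (substitutions/site).
#' @export
k2p_distance <- function(sub) {
  if (!is.list(sub) || is.null(sub$P) || is.null(sub$Q))
    stop("expected a pairwise_substitution (list with P and Q)")
  P <- sub$P; Q <- sub$Q
  if (P < 0 || Q < 0 || P + Q > 1) stop("invalid P/Q proportions")
  d <- .k2p(P, Q)
  if (!is.finite(d)) stop("K2P distance undefined (saturation)")
  d
}

#' All pairwise K2P distances of an aligned panel
#'
#' @param records a [seq_panel()] of at least two aligned sequences sharing
#'   one marker.
#' @return Object of class `k2p_dist`: list with `labels`, symmetric
#'   distance matrix `d` (zero diagonal), and per-pair matrices `P`, `Q`,
#'   `n_sites`.
#' @export
distance_matrix <- function(records) {
  stopifnot(inherits(records, "seq_panel"))
  if (nrow(records) < 2) stop("need at least 2 sequences")
  codes <- .seq_codes(records$residues)
  cnt <- .pair_counts_cpp(codes, rep(1, nrow(codes)))
  labels <- records$id
  off <- upper.tri(cnt$n_sites)
  if (any(cnt$n_sites[off] == 0)) {
    ij <- which(cnt$n_sites == 0 & off, arr.ind = TRUE)[1, ]
    stop("no comparable sites between ", labels[ij[1]], " and ",
         labels[ij[2]])
  }
  P <- cnt$transitions / cnt$n_sites
  Q <- cnt$transversions / cnt$n_sites
  diag(P) <- diag(Q) <- 0
  d <- .k2p(P, Q)
  diag(d) <- 0
  if (any(!is.finite(d))) {
    ij <- which(!is.finite(d) & off, arr.ind = TRUE)[1, ]
    stop("K2P distance undefined (saturation) between ", labels[ij[1]],
         " and ", labels[ij[2]])
  }
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- list(labels, labels)
  dimnames(cnt$n_sites) <- list(labels, labels)
  structure(list(labels = labels, d = d, P = P, Q = Q,
                 n_sites = cnt$n_sites),
            class = "k2p_dist")
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix:", length(x$labels), "sequences\n")
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("  range %.4f - %.4f substitutions/site\n",
              min(off), max(off)))
  invisible(x)
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  stopifnot(inherits(dm, "k2p_dist"))
  n <- length(dm$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(dm$labels[i], width = -10), "  ",
                      paste(sprintf("%.8f", dm$d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Long-format pairwise distance table
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @return data.frame with columns `id1`, `id2`, `n_sites`, `P`, `Q`, `d`
#'   (one row per unordered pair).
#' @export
distance_long <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  ij <- which(upper.tri(dm$d), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(id1 = dm$labels[ij[, 1]], id2 = dm$labels[ij[, 2]],
             n_sites = dm$n_sites[ij], P = dm$P[ij], Q = dm$Q[ij],
             d = dm$d[ij], stringsAsFactors = FALSE)
}
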