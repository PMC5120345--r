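#' Naive-Bayes species posterior from coded traits and filament length
#'
#' A transparent probabilistic counterpart to visual discrimination,
#' parameterized directly by a [trait_profile_table()]: the posterior for
#' each species is proportional to its prior (specimen counts) times one
#' categorical likelihood per coded trait (with additive smoothing of the
#' published frequencies) times a Gaussian density for the plate-averaged
#' filament length. Traits are treated as independent given species — the
#' published table reports only marginal frequencies.
#'
#' Smoothing uses pseudo-count `smoothing` against the species prior count:
#' `p = (freq * n + smoothing) / (n + smoothing * K)` for a trait with `K`
#' levels, so `smoothing = 0` reproduces the published frequencies exactly
#' (and zero-frequency traits then veto a species). Missing (`NA`) traits
#' or lengths simply drop their factor. If every species has zero
#' likelihood the prior is returned with a warning.
#'
#' @param specimens specimen data.frame (trait columns and `fl1`..`fl5`;
#'   `NA` traits allowed).
#' @param profile a `trait_profile` (default [mobulid_trait_profile()]).
#' @param smoothing additive pseudo-count, >= 0 (default 0.5).
#' @return Numeric matrix of posteriors (rows = specimens, columns =
#'   species; each row sums to 1) with the argmax species as attribute
#'   `"call"`.
#' @export
trait_bayes_classify <- function(specimens, profile = mobulid_trait_profile(),
                                 smoothing = 0.5) {
  stopifnot(inherits(profile, "trait_profile"))
  if (smoothing < 0) stop("smoothing must be >= 0")
  sp <- profile$species
  n <- nrow(specimens)
  prior <- profile$priors / sum(profile$priors)
  logpost <- matrix(rep(log(prior), each = n), nrow = n,
                    dimnames = list(specimens$id, sp))

  for (tr in names(profile$freqs)) {
    m <- profile$freqs[[tr]]
    K <- ncol(m)
    pc <- profile$priors
    sm <- sweep(m * pc, 1, pc + smoothing * K, "/") + # (freq*n + s)/(n + sK)
      smoothing / (pc + smoothing * K)
    obs <- specimens[[tr]]
    lev <- match(obs, colnames(m))
    for (i in which(!is.na(lev)))
      logpost[i, ] <- logpost[i, ] + log(sm[, lev[i]])
  }

  len <- tryCatch(mean_filament_length(specimens), error = function(e) NULL)
  if (!is.null(len)) {
    for (i in which(is.finite(len)))
      logpost[i, ] <- logpost[i, ] +
        dnorm(len[i], profile$length_mean, profile$length_sd, log = TRUE)
  }

  post <- exp(logpost - apply(logpost, 1, max))
  bad <- !is.finite(rowSums(post)) | rowSums(post) == 0
  if (any(bad)) {
    warning("zero likelihood for every species in ", sum(bad),
            " specimen(s); returning the prior")
    post[bad, ] <- rep(prior, each = sum(bad))
  }
  post <- post / rowSums(post)
  attr(post, "call") <- sp[max.col(post, ties.method = "first")]
  post
}
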