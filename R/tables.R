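#' Species handled by the package
#'
#' The five mobulid species found in dried gill-raker ("Peng Yu Sai") market
#' surveys in southern China: four devil rays (*Mobula*) and the giant manta
#' ray (*Manta birostris*, CITES Appendix II).
#'
#' @return Character vector of five species names, underscored
#'   (`"Mobula_japanica"`, ...), in market-table order.
#' @export
mobulid_species <- function() {
  c("Mobula_japanica", "Mobula_kuhlii", "Mobula_tarapacana",
    "Mobula_thurstoni", "Manta_birostris")
}

#' Categorical trait levels for dried gill-raker coding
#'
#' Four visual traits are coded on each dried gill-raker plate: filament
#' arrangement, filament color, middle-lobe structure (viewed through a hand
#' loupe) and terminal-lobe shape.
#'
#' @return Named list of character vectors, one per trait.
#' @export
trait_levels <- function() {
  list(
    arrangement   = c("loose", "general", "tight"),
    color         = c("light_end", "light_base", "whole_light", "whole_dark"),
    middle_lobe   = c("finger_like", "veins", "oval", "cilia", "none_obvious"),
    terminal_lobe = c("large_fused", "oval", "sharp_apex")
  )
}

#' Default market table: specimen counts and prices per species
#'
#' Published market-survey composition of 188 DNA-identified dried
#' gill-raker specimens with per-species average prices in US$/kg. The
#' *Mobula kuhlii* price rests on a single observation, so its standard
#' deviation is unreported (NA here; the synthetic generator substitutes a
#' configurable default).
#'
#' @return data.frame with columns `species`, `n`, `price_mean`, `price_sd`.
#' @export
mobulid_market_table <- function() {
  data.frame(
    species    = mobulid_species(),
    n          = c(103L, 25L, 27L, 12L, 21L),
    price_mean = c(208, 130, 267, 187, 348),
    price_sd   = c(50, NA, 103, 64, 170),
    stringsAsFactors = FALSE
  )
}

#' Default filament-length parameters per species
#'
#' Mean and standard deviation (mm) of the plate-averaged filament length
#' for each species, as published for DNA-identified market specimens.
#'
#' @return data.frame with columns `species`, `length_mean`, `length_sd`.
#' @export
mobulid_length_table <- function() {
  data.frame(
    species     = mobulid_species(),
    length_mean = c(36.0, 20.4, 51.4, 25.5, 62.6),
    length_sd   = c(8.4, 5.7, 9.8, 8.5, 16.7),
    stringsAsFactors = FALSE
  )
}

# Published categorical trait frequencies (percent, verbatim). Two
# terminal-lobe columns and one color column do not total 100 (rounding /
# reporting in the source table); trait_profile_table() renormalizes.
.default_trait_freqs <- function() {
  sp <- mobulid_species()
  lv <- trait_levels()
  mk <- function(x, trait) {
    m <- matrix(x / 100, nrow = 5, byrow = TRUE,
                dimnames = list(sp, lv[[trait]]))
    m
  }
  list(
    arrangement = mk(c(59, 33,  8,
                       64, 36,  0,
                        0, 26, 74,
                       50, 50,  0,
                        0, 48, 52), "arrangement"),
    color = mk(c(30,  2,  4, 64,
                  0, 44,  4, 52,
                  0, 93,  4,  4,
                  0, 58,  0, 42,
                  0,  5, 33, 62), "color"),
    middle_lobe = mk(c( 0, 52,   2,  0, 46,
                        0,  8,  92,  0,  0,
                        0,  0,   0, 81, 19,
                        0,  0, 100,  0,  0,
                       81,  0,   0,  0, 19), "middle_lobe"),
    terminal_lobe = mk(c(  2,  2, 96,
                           0, 76, 16,
                         100,  0,  0,
                           8, 67,  8,
                         100,  0,  0), "terminal_lobe")
  )
}

#' Construct a trait profile table
#'
#' A trait profile holds, per species, the prior specimen counts, the
#' filament-length Normal parameters (mm) and one categorical frequency
#' vector per visual trait. It parameterizes both the naive-Bayes classifier
#' and the synthetic specimen generator.
#'
#' Frequency vectors are renormalized to sum exactly to 1 (published rows
#' are rounded percentages and a few do not total 100); after normalization
#' each row must satisfy the sum-to-one invariant to within 0.005.
#'
#' @param species character vector of species names.
#' @param priors positive prior counts (or weights), one per species.
#' @param length_mean,length_sd filament-length Normal parameters (mm).
#' @param freqs named list of species-by-level frequency matrices, one per
#'   trait in [trait_levels()].
#' @return Object of class `trait_profile`.
#' @export
trait_profile_table <- function(species, priors, length_mean, length_sd,
                                freqs) {
  stopifnot(length(species) >= 1, !anyDuplicated(species))
  if (any(priors <= 0)) stop("priors must be > 0")
  if (any(length_sd <= 0) || any(length_mean <= 0))
    stop("length parameters must be > 0")
  lv <- trait_levels()
  if (!setequal(names(freqs), names(lv)))
    stop("freqs must have one matrix per trait: ",
         paste(names(lv), collapse = ", "))
  freqs <- lapply(names(lv), function(tr) {
    m <- freqs[[tr]]
    if (!all(species %in% rownames(m)))
      stop("trait '", tr, "' is missing rows for some species")
    m <- m[species, lv[[tr]], drop = FALSE]
    if (any(m < 0) || any(!is.finite(m)))
      stop("trait frequencies must be finite and >= 0")
    rs <- rowSums(m)
    if (any(rs <= 0)) stop("trait '", tr, "' has an all-zero frequency row")
    m <- m / rs
    stopifnot(all(abs(rowSums(m) - 1) < 0.005))
    m
  })
  names(freqs) <- names(lv)
  structure(
    list(species = species, priors = as.numeric(priors),
         length_mean = as.numeric(length_mean),
         length_sd = as.numeric(length_sd), freqs = freqs),
    class = "trait_profile"
  )
}

#' Default trait profile (published market-survey parameters)
#'
#' @return `trait_profile` built from the default market counts
#'   ([mobulid_market_table()]), length parameters
#'   ([mobulid_length_table()]) and published trait frequencies.
#' @export
mobulid_trait_profile <- function() {
  mt <- mobulid_market_table()
  lt <- mobulid_length_table()
  trait_profile_table(mt$species, mt$n, lt$length_mean, lt$length_sd,
                      .default_trait_freqs())
}

#' @export
print.trait_profile <- function(x, ...) {
  cat("Trait profile for", length(x$species), "species\n")
  cat("  priors:", paste0(x$species, "=", x$priors, collapse = ", "), "\n")
  cat("  length (mm):",
      paste0(round(x$length_mean, 1), "+/-", round(x$length_sd, 1),
             collapse = ", "), "\n")
  invisible(x)
}
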