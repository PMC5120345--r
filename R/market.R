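#' Market composition percentages
#'
#' Percentage of identified specimens per species, reported to 1 decimal
#' (so the five published counts 103/25/27/12/21 yield
#' 54.8/13.3/14.4/6.4/11.2).
#'
#' @param counts named non-negative counts with positive total.
#' @return Named numeric percentages (rounded to 1 decimal; the sum can
#'   deviate from 100 by rounding, within 0.2).
#' @export
composition_percentages <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0)
    stop("total count must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  round(100 * counts / sum(counts), 1)
}

#' Count-weighted overall mean price
#'
#' `sum(count * mean) / sum(count)` over species - the overall per-kilogram
#' average implied by per-species mean prices and specimen counts.
#'
#' @param counts named positive counts.
#' @param mean_prices positive per-species mean prices (US$/kg), aligned
#'   with `counts` (matched by name when both are named).
#' @return Weighted mean price (US$/kg).
#' @export
weighted_mean_price <- function(counts, mean_prices) {
  if (length(counts) == 0) stop("empty price map")
  if (!is.null(names(counts)) && !is.null(names(mean_prices)))
    mean_prices <- mean_prices[names(counts)]
  if (length(mean_prices) != length(counts))
    stop("counts and mean_prices must align")
  if (any(counts <= 0) || any(mean_prices <= 0) || anyNA(mean_prices))
    stop("counts and prices must be positive")
  sum(counts * mean_prices) / sum(counts)
}

#' Ordinary least-squares fit of price on mean filament length
#'
#' @param specimens specimen data.frame with `price_usd_kg` and `fl1..fl5`.
#' @return List with `slope` (US$/mm), `intercept`, `sign`, `n`, and the
#'   underlying `lm` fit.
#' @export
length_price_fit <- function(specimens) {
  len <- mean_filament_length(specimens)
  price <- specimens$price_usd_kg
  ok <- is.finite(len) & is.finite(price)
  if (sum(ok) < 3) stop("need >= 3 specimens with price and length")
  if (var(len[ok]) == 0) stop("zero length variance")
  fit <- lm(price ~ len, data = data.frame(price = price[ok],
                                           len = len[ok]))
  b <- coef(fit)
  list(slope = unname(b[2]), intercept = unname(b[1]),
       sign = sign(unname(b[2])), n = sum(ok), fit = fit)
}

#' Market summary: composition, prices and per-city means
#'
#' @param species character species call per specimen (non-species calls
#'   such as `UNASSIGNED` / `NO_SEQUENCE` / `NA` are excluded as
#'   unidentified).
#' @param price optional price per specimen (US$/kg).
#' @param city optional city per specimen.
#' @param known_species vector of valid species names (default
#'   [mobulid_species()], plus any other label present that looks like a
#'   species is NOT counted - restrict explicitly if needed).
#' @return Object of class `market_summary`: list with `per_species`
#'   (count, percentage, price mean/sd), `n_identified`, `overall_mean`,
#'   `overall_sd`, `per_city`.
#' @export
market_summary <- function(species, price = NULL, city = NULL,
                           known_species = mobulid_species()) {
  ident <- !is.na(species) & species %in% known_species
  if (!any(ident)) stop("no identified specimens")
  sp <- species[ident]
  counts <- table(factor(sp, levels = intersect(known_species, sp)))
  counts <- setNames(as.integer(counts), names(counts))
  pct <- composition_percentages(counts)

  per_species <- data.frame(species = names(counts), n = counts,
                            percentage = pct, price_mean = NA_real_,
                            price_sd = NA_real_, stringsAsFactors = FALSE,
                            row.names = NULL)
  overall_mean <- NA_real_
  overall_sd <- NA_real_
  per_city <- NULL
  if (!is.null(price)) {
    pr <- price[ident]
    for (i in seq_len(nrow(per_species))) {
      p <- pr[sp == per_species$species[i] & !is.na(pr)]
      if (length(p)) {
        per_species$price_mean[i] <- mean(p)
        per_species$price_sd[i] <- if (length(p) > 1) sd(p) else NA_real_
      }
    }
    has <- !is.na(per_species$price_mean)
    if (any(has))
      overall_mean <- weighted_mean_price(
        setNames(per_species$n[has], per_species$species[has]),
        setNames(per_species$price_mean[has], per_species$species[has]))
    overall_sd <- sd(pr[!is.na(pr)])
    if (!is.null(city)) {
      ct <- city[ident]
      ok <- !is.na(pr) & !is.na(ct)
      if (any(ok))
        per_city <- vapply(split(pr[ok], ct[ok]), mean, numeric(1))
    }
  }
  structure(list(per_species = per_species, n_identified = sum(ident),
                 overall_mean = overall_mean, overall_sd = overall_sd,
                 per_city = per_city),
            class = "market_summary")
}

#' @export
print.market_summary <- function(x, ...) {
  cat("Market summary:", x$n_identified, "identified specimens\n")
  df <- x$per_species
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-18s n=%3d  %5.1f%%  %s US$/kg\n", df$species[i],
                df$n[i], df$percentage[i],
                if (is.na(df$price_mean[i])) "-" else
                  sprintf("%.0f +/- %s", df$price_mean[i],
                          if (is.na(df$price_sd[i])) "NA" else
                            sprintf("%.0f", df$price_sd[i]))))
  if (!is.na(x$overall_mean))
    cat(sprintf("  overall: %.0f +/- %.0f US$/kg (count-weighted mean)\n",
                x$overall_mean, x$overall_sd))
  if (!is.null(x$per_city)) {
    cat("  per-city mean prices:",
        paste0(names(x$per_city), "=", round(x$per_city), collapse = ", "),
        "\n")
  }
  invisible(x)
}
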