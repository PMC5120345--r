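#' Validate a gill-raker specimen table
#'
#' A specimen table holds one dried gill-raker plate per row: five
#' filament-length measurements in mm (`fl1`..`fl5`: two plate edges, the
#' midpoint, and the two points in between), the four coded visual traits,
#' and optional `price_usd_kg`, `city` and `true_species` columns.
#'
#' @param df data.frame to validate.
#' @return The validated data.frame (invisibly coerced: ids as character,
#'   lengths numeric).
#' @export
validate_specimens <- function(df) {
  req <- c("id", paste0("fl", 1:5), names(trait_levels()))
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing specimen columns: ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (any(!nzchar(df$id))) stop("specimen ids must be non-empty")
  if (anyDuplicated(df$id)) stop("duplicate specimen id: ",
                                 df$id[duplicated(df$id)][1])
  fl <- as.matrix(df[paste0("fl", 1:5)])
  if (any(!is.finite(fl)) || any(fl <= 0))
    stop("filament lengths must be positive (5 points per specimen)")
  lv <- trait_levels()
  for (tr in names(lv)) {
    bad <- !df[[tr]] %in% lv[[tr]]
    if (any(bad))
      stop("invalid ", tr, " value '", df[[tr]][bad][1], "' for specimen ",
           df$id[bad][1])
  }
  if (!is.null(df$price_usd_kg) &&
      any(!is.na(df$price_usd_kg) & df$price_usd_kg <= 0))
    stop("prices must be positive")
  df
}

#' Read a specimen table from CSV
#'
#' CSV dialect: header row with columns `id, fl1..fl5, arrangement, color,
#' middle_lobe, terminal_lobe` and optionally `price_usd_kg, city,
#' true_species`; UTF-8, RFC-4180.
#'
#' @param path path to the CSV file.
#' @return Validated specimen data.frame.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) stop("empty specimen table: ", path)
  validate_specimens(df)
}

#' Write a specimen table to CSV
#'
#' @param df specimen data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plate-averaged filament length
#'
#' The arithmetic mean of the five per-plate measurements, the quantity
#' used for all downstream size analyses.
#'
#' @param x a specimen data.frame (columns `fl1`..`fl5`) or a numeric
#'   vector of five positive lengths.
#' @return Numeric vector of mean lengths (mm), one per specimen.
#' @export
mean_filament_length <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 5) stop("expected exactly 5 filament measurements")
    fl <- matrix(x, nrow = 1)
  } else {
    fl <- as.matrix(x[paste0("fl", 1:5)])
  }
  if (any(!is.finite(fl)) || any(fl <= 0))
    stop("filament lengths must be positive")
  rowMeans(fl)
}

#' Size screen for likely manta gill rakers
#'
#' Plates whose mean filament length strictly exceeds 70 mm are flagged as
#' likely *Manta birostris* — an enforcement rule of thumb, not an
#' identification (manta plates range from about 30 mm to almost 100 mm).
#'
#' @param length_mm positive mean filament length(s) in mm.
#' @return Character vector: `"MANTA_LIKELY"` (> 70 mm, strict) or
#'   `"NOT_FLAGGED"`.
#' @export
size_screen <- function(length_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    stop("lengths must be positive")
  ifelse(length_mm > 70, "MANTA_LIKELY", "NOT_FLAGGED")
}

#' Three-step enforcement classification of dried gill rakers
#'
#' The frontline decision rule for separating manta rays from devil rays
#' without DNA:
#'
#' 1. Plates whose terminal lobes are not enlarged-and-fused are weeded out
#'    (`OTHER_MOBULA`).
#' 2. Among fused plates, "variegated" gills — dark filaments with a light
#'    base and cilia on the middle lobes — are set aside as
#'    `MOBULA_TARAPACANA`.
#' 3. Finger-like projections on the middle lobes identify `MANTA`.
#'    Projections can be invisible on small or poorly preserved plates, so
#'    fused plates without them fall back to a low-confidence call: `MANTA`
#'    when uniformly colored with no obvious middle-lobe structure,
#'    otherwise `MOBULA_TARAPACANA`.
#'
#' @param specimens specimen data.frame (see [validate_specimens()]).
#' @param variegated_rule function(color, middle_lobe) returning logical;
#'   the default operationalizes "variegated" as
#'   `color == "light_base" & middle_lobe == "cilia"`.
#' @return data.frame with columns `id`, `call` (`MANTA`,
#'   `MOBULA_TARAPACANA` or `OTHER_MOBULA`), `step` (1-3) and
#'   `low_confidence`.
#' @export
three_step_classify <- function(specimens,
                                variegated_rule = function(color, middle_lobe)
                                  color == "light_base" &
                                  middle_lobe == "cilia") {
  specimens <- validate_specimens(specimens)
  n <- nrow(specimens)
  call <- rep("OTHER_MOBULA", n)
  step <- rep(1L, n)
  low <- rep(FALSE, n)

  fused <- specimens$terminal_lobe == "large_fused"
  varg <- fused & variegated_rule(specimens$color, specimens$middle_lobe)
  call[varg] <- "MOBULA_TARAPACANA"
  step[varg] <- 2L

  s3 <- fused & !varg
  finger <- s3 & specimens$middle_lobe == "finger_like"
  call[finger] <- "MANTA"
  step[finger] <- 3L

  rest <- s3 & !finger
  manta_like <- rest &
    specimens$color %in% c("whole_light", "whole_dark") &
    specimens$middle_lobe == "none_obvious"
  call[manta_like] <- "MANTA"
  call[rest & !manta_like] <- "MOBULA_TARAPACANA"
  step[rest] <- 3L
  low[rest] <- TRUE

  data.frame(id = specimens$id, call = call, step = step,
             low_confidence = low, stringsAsFactors = FALSE)
}
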