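# Measurement series: one row per sampling event.

MEASUREMENT_COLUMNS <- c("time_h", "p_before_bar", "p_after_bar",
                         "x_h2", "x_o2", "x_n2", "x_co", "x_co2",
                         "od600", "v_gas_ml", "v_liq_ml")

#' Assemble a validated measurement series
#'
#' One row per sampling event, carrying the manometer readings taken before
#' and after the event, raw GC mole fractions (normalized downstream), the
#' optical density of the aspirated culture sample, and the gas/liquid
#' volumes withdrawn. A missing `p_after_bar` is imputed assuming the nominal
#' gas sample volume was drawn at bottle pressure,
#' `p_after = p_before * (1 - v_gas / V_h)`, with a warning.
#'
#' @param points data.frame with columns `time_h`, `p_before_bar`,
#'   `p_after_bar`, `x_h2`, `x_o2`, `x_n2`, `x_co`, `x_co2`, `od600`
#'   (may be `NA`), `v_gas_ml`, `v_liq_ml`. `od600`, `v_gas_ml` (default 3)
#'   and `v_liq_ml` (default 1) may be omitted.
#' @param bottle a [bottle_spec()].
#' @return An object of class `measurement_series`.
#' @seealso [gas_balance()], [read_measurements()]
#' @export
measurement_series <- function(points, bottle = bottle_spec()) {
  stopifnot(inherits(bottle, "bottle_spec"))
  points <- as.data.frame(points)
  if (!"od600" %in% names(points)) points$od600 <- NA_real_
  if (!"v_gas_ml" %in% names(points)) points$v_gas_ml <- 3
  if (!"v_liq_ml" %in% names(points)) points$v_liq_ml <- 1
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(points))
  if (length(missing_cols))
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
  points <- points[MEASUREMENT_COLUMNS]
  for (col in MEASUREMENT_COLUMNS)
    points[[col]] <- suppressWarnings(as.numeric(points[[col]]))

  n <- nrow(points)
  if (n < 1) stop("measurement series is empty")
  t <- points$time_h
  if (anyNA(t) || any(t < 0)) stop("time_h must be non-negative and complete")
  if (n > 1 && any(diff(t) <= 0)) {
    bad <- t[which(diff(t) <= 0) + 1L][1L]
    stop(sprintf("sampling times must be strictly increasing (offending time %g h)", bad))
  }
  if (anyNA(points$p_before_bar) || any(points$p_before_bar <= 0))
    stop("p_before_bar must be positive at every point")
  if (any(points$v_gas_ml < 0, na.rm = TRUE) || any(points$v_liq_ml < 0, na.rm = TRUE))
    stop("sample volumes must be non-negative")
  points$v_gas_ml[is.na(points$v_gas_ml)] <- 0
  points$v_liq_ml[is.na(points$v_liq_ml)] <- 0

  for (col in paste0("x_", GAS_SPECIES)) {
    x <- points[[col]]
    bad <- which(is.na(x) | x < 0 | x > 1)
    if (length(bad))
      stop(sprintf("column %s out of [0,1] at row %d (time %g h)",
                   col, bad[1L], t[bad[1L]]))
  }

  if (anyNA(points$p_after_bar)) {
    idx <- which(is.na(points$p_after_bar))
    vh <- headspace_volume_path(bottle, points$v_liq_ml)
    points$p_after_bar[idx] <-
      points$p_before_bar[idx] * (1 - points$v_gas_ml[idx] / vh[idx])
    warning(sprintf("imputed p_after_bar at %d point(s) from the nominal gas sample volume",
                    length(idx)))
  }
  bad <- which(points$p_after_bar > points$p_before_bar + 1e-12)
  if (length(bad))
    stop(sprintf("p_after_bar exceeds p_before_bar at time %g h (inconsistent manometer readings)",
                 t[bad[1L]]))

  structure(list(bottle = bottle, points = points), class = "measurement_series")
}

# headspace volume at each point: liquid withdrawn at earlier points only
headspace_volume_path <- function(bottle, v_liq) {
  v0 <- bottle$total_volume - bottle$initial_liquid_volume
  v0 + c(0, cumsum(v_liq))[seq_along(v_liq)]
}

#' Headspace volume at a sampling point
#'
#' The gas phase grows as culture is aspirated for OD measurements:
#' `V_h(i) = total - initial_liquid + sum of liquid draws at points before i`.
#' The liquid drawn *at* point `i` does not count yet; pressures recorded at
#' point `i` refer to the pre-aspiration volume.
#'
#' @param bottle a [bottle_spec()].
#' @param series a [measurement_series()].
#' @param index point index (1-based).
#' @return Headspace volume in ml.
#' @export
headspace_volume_at <- function(bottle, series, index) {
  stopifnot(inherits(series, "measurement_series"))
  np <- nrow(series$points)
  if (length(index) != 1 || is.na(index) || index < 1 || index > np)
    stop(sprintf("index must be in 1..%d", np))
  headspace_volume_path(bottle, series$points$v_liq_ml)[index]
}

#' @export
print.measurement_series <- function(x, ...) {
  p <- x$points
  cat(sprintf("Measurement series: %d sampling events over %g h\n",
              nrow(p), max(p$time_h)))
  print(x$bottle)
  print(utils::head(p, 4), row.names = FALSE)
  if (nrow(p) > 4) cat(sprintf("  ... %d more rows\n", nrow(p) - 4))
  invisible(x)
}

#' @export
as.data.frame.measurement_series <- function(x, ...) x$points
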