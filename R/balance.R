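# Withdrawal-corrected headspace mole balance.
#
# All gas quantification happens in the headspace: amounts follow from the
# ideal gas law n_j = x_j * P * V_h / (R * T), and "consumed"/"produced" are
# defined net of sampling withdrawals -- gas that left through the syringe is
# credited back, so cumulative net production Q_j tracks reaction only.

#' Normalize a GC composition
#'
#' GC software reports mole fractions that rarely sum exactly to one;
#' fractions are rescaled proportionally.
#'
#' @param raw named mole fractions over (a subset of) [GAS_SPECIES].
#' @return Named fractions over the full species set summing to 1.
#' @examples
#' normalize_composition(c(co = 0.4, o2 = 0.1, n2 = 0.3))
#' @export
normalize_composition <- function(raw) {
  x <- as_species(raw)
  if (any(x < 0)) stop("mole fractions must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("empty GC record: all mole fractions are zero")
  x / s
}

#' Headspace amounts from the ideal gas law
#'
#' `n_j = x_j * P * V_h / (R * T)` in mmol. For the study's fill state
#' (200 ml headspace, 1 bar, 298.15 K, 50% CO / 50% air) this gives
#' 0.85 mmol O2 and 4.03 mmol CO.
#'
#' @param comp normalized composition (see [normalize_composition()]).
#' @param pressure total pressure (bar).
#' @param headspace_volume gas-phase volume (ml).
#' @param temperature temperature (K).
#' @return Named amounts (mmol) over [GAS_SPECIES].
#' @export
headspace_amounts <- function(comp, pressure, headspace_volume, temperature) {
  if (pressure <= 0 || headspace_volume <= 0 || temperature <= 0)
    stop("pressure, volume and temperature must be positive")
  x <- as_species(comp)
  x * pressure * headspace_volume / (R_GAS * temperature)
}

#' Moles removed by a gas sampling event
#'
#' The syringe draws headspace at bottle pressure; the removed amount per
#' species follows from the measured pressure drop,
#' `removed_j = x_j * (P_before - P_after) * V_h / (R * T)`.
#'
#' @param comp normalized composition at the sampling point.
#' @param pressure_before,pressure_after manometer readings (bar) bracketing
#'   the event; `pressure_after <= pressure_before`.
#' @param headspace_volume gas-phase volume at the event (ml).
#' @param temperature temperature (K).
#' @return Named removed amounts (mmol), all non-negative.
#' @export
withdrawal_amounts <- function(comp, pressure_before, pressure_after,
                               headspace_volume, temperature) {
  if (pressure_after > pressure_before)
    stop("pressure_after exceeds pressure_before: inconsistent manometer readings")
  if (headspace_volume <= 0 || temperature <= 0 || pressure_before <= 0)
    stop("pressure, volume and temperature must be positive")
  x <- as_species(comp)
  x * (pressure_before - pressure_after) * headspace_volume / (R_GAS * temperature)
}

#' Withdrawal-corrected cumulative gas balance
#'
#' The central computation: converts a [measurement_series()] into headspace
#' amounts, a withdrawal ledger and cumulative net production per species,
#'
#' \deqn{Q_j(i) = n_j(i) - n_j(0) + \sum_{k<i} removed_j(k),}
#'
#' where `n` uses each point's pre-sampling pressure at the incubation
#' temperature and the liquid-draw-corrected headspace volume. Negative
#' `Q_j` means net consumption by reaction; gas merely withdrawn through the
#' syringe is neither consumed nor produced. Summary statistics (H2/CO yield,
#' H2 onset, O2 depletion, growth maxima) are derived from the balance.
#'
#' @param series a [measurement_series()] with at least two points.
#' @param onset_threshold cumulative H2 (mmol) above which H2 is called
#'   detected (default 0.02).
#' @param o2_threshold headspace O2 (mmol) below which O2 is called depleted
#'   (default 0.05).
#' @return An object of class `gas_balance`: a per-point table (headspace
#'   volume, amounts `n_*`, removals `rem_*`, cumulative `q_*`) plus a
#'   `summary` list. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_wgs(scenario_preset("abiotic_control"))
#' bal <- gas_balance(sim$series)
#' summary(bal)
#' @export
gas_balance <- function(series, onset_threshold = 0.02, o2_threshold = 0.05) {
  stopifnot(inherits(series, "measurement_series"))
  p <- series$points
  if (nrow(p) < 2) stop("a balance needs at least 2 sampling points")
  bottle <- series$bottle
  temp <- bottle$incubation_temperature
  np <- nrow(p)
  vh <- headspace_volume_path(bottle, p$v_liq_ml)

  n <- matrix(0, np, length(GAS_SPECIES), dimnames = list(NULL, GAS_SPECIES))
  rem <- n
  for (i in seq_len(np)) {
    comp <- normalize_composition(setNames(as.numeric(p[i, paste0("x_", GAS_SPECIES)]),
                                           GAS_SPECIES))
    n[i, ] <- headspace_amounts(comp, p$p_before_bar[i], vh[i], temp)
    rem[i, ] <- withdrawal_amounts(comp, p$p_before_bar[i], p$p_after_bar[i],
                                   vh[i], temp)
  }
  # credit withdrawals at points strictly before i
  rem_before <- apply(rem, 2, function(col) c(0, cumsum(col))[seq_len(np)])
  q <- sweep(n, 2, n[1, ], "-") + rem_before

  tab <- data.frame(time_h = p$time_h, headspace_ml = vh,
                    setNames(as.data.frame(n), paste0("n_", GAS_SPECIES)),
                    setNames(as.data.frame(rem), paste0("rem_", GAS_SPECIES)),
                    setNames(as.data.frame(q), paste0("q_", GAS_SPECIES)))

  qf <- q[np, ]
  yield <- if (qf["co"] < 0) unname(qf["h2"] / -qf["co"]) else NA_real_
  onset <- first_time(p$time_h, q[, "h2"] > onset_threshold)
  depletion <- first_time(p$time_h, n[, "o2"] < o2_threshold)
  growth <- if (all(is.na(p$od600))) {
    list(max_od = NA_real_, max_od_time = NA_real_, final_od = NA_real_)
  } else growth_summary(series)

  structure(list(
    bottle = bottle, series = series, table = tab,
    summary = list(
      yield_h2_per_co = yield,
      h2_onset_time = onset,
      o2_depletion_time = depletion,
      max_od = growth$max_od, max_od_time = growth$max_od_time,
      final_od = growth$final_od,
      final_net_production = setNames(as.numeric(qf), GAS_SPECIES),
      total_withdrawn = setNames(colSums(rem), GAS_SPECIES),
      onset_threshold = onset_threshold, o2_threshold = o2_threshold)),
    class = "gas_balance")
}

first_time <- function(times, hit) {
  i <- which(hit)
  if (length(i)) times[i[1L]] else NA_real_
}

#' Molar H2 yield per CO consumed
#'
#' `Y = Q_H2(final) / (-Q_CO(final))`; defined only when CO was net consumed.
#' Reported to 2 decimals in printed summaries, full precision here.
#'
#' @param balance a [gas_balance()], or a named numeric vector with elements
#'   `h2` and `co` holding final cumulative net production (mmol).
#' @return The dimensionless yield.
#' @examples
#' yield_h2_per_co(c(h2 = 2.47, co = -2.28))  # 1.08 at 2 d.p.
#' @export
yield_h2_per_co <- function(balance) {
  q <- final_q(balance)
  if (!(q["co"] < 0)) stop("no CO was consumed: H2/CO yield is undefined")
  unname(q["h2"] / -q["co"])
}

final_q <- function(balance) {
  if (inherits(balance, "gas_balance"))
    return(balance$summary$final_net_production)
  q <- balance[intersect(names(balance), GAS_SPECIES)]
  if (!all(c("h2", "co") %in% names(q)))
    stop("supply a gas_balance or a named vector with 'h2' and 'co'")
  q
}

#' Time of first detected H2
#'
#' First sampling time at which cumulative net H2 production exceeds the
#' detection threshold (strict inequality); `NA` if never exceeded.
#'
#' @param balance a [gas_balance()].
#' @param threshold detection threshold in mmol (default 0.02).
#' @return Time in hours, or `NA_real_`.
#' @export
detect_h2_onset <- function(balance, threshold = 0.02) {
  stopifnot(inherits(balance, "gas_balance"), threshold > 0)
  first_time(balance$table$time_h, balance$table$q_h2 > threshold)
}

#' Time of O2 depletion
#'
#' First sampling time at which the headspace O2 amount falls strictly below
#' the threshold; `NA` if it never does.
#'
#' @param balance a [gas_balance()].
#' @param threshold depletion threshold in mmol (default 0.05).
#' @return Time in hours, or `NA_real_`.
#' @export
o2_depletion_time <- function(balance, threshold = 0.05) {
  stopifnot(inherits(balance, "gas_balance"))
  first_time(balance$table$time_h, balance$table$n_o2 < threshold)
}

#' Growth summary from the OD column
#'
#' Maximum OD600, the time it was (first) reached, and the last recorded OD.
#' Points without an OD reading are skipped.
#'
#' @param series a [measurement_series()] (or a [gas_balance()], whose series
#'   is used).
#' @return A list with `max_od`, `max_od_time`, `final_od`.
#' @export
growth_summary <- function(series) {
  if (inherits(series, "gas_balance")) series <- series$series
  stopifnot(inherits(series, "measurement_series"))
  p <- series$points
  ok <- !is.na(p$od600)
  if (!any(ok)) stop("no OD600 values recorded in this series")
  od <- p$od600[ok]; t <- p$time_h[ok]
  imax <- which.max(od)  # earliest maximum on ties
  list(max_od = od[imax], max_od_time = t[imax], final_od = od[length(od)])
}

#' @export
print.gas_balance <- function(x, ...) {
  s <- x$summary
  tab <- x$table
  cat(sprintf("Gas balance: %d points, %g h, %s\n", nrow(tab), max(tab$time_h),
              format(x$bottle$total_volume)))
  fmt_t <- function(v) if (is.na(v)) "not reached" else sprintf("%.2f h", v)
  q <- s$final_net_production
  cat(sprintf("  net production at %g h (mmol): H2 %+.2f  O2 %+.2f  CO %+.2f  CO2 %+.2f  N2 %+.2f\n",
              max(tab$time_h), q["h2"], q["o2"], q["co"], q["co2"], q["n2"]))
  cat(sprintf("  H2/CO yield: %s\n",
              if (is.na(s$yield_h2_per_co)) "undefined (no CO consumed)"
              else sprintf("%.2f", s$yield_h2_per_co)))
  cat(sprintf("  H2 onset (> %g mmol): %s   O2 depletion (< %g mmol): %s\n",
              s$onset_threshold, fmt_t(s$h2_onset_time),
              s$o2_threshold, fmt_t(s$o2_depletion_time)))
  if (!is.na(s$max_od))
    cat(sprintf("  growth: max OD600 %.2f at %.2f h, final %.2f\n",
                s$max_od, s$max_od_time, s$final_od))
  invisible(x)
}

#' @export
summary.gas_balance <- function(object, ...) object$summary

#' @export
as.data.frame.gas_balance <- function(x, ...) x$table

#' Quick-look plot of a gas balance
#'
#' Headspace amounts per species over time, with OD600 on a secondary axis
#' when available.
#'
#' @param x a [gas_balance()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gas_balance <- function(x, ...) {
  tab <- x$table
  amounts <- as.matrix(tab[paste0("n_", GAS_SPECIES)])
  op <- par(mar = c(4, 4, 1, 4)); on.exit(par(op))
  matplot(tab$time_h, amounts, type = "b", pch = 1, lty = 1,
          xlab = "time (h)", ylab = "headspace amount (mmol)", ...)
  legend("right", legend = toupper(GAS_SPECIES), col = seq_along(GAS_SPECIES),
         lty = 1, bty = "n", cex = 0.8)
  od <- x$series$points$od600
  if (any(!is.na(od))) {
    usr <- par("usr")
    sc <- max(amounts) / max(od, na.rm = TRUE)
    lines(tab$time_h, od * sc, lty = 2)
    axis(4, at = pretty(od, 4) * sc, labels = pretty(od, 4))
  }
  invisible(x)
}
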