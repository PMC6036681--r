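# Headspace accounting: ideal-gas conversions, withdrawal crediting and the
# derived summaries.

test_that("composition normalization rescales proportionally and rejects empty records", {
  x <- normalize_composition(c(co = 0.5, o2 = 0.105, n2 = 0.395))
  expect_equal(sum(x), 1)
  expect_equal(unname(x["co"]), 0.5)

  x <- normalize_composition(c(co = 1))
  expect_equal(unname(x["co"]), 1)

  x <- normalize_composition(c(co = 0.4, o2 = 0.1, n2 = 0.3))  # sums to 0.8
  expect_equal(unname(x[c("co", "o2", "n2")]), c(0.5, 0.125, 0.375))

  expect_error(normalize_composition(c(co = 0, o2 = 0)), "empty GC record")
  expect_error(normalize_composition(c(co = -0.1, o2 = 0.5)), "non-negative")
})

test_that("headspace amounts follow the ideal gas law", {
  n <- headspace_amounts(c(co = 0.5, n2 = 0.5), pressure = 1, 200, 298.15)
  expect_equal(unname(n["co"]), 0.5 * 1 * 200 / (0.0831446 * 298.15),
               tolerance = 1e-12)
  expect_equal(unname(round(n["co"], 3)), 4.034)
  expect_equal(unname(n["h2"]), 0)
  expect_equal(sum(n), 1 * 200 / (0.0831446 * 298.15))

  # 50% air fill: x_O2 = 0.5 * 0.21 -> the published initial O2
  n <- headspace_amounts(c(co = 0.5, o2 = 0.105, n2 = 0.395), 1, 200, 298.15)
  expect_equal(unname(round(n["o2"], 2)), 0.85)

  expect_error(headspace_amounts(c(co = 1), -1, 200, 298.15), "positive")
})

test_that("withdrawal amounts track the measured pressure drop", {
  z <- withdrawal_amounts(c(co = 1), 1, 1, 200, 333.15)
  expect_true(all(z == 0))

  w <- withdrawal_amounts(c(co = 0.5, n2 = 0.5), 1.015, 1.000, 200, 333.15)
  expect_equal(unname(w["co"]), 0.5 * 0.015 * 200 / (0.0831446 * 333.15),
               tolerance = 1e-12)
  expect_equal(unname(round(w["co"], 4)), 0.0542)

  # a 3 ml draw at 1 bar from 200 ml drops the pressure by 1.5%; the syringe
  # holds 3 ml at bottle pressure: n = 1.0 * 3 / (R * 333.15)
  dp <- 1.0 * 3 / 200
  w <- withdrawal_amounts(c(co = 0.5, n2 = 0.5), 1, 1 - dp, 200, 333.15)
  expect_equal(unname(round(sum(w), 4)), 0.1083)
  # total removed equals dP * V / (R T) exactly
  expect_equal(sum(w), dp * 200 / (0.0831446 * 333.15), tolerance = 1e-9)

  expect_error(withdrawal_amounts(c(co = 1), 1.0, 1.1, 200, 333.15),
               "inconsistent manometer")
})

test_that("headspace volume grows with prior liquid draws only", {
  rows <- lapply(0:5, function(i) mrow(i, 1, 0.985, c(co = 1), v_liq = 1))
  s <- make_series(rows)
  expect_equal(headspace_volume_at(s$bottle, s, 1), 200)
  expect_equal(headspace_volume_at(s$bottle, s, 6), 205)
  expect_error(headspace_volume_at(s$bottle, s, 7), "index")

  rows0 <- lapply(0:3, function(i) mrow(i, 1, 0.985, c(co = 1), v_liq = 0))
  s0 <- make_series(rows0)
  expect_equal(sapply(1:4, function(i) headspace_volume_at(s0$bottle, s0, i)),
               rep(200, 4))
})

test_that("cumulative balance reproduces an explicit toy mole ledger", {
  # point 0 holds 2.0 mmol CO; the sampling removes 0.1 mmol CO; at point 1
  # only 1.5 mmol remain: 0.4 mmol reacted, 0.1 mmol merely withdrawn.
  R <- 0.0831446; temp <- 333.15; vh <- 200
  p0 <- 2.0 * R * temp / vh
  dp <- 0.1 * R * temp / vh
  p1 <- 1.5 * R * temp / (vh + 1)
  s <- make_series(list(
    mrow(0, p0, p0 - dp, c(co = 1), v_liq = 1),
    mrow(10, p1, p1, c(co = 1), v_liq = 1)))
  bal <- gas_balance(s)
  tab <- as.data.frame(bal)
  expect_equal(tab$q_co[1], 0)
  expect_equal(tab$q_co[2], -0.4, tolerance = 1e-9)
  expect_equal(tab$rem_co[1], 0.1, tolerance = 1e-9)
})

test_that("two identical points without withdrawal balance to zero", {
  s <- make_series(list(
    mrow(0, 1, 1, c(co = 0.5, n2 = 0.5), v_gas = 0, v_liq = 0),
    mrow(5, 1, 1, c(co = 0.5, n2 = 0.5), v_gas = 0, v_liq = 0)))
  q <- as.matrix(as.data.frame(gas_balance(s))[paste0("q_", GAS_SPECIES)])
  expect_true(all(abs(q) < 1e-12))
})

test_that("cumulative balance agrees with the brute-force ledger oracle on short series", {
  set.seed(42)
  for (trial in 1:20) {
    npts <- sample(2:5, 1)
    rows <- list()
    pb <- 1.1
    for (i in seq_len(npts)) {
      x <- runif(5); x <- x / sum(x)
      pa <- pb * runif(1, 0.97, 1.0)
      rows[[i]] <- mrow((i - 1) * 4, pb, pa,
                        setNames(x, c("h2", "o2", "n2", "co", "co2")),
                        v_liq = sample(0:2, 1))
      pb <- pa * runif(1, 0.95, 1.05)
    }
    s <- make_series(rows)
    got <- as.matrix(as.data.frame(gas_balance(s))[paste0("q_", GAS_SPECIES)])
    want <- ledger_oracle(s)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("yield, onset, depletion and growth summaries behave per contract", {
  expect_equal(round(yield_h2_per_co(c(h2 = 2.47, co = -2.28)), 2), 1.08)
  expect_equal(yield_h2_per_co(c(h2 = 1, co = -1)), 1)
  expect_equal(round(yield_h2_per_co(c(h2 = 0, co = -0.37)), 2), 0)
  expect_error(yield_h2_per_co(c(h2 = 1, co = 0.2)), "undefined")

  # balance with a known Q_H2 path: 0, 0.01, 0.05 at 0/10/20 h
  R <- 0.0831446; temp <- 333.15; vh <- 200
  n2p <- function(n, v = vh) n * R * temp / v
  s <- make_series(list(
    mrow(0, n2p(5), n2p(5), c(n2 = 1), od = 0.5, v_liq = 0),
    mrow(10, n2p(5.01), n2p(5.01), c(h2 = 0.01 / 5.01, n2 = 5 / 5.01),
         od = 0.5, v_liq = 0),
    mrow(20, n2p(5.05), n2p(5.05), c(h2 = 0.05 / 5.05, n2 = 5 / 5.05),
         od = 0.3, v_liq = 0)))
  bal <- gas_balance(s)
  expect_equal(detect_h2_onset(bal, 0.02), 20)
  expect_true(is.na(detect_h2_onset(bal, 1)))
  expect_true(is.na(o2_depletion_time(bal, 0)))  # strict inequality

  g <- growth_summary(s)
  expect_equal(g, list(max_od = 0.5, max_od_time = 0, final_od = 0.3))
  s_no_od <- make_series(list(mrow(0, 1, 1, c(n2 = 1), v_liq = 0),
                              mrow(5, 1, 1, c(n2 = 1), v_liq = 0)))
  expect_error(growth_summary(s_no_od), "no OD600")
})

test_that("growth summary ties resolve to the earliest time and NAs are skipped", {
  s <- make_series(list(
    mrow(0, 1, 1, c(n2 = 1), od = 0.5, v_liq = 0),
    mrow(5, 1, 1, c(n2 = 1), od = NA, v_liq = 0),
    mrow(9, 1, 1, c(n2 = 1), od = 0.5, v_liq = 0)))
  g <- growth_summary(s)
  expect_equal(g$max_od_time, 0)
  expect_equal(g$final_od, 0.5)
})
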