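# Independent oracles used across the suite. These deliberately share no code
# with the package internals.

# Brute-force mole ledger: explicit per-event bookkeeping of a measurement
# series, enumerating every withdrawal and state one by one.
ledger_oracle <- function(series) {
  b <- series$bottle
  p <- series$points
  R <- 0.0831446
  temp <- b$incubation_temperature
  species <- c("h2", "o2", "n2", "co", "co2")
  vh <- b$total_volume - b$initial_liquid_volume
  withdrawn <- setNames(numeric(5), species)
  q <- matrix(NA_real_, nrow(p), 5, dimnames = list(NULL, species))
  n0 <- NULL
  for (i in seq_len(nrow(p))) {
    x <- as.numeric(p[i, paste0("x_", species)])
    x <- x / sum(x)
    n_i <- x * p$p_before_bar[i] * vh / (R * temp)
    if (i == 1) n0 <- n_i
    q[i, ] <- n_i - n0 + withdrawn
    rem <- x * (p$p_before_bar[i] - p$p_after_bar[i]) * vh / (R * temp)
    withdrawn <- withdrawn + rem
    vh <- vh + p$v_liq_ml[i]
  }
  q
}

# Exhaustive local-alignment score: maximizes over every gapped local
# alignment of a against b under affine gap costs (a gap of length L costs
# open + L * ext). Memoized exhaustive recursion, independent of any
# alignment engine.
exhaustive_local_score <- function(a, b, submat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0  # stop the alignment here
    if (i <= na && j <= nb)
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    if (i <= na)  # a[i] against a gap in b
      best <- max(best, -(if (last == "ga") ext else open + ext) + rec(i + 1, j, "ga"))
    if (j <= nb)  # gap in a against b[j]
      best <- max(best, -(if (last == "gb") ext else open + ext) + rec(i, j + 1, "gb"))
    memo[[key]] <- best
    best
  }
  best_overall <- 0
  for (i in seq_len(na)) for (j in seq_len(nb))
    best_overall <- max(best_overall, rec(i, j, "s"))
  best_overall
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# small hand-made series builder
make_series <- function(rows, bottle = bottle_spec()) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  measurement_series(df, bottle)
}

mrow <- function(time, pb, pa, x, od = NA, v_gas = 3, v_liq = 1) {
  xx <- setNames(numeric(5), c("x_h2", "x_o2", "x_n2", "x_co", "x_co2"))
  xx[paste0("x_", names(x))] <- x
  c(time_h = time, p_before_bar = pb, p_after_bar = pa, xx, od600 = od,
    v_gas_ml = v_gas, v_liq_ml = v_liq)
}
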