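# Kinetic simulator of a facultatively anaerobic carboxydotroph in a closed
# bottle: aerobic growth on a finite substrate pool, respiration, an
# O2-inhibited water-gas-shift (WGS) reaction, optional aerobic CO oxidation,
# an unattributed first-order aerobic CO loss, and fermentative H2 from a
# finite formate pool (formate hydrogenlyase, FHL). Kinetics act on headspace
# partial pressures; gas-liquid transfer is lumped into the apparent rate
# constants.

#' Kinetic rate constants for the bottle model
#'
#' All rates are expressed per OD600 unit of biomass; Monod constants are
#' partial pressures in bar. Defaults describe an inert bottle (all rates
#' zero); presets in [scenario_preset()] carry calibrated values.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_O2 O2 Monod constant for growth and respiration (bar).
#' @param k_d specific decline rate once O2 is spent (1/h).
#' @param q_o2 respiration rate (mmol O2/h per OD unit).
#' @param y_co2_per_o2 respiratory CO2 released per O2 consumed
#'   (dimensionless; CO2 dissolution is absorbed into this coefficient).
#' @param q_wgs water-gas-shift rate (mmol CO/h per OD unit).
#' @param K_CO CO Monod constant (bar).
#' @param K_I_O2 O2 inhibition constant of the CODH/hydrogenase complex
#'   (bar); the WGS and FHL rates are scaled by `K_I_O2 / (K_I_O2 + p_O2)`.
#' @param q_aco aerobic CO oxidation rate (mmol CO/h per OD unit; consumes
#'   0.5 O2 per CO).
#' @param k_co_loss unattributed first-order aerobic CO loss (1/h).
#' @param formate_pool initial formate available to FHL (mmol).
#' @param q_fhl formate hydrogenlyase rate (mmol/h per OD unit).
#' @param K_F formate half-saturation (mmol).
#' @param substrate_pool finite growth substrate in OD600-equivalent units;
#'   `Inf` disables substrate limitation.
#' @param K_S substrate half-saturation (OD600-equivalent units).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max = 0, K_O2 = 0.01, k_d = 0, q_o2 = 0,
                           y_co2_per_o2 = 0.45, q_wgs = 0, K_CO = 0.05,
                           K_I_O2 = 1e-4, q_aco = 0, k_co_loss = 0,
                           formate_pool = 0, q_fhl = 0, K_F = 0.01,
                           substrate_pool = Inf, K_S = 0.02) {
  p <- as.list(environment())
  rates <- c("mu_max", "k_d", "q_o2", "q_wgs", "q_aco", "k_co_loss", "q_fhl",
             "y_co2_per_o2", "formate_pool")
  if (any(unlist(p[rates]) < 0)) stop("rate constants and pools must be non-negative")
  if (any(unlist(p[c("K_O2", "K_CO", "K_I_O2", "K_F", "K_S")]) <= 0))
    stop("half-saturation constants must be positive")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (rates per OD600 unit):\n")
  v <- unlist(x)
  cat(paste0("  ", names(v), " = ", signif(v, 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Observation-noise settings
#'
#' @param gc_cv multiplicative coefficient of variation on GC mole fractions
#'   (renormalized after perturbation).
#' @param pressure_sd_bar additive Gaussian noise on manometer readings (bar).
#' @param od_sd additive Gaussian noise on OD600.
#' @return A list usable as the `noise` field of [wgs_scenario()].
#' @export
wgs_noise <- function(gc_cv = 0, pressure_sd_bar = 0, od_sd = 0) {
  stopifnot(gc_cv >= 0, pressure_sd_bar >= 0, od_sd >= 0)
  list(gc_cv = gc_cv, pressure_sd_bar = pressure_sd_bar, od_sd = od_sd)
}

#' Configure a simulated cultivation
#'
#' @param name scenario label.
#' @param bottle a [bottle_spec()].
#' @param initial_amounts named initial headspace amounts (mmol) over
#'   [GAS_SPECIES]; see [initial_headspace_amounts()].
#' @param initial_od OD600 at inoculation.
#' @param sampling_times strictly increasing sampling schedule (h); every gap
#'   must be a multiple of `integration_step`.
#' @param gas_sample_volume headspace volume drawn per event (ml).
#' @param liquid_sample_volume culture volume aspirated per event (ml).
#' @param noise a [wgs_noise()] list.
#' @param seed integer seed for the observation noise generator.
#' @param integration_step fixed RK4 step (h).
#' @return An object of class `wgs_scenario`.
#' @export
wgs_scenario <- function(name = "custom", bottle = bottle_spec(),
                         initial_amounts, initial_od = 0.05,
                         sampling_times = c(seq(0, 48, by = 4), 60, 72, 84),
                         gas_sample_volume = 3, liquid_sample_volume = 1,
                         noise = wgs_noise(), seed = 1L,
                         integration_step = 0.01) {
  if (any(diff(sampling_times) <= 0)) stop("sampling_times must be strictly increasing")
  if (integration_step <= 0) stop("integration_step must be positive")
  if (length(sampling_times) > 1 &&
      integration_step > min(diff(sampling_times)) + 1e-12)
    stop("integration_step exceeds the smallest sampling gap")
  amounts <- as_species(initial_amounts)
  if (any(amounts < 0)) stop("initial amounts must be non-negative")
  if (initial_od < 0) stop("initial_od must be non-negative")
  if (gas_sample_volume < 0 || liquid_sample_volume < 0)
    stop("sample volumes must be non-negative")
  structure(list(name = name, bottle = bottle, initial_amounts = amounts,
                 initial_od = initial_od, sampling_times = sampling_times,
                 gas_sample_volume = gas_sample_volume,
                 liquid_sample_volume = liquid_sample_volume,
                 noise = noise, seed = as.integer(seed),
                 integration_step = integration_step),
            class = "wgs_scenario")
}

# deSolve-compatible right-hand side. State: biomass X, substrate S
# (OD-equivalents), headspace mmol h2/o2/n2/co/co2, formate F, and cumulative
# pathway integrals c_wgs (CO through WGS), c_resp (O2 respired), c_aco (CO
# aerobically oxidized), c_fhl (formate split), c_loss (CO lost first-order).
wgs_derivs <- function(t, state, parms) {
  if (any(state < -1e-8, na.rm = TRUE))
    stop("negative state in kinetic model at t = ", signif(t, 6))
  kp <- parms$params
  s <- pmax(state, 0)
  rt_v <- R_GAS * parms$temperature / parms$headspace_ml
  p_o2 <- s[["o2"]] * rt_v
  p_co <- s[["co"]] * rt_v
  f_o2 <- p_o2 / (kp$K_O2 + p_o2)
  f_co <- p_co / (kp$K_CO + p_co)
  inhib <- kp$K_I_O2 / (kp$K_I_O2 + p_o2)
  limited <- is.finite(kp$substrate_pool)
  f_s <- if (limited) s[["S"]] / (kp$K_S + s[["S"]]) else 1
  f_f <- s[["Fp"]] / (kp$K_F + s[["Fp"]])
  X <- s[["X"]]

  r_grow <- kp$mu_max * f_o2 * f_s * X
  r_dec  <- kp$k_d * (1 - f_o2) * X
  r_resp <- kp$q_o2 * f_o2 * X
  r_wgs  <- kp$q_wgs * f_co * inhib * X
  r_aco  <- kp$q_aco * f_co * f_o2 * X
  r_loss <- kp$k_co_loss * f_o2 * s[["co"]]
  r_fhl  <- kp$q_fhl * inhib * f_f * X

  list(c(
    X = r_grow - r_dec,
    S = if (limited) -r_grow else 0,
    h2 = r_wgs + r_fhl,
    o2 = -r_resp - 0.5 * r_aco,
    n2 = 0,
    co = -(r_wgs + r_aco + r_loss),
    co2 = r_wgs + r_aco + r_loss + kp$y_co2_per_o2 * r_resp + r_fhl,
    Fp = -r_fhl,
    c_wgs = r_wgs, c_resp = r_resp, c_aco = r_aco, c_fhl = r_fhl,
    c_loss = r_loss))
}

#' Kinetic rates of the bottle model
#'
#' Evaluates the model right-hand side once: Monod terms on O2 and CO partial
#' pressures, competitive O2 inhibition of the CODH-hydrogenase complex
#' (`K_I_O2 / (K_I_O2 + p_O2)`), substrate-limited growth and the WGS /
#' respiration / aerobic-CO-oxidation / FHL pathway rates. Mainly useful for
#' inspecting stoichiometry; [simulate_wgs()] integrates it.
#'
#' @param state named numeric: `X`, `S`, `h2`, `o2`, `n2`, `co`, `co2`, `Fp`
#'   (formate, mmol). Cumulative-integral slots are added if absent.
#' @param params a [kinetic_params()].
#' @param bottle a [bottle_spec()] (provides temperature).
#' @param headspace_ml current headspace volume (ml).
#' @return Named derivative vector (per hour).
#' @export
wgs_rates <- function(state, params, bottle = bottle_spec(),
                      headspace_ml = bottle$total_volume - bottle$initial_liquid_volume) {
  stopifnot(inherits(params, "kinetic_params"))
  full <- setNames(numeric(13),
                   c("X", "S", "h2", "o2", "n2", "co", "co2", "Fp",
                     "c_wgs", "c_resp", "c_aco", "c_fhl", "c_loss"))
  full["S"] <- if (is.finite(params$substrate_pool)) params$substrate_pool else 0
  full[names(state)] <- state
  d <- wgs_derivs(0, full, list(params = params, headspace_ml = headspace_ml,
                                temperature = bottle$incubation_temperature))[[1]]
  setNames(as.numeric(d), names(full))
}

#' Simulate a closed-bottle cultivation with sampling withdrawals
#'
#' Integrates the kinetic model with fixed-step 4th-order Runge-Kutta
#' (via [deSolve::ode()]) between sampling times. At each sampling time the
#' observation layer records pressure, GC fractions and OD (optionally with
#' seeded Gaussian noise), removes `gas_sample_volume` of headspace at bottle
#' pressure, records the post-removal pressure, and then enlarges the
#' headspace by the aspirated liquid volume. With zero noise the output is
#' bit-reproducible.
#'
#' @param scenario a [wgs_scenario()], or the list returned by
#'   [scenario_preset()] (its `params` are then used).
#' @param params a [kinetic_params()]; defaults to the preset's params when
#'   `scenario` is a preset bundle.
#' @return An object of class `wgs_simulation`: `series` (a
#'   [measurement_series()] of the observed data), and `truth` with the dense
#'   `trajectory`, the per-event withdrawal `ledger` (mmol per species), and
#'   `pathways`, the cumulative pathway integrals at the end of the run.
#' @examples
#' sim <- simulate_wgs(scenario_preset("abiotic_control"))
#' gas_balance(sim$series)
#' @export
simulate_wgs <- function(scenario, params = NULL) {
  if (is.list(scenario) && !inherits(scenario, "wgs_scenario") &&
      !is.null(scenario$scenario)) {
    if (is.null(params)) params <- scenario$params
    scenario <- scenario$scenario
  }
  stopifnot(inherits(scenario, "wgs_scenario"))
  if (is.null(params)) params <- kinetic_params()
  stopifnot(inherits(params, "kinetic_params"))

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(scenario$seed)

  bottle <- scenario$bottle
  temp <- bottle$incubation_temperature
  vh <- bottle$total_volume - bottle$initial_liquid_volume
  noise <- scenario$noise
  times <- scenario$sampling_times
  nt <- length(times)

  state <- c(X = scenario$initial_od,
             S = if (is.finite(params$substrate_pool)) params$substrate_pool else 0,
             scenario$initial_amounts["h2"], scenario$initial_amounts["o2"],
             scenario$initial_amounts["n2"], scenario$initial_amounts["co"],
             scenario$initial_amounts["co2"], Fp = params$formate_pool,
             c_wgs = 0, c_resp = 0, c_aco = 0, c_fhl = 0, c_loss = 0)

  obs <- vector("list", nt)
  ledger <- matrix(0, nt, length(GAS_SPECIES), dimnames = list(NULL, GAS_SPECIES))
  traj <- list()
  pathways_at <- matrix(0, nt, 5,
                        dimnames = list(NULL, c("c_wgs", "c_resp", "c_aco",
                                                "c_fhl", "c_loss")))

  perturb <- function(x, sd) if (sd > 0) x + rnorm(length(x), 0, sd) else x

  for (k in seq_len(nt)) {
    # ---- observe (pre-sampling) ----
    n_gas <- state[GAS_SPECIES]
    n_tot <- sum(n_gas)
    p_true <- n_tot * R_GAS * temp / vh
    x_true <- n_gas / n_tot
    p_obs <- perturb(p_true, noise$pressure_sd_bar)
    x_obs <- x_true
    if (noise$gc_cv > 0) {
      x_obs <- pmax(x_true * (1 + rnorm(length(x_true), 0, noise$gc_cv)), 0)
      x_obs <- x_obs / sum(x_obs)
    }
    od_obs <- max(perturb(state[["X"]], noise$od_sd), 0)

    # ---- withdraw gas at bottle pressure ----
    if (scenario$gas_sample_volume >= vh)
      stop("oversampled: gas sample volume exceeds the headspace")
    frac <- scenario$gas_sample_volume / vh
    removed <- n_gas * frac
    if (any(n_gas - removed < -1e-12)) stop("oversampled: negative amounts after removal")
    state[GAS_SPECIES] <- n_gas - removed
    ledger[k, ] <- removed
    p_after_true <- sum(state[GAS_SPECIES]) * R_GAS * temp / vh
    p_after_obs <- min(perturb(p_after_true, noise$pressure_sd_bar), p_obs)

    obs[[k]] <- c(time_h = times[k], p_before_bar = p_obs,
                  p_after_bar = p_after_obs,
                  setNames(as.numeric(x_obs), paste0("x_", GAS_SPECIES)),
                  od600 = od_obs, v_gas_ml = scenario$gas_sample_volume,
                  v_liq_ml = scenario$liquid_sample_volume)
    pathways_at[k, ] <- state[colnames(pathways_at)]

    # ---- liquid draw enlarges the headspace ----
    vh <- vh + scenario$liquid_sample_volume

    # ---- integrate to the next sampling time ----
    if (k < nt) {
      grid <- seq(times[k], times[k + 1], by = scenario$integration_step)
      if (abs(grid[length(grid)] - times[k + 1]) > 1e-9)
        stop(sprintf("sampling gap %g-%g h is not a multiple of the integration step",
                     times[k], times[k + 1]))
      sol <- deSolve::ode(y = state, times = grid, func = wgs_derivs,
                          parms = list(params = params, headspace_ml = vh,
                                       temperature = temp),
                          method = "rk4")
      seg <- as.data.frame(sol)
      seg$headspace_ml <- vh
      traj[[k]] <- seg
      state <- setNames(as.numeric(sol[nrow(sol), -1]), names(state))
      if (any(state < -1e-9)) stop("integration produced negative amounts")
      state <- pmax(state, 0)
    }
  }

  trajectory <- do.call(rbind, traj)
  if (is.null(trajectory)) trajectory <- data.frame()
  obs_df <- as.data.frame(do.call(rbind, obs))
  series <- measurement_series(obs_df, bottle)

  structure(list(
    series = series,
    truth = list(trajectory = trajectory, ledger = ledger,
                 pathways_at_sampling = data.frame(time_h = times, pathways_at),
                 pathways = setNames(as.numeric(state[colnames(pathways_at)]),
                                     colnames(pathways_at)),
                 final_state = state),
    scenario = scenario, params = params),
    class = "wgs_simulation")
}

#' @export
print.wgs_simulation <- function(x, ...) {
  cat(sprintf("Simulated cultivation '%s': %d sampling events over %g h\n",
              x$scenario$name, length(x$scenario$sampling_times),
              max(x$scenario$sampling_times)))
  gt <- ground_truth_balance(x)
  cat(sprintf("  true reacted (mmol): CO %.3f consumed, H2 %.3f produced, CO2 %.3f produced\n",
              -gt$q["co"], gt$q["h2"], gt$q["co2"]))
  invisible(x)
}

#' Ground-truth balance of a simulation
#'
#' Reads the simulator's internal pathway integrals and withdrawal ledger and
#' expresses them in the same cumulative-net-production convention as
#' [gas_balance()]: `q` is signed net production per species due to reaction
#' only (withdrawn gas excluded), so a correct accounting pipeline applied to
#' the noise-free observations must recover `q`.
#'
#' @param sim a [simulate_wgs()] result.
#' @return List with `q` (named signed mmol per species), `withdrawn` (ledger
#'   column sums), and `pathways` (cumulative mmol through each pathway).
#' @export
ground_truth_balance <- function(sim) {
  stopifnot(inherits(sim, "wgs_simulation"))
  pw <- sim$truth$pathways
  y <- sim$params$y_co2_per_o2
  q <- c(h2 = pw[["c_wgs"]] + pw[["c_fhl"]],
         o2 = -(pw[["c_resp"]] + 0.5 * pw[["c_aco"]]),
         n2 = 0,
         co = -(pw[["c_wgs"]] + pw[["c_aco"]] + pw[["c_loss"]]),
         co2 = pw[["c_wgs"]] + pw[["c_aco"]] + pw[["c_loss"]] +
           y * pw[["c_resp"]] + pw[["c_fhl"]])
  list(q = q[GAS_SPECIES], withdrawn = colSums(sim$truth$ledger),
       pathways = pw)
}
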