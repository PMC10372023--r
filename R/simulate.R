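#' Growth-simulation parameters for a synthetic cohort
#'
#' Defaults describe the package's reference murine-carcinoma-like cohort:
#' enrollment at ~60 mm^3, Gompertz growth toward a carrying capacity, caliper
#' measurements every 2 days over a 20-day study, and mild multiplicative
#' measurement noise. See the methods vignette for how these values were
#' fixed.
#'
#' @param V0 Enrollment volume, mm^3.
#' @param a Gompertz rate constant, day^-1.
#' @param K Carrying capacity, mm^3 (must exceed `V0`).
#' @param noise_cv Lognormal coefficient of variation of a measured volume
#'   (0 = noiseless). Noise is applied at measurement, not to the latent
#'   trajectory.
#' @param step Measurement interval, days.
#' @param horizon Last measurement day.
#' @return A `growth_sim_params` list.
#' @export
growth_sim_params <- function(V0 = 60, a = 0.03, K = 4000, noise_cv = 0.05,
                              step = 2L, horizon = 20L) {
  stopifnot(V0 > 0, K > V0, a > 0, noise_cv >= 0, step >= 1, horizon >= step)
  structure(list(V0 = V0, a = a, K = K, noise_cv = noise_cv,
                 step = as.integer(step), horizon = as.integer(horizon)),
            class = "growth_sim_params")
}

#' Phenomenological treatment effect of an irradiation event
#'
#' Each irradiation adds an exponentially decaying death-rate pulse to the
#' growth equation: from `onset_lag` days after the event (adaptive responses
#' need days to expand), the extra per-capita death rate is
#' \eqn{A_i e^{-(t - t_i - \mathrm{lag})/\tau_\mathrm{eff}}}. The first
#' (vaccination-day) event has amplitude `k0`. Booster amplitudes are
#' attenuated by two factors: vaccine-depot decay
#' \eqn{e^{-(t_i - t_1)/\tau_\mathrm{vax}}} (the injected depot is metabolised
#' over time, so late boosts re-heat less antigen) and refractory blunting
#' \eqn{1 - e^{-\Delta/\tau_\mathrm{refract}}} where \eqn{\Delta} is the gap
#' to the previous event (re-irradiating while the prior response is still
#' expanding adds little). Together these give boosting an interior optimum
#' in time, the behaviour growth-rate-guided scheduling exploits.
#'
#' @param k0 Peak extra death rate of the first event, day^-1 (0 disables
#'   treatment entirely).
#' @param tau_eff Decay time of each pulse, days.
#' @param onset_lag Delay between irradiation and effect onset, days.
#' @param vax_decay Vaccine-depot decay time for booster amplitude, days.
#' @param refractory Refractory time constant for booster amplitude, days.
#' @return A `treatment_effect` list.
#' @export
treatment_effect <- function(k0 = 0.25, tau_eff = 6, onset_lag = 3,
                             vax_decay = 15, refractory = 5) {
  stopifnot(k0 >= 0, tau_eff > 0, onset_lag >= 0, vax_decay > 0, refractory > 0)
  structure(list(k0 = k0, tau_eff = tau_eff, onset_lag = onset_lag,
                 vax_decay = vax_decay, refractory = refractory),
            class = "treatment_effect")
}

#' An irradiation event
#'
#' @param day Day of irradiation (integer, day 0 = vaccination).
#' @param duration Minutes of exposure.
#' @param power_density W/cm^2.
#' @param wavelength nm.
#' @param setpoint_temp Target skin temperature, degrees C.
#' @return A one-row data.frame.
#' @export
irradiation_event <- function(day, duration = 20, power_density = 0.65,
                              wavelength = 808, setpoint_temp = 41) {
  stopifnot(duration > 0, power_density > 0)
  data.frame(day = as.integer(day), duration = duration,
             power_density = power_density, wavelength = wavelength,
             setpoint_temp = setpoint_temp)
}

# Pulse amplitudes for an ordered vector of event days. First event carries
# the full k0; boosters are attenuated by depot decay (time since the first
# event) and refractory blunting (gap to the previous event).
event_amplitudes <- function(event_days, effect) {
  if (length(event_days) == 0L) return(numeric(0))
  ed <- sort(event_days)
  amp <- numeric(length(ed))
  amp[1L] <- effect$k0
  if (length(ed) > 1L) {
    for (i in 2:length(ed)) {
      depot <- exp(-(ed[i] - ed[1L]) / effect$vax_decay)
      refract <- 1 - exp(-(ed[i] - ed[i - 1L]) / effect$refractory)
      amp[i] <- effect$k0 * depot * refract
    }
  }
  amp
}

# Total extra death rate k(t) from all events (vectorised in t).
kill_rate <- function(t, event_days, effect) {
  if (is.null(effect) || length(event_days) == 0L || effect$k0 == 0) {
    return(rep(0, length(t)))
  }
  ed <- sort(event_days)
  amp <- event_amplitudes(ed, effect)
  k <- rep(0, length(t))
  for (i in seq_along(ed)) {
    s <- t - ed[i] - effect$onset_lag
    on <- s >= 0
    k[on] <- k[on] + amp[i] * exp(-s[on] / effect$tau_eff)
  }
  k
}

#' Closed-form Gompertz volume
#'
#' \deqn{V(t) = K \exp\!\big(\ln(V_0/K)\, e^{-a t}\big)}
#' The untreated latent trajectory of the simulator; used as the analytic
#' oracle for the numerical integrator.
#'
#' @param params A [growth_sim_params()].
#' @param t Time(s) in days.
#' @return Volume(s), mm^3.
#' @export
gompertz_closed_form <- function(params, t) {
  stopifnot(inherits(params, "growth_sim_params"))
  params$K * exp(log(params$V0 / params$K) * exp(-params$a * t))
}

# Fixed-step RK4 for dV/dt = a V ln(K/V) - k(t) V from t0 to t1.
# Deterministic across platforms; dt = 0.01 day resolves the smooth dynamics
# far below measurement noise. Volumes are floored at 1e-6 mm^3.
integrate_growth <- function(V, t0, t1, params, effect, event_days, dt = 0.01) {
  if (t1 <= t0) return(V)
  f <- function(t, V) {
    params$a * V * log(params$K / V) -
      kill_rate(t, event_days, effect) * V
  }
  n <- round((t1 - t0) / dt)
  h <- (t1 - t0) / n
  t <- t0
  floored <- FALSE
  for (i in seq_len(n)) {
    k1 <- f(t, V)
    k2 <- f(t + h / 2, V + h / 2 * k1)
    k3 <- f(t + h / 2, V + h / 2 * k2)
    k4 <- f(t + h, V + h * k3)
    V <- V + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(V) || V < 1e-6) {
      V <- 1e-6
      floored <- TRUE
    }
    t <- t0 + i * h
  }
  if (floored) {
    warn_ftgr("latent volume reached the 1e-6 mm^3 floor during integration",
              class = "ftgr_floor_warning")
  }
  V
}

# Latent volume at each requested measurement time (times sorted, >= 0).
simulate_latent <- function(params, effect, event_days, times, dt = 0.01) {
  out <- numeric(length(times))
  V <- params$V0
  t_prev <- 0
  for (i in seq_along(times)) {
    V <- integrate_growth(V, t_prev, times[i], params, effect, event_days, dt)
    out[i] <- V
    t_prev <- times[i]
  }
  out
}

# Mean-one multiplicative lognormal measurement factors, animals x days.
# Drawn in one block so the same seed yields the same factors regardless of
# the treatment schedule.
draw_noise_factors <- function(n_animals, n_days, cv) {
  if (cv == 0) return(matrix(1, n_animals, n_days))
  sdlog <- sqrt(log(1 + cv^2))
  matrix(exp(stats::rnorm(n_animals * n_days, -sdlog^2 / 2, sdlog)),
         nrow = n_animals, ncol = n_days)
}

# Back-solve caliper width/length from a volume under aspect ratio
# width = r * length, so compute_volume() reproduces the volume exactly.
dims_from_volume <- function(volume, aspect_ratio = 0.8) {
  length_mm <- (2 * volume / aspect_ratio^2)^(1 / 3)
  list(width_mm = aspect_ratio * length_mm, length_mm = length_mm)
}

#' Simulate a caliper-measured cohort
#'
#' Integrates the treated growth law
#' \eqn{dV/dt = a V \ln(K/V) - k(t) V} (fixed-step RK4, 0.01-day step) for
#' each animal, samples it on the measurement grid with multiplicative
#' lognormal noise, and back-solves width/length so [compute_volume()]
#' reproduces the noisy volume exactly. All animals share the latent
#' trajectory; only measurement noise differs.
#'
#' @param params A [growth_sim_params()].
#' @param effect A [treatment_effect()], or `NULL` for untreated.
#' @param events Data.frame of [irradiation_event()]s (or `NULL`).
#' @param n_animals Cohort size.
#' @param seed Integer seed; the same seed reproduces the records exactly.
#' @param group_id Group label for the records.
#' @param aspect_ratio Width/length ratio used to back-solve dimensions.
#' @return A [caliper_records()] table with attributes `seed`, `params`,
#'   `effect`, `events`, `latent` (noise-free volumes on the grid).
#' @export
simulate_cohort <- function(params, effect = NULL, events = NULL,
                            n_animals = 6L, seed = 1L, group_id = "sim",
                            aspect_ratio = 0.8) {
  stopifnot(inherits(params, "growth_sim_params"), n_animals >= 1)
  event_days <- if (is.null(events)) integer(0) else sort(events$day)
  days <- seq(0L, params$horizon, by = params$step)
  latent <- simulate_latent(params, effect, event_days, days)
  fac <- with_seed(seed, draw_noise_factors(n_animals, length(days),
                                            params$noise_cv))
  rows <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    v <- latent * fac[i, ]
    d <- dims_from_volume(v, aspect_ratio)
    rows[[i]] <- data.frame(
      animal_id = sprintf("%s_a%02d", group_id, i), group_id = group_id,
      day = days, width_mm = d$width_mm, length_mm = d$length_mm, alive = TRUE)
  }
  rec <- caliper_records(do.call(rbind, rows))
  attr(rec, "seed") <- seed
  attr(rec, "params") <- params
  attr(rec, "effect") <- effect
  attr(rec, "events") <- events
  attr(rec, "latent") <- latent
  rec
}

#' Fit Gompertz parameters to an untreated volume series
#'
#' Least-squares fit of \eqn{\ln V(t) = \ln K + \ln(V_0/K) e^{-a t}} on the
#' log scale, with \eqn{V_0} taken from the first grid point. A diagnostic
#' companion to the simulator, used to verify parameter recovery.
#'
#' @param series A `volume_series` starting at the enrollment day.
#' @return A list with `a`, `K`, `V0` and the residual sum of squares.
#' @export
fit_gompertz <- function(series) {
  stopifnot(inherits(series, "volume_series"), length(series$days) >= 4L)
  t <- series$days - series$days[1L]
  y <- log(series$volumes)
  V0 <- series$volumes[1L]
  sse <- function(p) {
    a <- exp(p[1L]); K <- exp(p[2L])
    if (K <= V0) return(1e10)
    sum((y - (log(K) + log(V0 / K) * exp(-a * t)))^2)
  }
  init <- c(log(0.05), log(max(series$volumes) * 2))
  fit <- stats::optim(init, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(a = exp(fit$par[1L]), K = exp(fit$par[2L]), V0 = V0, sse = fit$value)
}

#' Simulate a Newtonian heating/cooling thermal trace
#'
#' Piecewise analytic solution of the single-compartment energy balance:
#' during irradiation the temperature relaxes toward
#' \eqn{T_\mathrm{surr} + \Delta T_\mathrm{eq}} and with the laser off toward
#' ambient, both with time constant \eqn{\tau_s}; optional Gaussian sensor
#' noise is added on top.
#'
#' @param constants A [system_constants()] including `tau_s` and `absorbance`.
#' @param eta Photothermal conversion efficiency (fraction).
#' @param schedule Data.frame with columns `on_s` and `off_s`: start and end
#'   of each irradiation interval, seconds.
#' @param noise_sd Gaussian sensor noise, K.
#' @param seed Integer seed for the noise.
#' @param dt Sampling interval, seconds.
#' @param tail_s Extra cooling time recorded after the last interval.
#' @return A [thermal_trace()].
#' @export
simulate_thermal_trace <- function(constants, eta, schedule, noise_sd = 0,
                                   seed = 1L, dt = 1, tail_s = NULL) {
  stopifnot(inherits(constants, "system_constants"))
  if (is.null(constants$tau_s)) {
    stop_ftgr("constants must include tau_s to forward-simulate",
              class = "ftgr_missing_constant")
  }
  dTeq <- steady_state_rise(constants, eta)
  if (is.null(tail_s)) tail_s <- 5 * constants$tau_s
  t_end <- max(schedule$off_s) + tail_s
  time <- seq(0, t_end, by = dt)
  on <- rep(FALSE, length(time))
  for (i in seq_len(nrow(schedule))) {
    on <- on | (time >= schedule$on_s[i] & time < schedule$off_s[i])
  }
  temp <- numeric(length(time))
  Temp <- constants$t_ambient
  for (j in seq_along(time)) {
    if (j > 1L) {
      target <- if (on[j - 1L]) constants$t_ambient + dTeq else constants$t_ambient
      Temp <- target + (Temp - target) * exp(-(time[j] - time[j - 1L]) / constants$tau_s)
    }
    temp[j] <- Temp
  }
  if (noise_sd > 0) {
    temp <- temp + with_seed(seed, stats::rnorm(length(temp), 0, noise_sd))
  }
  thermal_trace(time_s = time, temp_C = temp, laser_on = on)
}
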