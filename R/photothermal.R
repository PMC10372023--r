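#' System constants for the photothermal energy balance
#'
#' Collects the physical constants of the cuvette/laser system needed to
#' convert a heating-cooling trace into a conversion efficiency. Laser power
#' is `power_density * area_cm2` unless `power_w` is given directly.
#'
#' @param mass_g Sample mass, g.
#' @param cp Specific heat capacity, J g^-1 K^-1 (water by default).
#' @param power_w Laser power reaching the sample, W. Computed from
#'   `power_density * area_cm2` when `NULL`.
#' @param power_density Laser output power density, W/cm^2.
#' @param area_cm2 Irradiated spot area, cm^2 (required unless `power_w`
#'   supplied; no default because it is rig-specific).
#' @param absorbance Sample absorbance at the laser wavelength
#'   (dimensionless); required by [estimate_eta()].
#' @param t_ambient Ambient/surrounding temperature, degrees C. If `NULL`,
#'   estimators fall back to the first sample of the trace.
#' @param q_dis Baseline heat input from solvent and container, W. If left
#'   `NULL` it is treated as 0 and [estimate_eta()] warns, since the blank
#'   contribution was then not measured.
#' @param tau_s Cooling time constant, s (only needed to forward-simulate;
#'   estimated from data otherwise).
#' @return A `system_constants` list.
#' @export
system_constants <- function(mass_g = 1, cp = 4.186, power_w = NULL,
                             power_density = 0.65, area_cm2 = NULL,
                             absorbance = NULL, t_ambient = 25,
                             q_dis = NULL, tau_s = NULL) {
  if (is.null(power_w)) {
    if (is.null(area_cm2)) {
      stop_ftgr("supply either power_w or area_cm2 (power = density x area)",
                class = "ftgr_missing_constant")
    }
    power_w <- power_density * area_cm2
  }
  stopifnot(mass_g > 0, cp > 0, power_w > 0)
  if (!is.null(q_dis)) stopifnot(q_dis >= 0)
  if (!is.null(tau_s)) stopifnot(tau_s > 0)
  structure(list(mass_g = mass_g, cp = cp, power_w = power_w,
                 power_density = power_density, area_cm2 = area_cm2,
                 absorbance = absorbance, t_ambient = t_ambient,
                 q_dis = q_dis, tau_s = tau_s),
            class = "system_constants")
}

# Absorbed-power steady-state temperature rise above ambient.
steady_state_rise <- function(constants, eta) {
  if (is.null(constants$absorbance)) {
    stop_ftgr("absorbance at the laser wavelength is required",
              class = "ftgr_missing_constant")
  }
  hS <- constants$mass_g * constants$cp / constants$tau_s
  q_dis <- if (is.null(constants$q_dis)) 0 else constants$q_dis
  (eta * constants$power_w * (1 - 10^(-constants$absorbance)) + q_dis) / hS
}

#' Construct a validated thermal trace
#'
#' @param time_s Strictly increasing sample times, s.
#' @param temp_C Temperatures, degrees C.
#' @param laser_on Logical (or 0/1) laser state per sample.
#' @return A data.frame of class `thermal_trace`.
#' @export
thermal_trace <- function(time_s, temp_C, laser_on) {
  if (length(time_s) != length(temp_C) || length(time_s) != length(laser_on)) {
    stop_ftgr("time_s, temp_C and laser_on must have equal length",
              class = "ftgr_schema_error")
  }
  if (any(diff(time_s) <= 0)) {
    stop_ftgr("time_s must be strictly increasing", class = "ftgr_schema_error")
  }
  laser_on <- as.logical(laser_on)
  if (anyNA(laser_on) || anyNA(temp_C)) {
    stop_ftgr("temp_C and laser_on must be non-missing", class = "ftgr_schema_error")
  }
  structure(data.frame(time_s = time_s, temp_C = temp_C, laser_on = laser_on),
            class = c("thermal_trace", "data.frame"))
}

#' @export
plot.thermal_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$temp_C, type = "l",
                 xlab = "time (s)", ylab = expression(temperature ~ (degree * C)),
                 ...)
  on_runs <- segment_phases(x, quiet = TRUE)$heating
  for (seg in on_runs) {
    graphics::rect(min(seg$time_s), graphics::par("usr")[3], max(seg$time_s),
                   graphics::par("usr")[4], col = grDevices::adjustcolor("red", 0.08),
                   border = NA)
  }
  invisible(x)
}

#' Split a thermal trace into heating and cooling phases
#'
#' Contiguous maximal runs of constant laser state. Runs with fewer than two
#' samples carry no slope information and are dropped with a warning.
#'
#' @param trace A [thermal_trace()].
#' @param quiet Suppress the short-run warning.
#' @return List with elements `heating` and `cooling`, each a list of
#'   `thermal_trace` segments in time order.
#' @export
segment_phases <- function(trace, quiet = FALSE) {
  stopifnot(inherits(trace, "thermal_trace"))
  r <- rle(trace$laser_on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  heating <- list(); cooling <- list()
  dropped <- 0L
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] < 2L) { dropped <- dropped + 1L; next }
    seg <- trace[starts[i]:ends[i], , drop = FALSE]
    class(seg) <- c("thermal_trace", "data.frame")
    if (r$values[i]) heating[[length(heating) + 1L]] <- seg
    else cooling[[length(cooling) + 1L]] <- seg
  }
  if (dropped > 0L && !quiet) {
    warn_ftgr(dropped, " single-sample phase run(s) dropped",
              class = "ftgr_segment_warning")
  }
  list(heating = heating, cooling = cooling)
}

#' Fit the Newtonian cooling time constant
#'
#' With driving temperature \eqn{\theta = (T - T_\mathrm{surr}) /
#' (T_\mathrm{max} - T_\mathrm{surr})}, Newtonian cooling obeys
#' \eqn{t = -\tau_s \ln\theta}. The time constant is the least-squares slope
#' of elapsed time against \eqn{-\ln\theta}, restricted to
#' \eqn{\theta \in} `theta_window` to exclude the log blow-up near ambient
#' and transients near the plateau.
#'
#' @param segment A cooling `thermal_trace` segment (temperatures decaying
#'   toward ambient).
#' @param ambient Surrounding temperature, degrees C.
#' @param theta_window Inclusive \eqn{\theta} range used for the fit.
#' @param r2_warn Warn about a poor (non-single-exponential) fit below this
#'   R^2.
#' @return List with `tau_s` (s) and `fit_r2`.
#' @export
fit_cooling_tau <- function(segment, ambient, theta_window = c(0.1, 0.9),
                            r2_warn = 0.995) {
  stopifnot(inherits(segment, "thermal_trace"))
  t_max <- segment$temp_C[1L]
  if (ambient >= t_max) {
    stop_ftgr("ambient temperature must lie below the segment start",
              class = "ftgr_fit_error")
  }
  theta <- (segment$temp_C - ambient) / (t_max - ambient)
  use <- theta >= theta_window[1L] & theta <= theta_window[2L]
  if (sum(use) < 3L) {
    stop_ftgr("fewer than 3 samples inside the theta window",
              class = "ftgr_fit_error")
  }
  x <- -log(theta[use])
  y <- segment$time_s[use] - segment$time_s[1L]
  # slope and R^2 by hand: summary.lm warns on the exact-exponential case
  tau <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - mean(y) - tau * (x - mean(x))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  if (tau <= 0) {
    stop_ftgr("cooling fit produced a non-positive time constant",
              class = "ftgr_fit_error")
  }
  if (r2 < r2_warn) {
    warn_ftgr(sprintf("cooling fit R^2 = %.4f: decay is not single-exponential",
                      r2), class = "ftgr_poor_fit_warning")
  }
  list(tau_s = tau, fit_r2 = r2)
}

#' Estimate photothermal conversion efficiency from a heating-cooling trace
#'
#' Single-compartment energy-balance estimate. The steady-state rise
#' \eqn{\Delta T_\mathrm{max}} is the mean of the final fraction
#' (`plateau_window`) of the hottest heating phase minus ambient; the heat
#' transfer coefficient is \eqn{hS = m C_p / \tau_s} with \eqn{\tau_s} fitted
#' on the cooling phase that follows; the efficiency is
#' \deqn{\eta = \frac{hS\,\Delta T_\mathrm{max} - Q_\mathrm{dis}}
#'              {I\,(1 - 10^{-A})}}
#' with laser power \eqn{I} and absorbance \eqn{A} at the laser wavelength.
#'
#' @param trace A [thermal_trace()] with at least one heating-to-plateau
#'   phase followed by a cooling phase. The heating phase should last several
#'   time constants (>= ~6 tau_s): the tail-mean plateau estimator is biased
#'   low on a heating phase truncated before steady state.
#' @param constants A [system_constants()] with `absorbance` set.
#' @param plateau_window Final fraction of the heating phase averaged for the
#'   plateau (default 0.1).
#' @param theta_window Passed to [fit_cooling_tau()].
#' @return An object of class `eta_fit` with components `eta` (fraction),
#'   `tau_s`, `hS`, `delta_T_max`, `fit_r2`, `t_ambient`, `constants`.
#' @export
estimate_eta <- function(trace, constants, plateau_window = 0.1,
                         theta_window = c(0.1, 0.9)) {
  stopifnot(inherits(trace, "thermal_trace"), inherits(constants, "system_constants"))
  if (is.null(constants$absorbance)) {
    stop_ftgr("absorbance at the laser wavelength is required",
              class = "ftgr_missing_constant")
  }
  ambient <- constants$t_ambient
  if (is.null(ambient)) ambient <- trace$temp_C[1L]
  phases <- segment_phases(trace, quiet = TRUE)
  if (length(phases$heating) == 0L) {
    stop_ftgr("no heating phase in trace", class = "ftgr_fit_error")
  }
  if (length(phases$cooling) == 0L) {
    stop_ftgr("no cooling phase in trace: cannot fit tau_s",
              class = "ftgr_fit_error")
  }
  # hottest heating phase defines the plateau; tau from the cooling phase
  # that follows it (or the last cooling phase if none follows)
  peak <- vapply(phases$heating, function(s) max(s$temp_C), numeric(1))
  hseg <- phases$heating[[which.max(peak)]]
  n_tail <- max(2L, ceiling(plateau_window * nrow(hseg)))
  plateau <- mean(utils::tail(hseg$temp_C, n_tail))
  after <- vapply(phases$cooling, function(s) s$time_s[1L] >= max(hseg$time_s),
                  logical(1))
  cseg <- if (any(after)) phases$cooling[[which(after)[1L]]] else
    phases$cooling[[length(phases$cooling)]]
  cool <- fit_cooling_tau(cseg, ambient, theta_window)
  hS <- constants$mass_g * constants$cp / cool$tau_s
  dTmax <- plateau - ambient
  q_dis <- constants$q_dis
  if (is.null(q_dis)) {
    warn_ftgr("no dissipation baseline (q_dis) supplied; assuming 0 W ",
              "(measure a solvent blank to correct)",
              class = "ftgr_qdis_warning")
    q_dis <- 0
  }
  eta <- (hS * dTmax - q_dis) /
    (constants$power_w * (1 - 10^(-constants$absorbance)))
  if (eta < 0) {
    warn_ftgr("energy balance gave a negative efficiency; clipping to 0",
              class = "ftgr_eta_range_warning")
    eta <- 0
  } else if (eta > 1) {
    warn_ftgr(sprintf("efficiency %.3f exceeds 1: check constants", eta),
              class = "ftgr_eta_range_warning")
  }
  structure(list(eta = eta, tau_s = cool$tau_s, hS = hS,
                 delta_T_max = dTmax, fit_r2 = cool$fit_r2,
                 t_ambient = ambient, q_dis = q_dis, constants = constants),
            class = "eta_fit")
}

#' @export
print.eta_fit <- function(x, ...) {
  cat("Photothermal conversion efficiency (energy-balance estimate)\n")
  cat(sprintf("  eta          = %.4f (%.2f%%)\n", x$eta, 100 * x$eta))
  cat(sprintf("  tau_s        = %.1f s   (cooling fit R^2 = %.4f)\n",
              x$tau_s, x$fit_r2))
  cat(sprintf("  hS           = %.5f W/K\n", x$hS))
  cat(sprintf("  delta T_max  = %.2f K above %.2f C ambient\n",
              x$delta_T_max, x$t_ambient))
  invisible(x)
}

#' @export
summary.eta_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  laser power  = %.3f W, absorbance = %.3f, Q_dis = %.4f W\n",
              object$constants$power_w, object$constants$absorbance,
              object$q_dis))
  invisible(object)
}

#' @export
coef.eta_fit <- function(object, ...) {
  c(eta = object$eta, tau_s = object$tau_s, hS = object$hS,
    delta_T_max = object$delta_T_max)
}

#' Forward model: analytic heating curve
#'
#' Solves \eqn{C\,dT/dt = \eta I (1 - 10^{-A}) + Q_\mathrm{dis} -
#' hS (T - T_\mathrm{surr})}:
#' \eqn{T(t) = T_\mathrm{surr} + \Delta T_\mathrm{eq} (1 - e^{-t/\tau_s})}
#' with plateau \eqn{\Delta T_\mathrm{eq} = (\eta I (1-10^{-A}) +
#' Q_\mathrm{dis}) / hS}. The inverse of [estimate_eta()]; used for
#' round-trip validation.
#'
#' @param constants A [system_constants()] including `tau_s` and `absorbance`.
#' @param eta Conversion efficiency, fraction.
#' @param duration Irradiation time, s.
#' @param dt Sampling interval, s.
#' @return A [thermal_trace()] with `laser_on = TRUE` throughout.
#' @export
predict_heating_curve <- function(constants, eta, duration, dt = 1) {
  stopifnot(inherits(constants, "system_constants"), dt > 0, duration > dt)
  if (is.null(constants$tau_s)) {
    stop_ftgr("constants must include tau_s to forward-simulate",
              class = "ftgr_missing_constant")
  }
  dTeq <- steady_state_rise(constants, eta)
  time <- seq(0, duration, by = dt)
  temp <- constants$t_ambient + dTeq * (1 - exp(-time / constants$tau_s))
  thermal_trace(time_s = time, temp_C = temp,
                laser_on = rep(TRUE, length(time)))
}
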