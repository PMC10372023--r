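test_that("phase segmentation splits runs by laser state", {
  sched <- data.frame(on_s = c(0, 2400, 4800, 6200),
                      off_s = c(1200, 3600, 6000, 7400))
  tr <- simulate_thermal_trace(ref_constants(), 0.7, sched)
  ph <- segment_phases(tr)
  expect_length(ph$heating, 4)
  expect_length(ph$cooling, 4)
  expect_true(all(vapply(ph$heating, function(s) all(s$laser_on), logical(1))))
  expect_true(all(vapply(ph$cooling, function(s) !any(s$laser_on), logical(1))))
  # an all-on trace has no cooling phase, so no time constant downstream
  always_on <- predict_heating_curve(ref_constants(), 0.7, duration = 600)
  ph2 <- segment_phases(always_on)
  expect_length(ph2$heating, 1)
  expect_length(ph2$cooling, 0)
  expect_error(estimate_eta(always_on, ref_constants()),
               class = "ftgr_fit_error")
  # a single off-phase trace is one cooling segment spanning all samples
  cool_only <- thermal_trace(0:100, 45 - 0.1 * (0:100), rep(FALSE, 101))
  ph3 <- segment_phases(cool_only)
  expect_length(ph3$cooling, 1)
  expect_equal(nrow(ph3$cooling[[1]]), 101)
})

test_that("cooling fit recovers an exact exponential time constant", {
  tt <- 0:1200
  seg <- thermal_trace(tt, 25 + 18 * exp(-tt / 300), rep(FALSE, length(tt)))
  fit <- fit_cooling_tau(seg, ambient = 25)
  expect_equal(fit$tau_s, 300, tolerance = 1e-9)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_error(fit_cooling_tau(seg, ambient = 50), class = "ftgr_fit_error")
})

test_that("cooling fit is accurate under sensor noise (Monte Carlo)", {
  taus <- vapply(1:100, function(s) {
    tt <- 0:1200
    temp <- 25 + 18 * exp(-tt / 300) +
      withr::with_seed(s, rnorm(length(tt), 0, 0.05))
    fit_cooling_tau(thermal_trace(tt, temp, rep(FALSE, length(tt))), 25)$tau_s
  }, numeric(1))
  expect_lt(max(abs(taus - 300) / 300), 0.02)
})

test_that("a biexponential decay triggers the poor-fit warning", {
  tt <- 0:900
  temp <- 25 + 18 * (0.7 * exp(-tt / 100) + 0.3 * exp(-tt / 600))
  expect_warning(
    fit_cooling_tau(thermal_trace(tt, temp, rep(FALSE, length(tt))), 25),
    class = "ftgr_poor_fit_warning")
  # while a clean single exponential does not warn
  expect_no_warning(
    fit_cooling_tau(thermal_trace(tt, 25 + 18 * exp(-tt / 300),
                                  rep(FALSE, length(tt))), 25))
})

test_that("eta estimation round-trips the forward model", {
  sc <- ref_constants()
  for (eta_true in c(0.2, 0.5, 0.73)) {
    fit <- estimate_eta(simulate_thermal_trace(sc, eta_true, ref_schedule()), sc)
    expect_lt(abs(fit$eta - eta_true), 0.005)
    expect_equal(fit$tau_s, 300, tolerance = 1e-3)
  }
})

test_that("eta estimation stays within 3% under sensor noise", {
  sc <- ref_constants()
  est <- vapply(1:100, function(s) {
    tr <- simulate_thermal_trace(sc, 0.7319, ref_schedule(),
                                 noise_sd = 0.05, seed = s)
    estimate_eta(tr, sc)$eta
  }, numeric(1))
  expect_lt(max(abs(est - 0.7319)), 0.03)
  expect_lt(abs(mean(est) - 0.7319), 0.005)
})

test_that("energy-balance identities and degenerate cases", {
  sc <- ref_constants()
  fit <- estimate_eta(simulate_thermal_trace(sc, 0.6, ref_schedule()), sc)
  # hS tau_s = m C_p holds exactly as returned
  expect_equal(fit$hS * fit$tau_s, sc$mass_g * sc$cp)
  # blank-solvent case: Q_dis equal to the whole steady-state loss gives 0
  blank <- ref_constants(q_dis = fit$hS * fit$delta_T_max)
  fit0 <- estimate_eta(simulate_thermal_trace(sc, 0.6, ref_schedule()), blank)
  expect_equal(fit0$eta, 0, tolerance = 1e-6)
  # unspecified q_dis warns and assumes 0 W
  expect_warning(
    estimate_eta(simulate_thermal_trace(sc, 0.6, ref_schedule()),
                 ref_constants(q_dis = NULL)),
    class = "ftgr_qdis_warning")
  # a negative numerator clips to 0 with a warning
  over <- ref_constants(q_dis = 10)
  expect_warning(
    fit_neg <- estimate_eta(simulate_thermal_trace(sc, 0.2, ref_schedule()), over),
    class = "ftgr_eta_range_warning")
  expect_equal(fit_neg$eta, 0)
  # absorbance is mandatory
  expect_error(
    estimate_eta(simulate_thermal_trace(sc, 0.6, ref_schedule()),
                 ref_constants(absorbance = NULL)),
    class = "ftgr_missing_constant")
})

test_that("estimates are invariant to time shift and temperature offset", {
  sc <- ref_constants()
  tr <- simulate_thermal_trace(sc, 0.65, ref_schedule())
  base <- estimate_eta(tr, sc)
  shifted <- thermal_trace(tr$time_s + 5000, tr$temp_C, tr$laser_on)
  fit_t <- estimate_eta(shifted, sc)
  expect_equal(fit_t$eta, base$eta)
  expect_equal(fit_t$tau_s, base$tau_s)
  # whole-trace offset (e.g. C -> K) with ambient taken from the trace
  offset <- thermal_trace(tr$time_s, tr$temp_C + 273.15, tr$laser_on)
  kelvin_constants <- system_constants(mass_g = 1, cp = 4.186, area_cm2 = 1,
                                       absorbance = 0.33, t_ambient = NULL,
                                       q_dis = 0, tau_s = 300)
  fit_k <- estimate_eta(offset, kelvin_constants)
  expect_equal(fit_k$tau_s, base$tau_s, tolerance = 1e-9)
  expect_equal(fit_k$delta_T_max, base$delta_T_max, tolerance = 1e-9)
})

test_that("forward heating curve has the analytic plateau and monotone response", {
  sc <- ref_constants()
  hS <- sc$mass_g * sc$cp / sc$tau_s
  dTeq <- 0.7 * sc$power_w * (1 - 10^(-sc$absorbance)) / hS
  long <- predict_heating_curve(sc, 0.7, duration = 30 * sc$tau_s, dt = 10)
  expect_equal(max(long$temp_C), sc$t_ambient + dTeq, tolerance = 1e-8)
  # eta = 0 with no dissipation input stays flat at ambient
  flat <- predict_heating_curve(sc, 0, duration = 600)
  expect_equal(flat$temp_C, rep(sc$t_ambient, length(flat$temp_C)))
  # plateau strictly increases with absorbance (concentration sweep)
  plateaus <- vapply(c(0.1, 0.3, 0.6, 1, 2), function(a) {
    max(predict_heating_curve(ref_constants(absorbance = a), 0.7,
                              duration = 20 * 300)$temp_C)
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
})

test_that("repeated irradiation cycles reach the same peak", {
  sched <- data.frame(on_s = c(0, 4000, 8000, 12000),
                      off_s = c(2400, 6400, 10400, 14400))
  tr <- simulate_thermal_trace(ref_constants(), 0.7319, sched)
  peaks <- vapply(segment_phases(tr)$heating, function(s) max(s$temp_C),
                  numeric(1))
  expect_lt(max(peaks) - min(peaks), 0.05)
  fit <- estimate_eta(tr, ref_constants())
  expect_lt(abs(fit$eta - 0.7319), 0.005)
})
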