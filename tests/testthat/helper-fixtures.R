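# Shared fixtures and independent oracles for the test suite.

# Brute-force FTGR oracle: scalar transcription of the indicator definition,
# evaluated triplet by triplet. Kept deliberately independent of
# compute_ftgr()'s vectorised path.
ftgr_oracle <- function(v) {
  out <- numeric(0)
  for (n in 2:(length(v) - 1L)) {
    fwd <- (v[n + 1L] - v[n]) / v[n] * 100
    bwd <- (v[n] - v[n - 1L]) / v[n - 1L] * 100
    out <- c(out, fwd - bwd)
  }
  out
}

# Reference thermal rig used throughout the photothermal tests: 1 mL of
# water-like sample, 0.65 W/cm^2 over 1 cm^2, absorbance 0.33 at 808 nm,
# tau_s = 300 s. Chosen so an efficiency near 0.73 plateaus around 43 C
# from 25 C ambient.
ref_constants <- function(...) {
  args <- utils::modifyList(
    list(mass_g = 1, cp = 4.186, area_cm2 = 1, absorbance = 0.33,
         t_ambient = 25, q_dis = 0, tau_s = 300),
    list(...))
  do.call(system_constants, args)
}

# One long heating phase (8 tau, so the tail-mean plateau is unbiased)
# followed by free cooling.
ref_schedule <- function(tau = 300) data.frame(on_s = 0, off_s = 8 * tau)

# A small two-animal caliper table on a 2-day grid.
two_animal_records <- function() {
  caliper_records(data.frame(
    animal_id = rep(c("a1", "a2"), each = 4L),
    group_id = "G1",
    day = rep(c(0, 2, 4, 6), 2L),
    width_mm = c(4.0, 4.4, 4.8, 5.3, 4.2, 4.6, 5.0, 5.5),
    length_mm = c(7.5, 8.0, 8.6, 9.2, 7.6, 8.2, 8.8, 9.4)))
}

# Geometric (exact exponential) volume series V0 * f^i.
exp_series <- function(V0 = 60, fold = 1.3, n = 8L, step = 2L, group = "exp") {
  volume_series(group, days = seq(0L, by = step, length.out = n),
                volumes = V0 * fold^(seq_len(n) - 1L))
}

make_ftgr_trace <- function(days, values, convention = "latest", h = 2L) {
  structure(list(days = as.integer(days), values = as.numeric(values),
                 label_convention = convention, group_id = "manual", h = h),
            class = "ftgr_trace")
}
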