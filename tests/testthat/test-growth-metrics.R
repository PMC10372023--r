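test_that("caliper volume formula and its edge cases", {
  expect_equal(compute_volume(4.0, 7.5), 60.0)
  expect_equal(compute_volume(3.0, 8.0), 36.0)
  expect_equal(compute_volume(2, 2), 4.0)           # cube case 0.5 w^3
  expect_equal(compute_volume(c(4, 3), c(7.5, 8)), c(60, 36))
  expect_error(compute_volume(0, 5), class = "ftgr_invalid_measurement")
  expect_error(compute_volume(4, -1), class = "ftgr_invalid_measurement")
})

test_that("caliper records enforce conventions", {
  rec <- two_animal_records()
  expect_s3_class(rec, "caliper_records")
  expect_equal(rec$volume_mm3[1], 60)
  # transposed width/length is swapped with a warning
  df <- data.frame(animal_id = "a", group_id = "G", day = 0,
                   width_mm = 8, length_mm = 3)
  expect_warning(fixed <- caliper_records(df), class = "ftgr_swap_warning")
  expect_equal(fixed$width_mm, 3)
  expect_equal(fixed$length_mm, 8)
  expect_equal(fixed$volume_mm3, 36)
  # duplicated animal x day is a hard error
  dup <- data.frame(animal_id = "a", group_id = "G", day = c(0, 0),
                    width_mm = 3, length_mm = 4)
  expect_error(caliper_records(dup), class = "ftgr_duplicate_error")
})

test_that("group means average alive animals and censor the dead", {
  df <- data.frame(animal_id = rep(c("a", "b"), each = 4),
                   group_id = "G", day = rep(c(0, 2, 4, 6), 2),
                   width_mm = 4, length_mm = 7.5,
                   alive = c(TRUE, TRUE, TRUE, TRUE,
                             TRUE, TRUE, FALSE, FALSE))
  s <- group_mean_series(caliper_records(df), "G")
  expect_equal(s$n_animals, c(2L, 2L, 1L, 1L))
  expect_equal(s$volumes, rep(60, 4))
  # two animals at 60 and 80 average to 70
  df2 <- data.frame(animal_id = c("a", "b"), group_id = "G", day = 0,
                    width_mm = c(4, 4), length_mm = c(7.5, 10))
  s2 <- group_mean_series(caliper_records(df2), "G")
  expect_equal(s2$volumes, 70)
  expect_equal(s2$n_animals, 2L)
  expect_error(group_mean_series(caliper_records(df2), "nope"),
               class = "ftgr_empty_group")
})

test_that("ragged grids error unless log-linear interpolation is requested", {
  df <- data.frame(animal_id = c("a", "a", "a", "b", "b"),
                   group_id = "G", day = c(0, 2, 4, 0, 4),
                   width_mm = 4, length_mm = c(7.5, 7.5, 7.5, 7.5, 30))
  expect_error(group_mean_series(caliper_records(df), "G"),
               class = "ftgr_grid_error")
  s <- group_mean_series(caliper_records(df), "G", interpolate_gaps = TRUE)
  # b: 60 -> 240 over 4 days, log-linear midpoint is sqrt(60 * 240) = 120
  expect_equal(s$volumes[2], mean(c(60, 120)))
})

test_that("noiseless identical growth makes the group mean equal one animal", {
  p <- growth_sim_params(noise_cv = 0)
  rec <- simulate_cohort(p, n_animals = 6, seed = 3)
  s6 <- group_mean_series(rec, "sim")
  s1 <- group_mean_series(simulate_cohort(p, n_animals = 1, seed = 3), "sim")
  expect_equal(s6$volumes, s1$volumes)
  expect_equal(s6$n_animals, rep(6L, length(s6$days)))
})

test_that("interval growth rate is the percent fold over one step", {
  s <- volume_series("G", c(0, 2), c(60, 80))
  expect_equal(interval_growth_rate(s, 2), 100 / 3)
  const <- volume_series("G", c(0, 2, 4), c(70, 70, 70))
  expect_equal(interval_growth_rate(const, 4), 0)
  # exponential series: same 100 (f - 1) at every step
  es <- exp_series(fold = 1.25)
  rates <- vapply(es$days[-1], function(d) interval_growth_rate(es, d),
                  numeric(1))
  expect_equal(rates, rep(25, length(rates)))
  expect_error(interval_growth_rate(s, 0), class = "ftgr_grid_error")
  expect_error(interval_growth_rate(s, 3), class = "ftgr_grid_error")
})

test_that("FTGR reproduces the worked triplet and labelling conventions", {
  s <- volume_series("G", c(0, 2, 4, 6), c(60, 80, 90, 120))
  latest <- compute_ftgr(s, "latest")
  expect_equal(latest$days, c(4L, 6L))
  expect_equal(latest$values, c(12.5 - 100 / 3, 100 / 3 - 12.5))
  expect_equal(latest$values, c(-20.83, 20.83), tolerance = 2e-4)
  middle <- compute_ftgr(s, "middle")
  expect_equal(middle$days, c(2L, 4L))
  expect_equal(middle$values, latest$values)
  expect_error(compute_ftgr(volume_series("G", c(0, 2), c(60, 80))),
               class = "ftgr_grid_error")
})

test_that("FTGR is zero for constant and exact exponential growth", {
  expect_equal(compute_ftgr(volume_series("G", 0:4 * 2, rep(55, 5)))$values,
               rep(0, 3))
  for (fold in c(1.05, 1.4, 2.7)) {
    tr <- compute_ftgr(exp_series(fold = fold, n = 10))
    expect_lt(max(abs(tr$values)), 1e-9)
  }
})

test_that("FTGR invariances: scaling, convention shift, causality", {
  set.seed(42)
  for (rep in 1:25) {
    v <- exp(rnorm(10, log(100), 0.6))
    s <- volume_series("G", 0:9 * 2, v)
    tr <- compute_ftgr(s)
    # scale invariance
    for (c_ in c(0.02, 3, 117)) {
      expect_equal(compute_ftgr(volume_series("G", 0:9 * 2, c_ * v))$values,
                   tr$values)
    }
    # latest labels are middle labels shifted by one step
    mid <- compute_ftgr(s, "middle")
    expect_equal(tr$values, mid$values)
    expect_equal(tr$days, mid$days + 2L)
    # causality: value at day d only uses volumes at days <= d
    v2 <- v
    v2[10] <- v2[10] * 5   # perturb the last day only
    tr2 <- compute_ftgr(volume_series("G", 0:9 * 2, v2))
    expect_equal(tr2$values[1:7], tr$values[1:7])
    expect_false(isTRUE(all.equal(tr2$values[8], tr$values[8])))
  }
})

test_that("TGI matches the fold-change formula and its limits", {
  trt <- volume_series("T", c(0, 20), c(62, 124))   # fold 2
  ctl <- volume_series("C", c(0, 20), c(58, 580))   # fold 10
  expect_equal(compute_tgi(trt, ctl, 20)$tgi, 80)
  # equal fold-changes in both arms give 0
  same <- compute_tgi(volume_series("T", c(0, 20), c(50, 400)),
                      volume_series("C", c(0, 20), c(90, 720)), 20)
  expect_equal(same$tgi, 0)
  # treated shrinking toward zero drives TGI toward 100
  shrink <- compute_tgi(volume_series("T", c(0, 20), c(62, 1e-9)), ctl, 20)
  expect_equal(shrink$tgi, 100, tolerance = 1e-9)
  expect_lte(compute_tgi(trt, ctl, 20)$tgi, 100)
  expect_error(compute_tgi(trt, ctl, 14), class = "ftgr_grid_error")
})

test_that("TGI is invariant to per-arm unit rescaling", {
  trt <- volume_series("T", c(0, 20), c(62, 124))
  ctl <- volume_series("C", c(0, 20), c(58, 580))
  base <- compute_tgi(trt, ctl, 20)$tgi
  trt2 <- volume_series("T", c(0, 20), 1000 * c(62, 124))
  ctl2 <- volume_series("C", c(0, 20), 0.3 * c(58, 580))
  expect_equal(compute_tgi(trt2, ctl2, 20)$tgi, base)
})
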