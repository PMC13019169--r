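test_that("moving-average smoothing has closed-form behaviour", {
  a <- rnorm(50)
  expect_equal(smooth_activity(a, 1, 1), a)  # one-sample window: identity
  step <- c(rep(0, 20), rep(1, 20))
  s <- smooth_activity(step, 1, 5)
  ramp <- which(s > 0 & s < 1)
  expect_equal(length(ramp), 4)  # linear ramp of width = window - 1
  expect_error(smooth_activity(a, 1, 100), "shorter than the trace")
})

test_that("a clean telegraph yields exactly its switching events", {
  tr <- make_telegraph(c(40, 95, 130, 180, 240), duration = 300)
  ev <- detect_events(tr, event_params())
  expect_equal(nrow(ev), 5)
  expect_equal(ev$direction, c(1L, -1L, 1L, -1L, 1L))
  # event times carry the ~half-filter-width jitter of the derivative peak
  expect_lt(max(abs(ev$t_event - c(40, 95, 130, 180, 240))), 2.5)
  expect_equal(ev$residence[1:4], c(55, 35, 50, 60), tolerance = 0.08)
})

test_that("constant and pure-noise traces produce no events", {
  flat <- data.frame(time = 0:500, activity = rep(0.4, 501))
  expect_equal(nrow(detect_events(flat, event_params())), 0)

  fp <- sapply(1:30, function(s) {
    set.seed(s)
    tr <- data.frame(time = 0:999, activity = 0.5 + rnorm(1000, sd = 0.1))
    nrow(detect_events(tr, event_params()))
  })
  expect_lt(mean(fp), 1)  # < 1 false event per 1000 s trace
})

test_that("transition-time fits recover generator ramps", {
  r <- make_ramp(2.0)
  expect_equal(fit_transition_time(r$time, r$activity, 20, 1), 2.0,
               tolerance = 0.025)
  # instantaneous step: resolution floor of one sample
  step <- make_telegraph(20, duration = 60)
  expect_lte(fit_transition_time(step$time, step$activity, 20, 1), 1)
  # experiment-like noise, averaged over events
  set.seed(5)
  est <- replicate(200, {
    r <- make_ramp(2.0, t0 = 35, n = 81, sigma = 0.15)
    s <- smooth_activity(r$activity, 1, 3)
    k <- which.max(diff(s)[20:60]) + 19
    fit_transition_time(r$time, r$activity, r$time[k], 1, window = 40,
                        smooth_window = 3)
  })
  expect_lt(abs(mean(est) - 2.0) / 2.0, 0.10)
})

test_that("free-energy bias follows its log-ratio formula", {
  expect_equal(delta_G(0.5), 0)
  expect_equal(delta_G(0.9), log(1 / 9))
  expect_equal(delta_G(0.9), -2.197, tolerance = 1e-3)
  expect_error(delta_G(1), "strictly inside")
  expect_error(delta_G(0), "strictly inside")
})

test_that("timescale ratio reproduces the printed receptor values", {
  expect_equal(round(timescale_ratio(47.0, 4.79, 6.06)), 9)
  expect_equal(timescale_ratio(47.0, 4.79, 6.06), 8.66, tolerance = 1e-2)
  expect_equal(timescale_ratio(65.5, 4.29, 6.07), 12.64, tolerance = 1e-2)
  expect_equal(timescale_ratio(10, 10, 10), 1)
  expect_error(timescale_ratio(10, 0, 5), "positive")
})

test_that("noise strength matches the telegraph closed form", {
  expect_equal(noise_strength(rep(0.4, 100), 0.4), 0)
  a <- rep(c(0, 1), 5000)
  expect_equal(noise_strength(a, 0.5), 1, tolerance = 1e-3)
  expect_error(noise_strength(a, 0), "a0 must")
})

test_that("two-state classification applies the 65%/0.7 rule", {
  # 10 large transitions -> two-state
  tr <- make_telegraph(seq(30, 300, by = 30), duration = 350)
  cls <- classify_two_state(tr)
  expect_true(cls$is_two_state)
  expect_equal(cls$fraction_large, 1)

  # 60% large transitions (6 of 10) -> below the 65% threshold
  set.seed(9)
  tt <- 0:600
  a <- rep(0, length(tt))
  times <- seq(50, 500, by = 50)
  sizes <- c(1, 1, 1, 1, 1, 1, 0.4, 0.4, 0.4, 0.4)
  state <- 0
  for (i in seq_along(times)) {
    state <- ifelse(i %% 2 == 1, sizes[i], 0)
    a[tt >= times[i]] <- state
  }
  cls2 <- classify_two_state(data.frame(time = tt, activity = a),
                             params = event_params(amp_min = 0.2))
  expect_false(cls2$is_two_state)
  expect_lt(cls2$fraction_large, 0.65)

  # too few events -> non-switching, not an error
  flat <- data.frame(time = 0:200, activity = rep(0.3, 201))
  expect_equal(classify_two_state(flat)$classification, "non-switching")
})

test_that("raising the classification thresholds barely moves the statistics", {
  co <- gen_cohort(8, bias_range = c(0.35, 0.65), mean_dt = 50, seed = 17,
                   duration = 2500, sigma = 0.1)
  s1 <- analyze_cohort(co$activity, event_params())
  s2 <- analyze_cohort(co$activity,
                       event_params(two_state_frac = 0.80,
                                    two_state_amp = 0.8))
  m1 <- mean(c(s1$mean_dt_up, s1$mean_dt_down), na.rm = TRUE)
  m2 <- mean(c(s2$mean_dt_up, s2$mean_dt_down), na.rm = TRUE)
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("exponential dwell fits recover rates and reject regular dwells", {
  set.seed(3)
  d <- rexp(500, rate = 1 / 50)
  f <- fit_exponential_residence(d)
  expect_true(f$fitted)
  se <- 50 / sqrt(500)
  expect_lt(abs(f$mean - mean(d)), 1e-9)
  expect_lt(abs(f$mean - 50), 3 * se)
  expect_gt(f$ks_p, 0.01)

  f2 <- fit_exponential_residence(rep(10, 100))
  expect_lt(f2$ks_p, 0.01)

  f3 <- fit_exponential_residence(rexp(5))
  expect_false(f3$fitted)
})

test_that("energy landscapes show the expected wells and depth differences", {
  set.seed(4)
  # balanced two-state cohort: symmetric wells
  a_bal <- c(rnorm(5000, 0.05, 0.05), rnorm(5000, 0.95, 0.05))
  el <- energy_landscape(a_bal)
  expect_lt(abs(el$depth_difference), 0.3)

  # bias 0.9 -> depth difference ~ delta_G(0.9) = 2.2 kT
  a_b9 <- c(rnorm(1000, 0.05, 0.05), rnorm(9000, 0.95, 0.05))
  el9 <- energy_landscape(a_b9)
  expect_equal(el9$depth_difference, log(9), tolerance = 0.25)

  # unimodal noise: single minimum
  el1 <- energy_landscape(rnorm(5000, 0.5, 0.08))
  finite <- which(is.finite(el1$G))
  mins <- finite[which(el1$G[finite] < 0.2)]
  expect_lt(diff(range(el1$mids[mins])), 0.25)
})

test_that("Arrhenius fits recover imposed scaling and flag degeneracies", {
  co <- gen_cohort(30, bias_range = c(0.25, 0.75), gamma_up = 0.35,
                   gamma_down = -0.35, mean_dt = 60, seed = 11,
                   duration = 2500, sigma = 0.1)
  summ <- analyze_cohort(co$activity, event_params())
  summ <- summ[summ$n_events >= 5, ]
  af <- arrhenius_fit(summ)
  ci_up <- confint(af$fit_up, level = 0.99)
  ci_dn <- confint(af$fit_down, level = 0.99)
  expect_gt(-0.35, ci_up["delta_G", 1]); expect_lt(-0.35, ci_up["delta_G", 2])
  expect_gt(0.35, ci_dn["delta_G", 1]); expect_lt(0.35, ci_dn["delta_G", 2])
  expect_equal(af$mean_dt, 60, tolerance = 0.25)

  # gamma_up = -gamma_down with symmetric design -> crossing at Delta G ~ 0
  expect_lt(abs(af$crossing_dG), 0.5)

  same <- summ
  same$delta_G <- 0.3
  expect_error(arrhenius_fit(same), "identical Delta G")
  expect_error(arrhenius_fit(summ[1:2, ]), "at least 3")
})
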