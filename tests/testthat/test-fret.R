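test_that("stimulus windows reject overlap and malformed intervals", {
  w <- stimulus_windows(attractant = c(10, 20), repellent = c(30, 40))
  expect_equal(nrow(w$attractant), 1)
  expect_error(stimulus_windows(attractant = c(10, 20), repellent = c(15, 25)),
               "overlap")
  expect_error(stimulus_windows(attractant = c(20, 10)), "end must exceed")
})

test_that("constant channels give a flat corrected ratio", {
  tr <- data.frame(time = 0:99, donor = rep(100, 100), acceptor = rep(55, 100))
  w <- stimulus_windows(attractant = c(5, 15), repellent = c(80, 90))
  R <- ratio_and_bleach_correct(tr, w)
  expect_equal(as.numeric(R), rep(0.55, 100))
  expect_true(attr(R, "bleach_corrected"))

  tr$donor[50] <- 0
  expect_error(ratio_and_bleach_correct(tr, w), "positive")
})

test_that("a known shared exponential decay is divided out", {
  tt <- 0:299
  decay <- exp(-tt / 400)
  tr <- data.frame(time = tt, donor = 200 * exp(-tt / 800),
                   acceptor = 90 * decay * exp(-tt / 800))
  w <- stimulus_windows(attractant = c(5, 15), repellent = c(280, 290))
  R <- ratio_and_bleach_correct(tr, w)
  baseline <- as.numeric(R) / 0.45
  expect_lt(sd(baseline) / mean(baseline), 0.02)
  expect_equal(attr(R, "bleach_tau"), 400, tolerance = 0.02)
})

test_that("the ratiometric index matches its closed form and is monotone", {
  expect_equal(fret_index(0.5, R0 = 0.4, alpha = 0.3), 0.125,
               ignore_attr = TRUE)
  R <- rep(0.4, 10)
  expect_equal(as.numeric(fret_index(R, R0 = 0.4)), rep(0, 10))
  grid <- seq(0.05, 1.5, by = 0.05)
  f <- fret_index(grid, R0 = 0.4)
  expect_true(all(diff(f) > 0))
  expect_error(fret_index(-0.5, R0 = 0.4, alpha = 0.3), "positive")
})

test_that("normalization maps repellent windows to one and needs both windows", {
  tt <- 0:199
  w <- stimulus_windows(attractant = c(10, 40), repellent = c(150, 180))
  f <- ifelse(tt >= 150 & tt < 180, 0.15, 0.075)
  act <- normalize_activity(f, tt, w)
  rep_w <- tt >= 152 & tt < 178
  expect_equal(mean(act$activity[rep_w]), 1)

  w_missing <- stimulus_windows(attractant = c(10, 40))
  expect_error(normalize_activity(f, tt, w_missing), "both")
})

test_that("the full pipeline inverts the generator exactly on plateau traces", {
  p <- synth_params(bias = 0.5, mean_dt = 50, tau_up = 1e-3, tau_down = 1e-3,
                    sigma = 0, duration = 800)
  g <- gen_two_state_activity(p, seed = 2)
  fl <- gen_fret_cell(data.frame(time = g$trace$time, activity = g$clean), p)
  act <- fret_activity(cbind(cell_id = "c1", fl), p$windows)
  expect_lt(max(abs(act$activity - g$clean)), 1e-6)
})

test_that("noisy-channel recovery error stays below the activity noise scale", {
  errs <- sapply(1:20, function(seed) {
    p <- synth_params(bias = 0.4 + 0.02 * (seed %% 10), sigma = 0,
                      duration = 800, intensity_sigma = 0.005)
    g <- gen_two_state_activity(p, seed = seed)
    fl <- gen_fret_cell(data.frame(time = g$trace$time, activity = g$clean),
                        p, seed = seed + 100)
    act <- fret_activity(cbind(cell_id = "c", fl), p$windows)
    sqrt(mean((act$activity - g$clean)^2))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("per-cell bias survives preprocessing", {
  p <- synth_params(bias = 0.7, sigma = 0, duration = 1500,
                    bleach_donor = Inf, bleach_acceptor = Inf)
  g <- gen_two_state_activity(p, seed = 5)
  fl <- gen_fret_cell(data.frame(time = g$trace$time, activity = g$clean), p)
  act <- fret_activity(cbind(cell_id = "c", fl), p$windows)
  buf <- act$time > 60 & act$time < 1440
  expect_equal(mean(act$activity[buf]), mean(g$clean[buf]), tolerance = 0.01)
  expect_lt(abs(mean(act$activity[buf]) - 0.7), 0.1)  # finite-trace wobble
})

test_that("cluster intensity is max minus mean, shift-invariant and non-negative", {
  expect_equal(cluster_intensity(rep(5, 40)), 0)
  prof <- gen_cluster_profile(length = 200, background = 100, amplitude = 50,
                              width = 2, noise = 0, seed = 1)
  dI <- cluster_intensity(prof)
  expect_equal(dI, 50, tolerance = 0.05)
  expect_equal(cluster_intensity(prof$intensity + 123), dI)
  set.seed(3)
  noise_prof <- -abs(rnorm(50))
  expect_gte(cluster_intensity(noise_prof), 0)
  expect_error(cluster_intensity(numeric(0)), "empty")
})
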