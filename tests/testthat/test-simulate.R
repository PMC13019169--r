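test_that("kmc occupancy matches the exact Boltzmann table across fields", {
  for (L in c(2L, 3L)) {
    for (J in c(0, 0.3, 0.6)) {
      for (Hb in c(0, 0.5, -0.5)) {
        p <- model_params(L, J, H_b = Hb)
        ex <- exact_equilibrium(p)
        set.seed(1000 + L * 100 + round(10 * J) + round(10 * Hb))
        occ <- arraycrit:::.cs_occupancy(L, rep(1L, L * L), J, Hb, 0, 1, 4e6)
        tv <- 0.5 * sum(abs(occ - ex$p))
        expect_lt(tv, 0.01)
      }
    }
  }
})

test_that("independent symmetric spins average to one half", {
  tr <- simulate_activity(model_params(8, 0), duration = 4000,
                          sample_interval = 4, seed = 2)
  se <- sd(tr$activity) / sqrt(nrow(tr) / 4)  # conservative effective n
  expect_lt(abs(mean(tr$activity) - 0.5), 3 * se + 0.01)
})

test_that("activity distribution is symmetric about one half at zero field", {
  tr <- simulate_activity(model_params(8, 0.35), duration = 8000,
                          sample_interval = 4, seed = 3)
  expect_lt(abs(mean(tr$activity) - 0.5), 0.05)
  expect_lt(abs(median(tr$activity) - 0.5), 0.08)
})

test_that("a strong negative field drives the array fully active", {
  tr <- simulate_activity(model_params(6, 0, H_b = -5), duration = 200,
                          sample_interval = 1, seed = 4)
  expect_gt(mean(tail(tr$activity, 100)), 0.95)
})

test_that("the two-state regime is bimodal and polarized", {
  tr <- simulate_activity(model_params(12, 0.5), duration = 40000,
                          sample_interval = 10, seed = 11)
  h <- hist(tr$activity, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  lo_peak <- max(h$counts[h$mids < 0.25])
  hi_peak <- max(h$counts[h$mids > 0.75])
  valley <- min(h$counts[h$mids > 0.35 & h$mids < 0.65])
  expect_gt(lo_peak, 3 * valley)
  expect_gt(hi_peak, 3 * valley)
  expect_true(classify_polarized(tr)$polarized)
})

test_that("adaptation rate arithmetic matches the enzyme-number formula", {
  expect_equal(compute_adaptation_rates(200, 0.1, 20, 1 / 0.030), 0.0015)
  expect_equal(compute_adaptation_rates(0, 0.1, 20, 33.33), 0)
  expect_equal(compute_adaptation_rates(400, 0.1, 20, 100 / 3), 0.0030)
  expect_error(compute_adaptation_rates(200, 0.1, 0, 33), "must be > 0")
})

test_that("adaptation drives the mean activity to k_R/(k_R + k_B)", {
  # equal rates -> 1/2 (faster rates than the experimental calibration to
  # keep the equilibration short)
  ad <- adaptation_params(k_R = 0.005, k_B = 0.005)
  tr <- simulate_adapting(model_params(10, 0.47), ad, duration = 3e4,
                          sample_interval = 30, seed = 1)
  expect_lt(abs(mean(tr$activity[tr$time > 1e4]) - 0.5), 0.05)

  # k_R = 2 k_B -> 2/3
  ad2 <- adaptation_params(k_R = 0.01, k_B = 0.005)
  tr2 <- simulate_adapting(model_params(10, 0.4), ad2, duration = 3e4,
                           sample_interval = 30, seed = 2)
  expect_lt(abs(mean(tr2$activity[tr2$time > 1e4]) - 2 / 3), 0.05)
})

test_that("zero adaptation rates freeze the methylation field", {
  ad <- adaptation_params(k_R = 0, k_B = 0)
  tr <- simulate_adapting(model_params(6, 0.3), ad, duration = 2000,
                          sample_interval = 20, seed = 3)
  expect_true(all(tr$mean_m == tr$mean_m[1]))
  expect_identical(attr(tr, "meta")$final_m, matrix(8L, 6, 6))
})

test_that("the array re-adapts after a ligand step of either sign", {
  ad <- adaptation_params(k_R = 0.005, k_B = 0.005)
  for (dH in c(0.5, -0.5)) {
    prot <- field_protocol(t = 2e4, dH = dH)
    tr <- simulate_adapting(model_params(8, 0.45), ad, duration = 6e4,
                            sample_interval = 50, seed = 40 + round(dH),
                            protocol = prot)
    late <- tr$time > 5e4
    expect_lt(abs(mean(tr$activity[late]) - 0.5), 0.05)
  }
})

test_that("a positive ligand step transiently suppresses activity", {
  ad <- adaptation_params(k_R = 0.005, k_B = 0.005)
  prot <- field_protocol(t = 2e4, dH = 2)
  tr <- simulate_adapting(model_params(8, 0.45), ad, duration = 4e4,
                          sample_interval = 20, seed = 8, protocol = prot)
  pre <- mean(tr$activity[tr$time > 1.5e4 & tr$time < 2e4])
  just_after <- mean(tr$activity[tr$time > 2e4 & tr$time < 2.05e4])
  expect_lt(just_after, pre - 0.2)
})

test_that("correlation length is near zero for independent spins and grows with J", {
  st0 <- sample_states(model_params(24, 0), n_states = 12, burn_in = 100,
                       spacing = 30, seed = 1)
  r0 <- correlation_length(st0)
  expect_lt(r0$xi, 0.5)

  st1 <- sample_states(model_params(24, 0.2), n_states = 16, burn_in = 400,
                       spacing = 100, seed = 2)
  st2 <- sample_states(model_params(24, 0.38), n_states = 16, burn_in = 800,
                       spacing = 150, seed = 3)
  x1 <- correlation_length(st1)
  x2 <- correlation_length(st2)
  expect_gt(x2$xi, x1$xi)
})

test_that("frozen ensembles are flagged not measurable", {
  frozen <- replicate(3, matrix(1L, 8, 8), simplify = FALSE)
  expect_equal(correlation_length(frozen)$status, "not_measurable")
})

test_that("field protocols must be strictly ordered", {
  expect_error(field_protocol(c(10, 5), c(0.1, 0.1)), "strictly increasing")
  expect_error(field_protocol(1, c(0.1, 0.2)), "equal length")
})
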