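test_that("finite-size critical coupling has the right limits", {
  expect_equal(round(jstar_of_L(1e9), 2), 0.44)
  expect_equal(jstar_of_L(20), 0.4407 / (1 - 1.25 / 20), tolerance = 2e-4)
  expect_equal(jstar_of_L(20), 0.4701, tolerance = 1e-3)
  expect_error(jstar_of_L(1), "exceed")
  # monotone decreasing toward the thermodynamic limit
  Ls <- c(8, 12, 16, 24, 48, 1000)
  expect_true(all(diff(jstar_of_L(Ls)) < 0))
})

test_that("reduced temperature is the relative distance to criticality", {
  expect_equal(reduced_temperature(0.4407, 0.4407), 0)
  expect_equal(reduced_temperature(0.40, 0.44), 0.10)
  expect_error(reduced_temperature(0), "J must")
})

test_that("polarization classification separates telegraph from noise", {
  tele <- make_telegraph(seq(20, 950, by = 35), duration = 1000)
  expect_true(classify_polarized(tele)$polarized)
  set.seed(2)
  noise <- data.frame(time = 0:999, activity = 0.5 + rnorm(1000, 0, 0.08))
  expect_false(classify_polarized(noise)$polarized)
  short <- data.frame(time = 0:10, activity = rep(0.5, 11))
  expect_true(is.na(classify_polarized(short)$polarized))
})

test_that("crossing extraction matches generator ground truth", {
  p <- synth_params(bias = 0.5, mean_dt = 60, tau_up = 5, tau_down = 5,
                    sigma = 0, duration = 6000,
                    windows = stimulus_windows(attractant = c(0, 1),
                                               repellent = c(2, 3)))
  g <- gen_two_state_activity(p, seed = 12)
  ev <- extract_switching_sim(g$trace)
  expect_gt(nrow(ev), 0.75 * nrow(g$truth))
  # tau here is the 10-90% traversal duration ~ ln(9) exponential constants
  expect_equal(mean(ev$tau) / log(9), 5, tolerance = 0.15)
  dw <- ev$residence[is.finite(ev$residence)]
  expect_equal(mean(dw), 60, tolerance = 0.25)
})

test_that("scaling constants are recovered from a synthetic scaling law", {
  set.seed(3)
  z <- 2.2; b <- 1.45; c0 <- 1.9; ct <- 0.9
  grid <- expand.grid(L = c(12, 16, 20, 24, 28), J = seq(0.42, 0.52, 0.02))
  grid$mean_tau <- ct * grid$L^b * exp(rnorm(nrow(grid), 0, 0.05))
  eps <- reduced_temperature(grid$J)
  grid$r <- grid$L^(z - b) * exp(c0 * eps * grid$L) *
    exp(rnorm(nrow(grid), 0, 0.05))
  grid$mean_dt <- grid$r * grid$mean_tau
  fc <- fit_scaling_constants(grid)
  expect_lt(abs(fc$z - z) / z, 0.10)
  expect_lt(abs(fc$b - b) / b, 0.10)
  expect_lt(abs(fc$c0 - c0) / c0, 0.10)
  expect_lt(abs(fc$c_tau - ct) / ct, 0.10)
  expect_gt(fc$collapse_r2, 0.9)

  # fitted constants beat perturbed ones on the collapse residual
  pert <- fc; pert$c0 <- fc$c0 * 1.5; pert$z <- fc$z * 1.5
  expect_lt(collapse_residual(grid, fc), collapse_residual(grid, pert))

  expect_error(fit_scaling_constants(grid[grid$L == 12, ]), "at least 4")
})

test_that("isolines invert a synthetic scaling law to within one percent", {
  z <- 2.2; b <- 1.45; c0 <- 1.9
  mk <- function(L, J) {
    eps <- reduced_temperature(J)
    data.frame(L = L, J = J, mean_tau = 1, r = L^(z - b) * exp(c0 * eps * L),
               mean_dt = NA)
  }
  grid <- do.call(rbind, lapply(c(16, 20, 24), function(L)
    mk(L, seq(0.45, 0.60, by = 0.01))))
  iso <- isoline(grid, 30)
  for (i in seq_len(nrow(iso))) {
    L <- iso$L[i]
    # closed-form inversion of the law on the J > J*(inf) branch
    eps_t <- log(30 / L^(z - b)) / (c0 * L)
    J_true <- 0.4406868 / (1 - eps_t)
    expect_lt(abs(iso$J_iso[i] - J_true) / J_true, 0.01)
  }
  # unbracketed targets are flagged per L
  iso2 <- isoline(grid, 1e9)
  expect_true(all(!iso2$bracketed))
  expect_true(all(is.na(iso2$J_iso)))
})

test_that("omega0 calibration is linear in r and rejects bad input", {
  const <- structure(list(z = 2.2, b = 1.45, c0 = 1.9, c_tau = 0.15,
                          J_inf = log(1 + sqrt(2)) / 2, c_bc = 1.25),
                     class = "scaling_constants")
  cal1 <- calibrate_omega0(12, 65.5, 17:30, const)
  cal2 <- calibrate_omega0(24, 65.5, 17:30, const)
  expect_equal(cal2$omega0, 2 * cal1$omega0)
  expect_error(calibrate_omega0(12, 0, 17:30, const), "positive")
})
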