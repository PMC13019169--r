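test_that("lattice construction and neighbour counts follow free boundaries", {
  p <- model_params(4, 0.5)
  st <- build_lattice(p, "all_active")
  expect_true(all(st$spins == 1L))
  expect_equal(mean((st$spins + 1) / 2), 1.0)

  nc <- neighbour_counts(4)
  expect_equal(sum(nc == 2L), 4)  # corners
  expect_equal(sum(nc == 3L), 8)  # edges
  expect_equal(sum(nc == 4L), 4)  # interior
  # bond count 2L(L-1): each bond counted twice in the neighbour sum
  expect_equal(sum(nc), 2 * 2 * 4 * 3)

  expect_error(model_params(1, 0.5), "L must")
  expect_error(neighbour_counts(1), "L must")
})

test_that("total energy matches hand-evaluated configurations", {
  p <- model_params(2, 0.5)
  up <- build_lattice(p, "all_active")
  expect_equal(total_energy(up, p), -2.0)  # 4 bonds x (-0.5)

  checker <- up
  checker$spins <- matrix(c(1L, -1L, -1L, 1L), 2, 2)
  expect_equal(total_energy(checker, p), 2.0)

  p2 <- model_params(2, 0, H_b = 1)
  expect_equal(total_energy(up, p2), 2.0)  # 0.5 * 4 spins
})

test_that("site flip rates follow the exponential rate law", {
  p0 <- model_params(4, 0, H_b = 0)
  st <- build_lattice(p0, "all_active")
  expect_equal(site_flip_rate(st, c(2, 2), p0), 1.0)

  p1 <- model_params(4, 0.5)
  expect_equal(site_flip_rate(st, c(2, 2), p1), exp(-2))  # 4 aligned neighbours

  p2 <- model_params(4, 0, H_b = 0.2)
  expect_equal(site_flip_rate(st, c(2, 2), p2), exp(0.1))

  expect_error(site_flip_rate(st, c(0, 1), p1), "outside")
})

test_that("flip rates satisfy detailed balance exactly", {
  set.seed(7)
  p <- model_params(4, 0.37, H_b = 0.21, H_L = -0.1)
  st <- build_lattice(p, "random", seed = 3)
  for (i in 1:100) {
    site <- c(sample(4, 1), sample(4, 1))
    st2 <- st
    st2$spins[site[1], site[2]] <- -st2$spins[site[1], site[2]]
    ratio <- site_flip_rate(st, site, p) / site_flip_rate(st2, site, p)
    dH <- total_energy(st2, p) - total_energy(st, p)
    expect_equal(ratio, exp(-dH), tolerance = 1e-12)
    if (i %% 3 == 0) st <- st2  # walk through configuration space
  }
})

test_that("kmc waiting times have the analytic mean for independent spins", {
  set.seed(11)
  p <- model_params(2, 0)  # total rate 4 * omega0
  st <- build_lattice(p, "all_active")
  waits <- replicate(4000, kmc_step(st, p)$waiting_time)
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 0.25), 3 * se)
})

test_that("seeded trajectories are bit-reproducible", {
  p <- model_params(6, 0.4)
  a <- simulate_activity(p, duration = 500, sample_interval = 5, seed = 42)
  b <- simulate_activity(p, duration = 500, sample_interval = 5, seed = 42)
  expect_identical(a$activity, b$activity)
  expect_identical(attr(a, "meta")$final_spins, attr(b, "meta")$final_spins)
})

test_that("species assignment gives Bernoulli bond statistics", {
  sp <- assign_species(50, 0, J_same = 0.5, J_cross = 0.2, seed = 1)
  expect_true(all(sp == 0L))

  sp2 <- assign_species(50, 0.3, J_same = 0.5, J_cross = 0.2, seed = 2)
  L <- 50
  cross_h <- sp2[, -L] != sp2[, -1]
  cross_v <- sp2[-L, ] != sp2[-1, ]
  frac <- mean(c(cross_h, cross_v))
  p_cross <- 2 * 0.3 * 0.7
  se <- sqrt(p_cross * (1 - p_cross) / (2 * L * (L - 1)))
  expect_lt(abs(frac - p_cross), 4 * se)

  expect_error(assign_species(10, 1.2, 0.5, 0.2), "tar_fraction")
})

test_that("matched couplings make bond disorder reduce to the homogeneous case", {
  p <- model_params(8, 0.45)
  sp <- assign_species(8, 0.4, J_same = 0.45, J_cross = 0.45, seed = 5)
  a <- simulate_activity(p, duration = 300, sample_interval = 5, seed = 9)
  b <- simulate_activity(p, duration = 300, sample_interval = 5, seed = 9,
                         species = sp)
  expect_identical(a$activity, b$activity)
})

test_that("exact enumeration returns Boltzmann probabilities", {
  pu <- model_params(2, 0)
  tab <- exact_equilibrium(pu)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$p, rep(1 / 16, 16))
  expect_equal(sum(tab$p), 1)

  ps <- model_params(2, 5)
  tab2 <- exact_equilibrium(ps)
  aligned <- tab2$code %in% c(0, 15)
  expect_gte(sum(tab2$p[aligned]), 0.99)
  expect_equal(tab2$p[tab2$code == 0], tab2$p[tab2$code == 15])

  expect_error(exact_equilibrium(model_params(4, 0.3)), "L <= 3")
})
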