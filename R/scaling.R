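# Finite-size scaling: (L, J) sweeps of switching statistics, polarization
# classification, scaling-constant fits, data collapse, J-isolines and
# calibration of the fundamental flip frequency.

#' Finite-size critical coupling
#'
#' `J*(L) = J*(inf) / (1 - c/L)`: the effective critical coupling of an
#' `L` x `L` free-boundary lattice, with `J*(inf) = ln(1 + sqrt(2))/2
#' (about 0.4407 kT, the exact square-lattice value) and boundary-condition
#' constant `c = 1.25` for free boundaries.
#'
#' @param L lattice side(s) (> `c_bc`).
#' @param J_inf thermodynamic-limit critical coupling (kT).
#' @param c_bc boundary-condition constant.
#' @return `J*(L)` (kT), vectorized over `L`.
#' @export
jstar_of_L <- function(L, J_inf = log(1 + sqrt(2)) / 2, c_bc = 1.25) {
  if (any(L <= c_bc)) stop("L must exceed the boundary-condition constant")
  J_inf / (1 - c_bc / L)
}

#' Reduced temperature
#'
#' `epsilon = |J_ref - J| / J`, the dimensionless distance to criticality.
#' By default `J_ref` is the thermodynamic-limit critical coupling.
#'
#' @param J coupling (> 0, kT).
#' @param J_ref reference critical coupling (kT).
#' @return epsilon, vectorized.
#' @export
reduced_temperature <- function(J, J_ref = log(1 + sqrt(2)) / 2) {
  if (any(J <= 0)) stop("J must be > 0")
  abs(J_ref - J) / J
}

#' Default detector settings for simulation traces
#'
#' Simulated traces are noise-free apart from finite-size fluctuations, are
#' sampled in `1/omega0` units, and have transition ramps of order `L^b`
#' time units, so the 1 Hz-scale experimental defaults do not transfer.
#' These defaults scale the smoothing, separation and amplitude windows off
#' the sampling interval.
#'
#' @param dt trace sampling interval (in `1/omega0` units).
#' @return an [event_params()] list.
#' @export
sim_event_params <- function(dt) {
  event_params(smooth_window = 3 * dt, prominence = 0.02,
               min_separation = 5 * dt, amp_window = 4 * dt,
               amp_min = 0.5, tau_window = 20 * dt)
}

#' Crossing-based switching extraction for simulated traces
#'
#' Noise-free simulated activity traces admit a more robust event
#' definition than the derivative-peak detector used for experimental data:
#' the two state levels are located from the activity histogram peaks, and
#' switching events are complete alternating crossings between the 10% and
#' 90% amplitude bands. Each event records the event time (first
#' mid-amplitude crossing), the transition time `tau` (duration of the
#' band-to-band traversal, the transient duration as drawn in the
#' residence/transition-time definitions), and the residence time to the
#' next event (midpoint-to-midpoint gap; terminal interval censored).
#'
#' @param trace data.frame `time`, `activity`.
#' @param band amplitude fraction defining the state bands (default 0.1:
#'   bands at 10% and 90% of the peak-to-peak amplitude).
#' @return `switch_events` data.frame (`t_event`, `direction`, `amplitude`,
#'   `tau`, `residence`).
#' @export
extract_switching_sim <- function(trace, band = 0.1) {
  tt <- trace_time(trace); a <- trace_activity(trace)
  h <- hist(a, breaks = seq(min(a) - 0.025, max(a) + 0.075, by = 0.05),
            plot = FALSE)
  lo_side <- h$mids < 0.5; hi_side <- !lo_side
  empty <- data.frame(t_event = numeric(0), direction = integer(0),
                      amplitude = numeric(0), tau = numeric(0),
                      residence = numeric(0))
  class(empty) <- c("switch_events", "data.frame")
  if (!any(lo_side) || !any(hi_side)) return(empty)
  lo_pk <- h$mids[lo_side][which.max(h$counts[lo_side])]
  hi_pk <- h$mids[hi_side][which.max(h$counts[hi_side])]
  amp <- hi_pk - lo_pk
  if (amp < 0.3) return(empty)
  cr <- .cs_crossings(tt, a, lo_pk + band * amp, lo_pk + (1 - band) * amp,
                      lo_pk + amp / 2)
  if (length(cr$t_event) == 0) return(empty)
  ev <- data.frame(t_event = cr$t_event, direction = cr$direction,
                   amplitude = cr$direction * amp,
                   tau = cr$t_end - cr$t_start,
                   residence = c(diff(cr$t_event), NA_real_))
  class(ev) <- c("switch_events", "data.frame")
  ev
}

#' Switching statistics of one (L, J) point
#'
#' Simulates the model at a single `(L, J)` (growing the run adaptively
#' until about `min_events` switching events are banked or the time budget
#' is exhausted) and extracts residence times, transition times and the
#' timescale ratio `r` with [extract_switching_sim()].
#'
#' @param L lattice side.
#' @param J coupling (kT).
#' @param H_b uniform biasing field.
#' @param min_events target number of switching events.
#' @param seed RNG seed.
#' @param sample_interval sampling interval (`1/omega0` units).
#' @param max_time simulated-time budget cap.
#' @param burn_in equilibration time discarded before statistics.
#' @return one-row data.frame (`L`, `J`, `H_b`, `n_events`, `mean_dt`,
#'   `mean_tau`, `r`, `polarized`, `seed`, `flag`).
#' @export
sweep_point <- function(L, J, H_b = 0, min_events = 100, seed = 1,
                        sample_interval = 5, max_time = 5e6,
                        burn_in = 2e4) {
  set.seed(seed)
  p <- model_params(L = L, J = J, H_b = H_b)
  burn <- simulate_activity(p, duration = burn_in,
                            sample_interval = burn_in / 2, init = "random")
  cur <- attr(burn, "meta")$final_spins
  chunk <- 5e4
  act <- NULL; tt <- NULL; t_off <- 0
  ev <- NULL
  while (t_off < max_time) {
    tr <- simulate_activity(p, duration = chunk,
                            sample_interval = sample_interval, init = cur)
    cur <- attr(tr, "meta")$final_spins
    act <- c(act, tr$activity); tt <- c(tt, tr$time + t_off)
    t_off <- t_off + chunk
    ev <- extract_switching_sim(data.frame(time = tt, activity = act))
    if (nrow(ev) >= min_events) break
    chunk <- min(2 * chunk, max_time - t_off)
    if (chunk <= 0) break
  }
  pol <- classify_polarized(data.frame(time = tt, activity = act))
  flag <- if (nrow(ev) < min_events) "under-sampled" else "ok"
  if (nrow(ev) < 4)
    return(data.frame(L = L, J = J, H_b = H_b, n_events = nrow(ev),
                      mean_dt = NA_real_, mean_tau = NA_real_, r = NA_real_,
                      polarized = isTRUE(pol$polarized), seed = seed,
                      flag = "no-switching"))
  dwell <- ev$residence[is.finite(ev$residence)]
  tau_up <- mean(ev$tau[ev$direction > 0])
  tau_dn <- mean(ev$tau[ev$direction < 0])
  mean_tau <- mean(c(tau_up, tau_dn), na.rm = TRUE)
  mean_dt <- mean(dwell)
  data.frame(L = L, J = J, H_b = H_b, n_events = nrow(ev),
             mean_dt = mean_dt, mean_tau = mean_tau,
             r = mean_dt / mean_tau,
             polarized = isTRUE(pol$polarized), seed = seed, flag = flag)
}

#' Sweep switching statistics over an (L, J) grid
#'
#' Runs [sweep_point()] on every combination of `L` and `J` with
#' deterministic per-point sub-seeds.
#'
#' @param L_values,J_values grid axes. `J_values` may instead be a function
#'   of `L` returning the couplings for that size (useful for grids centred
#'   on `J*(L)`).
#' @param H_b uniform biasing field.
#' @param min_events events per point.
#' @param seed master seed.
#' @param ... passed to [sweep_point()].
#' @return data.frame of class `sweep_table`, one row per grid point.
#' @export
sweep_grid <- function(L_values, J_values, H_b = 0, min_events = 200,
                       seed = 1, ...) {
  set.seed(seed)
  rows <- list()
  for (L in L_values) {
    Js <- if (is.function(J_values)) J_values(L) else J_values
    for (J in Js) {
      sub <- (seed * 1000003L + L * 1009L + round(J * 1e4)) %% .Machine$integer.max
      rows[[length(rows) + 1]] <-
        sweep_point(L, J, H_b = H_b, min_events = min_events,
                    seed = as.integer(sub), ...)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Polarization classification of an activity trace
#'
#' Histograms the activity on fixed bins and classifies the trace as
#' polarized (two-state) when the smaller of the peaks near 0 and near 1
#' exceeds the valley near 0.5 by at least `threshold` (peak-valley ratio).
#'
#' @param trace data.frame `time`, `activity`.
#' @param threshold peak-valley ratio (default 3).
#' @param n_bins histogram bins over `[0, 1]`.
#' @param min_samples traces shorter than this return `polarized = NA`.
#' @return list `polarized`, `peak_valley_ratio`.
#' @export
classify_polarized <- function(trace, threshold = 3, n_bins = 20,
                               min_samples = 200) {
  a <- trace_activity(trace)
  if (length(a) < min_samples)
    return(list(polarized = NA, peak_valley_ratio = NA_real_))
  h <- hist(pmin(pmax(a, 0), 1), breaks = seq(0, 1, length.out = n_bins + 1),
            plot = FALSE)
  lo <- h$mids < 0.25; mid <- h$mids >= 0.35 & h$mids <= 0.65; hi <- h$mids > 0.75
  peak <- min(max(h$counts[lo]), max(h$counts[hi]))
  valley <- max(min(h$counts[mid]), 1)
  ratio <- peak / valley
  list(polarized = ratio >= threshold, peak_valley_ratio = ratio)
}

#' Fit the finite-size scaling constants
#'
#' Two-stage fit of the scaling law `r ~ L^(z - b) exp(c0 epsilon L)`:
#' (1) `b` and `c_tau` from a log-log regression of the mean transition
#' time against `L`; (2) `z - b` and the collapse constant `c0` from a
#' joint regression of `ln r` on `ln L` and `epsilon * L` over the
#' near-critical sweep.
#'
#' @param sweep a `sweep_table` spanning several `L` and `J` values.
#' @param J_ref reference for the reduced temperature (default the
#'   thermodynamic-limit critical coupling).
#' @param n_boot bootstrap replicates for confidence intervals (rows
#'   resampled within the collapse regression; 0 disables).
#' @return list of class `scaling_constants`: `z`, `b`, `c0`, `c_tau`,
#'   `J_inf`, `c_bc`, and bootstrap CIs when requested.
#' @export
fit_scaling_constants <- function(sweep, J_ref = log(1 + sqrt(2)) / 2,
                                  n_boot = 200) {
  sweep <- sweep[is.finite(sweep$r) & is.finite(sweep$mean_tau) &
                   sweep$mean_tau > 0, ]
  Ls <- sort(unique(sweep$L))
  if (length(Ls) < 4 || length(unique(sweep$J)) < 4)
    stop("sweep must span at least 4 lattice sizes and 4 couplings")
  # stage 1: transition-time scaling <tau> ~ c_tau * L^b (the residual J
  # dependence of tau near criticality is weak and treated as noise)
  f_tau <- lm(log(mean_tau) ~ log(L), data = sweep)
  b <- coef(f_tau)[[2]]
  c_tau <- exp(coef(f_tau)[[1]])
  # stage 2: joint collapse regression ln r = (z - b) ln L + c0 * eps * L
  lr <- log(sweep$r)
  lL <- log(sweep$L)
  x <- reduced_temperature(sweep$J, J_ref) * sweep$L
  f_c0 <- lm(lr ~ 0 + lL + x)
  z <- b + coef(f_c0)[["lL"]]
  c0 <- coef(f_c0)[["x"]]
  boot <- NULL
  if (n_boot > 0 && nrow(sweep) > 4) {
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(sweep), replace = TRUE)
      cf <- coef(lm(lr[i] ~ 0 + lL[i] + x[i]))
      c(b + cf[[1]], cf[[2]])
    })
    boot <- list(z = quantile(bs[1, ], c(0.025, 0.975)),
                 c0 = quantile(bs[2, ], c(0.025, 0.975)))
  }
  structure(list(z = z, b = b, c0 = c0, c_tau = c_tau,
                 J_inf = log(1 + sqrt(2)) / 2, c_bc = 1.25,
                 boot_ci = boot, collapse_r2 = summary(f_c0)$r.squared),
            class = "scaling_constants")
}

#' @export
print.scaling_constants <- function(x, ...) {
  cat(sprintf("Finite-size scaling constants:\n  z = %.3f, b = %.3f, c0 = %.3f, c_tau = %.4f\n  J*(inf) = %.4f kT, c_bc = %.2f\n",
              x$z, x$b, x$c0, x$c_tau, x$J_inf, x$c_bc))
  invisible(x)
}

#' Collapse residual of a sweep under given scaling constants
#'
#' Mean squared residual of `ln r - (z - b) ln L` about the line
#' `c0 * epsilon * L`; used to sanity-check fitted constants.
#'
#' @param sweep a `sweep_table`.
#' @param constants a `scaling_constants` list.
#' @param J_ref reduced-temperature reference.
#' @return mean squared residual.
#' @export
collapse_residual <- function(sweep, constants,
                              J_ref = log(1 + sqrt(2)) / 2) {
  sweep <- sweep[is.finite(sweep$r), ]
  y <- log(sweep$r) - (constants$z - constants$b) * log(sweep$L)
  x <- reduced_temperature(sweep$J, J_ref) * sweep$L
  mean((y - constants$c0 * x)^2)
}

#' J-isolines of constant timescale ratio
#'
#' For each lattice size, inverts the (monotone) swept relation `r(J)` by
#' interpolation of `ln r` against `J` to find the coupling `J_iso` at which
#' the timescale ratio equals `r_target`, and reports the percent deviation
#' from the finite-size critical coupling `J*(L)`.
#'
#' @param sweep a `sweep_table` with several `J` per `L` bracketing the
#'   target.
#' @param r_target target timescale ratio(s).
#' @return data.frame of class `isoline_result`: `r_target`, `L`, `J_iso`,
#'   `J_star`, `pct_dev`, `bracketed`.
#' @export
isoline <- function(sweep, r_target) {
  rows <- list()
  for (rt in r_target) {
    for (L in sort(unique(sweep$L))) {
      s <- sweep[sweep$L == L & is.finite(sweep$r), ]
      s <- s[order(s$J), ]
      ok <- nrow(s) >= 2 && min(s$r) <= rt && max(s$r) >= rt
      J_iso <- if (!ok) NA_real_
      else {
        # local-linear inversion of ln r(J) around the target: robust to
        # sampling noise while avoiding curvature over a wide J range
        dlr <- abs(log(s$r) - log(rt))
        near <- order(dlr)[seq_len(min(4, nrow(s)))]
        sl <- s[near, ]
        if (nrow(sl) >= 3) {
          f <- lm(J ~ lr, data = data.frame(J = sl$J, lr = log(sl$r)))
          unname(predict(f, newdata = data.frame(lr = log(rt))))
        } else {
          approx(log(s$r), s$J, xout = log(rt), ties = "ordered")$y
        }
      }
      Jst <- jstar_of_L(L)
      rows[[length(rows) + 1]] <- data.frame(
        r_target = rt, L = L, J_iso = J_iso, J_star = Jst,
        pct_dev = 100 * (J_iso / Jst - 1), bracketed = ok)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("isoline_result", "data.frame")
  out
}

#' Calibrate the fundamental flip frequency
#'
#' Along an isoline of constant timescale ratio `r`, the simulated
#' transition time scales as `c_tau * L^b`, so matching the experimental
#' characteristic residence time `Dt_exp` (seconds) gives
#' `omega0(L) = r * c_tau * L^b / Dt_exp` (1/s).
#'
#' @param r measured timescale ratio.
#' @param mean_residence_s experimental characteristic residence time (s).
#' @param L_range lattice sizes over which to evaluate.
#' @param constants a `scaling_constants` list (needs `b`, `c_tau`).
#' @return data.frame `L`, `omega0` (1/s), `timescale_ms` (= 1000/omega0).
#' @export
calibrate_omega0 <- function(r, mean_residence_s, L_range, constants) {
  if (r <= 0 || mean_residence_s <= 0 || any(L_range <= 0))
    stop("all inputs must be positive")
  om <- r * constants$c_tau * L_range^constants$b / mean_residence_s
  data.frame(L = L_range, omega0 = om, timescale_ms = 1000 / om)
}
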