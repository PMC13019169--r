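# Step-stimulus response analysis: replicate ensembles, response-time
# estimators and speed-amplitude trade-off scans with and without
# adaptation feedback.

#' Ensemble of step-stimulus responses
#'
#' Simulates `n_reps` stochastic replicates in which a ligand-field step
#' `dH` is applied at `t = 0`, and returns the per-replicate traces plus
#' their ensemble mean. Without adaptation the lattice starts from the
#' requested `init` (all-active by default, mimicking a fully active
#' pre-stimulus array); with adaptation each replicate is first pre-adapted
#' to its steady state with `H_L = 0` for `pre_adapt` time units.
#'
#' @param params a [model_params()] object (with `H_L = 0`).
#' @param dH ligand-field step (kT) applied at `t = 0`.
#' @param n_reps replicates (paper-style defaults: 48 non-adapting, 96
#'   adapting).
#' @param duration post-stimulus window (in `1/omega0` units).
#' @param sample_interval sampling interval.
#' @param adapt optional [adaptation_params()]; switches on feedback.
#' @param init initial state for the non-adapting case.
#' @param pre_adapt pre-adaptation time for the adapting case (one shared
#'   equilibration chain; replicates branch off decorrelated snapshots).
#' @param decorr chain time between adapting-replicate snapshots.
#' @param seed master seed; per-replicate seeds derived deterministically.
#' @return list of class `response_ensemble`: `time`, `mean` (ensemble
#'   average activity), `replicates` (matrix, one column per replicate),
#'   `dH`, `adapting`.
#' @export
step_response_ensemble <- function(params, dH, n_reps = 48, duration = 3000,
                                   sample_interval = 10, adapt = NULL,
                                   init = "all_active", pre_adapt = 20000,
                                   decorr = 2000, seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2, n_reps)
  reps <- matrix(NA_real_, nrow = floor(duration / sample_interval) + 1,
                 ncol = n_reps)
  tt <- NULL
  p <- model_params(params$L, params$J, params$H_b, params$H_L + dH,
                    params$omega0)
  chain_spins <- NULL; chain_m <- NULL
  if (!is.null(adapt)) {
    pre <- simulate_adapting(params, adapt, duration = pre_adapt,
                             sample_interval = pre_adapt / 4,
                             init = "random")
    meta <- attr(pre, "meta")
    chain_spins <- meta$final_spins; chain_m <- meta$final_m
  }
  for (k in seq_len(n_reps)) {
    if (is.null(adapt)) {
      set.seed(rep_seeds[k])
      tr <- simulate_activity(p, duration = duration,
                              sample_interval = sample_interval, init = init)
    } else {
      if (k > 1) {  # advance the unstimulated chain to decorrelate
        step <- simulate_adapting(params, adapt, duration = decorr,
                                  sample_interval = decorr / 2,
                                  init = chain_spins, m_init = chain_m)
        meta <- attr(step, "meta")
        chain_spins <- meta$final_spins; chain_m <- meta$final_m
      }
      tr <- simulate_adapting(p, adapt, duration = duration,
                              sample_interval = sample_interval,
                              init = chain_spins, m_init = chain_m)
    }
    reps[, k] <- tr$activity
    tt <- tr$time
  }
  structure(list(time = tt, mean = rowMeans(reps), replicates = reps,
                 dH = dH, adapting = !is.null(adapt), params = params),
            class = "response_ensemble")
}

#' Response time of a step response
#'
#' Three estimators:
#' `half_crossing` - mean over replicates of the first time the (lightly
#' smoothed) activity crosses `a = 0.5`; replicates that never cross are
#' censored at the window end and included as lower bounds (flagged).
#' `exponential` - time constant of `a(t) = a_inf + (a_0 - a_inf)
#' exp(-t/tau)` fitted to the ensemble mean (used for sub-saturating,
#' adapting responses).
#' `sigmoidal` - midpoint time of a logistic fit to the ensemble mean
#' (used for saturating stimuli).
#'
#' @param ens a `response_ensemble` (or, for `half_crossing`, any matrix of
#'   replicate traces with a `time` vector).
#' @param method one of `"half_crossing"`, `"exponential"`, `"sigmoidal"`.
#' @param smooth_window light smoothing before crossing detection.
#' @return list `t_R`, `censored_frac`, `method`, plus fit details for the
#'   fitting methods (`a_inf` is the fitted plateau).
#' @export
response_time <- function(ens, method = c("half_crossing", "exponential",
                                          "sigmoidal"),
                          smooth_window = 0) {
  method <- match.arg(method)
  tt <- ens$time
  if (method == "half_crossing") {
    dt <- median(diff(tt))
    cross <- apply(ens$replicates, 2, function(a) {
      if (smooth_window > 0) a <- smooth_activity(a, dt, smooth_window)
      i <- which(a <= 0.5)
      if (length(i) == 0) NA_real_ else tt[i[1]]
    })
    cens <- is.na(cross)
    cross[cens] <- max(tt)
    return(list(t_R = mean(cross), censored_frac = mean(cens),
                method = method))
  }
  y <- ens$mean
  if (method == "exponential") {
    # adapting responses recover after the trough; fit the decay segment only
    dtt <- median(diff(tt))
    ys <- smooth_activity(y, dtt, 5 * dtt)
    i_min <- which.min(ys)
    if (i_min >= 5 && i_min < length(y)) {
      tt <- tt[seq_len(i_min)]
      y <- y[seq_len(i_min)]
    }
    a0 <- y[1]
    ainf_guess <- min(y)
    # time at which the mean has covered (1 - 1/e) of its total excursion
    lvl <- a0 + (ainf_guess - a0) * (1 - exp(-1))
    tau_guess <- max(tt[which.min(abs(y - lvl))], median(diff(tt)))
    ssr <- function(par) {
      v <- sum((y - (par[1] + (a0 - par[1]) * exp(-tt / exp(par[2]))))^2)
      if (is.finite(v)) v else Inf
    }
    fit <- tryCatch(
      optim(c(ainf_guess, log(tau_guess)), ssr, method = "L-BFGS-B",
            lower = c(-0.5, log(median(diff(tt)) / 10)),
            upper = c(1.5, log(10 * max(tt)))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value))
      stop("exponential response fit did not converge")
    # a mean trace with no decaying structure gives a degenerate fit
    if (fit$value > ssr(c(mean(y), log(tau_guess))) &&
        abs(a0 - ainf_guess) < 0.05)
      stop("exponential response fit did not converge")
    return(list(t_R = exp(fit$par[2]), a_inf = fit$par[1], method = method))
  }
  # sigmoidal: logistic decay midpoint
  a0 <- max(y); a1 <- min(y)
  dt <- median(diff(tt))
  t_half_guess <- max(tt[which.min(abs(y - (a0 + a1) / 2))], dt / 2)
  ssr <- function(par) {
    v <- sum((y - (par[1] + (par[2] - par[1]) /
                     (1 + exp((tt - par[3]) / exp(par[4])))))^2)
    if (is.finite(v)) v else Inf
  }
  fit <- NULL; best <- Inf
  for (s_try in c(diff(range(tt)) / 20, 5 * dt, dt, dt / 4)) {
    f <- tryCatch(
      optim(c(a1, a0, t_half_guess, log(s_try)), ssr, method = "L-BFGS-B",
            lower = c(-0.5, 0, dt / 10, log(dt / 20)),
            upper = c(1.5, 1.5, max(tt), log(diff(range(tt))))),
      error = function(e) NULL)
    if (!is.null(f) && f$value < best) { best <- f$value; fit <- f }
  }
  if (is.null(fit) || best > 0.05 * length(y) * max(1e-6, var(y)))
    stop("sigmoidal response fit did not converge")
  list(t_R = fit$par[3], a_inf = fit$par[1], method = method)
}

#' Response amplitude
#'
#' `1 - <a>_post / 0.5`: the fractional drop of the post-response activity
#' relative to the half-maximal level.
#'
#' @param post_activity post-response mean activity (late-time plateau for
#'   non-adapting responses; fitted trough for adapting ones).
#' @return amplitude (0 when `<a> = 0.5`, 1 when `<a> = 0`).
#' @export
response_amplitude <- function(post_activity) {
  1 - post_activity / 0.5
}

#' Speed-amplitude trade-off scan
#'
#' For each `(J, dH)` combination, runs a step-response ensemble and records
#' the response time (half-crossing for non-adapting, exponential fit for
#' adapting), amplitude and speed `1/t_R`. The rows with `J` closest to
#' `J*(L)` form the critical isoline.
#'
#' @param L lattice side.
#' @param J_values couplings to scan (kT).
#' @param dH_values ligand-field steps (kT).
#' @param adapt optional [adaptation_params()].
#' @param n_reps replicates per point.
#' @param duration post-stimulus window (`1/omega0` units).
#' @param seed master seed.
#' @param ... passed to [step_response_ensemble()].
#' @return data.frame `J`, `dH`, `t_R`, `post_a`, `amplitude`, `speed`,
#'   `censored_frac`, `critical` (flag for the `J*(L)`-nearest row of each
#'   `dH`).
#' @export
tradeoff_scan <- function(L, J_values, dH_values, adapt = NULL, n_reps = 16,
                          duration = 3000, seed = 1, ...) {
  rows <- list()
  for (dH in dH_values) for (J in J_values) {
    sub <- (seed * 7907L + round(J * 1e4) + round(dH * 1e5)) %%
      .Machine$integer.max
    p <- model_params(L = L, J = J)
    ens <- step_response_ensemble(p, dH = dH, n_reps = n_reps,
                                  duration = duration, adapt = adapt,
                                  seed = as.integer(sub), ...)
    if (is.null(adapt)) {
      rt <- response_time(ens, "half_crossing")
      late <- ens$time >= 0.75 * max(ens$time)
      post <- mean(ens$mean[late])
      cens <- rt$censored_frac
    } else {
      rt <- tryCatch(response_time(ens, "exponential"), error = function(e) NULL)
      if (is.null(rt)) {
        rt <- list(t_R = NA_real_, a_inf = min(ens$mean))
      }
      post <- rt$a_inf  # fitted trough before re-adaptation
      cens <- NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      J = J, dH = dH, t_R = rt$t_R, post_a = post,
      amplitude = min(max(response_amplitude(post), 0), 1),
      speed = 1 / rt$t_R, censored_frac = cens)
  }
  out <- do.call(rbind, rows)
  Jst <- jstar_of_L(L)
  out$critical <- abs(out$J - Jst) == ave(abs(out$J - Jst), out$dH, FUN = min)
  out
}
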