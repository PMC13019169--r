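# Simulation front-ends over the compiled kinetic Monte Carlo event loop.

init_spins <- function(L, init, seed = NULL) {
  if (is.matrix(init)) {
    stopifnot(all(dim(init) == c(L, L)), all(init %in% c(-1L, 1L)))
    return(as.integer(t(init)))  # row-major for the C++ core
  }
  init <- match.arg(init, c("all_active", "all_inactive", "random"))
  switch(init,
    all_active = rep(1L, L * L),
    all_inactive = rep(-1L, L * L),
    random = {
      if (!is.null(seed)) set.seed(seed)
      sample(c(-1L, 1L), L * L, replace = TRUE)
    })
}

new_sim_trace <- function(times, activity, mean_m = NULL, meta = list()) {
  df <- data.frame(time = times, activity = activity)
  if (!is.null(mean_m) && length(mean_m) == length(times))
    df$mean_m <- mean_m
  structure(df, class = c("sim_trace", "data.frame"), meta = meta)
}

#' @export
print.sim_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Activity trace: %d samples, t in [%g, %g], <a> = %.3f\n",
              nrow(x), min(x$time), max(x$time), mean(x$activity)))
  if (!is.null(meta$params))
    cat(sprintf("  L = %d, J = %g kT, omega0 = %g%s\n",
                meta$params$L, meta$params$J, meta$params$omega0,
                if (isTRUE(meta$adapting)) ", adapting" else ""))
  invisible(x)
}

#' @export
plot.sim_trace <- function(x, ...) {
  plot(x$time, x$activity, type = "l", xlab = "time", ylab = "activity a(t)",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Simulate the conformational-spread model
#'
#' Runs the rejection-free kinetic Monte Carlo dynamics of the model and
#' returns the mean array activity `a(t)` in `[0, 1]` read piecewise-constant
#' on a uniform sample grid. The default `sample_interval = 33` (in `1/omega0`
#' units) mimics 1 Hz acquisition at the calibrated fundamental timescale of
#' about 30 ms; `downsample` applies a further integer decimation.
#'
#' @param params a [model_params()] object.
#' @param duration total simulated time (in `1/omega0` units).
#' @param sample_interval spacing of the output grid (same units).
#' @param init `"all_active"`, `"all_inactive"`, `"random"`, or an `L` x `L`
#'   spin matrix.
#' @param seed RNG seed (integer); the whole trajectory is reproducible.
#' @param downsample integer decimation factor applied after sampling.
#' @param species optional species grid from [assign_species()] for bond
#'   disorder.
#' @param site_bias optional `L` x `L` matrix of per-site static biasing
#'   fields (kT), added to `params$H_b`.
#' @param protocol optional [field_protocol()] of ligand-field steps.
#' @param max_events event budget safeguard.
#' @return a `sim_trace`: data.frame `time`, `activity` with simulation
#'   metadata in `attr(, "meta")` (including the final lattice for chaining).
#' @examples
#' p <- model_params(L = 8, J = 0.3)
#' tr <- simulate_activity(p, duration = 2000, sample_interval = 10, seed = 1)
#' mean(tr$activity)
#' @export
simulate_activity <- function(params, duration, sample_interval = 33,
                              init = "random", seed = NULL, downsample = 1L,
                              species = NULL, site_bias = NULL,
                              protocol = NULL, max_events = Inf) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  run_core(params, adapt = NULL, duration = duration,
           sample_interval = sample_interval, init = init,
           downsample = downsample, species = species, site_bias = site_bias,
           protocol = protocol, max_events = max_events, m_init = NULL,
           seed = seed)
}

#' Simulate with methylation adaptation feedback
#'
#' As [simulate_activity()], with per-site methylation dynamics entering the
#' same continuous-time event queue as the spin flips: eligible inactive
#' units methylate at rate `k_R`, eligible active units demethylate at rate
#' `k_B`, and each event shifts the unit's biasing field by one `alpha`
#' step with a sign that counteracts its activity (negative feedback). The
#' steady-state mean activity is `a0 = k_R / (k_R + k_B)` and after a
#' ligand-field step the mean activity re-adapts toward `a0`.
#'
#' @inheritParams simulate_activity
#' @param adapt an [adaptation_params()] object.
#' @param m_init optional `L` x `L` integer matrix of initial methylation
#'   levels (defaults to `m0` everywhere).
#' @return a `sim_trace` with an extra `mean_m` column.
#' @export
simulate_adapting <- function(params, adapt, duration, sample_interval = 33,
                              init = "random", seed = NULL, downsample = 1L,
                              species = NULL, site_bias = NULL,
                              protocol = NULL, m_init = NULL,
                              max_events = Inf) {
  stopifnot(inherits(params, "model_params"), inherits(adapt, "adaptation_params"))
  if (!is.null(seed)) set.seed(seed)
  run_core(params, adapt = adapt, duration = duration,
           sample_interval = sample_interval, init = init,
           downsample = downsample, species = species, site_bias = site_bias,
           protocol = protocol, max_events = max_events, m_init = m_init,
           seed = seed)
}

run_core <- function(params, adapt, duration, sample_interval, init,
                     downsample, species, site_bias, protocol, max_events,
                     m_init, seed) {
  L <- params$L
  spins0 <- init_spins(L, init)
  sb <- if (is.null(site_bias)) numeric(0) else as.numeric(t(site_bias))
  spv <- if (is.null(species)) integer(0) else as.integer(t(unclass(species)))
  js <- if (is.null(species)) 0 else attr(species, "J_same")
  jc <- if (is.null(species)) 0 else attr(species, "J_cross")
  pt <- if (is.null(protocol)) numeric(0) else protocol$t
  pd <- if (is.null(protocol)) numeric(0) else protocol$dH
  use_adapt <- !is.null(adapt)
  mi <- if (is.null(m_init)) integer(0) else as.integer(t(m_init))
  res <- .cs_simulate(L, spins0, params$J, params$H_b, sb, params$H_L,
                      params$omega0, duration, sample_interval, spv, js, jc,
                      use_adapt,
                      if (use_adapt) adapt$alpha else 0,
                      if (use_adapt) adapt$M else 0L,
                      if (use_adapt) adapt$m0 else 0L,
                      if (use_adapt) adapt$k_R else 0,
                      if (use_adapt) adapt$k_B else 0,
                      mi, pt, pd, max_events, use_adapt)
  keep <- seq(1, length(res$times), by = max(1L, as.integer(downsample)))
  meta <- list(params = params, adapt = adapt, seed = seed,
               sample_interval = sample_interval * max(1L, as.integer(downsample)),
               adapting = use_adapt, n_events = res$n_events,
               final_spins = matrix(res$final_spins, L, L, byrow = TRUE),
               final_m = if (use_adapt) matrix(res$final_m, L, L, byrow = TRUE),
               final_HL = res$final_HL)
  new_sim_trace(res$times[keep], res$activity[keep],
                if (use_adapt) res$mean_m[keep], meta)
}

#' Ligand-field stimulus protocol
#'
#' Ordered ligand-field changes `dH` (kT) applied at times `t`; each step is
#' added to the current ligand field. A positive step mimics attractant
#' (drives activity down).
#'
#' @param t event times (strictly increasing).
#' @param dH field increments (kT), same length as `t`.
#' @param initial_state initialization tag carried along for bookkeeping.
#' @return object of class `field_protocol`.
#' @export
field_protocol <- function(t, dH,
                           initial_state = c("equilibrated", "all_active",
                                             "all_inactive", "random")) {
  if (length(t) != length(dH)) stop("t and dH must have equal length")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  structure(list(t = as.numeric(t), dH = as.numeric(dH),
                 initial_state = match.arg(initial_state)),
            class = "field_protocol")
}

#' Sample decorrelated equilibrium lattice states
#'
#' Equilibrates the lattice for `burn_in` time units, then records `n_states`
#' spin configurations separated by `spacing` time units, chaining the
#' dynamics so states come from one continuous trajectory.
#'
#' @inheritParams simulate_activity
#' @param n_states number of snapshots (default 48).
#' @param burn_in equilibration time before the first snapshot.
#' @param spacing time between snapshots.
#' @return list of `L` x `L` spin matrices.
#' @export
sample_states <- function(params, n_states = 48, burn_in = 500, spacing = 100,
                          init = "random", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- vector("list", n_states)
  tr <- simulate_activity(params, duration = burn_in,
                          sample_interval = burn_in / 2, init = init)
  cur <- attr(tr, "meta")$final_spins
  for (k in seq_len(n_states)) {
    tr <- simulate_activity(params, duration = spacing,
                            sample_interval = spacing / 2, init = cur)
    cur <- attr(tr, "meta")$final_spins
    states[[k]] <- cur
  }
  states
}

#' Correlation length from equilibrium states
#'
#' Computes the two-point correlation `c(r)`, the spin product averaged over
#' all horizontally and vertically separated pairs at distance `r` (diagonal
#' pairs ignored), for each state of an ensemble, fits `c(r) = exp(-r/xi)`
#' on `fit_range` by least squares on `log c(r)`, and averages `xi` over the
#' ensemble.
#'
#' Uncorrelated ensembles (some `c(r) <= 0` in the fit range) return
#' `xi = 0` with `status = "uncorrelated"`; fully frozen ensembles
#' (`c(r) = 1` everywhere) return `status = "not_measurable"`.
#'
#' @param states list of spin matrices (e.g. from [sample_states()]).
#' @param fit_range integer separations to fit (default `1:floor(L/4)`).
#' @return list with `xi`, per-state `xi_i`, the mean correlation `c_r`,
#'   and `status`.
#' @export
correlation_length <- function(states, fit_range = NULL) {
  if (length(states) < 1) stop("need at least one state")
  L <- nrow(states[[1]])
  if (is.null(fit_range)) fit_range <- seq_len(max(2L, L %/% 4L))
  corr_one <- function(sp, r) {
    h <- sp[, seq_len(L - r), drop = FALSE] * sp[, seq_len(L - r) + r, drop = FALSE]
    v <- sp[seq_len(L - r), , drop = FALSE] * sp[seq_len(L - r) + r, , drop = FALSE]
    mean(c(h, v))
  }
  cmat <- vapply(states, function(sp) vapply(fit_range, function(r) corr_one(sp, r),
                                             numeric(1)), numeric(length(fit_range)))
  cmat <- matrix(cmat, nrow = length(fit_range))
  cbar <- rowMeans(cmat)
  if (all(abs(cbar - 1) < 1e-12))
    return(list(xi = NA_real_, xi_i = rep(NA_real_, length(states)),
                c_r = cbar, r = fit_range, status = "not_measurable"))
  fit_xi <- function(cr) {
    if (any(cr <= 0)) return(0)
    f <- lm(log(cr) ~ 0 + fit_range)
    slope <- coef(f)[[1]]
    if (slope >= 0) return(Inf)
    -1 / slope
  }
  xi_i <- apply(cmat, 2, fit_xi)
  status <- if (any(cbar <= 0)) "uncorrelated" else "ok"
  xi <- if (status == "uncorrelated") 0 else mean(xi_i[is.finite(xi_i)])
  list(xi = xi, xi_i = xi_i, c_r = cbar, r = fit_range, status = status)
}
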