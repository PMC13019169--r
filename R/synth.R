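# Synthetic single-cell FRET experiments and mock switching traces with
# known ground truth, used to validate every stage of the pipeline.

#' Parameters of a synthetic two-state cell
#'
#' Defaults emulate the experimentally observed switching phenotype:
#' residence times of order 50 s, transition times of order 5 s, 1 Hz
#' sampling, additive Gaussian noise of 0.15 activity units, and
#' photobleaching with a time constant of several hundred seconds.
#'
#' @param bias long-run activity bias (fraction of time in the up state).
#' @param mean_dt_up,mean_dt_down mean residence times (s) in the up/down
#'   state. If `NULL`, they are derived from `bias` and `mean_dt`:
#'   `mean_dt_up = 2 * bias * mean_dt`, `mean_dt_down = 2 * (1 - bias) *
#'   mean_dt`.
#' @param mean_dt characteristic residence scale (s) used when the per-state
#'   means are derived from `bias`.
#' @param tau_up,tau_down transition-ramp time constants (s).
#' @param sigma additive Gaussian noise s.d. (activity units).
#' @param sample_rate sampling rate (Hz).
#' @param duration trace length (s).
#' @param bleach_donor,bleach_acceptor per-channel bleaching time constants
#'   (s; `Inf` disables).
#' @param donor0,acceptor0 base channel intensities (a.u.).
#' @param R0 acceptor/donor ratio at zero FRET.
#' @param fret_max FRET index at full activity.
#' @param alpha_fret FRET setup constant.
#' @param intensity_sigma relative (fractional) Gaussian noise on each
#'   channel.
#' @param tau_sample optional vector of transition times; when given, each
#'   transition's ramp constant is resampled from it (rescaled to mean
#'   `tau_up`/`tau_down`), so mock traces can mirror an empirical
#'   transition-time distribution.
#' @param windows a [stimulus_windows()] object; the default puts an
#'   attractant window early and a repellent window late in the trace.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(bias = 0.5, mean_dt_up = NULL, mean_dt_down = NULL,
                         mean_dt = 50, tau_up = 5, tau_down = 5,
                         sigma = 0.15, sample_rate = 1, duration = 1000,
                         bleach_donor = 800, bleach_acceptor = 500,
                         donor0 = 1000, acceptor0 = NULL, R0 = 0.45,
                         fret_max = 0.15, alpha_fret = 0.3,
                         intensity_sigma = 0, windows = NULL,
                         tau_sample = NULL) {
  if (is.null(mean_dt_up)) mean_dt_up <- 2 * bias * mean_dt
  if (is.null(mean_dt_down)) mean_dt_down <- 2 * (1 - bias) * mean_dt
  stopifnot(bias > 0, bias < 1, mean_dt_up > tau_up, mean_dt_down > tau_down,
            sigma >= 0, sample_rate > 0, duration > 0)
  if (is.null(windows))
    windows <- stimulus_windows(attractant = c(20, 60),
                                repellent = c(duration - 60, duration - 20))
  if (is.null(acceptor0)) acceptor0 <- donor0 * R0
  structure(list(bias = bias, mean_dt_up = mean_dt_up,
                 mean_dt_down = mean_dt_down, tau_up = tau_up,
                 tau_down = tau_down, sigma = sigma,
                 sample_rate = sample_rate, duration = duration,
                 bleach_donor = bleach_donor, bleach_acceptor = bleach_acceptor,
                 donor0 = donor0, acceptor0 = acceptor0, R0 = R0,
                 fret_max = fret_max, alpha_fret = alpha_fret,
                 intensity_sigma = intensity_sigma, windows = windows,
                 tau_sample = tau_sample),
            class = "synth_params")
}

#' Generate a two-state telegraph activity trace
#'
#' Alternating exponential dwells in the up (`a = 1`) and down (`a = 0`)
#' states with the configured means, connected by deterministic saturating
#' exponential ramps with time constants `tau_up`/`tau_down`, clamped to the
#' stimulus windows (attractant forces 0, repellent forces 1), then additive
#' Gaussian noise. The ground-truth event list (times, directions, dwell
#' draws) is returned alongside.
#'
#' @param params a [synth_params()] list.
#' @param seed RNG seed.
#' @return list with `trace` (data.frame `time`, `activity`), `truth`
#'   (data.frame of switch events `t_event`, `direction`), `clean`
#'   (noise-free activity), `params`.
#' @export
gen_two_state_activity <- function(params = synth_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dt <- 1 / p$sample_rate
  tt <- seq(0, p$duration, by = dt)
  # alternate exponential dwells; start state drawn by the bias
  state <- as.integer(runif(1) < p$bias)
  t_cur <- 0
  ev_t <- numeric(0); ev_dir <- integer(0)
  states <- integer(0); starts <- numeric(0)
  while (t_cur < p$duration) {
    starts <- c(starts, t_cur); states <- c(states, state)
    dwell <- rexp(1, rate = 1 / if (state == 1) p$mean_dt_up else p$mean_dt_down)
    t_cur <- t_cur + dwell
    if (t_cur < p$duration) {
      state <- 1L - state
      ev_t <- c(ev_t, t_cur)
      ev_dir <- c(ev_dir, if (state == 1) 1L else -1L)
    }
  }
  # piecewise telegraph with saturating-exponential onset after each switch
  a <- numeric(length(tt))
  bounds <- c(starts, p$duration)
  for (k in seq_along(states)) {
    seg <- tt >= bounds[k] & tt < bounds[k + 1]
    if (!any(seg)) next
    target <- as.numeric(states[k])
    if (k == 1) {
      a[seg] <- target
    } else {
      tau <- if (states[k] == 1) p$tau_up else p$tau_down
      if (!is.null(p$tau_sample))
        tau <- tau * sample(p$tau_sample, 1) / mean(p$tau_sample)
      from <- as.numeric(states[k - 1])
      a[seg] <- target + (from - target) * exp(-(tt[seg] - bounds[k]) / tau)
    }
  }
  a[tt >= bounds[length(bounds)]] <- as.numeric(states[length(states)])
  # clamp to stimulus windows
  a[in_windows(tt, p$windows$attractant)] <- 0
  a[in_windows(tt, p$windows$repellent)] <- 1
  clean <- a
  if (p$sigma > 0) a <- a + rnorm(length(a), sd = p$sigma)
  truth <- data.frame(t_event = ev_t, direction = ev_dir)
  list(trace = data.frame(time = tt, activity = a),
       truth = truth, clean = clean, params = p)
}

#' Synthesize donor/acceptor fluorescence from an activity trace
#'
#' Inverts the preprocessing chain: `FRET(t) = a(t) * fret_max`, the ratio
#' `R(t)` is solved from the ratiometric index
#' `FRET = (R - R0)/(R + alpha)`, and donor/acceptor channels are built with
#' per-channel exponential bleaching and multiplicative Gaussian noise. With
#' zero noise and no bleaching, [fret_activity()] recovers the input
#' activity exactly.
#'
#' @param activity data.frame `time`, `activity` (e.g. the `clean` or
#'   `trace` output of [gen_two_state_activity()]).
#' @param params a [synth_params()] list.
#' @param seed RNG seed for the channel noise.
#' @return data.frame `time`, `donor`, `acceptor`.
#' @export
gen_fret_cell <- function(activity, params = synth_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  tt <- activity$time
  f <- activity$activity * p$fret_max
  if (any(1 - f <= 0)) stop("activity * fret_max must stay below 1")
  R <- (p$R0 + p$alpha_fret * f) / (1 - f)
  if (any(R + p$alpha_fret <= 0)) stop("implied ratio violates R > -alpha")
  D <- p$donor0 * exp(-tt / p$bleach_donor)
  A <- R * p$donor0 * exp(-tt / p$bleach_acceptor)
  if (p$intensity_sigma > 0) {
    D <- D * (1 + rnorm(length(D), sd = p$intensity_sigma))
    A <- A * (1 + rnorm(length(A), sd = p$intensity_sigma))
    D <- pmax(D, p$donor0 * 1e-3)
  }
  data.frame(time = tt, donor = D, acceptor = A)
}

#' Generate a synthetic single-cell FRET cohort
#'
#' Draws per-cell biases (and optionally Arrhenius-structured residence
#' means), generates each cell's telegraph activity and fluorescence
#' channels with derived sub-seeds, and returns the traces, the shared
#' stimulus windows and a full ground-truth record.
#'
#' @param n_cells number of cells (>= 0).
#' @param bias_range biases are drawn uniformly from this interval.
#' @param gamma_up,gamma_down if non-`NULL`, impose Arrhenius structure on
#'   the per-cell residence means: `mean_dt_up = mean_dt *
#'   exp(-gamma_up * dG)` (and likewise down) with `dG = delta_G(bias)`.
#' @param mean_dt characteristic residence time (s).
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param ... further arguments to [synth_params()].
#' @return list with `traces` (long data.frame `cell_id`, `time`, `donor`,
#'   `acceptor`), `activity` (ground-truth noisy activity), `windows`,
#'   `truth` (per-cell parameters and event lists).
#' @export
gen_cohort <- function(n_cells, bias_range = c(0.2, 0.8), gamma_up = NULL,
                       gamma_down = NULL, mean_dt = 50, seed = 1, ...) {
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max %/% 2, max(n_cells, 1))
  shared <- synth_params(mean_dt = mean_dt, ...)
  traces <- list(); act <- list(); truth <- list()
  for (i in seq_len(n_cells)) {
    set.seed(cell_seeds[i])
    bias <- runif(1, bias_range[1], bias_range[2])
    if (!is.null(gamma_up)) {
      dg <- delta_G(bias)
      up <- mean_dt * exp(-gamma_up * dg)
      dn <- mean_dt * exp(-gamma_down * dg)
    } else {
      up <- 2 * bias * mean_dt
      dn <- 2 * (1 - bias) * mean_dt
    }
    p <- synth_params(bias = bias, mean_dt_up = up, mean_dt_down = dn,
                      mean_dt = mean_dt, ...)
    g <- gen_two_state_activity(p)
    fl <- gen_fret_cell(data.frame(time = g$trace$time,
                                   activity = g$clean), p)
    id <- sprintf("cell%03d", i)
    traces[[i]] <- cbind(cell_id = id, fl)
    act[[i]] <- cbind(cell_id = id, g$trace)
    truth[[i]] <- list(cell_id = id, bias = bias, mean_dt_up = up,
                       mean_dt_down = dn, tau_up = p$tau_up,
                       tau_down = p$tau_down, seed = cell_seeds[i],
                       events = g$truth)
  }
  list(traces = if (n_cells) do.call(rbind, traces) else
         data.frame(cell_id = character(0), time = numeric(0),
                    donor = numeric(0), acceptor = numeric(0)),
       activity = if (n_cells) do.call(rbind, act) else
         data.frame(cell_id = character(0), time = numeric(0),
                    activity = numeric(0)),
       windows = shared$windows,
       truth = truth)
}

#' Synthetic receptor-cluster intensity profile
#'
#' A Gaussian bump of the given amplitude and width on a constant
#' background, plus Gaussian noise: a fixture for [cluster_intensity()].
#'
#' @param length profile length (samples).
#' @param background constant background level.
#' @param amplitude peak height above background.
#' @param width Gaussian s.d. of the peak (samples; must be < length).
#' @param noise additive Gaussian noise s.d.
#' @param seed RNG seed.
#' @return data.frame `position`, `intensity`.
#' @export
gen_cluster_profile <- function(length = 100, background = 100,
                                amplitude = 50, width = 3, noise = 0,
                                seed = NULL) {
  if (width >= length) stop("peak width must be smaller than the profile")
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(length)
  I <- background + amplitude * exp(-(x - length / 2)^2 / (2 * width^2))
  if (noise > 0) I <- I + rnorm(length, sd = noise)
  data.frame(position = x, intensity = I)
}
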