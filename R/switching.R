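# Switching statistics of two-state kinase-activity traces: event detection,
# residence and transition times, two-state classification, free-energy bias,
# Arrhenius scaling, dwell-time fits, energy landscapes, timescale ratio and
# noise strength.

#' Event-detection parameters
#'
#' Tunables of the derivative-peak switching-event detector. All time-like
#' quantities are in the time units of the trace (seconds for 1 Hz FRET
#' data, `1/omega0` for simulated traces).
#'
#' @param smooth_window moving-average width (default 3 time units, the
#'   low-pass filter applied before differentiation).
#' @param prominence threshold on the per-sample derivative of the filtered
#'   signal (activity units/sample).
#' @param min_separation minimum time between events.
#' @param amp_window width of the flanking windows whose medians define the
#'   event amplitude.
#' @param amp_gap offset of the amplitude windows from the event (default
#'   `amp_window/2`), so they sample the plateaus, not the ramp.
#' @param amp_min minimum |amplitude| for a candidate to count as an event
#'   (vetoes derivative peaks produced by noise).
#' @param two_state_frac fraction of transitions that must be large for a
#'   cell to classify as two-state (default 0.65).
#' @param two_state_amp amplitude threshold defining a "large" transition
#'   (default 0.7).
#' @param min_events minimum number of events for a cell to count as
#'   switching (default 3).
#' @param tau_window half-width of the per-event context used for the
#'   transition-time fit (time units); always truncated at the neighbouring
#'   events.
#' @return list of class `event_params`.
#' @export
event_params <- function(smooth_window = 3, prominence = 0.10,
                         min_separation = 5, amp_window = 4,
                         amp_gap = amp_window / 2, amp_min = 0.3,
                         two_state_frac = 0.65, two_state_amp = 0.7,
                         min_events = 3, tau_window = 40) {
  stopifnot(smooth_window > 0, prominence > 0, min_separation >= 0,
            amp_window > 0, amp_gap >= 0, amp_min >= 0,
            two_state_frac > 0, two_state_frac <= 1,
            two_state_amp > 0, two_state_amp <= 1, min_events >= 1,
            tau_window > 0)
  structure(list(smooth_window = smooth_window, prominence = prominence,
                 min_separation = min_separation, amp_window = amp_window,
                 amp_gap = amp_gap, amp_min = amp_min,
                 two_state_frac = two_state_frac,
                 two_state_amp = two_state_amp, min_events = min_events,
                 tau_window = tau_window),
            class = "event_params")
}

#' Moving-average smoothing
#'
#' Centred moving average of width `window` (time units); edge samples use
#' truncated windows. With a window of one sample this is the identity.
#'
#' @param a activity samples (uniformly spaced).
#' @param dt sample interval.
#' @param window smoothing window in time units.
#' @return smoothed series, same length.
#' @export
smooth_activity <- function(a, dt, window = 3) {
  n <- length(a)
  if (window >= n * dt) stop("smoothing window must be shorter than the trace")
  half <- max(0L, as.integer(floor(window / dt / 2)))
  if (half == 0L) return(a)
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

trace_time <- function(trace) {
  if (is.data.frame(trace)) trace$time else attr(trace, "time")
}
trace_activity <- function(trace) {
  if (is.data.frame(trace)) trace$activity else as.numeric(trace)
}

#' Detect switching events
#'
#' Low-pass filters the activity trace with a centred moving average, takes
#' its per-sample derivative, and marks switching events at derivative peaks
#' exceeding the prominence threshold, separated by at least
#' `min_separation`. Each event gets an amplitude (difference of the median
#' activity over `amp_window`-wide windows after vs before the event; its
#' sign is the switch direction), a transition time from a saturating
#' exponential fit ([fit_transition_time()]), and a residence time equal to
#' the gap to the next event. The interval before the first event and the
#' censored terminal interval are dropped from residence statistics.
#'
#' @param trace data.frame with `time` and `activity` (uniform sampling).
#' @param params an [event_params()] list.
#' @param fit_tau logical; fit per-event transition times (default TRUE).
#' @return data.frame of class `switch_events` with columns `t_event`,
#'   `direction`, `amplitude`, `tau`, `residence` (NA for the last event).
#' @export
detect_events <- function(trace, params = event_params(), fit_tau = TRUE) {
  tt <- trace_time(trace); a <- trace_activity(trace)
  n <- length(a)
  empty <- data.frame(t_event = numeric(0), direction = integer(0),
                      amplitude = numeric(0), tau = numeric(0),
                      residence = numeric(0))
  class(empty) <- c("switch_events", "data.frame")
  if (n < 5) return(empty)
  dt <- median(diff(tt))
  s <- smooth_activity(a, dt, params$smooth_window)
  d <- diff(s)  # activity units per sample
  # candidate peaks: local maxima of |d| above threshold
  absd <- abs(d)
  cand <- which(absd >= params$prominence)
  cand <- cand[cand > 1 & cand < length(d)]
  cand <- cand[absd[cand] >= absd[cand - 1] & absd[cand] >= absd[cand + 1]]
  if (length(cand) == 0) return(empty)
  # enforce minimum separation, keeping the strongest peak of each cluster
  cand <- cand[order(-absd[cand])]
  keep <- logical(0); kept <- integer(0)
  min_gap <- params$min_separation / dt
  for (k in cand) {
    if (all(abs(k - kept) >= min_gap)) kept <- c(kept, k)
  }
  kept <- sort(kept)
  # amplitude from flanking medians, offset by a gap so the windows sit on
  # the plateaus rather than inside the transition ramp
  wA <- max(1L, as.integer(round(params$amp_window / dt)))
  gap <- max(1L, as.integer(round(params$amp_gap / dt)))
  amp <- vapply(kept, function(k) {
    pre <- a[max(1, k - gap - wA):max(1, k - gap)]
    post <- a[min(n, k + 1 + gap):min(n, k + 1 + gap + wA)]
    median(post) - median(pre)
  }, numeric(1))
  # veto small amplitudes and candidates whose amplitude sign disagrees
  # with the derivative (noise peaks riding next to a genuine transition)
  ok <- abs(amp) >= params$amp_min & sign(amp) == sign(d[kept])
  kept <- kept[ok]; amp <- amp[ok]
  if (length(kept) == 0) return(empty)
  # a two-state signal alternates: of two same-direction events in close
  # succession (echoes of one transition), keep the stronger
  prox <- max(3 * params$amp_window, 2 * params$min_separation) / dt
  repeat {
    if (length(kept) < 2) break
    dup <- which(diff(sign(amp)) == 0 & diff(kept) < prox)
    if (length(dup) == 0) break
    i <- dup[1]
    drop_i <- if (abs(amp[i]) >= abs(amp[i + 1])) i + 1 else i
    kept <- kept[-drop_i]; amp <- amp[-drop_i]
  }
  ev <- data.frame(t_event = tt[kept],
                   direction = ifelse(amp > 0, 1L, -1L),
                   amplitude = amp,
                   tau = NA_real_,
                   residence = c(diff(tt[kept]), NA_real_))
  if (fit_tau) {
    tev <- ev$t_event
    for (i in seq_len(nrow(ev))) {
      lo <- if (i > 1) tev[i - 1] + dt else tt[1]
      hi <- if (i < length(tev)) tev[i + 1] - dt else tt[n]
      # too little plateau context on either side makes the ramp fit
      # unreliable; leave tau flagged missing for such events
      if (tev[i] - lo < params$tau_window / 3 ||
          hi - tev[i] < params$tau_window / 3) next
      ev$tau[i] <- fit_transition_time(tt, a, tev[i], ev$direction[i],
                                       window = params$tau_window,
                                       bounds = c(lo, hi),
                                       smooth_window = params$smooth_window)
    }
  }
  class(ev) <- c("switch_events", "data.frame")
  ev
}

#' @export
print.switch_events <- function(x, ...) {
  cat(sprintf("%d switching events (%d up, %d down); mean |amplitude| %.2f\n",
              nrow(x), sum(x$direction > 0), sum(x$direction < 0),
              if (nrow(x)) mean(abs(x$amplitude)) else NA))
  if (nrow(x)) print.data.frame(head(x, 10), ...)
  invisible(x)
}

#' Transition time of a single switching event
#'
#' Fits a saturating exponential `a(t) = a_pre + Da * (1 - exp(-(t - t0)/tau))`
#' for `t > t0` (time-mirrored for downward switches by sign of `Da`) to the
#' raw samples around the event; the plateaus `a_pre` and `a_pre + Da` are
#' anchored at the flanking medians and `(t0, tau)` are optimized by bounded
#' least squares. `tau` is the time to traverse a fraction `1 - 1/e` of the
#' amplitude. An instantaneous step sampled at interval `dt` returns
#' `tau <= dt`.
#'
#' @param time,activity the raw trace.
#' @param t_event event time from [detect_events()].
#' @param direction +1 (up) or -1 (down).
#' @param window half-width (time units) of the fit context.
#' @param bounds optional `c(tmin, tmax)` truncating the context (e.g. at
#'   neighbouring events).
#' @param smooth_window if positive, the ramp model is compared on the
#'   moving-average-filtered trace, with the model convolved by the same
#'   filter (noise-robust and free of the widening bias a filter would
#'   otherwise introduce).
#' @return `tau` (time units), or `NA` if the fit is degenerate.
#' @export
fit_transition_time <- function(time, activity, t_event, direction,
                                window = 20, bounds = NULL,
                                smooth_window = 0) {
  dt <- median(diff(time))
  half <- if (smooth_window > 0)
    max(0L, as.integer(floor(smooth_window / dt / 2))) else 0L
  lo <- t_event - window; hi <- t_event + window
  if (!is.null(bounds)) {
    lo <- max(lo, bounds[1]); hi <- min(hi, bounds[2])
  }
  # extend the context so the filter of the model sees the same neighbours
  sel <- which(time >= lo - half * dt & time <= hi + half * dt)
  if (length(sel) < 8) return(NA_real_)
  tt <- time[sel]; a <- activity[sel]
  core <- tt >= lo & tt <= hi
  pre <- a[tt < t_event - dt & core]
  post <- a[tt > t_event + dt & core]
  if (length(pre) < 3 || length(post) < 3) return(NA_real_)
  # anchor the pre plateau on the outer half, away from the ramp
  a0 <- median(pre[seq_len(ceiling(length(pre) / 2))])
  obs <- if (half > 0) smooth_activity(a, dt, smooth_window) else a
  span <- (hi - lo) / 2
  lower <- c(max(lo, t_event - span / 2), log(dt / 10))
  upper <- c(min(hi, t_event + span / 2), log(span))
  tau <- NA_real_
  tau_guess <- 3 * dt
  # iterate: the post-plateau anchor must exclude the ramp, whose extent
  # (~3 tau) is only known once tau is fitted
  for (iter in 1:3) {
    far <- a[tt > t_event + 3 * tau_guess & tt <= hi]
    a1 <- if (length(far) >= 3) median(far)
    else median(post[seq(length.out = ceiling(length(post) / 2),
                         from = floor(length(post) / 2) + 1)])
    Da <- a1 - a0
    if (!is.finite(Da) || Da * direction <= 0) Da <- direction * abs(Da)
    model <- function(par) {
      t0 <- par[1]; tau <- exp(par[2])
      pred <- ifelse(tt <= t0, a0, a0 + Da * (1 - exp(-(tt - t0) / tau)))
      if (half > 0) pred <- smooth_activity(pred, dt, smooth_window)
      v <- sum((obs[core] - pred[core])^2)
      if (is.finite(v)) v else Inf
    }
    # coarse grid over (t0, log tau) to dodge local minima, then polish
    best <- NULL; best_v <- Inf
    for (t0g in seq(lower[1], upper[1], length.out = 9))
      for (ltg in seq(lower[2], upper[2], length.out = 9)) {
        v <- model(c(t0g, ltg))
        if (v < best_v) { best_v <- v; best <- c(t0g, ltg) }
      }
    if (!is.finite(best_v)) return(NA_real_)
    fit <- tryCatch(
      optim(best, model, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    tau <- exp(fit$par[2])
    if (abs(tau - tau_guess) < 0.05 * tau_guess) break
    tau_guess <- tau
  }
  tau
}

#' Free-energy bias from the mean activity
#'
#' `Delta G = ln((1 - <a>)/<a>)` in kT: the free-energy difference between
#' the down and up wells of the two-state landscape. `<a> > 1/2` gives
#' `Delta G < 0`.
#'
#' @param mean_activity mean activity in (0, 1).
#' @return `Delta G` (kT).
#' @export
delta_G <- function(mean_activity) {
  if (any(mean_activity <= 0 | mean_activity >= 1))
    stop("mean activity must lie strictly inside (0, 1)")
  log((1 - mean_activity) / mean_activity)
}

#' Timescale ratio r
#'
#' The dimensionless ratio `r = <Dt> / <tau>` with
#' `<tau> = (<tau_+> + <tau_->)/2`; it cancels the unknown fundamental flip
#' frequency and is the key observable for finite-size scaling.
#'
#' @param mean_dt characteristic residence time.
#' @param tau_up,tau_down mean upward/downward transition times.
#' @return `r`.
#' @examples
#' timescale_ratio(47.0, 4.79, 6.06)  # about 8.7, i.e. r ~ 9
#' @export
timescale_ratio <- function(mean_dt, tau_up, tau_down) {
  if (mean_dt <= 0 || tau_up <= 0 || tau_down <= 0)
    stop("timescales must be positive")
  mean_dt / ((tau_up + tau_down) / 2)
}

#' Noise strength of an activity trace
#'
#' `eta = sd(a) / a0`, the standard deviation of the activity over the
#' analysis window divided by the steady-state mean.
#'
#' @param a activity samples.
#' @param a0 steady-state mean activity (> 0).
#' @return `eta >= 0`.
#' @export
noise_strength <- function(a, a0) {
  if (a0 <= 0) stop("a0 must be > 0")
  sd(a) / a0
}

#' Two-state classification and renormalization
#'
#' A cell is two-state when at least `two_state_frac` of its transitions
#' have `|amplitude| >= two_state_amp` (defaults 65% and 0.7) and it has at
#' least `min_events` events. For two-state cells a second pass refines the
#' bleach correction using only dwell segments in the dominant state
#' (low-activity segments when the bias is below 0.5, high-activity
#' otherwise), renormalizes the trace by the upper histogram peak, and
#' re-extracts the events.
#'
#' @param trace data.frame `time`, `activity`.
#' @param events events from [detect_events()]; re-detected internally after
#'   refinement.
#' @param params an [event_params()] list.
#' @return list with `is_two_state`, `fraction_large`, `events` (refined for
#'   two-state cells), `trace` (refined), `bias`.
#' @export
classify_two_state <- function(trace, events = NULL, params = event_params()) {
  if (is.null(events)) events <- detect_events(trace, params)
  n_ev <- nrow(events)
  frac <- if (n_ev > 0) mean(abs(events$amplitude) >= params$two_state_amp) else 0
  if (n_ev < params$min_events)
    return(list(is_two_state = FALSE, classification = "non-switching",
                fraction_large = frac, events = events, trace = trace,
                bias = mean(trace$activity)))
  if (frac < params$two_state_frac)
    return(list(is_two_state = FALSE, classification = "multi-state",
                fraction_large = frac, events = events, trace = trace,
                bias = mean(trace$activity)))
  ref <- refine_two_state(trace, params)
  ev2 <- detect_events(ref, params)
  list(is_two_state = TRUE, classification = "two-state",
       fraction_large = frac, events = ev2, trace = ref,
       bias = mean(ref$activity))
}

# Second-pass bleach refinement on the dominant-state dwell segments plus
# histogram-peak renormalization.
refine_two_state <- function(trace, params) {
  tt <- trace$time; a <- trace$activity
  dt <- median(diff(tt))
  s <- smooth_activity(a, dt, params$smooth_window)
  bias <- mean(a)
  dom_low <- bias < 0.5
  seg <- if (dom_low) s < 0.3 else s > 0.7
  if (sum(seg) >= 10) {
    base <- a[seg]
    tb <- tt[seg]
    # residual linear drift of the dominant plateau (log-domain when high)
    if (dom_low) {
      f <- lm(base ~ tb)
      a <- a - (predict(f, newdata = data.frame(tb = tt)) - coef(f)[[1]])
    } else {
      f <- lm(log(pmax(base, 0.05)) ~ tb)
      a <- a / exp(predict(f, newdata = data.frame(tb = tt)) - coef(f)[[1]])
    }
  }
  # renormalize by the location of the upper histogram peak
  h <- hist(a, breaks = seq(min(a) - 0.025, max(a) + 0.075, by = 0.05),
            plot = FALSE)
  hi <- h$mids > 0.5 * max(a)
  if (any(hi)) {
    peak <- h$mids[hi][which.max(h$counts[hi])]
    if (peak > 0.2) a <- a / peak
  }
  out <- data.frame(time = tt, activity = a)
  if ("cell_id" %in% names(trace)) out$cell_id <- trace$cell_id
  out
}

#' Maximum-likelihood exponential fit of dwell times
#'
#' Fits an exponential distribution to a group of residence times by maximum
#' likelihood (rate = 1/mean) and reports a Kolmogorov-Smirnov statistic and
#' p-value against the fitted exponential. Groups smaller than `min_n` are
#' skipped (`fitted = FALSE`).
#'
#' @param dwells positive dwell samples.
#' @param min_n minimum group size (default 20).
#' @return list `rate`, `mean`, `n`, `ks_stat`, `ks_p`, `fitted`.
#' @export
fit_exponential_residence <- function(dwells, min_n = 20) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  n <- length(dwells)
  if (n < min_n)
    return(list(rate = NA_real_, mean = NA_real_, n = n,
                ks_stat = NA_real_, ks_p = NA_real_, fitted = FALSE))
  m <- mean(dwells)
  ks <- suppressWarnings(ks.test(dwells, "pexp", rate = 1 / m))
  list(rate = 1 / m, mean = m, n = n,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value, fitted = TRUE)
}

#' Energy landscape from pooled activity samples
#'
#' The coarse-grained landscape `-ln p(a)` (kT), min-shifted to zero, from a
#' histogram of pooled activity samples. Also reports the well-depth
#' difference between the low- and high-activity minima when both exist.
#'
#' @param a pooled activity samples (possibly several cells at similar bias).
#' @param n_bins histogram bins (default 25 over the data range).
#' @return list of class `energy_landscape`: `mids`, `G`, `depth_difference`.
#' @export
energy_landscape <- function(a, n_bins = 25) {
  rng <- range(a)
  h <- hist(a, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  G <- ifelse(p > 0, -log(p), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  lo <- h$mids < 0.5; hi <- !lo
  depth <- if (any(is.finite(G[lo])) && any(is.finite(G[hi])))
    min(G[lo], na.rm = TRUE) - min(G[hi], na.rm = TRUE) else NA_real_
  structure(list(mids = h$mids, G = G, depth_difference = depth),
            class = "energy_landscape")
}

#' @export
plot.energy_landscape <- function(x, ...) {
  plot(x$mids, x$G, type = "b", xlab = "activity a",
       ylab = expression(-ln ~ p(a) ~ "(kT)"), ...)
  invisible(x)
}

#' Per-cell switching summary
#'
#' Runs detection and two-state classification on one activity trace and
#' assembles the per-cell statistics: activity bias, `Delta G`, event
#' counts, mean residence times up/down, mean transition times, the per-cell
#' timescale ratio `r` and the noise strength `eta`.
#'
#' @param trace data.frame `time`, `activity` (one cell).
#' @param params an [event_params()] list.
#' @param cell_id optional identifier.
#' @return one-row data.frame of class `cell_summary`.
#' @export
summarize_switching <- function(trace, params = event_params(),
                                cell_id = NA) {
  cls <- classify_two_state(trace, params = params)
  ev <- cls$events
  a <- cls$trace$activity
  bias <- mean(a)
  up <- ev$direction > 0
  # residence after an upward switch is time spent up, and vice versa
  dt_up <- ev$residence[up]; dt_down <- ev$residence[!up]
  dt_up <- dt_up[is.finite(dt_up)]; dt_down <- dt_down[is.finite(dt_down)]
  tau_up <- mean(ev$tau[up], na.rm = TRUE)
  tau_down <- mean(ev$tau[!up], na.rm = TRUE)
  mean_tau <- mean(c(tau_up, tau_down), na.rm = TRUE)
  mean_dt <- mean(c(dt_up, dt_down))
  r <- if (is.finite(mean_dt) && is.finite(mean_tau) && mean_tau > 0)
    mean_dt / mean_tau else NA_real_
  out <- data.frame(
    cell_id = cell_id,
    bias = bias,
    delta_G = if (bias > 0 && bias < 1) delta_G(bias) else NA_real_,
    n_events = nrow(ev),
    fraction_large = cls$fraction_large,
    is_two_state = cls$is_two_state,
    mean_dt_up = if (length(dt_up)) mean(dt_up) else NA_real_,
    mean_dt_down = if (length(dt_down)) mean(dt_down) else NA_real_,
    mean_tau_up = tau_up,
    mean_tau_down = tau_down,
    mean_tau = mean_tau,
    r = r,
    eta = noise_strength(a, a0 = bias))
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Cohort switching summary
#'
#' Applies [summarize_switching()] per cell of a long-format activity table.
#'
#' @param activity data.frame `cell_id`, `time`, `activity`.
#' @param params an [event_params()] list.
#' @return data.frame, one row per cell.
#' @export
analyze_cohort <- function(activity, params = event_params()) {
  ids <- unique(activity$cell_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- activity[activity$cell_id == id, c("time", "activity")]
    summarize_switching(tr, params, cell_id = id)
  }))
}

#' Arrhenius fit of residence times versus activity bias
#'
#' Fits `ln <Dt_up>` and `ln <Dt_down>` as linear (unweighted least squares)
#' functions of the per-cell free-energy bias `Delta G`, following
#' `<Dt_up,down>(Delta G) = <Dt> exp(-gamma_up,down Delta G)`. The
#' characteristic residence time `<Dt>` is the ordinate at the crossing of
#' the two lines.
#'
#' @param summaries per-cell summary table (from [analyze_cohort()]); needs
#'   finite `delta_G`, `mean_dt_up`, `mean_dt_down`.
#' @return list of class `arrhenius_fit`: `gamma_up`, `gamma_down`,
#'   `mean_dt` (characteristic), `crossing_dG`, the two `lm` fits.
#' @export
arrhenius_fit <- function(summaries) {
  s_up <- summaries[is.finite(summaries$delta_G) &
                      is.finite(summaries$mean_dt_up) &
                      summaries$mean_dt_up > 0, ]
  s_dn <- summaries[is.finite(summaries$delta_G) &
                      is.finite(summaries$mean_dt_down) &
                      summaries$mean_dt_down > 0, ]
  if (nrow(s_up) < 3 || nrow(s_dn) < 3)
    stop("need at least 3 cells with up- and 3 with down-residences")
  if (sd(s_up$delta_G) == 0 || sd(s_dn$delta_G) == 0)
    stop("degenerate design: all cells at identical Delta G")
  f_up <- lm(log(mean_dt_up) ~ delta_G, data = s_up)
  f_dn <- lm(log(mean_dt_down) ~ delta_G, data = s_dn)
  b_up <- coef(f_up); b_dn <- coef(f_dn)
  if (abs(b_up[[2]] - b_dn[[2]]) < 1e-10)
    stop("Arrhenius lines are parallel: no crossing")
  xg <- (b_dn[[1]] - b_up[[1]]) / (b_up[[2]] - b_dn[[2]])
  ln_dt <- b_up[[1]] + b_up[[2]] * xg
  structure(list(gamma_up = -b_up[[2]], gamma_down = -b_dn[[2]],
                 mean_dt = exp(ln_dt), crossing_dG = xg,
                 fit_up = f_up, fit_down = f_dn),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius residence-time fit:\n  gamma_up = %.3f, gamma_down = %.3f\n  characteristic <Dt> = %.2f at crossing Delta G = %.3f\n",
              x$gamma_up, x$gamma_down, x$mean_dt, x$crossing_dG))
  invisible(x)
}
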