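# Preprocessing of ratiometric FRET recordings into normalized
# kinase-activity traces, plus receptor-cluster intensity quantification.

#' Stimulus window annotations
#'
#' Non-overlapping `[t0, t1)` intervals (seconds) during which a saturating
#' attractant (kinase fully inactive) or repellent (kinase fully active)
#' stimulus was applied; everything else is buffer.
#'
#' @param attractant matrix or list of `c(t0, t1)` intervals.
#' @param repellent matrix or list of `c(t0, t1)` intervals.
#' @return object of class `stimulus_windows`.
#' @export
stimulus_windows <- function(attractant = NULL, repellent = NULL) {
  norm <- function(x) {
    if (is.null(x) || length(x) == 0) return(matrix(numeric(0), ncol = 2))
    if (is.list(x)) x <- do.call(rbind, x)
    x <- matrix(as.numeric(x), ncol = 2)
    if (any(x[, 2] <= x[, 1])) stop("window end must exceed start")
    x[order(x[, 1]), , drop = FALSE]
  }
  w <- structure(list(attractant = norm(attractant), repellent = norm(repellent)),
                 class = "stimulus_windows")
  iv <- rbind(w$attractant, w$repellent)
  if (nrow(iv) > 1) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("stimulus windows overlap")
  }
  w
}

in_windows <- function(time, iv, trim = 0) {
  if (nrow(iv) == 0) return(rep(FALSE, length(time)))
  out <- rep(FALSE, length(time))
  dt <- if (length(time) > 1) median(diff(time)) else 1
  for (k in seq_len(nrow(iv)))
    out <- out | (time >= iv[k, 1] + trim * dt & time < iv[k, 2] - trim * dt)
  out
}

#' Ratio with photobleaching correction
#'
#' Forms the acceptor/donor ratio `R(t) = A(t)/D(t)` and divides out a
#' single-exponential bleaching trend fitted to the buffer-window samples
#' only (stimulus windows excluded so the saturating responses do not bias
#' the trend). If the exponential fit fails to converge the ratio is
#' returned uncorrected with `attr(, "bleach_corrected") = FALSE` and a
#' warning.
#'
#' @param trace data.frame with columns `time`, `donor`, `acceptor`
#'   (and optionally `cell_id`).
#' @param windows a [stimulus_windows()] object.
#' @return numeric vector `R(t)` rescaled so the fitted trend at `t = 0` is
#'   preserved; attributes `bleach_tau` and `bleach_corrected`.
#' @export
ratio_and_bleach_correct <- function(trace, windows) {
  if (any(trace$donor <= 0)) stop("donor intensities must be positive")
  R <- trace$acceptor / trace$donor
  tt <- trace$time
  buf <- !in_windows(tt, windows$attractant) & !in_windows(tt, windows$repellent)
  # switching-aware exponential trend fit: the kinase telegraph rides on
  # top of the bleaching trend, so a naive regression through the buffer
  # samples is biased by whichever state happens to dominate early or late.
  # Iterate a two-level (high/low ratio) classification of the detrended
  # log-ratio and refit a shared slope with per-level intercepts on the
  # plateau samples. Exact when the noise is zero; robust otherwise.
  k <- tryCatch(bleach_rate_twostate(tt[buf], log(R[buf])),
                error = function(e) NA_real_)
  if (!is.finite(k)) {
    warning("bleach fit did not converge; returning uncorrected ratio")
    attr(R, "bleach_corrected") <- FALSE
    attr(R, "bleach_tau") <- NA_real_
    return(R)
  }
  span <- max(tt) - min(tt)
  if (abs(k) * span < 1e-8) k <- 0  # no measurable trend
  Rcorr <- R / exp(-k * tt)
  attr(Rcorr, "bleach_corrected") <- TRUE
  attr(Rcorr, "bleach_tau") <- if (k == 0) Inf else 1 / k
  Rcorr
}

# Shared decay slope of a (possibly two-level) log-ratio series.
# Returns k such that the trend is exp(-k t).
bleach_rate_twostate <- function(t, y) {
  k <- -coef(lm(y ~ t))[[2]]
  for (iter in 1:4) {
    res <- y + k * t
    c_lo <- quantile(res, 0.1, names = FALSE)
    c_hi <- quantile(res, 0.9, names = FALSE)
    if (c_hi - c_lo < 1e-12) {  # single level
      k <- -coef(lm(y ~ t))[[2]]
      break
    }
    for (i in 1:10) {  # 1-D two-means on the detrended level
      hi <- abs(res - c_hi) < abs(res - c_lo)
      if (!any(hi) || all(hi)) break
      c_hi_new <- mean(res[hi]); c_lo_new <- mean(res[!hi])
      if (abs(c_hi_new - c_hi) + abs(c_lo_new - c_lo) < 1e-12) {
        c_hi <- c_hi_new; c_lo <- c_lo_new; break
      }
      c_hi <- c_hi_new; c_lo <- c_lo_new
    }
    hi <- abs(res - c_hi) < abs(res - c_lo)
    if (c_hi - c_lo < 0.02) {  # effectively one level: plain fit
      k <- -coef(lm(y ~ t))[[2]]
      break
    }
    # plateau samples only: drop mid-transition points far from both levels
    dev <- ifelse(hi, abs(res - c_hi), abs(res - c_lo))
    tol <- max(3 * median(dev), 1e-9 * (1 + c_hi - c_lo))
    keep <- dev <= tol
    if (sum(keep) < 4 || length(unique(hi[keep])) == 0) break
    f <- if (length(unique(hi[keep])) == 2)
      lm(y[keep] ~ t[keep] + hi[keep]) else lm(y[keep] ~ t[keep])
    k_new <- -coef(f)[[2]]
    if (abs(k_new - k) * (max(t) - min(t)) < 1e-12) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' Ratiometric FRET index
#'
#' Converts the (bleach-corrected) ratio into the FRET index
#' `FRET(t) = (R(t) - R0) / (R(t) + alpha)`, where `R0` is the ratio at zero
#' FRET, estimated as the trimmed mean ratio during the saturating-attractant
#' windows unless supplied, and `alpha` is a setup constant (default 0.3).
#' Values may be slightly negative from noise and are deliberately not
#' clipped. The index is monotone increasing in `R` for `R > -alpha`.
#'
#' @param R corrected ratio series.
#' @param time sample times (needed when `R0` is estimated from windows).
#' @param windows a [stimulus_windows()] object (needs attractant windows
#'   when `R0` is not given).
#' @param R0 ratio at zero FRET; estimated from attractant windows if `NULL`.
#' @param alpha setup constant (> 0).
#' @param trim samples trimmed from each window edge to avoid flow-exchange
#'   transients.
#' @return numeric FRET(t), with `attr(, "R0")`.
#' @export
fret_index <- function(R, time = NULL, windows = NULL, R0 = NULL,
                       alpha = 0.3, trim = 2) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (is.null(R0)) {
    if (is.null(windows) || nrow(windows$attractant) == 0 || is.null(time))
      stop("R0 must be given, or estimable from attractant windows")
    att <- in_windows(time, windows$attractant, trim = trim)
    if (!any(att)) stop("attractant windows contain no samples")
    R0 <- mean(R[att])
  }
  if (any(R + alpha <= 0)) stop("R + alpha must be positive")
  f <- (R - R0) / (R + alpha)
  attr(f, "R0") <- R0
  f
}

#' Normalize FRET to kinase activity
#'
#' Scales the FRET index by its maximum, `FRET_max`, taken as the trimmed
#' mean during saturating-repellent windows, so repellent windows map to
#' activity 1 and (by the `R0` choice) attractant windows map to about 0.
#'
#' @param fret FRET index series.
#' @param time sample times.
#' @param windows a [stimulus_windows()] object with at least one attractant
#'   and one repellent window.
#' @param cell_id optional identifier carried into the output.
#' @param trim window-edge trim in samples.
#' @return data.frame `time`, `activity` (class `activity_trace`), with
#'   `attr(, "fret_max")`.
#' @export
normalize_activity <- function(fret, time, windows, cell_id = NA, trim = 2) {
  if (nrow(windows$attractant) == 0 || nrow(windows$repellent) == 0)
    stop("normalization needs both attractant and repellent windows")
  rep_w <- in_windows(time, windows$repellent, trim = trim)
  if (!any(rep_w)) stop("repellent windows contain no samples")
  fmax <- mean(fret[rep_w])
  if (fmax <= 0) stop("non-positive FRET_max; check window annotations")
  out <- data.frame(time = time, activity = as.numeric(fret) / fmax)
  if (!is.na(cell_id)) out <- cbind(cell_id = cell_id, out)
  structure(out, class = c("activity_trace", "data.frame"), fret_max = fmax)
}

#' Full FRET-to-activity pipeline for one cell
#'
#' Chains [ratio_and_bleach_correct()], [fret_index()] and
#' [normalize_activity()].
#'
#' @inheritParams ratio_and_bleach_correct
#' @inheritParams fret_index
#' @return an `activity_trace` data.frame.
#' @export
fret_activity <- function(trace, windows, alpha = 0.3, trim = 2) {
  R <- ratio_and_bleach_correct(trace, windows)
  f <- fret_index(R, time = trace$time, windows = windows, alpha = alpha,
                  trim = trim)
  cell <- if ("cell_id" %in% names(trace)) trace$cell_id[1] else NA
  normalize_activity(f, trace$time, windows, cell_id = cell, trim = trim)
}

#' Receptor-cluster intensity from a 1D profile
#'
#' The cluster size proxy `Delta I = I_max - <I>`, where `<I>` is the mean
#' intensity along the sampled profile (the discrete analogue of a
#' normalized line integral). `Delta I` is non-negative and invariant under
#' adding a constant to the profile.
#'
#' @param profile numeric intensity values, or a data.frame with an
#'   `intensity` column.
#' @return `Delta I` (same units as the profile).
#' @export
cluster_intensity <- function(profile) {
  I <- if (is.data.frame(profile)) profile$intensity else as.numeric(profile)
  if (length(I) == 0) stop("empty intensity profile")
  max(I) - mean(I)
}
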