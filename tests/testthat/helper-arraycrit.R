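# Shared fixtures: small, fast synthetic objects built in code.

# clean saturating-exponential ramp for transition-time oracles
make_ramp <- function(tau, t0 = 20, n = 61, sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, n - 1)
  a <- ifelse(tt < t0, 0, 1 - exp(-(tt - t0) / tau))
  if (sigma > 0) a <- a + rnorm(n, sd = sigma)
  data.frame(time = tt, activity = a)
}

# deterministic telegraph with instant switches at given times
make_telegraph <- function(switch_times, duration = 200, dt = 1, start = 0) {
  tt <- seq(0, duration, by = dt)
  a <- rep(start, length(tt))
  state <- start
  for (ts in switch_times) {
    state <- 1 - state
    a[tt >= ts] <- state
  }
  data.frame(time = tt, activity = a)
}

# default windows for short synthetic cells
test_windows <- function(duration) {
  stimulus_windows(attractant = c(20, 60),
                   repellent = c(duration - 60, duration - 20))
}
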