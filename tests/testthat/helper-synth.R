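# Shared fixtures, built once per test run.

fs_t <- 1000

# small cached backgrounds so several files can reuse them
bg_cache <- new.env()
get_background <- function(duration, exponent = 2, seed = 101) {
  key <- paste(duration, exponent, seed, sep = "_")
  if (is.null(bg_cache[[key]])) {
    cfg <- synth_config(duration = duration, seed = seed,
                        aperiodic_exponent = exponent)
    bg_cache[[key]] <- gen_aperiodic(cfg)
  }
  bg_cache[[key]]
}

# von Mises sampler (Best & Fisher rejection), used as an independent oracle
# for phase-locked spike statistics
rvonmises <- function(n, kappa, mu = 0) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# Welch log-log slope of a signal: independent check of spectral shaping
welch_slope <- function(x, fs, fmin = 2, fmax = 150) {
  ps <- welch_psd(x, fs, fmin = fmin, fmax = fmax)
  stats::coef(stats::lm(log10(ps$power) ~ log10(ps$freqs)))[2]
}

# overlap fraction of truth intervals recovered by detected events
interval_recovery <- function(truth_start, truth_end, det_start, det_end) {
  if (!length(truth_start)) return(numeric(0))
  vapply(seq_along(truth_start), function(i)
    any(det_start <= truth_end[i] & det_end >= truth_start[i]), logical(1))
}
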