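#' Configuration for a synthetic recording session
#'
#' Builds the parameter set for [make_session()]. The defaults emulate the
#' statistical structure of pyramidal-layer CA1 recordings from a primate
#' alternating between active visual search and quiescent rest: a 1/f^x
#' aperiodic background, theta bouts (~8 Hz) that are far more prevalent in
#' rest, beta2/slow-gamma bouts (~20-35 Hz) prevalent in search, high-frequency
#' (60-150 Hz) activity accompanying theta, sharp-wave ripples (SWRs) confined
#' mostly to rest, and spike trains that can be phase-locked to a chosen band
#' and gain-modulated inside SWRs.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param duration session length in seconds.
#' @param aperiodic_exponent exponent x of the 1/f^x background (log10 power
#'   falls as `offset - x * log10(f)`).
#' @param aperiodic_offset log10 power density at 1 Hz.
#' @param state_plan data.frame with columns `state` ("search"/"rest"),
#'   `start`, `end` (seconds); intervals must be non-overlapping and inside
#'   `[0, duration]`.
#' @param bout_specs data.frame with one row per transient-oscillation class:
#'   `label`, `freq` (center, Hz), `bandwidth` (Hz), `rate_search`,
#'   `rate_rest` (bouts per minute per state), `dur_mean`, `dur_sd` (s),
#'   `amp` (peak amplitude as a multiple of the background SD).
#' @param swr_spec list with `rate_search`, `rate_rest` (events/min),
#'   `ripple_freq` (Hz), `ripple_dur` (ms), `ripple_amp` (SD of the 100-250 Hz
#'   filtered background), `sw_amp` (SD of the raw background), `sw_width` (ms).
#' @param unit_specs data.frame with one row per unit: `base_rate` (Hz),
#'   `locked_freq` (Hz or NA for unmodulated), `kappa` (von Mises
#'   concentration), `swr_gain` (rate multiplier inside SWR windows).
#' @param artifact_rate broadband artifacts per minute, injected on both the
#'   signal and the noise channel (for artifact-rejection tests).
#' @param seed integer; the single seed from which all per-component
#'   substreams are derived.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 1000,
                         duration = 600,
                         aperiodic_exponent = 2,
                         aperiodic_offset = 0,
                         state_plan = NULL,
                         bout_specs = data.frame(
                           label       = c("theta", "beta2", "highfreq"),
                           freq        = c(8, 28, 90),
                           bandwidth   = c(2, 8, 30),
                           rate_search = c(0.5, 6, 1),
                           rate_rest   = c(6, 0.5, 4),
                           dur_mean    = c(1.0, 0.6, 0.3),
                           dur_sd      = c(0.3, 0.2, 0.1),
                           amp         = c(4, 3, 0.5)),
                         swr_spec = list(
                           rate_search = 0.2, rate_rest = 6,
                           ripple_freq = 140, ripple_dur = 80,
                           ripple_amp = 5, sw_amp = 3, sw_width = 80),
                         unit_specs = data.frame(
                           base_rate   = c(5, 8, 3),
                           locked_freq = c(8, NA, 28),
                           kappa       = c(1.5, 0, 1),
                           swr_gain    = c(1, 4, 1)),
                         artifact_rate = 0.5,
                         seed = 1L) {
  if (is.null(state_plan)) {
    # default: rest/search alternation in four equal blocks
    q <- duration / 4
    state_plan <- data.frame(
      state = c("rest", "search", "rest", "search"),
      start = q * 0:3, end = q * 1:4)
  }
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              aperiodic_exponent = aperiodic_exponent,
              aperiodic_offset = aperiodic_offset,
              state_plan = state_plan, bout_specs = bout_specs,
              swr_spec = swr_spec, unit_specs = unit_specs,
              artifact_rate = artifact_rate, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  num <- c(cfg$sampling_rate, cfg$duration, cfg$aperiodic_exponent,
           cfg$aperiodic_offset, cfg$artifact_rate,
           unlist(cfg$swr_spec))
  if (any(!is.finite(num))) stop("non-finite value in synth_config")
  if (cfg$aperiodic_exponent < 0) stop("aperiodic exponent must be >= 0")
  sp <- cfg$state_plan
  if (any(sp$start < 0) || any(sp$end > cfg$duration) || any(sp$end <= sp$start))
    stop("state intervals must lie within [0, duration] with start < end")
  o <- order(sp$start)
  if (any(sp$start[o][-1] < sp$end[o][-nrow(sp)]))
    stop("state intervals must not overlap")
  bs <- cfg$bout_specs
  if (nrow(bs) && any(c(bs$rate_search, bs$rate_rest, bs$dur_mean, bs$amp) < 0))
    stop("bout rates, durations and amplitudes must be >= 0")
  us <- cfg$unit_specs
  if (nrow(us)) {
    if (any(us$kappa < 0) || any(us$base_rate < 0))
      stop("unit base rates and kappa must be >= 0")
    lf <- us$locked_freq[!is.na(us$locked_freq)]
    if (length(lf) && any(lf >= cfg$sampling_rate / 2))
      stop("locked frequency at or above Nyquist")
  }
  top <- max(c(bs$freq + bs$bandwidth / 2, cfg$swr_spec$ripple_freq, 0))
  if (cfg$sampling_rate < 4 * top)
    stop("sampling_rate must be >= 4x the highest generated frequency")
  invisible(cfg)
}

#' Generate a 1/f^x aperiodic background signal
#'
#' Spectrally shapes white Gaussian noise by inverse FFT so the expected
#' power spectral density is `offset - exponent * log10(f)` in log10 space.
#'
#' @param config a [synth_config()] (only `sampling_rate`, `duration`,
#'   `aperiodic_exponent`, `aperiodic_offset` and `seed` are used).
#' @return zero-mean numeric vector of `duration * sampling_rate` samples.
#' @export
gen_aperiodic <- function(config) {
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  if (n < 2^12) stop("need at least 2^12 samples for stable spectral shaping")
  x <- config$aperiodic_exponent
  if (!is.finite(x) || x < 0) stop("aperiodic exponent must be finite and >= 0")
  set.seed(substream_seed(config$seed, "aperiodic"))
  freqs <- seq(0, fs / 2, by = fs / n)          # bins 0 .. n/2
  nhalf <- length(freqs)
  # one-sided target PSD; DC excluded
  psd <- c(0, 10^config$aperiodic_offset * freqs[-1]^(-x))
  amp <- sqrt(psd * n * fs / 2)
  z <- complex(real = stats::rnorm(nhalf), imaginary = stats::rnorm(nhalf)) /
    sqrt(2)
  X <- rep(0 + 0i, n)
  X[1] <- 0
  X[2:nhalf] <- amp[-1] * z[-1]
  if (n %% 2 == 0) X[nhalf] <- amp[nhalf] * sqrt(2) * Re(z[nhalf])  # Nyquist real
  X[(n:2)[seq_len(n - nhalf)]] <- Conj(X[2:(n - nhalf + 1)])
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out - mean(out)
}

# Poisson event starts within each state interval for a given per-state rate
# (events per minute). Returns start times in seconds.
poisson_starts <- function(state_plan, rate_search, rate_rest) {
  starts <- numeric(0)
  for (i in seq_len(nrow(state_plan))) {
    rate <- if (state_plan$state[i] == "rest") rate_rest else rate_search
    dur <- state_plan$end[i] - state_plan$start[i]
    k <- stats::rpois(1, rate * dur / 60)
    if (k > 0) starts <- c(starts, state_plan$start[i] + stats::runif(k) * dur)
  }
  sort(starts)
}

state_at <- function(state_plan, t) {
  hit <- which(t >= state_plan$start & t < state_plan$end)
  if (length(hit)) state_plan$state[hit[1]] else NA_character_
}

#' Inject Hann-tapered narrowband oscillation bouts
#'
#' Places bouts by a per-state Poisson process and returns both the summed
#' waveform and a ground-truth table. Bouts are amplitude-tapered with a Hann
#' envelope so they start and end at zero, avoiding spectral splatter. Bouts
#' that would outrun their state interval are truncated and flagged.
#'
#' @param config a [synth_config()].
#' @param state_intervals state plan data.frame (defaults to the config's).
#' @param bg_sd standard deviation of the background the amplitudes are
#'   expressed in multiples of.
#' @return list with `signal` (numeric vector), `truth` (data.frame: label,
#'   freq, start, end, amp, state, truncated), and `band_signals` (named list
#'   of the per-class noiseless waveforms, used as phase ground truth for
#'   spike locking).
#' @export
gen_bouts <- function(config, state_intervals = config$state_plan, bg_sd = 1) {
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  set.seed(substream_seed(config$seed, "bouts"))
  sig <- numeric(n)
  band_signals <- list()
  rows <- list()
  bs <- config$bout_specs
  for (b in seq_len(nrow(bs))) {
    bsig <- numeric(n)
    for (i in seq_len(nrow(state_intervals))) {
      st <- state_intervals[i, ]
      rate <- if (st$state == "rest") bs$rate_rest[b] else bs$rate_search[b]
      k <- stats::rpois(1, rate * (st$end - st$start) / 60)
      if (k == 0) next
      starts <- st$start + stats::runif(k) * (st$end - st$start)
      for (t0 in starts) {
        f <- stats::runif(1, bs$freq[b] - bs$bandwidth[b] / 2,
                          bs$freq[b] + bs$bandwidth[b] / 2)
        dur <- max(3 / f, stats::rnorm(1, bs$dur_mean[b], bs$dur_sd[b]))
        truncated <- FALSE
        if (t0 + dur > st$end) {          # confine bout to its state
          dur <- st$end - t0
          truncated <- TRUE
          if (dur < 3 / f) next
        }
        i0 <- floor(t0 * fs) + 1
        i1 <- min(n, floor((t0 + dur) * fs))
        len <- i1 - i0 + 1
        tt <- (seq_len(len) - 1) / fs
        phi <- stats::runif(1, 0, 2 * pi)
        w <- bs$amp[b] * bg_sd * hann_window(len) * sin(2 * pi * f * tt + phi)
        bsig[i0:i1] <- bsig[i0:i1] + w
        rows[[length(rows) + 1]] <- data.frame(
          label = bs$label[b], freq = f, start = t0, end = t0 + dur,
          amp = bs$amp[b], state = st$state, truncated = truncated)
      }
    }
    band_signals[[bs$label[b]]] <- bsig
    sig <- sig + bsig
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), freq = numeric(), start = numeric(),
               end = numeric(), amp = numeric(), state = character(),
               truncated = logical())
  list(signal = sig, truth = truth[order(truth$start), , drop = FALSE],
       band_signals = band_signals)
}

#' Inject sharp-wave-ripple complexes
#'
#' Each event is a slow biphasic deflection (difference-of-Gaussians, energy
#' below 10 Hz) plus a Hann-tapered ripple burst. Ripple amplitude is
#' expressed in SD units of the 100-250 Hz filtered background; overlapping
#' events are resampled.
#'
#' @param config a [synth_config()].
#' @param state_intervals state plan (defaults to the config's).
#' @param background the aperiodic background signal the SD references are
#'   computed from; if NULL, unit SDs are assumed.
#' @return list with `signal` and `truth` (data.frame: start, peak, end,
#'   state).
#' @export
gen_swrs <- function(config, state_intervals = config$state_plan,
                     background = NULL) {
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  sp <- config$swr_spec
  set.seed(substream_seed(config$seed, "swrs"))
  ripple_sd <- if (is.null(background)) 1 else
    stats::sd(bandpass_filter(background, fs, 100, min(250, fs / 2 - 1)))
  raw_sd <- if (is.null(background)) 1 else stats::sd(background)
  centers <- poisson_starts(state_intervals, sp$rate_search, sp$rate_rest)
  half <- max(sp$ripple_dur / 1000, 3 * sp$sw_width / 1000) / 2
  # enforce non-overlap by dropping the later of colliding events
  if (length(centers) > 1) {
    keep <- c(TRUE, diff(centers) > 2 * half + 0.05)
    centers <- centers[keep]
  }
  centers <- centers[centers - half > 0 & centers + half < config$duration]
  sig <- numeric(n)
  rows <- list()
  for (t0 in centers) {
    # slow biphasic sharp wave: difference of Gaussians
    sw_sigma <- sp$sw_width / 1000 / 2.355          # FWHM -> sigma
    # support wide enough for the broader subtracted Gaussian, Hann-tapered to
    # zero so the injected waveform has no edge discontinuity (a step would
    # leak broadband energy into the ripple band)
    tt <- seq(-5 * sw_sigma, 5 * sw_sigma, by = 1 / fs)
    dog <- exp(-tt^2 / (2 * sw_sigma^2)) -
      0.55 * exp(-tt^2 / (2 * (1.8 * sw_sigma)^2))
    dog <- dog * hann_window(length(dog))
    sw <- -sp$sw_amp * raw_sd * dog / max(abs(dog))
    add_at <- function(wave, tc) {
      i0 <- round(tc * fs) + 1 - floor(length(wave) / 2)
      i1 <- i0 + length(wave) - 1
      lo <- max(1, i0); hi <- min(n, i1)
      sig[lo:hi] <<- sig[lo:hi] + wave[(lo - i0 + 1):(hi - i0 + 1)]
    }
    add_at(sw, t0)
    rd <- sp$ripple_dur / 1000
    len <- round(rd * fs)
    if (len > 1 && sp$ripple_amp > 0) {
      # flat-topped taper: the burst sustains its nominal amplitude over its
      # nominal duration (a fully tapered burst would halve the effective one)
      tr <- (seq_len(len) - 1) / fs
      rip <- sp$ripple_amp * ripple_sd * tukey_window(len, 0.3) *
        sin(2 * pi * sp$ripple_freq * tr)
      add_at(rip, t0)
    }
    rows[[length(rows) + 1]] <- data.frame(
      start = t0 - max(rd, 3 * sw_sigma * 2) / 2, peak = t0,
      end = t0 + max(rd, 3 * sw_sigma * 2) / 2,
      state = state_at(state_intervals, t0))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(), peak = numeric(), end = numeric(),
               state = character())
  list(signal = sig, truth = truth)
}

#' Generate phase-locked, SWR-gain-modulated spike trains
#'
#' Spikes are drawn from an inhomogeneous Poisson process by thinning, with
#' rate `r(t) = base * exp(kappa * cos(theta(t))) / I0(kappa) * gain(t)`.
#' The von Mises normalization `1/I0(kappa)` keeps the time-averaged rate at
#' the base rate when the phase sweeps uniformly. `theta(t)` is taken from a
#' supplied noiseless phase series (exact ground truth) or, by default, from
#' an ideal oscillator `2*pi*f*t` at the unit's locked frequency.
#'
#' @param config a [synth_config()].
#' @param phase optional named list mapping locked frequency (as character)
#'   to an instantaneous-phase vector of length `duration * fs`.
#' @param swr_windows data.frame with `start`, `end` (s) inside which the
#'   unit's `swr_gain` multiplies the rate; NULL for none.
#' @return list of numeric vectors of sorted spike times (seconds), one per
#'   unit row of `config$unit_specs`.
#' @export
gen_spikes <- function(config, phase = NULL, swr_windows = NULL) {
  fs <- config$sampling_rate
  dur <- config$duration
  n <- round(dur * fs)
  us <- config$unit_specs
  out <- vector("list", nrow(us))
  for (u in seq_len(nrow(us))) {
    set.seed(substream_seed(config$seed, paste0("unit", u)))
    base <- us$base_rate[u]
    kap <- us$kappa[u]
    f <- us$locked_freq[u]
    gain <- us$swr_gain[u]
    if (!is.na(f) && f >= fs / 2) stop("locked frequency above Nyquist")
    rmax <- base * exp(kap) / besselI(kap, 0) * max(gain, 1)
    ncand <- stats::rpois(1, rmax * dur)
    tcand <- sort(stats::runif(ncand, 0, dur))
    if (kap > 0 && !is.na(f)) {
      key <- as.character(f)
      if (!is.null(phase) && key %in% names(phase)) {
        idx <- pmin(n, pmax(1, round(tcand * fs) + 1))
        th <- phase[[key]][idx]
      } else {
        th <- 2 * pi * f * tcand
      }
      r <- base * exp(kap * cos(th)) / besselI(kap, 0)
    } else {
      r <- rep(base, length(tcand))
    }
    if (!is.null(swr_windows) && nrow(swr_windows) && gain != 1) {
      inswr <- rep(FALSE, length(tcand))
      for (i in seq_len(nrow(swr_windows)))
        inswr <- inswr | (tcand >= swr_windows$start[i] &
                          tcand <= swr_windows$end[i])
      r[inswr] <- r[inswr] * gain
    }
    keep <- stats::runif(length(tcand)) < r / rmax
    out[[u]] <- tcand[keep]
  }
  out
}

#' Assemble a complete synthetic session
#'
#' Runs the aperiodic, bout, SWR, artifact and spike generators and bundles
#' their outputs with ground truth. All randomness is derived from the
#' config's single seed via per-component substreams, so identical configs
#' give bit-identical bundles.
#'
#' @param config a [synth_config()].
#' @return an object of class `session_bundle`: list with `lfp`,
#'   `noise_channel`, `fs`, `duration`, `spikes` (list per unit), `states`,
#'   `truth` (list: bouts, swrs, artifacts) and `config`.
#' @export
make_session <- function(config) {
  validate_synth_config(config)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  bg <- gen_aperiodic(config)
  bg_sd <- stats::sd(bg)
  bouts <- gen_bouts(config, bg_sd = bg_sd)
  swrs <- gen_swrs(config, background = bg)
  lfp <- bg + bouts$signal + swrs$signal

  # independent background on the noise channel
  cfg_noise <- config
  cfg_noise$seed <- substream_seed(config$seed, "noisechan")
  noise <- gen_aperiodic(cfg_noise)

  # broadband artifacts, present on BOTH channels
  set.seed(substream_seed(config$seed, "artifacts"))
  k_art <- stats::rpois(1, config$artifact_rate * config$duration / 60)
  art_rows <- list()
  if (k_art > 0) {
    t_art <- sort(stats::runif(k_art, 0.5, config$duration - 0.5))
    for (t0 in t_art) {
      len <- round(0.08 * fs)
      i0 <- round(t0 * fs) + 1
      burst <- 8 * bg_sd * hann_window(len) * stats::rnorm(len)
      idx <- i0:(i0 + len - 1)
      lfp[idx] <- lfp[idx] + burst
      noise[idx] <- noise[idx] + burst
      art_rows[[length(art_rows) + 1]] <-
        data.frame(start = t0, end = t0 + len / fs)
    }
  }
  artifacts <- if (length(art_rows)) do.call(rbind, art_rows) else
    data.frame(start = numeric(), end = numeric())

  # spike phase ground truth from the noiseless injected band signals
  phase <- list()
  us <- config$unit_specs
  for (f in unique(us$locked_freq[!is.na(us$locked_freq)])) {
    band <- which.min(abs(config$bout_specs$freq - f))
    bsig <- bouts$band_signals[[config$bout_specs$label[band]]]
    if (!is.null(bsig) && any(bsig != 0)) {
      an <- analytic_signal(bsig)
      ph <- Arg(an)
      # outside bouts the injected signal is zero: fall back to ideal phase
      env <- Mod(an)
      ideal <- 2 * pi * f * (seq_len(n) - 1) / fs
      ph[env < 1e-3 * max(env)] <- ideal[env < 1e-3 * max(env)]
      phase[[as.character(f)]] <- ph
    }
  }
  spikes <- gen_spikes(config, phase = phase, swr_windows = swrs$truth)
  spikes <- lapply(spikes, function(s) s[s > 0 & s < config$duration])

  structure(list(
    lfp = lfp, noise_channel = noise, fs = fs, duration = config$duration,
    spikes = spikes, states = config$state_plan,
    truth = list(bouts = bouts$truth, swrs = swrs$truth,
                 artifacts = artifacts),
    config = config), class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("session_bundle:", x$duration, "s at", x$fs, "Hz\n")
  cat("  states:", paste(unique(x$states$state), collapse = ", "), "\n")
  cat("  units:", length(x$spikes), " bouts:", nrow(x$truth$bouts),
      " SWRs:", nrow(x$truth$swrs), "\n")
  invisible(x)
}

# Analytic signal via FFT (Hilbert transform), for envelope/phase extraction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Generate tones with envelopes of prescribed cross-frequency correlation
#'
#' Builds a signal in which narrowband components at chosen frequencies ride
#' on slow positive envelopes whose pairwise correlations are set by
#' construction: envelope i is `1 + depth * u_i` with `(u_1 .. u_m)` slow
#' Gaussian processes mixed to the requested correlation with the first
#' component. Used to validate comodulogram recovery against ground truth.
#'
#' @param duration seconds.
#' @param fs sampling rate (Hz).
#' @param freqs tone frequencies (Hz); the first is the reference.
#' @param rho numeric of length `length(freqs) - 1`: target correlation of
#'   each later envelope with the first.
#' @param amp tone amplitudes (recycled).
#' @param depth envelope modulation depth (fraction of the unit mean).
#' @param cutoff lowpass cutoff of the envelope processes (Hz).
#' @param background optional background signal added to the tones.
#' @param seed integer seed.
#' @return list with `signal`, `envelopes` (sample x tone matrix), `freqs`.
#' @export
gen_coupled_envelopes <- function(duration, fs, freqs = c(5, 30, 100),
                                  rho = c(-0.7, 0.7), amp = 5, depth = 0.25,
                                  cutoff = 0.2, background = NULL,
                                  seed = 1L) {
  stopifnot(length(rho) == length(freqs) - 1)
  set.seed(substream_seed(seed, "coupledenv"))
  n <- round(duration * fs)
  # band-limited noise built in the frequency domain: IIR lowpass filters are
  # numerically fragile at normalized cutoffs this small (~1e-4)
  slow <- function() {
    X <- stats::fft(stats::rnorm(n))
    f <- (seq_len(n) - 1) * fs / n
    keep <- pmin(f, fs - f) <= cutoff & pmin(f, fs - f) > 0
    X[!keep] <- 0
    u <- Re(stats::fft(X, inverse = TRUE)) / n
    (u - mean(u)) / stats::sd(u)
  }
  u1 <- slow()
  # orthogonalize each mixing residual against u1 so the SAMPLE correlation
  # equals the target exactly (slow envelopes have few effective degrees of
  # freedom, so relying on expectation alone would leave +/-0.1 wobble)
  U <- cbind(u1, sapply(rho, function(r) {
    z <- slow()
    z <- z - u1 * sum(z * u1) / sum(u1^2)
    z <- z / stats::sd(z)
    r * u1 + sqrt(1 - r^2) * z
  }))
  env <- pmax(1 + depth * U, 0)
  amp <- rep_len(amp, length(freqs))
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (j in seq_along(freqs))
    sig <- sig + amp[j] * env[, j] * sin(2 * pi * freqs[j] * t +
                                         stats::runif(1, 0, 2 * pi))
  if (!is.null(background)) sig <- sig + background
  list(signal = sig, envelopes = env, freqs = freqs)
}
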