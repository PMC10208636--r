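#' Morlet wavelet power spectrogram
#'
#' Continuous wavelet transform with 6-cycle Morlet wavelets on a log-spaced
#' frequency grid, the time-frequency front end for transient-bout detection.
#' Samples within one wavelet support (3 Gaussian SDs) of either signal edge
#' are flagged invalid and never produce detections.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz; default 29 log-spaced points, 2-128 Hz.
#' @param n_cycles wavelet width in cycles.
#' @return object of class `wavelet_spectrogram`: `freqs`, `power` (frequency
#'   x time matrix), `valid` (frequency x time logical), `fs`, `n_cycles`.
#' @export
wavelet_power <- function(signal, fs, freqs = 2^seq(1, 7, length.out = 29),
                          n_cycles = 6) {
  if (any(!is.finite(signal))) stop("non-finite sample in signal")
  if (any(freqs >= fs / 2)) stop("wavelet frequency at or above Nyquist")
  n <- length(signal)
  pw <- matrix(0, length(freqs), n)
  valid <- matrix(TRUE, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f)
    # 5-sigma support: harsher truncation leaves sidelobes that sample the
    # steep low-frequency part of 1/f^x spectra and bias the mean power by
    # up to ~15% at high frequencies
    half <- ceiling(5 * sigma_t * fs)
    tt <- (-half:half) / fs
    kern <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    # unit-energy normalization: mean power of colored noise at f tracks the
    # PSD S(f) itself, so the log-log background fit recovers the exponent
    kern <- kern / sqrt(sum(Mod(kern)^2))
    co <- fft_convolve_same(signal + 0i, kern)
    pw[i, ] <- Mod(co)^2
    if (half >= 1) {
      edge <- min(half, n)
      valid[i, seq_len(edge)] <- FALSE
      valid[i, (n - edge + 1):n] <- FALSE
    }
  }
  structure(list(freqs = freqs, power = pw, valid = valid, fs = fs,
                 n_cycles = n_cycles), class = "wavelet_spectrogram")
}

#' Fit the aperiodic background of a wavelet spectrogram and derive
#' amplitude thresholds
#'
#' Regresses log mean wavelet power on log frequency (the spectral tilt),
#' optionally excluding configured peak bands from the regression so genuine
#' oscillations do not inflate the background. The per-frequency amplitude
#' threshold is the 95th percentile of a chi-square distribution with 2
#' degrees of freedom (the distribution of wavelet power of Gaussian noise),
#' scaled so its mean equals the fitted background power.
#'
#' @param wsp a [wavelet_power()] result.
#' @param exclude_bands optional list of length-2 numeric vectors (Hz) left
#'   out of the background regression.
#' @param prob exceedance quantile for the threshold.
#' @return list with `threshold` (per frequency), `background` (fitted mean
#'   power per frequency), `slope`, `intercept` (log-log fit).
#' @export
fit_background <- function(wsp, exclude_bands = NULL, prob = 0.95) {
  f <- wsp$freqs
  if (length(f) < 5) stop("need at least 5 frequencies to fit a background")
  mp <- vapply(seq_along(f),
               function(i) mean(wsp$power[i, wsp$valid[i, ]]), numeric(1))
  keep <- rep(TRUE, length(f))
  for (b in exclude_bands) keep <- keep & !(f >= b[1] & f <= b[2])
  fit <- stats::lm.fit(cbind(1, log10(f[keep])), log10(mp[keep]))
  bg <- 10^(fit$coefficients[1] + fit$coefficients[2] * log10(f))
  # chi-square(2) scaled to mean bg: power ~ bg * chisq_2 / 2
  thr <- bg * stats::qchisq(prob, df = 2) / 2
  list(threshold = unname(thr), background = unname(bg),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Detect transient oscillatory bouts by joint amplitude-duration
#' thresholding
#'
#' A frequency-time cell is a "hit" when wavelet power exceeds the amplitude
#' threshold continuously for at least `n_cycles_min` cycles of that
#' frequency. Classifies the graded power measure into discrete detected
#' episodes.
#'
#' @param wsp a [wavelet_power()] result.
#' @param threshold per-frequency amplitude threshold, e.g.
#'   `fit_background(wsp)$threshold`.
#' @param n_cycles_min duration threshold in cycles.
#' @return object of class `bout_mask`: `mask` (logical frequency x time),
#'   `freqs`, `fs`, `threshold`, `n_cycles_min`.
#' @export
detect_bouts <- function(wsp, threshold, n_cycles_min = 3) {
  stopifnot(length(threshold) == length(wsp$freqs))
  mask <- matrix(FALSE, nrow(wsp$power), ncol(wsp$power))
  for (i in seq_along(wsp$freqs)) {
    above <- wsp$power[i, ] > threshold[i] & wsp$valid[i, ]
    minlen <- ceiling(n_cycles_min * wsp$fs / wsp$freqs[i])
    if (!any(above)) next
    runs <- logical_runs(above)
    long <- runs[runs[, "end"] - runs[, "start"] + 1 >= minlen, , drop = FALSE]
    for (r in seq_len(nrow(long)))
      mask[i, long[r, "start"]:long[r, "end"]] <- TRUE
  }
  structure(list(mask = mask, freqs = wsp$freqs, fs = wsp$fs,
                 threshold = threshold, n_cycles_min = n_cycles_min),
            class = "bout_mask")
}

#' Occupancy rate (P_episode) per frequency
#'
#' Percentage of recording time covered by detected oscillatory episodes at
#' each frequency: total detected duration / signal duration x 100.
#'
#' @param bm a [detect_bouts()] result, or a logical frequency x time matrix.
#' @return data.frame with `freq` and `occupancy` (percent).
#' @export
occupancy <- function(bm) {
  if (is.matrix(bm)) {
    mask <- bm
    freqs <- seq_len(nrow(bm))
  } else {
    mask <- bm$mask
    freqs <- bm$freqs
  }
  data.frame(freq = freqs, occupancy = 100 * rowMeans(mask))
}

#' Band-collapsed bout intervals and durations
#'
#' Collapses the detection mask over a frequency band (logical OR across
#' rows: a time point is inside a bout if any frequency in the band is a
#' hit), extracts start/stop transitions, drops incomplete events that touch
#' the signal edges, and summarizes durations with a kernel density.
#'
#' @param bm a [detect_bouts()] result.
#' @param band length-2 numeric, frequency band in Hz.
#' @param label band label recorded in the output.
#' @param kde_bw kernel density bandwidth for the duration distribution, in
#'   milliseconds.
#' @return object of class `bout_table`: data.frame with `label`, `start`,
#'   `end`, `duration` (s); attribute `kde` holds the duration density
#'   (`stats::density` object, ms scale) when there are >= 2 events.
#' @export
bout_durations <- function(bm, band, label = paste0(band[1], "-", band[2], "Hz"),
                           kde_bw = 50) {
  rows <- bm$freqs >= band[1] & bm$freqs <= band[2]
  if (!any(rows)) stop("band contains no grid frequencies")
  collapsed <- colSums(bm$mask[rows, , drop = FALSE]) >= 1
  n <- length(collapsed)
  runs <- logical_runs(collapsed)
  # incomplete events: missing a start (begins at sample 1) or a stop
  if (nrow(runs)) {
    complete <- runs[, "start"] > 1 & runs[, "end"] < n
    runs <- runs[complete, , drop = FALSE]
  }
  tab <- data.frame(label = rep(label, nrow(runs)),
                    start = (runs[, "start"] - 1) / bm$fs,
                    end = runs[, "end"] / bm$fs)
  tab$duration <- tab$end - tab$start
  kde <- if (nrow(tab) >= 2)
    stats::density(tab$duration * 1000, bw = kde_bw) else NULL
  structure(tab, class = c("bout_table", "data.frame"), kde = kde)
}
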