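#' Welch power spectral density with per-window segments
#'
#' Estimates the PSD with 50%-overlapping Hann-tapered sliding windows
#' (default 1024 samples). Windows are zero-padded four-fold before the FFT
#' so that a 1 kHz recording lands on a ~0.25 Hz frequency grid; zero-padding
#' only interpolates the same estimator and leaves the Welch statistics
#' unchanged. One-sided density scaling is used, so the integral of the PSD
#' over frequency equals the signal variance.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param nwin window length in samples.
#' @param fmin,fmax returned frequency range in Hz.
#' @param pad zero-padding factor (FFT length = `pad * nwin`).
#' @return object of class `power_spectrum`: list with `freqs`, `power`
#'   (averaged PSD), and `segments` (window x frequency matrix).
#' @export
welch_psd <- function(signal, fs, nwin = 1024, fmin = 1, fmax = 150,
                      pad = 4) {
  bad <- which(!is.finite(signal))
  if (length(bad)) stop("non-finite sample in signal at index ", bad[1])
  n <- length(signal)
  if (n < 2 * nwin) stop("signal must be at least two windows long")
  step <- nwin / 2
  starts <- seq(1, n - nwin + 1, by = step)
  w <- hann_window(nwin)
  nfft <- pad * nwin
  scale <- 2 / (fs * sum(w^2))
  freqs_all <- (0:(nfft / 2)) * fs / nfft
  keep <- which(freqs_all >= fmin & freqs_all <= fmax)
  segs <- matrix(0, length(starts), length(keep))
  for (i in seq_along(starts)) {
    x <- signal[starts[i]:(starts[i] + nwin - 1)]
    x <- (x - mean(x)) * w
    X <- stats::fft(c(x, rep(0, nfft - nwin)))
    p <- scale * Mod(X[seq_len(nfft / 2 + 1)])^2
    segs[i, ] <- p[keep]
  }
  structure(list(freqs = freqs_all[keep], power = colMeans(segs),
                 segments = segs, fs = fs, nwin = nwin),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("power_spectrum:", length(x$freqs), "frequencies",
      sprintf("(%.2f-%.2f Hz),", min(x$freqs), max(x$freqs)),
      nrow(x$segments), "windows\n")
  invisible(x)
}

gaussian_peak <- function(f, center, height, width) {
  height * exp(-(f - center)^2 / (2 * width^2))
}

# Robust aperiodic fit in log-log space: OLS, drop points whose positive
# residual exceeds 1 SD (candidate peak regions), refit.
fit_aperiodic_robust <- function(logf, logp) {
  fit <- stats::lm.fit(cbind(1, logf), logp)
  res <- logp - cbind(1, logf) %*% fit$coefficients
  keep <- res <= stats::sd(res)
  fit2 <- stats::lm.fit(cbind(1, logf[keep]), logp[keep])
  c(offset = unname(fit2$coefficients[1]),
    exponent = unname(-fit2$coefficients[2]))
}

#' Parametrize a power spectrum into aperiodic and periodic components
#'
#' Decomposes log10 power into a linear 1/f^x aperiodic component plus a sum
#' of Gaussian peaks, in the spirit of spectral-parametrization tools used
#' for electrophysiology. The procedure: (1) robust log-log linear fit of the
#' aperiodic background with candidate peak regions excluded; (2) greedy
#' extraction of Gaussians from the flattened residual, tallest first, each
#' refined by bounded nonlinear least squares, until no residual point
#' exceeds `peak_threshold` residual SDs (ties on height broken toward lower
#' frequency); (3) aperiodic refit on the peak-subtracted spectrum.
#'
#' @param ps a [welch_psd()] result, or any list with `freqs` and `power`.
#' @param fmin,fmax fit range in Hz (grid capped at available frequencies).
#' @param peak_width_limits length-2 numeric, allowed Gaussian SD range (Hz).
#' @param peak_threshold residual threshold in SD units for accepting a peak.
#' @param min_peak_height minimum peak height (log10 power).
#' @param max_peaks hard cap on the number of extracted peaks.
#' @return object of class `spectral_model`: `aperiodic` (offset, exponent),
#'   `peaks` (data.frame center/height/width), `residual` (flattened
#'   spectrum), `freqs`, `fitted` (full model, log10).
#' @export
fit_spectral_model <- function(ps, fmin = 1, fmax = 200,
                               peak_width_limits = c(0.5, 12),
                               peak_threshold = 2.0,
                               min_peak_height = 0,
                               max_peaks = 20) {
  sel <- ps$freqs >= fmin & ps$freqs <= fmax
  f <- ps$freqs[sel]
  p <- ps$power[sel]
  if (any(p <= 0)) stop("non-positive power in fit range; log10 undefined")
  logf <- log10(f)
  logp <- log10(p)

  ap <- fit_aperiodic_robust(logf, logp)
  flat <- logp - (ap["offset"] - ap["exponent"] * logf)

  peaks <- list()
  resid <- flat
  for (k in seq_len(max_peaks + 1)) {
    s <- stats::sd(resid)
    hmax <- max(resid)
    if (hmax < peak_threshold * s || hmax <= min_peak_height) break
    if (k > max_peaks) {
      warning("peak cap of ", max_peaks, " reached; remaining peaks ignored")
      break
    }
    # tallest residual point; tie toward lower frequency
    i0 <- which(resid == hmax)[1]
    guess <- c(center = f[i0], height = hmax,
               width = mean(peak_width_limits[1], 2))
    lo <- c(max(fmin, f[i0] - 5), min_peak_height, peak_width_limits[1])
    hi <- c(min(fmax, f[i0] + 5), 2 * hmax, peak_width_limits[2])
    df <- data.frame(f = f, y = resid)
    fit <- try(minpack.lm::nlsLM(
      y ~ height * exp(-(f - center)^2 / (2 * width^2)),
      data = df,
      start = list(center = f[i0], height = hmax, width = 2),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) break
    cf <- stats::coef(fit)
    peaks[[length(peaks) + 1]] <- data.frame(
      center = cf["center"], height = cf["height"], width = cf["width"])
    resid <- resid - gaussian_peak(f, cf["center"], cf["height"], cf["width"])
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(center = numeric(), height = numeric(), width = numeric())
  rownames(peaks) <- NULL

  # refit aperiodic on the peak-subtracted spectrum (plain OLS: peaks removed)
  peak_sum <- if (nrow(peaks))
    rowSums(sapply(seq_len(nrow(peaks)), function(i)
      gaussian_peak(f, peaks$center[i], peaks$height[i], peaks$width[i])))
    else 0
  fit2 <- stats::lm.fit(cbind(1, logf), logp - peak_sum)
  ap <- c(offset = unname(fit2$coefficients[1]),
          exponent = unname(-fit2$coefficients[2]))
  ap_line <- ap["offset"] - ap["exponent"] * logf
  structure(list(
    aperiodic = ap, peaks = peaks,
    residual = logp - ap_line, freqs = f,
    fitted = ap_line + peak_sum), class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("spectral_model: offset %.3f, exponent %.3f, %d peak(s)\n",
              x$aperiodic["offset"], x$aperiodic["exponent"], nrow(x$peaks)))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Flatten a power spectrum by removing the fitted aperiodic component
#'
#' @param ps a [welch_psd()] result.
#' @param model a [fit_spectral_model()] result for the same spectrum; fitted
#'   on the fly if NULL.
#' @return data.frame with `freq` and `residual` (log10 observed minus
#'   aperiodic), restricted to the model's fit range.
#' @export
flatten <- function(ps, model = NULL) {
  if (is.null(model)) model <- fit_spectral_model(ps)
  sel <- ps$freqs >= min(model$freqs) & ps$freqs <= max(model$freqs)
  logp <- log10(ps$power[sel])
  ap <- model$aperiodic["offset"] -
    model$aperiodic["exponent"] * log10(ps$freqs[sel])
  data.frame(freq = ps$freqs[sel], residual = logp - ap)
}

#' Quantile-sorted spectral density map
#'
#' Normalizes each PSD segment by its median, sorts segments by mean power in
#' a sorting band (default 20-30 Hz), and averages them into `nbins`
#' equal-count quantile bins. Visualizes how the rest of the spectrum behaves
#' as a function of power in the sorting band.
#'
#' @param ps a [welch_psd()] result with per-window `segments`.
#' @param sort_band length-2 numeric, the band whose mean power defines the
#'   sort key (Hz).
#' @param nbins number of quantile bins.
#' @return object of class `sorted_spectral_map`: `map` (nbins x frequency
#'   matrix, ascending sort key), `freqs`, `sort_key` (per retained segment),
#'   `dropped` (indices of zero-median segments).
#' @export
sorted_spectral_map <- function(ps, sort_band = c(20, 30), nbins = 50) {
  segs <- ps$segments
  if (nrow(segs) < nbins) stop("need at least ", nbins, " segments")
  med <- apply(segs, 1, stats::median)
  dropped <- which(med == 0)
  if (length(dropped)) {
    message(length(dropped), " zero-median segment(s) dropped")
    segs <- segs[-dropped, , drop = FALSE]
    med <- med[-dropped]
  }
  segs <- segs / med
  bsel <- ps$freqs >= sort_band[1] & ps$freqs <= sort_band[2]
  key <- rowMeans(segs[, bsel, drop = FALSE])
  ord <- order(key)
  segs <- segs[ord, , drop = FALSE]
  # equal-count (+/-1) partition of sorted segments into nbins
  bin <- as.integer(cut(seq_len(nrow(segs)), breaks = nbins, labels = FALSE))
  map <- t(vapply(seq_len(nbins),
                  function(b) colMeans(segs[bin == b, , drop = FALSE]),
                  numeric(ncol(segs))))
  structure(list(map = map, freqs = ps$freqs, sort_key = key[ord],
                 dropped = dropped), class = "sorted_spectral_map")
}

#' Per-frequency paired contrast between behavioral states
#'
#' Wilcoxon signed rank test at each frequency on paired per-session values
#' (e.g. flattened power in search vs rest), with Benjamini-Hochberg FDR
#' correction across frequencies.
#'
#' @param search,rest numeric matrices, session x frequency, paired by row,
#'   on the same frequency grid.
#' @param freqs frequency grid (Hz).
#' @param alpha significance level applied to the adjusted p-values.
#' @return object of class `state_contrast`: data.frame with `freq`,
#'   `direction` (median search - rest), `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
compare_states <- function(search, rest, freqs, alpha = 0.05) {
  search <- as.matrix(search); rest <- as.matrix(rest)
  if (!all(dim(search) == dim(rest)))
    stop("search and rest must be paired: identical dimensions required")
  if (ncol(search) != length(freqs))
    stop("column count must match the frequency grid")
  nf <- length(freqs)
  p <- stat <- dir <- numeric(nf)
  for (j in seq_len(nf)) {
    d <- search[, j] - rest[, j]
    if (all(d == 0)) {            # exact ties carry no evidence
      p[j] <- 1
      stat[j] <- 0
    } else {
      wt <- stats::wilcox.test(d, exact = FALSE)
      p[j] <- wt$p.value
      stat[j] <- unname(wt$statistic)
    }
    dir[j] <- stats::median(d)
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  structure(data.frame(freq = freqs, direction = dir, statistic = stat,
                       p = p, p_adj = p_adj,
                       significant = p_adj < alpha),
            class = c("state_contrast", "data.frame"))
}
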