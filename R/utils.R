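#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, the standard
#' pre-processing step for envelope and event detection on LFP traces.
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz. Use `low = NULL` for a lowpass and
#'   `high = NULL` for a highpass.
#' @param order filter order (applied twice by filtfilt, so the effective
#'   attenuation is doubled).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 4) {
  nyq <- fs / 2
  if (!is.null(high) && high >= nyq) {
    stop("filter band edge ", high, " Hz is at or beyond Nyquist (", nyq, " Hz)")
  }
  if (is.null(low)) {
    bf <- signal::butter(order, high / nyq, type = "low")
  } else if (is.null(high)) {
    bf <- signal::butter(order, low / nyq, type = "high")
  } else {
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  # reflect-pad so filter edge transients fall outside the returned signal;
  # the transient length scales with the period of the narrowest corner
  n <- length(x)
  corner <- if (!is.null(low)) low else high
  pad <- min(n - 1, ceiling(3 * fs / corner))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

#' Hann window
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @keywords internal
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Linear FFT convolution returning the "same"-length central part,
# aligned so that out[t] = sum_k x[t + k - center] * kern[k].
fft_convolve_same <- function(x, kern) {
  nx <- length(x)
  nk <- length(kern)
  nfft <- stats::nextn(nx + nk - 1, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - nx))) *
                  stats::fft(c(kern, rep(0, nfft - nk))), inverse = TRUE) / nfft
  start <- floor((nk - 1) / 2) + 1
  y[start:(start + nx - 1)]
}

# Derive an independent substream seed from a global seed and a component tag.
# Keeps components reproducible yet decoupled when one of them consumes a
# different amount of randomness.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Run-length encode a logical vector into (start, end) sample index pairs
# (inclusive) of the TRUE runs.
logical_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Empirical two-sided permutation p-value with add-one correction.
perm_p_two_sided <- function(obs, null) {
  n <- length(null)
  p_hi <- (1 + sum(null >= obs)) / (1 + n)
  p_lo <- (1 + sum(null <= obs)) / (1 + n)
  min(1, 2 * min(p_hi, p_lo))
}

# Label 4-connected clusters of TRUE cells in a logical matrix.
# Returns an integer matrix of cluster ids (0 = background).
label_clusters_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cell] != 0L || !mask[cell]) next
      lab[cell] <- cur
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      if (i > 1L)  stack <- c(stack, cell - 1L)
      if (i < nr)  stack <- c(stack, cell + 1L)
      if (j > 1L)  stack <- c(stack, cell - nr)
      if (j < nc)  stack <- c(stack, cell + nr)
    }
  }
  lab
}

# Size of the largest 4-connected TRUE cluster (0 if none).
max_cluster_size <- function(mask) {
  lab <- label_clusters_4(mask)
  if (!any(lab > 0L)) return(0L)
  max(tabulate(lab[lab > 0L]))
}

#' Tukey (tapered cosine) window
#' @param n window length in samples.
#' @param alpha fraction of the window inside the cosine tapers.
#' @return numeric vector of length `n`; flat at 1 over the central
#'   `1 - alpha` fraction.
#' @keywords internal
tukey_window <- function(n, alpha = 0.3) {
  if (n == 1) return(1)
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}
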