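#' Cross-frequency power comodulogram
#'
#' Pearson correlation, across sliding spectral windows, of per-window power
#' between every pair of frequencies: entry (i, j) correlates the power time
#' series at frequency i with that at frequency j.
#'
#' @param segments window x frequency matrix of per-window PSD values, e.g.
#'   `welch_psd(x, fs)$segments`.
#' @param freqs frequency grid matching the columns.
#' @return object of class `comodulogram`: `corr` (frequency x frequency),
#'   `freqs`, `n_windows`.
#' @export
power_comodulogram <- function(segments, freqs = seq_len(ncol(segments))) {
  segments <- as.matrix(segments)
  if (nrow(segments) < 30)
    stop("need at least 30 windows for a stable comodulogram")
  cc <- stats::cor(segments)
  dimnames(cc) <- NULL
  structure(list(corr = cc, freqs = freqs, n_windows = nrow(segments)),
            class = "comodulogram")
}

# per-cell two-sided p-values and signed significance masks from a null array
cell_p_from_null <- function(obs, null_arr) {
  n <- dim(null_arr)[3]
  p <- (1 + apply(sweep(abs(null_arr), c(1, 2), abs(obs), ">="), c(1, 2), sum)) /
    (1 + n)
  p
}

#' Surrogate cluster-based significance test for a comodulogram
#'
#' Destroys cross-frequency coupling by permuting the window order
#' independently for each frequency column, recomputing the comodulogram each
#' time. Per-cell two-sided p-values come from the surrogate distribution;
#' cells with p below `alpha` are clustered by 4-connectivity (positive and
#' negative correlations clustered separately), and observed cluster sizes
#' are compared with the 95th quantile of the surrogate maximum-cluster-size
#' distribution.
#'
#' @param segments window x frequency PSD matrix.
#' @param freqs frequency grid.
#' @param n_perm number of surrogate permutations.
#' @param alpha cell-level and cluster-level significance threshold.
#' @param seed optional integer seed for the permutations.
#' @return object of class `cluster_test`: `corr` (observed), `p` (per-cell),
#'   `sig_uncorrected`, `sig` (cluster-corrected mask), `cluster_null`
#'   (surrogate max cluster sizes), `cluster_threshold`.
#' @export
surrogate_cluster_test <- function(segments, freqs = seq_len(ncol(segments)),
                                   n_perm = 5000, alpha = 0.05, seed = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations: unstable quantiles")
  if (!is.null(seed)) set.seed(seed)
  segments <- as.matrix(segments)
  obs <- power_comodulogram(segments, freqs)$corr
  k <- nrow(segments)
  nf <- ncol(segments)
  null_arr <- array(0, c(nf, nf, n_perm))
  for (s in seq_len(n_perm)) {
    perm <- apply(segments, 2, function(col) col[sample.int(k)])
    null_arr[, , s] <- stats::cor(perm)
  }
  p <- cell_p_from_null(obs, null_arr)
  diag(p) <- 1                       # the unit diagonal is not a finding

  # identical scoring rule for the observed matrix and every surrogate:
  # a cell exceeds when its |corr| beats the k-th largest surrogate value,
  # k = floor(alpha * (n_perm + 1)); this matches the add-one p < alpha rule
  # exactly, so observed and surrogate cluster sizes are exchangeable under
  # the null (scoring the surrogates against a quantile while scoring the
  # observed map with the add-one p is asymmetric and makes the test
  # conservative, increasingly so on larger grids)
  k <- max(1L, floor(alpha * (n_perm + 1)))
  thr_cell <- apply(abs(null_arr), c(1, 2),
                    function(v) sort(v, decreasing = TRUE)[k])
  sig_unc <- abs(obs) > thr_cell
  diag(sig_unc) <- FALSE
  null_max <- vapply(seq_len(n_perm), function(s) {
    m <- null_arr[, , s]
    exceed <- abs(m) > thr_cell
    diag(exceed) <- FALSE
    max(max_cluster_size(exceed & m > 0), max_cluster_size(exceed & m < 0))
  }, numeric(1))
  cthr <- stats::quantile(null_max, 1 - alpha, names = FALSE)

  sig <- matrix(FALSE, nf, nf)
  for (sign_dir in c(1, -1)) {
    cand <- sig_unc & (sign(obs) == sign_dir)
    lab <- label_clusters_4(cand)
    if (any(lab > 0)) {
      sizes <- tabulate(lab[lab > 0])
      for (cl in which(sizes > cthr)) sig[lab == cl] <- TRUE
    }
  }
  structure(list(corr = obs, freqs = freqs, p = p, sig_uncorrected = sig_unc,
                 sig = sig, cluster_null = null_max,
                 cluster_threshold = cthr, n_perm = n_perm,
                 alpha = alpha), class = "cluster_test")
}

#' Hilbert amplitude-envelope correlation between two frequencies
#'
#' Zero-phase third-order Butterworth bandpass with a 2 Hz bandwidth around
#' each frequency, Hilbert amplitude envelope, Pearson correlation of the two
#' envelopes.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param f_i,f_j center frequencies (Hz).
#' @param bandwidth filter bandwidth (Hz).
#' @return correlation coefficient.
#' @export
envelope_correlation <- function(signal, fs, f_i, f_j, bandwidth = 2) {
  env <- function(f) {
    b <- bandpass_filter(signal, fs, f - bandwidth / 2, f + bandwidth / 2,
                         order = 3)
    Mod(analytic_signal(b))
  }
  e1 <- env(f_i)
  e2 <- if (f_j == f_i) e1 else env(f_j)
  stats::cor(e1, e2)
}

#' Bicoherence matrix
#'
#' Normalized bispectrum over 50%-overlapping Hann-tapered segments:
#' `B(f1,f2) = |<F(f1) F(f2) F*(f1+f2)>| / <|F(f1) F(f2) F*(f1+f2)|>`,
#' bounded in [0, 1]; values near 1 indicate quadratic phase coupling of the
#' triad (f1, f2, f1+f2). Invariant to overall amplitude scaling.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param f1_max,f2_max upper edges of the f1 and f2 axes (Hz); the grid is
#'   1 Hz-stepped and f1 + f2 is capped at Nyquist.
#' @param seg_len segment length in samples.
#' @return object of class `bicoherence_matrix`: `B` (f1 x f2), `f1`, `f2`,
#'   `n_segments`.
#' @export
bicoherence <- function(signal, fs, f1_max = 75, f2_max = 150,
                        seg_len = 1024) {
  n <- length(signal)
  step <- seg_len / 2
  starts <- seq(1, n - seg_len + 1, by = step)
  if (length(starts) < 2) stop("signal shorter than two segments")
  w <- hann_window(seg_len)
  df <- fs / seg_len
  f1 <- seq(1, f1_max)
  f2 <- seq(1, f2_max)
  i1 <- round(f1 / df) + 1            # nearest FFT bin
  i2 <- round(f2 / df) + 1
  nyq_bin <- seg_len / 2 + 1
  num <- matrix(0 + 0i, length(f1), length(f2))
  den <- matrix(0, length(f1), length(f2))
  valid <- outer(i1, i2, "+") - 1 <= nyq_bin
  for (s in starts) {
    x <- signal[s:(s + seg_len - 1)]
    X <- stats::fft((x - mean(x)) * w)
    trip <- outer(X[i1], X[i2]) * Conj(matrix(X[outer(i1, i2, "+") - 1],
                                              length(f1), length(f2)))
    trip[!valid] <- 0
    num <- num + trip
    den <- den + Mod(trip)
  }
  B <- Mod(num) / den
  B[!valid] <- NA_real_
  B[den == 0 & valid] <- 0
  structure(list(B = B, f1 = f1, f2 = f2, n_segments = length(starts),
                 fs = fs, seg_len = seg_len), class = "bicoherence_matrix")
}

# AR(1) surrogate matched to the signal's lag-1 autocorrelation and variance.
ar1_surrogate <- function(n, phi, sd_innov) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
  innov <- stats::rnorm(n - 1, 0, sd_innov)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

#' Red-noise significance test for bicoherence
#'
#' Bicoherence has a positive bias, so significance is referenced to matched
#' red noise: AR(1) surrogates with the signal's lag-1 autocorrelation and
#' variance, each run through the same bicoherence estimator. Per-cell
#' one-sided p-values are cluster-corrected exactly as in
#' [surrogate_cluster_test()].
#'
#' @param bic a [bicoherence()] result for the observed signal.
#' @param signal the observed signal (used to fit the AR(1) null).
#' @param n_surr number of red-noise surrogates.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return object of class `cluster_test` with fields `B` (observed), `p`,
#'   `sig_uncorrected`, `sig`, `cluster_null`, `cluster_threshold`, `ar_phi`.
#' @export
bicoherence_rednoise_test <- function(bic, signal, n_surr = 5000,
                                      alpha = 0.05, seed = NULL) {
  if (n_surr < 1) stop("need at least one surrogate to build a null")
  if (!is.null(seed)) set.seed(seed)
  phi <- stats::cor(signal[-1], signal[-length(signal)])
  sd_innov <- stats::sd(signal) * sqrt(1 - phi^2)
  dims <- dim(bic$B)
  null_arr <- array(0, c(dims, n_surr))
  for (s in seq_len(n_surr)) {
    surr <- ar1_surrogate(length(signal), phi, sd_innov)
    null_arr[, , s] <- bicoherence(surr, bic$fs, max(bic$f1), max(bic$f2),
                                   bic$seg_len)$B
  }
  ok <- !is.na(bic$B)
  cnt <- apply(sweep(null_arr, c(1, 2), bic$B, ">="), c(1, 2),
               sum, na.rm = TRUE)
  p <- (1 + cnt) / (1 + n_surr)
  p[!ok] <- 1

  # same top-k rank rule for observed and surrogate maps (see
  # surrogate_cluster_test): keeps cluster sizes exchangeable under the null
  k <- max(1L, floor(alpha * (n_surr + 1)))
  thr_cell <- apply(null_arr, c(1, 2),
                    function(v) sort(v, decreasing = TRUE)[k])
  sig_unc <- bic$B > thr_cell & ok
  sig_unc[is.na(sig_unc)] <- FALSE
  null_max <- vapply(seq_len(n_surr), function(s) {
    ex <- null_arr[, , s] > thr_cell & ok
    ex[is.na(ex)] <- FALSE
    max_cluster_size(ex)
  }, numeric(1))
  cthr <- stats::quantile(null_max, 1 - alpha, names = FALSE)

  sig <- matrix(FALSE, dims[1], dims[2])
  lab <- label_clusters_4(sig_unc)
  if (any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    for (cl in which(sizes > cthr)) sig[lab == cl] <- TRUE
  }
  structure(list(B = bic$B, f1 = bic$f1, f2 = bic$f2, p = p,
                 sig_uncorrected = sig_unc, sig = sig,
                 cluster_null = null_max, cluster_threshold = cthr,
                 ar_phi = phi, n_surr = n_surr, alpha = alpha),
            class = "cluster_test")
}
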