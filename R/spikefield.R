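#' Spike-triggered LFP phases across frequencies
#'
#' For each frequency, the LFP is projected onto a complex exponential
#' through a frequency-dependent Hann window of 5 cycles centered on each
#' spike; the argument of that windowed Fourier coefficient is the spike's
#' phase at that frequency (0 = LFP cosine peak). Spikes whose window would
#' overrun the signal edges are excluded at that frequency.
#'
#' Implemented as one FFT convolution of the LFP with the windowed-exponential
#' kernel per frequency, evaluated at the spike samples; the full phase time
#' series is retained internally so spike-time shuffles can reuse it.
#'
#' @param lfp numeric vector.
#' @param spikes spike times in seconds.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid (Hz), 1 Hz steps by default.
#' @param n_cycles window length in cycles per frequency.
#' @param keep_series keep the full per-frequency phase series (memory-heavy;
#'   needed by [ppc_significance()]).
#' @return object of class `spike_phase_set`: `phases` (list per frequency of
#'   spike phases in (-pi, pi]), `freqs`, `spike_index` (list of indices into
#'   `spikes` retained per frequency), `series` (optional matrix frequency x
#'   time of unwrapped complex phase), `n_spikes`.
#' @export
spike_phases <- function(lfp, spikes, fs, freqs = 2:150, n_cycles = 5,
                         keep_series = FALSE) {
  n <- length(lfp)
  samp <- round(spikes * fs) + 1
  phases <- vector("list", length(freqs))
  spike_index <- vector("list", length(freqs))
  series <- if (keep_series) matrix(0, length(freqs), n) else NULL
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    L <- round(n_cycles * fs / f)
    L <- L + (1 - L %% 2)                 # odd length, centered
    w <- hann_window(L)
    tt <- ((seq_len(L) - 1) - (L - 1) / 2) / fs
    # FFT convolution flips the kernel, so the +i kernel implements the
    # -i correlation that defines the phase (0 = cosine peak)
    kern <- w * exp(2i * pi * f * tt)
    co <- fft_convolve_same(lfp + 0i, kern)
    half <- (L - 1) / 2
    ok <- samp - half >= 1 & samp + half <= n
    phases[[i]] <- Arg(co[samp[ok]])
    spike_index[[i]] <- which(ok)
    if (keep_series) series[i, ] <- Arg(co)
  }
  structure(list(phases = phases, freqs = freqs, spike_index = spike_index,
                 series = series, n_spikes = length(spikes), fs = fs,
                 n = n, n_cycles = n_cycles),
            class = "spike_phase_set")
}

#' Pairwise phase consistency
#'
#' Mean over all unordered spike pairs of `cos(theta_j - theta_k)`, computed
#' in closed form as `((sum cos)^2 + (sum sin)^2 - N) / (N (N - 1))`. The
#' estimator is unbiased by spike count: its expectation equals the squared
#' resultant of the underlying phase distribution regardless of N.
#'
#' @param phases numeric vector of phases (radians).
#' @return PPC value in `[-1/(N-1), 1]`; error if fewer than two phases.
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) stop("PPC undefined for fewer than 2 spikes")
  (sum(cos(phases))^2 + sum(sin(phases))^2 - n) / (n * (n - 1))
}

# Rayleigh test p-value (large-sample approximation p = exp(-z), z = N R^2)
rayleigh_p <- function(phases) {
  n <- length(phases)
  r2 <- (mean(cos(phases))^2 + mean(sin(phases))^2)
  z <- n * r2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

#' PPC spectrum with shuffle-based significance
#'
#' Computes the per-frequency PPC of a unit and assesses significance against
#' a null built from `n_shuffle` spike-time shuffles (uniform redraw of the
#' same number of spike times over the recording). A frequency is significant
#' when (i) its PPC exceeds the 95th percentile of the shuffle null, (ii) the
#' Rayleigh test on its phases has p < 0.05, and (iii) it lies on a spectrum
#' peak with height and prominence of at least `min_prominence`.
#'
#' @param lfp numeric vector.
#' @param spikes spike times (s).
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid (Hz).
#' @param n_shuffle number of spike-time shuffles.
#' @param n_cycles phase-estimation window length in cycles.
#' @param min_prominence minimum peak height and prominence for significance.
#' @param seed optional integer seed for the shuffles.
#' @return object of class `ppc_spectrum`: data.frame with `freq`, `ppc`,
#'   `n_spikes`, `shuffle_q95`, `rayleigh_p`, `significant`; attribute
#'   `peaks`.
#' @export
ppc_significance <- function(lfp, spikes, fs, freqs = 2:150,
                             n_shuffle = 1000, n_cycles = 5,
                             min_prominence = 0.005, seed = NULL) {
  if (n_shuffle < 1) stop("need at least one shuffle for a null")
  if (!is.null(seed)) set.seed(seed)
  n <- length(lfp)
  nf <- length(freqs)
  samp <- round(spikes * fs) + 1
  # each shuffle is one redrawn spike train, evaluated at every frequency
  shuf_idx <- matrix(sample.int(n, n_shuffle * length(spikes),
                                replace = TRUE), n_shuffle)
  obs <- ray <- q95 <- numeric(nf)
  n_spk <- integer(nf)
  for (i in seq_len(nf)) {
    f <- freqs[i]
    L <- round(n_cycles * fs / f)
    L <- L + (1 - L %% 2)
    w <- hann_window(L)
    tt <- ((seq_len(L) - 1) - (L - 1) / 2) / fs
    co <- fft_convolve_same(lfp + 0i, w * exp(2i * pi * f * tt))  # see spike_phases
    phase_t <- Arg(co)
    half <- (L - 1) / 2
    ok <- samp - half >= 1 & samp + half <= n
    ph <- phase_t[samp[ok]]
    obs[i] <- ppc(ph)
    ray[i] <- rayleigh_p(ph)
    n_spk[i] <- sum(ok)
    # vectorized shuffle null: indexed cos/sin sums per shuffled train,
    # with out-of-bounds samples dropped from the sums
    inb <- shuf_idx - half >= 1 & shuf_idx + half <= n
    ci <- matrix(cos(phase_t[pmin(pmax(shuf_idx, 1), n)]), n_shuffle)
    si <- matrix(sin(phase_t[pmin(pmax(shuf_idx, 1), n)]), n_shuffle)
    ci[!inb] <- 0; si[!inb] <- 0
    m <- rowSums(inb)
    null_i <- (rowSums(ci)^2 + rowSums(si)^2 - m) / (m * (m - 1))
    null_i[m < 2] <- NA
    q95[i] <- stats::quantile(null_i, 0.95, na.rm = TRUE, names = FALSE)
  }

  pk <- find_spectrum_peaks(obs, min_prominence)
  on_peak <- rep(FALSE, nf)
  # a peak carries its whole top: the 5-cycle phase window cannot resolve
  # frequencies finer than ~f/5, so locking shows up as a mesa rather than a
  # single-sample maximum
  for (i in pk) {
    j <- i
    while (j > 1 && obs[j - 1] >= obs[i] - min_prominence) j <- j - 1
    k <- i
    while (k < nf && obs[k + 1] >= obs[i] - min_prominence) k <- k + 1
    on_peak[j:k] <- TRUE
  }
  sig <- obs > q95 & ray < 0.05 & on_peak
  out <- data.frame(freq = freqs, ppc = obs, n_spikes = n_spk,
                    shuffle_q95 = q95, rayleigh_p = ray, significant = sig)
  structure(out, class = c("ppc_spectrum", "data.frame"), peaks = freqs[pk])
}

# indices of local maxima with height and prominence >= min_prom
find_spectrum_peaks <- function(y, min_prom) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(diff(sign(diff(y))) == -2) + 1
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (y[i] < min_prom) next
    # prominence: height above the higher of the two flanking minima between
    # this peak and the nearest higher terrain (or series edge)
    left <- y[seq_len(i - 1)]
    right <- y[(i + 1):n]
    lh <- which(left > y[i]); rh <- which(right > y[i])
    lmin <- min(left[if (length(lh)) (max(lh) + 1):(i - 1) else seq_len(i - 1)])
    rmin <- min(right[if (length(rh)) seq_len(min(rh) - 1) else seq_along(right)])
    keep[k] <- (y[i] - max(lmin, rmin)) >= min_prom
  }
  idx[keep]
}

#' Kernel density of significant / preferred spike-field frequencies
#'
#' Pools, across units, either every significant frequency or each unit's
#' preferred (peak-PPC significant) frequency, and fits a Gaussian kernel
#' density with a 4 Hz bandwidth.
#'
#' @param spectra list of [ppc_significance()] results.
#' @param what "significant" (all significant frequencies) or "preferred"
#'   (one peak frequency per unit).
#' @param bw kernel bandwidth (Hz).
#' @return `stats::density` object; error if no unit contributes.
#' @export
preferred_frequency_distribution <- function(spectra,
                                             what = c("significant",
                                                      "preferred"),
                                             bw = 4) {
  what <- match.arg(what)
  vals <- unlist(lapply(spectra, function(sp) {
    sig <- sp$freq[sp$significant]
    if (!length(sig)) return(numeric(0))
    if (what == "significant") sig
    else sp$freq[sp$significant][which.max(sp$ppc[sp$significant])]
  }))
  if (!length(vals)) stop("no significant frequencies across units")
  stats::density(vals, bw = bw)
}

# merge overlapping windows [start, end] into disjoint intervals
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i] }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

#' SWR-conditioned decomposition of spike-field coupling
#'
#' Splits a unit's spikes into those inside 600 ms windows centered on SWR
#' peaks (merged when they overlap, so the partition is disjoint and
#' exhaustive) and the residual spikes, computes PPC spectra for both, and
#' tests the per-band difference against a count-matched null: spikes are
#' randomly reassigned to the two conditions preserving the original counts,
#' and the difference of PPCs is recomputed `n_iter` times. In each frequency
#' band only the frequency with the largest absolute observed difference is
#' tested (two-tailed); p-values are FDR-adjusted across bands.
#'
#' @param lfp numeric vector.
#' @param spikes spike times (s) for one unit.
#' @param swr_times SWR event peak times (s), e.g. `detect_events()$peak`.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid (Hz).
#' @param bands list of length-2 numeric band edges (Hz).
#' @param window SWR window length (s), centered on each event.
#' @param n_iter count-matched reassignments.
#' @param min_swr_spikes minimum spikes inside SWR windows for inclusion.
#' @param n_cycles phase-window cycles.
#' @param seed optional integer seed.
#' @return object of class `swr_ppc`: list with `included` (logical; FALSE
#'   with `reason` when the unit is excluded), `freqs`, `ppc_swr`,
#'   `ppc_residual`, `n_swr`, `n_residual`, and `band_tests` (data.frame:
#'   band, peak_freq, delta, p, p_adj, significant).
#' @export
swr_conditioned_ppc <- function(lfp, spikes, swr_times, fs, freqs = 2:150,
                                bands = list(c(2, 3), c(4, 10), c(11, 20),
                                             c(21, 40), c(41, 100),
                                             c(101, 200)),
                                window = 0.6, n_iter = 1000,
                                min_swr_spikes = 20, n_cycles = 5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  excluded <- function(reason)
    structure(list(included = FALSE, reason = reason), class = "swr_ppc")
  if (!length(swr_times)) return(excluded("no SWR events"))
  win <- merge_intervals(swr_times - window / 2, swr_times + window / 2)
  inswr <- rep(FALSE, length(spikes))
  for (r in seq_len(nrow(win)))
    inswr <- inswr | (spikes >= win[r, 1] & spikes <= win[r, 2])
  if (sum(inswr) < min_swr_spikes)
    return(excluded(sprintf("only %d spikes in SWR windows (< %d)",
                            sum(inswr), min_swr_spikes)))
  if (sum(!inswr) < min_swr_spikes)
    return(excluded("too few residual spikes for a PPC"))

  sps <- spike_phases(lfp, spikes, fs, freqs, n_cycles)
  nf <- length(freqs)
  ppc_pair <- function(cond) {
    vapply(seq_len(nf), function(i) {
      ci <- cond[sps$spike_index[[i]]]
      ph <- sps$phases[[i]]
      c(if (sum(ci) >= 2) ppc(ph[ci]) else NA_real_,
        if (sum(!ci) >= 2) ppc(ph[!ci]) else NA_real_)
    }, numeric(2))
  }
  obs <- ppc_pair(inswr)
  delta_obs <- obs[1, ] - obs[2, ]

  n_sw <- sum(inswr)
  # count-matched reassignment null, vectorized: indicator matrix of the
  # random SWR assignments, then per-frequency indexed cos/sin sums
  ind <- matrix(FALSE, length(spikes), n_iter)
  for (s in seq_len(n_iter))
    ind[sample.int(length(spikes), n_sw), s] <- TRUE
  null_delta <- matrix(NA_real_, n_iter, nf)
  for (i in seq_len(nf)) {
    ph <- sps$phases[[i]]
    if (length(ph) < 4) next
    sub <- ind[sps$spike_index[[i]], , drop = FALSE]
    cs <- cos(ph); sn <- sin(ph)
    tot_c <- sum(cs); tot_s <- sum(sn); ntot <- length(ph)
    c1 <- crossprod(sub, cs)[, 1]; s1 <- crossprod(sub, sn)[, 1]
    m1 <- colSums(sub)
    c2 <- tot_c - c1; s2 <- tot_s - s1; m2 <- ntot - m1
    p1 <- (c1^2 + s1^2 - m1) / (m1 * (m1 - 1))
    p2 <- (c2^2 + s2^2 - m2) / (m2 * (m2 - 1))
    p1[m1 < 2] <- NA; p2[m2 < 2] <- NA
    null_delta[, i] <- p1 - p2
  }

  band_rows <- lapply(bands, function(b) {
    sel <- which(freqs >= b[1] & freqs <= b[2] & !is.na(delta_obs))
    if (!length(sel))
      return(data.frame(band = paste0(b[1], "-", b[2]), peak_freq = NA,
                        delta = NA, p = NA))
    i <- sel[which.max(abs(delta_obs[sel]))]
    # the tested frequency is selected as the band's max |delta|, so the null
    # must undergo the same selection: compare against the distribution of the
    # max |delta| over the band in each reassignment (two-tailed by absolute
    # value); testing the selected frequency against its own pointwise null
    # would be anti-conservative
    null_max <- apply(abs(null_delta[, sel, drop = FALSE]), 1, max,
                      na.rm = TRUE)
    null_max <- null_max[is.finite(null_max)]
    data.frame(band = paste0(b[1], "-", b[2]), peak_freq = freqs[i],
               delta = delta_obs[i],
               p = (1 + sum(null_max >= abs(delta_obs[i]))) /
                 (1 + length(null_max)))
  })
  bt <- do.call(rbind, band_rows)
  bt$p_adj <- stats::p.adjust(bt$p, method = "BH")
  bt$significant <- !is.na(bt$p_adj) & bt$p_adj < 0.05
  structure(list(included = TRUE, freqs = freqs,
                 ppc_swr = obs[1, ], ppc_residual = obs[2, ],
                 n_swr = n_sw, n_residual = sum(!inswr),
                 band_tests = bt, swr_windows = win),
            class = "swr_ppc")
}

#' @export
print.swr_ppc <- function(x, ...) {
  if (!x$included) {
    cat("swr_ppc: unit excluded —", x$reason, "\n")
  } else {
    cat(sprintf("swr_ppc: %d SWR spikes, %d residual spikes\n",
                x$n_swr, x$n_residual))
    print(x$band_tests)
  }
  invisible(x)
}
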