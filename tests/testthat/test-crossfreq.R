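test_that("comodulogram reproduces exact linear dependences", {
  set.seed(2)
  k <- 60
  base <- stats::rexp(k) + 1
  segs <- cbind(base, base, -base + 10, stats::rexp(k))
  cm <- power_comodulogram(segs, freqs = c(5, 6, 30, 80))
  expect_equal(cm$corr[1, 2], 1)
  expect_equal(cm$corr[1, 3], -1)
  expect_true(isSymmetric(cm$corr))
  expect_true(all(abs(diag(cm$corr) - 1) < 1e-12))
  expect_true(all(cm$corr >= -1 & cm$corr <= 1))
  expect_error(power_comodulogram(segs[1:10, ]), "30 windows")
})

test_that("comodulogram recovers generated envelope couplings with signs", {
  bg <- get_background(240, exponent = 1, seed = 103)
  ce <- gen_coupled_envelopes(240, fs_t, freqs = c(5, 30, 100),
                              rho = c(-0.7, 0.7), amp = 5 * stats::sd(bg),
                              background = bg, seed = 4)
  ps <- welch_psd(ce$signal, fs_t, fmin = 2, fmax = 120)
  keep <- seq(1, length(ps$freqs), by = 8)
  cm <- power_comodulogram(ps$segments[, keep], ps$freqs[keep])
  ix <- function(f) which.min(abs(cm$freqs - f))
  expect_equal(cm$corr[ix(5), ix(30)], -0.7, tolerance = 0.1)
  expect_equal(cm$corr[ix(5), ix(100)], 0.7, tolerance = 0.1)
})

test_that("surrogate cluster test flags real couplings, not shuffled ones", {
  bg <- get_background(240, exponent = 1, seed = 103)
  ce <- gen_coupled_envelopes(240, fs_t, freqs = c(5, 30, 100),
                              rho = c(-0.7, 0.7), amp = 5 * stats::sd(bg),
                              background = bg, seed = 4)
  ps <- welch_psd(ce$signal, fs_t, fmin = 2, fmax = 120)
  keep <- seq(1, length(ps$freqs), by = 8)
  st <- surrogate_cluster_test(ps$segments[, keep], ps$freqs[keep],
                               n_perm = 300, seed = 5)
  ix <- function(f) which.min(abs(st$freqs - f))
  expect_true(st$sig[ix(5), ix(30)])
  expect_true(st$sig[ix(5), ix(100)])
  expect_true(st$corr[ix(5), ix(30)] < 0)
  # corrected significance is a subset of uncorrected
  expect_true(all(!(st$sig & !st$sig_uncorrected)))
  # independent rows: no significant cluster expected for this seed
  set.seed(9)
  null_segs <- matrix(stats::rexp(60 * 12), 60, 12)
  st0 <- surrogate_cluster_test(null_segs, 1:12, n_perm = 300, seed = 6)
  expect_equal(sum(st0$sig), 0)
  expect_warning(surrogate_cluster_test(null_segs, 1:12, n_perm = 50),
                 "permutations")
})

test_that("envelope correlation tracks shared amplitude modulation", {
  n <- 240 * fs_t
  t <- (seq_len(n) - 1) / fs_t
  set.seed(11)
  ce <- gen_coupled_envelopes(240, fs_t, freqs = c(10, 40), rho = 1,
                              seed = 11)
  r_shared <- envelope_correlation(ce$signal, fs_t, 10, 40)
  expect_gt(r_shared, 0.8)
  # same frequency: correlation 1 by construction
  expect_equal(envelope_correlation(ce$signal, fs_t, 10, 10), 1)
  # independent narrowband noises decorrelate
  x1 <- bandpass_filter(stats::rnorm(n), fs_t, 9, 11)
  x2 <- bandpass_filter(stats::rnorm(n), fs_t, 39, 41)
  expect_lt(abs(envelope_correlation(x1 + x2, fs_t, 10, 40)), 0.1)
})

test_that("envelope correlation concords with the comodulogram entry", {
  bg <- get_background(240, exponent = 1, seed = 103)
  ce <- gen_coupled_envelopes(240, fs_t, freqs = c(5, 30), rho = -0.7,
                              amp = 5 * stats::sd(bg), background = bg,
                              seed = 12)
  ps <- welch_psd(ce$signal, fs_t, fmin = 2, fmax = 60)
  keep <- seq(1, length(ps$freqs), by = 8)
  cm <- power_comodulogram(ps$segments[, keep], ps$freqs[keep])
  ix <- function(f) which.min(abs(cm$freqs - f))
  ec <- envelope_correlation(ce$signal, fs_t, 5, 30)
  expect_lt(abs(ec - cm$corr[ix(5), ix(30)]), 0.15)
})

test_that("bicoherence detects quadratic phase coupling and stays in [0,1]", {
  n <- 120 * fs_t
  t <- (seq_len(n) - 1) / fs_t
  set.seed(13)
  ps1 <- cumsum(stats::rnorm(n, 0, 0.02))
  ps2 <- cumsum(stats::rnorm(n, 0, 0.02))
  coupled <- cos(2 * pi * 20 * t + ps1) + cos(2 * pi * 40 * t + ps2) +
    cos(2 * pi * 60 * t + ps1 + ps2) + stats::rnorm(n) * 0.5
  b <- bicoherence(coupled, fs_t)
  expect_gt(b$B[20, 40], 0.9)
  ok <- !is.na(b$B)
  expect_true(all(b$B[ok] >= 0 & b$B[ok] <= 1 + 1e-12))
  # amplitude-scaling invariance
  b5 <- bicoherence(5 * coupled, fs_t)
  expect_equal(b5$B, b$B, tolerance = 1e-10)
  # independent third phase: no coupling at (20, 40)
  ps3 <- cumsum(stats::rnorm(n, 0, 0.02))
  indep <- cos(2 * pi * 20 * t + ps1) + cos(2 * pi * 40 * t + ps2) +
    cos(2 * pi * 60 * t + ps3) + stats::rnorm(n) * 0.5
  b0 <- bicoherence(indep, fs_t)
  expect_lt(b0$B[20, 40], 0.3)
})

test_that("bicoherence matches a direct triple-product oracle", {
  set.seed(14)
  x <- stats::rnorm(6 * 1024)
  b <- bicoherence(x, fs_t, f1_max = 10, f2_max = 20, seg_len = 1024)
  # direct computation on the same non-overlapping + half-overlapping grid
  starts <- seq(1, length(x) - 1023, by = 512)
  w <- lfposc:::hann_window(1024)
  df <- fs_t / 1024
  direct <- function(f1, f2) {
    i1 <- round(f1 / df) + 1; i2 <- round(f2 / df) + 1; i3 <- i1 + i2 - 1
    num <- 0 + 0i; den <- 0
    for (s in starts) {
      seg <- x[s:(s + 1023)]
      X <- stats::fft((seg - mean(seg)) * w)
      tp <- X[i1] * X[i2] * Conj(X[i3])
      num <- num + tp; den <- den + Mod(tp)
    }
    Mod(num) / den
  }
  for (pr in list(c(3, 7), c(5, 12), c(9, 18)))
    expect_equal(b$B[pr[1], pr[2]], direct(pr[1], pr[2]), tolerance = 1e-10)
})

test_that("red-noise null separates coupling from AR(1) structure", {
  n <- 120 * fs_t
  t <- (seq_len(n) - 1) / fs_t
  set.seed(15)
  ps1 <- cumsum(stats::rnorm(n, 0, 0.02))
  ps2 <- cumsum(stats::rnorm(n, 0, 0.02))
  sig <- cos(2 * pi * 20 * t + ps1) + cos(2 * pi * 40 * t + ps2) +
    cos(2 * pi * 60 * t + ps1 + ps2) + stats::rnorm(n)
  b <- bicoherence(sig, fs_t, f1_max = 30, f2_max = 50)
  rt <- bicoherence_rednoise_test(b, sig, n_surr = 60, seed = 16)
  expect_true(rt$sig[20, 40])
  lab <- lfposc:::label_clusters_4(rt$sig)
  expect_gt(max(lab), 0)
  # AR(1) input against its own null: nothing survives correction
  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 60 * fs_t))
  bar <- bicoherence(ar, fs_t, f1_max = 30, f2_max = 50)
  rt0 <- bicoherence_rednoise_test(bar, ar, n_surr = 60, seed = 17)
  expect_equal(sum(rt0$sig), 0)
  expect_error(bicoherence_rednoise_test(b, sig, n_surr = 0), "surrogate")
})
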