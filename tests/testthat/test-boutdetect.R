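test_that("wavelet power localizes tones and scales quadratically", {
  t <- (0:(20 * fs_t - 1)) / fs_t
  w1 <- wavelet_power(sin(2 * pi * 8 * t), fs_t)
  mid <- (5 * fs_t):(15 * fs_t)
  ridge <- w1$freqs[which.max(rowMeans(w1$power[, mid]))]
  expect_lt(abs(log2(ridge / 8)), diff(log2(w1$freqs[1:2])))
  w2 <- wavelet_power(2 * sin(2 * pi * 8 * t), fs_t)
  expect_equal(w2$power[, mid], 4 * w1$power[, mid], tolerance = 1e-10)
})

test_that("chirp ridge frequency increases monotonically", {
  dur <- 30
  t <- (0:(dur * fs_t - 1)) / fs_t
  f_inst <- 5 + (20 - 5) * t / dur
  chirp <- sin(2 * pi * cumsum(f_inst) / fs_t)
  w <- wavelet_power(chirp, fs_t)
  probe <- seq(3 * fs_t, (dur - 3) * fs_t, by = fs_t)
  ridge <- w$freqs[apply(w$power[, probe], 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[length(ridge)], ridge[1])
})

test_that("background fit recovers the spectral tilt and calibrates the
           threshold at the chi-square tail", {
  # white background: flat fit, constant threshold
  set.seed(31)
  wpw <- wavelet_power(stats::rnorm(120 * fs_t), fs_t)
  bw <- fit_background(wpw)
  expect_lt(abs(bw$slope), 0.1)
  expect_lt(diff(range(bw$threshold)) / mean(bw$threshold), 0.3)
  # 1/f^2 background: slope -2, ~5% exceedance per frequency
  wp <- wavelet_power(get_background(600), fs_t)
  bf <- fit_background(wp)
  expect_equal(bf$slope, -2, tolerance = 0.1)
  exceed <- vapply(seq_along(wp$freqs), function(i)
    mean(wp$power[i, wp$valid[i, ]] > bf$threshold[i]), numeric(1))
  expect_true(all(abs(exceed - 0.05) <= 0.01))
  expect_error(fit_background(structure(list(freqs = 1:4), class = "x")),
               "5 frequencies")
})

test_that("detect_bouts equals a brute-force run-length scanner", {
  set.seed(7)
  freqs <- c(4, 8, 16)
  n <- 4000
  pw <- matrix(stats::rexp(3 * n), 3, n)
  wsp <- structure(list(freqs = freqs, power = pw,
                        valid = matrix(TRUE, 3, n), fs = fs_t, n_cycles = 6),
                   class = "wavelet_spectrogram")
  thr <- rep(3, 3)
  bm <- detect_bouts(wsp, thr, n_cycles_min = 3)
  brute <- matrix(FALSE, 3, n)
  for (i in 1:3) {
    minlen <- ceiling(3 * fs_t / freqs[i])
    above <- pw[i, ] > 3
    run <- 0
    for (tt in seq_len(n)) {
      run <- if (above[tt]) run + 1 else 0
      if (above[tt] && run >= minlen && (tt == n || !above[tt + 1])) {
        brute[i, (tt - run + 1):tt] <- TRUE
      }
    }
  }
  expect_identical(bm$mask, brute)
})

test_that("an injected high-SNR bout is recovered with >= 80% overlap", {
  bg <- get_background(120)
  n <- length(bg)
  len <- 2 * fs_t
  tt <- (seq_len(len) - 1) / fs_t
  sig <- bg
  i0 <- 30 * fs_t
  sig[i0:(i0 + len - 1)] <- sig[i0:(i0 + len - 1)] +
    6 * stats::sd(bg) * lfposc:::hann_window(len) * sin(2 * pi * 8 * tt)
  wp <- wavelet_power(sig, fs_t)
  thr <- fit_background(wp, exclude_bands = list(c(6, 10)))$threshold
  bt <- bout_durations(detect_bouts(wp, thr), c(7, 9), "theta")
  long <- bt[bt$start <= 32 & bt$end >= 30, ]
  expect_equal(nrow(long), 1)
  ov <- min(long$end[1], 32) - max(long$start[1], 30)
  expect_gte(ov / 2.0, 0.8)
})

test_that("occupancy arithmetic and band collapse follow the definitions", {
  mask <- matrix(FALSE, 2, 1000)
  mask[1, ] <- TRUE
  occ <- occupancy(mask)
  expect_equal(occ$occupancy, c(100, 0))

  # band collapse is a logical OR: overlapping rows merge into one event
  bm <- structure(list(mask = rbind(
    c(rep(FALSE, 100), rep(TRUE, 300), rep(FALSE, 600)),
    c(rep(FALSE, 300), rep(TRUE, 300), rep(FALSE, 400))),
    freqs = c(7, 8), fs = 1000, n_cycles_min = 3), class = "bout_mask")
  bt <- bout_durations(bm, c(6, 9))
  expect_equal(nrow(bt), 1)
  expect_equal(bt$duration, 0.5, tolerance = 1e-6)

  # run touching the signal end is incomplete and dropped
  bm2 <- structure(list(mask = rbind(c(rep(FALSE, 500), rep(TRUE, 500))),
                        freqs = 8, fs = 1000, n_cycles_min = 3),
                   class = "bout_mask")
  expect_equal(nrow(bout_durations(bm2, c(6, 9))), 0)
})

test_that("state-dependent bout rates appear in detected occupancy", {
  cfg <- synth_config(duration = 600, seed = 19)
  s <- make_session(cfg)
  wp <- wavelet_power(s$lfp, s$fs)
  thr <- fit_background(wp, exclude_bands = list(c(6, 10), c(20, 35)))$threshold
  bm <- detect_bouts(wp, thr)
  occ_state <- function(band, state) {
    iv <- s$states[s$states$state == state, ]
    cols <- unlist(lapply(seq_len(nrow(iv)), function(i)
      (floor(iv$start[i] * s$fs) + 1):floor(iv$end[i] * s$fs)))
    rows <- bm$freqs >= band[1] & bm$freqs <= band[2]
    mean(colSums(bm$mask[rows, cols, drop = FALSE]) >= 1) * 100
  }
  expect_gt(occ_state(c(6, 10), "rest"), occ_state(c(6, 10), "search"))
  expect_gt(occ_state(c(20, 35), "search"), occ_state(c(20, 35), "rest"))
})

test_that("occupancy grows proportionally with bout rate", {
  occ_at_rate <- function(rate, seed) {
    cfg <- synth_config(duration = 600, seed = seed, bout_specs = data.frame(
      label = "theta", freq = 8, bandwidth = 2, rate_search = rate,
      rate_rest = rate, dur_mean = 0.8, dur_sd = 0.1, amp = 5),
      swr_spec = list(rate_search = 0, rate_rest = 0, ripple_freq = 140,
                      ripple_dur = 80, ripple_amp = 0, sw_amp = 0,
                      sw_width = 80),
      unit_specs = data.frame(base_rate = 1, locked_freq = NA, kappa = 0,
                              swr_gain = 1), artifact_rate = 0)
    b <- gen_bouts(cfg, bg_sd = 1)
    sum(b$truth$end - b$truth$start) / 600 * 100
  }
  o1 <- occ_at_rate(2, 61)
  o2 <- occ_at_rate(4, 61)
  expect_equal(o2 / o1, 2, tolerance = 0.35)
})
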