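test_that("aperiodic generator produces the requested spectral exponent", {
  for (x in c(0, 2)) {
    cfg <- synth_config(duration = 120, seed = 11, aperiodic_exponent = x)
    sig <- gen_aperiodic(cfg)
    expect_true(abs(mean(sig)) < 1e-8)
    expect_equal(unname(welch_slope(sig, fs_t)), -x, tolerance = 0.1)
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(duration = 60, seed = 5)
  s1 <- make_session(cfg)
  s2 <- make_session(cfg)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$truth$bouts, s2$truth$bouts)
})

test_that("config validation rejects bad inputs", {
  expect_error(synth_config(aperiodic_exponent = NA), "non-finite")
  expect_error(synth_config(state_plan = data.frame(
    state = c("rest", "search"), start = c(0, 100), end = c(200, 300),
    stringsAsFactors = FALSE), duration = 600), "overlap")
  expect_error(synth_config(unit_specs = data.frame(
    base_rate = 5, locked_freq = 600, kappa = 1, swr_gain = 1)), "Nyquist")
})

test_that("bouts are confined to their states and zero rates stay silent", {
  cfg <- synth_config(duration = 300, seed = 9, bout_specs = data.frame(
    label = "theta", freq = 8, bandwidth = 2, rate_search = 0,
    rate_rest = 6, dur_mean = 1, dur_sd = 0.3, amp = 4))
  b <- gen_bouts(cfg, bg_sd = 1)
  expect_true(all(b$truth$state == "rest"))
  plan <- cfg$state_plan
  for (i in seq_len(nrow(b$truth))) {
    st <- plan[plan$state == b$truth$state[i] &
               plan$start <= b$truth$start[i] + 1e-9 &
               plan$end >= b$truth$end[i] - 1e-9, ]
    expect_equal(nrow(st), 1)
  }
})

test_that("rest theta occupancy exceeds search theta occupancy in truth", {
  cfg <- synth_config(duration = 600, seed = 13)
  b <- gen_bouts(cfg, bg_sd = 1)
  th <- b$truth[b$truth$label == "theta", ]
  occ <- function(st) sum(th$end[th$state == st] - th$start[th$state == st])
  expect_gt(occ("rest"), occ("search"))
})

test_that("an injected bout dominates the bandpassed envelope", {
  bg <- get_background(60)
  n <- length(bg)
  len <- fs_t
  tt <- (seq_len(len) - 1) / fs_t
  bout <- numeric(n)
  i0 <- 30 * fs_t
  bout[i0:(i0 + len - 1)] <- 4 * stats::sd(bg) *
    lfposc:::hann_window(len) * sin(2 * pi * 8 * tt)
  filt <- bandpass_filter(bg + bout, fs_t, 7, 9)
  env <- Mod(lfposc:::analytic_signal(filt))
  inside <- max(env[i0:(i0 + len - 1)])
  outside_sd <- stats::sd(env[1:(20 * fs_t)])
  expect_gt(inside, 3 * outside_sd)
})

test_that("SWR generator honors zero rate and writes truth intervals", {
  cfg0 <- synth_config(duration = 120, seed = 3, swr_spec = list(
    rate_search = 0, rate_rest = 0, ripple_freq = 140, ripple_dur = 80,
    ripple_amp = 5, sw_amp = 3, sw_width = 80))
  sw0 <- gen_swrs(cfg0)
  expect_equal(nrow(sw0$truth), 0)
  expect_true(all(sw0$signal == 0))

  cfg <- synth_config(duration = 300, seed = 3)
  sw <- gen_swrs(cfg, background = get_background(300))
  if (nrow(sw$truth)) {
    expect_true(all(sw$truth$start < sw$truth$peak))
    expect_true(all(sw$truth$peak < sw$truth$end))
  }
})

test_that("unlocked units are Poisson with the configured rate", {
  cfg <- synth_config(duration = 600, seed = 21, unit_specs = data.frame(
    base_rate = 5, locked_freq = NA, kappa = 0, swr_gain = 1))
  spk <- gen_spikes(cfg)[[1]]
  n <- length(spk)
  # rate conservation within 3 SEM
  expect_lt(abs(n / 600 - 5), 3 * sqrt(5 / 600))
  # no phase locking: PPC near zero at several probe frequencies
  for (f in c(4, 8, 30)) {
    ph <- (2 * pi * f * spk) %% (2 * pi)
    expect_lt(abs(ppc(ph)), 3 / sqrt(choose(n, 2)))
  }
})

test_that("locked units hit the analytic von Mises PPC", {
  kappa <- 2
  cfg <- synth_config(duration = 600, seed = 23, unit_specs = data.frame(
    base_rate = 5, locked_freq = 8, kappa = kappa, swr_gain = 1))
  spk <- gen_spikes(cfg)[[1]]
  ph <- (2 * pi * 8 * spk) %% (2 * pi)
  target <- (besselI(kappa, 1) / besselI(kappa, 0))^2
  # Monte-Carlo SE of PPC at this N, from the independent von Mises sampler
  set.seed(77)
  se <- stats::sd(replicate(200, ppc(rvonmises(length(ph), kappa))))
  expect_lt(abs(ppc(ph) - target), 3 * se)
})

test_that("SWR gain multiplies spike counts inside event windows", {
  win <- data.frame(start = seq(5, 590, by = 6), end = seq(5.5, 590.5, by = 6))
  cfg <- synth_config(duration = 600, seed = 25, unit_specs = data.frame(
    base_rate = 5, locked_freq = NA, kappa = 0, swr_gain = 5))
  spk <- gen_spikes(cfg, swr_windows = win)[[1]]
  inw <- rowSums(outer(spk, win$start, ">=") &
                 outer(spk, win$end, "<=")) > 0
  t_in <- sum(win$end - win$start)
  ratio <- (sum(inw) / t_in) / (sum(!inw) / (600 - t_in))
  expect_equal(ratio, 5, tolerance = 0.2)
})

test_that("session bundles satisfy their invariants", {
  s <- make_session(synth_config(duration = 60, seed = 2))
  expect_true(all(is.finite(s$lfp)))
  expect_true(all(is.finite(s$noise_channel)))
  for (spk in s$spikes) {
    expect_true(all(spk > 0 & spk < s$duration))
    expect_false(is.unsorted(spk))
  }
  expect_true(all(s$truth$bouts$end <= s$duration))
})

test_that("coupled-envelope generator hits its target correlations", {
  ce <- gen_coupled_envelopes(240, fs_t, freqs = c(5, 30, 100),
                              rho = c(-0.7, 0.7), seed = 4)
  expect_equal(stats::cor(ce$envelopes[, 1], ce$envelopes[, 2]), -0.7,
               tolerance = 0.05)
  expect_equal(stats::cor(ce$envelopes[, 1], ce$envelopes[, 3]), 0.7,
               tolerance = 0.05)
})
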