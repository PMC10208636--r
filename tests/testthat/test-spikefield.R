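test_that("ppc closed form equals the brute-force pairwise mean", {
  set.seed(21)
  for (n in c(5, 50, 200)) {
    th <- stats::runif(n, -pi, pi)
    brute <- mean(utils::combn(n, 2, function(ix) cos(th[ix[1]] - th[ix[2]])))
    expect_equal(ppc(th), brute, tolerance = 1e-12)
  }
  expect_equal(ppc(c(0, pi / 2, pi, 3 * pi / 2)), -1 / 3, tolerance = 1e-12)
  expect_equal(ppc(rep(0.7, 10)), 1, tolerance = 1e-12)
  expect_error(ppc(1), "fewer than 2")
})

test_that("ppc is invariant to phase wrapping", {
  set.seed(22)
  th <- stats::runif(100, -pi, pi)
  th2 <- th + 2 * pi * sample(0:3, 100, replace = TRUE)
  expect_equal(ppc(th), ppc(th2), tolerance = 1e-9)
})

test_that("ppc matches the analytic von Mises expectation and is unbiased
           in the spike count", {
  kappa <- 2
  target <- (besselI(kappa, 1) / besselI(kappa, 0))^2
  set.seed(23)
  v <- replicate(300, ppc(rvonmises(500, kappa)))
  expect_lt(abs(mean(v) - target), 3 * stats::sd(v) / sqrt(300))
  # mean PPC independent of N: regression slope over N indistinguishable
  # from zero at the stated scale
  ns <- c(20, 50, 200, 1000)
  means <- vapply(ns, function(n)
    mean(replicate(200, ppc(rvonmises(n, kappa)))), numeric(1))
  slope <- stats::coef(stats::lm(means ~ ns))[2]
  expect_lt(abs(slope) * max(ns), 0.01)
})

test_that("spike phases line up with LFP landmarks and the Hilbert oracle", {
  dur <- 120
  t <- (0:(dur * fs_t - 1)) / fs_t
  lfp <- cos(2 * pi * 8 * t)
  peaks <- seq(1, dur - 1, by = 1 / 8)
  sp <- spike_phases(lfp, peaks, fs_t, freqs = 8)
  expect_lt(max(abs(sp$phases[[1]])), 0.05)
  # a quarter-cycle after the peak the oscillation is at its descending
  # zero-crossing: phase +pi/2
  sp2 <- spike_phases(lfp, peaks + 1 / 32, fs_t, freqs = 8)
  expect_lt(abs(mean(sp2$phases[[1]]) - pi / 2), 0.05)
  # narrowband noise (band narrower than the 5-cycle estimator bandwidth),
  # built in the frequency domain: windowed estimator vs Hilbert phase
  set.seed(24)
  n <- dur * fs_t
  X <- stats::fft(stats::rnorm(n))
  fgrid <- (seq_len(n) - 1) * fs_t / n
  fa <- pmin(fgrid, fs_t - fgrid)
  X[fa < 7.75 | fa > 8.25] <- 0
  nb <- Re(stats::fft(X, inverse = TRUE)) / n
  spk <- sort(stats::runif(300, 5, dur - 5))
  est <- spike_phases(nb, spk, fs_t, freqs = 8)$phases[[1]]
  hil <- Arg(lfposc:::analytic_signal(nb))[round(spk * fs_t) + 1]
  circ_rmse <- sqrt(mean((Arg(exp(1i * (est - hil))))^2))
  expect_lt(circ_rmse, 0.2)
})

test_that("shuffle significance flags locked frequencies and spares null
           units", {
  dur <- 180
  cfg <- synth_config(duration = dur, seed = 37, aperiodic_exponent = 1.5,
                      unit_specs = data.frame(base_rate = 5, locked_freq = 8,
                                              kappa = 2, swr_gain = 1))
  bg <- gen_aperiodic(cfg)
  t <- (0:(dur * fs_t - 1)) / fs_t
  lfp <- bg + 3 * stats::sd(bg) * sin(2 * pi * 8 * t)
  spk <- gen_spikes(cfg)[[1]]
  pp <- ppc_significance(lfp, spk, fs_t, freqs = 2:40, n_shuffle = 200,
                         seed = 3)
  expect_true(all(c(7, 8, 9) %in% pp$freq[pp$significant]))
  expect_equal(pp$ppc[pp$freq == 8],
               (besselI(2, 1) / besselI(2, 0))^2, tolerance = 0.1)
  # Poisson unit on pure background: nothing significant
  cfg0 <- synth_config(duration = dur, seed = 38,
                       unit_specs = data.frame(base_rate = 5,
                                               locked_freq = NA, kappa = 0,
                                               swr_gain = 1))
  spk0 <- gen_spikes(cfg0)[[1]]
  pp0 <- ppc_significance(bg, spk0, fs_t, freqs = 2:40, n_shuffle = 200,
                          seed = 3)
  expect_equal(sum(pp0$significant), 0)
  expect_error(ppc_significance(bg, spk0, fs_t, n_shuffle = 0), "shuffle")
})

test_that("preferred-frequency density reflects the unit mixture", {
  mk_spec <- function(fpref) {
    df <- data.frame(freq = 2:60, ppc = 0.001, n_spikes = 500,
                     shuffle_q95 = 0.002, rayleigh_p = 1,
                     significant = FALSE)
    sel <- abs(df$freq - fpref) <= 1
    df$ppc[sel] <- 0.3
    df$significant[sel] <- TRUE
    structure(df, class = c("ppc_spectrum", "data.frame"))
  }
  # all units at 8 Hz: mode at 8
  d8 <- preferred_frequency_distribution(replicate(10, mk_spec(8),
                                                   simplify = FALSE))
  expect_lt(abs(d8$x[which.max(d8$y)] - 8), 1)
  # 50/50 split 8 vs 30 Hz: bimodal with near-equal mass
  specs <- c(replicate(10, mk_spec(8), simplify = FALSE),
             replicate(10, mk_spec(30), simplify = FALSE))
  d <- preferred_frequency_distribution(specs, what = "preferred")
  mass <- function(lo, hi) sum(d$y[d$x >= lo & d$x <= hi]) /
    sum(d$y)
  expect_equal(mass(0, 19), mass(19, 41), tolerance = 0.04)
  expect_error(preferred_frequency_distribution(list(mk_spec(8)[0, ])),
               "no significant")
})

test_that("swr-conditioned decomposition isolates event-specific locking", {
  dur <- 300
  cfg <- synth_config(duration = dur, seed = 41, aperiodic_exponent = 1.5)
  bg <- gen_aperiodic(cfg)
  t <- (0:(dur * fs_t - 1)) / fs_t
  lfp <- bg + 2.5 * stats::sd(bg) * sin(2 * pi * 6 * t)
  set.seed(42)
  swr_times <- seq(3, dur - 3, by = 4) + stats::runif(74, -0.5, 0.5)
  win <- cbind(swr_times - 0.3, swr_times + 0.3)
  base <- 4
  rmax <- base * exp(3) / besselI(3, 0)
  cand <- sort(stats::runif(stats::rpois(1, rmax * dur), 0, dur))
  inw <- vapply(cand, function(x) any(x >= win[, 1] & x <= win[, 2]),
                logical(1))
  th <- 2 * pi * 6 * cand
  r <- ifelse(inw, base * exp(3 * cos(th)) / besselI(3, 0), base)
  spk <- cand[stats::runif(length(cand)) < r / rmax]
  res <- swr_conditioned_ppc(lfp, spk, swr_times, fs_t, freqs = 2:60,
                             n_iter = 300, seed = 7)
  expect_true(res$included)
  row <- res$band_tests[res$band_tests$band == "4-10", ]
  expect_true(row$significant)
  expect_gt(row$delta, 0)
  # spike partition is exhaustive and disjoint
  expect_equal(res$n_swr + res$n_residual, length(spk))
  # count-matched null symmetry: mean delta ~ 0 under uniform locking
  r2 <- base * exp(1.5 * cos(th)) / besselI(1.5, 0)
  spk2 <- cand[stats::runif(length(cand)) <
               r2 / (base * exp(1.5) / besselI(1.5, 0))]
  res2 <- swr_conditioned_ppc(lfp, spk2, swr_times, fs_t, freqs = 2:60,
                              n_iter = 300, seed = 8)
  expect_false(any(res2$band_tests$significant, na.rm = TRUE))
})

test_that("units with degenerate partitions are excluded with reasons", {
  dur <- 60
  lfp <- get_background(60)
  # too few spikes inside SWR windows
  spk <- sort(stats::runif(200, 0, dur))
  out <- swr_conditioned_ppc(lfp, spk, swr_times = 59.9, fs = fs_t,
                             freqs = 4:10, n_iter = 10)
  expect_false(out$included)
  expect_match(out$reason, "spikes in SWR windows")
  # all spikes inside SWR windows: no residual PPC possible
  spk_in <- sort(stats::runif(100, 29.8, 30.2))
  out2 <- swr_conditioned_ppc(lfp, spk_in, swr_times = 30, fs = fs_t,
                              freqs = 4:10, n_iter = 10)
  expect_false(out2$included)
  expect_match(out2$reason, "residual")
  # no events at all
  out3 <- swr_conditioned_ppc(lfp, spk, numeric(0), fs_t)
  expect_false(out3$included)
})
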