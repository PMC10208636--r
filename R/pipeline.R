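#' Default analysis parameters
#'
#' One place for every numeric the analysis chain uses by default: Welch
#' windowing, spectral-parametrization settings, bout-detection grid and
#' thresholds, event-detection bands, spike-field settings and the
#' autocorrelogram fit constraints. Stage blocks omitted from a run
#' configuration fall back to these values.
#'
#' @return nested named list of parameter blocks.
#' @export
pipeline_defaults <- function() {
  list(
    spectral = list(nwin = 1024, fmin = 1, fmax = 150, pad = 4,
                    fit_fmin = 1, fit_fmax = 200,
                    peak_width_limits = c(0.5, 12), peak_threshold = 2.0,
                    min_peak_height = 0, max_peaks = 20,
                    sort_band = c(20, 30), map_bins = 50),
    boutdetect = list(freqs = 2^seq(1, 7, length.out = 29), n_cycles = 6,
                      duration_cycles = 3, threshold_prob = 0.95,
                      exclude_bands = list(c(6, 10), c(20, 35)),
                      bands = list(theta = c(3, 10), beta2 = c(20, 35)),
                      kde_bw = c(theta = 50, beta2 = 10)),
    swr = list(labels = c("SWR", "highGamma", "HFO")),
    crossfreq = list(n_perm = 5000, alpha = 0.05, freq_step = 8,
                     bic_f1 = 75, bic_f2 = 150, bic_nseg = 1024),
    spikefield = list(freqs = 2:150, n_shuffle = 1000, n_cycles = 5,
                      min_prominence = 0.005, swr_window = 0.6,
                      n_iter = 1000, min_swr_spikes = 20,
                      bands = list(c(2, 3), c(4, 10), c(11, 20), c(21, 40),
                                   c(41, 100), c(101, 200))),
    rhythmicity = list(bin_width = 0.010, max_lag = 0.500, min_counts = 100))
}

pipeline_stages <- c("synthgen", "spectral", "boutdetect", "swr",
                     "crossfreq", "spikefield", "rhythmicity")

# per-state Welch segments: windows are computed inside each state interval
# so no window straddles a state boundary
state_psd <- function(session, state, p) {
  segs <- NULL
  iv <- session$states[session$states$state == state, ]
  for (i in seq_len(nrow(iv))) {
    i0 <- floor(iv$start[i] * session$fs) + 1
    i1 <- min(length(session$lfp), floor(iv$end[i] * session$fs))
    if (i1 - i0 + 1 < 2 * p$nwin) next
    ps <- welch_psd(session$lfp[i0:i1], session$fs, nwin = p$nwin,
                    fmin = p$fmin, fmax = p$fmax, pad = p$pad)
    segs <- rbind(segs, ps$segments)
    freqs <- ps$freqs
  }
  if (is.null(segs)) return(NULL)
  structure(list(freqs = freqs, power = colMeans(segs), segments = segs),
            class = "power_spectrum")
}

#' Run the full analysis chain on a (synthetic or supplied) session
#'
#' Executes the requested stages in dependency order — session generation,
#' state-resolved spectral parametrization, transient-bout detection and
#' occupancy, ripple-band event detection, cross-frequency analyses,
#' spike-field coupling with the SWR-conditioned decomposition, and
#' autocorrelogram rhythmicity — writing each stage's tables under
#' `config$out_dir` and returning a manifest that records parameters, output
#' files and status per stage. All randomness derives from `config$seed`.
#'
#' @param config list with `out_dir`, `seed`, optional `stages` (subset of
#'   the stage names, default all), optional `synth` (arguments passed to
#'   [synth_config()]), and optional per-stage parameter blocks overriding
#'   [pipeline_defaults()]. Set `config$session` to an existing
#'   `session_bundle` to skip generation.
#' @param quiet suppress per-stage messages.
#' @return manifest: list of class `run_manifest`, one entry per executed
#'   stage (`params`, `outputs`, `status`, `elapsed_s`), written also to
#'   `run_manifest.yaml`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- config$seed %||% 1L
  defaults <- pipeline_defaults()
  par_of <- function(stage) utils::modifyList(defaults[[stage]] %||% list(),
                                              config[[stage]] %||% list())
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  t_all <- Sys.time()
  note <- function(...) if (!quiet) message(...)

  record <- function(stage, params, outputs, t0, status = "ok") {
    manifest[[stage]] <<- list(
      params = params, outputs = outputs, status = status,
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }

  # --- synthgen ------------------------------------------------------------
  session <- config$session
  if ("synthgen" %in% stages || is.null(session)) {
    t0 <- Sys.time()
    note("synthgen: generating session")
    sargs <- config$synth %||% list()
    sargs$seed <- seed
    scfg <- do.call(synth_config, sargs)
    session <- make_session(scfg)
    sdir <- file.path(out_dir, "session")
    write_session(session, sdir)
    record("synthgen", sargs, list.files(sdir, full.names = TRUE), t0)
  }

  # --- spectral ------------------------------------------------------------
  if ("spectral" %in% stages) {
    t0 <- Sys.time()
    note("spectral: Welch PSD, parametrization, sorted map")
    p <- par_of("spectral")
    outs <- character(0)
    psds <- list()
    for (st in unique(session$states$state)) {
      ps <- state_psd(session, st, p)
      if (is.null(ps)) next
      psds[[st]] <- ps
      mdl <- fit_spectral_model(ps, fmin = p$fit_fmin, fmax = p$fit_fmax,
                                peak_width_limits = p$peak_width_limits,
                                peak_threshold = p$peak_threshold,
                                min_peak_height = p$min_peak_height,
                                max_peaks = p$max_peaks)
      fl <- flatten(ps, mdl)
      f1 <- file.path(out_dir, paste0("psd_", st, ".csv"))
      utils::write.csv(data.frame(freq = ps$freqs, power = ps$power,
                                  flattened = fl$residual[match(
                                    round(ps$freqs, 6),
                                    round(fl$freq, 6))]),
                       f1, row.names = FALSE)
      f2 <- file.path(out_dir, paste0("spectral_model_", st, ".csv"))
      utils::write.csv(data.frame(
        parameter = c("offset", "exponent",
                      if (nrow(mdl$peaks)) paste0("peak", seq_len(nrow(mdl$peaks)),
                                                  "_center")),
        value = c(mdl$aperiodic, mdl$peaks$center)), f2, row.names = FALSE)
      outs <- c(outs, f1, f2)
    }
    if (!is.null(psds$rest)) {
      sm <- sorted_spectral_map(psds$rest, sort_band = p$sort_band,
                                nbins = min(p$map_bins,
                                            nrow(psds$rest$segments)))
      f3 <- file.path(out_dir, "sorted_spectral_map_rest.csv")
      utils::write.csv(as.data.frame(sm$map), f3, row.names = FALSE)
      outs <- c(outs, f3)
    }
    record("spectral", p, outs, t0)
  }

  # --- boutdetect ----------------------------------------------------------
  if ("boutdetect" %in% stages) {
    t0 <- Sys.time()
    note("boutdetect: wavelet transform and bout detection")
    p <- par_of("boutdetect")
    wp <- wavelet_power(session$lfp, session$fs, freqs = p$freqs,
                        n_cycles = p$n_cycles)
    thr <- fit_background(wp, exclude_bands = p$exclude_bands,
                          prob = p$threshold_prob)$threshold
    bm <- detect_bouts(wp, thr, n_cycles_min = p$duration_cycles)
    outs <- character(0)
    occ_rows <- list()
    for (st in unique(session$states$state)) {
      iv <- session$states[session$states$state == st, ]
      cols <- unlist(lapply(seq_len(nrow(iv)), function(i)
        (floor(iv$start[i] * session$fs) + 1):
          min(ncol(bm$mask), floor(iv$end[i] * session$fs))))
      occ <- occupancy(bm$mask[, cols, drop = FALSE])
      occ$freq <- bm$freqs
      occ$state <- st
      occ_rows[[st]] <- occ
    }
    f1 <- file.path(out_dir, "occupancy_by_state.csv")
    utils::write.csv(do.call(rbind, occ_rows), f1, row.names = FALSE)
    outs <- c(outs, f1)
    for (bn in names(p$bands)) {
      bt <- bout_durations(bm, p$bands[[bn]], label = bn,
                           kde_bw = p$kde_bw[[bn]] %||% 50)
      f2 <- file.path(out_dir, paste0("bouts_", bn, ".csv"))
      utils::write.csv(as.data.frame(bt), f2, row.names = FALSE)
      outs <- c(outs, f2)
    }
    record("boutdetect", p, outs, t0)
  }

  # --- swr -----------------------------------------------------------------
  swr_events <- NULL
  if ("swr" %in% stages) {
    t0 <- Sys.time()
    note("swr: ripple-band event detection")
    p <- par_of("swr")
    per_band <- lapply(p$labels, function(lb)
      detect_events(session$lfp, session$noise_channel, session$fs,
                    detection_params(lb)))
    consolidated <- label_duplicates(per_band)
    swr_events <- consolidated[consolidated$label == "SWR", ]
    f1 <- file.path(out_dir, "events.csv")
    utils::write.csv(as.data.frame(consolidated), f1, row.names = FALSE)
    record("swr", p, f1, t0)
  }

  # --- crossfreq -----------------------------------------------------------
  if ("crossfreq" %in% stages) {
    t0 <- Sys.time()
    note("crossfreq: comodulogram and bicoherence")
    p <- par_of("crossfreq")
    set.seed(substream_seed(seed, "crossfreq"))
    ps <- welch_psd(session$lfp, session$fs)
    keep <- seq(1, length(ps$freqs), by = p$freq_step)
    st <- surrogate_cluster_test(ps$segments[, keep], ps$freqs[keep],
                                 n_perm = p$n_perm, alpha = p$alpha)
    f1 <- file.path(out_dir, "comodulogram.csv")
    utils::write.csv(data.frame(
      f_i = rep(st$freqs, times = length(st$freqs)),
      f_j = rep(st$freqs, each = length(st$freqs)),
      corr = as.vector(st$corr), p = as.vector(st$p),
      significant = as.vector(st$sig)), f1, row.names = FALSE)
    bic <- bicoherence(session$lfp, session$fs, p$bic_f1, p$bic_f2,
                       p$bic_nseg)
    f2 <- file.path(out_dir, "bicoherence.csv")
    utils::write.csv(data.frame(
      f1 = rep(bic$f1, times = length(bic$f2)),
      f2 = rep(bic$f2, each = length(bic$f1)),
      B = as.vector(bic$B)), f2, row.names = FALSE)
    record("crossfreq", p, c(f1, f2), t0)
  }

  # --- spikefield ----------------------------------------------------------
  if ("spikefield" %in% stages) {
    t0 <- Sys.time()
    note("spikefield: PPC spectra and SWR-conditioned decomposition")
    p <- par_of("spikefield")
    outs <- character(0)
    ppc_rows <- list()
    band_rows <- list()
    swr_peaks <- if (!is.null(swr_events) && nrow(swr_events))
      swr_events$peak else session$truth$swrs$peak
    for (u in seq_along(session$spikes)) {
      spk <- session$spikes[[u]]
      if (length(spk) < 10) next
      sp <- ppc_significance(session$lfp, spk, session$fs, freqs = p$freqs,
                             n_shuffle = p$n_shuffle, n_cycles = p$n_cycles,
                             min_prominence = p$min_prominence,
                             seed = substream_seed(seed, paste0("ppc", u)))
      sp$unit <- u
      ppc_rows[[u]] <- sp
      if (length(swr_peaks)) {
        sc <- swr_conditioned_ppc(session$lfp, spk, swr_peaks, session$fs,
                                  freqs = p$freqs, bands = p$bands,
                                  window = p$swr_window, n_iter = p$n_iter,
                                  min_swr_spikes = p$min_swr_spikes,
                                  n_cycles = p$n_cycles,
                                  seed = substream_seed(seed,
                                                        paste0("swrppc", u)))
        if (sc$included) {
          bt <- sc$band_tests
          bt$unit <- u
          band_rows[[u]] <- bt
        }
      }
    }
    f1 <- file.path(out_dir, "ppc_spectra.csv")
    utils::write.csv(do.call(rbind, ppc_rows), f1, row.names = FALSE)
    outs <- c(outs, f1)
    if (length(band_rows)) {
      f2 <- file.path(out_dir, "swr_ppc_band_tests.csv")
      utils::write.csv(do.call(rbind, band_rows), f2, row.names = FALSE)
      outs <- c(outs, f2)
    }
    record("spikefield", p, outs, t0)
  }

  # --- rhythmicity ---------------------------------------------------------
  if ("rhythmicity" %in% stages) {
    t0 <- Sys.time()
    note("rhythmicity: autocorrelogram theta-index fits")
    p <- par_of("rhythmicity")
    tab <- theta_index_table(session$spikes)
    f1 <- file.path(out_dir, "theta_index.csv")
    utils::write.csv(tab, f1, row.names = FALSE)
    record("rhythmicity", p, f1, t0)
  }

  manifest$total_elapsed_s <- round(as.numeric(Sys.time() - t_all,
                                               units = "secs"), 2)
  manifest$seed <- seed
  yaml::write_yaml(lapply(manifest, function(x)
    if (is.list(x)) utils::modifyList(x, list(params = NULL)) else x),
    file.path(out_dir, "run_manifest.yaml"))
  structure(manifest, class = "run_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged demonstration configuration
#'
#' A complete 10-minute synthetic session (rest/search alternation, three
#' units) run through every stage. Permutation and shuffle counts are reduced
#' below the full-analysis defaults so the demonstration finishes in minutes;
#' a message notes the reduction.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return a config list for [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  message("demo config: permutation/shuffle counts reduced below the ",
          "full-analysis defaults (5000/1000) for a fast demonstration")
  list(out_dir = out_dir, seed = as.integer(seed),
       synth = list(duration = 600),
       crossfreq = list(n_perm = 300, freq_step = 12),
       spikefield = list(n_shuffle = 300, n_iter = 300))
}
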