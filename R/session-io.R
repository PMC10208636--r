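#' Write a session bundle to disk
#'
#' LFP channels go to flat little-endian float64 binary files with a YAML
#' sidecar carrying the sampling rate, channel names and lengths; spike
#' trains, state intervals and ground-truth tables go to CSV. The layout is
#' self-describing and readable from any language.
#'
#' @param session a [make_session()] bundle.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(as.numeric(session$lfp), file.path(dir, "lfp.f64"),
           size = 8, endian = "little")
  writeBin(as.numeric(session$noise_channel), file.path(dir, "noise.f64"),
           size = 8, endian = "little")
  meta <- list(sampling_rate = session$fs, duration = session$duration,
               n_samples = length(session$lfp),
               channels = list(lfp = "lfp.f64", noise = "noise.f64"),
               n_units = length(session$spikes))
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  spikes <- do.call(rbind, lapply(seq_along(session$spikes), function(u)
    if (length(session$spikes[[u]]))
      data.frame(unit_id = u, time_s = session$spikes[[u]]) else NULL))
  if (is.null(spikes)) spikes <- data.frame(unit_id = integer(),
                                            time_s = numeric())
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$states, file.path(dir, "states.csv"),
                   row.names = FALSE)
  utils::write.csv(session$truth$bouts, file.path(dir, "truth_bouts.csv"),
                   row.names = FALSE)
  utils::write.csv(session$truth$swrs, file.path(dir, "truth_swrs.csv"),
                   row.names = FALSE)
  utils::write.csv(session$truth$artifacts,
                   file.path(dir, "truth_artifacts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir directory containing `session.yaml` and its companions.
#' @return a `session_bundle` (without the generating config).
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  n <- meta$n_samples
  lfp <- readBin(file.path(dir, meta$channels$lfp), what = "numeric",
                 n = n, size = 8, endian = "little")
  noise <- readBin(file.path(dir, meta$channels$noise), what = "numeric",
                   n = n, size = 8, endian = "little")
  spikes_df <- utils::read.csv(file.path(dir, "spikes.csv"))
  spikes <- lapply(seq_len(meta$n_units), function(u)
    sort(spikes_df$time_s[spikes_df$unit_id == u]))
  read_or_empty <- function(f) {
    path <- file.path(dir, f)
    if (file.exists(path)) utils::read.csv(path) else NULL
  }
  structure(list(
    lfp = lfp, noise_channel = noise, fs = meta$sampling_rate,
    duration = meta$duration, spikes = spikes,
    states = utils::read.csv(file.path(dir, "states.csv")),
    truth = list(bouts = read_or_empty("truth_bouts.csv"),
                 swrs = read_or_empty("truth_swrs.csv"),
                 artifacts = read_or_empty("truth_artifacts.csv")),
    config = NULL), class = "session_bundle")
}
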