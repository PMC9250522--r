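# Session container on disk: one directory per session holding plain-text
# files — protocol.json, trials.csv, neural_F.csv / neural_Fn.csv (cells x
# (trials*frames), dims in protocol.json), orofacial_*.csv (trials x
# samples), facial_motion.csv (time x pixels) and ground_truth.csv.

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a session to a directory of plain-text files
#'
#' Serializes a simulated (or assembled) session — protocol, trial table,
#' neural `F`/`F_n` arrays, orofacial traces, facial motion matrix and
#' ground truth — as CSV and JSON under `dir`. The trial table is exported
#' as `trials.csv` (trial, grating, odor, rep_index, onset_s).
#'
#' @param session A `session` list (see [simulate_session()]); the
#'   `orofacial` and `facial` elements are optional.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- session$protocol
  meta <- list(
    trial_duration_s = p$trial_duration_s, iti_s = p$iti_s,
    frame_rate_hz = p$frame_rate_hz, stim_onset_s = p$stim_onset_s,
    stim_epoch_s = p$stim_epoch_s, baseline_epoch_s = p$baseline_epoch_s,
    behavior_rate_hz = p$behavior_rate_hz, facial_rate_hz = p$facial_rate_hz,
    seed = p$seed,
    neural_dim = if (!is.null(session$neural)) dim(session$neural$F))
  jsonlite::write_json(meta, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(p$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(p$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  if (!is.null(session$neural)) {
    d <- dim(session$neural$F)
    write_matrix_csv(matrix(session$neural$F, d[1]),
                     file.path(dir, "neural_F.csv"))
    write_matrix_csv(matrix(session$neural$F_n, d[1]),
                     file.path(dir, "neural_Fn.csv"))
    utils::write.csv(session$neural$ground_truth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  if (!is.null(session$orofacial)) {
    for (ch in c("angle", "curvature", "pressure"))
      write_matrix_csv(session$orofacial[[ch]],
                       file.path(dir, paste0("orofacial_", ch, ".csv")))
  }
  if (!is.null(session$facial))
    write_matrix_csv(session$facial$motion,
                     file.path(dir, "facial_motion.csv"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `session` list with the protocol rebuilt from the stored
#'   trial table and whichever channels are present.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "protocol.json"),
                              simplifyVector = TRUE)
  trials <- as_tibble(utils::read.csv(file.path(dir, "trials.csv"),
                                      colClasses = c(grating = "character",
                                                     odor = "character")))
  conditions <- as_tibble(utils::read.csv(
    file.path(dir, "conditions.csv"),
    colClasses = c(grating = "character", odor = "character")))
  proto <- structure(
    list(conditions = conditions, trials = trials,
         trial_duration_s = meta$trial_duration_s, iti_s = meta$iti_s,
         frame_rate_hz = meta$frame_rate_hz,
         stim_onset_s = meta$stim_onset_s,
         stim_epoch_s = meta$stim_epoch_s,
         baseline_epoch_s = meta$baseline_epoch_s,
         behavior_rate_hz = meta$behavior_rate_hz,
         facial_rate_hz = meta$facial_rate_hz, seed = meta$seed),
    class = "stim_protocol")
  out <- list(protocol = proto)
  fF <- file.path(dir, "neural_F.csv")
  if (file.exists(fF)) {
    d <- meta$neural_dim
    gt <- as_tibble(utils::read.csv(file.path(dir, "ground_truth.csv")))
    out$neural <- structure(
      list(F = array(read_matrix_csv(fF), d),
           F_n = array(read_matrix_csv(file.path(dir, "neural_Fn.csv")), d),
           frame_times_s = frame_times(proto), protocol = proto,
           ground_truth = gt, params = list()),
      class = "roi_fluorescence")
  }
  fa <- file.path(dir, "orofacial_angle.csv")
  if (file.exists(fa)) {
    out$orofacial <- structure(
      list(angle = read_matrix_csv(fa),
           curvature = read_matrix_csv(file.path(dir,
                                                 "orofacial_curvature.csv")),
           pressure = read_matrix_csv(file.path(dir,
                                                "orofacial_pressure.csv")),
           times_s = frame_times(proto, meta$behavior_rate_hz),
           rate_hz = meta$behavior_rate_hz, protocol = proto,
           ground_truth = list()),
      class = "orofacial_series")
  }
  fm <- file.path(dir, "facial_motion.csv")
  if (file.exists(fm)) {
    M <- read_matrix_csv(fm)
    npt <- n_frames(proto, meta$facial_rate_hz)
    out$facial <- structure(
      list(motion = M,
           frames = tibble(
             trial = rep(trials$trial, each = npt),
             frame = rep(seq_len(npt), nrow(trials)),
             time_s = rep(frame_times(proto, meta$facial_rate_hz),
                          nrow(trials))),
           rate_hz = meta$facial_rate_hz, protocol = proto,
           params = list()),
      class = "facial_motion")
  }
  structure(out, class = "session")
}
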