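#' Build a stimulation protocol
#'
#' Defines the condition set, repetition counts and within-trial timing of an
#' olfacto-tactile imaging session, and draws a seeded pseudo-random trial
#' order. The default protocol crosses two grating orientations with two
#' odors (4 bimodal conditions, 10 repetitions each), presents each grating
#' and each odor alone (4 unimodal conditions, 20 repetitions each) and adds
#' a blank (30 repetitions), for 150 trials of 11 s imaged at 31.5 Hz.
#'
#' Epoch conventions: all windows are given in seconds relative to stimulus
#' onset and are half-open `[start, end)`. The stimulation epoch defaults to
#' the 2 s of stimulus presentation, the baseline epoch to 1-2 s before
#' onset.
#'
#' @param gratings Character vector of grating orientations (degrees).
#' @param odors Character vector of odor identities.
#' @param reps_bimodal,reps_unimodal,reps_blank Repetitions per bimodal
#'   condition, per unimodal condition, and for the blank. Set `reps_blank`
#'   (or the others) to 0 to drop that condition class.
#' @param trial_duration_s Trial length in seconds.
#' @param iti_s Inter-trial interval in seconds.
#' @param frame_rate_hz Two-photon imaging frame rate (Hz).
#' @param stim_onset_s Stimulus onset, seconds from trial start.
#' @param stim_epoch_s Length-2 numeric, stimulation window relative to onset.
#' @param baseline_epoch_s Length-2 numeric, baseline window relative to
#'   onset; must end at or before onset.
#' @param behavior_rate_hz Sampling rate of whisker/breathing channels (Hz).
#' @param facial_rate_hz Sampling rate of the facial video channel (Hz).
#' @param seed Integer seed for the pseudo-random trial order.
#'
#' @return A `stim_protocol` object: a list with a `conditions` tibble
#'   (condition, grating, odor, reps), a `trials` tibble in presentation
#'   order (trial, condition, grating, odor, rep_index, onset_s), and the
#'   timing fields.
#' @examples
#' p <- make_protocol()
#' nrow(p$trials)      # 150
#' nrow(p$conditions)  # 9
#' @export
make_protocol <- function(gratings = c("0", "90"),
                          odors = c("AA", "EB"),
                          reps_bimodal = 10,
                          reps_unimodal = 20,
                          reps_blank = 30,
                          trial_duration_s = 11,
                          iti_s = 8,
                          frame_rate_hz = 31.5,
                          stim_onset_s = 4,
                          stim_epoch_s = c(0, 2),
                          baseline_epoch_s = c(-2, -1),
                          behavior_rate_hz = 500,
                          facial_rate_hz = 20,
                          seed = 1L) {
  if (trial_duration_s <= 0) abort("`trial_duration_s` must be positive")
  check_epoch <- function(w, name) {
    if (length(w) != 2 || w[1] >= w[2])
      abort(sprintf("`%s` must be (start, end) with start < end", name))
    abs_w <- stim_onset_s + w
    if (abs_w[1] < 0 || abs_w[2] > trial_duration_s)
      abort(sprintf("`%s` = (%g, %g) falls outside the trial [0, %g]",
                    name, w[1], w[2], trial_duration_s))
  }
  check_epoch(stim_epoch_s, "stim_epoch_s")
  check_epoch(baseline_epoch_s, "baseline_epoch_s")
  if (baseline_epoch_s[2] > 0)
    abort("`baseline_epoch_s` must end at or before stimulus onset")

  cond <- list()
  if (reps_bimodal > 0)
    cond$bimodal <- tidyr::expand_grid(grating = gratings, odor = odors) |>
      dplyr::mutate(reps = as.integer(reps_bimodal))
  if (reps_unimodal > 0)
    cond$unimodal <- dplyr::bind_rows(
      tibble(grating = gratings, odor = "none"),
      tibble(grating = "none", odor = odors)
    ) |> dplyr::mutate(reps = as.integer(reps_unimodal))
  if (reps_blank > 0)
    cond$blank <- tibble(grating = "none", odor = "none",
                         reps = as.integer(reps_blank))
  conditions <- dplyr::bind_rows(cond)
  if (nrow(conditions) == 0) abort("protocol has no conditions (all reps are 0)")
  if (any(conditions$reps <= 0)) abort("`reps` must be positive")
  conditions$condition <- paste(conditions$grating, conditions$odor, sep = "|")
  conditions <- conditions[, c("condition", "grating", "odor", "reps")]

  schedule <- conditions |>
    dplyr::rowwise() |>
    dplyr::reframe(condition = .data$condition, grating = .data$grating,
                   odor = .data$odor, rep_index = seq_len(.data$reps))
  ord <- withr::with_seed(seed, sample.int(nrow(schedule)))
  trials <- schedule[ord, , drop = FALSE]
  trials$trial <- seq_len(nrow(trials))
  trials$onset_s <- (trials$trial - 1) * (trial_duration_s + iti_s) + stim_onset_s
  trials <- as_tibble(trials[, c("trial", "condition", "grating", "odor",
                                 "rep_index", "onset_s")])

  structure(
    list(conditions = as_tibble(conditions), trials = trials,
         trial_duration_s = trial_duration_s, iti_s = iti_s,
         frame_rate_hz = frame_rate_hz, stim_onset_s = stim_onset_s,
         stim_epoch_s = stim_epoch_s, baseline_epoch_s = baseline_epoch_s,
         behavior_rate_hz = behavior_rate_hz, facial_rate_hz = facial_rate_hz,
         seed = seed),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d conditions, %d trials, %.3g s trials at %.3g Hz\n",
              nrow(x$conditions), nrow(x$trials), x$trial_duration_s,
              x$frame_rate_hz))
  cat(sprintf("  onset %.3g s; stim epoch [%g, %g) s; baseline [%g, %g) s (rel. onset)\n",
              x$stim_onset_s, x$stim_epoch_s[1], x$stim_epoch_s[2],
              x$baseline_epoch_s[1], x$baseline_epoch_s[2]))
  invisible(x)
}

n_trials <- function(protocol) nrow(protocol$trials)

n_frames <- function(protocol, rate = protocol$frame_rate_hz) {
  floor(protocol$trial_duration_s * rate)
}

#' Within-trial sample times
#'
#' @param protocol A `stim_protocol`.
#' @param rate Sampling rate in Hz; defaults to the imaging frame rate.
#' @return Numeric vector of sample times in seconds from trial start.
#' @export
frame_times <- function(protocol, rate = protocol$frame_rate_hz) {
  (seq_len(n_frames(protocol, rate)) - 1) / rate
}

# indices of samples whose time (relative to onset) lies in [window[1], window[2])
epoch_index <- function(protocol, window, rate = protocol$frame_rate_hz) {
  t_rel <- frame_times(protocol, rate) - protocol$stim_onset_s
  which(t_rel >= window[1] & t_rel < window[2])
}

# logical masks over trials for odor-bearing / grating-bearing trials
trial_has_odor <- function(protocol) protocol$trials$odor != "none"
trial_has_grating <- function(protocol) protocol$trials$grating != "none"
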