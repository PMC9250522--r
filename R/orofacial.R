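# analytic signal via FFT: zero negative frequencies, double positives
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-pass filter and analytic decomposition
#'
#' Zero-phase (forward-backward) Butterworth band-pass filter followed by
#' the analytic signal, yielding the instantaneous envelope and unwrapped
#' phase. This is the common front end for whisking (4-30 Hz) and breathing
#' (4-20 Hz) kinematics.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate (Hz); must exceed twice the band's upper edge.
#' @param band Length-2 numeric `(low, high)` pass band in Hz.
#' @param order Butterworth order (default 2).
#' @return Tibble (time_s, filtered, envelope, phase); phase is unwrapped
#'   radians.
#' @export
analytic_decompose <- function(x, fs, band, order = 2) {
  if (any(!is.finite(x))) abort("`x` must be finite")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    abort("`band` must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # demean and odd-reflect the edges before the forward-backward pass to
  # suppress start-up transients (about 3 periods of the lowest band edge)
  n <- length(x)
  xc <- x - mean(x)
  pad <- min(n - 1, 3 * ceiling(fs / band[1]))
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc,
          2 * xc[n] - xc[(n - 1):(n - pad)])
  filt <- signal::filtfilt(bf, xp)[pad + seq_len(n)]
  a <- analytic_signal(filt)
  tibble(time_s = (seq_along(x) - 1) / fs,
         filtered = Re(a),
         envelope = Mod(a),
         phase = signal::unwrap(Arg(a)))
}

# quadratic (parabolic) refinement of an extremum at sample index j
quad_refine <- function(y, j, fs) {
  n <- length(y)
  if (j <= 1 || j >= n) return(list(t = (j - 1) / fs, v = y[j]))
  y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
  den <- y0 - 2 * y1 + y2
  d <- if (abs(den) > .Machine$double.eps) 0.5 * (y0 - y2) / den else 0
  d <- max(min(d, 0.5), -0.5)
  list(t = (j - 1 + d) / fs, v = y1 - 0.25 * (y0 - y2) * d)
}

# cycle boundaries from the unwrapped phase: crossings of multiples of 2*pi
phase_cycles <- function(phase, envelope, fs, min_amplitude) {
  k0 <- ceiling(phase[1] / (2 * pi))
  k1 <- floor(phase[length(phase)] / (2 * pi))
  if (k1 <= k0) return(NULL)
  targets <- 2 * pi * (k0:k1)
  cross_t <- vapply(targets, function(tg) {
    i <- which(phase >= tg)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    (i - 2 + (tg - phase[i - 1]) / (phase[i] - phase[i - 1])) / fs
  }, numeric(1))
  cross_t <- cross_t[is.finite(cross_t)]
  if (length(cross_t) < 2) return(NULL)
  out <- purrr::map_dfr(seq_len(length(cross_t) - 1), function(c) {
    i0 <- max(1, ceiling(cross_t[c] * fs) + 1)
    i1 <- min(length(phase), floor(cross_t[c + 1] * fs) + 1)
    if (i1 - i0 < 2) return(NULL)
    tibble(t_start = cross_t[c], t_end = cross_t[c + 1],
           i0 = i0, i1 = i1,
           env_mean = mean(envelope[i0:i1]))
  })
  if (is.null(out) || nrow(out) == 0) return(NULL)
  out <- out[out$env_mean >= min_amplitude, , drop = FALSE]
  if (nrow(out) == 0) NULL else out
}

#' Whisking cycle table
#'
#' Detects whisk cycles as 2*pi crossings of the unwrapped phase of the
#' band-pass filtered (4-30 Hz) whisker angle, then measures each cycle on
#' the raw angle: the extrema (maximum protraction and retraction) are
#' refined by quadratic interpolation of the three samples around each
#' sampled extremum; amplitude is the angular range (max - min) and
#' setpoint the center ((max + min) / 2) of the cycle.
#'
#' @param angle Whisker-pad azimuthal angle (deg), one trial's trace.
#' @param fs Sampling rate (Hz).
#' @param band Pass band (Hz), default `c(4, 30)`.
#' @param min_amplitude Minimum mean envelope (deg) for a cycle to count;
#'   suppresses spurious cycles in near-constant signals.
#' @return Tibble, one row per cycle: t_start, t_end, frequency (Hz),
#'   amplitude (deg), setpoint (deg), t_protraction, t_retraction (s).
#'   Empty when no in-band cycles exist.
#' @export
whisk_cycles <- function(angle, fs, band = c(4, 30), min_amplitude = 1e-3) {
  dec <- analytic_decompose(angle, fs, band)
  cyc <- phase_cycles(dec$phase, dec$envelope, fs, min_amplitude)
  empty <- tibble(t_start = numeric(), t_end = numeric(),
                  frequency = numeric(), amplitude = numeric(),
                  setpoint = numeric(), t_protraction = numeric(),
                  t_retraction = numeric())
  if (is.null(cyc)) return(empty)
  purrr::map_dfr(seq_len(nrow(cyc)), function(c) {
    idx <- cyc$i0[c]:cyc$i1[c]
    jmax <- idx[which.max(angle[idx])]
    jmin <- idx[which.min(angle[idx])]
    pro <- quad_refine(angle, jmax, fs)
    ret <- quad_refine(angle, jmin, fs)
    tibble(t_start = cyc$t_start[c], t_end = cyc$t_end[c],
           frequency = 1 / (cyc$t_end[c] - cyc$t_start[c]),
           amplitude = pro$v - ret$v,
           setpoint = (pro$v + ret$v) / 2,
           t_protraction = pro$t, t_retraction = ret$t)
  })
}

#' Breathing cycle table
#'
#' Detects breathing cycles from the band-pass filtered (4-20 Hz) pressure
#' signal via the analytic phase, like [whisk_cycles()]. Per cycle,
#' amplitude is the mean analytic envelope and frequency the inverse cycle
#' duration. Inhalations are negative pressure deflections; the inhalation
#' peak is the cycle's filtered-signal minimum.
#'
#' @param pressure Breathing pressure trace (a.u.).
#' @param fs Sampling rate (Hz); must exceed 40 Hz.
#' @param band Pass band (Hz), default `c(4, 20)`.
#' @param min_amplitude Minimum mean envelope for a cycle to count.
#' @return Tibble per cycle: t_start, t_end, frequency (Hz), amplitude
#'   (a.u.), t_inhalation (s). Empty when no in-band cycles exist.
#' @export
breath_cycles <- function(pressure, fs, band = c(4, 20),
                          min_amplitude = 1e-3) {
  if (fs <= 2 * band[2]) abort("`fs` must exceed twice the band's upper edge")
  dec <- analytic_decompose(pressure, fs, band)
  cyc <- phase_cycles(dec$phase, dec$envelope, fs, min_amplitude)
  empty <- tibble(t_start = numeric(), t_end = numeric(),
                  frequency = numeric(), amplitude = numeric(),
                  t_inhalation = numeric())
  if (is.null(cyc)) return(empty)
  purrr::map_dfr(seq_len(nrow(cyc)), function(c) {
    idx <- cyc$i0[c]:cyc$i1[c]
    jmin <- idx[which.min(dec$filtered[idx])]
    inh <- quad_refine(dec$filtered, jmin, fs)
    tibble(t_start = cyc$t_start[c], t_end = cyc$t_end[c],
           frequency = 1 / (cyc$t_end[c] - cyc$t_start[c]),
           amplitude = cyc$env_mean[c],
           t_inhalation = inh$t)
  })
}

#' Baseline-subtracted absolute curvature change
#'
#' Takes the absolute whisker curvature and subtracts, per trial, the mean
#' absolute curvature over the pre-stimulus baseline epoch (rectification
#' before baselining).
#'
#' @param curvature Trials x samples matrix (or a single trial's vector) of
#'   whisker curvature (1/mm) at the protocol's behaviour rate.
#' @param protocol A [make_protocol()] object.
#' @return `|curvature|` minus the per-trial baseline mean, same shape.
#' @export
curvature_change <- function(curvature, protocol) {
  vec <- is.null(dim(curvature))
  if (vec) curvature <- matrix(curvature, 1)
  bidx <- epoch_index(protocol, protocol$baseline_epoch_s,
                      rate = protocol$behavior_rate_hz)
  if (length(bidx) == 0) abort("baseline epoch contains no samples")
  if (max(bidx) > ncol(curvature)) abort("baseline epoch exceeds the trace")
  ak <- abs(curvature)
  out <- ak - rowMeans(ak[, bidx, drop = FALSE])
  if (vec) out[1, ] else out
}

#' Trial-wise orofacial kinematics over an epoch
#'
#' Extracts whisk and breath cycles per trial and summarizes, over a stated
#' window (default the 2-s stimulation epoch), the mean whisking amplitude
#' and setpoint, mean baseline-subtracted absolute curvature, and mean
#' breathing amplitude and frequency. Cycles are attributed to the window
#' by their midpoint.
#'
#' @param series An `orofacial_series` (see [simulate_orofacial()]), or any
#'   list with matrices `angle`, `curvature`, `pressure` (trials x samples)
#'   and `rate_hz`.
#' @param protocol A [make_protocol()] object.
#' @param window Length-2 numeric, seconds relative to onset.
#' @return Tibble, one row per trial: trial, grating, odor, has_odor,
#'   has_grating, whisk_amplitude, whisk_setpoint, dcurv, breath_amplitude,
#'   breath_frequency.
#' @export
epoch_kinematics <- function(series, protocol,
                             window = protocol$stim_epoch_s) {
  fs <- series$rate_hz %||% protocol$behavior_rate_hz
  win_abs <- protocol$stim_onset_s + window
  trials <- protocol$trials
  nt <- nrow(trials)
  widx <- epoch_index(protocol, window, rate = fs)
  dk <- if (!is.null(series$curvature))
    curvature_change(series$curvature, protocol) else NULL

  in_win <- function(tb) {
    if (nrow(tb) == 0) return(tb[0, ])
    mid <- (tb$t_start + tb$t_end) / 2
    tb[mid >= win_abs[1] & mid < win_abs[2], , drop = FALSE]
  }
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)

  purrr::map_dfr(seq_len(nt), function(i) {
    wa <- ws <- ba <- bf <- dkm <- NA_real_
    if (!is.null(series$angle)) {
      wc <- in_win(whisk_cycles(series$angle[i, ], fs))
      wa <- mean_or_na(wc$amplitude); ws <- mean_or_na(wc$setpoint)
    }
    if (!is.null(series$pressure)) {
      bc <- in_win(breath_cycles(series$pressure[i, ], fs))
      ba <- mean_or_na(bc$amplitude); bf <- mean_or_na(bc$frequency)
    }
    if (!is.null(dk)) dkm <- mean(dk[i, widx])
    tibble(trial = trials$trial[i], grating = trials$grating[i],
           odor = trials$odor[i],
           has_odor = trials$odor[i] != "none",
           has_grating = trials$grating[i] != "none",
           whisk_amplitude = wa, whisk_setpoint = ws, dcurv = dkm,
           breath_amplitude = ba, breath_frequency = bf)
  })
}

#' Odor-contrast tests on kinematic epoch statistics
#'
#' Compares each kinematic measure between odor-bearing and odor-free
#' trials, separately within grating and no-grating contexts. For a single
#' session the test is an unpaired two-sided Mann-Whitney across trials;
#' when `stats` carries a `session` column with two or more sessions, a
#' paired Wilcoxon signed-rank test on the per-session condition means is
#' used. Measures whose channel is missing (all `NA`) are skipped with a
#' warning.
#'
#' @param stats Output of [epoch_kinematics()], optionally row-bound across
#'   sessions with a `session` column.
#' @param measures Character vector of measure columns to test.
#' @return Tibble (grating_context, measure, test, n_a, n_b, mean_a,
#'   mean_b, p_value); group A is odor-bearing.
#' @export
kinematics_tests <- function(stats,
                             measures = c("whisk_amplitude",
                                          "whisk_setpoint", "dcurv",
                                          "breath_amplitude",
                                          "breath_frequency")) {
  multi <- "session" %in% names(stats) &&
    length(unique(stats$session)) >= 2
  missing_m <- measures[vapply(measures, function(m)
    !m %in% names(stats) || all(is.na(stats[[m]])), logical(1))]
  if (length(missing_m) > 0)
    warn(paste("skipping measures with missing channel:",
               paste(missing_m, collapse = ", ")))
  measures <- setdiff(measures, missing_m)

  purrr::map_dfr(c(TRUE, FALSE), function(gctx) {
    sub <- stats[stats$has_grating == gctx, , drop = FALSE]
    if (nrow(sub) == 0 || length(unique(sub$has_odor)) < 2) return(NULL)
    purrr::map_dfr(measures, function(m) {
      if (multi) {
        sm <- sub |>
          dplyr::group_by(.data$session, .data$has_odor) |>
          dplyr::summarise(v = mean(.data[[m]], na.rm = TRUE),
                           .groups = "drop") |>
          tidyr::pivot_wider(names_from = "has_odor", values_from = "v")
        a <- sm[["TRUE"]]; b <- sm[["FALSE"]]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) < 2) return(NULL)
        p <- suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
        tibble(grating_context = gctx, measure = m,
               test = "paired_wilcoxon_sessions",
               n_a = sum(ok), n_b = sum(ok),
               mean_a = mean(a[ok]), mean_b = mean(b[ok]), p_value = p)
      } else {
        a <- sub[[m]][sub$has_odor]; b <- sub[[m]][!sub$has_odor]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        p <- suppressWarnings(wilcox.test(a, b)$p.value)
        tibble(grating_context = gctx, measure = m,
               test = "mann_whitney_trials",
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b), p_value = p)
      }
    })
  })
}
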