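#' Simulate ROI fluorescence for a population with known ground truth
#'
#' Generates raw ROI fluorescence `F` and neuropil traces `F_n`
#' (cells x trials x frames) whose condition structure emulates a
#' barrel-cortex imaging session: tactile cells respond to gratings with an
#' orientation preference, a configurable fraction of cells is enhanced or
#' suppressed on odor-bearing trials, and an odor-identity axis with a
#' configurable angle to the tactile discriminant carries odor-specific
#' signal. Responses are boxcar drives over the stimulation epoch convolved
#' with a single-exponential calcium kernel (GCaMP6s-like, `tau_s` default
#' 1.5 s) and normalized so that the mean of the kernel over the stimulation
#' epoch is 1: an injected effect of `e` dF/F units moves the stimulus-epoch
#' mean dF/F by exactly `e` in the noiseless case.
#'
#' A shared slow neuropil signal is mixed into each cell's `F` with the same
#' coefficient `neuropil_r` used for correction, so that neuropil correction
#' removes it exactly when noise is zero. With `frac_odor_mod = 0` and
#' `odor_identity_amp = 0` the per-cell response distributions are
#' exchangeable across odor and no-odor trial labels.
#'
#' @param protocol A [make_protocol()] object.
#' @param n_cells Number of ROIs.
#' @param frac_tactile Fraction of cells responding to gratings.
#' @param frac_odor_mod Fraction of cells whose stimulus-epoch response is
#'   modulated on odor-bearing trials (independent of tactile identity;
#'   odor-only cells are allowed).
#' @param frac_enhanced Among modulated cells, fraction enhanced (the rest
#'   are suppressed).
#' @param effect_mean Median injected modulation effect, dF/F units.
#' @param effect_sdlog Log-normal spread of effect sizes; 0 makes every
#'   modulated cell carry exactly `effect_mean`.
#' @param tactile_amp Median tactile response amplitude (dF/F).
#' @param tactile_gain_sd Log-normal SD of the trial-to-trial multiplicative
#'   gain on the tactile response (whisking/contact variability); applied
#'   identically across cells within a trial.
#' @param selectivity Median orientation-selective amplitude added for the
#'   preferred grating (dF/F).
#' @param odor_identity_amp Amplitude of the odor-identity signal along the
#'   odor-coding axis (dF/F); 0 removes odor-identity information.
#' @param subspace_angle_deg Angle between the odor-identity axis and the
#'   tactile (orientation) discriminant; 90 makes them orthogonal.
#' @param tau_s Calcium kernel decay constant (s).
#' @param noise_sd Gaussian noise SD on `F`, in units of each cell's
#'   baseline fluorescence (i.e. dF/F units).
#' @param neuropil_amp Amplitude of the shared slow neuropil signal
#'   (fractional units of the neuropil baseline).
#' @param neuropil_r Mixing coefficient of neuropil into `F` (matches the
#'   correction coefficient).
#' @param baseline_f Median baseline fluorescence (a.u.).
#' @param seed Integer seed; identical (arguments, seed) give bit-identical
#'   output.
#'
#' @return A `roi_fluorescence` object: list with arrays `F` and `F_n`
#'   (cells x trials x frames), `frame_times_s`, the `protocol`, and a
#'   `ground_truth` tibble (cell, f0, tactile, pref_grating, tact_amp,
#'   sel_amp, odor_modulated, direction, effect, odor_axis, tact_axis).
#' @export
simulate_population <- function(protocol,
                                n_cells = 200,
                                frac_tactile = 0.3,
                                frac_odor_mod = 0.1,
                                frac_enhanced = 0.5,
                                effect_mean = 0.5,
                                effect_sdlog = 0.4,
                                tactile_amp = 1.0,
                                tactile_gain_sd = 0.25,
                                selectivity = 0.5,
                                odor_identity_amp = 0.3,
                                subspace_angle_deg = 90,
                                tau_s = 1.5,
                                noise_sd = 0.1,
                                neuropil_amp = 0.2,
                                neuropil_r = 0.7,
                                baseline_f = 100,
                                seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"))
  for (f in c(frac_tactile, frac_odor_mod, frac_enhanced))
    if (f < 0 || f > 1) abort("cell fractions must lie in [0, 1]")
  if (tau_s <= 0) abort("`tau_s` must be positive")

  trials <- protocol$trials
  nt <- nrow(trials)
  nf <- n_frames(protocol)
  tt <- frame_times(protocol)

  withr::with_seed(seed, {
    f0 <- baseline_f * exp(rnorm(n_cells, 0, 0.3))
    fn0 <- 0.8 * baseline_f * exp(rnorm(n_cells, 0, 0.2))

    gratings <- setdiff(unique(trials$grating), "none")
    odors <- setdiff(unique(trials$odor), "none")

    tactile <- seq_len(n_cells) <= round(frac_tactile * n_cells)
    pref <- rep(NA_character_, n_cells)
    if (length(gratings) > 0 && any(tactile))
      pref[tactile] <- sample(gratings, sum(tactile), replace = TRUE)
    tact_amp <- ifelse(tactile, tactile_amp * exp(rnorm(n_cells, 0, 0.4)), 0)
    sel_amp <- ifelse(tactile, selectivity * exp(rnorm(n_cells, 0, 0.4)), 0)

    n_mod <- round(frac_odor_mod * n_cells)
    modulated <- sample.int(n_cells) <= n_mod
    direction <- rep("none", n_cells)
    if (n_mod > 0) {
      enh <- runif(n_cells) < frac_enhanced
      direction[modulated] <- ifelse(enh[modulated], "enhanced", "suppressed")
    }
    effect <- ifelse(modulated,
                     effect_mean * exp(rnorm(n_cells, 0, effect_sdlog)), 0)
    effect <- effect * ifelse(direction == "suppressed", -1, 1)

    # tactile discriminant u: signed selectivity pattern; odor axis v at
    # the requested angle within the span of u and a random orthogonal w
    u <- sel_amp * ifelse(is.na(pref) | pref == gratings[1] %||% "", 1, -1)
    u[!tactile] <- 0
    if (sum(u^2) > 0) u <- u / sqrt(sum(u^2))
    w <- rnorm(n_cells)
    if (sum(u^2) > 0) w <- w - sum(w * u) * u
    w <- w / sqrt(sum(w^2))
    th <- subspace_angle_deg * pi / 180
    v <- if (sum(u^2) > 0) cos(th) * u + sin(th) * w else w
    v <- v / sqrt(sum(v^2))

    # per-odor coefficient on the identity axis, spread over [-1, 1]
    odor_coef <- if (length(odors) > 1)
      setNames(seq(-1, 1, length.out = length(odors)), odors)
    else setNames(rep(1, length(odors)), odors)

    # cells x trials response amplitude, dF/F units
    amp_t <- matrix(0, n_cells, nt)
    amp_o <- matrix(0, n_cells, nt)
    has_g <- trials$grating != "none"
    has_o <- trials$odor != "none"
    if (any(has_g)) {
      amp_t[, has_g] <- amp_t[, has_g] + tact_amp
      pref_match <- outer(pref, trials$grating, `==`)
      pref_match[is.na(pref_match)] <- FALSE
      amp_t <- amp_t + sel_amp * pref_match
      if (tactile_gain_sd > 0) {
        gain <- exp(rnorm(nt, 0, tactile_gain_sd))
        amp_t <- sweep(amp_t, 2, gain, `*`)
      }
    }
    if (any(has_o)) {
      amp_o[, has_o] <- amp_o[, has_o] + effect
      co <- ifelse(has_o, odor_coef[trials$odor], 0)
      amp_o <- amp_o + odor_identity_amp * tcrossprod(v, co)
    }
    amp <- amp_t + amp_o

    # calcium kernel on the frame grid, epoch-mean normalized
    t_rel <- tt - protocol$stim_onset_s
    dur <- diff(protocol$stim_epoch_s)
    t_k <- t_rel - protocol$stim_epoch_s[1]
    k <- ifelse(t_k < 0, 0,
                ifelse(t_k < dur, 1 - exp(-t_k / tau_s),
                       (1 - exp(-dur / tau_s)) * exp(-(t_k - dur) / tau_s)))
    stim_idx <- epoch_index(protocol, protocol$stim_epoch_s)
    k <- k / mean(k[stim_idx])

    # signal tensor s = amp (x) kernel, floored so suppression cannot push
    # fluorescence below half the baseline; then F = f0 (1+s) + r * F_n + noise
    s <- pmax(outer(amp, k), -0.5)                   # cells x trials x frames
    npil <- t(replicate(nt, {
      ph <- runif(2, 0, 2 * pi)
      neuropil_amp * (0.7 * sin(2 * pi * 0.1 * tt + ph[1]) +
                      0.3 * sin(2 * pi * 0.23 * tt + ph[2]))
    }))                                               # trials x frames
    Fn <- array(fn0, c(n_cells, nt, nf)) *
      (1 + array(rep(npil, each = n_cells), c(n_cells, nt, nf)))
    Fl <- array(f0, c(n_cells, nt, nf)) * (1 + s) + neuropil_r * Fn
    if (noise_sd > 0) {
      Fl <- Fl + array(f0, c(n_cells, nt, nf)) *
        array(rnorm(n_cells * nt * nf, 0, noise_sd), c(n_cells, nt, nf))
      Fn <- Fn + array(fn0, c(n_cells, nt, nf)) *
        array(rnorm(n_cells * nt * nf, 0, noise_sd), c(n_cells, nt, nf))
    }

    gt <- tibble(
      cell = seq_len(n_cells), f0 = f0, tactile = tactile,
      pref_grating = pref, tact_amp = tact_amp, sel_amp = sel_amp,
      odor_modulated = modulated, direction = direction, effect = effect,
      odor_axis = v, tact_axis = u)
  })

  structure(list(F = Fl, F_n = Fn, frame_times_s = tt, protocol = protocol,
                 ground_truth = gt,
                 params = list(tau_s = tau_s, noise_sd = noise_sd,
                               neuropil_r = neuropil_r,
                               subspace_angle_deg = subspace_angle_deg,
                               odor_identity_amp = odor_identity_amp)),
            class = "roi_fluorescence")
}

#' @export
print.roi_fluorescence <- function(x, ...) {
  d <- dim(x$F)
  cat(sprintf("<roi_fluorescence> %d cells x %d trials x %d frames\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate whisker-pad and breathing time series
#'
#' Generates per-trial whisker angle, whisker curvature and breathing
#' pressure traces at the protocol's behaviour sampling rate. The angle is
#' `setpoint + A(t) sin(phase(t))` with whisking at `whisk_f0`; on
#' odor-bearing trials the oscillation amplitude is multiplied by
#' `whisk_gain` and the setpoint shifted by `setpoint_shift_deg` from
#' stimulus onset onward. Breathing is a sinusoidal pressure trace at
#' `breath_f0` whose inhalations are negative deflections; odor trials
#' multiply its amplitude by `breath_gain` from onset. Curvature magnitude
#' steps up by `touch_curv` on grating trials during the stimulation epoch.
#'
#' @param protocol A [make_protocol()] object.
#' @param whisk_f0 Whisking frequency (Hz); must lie in the 4-30 Hz analysis
#'   band or a warning is raised.
#' @param whisk_range Peak-to-peak whisking range (deg), i.e. the per-cycle
#'   amplitude recovered by [whisk_cycles()].
#' @param whisk_setpoint Whisking setpoint (deg).
#' @param whisk_gain Multiplicative odor effect on whisking amplitude.
#' @param setpoint_shift_deg Additive odor effect on the setpoint (deg).
#' @param breath_f0 Breathing frequency (Hz); 4-20 Hz band.
#' @param breath_amp Breathing pressure amplitude (a.u.).
#' @param breath_gain Multiplicative odor effect on breathing amplitude.
#' @param base_curv Baseline absolute whisker curvature (1/mm).
#' @param touch_curv Added absolute curvature during grating contact (1/mm).
#' @param angle_noise,pressure_noise,curv_noise Gaussian noise SDs per
#'   channel (deg, a.u., 1/mm).
#' @param seed Integer seed.
#'
#' @return An `orofacial_series` object: matrices `angle`, `curvature`,
#'   `pressure` (trials x samples), sample `times_s`, the protocol and the
#'   injected ground-truth parameters.
#' @export
simulate_orofacial <- function(protocol,
                               whisk_f0 = 8, whisk_range = 15,
                               whisk_setpoint = 10, whisk_gain = 1.2,
                               setpoint_shift_deg = 2,
                               breath_f0 = 6, breath_amp = 1,
                               breath_gain = 1.3,
                               base_curv = 0.01, touch_curv = 0.02,
                               angle_noise = 0.2, pressure_noise = 0.02,
                               curv_noise = 5e-4,
                               seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (whisk_f0 <= 4 || whisk_f0 >= 30)
    warn("`whisk_f0` lies outside the 4-30 Hz whisking band; cycles will be attenuated")
  if (breath_f0 <= 4 || breath_f0 >= 20)
    warn("`breath_f0` lies outside the 4-20 Hz breathing band; cycles will be attenuated")

  fs <- protocol$behavior_rate_hz
  tt <- frame_times(protocol, fs)
  ns <- length(tt)
  trials <- protocol$trials
  nt <- nrow(trials)
  onset <- protocol$stim_onset_s
  stim_win <- onset + protocol$stim_epoch_s
  post <- tt >= onset
  in_stim <- tt >= stim_win[1] & tt < stim_win[2]

  withr::with_seed(seed, {
    angle <- curv <- pres <- matrix(0, nt, ns)
    for (i in seq_len(nt)) {
      has_o <- trials$odor[i] != "none"
      has_g <- trials$grating[i] != "none"
      wg <- ifelse(post & has_o, whisk_gain, 1)
      sp <- whisk_setpoint + ifelse(post & has_o, setpoint_shift_deg, 0)
      bg <- ifelse(post & has_o, breath_gain, 1)
      phw <- runif(1, 0, 2 * pi)
      phb <- runif(1, 0, 2 * pi)
      angle[i, ] <- sp + (whisk_range / 2) * wg * sin(2 * pi * whisk_f0 * tt + phw)
      pres[i, ] <- -breath_amp * bg * sin(2 * pi * breath_f0 * tt + phb)
      curv[i, ] <- base_curv + ifelse(in_stim & has_g, touch_curv, 0)
      if (angle_noise > 0) angle[i, ] <- angle[i, ] + rnorm(ns, 0, angle_noise)
      if (pressure_noise > 0) pres[i, ] <- pres[i, ] + rnorm(ns, 0, pressure_noise)
      if (curv_noise > 0) curv[i, ] <- curv[i, ] + rnorm(ns, 0, curv_noise)
    }
  })

  structure(list(angle = angle, curvature = curv, pressure = pres,
                 times_s = tt, rate_hz = fs, protocol = protocol,
                 ground_truth = list(
                   whisk_f0 = whisk_f0, whisk_range = whisk_range,
                   whisk_setpoint = whisk_setpoint, whisk_gain = whisk_gain,
                   setpoint_shift_deg = setpoint_shift_deg,
                   breath_f0 = breath_f0, breath_amp = breath_amp,
                   breath_gain = breath_gain, base_curv = base_curv,
                   touch_curv = touch_curv)),
            class = "orofacial_series")
}

#' @export
print.orofacial_series <- function(x, ...) {
  cat(sprintf("<orofacial_series> %d trials x %d samples at %g Hz\n",
              nrow(x$angle), ncol(x$angle), x$rate_hz))
  invisible(x)
}

#' Simulate a facial motion-energy matrix
#'
#' Builds a low-rank-plus-noise motion-energy matrix (time x pixels) at the
#' protocol's facial video rate. Each of `rank` components has an orthonormal
#' spatial map and a smooth temporal course. When `odor_informative = TRUE`,
#' each odor adds a component-space deflection during the stimulation epoch
#' of its trials, so that odor identity is linearly decodable from the video;
#' when `FALSE` the component time courses are independent of the odor
#' labels.
#'
#' @param protocol A [make_protocol()] object.
#' @param rank Number of spatial components (>= 1).
#' @param n_pixels Number of pixels.
#' @param odor_informative Logical; inject odor-dependent motion?
#' @param effect Amplitude of the odor-dependent deflection.
#' @param noise_sd Gaussian pixel noise SD; 0 gives an exactly rank-`rank`
#'   matrix.
#' @param seed Integer seed.
#'
#' @return A `facial_motion` object: `motion` matrix (time x pixels), the
#'   frame-to-trial index `frames` tibble (trial, frame, time_s), and the
#'   generator parameters.
#' @export
simulate_facial_motion <- function(protocol, rank = 3, n_pixels = 200,
                                   odor_informative = FALSE, effect = 1,
                                   noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (rank < 1) abort("`rank` must be >= 1")
  fs <- protocol$facial_rate_hz
  npt <- n_frames(protocol, fs)
  trials <- protocol$trials
  nt <- nrow(trials)
  total <- nt * npt
  tt <- frame_times(protocol, fs)
  stim <- tt >= protocol$stim_onset_s + protocol$stim_epoch_s[1] &
    tt < protocol$stim_onset_s + protocol$stim_epoch_s[2]
  odors <- setdiff(unique(trials$odor), "none")

  withr::with_seed(seed, {
    W <- qr.Q(qr(matrix(rnorm(n_pixels * rank), n_pixels, rank)))
    sv <- seq(rank, 1)                       # decreasing component scales
    # smooth temporal courses: moving-average filtered white noise
    Tm <- matrix(rnorm(total * rank), total, rank)
    win <- max(1, round(fs / 2))
    Tm <- apply(Tm, 2, function(z)
      as.numeric(stats::filter(z, rep(1 / win, win), sides = 2)))
    Tm[is.na(Tm)] <- 0
    if (odor_informative && length(odors) > 0) {
      P <- matrix(rnorm(rank * length(odors)), rank, length(odors))
      P <- P / sqrt(colSums(P^2))[col(P)]
      for (i in seq_len(nt)) {
        o <- trials$odor[i]
        if (o %in% odors) {
          rows <- (i - 1) * npt + which(stim)
          Tm[rows, ] <- Tm[rows, ] +
            effect * matrix(P[, o == odors], length(rows), rank, byrow = TRUE)
        }
      }
    }
    M <- Tm %*% (sv * t(W))
    if (noise_sd > 0) M <- M + matrix(rnorm(total * n_pixels, 0, noise_sd),
                                      total, n_pixels)
  })

  frames <- tibble(trial = rep(trials$trial, each = npt),
                   frame = rep(seq_len(npt), nt),
                   time_s = rep(tt, nt))
  structure(list(motion = M, frames = frames, rate_hz = fs,
                 protocol = protocol,
                 params = list(rank = rank, odor_informative = odor_informative,
                               effect = effect, noise_sd = noise_sd)),
            class = "facial_motion")
}

#' @export
print.facial_motion <- function(x, ...) {
  cat(sprintf("<facial_motion> %d frames x %d pixels at %g Hz (rank %d)\n",
              nrow(x$motion), ncol(x$motion), x$rate_hz, x$params$rank))
  invisible(x)
}

#' Simulate a complete session
#'
#' Convenience wrapper generating the neural, orofacial and facial channels
#' of one session from a single seed.
#'
#' @param protocol A [make_protocol()] object.
#' @param neural,orofacial,facial Named lists of arguments forwarded to
#'   [simulate_population()], [simulate_orofacial()] and
#'   [simulate_facial_motion()].
#' @param seed Integer seed; sub-seeds for the three channels are derived
#'   from it.
#' @return A `session` list with elements `protocol`, `neural`, `orofacial`,
#'   `facial`.
#' @export
simulate_session <- function(protocol, neural = list(), orofacial = list(),
                             facial = list(), seed = 1L) {
  structure(list(
    protocol = protocol,
    neural = do.call(simulate_population,
                     c(list(protocol = protocol, seed = seed), neural)),
    orofacial = do.call(simulate_orofacial,
                        c(list(protocol = protocol, seed = seed + 1000L),
                          orofacial)),
    facial = do.call(simulate_facial_motion,
                     c(list(protocol = protocol, seed = seed + 2000L),
                       facial))),
    class = "session")
}
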