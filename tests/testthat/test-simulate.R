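test_that("simulation is bit-identical for identical seeds", {
  p <- tiny_protocol()
  a <- simulate_population(p, n_cells = 10, seed = 3)
  b <- simulate_population(p, n_cells = 10, seed = 3)
  expect_identical(a$F, b$F)
  expect_identical(a$F_n, b$F_n)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_population(p, n_cells = 10, seed = 4)
  expect_false(identical(a$F, c$F))

  oa <- simulate_orofacial(p, seed = 3)
  ob <- simulate_orofacial(p, seed = 3)
  expect_identical(oa$angle, ob$angle)
  fa <- simulate_facial_motion(p, seed = 3)
  fb <- simulate_facial_motion(p, seed = 3)
  expect_identical(fa$motion, fb$motion)
})

test_that("parameter validation rejects bad fractions and time constants", {
  p <- tiny_protocol()
  expect_error(simulate_population(p, frac_odor_mod = 1.2), "fractions")
  expect_error(simulate_population(p, frac_tactile = -0.1), "fractions")
  expect_error(simulate_population(p, tau_s = 0), "tau_s")
  expect_warning(simulate_orofacial(p, whisk_f0 = 35), "4-30")
  expect_warning(simulate_orofacial(p, breath_f0 = 2), "4-20")
  expect_error(simulate_facial_motion(p, rank = 0), "rank")
})

test_that("fluorescence traces are strictly positive and shaped by the protocol", {
  p <- tiny_protocol()
  sim <- simulate_population(p, n_cells = 15, noise_sd = 0.05, seed = 5)
  expect_equal(dim(sim$F), c(15, nrow(p$trials),
                             length(frame_times(p))))
  expect_identical(dim(sim$F), dim(sim$F_n))
  expect_true(all(sim$F > 0))
  expect_true(all(sim$F_n > 0))
})

test_that("a noiseless enhanced cell moves the stimulus-epoch mean by its effect", {
  p <- tiny_protocol()
  sim <- simulate_population(p, n_cells = 4, frac_tactile = 0,
                             frac_odor_mod = 1, frac_enhanced = 1,
                             effect_mean = 1, effect_sdlog = 0,
                             odor_identity_amp = 0, noise_sd = 0,
                             seed = 2)
  dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
  em <- epoch_average(dff)
  grp <- contrast_trials(p, "bimodal_vs_grating")
  diff <- rowMeans(em[, grp$a]) - rowMeans(em[, grp$b])
  expect_equal(diff, rep(1, 4), tolerance = 1e-8)
})

test_that("neuropil correction exactly removes the shared signal when noiseless", {
  p <- tiny_protocol()
  sim <- simulate_population(p, n_cells = 3, frac_tactile = 0,
                             frac_odor_mod = 0, odor_identity_amp = 0,
                             noise_sd = 0, seed = 6)
  fcor <- neuropil_correct(sim$F, sim$F_n)
  # without any injected effect the corrected trace is flat per cell
  expect_lt(max(abs(sweep(fcor, 1, sim$ground_truth$f0))), 1e-9)
})

test_that("effect-free sessions give near-nominal Mann-Whitney detection rates", {
  p <- coarse_protocol()
  grp <- contrast_trials(p, "bimodal_vs_grating")
  flags <- unlist(lapply(1:12, function(s) {
    em <- null_session_epoch_means(p, n_cells = 60, seed = 400 + s)
    mod <- score_modulation(em, grp$a, grp$b)
    mod$direction != "none"
  }))
  rate <- mean(flags)   # 720 independent cells; achievable level ~ 0.0487
  expect_gt(rate, 0.030)
  expect_lt(rate, 0.070)
})

test_that("detection power is monotone in the injected effect size", {
  p <- coarse_protocol()
  grp <- contrast_trials(p, "bimodal_vs_grating")
  rates <- vapply(c(0.02, 0.1, 0.6), function(eff) {
    flags <- unlist(lapply(1:3, function(s) {
      sim <- simulate_population(p, n_cells = 60, frac_odor_mod = 1,
                                 frac_enhanced = 1, effect_mean = eff,
                                 effect_sdlog = 0, odor_identity_amp = 0,
                                 seed = 700 + s)
      dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
      em <- epoch_average(dff)
      score_modulation(em, grp$a, grp$b)$direction != "none"
    }))
    mean(flags)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.95)
})

test_that("orofacial gains are recovered end-to-end from the kinematics", {
  p <- tiny_protocol(reps_bimodal = 0, reps_unimodal = 2, reps_blank = 2)
  oro <- simulate_orofacial(p, whisk_gain = 1.5, breath_gain = 0.5,
                            setpoint_shift_deg = 0,
                            angle_noise = 0, pressure_noise = 0,
                            curv_noise = 0, seed = 8)
  kin <- epoch_kinematics(oro, p)
  amp_ratio <- mean(kin$whisk_amplitude[kin$has_odor]) /
    mean(kin$whisk_amplitude[!kin$has_odor])
  expect_equal(amp_ratio, 1.5, tolerance = 0.02)
  br_ratio <- mean(kin$breath_amplitude[kin$has_odor]) /
    mean(kin$breath_amplitude[!kin$has_odor])
  expect_equal(br_ratio, 0.5, tolerance = 0.02)
})

test_that("unit orofacial gains leave odor and blank trials equivalent", {
  p <- tiny_protocol(reps_bimodal = 0, reps_unimodal = 3, reps_blank = 3)
  oro <- simulate_orofacial(p, whisk_gain = 1, breath_gain = 1,
                            setpoint_shift_deg = 0, angle_noise = 0,
                            pressure_noise = 0, curv_noise = 0, seed = 9)
  kin <- epoch_kinematics(oro, p)
  expect_equal(mean(kin$whisk_amplitude[kin$has_odor]),
               mean(kin$whisk_amplitude[!kin$has_odor]),
               tolerance = 1e-3)
  expect_equal(mean(kin$breath_amplitude[kin$has_odor]),
               mean(kin$breath_amplitude[!kin$has_odor]),
               tolerance = 1e-3)
})

test_that("noiseless rank-1 facial motion has exactly one nonzero singular value", {
  p <- tiny_protocol()
  fm <- simulate_facial_motion(p, rank = 1, n_pixels = 30, noise_sd = 0,
                               seed = 4)
  d <- svd(fm$motion, nu = 0, nv = 0)$d
  expect_gt(d[1], 0)
  expect_lt(d[2] / d[1], 1e-10)
})
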