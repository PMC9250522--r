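test_that("responsiveness detection flags separated conditions and stays near alpha on null data", {
  labels <- rep(letters[1:5], each = 12)
  # one condition shifted far away, no noise on the rest
  set.seed(21)
  x <- matrix(rnorm(3 * 60, sd = 1), 3)
  x[2, labels == "c"] <- x[2, labels == "c"] + 50
  r <- detect_responsive(x, labels)
  expect_lt(r$p_responsive[2], 1e-4)
  expect_true(r$responsive[2])
  # null calibration: many independent cells, flagged fraction near alpha
  set.seed(22)
  xn <- matrix(rnorm(1500 * 60), 1500)
  rn <- detect_responsive(xn, labels)
  expect_gt(mean(rn$responsive), 0.030)
  expect_lt(mean(rn$responsive), 0.070)
})

test_that("responsiveness handles degenerate cells and bad designs", {
  labels <- rep(c("a", "b"), each = 5)
  x <- rbind(rep(2, 10), rnorm(10))
  expect_warning(r <- detect_responsive(x, labels), "constant")
  expect_true(is.na(r$p_responsive[1]))
  expect_false(r$responsive[1])
  expect_error(detect_responsive(x, rep("a", 10)), "2 conditions")
  expect_error(detect_responsive(x[, 1:6], c(rep("a", 5), "b")),
               "fewer than 2 trials")
})

test_that("modulation index and direction follow the definitions", {
  # two groups of epoch means per synthetic cell, noiseless separation
  a20 <- c(rep(2, 10), rep(1, 10))   # mean_a 2, mean_b 1 -> MI 1
  a05 <- c(rep(0.5, 10), rep(1, 10)) # mean_a 0.5 -> MI -0.5, suppressed
  x <- rbind(a20 + rep(c(0, 0), each = 10), a05)
  # add tiny jitter so groups are cleanly separable without ties
  set.seed(31)
  x <- x + matrix(rnorm(40, sd = 1e-4), 2)
  mod <- score_modulation(x, 1:10, 11:20)
  expect_equal(mod$modulation_index, c(1, -0.5), tolerance = 1e-3)
  expect_equal(mod$direction, c("enhanced", "suppressed"))
  expect_lt(max(mod$p_modulated), 1e-3)
})

test_that("identical groups give zero index, p near 1 and no direction", {
  x <- matrix(rep(1:10, 2), 1)   # group B repeats group A exactly
  mod <- score_modulation(x, 1:10, 11:20)
  expect_equal(mod$modulation_index, 0)
  expect_equal(mod$p_modulated, 1)
  expect_equal(mod$direction, "none")
})

test_that("a near-zero reference mean yields an undefined index but a p-value", {
  set.seed(32)
  x <- rbind(c(rnorm(10, 5), rnorm(10, 0, 1e-15)))
  expect_warning(mod <- score_modulation(x, 1:10, 11:20), "undefined")
  expect_true(is.na(mod$modulation_index[1]))
  expect_false(is.na(mod$p_modulated[1]))
})

test_that("shuffle null is seed-deterministic and insensitive to real effects", {
  set.seed(41)
  # strong modulation in every cell
  x <- cbind(matrix(rnorm(200 * 40, mean = 3), 200),
             matrix(rnorm(200 * 40, mean = 0), 200))
  a <- shuffle_null_proportion(x, 1:40, 41:80, n_shuffles = 150, seed = 5)
  b <- shuffle_null_proportion(x, 1:40, 41:80, n_shuffles = 150, seed = 5)
  expect_identical(a$props, b$props)
  # label shuffling destroys the effect: the null level stays near the
  # test's achievable level (~4.87% for 40 vs 40), far below the real 100%
  mod <- score_modulation(x, 1:40, 41:80)
  expect_equal(modulated_proportion(mod), 100)
  se <- sd(a$props$prop_flagged) / sqrt(nrow(a$props))
  expect_lt(abs(a$mean - 4.87), 4 * se + 0.5)
  expect_error(shuffle_null_proportion(x, 1:40, 41:80, n_shuffles = 0),
               "n_shuffles")
})

test_that("session summaries collapse to point intervals at zero variance", {
  s <- tibble::tibble(prop_real = rep(20, 5), prop_shuffled = rep(5, 5),
                      prop_enhanced = rep(10, 5),
                      prop_suppressed = rep(10, 5))
  expect_warning(sm <- summarize_sessions(s), NA)
  r <- sm$summary[sm$summary$measure == "prop_real", ]
  expect_equal(c(r$ci_lo, r$ci_hi), c(20, 20))
  expect_equal(r$mean, 20)
})

test_that("paired session tests are calibrated when real equals shuffled in law", {
  # replicate experiments with no real effect: the real-vs-shuffled
  # Wilcoxon should reject at about its nominal rate
  rej <- vapply(1:100, function(r) {
    set.seed(600 + r)
    s <- tibble::tibble(prop_real = 5 + rnorm(8),
                        prop_shuffled = 5 + rnorm(8))
    sm <- summarize_sessions(s, n_boot = 50, seed = r)
    sm$tests$p_value[sm$tests$test == "real_vs_shuffled_wilcoxon"] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
})

test_that("a single session yields intervals only, with a warning", {
  s <- tibble::tibble(prop_real = 20, prop_shuffled = 5)
  expect_warning(sm <- summarize_sessions(s), "single session")
  expect_equal(nrow(sm$tests), 0)
  expect_equal(sm$summary$ci_lo, sm$summary$mean)
})

test_that("the KS comparison of modulation indices detects shifted distributions", {
  set.seed(51)
  s <- tibble::tibble(
    prop_real = rep(20, 4), prop_shuffled = rep(5, 4),
    mi_real = replicate(4, rnorm(200, 0.5), simplify = FALSE),
    mi_shuffled = replicate(4, rnorm(200, 0), simplify = FALSE))
  sm <- summarize_sessions(s)
  ks <- sm$tests[sm$tests$test == "mi_real_vs_shuffled_ks", ]
  expect_lt(ks$p_value, 1e-6)
})

test_that("chi-square proportion comparisons match closed-form expectations", {
  # homogeneous table: statistic exactly 0
  r0 <- compare_proportions(c(5, 10), c(5, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # [[50,50],[90,10]]: N(ad-bc)^2 / row/col products = 38.095...
  r1 <- compare_proportions(c(50, 100), c(90, 100))
  expect_equal(r1$statistic,
               200 * (50 * 10 - 50 * 90)^2 / (100 * 100 * 140 * 60),
               tolerance = 1e-12)
  expect_lt(r1$p_value, 1e-6)
  expect_error(compare_proportions(c(0, 0), c(0, 0)), "zero-total")
  expect_error(compare_proportions(c(5, 3), c(1, 2)), "flagged <= total")
})

test_that("injected modulated fractions are recovered with the analytic false-positive add-on", {
  p <- coarse_protocol()
  grp <- contrast_trials(p, "bimodal_vs_grating")
  for (m in c(0, 0.2)) {
    props <- vapply(1:3, function(s) {
      sim <- simulate_population(p, n_cells = 100, frac_odor_mod = m,
                                 effect_mean = 2, effect_sdlog = 0.2,
                                 odor_identity_amp = 0, seed = 900 + s)
      dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
      em <- epoch_average(dff)
      modulated_proportion(score_modulation(em, grp$a, grp$b))
    }, numeric(1))
    expected <- 100 * (m + 0.0487 * (1 - m))
    se <- max(sd(props) / sqrt(3), 1.5)
    expect_lt(abs(mean(props) - expected), 3 * se)
  }
})
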