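make_pv <- function(X, y, bin_t = c(0, 1), proto = NULL) {
  # minimal population_vectors wrapper around one feature matrix
  structure(list(
    X = list(X),
    y = tibble::tibble(trial = seq_along(y), condition = y,
                       grating = "none", odor = y, rep_index = 1L),
    bins = tibble::tibble(bin = 1L, t_start = bin_t[1], t_end = bin_t[2]),
    protocol = proto, z_scored = FALSE, pooled = FALSE),
    class = "population_vectors")
}

test_that("feature building tiles the trial and z-scores per feature", {
  p <- make_protocol(reps_bimodal = 2, reps_unimodal = 3, reps_blank = 3)
  sim <- simulate_population(p, n_cells = 12, seed = 15)
  dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
  pv <- build_features(dff, bin_s = 1)
  expect_length(pv$X, 11)               # 11-s trial, 1-s bins
  expect_equal(dim(pv$X[[1]]), c(nrow(p$trials), 12))
  pz <- build_features(dff, bin_s = 1, z_score = TRUE)
  expect_equal(colMeans(pz$X[[3]]), rep(0, 12), tolerance = 1e-12)
  expect_equal(apply(pz$X[[3]], 2, sd), rep(1, 12), tolerance = 1e-12)
})

test_that("pooled pseudo-populations concatenate cells over matched trials", {
  p1 <- tiny_protocol(seed = 1)
  p2 <- tiny_protocol(seed = 99)       # different presentation order
  s1 <- simulate_population(p1, n_cells = 5, noise_sd = 0, seed = 16)
  s2 <- simulate_population(p2, n_cells = 7, noise_sd = 0, seed = 17)
  d1 <- compute_dff(neuropil_correct(s1$F, s1$F_n), p1)
  d2 <- compute_dff(neuropil_correct(s2$F, s2$F_n), p2)
  pv <- build_features(list(d1, d2), bin_s = 1)
  expect_true(pv$pooled)
  expect_equal(ncol(pv$X[[1]]), 12)
  # trials are matched on (condition, repetition): labels align
  expect_equal(pv$y$condition,
               dplyr::arrange(p1$trials, condition, rep_index)$condition)
  # mismatched repetition counts name the condition
  p3 <- tiny_protocol(reps_blank = 5)
  s3 <- simulate_population(p3, n_cells = 4, seed = 18)
  d3 <- compute_dff(neuropil_correct(s3$F, s3$F_n), p3)
  expect_error(build_features(list(d1, d3)), "none|none")
})

test_that("nearest-centroid decoding is perfect on separated classes", {
  set.seed(61)
  X <- rbind(matrix(rnorm(40 * 5), 40),
             matrix(rnorm(40 * 5, mean = 100), 40))
  pv <- make_pv(X, rep(c("a", "b"), each = 40))
  res <- centroid_cv(pv, k = 10, seed = 1)
  expect_equal(res$bins$accuracy, 100)
  cm <- res$confusion[[1]]
  expect_equal(sum(cm), 80)
  expect_equal(diag(cm), c(a = 40L, b = 40L))
})

test_that("a hand-computed two-fold toy problem classifies perfectly", {
  # X = {0,0,1,1}, y = {a,a,b,b}, k = 2: each fold trains on one a (0) and
  # one b (1); centroids 0 and 1 classify the held-out pair correctly
  pv <- make_pv(matrix(c(0, 0, 1, 1), 4, 1), c("a", "a", "b", "b"))
  res <- centroid_cv(pv, k = 2, seed = 3)
  expect_equal(res$bins$accuracy, 100)
  expect_equal(res$fold_scores[, 1], c(100, 100))
})

test_that("class sizes below k raise a helpful error", {
  pv <- make_pv(matrix(rnorm(12), 6, 2), c("a", "a", "a", "a", "b", "b"))
  expect_error(centroid_cv(pv, k = 5, seed = 1), "smaller k")
})

test_that("decoding of label-independent data sits at chance", {
  accs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(80 * 10), 80)
    pv <- make_pv(X, rep(c("a", "b"), each = 40))
    centroid_cv(pv, k = 10, seed = s)$bins$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 3)
})

test_that("accuracy is invariant to a joint permutation of trials and labels", {
  set.seed(62)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rep(c("a", "b"), each = 30)
  pv1 <- make_pv(X, y)
  perm <- sample(60)
  pv2 <- make_pv(X[perm, ], y[perm])
  r1 <- centroid_cv(pv1, k = 10, seed = 4)
  r2 <- centroid_cv(pv2, k = 10, seed = 4)
  # stratification is seeded on the label structure, so the fold contents
  # are the same trials up to relabelling: equal expected accuracy
  expect_equal(r1$bins$accuracy, r2$bins$accuracy, tolerance = 15)
})

test_that("permutation p-values hit the 1/n floor on separable data and are deterministic", {
  set.seed(63)
  X <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4, 50), 20))
  pv <- make_pv(X, rep(c("a", "b"), each = 20))
  r1 <- permutation_pvalue(pv, "condition", "centroid", k = 5,
                           n_shuffles = 100, seed = 6)
  expect_equal(r1$bins$p_value, 0.01)
  r2 <- permutation_pvalue(pv, "condition", "centroid", k = 5,
                           n_shuffles = 100, seed = 6)
  expect_identical(r1$shuffle, r2$shuffle)
  # two-sided option doubles the smaller tail but keeps the floor
  r3 <- permutation_pvalue(pv, "condition", "centroid", k = 5,
                           n_shuffles = 100, seed = 6, sided = "two")
  expect_gte(r3$bins$p_value, 0.01)
})

test_that("transfer tests enforce disjoint trial sets", {
  set.seed(64)
  X <- matrix(rnorm(40 * 4), 40)
  pv <- make_pv(X, rep(c("a", "b"), 20))
  keep <- rep(c(TRUE, FALSE), 20)
  expect_error(transfer_test(pv, "condition", keep, keep, bins = 1),
               "disjoint")
  expect_error(transfer_test(pv, "condition", keep, rep(FALSE, 40),
                             bins = 1), "empty")
})

test_that("an orthogonal odor subspace leaves orientation transfer intact while odor transfer collapses", {
  p <- coarse_protocol()
  res <- purrr::map_dfr(1:4, function(s) {
    sim <- simulate_population(p, n_cells = 120, frac_tactile = 0.6,
                               frac_odor_mod = 0, odor_identity_amp = 0.3,
                               subspace_angle_deg = 90, tactile_amp = 3,
                               selectivity = 1.5, noise_sd = 0.1,
                               seed = 320 + s)
    dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
    pv <- build_features(dff, bin_s = 1)
    g <- pv$y$grating != "none"; o <- pv$y$odor != "none"
    ori <- transfer_test(pv, "grating", g & !o, g & o, k = 5, seed = s)
    odr <- transfer_test(pv, "odor", !g & o, g & o, k = 5, seed = s)
    tibble::tibble(session = s,
                   ori_in = ori$accuracy[1], ori_out = ori$accuracy[2],
                   odor_in = odr$accuracy[1], odor_out = odr$accuracy[2])
  })
  # orientation decoding survives the addition of odors
  expect_gt(mean(res$ori_out), mean(res$ori_in) - 5)
  expect_gt(mean(res$ori_in), 90)
  # the odor decoder trained without touch collapses to chance with touch
  expect_lt(abs(mean(res$odor_out) - 50), 12)
  expect_gt(mean(res$odor_in), 90)
})

test_that("linear SVM decoding separates classes and confusion rows conserve trials", {
  set.seed(65)
  X <- do.call(rbind, lapply(1:5, function(c)
    matrix(rnorm(12 * 6, mean = 10 * c), 12)))
  y <- rep(letters[1:5], each = 12)
  pv <- make_pv(X, y)
  res <- svm_decode(pv, "condition", k = 4, seed = 2, cost = 1)
  expect_equal(res$bins$accuracy, 100)
  expect_equal(unname(rowSums(res$confusion[[1]])), rep(12, 5))
})

test_that("the cost rule keeps baseline bins at chance", {
  p <- tiny_protocol(reps_bimodal = 0, reps_unimodal = 8, reps_blank = 0)
  sim <- simulate_population(p, n_cells = 30, frac_tactile = 0,
                             frac_odor_mod = 0, odor_identity_amp = 0.8,
                             noise_sd = 0.15, seed = 21)
  dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), p)
  pv <- build_features(dff, bin_s = 1)
  sub <- subset_trials(pv, pv$y$odor != "none")
  res <- svm_decode(sub, "odor", k = 4, seed = 3)
  expect_true(res$cost %in% 10^seq(-3, 2))
  bb <- odormod:::baseline_bin_indices(sub)
  n <- res$n_trials
  ci <- 100 * qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_true(all(res$bins$accuracy[bb] >= ci[1] &
                    res$bins$accuracy[bb] <= ci[2]))
})

test_that("mixture categorization assigns ratios to the dominant component", {
  set.seed(66)
  v <- rnorm(20); v <- v / sqrt(sum(v^2))
  mk <- function(coef, n) t(replicate(n, coef * v + rnorm(20, sd = 0.05)))
  x_pure <- rbind(mk(1, 30), mk(-1, 30))
  y_pure <- rep(c("AA", "EB"), each = 30)
  x_mix <- rbind(mk(0.6, 25), mk(-0.6, 25), mk(0, 50))
  labs <- rep(c("80/20", "20/80", "50/50"), c(25, 25, 50))
  res <- mixture_categorize(x_pure, y_pure, x_mix, labs)
  frac <- function(mx, cl) res$fraction[res$mixture == mx & res$class == cl]
  expect_gt(frac("80/20", "AA"), 0.8)
  expect_gt(frac("20/80", "EB"), 0.8)
  # balanced mixtures split evenly on average over training draws
  f50 <- vapply(1:5, function(s) {
    set.seed(500 + s)
    xp <- rbind(mk(1, 30), mk(-1, 30))
    r <- mixture_categorize(xp, y_pure, mk(0, 50), rep("50/50", 50))
    r$fraction[r$class == "AA"]
  }, numeric(1))
  expect_lt(abs(mean(f50) - 0.5), 0.15)
  # mixtures identical to a pure odor go entirely to that odor
  res2 <- mixture_categorize(x_pure, y_pure, mk(1, 20), rep("pureAA", 20))
  expect_equal(frac2 <- res2$fraction[res2$class == "AA"], 1)
  expect_error(mixture_categorize(x_pure[1:30, ], y_pure[1:30], x_mix,
                                  labs), "2 pure-odor classes")
})

test_that("facial decoding separates informative from uninformative motion", {
  p <- tiny_protocol(reps_bimodal = 0, reps_unimodal = 8, reps_blank = 0,
                     trial_duration_s = 6, facial_rate_hz = 10)
  inf <- simulate_facial_motion(p, rank = 3, n_pixels = 50,
                                odor_informative = TRUE, effect = 3,
                                noise_sd = 0.05, seed = 23)
  expect_warning(ri <- facial_decode(inf, n_pcs = 500, k = 4, seed = 2),
                 "truncating")
  sb <- which(ri$bins$t_start < 5 & ri$bins$t_end > 3)
  expect_gt(max(ri$bins$accuracy[sb]), 80)
  uni <- simulate_facial_motion(p, rank = 3, n_pixels = 50,
                                odor_informative = FALSE,
                                noise_sd = 0.05, seed = 24)
  ru <- suppressWarnings(facial_decode(uni, n_pcs = 20, k = 4, seed = 2))
  expect_lt(mean(ru$bins$accuracy), 75)
})
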