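#' Trial indices of the four condition categories
#'
#' Pools trials with different odors together (odor identity is a decoding
#' concern) and returns the two trial groups of a standard contrast:
#' bimodal vs grating-only, or odor-only vs blank.
#'
#' @param protocol A [make_protocol()] object.
#' @param contrast `"bimodal_vs_grating"` or `"odor_vs_blank"`.
#' @return List with integer trial indices `a` (odor-bearing group) and `b`
#'   (odor-free group).
#' @export
contrast_trials <- function(protocol,
                            contrast = c("bimodal_vs_grating",
                                         "odor_vs_blank")) {
  contrast <- match.arg(contrast)
  g <- trial_has_grating(protocol)
  o <- trial_has_odor(protocol)
  if (contrast == "bimodal_vs_grating")
    list(a = which(g & o), b = which(g & !o))
  else
    list(a = which(!g & o), b = which(!g & !o))
}

#' Detect stimulus-responsive cells
#'
#' Kruskal-Wallis test across all stimulation conditions per cell on the
#' stimulus-epoch response means. Cells whose responses are identical in
#' every trial (the test is undefined) are excluded with a warning.
#'
#' @param epoch_means Cells x trials matrix of epoch-mean dF/F (see
#'   [epoch_average()]).
#' @param condition_labels Condition label per trial (length = n trials).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble (cell, p_responsive, responsive); `p_responsive` is `NA`
#'   for degenerate cells.
#' @export
detect_responsive <- function(epoch_means, condition_labels, alpha = 0.05) {
  if (is.null(dim(epoch_means))) epoch_means <- matrix(epoch_means, 1)
  g <- factor(condition_labels)
  if (length(g) != ncol(epoch_means))
    abort("`condition_labels` must have one label per trial (column)")
  counts <- table(g)
  if (length(counts) < 2) abort("need at least 2 conditions")
  if (any(counts < 2))
    abort(sprintf("condition '%s' has fewer than 2 trials",
                  names(counts)[which(counts < 2)[1]]))
  p <- apply(epoch_means, 1, function(x) {
    if (all(is.na(x))) return(NA_real_)
    if (length(unique(x[!is.na(x)])) < 2) return(NA_real_)
    suppressWarnings(kruskal.test(x, g)$p.value)
  })
  if (anyNA(p))
    warn(sprintf("%d cell(s) with constant or missing responses excluded from the responsiveness test",
                 sum(is.na(p))))
  tibble(cell = seq_len(nrow(epoch_means)), p_responsive = p,
         responsive = !is.na(p) & p < alpha)
}

#' Score odor modulation per cell
#'
#' Two-sided Mann-Whitney U test per cell comparing stimulus-epoch response
#' means between an odor-bearing and an odor-free trial group, plus the
#' olfactory modulation index `MI = (mean_A - mean_B) / mean_B`. Cells with
#' `|mean_B|` below `mi_tol` get an undefined (`NA`) index; their p-value is
#' still computed. Significant cells are classed `enhanced` or `suppressed`
#' by the sign of `mean_A - mean_B`.
#'
#' The default p-value method is the normal approximation with tie and
#' continuity correction; `method = "exact"` uses the exact U distribution
#' (tie-free samples only).
#'
#' @param epoch_means Cells x trials matrix of epoch-mean dF/F.
#' @param trials_a Integer indices of the odor-bearing trials.
#' @param trials_b Integer indices of the odor-free trials.
#' @param alpha Significance threshold.
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @param mi_tol Tolerance below which `mean_B` is treated as zero.
#' @return A `cell_modulation` tibble (cell, mean_a, mean_b, p_modulated,
#'   modulation_index, direction) with the test settings in attributes.
#' @export
score_modulation <- function(epoch_means, trials_a, trials_b, alpha = 0.05,
                             method = "asymptotic", mi_tol = 1e-12) {
  if (is.null(dim(epoch_means))) epoch_means <- matrix(epoch_means, 1)
  if (length(trials_a) == 0 || length(trials_b) == 0)
    abort("both trial groups must be non-empty")
  res <- mw_test_rows(epoch_means, trials_a, trials_b, method = method)
  mi <- ifelse(abs(res$mean_b) > mi_tol,
               (res$mean_a - res$mean_b) / res$mean_b, NA_real_)
  if (anyNA(mi))
    warn(sprintf("%d cell(s) with near-zero reference mean: modulation index undefined",
                 sum(is.na(mi))))
  sig <- !is.na(res$p) & res$p < alpha
  direction <- ifelse(sig & res$mean_a > res$mean_b, "enhanced",
                      ifelse(sig & res$mean_a < res$mean_b, "suppressed",
                             "none"))
  out <- tibble(cell = seq_len(nrow(epoch_means)),
                mean_a = res$mean_a, mean_b = res$mean_b,
                p_modulated = res$p, modulation_index = mi,
                direction = direction)
  structure(out, class = c("cell_modulation", class(out)),
            alpha = alpha, n_a = length(trials_a), n_b = length(trials_b),
            method = method)
}

#' Proportion of flagged cells
#'
#' @param x A `cell_modulation` tibble.
#' @return Percentage of cells with `direction != "none"`.
#' @export
modulated_proportion <- function(x) {
  stopifnot(inherits(x, "cell_modulation"))
  100 * mean(x$direction != "none")
}

#' Shuffle-null distribution of the flagged proportion
#'
#' Permutes the trial labels of the two groups within the session
#' `n_shuffles` times, re-tests every cell with the two-sided Mann-Whitney
#' test at `alpha`, and records the flagged percentage per shuffle. Because
#' label permutation leaves the pooled sample unchanged, ranks and tie
#' corrections are computed once per cell, making large shuffle counts
#' cheap.
#'
#' @inheritParams score_modulation
#' @param n_shuffles Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @return A `shuffle_null` object: tibble `props` (shuffle, prop_flagged in
#'   %), the `mean`, a percentile 95% interval `ci` of the shuffle
#'   distribution, and the settings.
#' @export
shuffle_null_proportion <- function(epoch_means, trials_a, trials_b,
                                    alpha = 0.05, n_shuffles = 100,
                                    seed = 1L, method = "asymptotic") {
  if (is.null(dim(epoch_means))) epoch_means <- matrix(epoch_means, 1)
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1")
  m <- length(trials_a); n <- length(trials_b)
  if (m + n > ncol(epoch_means)) abort("more group trials than available trials")
  if (m < 1 || n < 1) abort("both trial groups must be non-empty")
  pooled <- epoch_means[, c(trials_a, trials_b), drop = FALSE]
  keep <- rowSums(is.na(pooled)) == 0
  pooled <- pooled[keep, , drop = FALSE]
  R <- row_ranks(pooled)
  tie <- row_tie_term(pooled)
  props <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      ia <- sample.int(m + n, m)
      ra <- rowSums(R[, ia, drop = FALSE])
      p <- mw_p_from_ranksum(ra, m, n, tie, method = method)$p
      100 * mean(!is.na(p) & p < alpha)
    }, numeric(1))
  })
  structure(list(props = tibble(shuffle = seq_len(n_shuffles),
                                prop_flagged = props),
                 mean = mean(props),
                 ci = unname(quantile(props, c(0.025, 0.975))),
                 n_shuffles = n_shuffles, alpha = alpha,
                 n_a = m, n_b = n, n_cells = nrow(pooled), seed = seed),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> %d shuffles, %d cells, %d vs %d trials\n",
              x$n_shuffles, x$n_cells, x$n_a, x$n_b))
  cat(sprintf("  mean flagged %.3f%% (95%% interval %.3f, %.3f)\n",
              x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Summarize modulation results across sessions
#'
#' Takes one row per session of modulation summaries and returns bootstrap
#' confidence intervals of the mean proportions (resampling sessions,
#' `n_boot` iterations), paired Wilcoxon signed-rank tests (real vs
#' shuffled proportion; enhanced vs suppressed proportion), and a two-sample
#' Kolmogorov-Smirnov comparison of the pooled modulation-index
#' distributions (real vs shuffled) when the `mi_real` / `mi_shuffled`
#' list-columns are present.
#'
#' @param sessions Tibble with one row per session and numeric columns
#'   `prop_real`, `prop_shuffled` (%), optionally `prop_enhanced`,
#'   `prop_suppressed`, and optional list-columns `mi_real`, `mi_shuffled`.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A `session_summary` object: `summary` tibble (measure, mean,
#'   ci_lo, ci_hi, n_sessions) and `tests` tibble (test, statistic,
#'   p_value, n).
#' @export
summarize_sessions <- function(sessions, n_boot = 1000, seed = 1L) {
  sessions <- as_tibble(sessions)
  if (!all(c("prop_real", "prop_shuffled") %in% names(sessions)))
    abort("`sessions` needs columns `prop_real` and `prop_shuffled`")
  ns <- nrow(sessions)
  num_cols <- intersect(c("prop_real", "prop_shuffled", "prop_enhanced",
                          "prop_suppressed"), names(sessions))
  boot_ci <- function(v) {
    if (length(v) == 1) return(c(v, v))
    bm <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1)))
    unname(quantile(bm, c(0.025, 0.975)))
  }
  summ <- purrr::map_dfr(num_cols, function(cn) {
    v <- sessions[[cn]]
    ci <- boot_ci(v)
    tibble(measure = cn, mean = mean(v), ci_lo = ci[1], ci_hi = ci[2],
           n_sessions = ns)
  })

  tests <- tibble(test = character(), statistic = numeric(),
                  p_value = numeric(), n = integer())
  if (ns >= 2) {
    wt <- suppressWarnings(wilcox.test(sessions$prop_real,
                                       sessions$prop_shuffled,
                                       paired = TRUE))
    tests <- dplyr::add_row(tests, test = "real_vs_shuffled_wilcoxon",
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, n = ns)
    if (all(c("prop_enhanced", "prop_suppressed") %in% names(sessions))) {
      we <- suppressWarnings(wilcox.test(sessions$prop_enhanced,
                                         sessions$prop_suppressed,
                                         paired = TRUE))
      tests <- dplyr::add_row(tests, test = "enhanced_vs_suppressed_wilcoxon",
                              statistic = unname(we$statistic),
                              p_value = we$p.value, n = ns)
    }
  } else {
    warn("single session: paired cross-session tests skipped")
  }
  if (all(c("mi_real", "mi_shuffled") %in% names(sessions))) {
    mr <- unlist(sessions$mi_real); msh <- unlist(sessions$mi_shuffled)
    mr <- mr[is.finite(mr)]; msh <- msh[is.finite(msh)]
    if (length(mr) > 1 && length(msh) > 1) {
      kt <- suppressWarnings(ks.test(mr, msh))
      tests <- dplyr::add_row(tests, test = "mi_real_vs_shuffled_ks",
                              statistic = unname(kt$statistic),
                              p_value = kt$p.value,
                              n = length(mr) + length(msh))
    }
  }
  structure(list(summary = summ, tests = tests, n_boot = n_boot),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>\n")
  print(x$summary)
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' Chi-square comparison of two flagged proportions
#'
#' Tests homogeneity of the modulated/not-modulated proportion between two
#' groups of cells on the 2 x 2 contingency table (Pearson chi-square,
#' no continuity correction).
#'
#' @param flagged_a,flagged_b Length-2 integer vectors `c(flagged, total)`
#'   for each group.
#' @return Tibble (statistic, df, p_value, prop_a, prop_b) in %.
#' @export
compare_proportions <- function(flagged_a, flagged_b) {
  if (length(flagged_a) != 2 || length(flagged_b) != 2)
    abort("each group must be c(flagged, total)")
  if (any(c(flagged_a, flagged_b) < 0) ||
      flagged_a[1] > flagged_a[2] || flagged_b[1] > flagged_b[2])
    abort("counts must satisfy 0 <= flagged <= total")
  if (flagged_a[2] + flagged_b[2] == 0) abort("zero-total table")
  tab <- rbind(c(flagged_a[1], flagged_a[2] - flagged_a[1]),
               c(flagged_b[1], flagged_b[2] - flagged_b[1]))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value,
         prop_a = 100 * flagged_a[1] / flagged_a[2],
         prop_b = 100 * flagged_b[1] / flagged_b[2])
}
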