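#' Build trial-by-feature population vectors
#'
#' Averages dF/F in consecutive time bins (default 1 s) tiling the trial,
#' one feature block per bin with one feature per cell. With a list of
#' sessions, a pooled pseudo-population is built by concatenating cells
#' across sessions after matching trials on (condition, repetition index),
#' undoing each session's pseudo-random presentation order; sessions must
#' share the same condition set and repetition counts.
#'
#' @param x A `dff_tensor` (see [compute_dff()]), or a list of them for a
#'   pooled pseudo-population.
#' @param bin_s Bin width in seconds; bins tile `[0, trial_duration)`.
#' @param z_score Z-score each feature across trials? (Applied globally, so
#'   each feature has mean 0 and SD 1 across all trials.)
#' @return A `population_vectors` object: list of per-bin trials x cells
#'   matrices `X`, trial-label tibble `y` (trial, condition, grating, odor,
#'   rep_index), `bins` tibble (bin, t_start, t_end, relative to trial
#'   start), and flags.
#' @export
build_features <- function(x, bin_s = 1, z_score = FALSE) {
  if (inherits(x, "dff_tensor")) x <- list(x)
  if (!all(vapply(x, inherits, logical(1), "dff_tensor")))
    abort("`x` must be a dff_tensor or a list of them")
  proto <- x[[1]]$protocol
  n_bins <- floor(proto$trial_duration_s / bin_s)
  if (n_bins < 1) abort("`bin_s` exceeds the trial duration")
  edges <- seq(0, by = bin_s, length.out = n_bins + 1)
  tt <- frame_times(proto)

  # canonical trial order: by condition then repetition index
  canon <- proto$trials |>
    dplyr::arrange(.data$condition, .data$rep_index)

  per_session <- purrr::imap(x, function(dt, si) {
    p <- dt$protocol
    key <- function(tr) paste(tr$condition, tr$rep_index)
    if (!setequal(key(p$trials), key(canon))) {
      cond_mismatch <- setdiff(unique(canon$condition),
                               unique(p$trials$condition))
      bad <- if (length(cond_mismatch)) cond_mismatch[1] else {
        ca <- table(canon$condition); cb <- table(p$trials$condition)
        names(ca)[which(ca[names(cb)] != cb)[1]]
      }
      abort(sprintf("session %s: repetition counts differ for condition '%s'",
                    si, bad))
    }
    ord <- match(key(canon), key(p$trials))
    d <- dim(dt$dff)
    m <- matrix(dt$dff, d[1] * d[2], d[3])
    lapply(seq_len(n_bins), function(b) {
      idx <- which(tt >= edges[b] & tt < edges[b + 1])
      em <- matrix(rowMeans(m[, idx, drop = FALSE]), d[1], d[2])
      t(em)[ord, , drop = FALSE]                 # trials x cells
    })
  })
  X <- lapply(seq_len(n_bins), function(b)
    do.call(cbind, lapply(per_session, `[[`, b)))
  if (z_score) X <- lapply(X, function(m) {
    s <- apply(m, 2, sd)
    m <- scale(m, scale = FALSE)
    m[, s > 0] <- sweep(m[, s > 0, drop = FALSE], 2, s[s > 0], `/`)
    m
  })
  structure(list(
    X = X,
    y = canon[, c("trial", "condition", "grating", "odor", "rep_index")],
    bins = tibble(bin = seq_len(n_bins), t_start = edges[-length(edges)],
                  t_end = edges[-1]),
    protocol = proto, z_scored = z_score, pooled = length(x) > 1),
    class = "population_vectors")
}

#' @export
print.population_vectors <- function(x, ...) {
  cat(sprintf("<population_vectors> %d trials x %d features x %d bins%s\n",
              nrow(x$X[[1]]), ncol(x$X[[1]]), length(x$X),
              if (x$pooled) " (pooled)" else ""))
  invisible(x)
}

#' Subset trials of a population-vectors object
#'
#' @param pv A `population_vectors` object.
#' @param keep Logical or integer vector over trials (rows of `pv$y`).
#' @return The subsetted `population_vectors`.
#' @export
subset_trials <- function(pv, keep) {
  stopifnot(inherits(pv, "population_vectors"))
  pv$X <- lapply(pv$X, function(m) m[keep, , drop = FALSE])
  pv$y <- pv$y[keep, , drop = FALSE]
  pv
}

# resolve a decoding target into a factor over trials
resolve_target <- function(pv, target) {
  y <- if (is.character(target) && length(target) == 1)
    pv$y[[target]] else target
  if (length(y) != nrow(pv$y)) abort("`target` must give one label per trial")
  factor(y)
}

# seeded stratified k-fold assignment
stratified_folds <- function(y, k, seed) {
  tab <- table(y)
  if (any(tab < k))
    abort(sprintf("class '%s' has %d trials, fewer than k = %d; use a smaller k",
                  names(tab)[which.min(tab)], min(tab), k))
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

# nearest-centroid fit/predict (Euclidean distance, first-min tie break)
centroid_fit_predict <- function(Xtr, ytr, Xte) {
  C <- rowsum(Xtr, ytr) / as.vector(table(ytr))
  d2 <- matrix(rowSums(Xte^2), nrow(Xte), nrow(C)) +
    matrix(rowSums(C^2), nrow(Xte), nrow(C), byrow = TRUE) -
    2 * Xte %*% t(C)
  factor(rownames(C)[apply(d2, 1, which.min)], levels = levels(ytr))
}

# generic per-bin cross-validated decoding
decode_cv_core <- function(Xlist, y, k, seed, fit_predict) {
  folds <- stratified_folds(y, k, seed)
  n_bins <- length(Xlist)
  fold_scores <- matrix(NA_real_, k, n_bins)
  confusion <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    cm <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(true = levels(y), pred = levels(y)))
    for (f in seq_len(k)) {
      te <- folds == f
      pred <- fit_predict(Xlist[[b]][!te, , drop = FALSE], y[!te],
                          Xlist[[b]][te, , drop = FALSE])
      fold_scores[f, b] <- 100 * mean(pred == y[te])
      cm <- cm + unclass(table(y[te], pred))
    }
    confusion[[b]] <- cm
  }
  list(accuracy = colMeans(fold_scores), fold_scores = fold_scores,
       confusion = confusion)
}

new_decode_result <- function(pv, y, core, k, seed, decoder,
                              extra = list()) {
  bins <- pv$bins
  bins$accuracy <- core$accuracy
  bins$p_value <- NA_real_
  structure(c(list(bins = bins, fold_scores = core$fold_scores,
                   confusion = core$confusion, k = k, seed = seed,
                   classes = levels(y), n_classes = nlevels(y),
                   n_trials = length(y), decoder = decoder,
                   shuffle = NULL, n_shuffles = 0L, protocol = pv$protocol),
              extra),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s, %d classes, %d trials, k = %d\n",
              x$decoder, x$n_classes, x$n_trials, x$k))
  best <- which.max(x$bins$accuracy)
  cat(sprintf("  peak accuracy %.1f%% in bin %d [%g, %g) s%s\n",
              x$bins$accuracy[best], best, x$bins$t_start[best],
              x$bins$t_end[best],
              if (x$n_shuffles > 0)
                sprintf("; min p = %.3g over bins", min(x$bins$p_value))
              else ""))
  invisible(x)
}

#' Nearest-centroid decoding with stratified cross-validation
#'
#' Per time bin, class centroids are computed from the training trials of
#' each stratified fold and test trials are assigned to the nearest
#' centroid (Euclidean distance); accuracy is the mean test performance
#' over the k folds, in percent.
#'
#' @param pv A `population_vectors` object (see [build_features()]).
#' @param target Column of `pv$y` naming the decoded label (default
#'   `"condition"`), or a vector of labels.
#' @param k Number of stratified folds (default 10); every class needs at
#'   least `k` trials.
#' @param seed Integer seed for the fold assignment.
#' @return A `decode_result`: per-bin accuracy table `bins`, per-fold
#'   scores, and a confusion matrix per bin (entries sum to the class
#'   trial counts).
#' @export
centroid_cv <- function(pv, target = "condition", k = 10, seed = 1L) {
  y <- resolve_target(pv, target)
  core <- decode_cv_core(pv$X, y, k, seed, centroid_fit_predict)
  new_decode_result(pv, y, core, k, seed, "centroid")
}

# shared shuffle machinery: rerun `run_fn(y_perm)` on permuted labels
permute_pvalues <- function(result, y, run_fn, n_shuffles, seed, sided) {
  n_bins <- nrow(result$bins)
  shuf <- matrix(NA_real_, n_shuffles, n_bins)
  withr::with_seed(seed, {
    for (s in seq_len(n_shuffles))
      shuf[s, ] <- run_fn(sample(y))
  })
  real <- result$bins$accuracy
  floor_p <- 1 / n_shuffles
  p_up <- colMeans(shuf >= matrix(real, n_shuffles, n_bins, byrow = TRUE))
  if (sided == "one") {
    p <- pmax(p_up, floor_p)
  } else {
    p_dn <- colMeans(shuf <= matrix(real, n_shuffles, n_bins, byrow = TRUE))
    p <- pmax(pmin(1, 2 * pmin(p_up, p_dn)), floor_p)
  }
  result$bins$p_value <- p
  result$shuffle <- shuf
  result$n_shuffles <- n_shuffles
  result$sided <- sided
  result
}

#' Permutation p-values for decoding accuracy
#'
#' Repeats the cross-validated decoding on `n_shuffles` label permutations
#' and locates the real accuracy in the shuffle distribution per bin. The
#' default p-value is the one-sided exceedance fraction floored at
#' `1/n_shuffles`; `sided = "two"` doubles the smaller tail.
#'
#' @inheritParams centroid_cv
#' @param decoder `"centroid"` or `"svm"`.
#' @param n_shuffles Number of label shuffles (default 1000).
#' @param sided `"one"` (default) or `"two"`.
#' @param ... Passed to [svm_decode()] when `decoder = "svm"` (e.g.
#'   `cost`).
#' @return A `decode_result` with per-bin `p_value` and the shuffle
#'   accuracy matrix in `$shuffle`.
#' @export
permutation_pvalue <- function(pv, target = "condition",
                               decoder = c("centroid", "svm"), k = 10,
                               n_shuffles = 1000, seed = 1L,
                               sided = c("one", "two"), ...) {
  decoder <- match.arg(decoder)
  sided <- match.arg(sided)
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1")
  y <- resolve_target(pv, target)
  if (decoder == "centroid") {
    res <- centroid_cv(pv, y, k = k, seed = seed)
    run_fn <- function(yp)
      decode_cv_core(pv$X, yp, k, seed, centroid_fit_predict)$accuracy
  } else {
    res <- svm_decode(pv, y, k = k, seed = seed, ...)
    fp <- svm_fit_predict(res$cost)
    run_fn <- function(yp) decode_cv_core(pv$X, yp, k, seed, fp)$accuracy
  }
  permute_pvalues(res, y, run_fn, n_shuffles, seed, sided)
}

#' Cross-condition decoder transfer test
#'
#' Trains a decoder on trials selected by `train_filter` and reports two
#' accuracies: the in-domain score (stratified cross-validation within the
#' training trials) and the out-of-domain score (fit on all training
#' trials, tested on the disjoint `test_filter` trials recorded under the
#' other stimulus context).
#'
#' @param pv A `population_vectors` object.
#' @param target Decoded label: column of `pv$y` or vector.
#' @param train_filter,test_filter Logical vectors over trials; must be
#'   disjoint.
#' @param bins Integer indices of the time bins whose features are
#'   concatenated (default: bins overlapping the stimulation epoch).
#' @param k Folds for the in-domain score.
#' @param seed Integer seed.
#' @return Tibble (domain = in_domain/out_of_domain, accuracy, n_trials).
#' @export
transfer_test <- function(pv, target, train_filter, test_filter,
                          bins = NULL, k = 10, seed = 1L) {
  stopifnot(inherits(pv, "population_vectors"))
  if (length(train_filter) != nrow(pv$y) ||
      length(test_filter) != nrow(pv$y))
    abort("filters must be logical vectors over trials")
  if (!any(train_filter) || !any(test_filter)) abort("empty trial filter")
  if (any(train_filter & test_filter))
    abort("train and test trial sets must be disjoint")
  if (is.null(bins)) bins <- stim_bin_indices(pv)
  Xb <- do.call(cbind, pv$X[bins])
  y <- resolve_target(pv, target)

  ytr <- droplevels(y[train_filter])
  in_core <- decode_cv_core(list(Xb[train_filter, , drop = FALSE]),
                            ytr, k, seed, centroid_fit_predict)
  pred_out <- centroid_fit_predict(Xb[train_filter, , drop = FALSE], ytr,
                                   Xb[test_filter, , drop = FALSE])
  acc_out <- 100 * mean(as.character(pred_out) ==
                          as.character(y[test_filter]))
  tibble(domain = c("in_domain", "out_of_domain"),
         accuracy = c(in_core$accuracy, acc_out),
         n_trials = c(sum(train_filter), sum(test_filter)))
}

# bins overlapping the stimulation epoch / fully inside the pre-onset baseline
stim_bin_indices <- function(pv) {
  p <- pv$protocol
  w <- p$stim_onset_s + p$stim_epoch_s
  which(pv$bins$t_start < w[2] & pv$bins$t_end > w[1])
}
baseline_bin_indices <- function(pv) {
  which(pv$bins$t_end <= pv$protocol$stim_onset_s)
}

svm_fit_predict <- function(cost) {
  force(cost)
  function(Xtr, ytr, Xte) {
    fit <- e1071::svm(Xtr, droplevels(ytr), kernel = "linear", cost = cost,
                      scale = FALSE)
    factor(as.character(predict(fit, Xte)), levels = levels(ytr))
  }
}

#' Multi-class linear SVM decoding
#'
#' Linear support-vector machine decoding per time bin with stratified
#' cross-validation. When `cost` is `NULL` the regularization parameter is
#' selected by the rule: over `cost_grid`, keep the values whose
#' baseline-bin accuracy stays within the binomial 95% interval of chance,
#' and among those pick the one maximizing accuracy over the
#' stimulation-epoch bins; if none satisfies the baseline constraint the
#' smallest cost is used with a warning.
#'
#' @inheritParams centroid_cv
#' @param cost Fixed SVM cost, or `NULL` to apply the selection rule.
#' @param cost_grid Candidate costs for the selection rule.
#' @return A `decode_result` with the chosen `cost` and per-bin confusion
#'   matrices.
#' @export
svm_decode <- function(pv, target = "condition", k = 10, seed = 1L,
                       cost = NULL, cost_grid = 10^seq(-3, 2)) {
  y <- resolve_target(pv, target)
  if (is.null(cost)) {
    sb <- stim_bin_indices(pv)
    bb <- baseline_bin_indices(pv)
    if (length(bb) == 0) {
      warn("no baseline bins before onset; using the smallest cost")
      cost <- min(cost_grid)
    } else {
      chance <- 1 / nlevels(y)
      n <- length(y)
      ci <- 100 * stats::qbinom(c(0.025, 0.975), n, chance) / n
      scores <- purrr::map(cost_grid, function(cc)
        decode_cv_core(pv$X[c(bb, sb)], y, k, seed,
                       svm_fit_predict(cc))$accuracy)
      ok <- vapply(scores, function(a) {
        base_acc <- a[seq_along(bb)]
        all(base_acc >= ci[1] & base_acc <= ci[2])
      }, logical(1))
      if (!any(ok)) {
        warn("no cost kept baseline accuracy at chance; using the smallest cost")
        cost <- min(cost_grid)
      } else {
        stim_acc <- vapply(scores, function(a)
          mean(a[-seq_along(bb)]), numeric(1))
        stim_acc[!ok] <- -Inf
        cost <- cost_grid[which.max(stim_acc)]
      }
    }
  }
  core <- decode_cv_core(pv$X, y, k, seed, svm_fit_predict(cost))
  new_decode_result(pv, y, core, k, seed, "svm", extra = list(cost = cost))
}

#' Categorize odor mixtures with a classifier trained on pure odors
#'
#' Trains a radial-basis-function SVM on the pure-odor trials only and
#' reports, for each mixture ratio, the fraction of its trials assigned to
#' each pure odor.
#'
#' @param x_pure Trials x features matrix of pure-odor trials.
#' @param y_pure Pure odor label per row of `x_pure` (>= 2 classes).
#' @param x_mix Trials x features matrix of mixture trials.
#' @param mix_labels Mixture ratio label per row of `x_mix`.
#' @param cost,gamma SVM parameters (defaults: cost 1, gamma `1/ncol`).
#' @return Tibble (mixture, class, n_trials, fraction).
#' @export
mixture_categorize <- function(x_pure, y_pure, x_mix, mix_labels,
                               cost = 1, gamma = NULL) {
  y_pure <- factor(y_pure)
  if (nlevels(y_pure) < 2) abort("need at least 2 pure-odor classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x_pure)
  fit <- e1071::svm(x_pure, y_pure, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  pred <- predict(fit, x_mix)
  tab <- table(mixture = mix_labels, class = pred)
  as_tibble(tab, .name_repair = "minimal") |>
    dplyr::rename(n_trials = "n") |>
    dplyr::group_by(.data$mixture) |>
    dplyr::mutate(fraction = .data$n_trials / sum(.data$n_trials)) |>
    dplyr::ungroup()
}

#' Decode odor identity from facial motion energy
#'
#' Truncated singular-value decomposition of the motion-energy matrix
#' (time x pixels), trial features from the first `n_pcs` principal
#' component time courses averaged in time bins, and multi-class linear SVM
#' decoding with optional shuffle p-values. With a list of sessions, the
#' per-session PC features are concatenated after matching trials on
#' (condition, repetition index).
#'
#' @param fm A `facial_motion` object (see [simulate_facial_motion()]) or a
#'   list of them (pooled mode).
#' @param n_pcs Number of principal components (default 500; truncated to
#'   the matrix rank with a warning).
#' @param target Label column (default `"odor"`); trials whose label is
#'   `"none"` are dropped.
#' @param bin_s Bin width (s) for the PC time courses.
#' @param k,seed,cost Passed to [svm_decode()].
#' @param n_shuffles If positive, permutation p-values per bin.
#' @return A `decode_result`.
#' @export
facial_decode <- function(fm, n_pcs = 500, target = "odor", bin_s = 1,
                          k = 10, seed = 1L, cost = 1, n_shuffles = 0) {
  if (inherits(fm, "facial_motion")) fm <- list(fm)
  proto <- fm[[1]]$protocol
  canon <- proto$trials |>
    dplyr::arrange(.data$condition, .data$rep_index)
  n_bins <- floor(proto$trial_duration_s / bin_s)
  edges <- seq(0, by = bin_s, length.out = n_bins + 1)

  per_session <- purrr::map(fm, function(s) {
    M <- s$motion
    r <- min(dim(M))
    np <- n_pcs
    if (np > r) {
      warn(sprintf("n_pcs = %d exceeds the matrix rank bound %d; truncating",
                   np, r))
      np <- r
    }
    sv <- svd(M, nu = np, nv = 0)
    scores <- sv$u * rep(sv$d[seq_len(np)], each = nrow(M))  # time x np
    ord <- match(paste(canon$condition, canon$rep_index),
                 paste(s$protocol$trials$condition,
                       s$protocol$trials$rep_index))
    lapply(seq_len(n_bins), function(b) {
      sel <- s$frames$time_s >= edges[b] & s$frames$time_s < edges[b + 1]
      em <- rowsum(scores[sel, , drop = FALSE], s$frames$trial[sel])
      em <- em / as.vector(table(s$frames$trial[sel]))
      em[ord, , drop = FALSE]
    })
  })
  X <- lapply(seq_len(n_bins), function(b)
    do.call(cbind, lapply(per_session, `[[`, b)))
  pv <- structure(list(
    X = X, y = canon[, c("trial", "condition", "grating", "odor",
                         "rep_index")],
    bins = tibble(bin = seq_len(n_bins), t_start = edges[-length(edges)],
                  t_end = edges[-1]),
    protocol = proto, z_scored = FALSE, pooled = length(fm) > 1),
    class = "population_vectors")
  if (identical(target, "odor")) pv <- subset_trials(pv, pv$y$odor != "none")
  if (n_shuffles > 0)
    permutation_pvalue(pv, target, decoder = "svm", k = k,
                       n_shuffles = n_shuffles, seed = seed, cost = cost)
  else
    svm_decode(pv, target, k = k, seed = seed, cost = cost)
}
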