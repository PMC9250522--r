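#' @exportS3Method generics::tidy
tidy.shuffle_null <- function(x, ...) x$props

#' @exportS3Method generics::glance
glance.shuffle_null <- function(x, ...) {
  tibble(mean_prop = x$mean, ci_lo = x$ci[1], ci_hi = x$ci[2],
         n_shuffles = x$n_shuffles, n_cells = x$n_cells,
         n_a = x$n_a, n_b = x$n_b, alpha = x$alpha)
}

#' @exportS3Method generics::tidy
tidy.decode_result <- function(x, ...) x$bins

#' @exportS3Method generics::glance
glance.decode_result <- function(x, ...) {
  best <- which.max(x$bins$accuracy)
  tibble(decoder = x$decoder, n_classes = x$n_classes,
         n_trials = x$n_trials, k = x$k,
         peak_accuracy = x$bins$accuracy[best],
         peak_bin = best,
         min_p = if (x$n_shuffles > 0) min(x$bins$p_value) else NA_real_,
         n_shuffles = x$n_shuffles)
}

#' @exportS3Method generics::tidy
tidy.session_summary <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.session_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary[, c("measure", "mean")],
    names_from = "measure", values_from = "mean")
  wt <- x$tests[x$tests$test == "real_vs_shuffled_wilcoxon", ]
  wide$p_real_vs_shuffled <- if (nrow(wt)) wt$p_value else NA_real_
  wide
}

#' @exportS3Method generics::tidy
tidy.dff_tensor <- function(x, window = x$protocol$stim_epoch_s, ...) {
  em <- epoch_average(x, window)
  tr <- x$protocol$trials
  tibble(cell = rep(seq_len(nrow(em)), ncol(em)),
         trial = rep(tr$trial, each = nrow(em)),
         condition = rep(tr$condition, each = nrow(em)),
         grating = rep(tr$grating, each = nrow(em)),
         odor = rep(tr$odor, each = nrow(em)),
         epoch_mean = as.vector(em))
}

#' @exportS3Method generics::glance
glance.dff_tensor <- function(x, ...) {
  d <- dim(x$dff)
  tibble(n_cells = d[1], n_trials = d[2], n_frames = d[3],
         n_flagged = nrow(x$flagged), percentile = x$percentile,
         baseline_subtracted = x$baseline_subtracted)
}

#' Accuracy-versus-time plot for a decoding result
#'
#' Accuracy per time bin with the shuffle distribution band (2.5-97.5
#' percentiles) when permutation shuffles are available, chance level, and
#' the stimulation epoch shaded.
#'
#' @param object A `decode_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decode_result <- function(object, ...) {
  df <- object$bins
  df$t_mid <- (df$t_start + df$t_end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid,
                                        y = .data$accuracy))
  proto <- object$protocol
  if (!is.null(proto)) {
    w <- proto$stim_onset_s + proto$stim_epoch_s
    p <- p + ggplot2::annotate("rect", xmin = w[1], xmax = w[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  if (!is.null(object$shuffle)) {
    qs <- apply(object$shuffle, 2, quantile, c(0.025, 0.975))
    df$sh_lo <- qs[1, ]; df$sh_hi <- qs[2, ]
    p <- p + ggplot2::geom_ribbon(
      data = df, ggplot2::aes(ymin = .data$sh_lo, ymax = .data$sh_hi),
      fill = "grey70", alpha = 0.5)
  }
  p + ggplot2::geom_hline(yintercept = 100 / object$n_classes,
                          linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time in trial (s)", y = "accuracy (%)",
                  title = sprintf("%s decoding (%d classes)",
                                  object$decoder, object$n_classes))
}

#' Shuffle-null histogram with the observed proportion
#'
#' @param object A `shuffle_null`.
#' @param observed Optional observed flagged proportion (%) drawn as a
#'   vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shuffle_null <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$props,
                       ggplot2::aes(x = .data$prop_flagged)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "grey30") +
    ggplot2::labs(x = "flagged cells (%)", y = "shuffles",
                  title = "trial-label shuffle null")
  if (!is.null(observed))
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  p
}

#' Modulation scatter of odor versus no-odor responses
#'
#' Mean stimulus-epoch dF/F with odor against without, one point per cell,
#' significant cells coloured by direction, diagonal dashed.
#'
#' @param object A `cell_modulation` tibble (see [score_modulation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_modulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_b, y = .data$mean_a,
                                       colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(enhanced = "#d95f02",
                                            suppressed = "#1b9e77",
                                            none = "grey70")) +
    ggplot2::labs(x = "mean dF/F without odor", y = "mean dF/F with odor",
                  colour = NULL)
}
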