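#' Assemble a run configuration
#'
#' Collects every knob of a simulate-preprocess-analyse run into one list
#' that is serialized verbatim (with a content hash) into the run outputs.
#'
#' @param n_sessions Number of synthetic sessions.
#' @param protocol Arguments for [make_protocol()].
#' @param neural,orofacial,facial Argument lists for the session generator
#'   (see [simulate_session()]).
#' @param alpha Significance threshold for the single-cell tests.
#' @param k Cross-validation folds.
#' @param n_shuffles Label shuffles for the modulation null and the decoder
#'   p-values.
#' @param n_boot Bootstrap iterations for session-level intervals.
#' @param bin_s Decoding bin width (s).
#' @param seed Master seed; per-session and per-stage seeds are derived
#'   from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_sessions = 3, protocol = list(), neural = list(),
                       orofacial = list(), facial = list(), alpha = 0.05,
                       k = 10, n_shuffles = 100, n_boot = 1000, bin_s = 1,
                       seed = 1L) {
  cfg <- list(n_sessions = n_sessions, protocol = protocol, neural = neural,
              orofacial = orofacial, facial = facial, alpha = alpha, k = k,
              n_shuffles = n_shuffles, n_boot = n_boot, bin_s = bin_s,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash; stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' For each session: simulate, preprocess (neuropil correction, dF/F0,
#' epoch means), score odor modulation for the bimodal-vs-grating and
#' odor-vs-blank contrasts with their shuffle nulls, extract orofacial
#' kinematics, and decode odor presence with a nearest-centroid classifier.
#' Cross-session summaries (bootstrap intervals, paired Wilcoxon, KS) are
#' computed at the end. A failing stage marks its record as failed and
#' downstream stages for that session are skipped.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and the run report as JSON.
#' @return An `odormod_run` object: per-session tables, cross-session
#'   summaries, decode results, warnings, and the config.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  proto <- do.call(make_protocol,
                   c(config$protocol, list(seed = config$seed)))
  failed <- character()

  sessions <- purrr::map(seq_len(config$n_sessions), function(si) {
    sseed <- config$seed + 17L * si
    tryCatch({
      neural <- do.call(simulate_population,
                        c(list(protocol = proto, seed = sseed),
                          config$neural))
      oro <- do.call(simulate_orofacial,
                     c(list(protocol = proto, seed = sseed + 1L),
                       config$orofacial))
      fcor <- neuropil_correct(neural$F, neural$F_n)
      dff <- compute_dff(fcor, proto)
      em <- epoch_average(dff)

      resp <- detect_responsive(em, proto$trials$condition, config$alpha)
      res <- purrr::map(c(bimodal_vs_grating = "bimodal_vs_grating",
                          odor_vs_blank = "odor_vs_blank"),
                        function(ct) {
        grp <- contrast_trials(proto, ct)
        mod <- score_modulation(em, grp$a, grp$b, config$alpha)
        nul <- shuffle_null_proportion(em, grp$a, grp$b, config$alpha,
                                       config$n_shuffles, seed = sseed)
        list(mod = mod, null = nul)
      })
      kin <- epoch_kinematics(oro, proto)

      pv <- build_features(dff, bin_s = config$bin_s)
      sub <- subset_trials(pv, pv$y$grating != "none")
      dec <- permutation_pvalue(
        sub,
        target = ifelse(sub$y$odor != "none", "odor_present", "odor_absent"),
        decoder = "centroid", k = config$k,
        n_shuffles = config$n_shuffles, seed = sseed)

      list(session = si, resp = resp, res = res, kin = kin, dec = dec,
           ok = TRUE)
    }, error = function(e) {
      list(session = si, ok = FALSE, error = conditionMessage(e))
    })
  })

  ok <- purrr::keep(sessions, "ok")
  failed <- purrr::map_chr(purrr::discard(sessions, "ok"),
                           ~ sprintf("session %d: %s", .x$session, .x$error))

  mod_tbl <- purrr::map_dfr(ok, function(s)
    purrr::imap_dfr(s$res, function(r, ct) {
      tibble(session = s$session, contrast = ct,
             prop_real = modulated_proportion(r$mod),
             prop_shuffled = r$null$mean,
             prop_enhanced = 100 * mean(r$mod$direction == "enhanced"),
             prop_suppressed = 100 * mean(r$mod$direction == "suppressed"),
             mi_real = list(r$mod$modulation_index))
    }))
  summaries <- if (nrow(mod_tbl) > 0)
    purrr::map(split(mod_tbl, mod_tbl$contrast), summarize_sessions,
               n_boot = config$n_boot, seed = config$seed)
  else list()

  kin_tbl <- purrr::map_dfr(ok, function(s)
    dplyr::mutate(s$kin, session = s$session))
  kin_tests <- if (nrow(kin_tbl) > 0) kinematics_tests(kin_tbl) else NULL

  dec_tbl <- purrr::map_dfr(ok, function(s)
    dplyr::mutate(s$dec$bins, session = s$session))

  run <- structure(list(config = config, protocol = proto,
                        modulation = mod_tbl, summaries = summaries,
                        kinematics = kin_tbl, kinematics_tests = kin_tests,
                        decoding = dec_tbl, failed = failed),
                   class = "odormod_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.odormod_run <- function(x, ...) {
  cat(sprintf("<odormod_run> %d session(s), config %s\n",
              length(unique(x$modulation$session)), x$config$hash))
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dplyr::select(run$modulation, -dplyr::any_of("mi_real")),
                   file.path(out_dir, "modulation.csv"), row.names = FALSE)
  utils::write.csv(run$kinematics, file.path(out_dir, "kinematics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$decoding, file.path(out_dir, "decoding.csv"),
                   row.names = FALSE)
  if (!is.null(run$kinematics_tests))
    utils::write.csv(run$kinematics_tests,
                     file.path(out_dir, "kinematics_tests.csv"),
                     row.names = FALSE)
  payload <- list(
    config = unclass(run$config),
    summaries = purrr::map(run$summaries, function(s)
      list(summary = s$summary, tests = s$tests)),
    failed = run$failed)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable run summary
#'
#' Reads a completed run directory (or takes an `odormod_run` object) and
#' returns a plain-text summary of the headline comparisons: real vs
#' shuffled modulated proportions per contrast, odor vs no-odor kinematic
#' contrasts, and decoding accuracy.
#'
#' @param x An `odormod_run` or a run directory path.
#' @return Character vector of report lines (invisibly printed).
#' @export
report <- function(x) {
  if (is.character(x)) {
    if (!file.exists(file.path(x, "report.json")))
      return(invisible(message_lines("no run found in ", x)))
    payload <- jsonlite::read_json(file.path(x, "report.json"),
                                   simplifyVector = TRUE)
    lines <- c(sprintf("run %s", payload$config$hash))
    for (ct in names(payload$summaries)) {
      s <- payload$summaries[[ct]]$summary
      r <- s[s$measure == "prop_real", ]
      sh <- s[s$measure == "prop_shuffled", ]
      lines <- c(lines, sprintf(
        "%s: %.2f%% modulated (95%% CI %.2f, %.2f) vs %.2f%% shuffled",
        ct, r$mean, r$ci_lo, r$ci_hi, sh$mean))
    }
    if (length(payload$failed))
      lines <- c(lines, paste("failed:", payload$failed))
    return(invisible(message_lines(lines)))
  }
  stopifnot(inherits(x, "odormod_run"))
  lines <- sprintf("run %s (%d sessions)", x$config$hash,
                   length(unique(x$modulation$session)))
  for (ct in names(x$summaries)) {
    s <- x$summaries[[ct]]
    r <- s$summary[s$summary$measure == "prop_real", ]
    sh <- s$summary[s$summary$measure == "prop_shuffled", ]
    wt <- s$tests[s$tests$test == "real_vs_shuffled_wilcoxon", ]
    lines <- c(lines, sprintf(
      "%s: %.2f%% modulated (95%% CI %.2f, %.2f) vs %.2f%% shuffled%s",
      ct, r$mean, r$ci_lo, r$ci_hi, sh$mean,
      if (nrow(wt)) sprintf(" (Wilcoxon p = %.3g)", wt$p_value) else ""))
  }
  if (!is.null(x$kinematics_tests) && nrow(x$kinematics_tests) > 0) {
    kt <- x$kinematics_tests
    lines <- c(lines, sprintf(
      "kinematics %s [%s context]: odor %.3g vs no-odor %.3g (p = %.3g)",
      kt$measure, ifelse(kt$grating_context, "grating", "no-grating"),
      kt$mean_a, kt$mean_b, kt$p_value))
  }
  if (nrow(x$decoding) > 0) {
    peak <- x$decoding |>
      dplyr::group_by(.data$session) |>
      dplyr::slice_max(.data$accuracy, n = 1, with_ties = FALSE)
    lines <- c(lines, sprintf(
      "decoding (odor presence): peak %.1f%% (session %d, bin [%g, %g) s, p = %.3g)",
      peak$accuracy, peak$session, peak$t_start, peak$t_end, peak$p_value))
  }
  if (length(x$failed)) lines <- c(lines, paste("failed:", x$failed))
  invisible(message_lines(lines))
}

message_lines <- function(...) {
  lines <- c(...)
  cat(paste(lines, collapse = "\n"), "\n")
  lines
}
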