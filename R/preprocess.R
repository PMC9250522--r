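#' Neuropil correction
#'
#' Subtracts a scaled neuropil trace from each ROI trace:
#' `F_cor = F - r * F_n`, with `r = 0.7` by default.
#'
#' @param f ROI fluorescence (vector, matrix or array, a.u.).
#' @param f_n Neuropil fluorescence, same shape as `f`.
#' @param r Neuropil coefficient in `[0, 1]`.
#' @return `f - r * f_n`, same shape as `f`.
#' @examples
#' neuropil_correct(10, 10)  # 3
#' @export
neuropil_correct <- function(f, f_n, r = 0.7) {
  if (!identical(dim(f) %||% length(f), dim(f_n) %||% length(f_n)))
    abort("`f` and `f_n` must have the same shape")
  if (r < 0 || r > 1) abort("`r` must lie in [0, 1]")
  f - r * f_n
}

#' Compute baseline-subtracted dF/F0
#'
#' Per cell and trial, estimates `F0` as the 8th percentile of that trial's
#' corrected trace (linear interpolation between order statistics), computes
#' `dff = (F_cor - F0) / F0`, then subtracts the scalar mean of `dff` over
#' the baseline epoch (default 1-2 s before stimulus onset) from the whole
#' trial, so the baseline-epoch mean of every trace is exactly zero.
#'
#' Cell/trial pairs with `F0 <= 0` cannot be normalized; their traces are
#' set to `NA` and recorded in the `flagged` table.
#'
#' @param f_cor Corrected fluorescence array, cells x trials x frames (see
#'   [neuropil_correct()]). A trials x frames matrix is treated as one cell.
#' @param protocol A [make_protocol()] object supplying frame rate and
#'   epochs.
#' @param percentile Baseline percentile (default 8).
#' @param baseline_subtract Subtract the pre-onset baseline mean?
#' @return A `dff_tensor` object: `dff` array (cells x trials x frames),
#'   `f0` matrix (cells x trials), `flagged` tibble (cell, trial), the
#'   protocol and window metadata.
#' @export
compute_dff <- function(f_cor, protocol, percentile = 8,
                        baseline_subtract = TRUE) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (length(dim(f_cor)) == 2)
    f_cor <- array(f_cor, c(1, dim(f_cor)))
  d <- dim(f_cor)
  if (length(d) != 3) abort("`f_cor` must be a cells x trials x frames array")
  if (d[3] < 2) abort("need at least 2 frames per trial")
  nc <- d[1]; nt <- d[2]; nf <- d[3]

  # row-wise percentile over a (cells*trials) x frames matrix
  m <- matrix(f_cor, nc * nt, nf)
  f0 <- apply(m, 1, quantile, probs = percentile / 100, names = FALSE,
              type = 7)
  bad <- f0 <= 0
  dffm <- (m - f0) / f0
  dffm[bad, ] <- NA_real_

  if (baseline_subtract) {
    bidx <- epoch_index(protocol, protocol$baseline_epoch_s)
    if (length(bidx) == 0) abort("baseline epoch contains no frames")
    dffm <- dffm - rowMeans(dffm[, bidx, drop = FALSE])
  }

  flagged <- if (any(bad)) {
    ij <- arrayInd(which(bad), c(nc, nt))
    tibble(cell = ij[, 1], trial = ij[, 2])
  } else tibble(cell = integer(), trial = integer())
  if (nrow(flagged) > 0)
    warn(sprintf("%d cell/trial trace(s) had F0 <= 0 and were flagged", nrow(flagged)))

  structure(list(dff = array(dffm, d), f0 = matrix(f0, nc, nt),
                 flagged = flagged, protocol = protocol,
                 percentile = percentile,
                 baseline_subtracted = baseline_subtract),
            class = "dff_tensor")
}

#' @export
print.dff_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_tensor> %d cells x %d trials x %d frames (%d flagged)\n",
              d[1], d[2], d[3], nrow(x$flagged)))
  invisible(x)
}

#' Average dF/F over a within-trial window
#'
#' Means over the frames whose time relative to stimulus onset lies in the
#' half-open window `[start, end)`.
#'
#' @param x A `dff_tensor` from [compute_dff()].
#' @param window Length-2 numeric, seconds relative to onset; defaults to
#'   the protocol's stimulation epoch.
#' @return A cells x trials matrix of epoch-mean dF/F.
#' @export
epoch_average <- function(x, window = x$protocol$stim_epoch_s) {
  stopifnot(inherits(x, "dff_tensor"))
  idx <- epoch_index(x$protocol, window)
  if (length(idx) == 0) abort("`window` contains no frames")
  d <- dim(x$dff)
  m <- matrix(x$dff, d[1] * d[2], d[3])
  matrix(rowMeans(m[, idx, drop = FALSE]), d[1], d[2])
}

#' Intrinsic-imaging reflectance response map
#'
#' Per-pixel relative reflectance change `(R_stim - R_base) / R_base`, where
#' both terms are means over the stated frame sets, averaged across
#' repetitions.
#'
#' @param r_stack Reflectance stack: frames x pixels matrix, or a
#'   repetitions x frames x pixels array (averaged over repetitions).
#' @param stim_frames,base_frames Integer frame indices of the stimulation
#'   and baseline epochs; both must be non-empty.
#' @return A `reflectance_map`: list with `map` (per-pixel relative change;
#'   `NaN` where `R_base = 0`, recorded in `flagged_pixels`) and the epoch
#'   definitions.
#' @export
intrinsic_response_map <- function(r_stack, stim_frames, base_frames) {
  if (length(stim_frames) == 0 || length(base_frames) == 0)
    abort("`stim_frames` and `base_frames` must be non-empty")
  if (length(dim(r_stack)) == 3)
    r_stack <- colMeans(r_stack)          # average repetitions
  if (length(dim(r_stack)) != 2)
    abort("`r_stack` must be frames x pixels (or reps x frames x pixels)")
  r_stim <- colMeans(r_stack[stim_frames, , drop = FALSE])
  r_base <- colMeans(r_stack[base_frames, , drop = FALSE])
  map <- (r_stim - r_base) / r_base
  map[r_base == 0] <- NaN
  structure(list(map = map, stim_frames = stim_frames,
                 base_frames = base_frames,
                 flagged_pixels = which(r_base == 0)),
            class = "reflectance_map")
}
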