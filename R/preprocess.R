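#' Extract ROI mean time courses from a dynamic series
#'
#' Unweighted mean over each ROI's voxels, per frame. ROIs are returned in
#' ascending label order.
#'
#' @param series A [dynamic_series()].
#' @param labels A [label_map()] voxel-aligned to the series (same spatial
#'   dimensions; no resampling is performed).
#' @return A [roi_curves()] object.
#' @export
extract_roi_timecourses <- function(series, labels) {
  stopifnot(inherits(series, "dynamic_series"), inherits(labels, "label_map"))
  dm <- dim(series$data)
  if (!identical(dm[1:3], dim(labels$labels)))
    stop("label map dimensions ", paste(dim(labels$labels), collapse = "x"),
         " do not match series ", paste(dm[1:3], collapse = "x"))
  labs <- sort(unique(as.integer(labels$labels)))
  labs <- labs[labs != 0L]
  if (!length(labs)) stop("label map contains no ROIs")
  flat <- matrix(series$data, prod(dm[1:3]), dm[4])
  lab_vec <- as.integer(labels$labels)
  sig <- vapply(labs, function(k) {
    vox <- which(lab_vec == k)
    if (!length(vox)) stop("ROI label ", k, " has zero voxels")
    colMeans(flat[vox, , drop = FALSE])
  }, numeric(dm[4]))
  roi_curves(series$time, sig, roi_id = labs,
             roi_name = unname(labels$names[as.character(labs)]),
             n_baseline_frames = series$n_baseline_frames,
             polarity = series$polarity)
}

#' Temporal averaging (multi-average reconstruction)
#'
#' Averages non-overlapping blocks of `n_average` consecutive frames; the
#' new frame time is the block mean of the original times and a trailing
#' remainder that does not fill a complete block is dropped. The baseline
#' frame count becomes `floor(n_baseline / n_average)`. With 312 frames of
#' 25 s and `n_average = 6` this yields 52 frames spaced 2.5 min.
#'
#' @param x A [roi_curves()] or [dynamic_series()].
#' @param n_average Block size (>= 1); 1 is the identity.
#' @return Same class as `x`.
#' @export
temporal_average <- function(x, n_average) UseMethod("temporal_average")

block_average <- function(m, n_average, n_frames) {
  n_average <- as.integer(n_average)
  if (n_average < 1L) stop("n_average must be >= 1")
  if (n_average > n_frames) stop("n_average (", n_average,
                                 ") exceeds frame count (", n_frames, ")")
  n_blocks <- n_frames %/% n_average
  keep <- seq_len(n_blocks * n_average)
  idx <- rep(seq_len(n_blocks), each = n_average)
  avg <- rowsum(m[keep, , drop = FALSE], idx, reorder = TRUE) / n_average
  rownames(avg) <- NULL
  list(n_blocks = n_blocks, avg = avg)
}

#' @export
temporal_average.roi_curves <- function(x, n_average) {
  if (n_average == 1L) return(x)
  ba <- block_average(cbind(x$time, x$signal), n_average, length(x$time))
  roi_curves(ba$avg[, 1], ba$avg[, -1, drop = FALSE],
             roi_id = x$roi_id, roi_name = x$roi_name,
             n_baseline_frames = x$n_baseline_frames %/% as.integer(n_average),
             polarity = x$polarity,
             baseline_subtracted = x$baseline_subtracted,
             normalized = x$normalized,
             reference_roi = x$reference_roi, reference_max = x$reference_max)
}

#' @export
temporal_average.dynamic_series <- function(x, n_average) {
  if (n_average == 1L) return(x)
  dm <- dim(x$data)
  flat <- t(matrix(x$data, prod(dm[1:3]), dm[4]))  # frames x voxels
  ba <- block_average(cbind(x$time, flat), n_average, dm[4])
  dynamic_series(array(t(ba$avg[, -1, drop = FALSE]),
                       c(dm[1:3], ba$n_blocks)),
                 time = ba$avg[, 1],
                 n_baseline_frames = max(1L, x$n_baseline_frames %/%
                                           as.integer(n_average)),
                 polarity = x$polarity, voxel_size = x$voxel_size)
}

#' Baseline subtraction
#'
#' Subtracts each ROI's mean over the first `n_baseline_frames` frames and
#' applies the polarity so that tracer uptake is positive for every agent
#' (water shortens T2 and darkens T2-weighted images; its raw signal change
#' is negative). Baseline frames are retained; their corrected value is
#' ~ 0 up to noise.
#'
#' @param curves A [roi_curves()].
#' @param n_baseline_frames Number of leading frames to average; defaults
#'   to the value stored in `curves`.
#' @param polarity Signal-change sign; defaults to the stored value.
#' @return A [roi_curves()] of polarity-corrected signal changes.
#' @export
subtract_baseline <- function(curves, n_baseline_frames = NULL,
                              polarity = NULL) {
  stopifnot(inherits(curves, "roi_curves"))
  nb <- as.integer(n_baseline_frames %||% curves$n_baseline_frames)
  pol <- as.integer(polarity %||% curves$polarity)
  if (nb < 1L) stop("n_baseline_frames must be >= 1")
  if (nb > length(curves$time)) stop("n_baseline_frames exceeds frame count")
  base <- colMeans(curves$signal[seq_len(nb), , drop = FALSE])
  ds <- pol * sweep(curves$signal, 2L, base)
  roi_curves(curves$time, ds, roi_id = curves$roi_id,
             roi_name = curves$roi_name, n_baseline_frames = nb,
             polarity = pol, baseline_subtracted = TRUE)
}

#' Input-function normalization
#'
#' Divides every baseline-subtracted curve by the maximum (over time) of
#' the reference ROI's curve -- the "input function" measured in a small
#' region surrounding the infusion site. The reference ROI's own normalized
#' curve then has maximum exactly 1.
#'
#' @param curves Baseline-subtracted [roi_curves()].
#' @param reference_roi Integer label of the reference (input-function) ROI.
#' @return A [roi_curves()] with `normalized = TRUE` and the reference
#'   maximum recorded in `reference_max`.
#' @export
normalize_by_input <- function(curves, reference_roi) {
  stopifnot(inherits(curves, "roi_curves"))
  if (!curves$baseline_subtracted)
    warning("normalizing curves that are not baseline-subtracted")
  k <- match(as.integer(reference_roi), curves$roi_id)
  if (is.na(k)) stop("reference ROI ", reference_roi, " not present")
  ref_max <- max(curves$signal[, k])
  if (!is.finite(ref_max) || ref_max <= 0)
    stop("reference ROI ", reference_roi,
         " has non-positive maximum signal change (no detectable infusion)")
  roi_curves(curves$time, curves$signal / ref_max, roi_id = curves$roi_id,
             roi_name = curves$roi_name,
             n_baseline_frames = curves$n_baseline_frames,
             polarity = curves$polarity, baseline_subtracted = TRUE,
             normalized = TRUE,
             reference_roi = as.integer(reference_roi),
             reference_max = ref_max)
}

#' Time maximum intensity projection (tMIP)
#'
#' Per-voxel maximum of the polarity-corrected signal change over the
#' post-baseline frames.
#'
#' @param series A [dynamic_series()].
#' @return 3D array of peak signal change, with the voxel size attached as
#'   attribute `voxel_size`.
#' @export
compute_tmip <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  dm <- dim(series$data)
  nb <- series$n_baseline_frames
  if (nb >= dm[4]) stop("no post-baseline frames")
  flat <- matrix(series$data, prod(dm[1:3]), dm[4])
  base <- rowMeans(flat[, seq_len(nb), drop = FALSE])
  ds <- series$polarity * (flat[, (nb + 1L):dm[4], drop = FALSE] - base)
  out <- array(do.call(pmax, as.data.frame(ds)), dm[1:3])
  attr(out, "voxel_size") <- series$voxel_size
  out
}
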