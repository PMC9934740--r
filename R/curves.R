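#' ROI time-course collection
#'
#' Container for per-ROI mean signal time courses sharing one time axis.
#' The signal matrix is frames x ROIs; columns are named by ROI.
#'
#' @param time Strictly increasing numeric vector of frame times (minutes).
#' @param signal Numeric matrix, `length(time)` rows, one column per ROI.
#' @param roi_id Integer ROI labels (as in the label map), one per column.
#' @param roi_name Character ROI names, one per column.
#' @param n_baseline_frames Number of leading pre-infusion frames.
#' @param polarity `+1` if tracer uptake increases the signal (T1 agents),
#'   `-1` if it decreases it (water on T2-weighted images).
#' @param baseline_subtracted,normalized Bookkeeping flags set by
#'   [subtract_baseline()] and [normalize_by_input()].
#' @param reference_roi,reference_max Input-function metadata recorded by
#'   [normalize_by_input()].
#' @return An object of class `roi_curves`.
#' @export
roi_curves <- function(time, signal, roi_id = seq_len(ncol(signal)),
                       roi_name = sprintf("roi_%02d", roi_id),
                       n_baseline_frames = 1L, polarity = 1L,
                       baseline_subtracted = FALSE, normalized = FALSE,
                       reference_roi = NA_integer_, reference_max = NA_real_) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(time), is.numeric(signal))
  if (nrow(signal) != length(time))
    stop("signal must have one row per time point")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  roi_id <- as.integer(roi_id)
  if (anyDuplicated(roi_id)) stop("duplicate roi_id")
  if (length(roi_id) != ncol(signal) || length(roi_name) != ncol(signal))
    stop("roi_id and roi_name must have one entry per signal column")
  if (!polarity %in% c(-1L, 1L)) stop("polarity must be +1 or -1")
  if (n_baseline_frames < 0L || n_baseline_frames > length(time))
    stop("n_baseline_frames out of range")
  colnames(signal) <- roi_name
  structure(
    list(time = as.numeric(time), signal = signal,
         roi_id = roi_id, roi_name = as.character(roi_name),
         n_baseline_frames = as.integer(n_baseline_frames),
         polarity = as.integer(polarity),
         baseline_subtracted = isTRUE(baseline_subtracted),
         normalized = isTRUE(normalized),
         reference_roi = as.integer(reference_roi),
         reference_max = as.numeric(reference_max)),
    class = "roi_curves")
}

#' @export
print.roi_curves <- function(x, ...) {
  cat(sprintf("ROI time courses: %d ROIs x %d frames (%.3g-%.3g min)\n",
              ncol(x$signal), length(x$time), min(x$time), max(x$time)))
  state <- c(if (x$baseline_subtracted) "baseline-subtracted",
             if (x$normalized) sprintf("input-normalized (ref roi %d, max %.4g)",
                                       x$reference_roi, x$reference_max))
  cat(sprintf("  baseline frames: %d, polarity: %+d%s\n",
              x$n_baseline_frames, x$polarity,
              if (length(state)) paste0(", ", paste(state, collapse = ", ")) else ""))
  invisible(x)
}

#' @export
as.matrix.roi_curves <- function(x, ...) x$signal

#' Number of frames / ROIs of a curve collection
#' @param x A [roi_curves()] object.
#' @return Integer count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.roi_curves <- function(x) length(x$time)

#' @rdname n_frames
#' @export
n_roi <- function(x) UseMethod("n_roi")

#' @export
n_roi.roi_curves <- function(x) ncol(x$signal)

#' Uniform frame interval of a curve collection
#'
#' @param x A [roi_curves()] object.
#' @param tol Relative tolerance on spacing uniformity.
#' @return The common frame spacing in minutes; errors if the axis is not
#'   uniformly spaced (the lag statistic requires a uniform grid).
#' @export
frame_interval <- function(x, tol = 1e-8) {
  d <- diff(x$time)
  if (length(d) == 0L) stop("need at least two frames")
  if (max(d) - min(d) > tol * mean(d))
    stop("time axis is not uniformly spaced")
  mean(d)
}

#' Subset ROIs of a curve collection
#' @param x A [roi_curves()] object.
#' @param i ROI selector (index, logical, or roi name).
#' @param ... Ignored.
#' @return A [roi_curves()] with the selected columns.
#' @export
`[.roi_curves` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$roi_name)
  roi_curves(x$time, x$signal[, i, drop = FALSE],
             roi_id = x$roi_id[i], roi_name = x$roi_name[i],
             n_baseline_frames = x$n_baseline_frames, polarity = x$polarity,
             baseline_subtracted = x$baseline_subtracted,
             normalized = x$normalized,
             reference_roi = x$reference_roi, reference_max = x$reference_max)
}
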