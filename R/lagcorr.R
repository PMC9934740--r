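# Shared lag selection: maximum correlation with deterministic tie-breaks
# (ties within `tol`: smallest |lag| first, then the negative lag).
select_max_lag <- function(lags, cc, tol = 1e-12) {
  ok <- is.finite(cc)
  if (!any(ok)) stop("cross-correlation undefined at every admissible lag ",
                     "(zero-variance overlaps)")
  lags <- lags[ok]; cc <- cc[ok]
  best <- max(cc)
  tie <- which(cc >= best - tol)
  tie <- tie[order(abs(lags[tie]), lags[tie])]
  list(lag = unname(lags[tie[1]]), cc = unname(cc[tie[1]]))
}

# Pearson correlation of x[t] with y[t + l] over the overlapping frames,
# both segments centred and scaled on the overlap; NA if either segment has
# zero variance or the overlap is shorter than 3 frames.
overlap_cor <- function(x, y, l) {
  n <- length(x)
  if (l >= 0) { a <- x[seq_len(n - l)]; b <- y[(1 + l):n] }
  else        { a <- x[(1 - l):n];      b <- y[seq_len(n + l)] }
  if (length(a) < 3L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Time-lagged cross-correlation of two curves
#'
#' For each integer frame lag l in the admissible window, computes the
#' Pearson correlation between `x` and `y` shifted by l frames on their
#' overlapping frames (each segment re-centred and re-scaled on the
#' overlap). The maximal cross-correlation coefficient (mCC) is the maximum
#' over lags; the lag time is the maximizing shift converted to minutes.
#' Positive lag means `y` is delayed relative to `x`. Ties are broken
#' towards the smallest `|lag|`, then the negative lag, so identical curves
#' deterministically return lag 0.
#'
#' @param x,y Numeric vectors on the same uniform time grid.
#' @param max_lag_frames Half-width of the lag search window in frames;
#'   default `floor(n/2)`.
#' @param min_overlap Minimum number of overlapping frames for a lag to be
#'   admissible; default `ceiling(n/2)`.
#' @param frame_interval Frame spacing in minutes (scales the reported lag).
#' @param lag_mode `"symmetric"` searches lags in `[-max_lag, +max_lag]`;
#'   `"nonnegative"` restricts to `[0, +max_lag]` (transport away from the
#'   reference is assumed, so `y` can only be delayed).
#' @return An object of class `lagcorr_pair`: `mcc`, `lag` (min),
#'   `lag_frames`, `overlap`, and the full `cc_profile` (named by lag).
#' @examples
#' x <- c(0, 1, 2, 1, 0, 0); y <- c(0, 0, 1, 2, 1, 0)
#' lagged_crosscorr(x, y, max_lag_frames = 2, frame_interval = 2.5)$lag_frames
#' @export
lagged_crosscorr <- function(x, y, max_lag_frames = NULL, min_overlap = NULL,
                             frame_interval = 1,
                             lag_mode = c("symmetric", "nonnegative")) {
  lag_mode <- match.arg(lag_mode)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 frames")
  if (is.null(max_lag_frames)) max_lag_frames <- n %/% 2L
  if (is.null(min_overlap)) min_overlap <- ceiling(n / 2)
  max_lag_frames <- as.integer(max_lag_frames)
  min_overlap <- max(3L, as.integer(min_overlap))
  if (max_lag_frames < 0L) stop("max_lag_frames must be >= 0")
  if (max_lag_frames > n - min_overlap)
    max_lag_frames <- n - min_overlap
  lags <- if (lag_mode == "symmetric") seq.int(-max_lag_frames, max_lag_frames)
          else seq.int(0L, max_lag_frames)
  cc <- vapply(lags, function(l) overlap_cor(x, y, l), numeric(1))
  names(cc) <- lags
  sel <- select_max_lag(lags, cc)
  structure(list(mcc = sel$cc, lag = sel$lag * frame_interval,
                 lag_frames = as.integer(sel$lag),
                 overlap = n - abs(as.integer(sel$lag)),
                 cc_profile = cc, n = n,
                 frame_interval = frame_interval),
            class = "lagcorr_pair")
}

#' @export
print.lagcorr_pair <- function(x, ...) {
  cat(sprintf("mCC = %.4f at lag %+g min (%+d frames, overlap %d of %d)\n",
              x$mcc, x$lag, x$lag_frames, x$overlap, x$n))
  invisible(x)
}

#' Pairwise mCC and lag-time matrices
#'
#' Computes [lagged_crosscorr()] for every unordered ROI pair and fills the
#' symmetric mCC matrix and the antisymmetric lag matrix (the invariants
#' hold exactly: each pair is computed once and mirrored).
#'
#' @param curves A [roi_curves()] (any numeric matrix with a uniform time
#'   grid also works via `time`).
#' @param max_lag_frames,min_overlap,lag_mode See [lagged_crosscorr()].
#' @return An object of class `lagcorr`: `mcc` (symmetric, unit diagonal),
#'   `lag` (antisymmetric, minutes), `lag_frames`, `overlap`, `roi_id`,
#'   `roi_name`, `frame_interval`.
#' @export
crosscorr_matrix <- function(curves, max_lag_frames = NULL,
                             min_overlap = NULL,
                             lag_mode = c("symmetric", "nonnegative")) {
  lag_mode <- match.arg(lag_mode)
  stopifnot(inherits(curves, "roi_curves"))
  p <- n_roi(curves)
  if (p < 2L) stop("need at least 2 ROIs")
  dt <- frame_interval(curves)
  X <- curves$signal
  nm <- curves$roi_name
  mcc <- matrix(1, p, p, dimnames = list(nm, nm))
  lagf <- matrix(0L, p, p, dimnames = list(nm, nm))
  ov <- matrix(nrow(X), p, p, dimnames = list(nm, nm))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    pr <- tryCatch(
      lagged_crosscorr(X[, i], X[, j], max_lag_frames, min_overlap,
                       frame_interval = dt, lag_mode = lag_mode),
      error = function(e) stop("ROI pair (", nm[i], ", ", nm[j], "): ",
                               conditionMessage(e), call. = FALSE))
    mcc[i, j] <- mcc[j, i] <- pr$mcc
    lagf[i, j] <- pr$lag_frames
    lagf[j, i] <- -pr$lag_frames
    ov[i, j] <- ov[j, i] <- pr$overlap
  }
  structure(list(mcc = mcc, lag = lagf * dt, lag_frames = lagf,
                 overlap = ov, roi_id = curves$roi_id, roi_name = nm,
                 frame_interval = dt, lag_mode = lag_mode),
            class = "lagcorr")
}

#' @export
print.lagcorr <- function(x, ...) {
  p <- nrow(x$mcc)
  off <- x$mcc[upper.tri(x$mcc)]
  cat(sprintf("Lagged cross-correlation: %d ROIs, frame interval %g min\n",
              p, x$frame_interval))
  cat(sprintf("  mCC range %.3f-%.3f, |lag| up to %g min\n",
              min(off), max(off), max(abs(x$lag))))
  invisible(x)
}

#' Dissimilarity matrix 1 - mCC
#'
#' @param result A [crosscorr_matrix()] result.
#' @return Symmetric matrix of class `dissimilarity` with zero diagonal,
#'   values in `[0, 2]` (no clamping is applied).
#' @export
to_dissimilarity <- function(result) {
  stopifnot(inherits(result, "lagcorr"))
  d <- 1 - result$mcc
  diag(d) <- 0
  class(d) <- c("dissimilarity", class(d))
  d
}

#' Combined mCC / lag-time table
#'
#' A single matrix with mCC in the lower triangle and lag time (minutes) in
#' the upper triangle, the layout used to report both statistics at once.
#'
#' @param result A [crosscorr_matrix()] result.
#' @return Numeric matrix with `NA` on the diagonal.
#' @export
mcc_lag_table <- function(result) {
  stopifnot(inherits(result, "lagcorr"))
  out <- result$mcc
  out[upper.tri(out)] <- result$lag[upper.tri(result$lag)]
  diag(out) <- NA_real_
  out
}
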