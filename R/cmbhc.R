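#' Correlation-matrix-based hierarchical clustering of ROI time courses
#'
#' The main model-fitting entry point. Given ROI time courses on one
#' uniform grid, `cmbhc()` computes the pairwise time-lagged
#' cross-correlation statistic (maximal cross-correlation coefficient mCC
#' and its lag time), forms the dissimilarity `1 - mCC`, builds the
#' complete-linkage dendrogram, cuts it at the dissimilarity threshold
#' (default 0.4), and -- when a [bootstrap_config()] is supplied -- attaches
#' multiscale-bootstrap AU/BP cluster probabilities to every node.
#'
#' @param x A [roi_curves()] object, or a numeric matrix (frames x ROIs)
#'   with `time` supplied.
#' @param time Frame times in minutes when `x` is a bare matrix.
#' @param max_lag_frames Lag search half-width in frames; default
#'   `floor(n/2)`, wide enough to admit transport delays up to half the
#'   scan duration.
#' @param min_overlap Minimum overlap per lag; default `ceiling(n/2)`, so
#'   similarity is never declared on a small fraction of the series.
#' @param lag_mode `"symmetric"` (default) or `"nonnegative"` lag window.
#' @param threshold Dissimilarity cut for cluster reporting.
#' @param boot `NULL` for no bootstrap, `TRUE` for defaults, or a
#'   [bootstrap_config()].
#' @return An object of class `cmbhc` with components `lagcorr`, `diss`,
#'   `tree`, `clusters`, `threshold`, `call`.
#' @seealso [crosscorr_matrix()], [complete_linkage()],
#'   [multiscale_bootstrap()], [cut_dendrogram()]
#' @examples
#' truth <- phantom_truth("four_cluster", seed = 7)
#' curves <- simulate_roi_curves(truth, noise_sd = 10, seed = 7)
#' curves <- subtract_baseline(curves)
#' fit <- cmbhc(curves)
#' fit$clusters
#' @export
cmbhc <- function(x, time = NULL, max_lag_frames = NULL, min_overlap = NULL,
                  lag_mode = c("symmetric", "nonnegative"), threshold = 0.4,
                  boot = NULL) {
  lag_mode <- match.arg(lag_mode)
  if (!inherits(x, "roi_curves")) {
    x <- as.matrix(x)
    if (is.null(time)) time <- seq_len(nrow(x))
    x <- roi_curves(time, x,
                    roi_name = colnames(x) %||%
                      sprintf("roi_%02d", seq_len(ncol(x))))
  }
  lc <- crosscorr_matrix(x, max_lag_frames, min_overlap, lag_mode)
  d <- to_dissimilarity(lc)
  if (isTRUE(boot)) boot <- bootstrap_config()
  tree <- if (inherits(boot, "bootstrap_config"))
    multiscale_bootstrap(x, lc, boot)
  else complete_linkage(d)
  fit <- structure(
    list(lagcorr = lc, diss = d, tree = tree,
         clusters = cut_dendrogram(tree, threshold),
         threshold = threshold,
         boot = if (inherits(boot, "bootstrap_config")) boot else NULL,
         curves = x, call = match.call()),
    class = "cmbhc")
  fit
}

#' @export
print.cmbhc <- function(x, ...) {
  cat("Correlation-matrix-based hierarchical clustering\n\n")
  print(x$lagcorr)
  print(x$clusters)
  if (any(is.finite(x$tree$au))) {
    ca <- cluster_confidence(x)
    cat(sprintf("  cluster AU p-values: %s\n",
                paste(sprintf("%s=%.2f", rownames(ca), ca[, "au"]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cmbhc <- function(object, ...) {
  res <- list(n_roi = length(object$lagcorr$roi_name),
              n_clusters = length(object$clusters$clusters),
              threshold = object$threshold,
              mcc_lag = mcc_lag_table(object$lagcorr),
              confidence = if (any(is.finite(object$tree$au)))
                cluster_confidence(object) else NULL)
  class(res) <- "summary.cmbhc"
  res
}

#' @export
print.summary.cmbhc <- function(x, ...) {
  cat(sprintf("cmbhc fit: %d ROIs, %d clusters at dissimilarity < %g\n",
              x$n_roi, x$n_clusters, x$threshold))
  cat("mCC (lower triangle) / lag min (upper triangle):\n")
  print(round(x$mcc_lag, 2))
  if (!is.null(x$confidence)) {
    cat("cluster confidence:\n")
    print(round(x$confidence, 3))
  }
  invisible(x)
}

#' AU/BP confidence of the reported clusters
#'
#' Matches each threshold cluster to its dendrogram node and returns that
#' node's AU p-value and BP value.
#'
#' @param fit A fitted [cmbhc()] object with bootstrap results.
#' @return Matrix with one row per cluster, columns `height`, `au`, `bp`.
#' @export
cluster_confidence <- function(fit) {
  stopifnot(inherits(fit, "cmbhc"))
  tree <- fit$tree
  keys <- vapply(tree$members, paste, character(1), collapse = ",")
  out <- t(vapply(fit$clusters$clusters, function(cl) {
    idx <- sort(match(cl, tree$labels))
    k <- match(paste(idx, collapse = ","), keys)
    c(height = tree$height[k], au = tree$au[k], bp = tree$bp[k])
  }, numeric(3)))
  rownames(out) <- names(fit$clusters$clusters)
  out
}

#' @export
cut_dendrogram.cmbhc <- function(tree, threshold = 0.4)
  cut_dendrogram(tree$tree, threshold)

#' @export
as.hclust.cmbhc <- function(x, ...) {
  out <- x$tree
  class(out) <- "hclust"
  out
}

#' Plot a fitted cmbhc dendrogram
#'
#' Plots the complete-linkage dendrogram on the 1 - mCC scale, draws the
#' threshold cut, and annotates internal nodes with AU (left, red) and BP
#' (right, green) percentages when the bootstrap was run.
#'
#' @param x A fitted [cmbhc()] object.
#' @param show_threshold Draw the dissimilarity cut line.
#' @param ... Passed to [graphics::plot()] for the dendrogram.
#' @return `x`, invisibly.
#' @export
plot.cmbhc <- function(x, show_threshold = TRUE, ...) {
  hc <- as.hclust(x)
  graphics::plot(hc, ylab = "dissimilarity (1 - mCC)", sub = "", xlab = "",
                 main = "Correlation-matrix-based clustering", ...)
  if (show_threshold)
    graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  if (any(is.finite(x$tree$au))) {
    pos <- node_positions(hc)
    graphics::text(pos$x - 0.15, pos$y, sprintf("%.0f", 100 * x$tree$au),
                   col = "red3", cex = 0.7, adj = c(1, -0.3))
    graphics::text(pos$x + 0.15, pos$y, sprintf("%.0f", 100 * x$tree$bp),
                   col = "green4", cex = 0.7, adj = c(0, -0.3))
  }
  invisible(x)
}

# x-position of each internal node in a plotted hclust
node_positions <- function(hc) {
  leaf_x <- match(seq_along(hc$order), hc$order)
  xs <- numeric(nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[s, ]
    xk <- vapply(kids, function(k) if (k < 0) leaf_x[-k] else xs[k],
                 numeric(1))
    xs[s] <- mean(xk)
  }
  list(x = xs, y = hc$height)
}

#' Residual dissimilarity of a fitted clustering
#'
#' Cophenetic residuals: the difference between the dendrogram's cophenetic
#' dissimilarity and the observed `1 - mCC` for every ROI pair. Large
#' positive residuals flag pairs whose similarity the tree under-represents.
#'
#' @param object A fitted [cmbhc()] object.
#' @param ... Ignored.
#' @return Symmetric matrix of residuals.
#' @export
residuals.cmbhc <- function(object, ...) {
  coph <- as.matrix(stats::cophenetic(as.hclust(object)))
  coph <- coph[rownames(object$diss), colnames(object$diss)]
  coph - unclass(object$diss)
}
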