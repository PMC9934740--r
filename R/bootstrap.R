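#' Multiscale-bootstrap configuration
#'
#' @param n_boot Bootstrap replicates per scale (default 1000).
#' @param scales Sampling-ratio grid r (resample size = `round(r * n)`
#'   frames); the default ten ratios 0.5-1.4 follow the standard multiscale
#'   bootstrap practice. At least two distinct usable scales are needed for
#'   AU p-values; a single scale yields raw BP values only.
#' @param seed Integer seed (mandatory for reproducible resampling).
#' @param min_scaled_n Scales whose resample size falls below this are
#'   dropped with a warning.
#' @param scheme `"frozen_lag"` (default) resamples time frames while
#'   keeping every pair aligned at its full-data optimal lag, so the
#'   time-lagged dissimilarity stays well-defined under resampling;
#'   `"plain"` resamples frames and uses zero-lag correlation, which is
#'   what a direct application of the classical correlation-distance
#'   bootstrap would do.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                             seed = 1L, min_scaled_n = 10L,
                             scheme = c("frozen_lag", "plain")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(n_boot), n_boot >= 1, is.numeric(scales),
            all(scales > 0), length(scales) >= 1,
            is.numeric(seed), is.numeric(min_scaled_n))
  structure(list(n_boot = as.integer(n_boot), scales = as.numeric(scales),
                 seed = as.integer(seed),
                 min_scaled_n = as.integer(min_scaled_n), scheme = scheme),
            class = "bootstrap_config")
}

# per-pair correlation at frozen lag, restricted to the resampled frame
# multiset; NA when fewer than 3 usable frames or zero variance
frozen_lag_cor <- function(x, y, l, idx) {
  n <- length(x)
  if (l >= 0) { sel <- idx[idx <= n - l]; a <- x[sel]; b <- y[sel + l] }
  else        { sel <- idx[idx <= n + l]; a <- x[sel - l]; b <- y[sel] }
  if (length(sel) < 3L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Multiscale-bootstrap AU/BP cluster probabilities
#'
#' Assesses the uncertainty of every dendrogram node by resampling time
#' frames at several sampling ratios r. For each of `n_boot` resamples per
#' scale the pairwise correlation matrix is recomputed (with each pair
#' aligned at its full-data optimal lag under the default scheme), the
#' complete-linkage dendrogram is rebuilt, and a node's bootstrap
#' probability BP_r is the fraction of resampled dendrograms containing
#' exactly the same member set. The approximately unbiased p-value AU is
#' obtained from the probit-scale model `qnorm(1 - BP_r) = v*sqrt(r) +
#' c/sqrt(r)` fitted across scales by weighted least squares (binomial
#' variance weights); `AU = 1 - pnorm(v - c)`. Scales where BP is exactly
#' 0 or 1 carry no curvature information and are excluded from the fit; if
#' fewer than two informative scales remain, AU is 1 (node in essentially
#' every resample) or 0 by the sign of the mean BP. With a single
#' configured scale no AU is computed and the reported BP is the raw
#' resample frequency.
#'
#' The reported BP value per node is the observed frequency at r = 1 when
#' that scale is present, otherwise the fitted value `1 - pnorm(v + c)`.
#'
#' @param curves The [roi_curves()] that produced `lag_result`.
#' @param lag_result A [crosscorr_matrix()] result (provides the frozen
#'   per-pair lags).
#' @param cfg A [bootstrap_config()].
#' @return The [complete_linkage()] tree of the full data with `au` and
#'   `bp` filled, plus a `bp_table` (scales x nodes) and the per-scale
#'   resample counts as attributes `boot_scales`, `boot_counts`.
#' @export
multiscale_bootstrap <- function(curves, lag_result,
                                 cfg = bootstrap_config()) {
  stopifnot(inherits(curves, "roi_curves"), inherits(lag_result, "lagcorr"),
            inherits(cfg, "bootstrap_config"))
  if (!identical(curves$roi_name, lag_result$roi_name))
    stop("curves and lag_result describe different ROI sets")
  X <- curves$signal
  n <- nrow(X)
  p <- ncol(X)
  tree <- complete_linkage(to_dissimilarity(lag_result))
  node_keys <- vapply(tree$members, paste, character(1), collapse = ",")

  n_r <- round(cfg$scales * n)
  usable <- n_r >= max(3L, cfg$min_scaled_n)
  if (any(!usable))
    warning("dropping scale(s) with resample size below min_scaled_n: ",
            paste(cfg$scales[!usable], collapse = ", "))
  scales <- cfg$scales[usable]
  n_r <- n_r[usable]
  if (!length(scales)) stop("no usable bootstrap scales")

  lagf <- lag_result$lag_frames
  pairs <- which(upper.tri(lagf), arr.ind = TRUE)
  set.seed(cfg$seed)
  bp_tab <- matrix(0, length(scales), length(node_keys),
                   dimnames = list(sprintf("r=%g", scales), node_keys))
  n_valid <- integer(length(scales))
  for (s in seq_along(scales)) {
    counts <- numeric(length(node_keys))
    valid <- 0L
    for (b in seq_len(cfg$n_boot)) {
      idx <- sample.int(n, n_r[s], replace = TRUE)
      cc <- matrix(1, p, p)
      ok <- TRUE
      if (cfg$scheme == "frozen_lag") {
        for (q in seq_len(nrow(pairs))) {
          i <- pairs[q, 1]; j <- pairs[q, 2]
          r <- frozen_lag_cor(X[, i], X[, j], lagf[i, j], idx)
          if (is.na(r)) { ok <- FALSE; break }
          cc[i, j] <- cc[j, i] <- r
        }
      } else {
        Xb <- X[idx, , drop = FALSE]
        cc <- suppressWarnings(stats::cor(Xb))
        if (anyNA(cc)) ok <- FALSE
      }
      if (!ok) next
      valid <- valid + 1L
      tb <- complete_linkage(1 - cc)
      keys <- vapply(tb$members, paste, character(1), collapse = ",")
      counts <- counts + (node_keys %in% keys)
    }
    if (valid == 0L) stop("all resamples failed at scale r=", scales[s])
    bp_tab[s, ] <- counts / valid
    n_valid[s] <- valid
  }

  fit <- au_bp_fit(bp_tab, scales, n_valid,
                   single_scale = length(scales) < 2L)
  tree$au <- fit$au
  tree$bp <- fit$bp
  tree$bp_table <- bp_tab
  attr(tree, "boot_scales") <- scales
  attr(tree, "boot_counts") <- n_valid
  tree
}

# probit-scale WLS fit across scales; returns au/bp per node
au_bp_fit <- function(bp_tab, scales, n_valid, single_scale = FALSE) {
  n_nodes <- ncol(bp_tab)
  au <- bp <- rep(NA_real_, n_nodes)
  at_one <- which(abs(scales - 1) < 1e-9)[1]
  for (k in seq_len(n_nodes)) {
    bps <- bp_tab[, k]
    if (single_scale) {
      bp[k] <- bps[1]          # raw resample frequency; AU undefined
      next
    }
    use <- bps > 0 & bps < 1
    if (sum(use) < 2L) {
      au[k] <- if (mean(bps) >= 0.5) 1 else 0
      bp[k] <- if (!is.na(at_one)) bps[at_one] else mean(bps)
      next
    }
    z <- stats::qnorm(1 - bps[use])
    r <- scales[use]
    Xd <- cbind(sqrt(r), 1 / sqrt(r))
    w <- n_valid[use] * stats::dnorm(z)^2 / (bps[use] * (1 - bps[use]))
    XtW <- t(Xd * w)
    coefs <- tryCatch(solve(XtW %*% Xd, XtW %*% z),
                      error = function(e) NULL)
    if (is.null(coefs)) {
      au[k] <- if (mean(bps) >= 0.5) 1 else 0
      bp[k] <- if (!is.na(at_one)) bps[at_one] else mean(bps)
      next
    }
    v <- coefs[1]; cc <- coefs[2]
    au[k] <- 1 - stats::pnorm(v - cc)
    bp[k] <- if (!is.na(at_one)) bps[at_one] else 1 - stats::pnorm(v + cc)
  }
  list(au = au, bp = bp)
}
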