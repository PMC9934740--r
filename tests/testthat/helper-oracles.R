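# Independent oracles used across tests. These deliberately avoid the
# package's code paths: Pearson from explicit sums, linkage by direct
# max-distance scans of the original matrix.

# Pearson correlation from raw sums
pearson_sums <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  if (den == 0) return(NA_real_)
  num / den
}

# exhaustive lag search: for every admissible integer lag, Pearson on the
# overlap; returns the profile and the winning lag under the package's
# tie-break contract (max cc, then smallest |lag|, then negative lag)
brute_force_lagcorr <- function(x, y, max_lag, min_overlap) {
  n <- length(x)
  lags <- -max_lag:max_lag
  cc <- sapply(lags, function(l) {
    if (l >= 0) { a <- x[seq_len(n - l)]; b <- y[(1 + l):n] }
    else        { a <- x[(1 - l):n];      b <- y[seq_len(n + l)] }
    if (length(a) < max(3, min_overlap)) return(NA_real_)
    pearson_sums(a, b)
  })
  ok <- which(is.finite(cc))
  best <- ok[order(-cc[ok], abs(lags[ok]), lags[ok])][1]
  list(lags = lags, cc = cc, mcc = cc[best], lag = lags[best])
}

# naive complete linkage: keeps explicit member lists and rescans the
# original dissimilarity matrix for the max cross-pair distance at every
# step (no Lance-Williams update); ties by smallest representative pair
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- max(d[clusters[[i]], clusters[[j]]])
      ri <- min(clusters[[i]]); rj <- min(clusters[[j]])
      if (dij < best_d ||
          (dij == best_d && (min(ri, rj) < min(best$ri, best$rj) ||
            (min(ri, rj) == min(best$ri, best$rj) &&
             max(ri, rj) < max(best$ri, best$rj))))) {
        best_d <- dij
        best <- list(i = i, j = j, ri = min(ri, rj), rj = max(ri, rj))
      }
    }
    heights <- c(heights, best_d)
    merges <- c(merges, list(sort(c(clusters[[best$i]], clusters[[best$j]]))))
    clusters[[best$i]] <- merges[[length(merges)]]
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, members = merges)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sa <- rowSums(tab); sb <- colSums(tab); N <- sum(tab)
  idx <- sum(choose(tab, 2))
  ea <- sum(choose(sa, 2)); eb <- sum(choose(sb, 2))
  expected <- ea * eb / choose(N, 2)
  mx <- (ea + eb) / 2
  (idx - expected) / (mx - expected)
}

# member sets of a tree keyed by sorted labels, order-independent
member_keys <- function(tree) {
  sort(vapply(tree$members,
              function(m) paste(sort(tree$labels[m]), collapse = "|"),
              character(1)))
}

# random symmetric dissimilarity matrix with zero diagonal
random_diss <- function(n) {
  m <- matrix(runif(n * n, 0.05, 1.5), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}
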