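test_that("two items merge once at their dissimilarity", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- complete_linkage(d)
  expect_equal(tr$height, 0.3)
  expect_equal(tr$members, list(c(1L, 2L)))
})

test_that("two tight pairs merge before the far root", {
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tr <- complete_linkage(d)
  expect_equal(tr$height, c(0.1, 0.1, 0.9))
  expect_equal(tr$members[[1]], c(1L, 2L))
  expect_equal(tr$members[[2]], c(3L, 4L))
  expect_equal(tr$members[[3]], 1:4)

  cut <- cut_dendrogram(tr, 0.4)
  expect_length(cut$clusters, 2)
  expect_equal(sort(cut$clusters$C1), c("a", "b"))
  expect_equal(sort(cut$clusters$C2), c("c", "d"))
  expect_length(cut$singletons, 0)
})

test_that("linkage matches the naive exhaustive reference on random matrices", {
  set.seed(11)
  for (rep in 1:500) {
    n <- sample(3:6, 1)
    d <- random_diss(n)
    tr <- complete_linkage(d)
    ref <- naive_complete_linkage(d)
    expect_equal(tr$height, ref$heights, tolerance = 1e-15)
    expect_identical(tr$members, ref$members)
  }
})

test_that("linkage heights agree with stats::hclust", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    d <- random_diss(n)
    tr <- complete_linkage(d)
    hc <- hclust(as.dist(d), method = "complete")
    expect_equal(tr$height, hc$height, tolerance = 1e-12)
    # same partition at every merge level
    for (k in 2:(n - 1)) {
      expect_equal(adjusted_rand(cutree(hc, k),
                                 cutree(structure(unclass(tr),
                                                  class = "hclust"), k)), 1)
    }
  }
})

test_that("heights are monotone non-decreasing toward the root", {
  set.seed(13)
  for (rep in 1:50) {
    tr <- complete_linkage(random_diss(sample(3:10, 1)))
    expect_false(is.unsorted(tr$height))
  }
})

test_that("non-finite dissimilarities are rejected with the pair named", {
  d <- random_diss(4)
  d[2, 3] <- d[3, 2] <- NaN
  expect_error(complete_linkage(d), "'b' and 'c'")
})

test_that("threshold cuts cover the degenerate cases", {
  tr <- complete_linkage(random_diss(6))
  all_in <- cut_dendrogram(tr, max(tr$height) + 1)
  expect_length(all_in$clusters, 1)
  expect_length(all_in$clusters[[1]], 6)
  none <- cut_dendrogram(tr, min(tr$height) / 2)
  expect_length(none$clusters, 0)
  expect_length(none$singletons, 6)
  expect_error(cut_dendrogram(tr, 0), "threshold")
})

test_that("cluster assignments partition the ROIs", {
  set.seed(14)
  for (rep in 1:20) {
    tr <- complete_linkage(random_diss(sample(4:10, 1)))
    cut <- cut_dendrogram(tr, runif(1, 0.2, 1.2))
    all_members <- c(unlist(cut$clusters), cut$singletons)
    expect_setequal(all_members, tr$labels)
    expect_equal(anyDuplicated(all_members), 0)
    if (length(cut$clusters))
      for (cl in cut$clusters) expect_gte(length(cl), 2)
  }
})

test_that("dendrogram JSON round trip preserves topology, heights, AU/BP", {
  truth <- phantom_truth("two_cluster", seed = 21)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 5, seed = 21))
  lc <- crosscorr_matrix(cur)
  tr <- multiscale_bootstrap(cur, lc,
                             bootstrap_config(n_boot = 30,
                                              scales = c(0.8, 1, 1.2),
                                              seed = 1))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  dendrogram_to_json(tr, tmp)
  tr2 <- dendrogram_from_json(tmp)
  expect_identical(member_keys(tr), member_keys(tr2))
  expect_equal(sort(tr$height), sort(tr2$height), tolerance = 1e-12)
  expect_equal(sort(tr$au), sort(tr2$au), tolerance = 1e-12)
  expect_equal(sort(tr$bp), sort(tr2$bp), tolerance = 1e-12)
})

test_that("Newick round trip preserves topology and heights to 1e-9", {
  set.seed(22)
  for (rep in 1:10) {
    tr <- complete_linkage(random_diss(sample(4:12, 1)))
    tr2 <- dendrogram_from_newick(dendrogram_to_newick(tr))
    expect_identical(member_keys(tr), member_keys(tr2))
    expect_equal(sort(tr$height), sort(tr2$height), tolerance = 1e-9)
  }
})
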