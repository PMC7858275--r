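test_that("PCA handles perfect correlation and conserves variance", {
  set.seed(1)
  v <- rnorm(30)
  m <- cbind(a = v, b = 2 * v + 1, c = rnorm(30))
  p <- pca(m)
  expect_equal(sum(p$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_false(is.unsorted(rev(p$explained_variance_fraction)))
  p2 <- pca(m[, c("a", "b")])
  expect_equal(p2$explained_variance_fraction[1], 1, tolerance = 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA reconstruction reproduces the standardized matrix", {
  set.seed(2)
  m <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, letters[1:5]))
  p <- pca(m)
  expect_equal(p$scores %*% t(p$loadings), scale(m), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PC1 aligns with the dominant axis of an anisotropic Gaussian", {
  set.seed(3)
  m <- cbind(x = rnorm(500, sd = 3), y = rnorm(500, sd = 1))
  p <- pca(m, standardize = FALSE)
  expect_gt(abs(p$loadings["x", 1]), 0.99)
})

test_that("PCA rejects zero-variance variables by name", {
  m <- cbind(a = rnorm(10), flat = rep(1, 10))
  expect_error(pca(m), "flat")
})

test_that("k-means on loadings recovers planted variable groups", {
  set.seed(4)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  truth <- rep(1:3, each = 5)
  load2 <- centers[truth, ] + matrix(rnorm(30, sd = 0.2), 15, 2)
  rownames(load2) <- sprintf("v%02d", 1:15)
  cl <- kmeans_variables(load2, k = 3, seed = 8)
  # planted partition recovered up to label permutation
  expect_equal(length(unique(paste(cl$assignments, truth))), 3L)
  cl2 <- kmeans_variables(load2, k = 3, seed = 8)
  expect_identical(cl$assignments, cl2$assignments)
  cl_all <- kmeans_variables(load2, k = 15, seed = 8)
  expect_equal(cl_all$wss, 0, tolerance = 1e-9)
  expect_error(kmeans_variables(load2, k = 0), "positive")
})

test_that("hierarchical clustering recovers planted replicate groups", {
  set.seed(5)
  m <- rbind(matrix(rnorm(20, 0), 4), matrix(rnorm(20, 8), 4))
  rownames(m) <- sprintf("s%d", 1:8)
  hc <- hierarchical_cluster(m, k = 2, standardize = FALSE)
  expect_equal(length(unique(hc$assignments[1:4])), 1L)
  expect_equal(length(unique(hc$assignments[5:8])), 1L)
  expect_false(hc$assignments[1] == hc$assignments[5])
  # merge heights monotone for the supported linkages
  for (lk in c("ward", "average", "complete")) {
    h <- hierarchical_cluster(m, k = 2, linkage = lk, standardize = FALSE)
    expect_false(is.unsorted(h$tree$height))
  }
  # duplicate samples merge at height zero
  md <- rbind(m, m[1, , drop = FALSE])
  rownames(md) <- sprintf("s%d", 1:9)
  hd <- hierarchical_cluster(md, k = 2, standardize = FALSE)
  expect_equal(min(hd$tree$height), 0, tolerance = 1e-12)
})

test_that("gap statistic selects the planted number of clusters", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    x <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 6), ncol = 2),
               matrix(rnorm(40, 12), ncol = 2))
    g <- gap_statistic(x, k_range = 1:6, B_references = 30, seed = s,
                       standardize = FALSE)
    hits <- hits + (g$optimal_k == 3L)
    expect_equal(nrow(g$table), 6L)
  }
  expect_gte(hits, 4)
  set.seed(10)
  y <- matrix(rnorm(120), ncol = 2)
  g1 <- gap_statistic(y, k_range = 1:5, B_references = 30, seed = 2,
                      standardize = FALSE)
  expect_equal(g1$optimal_k, 1L)
  expect_error(gap_statistic(y, k_range = 1:5, B_references = 5), "10")
})

test_that("gap statistic on substrate profiles merges overlapping groups", {
  # seven planted sample groups, of which the two oil-waste states overlap;
  # the selected number of clusters should fall below seven
  prof <- simulate_substrate_profiles(seed = 2)
  m <- as.matrix(prof[, setdiff(names(prof),
                                c("sample_id", "group", "diet", "phase"))])
  rownames(m) <- prof$sample_id
  g <- gap_statistic(m, k_range = 1:8, B_references = 30, seed = 2)
  expect_lt(g$optimal_k, 7L)
  expect_gt(g$optimal_k, 1L)
})
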