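# Multivariate analysis of physicochemical profiles ---------------------------

#' Principal component analysis of a sample-by-variable table
#'
#' Wrapper over the singular value decomposition ([stats::prcomp()]) with
#' the conventions used throughout the package: variables are centered and
#' (by default) scaled to unit variance, since physicochemical variables
#' have incommensurate units; component signs are fixed by making each
#' loading column's largest-magnitude entry positive, so results are fully
#' deterministic.
#'
#' @param x Numeric matrix or data frame, samples x variables, no missing
#'   values.
#' @param standardize Scale variables to unit variance (default `TRUE`).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained_variance_fraction`.
#' @export
pca <- function(x, standardize = TRUE) {
  m <- as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 samples and variables")
  if (anyNA(m)) stop("missing values not allowed in PCA input")
  if (standardize) {
    v <- apply(m, 2L, var)
    if (any(v == 0))
      stop("zero-variance variable(s): ",
           paste(colnames(m)[v == 0], collapse = ", "))
  }
  fit <- prcomp(m, center = TRUE, scale. = standardize)
  # sign convention: largest-magnitude loading entry positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2
  structure(list(scores = fit$x, loadings = fit$rotation,
                 explained_variance_fraction = ev / sum(ev)),
            class = "pca_result")
}

# k-means++ seeding, then Lloyd iterations via stats::kmeans
kmeanspp <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(0)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dn <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  x[centers, , drop = FALSE]
}

run_kmeans <- function(x, k, n_starts, seed, stream) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(x)) stop("k cannot exceed the number of items")
  with_stream_seed(seed, stream, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      init <- kmeanspp(x, k)
      fit <- suppressWarnings(
        kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' Cluster variables by their first two PCA loadings
#'
#' Groups the variable arrows of a PCA biplot by k-means (k-means++ seeding,
#' best of `n_starts` by total within-cluster sum of squares).
#'
#' @param loadings Variables x components loading matrix (a [pca()]
#'   `loadings` element); only the first two components are used.
#' @param k Number of clusters (<= number of variables).
#' @param n_starts Number of k-means++ restarts.
#' @param seed Integer seed.
#' @return List of class `cluster_result`: `assignments` (named integer
#'   vector), `k`, `wss` (total within-cluster SS), `method`.
#' @export
kmeans_variables <- function(loadings, k = 3L, n_starts = 25L, seed = 1L) {
  x <- as.matrix(loadings)[, 1:2, drop = FALSE]
  fit <- run_kmeans(x, k, n_starts, seed, "kmeans_vars")
  structure(list(assignments = setNames(fit$cluster, rownames(x)),
                 k = length(unique(fit$cluster)), wss = fit$tot.withinss,
                 method = "kmeans++"),
            class = "cluster_result")
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering ([stats::hclust()]) of samples on Euclidean
#' distance of standardized variables (or a supplied distance matrix), with
#' flat assignments cut at `k` groups.
#'
#' @param x Sample-by-variable table, or a `dist`/square distance matrix if
#'   `distance = "precomputed"`.
#' @param k Number of flat clusters to cut.
#' @param linkage `"ward"` (ward.D2), `"average"` or `"complete"`.
#' @param distance `"euclidean"` (on standardized variables) or
#'   `"precomputed"`.
#' @param standardize Standardize variables before computing distances.
#' @return List of class `hclust_result`: `tree` (an `hclust`),
#'   `assignments`, `k`.
#' @export
hierarchical_cluster <- function(x, k = 6L,
                                 linkage = c("ward", "average", "complete"),
                                 distance = c("euclidean", "precomputed"),
                                 standardize = TRUE) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (distance == "precomputed") {
    d <- as.dist(as.matrix(x))
  } else {
    m <- as.matrix(x)
    if (nrow(m) < 2L) stop("need at least two samples")
    if (standardize) {
      v <- apply(m, 2L, var)
      m <- scale(m[, v > 0, drop = FALSE])
    }
    d <- dist(m)
  }
  tree <- hclust(d, method = switch(linkage, ward = "ward.D2",
                                    average = "average",
                                    complete = "complete"))
  structure(list(tree = tree,
                 assignments = cutree(tree, k = min(k, attr(d, "Size"))),
                 k = min(k, attr(d, "Size"))),
            class = "hclust_result")
}

#' Gap-statistic selection of the number of clusters
#'
#' Tibshirani's gap statistic:
#' `Gap(k) = mean_b log(W_k^ref_b) - log(W_k)` with `W_k` the total
#' within-cluster sum of squares of a k-means partition and reference data
#' drawn uniformly over the data's bounding box in PCA-rotated coordinates
#' (the original recommendation). The selected k is the smallest k with
#' `Gap(k) >= Gap(k+1) - s(k+1)` (the "first SE max" rule), where
#' `s(k) = sd_b(log W_k^ref) * sqrt(1 + 1/B)`.
#'
#' @param x Sample-by-variable table.
#' @param k_range Candidate numbers of clusters (within `[1, n - 1]`).
#' @param B_references Number of reference datasets (>= 10).
#' @param n_starts k-means++ restarts per fit.
#' @param seed Integer seed.
#' @param standardize Standardize variables first.
#' @return List of class `gap_result`: `optimal_k`, `table` (data frame
#'   `k`, `logW`, `E_logW`, `gap`, `se`).
#' @export
gap_statistic <- function(x, k_range = 1:8, B_references = 50L,
                          n_starts = 10L, seed = 1L, standardize = TRUE) {
  if (B_references < 10L) stop("need at least 10 reference datasets")
  m <- as.matrix(x)
  if (standardize) {
    v <- apply(m, 2L, var)
    m <- scale(m[, v > 0, drop = FALSE])
  }
  n <- nrow(m)
  if (max(k_range) > n - 1L || min(k_range) < 1L)
    stop("k_range must lie within [1, n - 1]")

  # within-cluster dispersion W_k = sum_r (sum of pairwise Euclidean
  # distances within cluster r) / n_r, on the k-means partition
  wss_of <- function(data, k, stream) {
    cl <- if (k == 1L) rep(1L, nrow(data)) else
      run_kmeans(data, k, n_starts, seed, stream)$cluster
    sum(vapply(split(seq_len(nrow(data)), cl), function(ii)
      sum(dist(data[ii, , drop = FALSE])) / length(ii), 0))
  }
  logW <- vapply(k_range, function(k)
    log(wss_of(m, k, paste0("gap/data/", k))), 0)

  # references: uniform in the PCA-rotated bounding box
  sv <- svd(scale(m, scale = FALSE))
  rot <- scale(m, scale = FALSE) %*% sv$v
  lo <- apply(rot, 2L, min); hi <- apply(rot, 2L, max)
  ref_logW <- matrix(0, B_references, length(k_range))
  for (b in seq_len(B_references)) {
    ref <- with_stream_seed(seed, paste0("gap/ref/", b), {
      u <- matrix(runif(n * ncol(rot)), n, ncol(rot))
      sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+") %*% t(sv$v)
    })
    ref_logW[b, ] <- vapply(seq_along(k_range), function(i)
      log(wss_of(ref, k_range[i], paste0("gap/refk/", b, "/", k_range[i]))),
      0)
  }
  E_logW <- colMeans(ref_logW)
  se <- apply(ref_logW, 2L, sd) * sqrt(1 + 1 / B_references)
  gap <- E_logW - logW
  optimal <- k_range[length(k_range)]
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { optimal <- k_range[i]; break }
  }
  structure(list(optimal_k = optimal,
                 table = data.frame(k = k_range, logW = logW,
                                    E_logW = E_logW, gap = gap, se = se)),
            class = "gap_result")
}
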