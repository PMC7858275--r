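test_that("exhaustive PERMANOVA on the separated 3+3 toy gives p = 0.1", {
  d <- block_distances(c(3L, 3L), within = 0.1, between = 0.9)
  r <- permanova(d, rep(c("A", "B"), each = 3), permutations = "exhaustive")
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$n_permutations, 20L)
})

test_that("pseudo-F and R2 match the vegan adonis2 oracle", {
  m <- toy_counts(12, 15, seed = 31)
  d <- bray_curtis(m)
  g <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova(d, g, n_perm = 499, seed = 4)
  ref <- vegan::adonis2(as.dist(unclass(d)) ~ g, permutations = 499)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_true(mine$R2 >= 0 && mine$R2 <= 1)
})

test_that("PERMANOVA is invariant to sample order", {
  d <- bray_curtis(toy_counts(10, 8, seed = 5))
  g <- rep(c("a", "b"), each = 5)
  r1 <- permanova(d, g, n_perm = 99, seed = 1)
  perm <- c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6)
  r2 <- permanova(d[perm, perm], g[perm], n_perm = 99, seed = 1)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-12)
})

test_that("pairwise PERMANOVA applies the Bonferroni adjustment", {
  d <- block_distances(c(4L, 4L, 4L), within = 0.15, between = 0.85)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- permanova(d, g, n_perm = 199, seed = 2, pairwise = TRUE)
  expect_equal(nrow(r$pairwise), 3L)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p))
  expect_true(all(r$pairwise$p_adj <= 1))
})

test_that("PERMANOVA rejects degenerate groupings", {
  d <- block_distances(c(3L, 3L))
  expect_error(permanova(d, rep("a", 6)), "two groups")
  expect_error(permanova(d, c("a", "a", "a", "a", "a", "b")),
               "at least two samples")
})

test_that("Mantel r is exactly one for linearly related matrices", {
  d1 <- embeddable_distances(n = 12, seed = 9)
  r <- mantel(d1, 2 * d1, n_perm = 199, seed = 1)
  expect_equal(r$statistic, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 200, tolerance = 1e-12)
  # symmetric in argument order
  d2 <- embeddable_distances(n = 12, seed = 10)
  expect_equal(mantel(d1, d2, n_perm = 99, seed = 3)$statistic,
               mantel(d2, d1, n_perm = 99, seed = 3)$statistic,
               tolerance = 1e-12)
})

test_that("Mantel null on independent matrices is well calibrated", {
  ok <- 0
  for (s in 1:20) {
    d1 <- embeddable_distances(n = 20, seed = 100 + s)
    d2 <- embeddable_distances(n = 20, seed = 200 + s)
    r <- mantel(d1, d2, n_perm = 199, seed = s)
    ok <- ok + (abs(r$statistic) < 0.3 && r$p_value > 0.05)
  }
  expect_gte(ok, 18)
  expect_error(mantel(embeddable_distances(5), embeddable_distances(6)),
               "mismatch")
})

test_that("Mantel stability across subsampling depths of the same data", {
  md <- gut_metadata()
  tab <- simulate_communities(community_spec(), md, seed = 12)
  rs <- vapply(1:5, function(s) {
    t2 <- simulate_communities(community_spec(), md, seed = 300 + s)
    depths <- quantile(rowSums(t2$counts), c(0, 0.25)) # min and a deeper cut
    m1 <- bray_curtis(rarefy(t2, depths[1], seed = s))
    m2 <- bray_curtis(suppressWarnings(rarefy(t2, depths[2], seed = s)))
    common <- intersect(rownames(m1), rownames(m2))
    mantel(m1[common, common], m2[common, common], n_perm = 99,
           seed = s)$statistic
  }, 0)
  expect_gt(median(rs), 0.9)
})

test_that("alpha-diversity group tests report all four methods", {
  set.seed(8)
  H <- c(rnorm(6, 2, 0.2), rnorm(6, 2, 0.2), rnorm(6, 0.8, 0.2))
  g <- rep(c("INI", "CFD", "FWD"), each = 6)
  tt <- alpha_group_tests(H, g)
  expect_setequal(tt$method, c("anova", "pairwise_t_bonferroni",
                               "tukey_hsd", "bartlett"))
  expect_lt(tt$p[tt$method == "anova"], 0.01)
})

test_that("a planted diversity drop is reliably detected", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    H <- c(rnorm(6, 2.0, 0.2), rnorm(6, 1.4, 0.2))  # 3-sd effect
    p <- compare_groups(H, rep(c("ctl", "drop"), each = 6), "anova")$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 19)
})

test_that("Bonferroni-adjusted pairwise p-values dominate raw ones", {
  set.seed(14)
  H <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  adj <- compare_groups(H, g, "pairwise_t_bonferroni")$pairwise
  raw <- pairwise.t.test(H, factor(g), p.adjust.method = "none",
                         pool.sd = FALSE)$p.value
  expect_true(all(adj >= raw - 1e-12, na.rm = TRUE))
})
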