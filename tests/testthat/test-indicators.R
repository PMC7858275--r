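test_that("IndVal reaches one for a perfect indicator", {
  m <- matrix(c(5, 6, 7, 0, 0, 0), 6, 1,
              dimnames = list(sprintf("s%d", 1:6), "tx"))
  r <- indval_multipattern(m, rep(c("A", "B"), each = 3),
                           permutations = "exhaustive")
  expect_equal(r$indval_stat, 1, tolerance = 1e-12)
  expect_equal(r$group, "A")
  expect_equal(r$indval_p, 0.1, tolerance = 1e-12)  # 2/20 by enumeration
})

test_that("a uniform taxon over two groups scores sqrt(0.5)", {
  m <- matrix(10, 6, 2, dimnames = list(sprintf("s%d", 1:6), c("u", "v")))
  r <- indval_multipattern(m, rep(c("A", "B"), each = 3), n_perm = 99,
                           seed = 1)
  expect_equal(r$indval_stat, rep(sqrt(0.5), 2), tolerance = 1e-12)
})

test_that("IndVal statistic is monotone in within-group abundance", {
  set.seed(6)
  m <- toy_counts(9, 5, seed = 6)
  g <- rep(c("A", "B", "C"), each = 3)
  r0 <- indval_multipattern(m, g, n_perm = 49, seed = 1)
  for (tx in colnames(m)) {
    grp <- strsplit(r0$group[r0$taxon == tx], "+", fixed = TRUE)[[1]][1]
    m2 <- m
    m2[g == grp, tx] <- m2[g == grp, tx] + 50
    r2 <- indval_multipattern(m2, g, n_perm = 49, seed = 1)
    expect_gte(r2$indval_stat[r2$taxon == tx] + 1e-12,
               r0$indval_stat[r0$taxon == tx])
  }
})

test_that("with two groups combinations reduce to simple associations", {
  m <- toy_counts(8, 6, seed = 8)
  g <- rep(c("A", "B"), each = 4)
  with_c <- indval_multipattern(m, g, allow_combinations = TRUE,
                                n_perm = 49, seed = 2)
  without <- indval_multipattern(m, g, allow_combinations = FALSE,
                                 n_perm = 49, seed = 2)
  expect_equal(with_c$group, without$group)
  expect_equal(with_c$indval_stat, without$indval_stat, tolerance = 1e-12)
})

test_that("effect-size screen controls its null false-positive rate", {
  # classes drawn identically: fraction of taxa passing KW near alpha
  passes <- 0; total <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    m <- matrix(rpois(12 * 10, 15), 12, 10,
                dimnames = list(sprintf("s%d", 1:12),
                                sprintf("t%d", 1:10)))
    r <- lda_effect_size(m, rep(c("A", "B"), each = 6), seed = s)
    passes <- passes + sum(r$kw_p <= 0.05)
    total <- total + nrow(r)
  }
  expect_gt(passes / total, 0.02)
  expect_lt(passes / total, 0.09)
})

test_that("a strong planted effect is found with the right class", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rpois(12 * 20, 10), 12, 20,
                dimnames = list(sprintf("s%d", 1:12),
                                sprintf("t%d", 1:20)))
    m[1:6, 1] <- rpois(6, 200)   # ~50% in class A vs ~0.5% in class B
    r <- lda_effect_size(m, rep(c("A", "B"), each = 6), seed = s)
    hits <- hits + (r$significant[1] && r$class[1] == "A")
  }
  expect_gte(hits, 19)
})

test_that("constant taxa take p = 1 and are never scored", {
  m <- toy_counts(8, 3, seed = 9)
  m[, 2] <- 0   # taxon 2 constant zero across all samples
  r <- lda_effect_size(m, rep(c("A", "B"), each = 4), seed = 1)
  expect_equal(r$kw_p[2], 1)
  expect_true(is.na(r$lda_score[2]))
  expect_false(r$significant[2])
  expect_error(lda_effect_size(m, rep("A", 8)), "two classes")
  expect_error(lda_effect_size(m, c(rep("A", 6), "B", "B")), "3 samples")
})

test_that("consensus requires both screens and an agreeing group", {
  lf <- data.frame(taxon = c("t1", "t2", "t3"), kw_p = c(0.01, 0.01, 0.4),
                   lda_score = c(3, 3, NA), class = c("A", "A", NA),
                   significant = c(TRUE, TRUE, FALSE))
  iv <- data.frame(taxon = c("t1", "t2", "t3"),
                   indval_stat = c(0.9, 0.9, 0.5),
                   indval_p = c(0.01, 0.01, 0.6),
                   group = c("A+B", "C", "A"))
  m <- matrix(c(200, 200, 10, 10, 1, 1), 2, 3,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  cs <- consensus_indicators(lf, iv, m)
  expect_true(cs$consensus[cs$taxon == "t1"])    # class A within A+B
  expect_false(cs$consensus[cs$taxon == "t2"])   # groups disagree
  expect_false(cs$consensus[cs$taxon == "t3"])   # one method only
  expect_false(cs$below_display_threshold[1])
  expect_true(cs$below_display_threshold[3])
  expect_error(consensus_indicators(lf[1:2, ], iv, m), "do not match")
  empty <- consensus_indicators(lf[0, ], iv[0, ], m)
  expect_equal(nrow(empty), 0L)
})

test_that("the planted bloom taxon is a consensus indicator of its diets", {
  for (s in c(3, 8)) {
    tab <- simulate_communities(community_spec(), gut_metadata(), seed = s)
    filt <- prevalence_filter(rarefy(tab, "min", seed = s))
    g <- filt$metadata$diet
    lf <- lda_effect_size(filt, g, seed = s)
    iv <- indval_multipattern(filt, g, n_perm = 299, seed = s)
    cs <- consensus_indicators(lf, iv, filt)
    row <- cs[cs$taxon == "Otu0001", ]
    expect_true(row$consensus)
    expect_true(row$lda_class %in% c("FWD", "OWD"))
    expect_false(row$below_display_threshold)
  }
})
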