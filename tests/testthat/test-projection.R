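test_that("full-coverage single-taxon samples reproduce reference rows", {
  ref <- rbind(tA = c(0.6, 0.4, 0), tB = c(0, 0.5, 0.5))
  colnames(ref) <- c("p1", "p2", "p3")
  m <- rbind(s1 = c(100, 0), s2 = c(0, 80))
  colnames(m) <- c("tA", "tB")
  pr <- project_functions(m, ref)
  expect_equal(pr$profile[, "s1"], c(p1 = 0.6, p2 = 0.4, p3 = 0))
  expect_equal(pr$profile[, "s2"], c(p1 = 0, p2 = 0.5, p3 = 0.5))
  expect_equal(unname(pr$fraction_assigned), c(1, 1))
})

test_that("fraction assigned equals the covered read share", {
  ref <- rbind(tA = c(0.5, 0.5), tB = c(0, 0), tC = c(1, 0))
  colnames(ref) <- c("p1", "p2")
  m <- rbind(s1 = c(70, 30, 0))   # 70 covered reads of 100
  colnames(m) <- c("tA", "tB", "tC")
  pr <- project_functions(m, ref)
  expect_equal(unname(pr$fraction_assigned), 0.7)
  expect_equal(sum(pr$profile[, "s1"]), 1, tolerance = 1e-12)
  # zero covered reads: all-missing profile, fraction 0, warning
  m0 <- rbind(s1 = c(0, 50, 0))
  colnames(m0) <- c("tA", "tB", "tC")
  expect_warning(p0 <- project_functions(m0, ref), "zero covered")
  expect_true(all(is.na(p0$profile)))
  expect_equal(unname(p0$fraction_assigned), 0)
})

test_that("projection is linear in community composition", {
  set.seed(4)
  ref <- simulate_function_reference(n_taxa = 12, n_pathways = 10,
                                     n_level2_categories = 3,
                                     coverage_frac = 1, seed = 4)$reference
  a <- rpois(12, 20) + 1
  b <- rpois(12, 20) + 1
  m <- rbind(a = a, b = b, mix = a + b)  # 50/50 mixture at equal depth
  colnames(m) <- rownames(ref)
  pr <- project_functions(m, ref)
  expect_equal(pr$profile[, "mix"],
               (pr$profile[, "a"] * sum(a) + pr$profile[, "b"] * sum(b)) /
                 sum(a + b), tolerance = 1e-10)
  # identical compositions give identical profiles
  m2 <- rbind(x = a, y = 3 * a)
  colnames(m2) <- rownames(ref)
  p2 <- project_functions(m2, ref)
  expect_equal(p2$profile[, "x"], p2$profile[, "y"], tolerance = 1e-12)
})

test_that("hierarchy aggregation preserves per-sample mass", {
  ref <- simulate_function_reference(n_taxa = 10, n_pathways = 8,
                                     n_level2_categories = 3,
                                     coverage_frac = 1, seed = 5)
  m <- toy_counts(4, 10, seed = 5)
  colnames(m) <- rownames(ref$reference)
  pr <- project_functions(m, ref$reference)
  ag <- aggregate_hierarchy(pr, ref$hierarchy)
  expect_equal(colSums(ag$profile), colSums(pr$profile), tolerance = 1e-12)
  # all-to-one category concentrates everything
  one <- setNames(rep("all", 8), names(ref$hierarchy))
  a1 <- aggregate_hierarchy(pr, one)
  expect_equal(unname(a1$profile["all", ]), rep(1, 4), tolerance = 1e-12)
  # constructed 60/40 split
  prof <- structure(list(
    profile = matrix(c(0.3, 0.3, 0.2, 0.2), 4, 1,
                     dimnames = list(sprintf("p%d", 1:4), "s1")),
    fraction_assigned = c(s1 = 1), level = "pathway"),
    class = "functional_profile")
  map <- c(p1 = "c1", p2 = "c1", p3 = "c2", p4 = "c2")
  a2 <- aggregate_hierarchy(prof, map)
  expect_equal(unname(a2$profile[, "s1"]), c(0.6, 0.4))
  expect_error(aggregate_hierarchy(prof, map[1:3]), "unmapped")
})

test_that("shared reference rows blur planted taxonomic separation", {
  # two diets differ strongly in which taxa dominate, but the taxa share
  # few functional profiles: the diet signal must be weaker (never
  # stronger) on projected functions than on taxa
  worse <- 0
  for (s in 1:5) {
    set.seed(s)
    n_taxa <- 20
    profs <- matrix(rgamma(5 * 8, 1), 5, 8)
    profs <- profs / rowSums(profs)
    ref <- profs[rep(1:5, each = 4), ]   # each function shared by 4 taxa
    rownames(ref) <- sprintf("t%02d", 1:n_taxa)
    colnames(ref) <- sprintf("p%d", 1:8)
    base <- rgamma(n_taxa, 1)
    shift <- sample(n_taxa)               # diet B permutes taxon identities
    mk <- function(w) t(vapply(1:6, function(i)
      as.vector(rmultinom(1, 3000, w * rgamma(n_taxa, 50, 50))), numeric(n_taxa)))
    mA <- mk(base); mB <- mk(base[shift])
    m <- rbind(mA, mB)
    dimnames(m) <- list(sprintf("s%02d", 1:12), rownames(ref))
    g <- rep(c("A", "B"), each = 6)
    r_taxa <- permanova(bray_curtis(m), g, n_perm = 99, seed = s)
    pr <- project_functions(m, ref)
    r_fun <- permanova(bray_curtis(t(pr$profile)), g, n_perm = 99, seed = s)
    worse <- worse + (r_fun$R2 <= r_taxa$R2 + 1e-9)
  }
  expect_gte(worse, 4)
})
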