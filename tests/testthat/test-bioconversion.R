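test_that("feeding schedule enumerates events correctly", {
  expect_equal(schedule_feedings(0, 18, 2)$n_events, 10L)
  expect_equal(schedule_feedings(0, 0, 2)$n_events, 1L)
  expect_equal(schedule_feedings(0, 12, 2)$days, seq(0L, 12L, 2L))
  expect_error(schedule_feedings(0, 10, -1), "interval")
  expect_error(schedule_feedings(10, 0, 2), "end_day")
})

test_that("indices reproduce the printed control and food-waste values", {
  # control diet: AD/ECI/ECD column
  b <- mass_budget(I_offered_dry = 200, R_residue_dry = 100,
                   E_ingested_dry = 100, R_egesta_dry = 52.3,
                   B_gain_dry = 17.9, A_mean_biomass = 10, T_days = 18)
  ix <- compute_indices(b)
  expect_equal(ix$AD, 47.7, tolerance = 1e-9)
  expect_equal(ix$ECI, 17.9, tolerance = 1e-9)
  expect_equal(round(ix$ECD, 1), 37.5)
  # food-waste diet: substrate-reduction column at the 20-day duration
  b2 <- mass_budget(I_offered_dry = 100, R_residue_dry = 14.7,
                    E_ingested_dry = 90, R_egesta_dry = 10,
                    B_gain_dry = 9, A_mean_biomass = 10, T_days = 20)
  ix2 <- compute_indices(b2)
  expect_equal(ix2$SR, 85.3, tolerance = 1e-9)
  expect_equal(ix2$WRI, 4.265, tolerance = 1e-9)
  expect_equal(round(ix2$WRI, 1), 4.3)
})

test_that("index identities hold over random valid budgets", {
  set.seed(42)
  for (i in 1:50) {
    I <- runif(1, 50, 5000)
    E <- runif(1, 0.3, 1) * I
    Reg <- runif(1, 0.05, 0.95) * E
    b <- mass_budget(I_offered_dry = I,
                     R_residue_dry = (I - E) + Reg,
                     E_ingested_dry = E, R_egesta_dry = Reg,
                     B_gain_dry = runif(1, 0, E - Reg),
                     A_mean_biomass = runif(1, 10, 500),
                     T_days = sample(5:25, 1))
    ix <- compute_indices(b)
    expect_lt(abs(ix$ECI - ix$ECD * ix$AD / 100) / max(ix$ECI, 1e-9), 1e-9)
    expect_lt(abs(ix$WRI - ix$SR / b$T_days) / max(abs(ix$WRI), 1e-9), 1e-9)
    expect_true(ix$SR >= 0 && ix$SR <= 100)
    expect_true(ix$AD >= 0 && ix$AD <= 100)
  }
})

test_that("degenerate budgets are flagged, never errors", {
  # zero assimilation: egesta equal ingestion
  b <- mass_budget(I_offered_dry = 100, R_residue_dry = 100,
                   E_ingested_dry = 50, R_egesta_dry = 50, B_gain_dry = 0,
                   A_mean_biomass = 5, T_days = 10)
  ix <- compute_indices(b)
  expect_equal(ix$AD, 0)
  expect_true(is.na(ix$ECD))
  expect_match(ix$flags[["ECD"]], "assimilated")
  # nothing offered
  b0 <- mass_budget(I_offered_dry = 0, R_residue_dry = 0,
                    E_ingested_dry = 0, R_egesta_dry = 0, B_gain_dry = 0,
                    A_mean_biomass = 5, T_days = 10)
  ix0 <- compute_indices(b0)
  expect_true(is.na(ix0$SR))
  expect_match(ix0$flags[["SR"]], "offered")
})

test_that("budget assembly recovers the generator's exact truth", {
  tr <- noise_free_trial(seed = 13)
  for (box in names(tr$truth$budgets)) {
    est <- build_mass_budget(tr$observations, tr$feeding_log, tr$residues,
                             box, pupae = tr$pupae)
    truth <- tr$truth$budgets[[box]]
    for (f in c("I_offered_dry", "R_residue_dry", "E_ingested_dry",
                "R_egesta_dry", "B_gain_dry", "A_mean_biomass"))
      expect_lt(abs(est[[f]] - truth[[f]]) / max(abs(truth[[f]]), 1e-9),
                1e-6)
    ix <- compute_indices(est)
    it <- tr$truth$indices[[box]]
    for (v in c("GR", "SR", "CI", "WRI", "AD", "ECI", "ECD"))
      expect_lt(abs(ix[[v]] - it[[v]]) / max(abs(it[[v]]), 1e-9), 1e-6)
  }
})

test_that("mass budget rejects physically impossible inputs", {
  expect_error(mass_budget(100, 10, 150, 10, 5, 10, 10), "exceed offered")
  expect_error(mass_budget(100, 10, 50, 60, 5, 10, 10), "exceed ingested")
  expect_error(mass_budget(100, 10, 50, 10, 5, 10, 0), "T_days")
})

test_that("endpoint summary computes water as fresh minus dry", {
  obs <- data.frame(box = rep(c("CFD_B1", "CFD_B2"), each = 2),
                    diet = "CFD", day = rep(c(0, 18), 2),
                    n_alive = c(200, 180, 200, 176), n_pupae = c(0, 20, 0, 24),
                    mean_fresh_mg = c(10, 171, 10, 171),
                    mean_dry_mg = c(3, 63, 3, 63),
                    mean_vs_mg = c(2.8, 55, 2.8, 55))
  es <- endpoint_summary(obs)
  expect_equal(es$water_g, 0.108, tolerance = 1e-9)
  expect_equal(es$fresh_g - es$dry_g, es$water_g, tolerance = 1e-12)
  obs_bad <- obs
  obs_bad$mean_dry_mg[2] <- 200   # dry above fresh
  expect_error(endpoint_summary(obs_bad), "impossible")
})

test_that("group comparisons match a hand sum-of-squares oracle", {
  set.seed(7)
  y <- c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 15))
  g <- rep(c("a", "b", "c"), each = 4)
  # explicit one-way ANOVA decomposition
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 9)
  r <- compare_groups(y, g, "anova")
  expect_equal(r$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(r$p_value, pf(F_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("group comparison edge cases behave as documented", {
  r <- compare_groups(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_match(r$flags[["degenerate"]], "constant")
  # separated groups with near-zero within-variance
  y <- c(1, 1.0001, 1.0002, 9, 9.0001, 9.0002)
  r2 <- compare_groups(y, rep(c("a", "b"), each = 3), "anova")
  expect_lt(r2$p_value, 1e-10)
  expect_error(compare_groups(1:5, rep("a", 5)), "two groups")
})

test_that("Tukey letters are a partition-consistent display", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    means <- sample(c(0, 0, 5, 10, 10), k)
    y <- unlist(lapply(means, function(m) rnorm(4, m)))
    g <- rep(letters[1:k], each = 4)
    r <- compare_groups(y, g, "tukey_hsd")
    for (nm in rownames(r$pairwise)) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
      shared <- intersect(strsplit(r$letters[[pair[1]]], "")[[1]],
                          strsplit(r$letters[[pair[2]]], "")[[1]])
      if (r$pairwise[nm, "p adj"] < 0.05) {
        expect_length(shared, 0)
      } else {
        expect_gt(length(shared), 0)
      }
    }
  }
})

test_that("bartlett front-end agrees with the base test", {
  set.seed(3)
  y <- c(rnorm(6, 0, 1), rnorm(6, 0, 4))
  g <- rep(c("a", "b"), each = 6)
  r <- compare_groups(y, g, "bartlett")
  b <- bartlett.test(y, factor(g))
  expect_equal(r$statistic, unname(b$statistic))
  expect_equal(r$p_value, b$p.value)
})
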