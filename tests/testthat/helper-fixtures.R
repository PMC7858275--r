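# Shared fixture builders (all generated in code, no files)

# tiny count matrix with named samples/taxa
toy_counts <- function(n_samples = 6L, n_taxa = 8L, lambda = 20, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%02d", seq_len(n_taxa))))
  m
}

# distance matrix of an exact k-dimensional point configuration
embeddable_distances <- function(n = 10L, k = 2L, seed = 1L) {
  set.seed(seed)
  pts <- matrix(rnorm(n * k), n, k)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("p%02d", 1:n), sprintf("p%02d", 1:n))
  d
}

# block distance matrix: tight within groups, far between
block_distances <- function(sizes = c(3L, 3L), within = 0.1, between = 0.9) {
  n <- sum(sizes)
  g <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  for (i in seq_along(sizes)) d[g == i, g == i] <- within
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  d
}

# single-diet deterministic trial (no mortality, no pupation, no noise)
noise_free_trial <- function(seed = 1L, diet = "CFD",
                             params = growth_params(mortality_hazard = 0,
                                                    pupation_daily_prob = 0)) {
  design <- trial_design(diets = diet, boxes_per_diet = 2L,
                         end_day_per_diet = setNames(18L, diet),
                         observation_days = seq(0L, 18L, 2L))
  simulate_trial(design, setNames(list(params), diet), seed = seed,
                 obs_noise_cv = 0)
}

# gut-community metadata grid used by generator-based tests
gut_metadata <- function() hermetia:::fixture_community_metadata()
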