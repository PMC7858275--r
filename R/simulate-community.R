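# Synthetic 16S community generator -------------------------------------------

default_genus_pool <- c(
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Dysgonomonadaceae;Dysgonomonas",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Morganellaceae;Providencia",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Moraxellaceae;Acinetobacter",
  "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
  "Bacteria;Firmicutes;Bacilli;Lactobacillales;Leuconostocaceae;Leuconostoc",
  "Bacteria;Firmicutes;Bacilli;Lactobacillales;Enterococcaceae;Enterococcus",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Klebsiella",
  "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Weeksellaceae;Chryseobacterium",
  "Bacteria;Actinobacteriota;Actinobacteria;Actinomycetales;Actinomycetaceae;Actinomyces",
  "Bacteria;Actinobacteriota;Actinobacteria;Micrococcales;Micrococcaceae;Micrococcus",
  "Bacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Clostridium",
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella")

succession_fraction <- function(day, spec) {
  d0 <- spec$succession_day_range[1L]
  d1 <- spec$succession_day_range[2L]
  mid <- (d0 + d1) / 2
  s <- 1 / (1 + exp(-spec$succession_rate * (day - mid)))
  spec$succession_start_frac +
    (spec$succession_end_frac - spec$succession_start_frac) * s
}

#' Simulate an OTU count table with a planted diet-dependent succession
#'
#' Draws Dirichlet-multinomial counts for each sample in `metadata`. The
#' expected composition of samples from `succession_diets` gives the bloom
#' taxon a logistic expected relative abundance rising from
#' `succession_start_frac` to `succession_end_frac` over the succession day
#' range (emulating a *Morganella*-style take-over of the larval gut on
#' waste diets); all other samples follow the static baseline. Library
#' sizes are gamma-mixed Poisson (negative-binomial-like) around
#' `depth_mean`.
#'
#' @param spec A [community_spec()].
#' @param metadata Data frame with columns `sample`, `diet`, `day`,
#'   `replicate`; days of succession samples must lie within the spec's
#'   succession day range.
#' @param succession_diets Diet labels whose samples express the bloom;
#'   `NULL` applies the succession to every sample.
#' @param seed Integer seed.
#' @param sampling Set `FALSE` to return expected compositions scaled to
#'   `depth_mean` without Dirichlet or multinomial noise (exact
#'   expectation, used for limiting-case checks).
#' @return An [abundance_table()] with taxonomy lineages and `metadata`.
#' @export
simulate_communities <- function(spec = community_spec(), metadata,
                                 succession_diets = c("FWD", "OWD"),
                                 seed = 1L, sampling = TRUE) {
  stopifnot(all(c("sample", "diet", "day") %in% names(metadata)))
  if (anyDuplicated(metadata$sample)) stop("duplicate sample ids")
  n_taxa <- spec$n_taxa
  base <- spec$baseline_concentrations / sum(spec$baseline_concentrations)
  bloom <- spec$succession_taxon_index
  in_succession <- if (is.null(succession_diets)) rep(TRUE, nrow(metadata))
    else metadata$diet %in% succession_diets
  if (!is.na(bloom) && any(in_succession)) {
    rng <- spec$succession_day_range
    bad <- in_succession & (metadata$day < rng[1L] | metadata$day > rng[2L])
    if (any(bad))
      stop("succession sample days outside the succession day range: ",
           paste(metadata$sample[bad], collapse = ", "))
  }

  taxa <- sprintf("Otu%04d", seq_len(n_taxa))
  lineage <- rep_len(default_genus_pool, n_taxa)
  lineage <- paste0(lineage, "_", seq_len(n_taxa), ";")
  if (!is.na(bloom))
    lineage[bloom] <- paste0("Bacteria;Proteobacteria;Gammaproteobacteria;",
                             "Enterobacterales;Morganellaceae;Morganella;")
  names(lineage) <- taxa

  counts <- matrix(0, nrow(metadata), n_taxa,
                   dimnames = list(metadata$sample, taxa))
  for (i in seq_len(nrow(metadata))) {
    expected <- base
    if (!is.na(bloom)) {
      # the bloom taxon is a low-abundance resident outside the succession
      # and only takes over along it in the succession diets
      f <- if (in_succession[i]) succession_fraction(metadata$day[i], spec)
        else spec$resident_frac
      expected <- base * (1 - f) / sum(base[-bloom])
      expected[bloom] <- f
      expected <- expected / sum(expected)
    }
    s <- metadata$sample[i]
    if (!sampling) {
      counts[i, ] <- round(expected * spec$depth_mean)
      next
    }
    depth <- with_stream_seed(seed, paste0("depth/", s),
                              rnbinom(1L, mu = spec$depth_mean,
                                      size = spec$depth_shape))
    depth <- max(depth, 1L)  # zero-read draws redrawn as singletons
    p <- if (is.finite(spec$dispersion)) {
      with_stream_seed(seed, paste0("dirichlet/", s), {
        g <- rgamma(n_taxa, shape = expected * spec$dispersion, rate = 1)
        if (sum(g) == 0) expected else g / sum(g)
      })
    } else expected
    counts[i, ] <- with_stream_seed(seed, paste0("counts/", s),
                                    as.vector(rmultinom(1L, depth, p)))
  }
  abundance_table(counts, taxonomy = lineage, metadata = metadata)
}

#' Simulate a taxon-by-pathway function reference
#'
#' Builds a reference matrix for functional projection: a random
#' `coverage_frac` of taxa are "covered" (present in the reference
#' database) and receive a Dirichlet-distributed pathway profile summing to
#' one; uncovered taxa have all-zero rows. Pathways are mapped surjectively
#' onto level-2 categories.
#'
#' @param n_taxa,n_pathways,n_level2_categories Dimensions
#'   (`n_pathways >= n_level2_categories`).
#' @param coverage_frac Fraction of taxa covered, in (0, 1].
#' @param seed Integer seed.
#' @param taxa Optional taxon ids (default `Otu0001`...).
#' @return List: `reference` (taxa x pathways), `hierarchy` (named character
#'   vector pathway -> category), `covered` (character vector of covered
#'   taxon ids).
#' @export
simulate_function_reference <- function(n_taxa = 60, n_pathways = 40,
                                        n_level2_categories = 8,
                                        coverage_frac = 0.7, seed = 1L,
                                        taxa = sprintf("Otu%04d",
                                                       seq_len(n_taxa))) {
  if (coverage_frac <= 0 || coverage_frac > 1)
    stop("coverage_frac must be in (0, 1]")
  if (n_pathways < n_level2_categories)
    stop("n_pathways must be >= n_level2_categories")
  pathways <- sprintf("pwy%03d", seq_len(n_pathways))
  categories <- sprintf("L2_%02d", seq_len(n_level2_categories))
  n_cov <- round(coverage_frac * n_taxa)
  covered <- with_stream_seed(seed, "coverage",
                              sort(sample(taxa, n_cov)))
  ref <- matrix(0, n_taxa, n_pathways, dimnames = list(taxa, pathways))
  for (t in covered) {
    g <- with_stream_seed(seed, paste0("refrow/", t),
                          rgamma(n_pathways, shape = 0.5, rate = 1))
    if (sum(g) == 0) g[1L] <- 1
    ref[t, ] <- g / sum(g)
  }
  # surjective pathway -> category map
  hier <- with_stream_seed(seed, "hierarchy", {
    h <- c(categories,
           sample(categories, n_pathways - n_level2_categories,
                  replace = TRUE))
    setNames(sample(h), pathways)
  })
  list(reference = ref, hierarchy = hier, covered = covered)
}
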