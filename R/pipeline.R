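# Fixture bundle, configuration and the end-to-end pipeline -------------------

#' Write a complete synthetic study bundle to disk
#'
#' Generates every input the pipeline reads — trial observables (CSV),
#' physicochemical profiles (CSV), the gut-community shared/taxonomy/
#' metadata TSVs with a planted waste-diet succession, and a function
#' reference with hierarchy map — plus a README manifest. Deterministic
#' given the seed. The community design mirrors the study layout: an
#' initial population (INI) plus three diets sampled every few days over
#' three replicate guts, 36 samples in total.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param design A [trial_design()].
#' @param params Per-diet [growth_params()] list.
#' @param comm_spec A [community_spec()].
#' @param obs_noise_cv Observation noise for the trial tables.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture_bundle <- function(dir, seed = 1L, design = trial_design(),
                                params = default_diet_params(),
                                comm_spec = community_spec(),
                                obs_noise_cv = 0.02) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L) stop("unwritable path: ", dir)
  paths <- list(
    observations = file.path(dir, "observations.csv"),
    feeding_log = file.path(dir, "feeding_log.csv"),
    residues = file.path(dir, "residues.csv"),
    pupae = file.path(dir, "pupae.csv"),
    physicochemical = file.path(dir, "physicochemical.csv"),
    shared = file.path(dir, "community.shared"),
    taxonomy = file.path(dir, "community.taxonomy.tsv"),
    metadata = file.path(dir, "community.metadata.tsv"),
    reference = file.path(dir, "function_reference.tsv"),
    hierarchy = file.path(dir, "pathway_hierarchy.tsv"),
    readme = file.path(dir, "README.txt"))

  trial <- simulate_trial(design, params, seed = seed,
                          obs_noise_cv = obs_noise_cv)
  wcsv <- function(df, p) write.table(df, p, sep = ",", quote = FALSE,
                                      row.names = FALSE)
  wcsv(trial$observations, paths$observations)
  wcsv(trial$feeding_log, paths$feeding_log)
  wcsv(trial$residues, paths$residues)
  wcsv(trial$pupae, paths$pupae)
  wcsv(simulate_substrate_profiles(seed = seed), paths$physicochemical)

  md <- fixture_community_metadata(design)
  comm <- simulate_communities(comm_spec, md, seed = seed)
  write_abundance_table(comm, paths$shared, paths$taxonomy, paths$metadata)

  ref <- simulate_function_reference(n_taxa = comm_spec$n_taxa, seed = seed)
  write.table(data.frame(taxon = rownames(ref$reference),
                         as.data.frame(ref$reference, check.names = FALSE),
                         check.names = FALSE),
              paths$reference, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pathway = names(ref$hierarchy),
                         category = unname(ref$hierarchy)),
              paths$hierarchy, sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(c(
    "Synthetic black soldier fly feeding-trial bundle",
    paste0("seed: ", seed),
    paste0("diets: ", paste(design$diets, collapse = ", ")),
    paste0("boxes per diet: ", design$boxes_per_diet),
    paste0("larvae per box: ", design$larvae_per_box),
    "files:",
    paste0("  ", basename(unlist(paths)))), paths$readme)
  invisible(paths)
}

fixture_community_metadata <- function(design = trial_design()) {
  rows <- list(data.frame(diet = "INI", day = 0, replicate = 1:3))
  days_for <- function(diet) {
    end <- design$end_day_per_diet[[diet]]
    unique(c(seq(2, end, by = 6), end))
  }
  for (diet in design$diets)
    for (d in days_for(diet))
      rows[[length(rows) + 1L]] <- data.frame(diet = diet, day = d,
                                              replicate = 1:3)
  md <- do.call(rbind, rows)
  md$sample <- sprintf("%s_d%02d_r%d", md$diet, md$day, md$replicate)
  md[, c("sample", "diet", "day", "replicate")]
}

#' Pipeline configuration
#'
#' Validated configuration with every default equal to the study-stated
#' setting where one exists: Bray-Curtis distances, 1000 permutations,
#' Bonferroni adjustment, two NMDS dimensions, prevalence filter of count
#' >= 4 in >= 10% of samples, and a 1% indicator display threshold.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    subsample_depths = list("min", 2000, 4000),
    min_count = 4, min_sample_frac = 0.10,
    n_perm = 1000L, alpha = 0.05, p_adjust = "bonferroni",
    nmds_k = 2L, nmds_n_starts = 20L, nmds_tol = 1e-6,
    kw_alpha = 0.05, lda_threshold = 2.0, lda_n_boot = 30L,
    indicator_n_perm = 999L, report_min_rel_abund = 0.01,
    gap_k_range = 1:8, gap_B = 50L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_count > 0, cfg$min_sample_frac > 0,
            cfg$min_sample_frac <= 1, cfg$n_perm >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$nmds_k >= 1,
            cfg$report_min_rel_abund >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override the defaults.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a study bundle
#'
#' Reads a bundle written by [make_fixture_bundle()] (or real data in the
#' same layout) and runs every stage: per-box mass budgets and
#' bioconversion indices with diet-level comparisons; endpoint summaries;
#' PCA, loading k-means, hierarchical clustering and gap statistic of the
#' physicochemical profiles; rarefaction (with Mantel stability checks
#' across subsampling depths), prevalence filtering, alpha diversity with
#' group tests, Bray-Curtis NMDS and PERMANOVA; the indicator-species
#' consensus; and the functional projection with a category-level
#' PERMANOVA.
#'
#' @param in_dir Bundle directory.
#' @param out_dir Optional output directory for [write_results()].
#' @param config A [pipeline_config()].
#' @param stages Character vector selecting stages (default all of
#'   `"indices"`, `"multivariate"`, `"community"`, `"indicators"`,
#'   `"functions"`).
#' @param overwrite Passed to [write_results()].
#' @return List of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(in_dir, out_dir = NULL, config = pipeline_config(),
                         stages = c("indices", "multivariate", "community",
                                    "indicators", "functions"),
                         overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  res <- list(config = config)

  if ("indices" %in% stages) {
    tr <- read_trial_tables(file.path(in_dir, "observations.csv"),
                            file.path(in_dir, "feeding_log.csv"),
                            file.path(in_dir, "residues.csv"),
                            file.path(in_dir, "pupae.csv"))
    boxes <- unique(tr$observations$box)
    idx <- do.call(rbind, lapply(boxes, function(b) {
      bd <- build_mass_budget(tr$observations, tr$feeding_log, tr$residues,
                              b, pupae = tr$pupae)
      ix <- compute_indices(bd)
      data.frame(box = b,
                 diet = tr$observations$diet[match(b, tr$observations$box)],
                 GR = ix$GR, SR = ix$SR, CI = ix$CI, WRI = ix$WRI,
                 AD = ix$AD, ECI = ix$ECI, ECD = ix$ECD)
    }))
    res$indices <- idx
    res$index_summary <- summarize_indices(idx, alpha = config$alpha)
    res$endpoints <- endpoint_summary(tr$observations, tr$pupae)
  }

  if ("multivariate" %in% stages) {
    chem <- read.csv(file.path(in_dir, "physicochemical.csv"),
                     stringsAsFactors = FALSE)
    vars <- setdiff(names(chem), c("sample_id", "group", "diet", "phase"))
    m <- as.matrix(chem[, vars])
    rownames(m) <- chem$sample_id
    pc <- pca(m)
    res$pca <- pc
    res$variable_clusters <- kmeans_variables(pc$loadings, k = 3L,
                                              seed = seed)
    res$sample_clusters <- hierarchical_cluster(m, k = 6L)
    res$gap <- gap_statistic(m, k_range = config$gap_k_range,
                             B_references = config$gap_B, seed = seed)
  }

  if (any(c("community", "indicators", "functions") %in% stages)) {
    tab <- read_abundance_table(file.path(in_dir, "community.shared"),
                                file.path(in_dir, "community.taxonomy.tsv"),
                                file.path(in_dir, "community.metadata.tsv"))
    depths <- lapply(config$subsample_depths, function(d)
      if (identical(d, "min")) min(rowSums(tab$counts)) else as.numeric(d))
    rar <- rarefy(tab, depth = depths[[1L]], seed = seed)
    filt <- prevalence_filter(rar, min_count = config$min_count,
                              min_sample_frac = config$min_sample_frac)
    res$table_rarefied <- filt
  }

  if ("community" %in% stages) {
    if (length(depths) > 1L) {
      mats <- lapply(depths, function(d)
        bray_curtis(suppressWarnings(rarefy(tab, depth = d, seed = seed))))
      pairs <- combn(length(mats), 2L, simplify = FALSE)
      res$mantel_stability <- do.call(rbind, lapply(pairs, function(pr) {
        common <- intersect(rownames(mats[[pr[1L]]]),
                            rownames(mats[[pr[2L]]]))
        mt <- mantel(mats[[pr[1L]]][common, common],
                     mats[[pr[2L]]][common, common],
                     n_perm = config$n_perm, seed = seed)
        data.frame(depth1 = depths[[pr[1L]]], depth2 = depths[[pr[2L]]],
                   n_common = length(common), r = mt$statistic,
                   p = mt$p_value)
      }))
    }
    res$alpha <- alpha_diversity(filt)
    res$alpha_tests <- alpha_group_tests(res$alpha$H, res$alpha$diet)
    res$bray <- bray_curtis(filt)
    res$nmds <- nmds(res$bray, k = config$nmds_k,
                     n_starts = config$nmds_n_starts, tol = config$nmds_tol,
                     seed = seed)
    md <- filt$metadata
    res$permanova_diet <- permanova(res$bray, md$diet, n_perm = config$n_perm,
                                    seed = seed, pairwise = TRUE,
                                    p_adjust = config$p_adjust)
    res$permanova_day <- permanova(res$bray, paste0("d", md$day),
                                   n_perm = config$n_perm, seed = seed)
    res$permanova_diet_day <- permanova(res$bray,
                                        paste(md$diet, md$day, sep = "."),
                                        n_perm = config$n_perm, seed = seed)
  }

  if ("indicators" %in% stages) {
    md <- res$table_rarefied$metadata
    lf <- lda_effect_size(res$table_rarefied, md$diet,
                          kw_alpha = config$kw_alpha,
                          lda_threshold = config$lda_threshold,
                          n_boot = config$lda_n_boot, seed = seed)
    iv <- indval_multipattern(res$table_rarefied, md$diet,
                              n_perm = config$indicator_n_perm, seed = seed)
    res$indicators <- consensus_indicators(
      lf, iv, res$table_rarefied, indval_alpha = config$alpha,
      report_min_rel_abund = config$report_min_rel_abund)
  }

  if ("functions" %in% stages) {
    ref_df <- read.table(file.path(in_dir, "function_reference.tsv"),
                         header = TRUE, sep = "\t", check.names = FALSE)
    ref <- as.matrix(ref_df[, -1, drop = FALSE])
    rownames(ref) <- ref_df$taxon
    hier_df <- read.table(file.path(in_dir, "pathway_hierarchy.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    hier <- setNames(hier_df$category, hier_df$pathway)
    prof <- suppressWarnings(project_functions(tab, ref))
    res$functions <- aggregate_hierarchy(prof, hier)
    ok <- colnames(res$functions$profile)[
      colSums(is.na(res$functions$profile)) == 0]
    fm <- t(res$functions$profile[, ok, drop = FALSE])
    md <- tab$metadata[ok, , drop = FALSE]
    res$permanova_functions <- permanova(bray_curtis(fm), md$diet,
                                         n_perm = config$n_perm, seed = seed)
  }

  res <- structure(res, class = "pipeline_result")
  if (!is.null(out_dir)) write_results(res, out_dir, overwrite = overwrite)
  res
}

# Table-1-style per-diet mean +/- sd with Tukey letters per index
summarize_indices <- function(idx, alpha = 0.05) {
  out <- list()
  for (v in c("GR", "SR", "CI", "WRI", "AD", "ECI", "ECD")) {
    vals <- idx[[v]]
    ok <- !is.na(vals)
    letters <- tryCatch(
      compare_groups(vals[ok], idx$diet[ok], "tukey_hsd",
                     alpha = alpha)$letters,
      error = function(e) NULL)
    for (diet in unique(idx$diet)) {
      x <- vals[idx$diet == diet]
      out[[paste(v, diet)]] <- data.frame(
        index = v, diet = diet, mean = mean(x, na.rm = TRUE),
        sd = if (sum(!is.na(x)) >= 2L) sd(x, na.rm = TRUE) else NA_real_,
        letter = if (!is.null(letters) && diet %in% names(letters))
          letters[[diet]] else NA_character_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write pipeline results as report files
#'
#' Writes the tables of every stage present in `results` (bioconversion
#' index summary, endpoints, diversity, ordination coordinates, test
#' results, indicator table, function profiles, distance matrix) plus a
#' YAML run manifest recording the seed, configuration and output
#' checksums.
#'
#' @param results A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow overwriting existing files.
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(results, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    if (file.exists(p) && !overwrite)
      stop("output exists (use overwrite = TRUE): ", p)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  r <- results
  if (!is.null(r$indices)) put(round_df(r$indices, 1), "indices_per_box.tsv")
  if (!is.null(r$index_summary))
    put(round_df(r$index_summary, 1), "index_summary.tsv")
  if (!is.null(r$endpoints)) put(round_df(r$endpoints, 3), "endpoints.tsv")
  if (!is.null(r$pca)) {
    put(data.frame(sample = rownames(r$pca$scores),
                   round(r$pca$scores[, 1:2], 4)), "pca_scores.tsv")
    put(data.frame(variable = rownames(r$pca$loadings),
                   round(r$pca$loadings[, 1:2], 4),
                   cluster = r$variable_clusters$assignments[
                     rownames(r$pca$loadings)]), "pca_loadings.tsv")
  }
  if (!is.null(r$gap)) put(round_df(r$gap$table, 4), "gap_statistic.tsv")
  if (!is.null(r$sample_clusters))
    put(data.frame(sample = names(r$sample_clusters$assignments),
                   cluster = r$sample_clusters$assignments),
        "sample_clusters.tsv")
  if (!is.null(r$alpha)) put(round_df(r$alpha, 4), "alpha_diversity.tsv")
  if (!is.null(r$alpha_tests))
    put(round_df(r$alpha_tests, 4), "alpha_tests.tsv")
  if (!is.null(r$mantel_stability))
    put(round_df(r$mantel_stability, 4), "mantel_stability.tsv")
  if (!is.null(r$bray)) {
    p <- file.path(out_dir, "bray_curtis.tsv")
    if (file.exists(p) && !overwrite) stop("output exists: ", p)
    write_dist(round(unclass(r$bray), 6), p)
    written <- c(written, p)
  }
  if (!is.null(r$nmds))
    put(data.frame(sample = rownames(r$nmds$points),
                   round(r$nmds$points, 4), stress = round(r$nmds$stress, 4)),
        "nmds_coordinates.tsv")
  if (!is.null(r$permanova_diet)) {
    pv <- rbind(
      data.frame(term = "diet", F = r$permanova_diet$statistic,
                 R2 = r$permanova_diet$R2, p = r$permanova_diet$p_value),
      if (!is.null(r$permanova_day))
        data.frame(term = "day", F = r$permanova_day$statistic,
                   R2 = r$permanova_day$R2, p = r$permanova_day$p_value),
      if (!is.null(r$permanova_diet_day))
        data.frame(term = "diet.day", F = r$permanova_diet_day$statistic,
                   R2 = r$permanova_diet_day$R2,
                   p = r$permanova_diet_day$p_value),
      if (!is.null(r$permanova_functions))
        data.frame(term = "functions_diet",
                   F = r$permanova_functions$statistic,
                   R2 = r$permanova_functions$R2,
                   p = r$permanova_functions$p_value))
    put(round_df(pv, 4), "permanova.tsv")
    if (!is.null(r$permanova_diet$pairwise))
      put(round_df(r$permanova_diet$pairwise, 4), "permanova_pairwise.tsv")
  }
  if (!is.null(r$indicators))
    put(round_df(r$indicators, 4), "indicators.tsv")
  if (!is.null(r$functions)) {
    put(data.frame(category = rownames(r$functions$profile),
                   round(r$functions$profile, 5)), "functions_level2.tsv")
    put(data.frame(sample = names(r$functions$fraction_assigned),
                   fraction_assigned =
                     round(r$functions$fraction_assigned, 4)),
        "fraction_assigned.tsv")
  }
  manifest <- file.path(out_dir, "manifest.yaml")
  cfg <- unclass(r$config)
  cfg$gap_k_range <- as.integer(cfg$gap_k_range)
  yaml::write_yaml(list(
    package = "hermetia",
    version = as.character(utils::packageVersion("hermetia")),
    seed = cfg$seed,
    config = cfg,
    files = as.list(setNames(unname(tools::md5sum(written)),
                             basename(written)))), manifest)
  invisible(manifest)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
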