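# Taxon-to-function projection -------------------------------------------------

#' Project community composition onto functional pathway profiles
#'
#' Linear stand-in for reference-based metagenome imputation: each sample's
#' relative abundances are restricted to the taxa covered by the reference,
#' renormalized, and multiplied through the taxon-by-pathway reference
#' matrix; the resulting pathway vector is renormalized to sum to one. The
#' fraction of reads belonging to covered taxa is reported per sample (the
#' "assignable" fraction). A sample with zero covered reads gets an
#' all-missing profile and fraction 0, with a warning.
#'
#' @param x An [abundance_table()] or count matrix (samples x taxa).
#' @param reference Taxa x pathways matrix with rows indexed by taxon id.
#' @param covered Character vector of covered taxon ids; defaults to taxa
#'   with a nonzero reference row.
#' @return List of class `functional_profile`: `profile` (pathways x
#'   samples), `fraction_assigned` (named per sample), `level`.
#' @export
project_functions <- function(x, reference, covered = NULL) {
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  reference <- as.matrix(reference)
  if (is.null(rownames(reference)))
    stop("reference rows must be indexed by taxon id")
  if (is.null(covered))
    covered <- rownames(reference)[rowSums(reference) > 0]
  covered <- intersect(covered, colnames(m))
  profile <- matrix(NA_real_, ncol(reference), nrow(m),
                    dimnames = list(colnames(reference), rownames(m)))
  frac <- setNames(numeric(nrow(m)), rownames(m))
  for (s in rownames(m)) {
    tot <- sum(m[s, ])
    cov_reads <- sum(m[s, covered])
    frac[s] <- if (tot > 0) cov_reads / tot else 0
    if (cov_reads == 0) next
    w <- m[s, covered] / cov_reads
    pr <- as.vector(t(reference[covered, , drop = FALSE]) %*% w)
    if (sum(pr) > 0) profile[, s] <- pr / sum(pr)
  }
  if (any(frac == 0))
    warning("sample(s) with zero covered reads: ",
            paste(names(frac)[frac == 0], collapse = ", "))
  structure(list(profile = profile, fraction_assigned = frac,
                 level = "pathway"),
            class = "functional_profile")
}

#' Aggregate a functional profile up a pathway hierarchy
#'
#' Sums pathway values into their parent categories (e.g. level 2 of a
#' KEGG-style hierarchy); per-sample sums are preserved. Every pathway in
#' the profile must be mapped.
#'
#' @param profile A `functional_profile` from [project_functions()].
#' @param hierarchy Named character vector mapping pathway -> category.
#' @return A `functional_profile` at category level.
#' @export
aggregate_hierarchy <- function(profile, hierarchy) {
  stopifnot(inherits(profile, "functional_profile"))
  pw <- rownames(profile$profile)
  unmapped <- setdiff(pw, names(hierarchy))
  if (length(unmapped))
    stop("unmapped pathway(s): ", paste(unmapped, collapse = ", "))
  agg <- rowsum(profile$profile, group = hierarchy[pw])
  structure(list(profile = agg,
                 fraction_assigned = profile$fraction_assigned,
                 level = "category"),
            class = "functional_profile")
}
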