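# OTU-table container and community statistics --------------------------------

#' Construct a sample-by-taxon abundance table
#'
#' Container for 16S-style OTU/ASV counts: a non-negative integer matrix
#' (samples in rows, taxa in columns), per-taxon taxonomy lineage strings
#' (semicolon-delimited ranks) and per-sample metadata (diet, day,
#' replicate).
#'
#' @param counts Numeric matrix, samples x taxa; non-negative integers with
#'   unique row (sample) and column (taxon) names.
#' @param taxonomy Optional named character vector of lineage strings, one
#'   per taxon.
#' @param metadata Optional data frame with one row per sample (rownames or
#'   a `sample` column matching the count rows).
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (nrow(counts) > 0L &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop("counts must have unique sample (row) names")
  if (ncol(counts) > 0L &&
      (is.null(colnames(counts)) || anyDuplicated(colnames(counts))))
    stop("counts must have unique taxon (column) names")
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[colnames(counts)]
    names(taxonomy) <- colnames(counts)
  }
  if (!is.null(metadata)) {
    if (!is.null(metadata$sample)) rownames(metadata) <- metadata$sample
    missing <- setdiff(rownames(counts), rownames(metadata))
    if (length(missing))
      stop("metadata missing for samples: ", paste(missing, collapse = ", "))
    metadata <- metadata[rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

subset_abundance <- function(x, samples = NULL, taxa = NULL) {
  cc <- x$counts
  if (!is.null(samples)) cc <- cc[samples, , drop = FALSE]
  if (!is.null(taxa)) cc <- cc[, taxa, drop = FALSE]
  abundance_table(cc,
                  taxonomy = if (!is.null(x$taxonomy))
                    x$taxonomy[colnames(cc)] else NULL,
                  metadata = if (!is.null(x$metadata))
                    x$metadata[rownames(cc), , drop = FALSE] else NULL)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's counts to `depth` reads without replacement
#' (multivariate hypergeometric), the mothur-style normalization. Samples
#' whose total is below `depth` are dropped with a warning. With
#' `mode = "curve"`, returns the mean richness observed at a grid of depths
#' (a rarefaction curve) instead.
#'
#' @param x An [abundance_table()] (or bare count matrix).
#' @param depth Target depth (> 0), or `"min"` for the smallest sample sum.
#' @param seed Integer seed.
#' @param mode `"once"` for a rarefied table, `"curve"` for rarefaction
#'   curves.
#' @param reps Replicate draws per depth point for the curve.
#' @param curve_points Number of depth grid points for the curve.
#' @return Rarefied `abundance_table`, or a data frame
#'   (`sample`, `depth`, `richness`) in curve mode.
#' @export
rarefy <- function(x, depth = "min", seed = 1L, mode = c("once", "curve"),
                   reps = 10L, curve_points = 12L) {
  mode <- match.arg(mode)
  tab <- if (inherits(x, "abundance_table")) x else abundance_table(x)
  totals <- rowSums(tab$counts)
  if (identical(depth, "min")) depth <- min(totals)
  if (depth <= 0) stop("depth must be positive")

  draw <- function(counts, d) {
    # without-replacement draw of d reads from a count vector
    tot <- sum(counts)
    idx <- sort.int(sample.int(tot, d))
    hit <- findInterval(idx, cumsum(counts), left.open = TRUE) + 1L
    tabulate(hit, nbins = length(counts))
  }

  if (mode == "curve") {
    grid <- unique(round(seq(1, depth, length.out = curve_points)))
    out <- list()
    for (s in rownames(tab$counts)) {
      if (totals[s] < depth) next
      rich <- with_stream_seed(seed, paste0("curve/", s), {
        vapply(grid, function(d)
          mean(vapply(seq_len(reps), function(i)
            sum(draw(tab$counts[s, ], d) > 0), 0)), 0)
      })
      out[[s]] <- data.frame(sample = s, depth = grid, richness = rich)
    }
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }

  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(names(totals)[!keep], collapse = ", "))
  cc <- tab$counts[keep, , drop = FALSE]
  for (s in rownames(cc)) {
    if (sum(cc[s, ]) == depth) next   # already at depth: keep as is
    cc[s, ] <- with_stream_seed(seed, paste0("rarefy/", s),
                                draw(cc[s, ], depth))
  }
  subset_abundance(structure(list(counts = cc, taxonomy = tab$taxonomy,
                                  metadata = tab$metadata),
                             class = "abundance_table"))
}

#' Remove sparse taxa by abundance-prevalence filtering
#'
#' Keeps taxa with a count of at least `min_count` in at least
#' `ceiling(min_sample_frac x n_samples)` samples (default: count >= 4 in
#' >= 10% of samples). The alternative reading of "prevalence four"
#' (present, at any count, in at least four samples) is available via
#' `rule = "n_samples"`.
#'
#' @param x An [abundance_table()].
#' @param min_count Minimum per-sample count for a taxon to score as
#'   present (rule `"count_in_frac"`).
#' @param min_sample_frac Minimum fraction of samples.
#' @param rule `"count_in_frac"` (default) or `"n_samples"` (present in
#'   >= `min_count` samples regardless of abundance).
#' @return Filtered `abundance_table`.
#' @export
prevalence_filter <- function(x, min_count = 4, min_sample_frac = 0.10,
                              rule = c("count_in_frac", "n_samples")) {
  rule <- match.arg(rule)
  tab <- if (inherits(x, "abundance_table")) x else abundance_table(x)
  if (min_count <= 0 || min_sample_frac <= 0)
    stop("thresholds must be positive")
  if (ncol(tab$counts) == 0L) return(tab)
  if (rule == "count_in_frac") {
    need <- ceiling(min_sample_frac * nrow(tab$counts))
    keep <- colSums(tab$counts >= min_count) >= need
  } else {
    keep <- colSums(tab$counts > 0) >= min_count
  }
  subset_abundance(tab, taxa = colnames(tab$counts)[keep])
}

#' Shannon diversity, Pielou evenness and observed richness
#'
#' `H' = -sum p_i ln p_i` over taxa with positive counts,
#' `J = H'/ln(S)` with `S` the number of positive taxa (J is defined as 0
#' for a single-taxon sample), both on the natural logarithm.
#'
#' @param counts Non-negative count (or relative abundance) vector.
#' @return List with `H`, `J`, `S`.
#' @examples
#' shannon_evenness(c(25, 25, 25, 25))$H  # log(4)
#' @export
shannon_evenness <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero count vector")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  S <- length(p)
  list(H = H, J = if (S > 1L) H / log(S) else 0, S = S)
}

#' Per-sample alpha diversity table
#'
#' @param x An [abundance_table()].
#' @return Data frame: `sample`, `H`, `J`, `S` plus any sample metadata.
#' @export
alpha_diversity <- function(x) {
  tab <- if (inherits(x, "abundance_table")) x else abundance_table(x)
  res <- t(vapply(rownames(tab$counts), function(s)
    unlist(shannon_evenness(tab$counts[s, ])), c(H = 0, J = 0, S = 0)))
  out <- data.frame(sample = rownames(tab$counts), res, row.names = NULL)
  if (!is.null(tab$metadata))
    out <- cbind(out, tab$metadata[out$sample,
                                   setdiff(names(tab$metadata), "sample"),
                                   drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between all sample pairs,
#' on raw counts or after total-sum scaling to relative abundances.
#'
#' @param x An [abundance_table()] or numeric sample-by-taxon matrix.
#' @param input `"counts"` (as-is) or `"relative"` (rows scaled to sum 1).
#' @return Symmetric zero-diagonal `matrix` of class `dist_matrix` with
#'   sample names.
#' @examples
#' m <- rbind(a = c(2, 0, 1), b = c(1, 1, 0))
#' bray_curtis(m)["a", "b"]  # 0.6
#' @export
bray_curtis <- function(x, input = c("counts", "relative")) {
  input <- match.arg(input)
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  if (input == "relative") m <- m / rowSums(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    rest <- m[(i + 1L):n, , drop = FALSE]
    num <- rowSums(abs(sweep(rest, 2L, xi)))
    den <- rowSums(sweep(rest, 2L, xi, "+"))
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- num / den
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  structure(d, class = c("dist_matrix", "matrix"))
}
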