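# Interchange formats ----------------------------------------------------------
#
# Matrix-like outputs use tab-separated files in the mothur-adjacent dialect
# (shared/taxonomy/metadata TSV); trial observables use CSV. Sample identity
# is always the join key; row order never carries meaning.

#' Write an abundance table as shared-style + taxonomy + metadata TSV
#'
#' @param x An [abundance_table()].
#' @param shared_path,taxonomy_path,metadata_path Output file paths
#'   (`NULL` skips the file).
#' @param label OTU-clustering label for the shared file's first column.
#' @return Invisibly, the shared path.
#' @export
write_abundance_table <- function(x, shared_path, taxonomy_path = NULL,
                                  metadata_path = NULL, label = "0.03") {
  stopifnot(inherits(x, "abundance_table"))
  shared <- data.frame(label = label, Group = rownames(x$counts),
                       numOtus = ncol(x$counts),
                       as.data.frame(x$counts, check.names = FALSE),
                       check.names = FALSE)
  write.table(shared, shared_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    tax <- data.frame(OTU = colnames(x$counts),
                      Size = colSums(x$counts),
                      Taxonomy = unname(x$taxonomy[colnames(x$counts)]))
    write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(metadata_path) && !is.null(x$metadata)) {
    md <- x$metadata
    if (is.null(md$sample)) md <- cbind(sample = rownames(md), md)
    write.table(md, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(shared_path)
}

#' Read an abundance table from shared-style + taxonomy + metadata TSV
#'
#' Samples are intersected across the three files; samples missing from the
#' metadata are dropped with a warning. Counts must parse as non-negative
#' integers (the offending cell is named otherwise).
#'
#' @param shared_path Shared-style TSV (`label`, `Group`, `numOtus`,
#'   one column per OTU).
#' @param taxonomy_path Optional taxonomy TSV (`OTU`, `Size`, `Taxonomy`).
#' @param metadata_path Optional metadata TSV with a `sample` column.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(shared_path, taxonomy_path = NULL,
                                 metadata_path = NULL) {
  sh <- read.table(shared_path, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Group" %in% names(sh)) stop("shared file lacks a Group column")
  if (anyDuplicated(sh$Group))
    stop("duplicate sample ids in shared file")
  taxa_cols <- setdiff(names(sh), c("label", "Group", "numOtus"))
  counts <- as.matrix(sh[, taxa_cols, drop = FALSE])
  rownames(counts) <- sh$Group
  bad <- which(is.na(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at sample '",
         rownames(counts)[bad[1L, 1L]], "', taxon '",
         taxa_cols[bad[1L, 2L]], "'")
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- read.table(taxonomy_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    taxonomy <- setNames(tax$Taxonomy, tax$OTU)
  }
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read.table(metadata_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (!"sample" %in% names(metadata))
      stop("metadata lacks a sample column")
    keep <- rownames(counts) %in% metadata$sample
    if (!all(keep)) {
      warning("dropping sample(s) without metadata: ",
              paste(rownames(counts)[!keep], collapse = ", "))
      counts <- counts[keep, , drop = FALSE]
    }
    rownames(metadata) <- metadata$sample
    metadata <- metadata[rownames(counts), , drop = FALSE]
  }
  abundance_table(counts, taxonomy = taxonomy, metadata = metadata)
}

#' Read and validate feeding-trial tables
#'
#' Reads the observation, feeding-log and residue CSVs, checks the required
#' columns, sorts records by day within box (out-of-order input is sorted
#' with a message) and validates dry fractions.
#'
#' @param observations_path,feeding_path,residues_path CSV paths.
#' @param pupae_path Optional pupae CSV.
#' @return List: `observations`, `feeding_log`, `residues`, `pupae`.
#' @export
read_trial_tables <- function(observations_path, feeding_path, residues_path,
                              pupae_path = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " missing column(s): ", paste(miss, collapse = ", "))
    df
  }
  ob <- need(read.csv(observations_path, stringsAsFactors = FALSE),
             c("box", "diet", "day", "n_alive", "n_pupae", "mean_fresh_mg",
               "mean_dry_mg"), "observations")
  fl <- need(read.csv(feeding_path, stringsAsFactors = FALSE),
             c("box", "day", "offered_fresh_mg", "dry_frac"), "feeding log")
  rs <- need(read.csv(residues_path, stringsAsFactors = FALSE),
             c("box", "day", "residue_dry_mg"), "residues")
  if (any(fl$dry_frac > 1 | fl$dry_frac < 0))
    stop("dry fractions must lie in [0, 1]")
  if (is.unsorted(ob$day)) message("observations re-sorted by box and day")
  ob <- ob[order(ob$box, ob$day), , drop = FALSE]
  pp <- NULL
  if (!is.null(pupae_path) && file.exists(pupae_path))
    pp <- read.csv(pupae_path, stringsAsFactors = FALSE)
  list(observations = ob, feeding_log = fl, residues = rs, pupae = pp)
}

#' Write / read a labeled square distance matrix TSV
#'
#' @param d Square symmetric matrix with sample names.
#' @param path File path.
#' @return `write_dist` returns the path invisibly; `read_dist` returns a
#'   `dist_matrix`.
#' @export
write_dist <- function(d, path) {
  write.table(data.frame(sample = rownames(d), as.data.frame(unclass(d)),
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist
#' @export
read_dist <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  as_dist_matrix(m)
}
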