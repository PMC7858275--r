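# Permutation tests on distance matrices --------------------------------------

# distance-based one-way sum-of-squares decomposition
permanova_F <- function(d2, groups) {
  n <- length(groups)
  lev <- unique(groups)
  a <- length(lev)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_within <- ss_within +
      sum(d2[idx, idx][lower.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# all distinct orderings of a label multiset (small n only)
multiset_permutations <- function(labels, limit = 200000L) {
  lev <- unique(labels)
  counts <- table(factor(labels, levels = lev))
  total <- factorial(length(labels)) / prod(factorial(counts))
  if (total > limit) stop("too many exhaustive permutations (", total, ")")
  rec <- function(remaining) {
    if (sum(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (l in names(remaining)[remaining > 0L]) {
      r2 <- remaining; r2[l] <- r2[l] - 1L
      for (tail in rec(r2)) out[[length(out) + 1L]] <- c(l, tail)
    }
    out
  }
  do.call(rbind, rec(setNames(as.integer(counts), names(counts))))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F from the distance-based sum-of-squares decomposition
#' (`SS_total = sum of squared dissimilarities / n`, with the within-group
#' analogue per group), with a free permutation of sample labels as null.
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`; with
#' `permutations = "exhaustive"` all distinct label arrangements are
#' enumerated and `p = #{F >= F_obs} / N`. Optionally runs all pairwise
#' two-group tests with Bonferroni adjustment.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param pairwise If `TRUE`, also return the pairwise table.
#' @param p_adjust Adjustment method for pairwise p-values.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return List of class `permanova_result`: `statistic` (pseudo-F), `R2`,
#'   `p_value`, `n_permutations`, and optionally `pairwise` (data frame).
#' @export
permanova <- function(d, groups, n_perm = 1000L, seed = 1L, pairwise = FALSE,
                      p_adjust = "bonferroni",
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  d <- as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two samples")
  d2 <- d^2
  obs <- permanova_F(d2, groups)
  if (permutations == "exhaustive") {
    perms <- multiset_permutations(groups)
    Fs <- apply(perms, 1L, function(g) permanova_F(d2, g)$F)
    p <- mean(Fs >= obs$F - 1e-12)
    n_used <- nrow(perms)
  } else {
    Fs <- with_stream_seed(seed, "permanova", vapply(seq_len(n_perm),
      function(i) permanova_F(d2, sample(groups))$F, 0))
    p <- (sum(Fs >= obs$F - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  res <- list(statistic = obs$F, R2 = obs$R2, p_value = p,
              n_permutations = n_used)
  if (pairwise) {
    lev <- names(tab)
    rows <- list()
    for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
      idx <- groups %in% c(lev[i], lev[j])
      sub <- permanova(d[idx, idx], groups[idx], n_perm = n_perm,
                       seed = stream_seed(seed, paste0("pw/", i, "/", j)),
                       permutations = permutations)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j], F = sub$statistic, R2 = sub$R2,
        p = sub$p_value)
    }
    pw <- do.call(rbind, rows)
    pw$p_adj <- pmin(p.adjust(pw$p, method = p_adjust), 1)
    res$pairwise <- pw
  }
  structure(res, class = "permanova_result")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a null built by
#' permuting the sample order of the second matrix (rows and columns
#' jointly). One-sided upper-tail p-value with the `(x + 1)/(n + 1)` floor.
#'
#' @param d1,d2 Square symmetric matrices over the same samples, same order.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `mantel_result`: `statistic` (r), `p_value`,
#'   `n_permutations`.
#' @export
mantel <- function(d1, d2, n_perm = 1000L, seed = 1L) {
  d1 <- as_dist_matrix(d1); d2 <- as_dist_matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("dimension mismatch")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("sample ids of the two matrices do not match")
  low <- lower.tri(d1)
  r_obs <- cor(d1[low], d2[low])
  rs <- with_stream_seed(seed, "mantel", vapply(seq_len(n_perm), function(i) {
    p <- sample.int(nrow(d2))
    cor(d1[low], d2[p, p][low])
  }, 0))
  p <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = r_obs, p_value = p, n_permutations = n_perm),
            class = "mantel_result")
}

#' Alpha-diversity group tests
#'
#' Runs the full battery of diet/time group comparisons (ANOVA, pairwise
#' t with Bonferroni, Tukey HSD, Bartlett) on per-sample Shannon diversity,
#' delegating to [compare_groups()].
#'
#' @param H Numeric vector of per-sample diversity values.
#' @param groups Group label per sample.
#' @return Data frame with one row per method: `method`, `statistic`, `p`.
#' @export
alpha_group_tests <- function(H, groups) {
  methods <- c("anova", "pairwise_t_bonferroni", "tukey_hsd", "bartlett")
  do.call(rbind, lapply(methods, function(m) {
    r <- compare_groups(H, groups, method = m)
    data.frame(method = m,
               statistic = if (is.null(r$statistic)) NA_real_ else
                 as.numeric(r$statistic)[1],
               p = r$p_value)
  }))
}
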