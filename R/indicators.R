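# Indicator-species screens and their consensus -------------------------------

#' Kruskal-Wallis + discriminant effect-size screen (LEfSe-style)
#'
#' Biomarker screen in the spirit of LDA effect size: abundances are
#' total-sum scaled to per-mille, taxa are first filtered by a
#' Kruskal-Wallis test across classes at `kw_alpha`, and surviving taxa are
#' scored as the log10 of a bootstrap-averaged one-dimensional discriminant
#' effect (the largest absolute difference between class means of the
#' per-mille abundance, averaged over `n_boot` within-class bootstrap
#' resamples). A taxon is significant when its Kruskal-Wallis test passes
#' and its score reaches `lda_threshold`. Taxa that are constant across all
#' samples take the conventional p = 1 and are never scored.
#'
#' @param x An [abundance_table()] or count matrix (samples x taxa).
#' @param classes Class label per sample (>= 2 classes, each >= 3 samples).
#' @param kw_alpha Kruskal-Wallis screening level.
#' @param lda_threshold Log10 effect-size threshold for significance.
#' @param n_boot Bootstrap resamples for the effect size.
#' @param seed Integer seed.
#' @return Data frame: `taxon`, `kw_p`, `lda_score`, `class` (top class),
#'   `significant`.
#' @export
lda_effect_size <- function(x, classes, kw_alpha = 0.05, lda_threshold = 2.0,
                            n_boot = 30L, seed = 1L) {
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  classes <- factor(classes)
  stopifnot(length(classes) == nrow(m))
  if (nlevels(classes) < 2L) stop("need at least two classes")
  if (any(table(classes) < 3L)) stop("every class needs at least 3 samples")
  rs <- rowSums(m)
  rel <- m / ifelse(rs == 0, 1, rs) * 1000   # per-mille normalization

  idx_by_class <- split(seq_len(nrow(rel)), classes)
  boot_effect <- function(v) {
    effs <- vapply(seq_len(n_boot), function(b) {
      mns <- vapply(idx_by_class, function(ii)
        mean(v[sample(ii, length(ii), replace = TRUE)]), 0)
      max(dist(mns))
    }, 0)
    mean(effs)
  }

  res <- with_stream_seed(seed, "lefse", {
    do.call(rbind, lapply(colnames(rel), function(tx) {
      v <- rel[, tx]
      if (var(v) == 0) {
        return(data.frame(taxon = tx, kw_p = 1, lda_score = NA_real_,
                          class = NA_character_, significant = FALSE))
      }
      kw <- suppressWarnings(kruskal.test(v, classes))
      kw_p <- if (is.na(kw$p.value)) 1 else kw$p.value
      if (kw_p > kw_alpha) {
        return(data.frame(taxon = tx, kw_p = kw_p, lda_score = NA_real_,
                          class = NA_character_, significant = FALSE))
      }
      eff <- boot_effect(v)
      score <- log10(max(eff, 1e-6))
      top <- names(which.max(vapply(idx_by_class, function(ii)
        mean(v[ii]), 0)))
      data.frame(taxon = tx, kw_p = kw_p, lda_score = score, class = top,
                 significant = score >= lda_threshold)
    }))
  })
  rownames(res) <- NULL
  res
}

# IndVal.g statistics for every taxon and every candidate group set, given
# one label assignment; vectorized over taxa.
indval_stats <- function(rel, pres, groups, sets) {
  sizes <- table(groups)[rownames(rel_group_means(rel, groups))]
  gm <- rel_group_means(rel, groups)
  pc <- rowsum(pres, groups)
  tot <- colSums(gm)
  tot[tot == 0] <- Inf    # taxon absent everywhere: stat 0
  stats <- matrix(0, length(sets), ncol(rel),
                  dimnames = list(names(sets), colnames(rel)))
  for (i in seq_along(sets)) {
    S <- sets[[i]]
    A <- colSums(gm[S, , drop = FALSE]) / tot
    B <- colSums(pc[S, , drop = FALSE]) / sum(sizes[S])
    stats[i, ] <- sqrt(A * B)
  }
  stats
}

rel_group_means <- function(rel, groups) {
  rowsum(rel, groups) / as.vector(table(groups)[sort(unique(groups))])
}

#' Multi-level IndVal pattern analysis
#'
#' Group-size-corrected indicator value analysis (the IndVal.g statistic):
#' for a candidate group set `S`, specificity
#' `A = sum_{g in S} mean abundance in g / sum_h mean abundance in h`
#' uses per-group means of relative abundances (so group sizes do not bias
#' it), fidelity `B` is the fraction of `S`'s samples in which the taxon is
#' present (count > 0), and the statistic is `sqrt(A x B)`. Each taxon is
#' associated with its best set among all single groups and (optionally)
#' all non-trivial group combinations except the full set. The p-value
#' permutes sample labels, re-maximizing the taxon's statistic over the
#' candidate sets in each permutation:
#' `p = (#{perm max >= obs} + 1) / (n_perm + 1)` (or an exact enumeration
#' fraction with `permutations = "exhaustive"`).
#'
#' @param x An [abundance_table()] or count matrix.
#' @param groups Group label per sample.
#' @param allow_combinations Also consider group combinations.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param permutations `"random"` or `"exhaustive"` (small n only).
#' @return Data frame: `taxon`, `indval_stat`, `indval_p`, `group`
#'   (associated set, `+`-joined for combinations).
#' @export
indval_multipattern <- function(x, groups, allow_combinations = TRUE,
                                n_perm = 999L, seed = 1L,
                                permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  rs <- rowSums(m)
  rel <- m / ifelse(rs == 0, 1, rs)   # all-zero samples stay zero
  pres <- (m > 0) + 0

  sets <- lapply(lev, function(l) l)
  names(sets) <- lev
  if (allow_combinations && length(lev) > 2L) {
    for (sz in 2:(length(lev) - 1L)) {
      cmb <- combn(lev, sz, simplify = FALSE)
      for (S in cmb) sets[[paste(S, collapse = "+")]] <- S
    }
  }

  obs <- indval_stats(rel, pres, groups, sets)
  best <- apply(obs, 2L, which.max)
  stat <- obs[cbind(best, seq_len(ncol(obs)))]
  assoc <- rownames(obs)[best]

  if (permutations == "exhaustive") {
    perms <- multiset_permutations(groups)
    pm <- apply(perms, 1L, function(g)
      apply(indval_stats(rel, pres, g, sets), 2L, max))
    pm <- matrix(pm, ncol = nrow(perms))   # taxa x perms
    p <- rowMeans(pm >= matrix(stat, nrow(pm), ncol(pm)) - 1e-12)
  } else {
    exceed <- rep(0L, ncol(m))
    with_stream_seed(seed, "indval", {
      for (b in seq_len(n_perm)) {
        mx <- apply(indval_stats(rel, pres, sample(groups), sets), 2L, max)
        exceed <- exceed + (mx >= stat - 1e-12)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  data.frame(taxon = colnames(m), indval_stat = unname(stat),
             indval_p = unname(p), group = unname(assoc))
}

#' Consensus indicator species from the two screens
#'
#' A taxon is a consensus indicator when it is significant under the
#' effect-size screen ([lda_effect_size()]), significant under the IndVal
#' permutation test at `indval_alpha`, and both methods agree on the
#' associated group (for an IndVal group combination, the effect-size top
#' class must be a member of the combination). Records with mean relative
#' abundance below `report_min_rel_abund` are retained but flagged as below
#' the display threshold.
#'
#' @param lefse Result of [lda_effect_size()].
#' @param indval Result of [indval_multipattern()] over the same taxa.
#' @param x The underlying [abundance_table()] or count matrix (for mean
#'   relative abundances).
#' @param indval_alpha Significance level for the IndVal p-value.
#' @param report_min_rel_abund Display threshold on mean relative abundance.
#' @return Data frame: `taxon`, `kw_p`, `lda_score`, `lda_class`,
#'   `indval_stat`, `indval_p`, `indval_group`, `consensus`,
#'   `mean_rel_abund`, `below_display_threshold`.
#' @export
consensus_indicators <- function(lefse, indval, x, indval_alpha = 0.05,
                                 report_min_rel_abund = 0.01) {
  if (!setequal(lefse$taxon, indval$taxon))
    stop("taxon ids of the two screens do not match")
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  if (nrow(lefse) == 0L) {
    return(data.frame(taxon = character(), kw_p = double(),
                      lda_score = double(), lda_class = character(),
                      indval_stat = double(), indval_p = double(),
                      indval_group = character(), consensus = logical(),
                      mean_rel_abund = double(),
                      below_display_threshold = logical()))
  }
  iv <- indval[match(lefse$taxon, indval$taxon), ]
  rs <- rowSums(m)
  rel <- colMeans(m / ifelse(rs == 0, 1, rs))
  same_group <- mapply(function(cls, grp) {
    if (is.na(cls)) return(FALSE)
    cls %in% strsplit(grp, "+", fixed = TRUE)[[1]]
  }, lefse$class, iv$group)
  out <- data.frame(
    taxon = lefse$taxon, kw_p = lefse$kw_p, lda_score = lefse$lda_score,
    lda_class = lefse$class, indval_stat = iv$indval_stat,
    indval_p = iv$indval_p, indval_group = iv$group,
    consensus = lefse$significant & iv$indval_p <= indval_alpha & same_group,
    mean_rel_abund = unname(rel[lefse$taxon]))
  out$below_display_threshold <- out$mean_rel_abund < report_min_rel_abund
  out
}
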