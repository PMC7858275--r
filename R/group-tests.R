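# Diet-level group comparisons ------------------------------------------------

#' Compare a response across diet groups
#'
#' Thin, uniform front-end over the classical one-way tests used for
#' diet-level comparisons: one-way ANOVA, pairwise t-tests with Bonferroni
#' correction, Tukey's HSD (with a compact letter display), and Bartlett's
#' test of homogeneity of variances. Constant data across all groups yields
#' a flagged, undefined F rather than an error.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param method One of `"anova"`, `"pairwise_t_bonferroni"`, `"tukey_hsd"`,
#'   `"bartlett"`.
#' @param alpha Significance level for the Tukey letter display.
#' @return List with `method`, `statistic`, `p_value`, and for
#'   `tukey_hsd` additionally `pairwise` (the HSD table) and `letters`
#'   (named character vector; groups sharing a letter do not differ at
#'   `alpha`). For `pairwise_t_bonferroni`, `pairwise` holds the adjusted
#'   p-value matrix. `flags` names degeneracies.
#' @examples
#' compare_groups(c(1, 2, 1, 2, 8, 9), rep(c("a", "b", "c"), each = 2),
#'                method = "anova")$p_value
#' @export
compare_groups <- function(values, groups,
                           method = c("anova", "pairwise_t_bonferroni",
                                      "tukey_hsd", "bartlett"),
                           alpha = 0.05) {
  method <- match.arg(method)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  flags <- character()
  if (var(values) == 0) {
    # identical data everywhere: no between- or within-group variation
    return(list(method = method, statistic = 0, p_value = 1,
                flags = c(degenerate = "constant data across all groups")))
  }
  d <- data.frame(y = values, g = groups)
  if (method == "anova") {
    fit <- aov(y ~ g, data = d)
    s <- summary(fit)[[1]]
    list(method = method, statistic = s[["F value"]][1L],
         p_value = s[["Pr(>F)"]][1L], flags = flags)
  } else if (method == "pairwise_t_bonferroni") {
    pt <- pairwise.t.test(d$y, d$g, p.adjust.method = "bonferroni",
                          pool.sd = FALSE)
    list(method = method, statistic = NA_real_,
         p_value = min(pt$p.value, na.rm = TRUE), pairwise = pt$p.value,
         flags = flags)
  } else if (method == "tukey_hsd") {
    fit <- aov(y ~ g, data = d)
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    letters <- tukey_letters(tk[, "p adj"], levels(groups), alpha = alpha)
    list(method = method, statistic = summary(fit)[[1]][["F value"]][1L],
         p_value = min(tk[, "p adj"]), pairwise = tk, letters = letters,
         flags = flags)
  } else {
    bt <- bartlett.test(d$y, d$g)
    list(method = method, statistic = unname(bt$statistic),
         p_value = bt$p.value, flags = flags)
  }
}

# Compact letter display by insert-and-absorb: each group gets the set of
# letters of the cliques it belongs to; significant pairs never share one.
tukey_letters <- function(p_adj, group_levels, alpha = 0.05) {
  k <- length(group_levels)
  sig <- matrix(FALSE, k, k, dimnames = list(group_levels, group_levels))
  for (nm in names(p_adj)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% group_levels)) next
    s <- p_adj[[nm]] < alpha
    sig[pair[1L], pair[2L]] <- s
    sig[pair[2L], pair[1L]] <- s
  }
  # insert-and-absorb: split every letter column containing a significant
  # pair, then drop columns that became subsets of others
  columns <- list(group_levels)
  for (a in group_levels) for (b in group_levels) {
    if (a >= b || !sig[a, b]) next
    new_cols <- list()
    for (col in columns) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else new_cols <- c(new_cols, list(col))
    }
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[j] && all(new_cols[[i]] %in% new_cols[[j]]) &&
          (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    columns <- new_cols[keep]
  }
  lab <- setNames(rep("", k), group_levels)
  for (i in seq_along(columns))
    for (g in columns[[i]]) lab[g] <- paste0(lab[g], letters[i])
  lab
}
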