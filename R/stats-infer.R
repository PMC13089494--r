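# Group-comparison inference used across the figures: one-way ANOVA with
# Tukey HSD and Bonferroni correction across families, Wilcoxon rank-sum,
# and Spearman correlation.

#' Group comparisons: ANOVA + Tukey HSD + Bonferroni across families
#'
#' Runs a one-way ANOVA per family, follows with two-sided Tukey HSD over all
#' group pairs (studentized-range distribution), and Bonferroni-multiplies
#' the pairwise p-values by the number of families (capped at 1).
#'
#' @param g Tibble with columns `value`, `group`, and optionally `family`
#'   (a single family assumed when absent). Each group needs n >= 2.
#' @return Tibble `family`, `pair`, `estimate`, `p_raw`, `p_adj`.
#' @export
groupwise_comparison <- function(g) {
  if (!"family" %in% names(g)) g$family <- "all"
  fams <- unique(g$family)
  n_fam <- length(fams)
  out <- purrr::map(fams, function(fm) {
    sub <- g[g$family == fm, ]
    sizes <- table(sub$group)
    if (length(sizes) < 2) rlang::abort("need >= 2 groups per family")
    if (any(sizes < 2)) rlang::abort("group with n < 2")
    sub$group <- factor(sub$group)
    fit <- stats::aov(value ~ group, data = sub)
    tk <- stats::TukeyHSD(fit)$group
    tibble::tibble(family = fm, pair = rownames(tk),
                   estimate = tk[, "diff"], p_raw = tk[, "p adj"])
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(p_adj = pmin(.data$p_raw * n_fam, 1))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact permutation distribution of the rank sum when the combined
#' sample is at most `exact_below` and tie-free, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact_below Combined-size cutoff for the exact distribution.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 50) {
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y)) <= exact_below && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks with average-rank ties.
#'
#' @param x,y Numeric vectors (length >= 3), neither constant.
#' @return rho in \[-1, 1\].
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) < 3) rlang::abort("need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) rlang::abort("constant input")
  stats::cor(x, y, method = "spearman")
}
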