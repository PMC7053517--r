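# Cohort-level statistics: per-core activation against histopathological
# factors, composition tests across groups, and the qPCR classification rule
# for microdissected samples.

#' Test per-core activation against a histopathological factor
#'
#' Each core is represented by the mean activation of its cells. Two-level
#' factors are compared with a two-sample t-test; factors with more than two
#' levels with all pairwise pooled-sd t-tests, Holm-adjusted; numeric
#' covariates with the slope test of a linear model. Levels with fewer than
#' 2 cores are excluded with a message.
#'
#' @param core_means numeric vector of per-core mean activation.
#' @param factor_or_covariate factor/character (grouping) or numeric
#'   (covariate) of the same length.
#' @param var_equal use a pooled-variance t-test for the 2-level case.
#' @return data.frame with one row per comparison: `comparison`, `test`,
#'   `adjusted`, `p_value`.
#' @export
activation_vs_factor <- function(core_means, factor_or_covariate,
                                 var_equal = TRUE) {
  stopifnot(length(core_means) == length(factor_or_covariate))
  if (is.numeric(factor_or_covariate)) {
    fit <- lm(core_means ~ factor_or_covariate)
    p <- summary(fit)$coefficients["factor_or_covariate", "Pr(>|t|)"]
    return(data.frame(comparison = "covariate vs activation",
                      test = "linear model", adjusted = FALSE, p_value = p,
                      stringsAsFactors = FALSE))
  }
  g <- as.character(factor_or_covariate)
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    message("excluding level(s) with < 2 cores: ", paste(small, collapse = ", "))
    keep <- !g %in% small
    core_means <- core_means[keep]; g <- g[keep]
    tab <- table(g)
  }
  if (length(tab) < 2) stop("need at least 2 levels with >= 2 cores", call. = FALSE)
  if (length(tab) == 2) {
    lv <- names(tab)
    p <- t.test(core_means[g == lv[1]], core_means[g == lv[2]],
                var.equal = var_equal)$p.value
    return(data.frame(comparison = paste(lv, collapse = " vs "),
                      test = "t test", adjusted = FALSE, p_value = p,
                      stringsAsFactors = FALSE))
  }
  pw <- pairwise.t.test(core_means, g, pool.sd = TRUE,
                        p.adjust.method = "holm")
  m <- pw$p.value
  rows <- which(!is.na(m), arr.ind = TRUE)
  data.frame(
    comparison = paste(rownames(m)[rows[, 1]], "vs", colnames(m)[rows[, 2]]),
    test = "pairwise t test (pooled sd)", adjusted = TRUE,
    p_value = m[rows], stringsAsFactors = FALSE)
}

#' Test subpopulation composition between groups of cores
#'
#' For each subpopulation (column of `fractions`), compares its per-core
#' fraction across the groups: Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for three or more. Constant fractions give p = 1 with a
#' warning. Subpopulations with p < `flag_alpha` are flagged.
#'
#' @param fractions cores x subpopulations matrix of fractions in \[0, 1\].
#' @param group per-core grouping vector.
#' @param flag_alpha significance threshold for flagging.
#' @return data.frame: `subpopulation`, `test`, `p_value`, `significant`.
#' @export
composition_tests <- function(fractions, group, flag_alpha = 0.05) {
  fractions <- as.matrix(fractions)
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  group <- as.factor(group)
  two <- nlevels(group) == 2
  test_name <- if (two) "Wilcoxon rank sum" else "Kruskal-Wallis"
  p <- vapply(colnames(fractions), function(s) {
    v <- fractions[, s]
    if (length(unique(v)) == 1) {
      warning("constant fractions for ", s, "; p = 1")
      return(1)
    }
    if (two) {
      lv <- levels(group)
      wilcox.test(v[group == lv[1]], v[group == lv[2]], exact = FALSE)$p.value
    } else kruskal.test(v, group)$p.value
  }, 0)
  data.frame(subpopulation = colnames(fractions), test = test_name,
             p_value = p, significant = p < flag_alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-core subpopulation fractions
#'
#' @param cells cell table with `core_id` and a non-NA `phenotype` (or any
#'   label) column named by `label_col`.
#' @param label_col column holding the per-cell label.
#' @return cores x labels matrix of fractions summing to 1 per row.
#' @export
composition_fractions <- function(cells, label_col = "phenotype") {
  stopifnot_cols(cells, c("core_id", label_col))
  keep <- !is.na(cells[[label_col]])
  tab <- table(cells$core_id[keep], cells[[label_col]][keep])
  m <- as.matrix(tab)
  m / rowSums(m)
}

#' Classify qPCR samples of microdissected TILs
#'
#' A sample is `active` if log(IFNg / CD45) is strictly positive, and
#' `exhausted` if LAG3 and/or TIM3 is expressed while both IFNg and CD40L
#' are not; otherwise `neither`. "Expressed" means normalised expression
#' strictly above `floor` (default 0).
#'
#' @param samples data.frame with columns `sample_id`, `IFNg`, `TIM3`,
#'   `LAG3`, `CD40L`, `CD45` (non-negative expression values; CD45 must be
#'   positive).
#' @param floor expression threshold above which a gene counts as expressed.
#' @return the input with added `log_ifng_cd45` and `label` columns.
#' @export
qpcr_classify <- function(samples, floor = 0) {
  stopifnot_cols(samples, c("IFNg", "TIM3", "LAG3", "CD40L", "CD45"),
                 "qPCR table")
  if (any(samples$CD45 <= 0))
    stop("CD45 must be positive for the ratio computation", call. = FALSE)
  lr <- log(samples$IFNg / samples$CD45)
  active <- is.finite(lr) & lr > 0
  expressed <- function(v) v > floor
  exhausted <- (expressed(samples$LAG3) | expressed(samples$TIM3)) &
    !expressed(samples$IFNg) & !expressed(samples$CD40L)
  samples$log_ifng_cd45 <- lr
  samples$label <- ifelse(active, "active",
                          ifelse(exhausted, "exhausted", "neither"))
  samples
}
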