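# Shared fixtures and independent oracles used across the test files.

# Adjusted Rand index (closed form on the contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Strongly polarised activation mixes: the "well separated" condition for
# planted-status recovery checks.
strong_mix <- function() {
  rbind(Active     = c(active = 0.85, transition = 0.10, exhausted = 0.03, anergic = 0.02),
        Transition = c(active = 0.20, transition = 0.60, exhausted = 0.20, anergic = 0.00),
        Exhausted  = c(active = 0.03, transition = 0.10, exhausted = 0.85, anergic = 0.02))
}

# Small scored cohort: simulate, QC, normalise, score CD8 cells with the
# planted phenotypes attached (phenotyping is tested separately).
scored_cohort <- function(n_patients = 10, cores_per_patient = c(2, 2),
                          cells_per_core = c(300, 300), seed = 1,
                          activation_mix = strong_mix(), ...) {
  cfg <- cohort_config(n_patients = n_patients,
                       cores_per_patient = cores_per_patient,
                       cells_per_core = cells_per_core,
                       activation_mix = activation_mix, seed = seed, ...)
  coh <- simulate_cohort(cfg)
  cells <- suppressMessages(zscore_trim(filter_markers(filter_cells(coh$cells))))
  idx <- match(cells$cell_id, coh$truth$cell_truth$cell_id)
  cells$phenotype <- coh$truth$cell_truth$phenotype[idx]
  # small fixtures occasionally trip the PC1 common-mode fallback; that
  # behaviour has its own dedicated test
  sc <- suppressWarnings(score_activation(cells))
  list(cells = sc$table, model = sc$model, truth = coh$truth,
       clinical = coh$clinical)
}

# Textbook log-rank oracle (two groups, no ties handling beyond the
# standard hypergeometric formula).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Pooled-sd pairwise t-test oracle (common sd across all groups, as in
# pairwise comparisons with pooled sd).
pooled_t_oracle <- function(values, group) {
  g <- factor(group)
  k <- nlevels(g)
  ni <- tapply(values, g, length)
  mi <- tapply(values, g, mean)
  ss <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  df <- length(values) - k
  sp <- sqrt(ss / df)
  out <- list()
  lv <- levels(g)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    t <- (mi[[i]] - mi[[j]]) / (sp * sqrt(1 / ni[[i]] + 1 / ni[[j]]))
    out[[paste(lv[i], "vs", lv[j])]] <- unname(2 * pt(-abs(t), df))
  }
  unlist(out)
}

# Kruskal-Wallis statistic oracle (no ties).
kw_oracle <- function(values, group) {
  g <- factor(group)
  r <- rank(values)
  N <- length(values)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
}

# Exact rank-sum p-value by enumeration (two-sided, no ties).
wilcox_oracle <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- combn(length(all_v), length(x))
  ws <- apply(combos, 2, function(idx) sum(r[idx])) -
    length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}
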