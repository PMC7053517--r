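# Core / patient Active-Transition-Exhausted classification.
#
# Each unit (core or patient) is compared against the background distribution
# of activation scores (all scored cells, the unit's own included) with two
# one-tailed two-sample t-tests: mean(unit) > mean(background) supports the
# Active call, mean(unit) < mean(background) the Exhausted call. Raw p-values
# are collected across all units and FDR-adjusted (Benjamini-Hochberg),
# by default separately within the Active-side and Exhausted-side families.

# One unit's pair of one-tailed raw p-values.
status_tests <- function(values, background, var_equal = FALSE) {
  if (length(values) < 2 || length(background) < 2)
    return(c(p_active = NA_real_, p_exhausted = NA_real_))
  if (sd(values) == 0 && sd(background) == 0)
    return(c(p_active = 1, p_exhausted = 1))
  pa <- tryCatch(t.test(values, background, alternative = "greater",
                        var.equal = var_equal)$p.value, error = function(e) 1)
  pe <- tryCatch(t.test(values, background, alternative = "less",
                        var.equal = var_equal)$p.value, error = function(e) 1)
  c(p_active = pa, p_exhausted = pe)
}

label_from_p <- function(p_active_adj, p_exhausted_adj, alpha) {
  both <- p_active_adj < alpha & p_exhausted_adj < alpha
  if (any(both, na.rm = TRUE))
    warning("unit significant on both sides; labelled Transition")
  ifelse(both, "Transition",
         ifelse(p_active_adj < alpha, "Active",
                ifelse(p_exhausted_adj < alpha, "Exhausted", "Transition")))
}

#' Classify units (cores or patients) as Active / Transition / Exhausted
#'
#' Each unit's activation-score distribution is compared against the
#' background distribution (all scores pooled, the unit's own cells
#' included) with two one-tailed Welch t-tests. Raw p-values are adjusted by
#' Benjamini-Hochberg FDR across units — by default separately within the
#' Active-side and Exhausted-side families — and a unit is called Active if
#' its adjusted greater-than p-value is below `alpha`, Exhausted if the
#' less-than side is, and Transition otherwise. Units with fewer than 2 cells
#' are excluded with a message.
#'
#' @param scores numeric vector of per-cell activation scores.
#' @param unit factor/character of the same length: the unit of each cell.
#' @param alpha significance cut-off on the adjusted p-values.
#' @param family `"per_side"` (default) adjusts the two one-tailed families
#'   separately; `"joint"` adjusts all 2n p-values together.
#' @param background `"all"` (default) compares each unit against the pooled
#'   scores of every unit; `"loo"` excludes the unit's own cells.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame of class `status_calls`: `unit_id`, `status`,
#'   `n_cells`, `mean_activation`, `p_active`, `p_exhausted`,
#'   `p_active_adj`, `p_exhausted_adj`.
#' @export
classify_status <- function(scores, unit, alpha = 0.001,
                            family = c("per_side", "joint"),
                            background = c("all", "loo"),
                            var_equal = FALSE) {
  family <- match.arg(family)
  background <- match.arg(background)
  keep <- is.finite(scores)
  scores <- scores[keep]; unit <- as.character(unit)[keep]
  sp <- split(scores, unit)
  ns <- lengths(sp)
  if (any(ns < 2))
    message("excluding unclassifiable unit(s) with < 2 cells: ",
            paste(names(sp)[ns < 2], collapse = ", "))
  sp <- sp[ns >= 2]
  if (!length(sp)) stop("no classifiable units", call. = FALSE)
  p <- t(vapply(names(sp), function(u) {
    bg <- if (background == "loo") scores[unit != u] else scores
    status_tests(sp[[u]], bg, var_equal)
  }, c(p_active = 0, p_exhausted = 0)))
  if (family == "per_side") {
    pa_adj <- p.adjust(p[, "p_active"], method = "BH")
    pe_adj <- p.adjust(p[, "p_exhausted"], method = "BH")
  } else {
    adj <- p.adjust(c(p[, "p_active"], p[, "p_exhausted"]), method = "BH")
    pa_adj <- adj[seq_len(nrow(p))]
    pe_adj <- adj[nrow(p) + seq_len(nrow(p))]
  }
  out <- data.frame(
    unit_id = names(sp),
    status = label_from_p(pa_adj, pe_adj, alpha),
    n_cells = as.integer(lengths(sp)),
    mean_activation = vapply(sp, mean, 0),
    p_active = p[, "p_active"],
    p_exhausted = p[, "p_exhausted"],
    p_active_adj = pa_adj,
    p_exhausted_adj = pe_adj,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("status_calls", "data.frame")
  out
}

#' @rdname classify_status
#' @param x scored cell table (columns `activation`, `core_id`,
#'   `patient_id`); cells without a score (non-CD8) are ignored.
#' @param ... passed to [classify_status()].
#' @export
classify_cores <- function(x, alpha = 0.001, ...) {
  stopifnot_cols(x, c("activation", "core_id"))
  idx <- is.finite(x$activation)
  classify_status(x$activation[idx], x$core_id[idx], alpha = alpha, ...)
}

#' @rdname classify_status
#' @export
classify_patients <- function(x, alpha = 0.001, ...) {
  stopifnot_cols(x, c("activation", "patient_id"))
  idx <- is.finite(x$activation)
  classify_status(x$activation[idx], x$patient_id[idx], alpha = alpha, ...)
}

#' @export
print.status_calls <- function(x, ...) {
  cat("Status calls for", nrow(x), "unit(s):\n")
  print(table(x$status))
  NextMethod()
}

#' Resampling robustness of a patient's classification
#'
#' Reclassifies one patient `reps` times at each subsample size, drawing
#' cells without replacement (capped at the patient's cell count), and
#' records the fraction of replicates reproducing the full-data label. A
#' single resampled unit cannot be FDR-adjusted across units, so replicates
#' are labelled from the raw one-tailed p-values at `alpha`.
#'
#' @param values the patient's activation scores.
#' @param background the cohort background scores.
#' @param full_label the patient's full-data status label.
#' @param sizes subsample sizes (default 10 to 1000 by 10).
#' @param reps replicates per size.
#' @param alpha significance cut-off.
#' @param seed integer seed.
#' @return data.frame of class `robustness_curve` with `size` and
#'   `consistency`; attribute `"min_n_95"` is the smallest size with
#'   consistency >= 0.95 (NA if never reached).
#' @export
robustness_resample <- function(values, background, full_label,
                                sizes = seq(10, 1000, by = 10), reps = 100,
                                alpha = 0.001, seed = 1L) {
  set.seed(seed)
  consistency <- vapply(sizes, function(s) {
    n <- min(s, length(values))
    hits <- vapply(seq_len(reps), function(r) {
      v <- values[sample.int(length(values), n)]
      p <- status_tests(v, background)
      label_from_p(p["p_active"], p["p_exhausted"], alpha) == full_label
    }, NA)
    mean(hits)
  }, 0)
  out <- data.frame(size = sizes, consistency = consistency)
  ok <- which(consistency >= 0.95)
  attr(out, "min_n_95") <- if (length(ok)) sizes[min(ok)] else NA_integer_
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' Dichotomised survival comparison
#'
#' Represents each patient by the mean activation of its cells, dichotomises
#' into "active" (mean > 0) vs "exhausted" (mean <= 0), and compares
#' overall survival between the two groups with Kaplan-Meier curves and the
#' log-rank test.
#'
#' @param patient_means data.frame with `patient_id` and `mean_activation`.
#' @param clinical data.frame with `patient_id`, `os_months` (or `os_time`)
#'   and `os_event` (1 = death observed).
#' @return list with `groups` (per-patient group table), `fit` (a
#'   [survival::survfit] object), `chisq` and `p_value` from
#'   [survival::survdiff].
#' @export
dichotomize_logrank <- function(patient_means, clinical) {
  stopifnot_cols(patient_means, c("patient_id", "mean_activation"))
  tcol <- if ("os_months" %in% colnames(clinical)) "os_months" else "os_time"
  stopifnot_cols(clinical, c("patient_id", tcol, "os_event"), "clinical")
  d <- merge(patient_means, clinical, by = "patient_id")
  d$group <- ifelse(d$mean_activation > 0, "active", "exhausted")
  if (length(unique(d$group)) < 2)
    stop("one dichotomy group is empty; cannot compare survival", call. = FALSE)
  s <- survival::Surv(d[[tcol]], d$os_event)
  fit <- survival::survfit(s ~ group, data = d)
  sd_ <- survival::survdiff(s ~ group, data = d)
  p <- pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  list(groups = d[, c("patient_id", "mean_activation", "group")],
       fit = fit, chisq = unname(sd_$chisq), p_value = p)
}
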