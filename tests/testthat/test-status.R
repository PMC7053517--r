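# Core / patient status classification, robustness resampling, survival.

test_that("a unit drawn from the background is Transition; extremes are called", {
  set.seed(1)
  bg <- runif(2000, -1, 1)
  unit <- c(rep("u1", 200), rep("u2", 200), rep("u3", 1600))
  scores <- c(rep(1, 200), rep(-1, 200), bg[1:1600])
  calls <- classify_status(scores, unit, alpha = 0.001)
  expect_equal(calls$status[calls$unit_id == "u1"], "Active")
  expect_equal(calls$status[calls$unit_id == "u2"], "Exhausted")
  expect_equal(calls$status[calls$unit_id == "u3"], "Transition")
  # Welch oracle for the all-ones unit against the pooled background
  all_scores <- scores
  u1 <- scores[unit == "u1"]
  tt <- t.test(u1, all_scores, alternative = "greater")
  expect_equal(calls$p_active[calls$unit_id == "u1"], tt$p.value)
})

test_that("a single-core dataset classifies as Transition against itself", {
  set.seed(2)
  calls <- classify_status(rnorm(50), rep("only", 50))
  expect_equal(calls$status, "Transition")
})

test_that("units with identical score distributions get identical labels", {
  v <- c(rnorm(100, 1), rnorm(100, 1))
  unit <- rep(c("a", "b"), each = 100)
  v[101:200] <- v[1:100]
  calls <- classify_status(v, unit)
  expect_equal(calls$status[1], calls$status[2])
  expect_equal(calls$p_active[1], calls$p_active[2])
})

test_that("units with fewer than 2 cells are excluded with a message", {
  expect_message(
    calls <- classify_status(c(rnorm(50), 0.3), c(rep("a", 50), "tiny")),
    "tiny")
  expect_false("tiny" %in% calls$unit_id)
})

test_that("core and patient recovery reaches 95% under strong separation", {
  sc <- scored_cohort(n_patients = 10, cores_per_patient = c(2, 2),
                      cells_per_core = c(500, 500), seed = 31,
                      status_level = "patient")
  calls <- classify_cores(sc$cells)
  m <- merge(calls, sc$truth$core_truth, by.x = "unit_id", by.y = "core_id")
  expect_gte(mean(m$status.x == m$status.y), 0.95)
  pcalls <- classify_patients(sc$cells)
  mp <- merge(pcalls, sc$truth$patient_truth,
              by.x = "unit_id", by.y = "patient_id")
  expect_gte(mean(mp$status.x == mp$status.y), 0.95)
})

test_that("patient calls are invariant to fictitious core boundaries", {
  sc <- scored_cohort(n_patients = 4, seed = 5)
  cells <- sc$cells
  a <- classify_patients(cells)
  # reshuffle core ids within each patient: the pooled patient call is blind
  set.seed(9)
  cells$core_id <- paste0(cells$patient_id, "_X",
                          sample(1:5, nrow(cells), replace = TRUE))
  b <- classify_patients(cells)
  expect_equal(a$status, b$status)
  expect_equal(a$p_active, b$p_active)
})

test_that("null cohorts keep the non-Transition rate within the FDR budget", {
  set.seed(77)
  n_false <- 0; n_units <- 0
  for (r in 1:300) {
    scores <- rnorm(240)
    unit <- rep(paste0("u", 1:8), each = 30)
    calls <- classify_status(scores, unit, alpha = 0.001)
    n_false <- n_false + sum(calls$status != "Transition")
    n_units <- n_units + nrow(calls)
  }
  expect_lte(n_false / n_units, 0.01)
})

test_that("robustness is perfect for a degenerate all-active patient", {
  set.seed(3)
  bg <- runif(3000, -1, 1)
  curve <- robustness_resample(rep(1, 1200), bg, "Active",
                               sizes = seq(10, 200, 10), reps = 25, seed = 4)
  expect_true(all(curve$consistency == 1))
  expect_equal(attr(curve, "min_n_95"), 10)
})

test_that("robustness curves are reproducible and reach 95% quickly under strong separation", {
  set.seed(6)
  vals <- runif(800, 0.2, 1)          # strongly active patient
  bg <- c(vals, runif(4000, -1, 1))
  c1 <- robustness_resample(vals, bg, "Active", sizes = seq(10, 100, 10),
                            reps = 50, seed = 7)
  c2 <- robustness_resample(vals, bg, "Active", sizes = seq(10, 100, 10),
                            reps = 50, seed = 7)
  expect_identical(c1, c2)
  expect_lte(attr(c1, "min_n_95"), 100)
})

test_that("log-rank matches the textbook oracle on a hand-sized fixture", {
  pm <- data.frame(patient_id = paste0("P", 1:4),
                   mean_activation = c(0.5, 0.4, -0.2, -0.3))
  clin <- data.frame(patient_id = paste0("P", 1:4),
                     os_months = c(1, 2, 3, 4), os_event = c(1, 1, 1, 1))
  res <- dichotomize_logrank(pm, clin)
  oracle <- logrank_oracle(clin$os_months, clin$os_event,
                           c("active", "active", "exhausted", "exhausted"))
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
})

test_that("dichotomisation sends mean activation 0 to the exhausted group", {
  pm <- data.frame(patient_id = c("A", "B", "C"),
                   mean_activation = c(0, 0.2, -0.1))
  clin <- data.frame(patient_id = c("A", "B", "C"),
                     os_months = c(5, 6, 7), os_event = c(1, 0, 1))
  res <- dichotomize_logrank(pm, clin)
  expect_equal(res$groups$group[res$groups$patient_id == "A"], "exhausted")
  # an empty group is an error
  pm2 <- data.frame(patient_id = c("A", "B"), mean_activation = c(0.1, 0.2))
  clin2 <- clin[1:2, ]
  expect_error(dichotomize_logrank(pm2, clin2), "empty")
})

test_that("identical survival in both groups gives a null log-rank test", {
  pm <- data.frame(patient_id = paste0("P", 1:6),
                   mean_activation = rep(c(0.5, -0.5), 3))
  clin <- data.frame(patient_id = paste0("P", 1:6),
                     os_months = rep(c(2, 4, 6), each = 2),
                     os_event = rep(1, 6))
  res <- dichotomize_logrank(pm, clin)
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
})
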