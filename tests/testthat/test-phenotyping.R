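# Clustering methods, rulebook annotation, consensus, functional subclusters.

blob_fixture <- function(n = 100, seed = 42) {
  set.seed(seed)
  z <- rbind(matrix(rnorm(n * 2, 0), n),
             matrix(rnorm(n * 2, 6), n),
             cbind(rnorm(n, 12), rnorm(n, 0)))
  colnames(z) <- c("d1", "d2")
  list(z = z, truth = rep(1:3, each = n))
}

test_that("all three methods recover well-separated Gaussian blobs", {
  fx <- blob_fixture()
  cl <- cluster_three_ways(fx$z, k_range = c(2, 6), knn_k = 60, seed = 1)
  for (m in names(cl)) expect_gt(ari(cl[[m]], fx$truth), 0.95)
})

test_that("duplicate rows receive identical labels within each method", {
  fx <- blob_fixture(n = 40)
  z <- rbind(fx$z, fx$z[1, , drop = FALSE])  # exact duplicate of row 1
  cl <- cluster_three_ways(z, k_kmeans = 3, knn_k = 20, seed = 2)
  for (m in names(cl)) expect_equal(cl[[m]][1], cl[[m]][nrow(z)])
})

test_that("clustering is deterministic given the seed", {
  fx <- blob_fixture(n = 50)
  a <- cluster_three_ways(fx$z, k_kmeans = 3, seed = 7)
  b <- cluster_three_ways(fx$z, k_kmeans = 3, seed = 7)
  expect_identical(a, b)
  expect_error(cluster_three_ways(fx$z[1, , drop = FALSE]), "2 cells")
})

test_that("the rulebook annotates canonical phenotype mean vectors", {
  panel <- tilax_phenotypic_markers()
  mv <- matrix(-0.3, nrow = 4, ncol = length(panel),
               dimnames = list(c("k1", "k2", "k3", "k4"), panel))
  mv["k1", c("CD3", "CD8")] <- 2                 # Tcy
  mv["k2", c("CD3", "CD4", "FOXP3")] <- 2        # Treg
  mv["k3", ] <- 0                                # nothing expressed
  mv["k4", c("CD68", "Lysozyme")] <- 2           # Macroph
  ann <- annotate_clusters(mv)
  expect_equal(ann$phenotype, c("Tcy", "Treg", "unassigned", "Macroph"))
  expect_error(annotate_clusters(mv, rulebook = list()), "empty")
})

test_that("consensus requires two agreeing methods and reports inclusion", {
  labs <- list(c("Th", "Th", "Th"),
               c("Th", "Th", "Tcy"),
               c("Th", "Tcy", "BC"))
  cons <- consensus_assign(labs)
  expect_equal(as.character(cons), c("Th", "Th", NA))
  expect_equal(attr(cons, "inclusion_fraction"), 2 / 3)
  # unassigned never counts as agreement
  labs2 <- list(c("unassigned"), c("unassigned"), c("Tcy"))
  expect_true(is.na(consensus_assign(labs2)[1]))
  # consensus never invents a phenotype no method proposed
  set.seed(1)
  pool <- c("Th", "Tcy", "BC", "unassigned")
  for (r in 1:50) {
    votes <- list(sample(pool, 5, TRUE), sample(pool, 5, TRUE),
                  sample(pool, 5, TRUE))
    cons <- consensus_assign(votes)
    for (i in seq_len(5)) {
      if (!is.na(cons[i]))
        expect_true(cons[i] %in% c(votes[[1]][i], votes[[2]][i], votes[[3]][i]))
    }
  }
})

test_that("assignment is monotone non-increasing in rulebook strictness", {
  # tightening the high threshold can only turn clusters unassigned (the low
  # condition is unchanged), so the assigned fraction never grows
  sc <- scored_cohort(n_patients = 2, cells_per_core = c(250, 250), seed = 13)
  mk <- intersect(tilax_phenotypic_markers(), tilax:::cell_markers(sc$cells))
  z <- as.matrix(sc$cells[, mk])
  lab <- cluster_three_ways(z, k_kmeans = 10, seed = 3)$kmeans
  assigned <- vapply(c(0.2, 0.5, 0.8, 1.5, 3), function(thr) {
    ph <- tilax:::phenotype_by_method(z, lab, default_rulebook(),
                                      high_threshold = thr, high_margin = thr)
    mean(ph != "unassigned")
  }, 0)
  expect_true(all(diff(assigned) <= 1e-12))
  expect_lt(assigned[length(assigned)], assigned[1])
})

test_that("planted phenotypes are recovered on a well-separated cohort", {
  cfg <- cohort_config(
    n_patients = 2, cores_per_patient = c(1, 1), cells_per_core = c(1200, 1200),
    phenotype_proportions = c(Tcy = 0.25, Th = 0.25, Treg = 0.15,
                              BC = 0.15, Macroph = 0.2),
    noise_sd = 0.3, cell_intensity_sd = 0.1, seed = 17)
  coh <- simulate_cohort(cfg)
  cells <- suppressMessages(zscore_trim(filter_markers(filter_cells(coh$cells))))
  ph <- phenotype_cells(cells, seed = 17)
  truth <- coh$truth$cell_truth$phenotype[match(ph$cell_id,
                                                coh$truth$cell_truth$cell_id)]
  expect_gte(mean(!is.na(ph$phenotype) & ph$phenotype == truth), 0.9)
})

test_that("functional rules identify exhausted and anergic Tcy profiles", {
  mks <- tilax_tcy_functional_markers()
  mv <- matrix(0, 3, length(mks), dimnames = list(c("s1", "s2", "s3"), mks))
  mv["s1", c("LAG3", "TIM3")] <- c(1.5, 0.4)   # LAG3 and/or TIM3 high
  mv["s1", c("CD69", "OX40")] <- -0.5
  mv["s2", ] <- -0.4                           # everything low
  mv["s3", "CD69"] <- 1.8                      # active
  mv["s3", "TIM3"] <- -0.6
  ann <- annotate_clusters(mv, default_functional_rulebook())
  expect_equal(ann$phenotype, c("exhausted", "anergic", "active"))
})

test_that("functional subclustering recovers two planted subtypes", {
  set.seed(23)
  mks <- tilax_tcy_functional_markers()
  n <- 300
  mk_mat <- function(shift) {
    m <- matrix(rnorm(n * length(mks), 0, 0.3), n, length(mks),
                dimnames = list(NULL, mks))
    m[, names(shift)] <- m[, names(shift), drop = FALSE] +
      matrix(shift, n, length(shift), byrow = TRUE)
    m
  }
  z <- rbind(mk_mat(c(CD69 = 2, OX40 = 1.5)),
             mk_mat(c(TIM3 = 2, LAG3 = 1.5)))
  x <- data.frame(cell_id = seq_len(2 * n), z, check.names = FALSE)
  x <- tilax:::set_markers(x, mks)
  lab <- functional_subcluster(x, tcy = TRUE, seed = 23)
  truth <- rep(c("active", "exhausted"), each = n)
  expect_gt(ari(lab, truth), 0.9)
  expect_gte(mean(lab == truth), 0.9)
  # tiny phenotypes collapse to a single functional cluster with a warning
  expect_warning(functional_subcluster(x[1:5, ], tcy = TRUE, min_cells = 20),
                 "single functional cluster")
})
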