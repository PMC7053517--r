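#' Default per-phenotype marker intensity means
#'
#' Builds the (phenotype x marker) matrix of expected raw mean-fluorescence
#' intensities used by [simulate_cohort()]. Lineage-defining markers of each
#' phenotype sit at `high`, everything else at `background`. Intensities are
#' in arbitrary MFI units; the generator draws log-normal noise around them.
#'
#' @param phenotypes character vector of phenotype names (defaults to the
#'   phenotypes of [default_rulebook()]).
#' @param high,background positive reals: mean MFI of a lineage marker in the
#'   phenotype that carries it, and of all other markers.
#' @return numeric matrix, rownames = phenotypes, colnames = [tilax_panel()].
#' @export
default_marker_means <- function(phenotypes = NULL, high = 40, background = 5) {
  rb <- default_rulebook()
  if (is.null(phenotypes)) phenotypes <- vapply(rb, `[[`, "", "phenotype")
  panel <- tilax_panel()
  m <- matrix(background, nrow = length(phenotypes), ncol = length(panel),
              dimnames = list(phenotypes, panel))
  for (rule in rb) {
    ph <- rule$phenotype
    if (!ph %in% phenotypes) next
    m[ph, intersect(rule$high, panel)] <- high
  }
  m
}

# Multiplicative shifts of (CD69, OX40, LAG3, TIM3) per planted CD8
# functional class. Active = high CD69/OX40; exhausted = high TIM3 (some
# LAG3); transition = intermediate on both sides; anergic = low everything.
functional_class_shifts <- function() {
  rbind(active     = c(CD69 = 4.0, OX40 = 2.8, LAG3 = 0.7, TIM3 = 0.7),
        transition = c(CD69 = 2.0, OX40 = 1.6, LAG3 = 1.0, TIM3 = 2.0),
        exhausted  = c(CD69 = 0.7, OX40 = 0.7, LAG3 = 2.0, TIM3 = 4.0),
        anergic    = c(CD69 = 0.7, OX40 = 0.7, LAG3 = 0.7, TIM3 = 0.7))
}

#' Canonical activation mixtures for planted core statuses
#'
#' Fractions of (active, transition, exhausted, anergic) CD8 cells used for
#' cores planted as Active, Transition or Exhausted. The Active and Exhausted
#' profiles are strongly polarised; the Transition profile is balanced so its
#' mean activation sits at the cohort background.
#'
#' @return 3 x 4 matrix of fractions, rows summing to 1.
#' @export
status_activation_profiles <- function() {
  rbind(Active     = c(active = 0.70, transition = 0.20, exhausted = 0.05, anergic = 0.05),
        Transition = c(active = 0.25, transition = 0.45, exhausted = 0.25, anergic = 0.05),
        Exhausted  = c(active = 0.05, transition = 0.20, exhausted = 0.70, anergic = 0.05))
}

#' Configuration for the synthetic-cohort generator
#'
#' Validates and assembles the parameters that define a simulated
#' tissue-microarray cohort. Defaults mirror the study design the analysis is
#' aimed at: 29 patients, about 60 cores, thousands of cells per core, a
#' 39-marker panel, and one third of cores planted per activation status.
#'
#' @param n_patients number of patients.
#' @param cores_per_patient length-2 integer range; each patient receives a
#'   uniform draw from it.
#' @param cells_per_core length-2 integer range of cells per core.
#' @param field_size width/height of a core image in pixels.
#' @param phenotype_proportions named fractions summing to 1.
#' @param marker_means (phenotype x marker) positive matrix of mean MFIs.
#' @param noise_sd log-scale standard deviation of per-cell marker noise.
#' @param cell_intensity_sd log-scale sd of a per-cell common staining factor
#'   multiplying all markers (cell size / staining efficiency variability).
#' @param functional_intensity_sd log-scale sd of an additional per-cell
#'   factor on the four activation markers (CD69, OX40, LAG3, TIM3): the
#'   overall functional staining intensity of a cell, which creates the
#'   common-mode axis that dominates the first principal component of the
#'   activation PCA in real MFI data.
#' @param status_proportions fractions of cores planted Active / Transition /
#'   Exhausted.
#' @param status_level `"core"` (default) plants statuses on cores
#'   independently, so patients can be heterogeneous as in real cohorts;
#'   `"patient"` plants one status per patient inherited by all its cores.
#' @param activation_mix 3 x 4 matrix of per-status functional-class mixes
#'   (see [status_activation_profiles()]).
#' @param interaction_spec list of planted spatial interactions, each a list
#'   with elements `i`, `j` (phenotype names), `mode` ("attraction",
#'   "avoidance" or "none") and `strength` in \[0, 1\].
#' @param radius interaction radius in pixels used when planting interactions.
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `tilax_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 29,
                          cores_per_patient = c(1, 3),
                          cells_per_core = c(3000, 5000),
                          field_size = c(1000, 1000),
                          phenotype_proportions = NULL,
                          marker_means = NULL,
                          noise_sd = 0.4,
                          cell_intensity_sd = 0.15,
                          functional_intensity_sd = 0.8,
                          status_proportions = c(Active = 1/3, Transition = 1/3, Exhausted = 1/3),
                          status_level = c("core", "patient"),
                          activation_mix = status_activation_profiles(),
                          interaction_spec = list(),
                          radius = 30,
                          seed = 1L) {
  if (is.null(phenotype_proportions)) {
    phenotype_proportions <- c(
      Melanoma = 0.493, Macroph = 0.12, Tcy = 0.12, Th = 0.10, Treg = 0.03,
      Tfh = 0.025, BC = 0.005, PC = 0.012, cDC1 = 0.04, cDC2 = 0.025,
      Lang = 0.02, pDC = 0.005, NK = 0.005)
  }
  if (abs(sum(phenotype_proportions) - 1) > 1e-9)
    stop("phenotype_proportions must sum to 1", call. = FALSE)
  if (any(phenotype_proportions < 0))
    stop("phenotype_proportions must be non-negative", call. = FALSE)
  if (length(field_size) != 2 || any(field_size <= 0))
    stop("field_size must be two positive numbers", call. = FALSE)
  if (is.null(marker_means))
    marker_means <- default_marker_means(names(phenotype_proportions))
  if (any(marker_means < 0)) stop("marker_means must be non-negative", call. = FALSE)
  miss <- setdiff(names(phenotype_proportions), rownames(marker_means))
  if (length(miss))
    stop("marker_means lacks rows for: ", paste(miss, collapse = ", "), call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (abs(sum(status_proportions) - 1) > 1e-9)
    stop("status_proportions must sum to 1", call. = FALSE)
  if (!all(abs(rowSums(activation_mix) - 1) < 1e-9))
    stop("activation_mix rows must sum to 1", call. = FALSE)
  status_level <- match.arg(status_level)
  structure(list(
    n_patients = as.integer(n_patients),
    cores_per_patient = as.integer(cores_per_patient),
    cells_per_core = as.integer(cells_per_core),
    field_size = as.numeric(field_size),
    phenotype_proportions = phenotype_proportions,
    marker_means = marker_means,
    noise_sd = noise_sd,
    cell_intensity_sd = cell_intensity_sd,
    functional_intensity_sd = functional_intensity_sd,
    status_proportions = status_proportions,
    activation_mix = activation_mix,
    status_level = status_level,
    interaction_spec = interaction_spec,
    radius = radius,
    seed = as.integer(seed)
  ), class = "tilax_config")
}

#' Simulate a synthetic multiplexed-immunofluorescence cohort
#'
#' Generates a cell table with the statistical structure the downstream
#' analysis assumes: per-phenotype log-normal marker intensities around
#' lineage-specific means, a per-cell common staining factor, a planted
#' activation gradient on CD8+ (Tcy) cells over CD69/OX40/LAG3/TIM3, cores
#' planted as Active/Transition/Exhausted, optional planted spatial
#' attraction/avoidance between phenotypes, and a clinical table whose
#' overall-survival times depend on the planted patient status.
#'
#' @param config a [cohort_config()] object.
#' @return a list of class `tilax_cohort` with elements
#'   \describe{
#'     \item{cells}{data.frame: `cell_id`, `patient_id`, `core_id`, `x`, `y`
#'       and one raw-MFI column per marker (marker set in the `"markers"`
#'       attribute).}
#'     \item{truth}{list with `cell_truth` (`cell_id`, `phenotype`,
#'       `functional_class`), `core_truth` (`core_id`, `patient_id`,
#'       `status`), `patient_truth`, and the planted `interactions`.}
#'     \item{clinical}{data.frame: `patient_id`, `os_months`, `os_event`.}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "tilax_config"))
    stop("config must come from cohort_config()", call. = FALSE)
  set.seed(config$seed)
  panel <- colnames(config$marker_means)
  phen_names <- names(config$phenotype_proportions)
  shifts <- functional_class_shifts()
  act_markers <- tilax_activation_markers()

  # plant core statuses: deterministic counts by proportion, shuffled
  n_cores_pp <- if (config$cores_per_patient[1] == config$cores_per_patient[2])
    rep(config$cores_per_patient[1], config$n_patients)
  else sample(seq(config$cores_per_patient[1], config$cores_per_patient[2]),
              config$n_patients, replace = TRUE)
  n_cores <- sum(n_cores_pp)
  alloc <- function(n, prop) {
    k <- floor(prop * n)
    rem <- n - sum(k)
    if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
    sample(rep(names(k), k))
  }
  core_status <- if (config$status_level == "patient") {
    ps <- alloc(config$n_patients, config$status_proportions)
    rep(ps, n_cores_pp)
  } else alloc(n_cores, config$status_proportions)

  cells_list <- vector("list", n_cores)
  truth_list <- vector("list", n_cores)
  core_truth <- data.frame(core_id = character(), patient_id = character(),
                           status = character(), stringsAsFactors = FALSE)
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (ci in seq_len(n_cores_pp[p])) {
      k <- k + 1L
      cid <- sprintf("%s_C%d", pid, ci)
      status <- core_status[k]
      n <- if (config$cells_per_core[1] == config$cells_per_core[2])
        config$cells_per_core[1]
      else sample(seq(config$cells_per_core[1], config$cells_per_core[2]), 1)
      phen <- sample(phen_names, n, replace = TRUE,
                     prob = config$phenotype_proportions)
      pos <- place_cells(phen, config$interaction_spec, config$field_size,
                         config$radius)
      mu <- config$marker_means[phen, , drop = FALSE]
      # planted functional class for Tcy cells
      fclass <- rep(NA_character_, n)
      tcy <- which(phen == "Tcy")
      if (length(tcy)) {
        mix <- config$activation_mix[status, ]
        fclass[tcy] <- sample(colnames(config$activation_mix), length(tcy),
                              replace = TRUE, prob = mix)
        mu[tcy, act_markers] <- mu[tcy, act_markers, drop = FALSE] *
          shifts[fclass[tcy], act_markers, drop = FALSE]
      }
      cell_factor <- rlnorm(n, 0, config$cell_intensity_sd)
      func_factor <- rlnorm(n, 0, config$functional_intensity_sd)
      raw <- matrix(rlnorm(n * length(panel),
                           meanlog = log(pmax(t(mu), 1e-6)),
                           sdlog = config$noise_sd),
                    nrow = n, ncol = length(panel), byrow = TRUE,
                    dimnames = list(NULL, panel))
      raw <- raw * cell_factor
      fm <- intersect(act_markers, panel)
      raw[, fm] <- raw[, fm] * func_factor
      ids <- sprintf("%s_%05d", cid, seq_len(n))
      cells_list[[k]] <- data.frame(cell_id = ids, patient_id = pid,
                                    core_id = cid, x = pos$x, y = pos$y,
                                    raw, check.names = FALSE,
                                    stringsAsFactors = FALSE)
      truth_list[[k]] <- data.frame(cell_id = ids, phenotype = phen,
                                    functional_class = fclass,
                                    stringsAsFactors = FALSE)
      core_truth <- rbind(core_truth,
                          data.frame(core_id = cid, patient_id = pid,
                                     status = status, stringsAsFactors = FALSE))
    }
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  cells <- set_markers(cells, panel)
  cell_truth <- do.call(rbind, truth_list)
  rownames(cell_truth) <- NULL

  # patient truth = modal planted core status (ties broken toward Transition)
  patient_truth <- do.call(rbind, lapply(split(core_truth, core_truth$patient_id),
    function(d) {
      tab <- table(d$status)
      status <- if (sum(tab == max(tab)) > 1) "Transition" else names(which.max(tab))
      data.frame(patient_id = d$patient_id[1], status = status,
                 stringsAsFactors = FALSE)
    }))
  rownames(patient_truth) <- NULL

  # survival: Active patients live longer; censoring at 120 months
  med <- c(Active = 70, Transition = 45, Exhausted = 25)
  os <- rexp(nrow(patient_truth), rate = log(2) / med[patient_truth$status])
  cens <- runif(nrow(patient_truth), 60, 120)
  clinical <- data.frame(patient_id = patient_truth$patient_id,
                         os_months = pmin(os, cens),
                         os_event = as.integer(os <= cens),
                         stringsAsFactors = FALSE)

  structure(list(cells = cells,
                 truth = list(cell_truth = cell_truth,
                              core_truth = core_truth,
                              patient_truth = patient_truth,
                              interactions = config$interaction_spec),
                 clinical = clinical),
            class = "tilax_cohort")
}

#' @export
print.tilax_cohort <- function(x, ...) {
  cat("Synthetic TIL cohort:", nrow(x$cells), "cells,",
      nrow(x$truth$core_truth), "cores,",
      nrow(x$truth$patient_truth), "patients\n")
  cat("Planted core statuses:\n")
  print(table(x$truth$core_truth$status))
  invisible(x)
}

# Place cells of the given phenotypes in the field, honouring the planted
# interaction spec. Base pattern is uniform (CSR); "attraction" relocates a
# fraction `strength` of type-j cells into the radius of a random type-i
# cell; "avoidance" rejection-samples that fraction outside the radius of
# every type-i cell.
place_cells <- function(types, interaction_spec, field_size, radius,
                        max_attempts = 10000L) {
  n <- length(types)
  x <- runif(n, 0, field_size[1])
  y <- runif(n, 0, field_size[2])
  for (spec in interaction_spec) {
    mode <- match.arg(spec$mode, c("attraction", "avoidance", "none"))
    if (mode == "none") next
    idx_i <- which(types == spec$i)
    idx_j <- which(types == spec$j)
    if (!length(idx_i) || !length(idx_j)) next
    strength <- if (is.null(spec$strength)) 1 else spec$strength
    n_move <- round(strength * length(idx_j))
    if (n_move < 1) next
    move <- idx_j[seq_len(n_move)]
    if (mode == "attraction") {
      anchor <- sample(idx_i, n_move, replace = TRUE)
      for (m in seq_along(move)) {
        repeat {
          r <- radius * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          nx <- x[anchor[m]] + r * cos(th)
          ny <- y[anchor[m]] + r * sin(th)
          if (nx >= 0 && nx <= field_size[1] && ny >= 0 && ny <= field_size[2]) break
        }
        x[move[m]] <- nx; y[move[m]] <- ny
      }
    } else { # avoidance
      for (m in move) {
        ok <- FALSE
        for (a in seq_len(max_attempts)) {
          nx <- runif(1, 0, field_size[1])
          ny <- runif(1, 0, field_size[2])
          d2 <- (x[idx_i] - nx)^2 + (y[idx_i] - ny)^2
          if (all(d2 > radius^2)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("avoidance rejection sampling failed after ", max_attempts,
               " attempts; field too crowded", call. = FALSE)
        x[m] <- nx; y[m] <- ny
      }
    }
  }
  list(x = x, y = y)
}

#' Simulate a spatial point pattern with planted pairwise interactions
#'
#' Draws cell positions for each type uniformly over the field (complete
#' spatial randomness) and then applies the planted interaction modes:
#' `"attraction"` relocates a fraction `strength` of type-j cells to within
#' `radius` of a random type-i cell; `"avoidance"` rejection-samples them
#' outside `radius` of every type-i cell; `"none"` leaves CSR untouched.
#'
#' @param n_by_type named integer vector: number of cells per type.
#' @param interaction_spec as in [cohort_config()].
#' @param field_size width/height in pixels.
#' @param radius interaction radius in pixels; must be < min(field_size)/2.
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `type`.
#' @export
simulate_spatial_pattern <- function(n_by_type, interaction_spec = list(),
                                     field_size = c(1000, 1000), radius = 30,
                                     seed = 1L) {
  if (radius >= min(field_size) / 2)
    stop("radius must be smaller than half the field size", call. = FALSE)
  set.seed(seed)
  types <- rep(names(n_by_type), n_by_type)
  pos <- place_cells(types, interaction_spec, field_size, radius)
  data.frame(x = pos$x, y = pos$y, type = types, stringsAsFactors = FALSE)
}
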