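# Spatial neighbourhood analysis: radius graph, per-image label-permutation
# test with tri-state calls, cross-image weighted integration, and the
# nest-aware melanoma neighbour profile.

#' Build the radius neighbour graph of one image
#'
#' Connects every pair of cells whose Euclidean centroid distance is at most
#' `radius` (boundary inclusive). Uses grid bucketing so only nearby pairs
#' are examined.
#'
#' @param x,y cell centroid coordinates in pixels.
#' @param radius neighbourhood radius in pixels (default 30).
#' @return object of class `neighbor_graph`: list with `edges` (2-column
#'   matrix of index pairs, i < j), `n`, `radius`.
#' @export
build_neighbor_graph <- function(x, y, radius = 30) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("positions must be finite", call. = FALSE)
  if (anyDuplicated(cbind(x, y)))
    warning("duplicate coordinates present")
  r2 <- radius^2
  gx <- floor(x / radius); gy <- floor(y / radius)
  key <- paste(gx, gy, sep = ",")
  bins <- split(seq_len(n), key)
  bin_xy <- do.call(rbind, lapply(strsplit(names(bins), ","), as.numeric))
  # forward half of the 3x3 neighbourhood; (0,0) handled as within-bin pairs
  off <- rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  acc <- vector("list", length(bins) * nrow(off))
  a <- 0L
  for (b in seq_along(bins)) {
    ib <- bins[[b]]
    for (o in seq_len(nrow(off))) {
      if (off[o, 1] == 0 && off[o, 2] == 0) {
        if (length(ib) < 2) next
        pr <- utils::combn(ib, 2)
        ii <- pr[1, ]; jj <- pr[2, ]
      } else {
        nb <- paste(bin_xy[b, 1] + off[o, 1], bin_xy[b, 2] + off[o, 2],
                    sep = ",")
        jb <- bins[[nb]]
        if (is.null(jb)) next
        ii <- rep(ib, each = length(jb)); jj <- rep(jb, length(ib))
      }
      d2 <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2
      keep <- d2 <= r2
      if (any(keep)) {
        a <- a + 1L
        acc[[a]] <- cbind(pmin(ii[keep], jj[keep]), pmax(ii[keep], jj[keep]))
      }
    }
  }
  edges <- if (a) do.call(rbind, acc[seq_len(a)])
           else matrix(integer(), 0, 2)
  structure(list(edges = edges, n = n, radius = radius),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("Neighbour graph:", x$n, "cells,", nrow(x$edges),
      "edges at radius", x$radius, "px\n")
  invisible(x)
}

# Ordered type-pair neighbour counts for a label vector (integer codes 1..K).
pair_counts <- function(code, edges, K) {
  if (!nrow(edges)) return(matrix(0L, K, K))
  a <- c(edges[, 1], edges[, 2])
  b <- c(edges[, 2], edges[, 1])
  matrix(tabulate((code[a] - 1L) * K + code[b], K * K), K, K, byrow = TRUE)
}

#' Per-image permutation test of phenotype co-localisation
#'
#' For every ordered phenotype pair (i, j), the observed statistic is the
#' mean number of type-j neighbours per type-i cell (total count behind
#' `statistic = "total"`). The null distribution is built by permuting the
#' phenotype labels over the fixed cell positions `n_perm` times. One-sided
#' empirical p-values use the add-one estimator (r + 1) / (n_perm + 1), so
#' with `n_perm = 1000` and `alpha = 0.001` a call requires the observed
#' statistic to beat every permutation. The tri-state call is +1 (proximity)
#' if the proximity p-value is below `alpha`, -1 (avoidance) if the
#' avoidance p-value is, and 0 otherwise. Phenotypes absent from the image
#' get NA rows/columns (not evaluable).
#'
#' @param types per-cell phenotype labels (character or factor).
#' @param graph a [build_neighbor_graph()] object for the same cells.
#' @param n_perm number of label permutations.
#' @param alpha significance threshold on the empirical p-values.
#' @param seed integer seed.
#' @param statistic `"mean"` neighbours per i-cell (default) or `"total"`.
#' @param levels phenotype universe for the output matrices (defaults to the
#'   labels present).
#' @return object of class `neighborhood_test`: list with matrices `c`
#'   (tri-state calls), `p_proximity`, `p_avoidance`, `observed`, and
#'   `n_by_type`, `n_perm`, `alpha`.
#' @export
permutation_test_image <- function(types, graph, n_perm = 1000, alpha = 0.001,
                                   seed = 1L, statistic = c("mean", "total"),
                                   levels = NULL) {
  statistic <- match.arg(statistic)
  types <- as.character(types)
  if (length(types) != graph$n)
    stop("types length must match the graph", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(types))
  code <- match(types, levels)
  K <- length(levels)
  n_by_type <- tabulate(code, K)
  names(n_by_type) <- levels
  present <- n_by_type > 0
  if (sum(present) < 1) stop("no phenotypes present", call. = FALSE)

  obs <- pair_counts(code, graph$edges, K)
  set.seed(seed)
  ge <- matrix(0L, K, K); le <- matrix(0L, K, K)
  for (p in seq_len(n_perm)) {
    cnt <- pair_counts(sample(code), graph$edges, K)
    ge <- ge + (cnt >= obs)
    le <- le + (cnt <= obs)
  }
  p_prox <- (1 + ge) / (n_perm + 1)
  p_avoid <- (1 + le) / (n_perm + 1)
  cmat <- matrix(0L, K, K)
  cmat[p_prox < alpha] <- 1L
  cmat[p_avoid < alpha] <- -1L
  bad <- !present
  cmat[bad, ] <- NA; cmat[, bad] <- NA
  p_prox[bad, ] <- NA; p_prox[, bad] <- NA
  p_avoid[bad, ] <- NA; p_avoid[, bad] <- NA
  observed <- if (statistic == "mean") obs / pmax(n_by_type, 1) else obs
  dimnames(cmat) <- dimnames(p_prox) <- dimnames(p_avoid) <-
    dimnames(observed) <- list(levels, levels)
  structure(list(c = cmat, p_proximity = p_prox, p_avoidance = p_avoid,
                 observed = observed, n_by_type = n_by_type,
                 n_perm = n_perm, alpha = alpha),
            class = "neighborhood_test")
}

#' @export
print.neighborhood_test <- function(x, ...) {
  cat("Neighbourhood permutation test (", x$n_perm, " permutations, alpha ",
      x$alpha, ")\n", sep = "")
  cat("Tri-state calls (+1 proximity / -1 avoidance / 0 ns):\n")
  print(x$c)
  invisible(x)
}

#' Long-format interaction calls of one image
#'
#' Flattens a [permutation_test_image()] result into one row per evaluable
#' ordered phenotype pair, carrying the cell counts needed for cross-image
#' integration.
#'
#' @param test a `neighborhood_test`.
#' @param image_id identifier of the image.
#' @return data.frame: `image_id`, `i`, `j`, `c`, `n_i`, `n_j`.
#' @export
interaction_calls <- function(test, image_id) {
  lv <- rownames(test$c)
  g <- expand.grid(i = lv, j = lv, stringsAsFactors = FALSE)
  out <- data.frame(image_id = image_id, i = g$i, j = g$j,
                    c = as.vector(test$c),
                    n_i = test$n_by_type[g$i], n_j = test$n_by_type[g$j],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[!is.na(out$c), , drop = FALSE]
}

#' Integrate interaction calls across images
#'
#' Weighted integration of per-image tri-state calls: for phenotype pair
#' (i, j) with per-image calls c_ijk and weights N_ijk (geometric mean of
#' the two phenotypes' cell counts in image k),
#' P_ij = sum_k(c_ijk * N_ijk) / sum_k(N_ijk). Interaction strength is
#' categorised on |P|: strong > 0.75, moderate (0.5, 0.75\], weak
#' (0.25, 0.5\], non-significant <= 0.25.
#'
#' @param calls data.frame as produced by row-binding [interaction_calls()]
#'   over images (`image_id`, `i`, `j`, `c`, `n_i`, `n_j`).
#' @return data.frame of class `interaction_summary`: `i`, `j`, `M` (images
#'   contributing), `P`, `category`.
#' @export
integrate_images <- function(calls) {
  stopifnot_cols(calls, c("i", "j", "c", "n_i", "n_j"), "calls")
  calls <- calls[!is.na(calls$c), , drop = FALSE]
  if (!nrow(calls)) stop("no evaluable interaction calls", call. = FALSE)
  calls$N <- sqrt(calls$n_i * calls$n_j)
  sp <- split(calls, list(calls$i, calls$j), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(i = d$i[1], j = d$j[1], M = nrow(d),
               P = sum(d$c * d$N) / sum(d$N),
               stringsAsFactors = FALSE)
  }))
  out$category <- interaction_category(out$P)
  rownames(out) <- NULL
  class(out) <- c("interaction_summary", "data.frame")
  out
}

interaction_category <- function(P) {
  a <- abs(P)
  ifelse(a > 0.75, "strong",
         ifelse(a > 0.5, "moderate",
                ifelse(a > 0.25, "weak", "non-significant")))
}

#' Melanoma-nest neighbour profile
#'
#' The permutation model underestimates interactions with dominant cell
#' types growing in packed nests, so melanoma neighbours are profiled
#' directly: for each non-melanoma subpopulation, the number of its cells
#' lying within `radius` of a melanoma cell is summed over the cores where
#' the subpopulation appears and divided by the geometric mean of the
#' melanoma and subpopulation cell counts over those same cores.
#'
#' @param cells cell table with `core_id`, `x`, `y` and a `phenotype` column.
#' @param target phenotype label of the melanoma (nest-forming) class.
#' @param radius neighbourhood radius in pixels.
#' @return data.frame: `phenotype`, `adjacent` (summed adjacent-cell count),
#'   `n_target`, `n_pheno` (counts over qualifying cores), `profile` (the
#'   normalised value).
#' @export
melanoma_neighbor_profile <- function(cells, target = "Melanoma", radius = 30) {
  stopifnot_cols(cells, c("core_id", "x", "y", "phenotype"))
  cells <- cells[!is.na(cells$phenotype), , drop = FALSE]
  if (!any(cells$phenotype == target))
    stop("target phenotype absent from every core", call. = FALSE)
  phenos <- setdiff(unique(cells$phenotype), target)
  per_core <- lapply(split(cells, cells$core_id), function(d) {
    g <- build_neighbor_graph(d$x, d$y, radius)
    is_t <- d$phenotype == target
    adj_t <- rep(FALSE, nrow(d))
    if (nrow(g$edges)) {
      e <- g$edges
      adj_t[e[is_t[e[, 2]], 1]] <- TRUE
      adj_t[e[is_t[e[, 1]], 2]] <- TRUE
    }
    list(pheno = d$phenotype, adj = adj_t, n_target = sum(is_t))
  })
  out <- do.call(rbind, lapply(phenos, function(ph) {
    qual <- Filter(function(pc) any(pc$pheno == ph), per_core)
    if (!length(qual)) return(NULL)
    adjacent <- sum(vapply(qual, function(pc)
      sum(pc$pheno == ph & pc$adj), 0L))
    n_t <- sum(vapply(qual, `[[`, 0L, "n_target"))
    n_p <- sum(vapply(qual, function(pc) sum(pc$pheno == ph), 0L))
    data.frame(phenotype = ph, adjacent = adjacent, n_target = n_t,
               n_pheno = n_p, profile = adjacent / sqrt(n_t * n_p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
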