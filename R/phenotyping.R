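# Consensus phenotyping: three clustering algorithms (k-means, a
# PhenoGraph-style kNN/Louvain community detection, and a ClusterX-style
# density-peak clustering), a rulebook-based annotator mapping cluster mean
# z-vectors to phenotypes, and a >=2-of-3 consensus per cell.

#' Default phenotype rulebook
#'
#' Ordered marker rules translating cluster mean z-scores into cell
#' phenotypes (the externalised form of expert cluster annotation). Each rule
#' lists the markers whose cluster mean must be high and those that must be
#' low; rules are tried in priority order and the first match wins. With
#' `any_high = TRUE` one high marker suffices instead of all.
#'
#' @return list of rules, each a list with `phenotype`, `high`, `low`,
#'   `any_high`, `priority`.
#' @export
default_rulebook <- function() {
  rule <- function(phenotype, high, low = character(), any_high = FALSE, priority) {
    list(phenotype = phenotype, high = high, low = low,
         any_high = any_high, priority = priority)
  }
  list(
    rule("Treg", c("CD3", "CD4", "FOXP3"), low = c("CD20", "CD68"), priority = 1),
    rule("Tcy", c("CD3", "CD8"), low = c("CD4", "CD20", "CD68"), priority = 2),
    rule("Th", c("CD3", "CD4"), low = c("FOXP3", "CD8", "CD20", "CD68"),
         priority = 3),
    rule("Tfh", c("CXCL13", "PD-1"), low = c("CD8", "CD20", "CD68"), priority = 4),
    rule("BC", "CD20", low = c("CD3", "CD68"), priority = 5),
    rule("PC", c("IRF4", "Blimp1"), low = c("CD20", "CD3"), priority = 6),
    rule("cDC1", c("CD141", "CD4", "IRF8"), low = c("CD3", "CD20"), priority = 7),
    rule("cDC2", c("CD1c", "CD4", "HLA-DR"), low = c("CD3", "CD20"), priority = 8),
    rule("Lang", c("CD1a", "Langerin"), low = "CD3", priority = 9),
    rule("pDC", "CD123", low = c("CD3", "CD20"), priority = 10),
    rule("NK", "CD56", low = "CD3", priority = 11),
    rule("Macroph", c("CD68", "Lysozyme"), low = c("CD3", "CD20"), priority = 12),
    rule("Melanoma", c("S100AB", "MelanA"), low = c("CD3", "CD68"),
         any_high = TRUE, priority = 13)
  )
}

#' Default functional rulebook for cytotoxic T cells
#'
#' Functional subcluster annotation of Tcy cells: exhausted (LAG3 and/or
#' TIM3 high with CD69/OX40 low), active (CD69 high, TIM3 low), transition
#' (balanced CD69 and TIM3), proliferating (Ki-67 high) and anergic (all
#' activation/exhaustion markers low).
#'
#' @return rule list in the format of [default_rulebook()].
#' @export
default_functional_rulebook <- function() {
  rule <- function(phenotype, high, low = character(), any_high = FALSE, priority) {
    list(phenotype = phenotype, high = high, low = low,
         any_high = any_high, priority = priority)
  }
  list(
    rule("exhausted", c("TIM3", "LAG3"), low = c("CD69", "OX40"),
         any_high = TRUE, priority = 1),
    rule("active", "CD69", low = "TIM3", priority = 2),
    rule("transition", c("CD69", "TIM3"), priority = 3),
    rule("proliferating", "Ki-67", priority = 4),
    rule("anergic", character(), low = c("CD69", "OX40", "LAG3", "TIM3"),
         priority = 5)
  )
}

validate_rulebook <- function(rulebook, markers = NULL) {
  if (!length(rulebook)) stop("empty rulebook", call. = FALSE)
  pr <- vapply(rulebook, `[[`, 0, "priority")
  if (anyDuplicated(pr)) stop("rulebook priorities must be unique", call. = FALSE)
  if (!is.null(markers)) {
    used <- unique(unlist(lapply(rulebook, function(r) c(r$high, r$low))))
    miss <- setdiff(used, markers)
    if (length(miss))
      stop("rulebook references unknown marker(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  rulebook[order(pr)]
}

# Blocked brute-force k-nearest-neighbour indices (excluding self).
knn_index <- function(m, k, block = 1024L) {
  n <- nrow(m)
  k <- min(k, n - 1L)
  idx <- matrix(0L, n, k)
  sq <- rowSums(m^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(m[rows, , drop = FALSE], m)
    d2[cbind(seq_along(rows), rows)] <- Inf
    idx[rows, ] <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  }
  idx
}

#' PhenoGraph-style graph community clustering
#'
#' Builds the k-nearest-neighbour graph of the cells, weights each edge by
#' the Jaccard overlap of the two endpoints' neighbour sets, and partitions
#' the graph with Louvain community detection.
#'
#' @param z numeric matrix, cells x markers.
#' @param k number of nearest neighbours (default 30).
#' @param seed integer seed (Louvain is stochastic).
#' @param resolution Louvain resolution; values below 1 favour coarser
#'   partitions.
#' @return integer cluster labels, one per cell.
#' @export
phenograph_cluster <- function(z, k = 30, seed = 1L, resolution = 1) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 cells", call. = FALSE)
  nn <- knn_index(z, k)
  k <- ncol(nn)
  from <- rep(seq_len(nrow(z)), k)
  to <- as.vector(nn)
  # Jaccard weight of each kNN edge from shared neighbourhoods
  nb <- lapply(seq_len(nrow(z)), function(i) c(i, nn[i, ]))
  w <- vapply(seq_along(from), function(e) {
    a <- nb[[from[e]]]; b <- nb[[to[e]]]
    inter <- sum(a %in% b)
    inter / (length(a) + length(b) - inter)
  }, 0)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "mean")
  set.seed(seed)
  as.integer(igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
}

#' ClusterX-style density-peak clustering
#'
#' Density-peak clustering: each cell's local density is a Gaussian-kernel
#' sum at bandwidth `dc` (default: the 2% quantile of pairwise distances);
#' its separation is the distance to the nearest cell of higher density.
#' Cluster centres are selected automatically as the largest multiplicative
#' gap in the sorted density x separation product, and every other cell
#' inherits the cluster of its nearest higher-density neighbour.
#'
#' @param z numeric matrix, cells x markers.
#' @param dc kernel bandwidth; estimated from the data when NULL.
#' @param n_centers fixed number of centres; automatic when NULL.
#' @param center_threshold normalised density-times-separation threshold for
#'   the automatic centre selection.
#' @param max_centers upper bound for the automatic centre search.
#' @return integer cluster labels.
#' @export
densitypeak_cluster <- function(z, dc = NULL, n_centers = NULL,
                                center_threshold = 0.05, max_centers = 30L) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  d <- as.matrix(dist(z))
  if (is.null(dc)) {
    dc <- quantile(d[upper.tri(d)], 0.02)
    if (dc == 0) dc <- mean(d[upper.tri(d)])
    if (dc == 0) dc <- 1
  }
  rho <- rowSums(exp(-(d / dc)^2)) - 1
  # strict density order; ties broken by index so duplicates chain together
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nneigh <- integer(n)
  delta[ord[1]] <- max(d[ord[1], ])
  nneigh[ord[1]] <- ord[1]
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nneigh[i] <- j
  }
  # normalised density x separation product; a point is a centre when both
  # its density and its distance to any denser point are large
  gamma <- (rho / max(rho)) * (delta / max(delta))
  if (is.null(n_centers)) {
    centers <- which(gamma > center_threshold)
    if (!length(centers)) centers <- which.max(gamma)
    if (length(centers) > max_centers)
      centers <- order(gamma, decreasing = TRUE)[seq_len(max_centers)]
  } else {
    centers <- order(gamma, decreasing = TRUE)[seq_len(n_centers)]
  }
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] == 0L) labels[i] <- labels[nneigh[i]]
  }
  labels
}

#' Cluster cells with three independent algorithms
#'
#' Runs k-means, PhenoGraph-style kNN/Louvain, and ClusterX-style
#' density-peak clustering over the phenotypic-marker z-scores. The number of
#' k-means clusters defaults to the silhouette-best k over `k_range`
#' (computed on a subsample of at most 2000 cells for tractability).
#'
#' @param z numeric matrix, cells x phenotypic markers (z-scores).
#' @param k_kmeans fixed k for k-means; chosen by silhouette when NULL.
#' @param k_range candidate k range for the silhouette search.
#' @param knn_k neighbourhood size for the PhenoGraph-style method.
#' @param seed integer seed; all three methods are deterministic given it.
#' @return named list of integer label vectors (`kmeans`, `phenograph`,
#'   `clusterx`), with the parameters used stored in attribute `"params"`.
#' @export
cluster_three_ways <- function(z, k_kmeans = NULL, k_range = c(10, 30),
                               knn_k = 30, seed = 1L) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 cells", call. = FALSE)
  if (is.null(k_kmeans)) k_kmeans <- choose_k_silhouette(z, k_range, seed)
  set.seed(seed)
  km <- kmeans(z, centers = k_kmeans, nstart = 10, iter.max = 100)$cluster
  pg <- phenograph_cluster(z, k = knn_k, seed = seed)
  cx <- densitypeak_cluster(z)
  out <- list(kmeans = as.integer(km), phenograph = pg, clusterx = cx)
  attr(out, "params") <- list(k_kmeans = k_kmeans, knn_k = knn_k, seed = seed)
  out
}

choose_k_silhouette <- function(z, k_range, seed = 1L, max_cells = 2000L) {
  set.seed(seed)
  idx <- if (nrow(z) > max_cells) sample.int(nrow(z), max_cells) else seq_len(nrow(z))
  zz <- z[idx, , drop = FALSE]
  dd <- dist(zz)
  ks <- seq(max(2, k_range[1]), min(k_range[2], nrow(zz) - 1))
  sil <- vapply(ks, function(k) {
    cl <- kmeans(zz, centers = k, nstart = 5, iter.max = 50)$cluster
    mean(cluster::silhouette(cl, dd)[, 3])
  }, 0)
  ks[which.max(sil)]
}

#' Annotate clusters with phenotypes via the rulebook
#'
#' Represents each cluster by its per-marker mean z-vector and assigns the
#' highest-priority phenotype whose required-high markers all exceed
#' `high_threshold` (any one of them with `any_high`) and whose required-low
#' markers are not elevated; clusters matching no rule are `"unassigned"`.
#'
#' Thresholding is baseline-aware: overall staining brightness shifts every
#' marker of a cluster up or down together, so each mean is also read
#' relative to the cluster's across-marker baseline (the median of its mean
#' vector). A required-high marker passes when its mean exceeds
#' `high_threshold` absolutely or sits at least `high_margin` above the
#' baseline; a required-low marker passes when its mean is below
#' `low_threshold` or within `low_margin` of the baseline. A genuinely
#' co-expressed marker sits far above the baseline and still disqualifies a
#' required-low rule.
#'
#' @param mean_vectors clusters x markers matrix of mean z-scores (rownames =
#'   cluster ids).
#' @param rulebook a rule list as from [default_rulebook()].
#' @param high_threshold,low_threshold mean-z thresholds defining "high" and
#'   "low".
#' @param high_margin required elevation of a high marker above the
#'   cluster's across-marker median (alternative to the absolute threshold).
#' @param low_margin allowed elevation of a required-low marker above the
#'   cluster's across-marker median.
#' @return data.frame with `cluster_id` and `phenotype`.
#' @export
annotate_clusters <- function(mean_vectors, rulebook = default_rulebook(),
                              high_threshold = 0.5, low_threshold = -0.1,
                              high_margin = 0.5, low_margin = 0.2) {
  rulebook <- validate_rulebook(rulebook, colnames(mean_vectors))
  assign_one <- function(v) {
    base <- stats::median(v)
    hi_cut <- min(high_threshold, base + high_margin)
    lo_cut <- max(low_threshold, base + low_margin)
    for (r in rulebook) {
      hi <- v[r$high]
      ok_hi <- if (!length(r$high)) TRUE
        else if (isTRUE(r$any_high)) any(hi >= hi_cut)
        else all(hi >= hi_cut)
      ok_lo <- all(v[r$low] <= lo_cut)
      if (ok_hi && ok_lo) return(r$phenotype)
    }
    "unassigned"
  }
  data.frame(cluster_id = rownames(mean_vectors),
             phenotype = apply(mean_vectors, 1, assign_one),
             row.names = NULL, stringsAsFactors = FALSE)
}

cluster_means <- function(z, labels) {
  m <- aggregate(as.data.frame(z), by = list(.cluster = labels), FUN = mean)
  out <- as.matrix(m[, -1, drop = FALSE])
  rownames(out) <- as.character(m$.cluster)
  colnames(out) <- colnames(z)
  out
}

# Per-cell phenotype under one method: cluster, annotate, map back.
phenotype_by_method <- function(z, labels, rulebook, high_threshold = 0.5,
                                low_threshold = -0.1, ...) {
  ann <- annotate_clusters(cluster_means(z, labels), rulebook,
                           high_threshold, low_threshold, ...)
  ann$phenotype[match(as.character(labels), ann$cluster_id)]
}

#' Consensus phenotype assignment across methods
#'
#' A cell keeps a phenotype only if at least two of the three methods
#' annotate it with that same phenotype; otherwise it is discarded (NA).
#' `"unassigned"` never counts as an agreeing phenotype.
#'
#' @param labels_list list of three per-cell phenotype character vectors of
#'   equal length.
#' @return character vector of consensus phenotypes (NA = discarded);
#'   attribute `"inclusion_fraction"` is the fraction of cells retained.
#' @export
consensus_assign <- function(labels_list) {
  stopifnot(length(labels_list) >= 2)
  n <- unique(lengths(labels_list))
  if (length(n) != 1) stop("labelings must cover identical cell sets", call. = FALSE)
  m <- do.call(cbind, labels_list)
  out <- apply(m, 1, function(v) {
    v <- v[!is.na(v) & v != "unassigned"]
    if (!length(v)) return(NA_character_)
    tab <- table(v)
    if (max(tab) >= 2) names(which.max(tab)) else NA_character_
  })
  attr(out, "inclusion_fraction") <- mean(!is.na(out))
  out
}

#' Full consensus phenotyping of a cell table
#'
#' Clusters the phenotypic-marker z-scores three ways, annotates each
#' method's clusters with the rulebook, and keeps per cell the phenotype on
#' which at least two methods agree.
#'
#' @param x normalised cell table.
#' @param markers phenotypic markers to cluster on (default
#'   [tilax_phenotypic_markers()] intersected with the table's markers).
#' @param rulebook,high_threshold,low_threshold see [annotate_clusters()].
#' @param ... passed to [cluster_three_ways()].
#' @return the table with a `phenotype` column (NA = discarded); attributes
#'   `"inclusion_fraction"` and `"method_phenotypes"` (the three per-cell
#'   labelings).
#' @export
phenotype_cells <- function(x, markers = NULL, rulebook = default_rulebook(),
                            high_threshold = 0.5, low_threshold = -0.1, ...) {
  if (is.null(markers))
    markers <- intersect(tilax_phenotypic_markers(), cell_markers(x))
  z <- as.matrix(x[, markers, drop = FALSE])
  cl <- cluster_three_ways(z, ...)
  phens <- lapply(cl, function(lab)
    phenotype_by_method(z, lab, rulebook, high_threshold, low_threshold))
  cons <- consensus_assign(phens)
  x$phenotype <- as.character(cons)
  attr(x, "inclusion_fraction") <- attr(cons, "inclusion_fraction")
  attr(x, "method_phenotypes") <- phens
  x <- set_markers(x, cell_markers(x))
  x
}

#' Functional subclustering of one phenotype
#'
#' Applies the PhenoGraph-style clustering to the functional-marker z-scores
#' of the cells of one phenotype and annotates the subclusters with a
#' functional rulebook (Tcy cells use their personalised marker panel,
#' [tilax_tcy_functional_markers()], and [default_functional_rulebook()]).
#'
#' @param x cell table restricted to one phenotype.
#' @param markers functional markers (default depends on `tcy`).
#' @param rulebook functional rule list.
#' @param tcy use the Tcy personalised panel/rulebook defaults.
#' @param min_cells below this count the phenotype becomes a single
#'   functional cluster with a warning.
#' @param k,seed clustering parameters.
#' @param high_threshold,low_threshold annotation thresholds.
#' @return character vector of functional labels, one per cell.
#' @export
functional_subcluster <- function(x, markers = NULL, rulebook = NULL,
                                  tcy = FALSE, min_cells = 20L, k = 30,
                                  seed = 1L, high_threshold = 0.5,
                                  low_threshold = -0.1) {
  if (is.null(markers))
    markers <- intersect(
      if (tcy) tilax_tcy_functional_markers() else tilax_functional_markers(),
      cell_markers(x))
  if (is.null(rulebook)) rulebook <- default_functional_rulebook()
  z <- as.matrix(x[, markers, drop = FALSE])
  if (nrow(z) < min_cells) {
    warning("fewer than ", min_cells, " cells; single functional cluster")
    labels <- rep(1L, nrow(z))
  } else {
    labels <- phenograph_cluster(z, k = min(k, nrow(z) - 1), seed = seed)
  }
  phenotype_by_method(z, labels, rulebook, high_threshold, low_threshold)
}
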