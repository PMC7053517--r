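#' Remove cells expressed in too few markers
#'
#' Quality-control filter over the raw single-cell MFI table: a cell is kept
#' only if its raw intensity exceeds `threshold` in at least
#' `min_expressed_markers` markers. The positivity threshold is a parameter
#' (default 0, i.e. any signal after upstream background subtraction counts
#' as expression).
#'
#' @param x cell table with one raw-MFI column per marker.
#' @param min_expressed_markers minimum number of expressed markers.
#' @param threshold positivity threshold on the raw MFI.
#' @param markers marker columns (defaults to the table's `"markers"`
#'   attribute).
#' @return the filtered table; attribute `"n_removed"` records the count of
#'   dropped cells.
#' @export
filter_cells <- function(x, min_expressed_markers = 3, threshold = 0,
                         markers = NULL) {
  if (nrow(x) == 0) stop("empty cell table", call. = FALSE)
  markers <- cell_markers(x, markers)
  expressed <- rowSums(as.matrix(x[, markers, drop = FALSE]) > threshold)
  keep <- expressed >= min_expressed_markers
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- set_markers(out, markers)
  attr(out, "n_removed") <- sum(!keep)
  if (any(!keep))
    message(sum(!keep), " cell(s) removed (expressed in fewer than ",
            min_expressed_markers, " markers)")
  out
}

#' Remove markers expressed in too small a fraction of cells
#'
#' Drops marker columns whose raw intensity exceeds `threshold` in fewer than
#' `min_fraction` of the cells. A marker expressed in exactly `min_fraction`
#' of cells is retained ("at least" semantics).
#'
#' @inheritParams filter_cells
#' @param min_fraction minimum fraction of expressing cells.
#' @return the table without the dropped marker columns; attribute
#'   `"dropped_markers"` lists them.
#' @export
filter_markers <- function(x, min_fraction = 0.01, threshold = 0,
                           markers = NULL) {
  markers <- cell_markers(x, markers)
  if (length(markers) < 1) stop("no marker columns", call. = FALSE)
  frac <- colMeans(as.matrix(x[, markers, drop = FALSE]) > threshold)
  drop <- markers[frac < min_fraction]
  if (length(drop) == length(markers))
    stop("all markers would be dropped", call. = FALSE)
  keep <- setdiff(markers, drop)
  out <- x[, setdiff(colnames(x), drop), drop = FALSE]
  out <- set_markers(out, keep)
  attr(out, "dropped_markers") <- drop
  if (length(drop))
    message(length(drop), " marker(s) dropped (expressed in < ",
            min_fraction * 100, "% of cells): ", paste(drop, collapse = ", "))
  out
}

#' Normalise marker intensities to trimmed z-scores
#'
#' Per marker, computes z = (MFI - mean) / sd over all retained cells (sample
#' sd, n-1 denominator) and clamps the result to \[-clip, +clip\]. With
#' `per_core = TRUE` the mean/sd are computed within each core instead (a
#' sensitivity-analysis mode; the default global mode matches the standard
#' pre-processing).
#'
#' @inheritParams filter_cells
#' @param clip trim bound; z-scores beyond ±clip are clamped.
#' @param per_core compute the mean/sd per core instead of globally.
#' @return the table with marker columns replaced by trimmed z-scores;
#'   attribute `"n_clipped"` holds the number of clamped values.
#' @export
zscore_trim <- function(x, clip = 5, per_core = FALSE, markers = NULL) {
  markers <- cell_markers(x, markers)
  if (nrow(x) < 2) stop("need at least 2 cells to compute z-scores", call. = FALSE)
  z_block <- function(m) {
    sds <- apply(m, 2, sd)
    bad <- colnames(m)[!is.finite(sds) | sds == 0]
    if (length(bad))
      stop("zero-variance marker(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    scale(m, center = TRUE, scale = sds)
  }
  m <- as.matrix(x[, markers, drop = FALSE])
  z <- if (per_core) {
    out <- m
    for (cid in unique(x$core_id)) {
      idx <- x$core_id == cid
      out[idx, ] <- z_block(m[idx, , drop = FALSE])
    }
    out
  } else z_block(m)
  n_clipped <- sum(abs(z) > clip)
  z <- clamp(z, -clip, clip)
  x[markers] <- as.data.frame(as.matrix(z))
  x <- set_markers(x, markers)
  attr(x, "n_clipped") <- n_clipped
  x
}

#' Pearson correlation between markers
#'
#' @inheritParams filter_cells
#' @return symmetric marker-by-marker correlation matrix with unit diagonal.
#' @export
marker_correlation <- function(x, markers = NULL) {
  markers <- cell_markers(x, markers)
  if (nrow(x) < 2) stop("need at least 2 cells", call. = FALSE)
  cor(as.matrix(x[, markers, drop = FALSE]), method = "pearson")
}
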