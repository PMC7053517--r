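#' Fit the PCA activation gradient on CD8+ cells
#'
#' Fits a principal-component model over the z-scored intensities of the four
#' functional markers CD69, OX40, LAG3 and TIM3 measured on CD8+ (Tcy) cells,
#' and derives from it an activation gradient: a map from a cell's marker
#' profile to a score in \[-1, 1\], where +1 is maximal activation (the CD69
#' loading direction) and -1 maximal exhaustion (the TIM3 loading direction).
#'
#' The first principal component of MFI data of this kind is a common-mode
#' staining axis (all four loadings share one sign) and carries no functional
#' contrast; components 2 and 3 are therefore retained by default. If the
#' fitted PC1 is *not* common-mode a warning is emitted and the model falls
#' back to the pair of components whose plane maximally separates the CD69
#' and TIM3 loading directions in angle.
#'
#' Sign indeterminacy of the PCs is fixed by requiring the CD69 loading to
#' have a positive coordinate on the first retained component and the TIM3
#' loading a negative coordinate on the second; the anchor directions are the
#' unit CD69 and TIM3 loading vectors in the retained plane after this fix.
#'
#' @param z numeric matrix or data.frame of z-scored intensities with columns
#'   CD69, OX40, LAG3, TIM3 (in that order, or named so they can be
#'   reordered); one row per CD8+ cell, n >= 10.
#' @param components indices of the two retained components (default 2 and 3).
#' @param method gradient parameterisation used by [predict.activation_model()]:
#'   `"arc"` (linear in angle along the shorter arc between the anchors,
#'   clamped beyond them — the default) or `"axis"` (cosine of the angle to
#'   the anchor-difference axis).
#' @return an object of class `activation_model` with elements `rotation`
#'   (full 4x4 loadings), `loadings` (4x2 retained loadings after sign fix),
#'   `component_indices`, `center` (marker means of the training data),
#'   `centroid` (projected centroid, in the retained plane),
#'   `anchor_active`, `anchor_exhausted` (unit 2-vectors), `marker_order`,
#'   `method`, `n`, `sdev`, and `scores` (training activation scores).
#' @seealso [predict.activation_model()], [classify_cores()]
#' @export
activation_model <- function(z, components = c(2L, 3L),
                             method = c("arc", "axis")) {
  method <- match.arg(method)
  marker_order <- tilax_activation_markers()
  z <- as.matrix(z)
  if (!is.null(colnames(z))) {
    miss <- setdiff(marker_order, colnames(z))
    if (length(miss))
      stop("missing activation marker column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    z <- z[, marker_order, drop = FALSE]
  } else if (ncol(z) == 4) {
    colnames(z) <- marker_order
  } else stop("z must have 4 columns (CD69, OX40, LAG3, TIM3)", call. = FALSE)
  if (nrow(z) < 10) stop("need at least 10 CD8+ cells", call. = FALSE)
  sds <- apply(z, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(z)[sds == 0], collapse = ", "),
         call. = FALSE)

  pca <- prcomp(z, center = TRUE, scale. = FALSE)
  rot <- pca$rotation

  pc1_common <- all(rot[, 1] > 0) || all(rot[, 1] < 0)
  if (!pc1_common) {
    warning("PC1 loadings do not share a sign; falling back to the ",
            "component pair maximally separating CD69 from TIM3")
    pairs <- utils::combn(ncol(rot), 2)
    ang <- apply(pairs, 2, function(p) {
      a <- rot["CD69", p]; e <- rot["TIM3", p]
      if (all(a == 0) || all(e == 0)) return(0)
      acos(clamp(sum(unit(a) * unit(e)), -1, 1))
    })
    components <- pairs[, which.max(ang)]
  }
  components <- as.integer(components)
  if (length(components) != 2 || components[1] == components[2])
    stop("components must be two distinct indices", call. = FALSE)

  L <- rot[, components, drop = FALSE]
  # sign fix: CD69 positive on the first retained axis, TIM3 negative on the
  # second, so activation points "right" and exhaustion "down" reproducibly
  if (L["CD69", 1] < 0) L[, 1] <- -L[, 1]
  if (L["TIM3", 2] > 0) L[, 2] <- -L[, 2]

  anchor_active <- unit(L["CD69", ])
  anchor_exhausted <- unit(L["TIM3", ])
  cosang <- clamp(sum(anchor_active * anchor_exhausted), -1, 1)
  if (acos(cosang) < 1e-6)
    stop("CD69 and TIM3 anchors are collinear; no gradient plane", call. = FALSE)

  proj <- scale(z, center = pca$center, scale = FALSE) %*% L
  centroid <- colMeans(proj)

  model <- structure(list(
    rotation = rot,
    loadings = L,
    component_indices = components,
    center = pca$center,
    centroid = centroid,
    anchor_active = anchor_active,
    anchor_exhausted = anchor_exhausted,
    marker_order = marker_order,
    method = method,
    n = nrow(z),
    sdev = pca$sdev
  ), class = "activation_model")
  model$scores <- predict(model, z)
  model
}

#' Score cells along the activation gradient
#'
#' Projects cells into the retained component plane, centres them on the
#' model centroid, and maps the *direction* of each centred projection to an
#' activation score: +1 on the CD69 anchor, -1 on the TIM3 anchor, 0 at the
#' centroid and on the angular midpoint between the anchors. The score
#' depends only on the direction, not on the distance from the centroid. With
#' `method = "arc"` the score is linear in angle along the shorter arc from
#' the active to the exhausted anchor and clamped beyond the anchors; with
#' `method = "axis"` it is the cosine of the angle to the normalised
#' anchor-difference axis.
#'
#' @param object an [activation_model()].
#' @param newdata matrix/data.frame of z-scores with the model's four marker
#'   columns (CD69, OX40, LAG3, TIM3).
#' @param ... unused.
#' @return numeric vector of activation scores in \[-1, 1\].
#' @export
predict.activation_model <- function(object, newdata, ...) {
  z <- as.matrix(newdata)
  if (!is.null(colnames(z))) {
    miss <- setdiff(object$marker_order, colnames(z))
    if (length(miss))
      stop("marker order mismatch; missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    z <- z[, object$marker_order, drop = FALSE]
  } else if (ncol(z) != 4) {
    stop("newdata must have the model's 4 marker columns", call. = FALSE)
  }
  proj <- scale(z, center = object$center, scale = FALSE) %*% object$loadings
  v <- sweep(proj, 2, object$centroid)
  score_direction(v, object$anchor_active, object$anchor_exhausted,
                  object$method)
}

# Direction-only score of centred plane coordinates v (n x 2).
score_direction <- function(v, anchor_active, anchor_exhausted, method) {
  r <- sqrt(rowSums(v^2))
  theta <- atan2(v[, 2], v[, 1])
  th_a <- atan2(anchor_active[2], anchor_active[1])
  th_e <- atan2(anchor_exhausted[2], anchor_exhausted[1])
  if (method == "arc") {
    delta <- wrap_pi(th_e - th_a)          # signed shorter arc, active -> exhausted
    s <- sign(delta)
    # angle travelled from the active anchor in the arc direction, in [0, 2pi)
    u <- ((theta - th_a) * s) %% (2 * pi)
    w <- abs(delta)
    t <- clamp(u / w, 0, 1)
    score <- 1 - 2 * t
    # cells in the reflex region beyond the anchors: clamp to the nearer one
    reflex_mid <- (w + 2 * pi) / 2
    score[u > w & u < reflex_mid] <- -1
    score[u >= reflex_mid] <- 1
  } else {
    axis <- unit(anchor_active - anchor_exhausted)
    u <- v / ifelse(r > 0, r, 1)
    score <- clamp(u %*% axis, -1, 1)[, 1]
  }
  # the centroid is the gradient origin; distances at numerical-noise scale
  # count as "at the centroid"
  score[r < 1e-9] <- 0
  as.numeric(score)
}

#' @export
print.activation_model <- function(x, ...) {
  cat("Activation gradient model (PCA on CD69, OX40, LAG3, TIM3)\n")
  cat("  fitted on", x$n, "CD8+ cells; retained components:",
      paste0("PC", x$component_indices, collapse = ", "),
      "; method:", x$method, "\n")
  cat("  anchor (active, CD69):   ",
      sprintf("(% .3f, % .3f)", x$anchor_active[1], x$anchor_active[2]), "\n")
  cat("  anchor (exhausted, TIM3):",
      sprintf("(% .3f, % .3f)", x$anchor_exhausted[1], x$anchor_exhausted[2]), "\n")
  invisible(x)
}

#' @export
summary.activation_model <- function(object, ...) {
  ang <- acos(clamp(sum(object$anchor_active * object$anchor_exhausted), -1, 1))
  out <- list(model = object,
              anchor_angle_deg = ang * 180 / pi,
              var_explained = object$sdev^2 / sum(object$sdev^2),
              score_summary = summary(object$scores))
  class(out) <- "summary.activation_model"
  out
}

#' @export
print.summary.activation_model <- function(x, ...) {
  print(x$model)
  cat("  angle between anchors:", sprintf("%.1f deg", x$anchor_angle_deg), "\n")
  cat("  variance explained by PCs:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  cat("  training score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.activation_model <- function(object, ...) object$loadings

#' @export
fitted.activation_model <- function(object, ...) object$scores

#' Biplot of the activation gradient plane
#'
#' Plots the training cells in the retained component plane, coloured by
#' activation score, with the CD69 (active) and TIM3 (exhausted) anchor
#' directions drawn as arrows from the centroid.
#'
#' @param x an [activation_model()].
#' @param newdata optional z-score matrix to plot instead of nothing (the
#'   model does not store training projections; pass the training data to
#'   reproduce the fit plot).
#' @param ... passed to [graphics::plot()].
#' @export
plot.activation_model <- function(x, newdata = NULL, ...) {
  lab <- paste0("PC", x$component_indices)
  if (!is.null(newdata)) {
    z <- as.matrix(newdata)[, x$marker_order, drop = FALSE]
    proj <- scale(z, center = x$center, scale = FALSE) %*% x$loadings
    sc <- predict(x, newdata)
    col <- grDevices::hcl.colors(101, "RdYlBu")[round((sc + 1) * 50) + 1]
    plot(proj, col = col, pch = 16, cex = 0.4, xlab = lab[1], ylab = lab[2], ...)
  } else {
    plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2),
         xlab = lab[1], ylab = lab[2], ...)
  }
  arrows(x$centroid[1], x$centroid[2],
         x$centroid[1] + x$anchor_active[1], x$centroid[2] + x$anchor_active[2],
         col = "forestgreen", lwd = 2)
  arrows(x$centroid[1], x$centroid[2],
         x$centroid[1] + x$anchor_exhausted[1],
         x$centroid[2] + x$anchor_exhausted[2], col = "firebrick", lwd = 2)
  text(x$centroid[1] + 1.1 * x$anchor_active[1],
       x$centroid[2] + 1.1 * x$anchor_active[2], "CD69 (+1)", col = "forestgreen")
  text(x$centroid[1] + 1.1 * x$anchor_exhausted[1],
       x$centroid[2] + 1.1 * x$anchor_exhausted[2], "TIM3 (-1)", col = "firebrick")
  invisible(x)
}

#' Score every CD8+ cell of a cell table
#'
#' Convenience wrapper: selects the cells of `cd8_phenotype`, fits (or
#' re-uses) an [activation_model()] on their activation-marker z-scores and
#' writes the scores into an `activation` column.
#'
#' @param x normalised cell table with a `phenotype` column.
#' @param model optional pre-fitted model; fitted on `x`'s CD8 cells if NULL.
#' @param cd8_phenotype phenotype label identifying CD8+ cells.
#' @param ... passed to [activation_model()].
#' @return list with elements `table` (the input with an `activation` column,
#'   NA for non-CD8 cells) and `model`.
#' @export
score_activation <- function(x, model = NULL, cd8_phenotype = "Tcy", ...) {
  stopifnot_cols(x, "phenotype", "cell table")
  idx <- which(x$phenotype == cd8_phenotype)
  if (!length(idx)) stop("no cells with phenotype ", cd8_phenotype, call. = FALSE)
  z <- as.matrix(x[idx, tilax_activation_markers(), drop = FALSE])
  if (is.null(model)) model <- activation_model(z, ...)
  x$activation <- NA_real_
  x$activation[idx] <- predict(model, z)
  list(table = x, model = model)
}
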