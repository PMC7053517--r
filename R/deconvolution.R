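# Correlation-based assignment of single-cell expression profiles to immune
# signatures (LM22-style matrices), construction of Active/Exhausted CD8
# signatures from scored single cells, and fraction-based patient labelling.

#' Default activation transcript mapping
#'
#' A best-guess mapping of the four activation/exhaustion protein markers to
#' transcript symbols, shipped as a convenience default only — it is
#' synthetic/non-authoritative and should be replaced with the study-specific
#' gene list whenever one is available. OX40 maps to its receptor and ligand
#' transcripts (TNFRSF4, TNFSF4) and TIM3 to HAVCR2 and its ligand LGALS9.
#'
#' @return named character vector gene -> marker.
#' @export
default_activation_genes <- function() {
  c(CD69 = "CD69", OX40 = "TNFRSF4", OX40 = "TNFSF4",
    LAG3 = "LAG3", TIM3 = "HAVCR2", TIM3 = "LGALS9")
}

#' Assign cell types by Spearman correlation to signature profiles
#'
#' For each cell, computes the Spearman correlation of its expression vector
#' to every signature profile over the shared genes and assigns the
#' best-correlated type; cells whose maximum correlation is below `cutoff`
#' are unassigned (the rank correlation makes the assignment invariant to
#' any monotone transform of a cell's expression vector).
#'
#' @param expr cells x genes expression matrix (rownames = cell ids).
#' @param signatures genes x cell-types signature matrix (e.g. LM22 plus
#'   constructed profiles).
#' @param cutoff minimum correlation for an assignment (default 0.25; a cell
#'   at exactly the cutoff is assigned, below it removed).
#' @return data.frame: `cell_id`, `cell_type` (NA = unassigned), `max_cor`.
#' @export
assign_cell_types <- function(expr, signatures, cutoff = 0.25) {
  expr <- as.matrix(expr)
  signatures <- as.matrix(signatures)
  if (anyDuplicated(rownames(signatures)))
    stop("duplicate gene ids in the signature matrix", call. = FALSE)
  if (ncol(signatures) < 2)
    stop("need at least 2 signature cell types", call. = FALSE)
  shared <- intersect(toupper(colnames(expr)), toupper(rownames(signatures)))
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  message(length(shared), " shared gene(s) used for assignment")
  e <- expr[, match(shared, toupper(colnames(expr))), drop = FALSE]
  s <- signatures[match(shared, toupper(rownames(signatures))), , drop = FALSE]
  novar <- apply(e, 1, function(v) length(unique(v)) == 1)
  if (any(novar)) warning(sum(novar), " zero-variance cell(s) left unassigned")
  rho <- suppressWarnings(cor(t(e), s, method = "spearman"))
  best <- max.col(replace(rho, is.na(rho), -Inf), ties.method = "first")
  max_cor <- rho[cbind(seq_len(nrow(rho)), best)]
  type <- colnames(s)[best]
  type[is.na(max_cor) | max_cor < cutoff | novar] <- NA_character_
  data.frame(cell_id = if (is.null(rownames(expr))) seq_len(nrow(expr))
             else rownames(expr),
             cell_type = type, max_cor = max_cor,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build Active / Exhausted CD8 signature profiles
#'
#' Aggregates the activation transcripts to the four marker channels
#' (averaging multiple genes mapped to one marker), z-scores them, fits the
#' activation gradient ([activation_model()]) on the CD8 cells, splits cells
#' into Active (score > 0) and Exhausted (score <= 0), and returns the
#' per-class mean expression of the activation genes as two signature
#' profiles.
#'
#' @param cd8_expr cells x genes expression matrix of CD8+ cells.
#' @param activation_genes named character vector marker -> gene symbol (the
#'   6 activation transcripts; default [default_activation_genes()]).
#' @param ... passed to [activation_model()].
#' @return list with `profiles` (genes x 2 matrix, columns
#'   `T.cells.CD8.Active`, `T.cells.CD8.Exhausted`), `scores`, `class`,
#'   `model`.
#' @export
build_activation_signatures <- function(cd8_expr,
                                        activation_genes = default_activation_genes(),
                                        ...) {
  cd8_expr <- as.matrix(cd8_expr)
  genes <- intersect(unname(activation_genes), colnames(cd8_expr))
  if (length(genes) < 2)
    stop("too few activation genes found in the expression matrix", call. = FALSE)
  used <- activation_genes[activation_genes %in% genes]
  # aggregate transcripts to the four marker channels
  channels <- vapply(tilax_activation_markers(), function(mk) {
    g <- unname(used[names(used) == mk])
    if (!length(g)) return(rep(0, nrow(cd8_expr)))
    rowMeans(cd8_expr[, g, drop = FALSE])
  }, numeric(nrow(cd8_expr)))
  sds <- apply(channels, 2, sd)
  if (any(sds == 0))
    stop("constant activation channel(s): ",
         paste(colnames(channels)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(channels)
  model <- activation_model(z, ...)
  scores <- predict(model, z)
  cls <- ifelse(scores > 0, "Active", "Exhausted")
  if (length(unique(cls)) < 2)
    stop("one activation class is empty; cannot build both profiles",
         call. = FALSE)
  profiles <- cbind(
    T.cells.CD8.Active = colMeans(cd8_expr[cls == "Active", genes, drop = FALSE]),
    T.cells.CD8.Exhausted = colMeans(cd8_expr[cls == "Exhausted", genes, drop = FALSE]))
  list(profiles = profiles, scores = scores, class = cls, model = model)
}

#' Label patients from Active / Exhausted CD8 fractions
#'
#' A patient is Active if the fraction of Active CD8+ T cells is greater
#' than or equal to the Exhausted fraction, Exhausted otherwise. Patients
#' with a missing fraction are skipped with a message.
#'
#' @param fractions data.frame with `patient_id`, `active`, `exhausted`
#'   (non-negative fractions).
#' @return data.frame with `patient_id` and `label`.
#' @export
label_patients <- function(fractions) {
  stopifnot_cols(fractions, c("patient_id", "active", "exhausted"), "fractions")
  ok <- is.finite(fractions$active) & is.finite(fractions$exhausted)
  if (any(!ok))
    message("skipping patient(s) with missing fractions: ",
            paste(fractions$patient_id[!ok], collapse = ", "))
  d <- fractions[ok, , drop = FALSE]
  if (any(d$active < 0 | d$exhausted < 0))
    stop("fractions must be non-negative", call. = FALSE)
  data.frame(patient_id = d$patient_id,
             label = ifelse(d$active >= d$exhausted, "Active", "Exhausted"),
             row.names = NULL, stringsAsFactors = FALSE)
}
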