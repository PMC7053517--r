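# Internal helpers shared across modules.

# Marker columns of a cell table: the "markers" attribute when present,
# otherwise every column that is not a reserved id/coordinate/label column.
cell_markers <- function(x, markers = NULL) {
  if (!is.null(markers)) return(markers)
  m <- attr(x, "markers")
  if (!is.null(m)) return(m)
  reserved <- c("cell_id", "patient_id", "core_id", "x", "y",
                "phenotype", "functional_label", "activation")
  setdiff(colnames(x), reserved)
}

set_markers <- function(x, markers) {
  attr(x, "markers") <- markers
  x
}

stopifnot_cols <- function(x, cols, what = "table") {
  miss <- setdiff(cols, colnames(x))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

# Wrap an angle into (-pi, pi].
wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}
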