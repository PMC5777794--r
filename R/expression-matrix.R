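#' Construct an expression matrix container
#'
#' Light container for a log2-scale expression matrix (features x samples)
#' with optional per-cell detection flags, as produced by array platforms.
#' Feature and sample identifiers live in `rownames`/`colnames` and must be
#' unique; values must be finite.
#'
#' @param values Numeric matrix of log2 expression, features in rows,
#'   samples in columns. Must carry unique rownames and colnames.
#' @param detected Optional logical matrix of the same shape flagging
#'   whether each measurement was called detected on the array.
#' @return An object of class `"expr_mat"`: a list with elements `values`
#'   and `detected` (possibly `NULL`).
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' x <- expr_mat(m)
#' dim(x)
#' @export
expr_mat <- function(values, detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  # R normalizes zero-length dimnames to NULL, so empty dimensions are
  # exempt from the naming requirement
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (!is.null(detected)) {
    if (!is.logical(detected) || !identical(dim(detected), dim(values)))
      stop("'detected' must be a logical matrix with the same shape as 'values'")
    dimnames(detected) <- dimnames(values)
  }
  structure(list(values = values, detected = detected), class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
dimnames.expr_mat <- function(x) dimnames(x$values)

#' Subset an expression matrix
#'
#' Subsets features and/or samples, carrying detection flags along.
#'
#' @param x An [expr_mat()] object.
#' @param i,j Feature / sample indices (integer, logical or character).
#' @param ... Ignored.
#' @return An `expr_mat` with the selected rows and columns.
#' @export
`[.expr_mat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expr_mat(x$values[i, j, drop = FALSE],
           if (!is.null(x$detected)) x$detected[i, j, drop = FALSE])
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d features x %d samples (%s detection flags)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detected)) "no" else "with"))
  invisible(x)
}

#' Feature identifiers of an expression matrix
#' @param x An [expr_mat()] object.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) {
  rn <- rownames(x$values)
  if (is.null(rn)) character(0) else rn
}

#' Sample identifiers of an expression matrix
#' @param x An [expr_mat()] object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  cn <- colnames(x$values)
  if (is.null(cn)) character(0) else cn
}
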