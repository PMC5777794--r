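# Matrix-level preprocessing: probeset collapse, detection filtering,
# quantile normalization.

#' Collapse probesets to genes by maximal mean expression
#'
#' When several probesets map to one gene, the probeset whose mean across
#' samples is highest is kept verbatim as that gene's row. Probesets
#' absent from the map are dropped. Ties on the mean are broken toward the
#' lexicographically smallest probeset id, so the result is deterministic.
#'
#' @param m An [expr_mat()] keyed by probeset ids.
#' @param map Data frame with columns `probeset` and `gene`; probeset ids
#'   must be unique, a gene may own many probesets.
#' @return An [expr_mat()] keyed by gene symbols, one row per mapped gene.
#' @export
collapse_probesets <- function(m, map) {
  stopifnot(inherits(m, "expr_mat"),
            all(c("probeset", "gene") %in% names(map)))
  if (anyDuplicated(map$probeset)) stop("probeset ids in map must be unique")
  keep <- intersect(feature_ids(m), map$probeset)
  if (!length(keep)) stop("no probesets shared between matrix and map")
  m <- m[keep, ]
  gene <- map$gene[match(keep, map$probeset)]
  means <- rowMeans(m$values)
  # order: gene, then mean descending, then probeset id ascending; the
  # first row per gene is the winner
  o <- order(gene, -means, keep)
  first <- !duplicated(gene[o])
  win <- o[first]
  out <- m[win, ]
  rownames(out$values) <- gene[win]
  if (!is.null(out$detected)) rownames(out$detected) <- gene[win]
  out[order(gene[win]), ]
}

#' Filter features by detection fraction
#'
#' Keeps features detected in at least `min_frac` of samples. With the
#' default 0.25 this is the miRNA-platform rule (drop miRNAs detected in
#' fewer than 25% of samples); `min_frac = 0` with `mode = "any"` gives
#' the mRNA rule of dropping only features absent in every sample.
#'
#' @param m An [expr_mat()] with detection flags.
#' @param min_frac Minimum detection fraction in \[0, 1\].
#' @param mode `"frac"` keeps features with detection fraction >=
#'   `min_frac`; `"any"` keeps features detected in at least one sample
#'   (the all-absent rule), ignoring `min_frac`.
#' @return The filtered [expr_mat()].
#' @export
detection_filter <- function(m, min_frac = 0.25, mode = c("frac", "any")) {
  stopifnot(inherits(m, "expr_mat"))
  mode <- match.arg(mode)
  if (is.null(m$detected))
    stop("detection flags are required; supply an expr_mat with 'detected'")
  frac <- rowMeans(m$detected)
  keep <- if (mode == "any") frac > 0 else frac >= min_frac
  m[keep, ]
}

#' Quantile-normalize samples to a common distribution
#'
#' Forces every sample column onto the identical empirical distribution:
#' the value at within-column rank r is replaced by the mean over columns
#' of their r-th order statistics. Ties within a column receive the mean
#' of the reference quantiles they span (average ranks), so within-column
#' rank order is preserved.
#'
#' @param m An [expr_mat()].
#' @return The normalized [expr_mat()] (detection flags untouched).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  x <- m$values
  n <- nrow(x)
  if (n < 1 || ncol(x) < 1) stop("empty matrix")
  sorted <- apply(x, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(x, 2, function(col) {
    o <- order(col)
    # tied values span a block of sorted positions; each block gets the
    # mean of the reference quantiles it spans
    grp <- cumsum(!duplicated(col[o]))
    gm <- as.vector(rowsum(ref, grp) / tabulate(grp))
    res <- numeric(n)
    res[o] <- gm[grp]
    res
  })
  dimnames(out) <- dimnames(x)
  expr_mat(out, m$detected)
}
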