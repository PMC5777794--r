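# Readers/writers for the plain-text formats the pipeline exchanges:
# expression TSV (first column feature id, header = sample ids), sample
# annotation TSV, BED-like locus TSV, target-prediction TSV, GMT, edge lists.

#' Write an expression matrix to TSV
#'
#' First column `feature`, remaining columns one per sample. Detection
#' flags, when present, go to a sibling file `<path>.detected.tsv` with an
#' identical layout of TRUE/FALSE values.
#'
#' @param x An [expr_mat()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expr_tsv <- function(x, path) {
  df <- data.frame(feature = feature_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$detected)) {
    dd <- data.frame(feature = feature_ids(x), x$detected,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dd, paste0(path, ".detected.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Inverse of [write_expr_tsv()]; picks up `<path>.detected.tsv` when it
#' exists.
#'
#' @param path File written by [write_expr_tsv()].
#' @return An [expr_mat()] object.
#' @export
read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  det_path <- paste0(path, ".detected.tsv")
  det <- NULL
  if (file.exists(det_path)) {
    dd <- utils::read.delim(det_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    det <- as.matrix(dd[, -1, drop = FALSE]) == "TRUE" |
      as.matrix(dd[, -1, drop = FALSE]) == TRUE
    mode(det) <- "logical"
    rownames(det) <- dd[[1]]
  }
  expr_mat(vals, det)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids; the `description`
#'   field is kept in an attribute of the same name on each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    structure(unique(f[-(1:2)]), description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Read a BED-like gene locus table
#'
#' Four tab-separated columns without header: chromosome, start, end, gene
#' (0-based half-open coordinates).
#'
#' @param path Path to the locus TSV.
#' @return A `data.frame` with columns `gene`, `chrom`, `start`, `end` and
#'   an `order` column giving each gene's rank by start within its
#'   chromosome.
#' @export
read_gene_loci <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene"))
  as_gene_loci(df[, c("gene", "chrom", "start", "end")])
}

#' Validate and order a gene locus table
#'
#' @param df Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @return The same table with rows ordered by chromosome then start and an
#'   `order` column (1-based position index within chromosome).
#' @export
as_gene_loci <- function(df) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("one locus per gene required")
  if (any(df$start >= df$end)) stop("locus start must be < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$order <- stats::ave(df$start, df$chrom, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Write a gene locus table as BED
#' @param loci Table from [as_gene_loci()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_loci <- function(loci, path) {
  utils::write.table(loci[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV with a header
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-prediction table from TSV
#'
#' Expects the columns written by the synthetic generator: `mirna`, `gene`,
#' `source`, `pairing_score`, `conservation`, `context_score`,
#' `target_score` (score fields are `NA` for sources that do not report
#' them). A `col_map` renames nonstandard headers, e.g.
#' `c(miRNA = "mirna")`.
#'
#' @param path Path to the TSV.
#' @param col_map Optional named character vector mapping file column names
#'   to standard names.
#' @return A `data.frame` in standard column order.
#' @export
read_target_predictions <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    if (anyNA(idx)) stop("col_map names absent from file header")
    names(df)[idx] <- unname(col_map)
  }
  need <- c("mirna", "gene", "source", "pairing_score", "conservation",
            "context_score", "target_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing target-prediction columns: ",
                         paste(miss, collapse = ", "))
  df[, need]
}
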