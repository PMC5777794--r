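# Set-overlap Fisher tests, hypergeometric over-representation on GMT
# sets, positional (chromosomal-interval) enrichment, per-chromosome
# down-regulation summaries and a kernel-smoothed expression track.

#' Fisher / hypergeometric test of overlap between two gene sets
#'
#' Tests the 2x2 table ((overlap, a - overlap), (b - overlap,
#' universe - a - b + overlap)). The enrichment tail is the
#' hypergeometric upper tail P(X >= overlap); depletion is the lower
#' tail; two-sided uses Fisher's exact test.
#'
#' @param set_a_size,set_b_size Sizes of the two sets.
#' @param overlap Observed overlap.
#' @param universe Size of the gene universe both sets live in.
#' @param tail One of `"enrichment"`, `"depletion"`, `"two-sided"`.
#' @return List with `odds_ratio` (sample odds ratio of the table) and
#'   `p`.
#' @export
overlap_fisher <- function(set_a_size, set_b_size, overlap, universe,
                           tail = c("enrichment", "depletion", "two-sided")) {
  tail <- match.arg(tail)
  if (overlap > min(set_a_size, set_b_size) ||
      set_a_size > universe || set_b_size > universe ||
      universe - set_a_size - set_b_size + overlap < 0 || overlap < 0)
    stop("inconsistent 2x2 counts")
  tab <- matrix(c(overlap, set_a_size - overlap,
                  set_b_size - overlap,
                  universe - set_a_size - set_b_size + overlap), 2, 2)
  p <- switch(tail,
    enrichment = stats::phyper(overlap - 1, set_a_size,
                               universe - set_a_size, set_b_size,
                               lower.tail = FALSE),
    depletion = stats::phyper(overlap, set_a_size, universe - set_a_size,
                              set_b_size, lower.tail = TRUE),
    `two-sided` = stats::fisher.test(tab)$p.value)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = p)
}

#' Hypergeometric over-representation of gene sets
#'
#' Restricts each gene set to the universe, then tests its overlap with
#' the query genes by the hypergeometric upper tail; BH adjustment across
#' the tested sets. Sets disjoint from the universe are skipped with a
#' warning.
#'
#' @param de_genes Character vector of query genes (restricted to the
#'   universe internally).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: all genes eligible for selection.
#' @return Data.frame with `set`, `set_size`, `overlap`, `p`, `fdr`,
#'   ordered by p.
#' @export
gene_set_ora <- function(de_genes, gene_sets, universe) {
  universe <- unique(universe)
  de <- intersect(unique(de_genes), universe)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, universe)),
                  integer(1))
  empty <- sizes == 0
  if (any(empty))
    warning(sum(empty), " gene set(s) disjoint from universe skipped")
  gene_sets <- gene_sets[!empty]
  sizes <- sizes[!empty]
  if (!length(gene_sets))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  ov <- vapply(gene_sets, function(s)
    length(intersect(intersect(s, universe), de)), integer(1))
  p <- stats::phyper(ov - 1, length(de), length(universe) - length(de),
                     sizes, lower.tail = FALSE)
  out <- data.frame(set = names(gene_sets), set_size = sizes, overlap = ov,
                    p = p, fdr = benjamini_hochberg(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Positional enrichment of differential genes in chromosomal intervals
#'
#' Scans, per chromosome, every interval of consecutive genes (by
#' position order) up to `max_window` genes, scoring each with the
#' hypergeometric upper tail of its differential-gene count against the
#' genome-wide differential fraction. BH adjustment is applied across all
#' scored intervals, then non-overlapping intervals are retained greedily
#' in ascending p order; intervals with fdr above `fdr_cut` are dropped.
#'
#' @param de_genes Character vector of differential genes; genes without
#'   a locus are excluded with a warning.
#' @param loci Gene locus table from [as_gene_loci()].
#' @param max_window Maximum interval length in genes (default 250).
#' @param fdr_cut FDR threshold for retained intervals (default 0.05).
#' @return Data.frame with `chrom`, `first_order`, `last_order`, `start`,
#'   `end`, `n_genes`, `n_de`, `p`, `fdr`, ordered by p; zero rows when
#'   nothing passes.
#' @export
positional_enrichment <- function(de_genes, loci, max_window = 250L,
                                  fdr_cut = 0.05) {
  de_genes <- unique(de_genes)
  missing <- setdiff(de_genes, loci$gene)
  if (length(missing)) {
    warning(length(missing), " differential gene(s) without locus excluded: ",
            paste(utils::head(missing, 3), collapse = ", "))
    de_genes <- setdiff(de_genes, missing)
  }
  N <- nrow(loci)
  D <- length(de_genes)
  empty <- data.frame(chrom = character(0), first_order = integer(0),
                      last_order = integer(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      n_de = integer(0), p = numeric(0), fdr = numeric(0))
  if (D == 0) return(empty)
  loci <- loci[order(loci$chrom, loci$order), , drop = FALSE]
  is_de <- loci$gene %in% de_genes

  # collect candidate intervals (those containing >= 1 differential gene)
  # as flat vectors; intervals with zero hits have p = 1 exactly and enter
  # the BH pool only through their count
  chunks <- list()
  n_zero <- 0L
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    flags <- is_de[sel]
    nc <- length(sel)
    cs <- c(0L, cumsum(flags))
    for (w in seq_len(min(max_window, nc))) {
      starts <- seq_len(nc - w + 1L)
      nde <- cs[starts + w] - cs[starts]
      keep <- nde > 0L
      n_zero <- n_zero + sum(!keep)
      if (!any(keep)) next
      chunks[[length(chunks) + 1L]] <-
        list(ch = ch, first = starts[keep], w = w, nde = nde[keep])
    }
  }
  if (!length(chunks)) return(empty)
  a_chrom <- unlist(lapply(chunks, function(x) rep(x$ch, length(x$first))))
  a_first <- unlist(lapply(chunks, `[[`, "first"))
  a_w <- unlist(lapply(chunks, function(x) rep(x$w, length(x$first))))
  a_nde <- unlist(lapply(chunks, `[[`, "nde"))
  loc_idx <- match(paste(a_chrom, a_first), paste(loci$chrom, loci$order))
  end_idx <- match(paste(a_chrom, a_first + a_w - 1L),
                   paste(loci$chrom, loci$order))
  cand <- data.frame(chrom = a_chrom, first_order = a_first,
                     last_order = a_first + a_w - 1L,
                     start = loci$start[loc_idx], end = loci$end[end_idx],
                     n_genes = a_w, n_de = a_nde,
                     p = stats::phyper(a_nde - 1, D, N - D, a_w,
                                       lower.tail = FALSE),
                     stringsAsFactors = FALSE)
  cand$fdr <- bh_extra_ones(cand$p, n_zero)
  # greedy non-overlapping retention in ascending p order; dropping the
  # above-cutoff intervals first does not change the retained set, since
  # fdr is monotone in p and blockers always precede what they block
  cand <- cand[cand$fdr <= fdr_cut, , drop = FALSE]
  cand <- cand[order(cand$p, cand$n_genes, cand$chrom, cand$first_order), ,
               drop = FALSE]
  taken <- list()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    iv <- c(cand$first_order[i], cand$last_order[i])
    prev <- taken[[ch]]
    clash <- !is.null(prev) &&
      any(iv[1] <= prev[, 2] & iv[2] >= prev[, 1])
    if (!clash) {
      keep[i] <- TRUE
      taken[[ch]] <- rbind(prev, iv)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome direction summary of differential expression
#'
#' Counts, per chromosome, how many genes are down-regulated. With
#' `denominator = "significant"` only genes at `fdr <= fdr_cut` are
#' counted; with `"all"` every gene's fold-change sign contributes
#' (the convention behind per-chromosome percentages of down-regulated
#' genes computed over all genes on the chromosome).
#'
#' @param de A [moderated_t_test()] result.
#' @param loci Gene locus table; genes absent from it are ignored.
#' @param fdr_cut FDR threshold for the `"significant"` mode.
#' @param denominator `"significant"` or `"all"`.
#' @return Data.frame with `chrom`, `n_genes`, `n_down`, `frac_down`.
#' @export
chromosome_direction_summary <- function(de, loci, fdr_cut = 0.05,
                                         denominator = c("significant",
                                                         "all")) {
  denominator <- match.arg(denominator)
  i <- match(loci$gene, de$gene)
  ok <- !is.na(i)
  df <- data.frame(chrom = loci$chrom[ok],
                   down = de$log2fc[i[ok]] < 0,
                   sig = de$fdr[i[ok]] <= fdr_cut)
  if (denominator == "significant") df <- df[df$sig, , drop = FALSE]
  agg <- stats::aggregate(down ~ chrom, df,
                          FUN = function(x) c(n = length(x), d = sum(x)))
  data.frame(chrom = agg$chrom,
             n_genes = as.integer(agg$down[, "n"]),
             n_down = as.integer(agg$down[, "d"]),
             frac_down = agg$down[, "d"] / agg$down[, "n"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kernel-smoothed positional expression track
#'
#' Gaussian-kernel (Nadaraya-Watson) regression of per-gene values, e.g.
#' log2 fold changes, on genomic midpoint along one chromosome,
#' evaluated on a uniform grid. As the bandwidth shrinks the curve
#' interpolates the gene values at their positions.
#'
#' @param values Named numeric vector of per-gene values.
#' @param loci Locus table for one chromosome covering those genes.
#' @param bandwidth Gaussian kernel SD in base pairs.
#' @param n_grid Number of evaluation points (default 512).
#' @return Data.frame with `pos` and `value` (NA where no kernel mass).
#' @export
smoothed_position_track <- function(values, loci, bandwidth,
                                    n_grid = 512L) {
  stopifnot(length(unique(loci$chrom)) == 1, bandwidth > 0)
  i <- match(names(values), loci$gene)
  if (anyNA(i)) stop("values contain genes without loci")
  mid <- (loci$start[i] + loci$end[i]) / 2
  grid <- seq(min(mid), max(mid), length.out = n_grid)
  sm <- vapply(grid, function(g) {
    w <- stats::dnorm(mid - g, sd = bandwidth)
    if (sum(w) == 0) NA_real_ else sum(w * values) / sum(w)
  }, numeric(1))
  data.frame(pos = grid, value = sm)
}
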