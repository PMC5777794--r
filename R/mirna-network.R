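# Integrative miRNA-mRNA stage: three-source target-prediction filtering,
# expression anti-correlation testing, pair selection, and bipartite
# network construction.

#' Filter predicted miRNA targets by three-source intersection
#'
#' A candidate pair passes the miRanda-style source iff pairing score <
#' -0.5 AND conservation > 0.5; the TargetScan-style source iff context
#' score < -0.2; the miRDB-style source iff target score > 50. All
#' inequalities are strict. The returned set is the intersection of the
#' three per-source pass sets (`min_sources = 3`); a relaxed
#' at-least-k-of-3 rule is available.
#'
#' @param predictions Data.frame with columns `mirna`, `gene`,
#'   `pairing_score`, `conservation`, `context_score`, `target_score`
#'   (see [read_target_predictions()]).
#' @param thresholds Named list of cutoffs: `pairing` (-0.5),
#'   `conservation` (0.5), `context` (-0.2), `target` (50).
#' @param min_sources Number of sources a pair must pass (default 3).
#' @return Data.frame `mirna`, `gene` of passing pairs (unique rows),
#'   with attribute `per_source` listing each source's pass set.
#' @export
filter_predicted_targets <- function(predictions,
                                     thresholds = list(pairing = -0.5,
                                                       conservation = 0.5,
                                                       context = -0.2,
                                                       target = 50),
                                     min_sources = 3L) {
  need <- c("mirna", "gene", "pairing_score", "conservation",
            "context_score", "target_score")
  stopifnot(all(need %in% names(predictions)))
  p1 <- predictions$pairing_score < thresholds$pairing &
    predictions$conservation > thresholds$conservation
  p2 <- predictions$context_score < thresholds$context
  p3 <- predictions$target_score > thresholds$target
  p1[is.na(p1)] <- FALSE; p2[is.na(p2)] <- FALSE; p3[is.na(p3)] <- FALSE
  # pair-level pass per source: a pair passes a source when any of its
  # rows does, so the result is exactly the intersection (or k-of-3
  # union) of the per-source pair sets
  key <- paste(predictions$mirna, predictions$gene, sep = "\r")
  uk <- !duplicated(key)
  pair_pass <- function(p) as.logical(tapply(p, key, any)[key[uk]])
  q1 <- pair_pass(p1); q2 <- pair_pass(p2); q3 <- pair_pass(p3)
  keep <- (q1 + q2 + q3) >= min_sources
  out <- predictions[uk, c("mirna", "gene")][keep, , drop = FALSE]
  rownames(out) <- NULL
  pairs_u <- predictions[uk, c("mirna", "gene")]
  attr(out, "per_source") <- list(miranda = pairs_u[q1, , drop = FALSE],
                                  targetscan = pairs_u[q2, , drop = FALSE],
                                  mirdb = pairs_u[q3, , drop = FALSE])
  out
}

#' Spearman correlation tests for all candidate miRNA x gene pairs
#'
#' For every candidate miRNA against every expressed gene, computes the
#' Spearman rank correlation over the shared samples (average ranks for
#' ties), a two-sided p from the t approximation
#' t = rho sqrt((n - 2) / (1 - rho^2)) on n - 2 df, and BH fdr across
#' all computed pairs. Pairs involving a constant vector have undefined
#' rho: they are emitted with `NA` and excluded from the fdr pool.
#'
#' @param mirna_expr,mrna_expr [expr_mat()] objects.
#' @param candidate_mirnas miRNA ids to test (must be in `mirna_expr`).
#' @param shared_samples Sample ids present in both matrices; default is
#'   their intersection. At least 5 are required.
#' @return Data.frame with `mirna`, `gene`, `rho`, `p`, `fdr`, `n`.
#' @export
spearman_pair_test <- function(mirna_expr, mrna_expr, candidate_mirnas,
                               shared_samples = NULL) {
  stopifnot(inherits(mirna_expr, "expr_mat"), inherits(mrna_expr, "expr_mat"))
  if (is.null(shared_samples))
    shared_samples <- intersect(sample_ids(mirna_expr), sample_ids(mrna_expr))
  if (length(shared_samples) < 5) stop("need at least 5 shared samples")
  miss <- setdiff(candidate_mirnas, feature_ids(mirna_expr))
  if (length(miss)) stop("candidate miRNAs absent: ", miss[1], " ...")
  mm <- mirna_expr$values[candidate_mirnas, shared_samples, drop = FALSE]
  gg <- mrna_expr$values[, shared_samples, drop = FALSE]
  n <- length(shared_samples)
  const_m <- apply(mm, 1, function(x) length(unique(x)) == 1)
  const_g <- apply(gg, 1, function(x) length(unique(x)) == 1)
  # rank rows once, then Spearman rho is the Pearson correlation of ranks
  rk_m <- t(apply(mm, 1, rank, ties.method = "average"))
  rk_g <- t(apply(gg, 1, rank, ties.method = "average"))
  # constant vectors trigger cor's zero-sd warning; their entries are
  # overwritten with NA below, so the warning carries no information
  rho <- suppressWarnings(stats::cor(t(rk_g), t(rk_m)))  # genes x mirnas
  rho[const_g, ] <- NA
  rho[, const_m] <- NA
  rho_v <- as.vector(rho)
  tt <- rho_v * sqrt((n - 2) / pmax(1 - rho_v^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho_v) >= 1] <- 0
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- benjamini_hochberg(p[ok])
  data.frame(mirna = rep(colnames(rho), each = nrow(rho)),
             gene = rep(rownames(rho), times = ncol(rho)),
             rho = rho_v, p = p, fdr = fdr, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select functional anti-correlated, predicted miRNA-mRNA pairs
#'
#' Retains pairs with negative Spearman rho, fdr below the cutoff, and
#' membership in the predicted-target set. Also reports the fraction of
#' significant anti-correlated expression pairs that survive the
#' prediction filter, both over all computed pairs and over the
#' significant ones.
#'
#' @param pairs Output of [spearman_pair_test()].
#' @param predicted Data.frame `mirna`, `gene` from
#'   [filter_predicted_targets()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @return The retained subset of `pairs`, with attributes
#'   `n_significant` (anti-correlated significant expression pairs),
#'   `frac_of_significant` (retained / significant) and `frac_of_all`
#'   (retained / all computed pairs).
#' @export
select_functional_pairs <- function(pairs, predicted, fdr_cut = 0.05) {
  sig <- !is.na(pairs$rho) & pairs$rho < 0 & pairs$fdr < fdr_cut
  in_pred <- paste(pairs$mirna, pairs$gene) %in%
    paste(predicted$mirna, predicted$gene)
  out <- pairs[sig & in_pred, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(sig)
  attr(out, "frac_of_significant") <- if (sum(sig)) nrow(out) / sum(sig)
                                      else NA_real_
  attr(out, "frac_of_all") <- nrow(out) / nrow(pairs)
  out
}

#' Build the bipartite miRNA-mRNA network
#'
#' Nodes are miRNAs and genes of the selected pairs; edges carry the
#' Spearman rho, its absolute value as weight, and node attributes give
#' the node type and regulation direction taken from the differential
#' expression results (sign of the fold change: `"up"` / `"down"`).
#' Per-miRNA target counts and target-share fractions are attached.
#'
#' @param selected Output of [select_functional_pairs()].
#' @param de_mirnas,de_genes [moderated_t_test()] results supplying
#'   direction attributes (may be `NULL`).
#' @return List with `graph` (an igraph bipartite graph), `edges` (the
#'   edge table: `mirna`, `gene`, `rho`, `weight`) and `mirna_summary`
#'   (`mirna`, `n_targets`, `target_share`).
#' @export
build_network <- function(selected, de_mirnas = NULL, de_genes = NULL) {
  edges <- data.frame(mirna = selected$mirna, gene = selected$gene,
                      rho = selected$rho, weight = abs(selected$rho),
                      stringsAsFactors = FALSE)
  mirnas <- unique(edges$mirna)
  genes <- unique(edges$gene)
  direction <- function(ids, de) {
    if (is.null(de)) return(rep(NA_character_, length(ids)))
    s <- de$sign[match(ids, de$gene)]
    ifelse(is.na(s), NA_character_,
           ifelse(s > 0, "up", ifelse(s < 0, "down", "flat")))
  }
  verts <- data.frame(
    name = c(mirnas, genes),
    type = c(rep(FALSE, length(mirnas)), rep(TRUE, length(genes))),
    node_class = c(rep("mirna", length(mirnas)), rep("gene", length(genes))),
    direction = c(direction(mirnas, de_mirnas), direction(genes, de_genes)),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  counts <- table(edges$mirna)
  summary <- data.frame(mirna = names(counts),
                        n_targets = as.integer(counts),
                        target_share = as.integer(counts) / nrow(edges),
                        stringsAsFactors = FALSE, row.names = NULL)
  summary <- summary[order(-summary$n_targets), , drop = FALSE]
  rownames(summary) <- NULL
  list(graph = g, edges = edges, mirna_summary = summary)
}

#' Write a miRNA-mRNA network to edge-list TSV and GML
#'
#' @param network Output of [build_network()].
#' @param path_tsv Edge-list TSV path.
#' @param path_gml Optional GML path for graph tools.
#' @return Invisibly, `path_tsv`.
#' @export
write_network <- function(network, path_tsv, path_gml = NULL) {
  write_tsv(network$edges, path_tsv)
  if (!is.null(path_gml)) {
    # GML has no boolean type; igraph warns while casting the bipartite
    # 'type' flag to 0/1, which is the intended representation
    suppressWarnings(
      igraph::write_graph(network$graph, path_gml, format = "gml"))
  }
  invisible(path_tsv)
}
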