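# End-to-end orchestration: synthetic generation (or file inputs) ->
# preprocessing -> differential expression (mRNA and miRNA) -> robustness
# -> replication -> meta-analysis -> enrichment -> miRNA-mRNA network,
# with per-stage child seeds and a run manifest.

# per-stage child seed: deterministic function of the master seed and the
# stage name, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435761 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Bundles thresholds and seeds for [run_pipeline()]. When `sim` is a
#' [sim_config()], all inputs are generated synthetically; otherwise
#' supply file paths in `paths` (expression/annotation/loci/prediction
#' TSVs as written by [write_simulation()]).
#'
#' @param sim A [sim_config()], or `NULL` to read files from `paths`.
#' @param paths Named list of input paths (`mrna`, `mirna`, `annotation`,
#'   `annotation2`, `mrna2`, `loci`, `predictions`, `gmt`), used when
#'   `sim` is `NULL`.
#' @param de_fdr FDR cutoff declaring genes/miRNAs differential (0.05).
#' @param mirna_detection_frac Detection-fraction filter for miRNAs
#'   (0.25).
#' @param pair_fdr FDR cutoff for anti-correlated pairs (0.05).
#' @param pge_fdr FDR cutoff for positional enrichment (0.05).
#' @param n_perm_balance Balanced permutations (100).
#' @param n_perm_rp Rank-product permutations (100).
#' @param max_window Positional-scan window cap in genes (250).
#' @param seed Master seed; stages derive child seeds from it.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            de_fdr = 0.05, mirna_detection_frac = 0.25,
                            pair_fdr = 0.05, pge_fdr = 0.05,
                            n_perm_balance = 100L, n_perm_rp = 100L,
                            max_window = 250L, seed = 1L) {
  thr <- c(de_fdr, mirna_detection_frac, pair_fdr, pge_fdr)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must lie in (0, 1]")
  if (is.null(sim) && is.null(paths))
    stop("supply either a sim_config or input paths")
  structure(list(sim = sim, paths = paths, de_fdr = de_fdr,
                 mirna_detection_frac = mirna_detection_frac,
                 pair_fdr = pair_fdr, pge_fdr = pge_fdr,
                 n_perm_balance = as.integer(n_perm_balance),
                 n_perm_rp = as.integer(n_perm_rp),
                 max_window = as.integer(max_window),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or loading; miRNA detection
#' filtering and quantile normalization; moderated-t differential
#' expression for mRNA (small group vs pooled intracranial) and miRNA;
#' rank product and its concordance with the moderated t;
#' balanced-subsample permutation robustness; replication against the
#' second cohort (when present); ST-vs-PF random-effects meta-analysis
#' across cohorts (when both are present); positional enrichment and
#' per-chromosome direction summaries of the down-regulated genes; and
#' the anti-correlated miRNA-mRNA network. Optional stages missing their
#' inputs are skipped with a warning recorded in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every stage's tables and
#'   the manifest are written there.
#' @return List with all stage results (`data`, `de_mrna`, `de_mirna`,
#'   `rank_product`, `concordance`, `robustness`, `replication`, `meta`,
#'   `positional`, `chrom_summary`, `network`, `selected_pairs`) and
#'   `manifest` (parameter echo, per-stage row counts, skipped stages).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  skipped <- character(0)
  t0 <- Sys.time()

  # ---- inputs ----
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    base <- generate_expression(sim_cfg)
    mir <- generate_mirna_and_pairs(sim_cfg, base$expr, base$truth)
    rep2 <- generate_replicate_cohort(sim_cfg, mir$truth)
    data <- list(mrna = mir$mrna, mirna = mir$mirna,
                 annotation = base$annotation, loci = base$loci,
                 predictions = mir$predictions, truth = mir$truth,
                 replicate = rep2)
  } else {
    p <- config$paths
    data <- list(
      mrna = read_expr_tsv(p$mrna),
      mirna = if (!is.null(p$mirna)) read_expr_tsv(p$mirna),
      annotation = utils::read.delim(p$annotation, stringsAsFactors = FALSE),
      loci = if (!is.null(p$loci)) read_gene_loci(p$loci),
      predictions = if (!is.null(p$predictions))
        read_target_predictions(p$predictions),
      truth = NULL,
      replicate = if (!is.null(p$mrna2))
        list(expr = read_expr_tsv(p$mrna2),
             annotation = utils::read.delim(p$annotation2,
                                            stringsAsFactors = FALSE)))
  }
  ann <- data$annotation
  contrast <- list("SP", c("PF", "ST"))

  # ---- preprocessing ----
  mrna <- data$mrna
  if (!is.null(mrna$detected)) mrna <- detection_filter(mrna, mode = "any")
  mirna <- data$mirna
  if (!is.null(mirna)) {
    if (!is.null(mirna$detected))
      mirna <- detection_filter(mirna, config$mirna_detection_frac)
    mirna <- quantile_normalize(mirna)
  }

  # ---- differential expression ----
  de_mrna <- moderated_t_test(mrna, ann, contrast)
  de_genes <- de_mrna$gene[de_mrna$fdr < config$de_fdr]
  rp <- rank_product(mrna, ann, contrast, n_perm = config$n_perm_rp,
                     seed = stage_seed(config$seed, "rank_product"))
  conc <- if (length(de_genes) >= 3)
    concordance_t_vs_rp(de_mrna, rp, de_genes) else NULL

  de_mirna <- NULL
  de_mirs <- character(0)
  if (!is.null(mirna)) {
    mir_ann <- ann[ann$sample %in% sample_ids(mirna), , drop = FALSE]
    de_mirna <- tryCatch(moderated_t_test(mirna, mir_ann, contrast),
                         error = function(e) NULL)
    if (is.null(de_mirna)) skipped <- c(skipped, "diffexpr_mirna")
    else de_mirs <- de_mirna$gene[de_mirna$fdr < config$de_fdr]
  } else skipped <- c(skipped, "diffexpr_mirna")

  # ---- robustness ----
  robust <- NULL
  if (length(de_genes) >= 3) {
    robust <- balanced_permutation_analysis(
      mrna, ann, de_genes, n_perm = config$n_perm_balance,
      seed = stage_seed(config$seed, "balance"), contrast = contrast)
  } else skipped <- c(skipped, "robustness")

  # ---- replication + meta ----
  replication <- NULL
  meta <- NULL
  if (!is.null(data$replicate)) {
    rexpr <- data$replicate$expr
    if (!is.null(rexpr$detected)) rexpr <- detection_filter(rexpr, mode = "any")
    rann <- data$replicate$annotation
    de2 <- moderated_t_test(rexpr, rann, contrast)
    replication <- replication_summary(de_mrna, de2, de_genes)
    st_pf <- list("ST", "PF")
    eff <- rbind(study_effects(mrna, ann, st_pf, "DS1"),
                 study_effects(rexpr, rann, st_pf, "DS2"))
    meta <- random_effects_meta(eff)
  } else skipped <- c(skipped, "replication", "meta")

  # ---- enrichment ----
  positional <- NULL
  chrom_summary <- NULL
  if (!is.null(data$loci)) {
    down <- de_mrna$gene[de_mrna$fdr < config$de_fdr & de_mrna$log2fc < 0]
    down <- intersect(down, data$loci$gene)
    positional <- positional_enrichment(down, data$loci,
                                        max_window = config$max_window,
                                        fdr_cut = config$pge_fdr)
    chrom_summary <- chromosome_direction_summary(de_mrna, data$loci,
                                                  config$de_fdr, "all")
  } else skipped <- c(skipped, "enrichment")

  # ---- miRNA-mRNA network ----
  network <- NULL
  selected <- NULL
  if (!is.null(mirna) && !is.null(data$predictions) &&
      length(de_mirs) > 0) {
    predicted <- filter_predicted_targets(data$predictions)
    pairs <- spearman_pair_test(mirna, mrna, de_mirs)
    selected <- select_functional_pairs(pairs, predicted, config$pair_fdr)
    network <- build_network(selected, de_mirna, de_mrna)
  } else skipped <- c(skipped, "mirna_network")

  manifest <- list(
    package_version = as.character(utils::packageVersion("sepntx")),
    seed = config$seed,
    parameters = config[c("de_fdr", "mirna_detection_frac", "pair_fdr",
                          "pge_fdr", "n_perm_balance", "n_perm_rp",
                          "max_window")],
    n_genes_analyzed = nrow(mrna$values),
    n_mirnas_analyzed = if (!is.null(mirna)) nrow(mirna$values) else 0L,
    n_de_genes = length(de_genes),
    n_de_mirnas = length(de_mirs),
    n_selected_pairs = if (!is.null(selected)) nrow(selected) else 0L,
    n_enriched_regions = if (!is.null(positional)) nrow(positional) else 0L,
    skipped_stages = skipped,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(data = data, de_mrna = de_mrna, de_mirna = de_mirna,
              rank_product = rp, concordance = conc, robustness = robust,
              replication = replication, meta = meta,
              positional = positional, chrom_summary = chrom_summary,
              selected_pairs = selected, network = network,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# stage tables + manifest to disk
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$de_mrna, file.path(outdir, "de_mrna.tsv"))
  if (!is.null(res$de_mirna))
    write_tsv(res$de_mirna, file.path(outdir, "de_mirna.tsv"))
  write_tsv(res$rank_product, file.path(outdir, "rank_product.tsv"))
  if (!is.null(res$robustness)) {
    write_tsv(data.frame(perm = seq_along(res$robustness$r),
                         r = res$robustness$r),
              file.path(outdir, "balanced_permutation_r.tsv"))
    jsonlite::write_json(
      c(as.list(res$robustness$summary),
        frac_all_consistent = res$robustness$frac_all_consistent),
      file.path(outdir, "balanced_permutation_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$replication))
    jsonlite::write_json(res$replication,
                         file.path(outdir, "replication.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$meta)) write_tsv(res$meta, file.path(outdir, "meta.tsv"))
  if (!is.null(res$positional))
    write_tsv(res$positional, file.path(outdir, "positional_enrichment.tsv"))
  if (!is.null(res$chrom_summary))
    write_tsv(res$chrom_summary, file.path(outdir, "chromosome_summary.tsv"))
  if (!is.null(res$network))
    write_network(res$network, file.path(outdir, "network_edges.tsv"),
                  file.path(outdir, "network.gml"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
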