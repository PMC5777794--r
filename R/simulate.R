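# Synthetic two-platform microarray cohorts with planted truth.
#
# The generator emulates the statistical structure of an unbalanced
# pediatric ependymoma design: a small spinal (SP) group against a large
# intracranial group split into posterior-fossa (PF) and supratentorial
# (ST) samples, gene-wise variances following a scaled inverse-chi-square
# prior, a minority of planted group-effect genes, a chromosomal block
# enriched for down-regulated genes, planted anti-correlated miRNA->gene
# regulation with three-source target predictions plus decoys, and a
# replicate cohort on a second platform sharing the true effects.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the full study shape the generator emulates: 18,365
#' genes and 311 miRNAs, 6 spinal vs 30 + 30 intracranial samples (49 of
#' which carry miRNA profiles), a scaled inverse-chi-square variance prior
#' with 4 prior degrees of freedom and prior variance 0.05, 3% planted
#' differential genes with absolute log2 effects in [1, 3], and a 30-gene
#' chromosomal block in which 60% of genes are planted down-regulated.
#'
#' @param n_genes,n_mirnas Feature counts for the mRNA and miRNA platforms.
#' @param n_sp,n_pf,n_st Sample counts: spinal, posterior fossa,
#'   supratentorial. The intracranial group is PF + ST.
#' @param n_mirna_ic Number of intracranial samples that also carry miRNA
#'   profiles (the miRNA cohort is SP plus this many intracranial samples).
#' @param prior_df,prior_var True hyperparameters d0 and s0^2 of the scaled
#'   inverse-chi-square distribution the gene-wise error variances are
#'   drawn from.
#' @param frac_de Fraction of genes (and of miRNAs) given a nonzero group
#'   effect.
#' @param effect_range Length-2 numeric, the range of absolute log2 effect
#'   sizes; signs are random.
#' @param frac_planted_pairs Fraction of (differential miRNA) x (gene)
#'   pairs given true regulatory coupling.
#' @param regulation_slope Negative slope linking a target gene's
#'   expression to its regulating miRNA (log2 scale).
#' @param n_chromosomes Chromosome count for the synthetic gene map.
#' @param enriched_region List with `chrom`, `length`, `direction`
#'   (`"down"` or `"up"`) and `density`: a block of consecutive genes on
#'   one chromosome planted differential at the given density.
#' @param platform_noise_sd SD of the per-gene platform offset added to
#'   the replicate cohort's baseline means.
#' @param rep_n_sp,rep_n_pf,rep_n_st Replicate-cohort sample counts.
#' @param shared_frac Fraction of genes present on both platforms.
#' @param n_decoys Number of decoy rows added to the target-prediction
#'   table.
#' @param decoy_pass_rate Probability that a decoy passes each prediction
#'   source's filter, independently per source.
#' @param detect_mid,detect_scale Location and scale of the logistic curve
#'   giving each feature's per-sample detection probability as a function
#'   of its baseline mean.
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 18365, n_mirnas = 311,
                       n_sp = 6, n_pf = 30, n_st = 30,
                       n_mirna_ic = 43,
                       prior_df = 4, prior_var = 0.05,
                       frac_de = 0.03, effect_range = c(1, 3),
                       frac_planted_pairs = 0.001,
                       regulation_slope = -1,
                       n_chromosomes = 23,
                       enriched_region = list(chrom = 2, length = 30,
                                              direction = "down",
                                              density = 0.6),
                       platform_noise_sd = 0.3,
                       rep_n_sp = 4, rep_n_pf = 50, rep_n_st = 25,
                       shared_frac = 0.8,
                       n_decoys = 2000, decoy_pass_rate = 0.3,
                       detect_mid = 5, detect_scale = 0.7,
                       seed = 1L) {
  cfg <- as.list(environment())
  num <- unlist(cfg[c("n_genes", "n_mirnas", "n_sp", "n_pf", "n_st",
                      "n_mirna_ic", "prior_df", "prior_var", "frac_de",
                      "effect_range", "frac_planted_pairs",
                      "regulation_slope", "n_chromosomes",
                      "platform_noise_sd", "rep_n_sp", "rep_n_pf",
                      "rep_n_st", "shared_frac", "n_decoys",
                      "decoy_pass_rate", "detect_mid", "detect_scale",
                      "seed")])
  if (!all(is.finite(num))) stop("non-finite values in sim_config")
  stopifnot(cfg$n_genes >= 1, cfg$n_mirnas >= 1, cfg$n_sp >= 1,
            cfg$n_pf + cfg$n_st >= 1,
            cfg$n_sp + cfg$n_pf + cfg$n_st >= 4,
            cfg$prior_df > 0, cfg$prior_var > 0,
            cfg$frac_de >= 0, cfg$frac_de <= 1,
            length(cfg$effect_range) == 2,
            cfg$effect_range[1] > 0,
            cfg$effect_range[1] <= cfg$effect_range[2],
            cfg$regulation_slope <= 0,
            cfg$n_chromosomes >= 1,
            cfg$platform_noise_sd >= 0,
            cfg$shared_frac >= 0, cfg$shared_frac <= 1,
            cfg$decoy_pass_rate >= 0, cfg$decoy_pass_rate <= 1,
            cfg$n_mirna_ic <= cfg$n_pf + cfg$n_st)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# draws n variances from scaled-inv-chi-square(d0, s0sq):
# sigma^2 = d0 * s0sq / chisq_d0
rscinvchisq <- function(n, d0, s0sq) d0 * s0sq / stats::rchisq(n, df = d0)

sim_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
sim_mirna_ids <- function(n) sprintf("mir%04d", seq_len(n))

# contiguous assignment of genes to chromosomes; positions are ordered and
# non-overlapping so order-by-start equals gene index within chromosome
sim_gene_loci <- function(n_genes, n_chromosomes) {
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_genes))
  within <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (within - 1L) * 100000L
  data.frame(gene = sim_gene_ids(n_genes),
             chrom = paste0("chr", chrom),
             start = start, end = start + 10000L,
             order = within, stringsAsFactors = FALSE)
}

#' Generate the discovery-cohort mRNA matrix with planted truth
#'
#' Gene g, sample j takes value `mu_g + delta_g * [j in SP] + e_gj`, with
#' baselines `mu_g ~ Uniform(4, 14)` on the log2 scale, error variances
#' `sigma_g^2` drawn from scaled-inv-chi-square(`prior_df`, `prior_var`),
#' and Gaussian noise. A `frac_de` minority of genes get a signed effect
#' with magnitude uniform in `effect_range`; additionally the configured
#' chromosomal block is planted differential at its own density so
#' positional enrichment has a recoverable signal. Per-cell detection
#' flags are Bernoulli with a logistic dependence on `mu_g`.
#'
#' @param config A [sim_config()].
#' @return A list with components `expr` ([expr_mat()]), `annotation`
#'   (data.frame `sample`, `group` in SP/PF/ST, `age_class`, `study`),
#'   `loci` (gene locus table, see [as_gene_loci()]) and `truth` (list:
#'   `de_genes` named numeric vector of signed effects, `region_truth`,
#'   `d0_true`, `s0sq_true`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sim_gene_ids(n)
  n_ic <- config$n_pf + config$n_st
  samples <- sprintf("DS1_%02d", seq_len(config$n_sp + n_ic))
  group <- c(rep("SP", config$n_sp), rep("PF", config$n_pf),
             rep("ST", config$n_st))

  mu <- stats::runif(n, 4, 14)
  sigma2 <- rscinvchisq(n, config$prior_df, config$prior_var)

  loci <- sim_gene_loci(n, config$n_chromosomes)

  delta <- numeric(n)
  n_de <- round(config$frac_de * n)
  reg <- config$enriched_region
  region_idx <- integer(0)
  region_truth <- NULL
  if (!is.null(reg) && reg$length > 0) {
    chrom_lab <- paste0("chr", reg$chrom)
    on_chrom <- which(loci$chrom == chrom_lab)
    if (length(on_chrom) < reg$length)
      stop("enriched_region longer than its chromosome")
    region_idx <- on_chrom[seq_len(reg$length)]
    region_truth <- list(chrom = chrom_lab,
                         first_order = 1L, last_order = reg$length,
                         genes = genes[region_idx],
                         direction = reg$direction,
                         density = reg$density)
  }
  if (n_de > 0) {
    bg_pool <- setdiff(seq_len(n), region_idx)
    de_idx <- sample(bg_pool, min(n_de, length(bg_pool)))
    mag <- stats::runif(length(de_idx), config$effect_range[1],
                        config$effect_range[2])
    delta[de_idx] <- mag * sample(c(-1, 1), length(de_idx), replace = TRUE)
  }
  if (length(region_idx)) {
    hit <- region_idx[stats::runif(length(region_idx)) < reg$density]
    mag <- stats::runif(length(hit), config$effect_range[1],
                        config$effect_range[2])
    delta[hit] <- if (identical(reg$direction, "down")) -mag else mag
  }

  m <- ncol <- length(samples)
  e <- matrix(stats::rnorm(n * m, sd = sqrt(sigma2)), nrow = n)
  vals <- mu + e
  vals[, group == "SP"] <- vals[, group == "SP"] + delta
  dimnames(vals) <- list(genes, samples)

  p_det <- stats::plogis((mu - config$detect_mid) / config$detect_scale)
  det <- matrix(stats::runif(n * m) < p_det, nrow = n,
                dimnames = dimnames(vals))

  ann <- data.frame(sample = samples, group = group,
                    age_class = "pediatric", study = "DS1",
                    stringsAsFactors = FALSE)
  de <- delta[delta != 0]
  names(de) <- genes[delta != 0]
  list(expr = expr_mat(vals, det), annotation = ann, loci = loci,
       truth = list(de_genes = de, region_truth = region_truth,
                    d0_true = config$prior_df,
                    s0sq_true = config$prior_var))
}

# score draws: uniform inside or outside each source's pass region
draw_scores <- function(pass1, pass2, pass3) {
  k <- length(pass1)
  # miRanda-style: pairing score < -0.5 AND conservation > 0.5
  pairing <- ifelse(pass1, stats::runif(k, -1.5, -0.5 - 1e-6),
                    stats::runif(k, -0.5, 0.5))
  conserv <- ifelse(pass1, stats::runif(k, 0.5 + 1e-6, 1),
                    stats::runif(k, 0, 0.5))
  # for failing rows, let one of the two miRanda criteria pass at random
  flip <- !pass1 & stats::runif(k) < 0.5
  conserv[flip] <- stats::runif(sum(flip), 0.5 + 1e-6, 1)
  # TargetScan-style: context score < -0.2
  context <- ifelse(pass2, stats::runif(k, -1, -0.2 - 1e-6),
                    stats::runif(k, -0.2, 0.2))
  # miRDB-style: target score > 50
  target <- ifelse(pass3, stats::runif(k, 50 + 1e-6, 100),
                   stats::runif(k, 0, 50))
  data.frame(pairing_score = pairing, conservation = conserv,
             context_score = context, target_score = target)
}

#' Generate the miRNA matrix, planted regulation and target predictions
#'
#' Builds the miRNA platform like the gene platform (same baseline and
#' variance model, a `frac_de` minority with signed group effects), then
#' plants regulation: for each true (miRNA, gene) pair the gene's values
#' are rewritten as `mu_g + regulation_slope * (miRNA - mean) + noise`, so
#' the pair is anti-correlated across samples. Target genes are drawn from
#' the non-differential pool, one regulator per gene. The prediction table
#' contains every true pair with scores passing all three sources, plus
#' `n_decoys` decoy pairs whose scores pass each source independently with
#' probability `decoy_pass_rate`.
#'
#' Only `n_sp + n_mirna_ic` samples carry miRNA profiles (the miRNA cohort
#' emulates a subset of the mRNA cohort), but planted regulation acts on
#' all mRNA samples, so the (updated) mRNA matrix is returned as well.
#'
#' @param config A [sim_config()].
#' @param mrna The mRNA [expr_mat()] from [generate_expression()].
#' @param truth Truth list from [generate_expression()].
#' @return List with `mirna` ([expr_mat()]), `mrna` (updated
#'   [expr_mat()]), `predictions` (target-prediction data.frame) and
#'   `truth` extended with `de_mirnas` (named signed effects) and
#'   `true_pairs` (data.frame `mirna`, `gene`).
#' @export
generate_mirna_and_pairs <- function(config, mrna, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(mrna, "expr_mat"))
  set.seed(config$seed + 1L)
  nm <- config$n_mirnas
  mirnas <- sim_mirna_ids(nm)
  samples <- sample_ids(mrna)
  n_all <- length(samples)
  grp_sp <- seq_len(config$n_sp)

  mu <- stats::runif(nm, 4, 14)
  sigma2 <- rscinvchisq(nm, config$prior_df, config$prior_var)
  delta <- numeric(nm)
  n_de <- round(config$frac_de * nm)
  if (n_de > 0) {
    idx <- sample.int(nm, n_de)
    mag <- stats::runif(n_de, config$effect_range[1], config$effect_range[2])
    delta[idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  mvals <- mu + matrix(stats::rnorm(nm * n_all, sd = sqrt(sigma2)), nrow = nm)
  mvals[, grp_sp] <- mvals[, grp_sp] + delta
  dimnames(mvals) <- list(mirnas, samples)

  # planted regulation: rewrite target genes as a negative-slope response
  de_m <- mirnas[delta != 0]
  genes <- feature_ids(mrna)
  non_de_genes <- setdiff(genes, names(truth$de_genes))
  n_pairs <- round(config$frac_planted_pairs * length(de_m) * length(genes))
  n_pairs <- min(n_pairs, length(non_de_genes))
  vals <- mrna$values
  if (n_pairs > 0 && length(de_m) > 0) {
    tg <- sample(non_de_genes, n_pairs)
    tm <- sample(de_m, n_pairs, replace = TRUE)
    gi <- match(tg, genes)
    mi <- match(tm, mirnas)
    gmu <- rowMeans(vals[gi, , drop = FALSE])
    gsd <- sqrt(rscinvchisq(n_pairs, config$prior_df, config$prior_var))
    centered <- mvals[mi, , drop = FALSE] - rowMeans(mvals[mi, , drop = FALSE])
    vals[gi, ] <- gmu + config$regulation_slope * centered +
      matrix(stats::rnorm(n_pairs * n_all, sd = gsd), nrow = n_pairs)
    true_pairs <- data.frame(mirna = tm, gene = tg, stringsAsFactors = FALSE)
  } else {
    true_pairs <- data.frame(mirna = character(0), gene = character(0),
                             stringsAsFactors = FALSE)
  }

  # prediction table: all true pairs pass all three sources
  tp <- cbind(true_pairs,
              draw_scores(rep(TRUE, nrow(true_pairs)),
                          rep(TRUE, nrow(true_pairs)),
                          rep(TRUE, nrow(true_pairs))),
              is_true = rep(TRUE, nrow(true_pairs)))
  if (config$n_decoys > 0) {
    dm <- sample(mirnas, config$n_decoys, replace = TRUE)
    dg <- sample(genes, config$n_decoys, replace = TRUE)
    keep <- !(paste(dm, dg) %in% paste(true_pairs$mirna, true_pairs$gene))
    dm <- dm[keep]; dg <- dg[keep]
    kd <- length(dm)
    dec <- cbind(data.frame(mirna = dm, gene = dg, stringsAsFactors = FALSE),
                 draw_scores(stats::runif(kd) < config$decoy_pass_rate,
                             stats::runif(kd) < config$decoy_pass_rate,
                             stats::runif(kd) < config$decoy_pass_rate),
                 is_true = rep(FALSE, kd))
    tp <- rbind(tp, dec)
  }
  tp <- unique(tp)
  predictions <- data.frame(mirna = tp$mirna, gene = tp$gene,
                            source = "aggregated",
                            tp[, c("pairing_score", "conservation",
                                   "context_score", "target_score")],
                            stringsAsFactors = FALSE)

  # miRNA profiles exist for SP plus the first n_mirna_ic intracranial
  prof <- c(grp_sp, config$n_sp + seq_len(config$n_mirna_ic))
  p_det <- stats::plogis((mu - config$detect_mid) / config$detect_scale)
  det <- matrix(stats::runif(nm * length(prof)) < p_det, nrow = nm)
  mirna_mat <- mvals[, prof, drop = FALSE]
  dimnames(det) <- dimnames(mirna_mat)

  de_mir <- delta[delta != 0]
  names(de_mir) <- mirnas[delta != 0]
  truth$de_mirnas <- de_mir
  truth$true_pairs <- true_pairs
  list(mirna = expr_mat(mirna_mat, det),
       mrna = expr_mat(vals, mrna$detected),
       predictions = predictions, truth = truth)
}

#' Generate a replicate cohort on a second platform
#'
#' A new cohort with its own sample sizes shares the true gene effects of
#' the discovery cohort but gets fresh baselines perturbed by a per-gene
#' platform offset `~ Normal(0, platform_noise_sd^2)` and fresh error
#' variances from the same prior. Only a `shared_frac` subset of genes is
#' present on the second platform, emulating partial probe overlap between
#' array designs.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [generate_expression()] (or the extended
#'   one from [generate_mirna_and_pairs()]).
#' @return List with `expr` ([expr_mat()]) and `annotation` for the
#'   replicate cohort, plus `shared_genes` (character vector).
#' @export
generate_replicate_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_genes
  genes <- sim_gene_ids(n)
  keep <- sort(sample.int(n, round(config$shared_frac * n)))
  genes2 <- genes[keep]
  n2 <- length(genes2)
  n_ic <- config$rep_n_pf + config$rep_n_st
  samples <- sprintf("DS2_%02d", seq_len(config$rep_n_sp + n_ic))
  group <- c(rep("SP", config$rep_n_sp), rep("PF", config$rep_n_pf),
             rep("ST", config$rep_n_st))

  delta <- numeric(n2)
  hit <- match(intersect(names(truth$de_genes), genes2), genes2)
  delta[hit] <- truth$de_genes[genes2[hit]]

  mu <- stats::runif(n2, 4, 14) +
    stats::rnorm(n2, sd = config$platform_noise_sd)
  sigma2 <- rscinvchisq(n2, config$prior_df, config$prior_var)
  m <- length(samples)
  vals <- mu + matrix(stats::rnorm(n2 * m, sd = sqrt(sigma2)),
                      nrow = n2, ncol = m)
  vals[, group == "SP"] <- vals[, group == "SP"] + delta
  dimnames(vals) <- list(genes2, samples)
  p_det <- stats::plogis((mu - config$detect_mid) / config$detect_scale)
  det <- matrix(stats::runif(n2 * m) < p_det, nrow = n2, ncol = m,
                dimnames = dimnames(vals))
  ann <- data.frame(sample = samples, group = group,
                    age_class = "pediatric", study = "DS2",
                    stringsAsFactors = FALSE)
  list(expr = expr_mat(vals, det), annotation = ann, shared_genes = genes2)
}

#' Write all synthetic inputs to a directory
#'
#' Emits the TSV/JSON files a file-based pipeline run consumes: expression
#' matrices (with detection flags), sample annotations, gene loci (BED),
#' target predictions and the planted truth as JSON. Truth is written
#' separately; the matrices carry no truth columns.
#'
#' @param sim Output of the three generators combined (see
#'   [run_pipeline()] for the layout).
#' @param dir Output directory, created if missing.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expr_tsv(sim$mrna, file.path(dir, "mrna_expression.tsv"))
  write_expr_tsv(sim$mirna, file.path(dir, "mirna_expression.tsv"))
  write_tsv(sim$annotation, file.path(dir, "sample_annotation.tsv"))
  write_gene_loci(sim$loci, file.path(dir, "gene_loci.bed"))
  write_tsv(sim$predictions, file.path(dir, "target_predictions.tsv"))
  if (!is.null(sim$replicate)) {
    write_expr_tsv(sim$replicate$expr, file.path(dir, "mrna_expression_ds2.tsv"))
    write_tsv(sim$replicate$annotation,
              file.path(dir, "sample_annotation_ds2.tsv"))
  }
  truth <- sim$truth
  truth$de_genes <- as.list(truth$de_genes)
  truth$de_mirnas <- as.list(truth$de_mirnas)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
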