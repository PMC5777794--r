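# Stability procedures for the unbalanced design: balanced-subsample
# permutation analysis, cross-cohort replication metrics, and per-gene
# DerSimonian-Laird random-effects meta-analysis.

#' Balanced-subsample permutation analysis of imbalance robustness
#'
#' Repeatedly draws a balanced subsample of the large comparison group
#' (e.g. 6 of 60 intracranial samples to match 6 spinal samples), reruns
#' the moderated t-test on the balanced design, and compares it with the
#' full-data analysis: per permutation the Pearson correlation of
#' t-statistics over the selected genes, and per gene whether the fold
#' change kept its full-data direction. A gene is "direction consistent"
#' when its sign agrees with the full data in every permutation.
#'
#' @param m An [expr_mat()].
#' @param groups Sample annotation (`sample`, `group`).
#' @param de_genes Character vector of genes to track (typically the
#'   significant genes from the full analysis).
#' @param n_perm Number of balanced subsamples (default 100).
#' @param subsample_size Samples drawn from the comparison group per
#'   permutation (default = size of the small group).
#' @param seed Integer seed.
#' @param contrast As in [moderated_t_test()]; the second element names
#'   the strata that are subsampled.
#' @param stratify Draw proportionally from each stratum of the
#'   comparison group when `subsample_size` divides evenly (default
#'   TRUE); otherwise draw from the pooled comparison group.
#' @return List of class `"perm_robustness"`: `r` (per-permutation
#'   correlations), `consistency` (per-gene count of direction-agreeing
#'   permutations), `frac_all_consistent`, `n_perm`, and `summary`
#'   (median, mean, sd, 25th, 75th percentile of `r`).
#' @export
balanced_permutation_analysis <- function(m, groups, de_genes,
                                          n_perm = 100L,
                                          subsample_size = NULL,
                                          seed = 1L,
                                          contrast = list("SP", c("PF", "ST")),
                                          stratify = TRUE) {
  stopifnot(inherits(m, "expr_mat"))
  miss <- setdiff(de_genes, feature_ids(m))
  if (length(miss)) stop("de_genes absent from matrix: ", miss[1], " ...")
  grp <- groups$group[match(sample_ids(m), groups$sample)]
  small_idx <- which(grp %in% contrast[[1]])
  strata <- lapply(contrast[[2]], function(g) which(grp == g))
  names(strata) <- contrast[[2]]
  if (is.null(subsample_size)) subsample_size <- length(small_idx)
  pooled <- unlist(strata)
  if (subsample_size > length(pooled))
    stop("subsample_size exceeds the comparison group")
  per_stratum <- subsample_size / length(strata)
  use_strata <- stratify && per_stratum == floor(per_stratum) &&
    all(lengths(strata) >= per_stratum)

  full <- moderated_t_test(m, groups, contrast)
  gi <- match(de_genes, full$gene)
  full_t <- full$t_mod[gi]
  full_sign <- full$sign[gi]

  set.seed(seed)
  r <- numeric(n_perm)
  consistent <- integer(length(de_genes))
  for (b in seq_len(n_perm)) {
    pick <- if (use_strata) {
      unlist(lapply(strata, function(s) s[sample.int(length(s), per_stratum)]))
    } else {
      pooled[sample.int(length(pooled), subsample_size)]
    }
    sub <- m[, c(small_idx, pick)]
    res <- moderated_t_test(sub, groups, contrast)
    ri <- match(de_genes, res$gene)
    r[b] <- stats::cor(full_t, res$t_mod[ri])
    consistent <- consistent +
      as.integer(res$sign[ri] == full_sign & full_sign != 0)
  }
  structure(list(
    r = r,
    consistency = stats::setNames(consistent, de_genes),
    frac_all_consistent = mean(consistent == n_perm),
    n_perm = n_perm,
    summary = c(median = stats::median(r), mean = mean(r),
                sd = stats::sd(r),
                q25 = unname(stats::quantile(r, 0.25)),
                q75 = unname(stats::quantile(r, 0.75)))),
    class = "perm_robustness")
}

#' @export
print.perm_robustness <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "balanced-permutation robustness over %d permutations\n  r: median %.3f, mean %.3f, sd %.3f, IQR [%.3f, %.3f]\n  genes direction-consistent in all permutations: %.1f%%\n",
    x$n_perm, s["median"], s["mean"], s["sd"], s["q25"], s["q75"],
    100 * x$frac_all_consistent))
  invisible(x)
}

#' Cross-cohort replication summary
#'
#' Matches genes by id between two differential-expression results and
#' reports Pearson correlations of t-statistics over the tracked genes
#' (`r_de`) and over all common genes (`r_all`), plus the fraction of
#' tracked genes whose fold change has the same sign in both cohorts.
#' A fold change of exactly zero counts as discordant unless both are
#' zero.
#'
#' @param de1,de2 [moderated_t_test()] results from the two cohorts.
#' @param de_genes Character vector of genes of interest (typically the
#'   discovery cohort's significant genes).
#' @return List with `n_common_genes`, `n_shared_de`, `r_de`, `r_all`,
#'   `frac_same_direction`.
#' @export
replication_summary <- function(de1, de2, de_genes) {
  common <- intersect(de1$gene, de2$gene)
  if (!length(common))
    return(list(n_common_genes = 0L, n_shared_de = 0L, r_de = NA_real_,
                r_all = NA_real_, frac_same_direction = NA_real_))
  i1 <- match(common, de1$gene)
  i2 <- match(common, de2$gene)
  r_all <- stats::cor(de1$t_mod[i1], de2$t_mod[i2])
  shared_de <- intersect(de_genes, common)
  if (length(shared_de) >= 3) {
    j1 <- match(shared_de, de1$gene)
    j2 <- match(shared_de, de2$gene)
    r_de <- stats::cor(de1$t_mod[j1], de2$t_mod[j2])
    s1 <- sign(de1$log2fc[j1]); s2 <- sign(de2$log2fc[j2])
    frac <- mean((s1 == s2 & s1 != 0) | (s1 == 0 & s2 == 0))
  } else {
    r_de <- NA_real_
    frac <- NA_real_
  }
  list(n_common_genes = length(common), n_shared_de = length(shared_de),
       r_de = r_de, r_all = r_all, frac_same_direction = frac)
}

#' Per-study effect sizes for meta-analysis
#'
#' Builds one study's effect rows from an expression matrix: the log2
#' fold change between two groups with sampling variance
#' v = s_pooled^2 (1/n1 + 1/n2).
#'
#' @param m An [expr_mat()].
#' @param groups Sample annotation.
#' @param contrast Length-2 contrast, as in [moderated_t_test()].
#' @param study Study identifier stored in the output.
#' @return Data.frame with columns `gene`, `study`, `y`, `v`.
#' @export
study_effects <- function(m, groups, contrast, study) {
  gi <- group_indices(m, groups, contrast)
  x1 <- m$values[, gi$i1, drop = FALSE]
  x2 <- m$values[, gi$i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / (n1 + n2 - 2)
  data.frame(gene = feature_ids(m), study = study, y = m1 - m2,
             v = s2 * (1 / n1 + 1 / n2), stringsAsFactors = FALSE,
             row.names = NULL)
}

# DerSimonian-Laird for one gene's study effects
dl_one <- function(y, v) {
  k <- length(y)
  if (k == 1)
    return(c(pooled = y, tau_sq = 0, z = y / sqrt(v), se = sqrt(v), k = 1))
  w <- 1 / v
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  tau_sq <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau_sq)
  pooled <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  c(pooled = pooled, tau_sq = tau_sq, z = pooled / se, se = se, k = k)
}

#' Per-gene random-effects meta-analysis (DerSimonian-Laird)
#'
#' For each gene, integrates per-study effects with DerSimonian-Laird
#' moment estimation of the between-study variance tau^2: fixed weights
#' 1/v give Cochran's Q; tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
#' sum w)); random-effects weights 1/(v + tau^2) give the pooled effect
#' and its normal z / two-sided p. Genes observed in a single study pass
#' through with tau^2 = 0 and are flagged.
#'
#' @param effects Data.frame with columns `gene`, `study`, `y` (effect,
#'   e.g. log2 fold change) and `v` (its sampling variance, > 0).
#' @return Data.frame with `gene`, `pooled`, `tau_sq`, `z`, `p`, `fdr`,
#'   `n_studies`, `single_study`.
#' @export
random_effects_meta <- function(effects) {
  stopifnot(all(c("gene", "study", "y", "v") %in% names(effects)))
  if (any(effects$v <= 0)) stop("sampling variances must be positive")
  sp <- split(effects[, c("y", "v")], effects$gene)
  fit <- t(vapply(sp, function(d) dl_one(d$y, d$v), numeric(5)))
  p <- 2 * stats::pnorm(-abs(fit[, "z"]))
  data.frame(gene = names(sp), pooled = fit[, "pooled"],
             tau_sq = fit[, "tau_sq"], z = fit[, "z"], p = p,
             fdr = benjamini_hochberg(p),
             n_studies = as.integer(fit[, "k"]),
             single_study = fit[, "k"] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}
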