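# Two-group differential expression for small, unbalanced designs:
# empirical-Bayes moderated t with variance shrinkage toward a scaled
# inverse-chi-square prior, and the rank-product nonparametric statistic
# with a permutation null.

#' Estimate the variance prior by moment matching on log variances
#'
#' Under the hierarchical model sigma_g^2 ~ scaled-inv-chi-square(d0,
#' s0^2), the log sample variances z_g = log(s_g^2) satisfy
#' E(z) = log(s0^2) + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#' and Var(z) = trigamma(d/2) + trigamma(d0/2), with d the residual
#' degrees of freedom. Matching moments: with
#' e_g = z_g - digamma(d/2) + log(d/2), solve
#' trigamma(d0/2) = max(0, var(e) - trigamma(d/2)) for d0 by monotone
#' bisection (d0 = Inf when the right side is <= 0), then
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)).
#'
#' @param sample_vars Nonnegative gene-wise sample variances; at least 10
#'   must be positive. Zero variances are excluded from the fit.
#' @param residual_df Residual degrees of freedom of each variance
#'   (n1 + n2 - 2 for a two-group comparison).
#' @return List with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(sample_vars, residual_df) {
  if (any(!is.finite(sample_vars)) || any(sample_vars < 0))
    stop("sample variances must be finite and nonnegative")
  v <- sample_vars[sample_vars > 0]
  if (length(v) < 10)
    stop("need at least 10 features with positive variance")
  if (residual_df < 1) stop("residual_df must be >= 1")
  d <- residual_df
  e <- log(v) - digamma(d / 2) + log(d / 2)
  target <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(target) || target <= 0) {
    # no excess dispersion beyond sampling: infinite prior df; with
    # d0 = Inf the sample variances are unbiased for s0^2, so use their mean
    d0 <- Inf
    s0_sq <- mean(v)
  } else {
    d0 <- 2 * invert_trigamma(target)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# solve trigamma(x) = y for x > 0 by bisection; trigamma is strictly
# decreasing on (0, Inf) with range (0, Inf)
invert_trigamma <- function(y, tol = 1e-10, max_iter = 200L) {
  stopifnot(y > 0)
  lo <- 1e-8
  hi <- 1
  while (trigamma(lo) < y) lo <- lo / 2
  while (trigamma(hi) > y) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, lo)) break
  }
  (lo + hi) / 2
}

group_indices <- function(m, groups, contrast, min_n = 2L) {
  stopifnot(inherits(m, "expr_mat"), length(contrast) == 2,
            all(c("sample", "group") %in% names(groups)))
  grp <- groups$group[match(sample_ids(m), groups$sample)]
  i1 <- which(grp %in% contrast[[1]])
  i2 <- which(grp %in% contrast[[2]])
  if (length(i1) < min_n || length(i2) < min_n)
    stop("both contrast groups need at least ", min_n, " samples")
  list(i1 = i1, i2 = i2)
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' Per gene: log2 fold change is the difference of group means (first
#' contrast level minus second); the pooled within-group variance s_g^2
#' (d_g = n1 + n2 - 2 df) is shrunk toward the prior as
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g); the moderated statistic
#' t = log2fc / (s~_g sqrt(1/n1 + 1/n2)) is referred to a t distribution
#' on d0 + d_g degrees of freedom (standard normal when d0 = Inf).
#' Shrinkage stabilizes inference when one group is very small, the
#' regime this package targets (e.g. 6 spinal vs 60 intracranial tumors).
#'
#' @param m An [expr_mat()].
#' @param groups Sample annotation data frame with columns `sample` and
#'   `group`.
#' @param contrast Length-2 list/vector of group levels; each element may
#'   name several levels to pool (e.g. `list("SP", c("PF", "ST"))`).
#'   Positive fold changes mean higher in the first level.
#' @param prior Optional list with `d0`, `s0_sq` to override the prior
#'   estimated from the data (use `d0 = 0` for the ordinary t, `d0 = Inf`
#'   for complete shrinkage to the common variance).
#' @return A data.frame of class `"de_result"` with columns `gene`,
#'   `log2fc`, `mean_expr`, `t_mod`, `p`, `fdr`, `sign`, plus attributes
#'   `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(m, groups, contrast = list("SP", c("PF", "ST")),
                             prior = NULL) {
  gi <- group_indices(m, groups, contrast)
  x1 <- m$values[, gi$i1, drop = FALSE]
  x2 <- m$values[, gi$i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log2fc <- m1 - m2
  dg <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  if (is.null(prior)) prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- dg
  } else {
    s2_post <- (d0 * s0 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene = feature_ids(m), log2fc = log2fc,
                    mean_expr = rowMeans(m$values), t_mod = t_mod,
                    p = p, fdr = benjamini_hochberg(p),
                    sign = sign(log2fc), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q for the i-th smallest p-value is `min over j >= i of p_(j) * m / j`,
#' clipped to 1 and mapped back to input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# BH when the pool additionally contains n_ones tests with p exactly 1
# that are not materialized (they sort last, so only the total count m
# enters the step-up formula for the explicit entries)
bh_extra_ones <- function(p, n_ones) {
  m <- length(p) + n_ones
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_along(p))))
  q <- pmin(q, 1)
  out <- numeric(length(p))
  out[o] <- q
  out
}

#' Rank-product differential-expression statistic
#'
#' Forms all K = n1 * n2 pairwise sample comparisons between the contrast
#' groups. In comparison k, genes are ranked by the log2 difference in
#' descending order (rank 1 = most up-regulated in the first group),
#' giving ranks r_gk; the up rank product is the geometric mean
#' (prod_k r_gk)^(1/K), and the down statistic uses ascending ranks.
#' Significance comes from a label-free permutation null in which every
#' comparison's gene ranks are shuffled independently: with c(g) null
#' rank products (over all genes and permutations) at or below the
#' observed one, p(g) = c(g) / (n_perm * n_features) and the percentage
#' of false prediction is pfp(g) = (c(g) / n_perm) / rank(g).
#'
#' @inheritParams moderated_t_test
#' @param n_perm Number of null permutations (default 100).
#' @param seed Integer seed for the permutation null.
#' @return Data.frame with columns `gene`, `rp_up`, `p_up`, `pfp_up`,
#'   `percentile_up`, and the `_down` counterparts. Percentiles are the
#'   rank of each gene's statistic divided by the number of genes (small
#'   percentile = extreme).
#' @export
rank_product <- function(m, groups, contrast = list("SP", c("PF", "ST")),
                         n_perm = 100L, seed = 1L) {
  gi <- group_indices(m, groups, contrast, min_n = 1L)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(m$values)
  K <- length(gi$i1) * length(gi$i2)
  if (K == 0) stop("no pairwise comparisons")
  if (as.double(n_perm) * n > 2^52) stop("n_perm * n_features too large")

  # observed per-comparison log2 differences, ranked within comparison
  log_rp_up <- numeric(n)
  log_rp_down <- numeric(n)
  for (i in gi$i1) {
    d <- m$values[, i] - m$values[, gi$i2, drop = FALSE]
    for (k in seq_len(ncol(d))) {
      r_up <- rank(-d[, k], ties.method = "average")
      log_rp_up <- log_rp_up + log(r_up)
      log_rp_down <- log_rp_down + log(n + 1 - r_up)
    }
  }
  rp_up <- exp(log_rp_up / K)
  rp_down <- exp(log_rp_down / K)

  # label-free null: shuffle each comparison's ranks independently
  set.seed(seed)
  lr <- log(seq_len(n))
  null_up <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) {
    acc <- numeric(n)
    for (k in seq_len(K)) acc <- acc + lr[sample.int(n)]
    null_up[, b] <- exp(acc / K)
  }
  null_sorted <- sort(as.vector(null_up))
  count_le <- function(obs) findInterval(obs, null_sorted)
  c_up <- count_le(rp_up)
  c_down <- count_le(rp_down)

  rank_up <- rank(rp_up, ties.method = "average")
  rank_down <- rank(rp_down, ties.method = "average")
  data.frame(gene = feature_ids(m),
             rp_up = rp_up, p_up = c_up / (n_perm * n),
             pfp_up = (c_up / n_perm) / rank_up,
             percentile_up = rank_up / n,
             rp_down = rp_down, p_down = c_down / (n_perm * n),
             pfp_down = (c_down / n_perm) / rank_down,
             percentile_down = rank_down / n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance between moderated t and rank-product orderings
#'
#' Within the up- and down-regulated members of a gene subset (typically
#' the significant genes from the moderated t), computes the Pearson
#' correlation between the moderated t and minus the log rank product,
#' and the fraction of subset genes whose rank-product percentile falls
#' within the top `top_frac_cut` in the corresponding direction.
#'
#' @param de A [moderated_t_test()] result.
#' @param rp A [rank_product()] result on the same matrix.
#' @param gene_subset Character vector of gene ids to assess.
#' @param top_frac_cut Percentile cutoff defining "top" (default 0.15).
#' @return List with `corr_up`, `corr_down`, `frac_top`, `top_frac_cut`,
#'   `n_up`, `n_down`.
#' @export
concordance_t_vs_rp <- function(de, rp, gene_subset, top_frac_cut = 0.15) {
  if (!length(gene_subset)) stop("empty gene subset")
  i <- match(gene_subset, de$gene)
  j <- match(gene_subset, rp$gene)
  if (anyNA(i) || anyNA(j)) stop("subset genes missing from results")
  up <- de$sign[i] > 0
  dn <- de$sign[i] < 0
  # extreme genes have small rank products in their direction, so the
  # comparison is |t| against -log(rp); reported correlations are signed
  # the way |t| runs (more extreme = larger both)
  corr_dir <- function(sel, col_rp) {
    if (sum(sel) < 3) return(NA_real_)
    stats::cor(abs(de$t_mod[i][sel]), -log(rp[[col_rp]][j][sel]))
  }
  in_top <- ifelse(up, rp$percentile_up[j] <= top_frac_cut,
                   ifelse(dn, rp$percentile_down[j] <= top_frac_cut, FALSE))
  list(corr_up = corr_dir(up, "rp_up"),
       corr_down = corr_dir(dn, "rp_down"),
       frac_top = mean(in_top[up | dn]),
       top_frac_cut = top_frac_cut,
       n_up = sum(up), n_down = sum(dn))
}
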