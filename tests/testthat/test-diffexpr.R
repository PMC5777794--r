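# moderated t, variance prior, BH, rank product, concordance

test_that("equal variances give d0 = Inf and s0^2 = the common variance", {
  pr <- estimate_variance_prior(rep(0.3, 50), residual_df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.3, tolerance = 1e-12)
})

test_that("trigamma inversion matches a fine-grid oracle", {
  grid <- exp(seq(log(0.01), log(50), length.out = 20000))
  tg <- trigamma(grid)
  for (y in c(0.05, 0.3, 1, 5, 20)) {
    x_oracle <- grid[which.min(abs(tg - y))]
    expect_equal(sepntx:::invert_trigamma(y), x_oracle, tolerance = 1e-3)
    expect_equal(trigamma(sepntx:::invert_trigamma(y)), y, tolerance = 1e-8)
  }
})

test_that("prior recovery from scaled-inv-chi-square draws (10 seeds)", {
  d0s <- s0s <- numeric(10)
  for (i in 1:10) {
    set.seed(200 + i)
    sigma2 <- 4 * 0.05 / rchisq(5000, df = 4)
    s2 <- sigma2 * rchisq(5000, df = 4) / 4
    pr <- estimate_variance_prior(s2, residual_df = 4)
    d0s[i] <- pr$d0; s0s[i] <- pr$s0_sq
  }
  expect_true(all(d0s > 2.8 & d0s < 5.2))
  expect_true(all(s0s > 0.04 & s0s < 0.06))
})

test_that("degenerate variance input raises an error", {
  expect_error(estimate_variance_prior(rep(0, 50), 4), "positive variance")
})

# straight-line reimplementation of the moderated t for the oracle check
oracle_mod_t <- function(x1, x2, d0, s0) {
  n1 <- ncol(x1); n2 <- ncol(x2); dg <- n1 + n2 - 2
  res <- t(vapply(seq_len(nrow(x1)), function(g) {
    a <- x1[g, ]; b <- x2[g, ]
    fc <- mean(a) - mean(b)
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dg
    s2p <- (d0 * s0 + dg * s2) / (d0 + dg)
    tt <- fc / sqrt(s2p * (1 / n1 + 1 / n2))
    c(tt, 2 * pt(-abs(tt), df = d0 + dg))
  }, numeric(2)))
  list(t = res[, 1], p = res[, 2])
}

test_that("moderated t matches a step-by-step oracle to 1e-10", {
  d <- make_dataset(n_genes = 200, n_sp = 3, n_ic = 6, n_de = 30, seed = 30)
  fit <- moderated_t_test(d$xm, d$ann, prior = list(d0 = 4, s0_sq = 0.05))
  grp <- d$ann$group
  orc <- oracle_mod_t(d$xm$values[, grp == "SP"],
                      d$xm$values[, grp != "SP"], 4, 0.05)
  expect_equal(fit$t_mod, unname(orc$t), tolerance = 1e-10)
  expect_equal(fit$p, unname(orc$p), tolerance = 1e-10)
  expect_equal(fit$sign, sign(fit$log2fc))
  expect_true(all(fit$fdr >= fit$p))
})

test_that("d0 = 0 reduces to the classical pooled-variance t", {
  d <- make_dataset(n_genes = 40, n_sp = 4, n_ic = 4, seed = 31)
  fit <- moderated_t_test(d$xm, d$ann, prior = list(d0 = 0, s0_sq = 1))
  grp <- d$ann$group
  classic <- vapply(seq_len(40), function(g)
    t.test(d$xm$values[g, grp == "SP"], d$xm$values[g, grp != "SP"],
           var.equal = TRUE)$statistic, numeric(1))
  expect_equal(fit$t_mod, unname(classic), tolerance = 1e-12)
})

test_that("d0 = Inf shrinks every gene to the common variance, normal reference", {
  d <- make_dataset(n_genes = 30, n_sp = 3, n_ic = 5, seed = 32)
  fit <- moderated_t_test(d$xm, d$ann, prior = list(d0 = Inf, s0_sq = 0.25))
  se <- sqrt(0.25 * (1 / 3 + 1 / 5))
  expect_equal(fit$t_mod, fit$log2fc / se, tolerance = 1e-12)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$t_mod)), tolerance = 1e-12)
})

test_that("posterior variance is a convex combination of prior and sample variance", {
  d <- make_dataset(n_genes = 100, n_sp = 3, n_ic = 6, seed = 33)
  fit <- moderated_t_test(d$xm, d$ann)
  grp <- d$ann$group
  x1 <- d$xm$values[, grp == "SP"]; x2 <- d$xm$values[, grp != "SP"]
  dg <- ncol(x1) + ncol(x2) - 2
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
           rowSums((x2 - rowMeans(x2))^2)) / dg
  s0 <- attr(fit, "s0_sq"); d0 <- attr(fit, "d0")
  s2_post <- (fit$log2fc / fit$t_mod)^2 / (1 / ncol(x1) + 1 / ncol(x2))
  expect_true(all(s2_post >= pmin(s0, s2) - 1e-12 &
                    s2_post <= pmax(s0, s2) + 1e-12))
})

test_that("moderated t agrees with limma on the same data", {
  skip_if_not_installed("limma")
  set.seed(34)
  # heterogeneous gene variances so the prior df is finite
  sds <- sqrt(4 * 0.05 / rchisq(150, 4))
  vals <- matrix(rnorm(150 * 9, mean = 8, sd = sds), 150, 9)
  vals[1:20, 1:3] <- vals[1:20, 1:3] + 2
  xm <- make_xm(vals)
  ann <- make_ann(sample_ids(xm), 3)
  grp <- ann$group
  design <- cbind(1, as.integer(grp == "SP"))
  fit <- limma::eBayes(limma::lmFit(xm$values, design))
  mine <- moderated_t_test(xm, ann)
  expect_true(is.finite(attr(mine, "d0")))
  expect_equal(mine$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
})

test_that("BH follows the step-up formula and a suffix-min oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  set.seed(35)
  p <- runif(1000)
  q <- benjamini_hochberg(p)
  # brute-force suffix minimum
  o <- order(p); m <- length(p)
  oracle <- numeric(m)
  for (i in seq_len(m))
    oracle[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  expect_equal(q, oracle)
  expect_equal(q, p.adjust(p, "BH"))
  # permutation invariance
  perm <- sample(m)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
})

test_that("a gene ranked first in every comparison has rank product 1", {
  d <- make_dataset(n_genes = 10, n_sp = 2, n_ic = 3, seed = 36)
  d$xm$values[1, 1:2] <- d$xm$values[1, 1:2] + 100  # always most up
  rp <- rank_product(d$xm, d$ann, n_perm = 10, seed = 1)
  expect_equal(rp$rp_up[1], 1)
  expect_equal(rp$percentile_up[1], 1 / 10)
})

test_that("rank product permutation p converges to exact enumeration", {
  # 4 genes x 2 comparisons (1 SP vs 2 reference samples)
  set.seed(37)
  vals <- matrix(rnorm(12), 4, 3)
  xm <- make_xm(vals)
  ann <- data.frame(sample = sample_ids(xm), group = c("SP", "PF", "PF"))
  rp <- rank_product(xm, ann, contrast = list("SP", "PF"),
                     n_perm = 40000, seed = 2)
  # exact null: both comparisons' rank columns independently permuted,
  # all 4!^2 = 576 assignments equally likely
  all_orders <- all_perms(4)
  exact_p <- function(obs) {
    cnt <- 0L
    for (i in 1:24) for (j in 1:24) {
      null_rp <- sqrt(all_orders[i, ] * all_orders[j, ])
      cnt <- cnt + sum(null_rp <= obs + 1e-12)
    }
    cnt / (576 * 4)
  }
  for (g in 1:4)
    expect_lt(abs(rp$p_up[g] - exact_p(rp$rp_up[g])), 0.01)
})

test_that("rank product is invariant to monotone per-comparison transforms", {
  d <- make_dataset(n_genes = 25, n_sp = 2, n_ic = 2, seed = 38)
  rp1 <- rank_product(d$xm, d$ann, n_perm = 5, seed = 3)
  # a strictly increasing transform of the whole matrix preserves all
  # within-comparison difference orderings only if applied per sample in a
  # rank-preserving way; scaling and shifting each sample's values keeps
  # every pairwise difference ordering when the scale is shared
  xm2 <- make_xm(d$xm$values * 3 + 1)
  rp2 <- rank_product(xm2, d$ann, n_perm = 5, seed = 3)
  expect_equal(rp1$rp_up, rp2$rp_up)
  expect_equal(rp1$rp_down, rp2$rp_down)
})

test_that("top moderated-t genes concentrate in the rank-product top 15%", {
  cfg <- sim_config(n_genes = 1500, n_mirnas = 10, frac_de = 0.04,
                    enriched_region = NULL, n_decoys = 0, seed = 40)
  out <- generate_expression(cfg)
  de <- moderated_t_test(out$expr, out$annotation)
  rp <- rank_product(out$expr, out$annotation, n_perm = 20, seed = 4)
  sig <- de$gene[de$fdr < 0.05]
  conc <- concordance_t_vs_rp(de, rp, sig)
  expect_gte(conc$frac_top, 0.85)
  expect_gt(conc$corr_up, 0.3)
  expect_gt(conc$corr_down, 0.3)
})

test_that("concordance is exact for linearly aligned scores and errors on empty sets", {
  de <- data.frame(gene = paste0("g", 1:20), t_mod = 1:20,
                   sign = rep(1, 20))
  rp <- data.frame(gene = paste0("g", 1:20), rp_up = exp(-(1:20)),
                   rp_down = exp(1:20),
                   percentile_up = (20:1) / 20, percentile_down = (1:20) / 20)
  conc <- concordance_t_vs_rp(de, rp, de$gene, top_frac_cut = 0.5)
  expect_equal(conc$corr_up, 1)
  expect_error(concordance_t_vs_rp(de, rp, character(0)), "empty")
})

test_that("null data produce almost no discoveries (BH control, 20 seeds)", {
  counts <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(n_genes = 2000, n_mirnas = 10, frac_de = 0,
                      enriched_region = NULL, n_decoys = 0, seed = 300 + i)
    out <- generate_expression(cfg)
    de <- moderated_t_test(out$expr, out$annotation)
    counts[i] <- sum(de$fdr < 0.05)
  }
  expect_lte(mean(counts), 1)
})

test_that("planted large effects are recovered at high power (20 seeds)", {
  recovery <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(n_genes = 500, n_mirnas = 10, frac_de = 0.05,
                      effect_range = c(2, 3), enriched_region = NULL,
                      n_decoys = 0, seed = 400 + i)
    out <- generate_expression(cfg)
    de <- moderated_t_test(out$expr, out$annotation)
    sig <- de$gene[de$fdr < 0.05]
    recovery[i] <- mean(names(out$truth$de_genes) %in% sig)
  }
  expect_gte(mean(recovery), 0.9)
})
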