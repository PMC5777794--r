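# target-prediction filtering, Spearman pair tests, selection, network

pred_row <- function(mirna, gene, pairing, cons, context, target) {
  data.frame(mirna = mirna, gene = gene, source = "aggregated",
             pairing_score = pairing, conservation = cons,
             context_score = context, target_score = target,
             stringsAsFactors = FALSE)
}

test_that("three-source thresholds are strict and jointly required", {
  keep <- pred_row("m1", "g1", -0.6, 0.6, -0.3, 60)
  expect_equal(nrow(filter_predicted_targets(keep)), 1)
  # target score exactly at the boundary is rejected (strict > 50)
  expect_equal(nrow(filter_predicted_targets(
    pred_row("m1", "g1", -0.6, 0.6, -0.3, 50))), 0)
  # conservation exactly at the boundary is rejected (strict > 0.5)
  expect_equal(nrow(filter_predicted_targets(
    pred_row("m1", "g1", -0.6, 0.5, -0.3, 60))), 0)
  # failing any one source fails the intersection
  expect_equal(nrow(filter_predicted_targets(
    pred_row("m1", "g1", -0.4, 0.6, -0.3, 60))), 0)
  # empty table
  expect_equal(nrow(filter_predicted_targets(keep[0, ])), 0)
})

test_that("the pass set is the intersection of independently computed per-source sets", {
  set.seed(80)
  n <- 300
  tab <- pred_row(sample(paste0("m", 1:5), n, TRUE),
                  sample(paste0("g", 1:50), n, TRUE),
                  runif(n, -1.5, 0.5), runif(n), runif(n, -1, 0.2),
                  runif(n, 0, 100))
  out <- filter_predicted_targets(tab)
  # per-source pair sets computed independently, then intersected
  s1 <- tab$pairing_score < -0.5 & tab$conservation > 0.5
  s2 <- tab$context_score < -0.2
  s3 <- tab$target_score > 50
  pair_set <- function(sel) unique(paste(tab$mirna[sel], tab$gene[sel]))
  oracle <- intersect(intersect(pair_set(s1), pair_set(s2)), pair_set(s3))
  expect_setequal(paste(out$mirna, out$gene), oracle)
  per <- attr(out, "per_source")
  both <- intersect(intersect(paste(per$miranda$mirna, per$miranda$gene),
                              paste(per$targetscan$mirna, per$targetscan$gene)),
                    paste(per$mirdb$mirna, per$mirdb$gene))
  expect_setequal(paste(out$mirna, out$gene), both)
  # a 2-of-3 rule keeps at least as many pairs
  expect_gte(nrow(filter_predicted_targets(tab, min_sources = 2)), nrow(out))
})

test_that("Spearman rho hits the monotone limits and the tie-corrected formula", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  mir <- make_xm(x, genes = "m1")
  genes <- make_xm(rbind(-x, x^3), genes = c("gdec", "ginc"))
  res <- spearman_pair_test(mir, genes, "m1")
  expect_equal(res$rho[res$gene == "gdec"], -1)
  expect_equal(res$rho[res$gene == "ginc"], 1)
  expect_equal(res$p[res$gene == "ginc"], 0)

  # ties: against the tie-corrected rank-covariance formula
  set.seed(81)
  a <- sample(c(1, 1, 2, 3, 3, 4, 5, 6))
  b <- sample(c(2, 2, 2, 5, 5, 7, 8, 9))
  mir2 <- make_xm(matrix(a, 1, 8), genes = "m1")
  gen2 <- make_xm(matrix(b, 1, 8), genes = "g1")
  res2 <- spearman_pair_test(mir2, gen2, "m1")
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(res2$rho, oracle, tolerance = 1e-12)
  tt <- oracle * sqrt(6 / (1 - oracle^2))
  expect_equal(res2$p, 2 * pt(-abs(tt), df = 6), tolerance = 1e-12)
})

test_that("Spearman test is invariant under strictly monotone transforms", {
  set.seed(82)
  mir <- make_xm(matrix(rnorm(20), 2, 10), genes = c("m1", "m2"))
  gen <- make_xm(matrix(rnorm(30), 3, 10))
  a <- spearman_pair_test(mir, gen, c("m1", "m2"))
  mir2 <- make_xm(exp(mir$values), genes = c("m1", "m2"))
  gen2 <- make_xm(gen$values^3 + 5)
  b <- spearman_pair_test(mir2, gen2, c("m1", "m2"))
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("constant vectors yield NA rho excluded from the fdr pool", {
  mir <- make_xm(matrix(c(rep(1, 6), rnorm(6)), 2, 6, byrow = TRUE),
                 genes = c("mconst", "mvar"))
  gen <- make_xm(matrix(rnorm(12), 2, 6))
  res <- spearman_pair_test(mir, gen, c("mconst", "mvar"))
  expect_true(all(is.na(res$rho[res$mirna == "mconst"])))
  expect_true(all(is.na(res$fdr[res$mirna == "mconst"])))
  expect_true(all(!is.na(res$fdr[res$mirna == "mvar"])))
  expect_error(spearman_pair_test(mir[, 1:4], gen[, 1:4], "mvar"),
               "at least 5")
})

test_that("functional pair selection demands negative rho, low fdr and prediction", {
  pairs <- data.frame(mirna = rep("m1", 4), gene = paste0("g", 1:4),
                      rho = c(-0.9, -0.9, 0.9, -0.9),
                      p = c(1e-5, 1e-5, 1e-5, 1e-5),
                      fdr = c(1e-4, 1e-4, 1e-4, 0.5), n = 8)
  predicted <- data.frame(mirna = "m1", gene = c("g1", "g3", "g4"))
  out <- select_functional_pairs(pairs, predicted, 0.05)
  expect_equal(out$gene, "g1")  # g2 unpredicted, g3 positive, g4 high fdr
  expect_equal(attr(out, "n_significant"), 2)
  expect_equal(attr(out, "frac_of_significant"), 0.5)
  # empty prediction set
  expect_equal(nrow(select_functional_pairs(pairs, predicted[0, ], 0.05)), 0)
  # monotone in the fdr cutoff
  expect_lte(nrow(select_functional_pairs(pairs, predicted, 0.01)),
             nrow(select_functional_pairs(pairs, predicted, 0.6)))
})

test_that("planted pairs are recovered with high precision and recall (20 seeds)", {
  prec <- rec <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(n_genes = 600, n_mirnas = 60, n_chromosomes = 4,
                      frac_de = 0.05, frac_planted_pairs = 0.02,
                      n_decoys = 500, enriched_region = NULL,
                      seed = 600 + i)
    b <- generate_expression(cfg)
    m <- generate_mirna_and_pairs(cfg, b$expr, b$truth)
    mir_ann <- b$annotation[b$annotation$sample %in% sample_ids(m$mirna), ]
    de_mir <- moderated_t_test(m$mirna, mir_ann)
    cand <- union(de_mir$gene[de_mir$fdr < 0.05],
                  unique(m$truth$true_pairs$mirna))
    predicted <- filter_predicted_targets(m$predictions)
    pairs <- spearman_pair_test(m$mirna, m$mrna, cand)
    sel <- select_functional_pairs(pairs, predicted, 0.05)
    got <- paste(sel$mirna, sel$gene)
    truth <- paste(m$truth$true_pairs$mirna, m$truth$true_pairs$gene)
    prec[i] <- if (length(got)) mean(got %in% truth) else NA
    rec[i] <- mean(truth %in% got)
  }
  expect_gte(mean(prec, na.rm = TRUE), 0.8)
  expect_gte(mean(rec), 0.8)
})

test_that("network construction: directions, weights, shares, degree oracle", {
  sel <- data.frame(mirna = c("m1", "m1", "m1", "m2"),
                    gene = paste0("g", 1:4),
                    rho = c(-0.9, -0.8, -0.7, -0.6))
  de_m <- data.frame(gene = c("m1", "m2"), sign = c(-1, 1))
  de_g <- data.frame(gene = paste0("g", 1:4), sign = c(1, 1, -1, 1))
  net <- build_network(sel, de_m, de_g)
  expect_equal(net$mirna_summary$target_share[net$mirna_summary$mirna == "m1"],
               0.75)
  expect_true(igraph::is_bipartite(net$graph))
  deg <- igraph::degree(net$graph)
  expect_equal(unname(deg[c("m1", "m2")]), c(3, 1))
  expect_equal(unname(deg[paste0("g", 1:4)]), rep(1, 4))
  expect_equal(igraph::E(net$graph)$weight, abs(sel$rho))
  vattr <- igraph::vertex_attr(net$graph)
  expect_equal(vattr$direction[vattr$name == "m1"], "down")
  expect_equal(vattr$direction[vattr$name == "g3"], "down")
  # empty selection gives a valid empty graph
  net0 <- build_network(sel[0, ])
  expect_equal(igraph::vcount(net0$graph), 0)
  expect_equal(nrow(net0$mirna_summary), 0)
})

test_that("random pair lists give degrees matching a counting oracle", {
  set.seed(83)
  sel <- unique(data.frame(mirna = sample(paste0("m", 1:4), 30, TRUE),
                           gene = sample(paste0("g", 1:10), 30, TRUE)))
  sel$rho <- -runif(nrow(sel))
  net <- build_network(sel)
  deg <- igraph::degree(net$graph)
  for (m in unique(sel$mirna))
    expect_equal(unname(deg[m]), sum(sel$mirna == m))
  for (g in unique(sel$gene))
    expect_equal(unname(deg[g]), sum(sel$gene == g))
})
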