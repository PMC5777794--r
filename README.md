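# sepntx

Differential expression and miRNA–mRNA integration for severely
unbalanced tumor cohorts, modeled on the comparison of pediatric spinal
ependymoma (SP, n = 6) against intracranial ependymoma (posterior fossa
and supratentorial, n = 30 + 30).

## The problem

When one group has only a handful of samples, gene-wise variance
estimates are unstable and ordinary t-tests are unreliable. The field's
answer is the **empirical-Bayes moderated t**: gene-wise variances are
assumed to follow a scaled inverse-chi-square prior with hyperparameters
(d₀, s₀²) estimated from all genes, and each gene's pooled variance
s²_g (d_g = n₁ + n₂ − 2 df) is shrunk toward the prior:

    s̃²_g = (d₀ s₀² + d_g s²_g) / (d₀ + d_g)
    t_g  = (x̄₁ − x̄₂) / ( s̃_g √(1/n₁ + 1/n₂) ),   t_g ~ t(d₀ + d_g)

`sepntx` implements this with moment-matching estimation of (d₀, s₀²)
on the log variances (monotone bisection of the trigamma inversion),
together with the surrounding procedure such a study needs:

- **Rank product** — the nonparametric companion statistic: geometric
  mean of a gene's fold-change ranks over all n₁·n₂ pairwise sample
  comparisons, with a label-free permutation null giving p and the
  percentage of false prediction (pFP).
- **Balanced-subsample permutations** — repeatedly draw a balanced
  subset of the large group (6 of 60), rerun the moderated t, and
  summarize the correlation of t-statistics and per-gene direction
  consistency, quantifying robustness to group-size imbalance.
- **Cross-cohort replication** — correlation of test statistics and
  sign concordance against an independent cohort on a second platform.
- **Random-effects meta-analysis** — per-gene DerSimonian–Laird pooling
  of log2 fold changes across studies.
- **Enrichment** — exact Fisher/hypergeometric set-overlap tests,
  over-representation on GMT gene sets, a positional scan for
  chromosomal intervals enriched in differential genes (BH across all
  scored intervals, greedy non-overlapping retention), per-chromosome
  down-regulation summaries, and a Gaussian-kernel positional
  expression track.
- **miRNA–mRNA network** — three-source target-prediction filtering
  (miRanda-style pairing < −0.5 with conservation > 0.5;
  TargetScan-style context score < −0.2; miRDB-style target score
  > 50; strict intersection by default), Spearman anti-correlation at
  FDR < 0.05 across all candidate-miRNA × gene pairs, and a bipartite
  igraph network with per-miRNA target shares.
- **Synthetic cohorts with planted truth** — a generator that emulates
  the study's structure (unbalanced groups, inverse-chi-square
  variances, planted signed effects, a planted enriched chromosomal
  block, planted anti-correlated miRNA regulation with decoy
  predictions, and a two-platform replicate cohort), so every stage can
  be validated against known answers.

## Worked example

```r
library(sepntx)

cfg <- pipeline_config(
  sim = sim_config(n_genes = 2000, n_mirnas = 80,
                   frac_planted_pairs = 0.01, n_decoys = 800, seed = 1),
  n_perm_balance = 100, n_perm_rp = 100, seed = 1)
res <- run_pipeline(cfg)

res$manifest$n_de_genes
#> [1] 120
print(res$robustness)
#> balanced-permutation robustness over 100 permutations
#>   r: median 0.983, mean 0.983, sd 0.002, IQR [0.982, 0.985]
#>   genes direction-consistent in all permutations: 100.0%
round(c(r_de = res$replication$r_de, r_all = res$replication$r_all), 3)
#>  r_de r_all
#> 0.817 0.747
head(res$network$mirna_summary, 1)
#>     mirna n_targets target_share
#> 1 mir0021        12            1
head(res$positional[, c("chrom", "first_order", "last_order", "n_de", "fdr")], 1)
#>   chrom first_order last_order n_de          fdr
#> 1  chr2           1         30   15 3.272601e-13
```

Reading the output: 120 of 2000 genes are called differential at
FDR < 0.05 (the generator plants 3% plus a 30-gene down-regulated
block); the balanced 6-vs-6 permutations correlate r ≈ 0.98 with the
full-data t-statistics and every differential gene keeps its direction
in all 100 permutations, so the unbalanced design is not driving the
calls; the replicate cohort reproduces the t-statistics more strongly
over the differential genes (r_de) than over all common genes (r_all);
and the positional scan recovers the planted block on chromosome 2 as
its top region.

A command-line front-end with the same defaults lives at
`inst/scripts/sepntx-pipeline.R`.

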