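---
title: "Methods: moderated inference and miRNA-mRNA integration for unbalanced cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated inference and miRNA-mRNA integration for unbalanced cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepntx)
```

# Scope

`sepntx` implements the computational core of a transcriptomic
comparison between a very small tumor group and a much larger reference
group — the design that arises when contrasting pediatric spinal
ependymoma (6 samples) with intracranial ependymoma (60 samples) on
expression microarrays, with a parallel miRNA platform and a replicate
cohort on a second array design. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions
taken where the procedure was genuinely open.

# The moderated t and its variance prior

All inference operates on log2-scale expression. For gene $g$ with
group means $\bar x_{1g}, \bar x_{2g}$ and pooled within-group variance
$s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom, the hierarchical
model assumes

$$\sigma_g^2 \sim s_0^2 \, d_0 / \chi^2_{d_0},$$

a scaled inverse-chi-square prior. This is the assumption underlying
the moderated t itself; the generator adopts it for the same reason (no
published description of the real data's variance structure exists, and
the estimator being validated presumes exactly this family). The
posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ is a convex
combination of prior and sample variance, and
$t_g = (\bar x_{1g}-\bar x_{2g}) / (\tilde s_g \sqrt{1/n_1+1/n_2})$ is
referred to $t_{d_0+d_g}$.

Hyperparameters are estimated by moment matching on
$z_g = \log s_g^2$: writing
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$, the excess dispersion
$\mathrm{var}(e) - \psi'(d_g/2)$ equals $\psi'(d_0/2)$, which is
inverted by monotone bisection of the trigamma function (tolerance
$10^{-10}$ on the argument). When the excess is non-positive the prior
is degenerate ($d_0 = \infty$); every gene then uses the common
variance, estimated by the mean of the sample variances (which is
unbiased for $s_0^2$ in that limit), and the reference distribution is
standard normal — the $d_0 + d_g \to \infty$ limit of the t. The
boundary conventions $d_0 = 0$ (no shrinkage: the classical pooled t)
and $d_0 = \infty$ are both reachable through the `prior` argument of
`moderated_t_test()` and are covered by tests. Because
$\tilde s_g^2 \ge d_0 s_0^2/(d_0+d_g) > 0$ whenever $s_0^2 > 0$,
constant genes never divide by zero.

Contrast orientation is `SP` minus the pooled intracranial group, so
positive fold changes mean over-expression in the spinal group.

# Rank product

As a distribution-free companion, `rank_product()` forms all
$K = n_1 n_2$ pairwise sample differences, ranks genes within each
comparison (rank 1 = most up-regulated), and takes the geometric mean
of ranks. The null is label-free: each comparison's rank column is
shuffled independently, which is appropriate because the statistic
depends on the data only through within-comparison ranks. With $c(g)$
null rank products at or below the observed one over `n_perm`
permutations of all genes, $p(g) = c(g)/(n_\mathrm{perm} N)$ and
$\mathrm{pFP}(g) = (c(g)/n_\mathrm{perm}) / \mathrm{rank}(g)$. The
geometric-mean ("rank product") form is the default; the published
description of the original study mentions "rank-product sum
statistics" without defining a variant, and the up/down statistics are
both computed so either tail can be inspected. Agreement with the
moderated t is summarized by `concordance_t_vs_rp()` as the correlation
of $|t|$ with $-\log \mathrm{RP}$ per direction and the fraction of
significant genes inside the top 15% of rank-product percentiles.

# Robustness, replication, meta-analysis

`balanced_permutation_analysis()` draws a balanced subsample of the
reference group (default: as many as the small group, i.e. 6 of 60),
stratified equally over PF and ST when the subsample size divides
evenly (the source description — "six samples each from PF/ST" — is
ambiguous between pooled and stratified draws, so stratification is a
flag, on by default), reruns the moderated t, and records per-gene sign
agreement with the full data and the Pearson correlation of
t-statistics over the tracked genes.

`replication_summary()` matches genes by id between two cohorts and
reports the correlation of t-statistics over the tracked differential
genes (`r_de`), over all common genes (`r_all`), and the fraction of
tracked genes with the same fold-change direction. A fold change of
exactly zero is counted discordant unless both are zero — a
conservative, deterministic convention.

`random_effects_meta()` is a per-gene DerSimonian–Laird fit: fixed
weights $1/v_i$, Cochran's $Q$, moment estimate
$\tau^2 = \max(0, (Q - (k-1))/(\sum w_i - \sum w_i^2/\sum w_i))$,
random-effects weights $1/(v_i+\tau^2)$, normal z and two-sided p, BH
across genes. Per-study sampling variances come from ordinary pooled
variances ($v = s^2_\mathrm{pooled}(1/n_1+1/n_2)$); whether the
original analysis used moderated or ordinary variances is unstated, and
ordinary variances keep the studies independent of the shrinkage step.
Single-study genes pass through flagged, with $\tau^2 = 0$.

# Enrichment

Set overlaps use the exact hypergeometric upper tail for enrichment
(the direction of interest throughout), the lower tail for depletion,
and Fisher's exact test for the two-sided option. The universe is an
explicit parameter everywhere — published overlap tests rarely state
it, and it materially changes the answer.

`positional_enrichment()` scores every run of consecutive genes (by
chromosomal order) up to `max_window` genes with the hypergeometric
upper tail against the genome-wide differential fraction. BH runs
across **all** scored intervals — including the zero-hit ones, whose
p is exactly 1 and which enter the pool by count without being
materialized — because selecting intervals first and adjusting after
would understate multiplicity. Non-overlapping intervals are then
retained greedily in ascending p (ties broken by interval length, then
chromosome and start, so results are deterministic), and intervals
above `fdr_cut` are dropped; dropping them before or after the greedy
pass provably yields the same retained set since BH is monotone in p.
`max_window` defaults to 250 genes to bound the quadratic scan; the
published positional-enrichment tool's internal heuristics are not
documented anywhere and are not reproduced — this scan is the package's
own, fully specified procedure. The kernel track
(`smoothed_position_track()`) is plain Nadaraya–Watson regression with
a Gaussian kernel on genomic midpoints; bandwidth is in base pairs.

# miRNA–mRNA integration

Candidate targets must pass three prediction sources at the standard
thresholds (pairing score < −0.5 with conservation > 0.5; context
score < −0.2; target score > 50; all strict). A pair passes a source if
any of its score rows does, making the result exactly the intersection
of the three per-source pair sets; an at-least-k-of-3 relaxation is
available. Expression support is Spearman correlation over the shared
samples (average ranks for ties; p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$), computed for **all** candidate-miRNA
× expressed-gene pairs so the BH pool is the full pair space — the
convention that makes "x% of detected pairs" statements well defined.
Correlations use all profiled samples rather than one group: with 6
spinal samples alone, rank correlations would be nearly powerless, and
the regulatory relationship is expected to hold across the disease
spectrum; a per-group option is exposed. Selected pairs need negative
rho, FDR below the cutoff and prediction support; the bipartite network
weights edges by $|\rho|$ and annotates nodes with their
differential-expression direction.

# The synthetic generator

`sim_config()` defaults encode the study conditions end to end: 18,365
genes, 311 miRNAs, 6 SP vs 30 + 30 PF/ST samples with miRNA profiles
on 49 of them, prior $(d_0, s_0^2) = (4, 0.05)$, 3% differential genes
with $|\Delta| \in [1, 3]$ log2 units and random signs, a 30-gene block
on chromosome 2 planted down-regulated at 60% density, regulation slope
−1 for planted miRNA→gene pairs, a replicate cohort of 4 + 75 samples
sharing 80% of genes with per-gene platform offsets of SD 0.3, and
2,000 decoy prediction rows passing each source independently at rate
0.3. Baseline means are Uniform(4, 14) on the log2 scale, matching the
range of reported mean expressions without modeling array chemistry;
noise is Gaussian on the log2 scale because both platforms are arrays
analyzed on log2 intensities; detection flags are Bernoulli with a
logistic dependence on the baseline mean (location 5, scale 0.7),
since array "detected" calls are never defined beyond the flag itself.
Planted regulation rewrites each target gene as
baseline + slope × (centered miRNA) + noise, so the pair is
anti-correlated by construction; targets are drawn from the
non-differential pool (one regulator per gene) so the planted
differential-gene truth stays interpretable, and the regulating
miRNA's group effect propagates into its targets, as it would
biologically. Prediction scores are drawn uniformly inside/outside
each pass region, since only thresholds — not score distributions —
are published.

What the generator does **not** emulate: probe-level intensities,
batch effects, correlated gene modules, heavy-tailed noise, and
platform-specific detection biases. Passing tests therefore show the
procedures are correct and well calibrated under the stated model, not
that real arrays satisfy that model. Two deliberate simplifications to
note when comparing against published counts: planted effect signs are
symmetric (the real study saw 82% of differential genes
over-expressed), and the replicate cohort shares true effects exactly
(platform offsets only shift baselines), which makes replication
correlations optimistic relative to real cross-platform data.

# Numerical and reproducibility choices

Probeset collapse keeps the row with the highest mean, breaking ties
toward the lexicographically smallest probeset id. Quantile
normalization assigns tied values the mean of the reference quantiles
their block spans. BH is the step-up suffix minimum, clipped at 1.
Trigamma inversion brackets by doubling/halving and bisects to relative
tolerance $10^{-10}$. All stochastic stages take explicit seeds;
`run_pipeline()` fans a master seed into per-stage child seeds by a
fixed hash of the stage name (kept below $2^{31}$), so stages are
individually reproducible and reruns are byte-identical.

Problem sizes: the test suite exercises the statistics on matrices of
200–4,000 genes with 10–20 permutation replicates and 10–20 seed
averages per property; the acceptance script runs the full pipeline at
the complete study shape (18,365 genes, 100 balanced and 100
rank-product permutations) plus 10–20-seed property loops, chosen so a
complete validation pass stays within a coffee break on one core.

# Known limitations

- The moderated t assumes a common variance model per gene across
  groups; no multi-factor designs, covariates or array weights.
- Rank-product p-values are Monte Carlo estimates; their resolution is
  $1/(n_\mathrm{perm} N)$.
- The positional scan's null treats genes as exchangeable along the
  chromosome; correlated neighboring genes (co-expression domains)
  would inflate its significance on real data.
- Spearman p-values use the t approximation, adequate for the 49-66
  sample cohorts targeted here; an exact permutation option would be
  preferable below ~10 samples.
- The meta-analysis is DerSimonian–Laird only; no REML or
  meta-regression.
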