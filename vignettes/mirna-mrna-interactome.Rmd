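---
title: "Methods: the paired miRNA-mRNA interactome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the paired miRNA-mRNA interactome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

`mirlink` implements the analysis chain used to contrast two disease
etiologies from paired bulk mRNA-seq and miRNA-seq of the same small cohort
— typically 3–4 biopsies per group. This vignette documents the statistical
model behind each stage, the tunable parameters, the design choices that
were genuinely open, and what the synthetic validation does and does not
establish.

## Differential expression

Counts for feature *f* in sample *s* are modelled as negative binomial,

$$ y_{fs} \sim \mathrm{NB}(\mu_{fs},\, \alpha_f), \qquad
   \mathrm{Var}(y_{fs}) = \mu_{fs} + \alpha_f \mu_{fs}^2, $$

with $\log \mu_{fs} = \log s_s + \beta_{0f} + x_s \beta_{1f}$, where $s_s$
is the sample's median-of-ratios size factor and $x_s = \pm\tfrac12$ encodes
the two groups, so $\beta_{1f}/\log 2$ is the log2 fold change of the first
contrast level over the second. Size factors are reported exactly as the
median-of-ratios estimator produces them; their geometric mean is close to
but not renormalized to one, and only ratios between factors are
scale-invariant.

With 3–4 samples per group the per-feature dispersion cannot be estimated
on its own, so it is moderated across features in the DESeq2 style:

1. a **Cox–Reid adjusted profile likelihood** for $\alpha_f$ given the
   fitted means, maximized on a 60-point log grid over
   $[10^{-6}, 20]$ — the adjustment $-\tfrac12 \log\det(X^\top W X)$
   removes the downward bias caused by estimating the two mean parameters;
2. a **mean–dispersion trend** from binned trimmed means of the ML
   estimates on the linear scale (a median of logs would sit systematically
   below the truth for this right-skewed estimator), interpolated over
   $\log \bar\mu_f$;
3. **MAP shrinkage** of each log dispersion toward the trend under a
   log-normal prior whose variance is the spread of the ML estimates in
   excess of their expected sampling variance,
   $\max(\mathrm{mad}^2 - \psi_1((n-2)/2),\, 0.25)$; features more than two
   prior-plus-sampling standard deviations *above* the trend keep their own
   estimate (dispersion outliers must not be shrunk into false positives).

The Wald statistic $\beta_{1f}/\mathrm{se}(\beta_{1f})$ is referred to the
standard normal. An earlier design used the spec-simpler method-of-moments
estimator with a heavier-tailed t reference to restore calibration; a
simulation study against planted truth showed that this sacrifices exactly
the deep-tail power that an FDR screen over ~100 miRNAs needs, while the
likelihood-based moderation above is simultaneously calibrated (null
rejection ≈ 0.06 at the 5% level, measured at 2,000 features and 4 + 3
samples) and as powerful as the reference implementations. A weak ridge on
$\beta_{1f}$ (prior SD 10 natural-log units) keeps estimates finite when
one group is all zeros; no pseudocounts are added anywhere. Degenerate
features (identical normalized counts) are reported with statistic 0 and
p = 1; features with mean normalized count below `min_count = 0.5` are
flagged and excluded from BH adjustment.

The screening thresholds are strict inequalities: |log2FC| > 0.5 and
adjusted p < 0.05, so a feature sitting exactly at 0.5 is excluded. The
significance gate defaults to the BH-adjusted p-value (with
`use_adjusted = FALSE` available) because the results-level description of
the reference analysis states an FDR even though its methods section says
"p value"; the headline screen should use the stricter reading.

## Pre-ranked gene-set enrichment

Genes are ranked by **signed** log2 fold change, descending, with ties
broken lexicographically by feature ID. The signed metric (rather than
|log2FC|) is the default because down-regulated pathways are reported with
negative scores; the magnitude metric is available via `metric = "abs_lfc"`.

For a set $S$ with $k$ members among $N$ ranked genes, the running sum
increments at hits by $|r_i|^p / \sum_{j \in S} |r_j|^p$ (weight $p = 1$,
the classic default) and decrements at misses by $1/(N-k)$; ES is the
signed maximum deviation and lies in $[-1, 1]$. An exact tie between the
positive and negative extremes returns ES = 0, which keeps ES antisymmetric
under negation of all scores. The null distribution is built from `n_perm`
random same-size gene sets (gene permutation, not sample permutation —
with 3–4 samples per group the sample-permutation null is far too coarse);
NES divides ES by the mean |null ES| of matching sign, and the p-value is
the same-sign tail frequency with +1 smoothing so that p is never zero. At
$N \le 8$ the Monte-Carlo p matches a complete enumeration of all
$\binom{N}{k}$ sets within Monte-Carlo error; this enumeration is kept as a
test oracle. The permutation count, size bounds (5–500) and the smoothing
rule are declared package defaults — the reference analysis does not state
the ones it used.

## The correlation + evidence screen

Expression is transformed to $\log_2(\text{normalized count} + 1)$ (the
reference analysis does not state its transform; the option
`transform = "none"` is available) and every candidate (miRNA, gene) pair
receives a Pearson correlation over the samples in scope with the two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom.
Zero-variance features yield flagged records with undefined r that the
filter drops.

**Scope.** The source description says correlations were computed "in each
group", but with 3–4 samples per group the screen thresholds are nearly
unreachable (p < 0.05 at n = 3 needs |r| > 0.997), so the package defaults
to the pooled scope across all shared samples (n = 7 in the emulated
design) and exposes per-group scopes by configuration. This is the single
most consequential underdetermined choice in the chain, and pooled
correlations deliberately conflate between-group and within-group
covariation — which is also why the synthetic decoys exclude independently
DE genes (below).

The negative screen keeps records with r < −0.7 **and** p < 0.05, both
strict: a correlation of exactly −0.70 is excluded. No multiplicity
correction is applied at this stage, matching the published filter; a BH
column is carried in the pipeline output for transparency. Surviving pairs
are intersected with the evidence table, matching case-insensitively on the
mature miRNA ID or accession and on the gene symbol. An edge is emitted
when the pair has validated evidence (miRTarBase/TarBase) or at least
`min_predicted_dbs` distinct prediction databases (DIANA-microT, ElMMo,
PITA). The default is 1 with a validated bypass, because the printed
reference table retains single-database pairs even though a figure caption
mentions a three-database rule; the caption's rule is available via
configuration. Duplicate (miRNA, gene) rows collapse to one network edge
with merged evidence, and node directions come from the sign of the DE
log2FC.

## Cohort statistics

`rout_outliers()` implements ROUT specialized to the constant model: median
center, RSDR = 68.27th percentile of |residuals| × n/(n−1), and a BH-style
step-up at rate Q (default 1%) over the t-tail probabilities on n − 1
degrees of freedom. `compare_continuous()` gates on Shapiro–Wilk at the 5%
level per group, then uses the pooled-variance two-tailed Student t or the
Mann–Whitney test (exact for small untied samples); with summary input
(mean, SD, n) only the pooled t is possible — printed baseline tables carry
only summaries. `compare_categorical()` is the uncorrected Pearson
chi-square on the 2×2 table, chosen because it reproduces the reference
baseline rows that are reproducible at all; counts are reconstructed from
percentages as round(pct/100 × n), warning when a percentage is not within
0.51 percentage points of any integer count. Three baseline rows (sex, high
blood pressure, dyslipidemia) match neither chi-square nor Fisher on the
reconstructable counts and are reported as computed, not forced. Two
continuous/categorical rows (LVESD, diuretics) land within half a unit of
the printed third decimal when recomputed from the printed (rounded)
summaries — the residual discrepancy is print-rounding of the inputs, not a
different test.

## Quantification

`ddct()` computes, per sample, ΔCt = Ct(target) − mean(Ct of references)
— the arithmetic mean of reference Cts is the geometric mean of reference
expression in linear space, the standard multi-reference convention, used
here because the reference protocol lists two reference assays without
stating a combination rule — then ΔΔCt against the calibrator-group mean
and fold = 2^−ΔΔCt. No amplification-efficiency correction is applied. The
fold changes are invariant to any per-sample additive Ct offset. Group
comparison runs on the ΔCt values through `compare_continuous()`.
`luciferase_activity()` normalizes experimental luminescence to the
co-transfected control per well, rescales to baseline mean 1, and tests
each condition against baseline with the pooled Student t.

## The synthetic cohort generator

`sim_config()` pins the emulated study conditions: 4 + 3 samples (the
paired sequencing design), 1,000 genes and 100 miRNAs at desk scale,
negative-binomial counts with dispersion 0.05 and log-uniform library sizes
in [5×10⁵, 1.5×10⁶], 50 DE genes and 5 DE miRNAs with signed log2 effects
drawn from ±[1, 2.5] (comfortably above the 0.5 screen threshold), and 4
repressive pairs at coupling −1.5. Coupling acts at the log-mean level: the
target gene's log2 mean is shifted by the coupling strength times the
miRNA's realized log2 deviation from its overall mean, so the target's
differential expression and the negative cross-sample correlation arise
from one mechanism rather than post-hoc correlation injection. Library
sizes are log-uniform to reproduce size-factor spread without modelling
lane effects. The dispersion and library-size defaults are calibration
choices, not estimates of any real cohort.

Evidence fixtures guarantee every planted pair at least one database row
and add decoy rows for pairs that were never coupled. Decoy genes exclude
both coupled targets and independently DE genes: under pooled correlation a
pair of two independently DE features carries a genuine group-driven
negative correlation, so it is not a null pair, and planting such decoys
would make "zero decoy edges" unattainable by any correct implementation.

**What passing the synthetic validation shows — and what it does not.**
Recovery of planted pairs with zero decoy edges in ≥ 80% of seeded cohorts
shows the chain is wired correctly and calibrated at the emulated
conditions. It does not show the pipeline recovers true biology from real
tissue: the generator has no batch effects, no isomiR structure, no
donor-level pairing, no correlated co-regulation beyond the planted
couplings, and its NB dispersion is a single constant rather than the
heavy-tailed mean-dependent spread of real biopsies. Real-data screens at
n = 7 remain underpowered and enrichment-confounded in ways no synthetic
check can absolve.

## Numerical choices and degenerate inputs

Problem sizes used by the packaged validation: 2,000 features for the null
calibration, 50 seeded cohorts of 1,000 genes for recovery, 20,000
permutations for the enumeration check. Deterministic seeding derives
stage-level seeds below 2³¹ from the user seed. Ranking ties break
lexicographically; ES sign ties return 0; permutation p-values are
+1-smoothed; BH uses `p.adjust`; all readers fail with located errors
rather than silently dropping records; writers and readers are inverse on
valid artifacts. The pipeline warns but proceeds when `r_max` is positive
(a deliberately defeated screen), and aborts naming the stage on any
internal error.

## Known limitations

Two-group designs only (no covariates, no multi-factor contrasts); no
Cook's-style count-outlier replacement or apeglm-style effect shrinkage;
gene-permutation GSEA only; evidence is consumed as tables (no sequence
based target prediction); correlation scope choices cannot recover what the
reference analysis actually did, and per-group screens at n = 3–4 are
statistically near-vacuous.
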