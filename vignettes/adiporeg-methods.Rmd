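---
title: "adiporeg: models, calibration choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adiporeg: models, calibration choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiporeg)
```

# Scope

`adiporeg` analyzes transcriptional regulation across the three stages of
3T3-L1 adipocyte differentiation — *non* (t ≤ 0 h after MDI induction),
*early* (0 < t ≤ 48 h) and *late* (48 < t ≤ 260 h) — from gene-level
RNA-seq count matrices and ChIP-seq reads-in-peaks count matrices. It does
not align reads, call peaks or render signal tracks; it starts where
featureCounts- and MACS2-style tooling stops. The stage boundaries are
closed on the right (0 h is *non*, 48 h is *early*) and centralized in
`assign_stage()`.

# The count model

Both differential expression and differential peak binding use one
negative-binomial Wald core with variance function
$\mathrm{var}(Y) = \mu + \alpha\mu^2$:

* **Normalization.** Median-of-ratios size factors, rescaled to geometric
  mean 1. When no feature is positive in every sample the `"ratio"` method
  refuses and points to `"poscounts"`, which uses geometric means over
  positive counts only (relevant for sparse peak matrices).
* **Dispersion.** Per-feature method-of-moments on normalized counts with
  pooled within-group variance,
  $\hat\alpha = \max\!\big(0, (s^2 - \bar\mu\,\overline{1/s_j})/\bar\mu^2\big)$;
  the $\overline{1/s_j}$ term accounts for the extra shot noise introduced
  by dividing by size factors. Raw values are shrunk with fixed weight 0.5
  toward a parametric trend $a_0 + a_1/\mu$ fit by least squares with one
  outlier-trimming pass, and floored at $10^{-8}$. The weight is a fixed
  design choice, not empirical Bayes; it is exposed as an argument.
* **Testing.** Group NB means are fit by a vectorized Newton solver with
  size-factor offsets and fixed dispersion; the Wald statistic is
  $\log_2(\hat\mu_B/\hat\mu_A)$ over its standard error from the Fisher
  information of the two group log-means, with a two-sided normal p-value
  and BH adjustment within the contrast. Features all-zero in both groups
  report `log2FC = 0`, `p = NA` and are excluded from BH; non-converged
  fits (rare) are likewise flagged.

This is deliberately *not* numerically identical to DESeq2: there is no
Cox–Reid adjustment, no LFC shrinkage and no Cook's outlier handling. The
original study consumed only plain Wald log2FC/FDR thresholds, which this
core reproduces; under the null the test is calibrated (type-I error at
p < 0.05 measured at ≈ 0.05–0.06 with 8 samples per stage, see
`test-acceptance.R`).

Regulation labels follow the study thresholds with strict inequalities:
genes `up`/`down` when |log2FC| > 1 and FDR < 0.2; peaks when
|log2FC| > 0.5 and FDR < 0.2. A log2FC of exactly 1 (or 0.5) is `none`.

# Co-expression and its null

Counts are variance-stabilized as $\log_2(y/s + 1)$. This shifted log is
monotone, closed-form and adequate for Pearson correlation; it is *not*
the fitted variance-stabilizing transform of DESeq2 (documented
deviation — the fitted VST changes correlations negligibly at the read
depths simulated here but would need the full dispersion trend machinery).

Per stage, the factor–target Pearson correlation uses that stage's
samples only (at least 4). Differences between stages are tested on the
Fisher scale, $z = \operatorname{atanh}(r)$, $\mathrm{var}(z) = 1/(n-3)$,
with $z_\mathrm{diff} = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$.
Empirical p-values permute stage labels across the pooled samples B times
(default 1000, seed mandatory) and pool the null over all pairs —
matching DGCA's default pooling — with
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B \cdot \mathrm{pairs})$
and BH q-values; pairs are flagged at q < 0.2. Correlations at exactly
±1 are clamped to 1 − 10⁻¹² with a warning. The PCC values 0.25/0.5 the
study quotes for reporting are treated as reporting cutoffs, not test
thresholds.

One estimator subtlety: all pairs sharing one factor are correlated
through the factor's expression vector, so a type-I-error estimate from a
single factor is noisy. Calibration checks therefore aggregate over
several factors.

# Over-representation

The 2×2 over-representation test is the exact one-sided hypergeometric
upper tail $P[X \ge k]$ with the odds ratio Haldane-corrected when a cell
is zero; the universe is all features surviving the expression filter
(configurable). No read-length bias correction is applied (the synthetic
data carry no length covariate). Being a discrete one-sided test, the
null p-values are conservative (mean > 0.5), not uniform; the test suite
checks uniformity of the randomized-p version and conservative validity
of the reported p, and checks the tail values against brute-force
enumeration.

# Peak analytics

Coordinates are 0-based half-open everywhere in memory; GTF input is
shifted at the boundary. A peak is assigned to the gene minimizing the
absolute midpoint-to-TSS distance on its chromosome, ties broken by the
lexicographically smaller gene id (deterministic); signed distances are
strand-aware with negative = upstream. Region labels use midpoint
containment with precedence Promoter (±3 kb around the TSS, boundary
inclusive) > 5'UTR > 3'UTR > other — whether the original analysis used
midpoint or any-overlap membership is unstated; midpoint gives a single
unambiguous label per peak. Occupancy matrices sum size-factor-normalized
peak counts within gene (or gene × region) groups, so region rows of a
gene sum exactly to its total row. Stage occupancy change is
$\log_2((\bar m_B + 1)/(\bar m_A + 1))$.

# Link integration

The source narrative never states a formal link-calling rule; the rule
here is a conjunction, with every threshold in the configuration:

1. the factor has a Promoter-region peak on the target gene;
2. that peak's differential binding is significant (peak thresholds) in a
   stage contrast — `early_vs_non` nominates *early*,
   `late_vs_non`/`late_vs_early` nominate *late*;
3. the factor–target stage correlation exceeds 0.25 in absolute value in
   the nominated stage, and the factor itself is expressed there
   (normalized mean count ≥ 10; this operationalizes "availability of the
   factor in each stage").

Sign is induction (r > 0.25), repression (r < −0.25) or ambiguous. A
factor binding its own promoter gives mode `auto`; mutual direct links
form feedback pairs, reported as the pair of links plus a
`detect_feedback()` summary. Indirect links expand direct links on
autophagy TFs through *annotated* regulons (from the synthetic truth or a
user table) — the package does not infer regulons de novo. Knockdown
consistency marks a link `yes` if, at any profiled time point, the
knockdown of the factor moves the target in the direction the sign
predicts (induction → down, repression → up), `no` if tested and never
matching, `untested` otherwise.

# The synthetic world

The generator emulates the curated datasets' structure, not their
numbers. Defaults: 2000 genes with group sizes 5 adipogenic TFs, 6
autophagy TFs, 158 autophagy genes, 10 lipogenic genes (the 158 and 6
mirror the real GO-derived set sizes); 8 samples per stage at the
protocol's sampled hours (−48, 0, 4, 24, 48, 96, 240); NB counts with
baseline mean 100 (per-gene log-normal spread, sdlog 1) and dispersion
0.1; per-sample size factors log-uniform in [0.5, 2] so normalization is
exercised; 80% null fraction. Planted log2 effects are monotone
adipogenic-TF trajectories (+1.5 early, +2.5 late), signed autophagy
effects (±1.5/±1.0) and late lipogenic induction. Two ChIP factors get
~10 direct targets each (echoing Cebpb→{Becn1, Map1lc3b, Xbp1},
Pparg→{Becn1, Sqstm1, Tfeb, Foxo1}), one feedback 2-cycle, one
auto-regulation link, and promoter peaks with stage occupancy changes of
magnitude 1.5–2.75 (the upper value echoing the largest binding change
the study reports). Decoy peaks are placed distally and as unchanged
promoter peaks on background genes, so false-positive opportunities
exist. Knockdown arms reduce the factor's own mean by 2² and move each
direct target by 2^1.5 against its link sign (first-order propagation
only — no quantitative cascade model exists to emulate).

Stage-restricted co-expression is planted through a latent per-sample
factor activity (SD 0.8 log2 units) added to the factor gene everywhere
and to each target, scaled by the link sign, in the link's stage only.
The SD is a calibration choice: it yields stage correlations around
0.5–0.8 at 8 samples per stage, strong enough that a planted link fails
the |r| > 0.25 gate only a few percent of the time, without degenerate
correlations.

What the generator does **not** emulate: read-level sampling, sequence
content, gene length (hence no length bias in ORA), batch structure,
multi-chromosome realism beyond slot layout, cascade (second-order)
knockdown effects, and the empirical effect-size distribution of the real
data — the original study's fold-changes come from curated public
datasets that are not reproducible at desk scale. A green end-to-end test
therefore establishes that the pipeline recovers the *kind* of structure
the study describes at realistic sizes and noise, not that it reproduces
the study's published tables.

# Numerical and degenerate-input choices

* Newton fits floor means at 10⁻⁸; information terms are floored before
  inversion; all-zero features short-circuit to `p = NA`.
* `fisher_z` refuses n ≤ 3 and clamps |r| = 1.
* Zero-variance expression vectors drop pairs with a message rather than
  propagating `NA` silently.
* Stage boundaries, DE thresholds and the ±3 kb promoter window are
  closed/strict exactly as the acceptance tests assert; ties in
  nearest-gene distance are broken lexicographically.
* `classical_mds` reduces k with a warning when fewer positive
  eigenvalues exist; variance explained is per-dimension eigenvalue over
  the positive-eigenvalue mass.

# Known limitations

* The NB Wald test is slightly liberal at very low counts (as is any
  plug-in-dispersion Wald test); the expression filter (10 reads in 3
  samples by default — the original study's exact filter is unpublished)
  keeps the calibrated regime.
* Empirical p-values inherit pooled-null granularity 1/(1 + B·pairs).
* The integration rule is a formalization of a narrative; its precision
  and recall are properties of this rule on the synthetic world, and the
  published figure-level edge sets are not reproduction targets.
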