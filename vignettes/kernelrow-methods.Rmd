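---
title: "Methods: dissecting and predicting maize kernel row number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting and predicting maize kernel row number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelrow)
```

kernelrow implements a complete analysis pipeline for a quantitative maize
ear trait — kernel row number (KRN), the number of kernel rows per ear — as
studied in diverse inbred panels and biparental families: phenotype
summarization and BLUP, structured-panel GWAS with effective-test
correction, LD-block tagSNP banking, RR-BLUP whole-genome prediction
experiments, F2:3 interval mapping with gene-action classification, and
QTL/association co-localization. Because the panels this kind of study uses
are rarely deposited, the package ships a synthetic-data generator whose
defaults emulate the published study conditions, so every stage is
exercisable and testable end to end.

## The synthetic panel

`simulate_panel()` generates a structured panel of fully homozygous inbred
lines. Its defaults mirror a real diversity panel: 513 lines in four
subpopulations, ten chromosomes carrying ~49,000 SNPs after a MAF ≥ 0.05
filter, five environments with two replicates, and a repeatability target
of 0.94.

* **Structure.** Per-SNP ancestral frequencies are uniform on (0.1, 0.9);
  subpopulation frequencies follow a Balding–Nichols model,
  $p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$,
  with divergence $F$ (default 0.2, a typical between-group value for
  temperate versus tropical maize germplasm). A method-of-moments (Hudson)
  estimator applied to the simulated genotypes recovers $F$ within ±0.05.
* **Linkage disequilibrium.** Rather than a coalescent simulation, each
  line's haplotype is a Markov mosaic over `n_founders` founder haplotypes
  per subpopulation (default 40): the founder identity switches between
  adjacent SNPs with probability $1 - e^{-\rho\,\Delta bp}$. This is
  desk-scale and gives directly tunable LD: mean adjacent-SNP $r^2$ decays
  monotonically in $\rho$ (default $2\times10^{-6}$ per bp, giving
  appreciable LD over hundreds of kb).
* **Trait architecture.** `n_qtl` causal SNPs (default 30) are drawn from
  SNPs whose realized MAF lies in `qtl_maf_range` (default 0.05–0.3),
  reflecting the empirical pattern that large-effect KRN alleles segregate
  at low frequency. Absolute additive effects follow a geometric series
  (default scale 0.8 rows, ratio 0.92, signs random); the genetic value is
  $\mu + \sum_j a_j x_j$ with $x \in \{-1, +1\}$ from homozygote dosage.
* **Phenotypes and repeatability.** Observations add an environment main
  effect, a line×environment interaction and a replicate residual. When a
  `target_repeatability` $H^2$ is set, the interaction and residual SDs are
  jointly rescaled so that
  $V_g / (V_g + V_{ge}/n + V_e/(nr)) = H^2$ given the realized genetic
  variance; requesting $H^2 < 1$ with both error SDs at zero is a
  configuration error. The generator seed drives every stage, and outputs
  are bit-identical for a fixed seed.

What the generator does **not** emulate: genotyping error, ascertainment
bias of array SNPs, admixed individuals between subpopulations (membership
is discrete), epistasis, and selection. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean additive model, not
robustness to every pathology of real panel data.

## Phenotype summaries

`env_means_and_blup()` averages replicates within (line, environment) and
fits environment as fixed and line as random by REML (lme4), reporting each
line's BLUP as the fixed-effect grand mean plus its predicted random effect
— on the trait scale, directly comparable with environment means.
Replicates are averaged before fitting, matching trials where the replicate
mean is taken as the genotype's phenotype. `variance_components()` fits the
line and line×environment random model on replicate-level data; a balanced
expected-mean-squares ANOVA path cross-checks the REML estimates.
Repeatability is $\sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / nr)$ and
broad-sense (family-mean) heritability adds the interaction term
$\sigma_{ge}^2/n$.

## Association scans

`glm_scan()` is per-SNP OLS with optional structure covariates;
`mlm_scan()` is the mixed model $y = X\beta + x_j b_j + u + e$ with
$u \sim N(0, K\sigma_g^2)$. The variance ratio is REML-estimated once on
the null model via the spectrum of $K$ and then fixed for every SNP test
(the P3D/EMMAX approximation); exact per-SNP REML is available behind
`per_snp_reml = TRUE`. With $K = 0$ the MLM collapses to the OLS scan
exactly, which the suite asserts. Kinship is the VanRaden centered
cross-product rescaled to unit mean diagonal. Missing dosages are
mean-imputed per SNP for kinship, PCA and scans. p-values are floored at
the smallest positive representable number.

The effective number of tests follows the Li–Ji eigenvalue rule: per
chromosome, $M_{\mathrm{eff}} = \sum_i \left[ I(\lambda_i \ge 1) +
(\lambda_i - \lfloor \lambda_i \rfloor) \right]$ over eigenvalues of the
SNP correlation matrix, summed across chromosomes. Chromosome-wise
computation is a design choice: the genome-wide correlation matrix is
infeasible at ~49k SNPs and the SNPSpD lineage operates block-wise;
independence across chromosomes makes the sum exact in expectation.
Eigenvalues are rounded at 1e-10 before flooring so that exact-integer
eigenvalues (e.g. a perfectly correlated pair) land on the correct side of
the step. Thresholds are reported for $\alpha/M_{\mathrm{eff}}$ and
$\alpha/(0.1N)$ at $\alpha \in \{0.05, 0.10\}$.

Per-SNP variance explained is the structure-corrected
$R^2 = 1 - RSS_1/RSS_0$, where both models include the Q covariates.
Significant SNPs are grouped into loci greedily: the most significant
unassigned SNP seeds a locus and absorbs same-chromosome significant SNPs
with $r^2 > 0.2$ to the seed; ties break by (chromosome, position). The
greedy rule was chosen because it reproduces "the most significant SNP
represents its block" semantics directly; no block algorithm is prescribed
by the study design.

## tagSNP bank

`build_bank()` applies the same greedy, significance-seeded rule to *all*
SNPs: the top unassigned SNP tags a block and absorbs unassigned
same-chromosome SNPs with $r^2 > 0.2$ within `max_bp_window` (default 1 Mb
— LD beyond 1 Mb in diverse maize panels is negligible, and the cap keeps
the pairwise work linear). Blocks partition the SNP set; every tag is its
block's most significant member by construction; the pooled tags, sorted
by significance, form the marker bank. The $r^2$ comparison is strict
(`>`), and LD is the squared Pearson correlation of dosages (composite LD,
appropriate for inbreds).

## RR-BLUP prediction

`rrblup()` fits $y = 1\mu + Mu + e$, $u \sim N(0, I\sigma_u^2)$ by REML
profiled over $\sigma_u^2/\sigma_e^2$ on the eigenvalue spectrum of $MM'$
(tolerance of the 1-D optimizer ~1e-8 on the log scale), then recovers
marker effects through the ridge identity
$u = M'(MM' + \lambda I)^{-1}(y - 1\hat\mu)$, $\lambda =
\sigma_e^2/\sigma_u^2$. Markers are centered by training-set column means;
hybrids are coded on the same 0–2 dosage scale (heterozygote = 1), so
hybrid prediction uses the additive effects estimated in inbreds. The
ridge/GBLUP equivalence is asserted numerically in the suite against a
direct $(Z'Z + \lambda I)^{-1}$ solver.

`run_experiment()` reproduces the marker-set/training-set designs: top-k
tags (deterministic) versus random-k tags (five inner samplings per size,
averaged within a repeat), training sets drawn as a random half, a fixed
size, or a subpopulation, validation on held-out lines and optionally on
hybrids, each repeated (default 100 times). Accuracy is the mean over
repeats of the per-repeat Pearson correlation — matching "repeat, then
report one accuracy" — not the correlation of pooled predictions. The size
grid is free; representative sizes (17, 300, 1k, 10k, 24k) can be passed
directly. Random marker sets are interpreted as independent draws per size
on a stride-5-capable grid rather than cumulative augmentation of one set.

## F2:3 interval mapping

`simulate_f23()` crosses two homozygous parents, selfs the F1 via a
Haldane meiosis (`meiosis_gamete()`, no interference), and phenotypes each
F2 plant by its F3 family mean. The family-mean genotypic value at a QTL is
$a x + d h/2$: random selfing halves the dominance deviation relative to
the F2 plant (standard F2:3 expectation; the alternative — phenotyping the
F2 itself — would use $dh$). The same $h/2$ column enters the Haley–Knott
design so the reported dominance effect is on the F2 scale.

`hk_scan()` regresses family means at each 1-cM grid position on
$x^* = p_{QQ} - p_{qq}$ and $z^* = p_{Qq}/2$, where the conditional QTL
genotype probabilities given the flanking markers come from an exact
enumeration of the two independent F1 gametes under Haldane recombination
(missing markers marginalized; both missing gives the 1:2:1 prior).
Composite interval mapping adds forward-stepwise cofactors
(`select_cofactors()`, additive codes, entry p < 0.01, default cap 5) and
excludes cofactors within a 5-cM window of the test position.
$\mathrm{LOD} = (n/2)\log_{10}(RSS_{\mathrm{reduced}}/RSS_{\mathrm{full}})$.
Haley–Knott regression was chosen over EM interval mapping because the two
are nearly indistinguishable for F2:3 family means at this scale and the
regression form admits the fast cofactor machinery.

`call_qtl()` takes local maxima above LOD 2.5; two maxima are distinct
peaks when separated by a ≥1-LOD valley or by ≥20 cM (the peak-separation
rule is a package decision; no rule is prescribed). Each record carries the
flanking markers, their physical span (1-based closed), effects at the
peak, $PVE = 1 - RSS_{\mathrm{full}}/RSS_{\mathrm{null}}$ against the
intercept-only model, and the Stuber-scale gene action from $|d/a|$:
additive ≤ 0.20 < partial dominance ≤ 0.80 < dominant/overdominant
(merged). The ratio is classified unrounded and reported at 2 decimals.
Under a strong QTL with no cofactors, LOD can stay elevated across much of
a chromosome (linked markers carry signal), so distal local maxima may be
called; with cofactors the background is absorbed and a single planted QTL
yields a single record — the CIM configuration is the intended default.
`cluster_common_qtl()` merges records with overlapping physical intervals
(single linkage) into common QTLs.

## Hotspots and co-localization

`hotspot_scan()` tiles chromosomes with 10-Mb windows every 5 Mb, counts
distinct source intervals overlapping each window (closed intervals,
any-overlap; intervals sharing a provenance label count once, so one QTL
detected in several environments is a single detection), keeps windows with
≥2 detections and merges overlapping or abutting qualifying windows.
`colocalize()` flags a locus when any member SNP position falls inside a
target interval, and reports the cross-validated fraction. Overlap
semantics — 1-based closed, ≥1 bp — are the most permissive and the easiest
to audit; a midpoint mode exists behind a flag for window counting.

## Numerical choices and degenerate inputs

* REML ratio searches run on $\log\delta \in [-12, 12]$; boundary solutions
  (no or all polygenic/marker variance) are accepted silently.
* A constant phenotype in `rrblup()` returns the intercept-only fit with
  $\sigma_u^2$ at its lower bound; monomorphic SNPs in scans get
  $p = 1$, effect 0, and a `monomorphic` flag; zero-variance inputs to
  `ld_r2()`/`accuracy()` are errors.
* Ties in significance break by (chromosome, position) everywhere, making
  every greedy procedure deterministic.
* Every simulator takes one integer seed from which all stage randomness
  derives.

## Problem sizes in the test-suite and acceptance runs

The shipped suites exercise the pipeline at desk scale, chosen as the
smallest sizes at which the statistical claims are expected to hold
clearly: calibration of the mixed model uses 50 structured-null panels of
300 lines × 1,000 SNPs; the prediction experiment uses one panel of 500
lines × 5,000 SNPs with 30 causal loci at repeatability 0.9, 100
training/validation repeats for the top-versus-random comparison and 25
repeats for the size-curve shape; QTL recovery uses 100 F2:3 populations of
250 families on a 2-chromosome, 10-cM-spaced map with a planted QTL
(a = 0.8, d = 0.1, family-mean heritability 0.15) plus 50 null populations.
The structured-null subpopulation shift is 0.5 (≈20% of phenotypic
variance, the upper range of structure effects reported for KRN panels);
hybrid phenotypes use a noise SD of 0.5 rows, a plausible trial-level error
for a single-environment, multi-ear-averaged hybrid evaluation, which the
study design leaves unspecified.

## Known limitations

The MLM uses the P3D approximation by default; per-SNP REML is exact but
slower. Meff is chromosome-blocked, so cross-chromosome correlation (e.g.
from strong structure) is not captured — structure should be regressed out
or accepted as slight conservatism. The tagSNP bank depends on the scan
used to rank SNPs; a poorly calibrated scan propagates into Strategy-1
marker sets. The F2:3 machinery assumes bi-allelic codominant markers
(SSRs are represented as such) and no segregation distortion. Genetic-map
construction, Bayesian whole-genome regressions, and lift-over between
genome builds are out of scope.
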