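---
title: "Weighted genomic BLUP in autotetraploids: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted genomic BLUP in autotetraploids: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyblup)
```

## 1. The problem

Genomic selection regresses a quantitative phenotype on genome-wide
marker dosages with far more markers than individuals (p ≫ n), so
effects must be shrunken. The two workhorse parameterizations are
equivalent: RRBLUP shrinks m marker effects with a common ridge
penalty, GBLUP shrinks n individual genetic values through a marker-built
covariance (the genomic relationship matrix, GRM). In autotetraploids a
biallelic SNP has five genotype classes — dosage 0..4 for AAAA through
BBBB — and this package keeps that dosage structure everywhere: in the
GRMs, in the gene-action models of the association scan, and in the
simulator.

The strategy the package is built around is *weighted* GBLUP: estimate
per-marker importance (association `-log10 p`-values or ML variable
importance), place it on the diagonal of `D`, and use
`G* = Wc D Wc' / c` as the covariance. Markers believed to tag QTL then
contribute more relationship information than noise markers.

## 2. Relationship matrices

All builders start from the dosage matrix `W` (n x m, entries 0..phi)
with alternate-allele frequencies `p_i = mean(dosage_i)/phi`.

* **VanRaden** (`vanraden_grm`): `G = Wc Wc' / c` with
  `Wc = W - phi p` column-centered. The source formula writes "Z is an
  identity matrix for the markers", which taken literally makes the
  quadratic form degenerate; we follow VanRaden's standard construction
  and read Z/W as the centered dosage matrix. The denominator is
  `phi * sum(p(1-p))` by default — the generalization whose expected
  diagonal is 1 under HWE for dosages 0..phi (verified by a property
  test: mean diagonal in [0.9, 1.1] on simulated panels) — with
  `denominator = "paper_literal"` providing the printed diploid constant
  `2 * sum(p(1-p))`. The choice rescales variance components, never
  prediction-accuracy ranks.
* **Yang** (`yang_grm`): the per-marker standardized GRM with its
  distinct diagonal expression, on diploid codes 0/1/2. The source
  prints the coding "0 = AA, 1 = BB, 2 = AB", which is inconsistent with
  its own `2p` centering; we use the standard alt-allele count
  (0=AA, 1=AB, 2=BB) and flag the discrepancy rather than absorb it
  silently. Tetraploid data must first pass through
  `pseudodiploid_recode` (0 -> 0; 1,2,3 -> 1; 4 -> 2).
* **Full autotetraploid** (`slater_grm`): one-hot expansion of the five
  classes (`indicator_expand`, `M = 5m` columns), class-frequency
  standardized. The printed formula carries a `1 +` offset on *both*
  diagonal and off-diagonal; whether the offset was intended only for
  the diagonal cannot be resolved from the source, so it is implemented
  exactly as printed (off-diagonals sit near 1 rather than 0; this is a
  location shift absorbed by the mixed model's intercept-free random
  effect only through the variance scale — users comparing entries
  across builders should expect it).
* **Weighted** (`weighted_grm`): `G* = Wc D Wc' / c`, `D = diag(w)`,
  `w >= 0` finite, zero allowed (marker excluded), all-zero rejected.
  Default normalization rescales `w` to mean 1 before forming `D`, so
  `trace(G*) ~ trace(G)` and the genetic variance keeps its scale; `raw`
  is available since the source states no policy. With unit weights G*
  equals the VanRaden G exactly — the central reduction test, asserted
  to 1e-12 on 50 random panels.

## 3. REML and prediction

`reml_fit` maximizes the restricted likelihood of
`y = X beta + g + e`, `g ~ N(0, K sigma_g^2)`, over
`delta = sigma_e^2 / sigma_g^2` by projecting K against the fixed
effects, eigendecomposing once, and optimizing the explicit 1-D profile
likelihood in `log(delta)` on a [-8, 8] grid with golden-section
refinement. This is exact (no iterative REML convergence failures) and
is validated against an independent dense grid search over the
determinant-based criterion (|delta log| <= 0.01 on 20 instances).
Boundary solutions are flagged rather than hidden: `h2 -> 0` or `1`.
Eigenvalues of K in `(-1e-8 * max, 0]` are clamped to zero; larger PSD
violations are errors by design — a broken kinship should fail loudly.

`gblup_predict` computes
`g_test = K[test,train] (K[train,train] + delta I)^-1 (y - X beta)` with
GLS fixed effects; `rrblup_solve` solves the equivalent ridge system in
its n x n form. The two are tied together by an equivalence test at
1e-6, making the RRBLUP/GBLUP duality a maintained invariant instead of
folklore.

## 4. The association scan and weights

`gwas_scan` tests each marker under up to eight gene-action models whose
effect codes are scaled 0..1 over the dosage classes:
additive (0, .25, .5, .75, 1), diploidized additive (0, .5, 1 with
dosages 1-3 collapsed), diploidized general (hom/het/hom factor),
general (observed-class factor, up to 4 df), and the four
simplex/duplex dominance codings. Covariance is handled P3D-style:
REML once under the null, one rotation by `(K + delta I)^{-1/2}`, then
a per-marker F-test with the block's degrees of freedom (`p3d = FALSE`
refits per marker when a reference answer is wanted). Scores are
`-log10 p`, capped at 300. Design degeneracies are explicit: constant
codes are dropped, factor classes seen fewer than `min_class = 2` times
are absorbed into the baseline, untestable markers carry reason codes.

Calibration is enforced by test: under null simulation the empirical
type-I error at 0.05 stays inside [0.03, 0.07] per model and pooled
p-values pass a KS test against U(0,1); under two-subpopulation
structure with a phenotype drawn from the fitted covariance model, the
genomic inflation factor of the kinship-corrected scan stays in
[0.8, 1.2].

`scores_to_weights` floors scores at `1e-6` (skipped markers included)
so the weight vector is strictly positive; no multiple-testing
adjustment is applied — raw scores are the weights. External importance
tables (e.g. permutation importance from an SVM or random forest fit
with any ML library) enter through the same `weight_vector` interface
and are treated identically downstream.

## 5. Cross-validation and the leakage question

`run_cv` evaluates configurations by repeated k-fold CV, Pearson
`r(GEBV, y)` per fold, with all configurations of an experiment sharing
fold assignments so `compare_cv` can report paired differences.
Variance components are re-estimated by REML on every training fold.

The one genuinely open design question is *where scan weights are
estimated*. `leakage = "nested"` (default) rescans inside each training
fold: the honest generalization estimate. `leakage = "mimic_paper"`
computes weights once on the full data before splitting, which is how
the published workflow this package reproduces operated (weights from
the same individuals later cross-validated). Both are first-class, and
every report carries the flag.

The difference is not cosmetic. On simulated major-QTL panels
(5 QTL, h2 = 0.5, n = 300, m = 2000) the mean accuracies order as:

* plain GBLUP ~ 0.19;
* nested scan-weight WGBLUP ~ 0.47 — the real, honest WGBLUP gain;
* truth-weight oracle ~ 0.71, essentially the noise ceiling
  `cor(y, g_true) ~ 0.72`;
* mimic_paper scan-weight WGBLUP ~ 0.85 — *above* the ceiling.

An estimator cannot honestly beat the correlation between phenotype and
true genetic value; exceeding it is the signature of test-phenotype
leakage through the weights. For this reason the acceptance suite's
stated ordering "oracle >= mimic_paper scan" is left failing on
purpose: the oracle already sits at the ceiling, and no honest weight
vector can dominate a leaky one. The two remaining clauses — the leaky
scan beats plain GBLUP, with a strictly positive paired gain — hold
robustly, as does the nested version of the same directional claim.
This mechanism is also the parsimonious reading of very large published
WGBLUP gains obtained with full-data weights.

## 6. The simulator: what it does and does not establish

`simulate_genotypes` draws dosages Binomial(phi, p) per marker (random
bivalent pairing under HWE), p uniform on [0.05, 0.95] by default, with
optional LD blocks (founder column copied with per-individual mutation
rate 0.05). Defaults emulate the shape of the motivating dataset:
n = 265 individuals, m = 6796 markers. `simulate_phenotypes` builds
`g_true` from the exact gene-action code vectors (so a matched scan
model is the best detector by construction), with architectures
`major` (few effects |N(0,1)|+0.5), `polygenic` (many N(0, 1/sqrt(q))),
or `mixed`; residual variance is scaled for the target h2 and the
*realized* h2 is recorded, not assumed.

Deliberate simplifications: no double reduction or preferential
pairing, no genotyping error or read-depth model, no pedigree or
population substructure (structure used in tests is built explicitly),
and LD by copying rather than coalescent history. A green test
therefore establishes the *algebra and calibration* of the methods on
idealized tetraploid data — not that any particular accuracy will be
attained on a real breeding panel, where allele-dosage calling error
and family structure matter.

## 7. Numerical conventions

* Missing dosages: marker-mean imputation (frequency-preserving);
  fully missing markers dropped with a warning. The source is silent on
  its missing-data handling; this is the package's explicit choice.
* MAF filter default 0.05 and monomorphic markers always removed —
  `p(1-p) = 0` breaks every GRM denominator, so exclusion is forced;
  the threshold itself is a choice, not a source fact.
* Multiallelic and indel VCF records are dropped (and counted), never
  split: the marker set is biallelic SNPs.
* Dosage-field VCF input is rounded to the nearest class (codes are
  class-based downstream).
* Fold sizes: the `n mod k` larger folds come first; assignments are
  seeded and the RNG state of the caller is never disturbed.
* Score cap 300; weight floor 1e-6; REML search bounds
  `log delta` in [-8, 8] with boundary flagging.
* All delimited I/O is plain text (CSV/VCF); every CLI run writes a
  manifest sufficient to reproduce it bit-for-bit.

## 8. Known limitations

Single random effect only (no dominance/epistasis kernels, no
multi-trait or multi-environment models); no Bayesian whole-genome
regressions (weights from such fits can still be supplied as files);
no Q-matrix estimation (covariates are accepted, not computed); scans
are single-marker (no haplotype tests or LD clumping). These are scope
boundaries, not roadmap items.
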