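---
title: "Methods: disease-burden genetic risk scores in family-based longevity designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-burden genetic risk scores in family-based longevity designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsburden)
```

## The scientific question and the design

Family studies of exceptional longevity enrol probands with documented
familial longevity together with their siblings and offspring; the spouses
who married into those families carry no familial-longevity selection and
serve as controls. If longevity families simply lacked the common risk
alleles for age-related diseases, their members should carry measurably
fewer of them than the married-in controls. `grsburden` quantifies that
comparison with disease-specific *unweighted* genetic risk scores — each
risk allele counts one, so the score is the absolute burden of known risk
alleles rather than an effect-size-weighted prediction — and family-aware
rate models.

Two features of the design drive all the modelling choices. First, family
members share genotypes through descent, so observations are correlated
within families and any model that ignores that correlation overstates its
confidence. Second, genotyping is incomplete: individuals differ in how
many panel SNPs were called, so the natural outcome is a *rate* of risk
alleles per allele slot, handled with an offset of `log(2 m_i)` where `m_i`
is the number of called panel SNPs.

## Models

With `y_i` the risk-allele count, the primary model is a Poisson mixed
model,

$$\log E[y_i] = \log(2 m_i) + \beta_0 + \beta_1 \,\text{longevity}_i +
\gamma' z_i + b_{f(i)}, \qquad b_f \sim N(0, \sigma_b^2),$$

with `z_i` the adjustment covariates (sex within a generation; sex and
generation for combined data; never age, which is confounded with the
longevity indicator by the enrolment design). `exp(β₁)` is the ratio of
expected risk-allele rates between longevity members and controls, and
`100(1 − exp(β₁))` the percent fewer alleles carried by members. The
marginal likelihood integrates `b_f` by adaptive Gauss–Hermite quadrature
(9 nodes by default; 1 node is the Laplace approximation) via `lme4::glmer`.
Primary inference is the likelihood-ratio test for β₁ (χ², 1 df); Wald Z
statistics are always reported alongside because published tables
conventionally show them. The random-intercept variance is constrained to
be nonnegative; when it is estimated at the boundary the model coincides
with the plain GLM, and the boundary LRT uses the plain χ²₁ reference
without a mixture correction.

Three alternative fits probe robustness to the model specification:

* **Poisson GLM** ignoring family structure — the anti-conservative
  baseline (its coefficients have a closed form in the two-group case,
  which the tests exploit as an oracle);
* **Poisson GEE** with exchangeable working correlation and robust
  sandwich variance, written in-package by Fisher scoring with
  moment estimators for the working correlation and scale (no GEE solver
  is among the package's dependencies); it is checked in the tests against
  reference values from an independent implementation frozen on a small
  fixture. Wald inference only: GEE has no likelihood;
* **Gaussian LMM on the rate** `y_i / (2 m_i)` with covariance
  `σ²_g · 2Φ + σ²_e · I`, where Φ is the pedigree kinship matrix. REML
  estimation eigendecomposes the relationship matrix once, rotates the
  model to independence, and profiles the variance ratio by 1-d
  optimisation; the ratio is bounded below at zero. The Gaussian
  approximation is reasonable because panel counts are large (a 93-SNP
  panel gives counts near 90), but it is an approximation — it backs the
  Poisson models rather than replacing them.

## Panel construction rules

Catalog records survive filtering when `p < 5×10⁻⁸` (strict inequality —
a record at exactly the threshold is removed), a risk allele was reported
and parseable, and at most two common alleles are listed. Duplicate rsIDs
within a disease group collapse to the smallest p-value (the choice is
immaterial for an unweighted score, but it must be deterministic).
Literature-review SNPs are unioned in afterwards; a literature duplicate of
a catalog SNP defers to the catalog entry, and a risk-allele conflict
between the two sources is an error rather than a silent preference.

LD pruning computes r² as the squared Pearson correlation of dosage
vectors over individuals called at both SNPs (the standard composite
estimate for unphased data; no phasing or EM estimator is attempted) and
removes SNPs *until no pair exceeds the threshold*. A single pass over
pairs would leave violations behind chained LD (A–B and B–C both above
threshold); iterating to closure makes the postcondition testable and
exhaustively tested. Within a violating pair the dropped member is chosen
by a seeded fair coin, after pairs are ordered deterministically by rsID —
so a fixed seed reproduces the panel byte-for-byte while the removal is
still "random" in the published sense. Trait-to-disease-group assignment
is a user-editable keyword table (`default_trait_map()`), since no exact
published mapping is recoverable from a free-text trait column.

Strand-ambiguous SNPs (A/T, C/G) cannot be oriented to a risk allele
without strand metadata. The default policy is `keep`, correct for
simulated or single-platform data where strand is consistent; real
mixed-source catalogs should use `drop`. Only hard-call dosages are scored:
the unweighted score is defined on integer allele counts, and fractional
imputed dosages are out of scope.

## What the synthetic cohort emulates

The generator's defaults emulate a two-generation family longevity study:
583 families; generation 1 of one proband per family, full siblings
(Poisson, mean 1.379) and married-in spouses (each blood member has an
enrolled spouse with probability 0.126), totalling ≈1562 individuals of
whom ≈175 are controls; generation 2 of offspring (Poisson, mean 3.192 per
family) and their spouses at a 0.40 spouse fraction, totalling ≈3102. The
sibling and offspring means and the spouse rate are back-calculated so the
expected totals hit those targets; the generation-2 spouse fraction is not
derivable from published generation-1 tables, and 0.40 is our recorded
choice. Sex is Bernoulli(0.5) for blood members; spouses take the opposite
sex so every offspring has a father and mother.

Genotypes come from a Gaussian-copula founder-haplotype model: within an LD
block all SNPs share one allele frequency (drawn per block from the
configured range — a homogeneity assumption that makes the copula
calibration exact, not a claim about real haplotypes) and a common latent
correlation, calibrated by solving a 1-d integral equation so the *dosage*
r² matches the configured target. Blocks are independent. Proband sibships
descend from a latent (unenrolled) parent pair; offspring receive one
whole parental haplotype per block, so blocks segregate as unlinked units,
within-block LD survives transmission, and the kinship correlation the
models must absorb arises mechanically from descent rather than by
assumption. Latent parents appear in the pedigree only as parent ids —
enough for both the genotype simulator and the kinship recursion to treat
full siblings correctly, while the enrolled cohort matches the study's
roster.

The familial-longevity effect is injected *after* genotype generation by
per-allele-slot binomial thinning (rate ratio < 1: each carried risk allele
of a longevity member is kept independently with probability
`r_f = ratio × exp(b_f)`) or boosting (rate ratio > 1: each empty slot at
SNP j converts with probability `(r_f − 1) p_j / (1 − p_j)`, which
multiplies the per-slot rate `p_j` by exactly `r_f`). Controls are never
touched. This preserves integer dosages and matches the multiplicative
rate model the analysis fits, at a known cost: thinned genotypes are no
longer exactly Mendelian-consistent with the pedigree. That is acceptable
because the published comparison is about count rates, not transmission;
the kinship-dependent analyses are tested on un-thinned cohorts. The
per-family log-scale shift `b_f` (SD 0.01 by default — no published value
exists, so it is a configuration knob) enters at the same stage.

What the generator does **not** emulate: realistic human haplotype maps or
recombination within blocks, imputation uncertainty, X-chromosome
inheritance, genotyping batch effects, or disease phenotypes. Passing
tests therefore demonstrate that the *statistical machinery* is correct
under the design's assumed structure, not that any biological conclusion
transfers to real data.

## Power simulation

The power study simulates at the level of scores, not genotypes: per
family an intercept `b_f ~ N(log(2m × rate), σ²)`, per individual a linear
predictor `b_f + β × longevity`, and a Poisson GRS draw; the mixed-model
LRT at α = 0.05 decides rejection, and the rejection fraction over 100
replicates (by default) estimates power with binomial Monte-Carlo SE. The
baseline per-slot rate (0.5, i.e. λ = m) and intercept SD (0.01) are not
recoverable from published tables, so mid-range published power values can
only be matched qualitatively — power rising with panel size and with
sample size — while the saturated cells (large panels, combined
generations) are reproduced exactly at 1.00. As an internal truth
standard, the σ = 0 case is checked against the closed-form two-group
Poisson Wald power with `Var(β̂) = 1/Σλ₁ + 1/Σλ₀`.

Because the simulated model has no individual-level covariates, each
replicate's fit first collapses individuals to family-by-status totals —
an exact sufficient-statistic reduction (a sum of iid Poisson counts
sharing one random intercept is Poisson with the summed offset) that cuts
fit time several-fold without changing the likelihood. Replicates whose
optimizer fails are excluded from the power denominator and counted.

## Numerical choices and degenerate inputs

* GLMM: 9 adaptive quadrature nodes by default (stability beyond 5 nodes
  is tested); `ranef_variance = 0` takes the exact nested-GLM limit rather
  than forcing the optimizer to the boundary. For nAGQ > 1 the reported
  log-likelihood is corrected back to an absolute scale (lme4 reports it
  relative to the saturated model), so it is directly comparable with the
  package's dense-grid integration oracle.
* GEE: Fisher scoring to an update tolerance of 1e-12; the
  estimating-equation residual at the solution is exposed (`$ee_norm`) and
  tested below 1e-6. The working correlation is clamped to (−0.99, 0.99).
  Singleton clusters are valid (that is how external controls enter).
* Kinship LMM: eigenvalues clipped at zero; the variance-ratio profile is
  optimised on the log scale over ±12 and compared against the
  ratio-zero boundary, so σ²_g = 0 is reachable exactly.
* LD pruning: zero-variance SNPs correlate with nothing (r² treated as 0,
  with a warning) rather than poisoning the correlation matrix with NaN.
* Scoring: an individual with no called panel SNP has no defined rate;
  the record is dropped with a warning rather than given an infinite
  offset.
* Determinism: one root seed per run; every stage derives its own stream
  through a named hash, so adding a stage never shifts the streams of
  existing ones, and a fixed seed reproduces every output file
  byte-identically.

## Problem sizes used by the test-suite

Unit tests run on deliberately small cohorts (tens of families) where the
checked property is scale-free; the study-scale checks — parameter recovery
of a 1 % allele deficit at the full 583-family structure with the 431-SNP
panel, the 100-replicate power cell, and the 500-replicate null calibration
of the mixed-model LRT on a 50-family structure — use the smallest sizes at
which the property is statistically decidable, chosen once from the
Monte-Carlo error budget (calibration bands of ±2 binomial SEs).

## Known limitations

* The GEE small-sample sandwich is not bias-corrected; with few clusters
  its type-I error runs slightly above nominal (the tests allow up to 0.11
  at α = 0.05 over 120 replicates).
* The kinship LMM assumes Gaussian rates; for very small panels (published
  8-SNP subsets) the approximation is rough and the Poisson models should
  carry the inference.
* The copula calibration assumes equal allele frequencies within a block;
  heterogeneous-frequency blocks would need a per-pair calibration.
* Thinning-injected effects mildly distort Mendelian consistency (see
  above) and, with a nonzero family intercept SD, the member-vs-control
  contrast within a family absorbs the full intercept shift because
  controls are untouched.
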