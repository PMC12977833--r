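---
title: "Variance methylation QTL mapping with MZ twins: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance methylation QTL mapping with MZ twins: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(twinvqtl)
```

## The generative model

The simulator treats the methylation beta value of one CpG in one twin
individual as a convex combination of four min–max-scaled components:

$$Y \;=\; a_G\, s(G) + a_E\, s(E) + a_{GxE}\, s(G \times \mathrm{smoking}) + a_{err}\, s(\varepsilon),
\qquad a_G + a_E + a_{GxE} + a_{err} = 1,$$

where $s(\cdot)$ rescales a vector to $[0,1]$ over all $2n$ twin
individuals of a replicate, preserving its distributional shape. $G$ is a
biallelic dosage shared by co-twins (drawn under Hardy–Weinberg with every
genotype group required to hold at least 5 pairs, mirroring the QC rule
applied to real cohorts), and $\varepsilon$ is i.i.d. per twin from a
standard normal, a $\chi^2_1$, or a Gamma(shape 2, scale 0.5) law — the
latter two emulating the skewness of real methylation distributions.
Because the weights are convex and every term lies in $[0,1]$, $Y$ is a
valid beta value; `beta_to_m()` gives the M-value view
($M = \log_2(\beta/(1-\beta))$, boundary values clipped at $10^{-6}$).

**Environmental composite.** The phenotype equation has a single $E$, but
four environmental factors are simulated: age $\sim U(20,70)$ and sex
$\sim \mathrm{Bernoulli}(0.5)$ shared within a pair; BMI drawn per twin from
the pair's regime ($N(25,1)$ for 80% of pairs, $N(25,3)$ for 20%); smoking
$\sim \mathrm{Bernoulli}(0.1)$ per twin. We take $E$ to be the min–max-scaled
equal-weight sum $s(s(\mathrm{age}) + \mathrm{sex} + s(\mathrm{BMI}) +
\mathrm{smoking})$, so all four main effects are present for the
residualization step to remove, while the interaction term involves smoking
only — the factor whose within-pair discordance (about 18% of pairs) powers
the variance signal. Drawing BMI per twin (within a pair-level regime)
rather than once per pair is deliberate: the residualization covariates
include diff(BMI), which would be identically zero under pair-shared BMI.

**Interaction implies a mean effect.** Since
$E[G \times \mathrm{smoking} \mid G] = 0.1\,G$, a pure interaction locus
also shifts genotype-group means. This is a property of the model, not a
bug, and it shapes the behaviour of the spurious-signal filter discussed
below.

## The six within-pair models

With per-pair responses $|t_1 - t_2|$ and $(t_1 + t_2)/2$ residualized on
the covariate sets (simulation mode: age, sex, diff(BMI),
smoking-discordance; cohort mode additionally within-pair differences/means
of estimated cell proportions and a batch-concordance indicator, with sex
dropped when constant), the tests are OLS regressions on the additively
coded dosage:

| model | response | extra covariate |
|---|---|---|
| Twins1 | res(abs) | — |
| Twins2 | res²(abs) | — |
| Twins3 | res(abs)/res(mean) | — |
| Twins4 | res²(abs)/res²(mean) | — |
| Twins5 | res(abs) | res(mean) |
| Twins6 | res²(abs) | res(mean) |

Pairs with res(mean) exactly 0 are dropped from the ratio models (their
count is reported) rather than epsilon-inflated; fewer than 10 usable pairs
is a refusal. Two-sided p-values come from the t distribution with the
residual degrees of freedom, and `fit_twins_model()` is verified against a
closed-form normal-equations oracle to $10^{-10}$.

What the evaluation grid (`run_grid()`) shows under these conditions, with
350 pairs, $a_{err} = 0.2$ fixed and $a_E$ absorbing the remainder:

* all six models hold the 0.05 level in the fully null normal-noise cell;
* Twins1 keeps its level in additive-only cells ($a_G$ up to 0.4) — the
  headline robustness property of the within-pair design;
* with skewed noise and a nonzero additive effect, Twins5 and Twins6
  inflate dramatically (false-positive rates approaching 1 at $a_G = 0.3$):
  res(mean) correlates with $G$ and, through the skewness-induced
  mean–variance coupling, with the response, so conditioning on it opens a
  collider path. Notably, Twins6 can show measurable inflation at large
  $a_G$ even under normal noise, because the squared response is itself
  skewed; the calibration claims we assert are therefore at the cells where
  they hold, and the inflation cells are asserted to be inflated;
* Twins1 dominates Twins2 (and both dominate the noisy ratio models
  Twins3/4) for interaction weights below roughly 0.15, with Twins1's
  discovery rate rising steeply in $a_{GxE}$.

## Cis and trans mapping

Cis windows are ±1 Mb around the CpG, endpoints inclusive, 1-based
coordinates. For each CpG the best nominal p-value over in-window SNPs is
calibrated by permuting the per-pair residual vector (pairs are the
exchangeable units) 10,000 times, fitting the per-permutation minimum
p-values to a beta distribution by maximum likelihood (method-of-moments
start; degenerate fits fall back to the empirical rank p-value and are
flagged), and reading the empirical p as the beta CDF at the observed
minimum. Storey q-values (λ grid 0.05–0.95, cubic-spline π₀, BH fallback
and an exact BH mode) select significant CpGs at q < 0.05; the per-CpG
nominal threshold is the beta quantile at the global p-cutoff implied by
the q crossing, interpolated midway between the last significant and first
non-significant sorted values. The beta approximation is validated against
a 5,000-permutation empirical oracle (agreement within ±0.05 across 50
synthetic CpGs).

Trans pairs (different chromosome, or beyond the cis window) use 20
whole-scan permutations and the counting threshold
$\mathrm{FDR}(t) = \frac{N(p_{perm} < t)/N(p_{real} < t)}{20}$, taking the
largest $t$ with FDR ≤ 0.05; per CpG, significant trans SNPs are LD-clumped
so only index SNPs remain.

LD clumping is the standard greedy procedure (smallest p becomes an index;
unassigned SNPs within 500 kb with dosage r² ≥ 0.2 join its clump), with
ties broken by (chromosome, position, id) so results are deterministic.

**Spurious-signal filter.** For each CpG carrying both variance and mean
signals, all vmeQTL and meQTL SNPs are clumped jointly (separately per
cis/trans combination); a variance SNP in a clump whose strongest signal is
a mean signal is discarded, with an audit row naming the dominating meQTL.
Because an interaction locus genuinely shifts means (see above), this
filter is intentionally aggressive on dual-signal loci: in the end-to-end
synthetic-genome evaluation we therefore quantify retention on
variance-only loci (≥ 80% retained at $a_{GxE} = 0.25$); dual-locus
retention is substantially lower — the expected cost of prioritising
specificity — while mean-only loci essentially never survive as variance
calls (< 5%).

**Conditional refit.** For a SNP called as both meQTL and vmeQTL, the mean
effect is estimated with a family random-intercept model
(`DNAm ~ (1|pair) + G`) and subtracted before re-testing. Co-twins share
dosage, so this subtraction shifts both members of a pair equally and the
within-pair difference is exactly preserved — the refit can only drop a
call through the re-residualization, and an exact fast path (estimating the
slope from pair means) is provided and tested equivalent.

## Gene–environment interaction testing

Stage 1 fits `DNAm ~ (1|family) + (1|batch) + age + covariates` by REML,
excluding the modifier of interest and MLR (for the MLR modifier, stage 1
adjusts for age, BMI, smoking and the four cell components). Singular fits
are retained — a zero-variance random component is exactly the OLS limit —
and a fixed-effects fallback exists only for hard failures. Stage 2
regresses the conditional residuals on dosage, modifier and their product.

One design decision here deserves emphasis. The family random intercept
only BLUP-*shrinks* the between-pair component of the modifier's main
effect; the leftover (essentially the co-twin's modifier value) is an
omitted clustered term in stage 2. Under the generator's null this made
the literal two-stage interaction test visibly anti-conservative, and
neither pair-clustered robust standard errors nor a stage-2 family random
intercept repaired it. Adding the within-pair mean of the modifier as a
stage-2 main effect — a conventional within/between decomposition for
clustered covariates — restores nominal calibration (the uniformity of
null interaction p-values is asserted in the test suite), so
`test_interaction(family = )` does exactly that while leaving the
interaction term untouched. FDR is Benjamini–Hochberg across all
association × modifier tests (per-modifier pooling available).

## Singleton variance tests

For unrelated cohorts, DRM regresses $|y_i - \mathrm{median}(y,
\text{group}_i)|$ on dosage (groups from rounded hard calls, raw dosage as
regressor) and SVLM regresses squared mean-adjusted residuals on dosage.
Both hold their nominal level under homoscedastic nulls, SVLM is unmoved by
pure mean-shift QTLs, and replication demands FDR < 0.05 under *both*
tests. A constant phenotype returns slope 0, p = 1 by convention.

## Numerical and scale choices

* All OLS paths use pivoted QR; aliased columns are dropped silently except
  the tested term, which raises an error.
* Randomness flows from per-call seeds; grid cells and CpGs receive
  deterministically derived child seeds, so results are independent of
  execution order and bit-reproducible.
* Beta-fit clipping at $10^{-12}$; M-transform clipping at $10^{-6}$
  (configurable).
* Test-suite problem sizes are the package's own evaluation choices: 1,000
  replicates for calibration/power cells, 10 seeds × (500 SNPs × 100 CpGs)
  with 2,500 permutations per scan for the end-to-end truth-recovery check
  (the beta approximation itself is validated at 10,000 permutations
  against the empirical oracle), 1,000 replicates for the GxE and
  DRM/SVLM calibration checks.

## What the simulator does and does not emulate

It reproduces the statistical structure the analysis relies on: shared
genotype and covariates within pairs, covariate-driven and skewed noise,
mean/variance/dual causal wiring, tunable LD blocks, and cross-platform
and singleton designs. It does not model array measurement error, probe
cross-hybridization, cell-type deconvolution error, realistic genome-wide
LD, imprinting, or chorionicity; passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artefact of real array data. Real-cohort covariate
layouts (estimated cell proportions, technical batches) are supported as
inputs but their estimation is out of scope.
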