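---
title: "Drug-target Mendelian randomization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

A drug target whose genetically proxied expression or protein abundance
causally shifts disease risk is a candidate for repurposing (or a warning
flag). With only summary statistics available — per-variant marginal effect
sizes, standard errors and allele metadata from an expression/protein QTL
study and a disease GWAS — the screen proceeds in stages: harmonize effect
alleles, select LD-independent instruments, estimate the causal effect,
check it for pleiotropy and reverse causation, confirm that the QTL and
disease signals share one causal variant, infer which direction a drug
would push the risk, and ask whether the locus works through a known
mediator such as blood pressure.

This vignette documents the models behind each stage, the tunable
parameters with their defaults and units, what the synthetic-data generator
does and does not emulate, and the design decisions taken where reasonable
alternatives exist.

## Two-sample MR model and assumptions

Each instrument $j$ supplies $(\hat\beta_{Xj}, \sigma_{Xj})$ on the exposure
(expression units per allele) and $(\hat\beta_{Yj}, \sigma_{Yj})$ on the
outcome (log-odds per allele for case-control traits). Valid instruments
satisfy relevance (association with the exposure), independence from
confounders, and exclusion (no path to the outcome except through the
exposure). The estimators degrade differently when exclusion fails:

- `ivw()` is efficient but biased by any net directional pleiotropy;
- `mr_egger()` estimates the average pleiotropic effect as its intercept and
  remains consistent under the InSIDE assumption, at a large cost in power;
- `weighted_median()` tolerates up to half the weight being invalid;
- `mode_estimate()` tolerates any minority cluster of invalid instruments.

All estimators are equivariant to rescaling the exposure and to flipping
the allele coding of any instrument; the suite checks these as invariants.

### Numerical conventions

- Wald SEs use the first-order delta method ($\sigma_{Yj}/|\hat\beta_{Xj}|$);
  the second-order term is omitted, matching dominant practice.
- IVW defaults to multiplicative random effects when $k \ge 3$ (SE inflated
  by $\max(1, \sqrt{Q/(k-1)})$, never deflated) and fixed effects at
  $k = 2$.
- MR-Egger divides model SEs by $\min(1, \hat\sigma)$ — residual dispersion
  below 1 never tightens the fit — and uses $t_{k-2}$ inference.
- The weighted median interpolates ordered ratios at cumulative weight 0.5
  with weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ centred at $w_i/2$; ties in
  instrument selection break by smaller p, then larger $|\hat\beta_X|$, then
  variant ID, so every result is order-independent.
- The mode estimator smooths ratios with a normal kernel at
  `bandwidth_factor` × the modified Silverman rule
  $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$ and takes the argmax on a
  512-point grid spanning the ratios ±3 bandwidths. When the MAD is zero
  but ratios differ (a strict majority identical) the SD replaces it;
  exactly identical ratios return that ratio with SE 0.
- Bootstrap SEs (median, modes) resample $\hat\beta_X, \hat\beta_Y$ from
  their marginal normals, 1000 replicates by default; the seed is a
  mandatory argument, never ambient state.

## Harmonization

Outcome effects are re-oriented to the exposure's effect allele, resolving
swaps (negate), strand flips (complement), and both. Palindromic A/T and
G/C variants carry no strand information in their letters; when both
studies report an informative frequency ($\min(f, 1-f) \le 0.42$, i.e. a
window of 0.08 around 0.5) orientation is inferred from frequency
concordance, otherwise the variant is dropped. The 0.42 rule is standard
two-sample MR practice; it is a parameter (`palindromic_eaf_window`)
because cohorts with very accurate frequencies can justify a narrower
exclusion zone. Reported p-values inconsistent with $|\hat\beta/\sigma|$
(|z-difference| > 0.5) trigger a warning but are never altered: p-values
legitimately come from non-Wald tests.

## Instrument selection and gating

Greedy clumping keeps the smallest-p variant and removes everything with
$r^2 \ge$ `clump_r2` (default 0.1, a conventional cis-QTL choice) against
it, iterating until no candidates remain. LD is always an input — a signed
correlation matrix from a reference panel — never computed here. Two
significance tiers are conventional: a lenient $5\times10^{-5}$ that keeps
weakly instrumented targets in view and a strict genome-wide
$5\times10^{-8}$.

The instrument count gates the estimators: one variant permits only a Wald
ratio; two permit IVW; four (IVW's minimum plus two) permit MR-PRESSO. A
missing MR-PRESSO estimate never disqualifies a target — `selection_gate()`
requires the primary MR p below `ivw_alpha` (0.05) and, only when PRESSO
ran, a PRESSO estimate p not above it.

## Pleiotropy and directionality diagnostics

`mr_presso()` simulates the no-pleiotropy null: each instrument's outcome
effect is redrawn from $N(\hat\beta_{\mathrm{IVW}(-j)}\hat\beta_{Xj},
\sigma_{Yj})$, and the observed leave-one-out weighted residual sum of
squares is ranked among `n_sim` simulated ones (default 5000; the
calibration studies use 500 and accept coarser p-values). Outliers are
flagged per-variant with Bonferroni correction, and the distortion test
compares the all-instrument minus outlier-removed IVW difference against
1000 seeded random removals of equally many non-outlier instruments — a
permutation analogue of the reference distortion test, chosen because it
needs no distributional assumption on the outliers.

`steiger_test()` sums per-variant explained variance via
$r^2 = t^2/(t^2+n-2)$ and calls the orientation exposure→outcome when the
exposure sum is larger, with a Fisher-z two-sample test for the p-value.
Binary outcomes stay on the observed log-odds scale — conservative and free
of prevalence inputs; a liability-scale conversion was deliberately not
made the default because it requires an external prevalence estimate.

## Colocalization

`coloc_abf()` scores every variant with the Wakefield log-ABF
$\tfrac12\log(1-r) + \tfrac{z^2}{2}r$, $r = W/(V+W)$, and accumulates the
five single-causal-variant hypotheses in log space (log-sum-exp throughout;
the two-distinct-variants term uses `log1p(-exp(...))` and is exactly zero
for a single shared variant). Priors default to $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$; prior effect SDs to 0.15 (quantitative) and 0.2
(case-control) — the conventions of the ABF colocalization literature. The
window is ±100 kb around the most-significant exposure variant, bounds
inclusive, ties broken by larger $|z|$ then variant ID. Evidence is
declared at PP4 > 0.7. The one-causal-variant-per-trait assumption is the
method's known limitation; multi-signal loci dilute PP4 in favour of PP3.

## Mediation benchmark and conditioning

`mediation_consistency()` contrasts two estimates of the mediator→outcome
effect: the Wald ratio at a locus index variant versus the genome-wide IVW
excluding a ±1 Mb window around it (the locus extent is a parameter; 1 Mb
comfortably covers a cis region). Under full mediation both target the same
quantity; the report gives the ratio, a CI-overlap consistency call, and a
z-test on the difference. `condition_on_mediator()` applies the linear
(mtCOJO-style) adjustment $\beta_{\mathrm{cond}} = \beta_Y - \theta\beta_M$
with SE propagation
$\sqrt{\sigma_Y^2 + \theta^2\sigma_M^2 + \beta_M^2\sigma_\theta^2}$ —
including the often-ignored $\theta$-uncertainty term. This linear
adjustment is the largest methodological judgement call in the package:
individual-level conditional analysis is out of reach from summary
statistics, and the linear form is exact when mediator and outcome effects
are jointly linear, which is also how the synthetic truth is constructed.
Conditioning with $\theta = 0$ is the identity, and the conditioned SE is
not guaranteed to exceed the original.

## Drug direction inference

CMap-style perturbation similarity gives a sign: a drug whose signature
resembles a gene's knockdown is expected to lower that gene's level
(positive similarity), or raise it (negative); overexpression edges invert.
Composing with the MR sign yields the expected risk direction; the
2×2×2 truth table is exhaustively tested. Interaction-only (DGIdb) edges
are direction-less and always return `indeterminate`. Similarity magnitude
is ignored by default (`min_abs_similarity = 0`) because only the sign
carries a defensible interpretation; conflicting edges for one drug-gene
pair are all emitted with a conflict flag rather than silently aggregated.

## What the synthetic generator emulates — and what it does not

`simulate_qtl_outcome_pair()` draws sparse true effects $b$, propagates
them through an AR-1 LD matrix ($r_{ij} = \rho^{|i-j|}$, default
$\rho = 0.9$; analytically tractable, always positive definite), and adds
LD-correlated sampling noise at the SEs implied by the standard
approximations $\sigma \approx (2f(1-f)n)^{-1/2}$ (quantitative) and
$(2f(1-f)n\phi(1-\phi))^{-1/2}$ (case-control, case fraction $\phi$).
Study conditions were fixed once: cis-QTL effect magnitudes uniform in
0.2–0.8 exposure SD per allele (strong cis signals), MAF uniform in
0.05–0.5, an exposure GWAS of $10^5$, a case-control outcome of 79 429 with
7 495 cases, and a very large (750 000) quantitative mediator GWAS —
the sample-size scale of the motivating screen. Directional pleiotropy is
attached to the exposure-increasing allele, which is what makes it
*directional* for estimators that orient on the exposure; coding it in the
arbitrary allele frame would silently turn it into balanced pleiotropy.
The exposure and outcome draws are independent, as a two-sample design
assumes.

`simulate_coloc_scenario()` plants H0–H4 configurations with causal
$|z| = 8$ and, for H3, enforces $r^2 < 0.1$ between the two causal
variants. `simulate_mediation_scenario()` routes a locus effect $\tau$
(default $\log 3.02$) through a mediator share `mediation_fraction`, with
the genome-wide mediator→outcome effect $\theta_{\mathrm{med}} = 0.58$;
at a 10% mediated share the index-variant contrast reproduces an
observed-versus-expected gap of roughly 5.8 against 0.58.

Not emulated: realistic human LD maps (AR-1 only, block-composable),
sample overlap between studies, winner's-curse selection of instruments
from the same data, population stratification, and liability-scale
subtleties of binary traits. Passing tests therefore demonstrate the
correctness and calibration of the *methods* under their stated
assumptions, not robustness to every failure mode of real cohorts.

## Calibration choices in the validation suite

The recovery and calibration studies run at 50 instruments, 100–200
replicates, MR-PRESSO at 500 simulations, and colocalization at 100 seeded
loci per hypothesis — sizes chosen to give stable Monte-Carlo estimates on
a single CPU. The type-I-error check evaluates the *fixed-effect* IVW
p-value: the random-effects default is deliberately conservative (its SE
inflation floor makes the nominal level an upper bound), so calibration at
the nominal 5% is a property of the fixed-effect test. The
directional-pleiotropy robustness study uses a pleiotropic effect (mean
0.2) comparable to the causal-path effects themselves: substantially
smaller pleiotropy drowns in ratio sampling noise and the weighted-median
versus IVW contrast would measure noise rather than robustness.

## Known limitations

- Correlated-instrument (generalized) IVW, multivariable MR, and
  SuSiE-style multi-causal colocalization are out of scope.
- The Egger SIMEX correction for violation of NOME is not implemented.
- The conditioning adjustment assumes one mediator and linear effects.
- LD matrices must be externally supplied and keyed by the same variant IDs
  as the summary statistics; no liftover or ID translation is attempted.
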