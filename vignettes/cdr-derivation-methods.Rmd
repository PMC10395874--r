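---
title: "Deriving and validating clinical decision rules for pediatric fever in neutropenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating clinical decision rules for pediatric fever in neutropenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncdr)
```

## The problem

Children on myelosuppressive chemotherapy who present with fever in
neutropenia (FN) are admitted and treated empirically, although most
episodes turn out benign. Clinical decision rules (CDRs) try to separate
low-risk episodes — candidates for reduced-intensity management — from
episodes at risk of bacteremia, a serious medical complication (SMC: death,
ICU admission for organ support, or severe sepsis), or their composite, a
safety relevant event (SRE). `fncdr` implements the full machinery used to
derive such rules from a multicenter episode table and to externally
validate published rules: mixed-model screening, forward selection with a
cross-validated overfitting guard, integer score construction,
sensitivity-targeted thresholding, replicated internal cross-validation,
and a registry of eleven published pediatric FN rules with their
restricted-validation-dataset filters.

Because episode-level data from the multicenter cohort the design emulates
(six Swiss pediatric oncology centers, 158 patients, 360 FN episodes) are
not public, the package ships a seeded synthetic cohort generator that
reproduces the *structure* of those data. Everything downstream is
exercised against it.

## The statistical model

Each outcome is modeled by three-level mixed logistic regression: for
episode $j$ of patient $i$ in center $c$,

$$\operatorname{logit} P(y_{cij} = 1) = \beta_0 + x_{cij}^\top \beta
  + u_c + v_{i}, \qquad u_c \sim N(0, \sigma_c^2),\; v_i \sim N(0, \sigma_p^2),$$

with random intercepts per patient nested within centers. Fitting uses the
Laplace approximation (`lme4::glmer`, `nAGQ = 1`) with the BOBYQA
optimizer, which on these problems converges with scaled gradients around
1e-6 where the default optimizer pair stalls near 1e-2. "Model failure" —
which triggers the fallback ladder, first to a patient-only random
intercept and then to plain logistic regression — is operationalized as
optimizer non-convergence, a non-finite likelihood, a singular Hessian, or
a Hessian-scaled gradient above 1e-3 at the returned point. `levels_used`
on every fit records where on the ladder it landed. Complete separation is
flagged (huge finite coefficients, enormous standard errors), never
silently reported as a stable estimate.

P-values are two-tailed Wald tests for single-coefficient terms; for a
multi-level categorical characteristic (type of malignancy, age group) the
screening and entry decisions use the joint likelihood-ratio test against
the model without the block, refitted at the same ladder level. The
interaction screen against the randomized fever limit (38.5 vs 39.0 °C,
cluster-randomized by center) uses alpha = 0.01 to account for the number
of interaction analyses.

## From model to integer score

A fitted model becomes a points score by the rule: weight = coefficient
× 2, rounded *half away from zero* to the nearest integer. Rounding half
away from zero is a deliberate choice — "to the next integer" is ambiguous,
no published coefficient lands exactly on .5, and this rule reproduces
every published weight, e.g. 1.56 → 3 and −0.89 → −2. Negative weights are
removed per characteristic block: if any weight in a block is negative, the
absolute value of the block minimum is added to every weight of that block,
reference level included. For the published bacteremia model this adds 5 to
all six malignancy weights (CNS tumor, the minimum at 2 × (−2.58) → −5,
becomes 0; AML becomes 3 + 5 = 8); offsets are per block, not global, which
is the only reading consistent with the published tables.

```{r weights}
bact <- derive_weights(fn_reference_coefficients()$bacteremia, "bacteremia")
bact
```

The threshold is calibrated to a predefined sensitivity of at least 90%:
the *largest* integer T such that classifying score ≥ T as high risk keeps
sensitivity ≥ 90%. Taking the largest qualifying T (most specific) uniquely
reproduces the published choices (≥ 5 of 17 for bacteremia, ≥ 2 of 6 for
SMC, ≥ 4 of 15 for SRE); for SMC, T = 1 and T = 2 classify identically
because score 1 is unattainable, and the upward tie-break lands on 2 as
published. A threshold always exists, since the minimum observed score
classifies everyone high risk (sensitivity 1); that degenerate calibration
is flagged (`all_high`).

## Guarding selection and estimating performance

Forward selection admits, at each step, the candidate with the smallest
entry p-value below 0.05. After each admission the median AUROC of the
model's fixed-effect linear predictor over replicated 10-fold
cross-validation is compared with the previous step's; a decrease is read
as overfitting, the admission is rolled back, and selection stops. Only
score-compatible characteristics (binary or categorical) enter selection;
continuous blood counts are screened for association but a points score can
only carry their thresholded forms (leucocyte count < 0.3 G/L, platelet
count < 50 G/L — the forms the published models use).

`internal_cv()` estimates honest performance: per replication, episodes are
partitioned into outcome-stratified folds (patient-level folding is
available via `fold_by = "patient"`; the derivation study does not state
patient blocking, so episode-level stratified folds are the default); per
fold, the model is refitted on the training folds, the score re-derived,
the threshold re-calibrated, and held-out episodes classified. Held-out
episodes are always scored with fixed effects only. Within-fold refits use
plain logistic regression by default (`engine = "glm"`); `engine = "mixed"`
refits the mixed model per fold at roughly 30× the cost and, in our
simulations, indistinguishable held-out classifications — the score depends
only on the fixed effects, and in-fold coefficient differences between the
two engines are small relative to the integer rounding of the weights. The
95% CI across replications is the 2.5/97.5 percentile interval (the
interval type is our choice; nothing finer is published).

All proportions are reported with the continuity-corrected Wilson score
interval — the one-sample behavior of `prop.test`, including its quirk that
the correction is capped at |x − n/2|. AUROC is the midrank concordance
probability, identical to the trapezoidal area under the empirical ROC.
Reproducibility of an externally validated rule is operationalized as a
non-significant continuity-corrected two-proportion chi-square test (alpha
0.05) of sensitivity or specificity between the publication's
derivation-dataset counts and this cohort's, on the full or the restricted
validation dataset; the source study names no test, and a CI-overlap
variant can be substituted by comparing the reported intervals directly.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws patients into 6 centers (uneven occupancy),
gives each patient 1–6 episodes from a mass function with median 2, IQR
1–3 and mean ≈ 2.28 (so 158 patients yield ≈ 360 episodes), assigns the
randomized fever limit by center, and samples the 20 presentation
characteristics from documented, configurable marginals
(`default_covariate_params()`). Outcomes come from logistic models with the
published multivariable coefficients as generative defaults, plus Gaussian
center (σ = 0.3) and patient (σ = 0.8) random intercepts on the logit
scale. SMC receives an additional 1.8 log-odds when bacteremia is present —
the value implied by the published marginal counts (56 bacteremia, 30 SMC,
72 SRE imply a 14-episode overlap; logit(14/56) − logit(16/304) ≈ 1.8) — so
that SRE, computed exactly as the union, lands near 20%.

Intercepts are calibrated to the published marginal rates (15.6%
bacteremia, 8.3% SMC) by monotone bisection on a Monte-Carlo sample of at
least 10⁴ episodes. Two numerical points matter. First, the calibration
sample integrates the cluster effects with independent per-episode draws of
$N(0, \sqrt{\sigma_c^2 + \sigma_p^2})$: a marginal prevalence does not
depend on the clustering, and reusing a handful of shared center draws
would leave seed-level noise that no sample size removes. Second,
covariates, random intercepts, and outcome uniforms come from separate
named substreams of the master seed, so recalibrating an intercept never
perturbs the covariates — which also makes prevalence monotone in the
intercept realization by realization.

The generator emulates structure, not the real joint covariate
distribution: marginals are free parameters chosen once to be clinically
plausible (ALL the most common malignancy, most patients with a central
venous access device, log-normal cytopenic blood counts). Two consequences
are worth knowing. The real cohort's severely-reduced-general-condition /
low-platelet episodes were common enough that the two-characteristic SMC
rule reached 90% sensitivity at threshold 2; under the default synthetic
marginals the union of those traits is rarer among SMC episodes, and the
SMC rule typically calibrates to the degenerate all-high threshold. And
passing tests on synthetic cohorts shows the *machinery* is correct under
the declared generative model — it cannot show how any derived rule would
perform on real patients. An `age_years` column (integer years, 1–17) is
carried beyond the minimal characteristic set because the Rondinelli
(age ≤ 5) and Suttitossatam (age ≥ 10) rules need it; the categorical age
group (<6, 6–11, ≥ 12; boundaries are configuration, not published) is
derived from it.

## Published-rule registry

Each of the eleven rules is a deterministic tier function with the printed
boundary conventions (e.g. Rackoff high risk = AMC < 0.1 G/L *and*
temperature ≥ 39 °C; Baorto AMC < 0.155 G/L; Madsen temperature ≥ 39.5 °C
and AMC ≤ 0.01 G/L; Hakim ≥ 24 points with AML = 20, ALL/lymphoma = 7,
seriously unwell = 14, fever ≥ 39 °C = 11, ANC < 0.1 G/L = 10). Multi-tier
rules are consumed as low vs intermediate/high; all tiers feed the AUROC.
Rondinelli's printed bands leave scores below 2.5 unlabeled; everything
≤ 5 is treated as low risk. "Seriously unwell or toxic" is identified with
the severely-reduced-general-condition flag. Target outcomes are mapped
onto this schema declaratively (`inst/extdata/published_cdrs.yaml`, mirrored
by `cdr_registry_metadata()`): bacteremia-type outcomes → the bacteremia
flag; composite infection/adverse-event outcomes → SRE; organ-support-type
outcomes → SMC. The exact mappings used in the source validation are not
printed, so they are configuration, not code. Restricted validation
datasets apply only the schema-representable eligibility criteria (prior
HSCT, inpatient onset, first-episode, age); exclusions with no schema
counterpart (e.g. "AML intensive timing", "myeloablative chemotherapy")
are documented as not applied. Published derivation-dataset counts are not
shipped as real data; `inst/extdata/dd_counts_synthetic.csv` is a
synthetic stand-in for exercising the reproducibility comparison.

## Problem sizes used by the test suite

The stochastic checks run at sizes chosen for a laptop-scale test run and
stated here as the package's own design: marginal-rate checks average 100
replications of the ≈360-episode default cohort; the zero-variance
mixed-model check uses six replicate cohorts of ≈5000 episodes with
6-episode patients (well-identified variance components; a single σ̂ under
a true zero carries boundary noise of order 0.1 on its own); parameter
recovery uses 200 replications at ≈2000 episodes; end-to-end
characteristic recovery uses 50 replications at ≈2000 episodes with
fixed-effects screens, spot-checked against the mixed-model path. Internal
CV demonstrations use 20–100 replications rather than the 1000 a
production analysis would run (`internal_cv(..., reps = 1000)` is the
intended analysis setting).

## Known limitations

- The Laplace approximation is the fidelity choice (it is what the
  standard tooling uses), not the most accurate integral: with binary
  outcomes and 1–6 episodes per cluster, variance components are weakly
  identified and σ̂ is noisy; coefficients are far more stable.
- The synthetic covariate space is independent across characteristics
  except where stated (blood-count fractions, marrow involvement by
  malignancy class); real presentation characteristics are correlated.
- Scores carry only binary/categorical characteristics; a continuous
  characteristic that screens in cannot enter a points score unless a
  thresholded form is declared.
- Reproducibility verdicts depend on user-supplied derivation-dataset
  counts; absent counts yield "not assessable", never a pass.
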