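---
title: "Models and methods behind the NTS quality-by-design analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the NTS quality-by-design analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntsqbd)
```

This vignette explains the statistical machinery the package implements,
the choices that were genuinely open when building it, and what the
bundled tests do and do not demonstrate.

## The manufacturing problem

Notoginseng total saponins (NTS) are produced from *Panax notoginseng*
roots by ethanol reflux extraction, vacuum concentration, water
precipitation and macroporous-resin column chromatography. Raw-material
quality varies lot to lot, and some of that variation can be compensated
by the process — if one knows which process parameters matter and how
material attributes propagate to the product. The package operationalizes
that idea: characterize lots by *extractable* contents (what the
industrial solvent can actually pull out, not a pharmacopoeial assay),
screen ten process parameters and six material attributes jointly, and
convert the fitted models into a release rule for incoming material.

## Quality attributes and units

Material attributes are extractable contents in mg per g of raw material:
`Z1..Z5` for notoginsenoside R1 and ginsenosides Rg1, Re, Rb1, Rd, and
`Z6` for extractable dry matter. They derive from a pooled extract by mass
balance: `Z6 = 1000 * M_extract * DM_extract / M_material` (the factor
1000 converts the g/g dry-matter concentration to mg/g), and analogously
for the saponin concentrations already measured in mg/g.

Eluate process attributes: total saponin concentration `TSC` (sum of the
five concentrations), total saponin yield `TSY = M_eluate * TSC /
M_material`, dry-matter yield `DMY`, saponin purities `SP_i =
C_i / DM_eluate` and their sum `TSP`. Internally every purity is a
dimensionless fraction; percent appears only in files and printed output.
This is the scale on which the screening coefficients act — the
verification prediction for lot PN20 (4.83% Rd purity) only reproduces
with fractions against uncoded process parameters and raw mg/g
attributes, which fixes the convention. `TSY = TSP * DMY` is an algebraic
identity of these definitions and doubles as a consistency check on any
transcribed quality table (the bundled one satisfies it within 1% on all
32 runs, the slack being print rounding).

## The screening design

The bundled design crosses ten parameters (extraction ethanol
concentration `X1`, extraction time `X2`, solvent volume `X3`, concentrate
volume `X4`, precipitation water `X5`, sampling and washing flow rates
`X6`/`X7`, wash volume `X8`, elution ethanol concentration `X9`, elution
time `X10`) in 32 runs on 16 material lots. `validate_dsd()` reports the
definitive-screening-design structure rather than asserting it: 4 center
replicates, 20 runs with exactly one mid-level factor (the textbook DSD
signature), and 8 additional fold-over runs with none — the published
table is evidently a 21-run DSD augmented with extra two-level pairs, and
the validator is deliberately report-only so such hybrids can be examined
rather than rejected. Design *construction* is out of scope: screening
designs come from catalogs or vendors, and the analysis only needs the
realized table. Coded/uncoded conversion is the affine map sending
low/mid/high to −1/0/+1.

## Screening regression

Each process CQA (ginsenoside Rd purity, total saponin purity) is modeled
linearly in the uncoded `X` and raw `Z`. Selection is p-value based
bidirectional stepwise with entry and removal thresholds both 0.05:
repeatedly drop the included term with the largest partial p-value above
0.05, then admit the excluded candidate with the smallest partial p-value
below 0.05, until stable (a seen-state guard makes add/drop cycling
impossible; p-value ties break by candidate order, so selection is
deterministic).

**Starting point.** Selection starts from the *full* candidate model by
default. This was a genuinely open choice: forward-from-empty is the other
common reading of "stepwise". On the bundled data the two disagree for
total saponin purity — forward-from-empty stalls in a local model
(`{Z6, X1}`, R² 0.54) because `Z6` is strongly correlated with the saponin
attributes and enters first, while backward-from-full reaches
`{X1, Z1, Z2, Z4}` (R² 0.75), the model with the better fit and the one
whose coefficients match the study's published table. Removing
insignificant variables from the saturated screening model is also the
natural operation for a screening design, whose run count is sized to
support exactly that. `start = "empty"` remains available.

**Curvature.** `augment_and_refit()` adds the squares and pairwise
interactions of the retained CPPs as candidates and re-runs stepwise
*warm-started from the retained linear terms* — the added terms must earn
their way in. A cold start from the full augmented model would face
near-collinearity between a narrow-ranged factor and its square (over
`X1 ∈ [80, 90]`, `cor(X1, X1²) ≈ 1`) and can keep the square while
dropping the main effect; the warm start avoids manufacturing that
artifact. On the bundled data every square and interaction is rejected,
so the final models are the linear ones.

CPPs/CMAs are the unions of retained X and Z main effects across the CQA
models: `{X1, X9, X10}` and `{Z1, Z2, Z4, Z5, Z6}` here.

**What the selection can and cannot promise.** At α = 0.05 with 16
candidates, the chance of at least one false inclusion under a pure-noise
response is near 1 − 0.95¹⁶ ≈ 0.56 per model — that is the nature of
unadjusted stepwise, not a defect; the tests therefore check false
inclusion at the α-level rate rather than demanding a clean model. On
synthetic data generated from the fitted models at 4% relative noise, the
four strong Rd-purity terms (`X9, X10, Z5, Z6`, all |t| ≫ 2) are
recovered essentially always, while exact recovery of the full five-term
set is limited by `X1`, whose true effect sits right at the significance
boundary (fitted p ≈ 0.04): in roughly half of replicates it drops out or
a noise term joins. The tests assert the strong-term property.

## Monte Carlo design space

Measurement uncertainty is put into the *responses*: each iteration draws
`y* = y (1 + ε)`, `ε ~ N(0, rsd)` with `rsd = 0.04`, refits each CQA model
by OLS **on its fixed, previously selected term set**, and evaluates the
refits over a grid of CPP settings with the material's CMAs held at their
measured values. A cell's probability is the fraction of 1000 iterations
in which both limits (Rd purity ≥ 3.5%, TSP ≥ 85%) hold; the design space
is the cells with probability ≥ 0.90 (boundary included — the convention
only matters for cells at exactly 0.90). Re-running selection inside each
iteration would mix model-selection variability into what is meant to be a
measurement-error propagation, so refits keep the term sets fixed; both
CQAs' perturbations are drawn independently, as their residuals share no
structure that would justify coupling them.

Because the design matrix never changes, each refit is a fixed linear map
of the perturbed response vector; the implementation precomputes that map
and the grid matrix once, so the full 11 × 11 × 13 grid
(`X1` 80–90 by 1, `X9` 55–65 by 1, `X10` 120–180 by 5 — a resolution
chosen to give unit-step/5-min operational granularity) at 1000 iterations
runs in well under a second. Useful degenerate limits: `rsd = 0`
reproduces the central-model indicator exactly (and the indicator is
monotone along `+X1/+X9/+X10` for the Rd constraint, whose three CPP
coefficients are all positive); limits of 0 saturate every probability at
1. Per-cell probabilities from independent seeds differ by at most the
binomial 3σ ≈ 3·√(p(1−p)/1000). There is no published numeric grid to
compare against, so the design space is validated by these structural
properties rather than value-by-value.

## Grading inequalities

Each final (linear) model plus its limit gives an acceptance inequality.
Two modes:

* **Variable parameters** — a lot is acceptable iff some `X` in the
  investigated box satisfies all inequalities at once. This linear
  feasibility problem is solved *exactly* by Fourier–Motzkin elimination
  (the box bounds enter as inequalities), which also back-substitutes a
  witness setting, taking interval midpoints so the witness sits away from
  boundaries when possible. With the bundled models every parameter
  happens to enter all inequalities with a consistent sign, so a
  favorable-corner argument would suffice — the eliminator is there so
  conflicting signs (one CQA wanting a parameter high, another low) are
  still decided exactly, and the tests exercise that case against a dense
  grid oracle.
* **Fixed parameters** — the manufacturer's fixed `X` folds into each
  constant, leaving conditions on `Z` alone; lots split into high/low
  quality. Boundary (zero slack) counts as passing, matching the `≥` in
  both inequality systems. The fixed-mode slack equals
  `predict(model, X_fixed, Z) − limit` identically, which the tests assert
  at machine precision.

The simplified constants are always **recomputed from the model
coefficients**, never transcribed: the study's printed constants for the
fixed-process inequalities are not reproducible from its own printed
coefficients (the first, 730 on the 10⁵ scale, recomputes to ≈ 176 with
the stated fixed parameters; the second, 108.3 on the 10³ scale, matches
extraction ethanol at 90% rather than the stated 88%). The four worked
example lots (PN17–PN20) classify identically — low, high, low, high —
under either constant, so the discrepancy is treated as report-text
rounding/assembly, and recomputation is the defensible behavior. The same
reasoning excludes the PN18 predicted Rd purity from use as a reference
value (printed 4.70%, direct arithmetic on the printed coefficients gives
4.54%).

Since fixed parameters are one point of the box, high quality implies
variable-mode acceptability; a property test checks this on generated
lots. Mass-weighted blending (`blend_batches()`) is provided because lots
failing the fixed-process rule may still be usable after mixing: blend
attributes are the mass-weighted means, and grading applies to the blend.

## The synthetic-data generator

`generator_spec()` defaults *are* the study conditions: 16 lots, attribute
ranges spanning the characterized lots (Z1 7.2–16, Z2 32–59, Z3 3.2–8.4,
Z4 29–53, Z5 5.0–14.2, Z6 185–387 mg/g), the published coefficient sets as
truth, and multiplicative noise at `rsd = 0.04` truncated to positive
responses (redraw, not clamp, so the noise distribution is conditioned
rather than distorted). Attributes are drawn uniformly and independently
by default, with the physical constraint `Z1+..+Z5 ≤ Z6` enforced by
rejection; because real lots show strong inter-saponin correlation, a
single-latent-factor mode (one common "richness" factor at weight 0.7 plus
independent noise) is available for more realistic covariance.
`generate_extraction_record()` inverts the characterization formulas so a
round-trip through the quality metrics recovers `Z` to machine precision —
the tests lean on this closure.

What passing the synthetic tests shows: the estimator is unbiased under
the assumed error model, strong effects are recovered, the design-space
machinery closes the loop at zero noise. What it does not show: robustness
to attribute distributions unlike the uniform/latent-factor ones, to error
that is not multiplicative Gaussian, or to CMAs outside the characterized
ranges — conclusions about real lots stand on the bundled study data, not
on the generator.

## Numerical and testing choices

* OLS is solved by QR/Cholesky on the explicit term matrix; rank
  deficiency raises an error naming the aliased terms (stepwise skips
  aliased candidates instead of failing).
* Degenerate inputs: fitting requires at least two more observations than
  terms; constant candidates are rejected up front; an all-zero eluate is
  legal (zero purities) but a zero dry-matter concentration with nonzero
  saponins is not.
* Monte-Carlo-based tests run at reduced size (20–200 replicates, grids up
  to the default 1573 cells) with seeds fixed in the test code; stochastic
  assertions are calibrated to their own sampling error — e.g.
  unbiasedness is checked through bias z-scores with a family-wise 3σ
  bound across the 11 coefficients, since demanding 2σ from each of 11
  simultaneously would fail a perfect estimator about 43% of the time.
* The stepwise result is cross-checked against an exhaustive
  all-significant best-subset enumeration (an independent oracle) on a
  10-candidate instance; on the bundled data stepwise attains the
  exhaustive optimum's RSS exactly for both CQAs.

## Known limitations

* CMA–CPP interactions and nonlinear CMA effects are outside the model
  family, as in the underlying screening study; 32 runs cannot support
  them anyway.
* The grading inequalities inherit everything the central models miss —
  they are mean-value rules. A stricter probabilistic variant (grade by
  non-empty design space at threshold 0.90) can be assembled from
  `monte_carlo_design_space()`, at the cost of a Monte Carlo run per lot.
* Ginsenoside Re (`Z3`) is carried through the data model although no
  fitted model retains it; dropping it from characterization would save
  nothing and would break the attribute indexing.
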