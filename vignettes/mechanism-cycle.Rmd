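---
title: "Classifying inhibition mechanisms by thermodynamic-cycle consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying inhibition mechanisms by thermodynamic-cycle consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechcycle)
```

## The problem

Early inhibitor characterisation asks two linked questions. First, *how* does
the compound inhibit: does it bind the free enzyme only (competitive), the
enzyme–substrate complex only (uncompetitive), or both alike
(noncompetitive)? Second, *how strongly*: what is its IC50 in a functional
assay, and what molar inhibition constant does that imply?

`mechcycle` implements a docking-based answer to the first question and a
starch–iodine α-amylase pipeline for the second, plus the group statistics
used for accompanying in vivo endpoints.

## The thermodynamic-cycle test

Consider the four binding equilibria among enzyme E, substrate S and
inhibitor I, with constants in µM:

* K1:  E + S ⇌ ES
* Ka:  E + I ⇌ EI
* K4:  EI + S ⇌ EIS
* Kb:  ES + I ⇌ ESI

If the inhibitor binds E and ES at the same (allosteric) site with the same
affinity — the noncompetitive picture — all four complexes exist and the
free-energy cycle E → EI → EIS equals E → ES → ESI, forcing

$$K_b = \frac{K_4\,K_a}{K_1}.$$

A multi-ligand simultaneous docking run estimates Kb *directly* (docking
substrate and inhibitor into the receptor together), while K1, Ka, K4 come
from the individual docking runs. For a noncompetitive inhibitor the direct
and cycle-predicted Kb should agree; for a competitive or uncompetitive
inhibitor one edge of the cycle does not correspond to a stable complex and
the two estimates diverge. The test cannot tell competitive from
uncompetitive apart — both break the cycle — so those collapse into a single
verdict.

Because only the ratio K4·Ka/K1 and the ratio of predicted to direct Kb are
ever used, the association-versus-dissociation bookkeeping of the constants
cancels so long as the four are reported in one convention.

### Making "≈ vs ≠" operational

Published applications of this test judge agreement by eye. `mechcycle`
makes the rule explicit: the **fold discrepancy** is max/min of
(Kb_direct, Kb_pred), always ≥ 1 and symmetric, and the verdict is
noncompetitive iff it is at most a **threshold**, default 1.5. On the shipped
four-ligand reference set the accepted pairs have folds 1.284 and 1.032 and
the rejected pairs 2.111 and ~1.9e4, so any threshold in (1.29, 2.11)
reproduces the reference verdicts; 1.5 is a round midpoint and is exposed as
a parameter (`classify_mode(..., threshold = )`, CLI `--threshold`).
Ties at exactly the threshold classify as noncompetitive: approximate
equality is the affirmative claim the test makes.

```{r}
out <- classify_batch(load_docking_fixture())
out
```

Two printed-value discrepancies in the reference table are carried, not
resolved: one row prints a cycle prediction of 144.26 µM where the same
arithmetic on its own printed constants gives 144.57 (0.2%), and one ligand's
EI constant appears as 13.12 µM in the text but 13.66 µM in the table. Tests
hold the affected row to 0.5% relative tolerance.

## Free energy, Ki, IC50 and mass units

Docking suites report `Ki = exp(ΔG/RT)`. ΔG and the implied R, T are not
always printed together; `mechcycle` defaults to the AutoDock convention
R = 1.98719e-3 kcal mol⁻¹ K⁻¹, T = 298.15 K, which reproduces published
(ΔG, Ki) pairs within the rounding of the two-decimal energies (≤ 1%). Both
are overridable in `thermo_settings()`. All constants are carried in µM;
conversion to molar happens only inside the formulas.

The assay-side IC50 converts to a molar Ki through the Cheng–Prusoff family:
noncompetitive Ki = IC50; competitive Ki = IC50/(1 + S/Km); uncompetitive
Ki = IC50/(1 + Km/S). The substrate-dependent forms refuse to run without S
and Km. A mass IC50 (mg/mL) becomes molar via the molecular weight; the
`use_mass_fraction` flag of `mass_to_molar()` optionally attributes only the
active compound's share of the extract mass. The reference conversion
(0.14 mg/mL, MW 442.72) gives 316.2 µM where 314 µM was reported — a 0.7%
difference whose origin (an unrounded IC50, or an enzyme-concentration
correction) is unstated; both numbers are surfaced by `reproduce_paper()`
and neither is "fixed".

## The starch–iodine assay pipeline

Residual starch forms a blue iodine complex absorbing at 581 nm, so
absorbance falls as amylase digests starch. One arbitrary activity unit is
$(E_{B1} - E_S)/E_{B1} \times 800$ — 0 at the blank, 800 at complete
digestion. The 800 is an opaque historical scale factor; it cancels, along
with the blank, when activities are composed into percent inhibition
$(B - A)/B \times 100$ against the no-inhibitor control B.

The sign here deserves a note: the source formula is sometimes printed as
(A−B)/B×100, which is negative for inhibitors and contradicts the positive
inhibition ranges reported alongside it. `mechcycle` uses (B−A)/B×100 and
keeps the literal printed form behind `printed_form = TRUE`.

IC50s come from classical Finney probit analysis: maximum-likelihood probit
regression of the inhibition proportion on log10(concentration), fitted by
IRLS initialised from OLS on probit-transformed proportions, at most 100
iterations, deviance tolerance 1e-10 — fully deterministic. Proportions are
clipped to [1e-6, 1−1e-6] so 0% and 100% observations are usable. The IC50
is where the fitted probit crosses zero, $10^{-\beta_0/\beta_1}$; its
standard error comes from the coefficient covariance by the delta method.
Degenerate inputs (flat response, separation) return `converged = FALSE`
with a diagnostic instead of raising. IC50s outside the tested range are
retained but flagged extrapolated. Replicates are summarised as mean ± SEM
(SD/√n) of the converged fits.

## What the synthetic generators emulate — and what they don't

No raw absorbances or animal-level measurements behind the reference tables
were ever published, so replicate-level reproduction is impossible by
construction; the generators provide inputs with *known truth* instead, and
the tests are recovery- and calibration-based.

**Docking sets** (`generate_docking_sets()`): K1, Ka, K4 drawn log-uniformly
(defaults echo the reference magnitudes: substrate constants 1e5–1e6 µM,
inhibitor constants 10–300 µM), Kb_direct displaced from the cycle
prediction by a known fold factor, inverted with probability 1/2. The
classifier must recover the label exactly — it is a deterministic threshold
rule.

**Assay plates** (`generate_assay_plate()`): a fixed 7.5-minute incubation
digesting s0 = 0.4 mg/mL starch ("40 mg/dL" of the protocol). The digested
fraction is the linear-in-time approximation v·t/s0 with Michaelis–Menten
rate v; the inhibitor rescales Vmax (noncompetitive: /(1+I/Ki)), Km
(competitive: ×(1+I/Ki)) or both (uncompetitive). Integrating the full ODE
was rejected deliberately: the incubation is short, no kinetic constants for
rat plasma amylase on starch are available anyway, and the linear form
preserves exactly the identity the pipeline must recover — noncompetitive
IC50 = Ki in molar units. Km defaults to s0 for want of any measured value;
Vmax defaults to 0.075 mg/mL/min (≈70% digestion uninhibited), a config
error rejects any setting implying >100% digestion. Gaussian read noise
(default 0.01 OD on a 0.8 OD blank) models the spectrophotometer; real
plates also have pipetting error, drift and inter-plate effects the
generator does not model, so a green recovery test establishes correctness
of the analysis chain, not robustness to every laboratory artefact.

**Dose–response curves** (`generate_dose_response()`): points on an exact
probit curve plus Gaussian noise in percentage points (default SD 3). The
default slope of 1.5 probit units/decade makes the standard six-point
0.016–1.6 mg/mL ladder span ≈8–94% inhibition, matching the reported
dynamic range of the assay.

**Group measurements** (`generate_groups()`): seeded Normal draws from the
published group means and SDs (n = 6), truncated at zero by redrawing —
physiological measurements cannot be negative; the truncation is a mild,
documented deviation from normality that is negligible at the shipped
parameter values.

All generators restore the caller's RNG state: they are pure functions of
their config, seed included.

## Group statistics

One-way fixed-effects ANOVA is computed from the standard sums of squares,
with the F upper-tail p-value from the regularized incomplete beta function
(R's `pf`). Zero total variance is defined as F = 0, p = 1, flagged. Fisher
LSD follows: pair (i, j) differs when |mean_i − mean_j| exceeds
$t_{1-\alpha/2,\,df_w}\sqrt{MS_e(1/n_i + 1/n_j)}$ at the default
α = 0.01. This is the classical unadjusted rule, exactly a pooled-variance
t-test with MS_error; by default it is *protected* (applied only when the
omnibus F is significant, the textbook procedure), with the raw pairwise
decision always reported alongside so the equivalence to the t-test remains
testable. No further multiplicity adjustment is applied, by design — that is
the named procedure being implemented, not an endorsement.

Calibration is verified by simulation in the test suite: type-I error at
α = 0.01 within [0.005, 0.018] over 2000 null replicates, uniform null
p-values by Kolmogorov–Smirnov, and ≥90%-of-replicates reproduction of the
published qualitative significance patterns (therapeutic amylase activity
below both controls; week-2 blood glucose elevated only in the untreated
diabetic group).

## Numerical and design choices

* Fold threshold 1.5, a CLI flag; any value in (1.29, 2.11) reproduces the
  reference verdicts.
* Probit: IRLS, max 100 iterations, deviance tolerance 1e-10, clipping at
  1e-6; no randomness anywhere in the fitting path.
* CSV dialect: UTF-8, header row, "." decimals with "," accepted on read
  (European-style decimal commas appear in published tables and are
  normalised at ingest); numeric output at full double precision so tables
  round-trip to better than 12 significant digits.
* Run configuration is JSON rather than TOML: no TOML parser is available in
  the supported dependency set, and the config is a flat handful of keys;
  unknown keys are rejected so typos fail loudly.
* Exit codes: 0 success, 2 validation error, 3 failed reproduction check.

## Limitations

* The cycle test classifies noncompetitive vs not; separating competitive
  from uncompetitive inhibition needs kinetics (or prior literature) and is
  out of scope.
* Docking-derived constants inherit every limitation of the scoring
  function; the package treats them as given inputs.
* The kinetic plate model is a deliberate first-order approximation; its
  Km and Vmax defaults are placeholders, so all assay acceptance is
  parameter-recovery-based rather than value-based.
* IC50→Ki conversions ignore enzyme-concentration corrections (tight-binding
  regime), consistent with the reference analysis.
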