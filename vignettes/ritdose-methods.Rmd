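---
title: "Methods: preclinical RIT dosimetry and assay analysis with ritdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical RIT dosimetry and assay analysis with ritdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritdose)
```

ritdose implements the computational chain of a preclinical antibody
radioimmunotherapy (RIT) experiment: in-vitro radioligand assays,
biodistribution processing, tumor self-dose estimation, and growth-response
analysis, together with seeded generators that produce every input with
known ground truth. This vignette records the models, the tunable
parameters and their defaults, the numerical decisions, and what the
synthetic validation does and does not demonstrate.

## Physical constants and decay arithmetic

A `nuclide()` carries a half-life in hours and, for the therapeutic
emitter, a mean β energy per transition in MeV. Internally all decay
arithmetic is in hours; day-indexed biodistribution data are converted as
day × 24 exactly, because half-lives are conventionally quoted in hours
while sacrifice schedules are in days. The built-in registry fixes ⁹⁰Y at
T½ = 64.1 h and mean β energy 0.9331 MeV; the surrogate half-lives
(¹¹¹In 67.31 h, ¹²⁵I 1425.6 h) come from standard references and never
enter the dose chain, since biodistribution tables are decay-corrected by
convention. ⁹⁰Y's maximum β energy (2.3 MeV) and maximum range in water
(11.3 mm) are stored as annotation only — the dose model uses the mean
energy, not the spectrum. The registry is overridable from a JSON file
(`read_nuclide_registry()`).

The dose-conversion constant is
Δ = E_mean (MeV) × 1.60218·10⁻¹³ J/MeV, in Gy·kg/(Bq·s); for ⁹⁰Y,
`mean_energy_per_transition(0.9331)` = 1.495·10⁻¹³.

## Binding assays

**Immunoreactive fraction (Lindmo).** The saturation curve of bound
fraction versus cell number is linearized as
total/bound = 1/r + (1/r)(K/cells) and fitted by linear regression of
y = 1/bound on x = 1/cells; the immunoreactive fraction is r =
1/intercept. The default regression weights are proportional to bound²:
under multiplicative measurement noise the variance of 1/bound scales as
1/bound², so these weights approximately homogenize the transformed
residuals. Unweighted regression is available (`weighted = FALSE`).
Fits with non-positive intercepts, or r outside (0, 1.5], are errors with
diagnostics; r in (1.05, 1.5] is returned but flagged, since values
slightly above 1 arise numerically on noisy assays.

**Affinity (homologous competition).** The assay displaces a fixed trace
of labeled antibody with the same unlabeled antibody, so a one-site
homologous model is fixed:

B(c) = NS + (B₀ − NS) / (1 + c/IC50),  Kd = IC50 − L,

with L the labeled-antibody concentration — the homologous simplification
of the Cheng–Prusoff correction, valid because labeled and unlabeled
ligand are identical. Both IC50 and Kd are reported so users preferring a
heterologous correction can apply their own. The fit is constrained least
squares (B₀, NS ≥ 0, IC50 ∈ (0, 10⁴ nM]) via Levenberg–Marquardt from a
deterministic log-spaced multi-start grid of IC50 values (10⁻³–10⁴ nM,
half-decade steps); the best residual sum of squares wins, which makes the
fit reproducible without randomness and robust on small noisy assays.
When the fitted IC50 does not exceed L, Kd is floored at 10⁻⁶ nM and
flagged rather than reported as non-positive. A curve whose largest
competitor concentration is below 10 × IC50 is flagged for missing
plateau coverage.

**Internalization.** Compartment fractions are each count divided by the
four-compartment total per time point; acid-wash efficiency is taken at
face value. Rate-constant estimation is deliberately out of scope — the
closed-form kinetic model lives in the generator, not the fitter.

## Biodistribution

`percent_id_per_gram()` computes 100 · counts / (standard · weight),
divides by the decay factor for the counting offset, and multiplies by
body weight / 20 g. The normalization direction is a convention choice:
multiplying by BW/20 adjusts lighter mice downward, the common usage; the
reference weight is configurable. Aggregation uses the sample SD (n − 1),
matching the mean ± SD presentation of 5-mouse cohorts, and normalizes
per animal before aggregating. Ratios such as tumor-to-blood are invariant
to the normalization weight, which cancels.

Two cohort tables (antibodies 12A8 and 67A2, ¹¹¹In-labeled, days 1–10,
n = 5) ship as CSV fixtures with the exact printed values and load via
`packaged_biodist()`; CSV round-trips are bit-exact by writing full
precision.

## Tumor dosimetry

The chain `dose_table()` = extract tumor time–activity curve → remove the
decay correction with the therapeutic nuclide → zero-anchored trapezoid →
dose is the package's core. Decisions:

- **De-decay-correction** multiplies each decay-corrected value by
  exp(−λ·24t), with a guard against applying decay twice. The surrogate
  assumption (identical biological kinetics of the ¹¹¹In- and ⁹⁰Y-labeled
  conjugates) is recorded in every report's assumptions block.
- **Integration** is trapezoidal on the physical points with a (0, 0)
  anchor at injection (tumor activity is zero at t = 0) and no
  extrapolated tail beyond the last observed day. The anchored variant is
  the default because it reproduces the 12A8 arm's printed doses to about
  0.5%; starting at the first observed day instead is available with
  `anchor_zero_at_origin = FALSE`.
- **Units** are concentrated in one tested constant:
  (%ID/g)·day → s/kg is × 86 400 × 10 (per-day seconds, percent → fraction,
  gram → kilogram). Unit bugs dominate failure modes in this computation,
  so the whole conversion is a single named number,
  `PIDG_DAY_TO_S_PER_KG = 864000`.
- **Dose** is A₀ · AUC · Δ, assuming complete local absorption of the β
  energy — reasonable for the mean ⁹⁰Y β in tumors of this size, though an
  overestimate for very small nodules (no escape correction is applied).
- Red-marrow dose is *not* computed (it requires a phantom model); reports
  carry the study's literature value, 0.5 mGy/MBq in a 70-kg reference
  adult, as an annotation only.

On the packaged 67A2 table the recomputed doses sit ≈4–5% below the
study's printed 7.2/18.0/35.9 Gy; the printed table is rounded to one
decimal while the original AUC used unrounded data, so that arm carries a
5% documented tolerance (the 12A8 arm agrees within 1%).

## RIT outcomes

Tumor volume is width × height × depth / 2 (mm³), symmetric in the
dimensions. Animals are censored at the first measurement above the
humane-endpoint volume of 200 mm³; that measurement is kept and later
days are excluded from per-day summaries.

The study's outcome descriptions ("completely disappeared",
"started to increase again") are qualitative, so classification is
formalized with defaults: a tumor has *disappeared* when its volume is
≤ 1 mm³ (roughly the caliper detection floor) at any day ≥ 7, *complete
regression* requires it to stay there through the observation end
(day 28, the last observed day), *regrowth* is exceeding 2 × the
disappearance threshold after disappearing, *progression* is a final
volume above baseline with no sustained decrease (a drop to half or less
of the running maximum), and anything else is *growth delay*. All three
thresholds are parameters. The dose–response threshold is the minimum
absorbed dose among arms in which at most `allowed_exceptions` animals
(default 1, matching the single regrowing mid-dose animal observed in the
motivating study) failed to achieve complete regression; non-qualifying
arms above the threshold are reported as monotonicity violations.

Apoptosis is summarized as the mean ± SD TUNEL-positive fraction over at
least five 400× fields; arm comparisons delegate to Welch's t-test and
are reported descriptively. Repeated-measures ANOVA with post-hoc
multiple comparisons is deliberately not reimplemented — it is routine
statistics available elsewhere; the package emits the per-day descriptive
summaries such analyses consume.

## Synthetic-data generators

Every generator is deterministic given a seed, echoes the seed into its
truth sidecar, and uses mean-1 multiplicative lognormal noise for
strictly positive measurements (assay signals, %ID/g, volumes; CV default
0.1) and Poisson/binomial noise for field counts.

- **Binding**: bound(c) = r·c/(c + c½) with half-saturation cell number
  c½ (default 5·10⁶ cells), saturating to the immunoreactive fraction r.
- **Competition**: the one-site homologous model with IC50 = Kd + L.
- **Internalization**: a three-rate linear model (membrane → internalized
  k_int; membrane → medium protein-bound k_off; internalized → medium
  non-protein-bound k_release) solved in closed form. Residualizing
  (radiometal) defaults k_int = 0.25, k_off = 0.18, k_release = 0 /h give
  ≈58% internalized at 20 h, inside the 45–65% band reported for
  ¹¹¹In-labeled antibody; non-residualizing (iodine) defaults
  k_int = 0.65, k_off = 0.15, k_release = 0.09 /h place the interior
  maximum of the internalized fraction near 3 h with subsequent decline,
  reproducing dehalogenation-driven release.
- **Biodistribution**: per-tissue biexponential %ID/g curves
  A₁e^(−l₁t) + A₂e^(−l₂t). The named scenarios were fitted once by least
  squares to the printed tumor and blood rows of the packaged tables and
  shipped as recorded constants (12A8-like tumor: A = 29.5928,
  ke = 0.0941, ka = 0.5582 /day; 67A2-like tumor: A = 91.3315,
  ke = 0.1734, ka = 0.4146 /day; both peak at day 4 on the study grid).
  Noisy cohort values are converted back to counts and weights so the
  %ID/g arithmetic round-trips exactly, and the truth includes the
  closed-form AUC (with optional extra physical-decay rate), so the
  analytic truth dose is available without numerical integration.
- **RIT cohorts**: baseline volumes are drawn from N(4.4, 3.2²) mm³ (the
  study's reported baseline), floored just above the regrowth level so no
  palpable tumor starts "disappeared"; volumes grow exponentially at
  0.25/day (a fast SCLC xenograft doubling time of ≈2.8 days, which takes
  an untreated 4.4 mm³ tumor to the 200 mm³ endpoint in ≈15 days) with a
  kill term 0.04/day per Gy active over days 3–14 (growth until day 3,
  disappearance around two weeks, as observed). Cure is deterministic at
  ≥ 19 Gy, impossible at ≤ 12 Gy, and Bernoulli with linear probability
  between — so an 18 Gy arm typically yields 4–5 complete regressions and
  a ≥ 21 Gy arm always regresses completely. Truth labels are derived
  from the construction flags, independently of `classify_response()`.
- **Apoptosis**: per-field binomial counts whose positive fraction either
  rises linearly with dose or plateaus for any positive dose — the two
  induction patterns the two antibodies showed.

### What the synthetic validation shows — and what it does not

The generators emulate saturable binding, homologous displacement,
first-order internalization, biexponential kinetics with cohort sampling
noise, and exponential growth with dose-dependent kill. Passing
closed-loop tests therefore demonstrates that the estimators recover known
truth under these idealized mechanisms at realistic noise. Real data
deviate in ways the generators do not model: inter-animal correlation,
heterogeneous antigen expression, acid-wash inefficiency, caliper
measurement floors, antibody-specific biology (the study's low-dose
growth-delay without dose-dependence for one antibody), and
non-lognormal outliers. Closed-loop success is a necessary, not a
sufficient, check.

## Numerical choices and problem sizes

- The trapezoidal AUC of a biexponential sampled on the 5-day study grid
  underestimates the analytic integral by ≈2.5% — a property of the
  estimator, not of noise. The closed-loop dosimetry validation therefore
  samples the truth curve every eighth of a day, where the discretization
  bias (≈0.04%) is well below the Monte-Carlo standard error of the
  200-replicate mean (≈0.1%), so the comparison against the analytic
  truth dose tests bias from the noise-and-aggregation pipeline rather
  than grid coarseness. The packaged-table dose computations use the
  tables' own 5-day grid, as the study did.
- Parameter-recovery simulations use 200 replicates at 5% assay noise;
  cohort-coverage checks use 500 replicates of 5-animal days. These sizes
  give Monte-Carlo errors comfortably inside the asserted bounds while
  keeping the full suite under a minute.
- Fits never rely on random starts: the Lindmo fit is linear, and the
  competition fit multi-starts from a fixed IC50 grid.
- Degenerate inputs fail loudly: zero totals name the offending time
  point, missing CSV columns name the file and columns, double decay
  correction and decay-corrected AUC inputs are refused.

## Known limitations

- Dose is tumor self-dose only; no organ S-values, no β escape for small
  nodules, no red-marrow phantom.
- The biological kinetics of surrogate- and therapeutic-labeled
  conjugates are assumed identical; chelate-dependent differences are not
  modeled.
- Response classification is threshold-based on caliper volumes; it does
  not model measurement error near the detection floor.
- The generators are phenomenological; they are validation scaffolding,
  not a PBPK or radiobiological (LQ/TCP) model.
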