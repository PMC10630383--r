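---
title: "Methods: groundwater quality and probabilistic health risk in aquarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groundwater quality and probabilistic health risk in aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## The problem

Rural communities that depend on untreated groundwater can be chronically
exposed to nitrate (NO$_3^-$) and fluoride (F$^-$). Methemoglobinemia risk in
bottle-fed infants rises above about 45 mg/L nitrate; fluoride is protective
between roughly 0.6 and 1.5 mg/L but causes dental and skeletal fluorosis
above that. `aquarisk` implements the full appraisal chain a hydrogeochemical
survey of such an aquifer runs: analytical quality assurance, comparison with
drinking and irrigation standards, non-carcinogenic health risk assessment in
both deterministic and Monte Carlo form, hydrochemical facies and
source-apportionment diagnostics, and chemometric factor extraction.

## Analytical QA

Ion concentrations (mg/L) are converted to milliequivalents per litre using
equivalent weights fixed from standard atomic masses (Ca 20.04, Mg 12.15,
Na 22.99, K 39.10, HCO$_3$ 61.02, Cl 35.45, SO$_4$ 48.03, NO$_3$ 62.00,
F 19.00 mg/meq). The charge balance error

$$\mathrm{CBE}\% = \frac{\sum \text{cations} - \sum \text{anions}}
{\sum \text{cations} + \sum \text{anions}} \times 100$$

is the acceptance gate; an analysis passes when $|\mathrm{CBE}| \le 5\%$. A
sample with zero ion totals is flagged undefined rather than failed.

Exceedance against the standards registry is *strict*: a value exactly at a
limit is compliant, because the tabulated quantity is the share of samples
*above* the limit. Nitrate carries 45 mg/L as both the acceptable and the
permissible limit, since no relaxation is granted for it.

## Hazard quotients and the risk certainty level

For a chemical at concentration $C_M$ (mg/L) the average daily doses are

$$\mathrm{ADD}_{ing} = \frac{C_M \cdot IR_w \cdot EF_r \cdot ED}{BW \cdot AT_r},
\qquad
\mathrm{ADD}_{derm} = \frac{C_M \cdot SA \cdot K_p \cdot EF_r \cdot ED \cdot ET
\cdot CF}{BW \cdot AT_r},$$

hazard quotients are $HQ = \mathrm{ADD}/RfD$ with oral reference doses of
1.6 mg/kg/day (nitrate) and 0.06 mg/kg/day (fluoride), applied to both
pathways, and the hazard index is the pathway sum $HI = HQ_{ing} + HQ_{derm}$.
The **risk certainty level** (RCL) is the percentage of evaluated units with
$HQ > 1$ (strictly), computed over field samples in the deterministic design
and over Monte Carlo draws in the probabilistic one. It is reported even when
every summary statistic sits below 1, because tail exceedance is the quantity
of public-health interest.

Four age groups are assessed (infants, children, teens, adults). The shipped
exposure profiles are **synthetic**: deliberately high-end point values in the
range of the ICMR/USEPA exposure-factor literature (e.g. infants 0.8 L/day at
6.9 kg; adults 2.5 L/day at 57.5 kg, $K_p = 0.001$ cm/h,
$CF = 0.001$ L/cm$^3$, $EF_r = 365$ d/yr). Site studies must supply their own
values through the YAML configuration, which is the source of truth for any
reproduction attempt.

### Averaging time and the role of ED

$AT_r$ defaults to $ED \times 365$ days, the non-carcinogenic convention. In
the Monte Carlo engine $AT_r$ is **held at the age group's point value** while
$ED$ is drawn. If $AT_r$ were re-derived per draw, $ED$ would cancel exactly
out of the dose equation and could never influence the simulation —
contradicting the well-established observation that exposure duration is among
the most influential inputs in tornado plots of this assessment. Holding the
averaging time fixed while the realized duration varies preserves that
influence and is the package's deliberate reading of the convention.

### Deterministic versus probabilistic design

The deterministic table summarises the 27 per-sample HQ values with exposure
variables at their point values: only $C_M$ varies, so the printed SD tracks
the concentration SD, and the mean/median/5th/95th percentiles are statistics
over samples. Percentiles use linear interpolation between order statistics
(R's `quantile` type 7, the inclusive convention) — stated because percentile
conventions differ across software.

The probabilistic assessment draws every input independently (no correlation
structure is imposed between exposure variables) for 10,000 iterations, the
count at which the HQ/HI summaries are numerically stable. Each
(chemical, age group, variable) triple draws from its own child stream derived
from the master seed, so adding or widening one variable never perturbs
another's draws. The shipped Monte Carlo exposure specs place their central
tendency *below* the conservative point values (triangular ingestion rate,
uniform duration, normal body weight and skin area): the deterministic design
is the upper-bound screen, the probabilistic one the likely-range estimate,
which is exactly why the two are run as a pair.

### Concentration model and negative tails

Concentration inputs default to the fitted marginals: logistic for nitrate
(location 34.25, scale 24.04 mg/L) and uniform (0.01–1.97 mg/L) for fluoride.
The logistic is **not truncated at zero by default**: its lower tail implies
about 19% negative draws (`plogis(0, 34.25, 24.04)` $\approx 0.194$), which
propagate into negative 5th percentiles of HQ. That is a property of the
fitted concentration model, and the package reports it rather than masking it;
`truncate_conc_at_zero = TRUE` switches on rejection-based truncation for
users who prefer a physical support. Concentrations can also be resampled
from the measured values (`concentration_mode = "empirical"`).

## Distribution fitting and goodness of fit

`fit_distribution()` fits each candidate family (normal, lognormal, uniform,
logistic; triangular and point available) by maximum likelihood — closed-form
where textbook estimators exist, `fitdistrplus` for the logistic — and judges
each fitted candidate with three statistics: Anderson–Darling,
Kolmogorov–Smirnov, and a chi-square on $k = \max(5, \lfloor n/5 \rfloor)$
equal-probability bins with $df = k - 1 - (\#\text{estimated parameters})$.
The auto-selection takes the smallest AD statistic (ties broken by KS), the
default ranking of commercial risk software; the criterion is explicit and
configurable. KS p-values use the asymptotic Kolmogorov distribution and are
optimistic when parameters were estimated from the same sample — the report
says so rather than hiding it. AD p-values use Stephens' case formula for the
normal family and a seeded parametric bootstrap (499 replicates) elsewhere.

When the sampled quantity has known range limits, `truncate =` fits candidates
by *truncated* maximum likelihood and evaluates GoF against the truncated CDF.
This matters for round-trip validation of the synthetic generator: refitting a
plain logistic to range-limited nitrate draws is biased by several mg/L, while
the truncation-aware refit recovers location and scale within ±1.

## Sensitivity and uncertainty

Sensitivity uses contribution-to-variance via normalized squared Spearman rank
correlation: for each input, $100 \cdot \mathrm{sign}(\rho)\,\rho^2 / \sum
\rho^2$, so absolute contributions sum to 100 — the quantity behind the
familiar tornado plot. The method tag is recorded in the output because
tornado conventions vary. Constant inputs get zero with a flag. The
uncertainty report enumerates fixed-versus-distributed assumptions, truncation
settings, seed and iteration count, and flags an all-point configuration as
deterministic-equivalent.

## Hydrochemical diagnostics

**Piper**: cation (Ca, Mg, Na+K) and anion (HCO$_3$, Cl, SO$_4$) percentages
on the meq basis; a triangle zone is "dominant" only above 50%; the central
diamond facies follows from the alkaline-earth and weak-acid percentages; the
water type concatenates ions contributing cumulatively $\ge 50\%$ in
decreasing order — a convention that reproduces the classic end-member types
(Ca–HCO$_3$, Na–Cl, Ca–Mg–Cl) on pure waters.

**Gibbs**: `Na/(Na+Ca)` and `Cl/(Cl+HCO3)` against log$_{10}$ TDS, judged
against precipitation-, rock- and evaporation-dominance polygons. The classic
boomerang is drawn, never defined, in the literature; the shipped vertices are
this package's digitization and are fully replaceable, so zone percentages
should be treated as soft (±1 sample) near boundaries.

**Ionic ratios** (all meq basis, basis recorded in the output): Ca/Mg with the
customary reading (≈1 within [0.9, 1.1] dolomite; up to and including 2
calcite; above 2 silicate weathering), Na/Ca, HCO$_3$/Ca, (Na+K)/TZ$^+$, and
the Ca–SO$_4$ equiline position. Zero denominators flag the ratio undefined
instead of failing.

**Saturation index**: $SI = \log_{10}(\mathrm{IAP}/K_{sp})$ for fluorite
($K_{sp} = 10^{-10.6}$) and calcite ($K_{sp} = 10^{-8.48}$, carbonate activity
from bicarbonate and pH via $K_2 = 10^{-10.33}$), with molalities approximated
by molarities and single-ion activities from the extended Debye–Hückel
equation ($A = 0.5085$, $B = 0.3281$, Kielland-style ion size parameters).
Constants are 25 °C values. This is a screening index — no ion pairing, no
pCO$_2$ solving — adequate for the under/oversaturation call it supports, not
for speciation work.

## Chemometrics

Parameters are z-standardized; PCA is an eigendecomposition of the correlation
matrix; components with eigenvalue > 1 are retained (Kaiser); retained
loadings are varimax-rotated with Kaiser row normalization (convergence
tolerance $10^{-10}$) and each component's sign is flipped so its
largest-magnitude loading is positive. Communalities are row sums of squared
retained loadings, which orthogonal rotation preserves. Percent variance is
reported from the *unrotated* eigenvalues — the convention of the classic
rotated-component table — with rotated sums of squares also available.

Clustering is Ward's minimum-variance on squared Euclidean distances of the
standardized data, via the Lance–Williams recurrence (`hclust` `"ward.D"` on
the squared distance matrix). Two Ward conventions circulate; in this one the
merge heights equal exactly twice the increase in within-cluster error sum of
squares, which the test suite verifies against an exhaustive ESS-minimizing
oracle for small n. The dendrogram y-axis is the linkage quotient
$(D_{link}/D_{max}) \times 100$; the Sneath significance cut counts clusters
at a caller-chosen quotient threshold (a threshold is a parameter here, never
a constant, because published thresholds for this quotient are inconsistent —
values above 100 cannot be a percentage bound). The default cut is k = 3,
matching the usual three-regime reading of contaminated-aquifer surveys.

## The synthetic generator

`generate_samples()` emulates one pre-monsoon survey round of 27 samples:

* marginals: nitrate Logistic(34.25, 24.04) truncated to [0, 128.3] mg/L;
  fluoride Uniform(0.01, 1.97) mg/L; the other parameters normal with the
  survey means/SDs truncated to the observed ranges (e.g. pH 7.9 ± 0.3 on
  [7.2, 8.3], EC 941 ± 795 µS/cm on [313, 3446]);
* dependence: a Gaussian copula imposing target Spearman correlations that
  encode the reported pattern — nitrate against pH (−0.83) and with EC,
  hardness ions and chloride (the anthropogenic axis); fluoride with pH,
  sodium and bicarbonate and against calcium (the geogenic alkaline axis).
  Unreported pairs are filled with moderate values consistent with those axes
  and the matrix is repaired to positive semi-definiteness by eigenvalue
  clipping. Rank correlations are used because they survive the inverse-CDF
  marginal transform exactly;
* derived columns: TDS $= 0.64 \cdot EC +$ Normal(0, 10) noise (0.64 maps the
  observed EC range onto the observed TDS range almost exactly);
  TH $= 2.497\,Ca + 4.115\,Mg$;
* charge balance: bicarbonate — the dominant anion — is clamped per row into
  the interval that keeps $|\mathrm{CBE}| \le 5\%$; rows that would need
  negative bicarbonate are redrawn. Adjusting one anion distorts the target
  marginals far less than rescaling all ions, at the price of a bicarbonate
  marginal that is partly determined by the balance constraint (so dependence
  checks in the tests use pairs not involving HCO$_3$).

What the generator does **not** emulate: spatial structure, seasonality,
censoring at detection limits, analytical error correlated across ions, and
the exact joint distribution of a real aquifer. Tests that pass on synthetic
tables therefore validate the *computations*, not any claim about a specific
field site.

## Problem sizes and numerical choices

The test suite and acceptance script use 27-sample tables for pipeline-level
checks, 10,000 Monte Carlo iterations for the simulation checks (with
closed-form uniform-concentration oracles compared within three Monte Carlo
standard errors), 10,000 draws for distribution-recovery checks, and n ≤ 8
matrices for the exhaustive Ward oracle — sizes chosen so every oracle is
exact or statistically calibrated while a full run stays in the minutes range
on a single core. Degenerate inputs are handled explicitly throughout: a
zero-variance sample admits only the point family; zero ion totals flag CBE
and Piper outputs as undefined; zero denominators flag ratios; a truncation
region with negligible mass raises an error after bounded retries instead of
looping.

## Known limitations

* The deterministic/probabilistic comparison depends on the exposure
  configuration; with the synthetic defaults it demonstrates the method, not
  any site-specific risk level.
* The Gibbs zones are a digitization; samples near polygon edges can
  legitimately flip zones under a different digitization.
* The saturation index is screening-level chemistry.
* KS p-values after parameter estimation are optimistic (no Lilliefors-style
  correction beyond the AD bootstrap).
* No carcinogenic (slope-factor) risk, no inhalation pathway, no
  Latin-hypercube or two-dimensional Monte Carlo: the assessment is plain
  one-dimensional MC by design.
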