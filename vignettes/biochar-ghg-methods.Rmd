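---
title: "Methods: biochar GHG accounting with biocharGHG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biochar GHG accounting with biocharGHG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocharGHG)
```

## The problem and the model

Biochar — the carbon-rich solid produced by pyrolysing biomass — persists in
soil one to two orders of magnitude longer than the feedstock it was made
from, which makes land application of biochar one of the few carbon-dioxide
removal practices deployable at scale today. Crediting it, however, requires
an accounting method that works from data an inventory compiler can actually
obtain: tonnes of biochar applied, the feedstock, the pyrolysis temperature,
and optionally the elemental composition of the char.

`biocharGHG` implements an emission-factor (IPCC tier-1 style) balance for a
single application event on mineral soil:

$$\mathrm{GHG}_{bc} \;=\; M_{bc}\, F_C \,\tfrac{44}{12}\, F_{perm}
\;+\; r\, n\, \mathrm{GWP}_{N_2O}$$

where $M_{bc}$ is the biochar dry mass (Mg), $F_C$ the organic carbon
fraction of the char (dry-matter basis), $44/12$ the C-to-CO$_2$ mass ratio,
$F_{perm}$ the fraction of that carbon still unmineralized after the chosen
timeframe at the site's mean annual soil temperature, $n$ the baseline
first-year N$_2$O emission (Mg N$_2$O yr$^{-1}$) from the amended area,
$r = 0.23$ the first-year fractional reduction in N$_2$O emissions, and
GWP$_{N_2O}$ the 100-year global warming potential of N$_2$O (273 by
default; 298 for AR4-based comparisons). Methane and priming of native soil
organic carbon appear in every report as explicit zero line items: current
meta-analyses find no effect significant at $p<0.05$ for either, and the
method is deliberately conservative, so these are modelled decisions rather
than omissions.

A note on the N$_2$O term: the reference worked example for this method
quotes its N$_2$O contribution as "2.4 × 298", yet its printed total
(29,710 Mg CO$_2$e) is only reproduced when the 23% reduction factor is
applied to that product (2.4 × 0.23 × 298 = 164.5). The package therefore
implements the N$_2$O term as $r\,n\,\mathrm{GWP}$, which reproduces the
printed total exactly; we read the shorthand arithmetic as a typographical
ellipsis, not as the intended formula.

## Carbon fraction $F_C$

Two parameterizations are provided.

**Class table (default).** $F_C$ by feedstock class and production
condition: pyrolysis at low (350–450 °C), medium (450–600 °C) or high
(≥ 600 °C) temperature, the mean over the three ranges, or gasification.
This is the operational, emission-factor-style path: a numeric temperature
is binned to its class; with no temperature information at all the
pyrolysis-mean column is used (this is what makes the "feedstock-only"
conservative chain work). If a declared class contradicts a numeric
temperature, the numeric temperature wins with a warning, because
temperature-specific values are the more accurate parameterization.

**Continuous estimator (opt-in).** For users who want temperature
resolution inside a class, $F_C$ is assembled from three relations:

1. the dry-ash-free carbon fraction as a saturating exponential of
   temperature, $F_{C,daf}(T) = a - b e^{-cT}$;
2. the dry-ash-free char yield as a function of lignin and temperature,
   $Y_{bc}(L, T) = a' + m'L + b' e^{-k'T}$;
3. an ash mass balance — ash is conserved while organic matter shrinks by
   $Y_{bc}$ — giving the char ash fraction and finally
   $F_C = F_{C,daf}\,(1 - F_{a,bc})$.

The published sources give these regressions only in typeset form that was
not machine-recoverable, so the package's coefficients were **calibrated
once** against the class table itself: least squares over all 11 feedstocks
× 3 pyrolysis classes, driven by the packaged ash/lignin compositions at
class-representative temperatures of 400, 525 and 700 °C, under physically
motivated box constraints (saturation level, positive lignin effect,
declining yield with temperature). The calibrated curves reproduce every
class-table cell within 2 printed standard deviations, and the structural
predictions follow: $F_C$ falls with feedstock ash at fixed temperature, and
the temperature sensitivity of $F_C$ is much smaller for high-ash feedstocks
(sewage sludge) than for clean wood, because rising carbon concentration in
the organic fraction is offset by ash enrichment. The coefficients are
frozen in `fc_regression()` and pinned by tests; they are a calibration
artifact, not a transcription, and exact agreement with any externally
published coefficient set is not claimed. Chars from gasification residues
whose ash was partially removed are representable by neither path — supply
a measured $F_C$.

## Permanence $F_{perm}$

Biochar mineralization is modelled as multi-pool first-order decay; at
least two pools (fast and slow) are required to extrapolate from year-scale
incubations to centennial horizons. Decay rates move between temperatures
through a Q10 that itself declines with temperature,

$$Q_{10}(T) = 1.1 + 12.0\,e^{-0.19\,T},$$

so rescaling a rate constant from $T_1$ to $T_2$ integrates
$\ln Q_{10}(T)/10$ continuously over the interval rather than applying one
factor per decade. The integral is evaluated by Simpson's rule on a 0.1 °C
grid (the integrand is smooth; this matches adaptive quadrature to ~1e-9,
which a unit test verifies against `stats::integrate`). Whether the
underlying compilation used a stepwise or continuous convention is not
documented; the continuous form is adopted here and applied identically to
all pools.

The packaged permanence grid prints class-level $F_{perm}$ (with standard
errors) at 21 cells — timeframes of 100/500/1000 years × soil temperatures
of 5–25 °C in 5 °C steps plus the US (10.9 °C) and global (14.9 °C)
cropland means — together with coefficients of a linear regression of
$F_{perm}$ on the molar H/C$_{org}$ ratio for the same cells. Three query
routes exist, in order of preference:

1. **H/C regression** (`fperm_from_hc()`): preferred when H/C$_{org}$ has
   been measured, because the degree of aromatic condensation correlates
   more closely with persistence than pyrolysis temperature does. Raw
   regression values are clamped to [0, 1] with a recorded warning — the
   intercept exceeds 1 at low soil temperatures (1.13 at 5 °C), so clamping
   at small H/C is unavoidable, not exceptional. Off-grid coefficients are
   interpolated bilinearly in (soil temperature, log$_{10}$ timeframe).
2. **Temperature class** (`fperm_from_class()`): printed cells are always
   served verbatim, standard error included, so that inventory output is
   auditable against the published table bit for bit.
3. **Conservative fallback** (`fperm_conservative()`): the low-class value,
   used when neither H/C nor production conditions are known; low-
   temperature char is the least persistent class, so this bounds the
   credit from below.

**Off-grid queries and the calibrated surface.** The pool parameters behind
the printed grid were never published, so arbitrary-(t, T) queries are
served by a two-pool model *calibrated to the grid itself*: for each class,
the pool fraction and two rates (quoted at 14.9 °C) are fit to all 21 cells,
first by tolerance-weighted least squares and then polished on the
worst-case cell (minimax), under a deterministic multi-start. Every cell
must be reproduced within max(0.03, 1 SE) or calibration aborts naming the
worst cell; in practice the worst residual is 0.63–0.87 of tolerance
depending on class. The calibrated surfaces inherit the grid's qualitative
structure on dense grids — non-increasing in time and temperature, class
ordering low ≤ medium ≤ high — which the acceptance suite checks, and they
are continuous through the printed cells, though an off-grid value
infinitesimally close to a cell differs from the printed value by that
cell's (within-tolerance) calibration residual. Queries outside soil
temperature 5–25 °C or timeframe 100–1000 y are refused unless
`extrapolate = TRUE`, and then carry a warning: outside the fitted domain
the two-pool form is an extrapolation of an extrapolation.

## Decay-curve fitting

`fit_pools()` fits 2- or 3-pool sums of exponentials to incubation series by
nonlinear least squares. Constraints (fractions on the simplex, positive
rates) are enforced by parameterization — stick-breaking logits and log
rates — because sum-of-exponentials fitting is ill-conditioned and
constrained solvers add failure modes without adding identifiability.
Optimization is multi-start from a deterministic grid of eight starting
points (Nelder–Mead, then a quasi-Newton polish, then explicit Gauss–Newton
steps on the residual vector; the last stage is what reaches machine
precision on clean data — general-purpose optimizers stall near 1e-5
relative). Series must span at least one year — the inclusion filter used
when compiling decay studies — and contain at least $2p+1$ observations for
$p$ pools. `select_model()` prefers three pools only when AICc improves by
more than 2, the conventional evidence threshold, since "not a good fit" is
the only published guidance.

## Synthetic data

`simulate_series()` is the package's generator: exact decay curves from a
known pool set plus i.i.d. Gaussian measurement noise, clipped to
[0, 1.05] (small measurement overshoot above 1 is tolerated and flagged, as
in real incubation data). Defaults emulate a multi-year laboratory
incubation: a two-pool char (15% fast pool at 0.8 yr⁻¹, 85% slow at
0.004 yr⁻¹), σ = 0.01 absolute noise — typical of respirometry-derived
mass-balance series — and 25–50 observations over 5–8 years. It does *not*
emulate autocorrelated drift, moisture/texture covariates, or physical
export of char from the measurement volume, so a green round-trip test
establishes only that the fitting machinery is correct, not that two pools
suffice for any particular real biochar. One statistical caveat the tests
respect: on sparse designs (25 points over 5 years) the fast-pool fraction
is weakly identified and the residual bootstrap understates its sampling
spread by roughly half, so bootstrap-tolerance recovery checks are run on a
well-identified design (50 points over 8 years) where bootstrap and Monte
Carlo spreads agree.

## N2O credit

The baseline is pure tier 1: `area × N rate × EF × 1.57`, with EF = 0.01 Mg
N$_2$O–N per Mg N and 1.57 (≈ 44/28) converting N$_2$O–N to N$_2$O. The
credit is 23% of the baseline, first year only — the effect has not been
demonstrated beyond one year — and only where the application rate exceeds
10 Mg of biochar *carbon* per hectare, a strict inequality evaluated as
`mass × F_C / area`. The threshold's unit is stated inconsistently in the
sources (Mg C vs Mg biochar); the carbon-basis reading is adopted as the
literal unit of the governing sentence, and the reference example (15 Mg
biochar ha⁻¹ × 0.68 = 10.2 Mg C ha⁻¹) passes under both readings. The
baseline is rounded to two significant figures before the credit by default
(`rounding = TRUE`), reproducing the published arithmetic exactly;
`rounding = FALSE` exposes full precision. The credit is optional by
design — typically under 1% of the total — and `include_n2o = FALSE` keeps
the line item visible at zero with an "excluded (optional)" flag. The 23%
point estimate governs; its 95% CI (5–41%) ships in `bc_constants()` for
sensitivity analyses but does not move the default.

## Numerical and reporting conventions

* All masses are Mg (tonnes) and all mass fractions are fractions of dry
  matter; percent-denominated table columns are converted at load time, and
  kg-denominated activity columns are converted with a warning.
* Totals are carried at full precision; the display value rounds to the
  nearest 10 Mg CO$_2$e (R's half-to-even `round()`), which is the only
  convention under which the published example's final digit is
  reproducible (29,710.496 → 29,710).
* Defaults: 100-year timeframe, 14.9 °C soil temperature — the
  recommendation and the global cropland mean respectively.
* Organic soils (Histosols) and forest soils with organic horizons are
  refused outright: positive priming cannot be excluded there.
* Parameter tables ship as commented CSV with md5 checksums pinned in the
  test suite; the tables *are* the model, so transcription must be
  auditable.

## Worked example

```{r}
ev <- application_event(
  "worked-example",
  biochar_spec("maize stover", pyrolysis_temp = 500),
  mass = 15000, area_ha = 1000, soil_temp = 10, timeframe = 100,
  n_rate = 0.15
)
ghg_balance(ev, bc_config(gwp_n2o = 298))
```

## Known limitations

* The continuous $F_C$ coefficients are a calibration to class-level data,
  not independent regressions; they interpolate the table well but carry no
  claim outside 350–900 °C or for exotic feedstocks.
* The calibrated permanence surfaces compress heterogeneous multi-study
  fits into one two-pool model per class; within-tolerance cell residuals
  (up to ~0.03) are invisible to off-grid callers except through the
  documented grid-point discontinuity bound.
* First-year-only N$_2$O, zero CH$_4$ and zero priming are conservative
  simplifications that will need revisiting as long-term field data
  accumulate.
* Life-cycle terms — feedstock production, transport, pyrolysis energy,
  avoided decomposition of diverted biomass — are out of scope; this is a
  soil-flux method, not an LCA.
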