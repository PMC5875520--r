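---
title: "Modelling stacked radiotherapy sources: corrections, schedules and Monte Carlo validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stacked radiotherapy sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksource)
```

## The problem

Cobalt-60 teletherapy machines and Gamma Knife units replace their
sources after roughly one half-life, when treatment times have doubled.
The withdrawn source still holds half of its initial activity, and its
disposal is costly and increasingly regulated.  If the source holder
offers several axial positions, a used source can instead be pushed one
position back (or two used sources combined into one holder in a
multisource unit) and a correspondingly weaker new source installed at
the exit window.  `stacksource` quantifies the residual worth of a
stacked-back source at the machine focus and the activity and
encapsulation savings of the staged replacement schemes, and validates
the closed-form model with an independent Monte Carlo transport
estimator.

## Closed-form model

Two effects reduce the air-kerma strength of a source with `n` newer
capsules in front of it, both evaluated per capsule and multiplied:

**Attenuation.**  Narrow-beam primary-photon attenuation at the
1.25 MeV mean gamma energy through each front capsule's active column
and shell:

$$A(n) = e^{-\mu_{source}\, n\, h_{source}}\; e^{-\mu_{shell}\, n\, h_{shell}},
\qquad \mu = (\mu/\rho)\,\rho .$$

`h_shell` is the *combined* front and back shell thickness of one
capsule.  `A(n) = A(1)^n` exactly (log-linearity), which the tests
assert against a brute-force layer-enumeration oracle.

**Distance.**  Pushing the source back `n` pitches `l` moves it from
`d` to `d + n·l` from the focus; by the inverse-square law

$$D(n) = \frac{d^2}{(d + n\,l)^2}.$$

The point-source formula deviates from the finite-cylinder exposure
integral by at most about 0.1% when `d / h_source >= 5`;
`point_source_validity()` checks this ratio and warns — it does not
error — below the threshold.

The total correction `T(n) = A(n)·D(n)` is reported at full floating
precision; `comparison_view()` rounds half-to-even to 3 decimals, the
precision at which such corrections are conventionally tabulated.

### Parameters of the packaged fixture

| parameter | value | unit | meaning |
|---|---|---|---|
| μ/ρ (source) | 0.0527 | cm²/g | cobalt-60 pellets at 1.25 MeV |
| ρ (source) | 5.88 | g/cm³ | effective density of the pellet packing |
| μ/ρ (shell) | 0.0535 | cm²/g | stainless steel |
| ρ (shell) | 7.85 | g/cm³ | |
| h_source | 2 | cm | active column height |
| h_shell | 0.61 (0.12 + 0.49) | cm | front + back shell layers |
| l (pitch) | 2.72 | cm | axial spacing of stacked capsules |
| d | 40.1 | cm | source-focus distance |

Two deliberate modelling choices live here:

* The pitch (2.72 cm) exceeds the capsule layer sum
  (0.12 + 2 + 0.49 = 2.61 cm).  The fixture keeps both numbers; the
  transport geometry inserts the 0.11 cm difference as an air gap
  behind each capsule, with air treated as vacuum.  A pitch below the
  layer sum is rejected as a geometry error.
* The active column radius is nowhere published; the fixture defaults
  to 0.05 cm.  Only the Monte Carlo model uses it, it is configurable,
  and every tally records it.

```{r}
fx <- leksell4c_fixture()
comparison_view(relative_air_kerma(1:3, fx$capsule, fx$geometry))
```

## Replacement schedules

Both schedulers are epoch-quantized at exactly one half-life per step
and parameterised by a *transmission provider*: either the analytic
`T(n)` above (`analytic_transmission()`) or externally supplied
per-position factors (`table_transmission()`), e.g. Monte Carlo
results.  Decay bookkeeping uses `2^(-age)` with ages in half-lives, so
no half-life constant enters any result; `co60_half_life_years`
(5.2711 a) is packaged purely for calendar-time conversion.

**Push-back** (single-source holder of `capacity` positions): at every
half-life boundary each source ages, moves one position back (the one
beyond the last position is removed), and a new source at the window
restores the target output.  The report's epoch 0 is the initial
installation (saving 0); at the first replacement the retained source
contributes `0.5 · T(1)` and the per-epoch saving is
`residual / target`.  Dummy (zero-activity) sources fill unused
positions conceptually; they never contribute and are not tracked
beyond holder occupancy.

**Pair-combining** (multisource unit): implemented literally as the
rotating four-holder group: last epoch's single used sources pair into
2-deep holders, two 2-deep holders merge into one 4-deep holder
(newer batch in front), and 4-deep holders are retired.  Each epoch
after installation, half the holders receive new sources, hence a 50%
encapsulation saving, and conservation fixes the new activity:
`residual + new = n_holders × target`.  With the Monte Carlo factor
`T(1) = 0.344` the first combining epoch reproduces the worked
arithmetic: pair output 67.2%, each new source 132.8%, activity saving
33.6%.

```{r}
combine_pairs_schedule(2, table_transmission(c(0.344, 0.122, 0.043)))$table
```

Design notes on genuinely open points:

* One published sentence quotes an 81.7% replacement source after a
  17.2% residual; conservation gives 82.8%, and 81.7% instead matches
  using the *equation*-row factor (100% − 50% × 36.5%).  The package
  follows the conservation formula `required_new_activity()` and lets
  the caller pick the transmission row; the two readings differ only in
  which factor is supplied.
* The pair-combining arithmetic is per holder-pair; the report books
  the per-capsule activity (`new_activity_each`) and the total
  explicitly rather than resolving the per-source/total ambiguity
  silently.
* `n_holders` must be a multiple of 4: with only two holders the
  rotation starves (a lone aged single has no partner), so the even
  counts 2, 6, 10, … are rejected rather than scheduled unfaithfully.
  An odd count cannot pair at all and is likewise an error.
* Conservation clamps at zero: if the residual ever exceeded the
  target, the new activity is 0 with a logged message, never negative.

Every schedule emits an action log (sources removed, moved, added per
epoch); the tests replay that log source-by-source with independent
decay/transmission arithmetic and require the reported residuals to
match to 1e-12.

## Monte Carlo validation

`estimate_relative_kerma()` is a from-scratch forced-detection
estimator for primary photons: emission points are sampled uniformly in
the emitting active cylinder, and each history deterministically scores
`exp(-τ) / r²` toward the focus, where the optical depth `τ` is the
exact sum of `μ × chord` over every region the ray crosses
(ray/finite-cylinder intersection in closed form).  The estimate is the
ratio of this tally to the identical tally on the reference geometry
(the same capsule seated at the window), so capsule self-terms largely
cancel; the emitting active column is excluded from attenuation
outright, matching the closed-form model, which only attenuates by
material *in front of* the source capsule.  The ratio's standard error
combines the two tallies' sample variances by the delta method.
`n = 0` is the reference against itself and is returned as exactly 1.

Geometry and numerical choices:

* The focus sits on the stacking axis so that the *reference* active
  column midpoint is exactly `d` away; the point-source limit then
  recovers `A(n)·D(n)` identically, which the tests assert at 1e-8
  relative tolerance with a zero-radius, 1e-9 cm-high active column.
* Mono-energetic 1.25 MeV photons; no scatter, no collimator material,
  no phantom.  Scoring is the in-air kerma ratio at the focal point.
  Because scattered photons are excluded, agreement with a full MCNP
  tabulation is judged with the published ≤ 2.4 percentage-point
  equation-vs-MC spread, not with sampling error alone.
* Seeding is mandatory; identical (seed, histories, geometry) give
  bit-identical tallies (asserted).  The numerator uses the caller's
  seed, the reference seed + 1, and the comparison table seed + 2 per
  additional `n`.
* Histories are processed in chunks (default 1e5) purely to bound
  memory; chunking does not change the stream or the result.

Because the estimator forces detection analytically, its only variance
comes from the emission-point spread over the small active column, so
1e6 histories give standard errors of order 1e-5 in a few seconds; that
problem size is used by the test suite and the acceptance script.  The
estimator sits within ~0.003 percentage points of the closed-form
totals for the fixture — the extended source is a tiny *downward*
geometric correction (asserted as MC ≤ analytic + 3 SE) — while a full
scattered-photon simulation would sit a couple of percentage points
lower still; quantifying scatter is out of scope here.

## Synthetic scenarios

`random_scenario()` draws capsules, geometries and small holder
inventories from physically plausible ranges (μ/ρ ∈ [0.01, 0.2] cm²/g,
ρ ∈ [0.5, 12] g/cm³, active heights ∈ [0.1, 5] cm, d ∈ [10, 100] cm),
reproducibly from a seed.  By default draws respect
`d/h_source ≥ 5` so the closed-form model is valid on every generated
case; `violate_validity = TRUE` deliberately crosses the threshold to
exercise the warning path.  These bundles emulate the *structure* of
real source inventories — parameter sets, stack states, multi-epoch
aging — but not real-world features such as polyenergetic spectra,
scatter buildup, manufacturing tolerances or calibration drift, so
passing property suites demonstrates internal consistency of the
model, not clinical accuracy.

## Limitations

* Primary photons only: real stacked sources would gain some air kerma
  back from scatter, more so for wide sources.
* Mono-energetic 1.25 MeV treatment of the 1.17/1.33 MeV pair.
* The active-column radius of the fixture is an assumption (0.05 cm).
* Pair-combining fidelity is claimed for group size 2 arithmetic on
  four-holder rotations only.
* No monetary cost model: savings are fractions of activity and
  capsule counts, not currency.
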