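---
title: "Methods: the coning-angle drag model and the synthetic samara study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coning-angle drag model and the synthetic samara study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samaraflight)
```

## The physical model

An autorotating samara descends at a terminal velocity set by a vertical
force balance. Rather than resolving lift and drag separately, the
package lumps them into one aerodynamic force aligned with descent,

$$ m g \;=\; \tfrac12\, C_D\, \rho\, V_d^2\, A\, \lvert\cos\theta\rvert , $$

where $m$ is seed mass, $A$ the plan-view silhouette area, $V_d$ the
descent velocity, $\theta$ the coning angle measured from the descent
(spin) axis, $\rho$ the air density and $C_D$ a lumped drag coefficient.
$A\lvert\cos\theta\rvert$ is the area the spinning seed presents to the
vertical flow. Fitting $F_D = \rho V_d^2 A \lvert\cos\theta\rvert$
against weight $m g$ across a population gives a single line whose slope
is $2/C_D$; `fit_drag_model()` returns the slope, intercept,
$R^2$ and $C_D = 2/\mathrm{slope}$.

Two conventions deserve comment.

* **$\lvert\cos\theta\rvert$.** Nutlet-down autorotation produces coning
  angles beyond $90^\circ$, where $\cos\theta < 0$. A negative projected
  area is unphysical; only the magnitude of the projection matters, so
  the default convention is `abs_cos`. A `sin` convention is provided
  for data sets whose angle is recorded from the rotor plane instead of
  the descent axis.
* **Air density.** $\rho = 1.23\ \mathrm{kg\,m^{-3}}$ (dry air near
  15 °C). Sources occasionally misprint air density in
  $\mathrm{g\,cm^{-3}}$ — a water-like value three orders of magnitude
  too large; `samara_constants()` pins the default and allows an
  explicit override for altitude or temperature corrections.

The classical alternative, wing loading $V_d^2 \sim m g / A$, omits the
coning angle. `compare_models()` computes both descriptions on the same
specimens; whenever $\theta$ varies between specimens the drag model
correlates far more strongly, which is the quantitative reason it is
preferred for interspecific comparison.

Two auxiliary force constructs are included. The angle of attack is
tabulated at the 0.75-span station,
$\phi = \arctan\!\big(V_d / (0.75\,S\,\omega)\big)$. The centrifugal
force is $F_c = m\,\omega^2 r_c$; no standard fixes the centroid-path
radius $r_c$, and plausible conventions change $F_c$ by orders of
magnitude, so the package adopts $r_c = 0.25\,S$ (spin axis at the
nutlet end, centroid at quarter span — the complement of the 0.75-span
blade station), documents it, and makes it configurable
(`r_c_fraction`). Because the convention is not reconstructible from
typical reports, no quantitative claim is attached to $F_c$ beyond
internal consistency.

## Fitting conventions

Power laws are fitted by ordinary least squares in
$\log_{10}$–$\log_{10}$ space, the standard allometric convention
(`fit_power_law()`). For free fits, $R^2$ is the squared Pearson
correlation in fit space. With an imposed exponent (the allometric
predictions $2/3$, $2$, $2$, $1$) only the prefactor is estimated, and
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ against the mean of
$\log_{10} y$ — which can be negative and is never above the free fit's
$R^2$, since the free fit nests the fixed one.

The drag fit uses a free intercept by default: the intercept is a
diagnostic that over- and under-weighted species pull away from zero. A
`through_origin` flag constrains it. Each wind-tunnel point is the mean
of three flight replicates; the fit therefore aggregates replicates to
specimen means by default (`per_replicate = TRUE` switches to raw
observations). $C_D$ is always $2/\mathrm{slope}$.

Perturbation experiments are analysed in reduced variables: each
quantity divided by its specimen's unaltered (level-0) value
(`reduce_perturbation()`). Failed levels — no stable autorotation — are
excluded from fits but retained when summarising the sustained envelope
(`robustness_summary()`). Baseline points participate in the fits. The
pooled mass-response fit includes both the addition and subtraction
branches by default (`branch = "add"`/`"sub"` restricts), and
species-specific fits warn below four non-baseline levels. The headline
robustness number is the predicted descent-velocity change at doubled
mass, $2^b - 1$ for fitted exponent $b$: with $b \approx 0.12$ that is
below 9 %, against the 41 % a fixed-geometry force balance ($b = 0.5$)
would predict.

## Silhouette morphometry

Span is the longest dimension of the silhouette: the maximum distance
between foreground pixel centers, computed on the convex hull (whose
diameter equals the brute-force maximum over all pixel pairs — a
property the tests verify exactly). Among exactly tied pairs the
lexicographically smallest (row, col) pair wins, so symmetric shapes
measure deterministically. Chord is the extent of the pixel projections
perpendicular to the span line, clamped not to exceed the span
(floating-point guard); collinear silhouettes report a one-pixel chord
with a warning. Area is the foreground count times the pixel area. The
chord is measured on the whole silhouette, the natural reading of
"maximum dimension perpendicular to the span line" when nutlet and wing
are not sub-segmented.

Segmentation assumes high-contrast tabletop photographs: Otsu threshold
(explicit override available), largest 8-connected component (EBImage's
4-connected labelling, with diagonal-touching labels merged by
union–find), holes filled. Polarity is configurable; the scale
(mm/pixel) is user-supplied — ruler detection is out of scope.

Expected accuracy is bounded by discretisation: ±2 pixel-equivalents on
lengths and 2 % on areas at ≥ 10 px/mm. Rotating a shape changes all
three measures by under 2 % at that resolution. One caveat: the chord
inherits the span pair's direction, so shapes whose two transverse
extremes sit at very different spanwise stations can show chord
sensitivity beyond the naive pixel bound when near-tied span pairs flip
under discretisation; the rendered test shapes place both extremes
mid-wing, where the measurement is well conditioned (as in real samaras,
whose wing is the widest part).

## The synthetic study and its calibration

The generator (`generate_population()`) emulates an eight-species
population of 160 specimens (20 per species, three flight replicates
each). Per specimen, chord is lognormal about the species median
(lognormal sizes being the standard assumption for biological size
data), span follows from the species chord–span ratio (published values
where available: *A. ginnala* 0.33, *A. floridanum* 0.34,
*A. campestre* 0.25), area is $A = k\,cS$ with a shape factor
$k \in (0,1]$, and mass follows the allometric model
$m = w\,\mu\,A^{3/2}$. The weighting factor $w$ is the single lever that
produces departures from mass–area allometry: *A. saccharum* 1.45
(overweighted), *A. negundo* 0.60 (underweighted), all others 1.

Dynamics are drawn per replicate: $\theta$ Normal about the species mean
(means straddle 117.8°, clipped to nutlet-down flight, 91–179°), $V_d$
from the force balance at the configured $C_D$ (default 5.99) times
multiplicative lognormal noise ($\sigma = 0.05$; morphology is treated
as measured essentially noise-free), and $\omega$ backed out of a drawn
0.75-span angle of attack, Normal(42.5°, 3.2°) — so generated
populations reproduce the tight angle-of-attack band by construction
rather than by accident. Seeds are mandatory; identical configurations
generate identical tables.

**Calibration.** The mass coefficient $\mu$ is not free: substituting
$m = w\mu A^{3/2}$ into the force balance gives
$V = \sqrt{2 g w \mu \sqrt{A} / (C_D \rho \lvert\cos\theta\rvert)}$, and
$\mu$ is solved in closed form so the preset-ensemble mean of $V$ equals
0.83 m/s (`calibrate_mass_coefficient()`, with the coning-angle
expectation computed by quadrature over each species' truncated Normal).
The calibration is deterministic in the presets — fixed before any data
are drawn.

One consequence is worth stating plainly: the $A^{3/2}$ mass model makes
the joint envelope of published samara ranges unattainable — a 10.8×
area range implies a ~35× mass range, while real interspecific mass
ranges are far narrower (real samaras are closer to $m \propto A$, which
is *why* their descent speeds cluster). The presets therefore keep every
generated span inside 17.2–60.6 mm and every area inside
0.53–5.72 cm², and let mass land where the allometric model puts it
(roughly 6–55 mg). Synthetic populations consequently carry a wider
descent-velocity spread than real ones (sd ≈ 0.17 m/s about a mean of
0.83) — passing recovery tests on them demonstrates that the estimators
are unbiased and well-scaled under the model's own assumptions, not that
real populations satisfy those assumptions.

Perturbation series (`generate_perturbation_series()`) scale a
specimen's baseline dynamics by power laws of the driving ratio, with
the empirically measured exponents as defaults — mass driver: 0.12
($V$), 0.70 ($\omega$), −0.48 ($\theta$); ablation driver: −0.79, 0.03,
−0.38 — times lognormal noise, three replicates per level. These
exponents are imposed, not derived from aerodynamics; the generator
makes no mechanistic claim about autorotation failure either. Failure is
bookkept from per-species sustained envelopes (e.g. *A. negundo*
autorotates for $0.5 \lesssim m/m_0 \lesssim 2.25$; *A. macrophyllum*
fails past $m/m_0 \approx 1.3$ but tolerates the deepest ablation,
$A/A_0 \approx 0.6$), plus one physical guard: a scaled coning angle
leaving $(0,180)^\circ$ marks the record failed, since the
$\theta \propto (m/m_0)^{-0.48}$ law necessarily exits its domain under
deep mass subtraction for baselines above ~100°. Non-driving ratios
follow the lab procedure: wax addition grows area by at most 5 %,
trailing-edge ablation removes at most 4 % of mass.

The full study design (`generate_perturbation_study()`) mirrors the
experimental layout: mass alteration and ablation on four species — the
over- and under-weighted ones plus the largest and smallest — three
specimens each.

Rendered silhouettes (`render_silhouette()`) are single closed polygons
(nutlet ellipse arc joined to a Bezier-edged tapered wing), rasterised
by even-odd point-in-polygon tests at pixel centers; ground truth
(span, chord, area, pixel count) is computed by exact geometry on the
polygon itself, so morphometry can be checked against analytic values
with no reference imagery. These are clean, hole-free, single-component
shapes: they exercise the measurement geometry, not the segmentation
robustness needed for photographs with shadows, trichome texture or
touching seeds.

## Numerical choices and degenerate inputs

* Internal computation is exclusively SI; field units (mg, mm, cm²,
  degrees) appear only at I/O boundaries, and the round-trip is exact to
  1e−12 relative. Angles stay in degrees except inside trigonometry.
* $\theta = 90^\circ$ has no equilibrium (zero projected area);
  `velocity_from_balance()` refuses it. Non-positive masses, areas or
  drag coefficients are rejected with the offending field named.
* Free power-law fits require $n \ge 3$ and a non-degenerate predictor;
  fixed-exponent fits require $n \ge 2$. Non-positive data are rejected
  with the offending index.
* The drag fit refuses all-equal weights (singular design). A
  non-positive slope — an unphysical fit — warns rather than errors, so
  diagnostics can still be inspected.
* Response fits require at least three distinct driver values; an
  all-failed scope returns an empty result with a warning.
* `reduce_perturbation()` is idempotent, and each specimen must carry an
  unaltered baseline or the offending specimen is named.

## Problem sizes

The shipped defaults are the study conditions: populations of 160
specimens (8 species × 20) with 3 replicates; perturbation studies of 12
specimens (4 species × 3) with 6 mass levels spanning $m/m_0$ 0.5–2.0
and 5 ablation levels spanning $A/A_0$ 0.65–1.0. Monte-Carlo checks of
estimator calibration use 200 seeded replicates at those sizes.
Silhouette tests run at 5–10 px/mm on shapes 20–50 mm across.

## Known limitations

* The generator's dynamics satisfy the force balance by construction;
  recovery tests validate estimator implementation, not the model's
  adequacy for real seeds.
* The mass model's $A^{3/2}$ exponent widens interspecific mass and
  velocity spreads beyond realistic values (see the calibration section).
* The coning-angle response law is extrapolated outside its physical
  domain by deep mass subtraction; the generator flags such records
  failed rather than bending the law.
* Wing-loading $R^2$ in synthetic populations is near zero (the
  generator draws $\theta$ independently of wing loading), lower than
  typically observed; the qualitative contrast with the drag model is
  preserved but its magnitude is not calibrated.
* No confidence intervals are attached to fitted exponents; a bootstrap
  could be layered on `fit_power_law()` but is deliberately out of
  scope.
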