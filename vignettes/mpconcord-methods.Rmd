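---
title: "Methods: structure-function concordance on a microperimetry grid"
author: "mpconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-function concordance on a microperimetry grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpconcord)
```

# The problem

Polypoidal choroidal vasculopathy (PCV) is delineated structurally on
indocyanine green angiography (ICGA, the diagnostic standard) and on
spectral-domain OCT, while the functional consequence — loss of
differential light sensitivity (DLS) — is measured by fundus-tracked
microperimetry. The clinically interesting question is topographical:
*where* do the three modalities agree that the macula is abnormal, and by
how much does each extend beyond the others? `mpconcord` answers this by
expressing all three modalities as sets of affected locations on the same
56-point microperimetry stimulus grid and comparing the sets with
intersection-over-union statistics.

# The stimulus grid and coverage regions

The grid covers 10° of eccentricity with two resolutions: 1.4° spacing out
to 4.2° (28 locations, the *inner* zone) and 2.8° between 4.2° and 9.8°
(28 locations, the *outer* zone). The exact instrument coordinates are not
public, so the package ships a layout with precisely these properties: a
Cartesian offset lattice at 1.4° spacing (coordinates odd multiples of
0.7°) truncated to eccentricity ≤ 4.2° and reduced to the 28
lowest-eccentricity points, plus the analogous 2.8° lattice between 4.2°
and 9.8°, which contains exactly 28 points. The inner reduction hits a
genuine tie — eight candidate points share eccentricity 4.08° and only
four can stay — which we break axis-symmetrically in favour of the
horizontally extended quadruple (±3.5°, ±2.1°), consistent with the grid's
wider horizontal use. Any user-supplied 56-point layout satisfying the
invariants (count, 28/28 zone split, reflection symmetry about both axes,
zone-wise minimum spacing) is accepted; the layout is treated as
exchangeable input.

A lesion is credited to a location if it is visible within half the
inter-stimulus separation: a disc of radius 0.7° below 5° of eccentricity
and 1.4° between 5° and 10°. At the transition between resolutions the
area of consideration is elliptical; since the source does not say which
locations that affects or how the ellipse is oriented, we assign ellipses
to locations with eccentricity in [4.2°, 5°], radial semi-axis 1.4°
(bridging the spacing change along the fovea–location ray) and tangential
semi-axis 0.7°. Boundary conventions: "less than 5°" is strict, "between
5° and 10°" closed, the 4.2° resolution boundary belongs to the inner
zone, and each location's own center eccentricity (not the tested point's)
selects its radius.

Contiguity on this irregular grid is not defined by the instrument, so the
package defines it by distance: two locations are contiguous when their
separation is at most 1.5 times the nominal spacing of the less eccentric
member. On the regular sub-lattices this reproduces 8-connectivity
(orthogonal and diagonal neighbours) and excludes skip-one pairs; the
factor is exposed as a parameter.

## The largest undetectable defect

`max_uncovered_diameter()` reports the diameter of the largest disc that
fits between the coverage discs — the biggest focal defect the sampling
scheme could miss. We define the *tested extent* as the union of
per-location sampling catchments (radius half the cell diagonal, ≈0.99°
inner, ≈1.98° outer) and the gap at a point as its distance to the union
of the nominal coverage discs, `min_i(dist_i − radius_i)` clamped at zero
— i.e. the radius of the largest empty disc centered there. The nominal
(disc) radii are used for all locations, including the transition band,
because the gap question concerns the half-separation sampling rule, not
the elliptical projection refinement. With the default grid, dense
sampling at 0.01° pitch puts the maximum at the outer cell centers,
`2 × (2.8·√2/2 − 1.4) ≈ 1.16°`, which rounds to 1.2°.

# Normative model, Total and Pattern Deviation

Healthy DLS declines with eccentricity and age. `fit_normative()`
regresses healthy dB on age per location (OLS), giving an expected value
at any age; Total Deviation (TD) is measured minus expected. Pattern
Deviation (PD) subtracts the *general height* — our estimator is the 85th
percentile of the eye's non-missing TD values, the standard convention for
pattern-deviation analysis — so a uniform (diffuse) depression leaves PD
at zero while focal defects persist. The exact TD/PD definitions of the
original analysis are not public; the 85th-percentile convention is our
documented choice and is recorded in the pipeline's output metadata.

Abnormality levels use pooled empirical per-location quantiles (order
statistics with linear interpolation, `quantile` type 7) of the normative
TD residuals, and of normative PD values after general-height removal, at
5/2/1%. Thresholds are inclusive (a deviation exactly at a quantile is
flagged), missing locations are never flagged and are excluded from means
and the general-height percentile, and the residual SD is floored at
0.5 dB so degenerate zero-variance locations cannot produce spurious
flags. Visual field loss is defined as ≥ 3 contiguous locations at PD
level ≤ 5%, computed as connected components of the contiguity graph;
clusters must be contiguous through *measured* locations. A field is
reliable when its false-positive catch-trial rate is strictly below 15%.

Two numerical points deserve note. First, PD's diffuse-removal property —
adding a constant to every measured value leaves PD unchanged — holds
*bit-exactly* on the instrument's quantized 2-dB scale with integer
shifts (all quantities are then exactly representable), and to rounding
error (≤ 1e-9 in our tests) on a continuous scale. Second, the empirical
quantiles make the per-location flag rate on healthy eyes ≈ 5% by
construction; we verify calibration within ±1% by Monte Carlo.

# Lesion projection

ICGA and OCT boundaries arrive as polygons in degrees (GeoJSON-style,
fovea-centered, assumed co-registered; multiple rings allowed with
even-odd parity so opposite-wound inner rings are holes). A location is
abnormal when its coverage region intersects the polygon with positive
area or boundary contact; the stricter "lesion covers the location
center" predicate is also exposed, since the source is ambiguous between
the two readings. Ellipse–polygon intersection maps the ellipse to the
unit disc by an affine transform and tests the transformed polygon
against the disc (center-in-polygon parity, else minimum exact
segment-to-origin distance ≤ 1, tolerance 1e-9). Areas are shoelace sums
converted at 0.288 mm/° (schematic emmetropic eye); axial-length
dependence is deliberately handled by exposing the scale as a parameter
rather than per-eye modelling. All modality sets are clipped to the
common analysis extent: ±10° horizontally and ±5° or ±10° vertically
(the OCT volume's extent), applied to MP, OCT and ICGA alike.

# Concordance statistics

For abnormality sets A, B, C over the grid: the three-way concordance is
100·|A∩B∩C|/|A∪B∪C|, the pairwise concordance 100·|A∩B|/|A∪B|, and the
relative complement of A over B is 100·|A\\B|/|A∪B|. "Maximum total
abnormal area" is read as the union — the only reading under which each
pair's concordance and two complements partition 100%. Empty unions are
conventions, not observations: concordance 100 (agreement on absence),
complement 0; both configurable. A modality has *greater areal extent*
when its complement strictly exceeds 20% of the union (10% as sensitivity
analysis); both modalities can exceed it, and the `both` category is
counted separately and also contributes to each side's count. Cohort
summaries report medians and IQRs (25th/75th percentiles, linear
interpolation — the original software's convention is unknown) per
exudative group, with two-sided Wilcoxon rank-sum contrasts of areal
extents between groups.

# Structure–function associations

Per eye, PD values and total retinal thicknesses are summed over the
locations of a region — the eye's field-loss set ("abnormal") or the
three-way intersection ("concordant") — and the PD sum is regressed on
the thickness sum across eyes by OLS (the minimal reading of an R² with a
p value). Thickness is only available to 7° of eccentricity; locations
without thickness are skipped, never imputed, and the per-eye n is
retained. The subfoveal choroid analysis regresses the mean PD of
locations within 1.4° eccentricity (inclusive — the innermost ring of the
default layout) on the choroidal thickness; a zero-variance regressor
returns R² = 0 with slope "zero" by convention.

# The synthetic cohort generator

No patient data accompany the analysis, so `generate_cohort()` emulates
the statistical structure the pipeline assumes, with defaults fixed to
the conditions of the clinical cohort the package targets: 25 eyes, 16/25 exudative, patient ages uniform on
63–88 years (median ≈ 73), subfoveal choroid Normal(251, 100) μm
truncated positive and available for 21/25 eyes, and lognormal ICGA
lesion areas with an all-eyes median of 10 mm² (exudative eyes shifted up
by ×1.25 in the median, non-exudative down, matching the reported group
contrast). The healthy surface is a plane in age and eccentricity
(18 dB at the fovea at age 70, −0.3 dB/°, −0.05 dB/yr, residual SD
1.2 dB); measurement is simulated with a logistic-observer 4-2 staircase
(two reversals, last-seen value, 0–20 dB range) plus 1.5 dB test–retest
noise.

Lesions are star-shaped polygons (log-Gaussian radial splines, 48
vertices). Two calibration choices matter and were fixed against the
reported cohort statistics, not against any test outcome. First, lesions
are eccentric and irregular (center jitter SD 3.5°, irregularity 0.35):
fovea-centric circles of such areas would cover ~50 of 56
locations, swallowing the 85th-percentile general height and
contradicting the reported functional extent (median 38 PD defects ≤ 1%,
IQR 21–42; median TD ≈ −8 dB); eccentric irregular lesions of the same
areas reproduce those statistics. Second, the OCT boundary is the ICGA
boundary radially dilated by a lognormal margin (median 0.7°) plus smooth
boundary noise (SD 0.25°), so OCT is mostly — but not strictly — a
superset of ICGA, as observed. Functional depression is 12 dB at mapped
OCT locations with a shallower 8 dB halo applied with probability 0.7 to
locations within 2° beyond the OCT boundary; the probabilistic halo
creates eyes where field loss is not a strict superset of the OCT set,
matching the bidirectional complements. Retinal thickness is a 280 μm
baseline plus 25 μm inside the lesion plus 1.5 μm per dB of true
depression (yielding the negative PD–thickness association) with 12 μm
noise; choroid–PD coupling defaults to zero, matching the
non-significant reported association. Exudative status acts purely as the
lesion-scale multiplier — no sub-RPE CNV, PED or EZ-disruption modelling
beyond metadata flags.

Everything descends from one master seed, so cohorts regenerate
byte-identically. What the generator does *not* emulate: real lesion
morphology (polyp clusters, branching networks, multi-focal lesions),
fixation instability, learning effects, spatial correlation of
measurement noise, or anti-VEGF response dynamics. Passing tests
therefore demonstrate the *pipeline's* correctness and the qualitative
direction of its statistics under the assumed structure, not clinical
replication of any clinical cohort.

# Problem sizes and validation strategy

The test suite validates each stage against independent oracles:
brute-force bitmask enumeration for set metrics (1,000 random triples),
exhaustive reachability-matrix component search for the contiguity rule
(500 random flag patterns), dense edge-sampling (0.01° pitch) with a
winding-number interior test for lesion projection (200 random star
polygons), and closed-form least squares for the regressions. End-to-end,
a noise-free cohort must return the generator's truth exactly; noisy
validation uses 200-eye cohorts (age-slope recovery within ±10% on the
across-location mean — per-location slopes at n = 200 have sampling SE
larger than that band — and monotone decline of MP–OCT concordance in
halo width), and the direction checks use a 100-eye default cohort.
These sizes give stable medians while keeping the whole suite's runtime
in minutes on one core.

# Known limitations

The true instrument grid may differ from the packaged layout; the
pipeline treats the layout as input. The general-height estimator
saturates when more than ~85% of measured locations are depressed — eyes
with near-total field involvement are under-detected by PD analysis by
construction, a property of pattern deviation itself, and such eyes do
occur under the default generator. Thickness sums are restricted to ≤ 7°
by data availability, so the "abnormal" region sum ignores more
peripheral loss. Polygon inputs are assumed co-registered in degrees; no
image registration is attempted.
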