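# mpconcord

Structure–function concordance mapping on a microperimetry grid, for
macular disease — in particular polypoidal choroidal vasculopathy (PCV).

## The problem

PCV lesions are delineated structurally on indocyanine green angiography
(ICGA, the diagnostic standard) and on spectral-domain OCT; the
functional damage is measured by microperimetry as differential light
sensitivity (DLS, dB) at 56 retinal locations within 10° of eccentricity.
Clinicians want to know *where* these three views of the disease agree
and by how much each extends beyond the others. `mpconcord` is for
researchers who have per-eye microperimetry fields, lesion boundary
polygons and retinal/choroidal thickness measures (or who want to
simulate them) and need the full analysis chain:

1. **Grid geometry** — the 56-location stimulus grid (1.4° spacing to
   4.2°, 2.8° from 4.2° to 9.8°), its contiguity graph, and per-location
   coverage regions: discs of radius 0.7° (< 5° eccentricity) and 1.4°
   (5–10°), with radially oriented ellipses at the resolution transition.
2. **Normative analysis** — per-location age regression of healthy DLS;
   Total Deviation `TD = measured − expected(age)`; Pattern Deviation
   `PD = TD − GH` with general height `GH` the 85th percentile of TD
   (removing diffuse loss); empirical 5/2/1% probability maps; field
   loss = ≥ 3 contiguous locations at PD ≤ 5%.
3. **Lesion projection** — ICGA/OCT polygons (degrees, GeoJSON-style)
   mapped to the abnormality set of grid locations whose coverage region
   the lesion intersects, clipped to the common analysis extent.
4. **Concordance** — with abnormality sets A, B, C:
   three-way concordance `100·|A∩B∩C|/|A∪B∪C|`, pairwise
   `100·|A∩B|/|A∪B|`, relative complement `100·|A\B|/|A∪B|`, and
   greater-extent classification at a strict 20% (or 10%) threshold;
   cohort medians/IQRs and rank-sum group contrasts.
5. **Associations** — OLS of per-eye PD sums on retinal-thickness sums
   (over the abnormal or concordant region, ≤ 7° where thickness exists)
   and of central mean PD (≤ 1.4°) on subfoveal choroidal thickness.

A seeded synthetic-data generator (`generate_cohort()`) emulates the
assumed statistical structure — eccentric irregular lesions with
calibrated areas, OCT mostly dilating ICGA, depression with a
probabilistic halo beyond the lesion, thickening coupled to depression —
so the whole pipeline is testable without patient data.

## Worked example

```r
library(mpconcord)

grid   <- mp_grid()                          # 56 locations, 28 inner / 28 outer
cfg    <- generator_config(seed = 2026, n_eyes = 25)
cohort <- generate_cohort(cfg, grid)         # synthetic PCV case series
normative <- generate_normative_cohort(cfg, n = 120, age_range = c(45, 90),
                                       seed = 2027, grid = grid)
model  <- fit_normative(normative)           # age-referenced normative model
res    <- run_pipeline(cohort, model, grid)
print(res)
```

```
Cohort concordance summary (25 eyes)
...
[all] n = 25
  MP, SD-OCT, ICGA concordance (%) median (IQR): 75.0 (56.7, 79.4)
  MP, ICGA concordance (%)         median (IQR): 75.0 (59.1, 79.5)
  SD-OCT, ICGA concordance (%)     median (IQR): 89.2 (83.3, 93.1)
  MP, SD-OCT concordance (%)       median (IQR): 87.0 (72.4, 90.0)
  greater extent (eyes): MP>ICGA 14, ICGA>MP 3; OCT>ICGA 5, ICGA>OCT 0; MP>OCT 4, OCT>MP 3

Exudative vs non-exudative rank-sum p: n_mp = 0.55, n_oct = 0.28, n_icga = 0.4

Structure-function association [abnormal]: R^2 = 0.705, p = 2.86e-07, slope negative, n = 24 eyes
Structure-function association [concordant]: R^2 = 0.754, p = 3.75e-08, slope negative, n = 24 eyes
Structure-function association [central]: R^2 = 0.094, p = 0.145, slope negative, n = 24 eyes
```

Reading the output: the four concordance rows are the proportion of the
union of abnormal areas that is mutually abnormal (per modality pair or
all three); the greater-extent counts are eyes whose relative complement
exceeds 20% of the pairwise union — here functional loss (MP) exceeds the
angiographic lesion far more often than the reverse (14 vs 3 eyes), while
the PD sum falls with the thickness sum (negative slope) and the
choroid–PD relation is weak, as the generator's zero choroid coupling
implies. `run_pipeline(..., out_dir = "out")` additionally writes
`per_eye.csv`, `cohort_summary.json` and a readable `report.txt`;
`write_cohort()`/`read_cohort()` round-trip cohorts through CSV/GeoJSON
files with left eyes mirrored to right-eye convention at ingest.

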