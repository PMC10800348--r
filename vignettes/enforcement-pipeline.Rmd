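---
title: "Measuring environmental law enforcement: indicators, spatial targeting, and legality classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring environmental law enforcement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enforcelens)
```

## The problem

Command-and-control enforcement — infraction notices with prospective
fines, land-use embargoes, confiscation and destruction of equipment — is
the backbone of deforestation policy in the Brazilian Amazon. Whether it
works depends on more than the raw number of sanctions: on whether field
operations are *spatially targeted* at where deforestation actually
happens, on whether the deforestation being sanctioned is *illegal* under
the Forest Code, on whether notices *translate into paid fines* through
the prosecution funnel, and on what each sanction *costs* the public
purse. `enforcelens` implements each of those measurements as a tested,
reusable pipeline, and couples it to a synthetic landscape generator with
known ground truth so that every stage can be validated end to end without
access to the national IBAMA / PRODES / CAR / SIOP datasets.

## The measurements

### Annual enforcement indicators

`ingest_records()` cleans a raw sanction export: duplicate rows (identical
`record_id` or all fields equal) collapse to one, records outside the nine
Legal Amazon states or the study window are dropped, and — following
enforcement practice — infraction notices are restricted to flora-related
themes while embargoes and confiscations are kept regardless of theme,
because no unique key separates deforestation embargoes from other
flora-crime embargoes. `annual_indicators()` then produces per-year counts
per sanction type, fine totals and means, the geolocated share of notices,
and paid-fine counts. `percent_change()`, `period_aggregate()` and
`paid_fine_ratio()` provide the arithmetic of reported comparisons;
reported percentages round half-away-from-zero to integers
(`report_percent()`).

Two conventions worth flagging. The fine mean is taken over notices with a
nonzero fine, which keeps the identity
`fines_total = fines_mean x notices_with_nonzero_fines` exact. And
prosecution cohorts for the paid-fine ratio are defined by *filing* year,
not payment year: the ratio asks what fraction of processes opened in a
cohort ever reach the paid stage.

### The spatial-match statistic

The targeting measure correlates two kernel heatmaps per year: one of
geolocated fine locations, one of deforestation (patch centroids weighted
by area). The kernel density at a point $s$ from events $e_1, \dots, e_n$
with weights $w_i$ and bandwidth $h$ is

$$\hat f(s) = \sum_{i=1}^{n} w_i \, K_h(\lVert s - e_i \rVert), \qquad
K_h(d) = \frac{3}{\pi h^2}\Bigl(1 - \frac{d^2}{h^2}\Bigr)^2 \;
\text{for } d \le h,$$

the quartic (biweight) kernel with support radius equal to the bandwidth —
the common GIS kernel-density convention. A truncated Gaussian
($\sigma = h/3$, renormalized over the truncation disc so mass is conserved
exactly) is available as an option; the kernel family is recorded in the
raster metadata. No edge correction is applied, so densities within one
bandwidth of the region border are biased low; mass conservation is exact
(to the cell discretization) only for interior events, which is how the
tests check it against a brute-force kernel-sum oracle.

Before correlating, the lowest quartile of each map is set to null so that
the statistic compares *hotspots* rather than the empty background (which
would otherwise dominate the correlation with matching zeros). The
threshold is the `floor(q*n) + 1`-th order statistic of the `n` strictly
positive cells, and cells strictly below it (plus all zero cells) are
masked. We chose the order-statistic rule over an interpolated sample
quantile deliberately: with strict-below masking it guarantees that at
most a share `q` of positive cells is ever removed, for every `n` and
under ties, whereas an interpolated threshold can remove up to
`floor(1 + q(n-1))` cells — more than `q n` whenever `n` is not a
multiple of 4.

The Pearson correlation is then computed over cells valid in *both* maps
(intersection rule; masking alone does not determine union vs intersection
and intersection is what "compare the hotspots" means). `r` is invariant
under positive affine rescaling of either surface, equals 1 for identical
maps and −1 for an affine reversal; both are property-tested. The annual
series is smoothed with a *trailing* 4-year moving average (the value at
year `y` averages `y-3 … y`), defined only where the window is full, and
the quartile is taken per year per map, not pooled across years.

### Forest Code balance and legality classification

Per holding, `compute_fc_balance()` measures the native-vegetation
fraction `v` on the raster (cell-center rule) and the Legal Reserve
deficit

$$\text{deficit} = \max(0,\; r - v) \times \text{area}, \qquad r = 0.80$$

with compliance iff the deficit is zero. `classify_patches()` applies the
two legality rules the data can support at scale, in order:

1. patches below the minimum mapping unit (6.25 ha, the effective
   resolution of the annual deforestation maps) are set aside as
   `below_mmu` and never enter the statistics;
2. a patch intersecting a Riparian Preservation Area (APP; the union of
   30 m buffers around streams, width configurable) is
   `potentially_illegal` with reason `riparian_app`;
3. otherwise a patch on a non-compliant holding is `potentially_illegal`
   with reason `lr_deficit`;
4. otherwise `presumed_legal`.

The APP reason takes precedence when both apply, so exactly one reason is
reported. Patches are assigned to the holding with the largest area
overlap (exact convex clipping; representative-point fallback for
slivers). The balance is computed on the pre-patch native map — the patch
being judged is not first subtracted from the holding's vegetation. Full
statutory accounting (hilltop APPs, Legal Reserve compensation, pre-2008
amnesty ledgers) is out of scope.

`attribute_notices()` links a geolocated notice to the holding containing
its point, and marks the link deforestation-related only when the holding
has an above-MMU patch with `patch year <= notice year` — a notice is
only evidence of enforcement *against deforestation* if it came after
deforestation took place. The rule operates at year granularity because
sanction exports rarely carry reliable sub-annual dates.
`illegality_enforcement_series()` turns labels plus attribution into the
two annual coverage series (share of potentially illegal *area* noticed;
share of deforesting *holdings* noticed), and
`protected_overlap_flags()` flags holdings whose overlap with protected
areas strictly exceeds 25% — the land-grabbing indicator.
`land_category_breakdown()` apportions annual deforestation across land
categories with precedence indigenous land > conservation unit >
settlement > private holding > undesignated; every sample point inside a
patch is assigned to exactly one category, so per-year totals conserve
total patch area by construction.

### Operational efficiency

Expenditure series are deflated with a consumer-price index to a base
year and converted at a fixed R\$ 5 per USD 1
(`deflate_convert()`), then

$$OE_{i,y} = \frac{E_y}{I_{i,y}}$$

gives the cost per sanction of type `i` in year `y`
(`operational_efficiency()`). The same `E_y` backs every sanction type:
notices, embargoes and confiscations typically arise from the same field
operation, so the three unit costs are alternative readings of one
budget, not additive components. Multi-year unit costs
(`period_unit_cost()`) are pooled ratios of sums — total expenditure over
total sanctions — because reported period figures are totals over
multi-year windows; mean-of-ratios is available as an option and differs
whenever counts vary against spending.

## The synthetic landscape

`generate_landscape()` + `generate_enforcement()` emulate the statistical
structure of the real inputs on one flat projected plane in meters (no
geodesy):

* **Cadastre.** Holdings are Voronoi cells of uniformly random seed
  points clipped to the region — a gapless, non-overlapping tessellation,
  the simplest structure matching registry-like coverage. Categories
  (private holding / settlement / traditional community) are drawn
  85/10/5.
* **Deforestation.** Patches are axis-aligned rectangles with log-normal
  areas (median 20 ha, log-sd 1, so roughly 12% fall below the 6.25 ha
  MMU, mimicking the heavy right tail of mapped clearings) and aspect
  ratio uniform in [1, 3]; rectangles keep area bookkeeping exact for
  tests. 60 patches per year over 2009–2018 on the default 50 x 50 km
  region.
* **Illegality with known truth.** Each patch is illegal with probability
  0.8 (matching the reported ~82% share of deforesting holdings with
  potentially illegal clearing). Riparian illegality is induced by
  centering the patch on a stream vertex (the vertex is inside the
  rectangle, so APP intersection holds by construction); Legal Reserve
  illegality by placing the patch in a holding whose native raster was
  pre-cleared to 50–70% (safely below the 80% requirement, while
  compliant holdings stay above 95%); legal patches are placed in
  compliant holdings with a clearance margin beyond the APP buffer.
  Ground-truth labels follow from the placement mechanism plus the MMU
  rule — they are *constructed*, not computed by the classifier — which
  is what makes the oracle-equivalence test (100% recovery when
  classifier and generator share rule parameters) a genuine end-to-end
  check.
* **Enforcement coupling.** Notices are placed near a same-year patch
  centroid with probability `coupling_rho` (Gaussian jitter, 500 m
  default) and uniformly otherwise; `coupling_rho` is the ground-truth
  dial for spatial targeting, and the mean spatial-match `r` must
  increase in it — the pipeline-level analogue of interpreting the
  correlation series as targeting quality. Geolocation is carried with
  probability 0.6 (the real share rose from 5% to 61% over the study
  period). Each notice spawns an embargo with probability 0.35 and a
  confiscation with probability 0.2 on the same process, and opens a
  prosecution that advances filed -> judged -> paid with probabilities
  0.5 and 0.34, whose product 0.17 matches the historically observed
  paid-fine ratio. An alternative `coverage_fraction` mode issues one
  notice per selected deforesting holding, used to verify that the
  coverage statistics recover a configured rate.
* **Determinism.** All randomness flows from one seed through named
  sub-streams (holdings, protected, streams, native, patches, notices,
  records, prosecution, expenditure), so components can be regenerated
  independently and a fixed seed reproduces every output bit for bit.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial contagion of deforestation along roads
and frontiers, realistic parcel shapes and river geomorphology, column
dialects of real exports, reporting lags, and the systematic (not random)
geolocation missingness of early-period notices. The synthetic region is
also three orders of magnitude smaller than the biome.

## Numerical choices

* **Geometry.** All overlays are exact convex-polygon operations
  (Sutherland–Hodgman half-plane clipping, shoelace areas) in doubles;
  point-in-polygon is ray casting. Distances to stream networks are exact
  segment distances, so APP membership tests carry no discretization
  error; only APP *area* is measured by grid sampling (5 m default,
  < 1% error at a 30 m buffer).
* **Bandwidth at desk scale.** 30 km is the reference bandwidth at biome
  scale (about 1% of the domain extent). The synthetic pipeline defaults
  to 6% of the region extent (3 km on the 50 km region): large enough to
  bridge the 500 m notice jitter, small enough to resolve distinct
  hotspots. The biome-scale value remains the `spatial_match_config()`
  default; the pipeline override is a scale choice, not a different
  method.
* **Problem sizes in the test suite.** Property tests run on 20 km
  regions with 100 patches; the coupling-monotonicity check runs the full
  50 km / 100 m-cell condition with three seeds per coupling level; mass
  conservation uses 100 interior events against a brute-force double-loop
  oracle; funnel and coverage recovery use exact binomial 99% intervals
  at n >= 2000 and n ≈ 100 respectively.
* **Degenerate inputs.** Zero-area patches are skipped with a warning in
  rasterization; years with no events yield missing correlations rather
  than errors; zero notices make the geolocated share missing, zero
  filed processes make the paid-fine ratio an error (undefined, not 0);
  a constant raster over the joint support is an error rather than
  `r = NA` silently.

## Limitations

The classifier implements the two Forest Code rules that national-scale
data can test, not the full statute. The spatial-match statistic has no
significance test under spatial autocorrelation — the correlation of
smoothed surfaces is not a sample correlation, and its null distribution
is not pursued here. Correlations near region borders inherit the
kernel's edge bias. And all conclusions from synthetic runs are
statements about the pipeline's correctness, not about the Amazon: the
generator is a measurement instrument for the code, not a model of the
landscape.
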