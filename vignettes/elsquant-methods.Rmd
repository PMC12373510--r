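---
title: "Quantifying ectopic lymphoid structures in salivary-gland immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ectopic lymphoid structures in salivary-gland immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsquant)
```

## The measurement problem

Sialadenitis — inflammation of the salivary glands, the hallmark lesion of
Sjögren's disease and of its viral-induced murine models — is graded
histopathologically from the lymphocytic infiltrates that accumulate around
ducts. Two clinical indices dominate: the **focus score**, the number of
inflammatory foci (infiltrates of more than 50 lymphocytes) per unit gland
area scaled to 4 mm², and the **aggregate area fraction**, the percentage of
gland area occupied by infiltrate. When infiltrates organize into ectopic
lymphoid structures (ELS), the T-cell (CD3⁺) and B-cell (B220⁺/CD20⁺)
compartments segregate into discrete zones; the prevalence of segregated
aggregates is a third readout of immune organization.

`elsquant` implements this quantification as a reproducible pipeline over
multichannel immunofluorescence fields (DAPI plus one T and one B marker):

1. **Pixel classification** — a single global intensity threshold per
   channel, mirroring operator-gated analysis.
2. **Geometry** — marker-positive areas, their intersection, and connected
   T∪B components as aggregates; masks convert losslessly to and from
   polygon regions (GeoJSON) so externally drawn annotations interoperate.
3. **Histopathology** — nucleus counts per aggregate, focus calling
   (strictly more than 50 nuclei), focus score
   $\mathrm{FS} = \dfrac{n_\text{foci}}{A_\text{gland}\,[\mathrm{mm}^2]} \times 4$,
   aggregate area fraction
   $\mathrm{AAF} = 100 \cdot A_\text{aggregates}/A_\text{gland}$, and a
   segregation index per aggregate.
4. **Statistics** — exact nonparametric two-group tests, Spearman
   correlation matrices with Benjamini–Hochberg adjustment, Grubbs outlier
   screening and ΔΔCt fold changes for companion qPCR panels.

Every stage is exercised against a synthetic field generator with exhaustive
planted ground truth, so the pipeline's recovery properties are measurable
rather than asserted.

## Field geometry

Acquired fields have a fixed evaluated area of **1,229,054.6934 µm²**. The
acquisition pixel size is not part of the protocol record, so the simulator
defaults to a 1392 × 1040 px raster (a common 2/3" CCD frame) with the pixel
size derived from the fixed area,
$\sqrt{1229054.6934/(1392\cdot 1040)} \approx 0.92140\ \mu m$, which makes a
default field reproduce the printed area to double precision:

```{r}
default_field_geometry()
```

When no gland annotation is supplied, per-field results are reported against
this fixed area with no further normalization (the field-image convention);
supplying a gland polygon (e.g. a semi-manual GeoJSON outline) switches the
denominators to the annotated gland area (the whole-gland convention).

## The synthetic sialadenitis field

`simulate_field()` plants disc-shaped lymphocytic aggregates in a field (or
inside a gland polygon). Design choices, fixed once:

* **Nuclei** are 2.5 µm-radius discs stamped at pixel-snapped centres with a
  minimum centre separation of one diameter plus a 0.2 µm snap margin.
  Snapping makes every nuclear footprint an identical discrete disc, so
  DAPI-positive area is an exact integer multiple of
  `nominal_nucleus_footprint_px()` — the property that makes `area_ratio`
  nucleus counting exact on clean data.
* **Stained cells** paint 7 µm-radius discs into their marker channel
  (CD3 for T, B220 for B). The halo exceeding the nucleus emulates
  membrane/cytoplasmic staining plus optical blur, and is what creates
  T/B overlap in mixed aggregates. With the default packing fraction
  (0.4 of the cluster disc covered by nucleus-spacing discs) a Boolean-
  coverage estimate puts the expected overlap of one marker's area by the
  other at ≈65 % in mixed aggregates and near zero between separated
  sub-clusters; measured segregation indices fall at 0.22–0.44 (mixed)
  versus 0.90–0.99 (segregated), well clear of the 0.5 decision threshold.
* **Identities** are i.i.d. Bernoulli(`t_fraction`, default 0.5). Under
  `segregation_mode = "segregated"` the T and B nuclei occupy two
  sub-cluster discs whose centres sit `separation_factor` (default 1.5)
  aggregate radii apart; at `separation_factor = 2` the stained unions are
  fully disjoint and the planted intersection is exactly zero.
* **Aggregates** are placed by bounded rejection sampling (1000 attempts,
  then an error naming the aggregate) so that they never overlap each other
  or leave the gland — truth bookkeeping stays exact and detection is
  unambiguous.
* **Signal model**: constant background (default 200 camera units), marker
  plateaus (default 4000), additive Gaussian noise clipped at zero, then
  quantization to 16-bit integers — the simplest model that exercises
  threshold robustness and round-trips TIFF storage bit-exactly.
* **Ground truth** is measured from the noise-free label rasters (pixel
  counts), never from analytic disc areas, so truth and pipeline share the
  same discretization.

What the generator does **not** emulate: ducts (the "peri-ductal" context of
the clinical focus definition — focus calling here is purely by nucleus
count), optical point-spread functions, intensity texture or vignetting,
autofluorescence, and section artefacts. Passing recovery tests on this
generator therefore demonstrates the correctness of the measurement
geometry and bookkeeping, not robustness to real staining variability.

```{r, fig.width = 5, fig.height = 5, eval = FALSE}
f <- simulate_field(simulation_config(n_aggregates = 4), seed = 42)
autoplot(f$image)
```

## Quantification choices

* **Thresholds** are global per channel with inclusive `>=` comparison (the
  boundary convention is explicit and configurable). Otsu's 256-bin method
  is available for unattended runs on bimodal channels; on noisy full
  fields, where positive pixels are well under 1 % of the frame, Otsu's
  between-class criterion splits the background instead — the classic
  class-imbalance failure — so realistic runs should supply operator-style
  fixed thresholds (e.g. the midpoint of background and plateau).
* **Aggregates** are 8-connected components of the T∪B mask (diagonal
  contacts within an infiltrate should not split it); components under
  `min_aggregate_area_um2` (default 200 µm², about eight lymphocyte
  sections) are treated as debris.
* **Nucleus counting** defaults to `area_ratio` (DAPI area ÷ nominal
  nucleus footprint), exact when nuclei do not overlap; `peaks` (local
  maxima of the Gaussian-smoothed DAPI at two-radius separation) is the
  crowded-field alternative and merges abutting nuclei — planted-count
  recovery is exact for well-separated nuclei and within ~15 % at dense
  packing.
* **Focus calling** is strictly `> 50` nuclei: a 51-nucleus aggregate is a
  focus, a 50-nucleus aggregate is not.
* **Segregation** is scored as
  $S = 1 - \dfrac{A_{T \cap B}}{\min(A_T, A_B)}$, 1 when exactly one
  marker area is zero, undefined (and excluded from prevalence) when both
  are. The human call "T and B areas in discrete zones" becomes
  $S \ge 0.5$; index, threshold and per-aggregate values are all reported
  so alternative rules can be audited.

## Statistical layer

All tests are two-sided by default. Tie handling uses midranks throughout,
with tie-corrected variances and continuity correction in the normal
approximations. The Mann–Whitney U is exact (full enumeration of group
labelings) for $n_1+n_2 \le 12$ without ties; the signed-rank test
enumerates all $2^n$ sign patterns for $n \le 15$, conditioning on observed
midranks so it stays exact under tied differences. Zero paired differences
are dropped before ranking (Wilcoxon's original convention; the degenerate
all-zero case reports p = 1 with a warning). Benjamini–Hochberg step-up is
applied over the strict upper triangle of correlation matrices — each
variable pair is one test — with undefined correlations (constant
variables) excluded from the family. Grubbs screening uses the closed-form
critical value
$\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}$ and is
single-pass by default (iterated exclusion is available); qPCR fold changes
average duplicate wells on the Ct scale before forming
$2^{-\Delta\Delta Ct}$.

```{r}
mann_whitney(c(1, 2, 3), c(4, 5, 6))
bh_adjust(c(0.01, 0.02, 0.03, 0.04))
grubbs(c(10, 10.5, 9.5, 10.2, 9.8, 30))
```

## Validation scale and numerical conventions

The shipped test-suite validates, among others: exact equality of pipeline
focus score with planted truth and ≤2 % relative error on the area fraction
over 20 noise-free default-size glands (≤5 % at noise σ = 10 % of the
marker plateau); ≥95 % segregation classification accuracy over 100+
planted aggregates; exact agreement of the enumeration test paths with
independent brute-force oracles for all $n_1+n_2 \le 8$; and empirical
type-I error within 5 % ± 2 points over 2000 null two-group simulations at
n = 10 per group. These problem sizes were chosen as the smallest cohorts
at which the respective properties are sharp.

Conventions worth knowing when extending the package:

* Pixel coordinates are 0-based, origin top-left, y down; polygon vertices
  sit on pixel corners, so polygonized regions rasterize back exactly and
  region area equals pixel count × pixel area to machine precision.
* Boundary tracing keeps the foreground on the right of travel; at corner
  contacts the turn priority follows the chosen connectivity, so
  diagonally touching foreground stays one region under 8-connectivity
  (its rings may touch at a corner vertex) and splits under
  4-connectivity.
* Polygon-mode intersection areas are computed by scanline clipping of the
  vector regions' row-coverage intervals and agree exactly with the raster
  AND on pixel-aligned geometry.
* TIFF fields are stored as 16-bit integers scaled by 1/65535 with channel
  names and pixel calibration in a JSON companion file; integer-valued
  intensities in [0, 65535] round-trip bit-exactly.

## Known limitations

* The "peri-ductal" qualifier of the clinical focus definition is not
  checked — no duct channel exists in the data model.
* Otsu auto-thresholding is unreliable at extreme foreground/background
  imbalance (see above); it is a convenience, not a substitute for
  protocol thresholds.
* `peaks` counting under-counts densely packed nuclei; `area_ratio`
  over-counts when nuclei overlap appreciably (it assumes the nominal
  footprint tiles the DAPI area).
* The segregation index collapses spatial organization to area overlap; an
  aggregate with many small interleaved T/B patches and one with two clean
  zones can score alike only if their overlaps differ, which is what the
  planted-geometry validation establishes for disc-like aggregates.
* Focus scores from fluorescence fields and from H&E-stained whole
  sections are not interchangeable; when comparing against H&E-derived
  scores, treat the provenance difference explicitly.
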