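---
title: "Methods: dendritic spine morphometry and its validation by synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendritic spine morphometry and its validation by synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its measurement models,
the choices behind them, and what the synthetic-data validation does
and does not establish about real data.

## The measurement problem

Dendritic spines are micrometre-scale protrusions carrying most
excitatory synapses; their linear density (spines per µm of dendrite)
and their morphological class mix (mushroom / thin / stubby / branched)
index synaptic health. In amyloid mouse models, density additionally
varies with the distance from each dendrite to the nearest amyloid
plaque edge. The package measures these quantities from calibrated
multi-channel confocal stacks and fits the hierarchical statistics that
respect the design: many dendrites per mouse, two hemispheres
(treatments) per mouse, plaque proximity within transgenic animals.

All geometry is computed in physical micrometres. Voxel indexing is
0-based in the compiled layer and 1-based in R; the physical centre of
voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) − 0.5) *
voxel_size_um`, which makes anisotropic stacks (typical: 0.12–0.3 µm
laterally, 0.3 µm axially) unambiguous.

## Segmentation and skeletonisation

`segment_neurites()` smooths at the shaft scale (default σ = 0.2 µm)
and applies a hysteresis threshold: connected components above a weak
level are kept when they contain a voxel above a strong (Otsu) seed
level. The weak level is placed half-way between the background median
and the robust foreground peak, so the mask approximates the
half-maximum surface of bright tubes. A single Otsu level was rejected
during development because it severs sub-resolution spine necks, whose
blurred peak intensity falls well below the threshold that separates
shaft from background; the hysteresis variant keeps every level
*relative* to the stack's own statistics, so the mask is invariant to a
global intensity gain (a property the tests assert exactly).

`skeletonize()` produces a medial path graph by iterative
farthest-point geodesic tracing, the approach of shortest-path neurite
tracers rather than voxel thinning: the two geodesically farthest
voxels of a component are joined by a Dijkstra path whose edge costs
are physical step lengths weighted by closeness to the medial axis
(from the Euclidean distance transform); side branches longer than
`min_branch_um` (default 5 µm, above the spine length scale so spines
never enter the backbone) are traced onto the growing skeleton. Voxel
chains are smoothed with a short moving average before lengths are
computed, which removes the staircase bias of discrete paths; free tips
are trimmed while they run through sub-radius structure (end-cap
corners). On straight 30 µm test tubes the traced length is within
about 3 % of truth and the measured tortuosity is below 1.03.

`extract_segments()` returns branch-free paths between graph nodes and
applies the inclusion filter: only segments whose *path length*
exceeds 20 µm are analysed. (Whether such a filter should act on path
length or on straight-line extent is ambiguous; path length is
implemented, and the choice only matters for strongly curved
segments.)

`shaft_diameter()` measures the shaft calibre at three stations — the
midpoint and 2 µm inboard of each end, since full width at an end cap
is ill-defined. With the originating stack available the width is
photometric: the integrated intensity of a short slab around the local
tangent, divided by the fill amplitude, gives the true cross-section
area independent of blur and threshold (the median over three nearby
sub-stations resists a spine landing on a station); this recovers both
uniform 1.2 µm shafts and the midpoint of a 1→2 µm cone to within
about 0.1 µm. A mask-only fallback measures the half-peak mask's width
in the station's own z-slice with a calibrated quadrature correction
for the thresholded edge spread; it is accurate for near-uniform
calibres but inherits the global threshold's bias on strongly tapering
shafts.

## Spine detection and photometric measurement

`detect_spines()` works at a more sensitive level than the
segmentation (a fixed fraction, default 12 %, of the shaft's peak over
background), because thin-spine heads are far dimmer than the shaft.
Protrusions are connected components standing off the shaft laterally.
Two constraints come directly from confocal physics:

* the axial PSF (σ ≈ 0.6 µm) smears the shaft into a halo along z, so
  the search is restricted to near-plane directions; protrusions
  pointing along the optical axis are unresolvable at this resolution,
  and the synthetic generator correspondingly plants spines within
  ±20° of the imaging plane (mirroring how projection-based manual
  counting sees mostly in-plane spines);
* merged neighbours are split by distinct bright cores and by
  bimodality of their shaft-surface footprint (an exact 1-D two-means
  split — deterministic, no RNG is consumed by any measurement), and
  twin heads sharing one base are re-merged so a branched spine is one
  object.

`measure_spine()` is photometric rather than mask-based: blur conserves
integrated intensity, so in-bin flux divided by the fill amplitude
gives the true in-bin structure volume regardless of PSF. The fill
amplitude is estimated per segment by combining two blur-invariant
observables — flux per unit shaft length (`A·πr²`) and blurred peak
intensity (`A·atten(r)`, with the attenuation integral computed
numerically) — and solving for both `A` and the true radius. The
radial profile of equivalent cross-section widths then yields: head
diameter (distal bulb, sized from its flux volume as a sphere — the
cube root makes this robust to binning and moderate amplitude error),
neck diameter (minimal width between shaft spill zone and head), neck
visibility (the profile must be distally dominated: a stubby bump is
widest near its base and never re-widens; a flat profile counts as
neck-bearing only when long), and head count (distinct bright cores
above the branch vertex, plus a lateral-spread check for bridged twin
heads). Local reference profiles taken at spine-free offsets along the
shaft are subtracted bin-wise to remove the shaft's own blur spill, and
voxels owned by neighbouring protrusions are masked out of the
measurement cloud.

`classify_spine()` applies the morphological rules with precedence
branched > stubby > mushroom > thin: branched means more than one
head; stubby means no visible neck or head < neck; mushroom means head
≥ 2 × neck (the boundary ratio exactly 2 is mushroom, following the
"≥ 2×" convention); thin otherwise. The classifier is a total,
deterministic function and is tested for exact agreement with an
independently coded oracle on 10⁴ random inputs.

## Plaques, puncta and intensities

Plaques are segmented with the same hysteresis scheme at a coarser
smoothing scale, filtered at an equivalent diameter of 2 µm. The
per-dendrite plaque distance is the minimum 3-D Euclidean distance from
any path point to the plaque's voxel surface (edge distance, not
centroid distance), a single scalar per segment; with no plaque present
a distinguished `NA` is returned, never 0. Binning is near = [0, 30] µm
(closed at 30), far = (30, ∞). Whether real measurements of this kind
are taken in 3-D or on a projection is often unstated; 3-D is
implemented here.

Puncta detection is a difference-of-Gaussians band-pass with a robust
threshold, volume bounds, and nearest-peak splitting of touching blobs.
Colocalisation is object-level: greedy nearest-neighbour matching of
centroids under a criterion radius (default 0.5 µm), each punctum used
at most once, reported directionally (matched query puncta over all
query puncta); an empty query set gives an undefined fraction, not 0.
Pixel-correlation coefficients are deliberately out of scope.

Intensity normalisation divides the ROI mean by a background mean
sampled from the same z-sections the ROI occupies. The default
background policy takes all voxels well clear (2.5 µm) of the supplied
object mask; a lowest-decile variant exists for cluttered fields but is
not the default because order statistics of noisy voxels are biased low
and the package's validation requires the ratio estimator to be
unbiased under the shot + read noise model.

## The synthetic generator: what it emulates

`stack_recipe()` fixes the acquisition geometry (default lateral field
61.5 µm, z-step 0.3 µm), an anisotropic Gaussian PSF (σ = 0.2 µm
lateral, 0.6 µm axial — an adequate stand-in for confocal blur at
these scales), and the standard fluorescence noise model (Poisson shot
noise plus additive Gaussian read noise). Scenes are unions of capsules
(shafts, necks, plaques, somata) and additive Gaussian blobs (puncta).
Identical recipe + seed reproduce every voxel bit-for-bit; each planted
object draws from its own sub-stream, so adding objects never perturbs
existing ones.

Spines are planted as a homogeneous Poisson process per class along the
shaft, with canonical per-class geometry (mushroom 0.95/0.34 µm
head/neck, thin 0.48/0.34, stubby 0.55 head with a wider 0.65 base and
no constriction, branched with two 0.62 µm heads splayed ±47° along the
shaft axis) and small log-normal jitter constrained so no draw crosses
a classification boundary — the planted class always equals
`classify_spine()` of the planted geometry, by construction. Three
resolvability constraints are part of the generator's contract rather
than free dials: necks must span at least two lateral pixels (coarser
recipes are rejected with a calibration error), spines sit within ±20°
of the imaging plane, and spines keep 1.5 µm clear of the segment's cut
ends, where a protrusion could not be attributed unambiguously. The
default planted rate (≈ 0.53 spines/µm, class mix 42/32/19/7 %)
emulates the in-plane-visible subset of a wild-type-like total density
of roughly 2 spines/µm.

Plaques are quasi-spherical (a core sphere plus surface bumps kept
inside the nominal radius, so the recorded radius is the true outer
envelope). Neurite fields draw smooth two-harmonic curves whose
amplitude is solved numerically for an exact path/chord tortuosity;
Homer puncta are planted along the paths with a hard-core 0.8 µm
exclusion (two synapses closer than the PSF are one object), and a
binomial fraction of Kv3.4 puncta is placed on Homer sites (at most one
per site), the rest off-synapse and clear of every Homer punctum.

The tabular generator `make_spine_table()` draws per-dendrite densities
around the supplied per-mouse means (the built-in `mouse_cohort()`
reference table of 6 wild-type and 10 transgenic mice), with optional
extra mouse-level and dendrite-level dispersion, uniform plaque
distances within each bin (near 0–30 µm; far 30–90 µm, an upper bound
chosen to keep fields realistic since nothing above 30 µm is
distinguished), and an optional within-mouse distance–density slope
applied around the bin's mean distance so cell means are preserved.
With zero dispersion it reproduces every reference mean exactly. The
reference table does not state dendrite-level variance, so the default
dispersion parameters are documented assumptions, not reference values.

## What the validation shows — and what it cannot

Every measurement is validated by round-trip recovery: detection recall
and precision ≥ 0.9 (recall on *resolvable* spines, those without a
neighbour within 1 µm; two protrusions whose blurred envelopes overlap
are a single object at this resolution and are accounted as a detection
loss, not a classification one), class recovery ≥ 90 % on spines
without a neighbour within 1.3 µm, linear density within 10 %, plaque
centroids and edge distances within one voxel, puncta recall/precision
≥ 0.9, colocalisation within ±0.05 of the planted fraction, soma
intensity ratios unbiased over 50 noise realisations, and tortuosity
within ±0.03 of target.

The generator deliberately omits neuropil clutter, astrocytes, uneven
antibody penetration, depth-dependent attenuation and sample drift.
Passing these tests therefore demonstrates that the measurement chain
is correct and well-calibrated *under the stated optical model*; it
does not certify performance on cluttered tissue, where segmentation
thresholds and the background policy are the parameters a user should
revisit first.

## The inference layer

`fit_group_model()` fits `response ~ fixed factors (fully crossed) +
(1 | mouse)` by REML and reports a Type III ANOVA with Satterthwaite
denominator degrees of freedom (fractional denominators such as
F[1, 13.06] are the signature of this approximation). Singular fits are
flagged, never silently dropped. `emm_contrasts()` gives
Tukey-corrected pairwise estimated-marginal-mean contrasts.
`rmcorr()` is implemented from the ANCOVA definition (subject as
factor, common slope); its point estimate equals the Pearson
correlation of within-subject-centred data, a fact the tests exploit as
an independent oracle at 10⁻¹⁰ tolerance, with df = N − k − 1 and a
Fisher-z confidence interval on that df. `chisq_shape_test()` runs the
uncorrected Pearson chi-square on pooled spine counts (the per-mouse
mean proportions are reported separately by `class_proportions()`,
which averages mouse proportions rather than pooling) with per-class
collapsed post hocs, Bonferroni-corrected over the number of classes
tested; whether branched spines enter the table is a flag, since usage
varies. `tukey_ladder_transform()` selects a power from the fixed
ladder (−2, −1, −½, log, ½, 1, 2) by the Shapiro–Wilk statistic of the
(optionally within-cell centred) transformed values. `ddcq()` averages
the two reference genes per sample before the calibrator comparison;
samples missing a reference well are excluded with a warning.
Multiplicity is corrected within each post hoc family only; distinct
response models (density, intensity, tortuosity) are not jointly
adjusted, mirroring common practice.

Calibration is itself part of the test suite: the treatment F test
holds its type-I error within [0.03, 0.07] over 1000 null replicates of
the reference design, detects a planted 40 % effect in well over 80 %
of replicates, and the repeated-measures correlation is centred on
zero under the null.

## Desk-scale problem sizes

All tests and the acceptance script run on reduced fields (typically
24–40 µm laterally, 5–13 µm deep, 0.15–0.3 µm pixels) with a handful
of stacks per condition and hundreds of mixed-model replicates; these
sizes were chosen so the whole validation runs in minutes on one CPU
while every structure stays comfortably resolvable under the default
PSF. The measurement code itself is size-agnostic: full-size
acquisitions differ only in runtime.
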