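---
title: "Platelet morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Platelet morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletmorph)
```

# Overview

`plateletmorph` measures the architecture of the contractile cytoskeleton in
single spread platelets from registered two-channel fluorescence images:
F-actin for segmentation and fibre statistics, vinculin for the angular
arrangement of adhesion sites. This vignette explains each stage's model and
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic phantoms do and do not emulate, and the design
decisions taken where the method leaves room.

# Segmentation from the F-actin channel

Raw images are denoised with a 3×3 median filter and min–max normalized to
[0, 1] (`preprocess()`). A constant image is flagged rather than divided by
zero.

The background model (`estimate_background()`) assumes the image is
background-dominated: a 256-bin intensity histogram is smoothed with a
5-bin moving average (zero-padded at the ends — padding with partial-window
means would inflate the edge bins and can promote a spurious first-bin
peak), and the lowest-intensity local maximum over a ±2-bin window is taken
as the background level *bg*. Its spread *sd* is the σ of a Gaussian fitted
to the raw counts within ±15 bins; if the fit fails or returns a width
outside the resolvable range (below a third of a bin or above 20 bins), a
half-width-at-half-maximum estimate (HWHM/1.177) is used instead, and the
final value is floored at one bin's equivalent σ (bin width/2.355): a peak
narrower than one histogram bin is resolution-limited, not noise-free.
Without that floor a nearly-delta background histogram yields a threshold
inside the background distribution and segmentation collapses.

Cells are pixels above *bg* + 10·*sd*. The binary mask is cleaned in the
order: opening with a disc of radius 5 px (severs thin bridges between
touching cells), removal of components below 1000 px (3.6 µm² at 60 nm
pixels; strict), restoration of the surviving components' pre-opening
pixels, filling of interior holes below 1000 px (strict; a hole is a
background component not connected to the image border), and outline
smoothing with a 7×7 median filter.

**Undoing the shrink.** Restoring pre-opening pixels by plain morphological
reconstruction would re-merge any two cells that were joined by a thin
bridge, defeating the point of the opening. `clean_and_label()` instead
propagates the surviving opened components' labels geodesically within the
original mask (`EBImage::propagate`): where one survivor sits in one
original component this is exactly reconstruction; where a bridge connected
two survivors, the bridge pixels are split between them and the two cells
stay separate.

Geometry per cell: area = pixel count × pixel size², centroid of the binary
mask, and ellipticity √(λ₁/λ₂) from the eigenvalues of the mask's second
central moment matrix — the long-to-short axis ratio of the equivalent
ellipse (1 for a disc, rotation-invariant to within rasterization error).
Cells touching the image border are flagged excluded by default
(`exclude_border`), since truncated cells bias every downstream metric; a
manual exclusion table (fov_id, cell_id) represents visual quality control.
Only cells with area strictly above 20 µm² ("fully spread") are analysed
further.

# Fibre orientation, alignment, and radial order

The per-pixel fibre orientation comes from an intensity-weighted
second-derivative (Hessian-like) tensor: the preprocessed image is filtered
with the three second-order 5×5 Sobel kernels — separable products of the
smoothing stencil [1 4 6 4 1] with the second-difference [1 0 −2 0 1]
(S_xx, S_yy) and of the first-difference [−1 −2 0 2 1] with itself (S_xy).
Each response is multiplied pixelwise by the smoothed intensity (the only
smoothing defined at this point is the preprocessed image itself, which is
therefore the weight) and Gaussian-blurred with σ = 4 px. The axial angle
is φ = ½·atan2(2 I_xy, I_xx − I_yy).

**Sign convention.** For a bright ridge the blurred, intensity-weighted
Hessian is negative along the stripe normal, which flips the tensor's
orientation relative to the unweighted case. The denominator order
I_xx − I_yy is the one that returns φ = θ on gratings of known angle θ in
this package's row/column convention; this was fixed once by a grating
calibration and is locked in by tests (sub-degree agreement at 0°, 30°,
45°, 60°, 75°, 90°). Degenerate pixels (both tensor components ≈ 0) get
φ = 0 and a low-confidence flag.

The fibre mask selects ridge-like pixels: unsharp masking
(img − gaussian(img, σ), negatives clipped) at σ = 3, 5, 7, 9 px, summed,
3×3-median-denoised, renormalized to [0, 1] and thresholded at 0.08.
Because the threshold applies to the renormalized enhanced image, the mask
is invariant to global intensity gain.

**Axial statistics.** Fibre orientations are axial (φ and φ + π are the
same fibre), so all circular statistics run in doubled-angle space: the
mean orientation is φ₀ = ½·arg(Σ w·e^{2iφ}/Σ w) and the alignment order
parameter S = Σ w·cos 2(φ − φ₀)/Σ w equals the resultant length
|Σ w·e^{2iφ}|/Σ w. This form reproduces the stated limits exactly: S = 1
when all weighted angles coincide and S → 0 for uniformly random
orientations. A single-angle mean arg(Σ w·e^{iφ}) is ill-defined for axial
data (φ and φ + π cancel instead of reinforcing), which is why the package
uses the doubled-angle form throughout.

**Radial order.** With ψ the direction from the cell centroid to the
pixel, the per-pixel score is s = ½·cos 2(φ − ψ) + ½ and the cell value is
the intensity-weighted mean over the fibre mask (the centroid pixel, where
ψ is undefined, is excluded). The doubled angle is again what makes the
anchors exact: rings (φ ⊥ ψ) score 0, stars (φ ∥ ψ) score 1, and a 45°
spiral scores 0.5. The historical single-angle form ½·cos(φ − ψ) + ½
cannot reach 0 for rings under axial angles — it is stuck at 0.5 — and is
available behind `literal_radial = TRUE` for comparison only; a unit test
demonstrates the difference on an exact ring field.

Both metrics are weight-ratio statistics and therefore invariant to global
intensity scaling; S is rotation-invariant and radial order is invariant to
rotations about the centroid.

# Circumferential vinculin analysis

The cell mask is divided into 20 angular sectors of 18° about the centroid
(sector k covers [18k°, 18(k+1)°), counter-clockwise from +x). Vinculin
intensities are summed per sector, divided by their total and multiplied
by 20, giving a mean-1 profile. The profile is least-squares fitted at the
sector-centre angles with Y(α) = 1 + Σₖ₌₁⁴ aₖ cos kα + bₖ sin kα (constant
fixed at 1; 8 unknowns, 20 equations). On the uniform sector grid the
harmonics are orthogonal, so pure-harmonic profiles are recovered to
machine precision; wₖ = √(aₖ² + bₖ²) is rotation-invariant.

The morphology point uses r = max(Y) − 1.25 with the maximum taken over
the fitted continuous curve on a 1° grid (the fit precedes the maximum in
the method's definition; the 1° step contributes < 10⁻³ discretization in
r), and the angle φ = arg(x_w + i·y_w) with x_w = √3/2·(w₃ − w₂),
y_w = w₄ − ½(w₂ + w₃), so pure 2nd/3rd/4th-order profiles sit at exactly
210°/330°/90°. Cells with r < 0.33 are isotropic; otherwise classes occupy
120°-wide sectors centred on those three directions — the boundaries
(30°, 150°, 270°) are placed midway between the pure-component directions,
the natural choice when only the sector names and the isotropic circle are
given. For a pure profile 1 + a·cos kα the class switches from isotropic
exactly at a = 0.58 (r = 0.33). w₁ is computed and reported but plays no
role in classification, which uses orders 2–4 only. Deeply isotropic cells
(negative r) are plotted at the origin; their class is unaffected.

Populations are summarised on a [−1, 1]² grid with 0.02 bins, smoothed
with a Gaussian of σ = 2 bins (the smoothing scale is not prescribed by
the method; 2 bins = 0.04 morphology units is wide enough to merge
per-cell dots into population modes and narrow enough to keep the three
pure-class modes separate — it is exposed as `map_sigma_bins`), and
max-normalized. Two maps are compared by the zero-lag normalized
cross-correlation Σ A·B/√(Σ A²·Σ B²) — a cosine similarity, 1 for
identical maps and 0 for disjoint support; the method names this score
but does not define it, and the zero-lag cosine form is the simplest
normalized variant. The representative cell of a population is the cell
whose morphology point lies nearest the global map maximum, with ties
broken towards the smallest cell id so the choice is reproducible under
input reordering.

# Statistics

Group comparisons use the tie-corrected Kruskal–Wallis rank test with
Scheffé-type post-hoc contrasts on rank means: for groups i, j the
statistic (R̄ᵢ − R̄ⱼ)²/(S²(1/nᵢ + 1/nⱼ)), with S² the tie-corrected variance
of the pooled ranks, is referred to χ² with k − 1 degrees of freedom —
the classical simultaneous-contrast analogue for ranks, chosen because the
method names Scheffé post-hoc testing without defining it. The default
significance threshold is 10⁻⁴ (configurable). If every observation is
tied the comparison is flagged degenerate instead of returning a number.

Reproducibility between samples is reported as the mean absolute pairwise
difference of the per-sample means per metric (the "mean difference"
wording could also mean differences to the grand mean; the pairwise
reading is implemented and documented here), the coefficient of variation
of the sample means, and the mean pairwise CC^morph of the samples'
morphology maps.

Dose–response data are fitted with the four-parameter logistic Hill model
y = bottom + (top − bottom)/(1 + (x/IC₅₀)^h), parameterised in log-dose so
IC₅₀ stays positive, by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Initial values: top/bottom from the mean responses
at the extreme doses, IC₅₀ from the dose nearest the half-range response,
h = 1. Confidence intervals are percentile intervals from a nonparametric
case-resampling bootstrap (1000 resamples, seeded, refits started at the
point estimate). The fit is scale-equivariant in dose, and at x = IC₅₀ the
fitted curve passes through (top + bottom)/2 by construction.

# The synthetic phantoms

`make_fov()` renders what the analysis needs to be true of its inputs, with
exactly known ground truth: a dark background (5 % of the dynamic range)
with additive Gaussian noise (σ = 0.005), elliptical cells with a
ridge-stripe actin texture (raised-cosine stripes, period 8 px) following
one of five orientation laws — parallel(θ), radial spokes, concentric
rings, a constant-pitch logarithmic spiral (level curves everywhere at the
pitch angle to the radius), or block-random — and rim-located vinculin
puncta (Gaussian, σ = 2 px, at 0.72/0.84 of the local rim radius) whose
20-sector integrated profile follows 1 + a·cos(kα − α₀).

Cell rendering is deliberately constrained so that the ground-truth
orientation statistics are not contaminated by structures that are not
fibres:

- the texture is a **zero-mean modulation about a flat mean level**
  (0.55): a mean-intensity gradient inside the cell adds its own radially
  oriented curvature to the orientation tensor and measurably rotates
  angles wherever it overlaps the texture — the 45° spiral, whose radial
  order is first-order sensitive to angular bias, is the pattern that
  exposes this;
- the mean **dims towards the rim** (to 0.27 from 82 % of the semi-axis
  outwards, lamellipodium-like), keeping the weight of boundary pixels
  low;
- the boundary step is **sharp (2 px)**, confining the edge's tangential
  tensor signature to the σ = 4 px blur depth instead of spreading it;
- the centre is a **non-fibrous flat plateau** (35 % of the semi-axes,
  granulomere-like), where the centre-symmetric patterns would otherwise
  alias (spoke spacing and spiral wavelength shrink towards the centre);
- the spoke/spiral wavenumber is anchored near the rim (wavelength ≈ the
  stripe period at 90 % of the cell radius), where most of the
  intensity-weighted mass lives.

Texture troughs stay at ≥ 0.13, above the segmentation threshold, so masks
come out solid. With these choices the pipeline reads back alignment
≈ 1 on parallel phantoms and radial order ≈ 1/0/0.5 on star/ring/spiral
phantoms to within 0.02, as the acceptance suite verifies.

The vinculin puncta sit at the 20 sector-centre angles with amplitudes
solved, not prescribed: a punctum's in-mask per-sector mass is measured
from a unit render and amplitudes are corrected by a short fixed-point
loop; then, because the analysis preprocesses the channel (median +
min–max normalization subtly shifts the effective diffuse background), the
whole channel is rendered, preprocessed, its sector profile measured
against the target, and the targets corrected twice more. This closes the
loop on the stated contract — the *total* circumferential profile a sector
analysis sees follows 1 + a·cos(kα) — rather than on the puncta alone;
without the background compensation the diffuse vinculin background
dilutes the recovered amplitude by several percent, which matters because
a planted amplitude of 0.6 sits only 0.02 above the isotropic switch.

What the phantoms do **not** emulate: optics (no point-spread function;
ridges are rendered, not imaged), camera noise beyond additive Gaussian,
fibre crossings and partial bundles, cell-to-cell intensity variation,
clumped or touching cells, and out-of-focus light. Passing tests on
phantoms therefore validate the measurement chain — segmentation, tensor
orientation, sector Fourier analysis, classification, statistics — on
images whose answer is known; they do not certify biological accuracy on
any particular microscope's data.

# Numerical choices

- All convolutions use reflective padding; median filters operate on
  [0, 1]-scaled images.
- Angles are radians internally, degrees in outputs; orientation maps live
  on [−π/2, π/2).
- Coordinates in all tables are 1-based pixel indices (x = column,
  y = row), R's native convention.
- The orientation tensor's degenerate pixels (no directional information)
  are set to φ = 0 and flagged rather than dropped, but carry no weight in
  practice because their intensity is low.
- Empty fibre masks make alignment/radial order `NA` with a flag — never
  silently 0, which is a valid measured value.
- Problem sizes in the tests are chosen to exercise the asymptotics while
  staying desk-sized: single-cell phantoms use discs of radius 100 px in
  288² images (the radial-order anchors sharpen with cell size, since the
  rim band's weight share scales as 1/r); the end-to-end screen uses 60
  cells of radius ≈ 50 px (≈ 28 µm², platelet-like) across four 640²
  fields; the Kruskal–Wallis calibration uses 10⁴ null replicates of
  3 × 50; Hill coverage uses 200 simulations with 1000-resample
  bootstraps.

# Known limitations

- The orientation estimator is ridge-based; on textures whose local
  wavelength approaches 2 px (aliasing) or far exceeds the unsharp scales
  (no ridge contrast), the fibre mask thins and the metrics lose support.
- Pixels near a cell's boundary mix fibre and edge signatures within the
  σ = 4 px tensor blur; in real images the same happens at the
  lamellipodium. The radial-order anchors are met at radius 100 px; much
  smaller cells shift rim-sensitive patterns by a few hundredths.
- The histogram background model assumes a dominant background population;
  fields that are mostly cell will fail it (the error names the FOV and
  the batch runner continues).
- Scheffé-on-ranks is conservative (as simultaneous contrasts are); the
  overall Kruskal–Wallis p and the pairwise matrix are both reported so
  users can see the difference.
- The bootstrap CI for the Hill fit is percentile-based; with very few
  dose levels or a response that does not span the transition the fit is
  refused rather than returned unidentifiable.
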