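---
title: "Grading tuber shape by ellipse-fit similarity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading tuber shape by ellipse-fit similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubershape)
```

## The problem and the model

Shape is a primary external-quality attribute of potatoes: lobed, knobby, or
otherwise malformed tubers ("not conforming to the original morphological
characteristics of the variety") depress the value of a lot and should be
sorted out. `tubershape` implements a training-free vision method built on a
single observation: a regular tuber silhouette is close to an ellipse, and an
irregular one is not. The silhouette's contour is fitted to an ellipse, and
the *dissimilarity* between contour and fit is the irregularity score.

Two of the four features computed carry the decision signal:

* the **bidirectional Hausdorff distance** `H(P, Q)` between the sampled
  fitted-ellipse boundary `P` and the contour points `Q` — the largest
  distance from any point of either set to the other set. It captures the
  worst local mismatch (a single lobe) regardless of how well the rest of
  the outline fits.
* the **IoU** of the filled contour region and filled ellipse region — a
  global area-overlap score in [0, 1].

The perimeter ratio `C` and area ratio `A` are computed and reported as
well, but both compress the whole outline into one global number; shapes
with compensating protrusions and indentations can score near 1 on both, so
they are not used for thresholding.

Decision rule (at the 614 × 410 working extents): `H > 21` px → irregular,
`H ≤ 21` → regular; `IoU ≤ 0.925` → irregular, `IoU > 0.925` → regular.
The boundary cases follow the published identification standard exactly
(21 is regular; 0.925 is irregular). A combined mode labels irregular when
*either* feature votes irregular; this OR rule is this package's extension
(a sorting line prefers discarding a doubtful tuber), not part of the
original standard, which evaluates the two features separately.

### Multi-view aggregation

A top-down camera cannot see a lobe hidden underneath. When several views
of one tuber are available, `aggregate_views()` takes the **maximum** `H`
and the **minimum** IoU across views, so irregularity visible from any
angle wins. `C` and `A` are carried from the `H`-maximizing view — they are
reported, not thresholded, so any consistent choice works; tying them to
the worst view keeps the aggregate internally consistent.

## Preprocessing chain and its parameters

`preprocess_pipeline()` converts a raw capture to a clean centered mask:

1. **Resize** to the reference extents 614 × 410 by *region (area)
   interpolation*: each output pixel is the exact fractional-overlap
   weighted mean of the source region it covers (implemented with sparse
   weight matrices). Area interpolation is the correct anti-aliasing choice
   for 5× downscaling; a 3072 × 2048 capture at factor 0.2 lands exactly on
   614 × 410 with round-to-nearest extents. The resize primitive itself
   accepts any extents from 2 px up; the ≥ 8 px sanity floor applies at the
   pipeline entry, where real captures arrive.
2. **Graying** by the conventional luma weights 0.299/0.587/0.114 (the
   standard "weighted average" choice; the weights barely matter for a
   yellow-brown object on a black board).
3. **Otsu segmentation**: the threshold maximizing between-class variance of
   the 256-bin histogram; foreground is the brighter side by default
   (`polarity = "dark"` flips this for light-background rigs).
4. **Morphological opening then closing** with a disc of radius 2 px (5 × 5
   element): removes specks smaller than the element and fills pinholes.
   The kernel size is a configuration default chosen at the scale of sensor
   noise, an order of magnitude below the ~100 px object radius.
5. **Binary majority (median) smoothing**, window 5 px: smooths staircase
   edges. Windows are clipped at the border; an exact tie keeps the
   original pixel (which makes the filter stable under repetition). Both
   cleanup stages are near-idempotent: a second application changes well
   under 0.5% of pixels.
6. **Largest connected component**, then **centering**: the centroid is
   moved to the canvas center by an integer shift (foreground count
   preserved exactly). A shape that cannot be centered clear of the border
   is rejected — contour tracing needs background all around.

Every stage failure is re-signalled with the stage name attached, so batch
runs can report *where* an image failed.

## Contour, fit, and features: numerical choices

**Contour.** Moore boundary tracing of the binary mask yields the ordered
outer boundary; on a clean binary image this is the same pixel set an edge
detector would find, without hysteresis parameters. The polygon is
canonicalized — counter-clockwise (positive shoelace in (x, y)), starting
at the topmost-then-leftmost pixel — so contours are comparable across
calls. Coordinates are 0-based, (x right, y down), pixel centers at
integers.

**Ellipse fit.** The direct least-squares conic fit constrained by
`4AC − B² = 1` (Fitzgibbon), solved with the Halir–Flusser block
decomposition after mean-centering the points for conditioning. The
constraint makes the minimizer an ellipse by construction — important on
lobed contours where an unconstrained conic fit can drift to a hyperbola.
Noiseless elliptical inputs are recovered to ~1e-9 relative; under 1 px
isotropic noise on 200 points, the median axis error stays within 2%.
Sensitivity to outliers is handled upstream: the fit only ever sees a
filtered, single-component contour, so no robust/RANSAC machinery is used.

**Ellipse boundary set `P`.** Parametric samples at ≤ 1 px spacing
(`N ≥ perimeter / spacing`), so the point-set discretization contributes
less than a pixel to `H` — far below the 21 px threshold scale.

**Perimeters.** The ellipse perimeter uses Ramanujan's second
approximation (relative error < 1e-4 at the aspect ratios of tubers, < 1e-9
near circles), which is sampling-independent. The contour perimeter in the
ratio `C` uses the Kulpa-corrected digital length (0.948 × chain length)
when the contour is an 8-connected pixel chain: a raw polygon through chain
pixels converges to ~1.05 × the smooth boundary length (staircase effect),
and the correction restores `C → 1` on rasterized ellipses. Continuous
polygons (e.g., parametric samples) are measured exactly;
`polygon_perimeter()` itself is always exact polygon geometry.

**Rasterization.** Region operands of the IoU are filled with a scanline
even-odd rule at pixel centers, boundary pixels included (an axis-aligned
square with corners (0,0)–(10,10) covers all 121 lattice points); the
ellipse region contains the pixels whose centers satisfy the implicit
inequality. Both rasterizers are tested against per-pixel brute-force
oracles, and the Hausdorff implementation must equal a double-loop oracle
*exactly*, not approximately.

**Degenerate inputs** are errors with typed condition classes: empty masks,
single-intensity images (no Otsu threshold), collinear or < 5 fit points,
non-ellipse conics, border-touching foreground, out-of-canvas geometry.
Metric computations never divide by zero: evaluation metrics with empty
denominators return `NA` markers instead.

## The synthetic generator: what it emulates, what it does not

No public image set of graded irregular tubers exists, so validation runs
on a generator that emulates the capture geometry the thresholds assume: a
bright convex-ish blob on a near-black board, nominally captured at
3072 × 2048 and worked at 614 × 410.

Shapes are star-convex radial profiles about the object center:

```
r(phi) = r_ellipse(phi) * (1 + amplitude * cos(k * phi + phase)) + jitter(phi)
```

with `r_ellipse` the polar form of a base ellipse, one cosine lobe term of
order `k`, and `jitter` a seeded sum of order-8–13 harmonics with a given
radial RMS (sub-pixel by default) standing in for natural boundary
roughness. The analytic interior is the ground-truth mask, so segmentation
accuracy is measurable exactly (pipeline masks agree with truth on > 99% of
pixels). Photometry: object channels near (208, 186, 112) (gray level
~187), background near 30, Gaussian noise σ = 8 — strongly bimodal, as on
a black grading board under even lighting, which is the regime Otsu's
threshold assumes.

Dataset draws: semi-major axis `a ~ U[80, 140]` px (matching ~100–200 px
object diameters at working resolution), aspect `b/a ~ U[0.55, 0.95]`
(round-like through oval), rotation uniform, center jitter ±10 px.
Irregular samples get 4–6 lobes with relative amplitude `U[0.22, 0.42]`;
regular samples have amplitude 0. The amplitude range was calibrated once
against the fixed thresholds and frozen: the lobe deviation from the fitted
ellipse is roughly `amplitude × a`, so amplitudes ≥ 0.22 place nearly all
irregular draws above the 21 px Hausdorff threshold while amplitude-0
regular draws sit at `H ≈ 1–3` px and IoU ≈ 0.97–0.99. The severity mix of
real irregular tubers ("slightly" vs "severely" irregular) is unquantified
in the grading literature; the amplitude range is this package's proxy
for it.

What passing synthetic tests does **not** show: robustness to shadows,
specular highlights, soil, multi-object frames, or varietal shape
distributions — the generator has none of these. The thresholds themselves
are variety-dependent in practice; the defaults encode the published
operating point, and both thresholds live in configuration.

### Resolution coupling

`H` is a length in pixels, so it scales with the canvas: doubling the
extents doubles `H` within rasterization error (±2 px, verified on 20
shapes). The 21 px threshold is therefore enforced as valid *only* at
614 × 410 — the pipeline resizes every capture there — while the IoU
threshold, being dimensionless, is resolution-independent.

## Problem sizes used in validation

The shipped suites run: the 148-count published confusion matrices
(reproduced to 4 decimals); 50 random point-set pairs (up to 500 × 500) for
exact Hausdorff oracle equality; 100 noisy-fit seeds; 100 metric-axiom
triples; a 200-sample end-to-end synthetic set (100 regular / 100
irregular, F1 ≥ 0.95 in each single-feature mode); 60 single-sample
regular-class runs (≥ 98% pass rate); and 20 scale-covariance shapes.
`scripts/acceptance.R` re-renders a 148-sample validation set (98 regular /
50 irregular, the published class sizes) from a caller-supplied seed.
These sizes were chosen to estimate each property stably on a single CPU;
larger sets change none of the conclusions, only the runtimes.

## Known limitations

* Single-object frames only; the largest component wins and everything else
  is treated as noise.
* Star-convex generator shapes cannot represent folds or self-occluding
  lobes; real severely-deformed tubers can.
* The Kulpa perimeter correction assumes 8-connected chains from the
  package's own tracer; contours imported from other tools with different
  connectivity are measured as raw polygons.
* Thresholds are an operating point for one variety and one rig; treat
  them as configuration, not constants of nature.
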