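---
title: "Thresholding from boundary gradients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholding from boundary gradients: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradseg)
```

## The model

Thresholding assigns each pixel of a greyscale image $I$ to foreground
(the *phase*) or background. The premise of this package is that at the
correct threshold the *boundary of the phase* coincides with the strongest
gradients of $I$: objects and background differ in intensity, so the true
object outline is where local contrast peaks.

Both methods start from a gradient image $G$. The default is the Beucher
morphological gradient $(I \oplus A) - (I \ominus A)$ with the $3\times3$
square structuring element $A$; the Sobel magnitude is available as an
alternative and, on smooth images, nearly indistinguishable. For every
candidate level $L$ from the image minimum to maximum, the phase
$B(L)$ (pixels $\le L$ for dark objects; $\ge L$ for bright ones) and its
internal boundary $E(L) = B(L) - (B(L) \ominus A)$ are formed, and the
sweep records $N(L) = |E(L)|$,
$G_{\mathrm{Total}}(L) = \sum_{p \in E(L)} G(p)$ and
$G_{\mathrm{Average}}(L) = G_{\mathrm{Total}}(L)/N(L)$.

The **global** method (`findOptimalThreshold()`) returns the level
maximising one statistic. Curves are typically smooth with one dominant
maximum; secondary local maxima (`findThresholdMaxima()`) correspond to
alternative or additional thresholds — in a three-tone image (dark nuclei
inside darker-than-background cytoplasm) the two maxima of
$G_{\mathrm{Average}}$ segment nuclei and whole cells respectively.

The **region-based** method scores every 8-connected component $c$ of
$E(L)$ separately with $G_{\mathrm{Average}}(L, c)$, labels the component's
pixels with that score, and stores the labelled slice in a stack $S$
indexed by $L$. The maximum projection $P$ of $S$ is a simplified gradient:
each object's optimal boundary is a homogeneous plateau strictly above the
rings produced by non-optimal levels. Its regional maxima — connected
constant-value plateaus all of whose exterior 8-neighbours are strictly
lower — followed by binary filling produce the final regions, each
effectively thresholded at its own level. This makes the method adaptive
*per region* rather than per local window, so it copes with objects of
different intensity and with uneven illumination.

An **object specification** (minimum circularity $4\pi A / P^2$ and an
inclusive area range) may be applied *while the stack is built*: a
component enters $S$ only if its filled region passes. Filtering during
detection, rather than after it, removes implausible high-contrast
distractors before they can dominate the projection.

## Assumptions

* Objects are approximately uniform in intensity relative to their local
  background, with resolvable edges; the phase boundary at the correct
  level then falls on the gradient crest.
* Objects of interest are simply connected ("child" regions inside holes
  are not preserved by the binary fill — see Limitations).
* For the region method with specification, objects are roughly convex and
  within a known size band.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `polarity` | `dark` | search $[L_{\min}, L]$ (dark objects) or $[L, L_{\max}]$ |
| `gradientMethod` | `beucher` | $3\times3$ morphological gradient; `sobel` optional |
| `statistic` | `average` | curve statistic; `total` weighs long boundaries more |
| `gaussRadius` | 0 | Gaussian presmoothing sigma in px; 1 is typical for noisy acquisitions |
| `spec` | none | `objectSpec(0.5, 250, 3000)` is the nuclei operating range at ~0.3 µm/px; scale areas to your magnification |
| `mode` | `cumulative` | memory-efficient running maximum; `stack` materialises slices — both are bit-identical |
| `minProminence` | 0 | peak-height filter for multi-threshold detection |

The search always covers every integer level in the image's grey range; no
subsampling is offered, because the exhaustive sweep is what makes the
method deterministic and its output reproducible.

## Numerical choices

* **Border padding.** Greyscale morphology and convolution use replicate
  padding. Binary erosion treats outside-image as background, so a phase
  touching the frame acquires frame-edge boundary pixels and $E(L)$ stays
  a closed curve that the fill step can close. Frame-touching regions are
  flagged (`touches_border`) so a "no borders" analysis can drop them.
* **Inclusive thresholds.** Foreground is $0..L$ inclusive for dark
  polarity; ties at equal statistic values break toward the smallest
  level, making results deterministic.
* **Exact scores.** Component scores and the projection are kept in full
  floating precision (no quantisation to image bit depth). A component's
  pixels all carry exactly the same score, so plateau equality in the
  regional-maxima test uses exact comparison safely.
* **Provenance.** When the running maximum is updated, the winning level
  is recorded per pixel (lower level wins exact ties). This does not
  change the output mask; it is diagnostic metadata that lets each final
  region report the grey level at which it was segmented.
* **Degenerate inputs.** $G_{\mathrm{Average}}$ is defined 0 where
  $N(L) = 0$ and such levels are excluded from the search; a constant
  projection is vacuously one plateau, and `segmentRegions()` returns an
  empty result when no boundary is ever scored.
* **Perimeter estimator.** Circularity needs a perimeter. The package
  walks the outer 8-connected contour (Moore neighbour tracing) counting
  1 per axial and $\sqrt2$ per diagonal step; a single pixel is assigned
  4, and circularity is capped at 1. This estimator makes a 10×10 square
  measure exactly 36 and digital disks land within ~5% of $2\pi r$. It
  overestimates smooth curves by 3–5%, so disk circularities plateau near
  0.9 rather than 1; the admission bounds (0.4–0.5) sit far from this
  bias, but absolute circularities near a cut-off can shift slightly under
  a different estimator.

## The synthetic scenes

Real micrographs of the kind the method targets are not shipped; a
deterministic generator stands in. `generateScene()` emulates
haematoxylin-like fields: non-overlapping random ellipses (default 20,
semi-axes 8–16 px, per-object intensity 50–120) on a brighter background
(200), optionally under a linear illumination ramp (e.g. ±40 across the
field), blurred with a Gaussian of sigma 1 to create realistic gradient
skirts, plus seeded additive Gaussian noise. `threeToneScene()` nests
nuclei (tone 60) inside cytoplasm (140) on background (220) for
multi-threshold tests. Gold truth is the ideal pre-blur mask, so a Jaccard
of exactly 1 is unattainable by design; evaluation thresholds of 0.9–0.95
absorb the blur skirt.

What the scenes deliberately do **not** model: texture inside nuclei and
background, chromatic aberration and colour deconvolution artefacts,
clumped/touching nuclei, and out-of-focus fields. Passing tests therefore
demonstrate correctness of the algorithms under controlled contrast,
illumination and noise — not performance on arbitrary real specimens.

Problem sizes throughout the tests and the acceptance script are 96–256 px
square fields with 2–20 objects, and the noise experiment averages 5 noise
realisations per standard deviation at 0, 4, 8 and 15 grey levels — small
enough to run interactively, large enough that every code path (component
labelling, specification filtering, projection, regional maxima, fill,
matching) is exercised at realistic object counts.

## Design decisions on open points

* **Boundary connectivity is 8.** Regions are 8-connected; a thin diagonal
  boundary stays connected under 8-neighbours but fragments under 4, which
  would split one object's boundary into several scored components.
* **Matching rule.** Gold-to-test pairing is by greatest pixel overlap,
  one test region per gold object, ties by larger Jaccard then smaller
  region id; unmatched gold objects contribute 0 to the mean, so missed
  objects are penalised. This is the simplest deterministic rule; the
  report retains per-pair values so other aggregations can be computed.
* **Noise ordering.** In `noiseSweep()` noise is added to the raw image
  first and any Gaussian preprocessing runs afterwards, mirroring the
  evaluation of a noisy acquisition by a fixed pipeline.
* **Specification measures the filled region.** Circularity/area are
  evaluated on the filled region corresponding to a boundary component,
  using the same fill rule as the output stage, so admission and output
  geometry agree.
* **Equal-score ties across levels.** If two levels give a pixel exactly
  equal scores the lower level wins provenance and the projection value is
  unchanged. Touching objects whose boundaries tie exactly in score would
  merge into one plateau; with floating-point scores this is a measure-zero
  event on real data.

## Known limitations

* **Outward half-pixel bias of the global argmax on sharp edges.** On
  synthetic scenes with narrow (sigma 1) edge skirts, the level maximising
  either statistic sits slightly *outside* the ideal object extent: the
  internal boundary of the slightly dilated phase lies on the gradient
  crest, whereas the mask-faithful boundary lies on the crest's inner
  flank. The resulting masks are dilated by roughly 0.3–0.5 px
  (object-matched Jaccard ≈ 0.93 instead of ≥ 0.95 at radii 8–16 px), and
  $G_{\mathrm{Total}}$ is more biased than $G_{\mathrm{Average}}$. The
  mask-faithful level shows up as the *second* local maximum of
  $G_{\mathrm{Average}}$ — consistent with the original account of the
  method, which also picked a secondary maximum for nuclei. The
  region-based method inherits the same sub-pixel dilation but remains
  above 0.9 because per-object levels absorb intensity variation.
* **Child regions.** The binary fill keeps no holes: nested boundaries
  collapse into one solid region. Objects with internal structure that
  must survive (e.g. nucleoli as separate phases) need a hole-preserving
  fill, which is out of scope here.
* **Clumped objects.** A high circularity bound rejects clusters of
  touching nuclei early (a cluster is bigger and less circular than its
  members); the generator enforces non-overlap, so this failure mode is
  documented rather than simulated.
* **Touching objects with different scores** can fail the strict
  regional-maxima test (neither boundary is surrounded by strictly lower
  values on the shared side); the object specification usually resolves
  this in practice.
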