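---
title: "Quantifying organelle morphology and carrier dynamics in image-based screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle morphology and carrier dynamics in image-based screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgscreen)
library(tibble)
```

orgscreen quantifies two families of phenotypes from fluorescence
microscopy of perturbation screens: the spatial organisation of organelle
fragments in fixed cells, and the motility and morphology of membrane
transport carriers in live-cell time-lapse videos. This vignette explains
the models behind each stage, the parameters that matter, and what the
synthetic-data validation does and does not establish.

## The polar distribution score

The central statistic is the **polar distribution score (PDS)**, a per-cell
measure of how anisotropically organelle fragments surround the cell
centre. The procedure, implemented in `pds_for_cell()`:

1. Convert fragment centroids to polar angles about the cell centre,
   $\theta_i = \mathrm{atan2}(y_i - c_y,\, x_i - c_x)$. Radii are
   discarded — the score is purely angular, which makes it exactly
   invariant to radial rescaling of the fragment set.
2. Rotate all angles so their circular mean (the direction of the resultant
   vector, $\mathrm{atan2}(\overline{\sin\theta}, \overline{\cos\theta})$)
   is zero. This makes the score invariant to the cell's orientation in
   the image.
3. Bin the rotated angles into $K = 8$ equal sectors covering
   $(-\pi, \pi]$ and take frequencies $f_k$.
4. Score $= \sum_k |f_k - 1/K| \in [0,\, 2(1 - 1/K)] = [0, 1.75]$.

A uniform ring of fragments scores 0; all fragments in one sector score
1.75. Per-treatment means are normalized to the negative (non-silencing)
control, so normalized values below 1 read as "dispersed relative to
control" and above 1 as "compacted".

### Conventions and numerical choices

- **Centre.** The cell-mask centroid is the default centre for the polar
  conversion; the nucleus centroid is available via
  `pds_by_cell(center = "nucleus")`. The cell centroid needs no nuclear
  channel and treats the cell outline as the natural frame for "dividing
  the cell into sectors"; on our synthetic geometry the two choices give
  very similar scores because nuclei sit near cell centres.
- **Circular mean.** "Zero mean angle" uses the resultant-vector circular
  mean; an arithmetic mean of wrapped angles depends on the wrap point and
  is rejected. When the resultant length is numerically zero (e.g. two
  antipodal fragments) the mean direction is undefined: the convention is
  mean = 0 with a `degenerate` flag, and flagged cells are kept in
  downstream summaries (their score is well defined; only its sector
  alignment is arbitrary).
- **Bin edges.** Sectors are half-open intervals $[e_k, e_{k+1})$ anchored
  at $-\pi$; an angle exactly on an interior edge joins the sector above
  it, and the top edge $\pi$ wraps into the first sector (consistent with
  $\pi \equiv -\pi$).
- **Weighting.** Each fragment counts once, regardless of area or
  brightness — the histogram is of fragment *frequencies*.
- **Saturation at high concentration.** Because $0$ is itself a bin edge,
  a continuous cluster of angles rotated to zero mean straddles the two
  sectors adjacent to $0$: a very tight (but jittered) cluster therefore
  scores $\approx 1.5$ ($f \approx (\tfrac12, \tfrac12)$ in two adjacent
  bins) rather than the analytic maximum. The maximum 1.75 is attained
  when all fragments genuinely share one sector — e.g. identical angles,
  or any skewed set whose zero-mean residuals stay within one sector. In
  practice this only compresses the top of the scale; the score remains
  monotone in angular concentration, which is what screen ranking uses.
- **Zero-fragment cells** cannot be scored and are skipped with a message;
  a fragment exactly at the centre has no defined angle and is dropped
  with a warning.

## Synthetic scenes and what they emulate

`generate_cell_scene()` builds multi-channel images of HeLa-like cells with
exact ground truth, so every downstream stage can be validated against
known answers rather than hand annotation.

- **Cells** are star-convex perturbed ellipses (default radius 8 µm) with
  one off-centre elliptical nucleus (radius ≈ 1/3 of the cell, offset
  ≈ 0.35 radius in a random direction), placed without overlap on a
  jittered random layout; placement failure after bounded retries is an
  explicit error, never silent truncation.
- **Fragments** are discs whose polar angles about the cell centre follow
  a wrapped-normal distribution with standard deviation
  $1/\sqrt{\kappa}$ about the nucleus→cell-centroid axis (the
  juxtanuclear direction). $\kappa$ is the single dispersion knob:
  $\kappa = 0$ is the uniform circular distribution (fully dispersed
  phenotype), large $\kappa$ collapses all fragments onto the reference
  direction (intact juxtanuclear organelle). Radial positions are uniform
  in `radial_range` (default 1.5–4.5 µm). An optional `min_separation`
  enforces a pairwise distance between fragment centres, guaranteeing
  optically resolvable objects for detection benchmarks.
- **Puncta** (endosome/lysosome-like) are uniformly positioned discs with
  controllable count and intensity.
- **Rendering** draws solid shapes, convolves with a Gaussian PSF
  (default σ = 0.15 µm) and adds a constant background; read noise is
  additive Gaussian applied after rendering (off by default). Blur
  conserves integrated intensity away from borders, which the tests
  exploit as a conservation check.
- **Calibration** defaults to 0.1 µm/pixel and 1 s/frame: a 2 µm tubule
  spans 20 pixels and a one-minute video is 60 frames. These are not
  derived from any specific instrument; they are chosen so the default
  geometry is comfortably resolvable.

`generate_timelapse()` renders point-like and tubular carriers moving at
programmed speeds along straight or random-walk paths, recording exact
sub-pixel truth positions per frame. A carrier leaving the field of view
has its track truncated and flagged, not errored.

**What passing on synthetic data does not show.** The generator has no
photobleaching, stage drift, shot noise (optional Poisson noise is not
implemented), uneven illumination, 3D structure, or cell-to-cell contact;
cells are convex and isolated. Validation here establishes that the
*measurement chain is correct when its assumptions hold* — it does not
certify segmentation accuracy on crowded, textured real images, which is
why every scorer also accepts ground-truth masks as a bypass and why the
segmentation layer is deliberately conventional and replaceable.

## Segmentation

The segmentation layer re-implements the standard high-content recipe:

- `segment_nuclei()`: Otsu (or fixed) threshold, hole filling, 4-connected
  labelling, size filter; optional distance-transform watershed declumping
  for touching nuclei.
- `segment_cells()`: seeded propagation of nucleus labels through the
  thresholded cell-body channel, so each cell contains exactly one nucleus
  and cells partition the foreground. Border-touching cells are excluded
  by default (standard practice, since their features are truncated).
  A nucleus with no detectable cytoplasm is discarded with a warning.
- `detect_fragments()`: per-cell robust threshold at
  median + $k\cdot$MAD (default $k = 3$) with a floor of 10% of the
  cell's above-median intensity range; 4-connected components;
  `min_area_px` = 4 size filter. The floor matters for clean images: with
  zero noise the MAD is 0 and a bare MAD threshold would sit inside the
  PSF tails, fusing neighbouring fragments into single components.
  Centroids are intensity-weighted after subtracting the cell median,
  which gives sub-pixel accuracy on rendered spots.

Raising $k$ can only shrink the detected foreground, so fragment counts
are non-increasing in $k$ for resolvable (non-merging) objects; with very
low thresholds, merged PSF tails can split as the threshold rises, which
is a property of thresholding itself, not of this implementation.

## Carrier kinematics

Videos are preprocessed with the fixed recipe *subtract 10 (clipping at
zero) → Gaussian blur σ = 1 px → multiply by 3*, applied per frame.
Clipping reflects how unsigned-integer image pipelines behave; the blur
width follows the common single-pixel convention.

- **Detection**: threshold (Otsu by default), 4-connected components,
  intensity-weighted centroids. Object length is the principal-axis extent
  minus the perpendicular width (a stadium-shape correction approximating
  skeleton length) for elongated objects, and the equivalent-circle
  diameter for compact ones. On rendered 2.5 µm tubules this estimator is
  accurate to better than 10%.
- **Linking**: greedy nearest-neighbour assignment between consecutive
  frames, accepting links up to `max_step` (default 1.5 µm/frame), no gap
  closing. Unmatched detections start new tracks. This is the simplest
  linker whose failure modes (identity swaps at close encounters) are
  directly controllable in synthetic data.
- **Statistics**: mean speed = summed step distance / duration;
  displacement = straight-line start→end distance (which can never exceed
  the path length). Track filtering keeps displacements **strictly
  greater than 2 µm**, removing jittering near-stationary objects; the
  alternative reading of a per-frame mean displacement is not used.
- **Classification**: tubular iff length ≥ 2 µm (inclusive), vesicular
  below; size bins `<1`, `1–2`, `2–3`, `≥3` µm for tubular-fraction
  reporting.

On clean synthetic videos, programmed speeds of 0.2–1.0 µm/s are recovered
within 1%, and an arm programmed at 0.7× the control speed reports
70 ± 1% of control through the full render → preprocess → detect → link →
summarise pipeline.

## Screen statistics

- Mann–Whitney U tests of each arm against the NEG control (two-sided;
  exact for small samples without ties, continuity-corrected normal
  approximation otherwise), Bonferroni-adjusted by the number of
  comparisons. Under a 21-arm global null this controls family-wise error
  below 5% (verified by simulation).
- One-way ANOVA with Bonferroni-corrected contrasts against control, for
  assays analysed parametrically.
- Knockdown efficiency from qPCR Ct values by ΔΔCt:
  $2^{-(\Delta Ct_\text{treated} - \Delta Ct_\text{NEG})}$ with
  $\Delta Ct = Ct_\text{target} - Ct_\text{reference}$; the no-reference
  variant is available (`reference = FALSE`). Knockdown % =
  $(1 - \text{relative expression}) \times 100$.
- Replicate summaries use the mean ± s.e.m. across replicate means,
  matching the "n independent experiments" convention.

## Problem sizes used in validation

The test-suite simulations are sized to be statistically decisive while
keeping the whole suite quick to run: 100 cells per concentration level
for the dispersion-response curve (five levels), 1,000 random cells for
brute-force oracle equivalence and for the invariance properties, 40
cells per arm on the eight-arm screen correlation, 60-frame 512×512
videos for speed recovery, three replicate video pairs for the
programmed-ratio check, and 10,000 replicates of the 21-arm null for
family-wise error. Where a property is scale-free (score bounds,
classification boundary, fold-change inversion) small exact cases are
used instead.

## Known limitations

- The PDS compresses near its maximum for continuously jittered compact
  clusters (see above); comparisons at the top of the scale should use
  the normalized ratio, not the raw ceiling.
- Greedy linking swaps identities when carriers pass within `max_step` of
  each other; no merge/split or gap handling.
- Segmentation is threshold-based and assumes isolated, convex cells; it
  is a stand-in for whatever segmentation a real study would tune, which
  is why ground-truth bypasses exist at every stage.
- 2D only, single time-scale, no plate/batch-effect modelling (the
  synthetic design has no plates).
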