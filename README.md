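# orgscreen

Quantification of organelle morphology and membrane-carrier dynamics in
image-based (high-content) RNAi screens, with a synthetic-microscopy
generator that provides exact ground truth for validating every stage.

## Who this is for

Cell biologists and image analysts running siRNA/RNAi perturbation screens
who need per-cell, control-normalized readouts of:

- **Golgi (or other organelle) morphology** — fragment counts, occupied
  area, marker intensity, and the *polar distribution score* (below);
- **endosome/lysosome phenotypes** — puncta counts and per-cell intensities
  (EEA1/Rab5/LAMP1-style assays);
- **transport-carrier dynamics** — per-track speed and displacement of
  vesicular and tubular carriers in time-lapse videos, with
  tubular/vesicular classification;
- **screen statistics** — normalization to a non-silencing control (NEG),
  Mann–Whitney/ANOVA testing with Bonferroni correction, and qPCR
  knockdown efficiency (ΔΔCt).

Everything takes and returns tidy tibbles, so results chain with the pipe
and plot via `autoplot()`.

## The polar distribution score (PDS)

For each cell, fragment centroids \((x_i, y_i)\) are converted to polar
angles about the cell centre, \(\theta_i = \operatorname{atan2}(y_i - c_y,
x_i - c_x)\) (radii are discarded). Angles are rotated so their circular
mean \(\bar\theta = \operatorname{atan2}(\overline{\sin\theta},
\overline{\cos\theta})\) is zero, then binned into \(K = 8\) equal sectors
covering \((-\pi, \pi]\) with frequencies \(f_k\). The score is

\[
\mathrm{PDS} \;=\; \sum_{k=1}^{K} \left| f_k - \tfrac{1}{K} \right|
\;\in\; \left[0,\; 2\left(1 - \tfrac1K\right)\right] = [0, 1.75].
\]

PDS = 0 means fragments ring the centre uniformly (fully dispersed);
1.75 means every fragment sits in a single sector (a compact juxtanuclear
organelle). Per-treatment mean scores are divided by the NEG-control mean:
normalized values below 1 read as "dispersed", above 1 as "compacted".

## Worked example

Simulate a three-arm screen — a control, a fragmentation phenotype (more
fragments, dispersed) and a compaction phenotype (fewer fragments,
concentrated) — then score it:

```r
library(orgscreen)
library(tibble)

arms <- tibble(
  treatment   = c("NEG", "RhoX", "RhoY"),
  n_cells     = c(40, 40, 40),
  n_fragments = c(12, 30, 6),
  kappa       = c(8, 1, 64))     # angular concentration: low = dispersed

scenes <- simulate_golgi_screen(arms, seed = 42)
res <- score_golgi_screen(scenes)
res
#> <golgi_screen> 3 treatments, 120 cells; control = NEG
#>   normalized fragment count vs normalized PDS: r = -0.983
#> # A tibble: 3 × 6
#>   treatment n_cells mean_pds normalized_pds norm_fragment_count
#>   <chr>       <int>    <dbl>          <dbl>               <dbl>
#> 1 NEG            40    1.46           1                     1
#> 2 RhoX           40    0.841          0.577                 2.5
#> 3 RhoY           40    1.5            1.03                  0.5
```

The fragmentation arm (`RhoX`) has 2.5× the control's fragments and a
normalized PDS of 0.58 (dispersed); the compaction arm (`RhoY`) has half
the fragments and a PDS above 1. Across arms, normalized fragment count
and normalized PDS correlate negatively (r = −0.98): fragmentation and
dispersion go together. `tidy(res)` adds Bonferroni-adjusted Mann–Whitney
p-values per arm; `glance(res)` gives the one-row summary;
`autoplot(res)` draws the count-vs-PDS scatter.

For time-lapse carrier analysis:

```r
arms <- tibble(treatment = c("NEG", "KD"), n_carriers = 4,
               speed = c(0.8, 0.56), n_frames = 40)   # KD = 0.7x control
videos <- simulate_carrier_screen(arms, seed = 1)
trk <- track_carrier_screen(videos)
tidy(trk)   # per-arm mean speed/displacement as % of NEG (~70% for KD)
```

Images come in as plain matrices (grayscale TIFF via `read_scene()` /
`write_scene()`); segmentation (`segment_nuclei()`, `segment_cells()`,
`detect_fragments()`) replaces ground truth when analysing real data.

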