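---
title: "Tracking translucent larvae by mean-frame background subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking translucent larvae by mean-frame background subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

## The problem

Drosophila larvae are nearly transparent, so in transmitted-light video they
have very little contrast against the agar they crawl on. A plain binary
threshold faces a dilemma: set it high and the larva is missed whenever the
illumination dips; set it low and every static dark object in the arena —
above all the petri-dish edge — floods the detector with spurious objects,
and a larva that touches the edge merges with it and is lost. `larvatrack`
implements the processing approach that resolves this: remove everything
static from the movie *before* thresholding.

## The method

For a movie of frames $F_t$ (grayscale, intensities in $[0,1]$, dark
larvae on a light background) the pipeline is:

1. **Mean frame.** $\bar F = \frac{1}{T}\sum_t F_t$. Every static pixel —
   background, dish edge, debris — takes its long-run value here.
2. **Subtraction.** $R_t = \max(\bar F - F_t,\, 0)$. A static pixel cancels
   to zero; a pixel currently covered by a dark moving animal is darker
   than its time average and yields a positive residual close to the
   animal's optical contrast. Negatives are clipped: pixels *brighter* than
   average carry no information about a dark object, and a one-sided
   threshold has no use for them.
3. **Thresholding.** $M_t = R_t > \tau$ with $\tau = 0.028$ by default.
   Because static objects are gone, $\tau$ can sit far below any value
   usable on raw frames, and the *same* $\tau$ works across movies and
   lighting conditions — no per-movie tuning. The comparison is strict so
   that a perfectly static (all-zero residual) scene yields an empty mask.
4. **Labeling and pruning.** Connected components of $M_t$
   (8-connectivity by default) become candidate detections; components
   with fewer than 2 or more than 100 pixels are discarded (bounds
   inclusive). The lower bound removes single-pixel sensor speckle, the
   upper removes large artifacts such as an edge fragment or a hand
   passing over the arena.
5. **Linking.** Cluster centroids (unweighted pixel means) are joined
   frame to frame by greedy nearest-first matching: all (track head,
   detection) pairs are sorted by distance and accepted nearest first,
   each used at most once, provided the distance is strictly below
   10 px (about 3 mm at the default scale of 0.3 mm/px). Unmatched
   detections open new tracks; a track that finds no match is closed —
   there is no gap bridging, and no attempt to preserve identity through
   track crossings.
6. **Kinematics.** Tracks are smoothed coordinate-wise with a discrete
   Gaussian kernel, and instantaneous speed is the forward difference of
   the smoothed track scaled by `mm_per_px * fps`.

The package also implements the **baseline** this method is measured
against: thresholding $1 - F_t$ directly, with no subtraction. The raw
images give only the convention that larvae are dark, so the baseline is
defined as selecting pixels darker than $1-\tau_b$; a "high" $\tau_b$
(0.09) accepts only very dark pixels and misses a faint larva, a "low" one
floods the mask with static-edge pixels — the two failure modes the
subtraction step removes.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `fast_threshold` | 0.028 | intensity | residual threshold after subtraction |
| `baseline_threshold` | 0.09 | intensity | darkness threshold for the baseline |
| `min_cluster_px`, `max_cluster_px` | 2, 100 | px | inclusive size pruning window |
| `link_max_px` | 10 | px | strict upper bound on a per-frame jump |
| `connectivity` | 8 | — | pixel adjacency for labeling |
| `smoothing_sigma_frames` | 1 | frames | Gaussian smoothing width |
| `flicker_normalize` | FALSE | — | per-frame gain equalization before subtraction |
| `fps` | 3.75 | 1/s | acquisition frame rate |
| `mm_per_px` | 0.3 | mm | spatial scale (10 px ≈ 3 mm) |

The smoothing width is the one genuinely free parameter: no width is
dictated by the method, so the default is the smallest that visibly
removes single-frame jitter at 3.75 fps — one frame interval — with the
kernel truncated at $4\sigma$ and renormalized where it overhangs a track
end. Speed uses a forward difference (an $n$-point track yields $n-1$
speeds); a central-difference option exists for users who prefer its
phase behavior.

## Illumination flicker

Fluorescent lighting driven by 60 Hz mains emits at 120 Hz. A camera
whose internal clock is detuned from the mains by $\delta$ Hz samples
that oscillation aliased: at 3.75 fps, 120 Hz aliases exactly to zero
frequency and only the detuning survives, appearing as a slow beat of the
whole field's brightness across frames. `larvatrack` models this as a
multiplicative global gain
$g_k = 1 + A\sin\!\big(2\pi(2 f_{\text{mains}} + \delta)\,k/\text{fps}\big)$
sampled at the true frame times, not per-pixel — the fluctuation is a
property of the light source, uniform over the field.

Because subtraction compares each frame against the mean, a gain swing of
amplitude $A$ leaves residuals up to $A \cdot \text{background}$ on every
static pixel, which at $A = 0.03$ exceeds the 0.028 threshold near the
beat troughs. `flicker_normalize = TRUE` rescales each frame by
(mean of frame means)/(its own mean) before subtraction; a global
multiplicative gain is cancelled exactly, and the property suite checks
that detections on a flicker-modulated movie then match the unmodulated
movie to sub-pixel accuracy.

## The synthetic-movie generator

Real larval video cannot ship with a package, so every scenario is
exercised on ground-truthed synthetic movies built by `synth_scene()` /
`render_scene()`:

- frames are `clamp(gain * (background − ring − Σ blob·contrast) + noise)`,
  640×480 at 3.75 fps by default, background level 0.85;
- the **blob** is a rigid disc of radius 4 px (area ≈ 50 px, inside the
  pruning window) whose contrast stands in for the animal's optical
  density: 0.4 emulates a dye-fed larva with a darkened gut, 0.05 an
  undyed translucent one;
- the **ring** is a static dark annulus standing in for the dish edge;
- **flicker** is the aliased-gain model above (defaults $A=0.03$,
  60 Hz mains, 30 Hz camera clock, 0.1 Hz detuning);
- **noise** is iid Gaussian with sd 0.01 per pixel (about 2.5 digitization
  levels of an 8-bit sensor);
- the seed fully determines the rendered movie.

Trajectories are correlated random walks with constant step length
(`random_walk_path()`), or arbitrary user-supplied paths;
`jittered_track()` adds centroid-localization noise directly for testing
the kinematics stage without rendering.

Two preset families reproduce the benchmark scenarios, each isolating one
factor the way the original comparisons do. `scene_edge_crossing()` sends
a blob on a straight path through the ring with flicker off. The ring is a
16 px wide band: at this magnification a dish wall viewed obliquely is a
dark band wider than a larva, so the blob can be fully engulfed. The
background is 0.95 — mildly overexposed bright-field — so that the
baseline threshold of 0.09 cleanly separates background (residual darkness
0.05) from genuinely dark pixels. In the dyed variant (ring 0.35,
contrast 0.4) a blob on the ring is still darker than the ring's time
average, so subtraction tracks it straight through, while the baseline
merges it with the edge into an oversized component that pruning drops —
a broken track. In the undyed variant the exposure needed to resolve a
contrast-0.05 animal renders the edge nearly black (0.02); a blob on the
edge saturates into it, the residual (0.02) falls below the threshold,
and *both* methods lose the animal there — dye and subtraction are
individually necessary and only jointly sufficient. `scene_flicker()` has
no ring and flicker on, for the normalization comparison.

What the generator does **not** emulate: peristaltic shape change (the
blob is rigid; only centroid behavior is measured), partial translucency
gradients within the animal, shadows, condensation, or multiple animals
colliding. Passing tests therefore demonstrate the pipeline's logic —
static-object removal, threshold sensitivity, edge behavior, flicker
response — not robustness to every artifact of real video.

## Numerical and design choices

- **Coordinates** are 0-based with `x` = column, `y` = row and pixel
  centers at integer positions; frame indices are 0-based. Stated once
  here; every table and test relies on it.
- **Intensity convention**: 0 = black, 1 = white; loading rescales the
  native bit depth affinely (order-preserving) onto $[0,1]$, averaging
  color channels if present.
- **Ties** in linking are broken by lower track id, then lower detection
  index, making linking fully deterministic; a distance of exactly
  `link_max_px` does not link.
- **Mean-frame ghost**: the mean includes frames containing the animal,
  so a faint ghost of depth ≈ contrast × (dwell frames)/(total frames)
  remains in the background model. The threshold must exceed this ghost;
  with the default threshold that holds for any movie longer than a few
  tens of frames, and for short test movies the scenes are sized so it
  holds too.
- **Speckle tracks**: pixel noise of sd 0.01 against a threshold of 0.028
  is a 2.8σ cut, so a few two-pixel noise clusters survive pruning per
  frame and become single-frame tracks. This mirrors the method's real
  behavior at a very low threshold; analyses that need only real tracks
  filter by track length (the worked examples keep tracks of ≥ 5 points).
- **Degenerate inputs**: empty movies, zero-mean frames (flicker
  normalization), mismatched frame sizes and malformed CSVs raise typed
  errors rather than propagating NaNs.

## Problem sizes in the shipped tests

The test-suite scenes are 160×120 px with 40–75 frames, small enough that
the whole suite and the acceptance script run in minutes on one core
while preserving every geometric relation of the full 640×480 setting
(ring wider than blob, blob area inside the pruning window, steps well
below the linking cutoff). The smoothing-displacement benchmark uses 100
tracks of 100 points with 0.25 px jitter; labeling is verified against a
flood-fill oracle on 100 random 32×32 masks per connectivity.

## Known limitations

- Identity is not preserved through track crossings; crossing animals may
  swap labels, and multi-animal scenes are supported only in the sense
  that non-interacting animals yield parallel tracks.
- No gap bridging: one missed frame ends a track.
- AVI support covers the uncompressed 8-bit/24-bit subset this field's
  recording software writes; compressed codecs are rejected.
- The baseline's published "effective low threshold" (0.073) is used here
  simply as an example setting of the same darkness-threshold form; raw
  recordings could use either polarity convention, and only this reading
  is consistent with the reported failure modes.
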