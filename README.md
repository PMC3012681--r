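# larvatrack

Video tracking of translucent animals — Drosophila larvae above all — by
mean-frame background subtraction.

## The problem

A crawling third-instar larva is almost transparent: in transmitted-light
video it barely differs from the agar beneath it. Plain binary
thresholding of the raw frames is caught between two failures — a high
threshold loses the animal, a low one drowns in static dark objects, and
either way the track dies the moment the larva touches the petri-dish
edge, because animal and edge merge into one dark region. That makes
whole-assay trajectories, and everything downstream of them (speed
distributions, orientation analysis, high-throughput screens),
unobtainable with the naive method.

`larvatrack` implements the fix: average all frames of the movie, subtract
each frame from that mean, and threshold the residual,

```
R_t = max(F̄ − F_t, 0),    M_t = R_t > τ        (τ = 0.028 by default)
```

Every static object — dish edge included — cancels in the subtraction, so
a single very low threshold detects the animal in all movies without
per-movie tuning, including on top of the arena edge. Detections are
connected pixel components (8-connectivity), pruned to 2–100 px, linked
frame-to-frame by greedy nearest-first matching under a strict 10 px
cutoff, Gaussian-smoothed (σ = 1 frame), and converted to instantaneous
speeds in mm/s via the spatial scale (0.3 mm/px) and frame rate
(3.75 fps). A plain-threshold baseline, a flicker-normalization step for
mains-driven illumination beating, and a ground-truthed synthetic movie
generator (dish-edge ring, dyed vs. undyed contrast, flicker, sensor
noise) are included, so every claim is testable without real video.

## Worked example

Track a dyed larva crossing the dish edge, and compare against the
baseline:

```r
library(larvatrack)

scene <- scene_edge_crossing(dyed = TRUE, seed = 1)
rend  <- render_scene(scene)
rend$movie
#> <larva_movie> 40 frame(s), 160 x 120 px, 3.75 fps, 0.3 mm/px [synthetic (seed 1)]

cmp <- run_compare(rend$movie, pipeline_config(), truth = rend$truth)
cmp
#> <larva_comparison>
#> # A tibble: 2 × 3
#>   method   mean_objects max_objects
#>   <chr>           <dbl>       <int>
#> 1 baseline         0.65           1
#> 2 fast             1.27           2
#> # A tibble: 2 × 5
#>   blob_id n_frames n_covered completeness method
#>     <int>    <int>     <int>        <dbl> <chr>
#> 1       1       40        40         1    fast
#> 2       1       40        26         0.65 baseline
```

Subtraction (`fast`) covers all 40 ground-truth frames — completeness 1 —
while the baseline loses the animal in the 14 frames around the edge
crossing (completeness 0.65): the larva's dark pixels merge with the edge
into an oversized component that size pruning discards. The extra `fast`
objects are occasional two-pixel noise clusters that survive the very low
threshold; they form single-frame tracks easily excluded by length:

```r
rep <- run_track(rend$movie)
real <- dplyr::filter(dplyr::count(rep$tracks, track_id), n >= 5)
sp   <- dplyr::filter(rep$speeds, track_id %in% real$track_id)
round(mean(sp$speed_mm_s), 3)
#> [1] 2.19
```

2.19 mm/s is the recovered mean speed of the one real track; the scene's
blob moves 2 px/frame = 2.25 mm/s, so the estimate is within 3% (the
small deficit is smoothing at the track ends). Tracks, smoothed tracks,
speeds and a run report can be written to disk by passing `out_dir`, or
from the shell via the CLI at `inst/cli/larvatrack`
(`larvatrack track|compare|synth|stats`).

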