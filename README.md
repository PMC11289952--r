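# rnlscape

Do chemically defended species occupy background habitats that *look
different to a predator* from the backgrounds of undefended species?
`rnlscape` implements the full analysis chain for that question in visual
ecology, built around a receptor-noise-limited (RNL) model of a
trichromatic reef-fish observer (single cones sw/mw/lw plus a double cone
for luminance):

1. **Observer model** — channel Weber fractions
   `ω_i = ν √(η_max/η_i)` from relative photoreceptor abundances (1:2:2:2)
   and receptor noise (ν = 0.05), giving 0.07:0.05:0.05:0.05; chromatic
   distance ΔS is the receptor-noise-limited (Mahalanobis) distance on
   log cone catches, luminance distance ΔL = |Δln q_dbl|/ω_dbl, both in
   just-noticeable-difference (JND) units.
2. **Viewing-distance modeling** — Gaussian acuity blur (3 cycles/degree
   observer; 10% modulation transfer at the cutoff) at 2 cm and 30 cm,
   followed by an edge-preserving RNL ranked filter (falloff 3, radius 5,
   5 repetitions) and RNL clustering into patch classes discriminable at
   2 ΔS (color) / 4 ΔS (luminance).
3. **Pattern statistics** — the color-adjacency (CAA), visual-contrast
   (VCA), boundary-strength (BSA) and local-edge-intensity (LEIA) families,
   one row per image per distance.
4. **Defense scoring** — species-level unpalatability/toxicity indices
   (1 − ED50 / 1 − LD50 scaled to [0, 1]) classified at 0.25 / 0.74 into
   the three analysis groups: undefended, toxic–moderately unpalatable,
   toxic–highly unpalatable.
5. **Factor reduction** — complete-case filtering (uniform backgrounds drop
   out via NaN), a greedy |r| < 0.6 correlation filter, parallel-analysis
   factor retention, minres + varimax exploratory factor analysis with
   bootstrap loading intervals.
6. **Group comparison** — a Bayesian phylogenetic *distributional*
   Student-t model per factor: group × distance predict both the mean and
   the log residual scale, with species random intercepts/slopes and a
   Brownian-motion phylogenetic intercept; fitted cells and all pairwise
   contrasts (means and back-transformed residual scales) with 95% credible
   intervals.

A synthetic scene generator (`make_scene()`, `make_study()`) produces
cone-catch Voronoi mosaics with exact ground truth — patch scale, class
colors placed at exact JND spacings, defense groups with known effect
multipliers, assay tables, and a pure-birth tree — so the entire pipeline
is testable without any field photographs.

## Worked example

```r
library(rnlscape)

vs <- visual_system()
round(vs$weber, 2)
#>   sw   mw   lw  dbl
#> 0.07 0.05 0.05 0.05

# one synthetic background, viewed at 30 cm
sc   <- make_scene(scene_config(seed = 7), vs)
blur <- apply_acuity(sc$image, vs, viewing_geometry(30, sc$image$px_per_mm))
filt <- rnl_ranked_filter(blur, vs)
cl   <- rnl_cluster(filt, vs)
cl$class_table[, c("class", "abundance", "luminance", "saturation")]
#>   class abundance luminance saturation
#> 1     1 0.6747126 0.4925159   1.884376
#> 2     2 0.3252874 0.5010794   3.348425

st <- compute_pattern_stats(cl, filt, vs, "img1", "sp1", 30)
round(unlist(st[c("CAA.PT", "VCA.ML", "BSA.BML", "Lum.mean")]), 3)
#>   CAA.PT   VCA.ML  BSA.BML Lum.mean
#>   72.500    0.345    0.345    0.095
```

At 30 cm the three generated patch classes merge to the two that remain
discriminable after acuity loss — here along the chromatic axis
(saturations 1.9 vs 3.3 JND) with almost no luminance difference: `CAA.PT`
is the mean patch area in mm², `VCA.ML`/`BSA.BML` the abundance- and
boundary-weighted luminance contrasts in JND, `Lum.mean` the mean local
luminance edge contrast of the unsegmented image. The same scene at 2 cm
recovers all three generated classes.

The full chain, from simulated study to fitted group models:

```r
cfg <- pipeline_config(seed = 1)           # 12 species, 15 images each
res <- run_pipeline(cfg, out_dir = "results")
res$k                    # factors retained by parallel analysis
res$models$F1$cells      # fitted group x distance cell medians + 95% CI
res$models$F1$mean_contrasts
```

A command-line wrapper for the same run is installed at
`inst/scripts/run-pipeline.R`.

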