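---
title: "Predator-vision background analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predator-vision background analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rnlscape asks a visual-ecology question: do chemically defended species sit
on background habitats that *look different* — to a predator, not to us —
from the backgrounds of undefended species? The package implements the full
chain needed to answer it: an observer model, perceptual image processing,
spatiochromatic pattern statistics, dimension reduction, and a Bayesian
group comparison that respects phylogeny. A synthetic scene generator with
known ground truth makes every stage testable end to end.

## The observer model

All perceptual computation is driven by a receptor-noise-limited (RNL)
observer. The default observer is a trichromatic triggerfish-like reef fish
(single cones sw, mw, lw; a double cone dbl carrying luminance) with
relative photoreceptor abundances 1:2:2:2, receptor noise 0.05, and spatial
acuity 3 cycles per degree. Channel Weber fractions follow
$\omega_i = \nu \sqrt{\eta_{\max}/\eta_i}$, which reproduces the
conventional 0.07:0.05:0.05:0.05 for those inputs; the abundance square
root is the standard pooling argument (noise falls with the square root of
the number of receptors per integration unit), and we adopt it because it
maps the published inputs onto the published outputs exactly.

Chromatic distance between catch vectors $q^a, q^b$ uses log-catch
differences $\Delta f_i = \ln(q^a_i/q^b_i)$:

$$\Delta S^2 = \frac{\omega_1^2(\Delta f_2-\Delta f_3)^2 +
\omega_2^2(\Delta f_1-\Delta f_3)^2 + \omega_3^2(\Delta f_1-\Delta f_2)^2}
{(\omega_1\omega_2)^2+(\omega_1\omega_3)^2+(\omega_2\omega_3)^2}$$

This equals the Mahalanobis distance in $\Delta f$-space with covariance
$\mathrm{diag}(\omega^2)$, taken modulo the achromatic direction — the
package tests assert the equivalence to $10^{-9}$ against an independent
implementation. Achromatic contrast is
$\Delta L = |\Delta f_{dbl}|/\omega_{dbl}$. One unit of either is one just
noticeable difference (JND).

## Viewing distance and acuity

Viewing distance enters through a Gaussian low-pass filter. A pixel of size
$1/\text{px\_per\_mm}$ viewed at distance $d$ subtends a known angle; the
observer's acuity $a$ (cycles/degree) fixes a cutoff frequency in cycles
per pixel, and the Gaussian standard deviation is chosen so the modulation
transfer at that cutoff is 10%. The 10% point is a deliberate numerical
choice: it makes the operator deterministic and directly testable in the
frequency domain (gratings six times finer than the resolvable period must
lose over 90% of their amplitude, which the tests check), while the exact
kernel shape of any particular imaging toolbox is not reproducible from
first principles. The operator is linear and channel-wise identical; a blur
kernel wider than the image is refused rather than truncated.

At the study distances (2 cm and 30 cm, with 4 px/mm scenes) the 2 cm
filter is effectively an identity — its cutoff lies beyond the pixel
Nyquist frequency — while the 30 cm filter has $\sigma \approx 2.4$ px.
That asymmetry is the point of the escalating-sequence design: the same
scene carries different usable information at the two distances.

## Ranked filtering and perceptual clustering

Gaussian blur leaves shallow gradients at patch boundaries that would
otherwise fragment any threshold-based segmentation. The RNL ranked filter
(falloff 3, radius 5, repetition 5 by default) is an edge-preserving
smoother: each pixel's circular neighbourhood is ranked by combined
perceptual distance $\sqrt{\Delta S^2 + \Delta L^2}$ to the centre, and the
centre is replaced by the rank-weighted mean with weight
$(1-\text{rank}/N)^{\text{falloff}}$. Perceptually close neighbours
dominate, so plateaus flatten while genuine edges steepen. The internals
(ranking metric, weight law) are reconstructions from the conventional
parameter names; what the package treats as the filter's contract — and
tests — is edge preservation plus gradient removal: a blurred, salt-noised
two-class mosaic must come back with at least 99% of pixels assignable to
the correct class and the step edge in its original position.

Clustering then merges image regions that the observer cannot tell apart.
Starting from single-pixel regions inside the background mask, adjacent
regions merge while their means differ by less than 2 $\Delta S$
chromatically AND less than 4 $\Delta S$ in luminance; merging is smallest
combined distance first, means are recomputed after every merge, and ties
break on the lower class index so the fixed point is deterministic. We read
the two thresholds as "a pair is discriminable if it exceeds either axis"
— a pair differing strongly in luminance alone is plausibly discriminable —
so merging requires being below both; the alternative reading (merge when
below either) would fuse strongly luminance-contrasting patches and is not
adopted. After spatial agglomeration, class labels whose pooled means are
still mutually indiscriminable are fused globally, so the final class table
never contains two classes below both thresholds, adjacent or not.

## Pattern statistics

Four families of statistics summarize each image at each distance
(`stat_registry()` fixes their order; ~34 outputs). The full historical
inventory of 157 statistics is far larger; the catalogue here covers every
statistic named in the study's text and figures plus their horizontal and
vertical variants, behind a registry so definitions can be swapped without
touching downstream stages. Reconstructed definitions to be aware of:

* `CAA.*` — transition-matrix geometry. `CAA.PT` is the mean 4-connected
  patch area in mm²; `CAA.Qc`/`CAA.Qt` are Shannon evenness of class
  abundances and of off-diagonal transition frequencies (defined as 1 for a
  single class / single boundary type, NaN with no boundaries); `CAA.Asp`
  is the horizontal-to-vertical nonsynonymous transition rate ratio and is
  `Inf` when one direction has no boundaries.
* `VCA.*` — abundance-weighted pairwise class contrasts; `VCA.MSL` is the
  abundance-weighted standard deviation of pairwise luminance contrasts.
  Saturation is the chromatic distance of a class mean from the equal-catch
  (achromatic) locus, which is scale-free because chromatic distance
  ignores common scaling.
* `BSA.*` — the same contrasts weighted by how much boundary each class
  pair shares (normalized symmetrized off-diagonal transition counts).
* `Lum.*` / `Col.*` — local edge intensity on the *unsegmented* filtered
  image: JND contrasts between each in-mask pixel and its right (`.hrz`)
  and lower (`.vrt`) neighbour, summarized by mean, coefficient of
  variation, and excess kurtosis (normal = 0; NaN under zero variance).

Degenerate inputs propagate NaN rather than inventing numbers: fewer than
two classes leaves every pairwise statistic undefined, which is exactly the
mechanism the downstream complete-case filter uses to exclude uniform
backgrounds, with exclusion counts reported per distance.

## The synthetic study

The study's raw photographs are not redistributable, so the generator
defines the study conditions: 12 species in three defense groups (5
undefended, 4 toxic–moderately unpalatable, 3 toxic–highly unpalatable),
15 backgrounds per species, analyzed at 2 and 30 cm — the group sizes of
the original design. Scenes are Voronoi mosaics (one seed per nominal patch
area, giving a single parameter for patch scale and an exact ground-truth
class map) whose class means are placed in RNL coordinates so that the mean
pairwise chromatic and luminance separations equal the requested spreads
exactly; pixel noise is multiplicative lognormal (catches are positive and
the perceptual math is log-ratio based, so the noise parameter is the
log-scale standard deviation, about the relative catch noise). Defaults:
64×64 px at 4 px/mm, 3 patch classes, 8 mm nominal patch diameter, spreads
of 6 JND, 5% pixel noise. The patch diameter is set comfortably above the
30 cm resolution limit (~1.75 mm at 3 cpd) so that patch structure
survives, attenuated, at the far distance; smaller patches are legitimately
destroyed by acuity modeling, which is the biological phenomenon, not a
bug. Group effects enter as multipliers on the chromatic and luminance
spreads (edge contrast) of each species' scenes. Assay indices are drawn
uniformly inside the index interval of the species' group, so defense
classification round-trips exactly. A pure-birth tree (unit height, fixed
seed) supplies the phylogeny.

What the generator does *not* emulate: spatial luminance gradients,
textured patches, spectral correlations between channels, non-stationary
backgrounds, or any empirical distribution of real reef substrates. Tests
passing on these scenes demonstrate that the pipeline machinery is correct
and calibrated, not that real backgrounds behave this way.

## Factor reduction

Statistic tables are filtered to complete cases (rows with any NaN/Inf
dropped, counts reported per distance), then columns are filtered greedily
in registry order keeping each statistic only if its absolute Pearson
correlation with everything already kept is below 0.6. The greedy order
matters — a different order gives a different, equally valid survivor set —
which is why it is pinned and logged; the survivor list is reported rather
than asserted against any external list.

The number of factors comes from parallel analysis: observed correlation
eigenvalues against position-wise medians from standard-normal datasets of
the same shape (10,000 by default; 1,000 in the test suite, which recovery
simulations show is ample at these sizes), retaining strictly greater
positions. The factor model itself is least-squares ("minres"): uniqueness
values minimize the sum of squared off-diagonal residuals of the
correlation matrix, loadings come from the reduced matrix's leading
eigenstructure, rotation is varimax, and scores use the regression
(Thurstone) method. Near-Heywood cases clip uniqueness at 0.005 with a
warning. Bootstrap loading intervals resample rows, refit, and align each
replicate to the point estimate with the congruence-maximizing signed
column permutation before taking percentile intervals — without alignment,
factor order and sign switching would make the intervals meaningless.

## The group model

Each retained factor's scores are compared across groups and distances with
a Bayesian distributional location–scale model: Student-t response, with
group × distance (full interaction) predicting both the mean and the log
residual scale; a species random intercept and a species random slope over
distance; and a phylogenetic species intercept whose correlation matrix is
the Brownian-motion expectation from the tree (shared branch length over
total depth). Priors are normal(0, 5) for all mean and log-scale
coefficients, exponential(1) for every standard deviation, and
1 + gamma(2, 0.1) for the Student degrees of freedom (a standard weakly
informative choice keeping the likelihood finite; the reference analysis
does not state one). The intercept–slope correlation gets the
two-dimensional LKJ(2)-equivalent prior, expressed exactly as
$(1+\rho)/2 \sim \mathrm{Beta}(2,2)$.

Sampling is MCMC via JAGS with the Student-t written as a gamma scale
mixture of normals, which keeps the coefficient and random-effect updates
conjugate and lets the block samplers in JAGS's glm module move them
jointly. Two design choices matter for mixing and are worth recording.
First, the iid species intercept and the phylogenetic intercept are
*jointly* sampled as one multivariate normal whose covariance is the sum
$\sigma_{sp}^2 I + \sigma_{phy}^2 C$ (plus the correlated-slope block):
marginally identical to keeping two separate vectors, but the separate
vectors are only identified through their sum and mix very poorly under
Gibbs updates. Second, the degrees-of-freedom parameter mixes slowly under
the scale-mixture representation, so the sampler thins aggressively
(default: 16× thinning behind 500 stored draws per chain; the convergence
checks in the acceptance suite use 32×). Convergence is checked per
parameter against three criteria — split R-hat < 1.01, effective sample
size above 10% of stored draws, Monte Carlo standard error below 5% of the
posterior SD — and a violation warns (or errors, by choice) rather than
silently passing; replicate simulation studies run with checking off and
judge coverage instead.

Reported quantities are population-average fitted values per group ×
distance cell (random effects marginalized at zero), all 15 pairwise mean
contrasts, and all 15 pairwise contrasts of the residual scale
back-transformed from the log scale, each computed draw-wise and
summarized by median and 95% credible interval.

## Problem sizes and calibration

The test and acceptance suites run the model stage at two scales chosen as
the package's own desk-scale defaults: single convergence-contract fits use
4 chains × 500 stored draws (32× thinned, 3,000 burn-in); the 20-replicate
null-coverage and effect-recovery studies use 2 chains × 400 stored draws
(2× thinned) per replicate, which calibration runs showed is enough for
stable 95% interval endpoints on the contrast scale while keeping a full
20-replicate study under a few minutes. Replicate studies simulate the
factor-score table directly — the image stages are deterministic given a
scene and are exercised by their own tests; re-running them 20 times would
only add identical work, not information. When those replicates emulate a
*null* study (identical scene parameters for every species), species are
exchangeable, so the score-level stand-in draws only small species effects
of the order of scene-sampling noise; the generator's default species
standard deviations (0.5 intercept, 0.3 slope and phylogeny) describe a
real heterogeneous study and are used where such a study is being
emulated. The distinction matters: with 3–5 species per group, systematic
species heterogeneity makes simultaneous coverage of all 15 null contrasts
mathematically unattainable at nominal interval levels, whereas under
exchangeability the hierarchical intervals are conservative. The
full-scale profile (4 × 2000 = 8,000 stored draws) is available through
the pipeline configuration.

## Known limitations

* The ranked filter and several statistic definitions (`VCA.MSL`,
  `BSA.BCVSsat`, transect spacing) are documented reconstructions; they are
  kept behind the registry precisely so they can be swapped.
* The clustering fixed point depends on the stated merge order; other
  orders give slightly different segmentations near threshold.
* Saturation uses the equal-catch point as the achromatic reference; other
  conventions (e.g. adapting backgrounds) would shift `*Sat*` statistics.
* With 12 species, the split between iid and phylogenetic intercept
  variance is weakly informed; only their sum is well identified, which is
  why the model treats the sum as the sampling unit.
* Group contrasts are population-average statements conditional on the
  modeled random-effect structure; with 3–5 species per group, species
  sampling dominates the uncertainty, exactly as in the original design.
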