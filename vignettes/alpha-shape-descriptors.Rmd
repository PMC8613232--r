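---
title: "Alpha-shape descriptors of retinal vessel skeletons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-shape descriptors of retinal vessel skeletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package quantifies the global morphology of a retinal vessel *skeleton*
— the 1-pixel-wide centreline raster of a segmented vasculature — through
2D alpha-shapes.  Let $S$ be the set of skeleton pixel coordinates and
$DT(S)$ its Delaunay triangulation.  For a refinement radius $\alpha$, the
alpha-shape is the union of the Delaunay triangles whose circumradius is at
most $\alpha$: a disc of radius $\alpha$ rolled over the point set falls
into exactly the pockets wider than $\alpha$, so small $\alpha$ carves the
triangulation down to fine structure and $\alpha \to \infty$ recovers the
convex hull.

Four descriptors are computed per image:

* **Op$\alpha_{min}$** (complexity, pixels): the smallest $\alpha$ at which
  the shape is a *single* edge-connected region covering *every* skeleton
  point.  A complex, finely branched vasculature needs a smaller
  $\alpha$.
* **OpA** (spread, squared pixels): the area of the shape at
  Op$\alpha_{min}$.
* **VS** (vessel shape, pixels): $VS = OpA / Op\alpha_{min}$.
* **Grad$_\alpha$** (VS per percentage point): the slope of a robust
  regression of VS on the percentage of skeleton pixels remaining across a
  spur-erosion series (default 20 iterations, iteration 0 included at
  100%).  Spur erosion deletes every endpoint pixel per iteration, so free
  vessel ends shorten while loops persist.  A vasculature rich in small
  terminal vessels sheds many pixels that carry little alpha-shape area, so
  VS falls slowly per percentage point: **low Grad$_\alpha$ indicates
  fragmentation**, the morphological signature of neovascularisation.

A comparator fractal dimension (box counting, and a generalised sandbox
$D_q$) is included because FD is the established global descriptor this
family of methods is measured against.

## Key algorithmic choices

**Triangle filtration, not edge collection.**  The rolling-disc narrative
collects boundary edges; the area and single-region semantics require a
filled shape.  We adopt the standard Delaunay filtration (keep triangle iff
circumradius $\le \alpha$, boundary inclusive) so that Op$\alpha_{min}$ is
always a member of the finite critical-alpha spectrum (the sorted distinct
circumradii), and regions connect only through shared full edges —
vertex contact does not connect.

**Exact discrete search.**  Both optimality criteria are monotone in
$\alpha$ and the shape only changes at spectrum values, so
`find_optimal_alpha()` binary-searches the spectrum; the result is exact
and identical to a linear sweep (property-tested).

**Degenerate configurations.**  Skeletons live on an integer grid, where
cocircular quadruples are ubiquitous.  The Delaunay backend
(`interp::tri.mesh`, sweep-hull) resolves them deterministically, so
results are reproducible bit-for-bit; however the tie-break is not
equivariant under coordinate scaling, so exact scale covariance
($\alpha \to s\alpha$, area $\to s^2$·area) is guaranteed only for point
sets in general position.  On grids the discrepancy is confined to
exactly-cocircular quads; tests jitter grid fixtures by $\pm 0.05$ px when
asserting covariance to machine precision.  Duplicate points are removed
with a message.

**Robust regression.**  "Robust" is pinned as iteratively reweighted least
squares with Tukey's bisquare (tuning constant 4.685), scale re-estimated
each iteration as MAD/0.6745, at most 50 iterations, coefficient tolerance
1e-8.  On clean data it reduces to ordinary least squares; with gross
outliers the slope stays within a few percent of truth while OLS does not
(tested against a grid search on the same loss and `MASS::rlm`).

**Erosion bookkeeping.**  Iteration 0 enters the regression at 100%; if a
skeleton empties, the series truncates at the last nonempty iteration with
a warning; an iteration whose skeleton degenerates below 3 non-collinear
points truncates the Grad$_\alpha$ series.  The 20-iteration default is a
fixed count, not a stopping rule on percentage remaining.

## The synthetic world

Real fundus datasets cannot be bundled, so `generate_vessel_tree()`
emulates skeletonised vasculature: roots radiate from an optic-disc-like
hub and perform a random branching walk (per-segment bifurcation
probability, angular spread, normally distributed segment lengths).  The
defaults were chosen once to land in the regime the published measurements
describe — on a 909-pixel standardised raster, Op$\alpha_{min}$ around
40–50 px, i.e. Op$\alpha_{min}$/image-size ≈ 0.05, with the skeleton
occupying a few percent of the raster.  Tests scale the raster down
(192–256 px) with proportional segment lengths to stay inside CPU budgets;
this is a stated scale-down of the same world, not a recalibration.

Two degradation modes emulate pathology:

* **Neovascular tufts** (`add_neovascular_tufts()`): clusters of many
  short, strictly tree-structured twigs sprouting from *interior* vessels
  (anchors are drawn from the inner half of the skeleton by distance from
  its centroid, away from the large avascular pockets near the optimal-α
  threshold).  Three properties are enforced by construction and matter
  for the descriptors: twigs are simple open 8-paths that never touch
  each other (a loopy or staircase-cliqued tuft would resist spur erosion
  — real neovessels are exactly the fragile structures erosion consumes
  first); they stay within the tuft radius, well below Op$\alpha_{min}$;
  and a whole tuft layout is regenerated (seeded retries) if it
  incidentally moves Op$\alpha_{min}$ or OpA beyond a few percent of the
  base skeleton's values, at erosion iteration 0 or mid-series — the
  contract is *add small vessels without changing the global shape*.  The
  matched control's branch lengthening honours the mirror-image contract
  (growth must not move, or artificially freeze, the coverage radius).
* **Lesion noise** (`add_lesion_noise()`): small disconnected rings away
  from the tree, emulating erroneously segmented haemorrhages; each ring
  adds exactly one connected component.

The matched-pair protocol (`generate_matched_pair()`) isolates the tuft
phenotype from vessel mass: the control arm pads the *same* base tree to
the identical pixel count by lengthening the outermost branches from their
endpoints (growth that increases spread), pixel by pixel under a
thinness-preserving rule.  Under erosion the tufted arm sheds a large
fraction of near-zero-area pixels while the control sheds boundary pixels
that carry area, so the tufted arm shows the lower Grad$_\alpha$ and lower
OpA — the direction reported for PDR.  What a green paired test
establishes is exactly this directional separation in the synthetic world;
it does not certify effect sizes on real fundus images, where segmentation
artefacts, lesions and camera variation add noise the generator does not
model.

## Statistics stage

* Group comparison: Kruskal–Wallis omnibus per descriptor (midranks,
  tie-corrected), Benjamini–Hochberg across the descriptor family, Dunn
  pairwise z post-hoc with Bonferroni within each descriptor, reported only
  where the adjusted omnibus survives.  This layering (BH across
  parameters, Bonferroni within pairwise families) is the one the reported
  tables imply.
* Feature importance: per bootstrap trial, class-balanced resampling with
  replacement (default 40/40), regularised logistic regression
  (`glmnet`) under lasso (mixing 1), ridge (0) and elastic-net (0.5),
  fivefold cross-validated AUC choosing $\lambda_{min}$ and
  $\lambda_{1SE}$; importance is the count of trials with a non-zero
  coefficient.  The AUC confidence interval is a normal approximation on
  the trial means.  Two open points are pinned here: resampling is *with*
  replacement, and CV selection/reporting uses the AUC of the *pooled*
  held-out predictions, with the 1-SE band from the fold-to-fold spread.
  The pooled choice matters: per-fold AUCs on 16-observation folds are so
  noisy that maximising their mean over a 100-value $\lambda$ path
  inflates a null model's apparent AUC to ≈ 0.57, while pooled selection
  keeps it within sampling error of 0.5 — the calibration a null
  simulation must satisfy.
* Agreement: Dice coefficient between mask pairs, relative error
  $|AV - MV|/|AV|$ with the manual value as reference, Pearson correlation
  tests, and Wilcoxon rank-sum comparisons within the manual and automatic
  arms.

## Fractal comparators

The exact multifractal pipeline used alongside the published descriptors is
specified only by citation, so the module provides the two standard
estimators as documented comparators: box counting (origin-anchored grids,
scales $2, 4, \ldots \le \min(h,w)/8$ — larger boxes are dominated by
partial-box end effects) and the generalised sandbox method
($\langle (M(r)/M_0)^{q-1} \rangle \propto r^{(q-1)D_q}$ over seeded
foreground centres, discs clipped at the raster border excluded per
radius).  The single reported FD defaults to $D_0$; which $q$ the original
work reported is unknowable from the text and flagged, not guessed.

## Known limitations

* The generator produces clean trees; it does not emulate segmentation
  dropout, vessel-width variation, or the optic disc/fovea exclusion zones
  of real masks.
* Grad$_\alpha$ on very small rasters is noisy because Op$\alpha_{min}$ is
  quantised to the spectrum; paired designs (shared base tree) are needed
  for stable directional tests at that scale.
* TIFF input is not supported (no reader in the dependency set); use PNG
  or portable anymaps.
* The CLI resize option (bilinear, re-threshold at 0.5, re-thin) mirrors
  the published calibre standardisation only approximately.
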