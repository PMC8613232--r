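# alphavessel

Alpha-shape descriptors of retinal microvascular morphology.

## What problem this solves

Quantifying the global shape of the retinal vasculature from fundus
photographs — and detecting the signature of proliferative diabetic
retinopathy (PDR), namely neovascularisation: numerous fragile small
vessels — requires descriptors that are deterministic, cheap, and free of
the sampling and self-similarity assumptions of fractal dimension.  This
package implements a 2D alpha-shape approach for researchers working with
binary vessel segmentations or 1-pixel-wide vessel skeletons.

Given the skeleton point set *S* and its Delaunay triangulation *DT(S)*,
the alpha-shape at refinement radius α keeps exactly the triangles with
circumradius ≤ α.  The package computes, per image:

| Descriptor | Definition | Interpretation |
|---|---|---|
| Opα_min | minimum α giving a single region covering all of *S* | complexity (smaller = more complex) |
| OpA | area of the shape at Opα_min (px²) | vessel spread |
| VS | OpA / Opα_min | global vessel shape |
| Grad_α | robust-regression slope of VS against % pixels remaining over a 20-iteration spur-erosion series | fragmentation; low values flag many small vessels |

A comparator fractal dimension (box counting and generalised sandbox D_q),
a seeded synthetic vessel-skeleton generator (with neovascular-tuft and
lesion-noise modes), and the statistical evaluation stage (Kruskal–Wallis /
BH / Dunn–Bonferroni group comparison; bootstrapped lasso / ridge /
elastic-net logistic-regression feature importance with fivefold
cross-validated AUC; Dice / relative-error / correlation agreement
analysis) are included.

## Worked example

```r
library(alphavessel)

# a seeded synthetic vessel skeleton standing in for a segmented fundus image
params <- tree_params(image_size = 256, n_roots = 8, branch_probability = 0.45,
                      segment_length_mean = 14, segment_length_sd = 3.5,
                      max_depth = 8, seed = 7)
tree <- generate_vessel_tree(params)
tree$skeleton
#> skeleton: 256 x 256, 2829 px

rec <- compute_descriptors(tree$skeleton, image_id = "synthetic-7",
                           iterations = 20, fd = "box_counting")
rec
#> synthetic-7: Op_alpha_min = 15.53, OpA = 29648.5, VS = 1909.5, Grad_alpha = 39.57, FD = 1.251
```

Read: the shape becomes a single all-covering region at α ≈ 15.5 px
(complexity); it then covers ≈ 29.6k px² (spread); VS is their ratio; under
20 spur erosions VS falls ≈ 39.6 units per percentage point of skeleton
removed (a tufted, fragmented vasculature would show a markedly lower
value); the box-counting FD ≈ 1.25 says the skeleton is between a curve
and a plane-filling pattern, as a thinned vascular tree should be.

The same pipeline from the command line:

```sh
Rscript -e 'quit(status = alphavessel::run_cli())' synth --out-dir out --seed 7 --image-size 256
Rscript -e 'quit(status = alphavessel::run_cli())' descriptors --input out/synth_001.png --out out/descriptors.csv
```

(An equivalent executable script is installed as `exec/alphavessel`.)

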