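---
title: "IHC-supervised annotation of H&E stains: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IHC-supervised annotation of H&E stains: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualstain)
```

## The problem

Calculating tumor burden — the number of tumor-cell nuclei divided by the
number of all nuclei in an outlined region — is a prerequisite for
interpreting molecular assays such as BRAF mutation testing in melanoma.
Pathologists estimate it visually ("eyeballing") on H&E stains, with known
low accuracy. A neural network can do better, but training one for H&E
requires a very large set of pixel-level annotations distinguishing tumor
from normal nuclei, which is prohibitively expensive to produce by hand.

`dualstain` implements the alternative: *IHC-supervised annotation*. The
same physical section is scanned twice — first as H&E, then re-stained with
a chromogenic nuclear marker (SOX10 for melanocytic cells) and re-scanned.
Because the two whole-slide images depict the same tissue, marker-positive
nuclei detected on the IHC rendering can be labeled automatically and the
labels transferred onto the H&E rendering, yielding a large training set
with essentially no manual annotation. The package provides every stage of
that pipeline plus the statistics used to validate it, together with a
synthetic dual-stain simulator so that the whole system is testable without
any slide data.

## Stain model

All color arithmetic goes through the Beer–Lambert optical-density (OD)
model: a pixel's OD is `-log10(I / I0)` per channel, and stained tissue is
modeled as a nonnegative combination of unit OD vectors, one per stain.
Two bases are shipped: hematoxylin/eosin/DAB, using the classical published
OD vectors, and hematoxylin/eosin/Fast Red, whose third vector is
calibrated once from the simulator's pure chromogen color (RGB 0.91, 0.28,
0.58) and shipped as a constant. Melanin pigment is rendered with its own
broad-absorption OD direction, `unit(c(0.70, 0.62, 0.55))`, which is
deliberately close to DAB (brown pigment and brown chromogen are genuinely
confusable) and distinctly off the Fast-Red direction.

**Unmixing is nonnegative least squares, not a matrix inverse.** This is a
considered deviation from the more common inverse-plus-clipping recipe.
Because both bases share the hematoxylin and eosin columns, the
inverse-matrix concentration of the third stain depends only on a pixel's
component orthogonal to the hematoxylin–eosin plane; consequently *any*
off-basis color (melanin included) would produce Fast-Red and DAB
concentrations in a fixed ratio, and no pigment could ever register as
DAB-positive yet Fast-Red-negative. The physics says otherwise — pigment
absorbs red light strongly, Fast Red barely — and NNLS, which is nonlinear
in the active constraint set, recovers exactly that behavior: melanin
unmixes to a substantial DAB concentration but an (essentially zero)
Fast-Red concentration, with the mismatch reported in the residual map.
The three-stain NNLS problem is solved exactly by enumerating the eight
active sets in closed form, vectorized over pixels, so it is deterministic
and nearly as fast as the inverse. `method = "inverse"` remains available.

Chromaticity (each channel divided by the channel sum) is the package's
intensity measure for the red chromogen; black pixels are defined as
(1/3, 1/3, 1/3). Whether normalization should use the channel sum or
another denominator is a declared definition, not an inference.

## The simulator

`scene_config()` / `generate_scene()` / `render_pair()` produce paired
H&E/IHC tiles of one synthetic lesion with exact ground truth. Defaults
describe a 512×512 px tile at 0.44 µm/px (≈ 0.05 mm², the evaluation
square size used with 20X scans), with:

* tumor nuclei of 7 ± 1.2 µm mean radius and normal nuclei of 3 ± 0.45 µm
  (the large–small contrast of melanoma vs lymphocytes), drawn as rotated
  ellipses with low-order harmonic boundary perturbation;
* 80 tumor and 20 normal nuclei per tile, giving annotation rates of the
  order of 1600 and 400 labels/mm², matching the published rates;
* chromogen intensity 0.80 ± 0.07 OD in positive tumor nuclei (the
  staining-strength knob), hematoxylin intensities 0.70/0.85 for
  tumor/normal nuclei — free parameters of the simulator, since the source
  study does not characterize its intensity distributions;
* confounders, all off by default and switched on per experiment:
  melanin granule clumps (dark, OD ≈ 2.2 — granules are nearly opaque),
  unspecific red dots (IHC only), weak cytoplasmic chromogen rings
  (IHC only), SOX10-negative and pale tumor nuclei, mitotic figures,
  erythrocytes;
* touching normal-nucleus clusters with probability 0.15, to exercise
  cluster splitting;
* misalignment of the IHC rendering: a global shift plus an optional
  smooth sinusoidal warp, with the true inverse transform returned.

The renderer and the deconvolution share one stain basis, so unmixing is
exactly invertible on pure pixels. The RNG consumption order (binomial
counts first, then Poisson confounder counts) is part of the
reproducibility contract, and identical configurations give bit-identical
tiles.

What the simulator does *not* emulate: photorealistic texture, out-of-focus
regions, staining gradients across a slide, coverslip-removal artifacts,
epidermis, and the full morphological diversity of melanoma nuclei.
Passing tests therefore demonstrate that the algorithms are correct under
the stated optical model and confounder geometry — not that the shipped
thresholds would transfer to real scanners unchanged.

## Threshold annotator

`classify_pixels()` assigns each pixel one of four classes with priority
tumor > normal > background > remainder:

* tumor: deconvolved chromogen concentration ≥ 0.30;
* normal: hematoxylin concentration ≥ 0.30, blue chromaticity ≥ 0.36, and
  deconvolution reconstruction residual ≤ 0.35 OD;
* background: brightness ≥ 0.88 and saturation ≤ 0.08;
* remainder: everything else.

The residual gate encodes that material poorly explained by the stain
basis cannot be a counterstained nucleus. It matters for melanin under the
Fast-Red basis: dark pigment unmixes partly onto hematoxylin and is
blue-ish enough to pass the other normal gates, but its reconstruction
residual (≈ 0.48 OD at granule darkness) betrays it. Under the DAB basis
melanin reconstructs well (≈ 0.30 OD residual) — which is exactly why
brown pigment and brown chromogen are confusable, and why the
pigment-as-tumor failure mode of brown-chromogen thresholding survives the
gate, as it should.

The published description lists the ingredients (red/blue chromaticity and
contrast preprocessing, color deconvolution) but not the gate formulas or
values, so this is the smallest gate set consistent with that list; the
numeric defaults are declared constants chosen on simulator output, and
any gate set to `NA` falls back to Otsu's threshold per image. An optional
local-contrast window sharpens the hematoxylin channel before gating. The
tumor gate of 0.30 sits well below the nuclear chromogen intensity (≈ 0.8)
and well above the Fast-Red response of pigment (≈ 0), and classifies pale
nuclei (≈ 0.17) as negative — which is precisely the mechanism by which
pale/absent marker expression turns tumor nuclei into false-positive
*normal* annotations in metastases.

## Registration and label transfer

`estimate_transform()` recovers translation by phase correlation on
luminance, with optional affine refinement by least squares on matched
dark-blob centroids; the residual is the RMS distance of matched centroids
after alignment. Blank tiles raise an error rather than silently returning
the identity. Label masks are warped with nearest-neighbor interpolation
only (`transfer_labels()`): class codes are categorical and interpolation
would invent classes. Pixels mapping outside the source frame become
background. A configurable residual limit (default 3 px) excludes badly
aligned pairs from training export, mirroring the "skewed alignment"
error class.

## Postprocessing

`refine_mask()` applies per-class closing/opening with a disc brush and
reclassifies components outside [10, 600] µm² (defaults) to remainder; an
optional surround rule reassigns a nucleus component when the other
nucleus class dominates its dilated neighborhood by more than 2:1.
`split_clusters()` runs a distance-transform watershed; its tolerance
parameter is the h-maxima depth (operation default 2 px). Blobs whose
deepest convexity defect exceeds 3 px afterwards are re-split at half
tolerance. The original pipeline used a proprietary "polynomial blob
filter" with no published definition; the convexity-defect pass is this
package's stand-in with the same goal (separating merged blobs) and a
testable contract. Splitting never changes which pixels are foreground.

The shipped end-to-end composition (`annotate_pair()`) uses watershed
tolerance 1 px: on simulated lesions the dominant error is *under*-splitting
of touching normal nuclei, and the finer tolerance halves the tumor-burden
error (maximum ≈ 3 percentage points over 20 seeded scenes at the 320 px
desk scale) without inducing spurious splits of the larger tumor nuclei.
The per-application compositions of the original study were unspecified;
one shared default composition is used everywhere.

## The compact U-net

The classifier network is a canonical encoder–decoder with skip
connections, implemented in C++ (RcppArmadillo) inside the package: 3×3
convolutions via im2col, 2×2 max pooling, nearest-neighbor upsampling,
softmax cross-entropy with an ignore class (label 0 contributes zero loss
— only annotated pixels supervise training, so missed annotations merely
shrink the training set), and Adam. Both published training regimes are
expressible: 3-band input (IHC RGB) and 6-band input (H&E + IHC RGB
concatenated). The desk-scale defaults are depth 2 and 8 base channels on
64 px tiles with a learning rate of 1e-3; the published whole-slide regime
(512 px tiles, rates 1e-6/1e-7, hundreds of thousands of iterations) is
reachable through the same configuration object but is not a desk-scale
exercise. Checkpoints are evaluated every `checkpoint_every` iterations
and the best one by (validation or training) pixel accuracy is kept,
mirroring selection of a mid-training checkpoint by monitored performance
rather than the final iterate. Training is single-threaded and
bit-deterministic for a fixed seed; subnormal floating-point values are
flushed to zero in the numeric core, which changes results by strictly
less than the optimization noise and avoids order-of-magnitude slowdowns
in decayed channels.

Normal-nucleus labels can be dilated into an auxiliary "cluster" class
(`dilate_normal_labels()`) that augments but never overwrites tumor
labels; the dataset builder merges it back into the normal class for the
loss. Feature maps are classified by box mean filtering followed by
per-class thresholds with argmax among passing classes
(`classify_feature_maps()`); pixels passing no threshold become remainder.

The 3-band vs 6-band comparison in the test suite trains on simulator
ground-truth masks rather than threshold-annotator output, so that the
measured difference isolates the information content of the input bands:
unspecific red dots exist only in the IHC rendering, and only the H&E
bands reveal that they lack a nucleus.

## Quantification and stereology

`tumor_burden()` is a pure count ratio (areas play no role). The
stereological reference uses an unbiased counting frame of 30 µm × 25 µm —
the published "30 µm² × 25 µm²" is read as edge lengths, the standard
frame convention — with inclusion edges top and right and a forbidden line
running from above the top-left corner down the left edge, along the
bottom edge, and downward from the bottom-right corner. Counting is by
boundary contact, not centroid. Frames tiling the plane count every
object exactly once; the test suite checks this identity exactly.
Systematic-random sampling places a square grid with cell area
`roi_area / n_fields` at one uniform random offset and keeps fields whose
centers fall in the ROI, so a fixed point is covered with probability
field-area/cell-area — the Monte-Carlo inclusion test checks this against
the closed form.

## Validation statistics

Precision (TP/(TP+FP)) is the headline annotation-quality metric, since
false negatives only shrink an IHC-supervised training set. All proportion
intervals are Wilson score intervals with z = 1.959964; this value (rather
than 1.96) reproduces every printed reference interval at one-decimal
rounding, including the degenerate k = n rows. Reported percentages round
half away from zero to one decimal; internal values keep full precision.
Proportion differences use an unpooled Wald interval and a pooled-SE
z-test. Pixel-level evaluation uses a 3×3 confusion matrix over tumor /
normal / background (remainder merges into background), with one-vs-rest
metrics and support-weighted averages; a class never predicted reports
precision 0 with an explicit flag. Agreement between burden estimates uses
Bland–Altman limits of agreement (mean ± 1.96 SD) with a t-based CI on the
mean difference. Object matching is centroid-in-nucleus with greedy
assignment by centroid distance (an IoU rule is available); the matching
rule of the original study was visual and unstated, so the default is the
simplest deterministic rule, and tests confirm it attains the exhaustive
maximum matching on well-separated scenes.

The bundled `example_annotation_counts()` table carries the printed TP/FP
counts this module is validated against. One aggregate row of the
metastasis table is internally inconsistent in its source (its printed
aggregate TP differs from the sum of its printed subgroup TPs, and its
printed interval derives from the subgroup sum); the table therefore
carries both count sets, as documented on the data page.

## Desk-scale study conditions

The test suite and the acceptance script run the pipeline at reduced but
fixed sizes, chosen once: 320 px tiles with 22 tumor and 16 normal nuclei
for burden recovery (20 seeds); 256 px pigmented tiles (pigment density
1500/mm², 18 tumor nuclei of 5.5 µm) for the chromogen comparison
(20 seeds per chromogen); 96 px tiles with dense red dots and a
160-iteration, base-6 network trained on two scenes for the paired 3- vs
6-band comparison (20 seeds); a 300-iteration overfit check on four 64 px
tiles; and
10–14 counting frames per 320 px lesion for the stereology agreement
check. Nucleus radii are slightly reduced at the small tile sizes so the
configured counts always fit. These are the package's chosen desk-scale
study conditions; enlarging them only tightens the same checks.

## Known limitations

* The stain vectors are fixed constants; per-slide stain estimation and
  normalization are out of scope.
* The threshold gate values are calibrated to the simulator's optical
  model, not to any scanner.
* The affine registration refines a translation estimate; elastic
  whole-slide registration is out of scope.
* The convexity-defect splitter is a documented stand-in for an
  unpublished proprietary primitive.
* Simulated lesions cannot establish clinical performance; slide-level
  results from the original study that depend on its specimens and its
  trained network are deliberately not reproduced.
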