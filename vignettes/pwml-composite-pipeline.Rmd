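---
title: "Composite-image synthesis and detection evaluation for punctate white matter lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-image synthesis and detection evaluation for punctate white matter lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmltools)
```

## The problem

Punctate white matter lesions (PWMLs) are small, focal, often multiple
T1-hyperintense foci in the periventricular white matter of preterm and
term infants. Their number and location carry prognostic weight, so
reliable detection on screening MRI matters — but each infant carries only
a handful of lesions, and assembling a large annotated training corpus
from patients alone is rarely feasible. A practical workaround is
copy-paste synthesis: extract the lesions from the few available
lesion-rich cases, paste them at anatomically plausible positions into the
many available normal scans, and train an object detector on the resulting
composites.

`pwmltools` implements that synthesis protocol end to end, together with
the evaluation stack used to score any detector's output against ground
truth. Because clinical images cannot ship with a package, a geometric
brain-slice phantom with exactly known tissue maps and injectable lesions
stands in for the scans; every stage, from patch extraction to
threshold-swept sensitivity/PPV tables, runs on it deterministically.

## The phantom and what it does (and does not) emulate

A slice is a brain ellipse with a bright cortical ribbon of fixed
thickness, a darker unmyelinated white-matter interior, and two dark
ventricles that meet at the midline (so CSF is one connected structure and
the white matter one connected region). Intensities are per-tissue means
plus Gaussian noise, quantized to 8 bits; defaults follow the T1
appearance of the neonatal brain (cortex brighter than white matter, CSF
dark) at 0.83 mm in-plane resolution on a 256 px canvas. Small seeded
jitter of the axes, centre and ventricle size emulates slice-to-slice
anatomical variability; the amount of jitter is a package choice, since no
real-data estimate of it is available at this level of abstraction.

Lesions are isotropic Gaussian intensity bumps of amplitude `contrast`
above the local white matter, truncated at 2σ. The lesion *mask* is the
quarter-peak level set, so the `diameter_px` parameter (default 2–6 px ≈
1.7–5 mm at 0.83 mm/px) is the mask diameter. Per-case lesion counts are
drawn from a rounded normal with mean 6.0, SD 5.4, truncated to 1–19 — the
per-infant distribution the generator emulates; the held-out test group
uses 1–17, mean 5.1, SD 4.7.

The phantom deliberately omits bias fields, partial-volume gradients, 3D
continuity, gyral folding and scanner-dependent noise spectra. Passing
tests therefore demonstrate that the *pipeline machinery* is correct —
counts, geometry, statistics, file formats — not that any particular
detector will perform equally well on clinical data.

## Normalization

Interactive auto-contrast/auto-tone adjustments reduce, on a single
grayscale channel, to a percentile-clipped linear stretch. `auto_contrast()`
clips 0.1% of pixels at each tail by default (the conventional default of
such tools; the exact fractions any operator used are unknowable, so they
are parameters), maps the rest linearly to 0–255, and re-quantizes by
rounding half away from zero. The clip endpoints are order statistics, the
mapping is monotone, constant images pass through unchanged, and a second
application changes no pixel by more than one level.

## Lesion extraction

`extract_lesions()` models interactive auto-selection of punctate lesions
as seeded region growing against robust local background statistics:

1. **Local background.** A sliding median and MAD (31×31 window) give a
   per-pixel location/scale estimate. Robust statistics are essential, not
   cosmetic: periventricular lesions sit near tissue interfaces, where a
   windowed mean/SD is wrecked by cortex or CSF pixels. Candidate pixels
   exceed the local median by `k_sigma` (default 3) robust SDs.
2. **Seeding.** A candidate component must contain a pixel at
   `seed_k_sigma` (default 4.5) SDs — the analogue of clicking the wand on
   an unambiguous bright spot. Component background is then re-estimated
   from the surrounding window with all candidate pixels excluded,
   restricted to white matter when a tissue map is supplied and otherwise
   mode-trimmed, for the same interface-contamination reason.
3. **Mask.** The mask is grown from the component at the quarter-peak
   level (the same level-set convention that defines the injected lesions),
   clamped to at least two-thirds of the detection threshold so it cannot
   reach into background noise; the level set is evaluated on a 0.5 px
   Gaussian-smoothed copy so single rim pixels do not flicker in or out.
   Patch intensities stay raw.
4. **Inclusion rules.** Area must lie in `[min_area, max_area]`
   (default 2–40 px; "widespread" lesions excluded), elongation — the ratio
   of the square roots of the principal second central moments, with the
   1/12 single-pixel term, so a 3×15 streak scores exactly 5 — must not
   exceed 3 ("linear" excluded), peak contrast must reach `min_contrast`
   (default 10; "faint" excluded), and the integrated contrast-to-noise
   ratio `sum(excess)/(sd·sqrt(area))` must reach `min_blob_snr`
   (default 8). The last rule is what separates a genuine 3 px focus from a
   chance pair of bright noise pixels: a real lesion integrates contrast
   over its whole extent, a noise cluster does not, and no single-pixel
   threshold can split the two without sacrificing either recall or
   precision.

With these defaults, extraction over seeded phantoms recovers every
injected lesion of diameter ≥ 3 px at default contrast with no spurious
patch (the package's recovery property). Diameter-2 lesions can quantize
to single-pixel masks, which the minimum-area rule then excludes — the
same behaviour as excluding sub-resolution dots in manual reading.

## Compositing

`build_composites()` pairs every lesion-bearing slice with every normal
background — L slices × B backgrounds gives exactly L·B composites, the
arithmetic that produces the canonical 936 from 13 slices and 72 normals.
The white matter is divided into three equal anterior-to-posterior bands
(frontal through parietal); each patch is assigned a band by the
anterior-posterior rank of its source centroid and pasted at a position
drawn uniformly from band pixels whose distance transform guarantees the
whole footprint stays ≥ `margin` px (default 2) from any non-white-matter
pixel. Rejection sampling then only has to resolve overlaps between
patches, so placement cannot fail for geometric reasons under any seed.
Where the patch mask is true the background takes the patch values, with a
1 px Gaussian feather inside the mask edge (no intensity re-matching — both
sides are already normalized); every other pixel is bit-identical to the
background. Ground-truth boxes are the tight bounding boxes of the pasted
masks, 0-based and half-open.

The two-source-case fixture (`make_source_cases()`) regenerates the
study conditions: two cases carrying 19 and 17 lesions over 13 slices,
each slice lesioned, normalized and run through real extraction — not
injection records — so the compositor consumes what the bank produces.

## Augmentation

The fixed six-fold set: original, left-right flip, 0.95× and 1.05×
scaling, ±15° rotation. The ×6 multiplier implies the original is retained
alongside the five transforms (600/100 = 6). Scaling and rotation act
about the image centre on the original canvas (centre crop/pad), bilinear,
fill 0 — the canvas-preservation convention had to be chosen, and centre
crop/pad is the least surprising. Boxes ride through the same continuous
affine map; rotated boxes become the axis-aligned hull of their four
mapped corners, clipped to the canvas, and boxes below one pixel after
clipping are dropped with a warning. Image and box geometry share one
coordinate convention (pixel *i* spans `[i, i+1)`), which the test suite
pins down with a rasterization oracle.

## Annotations, split, detections

Pascal VOC XML uses labelImg's 1-based closed corners
(`xmin_voc = x_min + 1`, `xmax_voc = x_max`), so integer boxes round-trip
exactly. YOLO darknet lines are normalized to six decimals (sub-pixel at
any practical canvas). The train/validation split shuffles ids under a
seed and takes `floor(0.8·N)` for training — 748/188 on 936. Detections
interchange as JSON with probabilities in percent, matching the
detection-probability-threshold convention.

## The reference detector

`detect_lesions()` is a deterministic classical stand-in so the full
compose → annotate → detect → evaluate loop runs without any training: a
scale-normalized Laplacian-of-Gaussian filter bank at radii 1–4 px, local
maxima across space and scale inside an Otsu head mask, greedy NMS, and a
score of 100·response/max-response per image. The score is monotone in
response but *not* a calibrated probability; with per-image normalization
the strongest response is usually a cortical boundary, so the stand-in's
absolute PPV is low even while its false positives concentrate in the
cortex — the qualitative pattern that the false-positive localization
protocol exists to measure. The evaluation stack consumes detection JSON
from any source, so a trained network's output is scored identically.

## Evaluation

Matching is greedy in descending probability, one truth per detection;
`"iou"` mode (default threshold 0.5) is the object-detection convention,
`"center_in_box"` accepts a detection whose box contains the truth's
centre — the appropriate rule for targets a few pixels across, where IoU
between two honest small boxes is dominated by quantization (the pipeline
default). For disjoint truths at IoU ≥ 0.5, greedy matching provably
attains the maximum matching (a detection cannot overlap two disjoint
truths at ≥ 0.5 each); the oracle suite verifies this against exhaustive
search. Sensitivity TP/(TP+FN) and PPV TP/(TP+FP) are swept over the
20/30/40/50% thresholds; TP+FN equals the number of ground-truth lesions
at every threshold, and undefined ratios are reported as missing, not
zero. False positives are localized by majority tissue label among in-box
pixels restricted to cortex vs white matter (ties to cortex, neither →
"other"). TP-vs-FP score distributions are compared by Mann–Whitney
(exact for tie-free samples with n1·n2 ≤ 400, else normal approximation
with tie and continuity correction, via `stats::wilcox.test`); medians and
IQRs use linear-interpolation quantiles, a convention that had to be
fixed. Average precision is the all-point precision-envelope area; the
externally-reported mAP flavour of any given training library is unknown,
so absolute AP is reported but never asserted against.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains every stage under one seed; each stage draws from
a named substream (`derive_seed(seed, stage, index)`, a 31-bit fold hash),
so any stage can be re-run in isolation and reproduce its in-pipeline
numbers, and a rerun of the same configuration is bit-identical. The
default configuration is the full study condition (72 normals, 13 lesion
slices, sets 100/200/400/600, 32 held-out test cases). Evaluation runs on
the held-out lesioned phantoms, never on augmented composites — that
mirrors the assessment-on-unseen-patients protocol and avoids warping
tissue label maps through the augmentation transforms. The package's
acceptance script exercises the corpus arithmetic at full scale (936
composites; augmentation counted without materializing 3600 warped
images) and the detection metrics at a reduced scale (12 backgrounds, 16
test cases), sizes chosen to keep a complete from-scratch run around a
minute on one CPU.

## Numerical choices and degenerate inputs

8-bit quantization rounds half away from zero everywhere, so in-memory
values and written PNGs agree. Constant images normalize to themselves and
yield no detections. Empty box lists write valid empty annotation files.
PPV with no retained detections is `NA`. The robust scale floor is 0.75
intensity levels, so noise-free synthetic regions cannot produce a zero
threshold. Ties in the anterior-posterior patch ranking break by source
order; ties in FP localization break toward cortex.

## Known limitations

The phantom's simplicity means detector metrics obtained on it do not
transfer to clinical data; the package's claims are about pipeline
correctness. The reference detector is intentionally crude and
uncalibrated. Compositing pastes at native orientation and intensity (no
rotation or intensity modulation of patches), matching the protocol it
implements; richer harmonization (Poisson blending, noise matching) is out
of scope. Only single slices are modelled — no 3D lesion continuity, no
across-slice context.
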