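---
title: "Quantifying gene expression along a curved leading edge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression along a curved leading edge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonquant)
```

## The measurement problem

During dorsal closure, the leading edge (LE) of the *Drosophila* embryonic
epidermis is a single curved row of cells in which JNK signalling drives
the expression of a set of target genes. Fluorescent in situ hybridisation
shows that this expression is not uniform: it varies along the
anterior-posterior axis, and within each body segment it differs between
the anterior compartment (on average seven of the ten LE cells per
segment) and the posterior, En-expressing compartment (the remaining
three). To compare genes and genotypes quantitatively, the signal must be
read off a curved, hand-traced path, assigned to segments of unequal
pixel length, and placed on a common per-cell coordinate so embryos can
be pooled.

`ribbonquant` implements that measurement as four pre-treatment steps
followed by the quantification proper:

1. **Background correction.** The background is the median pixel
   intensity inside an operator-drawn polygon over the amnioserosa, the
   signal-free tissue enclosed by the two leading edges. The median is
   used because the amnioserosa occasionally contains bright debris; a
   mean would follow such specks. Correction is subtraction, and any
   resulting negative intensity is set to 0 — expression below background
   is reported as absent, not negative. The clamp is applied to the
   profile before any binning, so no bin can average a negative value
   away.
2. **Ribbon extraction and straightening.** A cubic spline is fitted
   through the traced midline points and re-parameterised by arc length,
   so that one unit of the curve parameter `s` is one micrometre of
   leading edge regardless of curvature. The image is then resampled on a
   regular grid of `s` (along the curve) and `t` (signed offset along the
   unit normal), with bilinear interpolation. Samples falling outside the
   image are masked and excluded from every mean, never zero-filled,
   because zero-filling would bias the profile downwards near image
   borders.
3. **Segment splitting.** Segment boundaries arrive as arc-length
   positions in the annotation file (in practice placed with the help of
   an En co-staining; `suggest_boundaries()` proposes candidate positions
   at Otsu-threshold up-crossings of the marker profile, but the
   annotation always wins). Segments are half-open intervals
   `[s_i, s_{i+1})`: a sample exactly on an internal boundary belongs to
   the posterior-adjacent segment, a deterministic tie-break; the last
   segment also includes its upper endpoint so the final sample is not
   dropped. When no marker is available, an `equal-10` mode splits the
   profile into ten equal-length segments.
4. **Length normalisation.** Each segment profile is resampled by linear
   interpolation onto `10 k` equally spaced midpoints (`k >= 4`,
   increased for well-sampled segments) and averaged within each tenth.
   The ten bins play the role of the ten LE cells. Because the bins have
   equal length by construction, the mean of the ten bin means equals the
   whole-segment mean `d_LE` exactly; this conservation property is
   asserted to 1e-9 in the tests. Resampling at bin midpoints (rather
   than binning raw samples with unequal counts) is what makes the
   identity hold for segments whose pixel count is not a multiple of ten.

The per-segment outputs are `d_LE` (mean signal over the segment) and
`d_NS` (the ten bin means of the length-normalised segment). The
parasegmental boundary is placed between bins 7 and 8, so the anterior
compartment mean is the mean of bins 1-7, the posterior mean that of bins
8-10, and the AP ratio their quotient (undefined, reported as `NA`, when
the posterior mean is 0).

Two pooling conventions mirror the two analyses usually reported: the
AP-axis analysis averages each segment's `d_LE` across embryos (n =
embryos, typically 15-20), while the compartmental analysis averages each
cell bin across all segments of all embryos (n = pooled segments,
150-200 at 10 segments per embryo). In both, s.e.m. = s.d. / sqrt(n), and
with a single contributing record the dispersion is written as an empty
field rather than 0.

```{r pipeline-example}
emb <- make_embryo(embryo_spec(image_size = c(512, 1024), pixel_size = 0.5,
                               midline_amplitude = 15, midline_period = 200,
                               center_row = 300, seed = 1))
q <- quantify_embryo(emb$signal, emb$annotations, embryo_id = "demo")
round(q$segments[[1]]$d_ns, 3)
compartment_stats(q$segments[[1]])$ap_ratio
```

## Tunable parameters

* `half_width` (default 5 um): normal extent of the straightened ribbon
  on each side of the midline. The source acquisitions do not fix this
  number; 5 um is about the apical extent of an LE cell and must stay
  below the expression band's own half width so the mean is not diluted
  by surrounding tissue. `straighten()` warns when
  `half_width * max_curvature >= 1`, the regime where the normal fan
  self-intersects.
* `step` (default: one pixel size): sampling step along both ribbon axes.
  One pixel is the natural resolution; finer steps only interpolate.
* `smoothing` (default 0): `spar` of a smoothing spline for noisy traces;
  0 interpolates the clicked points exactly.
* `n_bins` (default 10) and `anterior_bins` (default 1:7): the per-cell
  grid and the compartment split.
* `min_pixels` (default 25) for the background ROI: a smaller region
  makes the median unstable.

## Closure kinematics

The dynamics functions measure tissue sealing from annotated time-lapse
contours (the two opposing leading edges and the two canthi per frame,
in micrometres). Definitions and conventions:

* `L` is the canthus-to-canthus span projected on the AP axis; the seam
  (already fused LE) is the onset extent minus `L`. The closure stage
  %DC is `100 * seam / L0` with `L0` the onset extent — the onset
  denominator makes the stage variable bounded (0 at onset, 100 at full
  closure) and monotone, which a current-`L` denominator would not.
* The height `H` between the contours is measured along the image
  vertical at fractional stations of `L` (defaults 1/8..7/8, bounding the
  8 reported subdomains), with linear interpolation along the
  piecewise-linear contours.
* Closure speed is the negated least-squares slope of `H(t)` within each
  closure-stage bin, in nm/s, positive while closing. Whether published
  "speed of closure" values mean dH/dt or a per-flank dH/dt divided by
  two is not stated in the sources this design follows; dH/dt is used
  here, so comparisons to published per-stage values are qualitative.
  Stage-bin edges belong to the later bin; fully closed frames (H
  identically 0) are excluded from the fits so the per-bin relation
  stays linear.
* The final closure point is the station (fraction of the onset span,
  anterior = 0) where `H` last exceeds 1 um, a sub-pixel threshold at the
  usual magnifications. Symmetric canthus rates close at 0.5; rates
  `r_A : r_P` meet at `r_A / (r_A + r_P)`.
* Zipping-zone lengths and closure-delay distances are Euclidean
  distances between operator-marked points, exactly as they would be
  measured interactively on the micrograph.

## What the synthetic generator does and does not emulate

`make_embryo()` renders a 2048 x 2048 px field at 0.25 um/px (matching
the 2048 x 2048 12-bit acquisitions this pipeline targets; the confocal
pixel size is not published, and all conversions go through the
annotation's `pixel_size_um` anyway). The leading edge is a sinusoid of
25 um amplitude and 250 um period — a gentle curvature, about what an
embryo flank shows — carrying a 12 um-wide band whose value in segment
`i` is `a_i` over the anterior 70% and `p_i` over the posterior 30%
(defaults 0.6 and 0.3 on a 0-1 a.u. scale, over a 0.05 background, i.e.
a 2:1 AP ratio). Additive Gaussian noise (s.d. = 5% of the strongest
amplitude) is clipped at zero; the band is extended a few pixels past
both quantification limits, as real tissue continues past T1 and A7. The
marker channel carries one noiseless stripe per posterior compartment,
giving `suggest_boundaries()` an analytic truth. Ten segments are
labelled T1-T3, A1-A7.

`make_closure_series()` programs a 300 um opening with a 60 um apex
closing at canthus rates of 16 and 12 nm/s (sum chosen so closure takes
about three hours; anterior faster, matching the known asymmetry) in
300 s frames; contours are elliptical arcs whose apex shrinks
proportionally to the remaining span, so `H` at a fixed fraction of `L`
declines linearly under constant rates.

Passing the recovery tests on these fixtures shows that the geometry,
normalisation and bookkeeping are correct at realistic noise levels. It
does not show robustness to what the generator omits: non-Gaussian
(photon) noise, uneven illumination or bleaching gradients, tracing
error in the midline and boundary annotations, out-of-plane signal
surviving the maximum projection, or contours that fold back over the
AP axis. Those enter real measurements through the operator's
annotations, which this package deliberately treats as ground truth.

## Numerical choices and degenerate inputs

* Bilinear interpolation for all image sampling; test tolerances (1e-3
  of the dynamic range for the radial-field oracle) account for it.
* The midline spline is resampled densely (at least 1000 points) for
  arc-length re-parameterisation; the unit-speed property holds within
  1% and normals are perpendicular to machine precision.
* Otsu's threshold for stripe detection is computed by exact exhaustive
  search over the sorted profile values (no histogram binning), cutting
  only between distinct values; a flat marker profile is an error, a
  single stripe covering the whole profile returns its start flagged
  degenerate.
* A segment with no finite samples is an error; a segment with a single
  sample is treated as constant.
* `mc_oneway_test()` uses the between-group sum of squares as statistic
  (any permutation-exchangeable F-type statistic gives the same p-value
  under enumeration), centres the data so the permutation comparison is
  shift-invariant, and reports the add-one estimate
  `(1 + hits) / (1 + B)`, which cannot be 0. Dunnett, Kruskal-Wallis and
  Fisher's exact comparisons are delegated to standard R routines and
  are not re-implemented here.

## Problem sizes used by the test suite

Unit tests run on 512 x 1024 px fixtures; the end-to-end recovery checks
use 15 full-size (2048 x 2048) embryos, 1000 random segments for the
conservation property, and 1000 simulated null datasets (199 resamples
each) for the calibration of the permutation test — sizes chosen to
exercise the study conditions while keeping a full run in tens of
seconds on one core.

## Known limitations

* No automatic LE detection or contour tracking: midlines, contours and
  marks are operator annotations by design.
* "Cells" are equal-length bins, not segmented nuclei; genuine per-cell
  variation within a compartment is averaged.
* The %DC denominator and the dH/dt speed convention (above) are package
  choices where the conventions in the literature are ambiguous;
  cross-study comparisons should check which convention was used.
* Only maximum-intensity Z-projection is supported, matching how this
  kind of data is acquired and keeping parity across datasets.
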