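---
title: "Rotation- and scale-invariant texture description with ffirst: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ffirst methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffirst)
```

## The problem

Bark patches and scanned leaves are textures whose appearance changes
with camera rotation, distance and illumination, while species identity
does not. `ffirst` implements a texture descriptor that is invariant to
in-plane rotation and to affine intensity changes, robust to moderate
scale changes, and aware of object segmentation (a leaf's interior and
its serrated border carry different information), together with a
calibrated linear-SVM classification pipeline.

## The descriptor

### Local binary patterns, sign and magnitude

At each pixel, the intensities at P points on a circle of radius R are
compared with the centre. The sign code sets bit p when
`f(x,y) - f(x_p,y_p) <= 0` (ties give 1); the magnitude code sets bit p
when `|f(x,y) - f(x_p,y_p)|` does not exceed the threshold `t_p`, the
mean absolute difference of neighbour p over all described pixels.
Off-grid samples are bilinearly interpolated, which is exact on linear
intensity ramps and makes analytic tests possible. Both codes are
invariant under `a*f + b` (a > 0): differences scale by `a`, the
thresholds scale with them, and all comparisons (including ties) are
preserved exactly.

Sample-point geometry: neighbour 0 sits east, angles grow
counter-clockwise, and bit p carries weight `2^p`. For P divisible by 4
the offset table is built from the first quadrant and completed by exact
quarter-turn rotations, so a 90-degree image rotation permutes the
sample set exactly and code images are bit-equivariant under quarter
turns.

### Rotation invariants from orbit histograms

Rotating the image by one angular step (2*pi/P) turns each code into its
cyclic bit rotation. The 2^P codes therefore split into rotation orbits
(binary necklaces); for P = 8 there are 36 orbits, of sizes 1 (x2), 2,
4 (x3) and 8 (x30), and the count matches the closed form
`(1/P) * sum_{d|P} phi(d) 2^(P/d)`. The occurrence histogram is
collected per orbit, ordered by rotation index; an image rotation
cyclically shifts each orbit's histogram. Taking the DFT along the orbit
turns that shift into a pure phase, so the DFT magnitudes are rotation
invariants. An orbit of period d gets a length-d DFT and contributes
`floor(d/2)+1` magnitudes (the histogram is real, so the spectrum is
conjugate-symmetric): 163 values per code type in full mode. In uniform
mode only the 7 eight-member orbits of uniform patterns (at most two
circular 0-1 transitions, 0 < ones < 8) are transformed (5 magnitudes
each), plus three extra bins: the two constant patterns and the pooled
non-uniform mass - 38 values per code type.

The choice of a **period-length DFT** for the smaller orbits is ours:
the defining transform is written for full-period orbits, and a
length-d DFT is the unique choice that keeps the invariance exact for
symmetric patterns.

### Adjacent-orbit invariants

The first DFT coefficient of each orbit retains rotation information in
its phase; the product `z = H(n,1) * conj(H(n+1,1))` of two orbits of
the same period cancels it. We emit two real features per adjacent
same-period orbit pair (canonical order): `Re(w)` and `Im(w)` with
`w = z / sqrt(|z|)`.

Two design points deserve a note:

* **Same-period pairing.** Under a rotation by k steps an orbit of
  period d picks up the phase `exp(-2*pi*i*k/d)`; pairing orbits of
  different periods would leave a residual phase and break invariance.
  We therefore pair only consecutive same-period orbits (for P = 8 in
  full mode: 2 period-4 pairs and 29 period-8 pairs; uniform mode: 6
  pairs). This is forced by the invariance requirement itself.
* **`z/sqrt(|z|)` rather than the principal square root.** Both have
  magnitude `sqrt(|z|)` - the scale that matches the plain magnitudes -
  but the principal square root has a branch cut along the negative
  real axis, and measured z values land near it: floating-point noise
  then flips the sign of the imaginary part and invariance fails at the
  1e-9 level. `z/sqrt(|z|)` is continuous everywhere and exactly
  invariant.

These signed features are split into positive/negative parts before
kernel mapping, which requires non-negative inputs.

### Multi-scale stack

Radii grow geometrically, `R_1 = 1`, `R_i = R_{i-1} * sqrt(2)` (each
step halves the image area), with the effective sample radius
`r_i = R_i * sin(pi/P)` chosen so neighbouring samples' effective areas
touch. Before sampling at scale i the image is filtered with an
isotropic Gaussian of `sigma_i = r_i / 2`, which places about 95% of the
filter mass inside the effective area; filtering is skipped when
`sigma_i < 0.3`, where the discrete kernel degenerates to (almost) a
delta. The sigma rule is our realization of the mass criterion - no
explicit sigma is prescribed by the method's sources. Boundary handling
is reflective, which commutes with quarter-turn rotation on square
images and so preserves exact equivariance.

Descriptors of `c` adjacent scales are concatenated, and the window
slides over the `S` scales, producing `n_conc = S - c + 1` multi-scale
vectors per region. Defaults `S = 8, c = 5, n_conc = 4` span radii 1 to
11.31 - chosen to cover the radii the method illustrates; the source
material does not print S, c, n_conc, so they are configuration
parameters. Each window vector is L1-normalized (region sizes vary
enormously between a bark patch and a thin leaf border; the kernel map
expects histogram-scale inputs). Rescaling an image by `1/sqrt(2)`
shifts the per-scale sequence by one index, which is what makes the
max-posterior fusion over windows tolerate scale changes; the
acceptance suite checks a correlation of at least 0.95 for the shifted
alignment.

Empty regions are flagged: a window is empty when all its scales had an
empty region, and empty windows are zero vectors excluded from training
and from posterior fusion, never silently included.

## Segmentation-aware description

A segmented object region is split per LBP radius: border pixels are
the mask pixels with at least one sample point outside the mask (the
image frame always counts as outside; no padding is invented), interior
pixels are the rest. A sample point is "inside" only when every pixel
with nonzero bilinear weight is inside - an exact, testable rule rather
than a morphological approximation. Five recognition variants use this
split: `a` (whole region), `i` (interior only), `b` (border only), and
the fusions `ibsum`/`ibprod` which score each class by the maximum over
windows of the sum/product of interior and border posteriors.

Leaf-style masks come from Otsu's threshold on the 256-bin histogram of
min-max normalized intensities (first maximum on ties - on histograms
with an empty gap between modes the criterion is flat across the gap,
so the tie rule matters for determinism), followed by largest
8-connected component and hole filling by background flood fill from
the frame. The component/hole post-processing is our choice; the
sources only state thresholding.

## Classification

Windows are mapped through an explicit feature map of the histogram
intersection kernel (chi-square offered as an option): each
non-negative input dimension expands into 3 components built from the
kernel signature `kappa(l) = 2/(pi(1+4l^2))` sampled with period L. The
period matters: the approximation error is U-shaped in L, and the
package default L = 0.84 was fixed by a numeric study minimizing the
worst-case relative error of mapped inner products on L1-normalized
inputs (~4%; the acceptance bound is 5%). For chi-square
(`kappa(l) = sech(pi l)`) the tuned default is L = 0.60.

One linear SVM per class (one-vs-all) is trained on every non-empty
window of every training image (window-as-sample is the only reading
compatible with taking the maximal posterior over windows at
prediction time) by dual coordinate descent on the L2-regularized
hinge-loss dual, with an augmented bias feature and deterministic,
seeded permutations. Platt sigmoid parameters are fitted per class with
the robust Newton iteration on 3-fold cross-validated decision values;
folds are split by image so windows of one image never straddle a fold,
avoiding optimistic calibration. Posteriors are used raw (not
renormalized across classes) so they remain comparable between the
one-vs-all machines. The cost parameter defaults to C = 1; optional
tuning (`tune_C`) runs a 5-fold cross-validated grid
{0.01, 0.1, 1, 10, 100} with ties preferring the smaller C.

Evaluation reports the mean reciprocal rank
`MRR = (1/|Q|) sum 1/rank_i` and top-1/top-5 accuracy; rank ties count
strictly better scores plus tied classes of lower index, matching the
argmax tie-break.

## The synthetic world

All tests run on generated fixtures; nothing is downloaded.

**Textures.** Isotropic band-pass Gaussian noise. Because the
descriptor is rotation-invariant and the benchmark applies random
scaling in [0.8, 1.25], class identity must not sit in orientation and
*cannot* sit in absolute frequency alone: rescaling by s maps a band at
f to f/s, and self-similar single-band spectra of different classes
collide inside the stated scale range (this is an information-theoretic
fact about the fixtures, not a descriptor weakness). Class identity is
therefore a spectral code: five radial frequency slots at
`f0 * 1.68^(0:4)` (the 1.68 step exceeds the 1.5625 total scale spread,
so a rescaled slot grid can never align with a shifted copy of itself),
with each class activating a distinct pair of slots - the active ratio
set is invariant to rotation and scale, any two classes differ in at
least two slots, and all classes have equal energy. The default
`f0 = 0.044` puts the highest band at 0.35 cycles/pixel, inside the
Nyquist guard (0.45 after the strongest shrink).

**Leaves.** Serrated ellipses (radius modulated sinusoidally in
contour angle), dark interior texture on a near-white background, with
a narrow (2 px) distinct texture band along the contour and the true
mask emitted for segmentation tests. The "border-only" class family
shares the interior texture and overall shape and differs only in
serration and border-band frequency; with the narrow band, interior
descriptors of different classes are statistically indistinguishable
(checked by a permutation test), so any accuracy above chance for the
interior variant - and all of the border variant's accuracy - is
attributable to exactly the region that differs.

**What a green test does not establish.** The fixtures are stationary,
noise-free, perfectly segmentable and have exactly disjoint class
signatures; real bark and leaf data have none of these properties, and
the accuracies reached on fixtures say nothing about accuracy on real
collections - they verify the mechanics (invariances, recovery of a
recoverable signal, the ordering of region variants), not field
performance.

## Numerical choices and degenerate inputs

* Ties in both code comparisons follow `z <= 0 -> 1` exactly
  (bit-reproducibility).
* Sample offsets within 1e-9 of an integer are snapped, so samples that
  mathematically fall on grid points do not acquire zero-weight
  neighbours (this affects validity, not values).
* Histograms are normalized by the described-pixel count before the
  DFT, making descriptors comparable across region sizes; empty regions
  produce flagged zero descriptors, and prediction with no non-empty
  window is an error, not a guess.
* Constant images have no Otsu threshold (error); pure-white images
  fail segmentation loudly.
* The rotation-invariance acceptance test uses band-limited fixtures
  (top band 0.24 cycles/pixel) on a large disk: at higher bands the
  bilinear rotation operator itself attenuates content near Nyquist,
  and on small regions coarse-scale histograms are finite-sample noisy;
  both are artifacts of the test transform, not of the descriptor, and
  the test is designed so they do not dominate the quantity being
  verified.

## Known limitations

* Intensity-only: color is reduced to luminance (BT.601) by design.
* Raster I/O is limited to PGM (P2/P5) and CSV matrices in this
  environment; in-memory matrices are first-class everywhere.
* Segmentation targets objects on near-uniform backgrounds; natural
  backgrounds are out of scope.
* The solver stores dense mapped features; with the default
  configuration a training row is ~8600 doubles, fine for thousands of
  images, not for millions.
* `P > 24` is refused; orbit tables above P = 16 are slow and rarely
  useful.
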