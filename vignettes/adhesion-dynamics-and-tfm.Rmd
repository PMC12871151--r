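---
title: "Quantifying focal adhesion dynamics and traction forces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focal adhesion dynamics and traction forces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesionTFM)
```

## The problem

Integrin-based adhesions assemble at the leading edge of spreading cells as
diffraction-limited nascent adhesions (NAs), mature through focal complexes
(FCs) into focal adhesions (FAs), transmit traction to the substrate, and
disassemble. Quantifying this life cycle from two-channel TIRF time-lapse
movies (an adhesion marker such as paxillin plus a GFP-tagged protein of
interest, imaged every 20 s for about an hour) requires a chain of image
analysis stages, each with its own model assumptions. adhesionTFM implements
that chain — point-source detection, FC/FA segmentation and classification,
trajectory linking with maturation status, assembly/disassembly kinetics,
and traction force microscopy (TFM) — together with a synthetic-scene
generator whose ground truth is exhaustively known, so that every stage can
be validated end to end without any experimental data.

## Detection of nascent adhesions

NAs are modeled as isotropic Gaussian point sources of fixed width. The
default `sigma = 2.1` pixels corresponds to roughly 180 nm at the default
pixel size of 0.086 um/px — a diffraction-limited PSF at 60x
magnification. Detection proceeds in four steps:

1. **LoG filtering.** The frame is convolved with the negated,
   scale-normalized Laplacian of Gaussian at the PSF scale; bright blobs of
   matching width become positive response peaks. The kernel is exactly
   zero-mean, so constant backgrounds vanish.
2. **Local maxima and thresholding.** 8-connected maxima (raster-order tie
   break) are tested against a robust null model of the filtered response:
   the median and MAD of the response estimate the null location and scale,
   and a maximum is kept when its upper-tail p-value falls below
   `alpha / n_pixels`. This Bonferroni construction bounds the *expected
   number of false detections per frame* by `alpha` (default 0.05), a
   parameter-free and testable guarantee: the test suite measures the
   false-positive count on 100 pure-noise frames against the matching
   Poisson envelope.
3. **Sub-pixel localization.** Each surviving maximum is fit with
   \(A\,e^{-((x-x_0)^2+(y-y_0)^2)/2\sigma^2}+b\), sigma held fixed, by
   Levenberg-Marquardt. Non-converged or non-positive-amplitude fits are
   flagged and excluded, never silently dropped.
4. **Goodness-of-fit filtering.** A chi-square test on the standardized
   residuals within the fit window (degrees of freedom: window pixels minus
   the four fitted parameters) removes detections whose residuals are
   inconsistent with a point source plus i.i.d. noise, at `p < 0.05`. The
   frame noise scale is estimated from the MAD of horizontal pixel
   differences, which is insensitive to structures wider than one pixel.

The localization precision of the fixed-sigma fit is validated against a
numerically computed Cramér-Rao bound in the test suite.

## Segmentation and classification of FCs and FAs

The paxillin channel is smoothed with a small Gaussian (`smooth_sigma = 1`
px) and a large-radius median-filter background (`background_radius = 20`
px) is subtracted. The median background follows slow illumination
gradients but passes over adhesion-scale features, which keeps feature
contrast intact and makes the operation close to idempotent — both
properties are tested on planted fixtures.

The segmentation threshold combines two classical estimators: Otsu's
between-class-variance threshold (suited to bimodal histograms) and Rosin's
unimodal triangle threshold (suited to sparse images whose histogram is a
single background peak with a signal tail). Adhesion images move between
these two regimes as adhesion density changes, so the default combination
is the arithmetic mean; `mode = {"otsu", "rosin", "min", "max"}` are
exposed and both component values are attached to the result for audit.

Connected components use 8-connectivity. Components of 0.2 um^2 or less
are discarded outright; the remainder are classified by area with
boundaries closed on the left:

* area < 0.24 um^2 — `below_FC` (retained as a region, too small to be a
  focal complex);
* 0.24 <= area < 0.6 um^2 — `FC`;
* area >= 0.6 um^2 — `FA`.

Shape is summarized by the ellipse of equivalent second moments (with the
1/12-pixel variance correction); the eccentricity ratio is minor/major axis
length, 1 for a circle.

## Tracking, status, lifetimes

Frame-to-frame linking is a globally optimal linear assignment (Hungarian
algorithm) on squared displacement, with birth/death alternatives priced at
`search_radius^2` (default radius 3 px). Track ends may be joined to later
track starts across up to `max_gap = 2` missing frames, within a radius
scaled by the gap length. Every detection belongs to exactly one track —
singletons are tracks of length one — so the sum of track lengths equals
the number of detections, an invariant asserted in the tests.

Each tracked point is compared with the frame's segmentation to assign a
status: `FA` or `FC` when the position lies inside a region of that class,
`NA` when detected outside both, and optionally `BA` (before adhesion) for
back-extended frames preceding the first detection. Lifetimes follow the
convention (frames spanned, gap-closed frames included) x (frame
interval); tracks alive at the first or last movie frame are flagged
censored and excluded from default summaries. NA lifetimes are taken from
tracks that never overlap an FC/FA region; FC/FA lifetimes from tracks
containing FC or FA status at any point. A *nucleating* NA is a track born
after the first frame that persists at least `min_frames = 3` frames — an
operationalization, flagged as such in reports — and the maturing fraction
is the share of NA-born tracks that ever reach FC/FA.

## Assembly and disassembly kinetics

Background-subtracted intensity traces (the fitted Gaussian amplitudes)
are modeled as exponential in each phase, so the assembly rate is the slope
of \(\ln(I/I_0)\) and the disassembly rate the slope of \(\ln(I_0/I)\)
against time (natural logarithm; rates reported per minute). Because the
exponential phase has an unknown extent, the fitting window is selected
adaptively: assembly windows start at the trace start and end anywhere
between the minimum window length and the intensity peak; disassembly
windows end at the trace end and start anywhere between the peak and the
minimum window length from the end, with \(I_0\) re-anchored at each
candidate window's first sample. Each window is fit by ordinary least
squares and the window with the largest adjusted \(R^2\)
(\(1-(1-R^2)(n-1)/(n-2)\)) is selected, ties going to the longer window.
The same best adjusted \(R^2\) then filters noise-like traces at a 0.3
threshold.

**Minimum window length.** The window scan takes a maximum over many
candidate windows, so very short windows inflate the selected adjusted
\(R^2\) on pure noise: at a 4-point minimum, simulation shows the 0.3
filter retains over 40% of trend-free traces, which defeats its purpose.
The default minimum is therefore 7 samples (over 2 minutes of data at 20 s
sampling), at which null retention falls below 20% while changepoint
localization and rate recovery are unaffected; `min_points` remains a user
parameter. Windows containing non-positive background-subtracted
intensities are skipped individually rather than failing the trace, and a
trace whose peak sits too close to the end still reports the minimal
trailing window (so a monotonically rising trace yields a negative
disassembly slope rather than an error).

## Traction force microscopy

**Forward model.** The substrate is a linear-elastic half-space (Young's
modulus 5000 Pa for the 5 kPa silicone gels this workflow targets; Poisson
ratio 0.5 for incompressible silicone, exposed as a parameter). Tangential
surface tractions produce surface displacements through the
Boussinesq-Cerruti Green's tensor

\[ G(\mathbf r) \;=\; \frac{1+\nu}{\pi E\, r^3}
\begin{pmatrix} (1-\nu)r^2 + \nu x^2 & \nu x y \\
\nu x y & (1-\nu) r^2 + \nu y^2 \end{pmatrix}. \]

Traction is discretized as piecewise-constant on a regular quadrilateral
mesh at bead-spacing resolution, and the Green's tensor is integrated over
each element: by adaptive Gauss-Legendre quadrature (4/12 points per axis
by distance) for evaluation points off the element, and by an
exact-in-radius polar scheme for points on the element, where the 1/r
singularity cancels against the polar Jacobian and only the angular
integral is quadratured. The pointwise kernel is never evaluated at its
singularity. Element integrals are validated against dense brute-force
quadrature, far-field 1/r decay, elastic scaling, and Betti reciprocity.

**Displacements.** Bead displacements between the stressed and relaxed
images are measured by per-bead template matching: beads detected in the
relaxed image (shape filter off — fiducials are dense and mutually
overlapping, so bad matches are handled downstream), a 17-px template,
zero-normalized cross-correlation over a +/-50 px search window, and
3-point parabolic sub-pixel interpolation per axis. Exact template matches
(correlation numerically 1) skip the parabola. Vectors with correlation
peaks below 0.5 are marked invalid, and the universal normalized-median
neighborhood test (8 nearest neighbors, threshold 2.0, 0.1 px noise floor)
flags and replaces spurious vectors with the local median.

**Inversion.** Tractions solve the Tikhonov problem
\(\min_t \|Mt-u\|^2+\lambda\|t\|^2\). The regularization parameter is
chosen at the corner of the L-curve — the log-log plot of residual norm
against solution norm across a lambda grid (at least 10 values spanning at
least 4 decades). Because the forward matrix's SVD is available, the
curvature of the Tikhonov L-curve is computed *analytically* (all
derivatives of the residual and solution norms with respect to lambda are
closed-form sums over the spectrum), which proved more stable than
numerically differentiating a spline through the discrete curve; the
corner is the largest interior local curvature maximum, since grid-end
curvature maxima are truncation artifacts. When no interior positive
maximum exists (noiseless data; the corner degenerates) a warning is
issued and the curvature maximum is returned, flagged.

Readouts: total force is the sum of traction magnitudes times element area
over mesh nodes inside the cell mask, in Pa um^2 (10^4 Pa um^2 = 10 nN);
per-class adhesion tractions are bilinear interpolations of the traction
magnitude at adhesion positions, averaged per adhesion and grouped by
class.

## Statistics and reporting

Condition comparisons use the two-sided Mann-Whitney rank-sum test with
midrank ties. When both samples have at most 8 observations the p-value is
computed by exhaustive enumeration of all group assignments — exact even
under ties; larger samples use the normal approximation with tie and
continuity corrections. Report tables carry medians, quartiles and n per
condition, Tukey boxplot statistics, and significance stars at the
conventional thresholds (p < 1e-2, 1e-5, 1e-10); no multiple-testing
correction is applied, which the report footer states. The integrin
activation index is \(AI = (F-F_0)/(F_{max}-F_0)\), affine-invariant by
construction, with an explicit error when \(F_{max}=F_0\).

## The synthetic-scene generator

The generator is first-class, tested code, not a fixture. An adhesion
movie is defined by a scene configuration (frame count, 20 s frame
interval, 0.086 um/px, PSF sigma 2.1 px, background level and gradient,
Poisson shot noise and Gaussian read noise, RNG seed) plus a list of
adhesion ground truths. Each adhesion's peak intensity follows

\[ I(t) \;=\; \min\!\big(I_p,\; I_i\, e^{k_a (t-t_n)}\big)
\quad\text{then}\quad I(t_d)\, e^{-k_d (t-t_d)}, \]

an exponential rise capped at a plateau followed by exponential decay. This
shape was chosen deliberately: it makes \(\ln(I/I_0)\) exactly linear in
each phase, so the planted rate constants are recoverable by the
log-linear estimators and the window-selection changepoints are known —
the saturating-rise alternative \(I_p(1-e^{-k t})\) has no log-linear
segment and would leave the estimator without a defined ground truth. The
initial intensity defaults to 1/20 of the plateau. Footprints grow from
punctate to FA scale as elliptical Gaussians convolved with the PSF; the
GFP channel renders the same adhesions scaled by a per-adhesion coupling
factor; noise is applied last; and generation is a pure function of
(configuration, truths), bit-identical under a fixed seed.

TFM scenes place beads uniformly at random, displace them by the forward
model evaluated at their reference positions (beads outside the cell mask
move only through the elastic far field), and render both images as
Gaussian point sources. The bead density used in validation, 0.02 beads
per pixel^2 (about 1300 beads in a 64 x 64 um field at 0.25 um/px),
reflects the dense fiducial layers used on silicone TFM gels; densities
quoted per mm^2 in some protocols are not physically usable for TFM and
were not adopted. The scene records its maximum displacement and warns
when it exceeds half the PTV template.

**What the generator does not emulate:** cell-shape morphodynamics,
photobleaching, 3-D PSFs, finite gel thickness, adhesion splitting and
merging, and spatially correlated camera noise. Passing tests on these
scenes therefore validate the estimators under their stated models, not
robustness to every artifact of real data.

## Validation problem sizes

The shipped validation uses 160 x 160 px frames with 50 planted spots at
SNR 10 for detection; 30 random walkers over 20 frames for tracking; 500
seeded traces for kinetics recovery and for the null-retention rate; a
two-patch traction dipole (Gaussian patches, sd 2.5 um, peak magnitude
about 224 Pa) on a 64 x 64 um domain with a 36 x 36 element mesh and 5%
RMS displacement noise for the TFM round trip; and a 25-frame, 96 x 96 px
two-channel movie for the end-to-end determinism check. These sizes give
stable statistics while keeping the whole validation suite to a few
minutes on a laptop.

## Known limitations

* **L-curve under-smoothing.** For smooth traction fields the
  maximum-curvature corner systematically selects a lambda one decade or
  more below the truth-error-minimizing value — a documented property of
  the L-curve criterion, reproduced here across mesh resolutions, bead
  densities and noise models. Integral readouts (total force, peak
  location) are insensitive to this, but the corner-to-optimal distance
  hovers at the one-decade mark and the pointwise traction map at the
  corner is noisier than at the optimum. Users who can estimate their
  displacement noise should cross-check the corner against the discrepancy
  principle.
* **Half-space elasticity.** Finite gel thickness is ignored; for gels
  thinner than the lateral extent of the traction pattern the forward
  model overestimates displacements.
* **Fixed-width PSF.** Detection assumes a known, spatially uniform PSF
  sigma; defocus or aberration will inflate goodness-of-fit rejections.
* **Status by centroid containment.** A point on a region boundary is
  classified by its rounded pixel; sub-pixel containment is not
  interpolated.
* **No photobleaching correction.** Rate constants from long movies of
  bleaching fluorophores will be biased toward disassembly; correct the
  traces before fitting.
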