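---
title: "MC-ISM reconstruction: models, parameters and numerical choices"
author: "mcism package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MC-ISM reconstruction: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcism)
```

## The imaging model

Multi-confocal image scanning microscopy (MC-ISM) excites the sample with a
square array of diffraction-limited spots produced by a pinhole array, tilts
the array by a small angle relative to the scan axis, and sweeps it along a
single fast axis while a camera records one frame per scan position. Each
camera pixel acts as its own confocal point detector, so a scan carries
enough information for a two-fold lateral resolution gain over widefield.

The forward model per frame is

$$ I_i(r) \;=\; h_\mathrm{det} \ast \bigl( P_i \cdot O \bigr)(r) \; + \; B(r), $$

where $O$ is the object, $P_i$ the frame's illumination pattern (pinhole
disks convolved with the excitation PSF), $h_\mathrm{det}$ the detection PSF
and $B$ an additive out-of-focus background that does not move with the
scan. Every operator in the package — the simulator, the forward model of
the multi-image engines, and their adjoints — shares one zero-padded linear
convolution implementation, so the simulator output and `forwardModel()`
agree bit-for-bit and the forward/adjoint pair passes a dot-product test at
floating-point precision.

### PSF model

PSFs are isotropic Gaussians with lateral FWHM $0.51\,\lambda/\mathrm{NA}$
and axial FWHM $1.77\,n\,\lambda/\mathrm{NA}^2$ ($n = 1.515$). The Gaussian
approximation keeps every reassignment identity analytic (products and
convolutions of Gaussians stay Gaussian), which is what the package's
strongest invariants are anchored to. Kernels are rendered by exact pixel
integration (erf differences) and normalized to unit sum. Vectorial or
aberrated PSFs are out of scope; consequently the simulator makes no
attempt to reproduce instrument-specific blur (a real widefield channel can
be measurably wider than the diffraction estimate).

### Scan geometry

For an $n^2$-frame scan the lattice is tilted by $\arctan(1/n)$
(`tiltForUniformCoverage()`), which makes the slow-axis projections of the
lattice sites exactly equally spaced at $p/\sqrt{n^2+1}$ for pitch $p$. The
presets use the *exact-tiling* fast-axis step
$p\sqrt{n^2+1}/n^2$: the $n^2$-step sweep then advances by exactly one
fast-axis lattice period, and the union of spot positions is a perfectly
uniform comb. For the default 1.5 AU pitch this step is 0.217 AU for 49
frames — the nominal "quarter Airy unit" scan interval — and 0.306 AU for
25 frames. With the nominal 0.25 AU step the 49-step sweep would overshoot
the lattice period by ~15%, double-exposing a strip of every unit cell;
that nonuniformity measurably distorts the discrete reassignment PSF at
simulation scale, which is why the presets tile exactly.

Frame reduction keeps the slow-axis design coupled through
`frameReductionStepRatio()`: replacing 49 frames by 25 scales the step by
$\sqrt{50/26} = 1.387$ (the published 1.39). Note a deliberate 2%
inconsistency: exact tiling would scale the step by
$49\sqrt{26}/(25\sqrt{50}) = 1.413$; the closed form is retained for the
ratio quantity because it is the published design rule, while the presets
prioritize coverage uniformity.

## The synthetic-data generator

`makePhantom()`, `illuminationPattern()`, `simulateStack()` and
`addNoiseToSNR()` generate every input used by the tests: line pairs with
area-weighted sub-pixel rendering, seeded bead fields, filaments, uniform
plates and shell phantoms, on a 32.5 nm object grid by default under
640/680 nm excitation/emission at NA 1.49 (1 AU = 556.8 nm; 0.5 AU pinhole
diameter; 1:3 diameter:pitch).

Noise is calibrated to a stated SNR,
$\mathrm{SNR_{dB}} = 10\log_{10}\!\bigl(\overline{s^2}/\sigma^2\bigr)$,
measured over pixels whose noise-free signal exceeds 1% of the stack
maximum. This definition is recorded in the stack metadata because SNR
conventions differ between groups; Gaussian noise achieves the request
within 0.1 dB, and the Poisson path rescales to the photon budget whose
shot noise meets the request, preserving frame means in expectation.
Out-of-focus background is frame-independent by construction — exactly the
premise that OLID exploits.

What the generator does *not* emulate: depth-dependent 3D defocus of thick
tissue, camera gain/read-noise maps, speckle of coherent sources, drift,
and bleaching. Tests passing on this generator therefore validate the
reconstruction algebra and its noise behaviour, not robustness to every
systematic of real hardware.

## OLID background rejection

Along the frame axis every pixel of an in-focus structure is periodically
modulated as spots sweep past, while out-of-focus light is constant.
`olidFilter()` attenuates the zero-frequency bin of the per-pixel frame-axis
spectrum by `dcAttenuation` and keeps all other bins; since only the DC bin
is touched, this is implemented exactly as subtraction of
`(1 - dcAttenuation)` times the temporal mean. The default removes DC
entirely and clamps negatives, the factor is exposed and logged. The
operation is linear, annihilates any frame-constant background, and is
idempotent before clamping. On background-laden stacks spot localization
after OLID is never worse than before (paired 20-seed test).

## Spot localization

`detectSpotCandidates()` matched-filters each frame with the excitation
kernel, takes local maxima with a minimum mutual separation, and refines
each candidate by an iterated windowed centroid followed by a log-parabola
sub-pixel peak fit (exact for Gaussian peaks; noise-free accuracy better
than 0.05 px). `fitGridToFrames()` then regularizes all frames jointly with
the rigid model `origin + m b1 + k b2 + (f-1) step`, using iterated least
squares with integer site assignment and a MAD-based outlier threshold, so
dim or undetected spots inherit the fitted geometry. For simulated stacks
(and sparse phantoms such as a single point source, whose frames do not
visually reveal the illumination positions at all) the grid comes directly
from the known geometry via `spotGridFromGeometry()`.

## Pixel reassignment

`prReconstruct()` chains the PR stages:

1. band-limited upsampling (factor 2 by default) to reduce the integer
   placement error; interpolation undershoot is clamped at zero;
2. window extraction around each predicted centre (default radius just
   under half the pitch, enforced at least $3\sigma_\mathrm{base}$ and at
   most half the pitch to exclude neighbouring spots);
3. optional Gaussian digital pinhole of width
   `sigmaRel` $\times\,\sigma_\mathrm{base}$ centred on the located
   sub-pixel centre, where $\sigma_\mathrm{base}$ is a 2D Gaussian fit to
   the background-subtracted average spot (`estimateSigmaBase()`);
4. reassignment to a canvas at doubled coordinates and normalization by the
   accumulated weights (`prImage()`).

Two numerical choices matter here.

*Placement.* The window centre sample must land at the doubled coordinate
`round(c) + c`. Nearest-index placement leaves per-window errors of up to
0.75 upsampled px, and because only two or three spots dominate the
reassignment sum at any point, those errors perturb the PR PSF at first
order (about 5% FWHM at 2x upsampling). Sub-images are therefore placed
bilinearly at the exact target, which adds only a known symmetric sub-pixel
blur of well under 1% FWHM.

*Weights.* With a pinhole, the mask itself is accumulated as the weight.
Without one, a flat box weight imprints its count-quantization ripple
(windows-per-pixel jumps between integers) onto the normalized image —
observed as tens of percent shading on a uniform phantom. The package
instead accumulates a data-driven sensitivity profile: a Gaussian fitted to
the average sub-image, re-centred per window on its sub-pixel spot centre.
Uniform phantoms then normalize flat to within ~3%.

For matched Gaussian excitation and detection widths the reassigned PSF of
a point source narrows by exactly $\sqrt 2$; this is the package's primary
analytic anchor (verified to 3%). A corollary worth knowing: under this
model a Gaussian digital pinhole leaves the PR PSF *width* unchanged
whenever $\sigma_\mathrm{ex} = \sigma_\mathrm{det}$ — its benefit is noise
and background suppression, not a narrower kernel, and the 10 dB line-pair
experiment shows exactly that (strictly better dip contrast with the
pinhole, seed by seed).

The effective PR PSF used for the subsequent deconvolution is the
convolution of the excitation spot and detection PSF laid out at doubled
coordinates; its standard deviation equals the fitted spot-image width
$\sigma_\mathrm{base}$ in canvas units, i.e. $\sigma_\mathrm{base}/2$ in
object units (`prPSF()`). `mcismReconstruct()` applies Richardson-Lucy with
this kernel; the multiplicative updates preserve nonnegativity and conserve
flux for interior-supported images.

## Frame-reduction deconvolution

Because detector pixels at different offsets carry overlapping effective
PSFs, 25 frames still sample the object completely — with varying
sensitivity — and multi-image deconvolution can reconstruct without the
gaps plain PR shows at enlarged steps.

*Joint Richardson-Lucy* shares one estimate across frames,
$O \leftarrow O \cdot \bigl[\sum_i A_i^T\!\bigl(I_i/(A_i O + \epsilon)\bigr)\bigr] / \bigl[\sum_i A_i^T 1\bigr]$,
with $A_i O = h \ast (P_i O)$; with one frame and a uniform pattern it
reduces exactly to single-image RL.

*FISTA-GS* minimizes
$\tfrac12\sum_i \lVert A_i O_i - I_i\rVert_2^2 + \lambda \lVert \sum_i O_i \rVert_1$
over per-frame components $O_i \ge 0$, returning $O = \sum_i O_i$. On the
nonnegative orthant the group penalty is linear, so the proximal step
(penalty plus nonnegativity) is an exact elementwise shift-and-clip; the
unconstrained group prox (soft-threshold of the group sum) is available as
`proxGroupL1()` and tested against a numeric oracle, but composing it with
a projection is not an exact prox and demonstrably breaks objective
monotonicity. The gradient step defaults to $1/L$ with $L$ the guaranteed
OTF-based bound $\max_i (\max|\hat h| \cdot \max P_i)^2$; Nesterov momentum
restarts with a plain proximal-gradient step whenever it would increase the
objective, which makes the recorded objective non-increasing by the
majorization property. At $\lambda = 0$ the solution matches a direct
normal-equation solve on a toy problem to $10^{-6}$.

The regularization weight is never published for this class of method; the
package default is $\lambda = 0.01 \times \max_i \max_r I_i(r)$, chosen
once by a sweep over synthetic bead and line-pair data (resolvability of
the 140 nm pair, and PSNR/SSIM against ground truth at 25 dB, both peak
near this value, with quality degrading by under-regularized graininess two
decades below and over-smoothing one decade above). It is logged by every
pipeline run. Display uses the *sum* of the per-frame components, which is
the combination the regularizer couples.

## Metrology

`fwhm()` fits a Gaussian plus offset (multi-modal profiles are redirected
to the line-pair fit). `bigaussianFit()` fits two equal-width Gaussians
plus offset; the dip contrast is the fitted saddle value at the peak
midpoint divided by the mean fitted peak value (offset removed), and a pair
counts as resolved when the fitted separation is within 20% of nominal and
the dip is at most 0.75 — a Rayleigh-like saddle criterion; the
literature usually shows line profiles without committing to one. For equal Gaussians
this places the resolution limit near 1.19x the FWHM (the classic 0.735
saddle figure belongs to Airy profiles; equal Gaussians separated by one
FWHM give a saddle of 0.94). PSNR follows
$10\log_{10}(\max(\mathrm{ref})^2/\mathrm{MSE})$; SSIM uses the standard
constants over a Gaussian 7-pixel window after joint rescaling. FRC uses
one-pixel rings, a fixed 1/7 threshold by default (half-bit optional), and
an odd/even frame split is the intended source of independent
reconstructions; no crossing reports the Nyquist limit with a flag.

## Problem sizes and degenerate inputs

The validation suite runs on 96-128 px fields (3-4 um at 32.5 nm), 25 or
49 frames, 40-150 iterations — sizes chosen so the entire suite and the
acceptance script complete in minutes on a single core while keeping every
spot lattice at least 3-5 pitches wide so interior statistics are
meaningful. Degenerate inputs are rejected with specific errors: sub-pixel
phantom structures, single-frame OLID, windows beyond half the pitch,
collinear lattice candidates, all-zero stacks for SNR calibration or RL,
negative backgrounds, non-square frame counts in the reduction formula, and
unknown configuration keys. Division guards use $\epsilon = 10^{-12}$
throughout.

## Known limitations

* 2D only: axial widths are carried in the PSF model but reconstruction is
  per-slice; no 3D deconvolution.
* The Gaussian PSF approximation underestimates Airy side lobes; absolute
  resolution numbers on real data will differ from the simulated anchors.
* Image-based spot localization presumes a sample dense enough to light up
  most of the lattice; sparse samples must use the geometry-based grid.
* The light-dose accounting of a full acquisition is exposed only as raw
  per-pixel excitation integrals (`illuminationStack()` sums); no claim is
  made about dose ratios against other modalities.
* jRL is run for a fixed iteration budget; it has no principled stopping
  rule here, and FISTA-GS's `tol` applies to relative objective change
  only.
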