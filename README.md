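# mcism

Simulation and computational reconstruction for **multi-confocal image
scanning microscopy (MC-ISM)** — a multifocal super-resolution modality in
which a tilted pinhole-array illumination pattern is swept along a single
fast axis and the camera frames are recombined computationally.

The package is aimed at microscopy-methods developers who want a tested,
self-contained reference implementation of the MC-ISM processing chain:

* **Optics and geometry** — Airy-unit arithmetic, Gaussian PSF models,
  effective detector-pixel PSFs, tilted-lattice 1D scan trajectories and
  the frame-reduction step rule.
* **Forward simulator** — phantoms (line pairs, beads, filaments, plates),
  multifocal illumination patterns, the image-formation model
  `I_i = h_det * (P_i . O) + B`, and Gaussian/Poisson noise calibrated to a
  stated SNR.
* **OLID** — optical lock-in detection: per-pixel attenuation of the
  zero-frequency component along the frame axis, which removes
  scan-invariant out-of-focus background.
* **Spot localization** — matched filtering with sub-pixel refinement and
  a global lattice + trajectory fit.
* **Pixel reassignment (PR)** — sub-image extraction, Gaussian digital
  pinholes in units of the fitted spot width `sigma_base`, reassignment to
  a doubled-coordinate canvas with sensitivity-weighted normalization, and
  Richardson–Lucy deconvolution of the result (the MC-ISM image).
* **Frame-reduction deconvolution** — joint Richardson–Lucy and FISTA with
  a group-sparsity penalty, minimizing
  `0.5 * sum_i ||h * (P_i . O_i) - I_i||^2 + lambda * ||sum_i O_i||_1`
  over nonnegative per-frame components.
* **Metrology** — FWHM, bi-Gaussian line-pair resolvability (dip contrast
  at most 0.75 and separation within 20% of nominal), PSNR, SSIM, and
  Fourier ring correlation with a 1/7 (or half-bit) threshold.

The model, parameter defaults and every numerical choice are documented in
the methods vignette, `vignettes/mcism-methods.Rmd`.

## Worked example

A 49-frame scan of a point source with matched excitation/detection PSFs,
reconstructed by pixel reassignment and deconvolution:

```r
library(mcism)

cfg  <- opticalConfig(lambdaEx = 680, lambdaEm = 680, na = 1.49, pixelNm = 32.5)
pre  <- scanPreset(cfg, nFrames = 49L)
geom <- pre$geometry
geom@diameterNm <- 1e-3               # delta-pinhole limit: Gaussian spots

D   <- 128L
src <- matrix(0, D, D); src[D/2, D/2] <- 1
point <- new("Phantom", image = src, pixelNm = cfg@pixelNm,
             kind = "beads", params = list())
stack <- simulateStack(point, geom, pre$trajectory, cfg)

psfDet <- gaussianPSF(cfg, "emission")
wf     <- forwardModel(src, matrix(1, D, D), psfKernel(psfDet, cfg@pixelNm))
spots  <- spotGridFromGeometry(geom, pre$trajectory, cfg@pixelNm, c(D, D))
pr     <- prReconstruct(stack, spots, pinhole = NULL, upsample = 2L)
dec    <- mcismReconstruct(pr, psfKernel(psfModel(psfDet@sigmaLateralNm * sqrt(2) / 2,
                           pixelNm = pr@pixelNm), pr@pixelNm), nIter = 50L)

fwhm(wf, cfg@pixelNm)            # widefield:       233.8 nm
fwhm(prImage(pr), pr@pixelNm)    # reassignment:    166.3 nm  (sqrt(2) gain)
fwhm(dec, pr@pixelNm)            # after RL:         58.4 nm  (4.0-fold gain)
```

The widefield FWHM is the diffraction estimate `0.51 * lambda / NA`; pixel
reassignment narrows it by `sqrt(2)` (233.8 / 166.3 = 1.41), and
Richardson–Lucy deconvolution of the reassigned image carries the total
gain past the 2-fold MC-ISM design target.

The same chain on line pairs, with the frame-reduced 25-frame preset and
FISTA-GS, resolves a 140 nm pair without noise (bi-Gaussian dip contrast
0.66 at the 0.75 threshold), and with a `sigmaRel = 1` digital pinhole plus
RL it resolves a 170 nm pair at 10 dB SNR in every noise seed.

A YAML-configured end-to-end pipeline (`simulate -> olid -> locate ->
reconstruct -> metrics`) is available through `runPipeline()`; see
`inst/extdata/example-run.yaml` and the thin command-line wrapper
`inst/cli/mcism.R`:

```sh
Rscript inst/cli/mcism.R run --config inst/extdata/example-run.yaml --out out/
```

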