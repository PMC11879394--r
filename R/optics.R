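#' Create an optical configuration
#'
#' Defaults correspond to the reference MC-ISM setup: 640 nm excitation,
#' 680 nm emission through a 1.49 NA oil objective, with the object grid
#' sampled at 32.5 nm. The default `pinholeMagnification` is chosen so that a
#' 40 um physical pinhole projects to 0.5 Airy units at the sample plane.
#'
#' @param lambdaEx excitation wavelength (nm).
#' @param lambdaEm emission wavelength (nm).
#' @param na numerical aperture.
#' @param pixelNm sample-plane pixel size (nm).
#' @param pinholeMagnification pinhole-plane to sample-plane magnification;
#'   `NULL` selects the 40 um to 0.5 AU default.
#' @return an [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' airyUnit(cfg)
#' @export
opticalConfig <- function(lambdaEx = 640, lambdaEm = 680, na = 1.49,
                          pixelNm = 32.5, pinholeMagnification = NULL) {
  au <- 1.22 * lambdaEm / na
  if (is.null(pinholeMagnification))
    pinholeMagnification <- 40000 / (0.5 * au)
  new("OpticalConfig", lambdaEx = lambdaEx, lambdaEm = lambdaEm, na = na,
      pixelNm = pixelNm, pinholeMagnification = pinholeMagnification)
}

#' Airy unit at the sample plane
#'
#' The Airy unit is the diameter of the first minimum of the Airy diffraction
#' pattern, `1.22 * lambdaEm / NA`, evaluated at the sample plane. Pinhole
#' diameters and scan steps are conventionally quoted in this unit.
#'
#' @param cfg an [OpticalConfig-class].
#' @return length in nm.
#' @examples
#' airyUnit(opticalConfig(lambdaEm = 680, na = 1.49))  # 556.78 nm
#' @export
airyUnit <- function(cfg) {
  stopifnot(is(cfg, "OpticalConfig"))
  validObject(cfg)
  1.22 * cfg@lambdaEm / cfg@na
}

#' Gaussian PSF model from an optical configuration
#'
#' Gaussian approximation of the diffraction-limited PSF: lateral FWHM
#' `0.51 * lambda / NA` and axial FWHM `1.77 * n * lambda / NA^2` with an
#' assumed immersion index n = 1.515. Standard deviations are FWHM / 2.3548.
#'
#' @param cfg an [OpticalConfig-class].
#' @param mode `"excitation"` or `"emission"`: selects the wavelength.
#' @param supportSigmas rendered kernel support radius in units of sigma
#'   (default 4).
#' @return a [PSFModel-class].
#' @export
gaussianPSF <- function(cfg, mode = c("excitation", "emission"),
                        supportSigmas = 4) {
  stopifnot(is(cfg, "OpticalConfig"))
  validObject(cfg)
  mode <- match.arg(mode)
  lambda <- if (mode == "excitation") cfg@lambdaEx else cfg@lambdaEm
  fwhmFactor <- 2 * sqrt(2 * log(2))
  fwhmLat <- 0.51 * lambda / cfg@na
  fwhmAx <- 1.77 * 1.515 * lambda / cfg@na^2
  new("PSFModel",
      sigmaLateralNm = fwhmLat / fwhmFactor,
      sigmaAxialNm = fwhmAx / fwhmFactor,
      supportRadiusPx = as.integer(ceiling(
        supportSigmas * fwhmLat / fwhmFactor / cfg@pixelNm)))
}

#' Construct a Gaussian PSF model directly from a lateral sigma
#'
#' Convenience constructor used when the width is known (e.g. the effective
#' pixel-reassignment PSF, sigma_base / sqrt(2)).
#'
#' @param sigmaLateralNm lateral standard deviation (nm).
#' @param sigmaAxialNm axial standard deviation (nm); defaults to 3x lateral.
#' @param pixelNm pixel size used to size the kernel support.
#' @param supportSigmas support radius in sigmas.
#' @return a [PSFModel-class].
#' @export
psfModel <- function(sigmaLateralNm, sigmaAxialNm = 3 * sigmaLateralNm,
                     pixelNm = 32.5, supportSigmas = 4) {
  new("PSFModel", sigmaLateralNm = sigmaLateralNm,
      sigmaAxialNm = sigmaAxialNm,
      supportRadiusPx = as.integer(ceiling(
        supportSigmas * sigmaLateralNm / pixelNm)))
}

## pixel-integrated 1D Gaussian profile centred at `center` (px), unnormalized
gaussProfile1D <- function(idx, center, sigmaPx) {
  pnorm(idx + 0.5, center, sigmaPx) - pnorm(idx - 0.5, center, sigmaPx)
}

#' Render a PSF model as a discrete convolution kernel
#'
#' The Gaussian is integrated exactly over each pixel footprint (separable
#' erf differences) and normalized to unit sum, so the rendered kernel is
#' symmetric under 180 degree rotation and conserves flux under convolution.
#'
#' @param psf a [PSFModel-class].
#' @param pixelNm pixel size of the target grid (nm).
#' @param radiusPx kernel support radius; defaults to the model's
#'   `supportRadiusPx` rescaled to `pixelNm`.
#' @return an odd-sized numeric matrix summing to 1.
#' @export
psfKernel <- function(psf, pixelNm, radiusPx = NULL) {
  stopifnot(is(psf, "PSFModel"))
  sigmaPx <- psf@sigmaLateralNm / pixelNm
  if (is.null(radiusPx)) radiusPx <- as.integer(ceiling(4 * sigmaPx))
  radiusPx <- max(1L, as.integer(radiusPx))
  idx <- (-radiusPx):radiusPx
  g <- gaussProfile1D(idx, 0, sigmaPx)
  k <- outer(g, g)
  k / sum(k)
}

#' Effective PSF of an offset detector pixel
#'
#' In image scanning microscopy each camera pixel at integer offset `d` from
#' the illumination axis acts as its own point detector with effective PSF
#' `PSF_ex(r) * PSF_det(r - d)`. The product is integrated over the pixel
#' footprint with a 4x supersampled midpoint rule. For equal Gaussian
#' excitation and detection widths the product peaks at `d/2` with width
#' `sigma / sqrt(2)`, which is the physical basis of pixel reassignment;
#' adjacent-offset effective PSFs overlap, which is what frame-reduction
#' deconvolution exploits.
#'
#' @param psfEx excitation [PSFModel-class].
#' @param psfDet detection [PSFModel-class].
#' @param offsetPx integer (x, y) detector-pixel displacement; a single
#'   number means (d, 0).
#' @param pixelNm pixel size (nm).
#' @param radiusPx support radius of the returned image (defaults to the
#'   joint kernel support).
#' @return numeric matrix (unnormalized product PSF sampled per pixel); all
#'   zeros with a warning when the offset lies beyond the kernel support.
#' @export
effectivePixelPSF <- function(psfEx, psfDet, offsetPx, pixelNm,
                              radiusPx = NULL) {
  stopifnot(is(psfEx, "PSFModel"), is(psfDet, "PSFModel"))
  if (length(offsetPx) == 1L) offsetPx <- c(offsetPx, 0)
  sigmaEx <- psfEx@sigmaLateralNm / pixelNm
  sigmaDet <- psfDet@sigmaLateralNm / pixelNm
  if (is.null(radiusPx))
    radiusPx <- as.integer(ceiling(4 * max(sigmaEx, sigmaDet)))
  support <- 4 * max(sigmaEx, sigmaDet)
  n <- 2L * radiusPx + 1L
  if (sqrt(sum(offsetPx^2)) > support + radiusPx) {
    warning("detector-pixel offset lies beyond the PSF support; ",
            "returning a zero image")
    return(matrix(0, n, n))
  }
  ## 4x supersampled midpoint rule over each pixel footprint
  ss <- 4L
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  coarse <- (-radiusPx):radiusPx
  fine <- as.vector(outer(sub, coarse, `+`))  # ss samples per pixel
  gx <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))
  ## separable: product of two Gaussians stays separable for axis offsets
  fx <- gx(fine, 0, sigmaEx) * gx(fine, offsetPx[1L], sigmaDet)
  fy <- gx(fine, 0, sigmaEx) * gx(fine, offsetPx[2L], sigmaDet)
  px <- colMeans(matrix(fx, nrow = ss))
  py <- colMeans(matrix(fy, nrow = ss))
  outer(py, px)  # [row = y, col = x]
}

#' @describeIn OpticalConfig-class compact display
#' @param object an `OpticalConfig`
#' @export
setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig: ex", object@lambdaEx, "nm / em", object@lambdaEm,
      "nm, NA", object@na, "\n")
  cat("  pixel", object@pixelNm, "nm; 1 AU =",
      format(airyUnit(object), digits = 5), "nm; pinhole magnification",
      format(object@pinholeMagnification, digits = 5), "\n")
})

#' @describeIn PSFModel-class compact display
#' @param object a `PSFModel`
#' @export
setMethod("show", "PSFModel", function(object) {
  f <- 2 * sqrt(2 * log(2))
  cat("PSFModel: lateral sigma", format(object@sigmaLateralNm, digits = 4),
      "nm (FWHM", format(f * object@sigmaLateralNm, digits = 4),
      "nm), axial sigma", format(object@sigmaAxialNm, digits = 4), "nm\n")
})
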