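#' @import methods
NULL

setClassUnion("OptionalList", c("list", "NULL"))

#' Optical configuration of an MC-ISM acquisition
#'
#' Holds the wavelengths, numerical aperture and sample-plane pixel size of an
#' acquisition, together with the illumination-path magnification that maps a
#' physical pinhole diameter to its size at the sample plane. All derived
#' optical quantities (Airy unit, Gaussian PSF widths) are computed from this
#' object.
#'
#' @slot lambdaEx excitation wavelength (nm).
#' @slot lambdaEm emission wavelength (nm).
#' @slot na numerical aperture (dimensionless, at most the assumed immersion
#'   index 1.515).
#' @slot pixelNm sample-plane pixel size (nm).
#' @slot pinholeMagnification magnification from the pinhole plane to the
#'   sample plane; the default maps a 40 um physical pinhole to 0.5 Airy
#'   units at the sample.
#' @seealso [opticalConfig()], [airyUnit()], [gaussianPSF()]
#' @export
setClass("OpticalConfig",
  representation(
    lambdaEx = "numeric",
    lambdaEm = "numeric",
    na = "numeric",
    pixelNm = "numeric",
    pinholeMagnification = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  v <- c(object@lambdaEx, object@lambdaEm, object@na, object@pixelNm,
         object@pinholeMagnification)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all optical parameters must be finite and positive")
  if (object@na > 1.515)
    return("na exceeds the assumed immersion refractive index 1.515")
  TRUE
})

#' Gaussian point-spread-function model
#'
#' Isotropic lateral Gaussian approximation of the diffraction-limited PSF,
#' with an axial width carried along for 3D bookkeeping. Rendered kernels
#' (see [psfKernel()]) integrate the Gaussian over each pixel footprint and
#' are normalized to unit sum.
#'
#' @slot sigmaLateralNm lateral standard deviation (nm).
#' @slot sigmaAxialNm axial standard deviation (nm).
#' @slot supportRadiusPx rendered kernel support radius in pixels.
#' @export
setClass("PSFModel",
  representation(
    sigmaLateralNm = "numeric",
    sigmaAxialNm = "numeric",
    supportRadiusPx = "integer"
  )
)

setValidity("PSFModel", function(object) {
  if (object@sigmaLateralNm <= 0 || object@sigmaAxialNm <= 0)
    return("PSF standard deviations must be positive")
  if (object@supportRadiusPx < 1L)
    return("supportRadiusPx must be at least 1")
  TRUE
})

#' Pinhole-array geometry at the sample plane
#'
#' Square lattice of illumination pinholes, described at the sample plane, and
#' its rotation relative to the scan fast axis. The default aspect follows a
#' 1:3 diameter:pitch ratio.
#'
#' @slot pitchNm centre-to-centre spacing at the sample plane (nm).
#' @slot diameterNm pinhole diameter at the sample plane (nm).
#' @slot tiltDeg lattice rotation relative to the fast axis (degrees,
#'   strictly between 0 and 45).
#' @export
setClass("PinholeArrayGeometry",
  representation(
    pitchNm = "numeric",
    diameterNm = "numeric",
    tiltDeg = "numeric"
  )
)

setValidity("PinholeArrayGeometry", function(object) {
  if (object@diameterNm <= 0) return("diameterNm must be positive")
  if (object@pitchNm < object@diameterNm)
    return("pitchNm must be at least diameterNm")
  if (object@tiltDeg <= 0 || object@tiltDeg >= 45)
    return("tiltDeg must lie strictly between 0 and 45 degrees")
  TRUE
})

#' One-dimensional scan trajectory
#'
#' Per-frame rigid displacement of the whole pinhole lattice. The scan is a
#' strictly 1D constant-step walk along the fast axis: there is no retrace,
#' and all consecutive displacements are identical.
#'
#' @slot nFrames number of frames.
#' @slot stepNm fast-axis step (nm).
#' @slot direction unit 2-vector (x, y) along the fast axis.
#' @slot positions nFrames x 2 matrix of per-frame displacements (nm); the
#'   first row is (0, 0).
#' @export
setClass("ScanTrajectory",
  representation(
    nFrames = "integer",
    stepNm = "numeric",
    direction = "numeric",
    positions = "matrix"
  )
)

setValidity("ScanTrajectory", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (length(object@direction) != 2L ||
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit 2-vector")
  p <- object@positions
  if (!is.matrix(p) || nrow(p) != object@nFrames || ncol(p) != 2L)
    return("positions must be an nFrames x 2 matrix")
  if (any(abs(p[1L, ]) > 1e-12)) return("positions[1, ] must be (0, 0)")
  if (object@nFrames > 1L) {
    d <- diff(p)
    expect <- matrix(object@stepNm * object@direction,
                     nrow(d), 2L, byrow = TRUE)
    if (max(abs(d - expect)) > 1e-6 * max(1, abs(object@stepNm)))
      return("consecutive displacements must all equal stepNm * direction")
  }
  TRUE
})

#' Synthetic object (phantom) on a regular grid
#'
#' @slot image nonnegative 2D intensity matrix.
#' @slot pixelNm grid spacing (nm).
#' @slot kind one of \code{"line_pairs"}, \code{"beads"}, \code{"filaments"},
#'   \code{"plate"}, \code{"sphere_shell"}.
#' @slot params kind-specific parameters as supplied to [makePhantom()].
#' @export
setClass("Phantom",
  representation(
    image = "matrix",
    pixelNm = "numeric",
    kind = "character",
    params = "list"
  )
)

setValidity("Phantom", function(object) {
  if (any(!is.finite(object@image))) return("phantom image must be finite")
  if (any(object@image < 0)) return("phantom image must be nonnegative")
  if (object@pixelNm <= 0) return("pixelNm must be positive")
  TRUE
})

#' Raw multifocal scan stack
#'
#' The measured (or simulated) camera frames of one MC-ISM scan, together with
#' the full acquisition metadata. Frames are stored as a numeric array indexed
#' \code{[row, col, frame]}; the fast scan axis runs along columns (+x).
#'
#' @slot frames numeric array, H x W x nFrames, nonnegative intensities.
#' @slot pixelNm sample-plane pixel size of the stored frames (nm).
#' @slot optics an [OpticalConfig-class] or NULL when unknown.
#' @slot geometry a [PinholeArrayGeometry-class] or NULL.
#' @slot trajectory a [ScanTrajectory-class] or NULL.
#' @slot noise record of applied noise: list with elements \code{kind},
#'   \code{snrDb}, \code{achievedSnrDb}, \code{seed} (empty when noise-free).
#' @export
setClass("RawStack",
  representation(
    frames = "array",
    pixelNm = "numeric",
    optics = "ANY",
    geometry = "ANY",
    trajectory = "ANY",
    noise = "list"
  )
)

setValidity("RawStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array [row, col, frame]")
  if (any(!is.finite(object@frames))) return("frames contain NaN/Inf")
  if (!is.null(object@trajectory) &&
      is(object@trajectory, "ScanTrajectory") &&
      object@trajectory@nFrames != d[3L])
    return("frame count does not match trajectory nFrames")
  if (object@pixelNm <= 0) return("pixelNm must be positive")
  TRUE
})

#' Localized illumination-spot grid
#'
#' Sub-pixel illumination-spot centres for every frame, regularized by a
#' global lattice plus a single per-frame scan step. Centres are (row, col)
#' pixel coordinates (1-based, pixel centres at integer indices) on the grid
#' of the stack they were fitted to.
#'
#' @slot centers list (one element per frame) of k x 2 matrices of (row, col)
#'   centres.
#' @slot latticeVectors 2 x 2 matrix; columns are the two lattice basis
#'   vectors in (row, col) pixel units.
#' @slot origin length-2 (row, col) of the lattice origin in frame 1.
#' @slot stepPx length-2 (row, col) per-frame scan displacement.
#' @slot rmsResidual root-mean-square residual of the lattice fit (px).
#' @slot siteIndex list of k x 2 integer matrices of lattice indices (m, k)
#'   matching \code{centers}.
#' @export
setClass("SpotGrid",
  representation(
    centers = "list",
    latticeVectors = "matrix",
    origin = "numeric",
    stepPx = "numeric",
    rmsResidual = "numeric",
    siteIndex = "list"
  )
)

setValidity("SpotGrid", function(object) {
  if (!is.finite(object@rmsResidual)) return("rmsResidual must be finite")
  if (length(object@centers) < 1L) return("centers must have >= 1 frame")
  TRUE
})

#' Gaussian digital pinhole
#'
#' A Gaussian mask applied to each extracted sub-image, centred on the located
#' illumination-spot centre. Its width is expressed as a multiple
#' \code{sigmaRel} of the fitted base spot width \code{sigmaBasePx};
#' \code{sigmaRel = Inf} means no pinhole.
#'
#' @slot sigmaRel width as a multiple of the base width (positive, may be Inf).
#' @slot sigmaBasePx fitted standard deviation of the average illumination
#'   spot image (px on the raw stack grid).
#' @export
setClass("DigitalPinhole",
  representation(sigmaRel = "numeric", sigmaBasePx = "numeric")
)

setValidity("DigitalPinhole", function(object) {
  if (!(object@sigmaRel > 0)) return("sigmaRel must be positive (may be Inf)")
  if (!(object@sigmaBasePx > 0) || !is.finite(object@sigmaBasePx))
    return("sigmaBasePx must be positive and finite")
  TRUE
})

#' Pixel-reassignment result
#'
#' Accumulated reassignment canvas at doubled coordinates relative to the
#' (upsampled) input grid, plus the accumulated weight map used for
#' normalization. Use [prImage()] for the weight-normalized image.
#'
#' @slot canvas accumulated intensity canvas (2H x 2W of the upsampled input).
#' @slot weights accumulated mask (or unit-window) sums, same size as canvas.
#' @slot pixelNm effective object-plane sampling of one canvas pixel (nm);
#'   the canvas lives at doubled coordinates, so this equals the upsampled
#'   input pixel size divided by 2.
#' @slot params record of reconstruction parameters (upsampling factor,
#'   pinhole, window radius).
#' @export
setClass("PRResult",
  representation(
    canvas = "matrix",
    weights = "matrix",
    pixelNm = "numeric",
    params = "list"
  )
)

setValidity("PRResult", function(object) {
  if (!identical(dim(object@canvas), dim(object@weights)))
    return("canvas and weights must have identical dimensions")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  w <- object@weights > 0
  if (any(!is.finite(object@canvas[w])))
    return("canvas must be finite where weights > 0")
  TRUE
})

#' Multi-image deconvolution problem
#'
#' Bundles the measured frames, the per-frame illumination patterns, the PSF
#' and the regularization weight of the multi-image inverse problem solved by
#' [jrlDeconvolve()] and [fistaGS()]. The forward model per frame is
#' \code{I_i = h * (P_i . O)}: modulation by the illumination pattern followed
#' by convolution with the PSF.
#'
#' @slot measured numeric array H x W x n of measured frames.
#' @slot patterns numeric array H x W x n of illumination patterns.
#' @slot psf convolution kernel (odd-sized nonnegative matrix, unit sum).
#' @slot lambda group-sparsity regularization weight (>= 0).
#' @export
setClass("DeconvProblem",
  representation(
    measured = "array",
    patterns = "array",
    psf = "matrix",
    lambda = "numeric"
  )
)

setValidity("DeconvProblem", function(object) {
  dm <- dim(object@measured); dp <- dim(object@patterns)
  if (length(dm) != 3L || length(dp) != 3L)
    return("measured and patterns must be 3D arrays")
  if (!identical(dm, dp))
    return("measured and patterns must have identical dimensions")
  if (any(object@measured < 0) || any(object@patterns < 0))
    return("measured and patterns must be nonnegative")
  if (any(object@psf < 0)) return("psf must be nonnegative")
  if (any(dim(object@psf) %% 2L == 0L))
    return("psf kernel must have odd dimensions")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' Iteration controls for the deconvolution engines
#'
#' @slot nIter maximum number of iterations (>= 1).
#' @slot tol relative objective-change stopping tolerance (>= 0; 0 disables).
#' @slot step gradient step; NA requests 1/L with L estimated by power
#'   iteration.
#' @slot seed seed for randomized initialization (power iteration).
#' @slot epsilon guard added to denominators.
#' @export
setClass("DeconvParams",
  representation(
    nIter = "integer",
    tol = "numeric",
    step = "numeric",
    seed = "integer",
    epsilon = "numeric"
  )
)

setValidity("DeconvParams", function(object) {
  if (object@nIter < 1L) return("nIter must be >= 1")
  if (object@tol < 0) return("tol must be >= 0")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  TRUE
})

#' Bi-Gaussian line-pair fit
#'
#' Result of fitting two equal-width Gaussians plus a constant offset to a
#' line-pair profile. The dip contrast is the saddle value of the fitted
#' profile at the midpoint divided by the mean of the fitted profile at the
#' two peak positions (offset removed from both); a pair is flagged resolved
#' when the fitted separation is within 20% of the nominal spacing and the
#' dip contrast is at most 0.75.
#'
#' @slot positions fitted peak positions (px, ordered).
#' @slot sigma common Gaussian width (px).
#' @slot amplitudes fitted amplitudes.
#' @slot offset fitted constant offset.
#' @slot dipContrast midpoint-to-peak intensity ratio (offset-subtracted).
#' @slot resolved logical resolvability flag.
#' @slot converged logical; FALSE when the optimizer failed.
#' @export
setClass("LinePairFit",
  representation(
    positions = "numeric",
    sigma = "numeric",
    amplitudes = "numeric",
    offset = "numeric",
    dipContrast = "numeric",
    resolved = "logical",
    converged = "logical"
  )
)

#' Fourier ring correlation curve
#'
#' @slot freq spatial frequency at ring centres (1/nm).
#' @slot frc correlation per ring, between -1 and 1.
#' @slot threshold threshold curve used for the resolution criterion.
#' @slot resolutionNm estimated resolution (nm); Nyquist when no crossing.
#' @slot crossed TRUE when the curve actually crossed the threshold.
#' @export
setClass("FrcCurve",
  representation(
    freq = "numeric",
    frc = "numeric",
    threshold = "numeric",
    resolutionNm = "numeric",
    crossed = "logical"
  )
)
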