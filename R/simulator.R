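## Synthetic-data generator: phantoms, multifocal illumination patterns and
## the forward image-formation model frame_i = h_det * (P_i . O) + background.

## evaluate `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## nm coordinates (origin at field centre) -> fractional (row, col), 1-based
nmToPx <- function(xy, dim, pixelNm) {
  cbind(row = xy[, 2L] / pixelNm + (dim[1L] + 1) / 2,
        col = xy[, 1L] / pixelNm + (dim[2L] + 1) / 2)
}

## render antialiased unit-intensity disks into an H x W image; sub-pixel
## disks degenerate to bilinear point splats (the delta-pinhole limit)
renderDisks <- function(dim, centersPx, radiusPx, supersample = 4L) {
  img <- matrix(0, dim[1L], dim[2L])
  if (nrow(centersPx) == 0L) return(img)
  if (radiusPx < 0.5) {
    for (i in seq_len(nrow(centersPx))) {
      rc <- centersPx[i, 1L]; cc <- centersPx[i, 2L]
      r0 <- floor(rc); c0 <- floor(cc)
      fr <- rc - r0; fc <- cc - c0
      for (dr in 0:1) for (dc in 0:1) {
        rr <- r0 + dr; cj <- c0 + dc
        if (rr < 1L || rr > dim[1L] || cj < 1L || cj > dim[2L]) next
        w <- (if (dr == 0L) 1 - fr else fr) *
          (if (dc == 0L) 1 - fc else fc)
        img[rr, cj] <- img[rr, cj] + w
      }
    }
    return(img)
  }
  r <- ceiling(radiusPx) + 1L
  sub <- (seq_len(supersample) - 0.5) / supersample - 0.5
  for (i in seq_len(nrow(centersPx))) {
    rc <- centersPx[i, 1L]; cc <- centersPx[i, 2L]
    rLo <- max(1L, floor(rc) - r); rHi <- min(dim[1L], ceiling(rc) + r)
    cLo <- max(1L, floor(cc) - r); cHi <- min(dim[2L], ceiling(cc) + r)
    if (rHi < rLo || cHi < cLo) next
    rows <- rLo:rHi; cols <- cLo:cHi
    fr <- as.vector(outer(sub, rows, `+`)) - rc
    fc <- as.vector(outer(sub, cols, `+`)) - cc
    inside <- outer(fr^2, fc^2, `+`) <= radiusPx^2
    frac <- apply(array(inside, c(supersample, length(rows),
                                  supersample, length(cols))),
                  c(2L, 4L), mean)
    img[rows, cols] <- pmax(img[rows, cols], frac)
  }
  img
}

#' Generate a synthetic phantom
#'
#' Deterministic test objects on a regular grid. Available kinds:
#' \describe{
#'   \item{line_pairs}{two parallel unit-intensity vertical lines at the
#'     stated centre-to-centre spacing, centred in the field and rendered
#'     with area-weighted sub-pixel placement (`spacingNm`, optional
#'     `lineWidthNm`, default one pixel).}
#'   \item{beads}{`n` disks of `beadDiameterNm` placed uniformly at random
#'     under `seed` (identical output on repeated calls).}
#'   \item{filaments}{`n` smooth random curves under `seed`.}
#'   \item{plate}{a uniform unit-intensity field.}
#'   \item{sphere_shell}{projection-style annulus of `diameterNm` and
#'     `shellThicknessNm`.}
#' }
#'
#' @param kind phantom kind (see Details).
#' @param dim field size c(H, W) in pixels (single value = square).
#' @param pixelNm grid spacing (nm).
#' @param ... kind-specific parameters.
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom("line_pairs", dim = 64, pixelNm = 32.5, spacingNm = 140)
#' @export
makePhantom <- function(kind = c("line_pairs", "beads", "filaments",
                                 "plate", "sphere_shell"),
                        dim, pixelNm, ...) {
  kind <- match.arg(kind)
  if (length(dim) == 1L) dim <- c(dim, dim)
  dim <- as.integer(dim)
  p <- list(...)
  img <- matrix(0, dim[1L], dim[2L])
  if (kind == "plate") {
    img[] <- 1
  } else if (kind == "line_pairs") {
    spacing <- p$spacingNm
    if (is.null(spacing)) stop("line_pairs needs spacingNm")
    width <- if (is.null(p$lineWidthNm)) pixelNm else p$lineWidthNm
    if (spacing < pixelNm)
      stop("line spacing below one grid pixel; use a finer grid")
    if (width < 0.999 * pixelNm)
      stop("line width below one grid pixel; use a finer grid")
    centerCol <- (dim[2L] + 1) / 2
    for (x0 in c(-spacing / 2, spacing / 2)) {
      c0 <- centerCol + x0 / pixelNm
      lo <- c0 - width / pixelNm / 2
      hi <- c0 + width / pixelNm / 2
      cols <- floor(lo - 0.5):ceiling(hi + 0.5)
      cols <- cols[cols >= 1 & cols <= dim[2L]]
      cover <- pmax(0, pmin(cols + 0.5, hi) - pmax(cols - 0.5, lo))
      img[, cols] <- img[, cols] +
        matrix(cover, dim[1L], length(cols), byrow = TRUE)
    }
    img <- pmin(img, 1)
  } else if (kind == "beads") {
    n <- if (is.null(p$n)) 10L else p$n
    diam <- if (is.null(p$beadDiameterNm)) 2 * pixelNm else p$beadDiameterNm
    seed <- if (is.null(p$seed)) 1L else p$seed
    if (diam < pixelNm)
      stop("bead diameter below one grid pixel; use a finer grid")
    marginPx <- diam / pixelNm / 2 + 2
    centers <- withSeed(seed, cbind(
      runif(n, marginPx, dim[1L] - marginPx),
      runif(n, marginPx, dim[2L] - marginPx)))
    img <- renderDisks(dim, centers, diam / pixelNm / 2)
  } else if (kind == "filaments") {
    n <- if (is.null(p$n)) 3L else p$n
    seed <- if (is.null(p$seed)) 1L else p$seed
    img <- withSeed(seed, {
      out <- matrix(0, dim[1L], dim[2L])
      for (f in seq_len(n)) {
        npts <- 400L
        start <- runif(2L, 0.2, 0.8) * dim
        ang <- runif(1L, 0, 2 * pi)
        dang <- cumsum(rnorm(npts, 0, 0.05))
        pts <- start + apply(cbind(sin(ang + dang), cos(ang + dang)),
                             2L, cumsum) * (dim[1L] / npts) * 1.5
        keep <- pts[, 1L] >= 1 & pts[, 1L] <= dim[1L] &
          pts[, 2L] >= 1 & pts[, 2L] <= dim[2L]
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts)) out[cbind(round(pts[, 1L]), round(pts[, 2L]))] <- 1
      }
      out
    })
  } else if (kind == "sphere_shell") {
    diam <- if (is.null(p$diameterNm)) dim[1L] * pixelNm / 2 else p$diameterNm
    thick <- if (is.null(p$shellThicknessNm)) 2 * pixelNm else p$shellThicknessNm
    rr <- (seq_len(dim[1L]) - (dim[1L] + 1) / 2) * pixelNm
    cc <- (seq_len(dim[2L]) - (dim[2L] + 1) / 2) * pixelNm
    rad <- sqrt(outer(rr^2, cc^2, `+`))
    img[abs(rad - diam / 2) <= thick / 2] <- 1
  }
  new("Phantom", image = img, pixelNm = pixelNm, kind = kind, params = p)
}

#' Illumination pattern of one scan frame
#'
#' Pinhole disks at the frame's spot positions, convolved with the excitation
#' PSF and normalized to unit peak. The pattern lives on the object grid.
#'
#' @param geom a [PinholeArrayGeometry-class].
#' @param traj a [ScanTrajectory-class].
#' @param psfEx excitation [PSFModel-class].
#' @param frameIndex frame number (1-based).
#' @param dim field size c(H, W) px.
#' @param pixelNm grid spacing (nm).
#' @param originNm lattice origin offset (x, y) nm.
#' @return nonnegative H x W matrix with maximum 1.
#' @export
illuminationPattern <- function(geom, traj, psfEx, frameIndex, dim, pixelNm,
                                originNm = c(0, 0)) {
  if (frameIndex < 1L || frameIndex > traj@nFrames)
    stop("frameIndex out of range")
  illuminationStack(geom, traj, psfEx, dim, pixelNm, originNm,
                    frames = frameIndex)[, , 1L]
}

#' Illumination patterns for a set of frames
#'
#' @inheritParams illuminationPattern
#' @param frames frame indices (default all).
#' @return H x W x length(frames) array, each slice normalized to the common
#'   peak of the first frame so relative frame-to-frame intensity is kept.
#' @export
illuminationStack <- function(geom, traj, psfEx, dim, pixelNm,
                              originNm = c(0, 0),
                              frames = seq_len(traj@nFrames)) {
  if (length(dim) == 1L) dim <- c(dim, dim)
  dim <- as.integer(dim)
  fieldNm <- c(dim[2L], dim[1L]) * pixelNm
  pos <- scanPositions(geom, traj, fieldNm, originNm,
                       marginNm = geom@pitchNm / 2 +
                         4 * psfEx@sigmaLateralNm)
  kern <- psfKernel(psfEx, pixelNm)
  ops <- makeConvOps(dim, kern)
  radiusPx <- geom@diameterNm / 2 / pixelNm
  out <- array(0, c(dim, length(frames)))
  peak <- NA_real_
  for (j in seq_along(frames)) {
    ctr <- nmToPx(pos[[frames[j]]], dim, pixelNm)
    disks <- renderDisks(dim, ctr, radiusPx)
    pat <- ops$forward(disks)
    pat[pat < 0] <- 0
    if (is.na(peak)) peak <- max(pat)
    out[, , j] <- pat / peak
  }
  out
}

#' Simulate a multifocal scan stack
#'
#' Forward image formation for every frame:
#' `frame_i = h_det * (P_i . O) + background`, where `P_i` is the frame's
#' illumination pattern, `O` the phantom and `h_det` the detection PSF. The
#' out-of-focus background is frame-independent: either a constant plane
#' (`backgroundLevel`) or a supplied defocus image blurred by a wide kernel
#' (`backgroundImage`), matching the premise that out-of-focus light does not
#' move with the scan.
#'
#' @param phantom a [Phantom-class]; its grid is the scan field.
#' @param geom a [PinholeArrayGeometry-class].
#' @param traj a [ScanTrajectory-class].
#' @param optics an [OpticalConfig-class]; PSFs derive from it unless
#'   explicit models are given.
#' @param backgroundLevel constant additive background (>= 0).
#' @param backgroundImage optional matrix added to every frame (blurred
#'   defocus structure), same size as the phantom.
#' @param noise optional list(snrDb=, kind=, seed=) forwarded to
#'   [addNoiseToSNR()].
#' @param bin camera binning factor (block average), default 1.
#' @param psfEx,psfDet optional explicit [PSFModel-class] overrides.
#' @param originNm lattice origin offset (x, y) nm.
#' @return a [RawStack-class] carrying the full acquisition metadata.
#' @export
simulateStack <- function(phantom, geom, traj, optics,
                          backgroundLevel = 0, backgroundImage = NULL,
                          noise = NULL, bin = 1L,
                          psfEx = gaussianPSF(optics, "excitation"),
                          psfDet = gaussianPSF(optics, "emission"),
                          originNm = c(0, 0)) {
  stopifnot(is(phantom, "Phantom"))
  if (backgroundLevel < 0) stop("backgroundLevel must be nonnegative")
  dim <- dim(phantom@image)
  pixelNm <- phantom@pixelNm
  pats <- illuminationStack(geom, traj, psfEx, dim, pixelNm, originNm)
  kernDet <- psfKernel(psfDet, pixelNm)
  frames <- array(0, c(dim, traj@nFrames))
  bg <- matrix(backgroundLevel, dim[1L], dim[2L])
  if (!is.null(backgroundImage)) {
    if (!identical(dim(backgroundImage), dim))
      stop("backgroundImage must match the phantom grid")
    bg <- bg + backgroundImage
  }
  for (i in seq_len(traj@nFrames))
    frames[, , i] <- forwardModel(phantom@image, pats[, , i], kernDet) + bg
  if (bin > 1L) {
    H <- dim[1L] %/% bin; W <- dim[2L] %/% bin
    binned <- array(0, c(H, W, traj@nFrames))
    for (i in seq_len(traj@nFrames))
      binned[, , i] <- binImage(frames[, , i], as.integer(bin))
    frames <- binned
    pixelNm <- pixelNm * bin
  }
  stack <- new("RawStack", frames = frames, pixelNm = pixelNm,
               optics = optics, geometry = geom, trajectory = traj,
               noise = list())
  if (!is.null(noise))
    stack <- addNoiseToSNR(stack, noise$snrDb,
                           kind = if (is.null(noise$kind)) "gaussian"
                                  else noise$kind,
                           seed = if (is.null(noise$seed)) 1L else noise$seed)
  stack
}

#' Add noise at a controlled SNR
#'
#' SNR is defined as `10 log10(mean(signal^2) / sigma_noise^2)` over the
#' pixels where the noise-free signal exceeds 1% of the stack maximum. For
#' Gaussian noise the requested SNR is achieved within 0.1 dB on any
#' reasonably sized stack; for Poisson noise the stack is rescaled to the
#' photon budget whose shot-noise variance meets the request, then divided
#' back, so frame means are preserved in expectation. `snrDb = Inf` returns
#' the input unchanged.
#'
#' @param stack a [RawStack-class] (noise-free).
#' @param snrDb requested SNR in dB.
#' @param kind `"gaussian"`, `"poisson"` or `"mixed"` (half the noise power
#'   from each).
#' @param seed RNG seed, recorded in the stack metadata.
#' @return a [RawStack-class] with the noise record filled in.
#' @export
addNoiseToSNR <- function(stack, snrDb, kind = c("gaussian", "poisson",
                                                 "mixed"), seed = 1L) {
  stopifnot(is(stack, "RawStack"))
  kind <- match.arg(kind)
  if (is.infinite(snrDb) && snrDb > 0) return(stack)
  s <- stack@frames
  mx <- max(s)
  if (mx <= 0) stop("cannot set an SNR on an all-zero stack")
  mask <- s > 0.01 * mx
  ms <- mean(s[mask]^2)
  targetVar <- ms / 10^(snrDb / 10)
  noisy <- withSeed(seed, {
    if (kind == "gaussian") {
      s + array(rnorm(length(s), 0, sqrt(targetVar)), dim(s))
    } else if (kind == "poisson") {
      alpha <- mean(s[mask]) / targetVar
      array(rpois(length(s), alpha * s) / alpha, dim(s))
    } else {
      alpha <- mean(s[mask]) / (targetVar / 2)
      array(rpois(length(s), alpha * s) / alpha +
              rnorm(length(s), 0, sqrt(targetVar / 2)), dim(s))
    }
  })
  achieved <- 10 * log10(ms / stats::var(as.vector(noisy[mask] - s[mask])))
  out <- stack
  out@frames <- noisy
  out@noise <- list(kind = kind, snrDb = snrDb, achievedSnrDb = achieved,
                    seed = as.integer(seed))
  out
}

#' @describeIn RawStack-class compact display
#' @param object a `RawStack`
#' @export
setMethod("show", "RawStack", function(object) {
  d <- dim(object@frames)
  cat("RawStack:", d[3L], "frames of", d[1L], "x", d[2L], "px at",
      format(object@pixelNm, digits = 4), "nm/px\n")
  if (length(object@noise))
    cat("  noise:", object@noise$kind, "@",
        format(object@noise$snrDb, digits = 3), "dB (achieved",
        format(object@noise$achievedSnrDb, digits = 4), "dB), seed",
        object@noise$seed, "\n")
  else cat("  noise: none\n")
})

#' @describeIn Phantom-class compact display
#' @param object a `Phantom`
#' @export
setMethod("show", "Phantom", function(object) {
  d <- dim(object@image)
  cat("Phantom (", object@kind, "): ", d[1L], " x ", d[2L], " px at ",
      format(object@pixelNm, digits = 4), " nm/px\n", sep = "")
})

#' Accessors for stacks and results
#'
#' @param x a [RawStack-class].
#' @return `frames()` the H x W x n array; `nFrames()` the frame count;
#'   `pixelSize()` the pixel size in nm.
#' @export
frames <- function(x) x@frames

#' @rdname frames
#' @export
nFrames <- function(x) dim(x@frames)[3L]

#' @rdname frames
#' @export
pixelSize <- function(x) x@pixelNm
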