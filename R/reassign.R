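#' Construct a digital pinhole
#'
#' @param sigmaRel mask width as a multiple of the base spot width; `Inf`
#'   disables the pinhole.
#' @param sigmaBasePx fitted standard deviation of the average illumination
#'   spot (px on the raw grid), e.g. from [estimateSigmaBase()].
#' @return a [DigitalPinhole-class].
#' @export
digitalPinhole <- function(sigmaRel = 1, sigmaBasePx) {
  new("DigitalPinhole", sigmaRel = sigmaRel, sigmaBasePx = sigmaBasePx)
}

#' Estimate the base spot width sigma_base
#'
#' Aligns background-subtracted cut-outs around every predicted spot centre,
#' averages them, and fits a 2D Gaussian to the average. The fitted standard
#' deviation defines the unit in which digital-pinhole widths are expressed.
#'
#' @param stack a [RawStack-class] or H x W x n array.
#' @param spots a [SpotGrid-class] on the same grid.
#' @param windowRadiusPx cut-out radius (px); default just under half the
#'   lattice pitch.
#' @param sigmaRel `sigmaRel` stored in the returned pinhole.
#' @return a [DigitalPinhole-class] with the fitted `sigmaBasePx`.
#' @export
estimateSigmaBase <- function(stack, spots, windowRadiusPx = NULL,
                              sigmaRel = 1) {
  arr <- if (is(stack, "RawStack")) stack@frames else stack
  d <- dim(arr)
  if (is.null(windowRadiusPx)) {
    pitchPx <- sqrt(sum(spots@latticeVectors[, 1L]^2))
    windowRadiusPx <- max(3L, as.integer(floor(pitchPx / 2)) - 1L)
  }
  wr <- as.integer(windowRadiusPx)
  acc <- matrix(0, 2L * wr + 1L, 2L * wr + 1L)
  nAcc <- 0L
  for (f in seq_len(d[3L])) {
    cf <- spots@centers[[f]]
    for (j in seq_len(nrow(cf))) {
      r0 <- round(cf[j, 1L]); c0 <- round(cf[j, 2L])
      if (r0 - wr < 1 || r0 + wr > d[1L] || c0 - wr < 1 || c0 + wr > d[2L])
        next
      acc <- acc + arr[(r0 - wr):(r0 + wr), (c0 - wr):(c0 + wr), f]
      nAcc <- nAcc + 1L
    }
  }
  if (nAcc < 10L) stop("need at least 10 in-bounds spots to fit sigma_base")
  avg <- acc / nAcc
  ## background: median of the window border
  border <- c(avg[1L, ], avg[nrow(avg), ], avg[, 1L], avg[, ncol(avg)])
  avg <- avg - stats::median(border)
  fit <- fitGaussian2D(avg)
  if (!fit$converged || fit$sigma <= 0)
    stop("sigma_base Gaussian fit did not converge; residual rms ",
         format(fit$rms, digits = 3))
  digitalPinhole(sigmaRel = sigmaRel, sigmaBasePx = fit$sigma)
}

## least-squares isotropic 2D Gaussian + offset fit; moment initialization
fitGaussian2D <- function(img) {
  d <- dim(img)
  rows <- seq_len(d[1L]); cols <- seq_len(d[2L])
  w <- pmax(img, 0)
  sw <- sum(w)
  if (sw <= 0) return(list(converged = FALSE, sigma = NA_real_,
                           rms = NA_real_))
  mr <- sum(rows * rowSums(w)) / sw
  mc <- sum(cols * colSums(w)) / sw
  vr <- sum(outer(rows - mr, cols - mc, function(a, b) a^2) * w) / sw
  s0 <- sqrt(max(vr, 0.25))
  R <- outer(rows, cols, function(a, b) 0 * b + a)
  C <- outer(rows, cols, function(a, b) 0 * a + b)
  resFun <- function(p) {
    as.vector(p[1L] * exp(-((R - p[2L])^2 + (C - p[3L])^2) /
                            (2 * p[4L]^2)) + p[5L] - img)
  }
  p0 <- c(max(img), mr, mc, s0, 0)
  fit <- try(minpack.lm::nls.lm(p0, fn = resFun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(converged = FALSE, sigma = NA_real_, rms = NA_real_))
  p <- fit$par
  list(converged = fit$info %in% 1:4, amplitude = p[1L],
       center = c(p[2L], p[3L]), sigma = abs(p[4L]), offset = p[5L],
       rms = sqrt(mean(fit$fvec^2)))
}

#' Extract per-spot sub-images
#'
#' Cuts one window per predicted spot per frame, centred on the located
#' (sub-pixel) centre rounded to the nearest pixel of the working grid.
#' Windows reaching beyond the field edge are zero-filled and flagged
#' truncated; their valid-pixel mask is kept so reassignment weights stay
#' correct.
#'
#' @param stack a [RawStack-class] or H x W x n array (typically the
#'   upsampled OLID-filtered stack).
#' @param spots a [SpotGrid-class] on the same grid.
#' @param windowRadiusPx window radius (px). Must not exceed half the
#'   lattice pitch (cross-talk) and should be at least 3 sigma_base.
#' @param sigmaBasePx when given, enforce `windowRadiusPx >= 3 * sigmaBasePx`.
#' @return list of sub-image records: `frame`, `center` (row, col on the
#'   working grid), `img`, `valid` (logical matrix), `truncated`.
#' @export
extractSubimages <- function(stack, spots, windowRadiusPx,
                             sigmaBasePx = NULL) {
  arr <- if (is(stack, "RawStack")) stack@frames else stack
  d <- dim(arr)
  wr <- as.integer(windowRadiusPx)
  pitchPx <- sqrt(sum(spots@latticeVectors[, 1L]^2))
  if (wr > pitchPx / 2)
    stop("window radius ", wr, " px exceeds half the lattice pitch (",
         format(pitchPx / 2, digits = 4), " px): sub-images would overlap ",
         "neighbouring spots")
  if (!is.null(sigmaBasePx) && wr < 3 * sigmaBasePx)
    stop("window radius must be at least 3 * sigma_base = ",
         format(3 * sigmaBasePx, digits = 4), " px")
  n <- 2L * wr + 1L
  out <- vector("list", sum(vapply(spots@centers, nrow, integer(1))))
  pos <- 0L
  for (f in seq_len(d[3L])) {
    cf <- spots@centers[[f]]
    for (j in seq_len(nrow(cf))) {
      r0 <- round(cf[j, 1L]); c0 <- round(cf[j, 2L])
      rows <- (r0 - wr):(r0 + wr)
      cols <- (c0 - wr):(c0 + wr)
      okR <- rows >= 1L & rows <= d[1L]
      okC <- cols >= 1L & cols <= d[2L]
      img <- matrix(0, n, n)
      img[okR, okC] <- arr[rows[okR], cols[okC], f]
      valid <- outer(okR, okC, `&`)
      truncated <- !all(valid)
      pos <- pos + 1L
      out[[pos]] <- list(frame = f, center = as.numeric(cf[j, ]),
                         img = img, valid = valid, truncated = truncated)
    }
  }
  if (pos == 0L) stop("spot grid contains no in-bounds spots")
  out[seq_len(pos)]
}

#' Apply a Gaussian digital pinhole to a sub-image
#'
#' Multiplies the sub-image elementwise by
#' `exp(-rho^2 / (2 (sigmaRel * sigmaBase)^2))` where `rho` is the distance
#' from the located (sub-pixel) spot centre. `sigmaRel = Inf` is the
#' identity.
#'
#' @param sub one sub-image record from [extractSubimages()].
#' @param pinhole a [DigitalPinhole-class].
#' @param pxScale factor converting `sigmaBasePx` (raw grid) to the
#'   sub-image grid, i.e. the upsampling factor.
#' @return the record with `img` masked and the mask stored as `mask`.
#' @export
applyDigitalPinhole <- function(sub, pinhole, pxScale = 1) {
  n <- nrow(sub$img)
  wr <- (n - 1L) %/% 2L
  if (is.infinite(pinhole@sigmaRel)) {
    sub$mask <- matrix(1, n, n)
    return(sub)
  }
  sigma <- pinhole@sigmaRel * pinhole@sigmaBasePx * pxScale
  ## centre of the window in window coordinates, including the sub-pixel
  ## part of the located centre
  fr <- sub$center[1L] - round(sub$center[1L])
  fc <- sub$center[2L] - round(sub$center[2L])
  rr <- (-wr):wr - fr
  cc <- (-wr):wr - fc
  mask <- exp(-outer(rr^2, cc^2, `+`) / (2 * sigma^2))
  sub$img <- sub$img * mask
  sub$mask <- mask
  sub
}

#' Reassign sub-images onto a doubled-coordinate canvas
#'
#' Each sub-image is added to a canvas of twice the working-grid size,
#' centred at twice its located centre coordinate: a camera pixel at offset
#' `delta` from the spot centre lands at `center + delta` in object
#' coordinates, i.e. its offset is halved, which is pixel reassignment. The
#' pinhole mask (or the unit window, restricted to valid pixels) is
#' accumulated into the weight map at the same location; [prImage()] divides
#' the two.
#'
#' @param subimages list from [extractSubimages()], optionally after
#'   [applyDigitalPinhole()].
#' @param dimIn working-grid size c(H, W) of the stack the sub-images came
#'   from.
#' @param pixelNm pixel size of the working grid (nm).
#' @param params optional list stored in the result.
#' @return a [PRResult-class]; its `pixelNm` is `pixelNm / 2` (effective
#'   object sampling of the doubled-coordinate canvas).
#' @export
reassignAndAccumulate <- function(subimages, dimIn, pixelNm = 1,
                                  params = list()) {
  if (length(subimages) == 0L) stop("empty sub-image list")
  H <- 2L * dimIn[1L]; W <- 2L * dimIn[2L]
  canvas <- matrix(0, H, W)
  weights <- matrix(0, H, W)
  ## without a pinhole mask, weight each window by a data-driven
  ## sensitivity profile: a Gaussian fitted to the average sub-image,
  ## re-centred on each window's sub-pixel spot centre. A flat box weight
  ## would imprint its own count-quantization ripple on the normalized
  ## image; the fitted profile tracks the true per-window sensitivity.
  if (is.null(subimages[[1L]]$mask)) {
    avg <- Reduce(`+`, lapply(subimages, `[[`, "img")) / length(subimages)
    fit <- fitGaussian2D(avg)
    n1 <- nrow(subimages[[1L]]$img)
    wr1 <- (n1 - 1L) %/% 2L
    if (isTRUE(fit$converged) && is.finite(fit$sigma) && fit$sigma > 0) {
      subimages <- lapply(subimages, function(s) {
        fr <- s$center[1L] - round(s$center[1L])
        fc <- s$center[2L] - round(s$center[2L])
        rr <- (-wr1):wr1 - fr
        cc <- (-wr1):wr1 - fc
        s$mask <- exp(-outer(rr^2, cc^2, `+`) / (2 * fit$sigma^2))
        s
      })
    } else {
      mx <- max(avg)
      prof <- if (mx > 0) avg / mx else matrix(1, n1, n1)
      subimages <- lapply(subimages, function(s) { s$mask <- prof; s })
    }
  }
  for (sub in subimages) {
    n <- nrow(sub$img)
    wr <- (n - 1L) %/% 2L
    ## the window was cut around round(center); its centre pixel holds the
    ## sample at round(center) and must land at the exact doubled coordinate
    ## round(center) + center; the fractional part is distributed over the
    ## four neighbouring canvas alignments (bilinear placement)
    tgt <- round(sub$center) + sub$center
    base <- floor(tgt)
    frac <- tgt - base
    m <- if (is.null(sub$mask)) matrix(1, n, n) else sub$mask
    m <- m * sub$valid
    for (dr in 0:1) for (dc in 0:1) {
      w <- (if (dr == 0L) 1 - frac[1L] else frac[1L]) *
        (if (dc == 0L) 1 - frac[2L] else frac[2L])
      if (w <= 0) next
      rows <- (base[1L] + dr - wr):(base[1L] + dr + wr)
      cols <- (base[2L] + dc - wr):(base[2L] + dc + wr)
      okR <- rows >= 1L & rows <= H
      okC <- cols >= 1L & cols <= W
      if (!any(okR) || !any(okC)) next
      canvas[rows[okR], cols[okC]] <- canvas[rows[okR], cols[okC]] +
        w * sub$img[okR, okC]
      weights[rows[okR], cols[okC]] <- weights[rows[okR], cols[okC]] +
        w * m[okR, okC]
    }
  }
  new("PRResult", canvas = canvas, weights = weights,
      pixelNm = pixelNm / 2, params = params)
}

#' Weight-normalized pixel-reassignment image
#'
#' @param pr a [PRResult-class].
#' @param epsRel weights below `epsRel * max(weights)` give 0.
#' @return normalized canvas (matrix).
#' @export
prImage <- function(pr, epsRel = 1e-6) {
  w <- pr@weights
  out <- matrix(0, nrow(w), ncol(w))
  ok <- w > epsRel * max(w)
  out[ok] <- pr@canvas[ok] / w[ok]
  out
}

#' Pixel-reassignment reconstruction pipeline
#'
#' Convenience wrapper chaining the PR stages: band-limited upsampling of
#' the (OLID-filtered) stack, sub-image extraction at the located centres,
#' digital pinhole masking, and reassignment onto the doubled-coordinate
#' canvas.
#'
#' @param stack a [RawStack-class] or array (already OLID-filtered if
#'   desired).
#' @param spots a [SpotGrid-class] on the raw-stack grid.
#' @param pinhole a [DigitalPinhole-class], or `NULL` for no pinhole (unit
#'   windows).
#' @param upsample upsampling factor before extraction (1, 2 or 4;
#'   default 2).
#' @param windowRadiusPx window radius on the raw grid; defaults to just
#'   under half the pitch.
#' @param pixelNm raw-grid pixel size (nm); taken from the stack when
#'   available.
#' @return a [PRResult-class]. Its canvas samples the object at
#'   `pixelNm / (2 * upsample)` nm per canvas pixel.
#' @export
prReconstruct <- function(stack, spots, pinhole = NULL, upsample = 2L,
                          windowRadiusPx = NULL, pixelNm = NULL) {
  arr <- if (is(stack, "RawStack")) stack@frames else stack
  if (is.null(pixelNm))
    pixelNm <- if (is(stack, "RawStack")) stack@pixelNm else 1
  if (is.null(windowRadiusPx)) {
    pitchPx <- sqrt(sum(spots@latticeVectors[, 1L]^2))
    windowRadiusPx <- floor(pitchPx / 2) - 1
  }
  upsample <- as.integer(upsample)
  up <- upsampleStack(arr, upsample)
  up[up < 0] <- 0  # band-limited interpolation undershoot
  spotsUp <- scaleSpotGrid(spots, upsample)
  subs <- extractSubimages(up, spotsUp,
                           windowRadiusPx = round(windowRadiusPx * upsample))
  if (!is.null(pinhole))
    subs <- lapply(subs, applyDigitalPinhole, pinhole = pinhole,
                   pxScale = upsample)
  reassignAndAccumulate(subs, dim(up)[1:2], pixelNm = pixelNm / upsample,
                        params = list(upsample = upsample,
                                      windowRadiusPx = windowRadiusPx,
                                      sigmaRel =
                                        if (is.null(pinhole)) Inf
                                        else pinhole@sigmaRel))
}

#' MC-ISM reconstruction: deconvolution of the PR image
#'
#' The pixel-reassigned image is Richardson-Lucy deconvolved with the
#' effective PR PSF (for matched Gaussian excitation/detection widths,
#' a Gaussian of `sigma_base / sqrt(2)` on the canvas grid).
#'
#' @param pr a [PRResult-class].
#' @param psfPr effective PR PSF: a kernel matrix, or a [PSFModel-class]
#'   rendered at the canvas pixel size. In object units the PR PSF width is
#'   `sigma_base / 2` (the spot-image width at doubled canvas coordinates);
#'   see [prPSF()].
#' @param nIter RL iterations; 40 or more is typical, 0 returns the PR
#'   image unchanged.
#' @param epsilon division guard.
#' @return deconvolved image on the canvas grid.
#' @export
mcismReconstruct <- function(pr, psfPr, nIter = 40L, epsilon = 1e-12) {
  if (nIter < 0L) stop("nIter must be >= 0")
  img <- prImage(pr)
  if (nIter == 0L) return(img)
  kern <- if (is.matrix(psfPr)) psfPr else psfKernel(psfPr, pr@pixelNm)
  rlDeconvolve(img, kern, nIter = nIter, epsilon = epsilon)
}

#' Effective pixel-reassignment PSF
#'
#' The PR canvas point-spread function is the convolution of the excitation
#' spot profile with the detection PSF, laid out at doubled coordinates; its
#' standard deviation therefore equals the fitted spot-image width
#' `sigma_base` in canvas-doubled units, i.e. `sigma_base / 2` in object
#' units. This is the PSF to hand to [mcismReconstruct()].
#'
#' @param pinhole a [DigitalPinhole-class] carrying `sigmaBasePx` (raw grid).
#' @param pr the [PRResult-class] whose canvas will be deconvolved.
#' @param rawPixelNm pixel size of the raw grid `sigmaBasePx` refers to (nm).
#' @return kernel matrix rendered at the canvas pixel size.
#' @export
prPSF <- function(pinhole, pr, rawPixelNm) {
  sigmaNm <- pinhole@sigmaBasePx * rawPixelNm / 2
  psfKernel(psfModel(sigmaNm, pixelNm = pr@pixelNm), pr@pixelNm)
}

#' @describeIn PRResult-class compact display
#' @param object a `PRResult`
#' @export
setMethod("show", "PRResult", function(object) {
  d <- dim(object@canvas)
  cat("PRResult:", d[1L], "x", d[2L], "canvas at",
      format(object@pixelNm, digits = 4), "nm/px (doubled coordinates)\n")
  cat("  coverage:", round(100 * mean(object@weights > 0), 1),
      "% of canvas pixels\n")
})

#' @describeIn DigitalPinhole-class compact display
#' @param object a `DigitalPinhole`
#' @export
setMethod("show", "DigitalPinhole", function(object) {
  cat("DigitalPinhole: sigmaRel", object@sigmaRel, "x sigma_base",
      format(object@sigmaBasePx, digits = 4), "px\n")
})
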