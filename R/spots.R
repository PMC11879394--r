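#' Detect illumination-spot candidates in one frame
#'
#' Matched filtering: the frame is cross-correlated with the excitation
#' kernel, local maxima above a relative threshold are taken as candidates,
#' a minimum mutual separation is enforced (brightest first), and each
#' candidate is refined by an iterated windowed centroid with local
#' background subtraction.
#'
#' @param frame nonnegative matrix.
#' @param psfEx excitation [PSFModel-class] or a kernel matrix.
#' @param minSeparationPx minimum candidate separation (px).
#' @param pixelNm pixel size (needed when `psfEx` is a model).
#' @param threshold relative intensity threshold on the matched-filter
#'   response (fraction of its maximum).
#' @return k x 2 matrix of (row, col) sub-pixel centres; empty with a
#'   warning when nothing exceeds the threshold.
#' @export
detectSpotCandidates <- function(frame, psfEx, minSeparationPx,
                                 pixelNm = NULL, threshold = 0.25) {
  if (any(frame < 0)) stop("frame must be nonnegative")
  kern <- if (is.matrix(psfEx)) psfEx else {
    if (is.null(pixelNm)) stop("pixelNm required when psfEx is a PSFModel")
    psfKernel(psfEx, pixelNm)
  }
  sm <- convSame(frame, kern)
  d <- dim(sm)
  thr <- threshold * max(sm)
  if (max(sm) <= 0) {
    warning("no candidates above threshold")
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  }
  ## 8-neighbour local maxima (interior only)
  core <- sm[2:(d[1L] - 1L), 2:(d[2L] - 1L)]
  isMax <- core >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & core >= sm[2:(d[1L] - 1L) + dr, 2:(d[2L] - 1L) + dc]
  }
  idx <- which(isMax, arr.ind = TRUE) + 1L
  if (nrow(idx) == 0L) {
    warning("no candidates above threshold")
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  }
  ## brightest-first minimum-separation pruning
  ord <- order(sm[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1L):nrow(idx)
      d2 <- (idx[later, 1L] - idx[i, 1L])^2 + (idx[later, 2L] - idx[i, 2L])^2
      keep[later][d2 < minSeparationPx^2] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  ## windowed-centroid refinement on the matched-filter response, followed
  ## by a log-parabola sub-pixel peak fit (exact for Gaussian peaks)
  wr <- max(2L, as.integer(ceiling(1.5 * (dim(kern)[1L] %/% 2L) / 2)) + 1L)
  centers <- matrix(0, nrow(idx), 2L,
                    dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(nrow(idx))) {
    ctr <- as.numeric(idx[i, ])
    for (it in 1:3) {
      r0 <- round(ctr[1L]); c0 <- round(ctr[2L])
      rows <- max(1L, r0 - wr):min(d[1L], r0 + wr)
      cols <- max(1L, c0 - wr):min(d[2L], c0 + wr)
      w <- sm[rows, cols] - min(sm[rows, cols])
      sw <- sum(w)
      if (sw <= 0) break
      ctr <- c(sum(rows * rowSums(w)), sum(cols * colSums(w))) / sw
    }
    r0 <- round(ctr[1L]); c0 <- round(ctr[2L])
    if (r0 > 1L && r0 < d[1L] && c0 > 1L && c0 < d[2L]) {
      floorV <- min(sm[(r0 - 1L):(r0 + 1L), (c0 - 1L):(c0 + 1L)])
      v <- function(dr, dc) log(sm[r0 + dr, c0 + dc] - floorV +
                                  1e-12 * max(sm))
      denR <- v(-1L, 0L) - 2 * v(0L, 0L) + v(1L, 0L)
      denC <- v(0L, -1L) - 2 * v(0L, 0L) + v(0L, 1L)
      if (denR < 0 && denC < 0) {
        dR <- 0.5 * (v(-1L, 0L) - v(1L, 0L)) / denR
        dC <- 0.5 * (v(0L, -1L) - v(0L, 1L)) / denC
        if (abs(dR) <= 0.6 && abs(dC) <= 0.6) ctr <- c(r0 + dR, c0 + dC)
      }
    }
    centers[i, ] <- ctr
  }
  centers
}

## lattice basis (columns) in (row, col) px units from a geometry prior
latticeBasisPx <- function(geom, pixelNm) {
  th <- geom@tiltDeg * pi / 180
  p <- geom@pitchNm / pixelNm
  ## x -> col, y -> row
  cbind(c(p * sin(th), p * cos(th)),    # b1: (row, col)
        c(p * cos(th), -p * sin(th)))   # b2
}

#' Fit a global lattice and scan step to per-frame candidates
#'
#' Regularizes noisy per-frame spot detections with the rigid model
#' `center(f, m, k) = origin + m b1 + k b2 + (f - 1) step`, fitted by
#' iterated least squares with integer site assignment and outlier rejection
#' (residual > 3 x rms). The returned grid contains the model-predicted
#' centre of every lattice site inside the field for every frame, so dim or
#' undetected spots inherit the fitted geometry.
#'
#' @param candidates list (per frame) of k x 2 (row, col) candidate matrices,
#'   as returned by [detectSpotCandidates()].
#' @param geom a [PinholeArrayGeometry-class] prior.
#' @param traj a [ScanTrajectory-class] prior.
#' @param pixelNm pixel size of the candidate grid (nm).
#' @param dim field size c(H, W) px used to enumerate predicted sites.
#' @return a [SpotGrid-class].
#' @export
fitGridToFrames <- function(candidates, geom, traj, pixelNm, dim) {
  nF <- length(candidates)
  if (nF < 1L) stop("no frames")
  cnt <- vapply(candidates, nrow, integer(1))
  if (mean(cnt) < 4) stop("need at least 4 candidates per frame on average")
  B0 <- latticeBasisPx(geom, pixelNm)
  t0 <- traj@stepNm / pixelNm * c(traj@direction[2L], traj@direction[1L])
  ## anchor: frame-1 candidate closest to the field centre defines site (0,0)
  ctrPx <- (dim + 1) / 2
  c1 <- candidates[[1L]]
  if (nrow(c1) == 0L) stop("frame 1 has no candidates")
  o0 <- c1[which.min((c1[, 1L] - ctrPx[1L])^2 + (c1[, 2L] - ctrPx[2L])^2), ]
  o <- as.numeric(o0); B <- B0; tv <- t0
  obs <- NULL
  for (pass in 1:4) {
    rows <- lapply(seq_len(nF), function(f) {
      cf <- candidates[[f]]
      if (nrow(cf) == 0L) return(NULL)
      rel <- t(cf) - (o + (f - 1) * tv)
      mk <- round(solve(B) %*% rel)
      cbind(cf, t(mk), f - 1)
    })
    obs <- do.call(rbind, rows)
    X <- cbind(1, obs[, 3L], obs[, 4L], obs[, 5L])
    if (qr(X)$rank < 4L)
      stop("degenerate geometry: candidates do not span the lattice")
    fitR <- lm.fit(X, obs[, 1L])
    fitC <- lm.fit(X, obs[, 2L])
    res <- sqrt(fitR$residuals^2 + fitC$residuals^2)
    ## robust (MAD-based) outlier threshold so spurious candidates cannot
    ## inflate their own rejection limit
    keep <- res <= max(3 * 1.4826 * stats::median(res), 1e-9)
    if (!all(keep) && sum(keep) >= 4L) {
      fitR <- lm.fit(X[keep, , drop = FALSE], obs[keep, 1L])
      fitC <- lm.fit(X[keep, , drop = FALSE], obs[keep, 2L])
    }
    o <- unname(c(fitR$coefficients[1L], fitC$coefficients[1L]))
    B <- unname(rbind(c(fitR$coefficients[2L], fitR$coefficients[3L]),
                      c(fitC$coefficients[2L], fitC$coefficients[3L])))
    tv <- unname(c(fitR$coefficients[4L], fitC$coefficients[4L]))
  }
  resR <- obs[, 1L] - (o[1L] + B[1L, 1L] * obs[, 3L] + B[1L, 2L] * obs[, 4L] +
                         tv[1L] * obs[, 5L])
  resC <- obs[, 2L] - (o[2L] + B[2L, 1L] * obs[, 3L] + B[2L, 2L] * obs[, 4L] +
                         tv[2L] * obs[, 5L])
  res <- sqrt(resR^2 + resC^2)
  rms <- sqrt(mean(res[res <= 3 * sqrt(mean(res^2))]^2))
  predictSpotGrid(B, o, tv, nF, dim, rms)
}

## enumerate model-predicted centres for all in-bounds sites of all frames
predictSpotGrid <- function(B, o, tv, nF, dim, rms) {
  corners <- rbind(c(1, 1), c(1, dim[2L]), c(dim[1L], 1), dim)
  pad <- 2
  rng <- NULL
  for (f in c(1L, nF)) {
    ij <- t(solve(B) %*% (t(corners) - (o + (f - 1) * tv)))
    rng <- rbind(rng, ij)
  }
  mr <- (floor(min(rng[, 1L])) - pad):(ceiling(max(rng[, 1L])) + pad)
  kr <- (floor(min(rng[, 2L])) - pad):(ceiling(max(rng[, 2L])) + pad)
  grid <- as.matrix(expand.grid(m = mr, k = kr))
  base <- t(B %*% t(grid))
  centers <- vector("list", nF)
  siteIndex <- vector("list", nF)
  for (f in seq_len(nF)) {
    p <- base
    p[, 1L] <- p[, 1L] + o[1L] + (f - 1) * tv[1L]
    p[, 2L] <- p[, 2L] + o[2L] + (f - 1) * tv[2L]
    keep <- p[, 1L] >= 1 & p[, 1L] <= dim[1L] &
      p[, 2L] >= 1 & p[, 2L] <= dim[2L]
    cm <- p[keep, , drop = FALSE]
    colnames(cm) <- c("row", "col")
    centers[[f]] <- cm
    siteIndex[[f]] <- grid[keep, , drop = FALSE]
  }
  new("SpotGrid", centers = centers, latticeVectors = B, origin = o,
      stepPx = tv, rmsResidual = rms, siteIndex = siteIndex)
}

#' Spot grid from known acquisition geometry
#'
#' For simulated data (or a calibrated instrument) the illumination-spot
#' centres follow directly from the lattice geometry and scan trajectory; no
#' image-based localization is needed. This is the appropriate grid source
#' for sparse phantoms such as single point sources, whose frames do not
#' visually reveal the illumination positions.
#'
#' @param geom a [PinholeArrayGeometry-class].
#' @param traj a [ScanTrajectory-class].
#' @param pixelNm pixel size (nm).
#' @param dim field size c(H, W) px.
#' @param originNm lattice origin offset (x, y) nm from the field centre.
#' @return a [SpotGrid-class] with zero residual.
#' @export
spotGridFromGeometry <- function(geom, traj, pixelNm, dim,
                                 originNm = c(0, 0)) {
  if (length(dim) == 1L) dim <- c(dim, dim)
  B <- latticeBasisPx(geom, pixelNm)
  o <- c(originNm[2L] / pixelNm + (dim[1L] + 1) / 2,
         originNm[1L] / pixelNm + (dim[2L] + 1) / 2)
  tv <- traj@stepNm / pixelNm * c(traj@direction[2L], traj@direction[1L])
  predictSpotGrid(B, o, tv, traj@nFrames, as.integer(dim), 0)
}

#' Band-limited stack upsampling
#'
#' Frequency-domain zero-padding interpolation of every frame. The per-frame
#' mean (DC) is preserved and any sinusoid strictly below the input Nyquist
#' frequency is interpolated exactly. Used to mitigate the integer-index
#' placement error of pixel reassignment.
#'
#' @param stack a [RawStack-class] or an H x W x n array.
#' @param factor 1, 2 or 4.
#' @return same type as the input with H and W scaled by `factor` (for a
#'   [RawStack-class], `pixelNm` is divided accordingly).
#' @export
upsampleStack <- function(stack, factor) {
  if (!factor %in% c(1L, 2L, 4L)) stop("factor must be 1, 2 or 4")
  factor <- as.integer(factor)
  arr <- if (is(stack, "RawStack")) stack@frames else stack
  if (factor == 1L) return(stack)
  d <- dim(arr)
  out <- array(0, c(d[1:2] * factor, d[3L]))
  for (i in seq_len(d[3L])) out[, , i] <- upsampleImage(arr[, , i], factor)
  if (is(stack, "RawStack")) {
    res <- stack
    res@frames <- out
    res@pixelNm <- stack@pixelNm / factor
    res
  } else out
}

## map spot-grid coordinates onto an upsampled grid: index c -> 1 + (c-1)*f
scaleSpotGrid <- function(spots, factor) {
  if (factor == 1L) return(spots)
  f <- function(m) { m[, 1L] <- 1 + (m[, 1L] - 1) * factor
                     m[, 2L] <- 1 + (m[, 2L] - 1) * factor; m }
  new("SpotGrid",
      centers = lapply(spots@centers, f),
      latticeVectors = spots@latticeVectors * factor,
      origin = 1 + (spots@origin - 1) * factor,
      stepPx = spots@stepPx * factor,
      rmsResidual = spots@rmsResidual * factor,
      siteIndex = spots@siteIndex)
}

#' @describeIn SpotGrid-class compact display
#' @param object a `SpotGrid`
#' @export
setMethod("show", "SpotGrid", function(object) {
  n <- length(object@centers)
  k <- vapply(object@centers, nrow, integer(1))
  cat("SpotGrid:", n, "frames,", sum(k), "spot centres (",
      round(mean(k), 1), "per frame ), lattice fit rms",
      format(object@rmsResidual, digits = 3), "px\n")
})

#' Spot centres of one frame
#'
#' @param x a [SpotGrid-class].
#' @param frame frame index.
#' @return k x 2 (row, col) matrix.
#' @export
spotCenters <- function(x, frame = 1L) x@centers[[frame]]
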