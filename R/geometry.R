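#' Create a pinhole-array geometry
#'
#' By default the pinhole diameter is 0.5 Airy units at the sample plane and
#' the pitch follows the 1:3 diameter:pitch ratio; the tilt is matched to a
#' 49-frame (7 x 7) uniform-coverage scan.
#'
#' @param cfg an [OpticalConfig-class] used for Airy-unit conversion.
#' @param diameterAu pinhole diameter in Airy units.
#' @param pitchRatio pitch as a multiple of the diameter.
#' @param tiltDeg lattice tilt in degrees; `NULL` selects
#'   [tiltForUniformCoverage()] for `framesPerSide`.
#' @param framesPerSide frames-per-side n of the intended n^2-frame scan.
#' @return a [PinholeArrayGeometry-class].
#' @export
pinholeArrayGeometry <- function(cfg, diameterAu = 0.5, pitchRatio = 3,
                                 tiltDeg = NULL, framesPerSide = 7L) {
  au <- airyUnit(cfg)
  d <- diameterAu * au
  if (is.null(tiltDeg)) tiltDeg <- tiltForUniformCoverage(framesPerSide)
  new("PinholeArrayGeometry", pitchNm = pitchRatio * d, diameterNm = d,
      tiltDeg = tiltDeg)
}

#' Create a 1D scan trajectory
#'
#' @param nFrames number of frames.
#' @param stepNm fast-axis step (nm).
#' @param direction unit vector along the fast axis (default +x).
#' @return a [ScanTrajectory-class].
#' @export
scanTrajectory <- function(nFrames, stepNm, direction = c(1, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  pos <- outer((seq_len(nFrames) - 1) * stepNm, direction)
  new("ScanTrajectory", nFrames = as.integer(nFrames), stepNm = stepNm,
      direction = direction, positions = pos)
}

#' Tilt angle for uniform slow-axis coverage
#'
#' For a square lattice scanned along one axis with n^2 frames, rotating the
#' lattice by `atan(1/n)` makes the projections of the lattice sites on the
#' slow axis exactly equally spaced (spacing `pitch / sqrt(n^2 + 1)`), so a
#' purely 1D scan covers every unit cell uniformly.
#'
#' @param n frames per side (integer >= 2).
#' @return tilt angle in degrees.
#' @examples
#' tiltForUniformCoverage(5)  # 11.31
#' tiltForUniformCoverage(7)  # 8.13
#' @export
tiltForUniformCoverage <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  atan(1 / n) * 180 / pi
}

#' Scan-step ratio under frame reduction
#'
#' When an n^2-frame scan is replaced by an m^2-frame scan (with the tilt
#' re-matched via [tiltForUniformCoverage()]), the fast-axis step scales as
#' `sqrt(n^2 + 1) / sqrt(m^2 + 1)`. Reducing 49 frames to 25 therefore
#' enlarges the step by `sqrt(50/26) = 1.3868`, i.e. the printed factor 1.39.
#'
#' @param nFramesA frame count before reduction (perfect square).
#' @param nFramesB frame count after reduction (perfect square).
#' @return `stepB / stepA`.
#' @examples
#' frameReductionStepRatio(49, 25)  # 1.3868
#' @export
frameReductionStepRatio <- function(nFramesA, nFramesB) {
  chk <- function(f) {
    n <- sqrt(f)
    if (!is.finite(n) || n != round(n) || n < 2)
      stop("frame counts must be perfect squares n^2 with n >= 2")
    n
  }
  na <- chk(nFramesA); nb <- chk(nFramesB)
  sqrt(na^2 + 1) / sqrt(nb^2 + 1)
}

#' Standard scan presets
#'
#' The two acquisition presets: 49 frames (n = 7, tilt 8.13 deg) and the
#' frame-reduced 25 frames (n = 5, tilt 11.31 deg). The fast-axis step is
#' the exact-tiling value `pitch * sqrt(n^2 + 1) / n^2`, at which the
#' n^2-step sweep advances by exactly one fast-axis lattice period, so the
#' union of spot positions covers the field as a perfectly uniform comb
#' (no double-exposed or skipped strips). For the default 1.5 AU pitch this
#' is 0.217 AU (49 frames, the nominal quarter-Airy-unit scan interval) and
#' 0.306 AU (25 frames).
#'
#' @param cfg an [OpticalConfig-class].
#' @param nFrames 49 or 25.
#' @param diameterAu,pitchRatio forwarded to [pinholeArrayGeometry()].
#' @return list with elements `geometry` and `trajectory`.
#' @export
scanPreset <- function(cfg, nFrames = 49L, diameterAu = 0.5, pitchRatio = 3) {
  if (!nFrames %in% c(49L, 25L)) stop("presets exist for 49 or 25 frames")
  n <- as.integer(sqrt(nFrames))
  geometry <- pinholeArrayGeometry(cfg, diameterAu, pitchRatio,
                                   framesPerSide = n)
  step <- geometry@pitchNm * sqrt(n^2 + 1) / n^2
  list(geometry = geometry, trajectory = scanTrajectory(nFrames, step))
}

#' Per-frame illumination-spot centres
#'
#' Places the tilted square lattice over a field of the given size (origin at
#' the field centre) and translates it frame by frame along the scan
#' trajectory. Lattice sites are generated over an expanded bounding box so
#' that every spot whose sweep enters the field is present from frame 1.
#'
#' When `check = TRUE` the slow-axis projections of the union of all spots
#' are checked for uniform spacing; a wrong tilt/step combination triggers a
#' warning listing the maximum and minimum slow-axis gaps.
#'
#' @param geom a [PinholeArrayGeometry-class].
#' @param traj a [ScanTrajectory-class].
#' @param fieldNm field size, length-2 (width, height) in nm (a single value
#'   is square).
#' @param originNm lattice origin offset from the field centre (x, y) nm.
#' @param marginNm sites within this margin outside the field are kept.
#' @param check verify uniform slow-axis coverage.
#' @return list (one element per frame) of k x 2 matrices with columns
#'   (x, y) in nm relative to the field centre.
#' @export
scanPositions <- function(geom, traj, fieldNm, originNm = c(0, 0),
                          marginNm = geom@pitchNm / 2, check = FALSE) {
  stopifnot(is(geom, "PinholeArrayGeometry"), is(traj, "ScanTrajectory"))
  validObject(geom); validObject(traj)
  if (length(fieldNm) == 1L) fieldNm <- c(fieldNm, fieldNm)
  th <- geom@tiltDeg * pi / 180
  b1 <- geom@pitchNm * c(cos(th), sin(th))
  b2 <- geom@pitchNm * c(-sin(th), cos(th))
  ## expanded bounds: field + margin + full sweep extent (both signs)
  sweep <- apply(traj@positions, 2L, range)
  xr <- c(-fieldNm[1L] / 2 - marginNm - max(0, sweep[2L, 1L]),
          fieldNm[1L] / 2 + marginNm - min(0, sweep[1L, 1L]))
  yr <- c(-fieldNm[2L] / 2 - marginNm - max(0, sweep[2L, 2L]),
          fieldNm[2L] / 2 + marginNm - min(0, sweep[1L, 2L]))
  B <- cbind(b1, b2)
  corners <- rbind(c(xr[1L], yr[1L]), c(xr[1L], yr[2L]),
                   c(xr[2L], yr[1L]), c(xr[2L], yr[2L]))
  ij <- t(solve(B) %*% (t(corners) - originNm))
  mr <- floor(min(ij[, 1L])):ceiling(max(ij[, 1L]))
  kr <- floor(min(ij[, 2L])):ceiling(max(ij[, 2L]))
  grid <- as.matrix(expand.grid(m = mr, k = kr))
  base <- t(B %*% t(grid)) + matrix(originNm, nrow(grid), 2L, byrow = TRUE)
  colnames(base) <- c("x", "y")
  out <- lapply(seq_len(traj@nFrames), function(f) {
    p <- base
    p[, 1L] <- p[, 1L] + traj@positions[f, 1L]
    p[, 2L] <- p[, 2L] + traj@positions[f, 2L]
    keep <- p[, 1L] >= -fieldNm[1L] / 2 - marginNm &
      p[, 1L] <= fieldNm[1L] / 2 + marginNm &
      p[, 2L] >= -fieldNm[2L] / 2 - marginNm &
      p[, 2L] <= fieldNm[2L] / 2 + marginNm
    p[keep, , drop = FALSE]
  })
  if (check) {
    y <- sort(unique(round(do.call(rbind, out)[, 2L], 6)))
    gaps <- diff(y)
    gaps <- gaps[gaps > 1e-6]
    if (length(gaps) && (max(gaps) - min(gaps)) > 1e-6 * geom@pitchNm)
      warning(sprintf(
        "non-uniform slow-axis coverage: gaps range %.4g to %.4g nm",
        min(gaps), max(gaps)))
  }
  out
}

#' @describeIn PinholeArrayGeometry-class compact display
#' @param object a `PinholeArrayGeometry`
#' @export
setMethod("show", "PinholeArrayGeometry", function(object) {
  cat("PinholeArrayGeometry: diameter",
      format(object@diameterNm, digits = 5), "nm, pitch",
      format(object@pitchNm, digits = 5), "nm (1:",
      format(object@pitchNm / object@diameterNm, digits = 3),
      "), tilt ", format(object@tiltDeg, digits = 4), " deg\n", sep = "")
})

#' @describeIn ScanTrajectory-class compact display
#' @param object a `ScanTrajectory`
#' @export
setMethod("show", "ScanTrajectory", function(object) {
  cat("ScanTrajectory:", object@nFrames, "frames, step",
      format(object@stepNm, digits = 5), "nm along (",
      paste(format(object@direction, digits = 3), collapse = ", "), ")\n")
})
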