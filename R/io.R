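## Multi-page TIFF stack I/O with a JSON metadata sidecar.
##
## Frames are stored as 32-bit float TIFF pages, affinely mapped to [0, 1];
## the map (lo, hi) lives in the sidecar, so floating-point stacks round-trip
## to float32 precision. Stacks of integers up to 65535 are stored as 16-bit
## pages and round-trip bit-exactly.

metaToList <- function(stack) {
  m <- list(pixel_nm = stack@pixelNm)
  if (is(stack@optics, "OpticalConfig")) {
    o <- stack@optics
    m$optics <- list(lambda_ex = o@lambdaEx, lambda_em = o@lambdaEm,
                     na = o@na, pixel_nm = o@pixelNm,
                     pinhole_magnification = o@pinholeMagnification)
  }
  if (is(stack@geometry, "PinholeArrayGeometry")) {
    g <- stack@geometry
    m$geometry <- list(pitch_nm = g@pitchNm, diameter_nm = g@diameterNm,
                       tilt_deg = g@tiltDeg)
  }
  if (is(stack@trajectory, "ScanTrajectory")) {
    t <- stack@trajectory
    m$trajectory <- list(n_frames = t@nFrames, step_nm = t@stepNm,
                         direction = t@direction)
  }
  if (length(stack@noise)) m$noise <- stack@noise
  m
}

metaFromList <- function(m) {
  optics <- geometry <- trajectory <- NULL
  if (!is.null(m$optics))
    optics <- opticalConfig(m$optics$lambda_ex, m$optics$lambda_em,
                            m$optics$na, m$optics$pixel_nm,
                            m$optics$pinhole_magnification)
  if (!is.null(m$geometry))
    geometry <- new("PinholeArrayGeometry", pitchNm = m$geometry$pitch_nm,
                    diameterNm = m$geometry$diameter_nm,
                    tiltDeg = m$geometry$tilt_deg)
  if (!is.null(m$trajectory))
    trajectory <- scanTrajectory(m$trajectory$n_frames,
                                 m$trajectory$step_nm,
                                 unlist(m$trajectory$direction))
  list(optics = optics, geometry = geometry, trajectory = trajectory,
       noise = if (is.null(m$noise)) list() else m$noise,
       pixelNm = if (is.null(m$pixel_nm)) 1 else m$pixel_nm)
}

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack a [RawStack-class].
#' @param path output TIFF path.
#' @param sidecar metadata JSON path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(is(stack, "RawStack"))
  arr <- stack@frames
  isInt <- max(arr) <= 65535 && min(arr) >= 0 &&
    all(arr == round(arr))
  if (isInt) {
    enc <- list(mode = "uint16", lo = 0, hi = 65535)
    pages <- lapply(seq_len(dim(arr)[3L]),
                    function(i) arr[, , i] / 65535)
    bits <- 16L
  } else {
    lo <- min(arr); hi <- max(arr)
    if (hi <= lo) hi <- lo + 1
    enc <- list(mode = "float32", lo = lo, hi = hi)
    pages <- lapply(seq_len(dim(arr)[3L]),
                    function(i) (arr[, , i] - lo) / (hi - lo))
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- c(list(format = "mcism-stack-1", encoding = enc,
                 dim = dim(arr)), metaToList(stack))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' With the JSON sidecar present the original intensity scale and the full
#' acquisition metadata are restored (bit-exactly for 16-bit integer data,
#' to float32 precision otherwise). Without a sidecar the stack loads with
#' values as stored in the file and all metadata unknown (`optics`,
#' `geometry` and `trajectory` are NULL, `pixelNm` is 1).
#'
#' @param path TIFF path.
#' @param sidecar metadata JSON path (default `<path>.json`).
#' @return a [RawStack-class].
#' @export
readStack <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("RGB/multi-channel TIFF is not supported; expected grayscale pages")
  d <- c(dim(pages[[1L]]), length(pages))
  arr <- array(0, d)
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$dim) && !all(unlist(meta$dim) == d))
      stop("stack dimensions ", paste(d, collapse = "x"),
           " do not match sidecar metadata ",
           paste(unlist(meta$dim), collapse = "x"))
    enc <- meta$encoding
    if (identical(enc$mode, "uint16")) {
      arr <- round(arr * 65535)
    } else {
      arr <- arr * (enc$hi - enc$lo) + enc$lo
    }
    m <- metaFromList(meta)
    if (!is.null(m$trajectory) && m$trajectory@nFrames != d[3L])
      stop("frame count ", d[3L], " does not match sidecar trajectory (",
           m$trajectory@nFrames, " frames)")
    new("RawStack", frames = arr, pixelNm = m$pixelNm, optics = m$optics,
        geometry = m$geometry, trajectory = m$trajectory, noise = m$noise)
  } else {
    new("RawStack", frames = arr, pixelNm = 1, optics = NULL,
        geometry = NULL, trajectory = NULL, noise = list())
  }
}

#' Write an image as single-page float TIFF (with scale sidecar)
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  st <- new("RawStack", frames = array(image, c(dim(image), 1L)),
            pixelNm = 1, optics = NULL, geometry = NULL, trajectory = NULL,
            noise = list())
  writeStack(st, path)
}
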