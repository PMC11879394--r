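## Resolution and image-quality metrology: FWHM, bi-Gaussian line-pair fits,
## PSNR, SSIM, Fourier ring correlation.

## least-squares 1D Gaussian + offset; returns list(converged, A, mu, sigma,
## offset, rms)
fitGaussian1D <- function(y, x = seq_along(y)) {
  off0 <- min(y)
  w <- pmax(y - off0, 0)
  if (sum(w) <= 0) return(list(converged = FALSE))
  mu0 <- sum(x * w) / sum(w)
  s0 <- sqrt(max(sum((x - mu0)^2 * w) / sum(w), 0.25))
  p0 <- c(max(y) - off0, mu0, s0, off0)
  resFun <- function(p)
    p[1L] * exp(-(x - p[2L])^2 / (2 * p[3L]^2)) + p[4L] - y
  fit <- try(minpack.lm::nls.lm(p0, fn = resFun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(converged = FALSE))
  p <- fit$par
  list(converged = fit$info %in% 1:4, A = p[1L], mu = p[2L],
       sigma = abs(p[3L]), offset = p[4L], rms = sqrt(mean(fit$fvec^2)))
}

## crude modality check: number of well-separated strong local maxima
countStrongPeaks <- function(y) {
  n <- length(y)
  if (n < 5L) return(1L)
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  lo <- min(ys); hi <- max(ys)
  if (hi <= lo) return(1L)
  thr <- lo + 0.5 * (hi - lo)
  peaks <- which(diff(sign(diff(ys))) == -2) + 1L
  peaks <- peaks[ys[peaks] >= thr]
  if (length(peaks) < 2L) return(length(peaks))
  ## merge peaks not separated by a real valley
  keep <- peaks[1L]
  for (p in peaks[-1L]) {
    valley <- min(ys[keep[length(keep)]:p])
    if (valley < lo + 0.75 * (min(ys[keep[length(keep)]], ys[p]) - lo))
      keep <- c(keep, p)
  }
  length(keep)
}

#' Full width at half maximum of a single peak
#'
#' Fits a Gaussian plus offset to a profile, or to the row and column through
#' the peak of an image (the two estimates are averaged), and returns
#' `2.3548 * sigma`. FWHM is invariant under intensity scaling and
#' translation of the input. Profiles with more than one strong peak are
#' rejected with a pointer to [bigaussianFit()].
#'
#' @param x numeric profile or image matrix.
#' @param pixelNm pixel size; the result is in the same unit (px when 1).
#' @return FWHM in `pixelNm` units.
#' @export
fwhm <- function(x, pixelNm = 1) {
  fwhmFactor <- 2 * sqrt(2 * log(2))
  if (is.matrix(x)) {
    pk <- which(x == max(x), arr.ind = TRUE)[1L, ]
    f1 <- fwhm(x[pk[1L], ], pixelNm)
    f2 <- fwhm(x[, pk[2L]], pixelNm)
    return((f1 + f2) / 2)
  }
  if (countStrongPeaks(x) > 1L)
    stop("profile appears multi-modal; use bigaussianFit()")
  fit <- fitGaussian1D(x)
  if (!isTRUE(fit$converged)) stop("Gaussian fit did not converge")
  fwhmFactor * fit$sigma * pixelNm
}

#' Bi-Gaussian line-pair fit
#'
#' Fits two equal-width Gaussians plus a constant offset to a line-pair
#' profile. The dip contrast is the fitted profile value at the midpoint
#' between the two peaks divided by the mean fitted value at the peaks
#' (offset removed from both). The pair is flagged resolved when the fitted
#' separation is within 20% of `nominalSpacingPx` and the dip contrast is at
#' most 0.75 (a Rayleigh-like saddle criterion).
#'
#' @param profile numeric vector (length >= 8).
#' @param nominalSpacingPx expected peak separation (px).
#' @return a [LinePairFit-class].
#' @export
bigaussianFit <- function(profile, nominalSpacingPx) {
  if (length(profile) < 8L) stop("profile must have at least 8 samples")
  x <- seq_along(profile)
  off0 <- min(profile)
  w <- pmax(profile - off0, 0)
  ctr <- if (sum(w) > 0) sum(x * w) / sum(w) else mean(x)
  p0 <- c(A1 = max(profile) - off0, A2 = max(profile) - off0,
          mu1 = ctr - nominalSpacingPx / 2, mu2 = ctr + nominalSpacingPx / 2,
          sigma = max(nominalSpacingPx / 3, 0.8), offset = off0)
  model <- function(p, xx)
    p[1L] * exp(-(xx - p[3L])^2 / (2 * p[5L]^2)) +
    p[2L] * exp(-(xx - p[4L])^2 / (2 * p[5L]^2)) + p[6L]
  fit <- try(minpack.lm::nls.lm(p0, fn = function(p) model(p, x) - profile,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 400)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) {
    return(new("LinePairFit", positions = c(NA_real_, NA_real_),
               sigma = NA_real_, amplitudes = c(NA_real_, NA_real_),
               offset = NA_real_, dipContrast = NA_real_,
               resolved = FALSE, converged = FALSE))
  }
  p <- unname(fit$par)
  ord <- order(p[3:4])
  mu <- p[3:4][ord]
  A <- p[1:2][ord]
  sigma <- abs(p[5L])
  sep <- diff(mu)
  ## peaks of the fitted profile (maxima near each component centre, which
  ## sit slightly outside the centres for closely spaced pairs)
  peakVals <- vapply(mu, function(m) {
    -stats::optimize(function(u) -model(p, u),
                     interval = c(m - sigma, m + sigma))$objective - p[6L]
  }, numeric(1))
  midVal <- model(p, mean(mu)) - p[6L]
  dip <- if (mean(peakVals) > 0) midVal / mean(peakVals) else 1
  resolved <- isTRUE(abs(sep - nominalSpacingPx) <= 0.2 * nominalSpacingPx &&
                       dip <= 0.75 && all(A > 0))
  new("LinePairFit", positions = mu, sigma = sigma, amplitudes = A,
      offset = p[6L], dipContrast = dip, resolved = resolved,
      converged = TRUE)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(max(reference)^2 / MSE)`. Identical images give `Inf`.
#'
#' @param image,reference equal-shape numeric matrices.
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference) {
  if (!identical(dim(image), dim(reference))) stop("shapes differ")
  if (max(reference) <= 0) stop("reference must be nonzero")
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(reference)^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM with the standard constants (K1 = 0.01, K2 = 0.03) over a
#' Gaussian-weighted sliding window of size 7; both images are first
#' rescaled jointly to the unit interval.
#'
#' @param image,reference equal-shape numeric matrices.
#' @param windowSize odd sliding-window size (default 7).
#' @return SSIM value between -1 and 1.
#' @export
ssim <- function(image, reference, windowSize = 7L) {
  if (!identical(dim(image), dim(reference))) stop("shapes differ")
  lo <- min(image, reference); hi <- max(image, reference)
  if (hi <= lo) return(1)
  a <- (image - lo) / (hi - lo)
  b <- (reference - lo) / (hi - lo)
  r <- (windowSize - 1L) / 2
  g <- gaussProfile1D((-r):r, 0, 1.5)
  k <- outer(g, g); k <- k / sum(k)
  C1 <- 0.01^2; C2 <- 0.03^2
  muA <- convSame(a, k); muB <- convSame(b, k)
  sA <- convSame(a * a, k) - muA^2
  sB <- convSame(b * b, k) - muB^2
  sAB <- convSame(a * b, k) - muA * muB
  m <- ((2 * muA * muB + C1) * (2 * sAB + C2)) /
    ((muA^2 + muB^2 + C1) * (sA + sB + C2))
  ## trim the zero-padded border
  d <- dim(a)
  mean(m[(r + 1):(d[1L] - r), (r + 1):(d[2L] - r)])
}

#' Fourier ring correlation resolution
#'
#' Ring-wise normalized cross-correlation of the spectra of two independent
#' reconstructions (e.g. from odd and even frame subsets), ring width one
#' frequency pixel. The resolution is the inverse of the first frequency at
#' which the curve drops below the threshold (fixed 1/7 by default, or the
#' half-bit curve), linearly interpolated. Without a crossing the Nyquist
#' limit is reported and flagged.
#'
#' @param imageA,imageB equal-shape matrices.
#' @param pixelNm pixel size (nm).
#' @param threshold `"fixed"` (1/7) or `"half-bit"`.
#' @param fixedValue threshold value for `threshold = "fixed"`.
#' @return a [FrcCurve-class].
#' @export
frcResolution <- function(imageA, imageB, pixelNm,
                          threshold = c("fixed", "half-bit"),
                          fixedValue = 1 / 7) {
  if (!identical(dim(imageA), dim(imageB))) stop("shapes differ")
  threshold <- match.arg(threshold)
  d <- dim(imageA)
  FA <- fft(imageA); FB <- fft(imageB)
  fr <- c(0:(d[1L] %/% 2), -((d[1L] - 1L) %/% 2):-1) / d[1L]
  fc <- c(0:(d[2L] %/% 2), -((d[2L] - 1L) %/% 2):-1) / d[2L]
  radPx <- sqrt(outer(fr^2, fc^2, `+`)) * min(d)
  ring <- round(radPx)
  nRing <- min(d) %/% 2
  idx <- ring <= nRing
  num <- tapply(Re(FA * Conj(FB))[idx], ring[idx], sum)
  dA <- tapply(abs(FA[idx])^2, ring[idx], sum)
  dB <- tapply(abs(FB[idx])^2, ring[idx], sum)
  cnt <- tapply(rep(1, sum(idx)), ring[idx], sum)
  rings <- as.integer(names(cnt))
  ord <- order(rings)      # tapply orders level names lexicographically
  rings <- rings[ord]
  num <- as.numeric(num[ord]); dA <- as.numeric(dA[ord])
  dB <- as.numeric(dB[ord]); cnt <- as.numeric(cnt[ord])
  frc <- num / sqrt(dA * dB)
  frc[!is.finite(frc)] <- 0
  frc <- pmax(-1, pmin(1, frc))
  freq <- rings / (min(d) * pixelNm)
  thr <- if (threshold == "fixed") rep(fixedValue, length(rings)) else
    (0.2071 + 1.9102 / sqrt(cnt)) / (1.2071 + 0.9102 / sqrt(cnt))
  below <- which(frc < thr & rings > 0)
  nyquistNm <- 2 * pixelNm
  if (length(below) == 0L) {
    return(new("FrcCurve", freq = freq, frc = frc, threshold = as.numeric(thr),
               resolutionNm = nyquistNm, crossed = FALSE))
  }
  i <- below[1L]
  if (i == 1L) {
    fCross <- freq[1L]
  } else {
    f0 <- freq[i - 1L]; f1 <- freq[i]
    y0 <- frc[i - 1L] - thr[i - 1L]; y1 <- frc[i] - thr[i]
    fCross <- f0 + (f1 - f0) * y0 / (y0 - y1)
  }
  res <- if (fCross > 0) 1 / fCross else nyquistNm
  new("FrcCurve", freq = freq, frc = frc, threshold = as.numeric(thr),
      resolutionNm = unname(res), crossed = TRUE)
}

#' @describeIn LinePairFit-class compact display
#' @param object a `LinePairFit`
#' @export
setMethod("show", "LinePairFit", function(object) {
  if (!object@converged) { cat("LinePairFit: fit did not converge\n"); return(invisible(NULL)) }
  cat("LinePairFit: separation",
      format(diff(object@positions), digits = 4), "px, sigma",
      format(object@sigma, digits = 4), "px, dip contrast",
      format(object@dipContrast, digits = 3), "->",
      if (object@resolved) "resolved" else "not resolved", "\n")
})

#' @describeIn FrcCurve-class compact display
#' @param object a `FrcCurve`
#' @export
setMethod("show", "FrcCurve", function(object) {
  cat("FrcCurve:", length(object@frc), "rings; resolution",
      format(object@resolutionNm, digits = 4), "nm",
      if (!object@crossed) "(no threshold crossing; Nyquist limit)" else "",
      "\n")
})
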