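gauss1 <- function(x, mu, sigma, A = 1) A * exp(-(x - mu)^2 / (2 * sigma^2))

test_that("FWHM recovers 2.3548 sigma, invariant to scale and shift", {
  x <- seq_len(201)
  p <- gauss1(x, 101, 10)
  expect_equal(fwhm(p), 2 * sqrt(2 * log(2)) * 10, tolerance = 1e-6)
  expect_equal(fwhm(5 * p + 2), fwhm(p), tolerance = 1e-6)
  expect_equal(fwhm(gauss1(x, 140.3, 10)), fwhm(p), tolerance = 1e-6)
  expect_equal(fwhm(p, pixelNm = 32.5), 32.5 * fwhm(p), tolerance = 1e-9)
  ## multi-modal profiles are redirected to the line-pair fit
  expect_error(fwhm(gauss1(x, 70, 8) + gauss1(x, 130, 8)), "bigaussianFit")
})

test_that("widefield point-source FWHM matches the diffraction estimate", {
  cfg <- refOptics()
  D <- 96L
  src <- matrix(0, D, D); src[D / 2, D / 2] <- 1
  wf <- forwardModel(src, matrix(1, D, D),
                     psfKernel(gaussianPSF(cfg, "emission"), cfg@pixelNm))
  expect_equal(fwhm(wf, cfg@pixelNm), 0.51 * 680 / 1.49, tolerance = 0.03)
})

test_that("bi-Gaussian fit classifies separated, merged and borderline pairs", {
  x <- seq_len(120)
  sigma <- 5
  ## well separated (8 sigma): resolved with a vanishing dip
  p1 <- gauss1(x, 40, sigma) + gauss1(x, 80, sigma)
  f1 <- bigaussianFit(p1, 40)
  expect_true(f1@resolved)
  expect_lt(f1@dipContrast, 0.01)
  expect_equal(diff(f1@positions), 40, tolerance = 0.01)
  ## single Gaussian: not resolved
  f2 <- bigaussianFit(gauss1(x, 60, sigma), 30)
  expect_false(f2@resolved)
  ## separation equal to the FWHM: dip matches the direct-evaluation oracle
  sep <- 2 * sqrt(2 * log(2)) * sigma
  p3 <- gauss1(x, 60 - sep / 2, sigma) + gauss1(x, 60 + sep / 2, sigma)
  f3 <- bigaussianFit(p3, sep)
  profile <- function(u) gauss1(u, 60 - sep / 2, sigma) +
    gauss1(u, 60 + sep / 2, sigma)
  peakVal <- max(vapply(seq(40, 80, by = 0.01), profile, numeric(1)))
  oracleDip <- profile(60) / peakVal
  expect_equal(f3@dipContrast, oracleDip, tolerance = 0.01)
  expect_error(bigaussianFit(c(1, 2, 1), 1), "8 samples")
})

test_that("resolvability is monotone along a spacing ladder", {
  x <- seq_len(160)
  sigma <- 6
  resolved <- vapply(seq(8, 40, by = 4), function(sep) {
    p <- gauss1(x, 80 - sep / 2, sigma) + gauss1(x, 80 + sep / 2, sigma)
    bigaussianFit(p, sep)@resolved
  }, logical(1))
  ## once resolved, larger spacings stay resolved
  expect_true(all(diff(as.integer(resolved)) >= 0))
  expect_true(any(resolved) && !all(resolved))
})

test_that("PSNR matches its closed form and SSIM degrades with noise", {
  set.seed(21)
  ref <- matrix(runif(64 * 64, 0, 2), 64L, 64L)
  sigma <- 0.1
  noisy <- ref + matrix(rnorm(64 * 64, 0, sigma), 64L, 64L)
  expected <- 10 * log10(max(ref)^2 / sigma^2)
  expect_equal(psnr(noisy, ref), expected, tolerance = 0.1)
  expect_identical(psnr(ref, ref), Inf)
  expect_identical(ssim(ref, ref), 1)
  ssims <- vapply(c(0.05, 0.1, 0.2, 0.4), function(s) {
    ssim(ref + matrix(rnorm(64 * 64, 0, s), 64L, 64L), ref)
  }, numeric(1))
  expect_true(all(diff(ssims) < 0))
  expect_error(psnr(ref, matrix(1, 2L, 2L)), "shapes")
})

test_that("FRC is unity against itself and near zero for independent noise", {
  set.seed(31)
  img <- matrix(runif(96 * 96), 96L, 96L)
  self <- frcResolution(img, img, 30)
  expect_true(all(abs(self@frc - 1) < 1e-9))
  expect_false(self@crossed)
  expect_equal(self@resolutionNm, 2 * 30)
  ## nonnegative independent noise images (offset sets a shared mean)
  n1 <- 10 + matrix(rnorm(96 * 96), 96L, 96L)
  n2 <- 10 + matrix(rnorm(96 * 96), 96L, 96L)
  ind <- frcResolution(n1, n2, 30)
  hi <- ind@frc[ind@freq > 0.5 * max(ind@freq)]
  expect_lt(abs(mean(hi)), 0.05)
  expect_true(all(ind@frc >= -1 & ind@frc <= 1))
  expect_equal(ind@frc[1L], 1, tolerance = 1e-9)  # zero-frequency ring
})

test_that("FRC of a band-limited pair crosses near the band edge", {
  set.seed(41)
  n <- 96L
  ## shared band-limited structure + independent noise
  base <- matrix(rnorm(n * n), n, n)
  Fb <- fft(base)
  fr <- c(0:(n %/% 2), -((n - 1L) %/% 2):-1) / n
  rad <- sqrt(outer(fr^2, fr^2, `+`)) * n
  cut <- n / 6
  Fb[rad > cut] <- 0
  sig <- Re(fft(Fb, inverse = TRUE)) / (n * n)
  sig <- 50 * sig / stats::sd(sig)
  a <- sig + matrix(rnorm(n * n), n, n)
  b <- sig + matrix(rnorm(n * n), n, n)
  frc <- frcResolution(a, b, 30)
  expect_true(frc@crossed)
  bandEdgeNm <- n * 30 / cut
  expect_equal(frc@resolutionNm, bandEdgeNm, tolerance = 0.15)
  ## half-bit variant also runs and crosses in the same region
  hb <- frcResolution(a, b, 30, threshold = "half-bit")
  expect_true(hb@crossed)
  expect_equal(hb@resolutionNm, bandEdgeNm, tolerance = 0.2)
})
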