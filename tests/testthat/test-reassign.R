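test_that("sigma_base estimation recovers the spot-image width within 3%", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  ph <- makePhantom("plate", 96L, cfg@pixelNm)
  st <- simulateStack(ph, pre$geometry, pre$trajectory, cfg)
  spots <- spotGridFromGeometry(pre$geometry, pre$trajectory, cfg@pixelNm,
                                c(96L, 96L))
  pin <- estimateSigmaBase(st, spots)
  ## oracle: render one isolated spot image (pinhole disk conv excitation
  ## PSF conv detection PSF) directly and fit it the same way
  g1 <- pre$geometry; g1@pitchNm <- 1e6
  t1 <- scanTrajectory(1L, 100)
  spot <- simulateStack(ph, g1, t1, cfg)@frames[, , 1L]
  oracleSigma <- mcism:::fitGaussian2D(spot)$sigma
  expect_equal(pin@sigmaBasePx, oracleSigma, tolerance = 0.03)
  ## doubling the optical widths doubles sigma_base (within fit tolerance)
  cfg2 <- opticalConfig(lambdaEx = 2 * cfg@lambdaEx,
                        lambdaEm = 2 * cfg@lambdaEm, pixelNm = cfg@pixelNm)
  g2 <- pre$geometry
  g2@diameterNm <- 2 * g2@diameterNm
  g2@pitchNm <- 2 * g2@pitchNm
  t2 <- scanTrajectory(25L, 2 * pre$trajectory@stepNm)
  st2 <- simulateStack(makePhantom("plate", 192L, cfg@pixelNm), g2, t2, cfg2)
  spots2 <- spotGridFromGeometry(g2, t2, cfg@pixelNm, c(192L, 192L))
  pin2 <- estimateSigmaBase(st2, spots2)
  expect_equal(pin2@sigmaBasePx / pin@sigmaBasePx, 2, tolerance = 0.05)
})

test_that("averaging spots reduces the width-estimate scatter under noise", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  ph <- makePhantom("plate", 96L, cfg@pixelNm)
  clean <- simulateStack(ph, pre$geometry, pre$trajectory, cfg)
  spots <- spotGridFromGeometry(pre$geometry, pre$trajectory, cfg@pixelNm,
                                c(96L, 96L))
  manySpot <- numeric(8)
  oneSpot <- numeric(8)
  oneGrid <- spots
  oneGrid@centers <- c(spots@centers[1L], spots@centers[1L])
  oneGrid@centers[[1L]] <- spots@centers[[1L]][3L, , drop = FALSE]
  for (s in 1:8) {
    noisy <- addNoiseToSNR(clean, 10, "gaussian", seed = s)
    manySpot[s] <- estimateSigmaBase(noisy, spots)@sigmaBasePx
    ## single-spot fit: same machinery restricted to ~10 windows of one site
    one <- lapply(1:25, function(f) spots@centers[[f]][3L, , drop = FALSE])
    g1 <- spots; g1@centers <- one; g1@siteIndex <- g1@siteIndex[1:25]
    oneSpot[s] <- estimateSigmaBase(noisy, g1)@sigmaBasePx
  }
  expect_lt(stats::var(manySpot), stats::var(oneSpot))
})

test_that("sub-image extraction captures the spot energy and flags edges", {
  cfg <- refOptics()
  geom <- pinholeArrayGeometry(cfg)
  traj <- scanTrajectory(1L, 100)
  ph <- makePhantom("plate", 64L, cfg@pixelNm)
  gBig <- geom; gBig@pitchNm <- 1e6
  st <- simulateStack(ph, gBig, traj, cfg)
  spots <- spotGridFromGeometry(gBig, traj, cfg@pixelNm, c(64L, 64L))
  subs <- extractSubimages(st@frames, spots, windowRadiusPx = 24)
  expect_length(subs, 1L)
  expect_false(subs[[1L]]$truncated)
  expect_gt(sum(subs[[1L]]$img) / sum(st@frames[, , 1L]), 0.99)
  ## corner spot is flagged truncated
  corner <- spots
  corner@centers <- list(matrix(c(2, 2), 1L, 2L))
  subsC <- extractSubimages(st@frames, corner, windowRadiusPx = 24)
  expect_true(subsC[[1L]]$truncated)
  ## windows beyond half the pitch are rejected
  spots@latticeVectors <- mcism:::latticeBasisPx(geom, cfg@pixelNm)
  expect_error(extractSubimages(st@frames, spots, windowRadiusPx = 14),
               "half the lattice pitch")
})

test_that("digital pinhole masks follow the Gaussian product rule", {
  n <- 41L
  wr <- 20L
  sigma <- 5
  xx <- (-wr):wr
  g <- exp(-outer(xx^2, xx^2, `+`) / (2 * sigma^2))
  sub <- list(frame = 1L, center = c(50, 50), img = g,
              valid = matrix(TRUE, n, n), truncated = FALSE)
  ## sigmaRel = Inf is the identity
  pinInf <- digitalPinhole(Inf, sigma)
  expect_identical(applyDigitalPinhole(sub, pinInf)$img, g)
  ## sigmaRel = 1 on a Gaussian of sigma_base gives sigma/sqrt(2)
  pin1 <- digitalPinhole(1, sigma)
  masked <- applyDigitalPinhole(sub, pin1)$img
  fit <- mcism:::fitGaussian2D(masked)
  expect_equal(fit$sigma, sigma / sqrt(2), tolerance = 1e-3)
})

test_that("reassignment doubles coordinates and normalizes by weights", {
  ## single synthetic sub-image of a point source
  n <- 21L
  img <- matrix(0, n, n); img[11L, 11L] <- 1
  sub <- list(frame = 1L, center = c(30, 40), img = img,
              valid = matrix(TRUE, n, n), truncated = FALSE)
  pr <- reassignAndAccumulate(list(sub), dimIn = c(100L, 100L), pixelNm = 10)
  pk <- which(pr@canvas == max(pr@canvas), arr.ind = TRUE)[1L, ]
  expect_equal(as.integer(pk), c(60L, 80L))
  expect_equal(pr@pixelNm, 5)
  expect_error(reassignAndAccumulate(list(), c(10L, 10L)), "empty")
})

test_that("pixel reassignment is linear in the input stack", {
  x <- pointSourcePR()
  st <- x$stack
  a <- st; a@frames <- 2.5 * st@frames
  prA <- prReconstruct(a, x$spots, pinhole = NULL, upsample = 2L)
  expect_lt(max(abs(prA@canvas - 2.5 * x$pr@canvas)) / max(prA@canvas),
            1e-9)
})

test_that("a uniform phantom reassigns to a flat canvas", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  ph <- makePhantom("plate", 96L, cfg@pixelNm)
  st <- simulateStack(ph, pre$geometry, pre$trajectory, cfg)
  spots <- spotGridFromGeometry(pre$geometry, pre$trajectory, cfg@pixelNm,
                                c(96L, 96L))
  pr <- prReconstruct(st, spots, pinhole = NULL, upsample = 2L)
  img <- prImage(pr)
  interior <- img[120:264, 120:264]
  expect_lt(max(interior) / min(interior), 1.05)
})

test_that("PR is insensitive to small spot-centre displacement", {
  x <- pointSourcePR()
  shifted <- x$spots
  shifted@centers <- lapply(shifted@centers, function(m) m + 0.7)
  prS <- prReconstruct(x$stack, shifted, pinhole = NULL, upsample = 2L)
  f0 <- fwhm(prImage(x$pr), x$pr@pixelNm)
  f1 <- fwhm(prImage(prS), prS@pixelNm)
  expect_lt(abs(f1 - f0) / f0, 0.01)
})

test_that("mcismReconstruct with zero iterations returns the PR image", {
  x <- pointSourcePR()
  psfPr <- psfKernel(psfModel(x$sigmaDetNm * sqrt(2) / 2,
                              pixelNm = x$pr@pixelNm), x$pr@pixelNm)
  expect_identical(mcismReconstruct(x$pr, psfPr, nIter = 0L),
                   prImage(x$pr))
  expect_error(mcismReconstruct(x$pr, psfPr, nIter = -1L), ">= 0")
})
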