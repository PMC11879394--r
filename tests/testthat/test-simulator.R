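test_that("line-pair phantoms render at the requested sub-pixel spacing", {
  ph <- makePhantom("line_pairs", dim = 64L, pixelNm = 32.5, spacingNm = 140)
  img <- ph@image
  ## two lines, centre-of-mass separation 140/32.5 = 4.31 px
  colMass <- colSums(img)
  expect_equal(sum(colMass > 0), 4L)  # each sub-pixel line covers 2 columns
  half <- seq_len(32L)
  c1 <- sum(half * colMass[half]) / sum(colMass[half])
  c2 <- sum((33:64) * colMass[33:64]) / sum(colMass[33:64])
  expect_equal(c2 - c1, 140 / 32.5, tolerance = 1e-9)
  expect_true(all(img >= 0 & img <= 1))
  expect_error(makePhantom("line_pairs", 64L, 32.5, spacingNm = 20),
               "finer grid")
})

test_that("plate phantoms are constant and beads are seed-deterministic", {
  expect_true(all(makePhantom("plate", 16L, 32.5)@image == 1))
  b1 <- makePhantom("beads", 64L, 32.5, n = 10L, seed = 1L)
  b2 <- makePhantom("beads", 64L, 32.5, n = 10L, seed = 1L)
  expect_identical(b1@image, b2@image)
  b3 <- makePhantom("beads", 64L, 32.5, n = 10L, seed = 2L)
  expect_false(identical(b1@image, b3@image))
})

test_that("the delta-pinhole illumination pattern equals the excitation PSF", {
  cfg <- refOptics()
  geom <- deltaPinholeGeometry(cfg)
  ## single pinhole: huge pitch so only one spot is in the field
  geom@pitchNm <- 1e6
  traj <- scanTrajectory(1L, 100)
  psfEx <- gaussianPSF(cfg, "excitation")
  pat <- illuminationPattern(geom, traj, psfEx, 1L, dim = 33L,
                             pixelNm = cfg@pixelNm)
  kern <- psfKernel(psfEx, cfg@pixelNm, radiusPx = 16L)
  expect_gt(sum(pat * kern) / sqrt(sum(pat^2) * sum(kern^2)), 1 - 1e-6)
})

test_that("illumination patterns shift with the scan trajectory", {
  ## pixel grid chosen so the scan step is an exact number of pixels
  cfg <- refOptics()
  geom <- pinholeArrayGeometry(cfg, framesPerSide = 7L)
  stepPx <- 4L
  pixel <- geom@pitchNm * sqrt(50) / 49 / stepPx
  cfg2 <- opticalConfig(pixelNm = pixel)
  traj <- scanTrajectory(3L, stepPx * pixel)
  psfEx <- gaussianPSF(cfg2, "excitation")
  pats <- illuminationStack(geom, traj, psfEx, dim = 96L, pixelNm = pixel)
  ## compare the field interior (edge columns feel spots that enter or
  ## leave the expanded lattice bounds as the scan advances)
  p1 <- pats[, 30:60, 1L]
  p3 <- pats[, 30:60 + 2L * stepPx, 3L]
  expect_lt(max(abs(p1 - p3)), 1e-6 * max(pats))
})

test_that("spot-array patterns at 1:3 pitch have deep minima between spots", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 49L)
  pat <- illuminationPattern(pre$geometry, pre$trajectory,
                             gaussianPSF(cfg, "excitation"), 1L,
                             dim = 96L, pixelNm = cfg@pixelNm)
  ## direct evaluation oracle over the field interior
  interior <- pat[20:77, 20:77]
  expect_lt(min(interior), 0.02 * max(pat))
  expect_equal(max(pat), 1)
})

test_that("the forward model is linear and zero maps to zero", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 49L)
  traj <- scanTrajectory(3L, pre$trajectory@stepNm)
  zero <- new("Phantom", image = matrix(0, 48, 48), pixelNm = cfg@pixelNm,
              kind = "plate", params = list())
  st0 <- simulateStack(zero, pre$geometry, traj, cfg)
  expect_true(all(st0@frames == 0))
  set.seed(7)
  o1 <- matrix(runif(48 * 48), 48, 48)
  o2 <- matrix(runif(48 * 48), 48, 48)
  mk <- function(img) {
    ph <- new("Phantom", image = img, pixelNm = cfg@pixelNm, kind = "plate",
              params = list())
    simulateStack(ph, pre$geometry, traj, cfg)@frames
  }
  lhs <- mk(2 * o1 + 3 * o2)
  rhs <- 2 * mk(o1) + 3 * mk(o2)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("summed excitation over a full scan is uniform in the interior", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  pats <- illuminationStack(pre$geometry, pre$trajectory,
                            gaussianPSF(cfg, "excitation"),
                            dim = 96L, pixelNm = cfg@pixelNm)
  total <- rowSums(pats, dims = 2L)
  interior <- total[30:67, 30:67]
  expect_lt(max(interior) / min(interior), 1.05)
})

test_that("Gaussian noise hits the requested SNR and is reproducible", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 49L)
  traj <- scanTrajectory(5L, pre$trajectory@stepNm)
  ph <- makePhantom("plate", 48L, cfg@pixelNm)
  st <- simulateStack(ph, pre$geometry, traj, cfg)
  n1 <- addNoiseToSNR(st, 10, "gaussian", seed = 42L)
  expect_equal(n1@noise$achievedSnrDb, 10, tolerance = 0.1)
  n2 <- addNoiseToSNR(st, 10, "gaussian", seed = 42L)
  expect_identical(n1@frames, n2@frames)
  ## definition check: mean-square signal / noise variance on the support
  mask <- st@frames > 0.01 * max(st@frames)
  snr <- 10 * log10(mean(st@frames[mask]^2) /
                      stats::var(as.vector(n1@frames[mask] -
                                             st@frames[mask])))
  expect_equal(snr, 10, tolerance = 0.1)
  ## infinite SNR is the identity
  expect_identical(addNoiseToSNR(st, Inf, "gaussian")@frames, st@frames)
  zero <- st; zero@frames[] <- 0
  expect_error(addNoiseToSNR(zero, 10), "all-zero")
})

test_that("Poisson noise preserves frame means in expectation", {
  cfg <- refOptics()
  traj <- scanTrajectory(2L, 120)
  geom <- pinholeArrayGeometry(cfg)
  ph <- makePhantom("plate", 32L, cfg@pixelNm)
  st <- simulateStack(ph, geom, traj, cfg)
  m0 <- mean(st@frames)
  means <- vapply(1:100, function(s)
    mean(addNoiseToSNR(st, 15, "poisson", seed = s)@frames), numeric(1))
  ## 3-sigma band for the mean of 100 seeds
  se <- stats::sd(means) / 10
  expect_lt(abs(mean(means) - m0), 3 * se + 1e-12)
})

test_that("simulated frames match the forward operator bit-for-bit", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 49L)
  traj <- scanTrajectory(3L, pre$trajectory@stepNm)
  ph <- makePhantom("beads", 64L, cfg@pixelNm, n = 5L, seed = 3L)
  st <- simulateStack(ph, pre$geometry, traj, cfg)
  pats <- illuminationStack(pre$geometry, traj,
                            gaussianPSF(cfg, "excitation"),
                            dim = 64L, pixelNm = cfg@pixelNm)
  kern <- psfKernel(gaussianPSF(cfg, "emission"), cfg@pixelNm)
  for (i in 1:3)
    expect_identical(st@frames[, , i],
                     forwardModel(ph@image, pats[, , i], kern))
})

test_that("negative backgrounds are rejected", {
  cfg <- refOptics()
  geom <- pinholeArrayGeometry(cfg)
  traj <- scanTrajectory(2L, 120)
  ph <- makePhantom("plate", 32L, cfg@pixelNm)
  expect_error(simulateStack(ph, geom, traj, cfg, backgroundLevel = -1),
               "nonnegative")
})
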