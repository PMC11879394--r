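makeToyProblem <- function(lambda = 0) {
  ## tiny 1D-style problem: 8-pixel object (8 x 1), 2 frames
  h <- matrix(c(0.2, 0.55, 0.25), 3L, 1L)
  P <- array(0, c(8L, 1L, 2L))
  P[, , 1L] <- seq(0.4, 1, length.out = 8L)
  P[, , 2L] <- rev(seq(0.3, 1, length.out = 8L))
  O <- matrix(c(0, 1, 0.2, 0, 0, 2, 0.5, 0), 8L, 1L)
  I <- array(0, c(8L, 1L, 2L))
  for (i in 1:2) I[, , i] <- forwardModel(O, P[, , i, drop = TRUE], h)
  list(problem = deconvProblem(I, P, h, lambda = lambda), truth = O, h = h)
}

## independent operator matrix built from the definition (no FFT path)
operatorMatrix <- function(h, P) {
  n <- length(P)
  c0 <- (length(h) + 1L) %/% 2L
  A <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    k <- x - y + c0
    if (k >= 1L && k <= length(h)) A[x, y] <- h[k] * P[y]
  }
  A
}

test_that("the forward model reduces correctly in degenerate limits", {
  delta <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3L, 3L)
  set.seed(3)
  O <- matrix(runif(64), 8L, 8L)
  expect_equal(forwardModel(O, matrix(1, 8L, 8L), delta), O,
               tolerance = 1e-12)
  ## sifting: a delta object reproduces the kernel scaled by P at the site
  P <- matrix(runif(64, 0.5, 1), 8L, 8L)
  Od <- matrix(0, 8L, 8L); Od[4L, 5L] <- 1
  I <- forwardModel(Od, P, delta * 0 + psfKernel(psfModel(50, pixelNm = 30),
                                                 30, radiusPx = 1L))
  k <- psfKernel(psfModel(50, pixelNm = 30), 30, radiusPx = 1L)
  expect_equal(I[3:5, 4:6], P[4L, 5L] * k, tolerance = 1e-12)
  expect_error(forwardModel(O, matrix(1, 4L, 4L), delta), "shapes")
})

test_that("forward and adjoint form an exact adjoint pair", {
  set.seed(11)
  for (kr in c(1L, 3L, 7L)) {
    k <- psfKernel(psfModel(40 * kr, pixelNm = 30), 30, radiusPx = kr)
    x <- matrix(rnorm(35 * 29), 35L, 29L)
    y <- matrix(rnorm(35 * 29), 35L, 29L)
    P <- matrix(runif(35 * 29), 35L, 29L)
    lhs <- sum(forwardModel(x, P, k) * y)
    rhs <- sum(x * adjointModel(y, P, k))
    expect_lt(abs(lhs - rhs) / (abs(lhs) + abs(rhs)), 1e-9)
  }
  ## symmetric kernel: adjoint with uniform pattern equals the forward blur
  k <- psfKernel(psfModel(60, pixelNm = 30), 30)
  x <- matrix(rnorm(30 * 30), 30L, 30L)
  expect_equal(adjointModel(x, matrix(1, 30L, 30L), k),
               forwardModel(x, matrix(1, 30L, 30L), k), tolerance = 1e-12)
})

test_that("Richardson-Lucy sharpens, conserves flux, and fixes deltas", {
  delta <- matrix(0, 3L, 3L); delta[2L, 2L] <- 1
  set.seed(4)
  img <- matrix(runif(400), 20L, 20L)
  expect_equal(rlDeconvolve(img, delta, 10L), img, tolerance = 1e-9)
  ## blurred point source: FWHM strictly decreases every 10 iterations
  k <- psfKernel(psfModel(90, pixelNm = 30), 30)
  src <- matrix(0, 64L, 64L); src[32L, 32L] <- 1
  blur <- convSame <- forwardModel(src, matrix(1, 64L, 64L), k)
  widths <- vapply(c(10L, 20L, 30L, 40L, 50L),
                   function(n) fwhm(rlDeconvolve(blur, k, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  ## flux conservation for interior-supported images
  est <- rlDeconvolve(blur, k, 30L)
  expect_equal(sum(est), sum(blur), tolerance = 1e-6)
  expect_warning(z <- rlDeconvolve(matrix(0, 8L, 8L), k, 5L), "all-zero")
  expect_true(all(z == 0))
})

test_that("joint RL reduces exactly to RL for one uniform frame", {
  set.seed(5)
  k <- psfKernel(psfModel(70, pixelNm = 30), 30)
  src <- matrix(0, 32L, 32L); src[10:22, 16L] <- 1
  img <- forwardModel(src, matrix(1, 32L, 32L), k)
  prob <- deconvProblem(array(img, c(32L, 32L, 1L)),
                        array(1, c(32L, 32L, 1L)), k)
  jr <- jrlDeconvolve(prob, deconvParams(nIter = 25L))$estimate
  ## same multiplicative updates started from the same uniform initial
  rl0 <- matrix(mean(img), 32L, 32L)
  ops <- mcism:::makeConvOps(c(32L, 32L), k)
  flat <- ops$adjoint(matrix(1, 32L, 32L))
  for (i in 1:25)
    rl0 <- rl0 * ops$adjoint(img / (ops$forward(rl0) + 1e-12)) /
      (flat + 1e-12)
  expect_lt(max(abs(jr - rl0)), 1e-9 * max(rl0))
})

test_that("joint RL recovers two-bead separation within a pixel", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  D <- 96L
  img <- matrix(0, D, D)
  img[48L, 38L] <- 1; img[48L, 58L] <- 1   # 20 px = 650 nm apart
  ph <- new("Phantom", image = img, pixelNm = cfg@pixelNm, kind = "beads",
            params = list())
  st <- simulateStack(ph, pre$geometry, pre$trajectory, cfg)
  pats <- illuminationStack(pre$geometry, pre$trajectory,
                            gaussianPSF(cfg, "excitation"), c(D, D),
                            cfg@pixelNm)
  prob <- deconvProblem(st@frames, pats,
                        psfKernel(gaussianPSF(cfg, "emission"), cfg@pixelNm))
  est <- jrlDeconvolve(prob, deconvParams(nIter = 40L))$estimate
  prof <- est[48L, ]
  fit <- bigaussianFit(prof, 20)
  expect_true(fit@resolved)
  expect_lt(abs(diff(fit@positions) - 20), 1)
})

test_that("FISTA-GS with lambda = 0 matches the normal-equation solution", {
  toy <- makeToyProblem(0)
  fit <- fistaGS(toy$problem, deconvParams(nIter = 500L, tol = 0))
  ## independent oracle: per-frame least squares from the explicit operator
  oracle <- matrix(0, 8L, 1L)
  for (i in 1:2) {
    A <- operatorMatrix(as.numeric(toy$h), toy$problem@patterns[, , i])
    oracle <- oracle + solve(crossprod(A),
                             crossprod(A, toy$problem@measured[, , i]))
  }
  expect_lt(max(abs(fit$estimate - oracle)), 1e-6)
})

test_that("FISTA-GS prox and penalty behave as specified", {
  ## exact prox of lambda|sum| per pixel group vs numeric minimization
  set.seed(8)
  for (rep in 1:5) {
    x <- array(rnorm(4 * 3 * 3), c(3L, 3L, 4L))
    lam <- runif(1, 0.1, 2)
    p <- mcism:::proxGroupL1(x, lam)
    for (px in 1:3) for (py in 1:3) {
      v <- x[px, py, ]
      ## the quadratic term is separable and the penalty depends only on
      ## the sum, so the minimizer moves along the all-ones direction;
      ## solve that scalar problem numerically as the oracle
      n <- length(v)
      t0 <- optimize(function(t) 0.5 * n * t^2 + lam * abs(sum(v) + n * t),
                     interval = c(-10, 10), tol = 1e-10)$minimum
      expect_equal(p[px, py, ], v + t0, tolerance = 1e-6)
    }
  }
  ## huge lambda drives the summed estimate to zero
  toy <- makeToyProblem(1e6)
  fit <- fistaGS(toy$problem, deconvParams(nIter = 50L))
  expect_lt(max(abs(fit$estimate)), 1e-6 * max(toy$truth))
})

test_that("the FISTA-GS objective is monotone non-increasing", {
  toy <- makeToyProblem(0.01)
  fit <- fistaGS(toy$problem, deconvParams(nIter = 200L, tol = 0))
  expect_true(all(diff(fit$objective) <= 1e-9 * fit$objective[1L]))
  expect_lte(fit$objective[length(fit$objective)], fit$objective[1L])
})

test_that("reconstruction quality ranks FISTA-GS >= jRL >= PR at 25 dB", {
  cfg <- refOptics()
  pre <- scanPreset(cfg, 25L)
  D <- 96L
  ph <- makePhantom("beads", D, cfg@pixelNm, n = 8L, seed = 2L,
                    beadDiameterNm = 100)
  clean <- simulateStack(ph, pre$geometry, pre$trajectory, cfg)
  st <- addNoiseToSNR(clean, 25, "gaussian", seed = 1L)
  arr <- st@frames; arr[arr < 0] <- 0; st@frames <- arr
  pats <- illuminationStack(pre$geometry, pre$trajectory,
                            gaussianPSF(cfg, "excitation"), c(D, D),
                            cfg@pixelNm)
  kern <- psfKernel(gaussianPSF(cfg, "emission"), cfg@pixelNm)
  prob <- deconvProblem(st@frames, pats, kern,
                        lambda = 0.01 * max(st@frames))
  spots <- spotGridFromGeometry(pre$geometry, pre$trajectory, cfg@pixelNm,
                                c(D, D))
  pr <- prReconstruct(st, spots, pinhole = NULL, upsample = 2L)
  prDown <- mcism:::binImage(prImage(pr), 4L)  # back to the object grid
  jr <- jrlDeconvolve(prob, deconvParams(nIter = 40L))$estimate
  fg <- fistaGS(prob, deconvParams(nIter = 150L))$estimate
  ref <- ph@image
  ## each method's output has an arbitrary intensity scale; match it to the
  ## reference by least squares before scoring
  lsMatch <- function(x) {
    b <- stats::coef(stats::lm(as.vector(ref) ~ as.vector(x)))
    pmax(b[[1L]] + b[[2L]] * x, 0)
  }
  scoreP <- psnr(lsMatch(prDown), ref)
  scoreJ <- psnr(lsMatch(jr), ref)
  scoreF <- psnr(lsMatch(fg), ref)
  expect_gte(scoreF, scoreJ)
  expect_gte(scoreJ, scoreP)
  sP <- ssim(lsMatch(prDown), ref)
  sJ <- ssim(lsMatch(jr), ref)
  sF <- ssim(lsMatch(fg), ref)
  expect_gte(sF, sJ)
  expect_gte(sJ, sP)
})
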