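## Shared fixtures: everything is generated in code at test time.

## reference acquisition: 640/680 nm, 1.49 NA, 32.5 nm object grid
refOptics <- function(pixelNm = 32.5) opticalConfig(pixelNm = pixelNm)

## matched excitation/detection PSFs (both at the emission wavelength)
equalPsfOptics <- function(pixelNm = 32.5)
  opticalConfig(lambdaEx = 680, lambdaEm = 680, pixelNm = pixelNm)

## point-source phantom
pointPhantom <- function(D, pixelNm) {
  img <- matrix(0, D, D)
  img[D / 2, D / 2] <- 1
  new("Phantom", image = img, pixelNm = pixelNm, kind = "beads",
      params = list(point = TRUE))
}

## geometry with point-like pinholes (illumination spots are exactly the
## excitation PSF) for the analytic reassignment anchors
deltaPinholeGeometry <- function(cfg, framesPerSide = 7L) {
  g <- pinholeArrayGeometry(cfg, framesPerSide = framesPerSide)
  g@diameterNm <- 1e-3
  g
}

## cache for expensive shared simulations within one test run
.fixtureCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

## full point-source PR experiment shared by several tests: returns
## widefield FWHM, PR result and config pieces
pointSourcePR <- function() {
  cached("pointSourcePR", {
    cfg <- equalPsfOptics()
    pre <- scanPreset(cfg, 49L)
    geom <- deltaPinholeGeometry(cfg)
    D <- 128L
    ph <- pointPhantom(D, cfg@pixelNm)
    st <- simulateStack(ph, geom, pre$trajectory, cfg)
    psfDet <- gaussianPSF(cfg, "emission")
    wf <- forwardModel(ph@image, matrix(1, D, D),
                       psfKernel(psfDet, cfg@pixelNm))
    spots <- spotGridFromGeometry(geom, pre$trajectory, cfg@pixelNm, c(D, D))
    pr <- prReconstruct(st, spots, pinhole = NULL, upsample = 2L)
    list(cfg = cfg, geom = geom, traj = pre$trajectory, D = D,
         stack = st, spots = spots, wf = wf,
         fwhmWf = fwhm(wf, cfg@pixelNm), pr = pr,
         fwhmPr = fwhm(prImage(pr), pr@pixelNm),
         sigmaDetNm = psfDet@sigmaLateralNm)
  })
}

## line-pair MC-ISM reconstruction (PR [+ pinhole] + RL) and bi-Gaussian fit
linePairMcism <- function(stack, spots, cfg, spacingNm, usePinhole,
                          nIterRL = 40L) {
  pin <- estimateSigmaBase(stack, spots)
  pr <- prReconstruct(stack, spots,
                      pinhole = if (usePinhole) pin else NULL,
                      upsample = 2L)
  dec <- mcismReconstruct(pr, prPSF(pin, pr, cfg@pixelNm), nIter = nIterRL)
  H <- nrow(dec)
  prof <- colMeans(dec[(H / 4):(3 * H / 4), ])
  ctr <- round(length(prof) / 2)
  half <- min(40L, ctr - 1L)
  bigaussianFit(prof[(ctr - half):(ctr + half)], spacingNm / pr@pixelNm)
}

## dense direct (spatial-domain) 'same' convolution oracle, O(n^2 k^2)
naiveConvSame <- function(x, k) {
  kd <- dim(k)
  cr <- (kd[1] + 1) %/% 2
  cc <- (kd[2] + 1) %/% 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (a in seq_len(kd[1])) for (b in seq_len(kd[2])) {
      ii <- i - (a - cr); jj <- j - (b - cc)
      if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x))
        acc <- acc + k[a, b] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}
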