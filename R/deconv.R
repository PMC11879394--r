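#' Construct a multi-image deconvolution problem
#'
#' @param measured H x W x n array of measured frames (nonnegative).
#' @param patterns H x W x n array of illumination patterns.
#' @param psf odd-sized convolution kernel (unit sum recommended).
#' @param lambda group-sparsity weight (>= 0).
#' @return a [DeconvProblem-class].
#' @export
deconvProblem <- function(measured, patterns, psf, lambda = 0) {
  ## forgive floating-point undershoot from FFT convolution
  clampTiny <- function(a) {
    tol <- 1e-9 * max(abs(a), 1e-300)
    if (min(a) < -tol)
      stop("input contains genuinely negative values; clamp or offset first")
    a[a < 0] <- 0
    a
  }
  new("DeconvProblem", measured = clampTiny(measured),
      patterns = clampTiny(patterns), psf = psf, lambda = lambda)
}

#' Iteration controls
#'
#' @param nIter maximum iterations.
#' @param tol relative objective-change stopping tolerance (0 disables).
#' @param step gradient step; NA = 1/L via power iteration.
#' @param seed seed for randomized initialization.
#' @param epsilon division guard.
#' @return a [DeconvParams-class].
#' @export
deconvParams <- function(nIter = 100L, tol = 1e-6, step = NA_real_,
                         seed = 1L, epsilon = 1e-12) {
  new("DeconvParams", nIter = as.integer(nIter), tol = tol, step = step,
      seed = as.integer(seed), epsilon = epsilon)
}

#' Forward image-formation operator
#'
#' One frame of the MC-ISM forward model: the object is modulated by the
#' frame's illumination pattern, then convolved with the PSF,
#' `I = h * (P . O)`. Convolution is linear with zero padding ('same'
#' output); the identical operator is used by the simulator, so simulated
#' noise-free frames and `forwardModel` agree bit-for-bit on shared inputs.
#'
#' @param object object-grid image O.
#' @param pattern illumination pattern P (same size), use 1 for widefield.
#' @param psf odd-sized kernel h.
#' @return image of the same size as `object`.
#' @export
forwardModel <- function(object, pattern, psf) {
  if (is.matrix(pattern) && !identical(dim(object), dim(pattern)))
    stop("object and pattern shapes differ")
  convSame(object * pattern, psf)
}

#' Adjoint of the forward operator
#'
#' `adjointModel(y, P, h) = P . (h~ * y)` with `h~` the 180-degree rotated
#' kernel, implemented as the exact algebraic transpose of [forwardModel()]
#' (zero-padded correlation), so `<forward(O), y> == <O, adjoint(y)>` to
#' floating-point precision.
#'
#' @param y image-grid data.
#' @param pattern illumination pattern.
#' @param psf odd-sized kernel.
#' @return object-grid image.
#' @export
adjointModel <- function(y, pattern, psf) {
  if (is.matrix(pattern) && !identical(dim(y), dim(pattern)))
    stop("data and pattern shapes differ")
  pattern * makeConvOps(dim(y), psf)$adjoint(y)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative RL updates with an epsilon-guarded division and a
#' flat-field denominator that compensates the zero-padded boundary, so total
#' intensity is conserved for objects supported away from the field edge.
#' Nonnegativity is preserved by construction.
#'
#' @param image nonnegative input image.
#' @param psf odd-sized nonnegative kernel (unit sum).
#' @param nIter number of iterations (>= 1); 0 returns the input.
#' @param epsilon division guard.
#' @return deconvolved image.
#' @export
rlDeconvolve <- function(image, psf, nIter = 100L, epsilon = 1e-12) {
  if (nIter < 0) stop("nIter must be >= 0")
  if (nIter == 0L) return(image)
  if (all(image == 0)) {
    warning("all-zero image; returning unchanged")
    return(image)
  }
  if (min(image) < -1e-9 * max(abs(image)))
    stop("RL requires a nonnegative image")
  image[image < 0] <- 0
  ops <- makeConvOps(dim(image), psf)
  flat <- ops$adjoint(matrix(1, nrow(image), ncol(image)))
  est <- image
  for (k in seq_len(nIter)) {
    blur <- ops$forward(est)
    est <- est * ops$adjoint(image / (blur + epsilon)) / (flat + epsilon)
  }
  est
}

#' Joint Richardson-Lucy multi-image deconvolution
#'
#' A single object estimate shared by all frames is updated multiplicatively
#' with the sum of per-frame RL correction terms:
#' `O <- O * [sum_i adj_i(I_i / (fwd_i(O) + eps))] / [sum_i adj_i(1)]`.
#' With one frame and a uniform pattern this reduces exactly to
#' [rlDeconvolve()].
#'
#' @param problem a [DeconvProblem-class] (lambda is ignored by jRL).
#' @param params a [DeconvParams-class]; default 50 iterations.
#' @return list with `estimate` (object-grid image) and `iterations`.
#' @export
jrlDeconvolve <- function(problem, params = deconvParams(nIter = 50L)) {
  stopifnot(is(problem, "DeconvProblem"))
  validObject(problem)
  n <- dim(problem@measured)[3L]
  d <- dim(problem@measured)[1:2]
  eps <- params@epsilon
  ops <- makeConvOps(d, problem@psf)
  if (max(problem@patterns) <= 0)
    stop("illumination patterns are zero everywhere")
  denom <- matrix(0, d[1L], d[2L])
  for (i in seq_len(n))
    denom <- denom + problem@patterns[, , i] *
      ops$adjoint(matrix(1, d[1L], d[2L]))
  if (all(denom == 0)) stop("zero denominator field")
  est <- matrix(mean(problem@measured), d[1L], d[2L])
  for (k in seq_len(params@nIter)) {
    num <- matrix(0, d[1L], d[2L])
    for (i in seq_len(n)) {
      fwd <- ops$forward(problem@patterns[, , i] * est)
      num <- num + problem@patterns[, , i] *
        ops$adjoint(problem@measured[, , i] / (fwd + eps))
    }
    est <- est * num / (denom + eps)
  }
  list(estimate = est, iterations = params@nIter)
}

#' Exact unconstrained prox of the group penalty
#'
#' Proximal operator of `lambda * |sum_i x_i|` per pixel group (no sign
#' constraint): the zero-sum component of each group is untouched and the
#' group sum is soft-thresholded, i.e. only the mean moves.
#'
#' @param x H x W x n array of stacked per-frame components.
#' @param lambda penalty weight (already scaled by the gradient step).
#' @return array of the same shape.
#' @export
proxGroupL1 <- function(x, lambda) {
  n <- dim(x)[3L]
  s <- rowSums(x, dims = 2L)
  soft <- sign(s) * pmax(abs(s) - n * lambda, 0)
  shift <- (soft - s) / n
  x + array(shift, dim(x))
}

#' FISTA with group sparsity (FISTA-GS)
#'
#' Accelerated proximal-gradient minimization of
#' `0.5 * sum_i ||h * (P_i . O_i) - I_i||_2^2 + lambda * ||sum_i O_i||_1`
#' subject to `O_i >= 0`, over per-frame object components `O_i`: the
#' frame-reduction reconstruction objective. The fidelity gradient is
#' applied per frame through the exact forward/adjoint pair. On the
#' nonnegative orthant the group penalty `lambda |sum_i O_i|` is linear, so
#' the proximal step (penalty plus nonnegativity) is an exact elementwise
#' shift-and-clip; [proxGroupL1()] provides the unconstrained group prox for
#' reference. The step defaults to `1/L` with `L` a guaranteed OTF-based
#' bound on the blockwise operator norm; the Nesterov momentum sequence is
#' restarted with a plain proximal-gradient step whenever it would increase
#' the objective, which makes the recorded objective non-increasing. The
#' returned estimate is `O = sum_i O_i`.
#'
#' @param problem a [DeconvProblem-class].
#' @param params a [DeconvParams-class]; default 100 iterations.
#' @return list with `estimate` (the summed object), `components`
#'   (H x W x n array of `O_i`), `objective` (per-iteration values),
#'   `step`, and `restarts`.
#' @export
fistaGS <- function(problem, params = deconvParams(nIter = 100L)) {
  stopifnot(is(problem, "DeconvProblem"))
  validObject(problem)
  d <- dim(problem@measured)[1:2]
  n <- dim(problem@measured)[3L]
  lambda <- problem@lambda
  ops <- makeConvOps(d, problem@psf)
  fwd <- function(x, i) ops$forward(problem@patterns[, , i] * x)
  adj <- function(y, i) problem@patterns[, , i] * ops$adjoint(y)

  step <- params@step
  if (is.na(step)) {
    ## guaranteed Lipschitz bound for the blockwise fidelity gradient:
    ## ||A_i|| <= ||conv|| * max(P_i) and the padded-circulant norm of the
    ## convolution is the largest OTF magnitude
    kd <- dim(problem@psf)
    P1 <- goodFFTSize(d[1L] + kd[1L] - 1L)
    P2 <- goodFFTSize(d[2L] + kd[2L] - 1L)
    kp <- matrix(0, P1, P2)
    kp[seq_len(kd[1L]), seq_len(kd[2L])] <- problem@psf
    convNorm <- max(Mod(fft(kp)))
    pMax <- max(apply(problem@patterns, 3L, max))
    L <- (convNorm * pMax)^2
    if (L <= 0) stop("degenerate operator: Lipschitz bound is zero")
    step <- 1 / (1.05 * L)
  }

  objective <- function(x) {
    fid <- 0
    for (i in seq_len(n))
      fid <- fid + 0.5 * sum((fwd(x[, , i], i) - problem@measured[, , i])^2)
    fid + lambda * sum(abs(rowSums(x, dims = 2L)))
  }
  gradient <- function(x) {
    g <- array(0, c(d, n))
    for (i in seq_len(n))
      g[, , i] <- adj(fwd(x[, , i], i) - problem@measured[, , i], i)
    g
  }
  ## on the nonnegative orthant |sum_i O_i| = sum_i O_i, so the exact prox
  ## of the penalty plus the nonnegativity indicator is an elementwise
  ## shift-and-clip; using the exact prox keeps the proximal-gradient step
  ## monotone for step <= 1/L
  proxStep <- function(z) {
    y <- z - step * gradient(z) - step * lambda
    y[y < 0] <- 0
    y
  }

  x <- array(0, c(d, n))
  z <- x
  t <- 1
  obj <- numeric(params@nIter)
  fPrev <- objective(x)
  restarts <- 0L
  badStreak <- 0L
  for (k in seq_len(params@nIter)) {
    y <- proxStep(z)
    fy <- objective(y)
    if (fy > fPrev) {
      ## momentum overshoot: restart from the last iterate (plain proximal
      ## gradient step, monotone by the majorization property for step<=1/L)
      restarts <- restarts + 1L
      t <- 1
      y <- proxStep(x)
      fy <- objective(y)
      if (fy > fPrev * (1 + 1e-12)) {
        badStreak <- badStreak + 1L
        if (badStreak >= 10L)
          stop("objective increased for 10 consecutive iterations; ",
               "use a smaller step")
      } else badStreak <- 0L
    } else badStreak <- 0L
    tNext <- (1 + sqrt(1 + 4 * t^2)) / 2
    z <- y + ((t - 1) / tNext) * (y - x)
    x <- y
    t <- tNext
    obj[k] <- min(fy, fPrev)
    if (params@tol > 0 && k > 1L &&
        abs(obj[k] - obj[k - 1L]) <= params@tol * max(abs(obj[k - 1L]),
                                                      .Machine$double.eps)) {
      obj <- obj[seq_len(k)]
      fPrev <- obj[k]
      break
    }
    fPrev <- obj[k]
  }
  list(estimate = rowSums(x, dims = 2L), components = x,
       objective = obj, step = step, restarts = restarts)
}
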