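## Internal FFT convolution machinery.
##
## All image-formation operators in the package share a single zero-padded
## linear convolution with 'same'-size output, so the simulator, the forward
## model of the deconvolution engines and their adjoints are bit-identical on
## shared inputs and form an exact adjoint pair.

## next FFT-friendly size (2^a * 3^b * 5^c)
goodFFTSize <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

## Build forward/adjoint linear 'same' convolution closures for images of
## size dimIn (c(H, W)) and an odd-sized kernel. forward(x) = k * x with zero
## padding; adjoint(y) is its exact transpose (zero-padded correlation).
makeConvOps <- function(dimIn, kernel) {
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) stop("kernel must have odd dimensions")
  H <- dimIn[1L]; W <- dimIn[2L]
  P1 <- goodFFTSize(H + kd[1L] - 1L)
  P2 <- goodFFTSize(W + kd[2L] - 1L)
  kp <- matrix(0, P1, P2)
  kp[seq_len(kd[1L]), seq_len(kd[2L])] <- kernel
  Kf <- fft(kp)
  c1 <- (kd[1L] + 1L) %/% 2L  # kernel centre (1-based)
  c2 <- (kd[2L] + 1L) %/% 2L
  rows <- c1:(c1 + H - 1L)
  cols <- c2:(c2 + W - 1L)
  np <- P1 * P2
  forward <- function(x) {
    xp <- matrix(0, P1, P2)
    xp[seq_len(H), seq_len(W)] <- x
    full <- Re(fft(fft(xp) * Kf, inverse = TRUE)) / np
    full[rows, cols]
  }
  adjoint <- function(y) {
    yp <- matrix(0, P1, P2)
    yp[rows, cols] <- y
    full <- Re(fft(fft(yp) * Conj(Kf), inverse = TRUE)) / np
    full[seq_len(H), seq_len(W)]
  }
  list(forward = forward, adjoint = adjoint)
}

## One-off zero-padded 'same' convolution.
convSame <- function(x, kernel) makeConvOps(dim(x), kernel)$forward(x)

## Band-limited upsampling of one image by an integer factor using
## frequency-domain zero padding. The Nyquist coefficient of even-sized
## inputs is split symmetrically so that real inputs stay real and any
## sinusoid strictly below Nyquist is interpolated exactly; DC (the mean) is
## preserved.
upsampleImage <- function(x, factor) {
  if (factor == 1L) return(x)
  d <- dim(x)
  X <- fft(x)
  pad1 <- padSpectrum1(d[1L], factor)
  pad2 <- padSpectrum1(d[2L], factor)
  Xp <- matrix(0 + 0i, d[1L] * factor, d[2L] * factor)
  Xp[pad1$to, pad2$to] <- X[pad1$from, pad2$from] *
    outer(pad1$w, pad2$w)
  Re(fft(Xp, inverse = TRUE)) * factor^2 / length(Xp)
}

## index/weight map for zero-padding one FFT axis of length n by `factor`
padSpectrum1 <- function(n, factor) {
  N <- n * factor
  if (n %% 2L == 0L) {
    h <- n %/% 2L
    from <- c(1:(h + 1L), (h + 1L), (h + 2L):n)
    to <- c(1:(h + 1L), N - h + 1L, (N - h + 2L):N)
    w <- c(rep(1, h), 0.5, 0.5, rep(1, h - 1L))
    if (n == 2L) { # degenerate: only DC + Nyquist
      from <- c(1L, 2L, 2L); to <- c(1L, 2L, N); w <- c(1, 0.5, 0.5)
    }
  } else {
    h <- (n - 1L) %/% 2L
    from <- c(1:(h + 1L), (h + 2L):n)
    to <- c(1:(h + 1L), (N - h + 1L):N)
    w <- rep(1, n)
  }
  list(from = from, to = to, w = w)
}

## block-average downsampling (camera binning)
binImage <- function(x, factor) {
  if (factor == 1L) return(x)
  d <- dim(x)
  if (any(d %% factor != 0L)) stop("image size not divisible by bin factor")
  H <- d[1L] %/% factor; W <- d[2L] %/% factor
  xr <- array(x, c(factor, H, factor, W))
  out <- apply(xr, c(2L, 4L), mean)
  matrix(out, H, W)
}
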