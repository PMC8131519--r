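# Internal numerical helpers shared across modules.

## wrap an angle (or angle difference) to (-pi, pi]
wrapToPi <- function(x) {
  y <- atan2(sin(x), cos(x))
  # atan2 returns -pi for inputs equivalent to pi; fold onto +pi
  y[y == -pi] <- pi
  y
}

## C1 smoothstep: 0 for u <= 0, 1 for u >= 1
sstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

## orthonormal DCT-II matrix (n x n); t(D) is the inverse transform
dctMatrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

## normalized 1-D Gaussian kernel sampled at integer offsets
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

## dense 1-D smoothing operator with whole-sample mirror boundary
smoothOperator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  w <- gaussKernel1d(sigma)
  r <- (length(w) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (j in (-r):r) {
    idx <- seq_len(n) + j
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] + w[j + r + 1L]
  }
  S
}

## tolerant floor for counts that are exact in intent but fuzzy in floating point
floorTol <- function(x, tol = 1e-9) floor(x + tol)

## number of images implied by a scan duration and TR
imageCount <- function(scanDuration, tr) as.integer(floorTol(scanDuration / tr))

## Daubechies-4 (db2) analysis filters, orthonormal
db2Filters <- function() {
  s3 <- sqrt(3)
  lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  hi <- rev(lo) * c(1, -1, 1, -1)
  list(lo = lo, hi = hi)
}

## periodic 1-D filter + dyadic downsample along columns of a matrix
.filterDown <- function(x, h) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(h)) {
    sh <- (seq_len(n) + k - 2L) %% n + 1L
    out <- out + h[k] * x[sh, , drop = FALSE]
  }
  out[seq(1L, n, by = 2L), , drop = FALSE]
}

## finest-level diagonal (HH) subband of a single-level 2-D wavelet transform.
## x must have even dimensions (trimmed by one row/col otherwise).
waveletDiagonal <- function(x, wavelet = c("d4", "haar")) {
  wavelet <- match.arg(wavelet)
  ny <- nrow(x) - nrow(x) %% 2L
  nx <- ncol(x) - ncol(x) %% 2L
  x <- x[seq_len(ny), seq_len(nx), drop = FALSE]
  hi <- if (wavelet == "haar") c(1, -1) / sqrt(2) else db2Filters()$hi
  t(.filterDown(t(.filterDown(x, hi)), hi))
}
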