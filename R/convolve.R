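# 2-D convolution with reflective boundary handling, plus the spatial
# weight kernels used by every receptive-field stage.
#
# All model kernels are symmetric, non-negative and renormalized to unit
# sum over their discrete support, which makes every convolution a
# weighted spatial mean: uniform fields are fixed points and total image
# flux is conserved exactly under the reflective boundary.

#' Reflect an index into the valid range
#'
#' Symmetric (edge-repeating) reflection: for a 1-based axis of length
#' `n`, index 0 maps to 1, index -1 to 2, index n+1 to n, and so on.
#' Applied repeatedly for offsets larger than the axis.
#'
#' @param i Integer vector of (possibly out-of-range) 1-based indices.
#' @param n Axis length.
#' @return Integer vector of in-range indices.
#' @keywords internal
reflect_index <- function(i, n) {
  # period of the reflected sequence is 2n
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Pad a matrix by reflection
#'
#' @param x Numeric matrix.
#' @param ri,ci Number of rows/columns added on each side.
#' @return Padded matrix of size (H + 2 ri) x (W + 2 ci).
#' @keywords internal
reflect_pad <- function(x, ri, ci) {
  h <- nrow(x); w <- ncol(x)
  x[reflect_index(seq.int(1L - ri, h + ri), h),
    reflect_index(seq.int(1L - ci, w + ci), w), drop = FALSE]
}

#' Convolve an image plane with a kernel under reflective padding
#'
#' FFT-based convolution equivalent to padding `x` by the kernel radius
#' with symmetric reflection and taking the valid part. Kernels must
#' have odd dimensions (the center tap is the anchor).
#'
#' @param x Numeric H x W matrix.
#' @param k Odd-dimensioned kernel matrix, or a prepared operator from
#'   [conv_operator()] (reused across calls on same-sized images).
#' @return Matrix of the same size as `x`.
#' @export
convolve2d <- function(x, k) {
  op <- if (inherits(k, "conv_operator")) k else conv_operator(k, dim(x))
  if (!identical(op$imdim, dim(x)))
    stop("operator was prepared for a different image size")
  ri <- op$ri; ci <- op$ci
  xp <- matrix(0, op$P, op$Q)
  xp[seq_len(nrow(x) + 2L * ri), seq_len(ncol(x) + 2L * ci)] <-
    reflect_pad(x, ri, ci)
  full <- Re(stats::fft(stats::fft(xp) * op$kf, inverse = TRUE)) / (op$P * op$Q)
  full[ri + seq_len(nrow(x)), ci + seq_len(ncol(x)), drop = FALSE]
}

#' Prepare a reusable convolution operator
#'
#' Precomputes the kernel FFT on the padded grid for a fixed image size,
#' so iterative solvers can apply the same kernel many times cheaply.
#'
#' @param k Odd-dimensioned kernel matrix.
#' @param imdim `c(H, W)` of the images the operator will be applied to.
#' @return An object of class `conv_operator`.
#' @export
conv_operator <- function(k, imdim) {
  if (!all(dim(k) %% 2L == 1L)) stop("kernel dimensions must be odd")
  h <- imdim[1]; w <- imdim[2]
  ri <- (nrow(k) - 1L) %/% 2L
  ci <- (ncol(k) - 1L) %/% 2L
  if (ri > 4L * h || ci > 4L * w)
    stop("kernel support exceeds image size")
  # composite FFT sizes; padded interior rows never wrap into the zero fill
  P <- stats::nextn(h + 2L * ri, c(2, 3, 5))
  Q <- stats::nextn(w + 2L * ci, c(2, 3, 5))
  kf <- matrix(0, P, Q)
  kf[reflect_wrap(-ri:ri, P), reflect_wrap(-ci:ci, Q)] <- k
  structure(
    list(kf = stats::fft(kf), P = P, Q = Q, ri = ri, ci = ci,
         imdim = as.integer(imdim), center = k[ri + 1L, ci + 1L]),
    class = "conv_operator"
  )
}

# circular placement of kernel offsets on the FFT grid
reflect_wrap <- function(d, n) (d %% n) + 1L

# Convolve two planes at once by packing them into one complex FFT.
# Valid for symmetric kernels, whose transfer function is real: then
# conv(x + iy) = conv(x) + i conv(y) separates exactly.
convolve2d_pair <- function(x, y, op) {
  ri <- op$ri; ci <- op$ci
  h <- nrow(x); w <- ncol(x)
  zp <- matrix(0+0i, op$P, op$Q)
  zp[seq_len(h + 2L * ri), seq_len(w + 2L * ci)] <-
    reflect_pad(x, ri, ci) + 1i * reflect_pad(y, ri, ci)
  full <- stats::fft(stats::fft(zp) * Re(op$kf), inverse = TRUE) /
    (op$P * op$Q)
  crop <- full[ri + seq_len(h), ci + seq_len(w), drop = FALSE]
  list(x = Re(crop), y = Im(crop))
}

#' Isotropic Gaussian receptive-field kernel
#'
#' Discrete kernel with weights proportional to exp(-(x^2 + y^2) / rho^2),
#' truncated at `truncation * rho` and renormalized to unit sum (the
#' total weight of each receptive-field subregion is 1). `rho` is the
#' decay constant ("radius") of the subregion in pixels; as `rho -> 0`
#' the kernel tends to the unit impulse.
#'
#' @param rho Decay constant in pixels (> 0 yields a Gaussian; <= 0 or
#'   very small yields the unit impulse).
#' @param truncation Support radius as a multiple of `rho` (default 3,
#'   capturing > 98 percent of the continuous mass).
#' @return Odd-sized square matrix summing to 1.
#' @export
gaussian_kernel <- function(rho, truncation = 3) {
  r <- if (rho > 0) as.integer(ceiling(truncation * rho)) else 0L
  if (r < 1L) return(matrix(1, 1, 1))
  d <- seq.int(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / rho^2)
  g[outer(d^2, d^2, "+") > (truncation * rho)^2] <- 0
  if (sum(g) - g[r + 1L, r + 1L] == 0) return(matrix(1, 1, 1))  # impulse limit
  g / sum(g)
}

#' Gaussian point-spread kernel parameterized by its standard deviation
#'
#' @param sigma Standard deviation in pixels; 0 gives the unit impulse.
#' @param truncation Support radius in multiples of `sigma`.
#' @return Odd-sized square matrix summing to 1.
#' @keywords internal
gaussian_psf <- function(sigma, truncation = 4) {
  r <- if (sigma > 0) as.integer(ceiling(truncation * sigma)) else 0L
  if (r < 1L) return(matrix(1, 1, 1))
  d <- seq.int(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Annular kernel for the remote adaptation field
#'
#' Decaying-exponential weights over an annulus surrounding the entire
#' receptive field: support where `inner <= r <= outer`, weights
#' proportional to exp(-(x^2 + y^2) / rho^2), renormalized to unit sum
#' so the remote signal is a weighted spatial mean that excludes the
#' central RF region (the center tap weight is zero).
#'
#' @param inner Inner radius in pixels (pixels strictly closer are
#'   excluded).
#' @param outer Outer radius in pixels.
#' @param rho Decay constant of the weights in pixels.
#' @return Odd-sized square matrix summing to 1 with a zero center.
#' @export
annulus_kernel <- function(inner, outer, rho) {
  stopifnot(outer > inner, inner >= 1, rho > 0)
  r <- as.integer(floor(outer))   # no tap beyond radius `outer` survives
  d <- seq.int(-r, r)
  r2 <- outer(d^2, d^2, "+")
  g <- exp(-r2 / rho^2)
  g[r2 < inner^2 | r2 > outer^2] <- 0
  if (sum(g) <= 0) stop("annulus has empty support")
  g / sum(g)
}

#' Second moment of a kernel
#'
#' Mean squared radial distance under the kernel's weights; used to
#' compare effective blur extents.
#'
#' @param k Kernel matrix (unit sum assumed).
#' @return Scalar second moment in pixels squared.
#' @export
kernel_second_moment <- function(k) {
  ri <- (nrow(k) - 1) / 2
  ci <- (ncol(k) - 1) / 2
  r2 <- outer(seq(-ri, ri)^2, seq(-ci, ci)^2, "+")
  sum(k * r2)
}
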