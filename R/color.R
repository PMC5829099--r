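# Colorimetric conversions between display RGB and cone excitations.
#
# The cone transform is the Hunt-Pointer-Estevez LMS matrix applied to
# linear sRGB (via the IEC 61966-2-1 RGB->XYZ D65 matrix), with each row
# rescaled so that an equal-RGB (achromatic) pixel maps to L = M = S.
# That normalization is what the opponent model requires: a neutral
# surface must silence every chromatically opponent channel exactly.

# sRGB (linear, D65) -> CIE XYZ
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# CIE XYZ -> LMS (Hunt-Pointer-Estevez)
.xyz2lms <- matrix(c(
   0.38971, 0.68898, -0.07868,
  -0.22981, 1.18340,  0.04641,
   0.00000, 0.00000,  1.00000
), nrow = 3, byrow = TRUE)

.rgb2lms_raw <- .xyz2lms %*% .rgb2xyz
# Row-normalize so that RGB (1,1,1) -> LMS (1,1,1) exactly.
.rgb2lms <- .rgb2lms_raw / rowSums(.rgb2lms_raw)
.lms2rgb <- solve(.rgb2lms)

#' Cone transform matrices
#'
#' Returns the 3x3 matrix mapping linear sRGB to LMS cone excitations
#' (Hunt-Pointer-Estevez fundamentals, row-normalized so equal-RGB input
#' yields equal cone excitations), or its inverse.
#'
#' @param inverse If `TRUE`, return the LMS -> linear-RGB matrix.
#' @return A 3x3 numeric matrix.
#' @export
cone_matrix <- function(inverse = FALSE) {
  if (inverse) .lms2rgb else .rgb2lms
}

#' sRGB electro-optical transfer functions
#'
#' `srgb_decode()` maps gamma-encoded sRGB values to linear light;
#' `srgb_encode()` is its inverse. Both operate elementwise on any
#' numeric array and clip nothing.
#'
#' @param x Numeric vector/matrix/array of values in \[0, 1\].
#' @return Object of the same shape as `x`.
#' @export
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' Convert a linear RGB image to cone excitation planes
#'
#' Applies the fixed, invertible 3x3 cone transform (see [cone_matrix()])
#' per pixel. The input must already be linear light; gamma-encoded
#' images are rejected so the transform is never applied on the wrong
#' scale.
#'
#' @param img An [rgb_image] with `gamma = "linear"`.
#' @return A [cone_image] with planes `L`, `M`, `S`.
#' @export
rgb_to_cones <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  if (!identical(img$gamma, "linear")) {
    stop("rgb_to_cones() requires linear-light input; ",
         "linearize with srgb_decode() first")
  }
  m <- .rgb2lms
  # rows sum to 1, so each plane is written as a deviation from R;
  # an equal-RGB pixel then yields L = M = S bit-exactly
  cone_image(
    L = img$R + m[1, 2] * (img$G - img$R) + m[1, 3] * (img$B - img$R),
    M = img$R + m[2, 2] * (img$G - img$R) + m[2, 3] * (img$B - img$R),
    S = img$R + m[3, 2] * (img$G - img$R) + m[3, 3] * (img$B - img$R)
  )
}

#' Render cone excitation planes as a linear RGB image
#'
#' Inverse of [rgb_to_cones()]. Out-of-gamut values are clipped to
#' \[0, 1\] when `clip = TRUE` (the contract for rendering); with
#' `clip = FALSE` the exact linear inverse is returned, so
#' `cones_to_rgb(rgb_to_cones(x), clip = FALSE)` round-trips within
#' numerical precision for any in-gamut image.
#'
#' @param cones A [cone_image].
#' @param clip Clip the result to \[0, 1\]? Default `TRUE`.
#' @return An [rgb_image] (linear light).
#' @export
cones_to_rgb <- function(cones, clip = TRUE) {
  stopifnot(inherits(cones, "cone_image"))
  m <- .lms2rgb
  # delta form (rows sum to 1): equal-LMS input renders bit-exactly gray
  R <- cones$L + m[1, 2] * (cones$M - cones$L) + m[1, 3] * (cones$S - cones$L)
  G <- cones$L + m[2, 2] * (cones$M - cones$L) + m[2, 3] * (cones$S - cones$L)
  B <- cones$L + m[3, 2] * (cones$M - cones$L) + m[3, 3] * (cones$S - cones$L)
  if (clip) {
    R <- pmin(pmax(R, 0), 1)
    G <- pmin(pmax(G, 0), 1)
    B <- pmin(pmax(B, 0), 1)
  }
  rgb_image(R = R, G = G, B = B, gamma = "linear")
}
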