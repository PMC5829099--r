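# Lightweight S3 containers for the image pipeline. All planes are
# numeric H x W matrices indexed [row, column]; pixel centers sit at
# integer coordinates.

.check_planes <- function(planes, nonneg = FALSE, unit = FALSE) {
  dims <- lapply(planes, dim)
  if (any(vapply(planes, function(p) !is.matrix(p) || !is.numeric(p), TRUE)))
    stop("planes must be numeric matrices")
  if (length(unique(dims)) != 1L)
    stop("planes must share one shape")
  if (any(vapply(planes, function(p) any(!is.finite(p)), TRUE)))
    stop("planes must be finite")
  if (nonneg && any(vapply(planes, function(p) any(p < 0), TRUE)))
    stop("planes must be non-negative")
  if (unit && any(vapply(planes, function(p) any(p < 0 | p > 1), TRUE)))
    stop("planes must lie in [0, 1]")
  invisible(TRUE)
}

#' RGB raster image
#'
#' Three aligned display-primary planes. `gamma` records whether values
#' are linear light (`"linear"`) or sRGB-encoded (`"encoded"`); model
#' stages only accept linear images.
#'
#' @param R,G,B Numeric H x W matrices.
#' @param gamma `"linear"` or `"encoded"`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(R, G, B, gamma = c("linear", "encoded")) {
  gamma <- match.arg(gamma)
  .check_planes(list(R, G, B))
  structure(list(R = R, G = G, B = B, gamma = gamma), class = "rgb_image")
}

#' Cone excitation image
#'
#' Aligned L, M and S photoreceptor planes in linear cone-excitation
#' units. Under the package's cone transform an achromatic (equal-RGB)
#' pixel satisfies L = M = S exactly.
#'
#' @param L,M,S Numeric H x W matrices, non-negative.
#' @return An object of class `cone_image`.
#' @export
cone_image <- function(L, M, S) {
  .check_planes(list(L, M, S), nonneg = TRUE)
  structure(list(L = L, M = M, S = S), class = "cone_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$R)
  cat(sprintf("<rgb_image %d x %d, %s, range [%.4g, %.4g]>\n",
              d[1], d[2], x$gamma,
              min(x$R, x$G, x$B), max(x$R, x$G, x$B)))
  invisible(x)
}

#' @export
print.cone_image <- function(x, ...) {
  d <- dim(x$L)
  cat(sprintf("<cone_image %d x %d, range [%.4g, %.4g]>\n",
              d[1], d[2], min(x$L, x$M, x$S), max(x$L, x$M, x$S)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$R)

#' @export
dim.cone_image <- function(x) dim(x$L)
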