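# First-order gain adaptation of the cone signals.
#
# Each ganglion-cell input is adapted by a Naka-Rushton-style gain whose
# semisaturation combines a local term, a constant, and a "remote"
# signal pooled over an annulus surrounding the entire receptive field:
#
#   sigma   = a * photo + b + c * remote
#   adapted = photo / (photo + sigma) * (photo + remote)
#
# with remote(x, y) a decaying-exponential weighted mean of the same
# cone plane over the annulus. The multiplication by (photo + remote)
# implements the curve-shifting behaviour of the underlying adaptation
# model: the response curve's operating range follows the local and
# remote context. The identical operator is applied to L, M and S, so
# an achromatic input stays achromatic. A pure Naka-Rushton reading,
# adapted = photo / (photo + sigma), is available via `form`.

#' Adaptation parameters
#'
#' @param a Local gain weight (default 1: local and remote adaptation
#'   have equal strength).
#' @param b Adaptation-strength constant (default 3).
#' @param c_remote Remote gain weight (default 1).
#' @param remote_diameter Diameter of the remote annulus in pixels
#'   (default 35; odd, at least 3).
#' @param rho_remote Decay constant of the remote weights in pixels;
#'   default `remote_diameter / 4`.
#' @param inner_radius Inner radius of the annulus in pixels; default
#'   `9` (three surround decay constants, just outside the classical
#'   receptive field).
#' @param form `"curve_shift"` (default) or `"naka_rushton"`; see the
#'   module notes above.
#' @return An object of class `adaptation_params`.
#' @export
adaptation_params <- function(a = 1, b = 3, c_remote = 1,
                              remote_diameter = 35,
                              rho_remote = remote_diameter / 4,
                              inner_radius = 9,
                              form = c("curve_shift", "naka_rushton")) {
  form <- match.arg(form)
  stopifnot(a >= 0, b >= 0, c_remote >= 0,
            remote_diameter >= 3, remote_diameter %% 2 == 1,
            rho_remote > 0, inner_radius >= 1,
            inner_radius < remote_diameter / 2)
  structure(list(a = a, b = b, c_remote = c_remote,
                 remote_diameter = as.integer(remote_diameter),
                 rho_remote = rho_remote,
                 inner_radius = inner_radius,
                 form = form),
            class = "adaptation_params")
}

#' Remote adaptation kernel
#' @param params An [adaptation_params] object.
#' @return Annulus kernel matrix (unit sum, zero center region).
#' @export
remote_kernel <- function(params = adaptation_params()) {
  annulus_kernel(inner = params$inner_radius,
                 outer = params$remote_diameter / 2,
                 rho = params$rho_remote)
}

#' Remote signal of a cone plane
#'
#' Weighted mean of the plane over the surrounding annulus (reflective
#' boundary). The central receptive-field region is excluded, so a
#' single bright pixel does not contribute to its own remote signal.
#'
#' @param plane Numeric H x W matrix (non-negative cone signals).
#' @param params An [adaptation_params] object.
#' @return Matrix of remote signals, bounded by the plane's range.
#' @export
compute_remote <- function(plane, params = adaptation_params()) {
  k <- remote_kernel(params)
  if (nrow(k) > 2 * nrow(plane) || ncol(k) > 2 * ncol(plane))
    stop("remote annulus larger than the image")
  convolve2d(plane, k)
}

#' Adapt one cone plane
#'
#' Applies the per-pixel gain described in the module notes. Pixels with
#' zero photoreceptor signal have zero adapted response.
#'
#' @param photo Cone plane (non-negative matrix).
#' @param remote Matching remote-signal plane from [compute_remote()].
#' @param params An [adaptation_params] object.
#' @return Adapted plane, same shape.
#' @export
adapt_channel <- function(photo, remote, params = adaptation_params()) {
  stopifnot(identical(dim(photo), dim(remote)))
  if (any(photo < 0) || any(remote < 0))
    stop("cone signals must be non-negative")
  sigma <- params$a * photo + params$b + params$c_remote * remote
  gain <- photo / (photo + sigma)
  gain[photo == 0] <- 0                     # 0/0 guard; exact zero response
  if (params$form == "curve_shift") gain * (photo + remote) else gain
}

#' Adapt a cone image
#'
#' Channel-wise remote-signal computation followed by the adaptation
#' gain, using the identical operator for L, M and S.
#'
#' @param cones A [cone_image].
#' @param params An [adaptation_params] object.
#' @return An object of class `adapted_cones` (list of planes `L`, `M`,
#'   `S` plus the `remote` fields).
#' @export
adapt_image <- function(cones, params = adaptation_params()) {
  stopifnot(inherits(cones, "cone_image"))
  k <- remote_kernel(params)
  op <- conv_operator(k, dim(cones$L))
  remote <- lapply(cones[c("L", "M", "S")], convolve2d, k = op)
  planes <- mapply(adapt_channel, cones[c("L", "M", "S")], remote,
                   MoreArgs = list(params = params), SIMPLIFY = FALSE)
  structure(list(L = planes$L, M = planes$M, S = planes$S,
                 remote = remote, params = params),
            class = "adapted_cones")
}

#' @export
print.adapted_cones <- function(x, ...) {
  d <- dim(x$L)
  cat(sprintf("<adapted_cones %d x %d, range [%.4g, %.4g]>\n",
              d[1], d[2], min(x$L, x$M, x$S), max(x$L, x$M, x$S)))
  invisible(x)
}
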