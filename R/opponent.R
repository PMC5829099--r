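# Opponent receptive fields of the retinal color-coding ganglion cells.
#
# Type-I midget-like cells are spatially antagonistic differences of
# Gaussians with chromatic opponency: the L+M- cell takes an L-cone
# center minus an M-cone surround (and M+L- the converse), with the
# surround decay constant three times the center's. The type-II small
# bistratified cell (S+/LM-) is spatially coextensive: it integrates
# the pointwise chromatic difference S - (L + M)/2 under one
# single-signed Gaussian, so it responds to blue-yellow chromatic
# structure but gives a null response to any achromatic pattern --
# including achromatic edges whose S plane has been defocused away from
# the L/M planes only in luminance, which is the property the inverse
# stage exploits to discard chromatic-aberration fringes.
#
# All discrete kernels are renormalized to unit total weight.

#' Receptive-field geometry
#'
#' @param rho_cen Center Gaussian decay constant, pixels (default 1).
#' @param rho_sur Surround decay constant, pixels (default `3 * rho_cen`:
#'   the surround weight function is three times larger than the
#'   center's).
#' @param rho_s_rf Decay constant of the coextensive S-cell RF, pixels
#'   (default equals `rho_sur`, reflecting the large bistratified RF).
#' @param truncation Kernel support radius in multiples of rho
#'   (default 3).
#' @return An object of class `rf_geometry`.
#' @export
rf_geometry <- function(rho_cen = 1, rho_sur = 3 * rho_cen,
                        rho_s_rf = rho_sur, truncation = 3) {
  stopifnot(rho_cen > 0, rho_sur > 0, rho_s_rf > 0, truncation > 0)
  structure(list(rho_cen = rho_cen, rho_sur = rho_sur,
                 rho_s_rf = rho_s_rf, truncation = truncation),
            class = "rf_geometry")
}

#' Center and surround subregion responses
#'
#' Convolves the adapted L and M planes with the center kernel `f_c`
#' (decay `rho_cen`) and the surround kernel `f_s` (decay `rho_sur`),
#' both unit-sum, under reflective padding. Surrounds are computed per
#' cone plane; the chromatic pairing (L-center against M-surround) is
#' applied at the subtraction stage, which yields the same composite
#' opponent operator.
#'
#' @param adapted An [adapt_image()] result.
#' @param geom An [rf_geometry] object.
#' @return List of planes `L_cen`, `M_cen`, `L_sur`, `M_sur`.
#' @export
center_surround <- function(adapted, geom = rf_geometry()) {
  stopifnot(inherits(adapted, "adapted_cones"), inherits(geom, "rf_geometry"))
  fc <- gaussian_kernel(geom$rho_cen, geom$truncation)
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  list(L_cen = convolve2d(adapted$L, fc),
       M_cen = convolve2d(adapted$M, fc),
       L_sur = convolve2d(adapted$L, fs),
       M_sur = convolve2d(adapted$M, fs))
}

#' Type-I opponent responses
#'
#' The cell response is the subtraction of center and surround adapted
#' responses across the chromatic pairing:
#' `LplusM = L_cen - M_sur` and `MplusL = M_cen - L_sur`.
#'
#' @param maps A [center_surround()] result.
#' @return List with planes `LplusM` and `MplusL`.
#' @export
type1_responses <- function(maps) {
  list(LplusM = maps$L_cen - maps$M_sur,
       MplusL = maps$M_cen - maps$L_sur)
}

#' Type-II coextensive S-opponent response
#'
#' Integrates the chromatic difference `S - (L + M)/2` of the adapted
#' planes under a single-signed Gaussian of decay `rho_s_rf`: chromatic
#' opponency with no spatial antagonism.
#'
#' @param adapted An [adapt_image()] result.
#' @param geom An [rf_geometry] object.
#' @return Matrix `SplusLM`.
#' @export
type2_response <- function(adapted, geom = rf_geometry()) {
  stopifnot(inherits(adapted, "adapted_cones"), inherits(geom, "rf_geometry"))
  f <- gaussian_kernel(geom$rho_s_rf, geom$truncation)
  convolve2d(adapted$S - (adapted$L + adapted$M) / 2, f)
}

#' All opponent maps of an adapted image
#'
#' Convenience wrapper combining [center_surround()],
#' [type1_responses()] and [type2_response()].
#'
#' @param adapted An [adapt_image()] result.
#' @param geom An [rf_geometry] object.
#' @return An object of class `opponent_maps` with planes `LplusM`,
#'   `MplusL`, `SplusLM`.
#' @export
opponent_maps <- function(adapted, geom = rf_geometry()) {
  cs <- center_surround(adapted, geom)
  t1 <- type1_responses(cs)
  structure(list(LplusM = t1$LplusM, MplusL = t1$MplusL,
                 SplusLM = type2_response(adapted, geom),
                 geom = geom),
            class = "opponent_maps")
}

#' @export
print.opponent_maps <- function(x, ...) {
  d <- dim(x$LplusM)
  cat(sprintf(
    "<opponent_maps %d x %d; |L+M-| <= %.3g, |M+L-| <= %.3g, |S+LM-| <= %.3g>\n",
    d[1], d[2], max(abs(x$LplusM)), max(abs(x$MplusL)), max(abs(x$SplusLM))))
  invisible(x)
}
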