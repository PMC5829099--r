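# Chromatic fringe and induction metrics.
#
# Blue-yellow chromatic contrast is the ratio of the blue channel to
# the yellow channel, B / ((R + G)/2), on linear RGB: an achromatic
# pixel scores exactly 1, bluish deviations score above 1 and yellowish
# below. The yellow channel is the mean of R and G so that the
# achromatic reference is 1. The S-cone induction metric works in the
# perceived cone domain: mean S / (L + M) over the (physically
# identical) test-ring mask of the two inducer variants.

#' Blue-yellow contrast profile along an image row
#'
#' Computes `B / ((R + G)/2)` per pixel of one row of a linear-light
#' image. Pixels whose yellow channel falls below `eps` are flagged
#' (`NA` value, `flag = TRUE`) rather than silently dropped.
#'
#' @param img An [rgb_image] (linear light).
#' @param row Row index of the cross-section.
#' @param eps Guard threshold for the denominator (default 1e-8).
#' @return A data frame of class `contrast_profile` with columns
#'   `position`, `value`, `flag`.
#' @export
by_contrast_profile <- function(img, row, eps = 1e-8) {
  stopifnot(inherits(img, "rgb_image"))
  if (!identical(img$gamma, "linear"))
    stop("contrast profiles are defined on linear-light images")
  h <- nrow(img$R)
  if (row < 1 || row > h) stop("row outside the image")
  yellow <- (img$R[row, ] + img$G[row, ]) / 2
  blue <- img$B[row, ]
  flag <- yellow <= eps
  value <- ifelse(flag, NA_real_, blue / yellow)
  structure(data.frame(position = seq_along(blue), value = value,
                       flag = flag),
            class = c("contrast_profile", "data.frame"))
}

#' Fringe magnitude near known edges
#'
#' Maximum absolute deviation of the blue-yellow contrast from the
#' achromatic reference 1, over all unflagged pixels within `window`
#' pixels of any listed edge. An edge at position `e` lies between
#' pixels `e` and `e + 1`.
#'
#' @param profile A [by_contrast_profile()] result.
#' @param edges Integer vector of edge positions (from the fixture).
#' @param window Half-width of the evaluation band in pixels
#'   (default 9, three surround decay constants).
#' @return Scalar fringe magnitude (0 for a flat profile).
#' @export
fringe_magnitude <- function(profile, edges, window = 9) {
  stopifnot(inherits(profile, "contrast_profile"), length(edges) >= 1)
  near <- rep(FALSE, nrow(profile))
  for (e in edges) {
    lo <- max(1L, as.integer(e) - as.integer(window) + 1L)
    hi <- min(nrow(profile), as.integer(e) + as.integer(window))
    near[lo:hi] <- TRUE
  }
  v <- profile$value[near & !profile$flag]
  if (length(v) == 0L) return(0)
  max(abs(v - 1))
}

#' S-cone chromatic contrast of a region
#'
#' Mean `S / (L + M)` (or `S / ((L + M)/2)` with
#' `denominator = "mean"`) over a pixel mask of a perceived image.
#'
#' @param perceived A complete `perceived_image`.
#' @param mask Logical matrix selecting the region.
#' @param denominator `"sum"` (default) or `"mean"` convention for the
#'   L+M term.
#' @return Scalar chromatic contrast.
#' @export
s_chromatic_contrast <- function(perceived, mask,
                                 denominator = c("sum", "mean")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(perceived, "perceived_image"), !is.null(perceived$S))
  if (!any(mask)) stop("empty mask")
  lm <- perceived$L[mask] + perceived$M[mask]
  if (denominator == "mean") lm <- lm / 2
  mean(perceived$S[mask] / lm)
}

#' Chromatic induction report for a ring-pattern pair
#'
#' Compares the S-cone chromatic contrast of the physically identical
#' test ring between the two inducer variants of the ring pattern.
#' The shift is reported as an absolute difference; assimilation
#' predicts a higher test-ring contrast in the variant whose adjacent
#' inducers have the higher S excitation.
#'
#' @param perceived_a,perceived_b Complete `perceived_image`s of the
#'   two variants.
#' @param mask Logical test-ring mask (identical across variants).
#' @param denominator Passed to [s_chromatic_contrast()].
#' @return An object of class `induction_report`: list with
#'   `variant_a_contrast`, `variant_b_contrast`, `shift`.
#' @export
s_contrast_shift <- function(perceived_a, perceived_b, mask,
                             denominator = c("sum", "mean")) {
  denominator <- match.arg(denominator)
  ca <- s_chromatic_contrast(perceived_a, mask, denominator)
  cb <- s_chromatic_contrast(perceived_b, mask, denominator)
  structure(list(variant_a_contrast = ca,
                 variant_b_contrast = cb,
                 shift = abs(ca - cb)),
            class = "induction_report")
}

#' @export
print.induction_report <- function(x, ...) {
  cat(sprintf(
    "<induction_report: S/(L+M) test-ring contrast %.4f (A) vs %.4f (B), shift %.4f>\n",
    x$variant_a_contrast, x$variant_b_contrast, x$shift))
  invisible(x)
}

#' Write a contrast profile as CSV
#'
#' @param profile A [by_contrast_profile()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
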