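# Synthetic stimulus generators and raster image IO.
#
# Two families of fixtures drive the model: an achromatic grid of
# equal-energy squares (for chromatic-fringe demonstrations under
# defocus) and a concentric square-wave ring pattern with a fixed test
# ring and swappable inducer rings (the S-cone assimilation stimulus of
# Shevell and Monnier). Both are generated directly in linear light.

#' Stimulus specification
#'
#' Parameterizes the synthetic fixtures. `chromaticities` are linear RGB
#' triplets per region: for `kind = "grid"` exactly two gray levels
#' (bright, dark); for `kind = "rings"` a list with elements `test`,
#' `inducer_a` and `inducer_b`; for `kind = "uniform"` a single triplet.
#'
#' @param kind `"grid"`, `"rings"` or `"uniform"`.
#' @param size Image size in pixels, `c(H, W)` or a scalar.
#' @param square Grid square edge length in pixels.
#' @param ring_width Ring width in pixels.
#' @param n_rings Total number of rings (odd; the middle ring is the
#'   test ring).
#' @param chromaticities Region chromaticities, see Details.
#' @param background Linear RGB triplet outside the rings.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("grid", "rings", "uniform"),
                          size = 256,
                          square = 64,
                          ring_width = 8,
                          n_rings = 15,
                          chromaticities = NULL,
                          background = NULL) {
  kind <- match.arg(kind)
  if (length(size) == 1L) size <- c(size, size)
  stopifnot(all(size >= 1), square >= 1, ring_width >= 1, n_rings >= 1)
  if (kind == "rings" && n_rings %% 2L == 0L)
    stop("n_rings must be odd so a unique middle test ring exists")
  if (is.null(chromaticities)) {
    chromaticities <- switch(kind,
      grid = list(bright = rep(0.8, 3), dark = rep(0.1, 3)),
      rings = default_ring_chromaticities(),
      uniform = list(level = rep(0.5, 3))
    )
  }
  for (ch in chromaticities) {
    if (length(ch) != 3L || any(ch < 0) || any(ch > 1))
      stop("chromaticities must be RGB triplets in [0,1]^3")
  }
  bg <- if (is.null(background)) rep(0.4, 3) else background
  structure(list(kind = kind, size = as.integer(size),
                 square = as.integer(square),
                 ring_width = as.integer(ring_width),
                 n_rings = as.integer(n_rings),
                 chromaticities = chromaticities,
                 background = bg),
            class = "stimulus_spec")
}

#' Default ring-pattern chromaticities
#'
#' Linear RGB triplets approximating the Shevell-Monnier S-cone pattern
#' in this package's cone space: all rings share the same L and M
#' excitation (0.40) so the rings differ only in S-cone drive, with the
#' test ring at S = 0.40, a high-S "purple" inducer at S = 0.70 and a
#' low-S "lime" inducer at S = 0.15. The published stimulus
#' chromaticities are not tabulated; these are documented approximations
#' that preserve its defining structure (equal L+M, S-only contrast).
#'
#' @return Named list of RGB triplets (`test`, `inducer_a`, `inducer_b`).
#' @export
default_ring_chromaticities <- function() {
  lms <- list(test = c(0.40, 0.40, 0.40),
              inducer_a = c(0.40, 0.40, 0.70),  # purple: high S
              inducer_b = c(0.40, 0.40, 0.15))  # lime: low S
  lapply(lms, function(v) {
    rgb <- as.numeric(cone_matrix(inverse = TRUE) %*% v)
    pmin(pmax(rgb, 0), 1)
  })
}

#' Generate the achromatic grid fixture
#'
#' A checkerboard of alternating bright and dark squares, both
#' achromatic, in linear light. Used to demonstrate blue-yellow fringe
#' formation at pure luminance edges under chromatic defocus.
#'
#' @param spec A `stimulus_spec` with `kind = "grid"`.
#' @return An [rgb_image]; attribute `edges` holds the column indices of
#'   vertical square borders (edge lies between column `e` and `e + 1`).
#' @export
make_grid <- function(spec = stimulus_spec("grid")) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "grid")
  ch <- spec$chromaticities
  if (length(ch) != 2L) stop("grid needs exactly two chromaticities")
  achrom <- vapply(ch, function(v) diff(range(v)) < 1e-12, TRUE)
  if (!all(achrom))
    warning("grid fixture chromaticities are not achromatic")
  h <- spec$size[1]; w <- spec$size[2]; s <- spec$square
  ri <- (seq_len(h) - 1L) %/% s
  ci <- (seq_len(w) - 1L) %/% s
  parity <- outer(ri, ci, "+") %% 2L      # 0 = first level, 1 = second
  planes <- lapply(1:3, function(p) {
    matrix(ifelse(parity == 0L, ch[[1]][p], ch[[2]][p]), h, w)
  })
  img <- rgb_image(planes[[1]], planes[[2]], planes[[3]], gamma = "linear")
  edges <- which(diff(ci) != 0L)           # border between col e and e+1
  attr(img, "edges") <- edges
  img
}

#' Generate the concentric ring pattern
#'
#' Concentric square-wave rings around the image center: ring `i`
#' occupies radii `[(i-1) w, i w)`. The middle ring is the test ring;
#' all other rings alternate between the two inducer chromaticities.
#' `variant` chooses which inducer is adjacent to the test ring; the
#' test ring itself is pixel-identical across variants. Pixels beyond
#' the outermost ring take the background chromaticity.
#'
#' @param spec A `stimulus_spec` with `kind = "rings"`.
#' @param variant `"a"` (inducer A adjacent to the test ring) or `"b"`.
#' @return An [rgb_image]; attribute `masks` holds logical matrices
#'   `test`, `inducer` and `background`.
#' @export
make_ring_pattern <- function(spec = stimulus_spec("rings"), variant = c("a", "b")) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "rings")
  variant <- match.arg(variant)
  ch <- spec$chromaticities
  stopifnot(all(c("test", "inducer_a", "inducer_b") %in% names(ch)))
  h <- spec$size[1]; w <- spec$size[2]
  wr <- spec$ring_width; n <- spec$n_rings
  if (n * wr > min(h, w) / 2)
    stop("ring widths exceed the image radius")
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
  ring <- floor(r / wr) + 1   # ring index, 1-based from the center
  mid <- (n + 1L) %/% 2L
  test_mask <- ring == mid
  in_rings <- ring <= n
  # alternation phase: rings adjacent to the test ring carry the first
  # inducer in variant "a"; swapping the two inducers gives variant "b"
  first <- if (variant == "a") ch$inducer_a else ch$inducer_b
  second <- if (variant == "a") ch$inducer_b else ch$inducer_a
  adjacent <- (ring - mid) %% 2L == 1L
  planes <- lapply(1:3, function(p) {
    out <- matrix(spec$background[p], h, w)
    out[in_rings & adjacent] <- first[p]
    out[in_rings & !adjacent] <- second[p]
    out[test_mask] <- ch$test[p]
    out
  })
  img <- rgb_image(planes[[1]], planes[[2]], planes[[3]], gamma = "linear")
  attr(img, "masks") <- list(test = test_mask,
                             inducer = in_rings & !test_mask,
                             background = !in_rings)
  img
}

#' Generate a uniform field
#'
#' @param spec A `stimulus_spec` with `kind = "uniform"`.
#' @return An [rgb_image].
#' @export
make_uniform <- function(spec = stimulus_spec("uniform")) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "uniform")
  ch <- spec$chromaticities[[1]]
  h <- spec$size[1]; w <- spec$size[2]
  rgb_image(matrix(ch[1], h, w), matrix(ch[2], h, w), matrix(ch[3], h, w),
            gamma = "linear")
}

#' Read a PNG or TIFF image
#'
#' Reads 8- or 16-bit PNG/TIFF into an [rgb_image]. Grayscale files are
#' expanded to three equal planes; an alpha channel is dropped. Files
#' are assumed sRGB-encoded unless `assume_linear = TRUE`.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @param assume_linear Treat the stored values as linear light?
#' @return An [rgb_image] in linear light.
#' @export
read_image <- function(path, assume_linear = FALSE) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  R <- a[, , 1]; G <- a[, , 2]; B <- a[, , 3]
  if (!assume_linear) {
    R <- srgb_decode(R); G <- srgb_decode(G); B <- srgb_decode(B)
  }
  rgb_image(R, G, B, gamma = "linear")
}

#' Write an image to PNG or TIFF
#'
#' Values are clipped to \[0, 1\] on write. PNG output is 8-bit; TIFF
#' output is 16-bit (or 32-bit float with `bits = 32`, used for
#' diagnostic opponent-map dumps). With `encode = TRUE` (default for
#' PNG) linear values are sRGB-encoded for display.
#'
#' @param img An [rgb_image], or a bare matrix (written as grayscale).
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bits Bit depth for TIFF: 16 or 32.
#' @param encode Apply the sRGB transfer function before writing?
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16, encode = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (is.matrix(img)) img <- rgb_image(img, img, img, gamma = "linear")
  stopifnot(inherits(img, "rgb_image"))
  if (is.null(encode)) encode <- ext == "png"
  planes <- list(img$R, img$G, img$B)
  if (encode && identical(img$gamma, "linear"))
    planes <- lapply(planes, srgb_encode)
  if (ext == "png" || bits != 32)  # float TIFF keeps signed diagnostics
    planes <- lapply(planes, function(p) pmin(pmax(p, 0), 1))
  a <- array(unlist(planes), c(dim(planes[[1]]), 3L))
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = if (bits == 32) {
      # float samples may carry signed diagnostics; the range warning
      # only concerns integer formats
      suppressWarnings(tiff::writeTIFF(a, path, bits.per.sample = 32L,
                                       compression = "none"))
    } else {
      tiff::writeTIFF(a, path, bits.per.sample = as.integer(bits),
                      compression = "none")
    },
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
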