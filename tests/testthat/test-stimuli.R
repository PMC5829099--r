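test_that("grid fixture has exactly the two specified gray levels", {
  spec <- stimulus_spec("grid", size = 16, square = 8,
                        chromaticities = list(bright = rep(1, 3),
                                              dark = rep(0, 3)))
  img <- make_grid(spec)
  expect_identical(dim(img$R), c(16L, 16L))
  expect_equal(sum(img$R == 1), 128)
  expect_equal(sum(img$R == 0), 128)
  expect_identical(img$R, img$G)
  expect_identical(img$R, img$B)

  # 3x3-square grid at a non-unit pair: histogram has exactly two bins
  spec2 <- stimulus_spec("grid", size = 90, square = 30,
                         chromaticities = list(bright = rep(0.9, 3),
                                               dark = rep(0.1, 3)))
  img2 <- make_grid(spec2)
  expect_setequal(unique(as.vector(img2$R)), c(0.9, 0.1))
  # counting oracle: alternating 30-px squares in a 3x3 layout
  parity <- outer((seq_len(90) - 1) %/% 30, (seq_len(90) - 1) %/% 30, "+") %% 2
  expect_equal(sum(img2$R == 0.9), sum(parity == 0))
})

test_that("degenerate grid with equal levels is uniform and edge-free", {
  spec <- stimulus_spec("grid", size = 32, square = 8,
                        chromaticities = list(bright = rep(0.5, 3),
                                              dark = rep(0.5, 3)))
  img <- make_grid(spec)
  expect_true(all(img$R == 0.5))
  prof <- by_contrast_profile(img, 4)
  expect_true(all(abs(prof$value - 1) < 1e-12))
})

test_that("non-achromatic grid chromaticities raise a warning", {
  spec <- stimulus_spec("grid", size = 16, square = 8,
                        chromaticities = list(bright = c(0.9, 0.5, 0.5),
                                              dark = rep(0.1, 3)))
  expect_warning(make_grid(spec), "not achromatic")
})

test_that("ring pattern keeps the test ring pixel-identical across variants", {
  spec <- stimulus_spec("rings", size = 64, ring_width = 4, n_rings = 5,
                        chromaticities = list(test = c(0.8, 0.5, 0.6),
                                              inducer_a = c(0.5, 0.3, 0.8),
                                              inducer_b = c(0.6, 0.8, 0.3)))
  a <- make_ring_pattern(spec, "a")
  b <- make_ring_pattern(spec, "b")
  mask <- attr(a, "masks")$test
  expect_true(any(mask))
  for (p in c("R", "G", "B")) {
    expect_identical(a[[p]][mask], b[[p]][mask])
    # inducer regions actually differ between variants
    expect_false(isTRUE(all.equal(a[[p]][attr(a, "masks")$inducer],
                                  b[[p]][attr(b, "masks")$inducer])))
  }
  # masks partition the stimulus area exactly
  m <- attr(a, "masks")
  expect_equal(sum(m$test) + sum(m$inducer) + sum(m$background),
               prod(dim(a$R)))
  expect_false(any(m$test & m$inducer))
})

test_that("identical ring chromaticities yield a uniform annular region", {
  ch <- list(test = rep(0.5, 3), inducer_a = rep(0.5, 3),
             inducer_b = rep(0.5, 3))
  spec <- stimulus_spec("rings", size = 64, ring_width = 4, n_rings = 5,
                        chromaticities = ch, background = rep(0.5, 3))
  img <- make_ring_pattern(spec, "a")
  expect_true(all(img$R == 0.5))
})

test_that("ring widths exceeding the image radius are rejected", {
  spec <- stimulus_spec("rings", size = 64, ring_width = 16, n_rings = 5)
  expect_error(make_ring_pattern(spec), "radius")
  expect_error(stimulus_spec("rings", n_rings = 4), "odd")
})

test_that("cone transform is white-normalized, zero-preserving and invertible", {
  one <- matrix(1, 2, 2)
  white <- rgb_to_cones(rgb_image(one, one, one, gamma = "linear"))
  expect_equal(white$L, one)
  expect_equal(white$M, one)
  expect_equal(white$S, one)
  zero <- matrix(0, 2, 2)
  black <- rgb_to_cones(rgb_image(zero, zero, zero, gamma = "linear"))
  expect_equal(black$L, zero)

  # any equal-RGB image maps to L = M = S exactly
  set.seed(7)
  g <- matrix(runif(64), 8, 8)
  ach <- rgb_to_cones(rgb_image(g, g, g, gamma = "linear"))
  expect_identical(ach$L, ach$M)
  expect_identical(ach$M, ach$S)

  # round trip within 1e-10 on random pixels
  set.seed(8)
  img <- rgb_image(matrix(runif(64), 8), matrix(runif(64), 8),
                   matrix(runif(64), 8), gamma = "linear")
  cones <- rgb_to_cones(img)
  back <- cones_to_rgb(cones, clip = FALSE)
  expect_lt(max(abs(back$R - img$R), abs(back$G - img$G),
                abs(back$B - img$B)), 1e-10)
  # matrix inverse identity
  expect_lt(max(abs(cone_matrix() %*% cone_matrix(inverse = TRUE) -
                    diag(3))), 1e-12)
})

test_that("gamma-encoded input is rejected and clipping maps out-of-gamut to 1", {
  one <- matrix(1, 2, 2)
  enc <- rgb_image(one, one, one, gamma = "encoded")
  expect_error(rgb_to_cones(enc), "linear")
  sup <- cone_image(1.2 * one, 1.2 * one, 1.2 * one)
  expect_equal(cones_to_rgb(sup, clip = TRUE)$R, one)
})

test_that("PNG and 16-bit TIFF round-trips preserve pixel values", {
  set.seed(9)
  vals <- matrix(round(runif(64) * 65535) / 65535, 8, 8)
  img <- rgb_image(vals, vals, vals, gamma = "linear")
  tf <- withr::local_tempfile(fileext = ".tiff")
  write_image(img, tf, bits = 16, encode = FALSE)
  back <- read_image(tf, assume_linear = TRUE)
  expect_equal(back$R, vals, tolerance = 1e-12)

  pf <- withr::local_tempfile(fileext = ".png")
  vals8 <- matrix(round(runif(64) * 255) / 255, 8, 8)
  write_image(rgb_image(vals8, vals8, vals8, gamma = "linear"), pf,
              encode = FALSE)
  back8 <- read_image(pf, assume_linear = TRUE)
  expect_equal(back8$R, vals8, tolerance = 1e-12)
})
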