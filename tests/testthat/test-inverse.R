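test_that("achromatic initialization averages the adapted L and M planes", {
  ad <- list(L = matrix(0.4, 4, 4), M = matrix(0.2, 4, 4))
  init <- initialize_perceived(ad)
  expect_equal(init$L, matrix(0.3, 4, 4))
  expect_identical(init$L, init$M)
  expect_identical(init$L, init$S)

  # achromatic input: initialization equals L_ad exactly
  g <- matrix(runif(16), 4, 4)
  init2 <- initialize_perceived(list(L = g, M = g))
  expect_identical(init2$L, g)
})

test_that("residual error vanishes at the defining fixed point and matches its oracle", {
  geom <- rf_geometry()
  set.seed(31)
  L <- matrix(runif(64, 0.2, 0.8), 8, 8)
  M <- matrix(runif(64, 0.2, 0.8), 8, 8)
  opp <- forward_opponent(L, M, geom)
  e <- residual_error(L, M, opp, geom)
  expect_lt(attr(e, "total"), 1e-20)

  # nested-loop oracle on a perturbed pair
  Lp <- L + 0.01; Mp <- M - 0.02
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  rL <- Lp - opp$LplusM - brute_convolve(Mp, fs)
  rM <- Mp - opp$MplusL - brute_convolve(Lp, fs)
  e2 <- residual_error(Lp, Mp, opp, geom)
  expect_lt(max(abs(e2 - (rL^2 + rM^2))), 1e-12)

  # symmetry: joint relabeling L<->M with LplusM<->MplusL leaves E invariant
  opp_sw <- opp
  opp_sw$LplusM <- opp$MplusL; opp_sw$MplusL <- opp$LplusM
  e3 <- residual_error(Mp, Lp, opp_sw, geom)
  expect_equal(attr(e3, "total"), attr(e2, "total"), tolerance = 1e-12)
})

test_that("zero opponent maps with achromatic init need no iterations", {
  geom <- rf_geometry()
  z <- matrix(0, 12, 12)
  opp <- structure(list(LplusM = z, MplusL = z, SplusLM = z, geom = geom),
                   class = "opponent_maps")
  # any constant achromatic pair solves the homogeneous system
  init <- list(L = matrix(0.3, 12, 12), M = matrix(0.3, 12, 12))
  p <- solve_perceived_iterative(opp, init)
  expect_identical(p$iterations, 0L)
  expect_equal(p$final_error, 0)
  expect_equal(p$L, init$L)
})

test_that("iterative solver satisfies the opponent equations at convergence", {
  geom <- rf_geometry()
  opp <- random_opponent(16, 16, geom, seed = 32, scale = 0.05)
  init <- list(L = matrix(0, 16, 16), M = matrix(0, 16, 16))
  p <- solve_perceived_iterative(opp, init,
                                 settings = solver_settings(tol = 1e-9,
                                                            max_iter = 30000))
  expect_true(p$converged)
  # per-pixel residual of the opponent equations sits at the
  # least-squares floor (random maps are not exactly consistent)
  d <- solve_perceived_direct(opp, geom, init = init)
  rfloor <- sqrt(residual_error(d$L, d$M, opp, geom))
  rit <- sqrt(residual_error(p$L, p$M, opp, geom))
  expect_lt(max(abs(rit - rfloor)), 1e-6)
})

test_that("iterative and direct solutions agree within 1e-4 per pixel", {
  geom <- rf_geometry()
  for (seed in c(33, 34)) {
    opp <- random_opponent(16, 16, geom, seed = seed, scale = 0.05)
    init <- list(L = matrix(0.2, 16, 16), M = matrix(0.2, 16, 16))
    it <- solve_perceived_iterative(opp, init,
                                    settings = solver_settings(tol = 1e-9,
                                                               max_iter = 50000))
    dir <- solve_perceived_direct(opp, geom, init = init)
    expect_lt(max(abs(it$L - dir$L)), 1e-4)
    expect_lt(max(abs(it$M - dir$M)), 1e-4)
  }
})

test_that("energy is non-increasing across accepted iterations", {
  # instrument the descent by replaying it with a large step so the
  # halving guard must engage
  geom <- rf_geometry()
  opp <- random_opponent(12, 12, geom, seed = 35, scale = 0.2)
  init <- list(L = matrix(0, 12, 12), M = matrix(0, 12, 12))
  p_big <- solve_perceived_iterative(opp, init,
                                     settings = solver_settings(dt = 2,
                                                                max_iter = 400))
  expect_lt(p_big$dt, 2)  # guard halved the unstable step
  e0 <- attr(residual_error(init$L, init$M, opp, geom), "total")
  expect_lte(p_big$final_error, e0)

  # energy trace under the default step: monotone non-increasing
  settings <- solver_settings(max_iter = 60)
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  f0 <- fs[(nrow(fs) + 1) / 2, (ncol(fs) + 1) / 2]
  L <- init$L; M <- init$M
  E_trace <- numeric(60)
  for (i in 1:60) {
    rL <- L - opp$LplusM - brute_convolve(M, fs)
    rM <- M - opp$MplusL - brute_convolve(L, fs)
    L2 <- L - settings$dt * 2 * (rL - f0 * rM)
    M2 <- M - settings$dt * 2 * (rM - f0 * rL)
    L <- L2; M <- M2
    E_trace[i] <- attr(residual_error(L, M, opp, geom), "total")
  }
  expect_true(all(diff(E_trace) <= 1e-12))
})

test_that("forward-then-invert recovers random perceived planes", {
  geom <- rf_geometry()
  set.seed(36)
  L <- matrix(runif(64, 0.2, 0.8), 8, 8)
  M <- matrix(runif(64, 0.2, 0.8), 8, 8)
  opp <- forward_opponent(L, M, geom)
  # pin the constant mode with the true joint mean
  d <- solve_perceived_direct(opp, geom,
                              init = list(L = L, M = M))
  expect_lt(max(abs(d$L - L)), 1e-8)
  expect_lt(max(abs(d$M - M)), 1e-8)
  expect_lt(d$final_error, 1e-16)
})

test_that("direct-solver system matrix equals hand-assembled kernel taps", {
  geom <- rf_geometry(rho_cen = 0.5, rho_sur = 1, truncation = 2)
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  h <- 8; w <- 8
  S <- as.matrix(retinalca:::surround_matrix(fs, h, w))
  # row of an interior pixel reproduces the kernel stencil
  px <- function(i, j) (j - 1) * h + i
  r <- (nrow(fs) - 1) / 2
  for (di in -r:r) for (dj in -r:r) {
    expect_equal(S[px(4, 5), px(4 + di, 5 + dj)],
                 fs[di + r + 1, dj + r + 1])
  }
  # boundary rows fold reflected taps: all rows still sum to 1
  expect_equal(unname(rowSums(S)), rep(1, h * w), tolerance = 1e-12)
  # and applying the matrix equals the brute-force convolution
  set.seed(37)
  x <- matrix(runif(h * w), h, w)
  expect_lt(max(abs(matrix(S %*% as.vector(x), h, w) -
                    brute_convolve(x, fs))), 1e-12)
})

test_that("S recovery follows the pointwise formula", {
  z <- matrix(0, 4, 4)
  geom <- rf_geometry()
  opp <- structure(list(LplusM = z, MplusL = z, SplusLM = z + 0.1,
                        geom = geom), class = "opponent_maps")
  p <- perceived_image(L = z + 0.4, M = z + 0.2)
  p <- recover_s(opp, p)
  expect_equal(p$S, z + 0.4)   # 0.1 + (0.4 + 0.2)/2

  # zero S-opponency restores the achromatic carrier
  opp$SplusLM <- z
  p2 <- recover_s(opp, perceived_image(L = z + 0.3, M = z + 0.3))
  expect_equal(p2$S, z + 0.3)
})
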