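# Inverse transformation from opponent responses to the perceived image.
#
# The perceived L and M planes are defined implicitly by the opponent
# equations
#
#   LplusM = L_per - f_s * M_per      (surround of the perceived M)
#   MplusL = M_per - f_s * L_per
#
# where f_s is the same unit-sum surround kernel as in the forward
# model, now acting on the perceived domain. We solve them by
# minimizing the squared residual
#
#   E = sum[(L_per - LplusM - f_s*M_per)^2 + (M_per - MplusL - f_s*L_per)^2]
#
# with a damped Jacobi / gradient iteration started from the achromatic
# guess (L_ad + M_ad)/2, or exactly via a sparse linear solve (the
# oracle for small images). Since f_s has unit sum, adding the same
# constant to L_per and M_per leaves the equations unchanged: that
# one-dimensional null space is pinned by the achromatic
# initialization (iterative) or by an explicit mean constraint
# (direct). Finally the perceived S plane is read off pointwise:
#
#   S_per = SplusLM + (L_per + M_per)/2
#
# so the coextensive channel contributes chromaticity but no spatial
# detail: perceived brightness is carried by L_per and M_per alone.
#
# The damped iteration is the descent x <- x - dt * g with the
# gradient's off-diagonal surround term collapsed to its central tap
# (the Jacobi approximation):
#
#   gL = 2 (L - LplusM - f_s*M) - 2 f_s(0,0) (M - MplusL - f_s*L)
#   gM = 2 (M - MplusL - f_s*L) - 2 f_s(0,0) (L - LplusM - f_s*M)
#
# The exact gradient applies f_s (symmetric) instead of f_s(0,0) in the
# second term; since f_s(0,0) is small the approximation barely
# perturbs the descent direction, the true solution remains the unique
# fixed point, and a step-halving guard keeps E non-increasing.

#' Solver settings for the inverse transformation
#'
#' @param dt Initial step size (default 0.1; halved automatically
#'   whenever a step would increase the residual).
#' @param tol Convergence threshold: maximum absolute per-pixel update
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 5000).
#' @param method `"iterative"` (default, scales to full images) or
#'   `"direct"` (sparse linear solve, small images).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.1, tol = 1e-6, max_iter = 5000,
                            method = c("iterative", "direct")) {
  method <- match.arg(method)
  stopifnot(dt > 0, tol > 0, max_iter >= 1)
  structure(list(dt = dt, tol = tol, max_iter = as.integer(max_iter),
                 method = method),
            class = "solver_settings")
}

#' Achromatic initialization of the perceived planes
#'
#' All perceived channels start from `(L_ad + M_ad)/2`, the assumption
#' that the stimulus is achromatic; chromaticity then fills in over the
#' iterations.
#'
#' @param adapted An [adapt_image()] result (or any list with planes
#'   `L` and `M`).
#' @return List of identical planes `L`, `M`, `S`.
#' @export
initialize_perceived <- function(adapted) {
  init <- (adapted$L + adapted$M) / 2
  list(L = init, M = init, S = init)
}

#' Residual of the perceived-domain opponent equations
#'
#' Per-pixel squared residual of both equations; its total is the error
#' functional E driven to zero by the solver.
#'
#' @param L_per,M_per Perceived planes.
#' @param opp An [opponent_maps] object.
#' @param geom An [rf_geometry]; defaults to the geometry stored in
#'   `opp`.
#' @return Matrix of per-pixel squared residuals with attribute
#'   `total` (the scalar E).
#' @export
residual_error <- function(L_per, M_per, opp, geom = opp$geom) {
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  rL <- L_per - opp$LplusM - convolve2d(M_per, fs)
  rM <- M_per - opp$MplusL - convolve2d(L_per, fs)
  e <- rL^2 + rM^2
  attr(e, "total") <- sum(e)
  e
}

#' Solve for the perceived L/M planes by damped Jacobi iteration
#'
#' Gradient-style descent on the residual functional with the surround
#' cross-term collapsed to its central tap (see the module notes).
#' Iterates until the largest per-pixel update falls below
#' `settings$tol` or `settings$max_iter` is reached; steps that would
#' increase E are rejected and retried with a halved `dt`, so the
#' accepted-energy sequence is non-increasing. Non-convergence is
#' flagged on the result, not raised.
#'
#' @param opp An [opponent_maps] object.
#' @param init Initial planes (list with `L`, `M`), typically
#'   [initialize_perceived()].
#' @param geom An [rf_geometry]; defaults to the geometry in `opp`.
#' @param settings A [solver_settings] object.
#' @return A `perceived_image` (without `S`; see [recover_s()]).
#' @export
solve_perceived_iterative <- function(opp, init, geom = opp$geom,
                                      settings = solver_settings()) {
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  op <- conv_operator(fs, dim(opp$LplusM))
  f0 <- op$center
  A <- opp$LplusM; B <- opp$MplusL
  L <- init$L; M <- init$M
  dt <- settings$dt
  # f_s is symmetric, so both surround convolutions share one packed FFT
  cv <- convolve2d_pair(M, L, op)
  rL <- L - A - cv$x
  rM <- M - B - cv$y
  E <- sum(rL^2) + sum(rM^2)
  iter <- 0L
  converged <- FALSE
  while (iter < settings$max_iter) {
    dL <- -dt * 2 * (rL - f0 * rM)
    dM <- -dt * 2 * (rM - f0 * rL)
    # a common constant on both planes is the operator's null mode; it
    # is pinned by the initialization, so steps never move along it
    # (for opponent maps from the forward model this is a no-op: their
    # joint mean is zero by flux conservation)
    dm <- (mean(dL) + mean(dM)) / 2
    dL <- dL - dm
    dM <- dM - dm
    if (max(abs(dL), abs(dM)) < settings$tol) {   # fixed point reached
      converged <- TRUE
      break
    }
    repeat {
      Ln <- L + dL; Mn <- M + dM
      cvn <- convolve2d_pair(Mn, Ln, op)
      rLn <- Ln - A - cvn$x
      rMn <- Mn - B - cvn$y
      En <- sum(rLn^2) + sum(rMn^2)
      if (En <= E || dt < 1e-12) break
      dt <- dt / 2                        # reject: retry smaller step
      dL <- dL / 2; dM <- dM / 2
    }
    if (En > E) break                     # step size exhausted; stop
    iter <- iter + 1L
    L <- Ln; M <- Mn; rL <- rLn; rM <- rMn; E <- En
  }
  perceived_image(L = L, M = M, S = NULL, iterations = iter,
                  final_error = E, converged = converged, dt = dt)
}

# Sparse matrix of the unit-sum surround convolution with reflective
# boundary: row i holds the kernel taps of output pixel i.
surround_matrix <- function(fs, h, w) {
  ri <- (nrow(fs) - 1L) %/% 2L
  ci <- (ncol(fs) - 1L) %/% 2L
  n <- h * w
  taps <- which(fs != 0, arr.ind = TRUE)
  di <- taps[, 1] - (ri + 1L)
  dj <- taps[, 2] - (ci + 1L)
  wt <- fs[taps]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  px_i <- rep(seq_len(h), times = w)
  px_j <- rep(seq_len(w), each = h)
  idx <- function(i, j) (j - 1L) * h + i    # column-major pixel index
  for (t in seq_along(wt)) {
    si <- reflect_index(px_i + di[t], h)
    sj <- reflect_index(px_j + dj[t], w)
    rows <- c(rows, idx(px_i, px_j))
    cols <- c(cols, idx(si, sj))
    vals <- c(vals, rep(wt[t], n))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

#' Solve the perceived-domain equations exactly (direct oracle)
#'
#' Assembles the 2N x 2N sparse linear system of the two opponent
#' equations (N = pixel count; the surround operator as a sparse matrix
#' with reflective boundary) and solves the ridge-regularized normal
#' equations. Intended for small images as the ground-truth oracle for
#' the iterative solver. The system's one-dimensional null space (a
#' common constant on both planes) is fixed to match `init` when given,
#' otherwise the minimum-norm solution is returned.
#'
#' @param opp An [opponent_maps] object.
#' @param geom An [rf_geometry]; defaults to the geometry in `opp`.
#' @param init Optional initial planes whose joint mean pins the
#'   constant mode (use the same `init` as the iterative solver when
#'   comparing the two).
#' @param ridge Regularization weight (default 1e-9).
#' @return A `perceived_image` (without `S`).
#' @export
solve_perceived_direct <- function(opp, geom = opp$geom, init = NULL,
                                   ridge = 1e-9) {
  h <- nrow(opp$LplusM); w <- ncol(opp$LplusM)
  n <- h * w
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  S <- surround_matrix(fs, h, w)
  I <- Matrix::Diagonal(n)
  K <- rbind(cbind(I, -S), cbind(-S, I))
  b <- c(as.vector(opp$LplusM), as.vector(opp$MplusL))
  A <- Matrix::crossprod(K) + ridge * Matrix::Diagonal(2L * n)
  x <- as.numeric(Matrix::solve(A, Matrix::crossprod(K, b)))
  L <- matrix(x[seq_len(n)], h, w)
  M <- matrix(x[n + seq_len(n)], h, w)
  if (!is.null(init)) {
    shift <- mean((init$L + init$M) / 2) - mean((L + M) / 2)
    L <- L + shift
    M <- M + shift
  }
  e <- residual_error(L, M, opp, geom)
  perceived_image(L = L, M = M, S = NULL, iterations = 0L,
                  final_error = attr(e, "total"), converged = TRUE,
                  dt = NA_real_)
}

#' Recover the perceived S plane
#'
#' Pointwise: `S_per = SplusLM + (L_per + M_per)/2`. The coextensive
#' channel adds chromaticity on top of the achromatic carrier; it does
#' not contribute to perceived brightness.
#'
#' @param opp An [opponent_maps] object (supplies `SplusLM`).
#' @param perceived A `perceived_image` with solved `L` and `M`.
#' @return The same `perceived_image` with its `S` plane filled in.
#' @export
recover_s <- function(opp, perceived) {
  perceived$S <- opp$SplusLM + (perceived$L + perceived$M) / 2
  perceived
}

#' Solve the full inverse transformation
#'
#' Dispatches on `settings$method`, then recovers the S plane.
#'
#' @param opp An [opponent_maps] object.
#' @param adapted The [adapt_image()] result (for the achromatic
#'   initialization).
#' @param geom An [rf_geometry]; defaults to the geometry in `opp`.
#' @param settings A [solver_settings] object.
#' @return A complete `perceived_image`.
#' @export
solve_perceived <- function(opp, adapted, geom = opp$geom,
                            settings = solver_settings()) {
  init <- initialize_perceived(adapted)
  p <- switch(settings$method,
    iterative = solve_perceived_iterative(opp, init, geom, settings),
    direct = solve_perceived_direct(opp, geom, init = init)
  )
  recover_s(opp, p)
}

#' Perceived image container
#'
#' @param L,M,S Perceived planes (S may be `NULL` until [recover_s()]).
#' @param iterations Iterations used by the solver.
#' @param final_error Final value of the residual functional E.
#' @param converged Did the solver meet its tolerance?
#' @param dt Final accepted step size.
#' @return An object of class `perceived_image`.
#' @export
perceived_image <- function(L, M, S = NULL, iterations = 0L,
                            final_error = NA_real_, converged = NA,
                            dt = NA_real_) {
  stopifnot(final_error >= 0 || is.na(final_error))
  structure(list(L = L, M = M, S = S, iterations = iterations,
                 final_error = final_error, converged = converged,
                 dt = dt),
            class = "perceived_image")
}

#' @export
print.perceived_image <- function(x, ...) {
  d <- dim(x$L)
  cat(sprintf(
    "<perceived_image %d x %d; %d iterations, E = %.3g, %s>\n",
    d[1], d[2], x$iterations, x$final_error,
    if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Render a perceived image as RGB
#'
#' Perceived LMS values live on the adapted (compressed) scale, so a
#' global brightness gain is applied before the cone-to-RGB transform.
#' The gain acts on perceived brightness, which is carried by
#' `(L_per + M_per)/2` only; by default it maps that carrier's mean to
#' `target_mean`. Chromatic ratios are unaffected by the gain.
#'
#' @param perceived A complete `perceived_image`.
#' @param target_mean Desired mean of the brightness carrier after
#'   scaling (default 0.5); ignored when `gain` is given.
#' @param gain Explicit scalar gain (optional).
#' @return An [rgb_image] (linear light, clipped to gamut).
#' @export
render_perceived <- function(perceived, target_mean = 0.5, gain = NULL) {
  stopifnot(inherits(perceived, "perceived_image"), !is.null(perceived$S))
  if (is.null(gain)) {
    carrier <- mean((perceived$L + perceived$M) / 2)
    gain <- if (carrier > 0) target_mean / carrier else 1
  }
  cones <- cone_image(L = pmax(gain * perceived$L, 0),
                      M = pmax(gain * perceived$M, 0),
                      S = pmax(gain * perceived$S, 0))
  cones_to_rgb(cones, clip = TRUE)
}
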