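# Independent reference implementations used as oracles.

# O(N * K) nested-loop weighted sum with symmetric edge-repeating
# reflection; the reference for every receptive-field integral.
brute_convolve <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  ri <- (nrow(k) - 1L) %/% 2L
  ci <- (ncol(k) - 1L) %/% 2L
  reflect <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    if (j < n) j + 1L else 2L * n - j
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (di in -ri:ri) for (dj in -ci:ci) {
      s <- s + k[di + ri + 1L, dj + ci + 1L] *
        x[reflect(i + di, h), reflect(j + dj, w)]
    }
    out[i, j] <- s
  }
  out
}

# scalar-loop reference for the adaptation gain
brute_adapt <- function(photo, remote, a = 1, b = 3, c_remote = 1) {
  out <- matrix(0, nrow(photo), ncol(photo))
  for (i in seq_along(photo)) {
    p <- photo[i]; r <- remote[i]
    if (p > 0) {
      sigma <- a * p + b + c_remote * r
      out[i] <- p / (p + sigma) * (p + r)
    }
  }
  out
}

# random cone image fixture
random_cones <- function(h, w, seed = 1, lo = 0, hi = 1) {
  set.seed(seed)
  cone_image(L = matrix(runif(h * w, lo, hi), h, w),
             M = matrix(runif(h * w, lo, hi), h, w),
             S = matrix(runif(h * w, lo, hi), h, w))
}

# random opponent maps sharing one geometry
random_opponent <- function(h, w, geom = rf_geometry(), seed = 1,
                            scale = 0.1) {
  set.seed(seed)
  structure(list(LplusM = matrix(rnorm(h * w, sd = scale), h, w),
                 MplusL = matrix(rnorm(h * w, sd = scale), h, w),
                 SplusLM = matrix(rnorm(h * w, sd = scale), h, w),
                 geom = geom),
            class = "opponent_maps")
}

# forward application of the perceived-domain opponent equations
forward_opponent <- function(L_per, M_per, geom = rf_geometry()) {
  fs <- gaussian_kernel(geom$rho_sur, geom$truncation)
  structure(list(LplusM = L_per - brute_convolve(M_per, fs),
                 MplusL = M_per - brute_convolve(L_per, fs),
                 SplusLM = matrix(0, nrow(L_per), ncol(L_per)),
                 geom = geom),
            class = "opponent_maps")
}
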