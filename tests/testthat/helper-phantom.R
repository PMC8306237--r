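# Shared fixtures: all synthetic, built in code at test time.

# The standard study-condition phantom: 64 x 64 mass lesion, 2% Rician
# noise, 0.3-amplitude bias field, random per-band shifts within +-3 px.
std_mass_phantom <- function(seed = 1L, noise_sigma = 0.02,
                             bias_amplitude = 0.3, shifts = "random") {
  ivim_phantom(noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
               shifts = shifts, seed = seed)
}

# Independent Otsu oracle: naive loop over the same 256-bin candidate cut
# points, class statistics recomputed with mean() per split.
otsu_brute <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cand <- edges[2:n_bins]
  best_thr <- NA_real_
  best_bcv <- -Inf
  n <- length(values)
  for (t in cand) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_thr <- t
    }
  }
  best_thr
}

# Independent CEM oracle: minimize w' R w subject to w' d = 1 by
# null-space elimination (QR), no matrix inversion of R.
cem_qp_oracle <- function(X, d, ridge = 0) {
  N <- nrow(X)
  L <- ncol(X)
  R <- crossprod(X) / N + diag(ridge, L)
  w0 <- d / sum(d * d)                 # a feasible point
  Z <- qr.Q(qr(cbind(d)), complete = TRUE)[, -1, drop = FALSE]  # null(d')
  t_star <- solve(t(Z) %*% R %*% Z, -t(Z) %*% R %*% w0)
  as.numeric(w0 + Z %*% t_star)
}

# Direct enumeration of pixels inside an ellipse.
ellipse_count <- function(shape, center, axes) {
  n <- 0
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      if (((r - center[1]) / axes[1])^2 +
          ((c - center[2]) / axes[2])^2 <= 1) n <- n + 1
    }
  }
  n
}
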