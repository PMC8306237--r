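#' Automatic target generation process (ATGP)
#'
#' Extracts maximally distinct pixel signatures by successive orthogonal
#' projections: the first target is the pixel of largest norm; each
#' subsequent target is the pixel with the largest residual norm after
#' projecting all pixels onto the orthogonal complement of the targets
#' found so far. Ties resolve to the lowest row index. If the pixel set
#' runs out of rank before `n_targets`, fewer targets are returned with a
#' warning.
#'
#' @param X N x L matrix of pixel spectra (rows).
#' @param n_targets number of targets to extract (>= 1).
#' @return List with `indices` (row indices into `X`), `signatures`
#'   (k x L matrix) and `residual_norms` (squared residual norm at each
#'   selection, strictly decreasing).
#' @export
atgp <- function(X, n_targets) {
  stopifnot(is.matrix(X), n_targets >= 1)
  norms0 <- rowSums(X^2)
  if (max(norms0) == 0) stop("all pixel vectors are zero")
  idx <- integer(0)
  resn <- numeric(0)
  res <- norms0
  tol <- 1e-9 * max(norms0)
  for (k in seq_len(n_targets)) {
    if (max(res) <= tol) {
      warning(sprintf(
        "pixel set has rank %d; returning %d target(s) instead of %d",
        length(idx), length(idx), n_targets))
      break
    }
    pick <- which.max(res)  # first max = lowest flat index on ties
    idx <- c(idx, pick)
    resn <- c(resn, res[pick])
    U <- t(X[idx, , drop = FALSE])          # L x k
    Q <- qr.Q(qr(U))                        # orthonormal basis of span
    P <- X %*% Q                            # N x k projections
    res <- pmax(norms0 - rowSums(P^2), 0)
  }
  list(indices = idx, signatures = X[idx, , drop = FALSE],
       residual_norms = resn)
}

#' Spectral angle between two signatures
#'
#' Similarity of two spectra measured as the angle between them:
#' `acos(<x, d> / (|x| |d|))`, clamped to `[0, pi]`. Smaller angle means
#' more similar spectral shape, independent of magnitude.
#'
#' @param x,d numeric vectors of equal length, both nonzero.
#' @return Angle in radians.
#' @examples
#' sam_angle(c(1, 1), c(1, 0))  # pi / 4
#' @export
sam_angle <- function(x, d) {
  nx <- sqrt(sum(x^2))
  nd <- sqrt(sum(d^2))
  if (nx == 0 || nd == 0) stop("spectral angle is undefined for a zero vector")
  acos(min(1, max(-1, sum(x * d) / (nx * nd))))
}

#' Pool a training signature by spectral-angle matching
#'
#' Averages all pixel spectra within `angle_threshold` radians of the
#' seed signature (seed always included), turning a single possibly
#' unrepresentative seed pixel into a stable target signature.
#'
#' @param X N x L matrix of pixel spectra.
#' @param seed either a row index into `X` or a length-L signature.
#' @param angle_threshold inclusion threshold in radians.
#' @return Length-L averaged signature.
#' @export
pool_training_signature <- function(X, seed, angle_threshold) {
  stopifnot(angle_threshold >= 0)
  if (length(seed) == 1 && seed == round(seed)) {
    seed_idx <- as.integer(seed)
    d <- X[seed_idx, ]
  } else {
    seed_idx <- integer(0)
    d <- as.numeric(seed)
  }
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("seed signature is zero")
  nx <- sqrt(rowSums(X^2))
  cosang <- (X %*% d) / (pmax(nx, .Machine$double.eps) * nd)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  ang[nx == 0] <- pi  # zero pixels never match
  sel <- union(seed_idx, which(ang <= angle_threshold + 1e-12))
  if (length(sel) == 0) return(d)
  colMeans(X[sel, , drop = FALSE])
}

#' Constrained energy minimization (CEM) filter
#'
#' The linear filter `w` with unit response to the target signature
#' (`w' d = 1`) that minimizes the average output energy over the image,
#' `w' R w`, where `R = X'X / N` is the sample autocorrelation matrix.
#' Closed form: `w = R^-1 d / (d' R^-1 d)`. Unknown background signatures
#' are thereby suppressed while the target is passed at unit gain.
#'
#' @param X N x L matrix of pixel spectra.
#' @param d length-L target signature.
#' @param ridge non-negative diagonal loading added to `R` (use e.g.
#'   `1e-6 * mean(diag(R))` when `R` is ill-conditioned; default 0).
#' @return List with `weights` (length L), `scores` (length N filter
#'   output per pixel) and `R`.
#' @export
cem_filter <- function(X, d, ridge = 0) {
  stopifnot(is.matrix(X), length(d) == ncol(X), ridge >= 0)
  N <- nrow(X)
  R <- crossprod(X) / N
  if (ridge > 0) R <- R + diag(ridge, ncol(X))
  Rinv_d <- tryCatch(
    solve(R, d),
    error = function(e) stop(
      "autocorrelation matrix is singular; supply a positive `ridge` ",
      "(e.g. 1e-6 * mean(diag(R)))", call. = FALSE)
  )
  denom <- sum(d * Rinv_d)
  w <- Rinv_d / denom
  if (abs(sum(w * d) - 1) > 1e-10) {
    stop("unity constraint violated beyond tolerance; the problem is ",
         "too ill-conditioned, increase `ridge`")
  }
  list(weights = as.numeric(w), scores = as.numeric(X %*% w), R = R)
}

#' Otsu threshold of a value set
#'
#' Picks, among 256 histogram-bin cut points, the threshold maximizing
#' the between-class variance `w0 * w1 * (mu0 - mu1)^2`, with class
#' statistics computed from the actual values on each side of the cut.
#' Ties resolve to the lowest threshold.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins number of histogram bins spanning the value range
#'   (default 256).
#' @return List with `threshold` and `binary` (`values > threshold`).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)))
  rng <- range(values)
  if (rng[1] == rng[2]) stop("cannot threshold a constant value set")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cand <- edges[2:n_bins]
  vs <- sort(values)
  n <- length(vs)
  cs <- cumsum(vs)
  n0 <- findInterval(cand, vs)  # count of values <= candidate
  valid <- n0 > 0 & n0 < n
  s0 <- cs[pmax(n0, 1)]
  mu0 <- s0 / n0
  mu1 <- (cs[n] - s0) / (n - n0)
  bcv <- (n0 / n) * ((n - n0) / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  if (all(!is.finite(bcv))) stop("degenerate input: no valid threshold")
  thr <- cand[which.max(bcv)]  # first max = lowest threshold on ties
  list(threshold = thr, binary = values > thr)
}

# Shared target seeding for the CEM-family detectors: ATGP finds
# candidate extreme pixels; the tumor seed is the candidate with the
# highest mean high-b intensity (lesions stay bright at strong diffusion
# weighting); SAM pooling stabilizes it into the training signature.
initial_target_signature <- function(X, idx, cube, mask,
                                     n_targets = 5, sam_threshold = 0.10) {
  at <- suppressWarnings(atgp(X, n_targets))
  bv <- cube$bvalues
  high <- which(bv >= 0.4 * max(bv))
  d2 <- dim(cube$data)
  flat <- matrix(cube$data, d2[1] * d2[2], d2[3])
  score <- rowMeans(flat[idx[at$indices], high, drop = FALSE])
  seed_row <- at$indices[which.max(score)]
  d <- pool_training_signature(X, seed_row, sam_threshold)
  list(signature = d, seed_row = seed_row, atgp = at)
}

default_ridge <- function(X) {
  R_tr <- sum(colMeans(X^2))
  1e-6 * R_tr / ncol(X)
}

#' Iterative CEM (I-CEM) tumor detection
#'
#' Runs the CEM filter with an ATGP/SAM-seeded target signature, Otsu-
#' binarizes the detection map, then refines the signature by averaging
#' the spectra of a random 10% subsample of the detected pixels —
#' stabilized by the same spectral-angle pooling used for the initial
#' seed, so that a small resample does not inject pixel noise into the
#' target — and repeats. Iteration stops when the fraction of
#' breast-mask pixels whose binary label changed between consecutive
#' passes drops to `diff_tol` (default 1%) or `max_iter` is reached.
#' This removes the sensitivity of a single CEM pass to the initial
#' seed pixel.
#'
#' @param cube a [bvalue_cube()].
#' @param breast_mask logical H x W mask of pixels to process.
#' @param bep apply the band expansion process first (default TRUE).
#' @param resample_fraction fraction of detected pixels re-averaged into
#'   the next target signature (default 0.10).
#' @param diff_tol convergence threshold on the label-change rate
#'   (default 0.01).
#' @param max_iter iteration cap (default 50).
#' @param n_targets,sam_threshold seeding parameters, see
#'   [pool_training_signature()].
#' @param ridge diagonal loading for [cem_filter()]; default
#'   `1e-6 * trace(R) / L`.
#' @param seed RNG seed for the resampling; fixed seed, identical result.
#' @return List with `mask` (logical H x W), `map` (detection scores on
#'   the grid), `signature`, and `log` (data.frame with per-iteration
#'   threshold, positive count and difference rate).
#' @export
icem <- function(cube, breast_mask, bep = TRUE,
                 resample_fraction = 0.10, diff_tol = 0.01, max_iter = 50,
                 n_targets = 5, sam_threshold = 0.10,
                 ridge = NULL, seed = 1L) {
  stopifnot(resample_fraction > 0, resample_fraction <= 1)
  work <- if (bep) expand_bands(cube) else cube
  px <- cube_pixels(work, breast_mask)
  X <- px$X
  N <- nrow(X)
  ridge <- ridge %||% default_ridge(X)
  init <- initial_target_signature(X, px$idx, cube, breast_mask,
                                   n_targets, sam_threshold)
  d <- init$signature
  with_seed(seed, {
    prev <- NULL
    log_rows <- list()
    y <- NULL
    for (it in seq_len(max_iter)) {
      y <- cem_filter(X, d, ridge)$scores
      ot <- otsu_threshold(y)
      pos <- ot$binary
      npos <- sum(pos)
      if (npos == 0) {
        stop("empty detection at iteration ", it,
             ": Otsu found no pixels above threshold")
      }
      diff_rate <- if (is.null(prev)) NA_real_ else mean(pos != prev)
      log_rows[[it]] <- data.frame(iteration = it,
                                   threshold = ot$threshold,
                                   n_positive = npos,
                                   diff_rate = diff_rate)
      if (!is.null(prev) && diff_rate <= diff_tol) break
      prev <- pos
      ns <- ceiling(resample_fraction * npos)
      samp <- which(pos)[sample.int(npos, ns)]
      d <- pool_training_signature(X, colMeans(X[samp, , drop = FALSE]),
                                   sam_threshold)
    }
    d2 <- dim(cube$data)
    list(mask = map_from_values(pos, px$idx, d2, fill = FALSE) > 0,
         map = map_from_values(y, px$idx, d2),
         signature = d,
         log = do.call(rbind, log_rows))
  })
}

#' Kernel CEM (K-CEM) detection map
#'
#' CEM carried out in a kernel-induced feature space: with a seeded
#' subsample S of pixels and Gram matrix `K` over S, the detector output
#' at pixel r is
#' `y(r) = k_d' (K + ridge I)^-2 k_r / (k_d' (K + ridge I)^-2 k_d)`,
#' where `k_v = [k(s, v)]` over `s` in S. This is the feature-space
#' analogue of `d' R^-1 x / (d' R^-1 d)` (the squared inverse arises
#' because the feature-space autocorrelation is Phi'Phi while the Gram
#' matrix is Phi Phi'); with a linear kernel it reproduces the linear CEM
#' map, and the output at `r = d` is exactly 1. The default kernel is a
#' Gaussian RBF with sigma set to the root-mean-square pairwise distance
#' of the subsample, so `2 sigma^2` equals the mean squared pixel
#' separation; with the strongly clustered backgrounds of
#' diffusion-weighted cubes this keeps the kernel flat within a tissue
#' class while separating classes. The Gram ridge defaults to
#' `0.1 * trace(K) / m`: kernel detection maps need much heavier
#' diagonal loading than linear CEM because `(K + ridge I)^-2` otherwise
#' amplifies the noise directions of the nearly low-rank Gram matrix
#' into the per-pixel scores.
#'
#' @param cube a [bvalue_cube()].
#' @param breast_mask logical H x W mask of pixels to process.
#' @param d target signature in the (expanded) band space, or `NULL` to
#'   derive one by ATGP + SAM pooling.
#' @param bep apply the band expansion process first (default TRUE).
#' @param kernel `"rbf"` or `"linear"`.
#' @param sigma RBF bandwidth: a number, `"rms"` (default,
#'   root-mean-square pairwise distance of the subsample) or `"median"`
#'   (median pairwise distance).
#' @param sample_size Gram subsample size (default `min(N, 1000)`).
#' @param ridge diagonal loading of the Gram matrix; default
#'   `0.1 * trace(K) / m`.
#' @param n_targets,sam_threshold seeding parameters when `d` is NULL.
#' @param seed RNG seed for the subsample.
#' @return List with `map` (H x W detection scores), `mask` (Otsu-
#'   binarized map over the breast mask), `signature`, `sigma` and the
#'   subsample row indices `sample_rows`.
#' @export
kcem <- function(cube, breast_mask, d = NULL, bep = TRUE,
                 kernel = c("rbf", "linear"), sigma = "rms",
                 sample_size = 1000, ridge = NULL,
                 n_targets = 5, sam_threshold = 0.10, seed = 1L) {
  kernel <- match.arg(kernel)
  work <- if (bep) expand_bands(cube) else cube
  px <- cube_pixels(work, breast_mask)
  X <- px$X
  N <- nrow(X)
  if (is.null(d)) {
    d <- initial_target_signature(X, px$idx, cube, breast_mask,
                                  n_targets, sam_threshold)$signature
  }
  stopifnot(length(d) == ncol(X), sample_size >= 1)
  m <- min(sample_size, N)
  rows <- with_seed(seed, sort(sample.int(N, m)))
  S <- X[rows, , drop = FALSE]

  sq <- function(A) rowSums(A^2)
  cross_d2 <- function(A, B) {
    # squared Euclidean distances between rows of A and rows of B
    outer(sq(A), sq(B), "+") - 2 * tcrossprod(A, B)
  }
  if (kernel == "rbf") {
    D2_ss <- pmax(cross_d2(S, S), 0)
    if (identical(sigma, "rms")) {
      sigma <- sqrt(mean(D2_ss[upper.tri(D2_ss)]))
    } else if (identical(sigma, "median")) {
      sigma <- sqrt(stats::median(D2_ss[upper.tri(D2_ss)]))
    }
    if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
    kfun <- function(D2) exp(-pmax(D2, 0) / (2 * sigma^2))
    K <- kfun(D2_ss)
    K_xs <- kfun(cross_d2(X, S))
    k_d <- kfun(pmax(sq(S) + sum(d^2) - 2 * as.numeric(S %*% d), 0))
  } else {
    sigma <- NA_real_
    K <- tcrossprod(S)
    K_xs <- tcrossprod(X, S)
    k_d <- as.numeric(S %*% d)
  }
  ridge <- ridge %||% (0.1 * sum(diag(K)) / m)
  A <- K + diag(ridge, m)
  alpha <- solve(A, solve(A, k_d))  # (K + ridge I)^-2 k_d
  denom <- sum(k_d * alpha)
  y <- as.numeric(K_xs %*% alpha) / denom
  ot <- otsu_threshold(y)
  d2 <- dim(cube$data)
  list(map = map_from_values(y, px$idx, d2),
       mask = map_from_values(ot$binary, px$idx, d2, fill = FALSE) > 0,
       signature = d, sigma = sigma, sample_rows = rows)
}
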