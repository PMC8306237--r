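# Seeded k-means++ center initialization (shared by both clusterers).
kmeanspp_init <- function(X, k) {
  N <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(N, 1)
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / N, N)
    pick <- sample.int(N, 1, prob = probs)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

pair_d2 <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
}

#' K-means clustering of pixel spectra
#'
#' Lloyd iterations from a seeded k-means++ initialization, recording the
#' within-cluster sum-of-squares objective at every iteration (the trace
#' is non-increasing). Deterministic given the seed.
#'
#' @param X N x L matrix of pixel spectra.
#' @param k number of clusters (default 3: background-like, normal
#'   tissue, lesion).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 300).
#' @param tol stop when the largest centroid displacement falls below
#'   this (default 1e-4).
#' @return List of class `cluster_result` with `labels` (1..k per row),
#'   `centers` (k x L), `objective` (per-iteration trace) and
#'   `membership = NULL`.
#' @export
kmeans_cluster <- function(X, k = 3, seed = 1L, max_iter = 300,
                           tol = 1e-4) {
  stopifnot(is.matrix(X), k >= 1)
  N <- nrow(X)
  if (N < k) stop("need at least as many pixels as clusters")
  with_seed(seed, {
    C <- kmeanspp_init(X, k)
    objective <- numeric(0)
    labels <- integer(N)
    for (it in seq_len(max_iter)) {
      d2 <- pmax(pair_d2(X, C), 0)
      labels <- max.col(-d2, ties.method = "first")
      objective <- c(objective, sum(d2[cbind(seq_len(N), labels)]))
      C_new <- C
      for (j in seq_len(k)) {
        sel <- labels == j
        if (any(sel)) {
          C_new[j, ] <- colMeans(X[sel, , drop = FALSE])
        } else {
          # re-seed an empty cluster at the worst-fit point
          C_new[j, ] <- X[which.max(d2[cbind(seq_len(N), labels)]), ]
        }
      }
      shift <- sqrt(max(rowSums((C_new - C)^2)))
      C <- C_new
      if (shift < tol) break
    }
    structure(list(labels = labels, centers = C, membership = NULL,
                   objective = objective, k = k),
              class = "cluster_result")
  })
}

#' Fuzzy C-means clustering of pixel spectra
#'
#' Standard alternating updates with fuzziness exponent `m`:
#' memberships `u_ij = 1 / sum_l (|x_i - v_j| / |x_i - v_l|)^(2/(m-1))`
#' and centers `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`. A pixel exactly
#' on a center receives membership 1 there and 0 elsewhere. Stops when
#' the largest membership change falls below `tol`.
#'
#' @param X N x L matrix of pixel spectra.
#' @param c number of clusters (default 3).
#' @param m fuzziness exponent (> 1; default 2).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 300).
#' @param tol stop threshold on the max membership change (default 1e-5).
#' @return List of class `cluster_result` with `labels` (argmax
#'   membership), `membership` (N x c, rows sum to 1), `centers` and the
#'   `objective` trace.
#' @export
fcm_cluster <- function(X, c = 3, m = 2, seed = 1L, max_iter = 300,
                        tol = 1e-5) {
  stopifnot(is.matrix(X), c >= 2, m > 1)
  N <- nrow(X)
  if (N < c) stop("need at least as many pixels as clusters")
  with_seed(seed, {
    C <- kmeanspp_init(X, c)
    U <- matrix(1 / c, N, c)
    objective <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- pmax(pair_d2(X, C), 0)
      on_center <- d2 < .Machine$double.eps
      inv <- d2^(-1 / (m - 1))
      U_new <- inv / rowSums(inv)
      hit <- rowSums(on_center) > 0
      if (any(hit)) {
        U_new[hit, ] <- on_center[hit, , drop = FALSE] /
          rowSums(on_center[hit, , drop = FALSE])
      }
      objective <- c(objective, sum(U_new^m * d2))
      delta <- max(abs(U_new - U))
      U <- U_new
      Um <- U^m
      C <- (t(Um) %*% X) / colSums(Um)
      if (delta < tol) break
    }
    structure(list(labels = max.col(U, ties.method = "first"),
                   centers = C, membership = U,
                   objective = objective, k = c),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, %d pixels, %d iterations, final objective %.4g\n",
              x$k, length(x$labels), length(x$objective),
              utils::tail(x$objective, 1)))
  invisible(x)
}

#' Identify the tumor cluster and binarize it
#'
#' Anchors the tumor cluster with ATGP: the cluster containing the
#' ATGP-selected tumor seed pixel is taken as the lesion cluster (so no
#' fixed label index is ever relied on). The cluster is then rendered as
#' a grayscale image (b = 0 intensity on cluster pixels, 0 elsewhere
#' within the breast mask) and Otsu-binarized, which trims dim stragglers
#' from a mixed cluster.
#'
#' @param clustering a `cluster_result` from [kmeans_cluster()] or
#'   [fcm_cluster()], computed on the breast-mask pixels of `cube`.
#' @param X the N x L pixel matrix the clustering ran on.
#' @param cube the source [bvalue_cube()].
#' @param breast_mask logical H x W mask matching `X`'s pixels.
#' @param n_targets ATGP candidate count (default 5).
#' @return Logical H x W tumor mask (subset of the breast mask).
#' @export
pick_tumor_cluster <- function(clustering, X, cube, breast_mask,
                               n_targets = 5) {
  px <- cube_pixels(cube, breast_mask)
  stopifnot(length(clustering$labels) == nrow(X),
            nrow(px$X) == nrow(X))
  if (length(unique(clustering$labels)) == 1) {
    warning("single-cluster result: returning the whole breast region")
    return(breast_mask)
  }
  seed_row <- initial_target_signature(X, px$idx, cube, breast_mask,
                                       n_targets = n_targets,
                                       sam_threshold = 0)$seed_row
  cid <- clustering$labels[seed_row]
  in_cluster <- clustering$labels == cid
  d2 <- dim(cube$data)
  b0 <- cube$data[, , 1]
  gray <- numeric(nrow(X))
  gray[in_cluster] <- b0[px$idx[in_cluster]]
  ot <- otsu_threshold(gray)
  keep <- ot$binary & in_cluster
  map_from_values(keep, px$idx, d2, fill = FALSE) > 0
}
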