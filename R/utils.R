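# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Integer translation of a matrix: content moves dy rows down, dx columns
# right; vacated pixels take `fill`.
shift_image <- function(mat, dy, dx, fill = 0) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dy):min(nr, nr + dy)
  c_dst <- max(1L, 1L + dx):min(nc, nc + dx)
  if (length(r_dst) < 1 || length(c_dst) < 1 ||
      abs(dy) >= nr || abs(dx) >= nc) {
    return(out)
  }
  out[r_dst, c_dst] <- mat[r_dst - dy, c_dst - dx]
  out
}

# 2-D polynomial design matrix on centered/scaled pixel coordinates.
# Rows follow column-major matrix order so fitted values drop straight
# back into a matrix of the original shape.
poly2d_design <- function(nr, nc, order) {
  stopifnot(order %in% 1:3)
  u <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  v <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  U <- matrix(rep(u, nc), nr, nc)
  V <- matrix(rep(v, each = nr), nr, nc)
  cols <- list(`1` = rep(1, nr * nc), u = c(U), v = c(V))
  if (order >= 2) {
    cols <- c(cols, list(uu = c(U * U), uv = c(U * V), vv = c(V * V)))
  }
  if (order >= 3) {
    cols <- c(cols, list(uuu = c(U^3), uuv = c(U^2 * V),
                         uvv = c(U * V^2), vvv = c(V^3)))
  }
  do.call(cbind, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3x3 mean filter (zero-padded edges); used to stabilize correlation
# scoring on noise-dominated bands.
box_blur <- function(mat) {
  acc <- matrix(0, nrow(mat), ncol(mat))
  for (dy in -1:1) {
    for (dx in -1:1) {
      acc <- acc + shift_image(mat, dy, dx)
    }
  }
  acc / 9
}
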