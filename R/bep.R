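#' Number of bands after the band expansion process
#'
#' Original bands plus elementwise squares plus pairwise products:
#' `B + B + B(B-1)/2 = (B^2 + 3B) / 2`. For the 13-band acquisition this
#' gives 104 bands (13 original + 13 auto-correlation +
#' 78 cross-correlation).
#'
#' @param B original band count (>= 1).
#' @return Integer expanded band count.
#' @examples
#' expanded_band_count(13)  # 104
#' @export
expanded_band_count <- function(B) {
  B <- as.integer(B)
  if (length(B) != 1 || is.na(B) || B < 1) stop("B must be an integer >= 1")
  as.integer((B^2 + 3 * B) / 2)
}

#' Band expansion process (BEP)
#'
#' Augments a B-band cube with second-order correlation bands: the
#' elementwise square of each band (auto-correlation) and the elementwise
#' product of each band pair i < j (cross-correlation), exposing
#' second-order statistics to the linear detectors downstream. Band order
#' is originals, then autos, then crosses in lexicographic (i, j).
#'
#' Because products square the dynamic range, some rescaling is needed
#' before the expanded bands enter correlation matrices. The default
#' (`normalize = "global"`) divides the cube by its global maximum before
#' forming products, which bounds every band by 1 without touching the
#' relative scale of the bands: per-band rescaling (`"minmax"`) would
#' stretch the noise-dominated high-b product bands to full range and
#' drown the spectral structure the detectors rely on. `"none"` returns
#' raw products.
#'
#' @param cube a [bvalue_cube()] (or bare H x W x B array).
#' @param normalize `"global"` (default), `"minmax"`, or `"none"`;
#'   `TRUE`/`FALSE` are accepted as aliases for `"minmax"`/`"none"`.
#' @return An object of class `expanded_cube`: list with `data`
#'   (H x W x L), `band_labels` (data.frame with `kind`, `i`, `j`,
#'   `name`) and the source `bvalues` when available.
#' @export
expand_bands <- function(cube, normalize = "global") {
  if (isTRUE(normalize)) normalize <- "minmax"
  if (isFALSE(normalize)) normalize <- "none"
  normalize <- match.arg(normalize, c("global", "minmax", "none"))
  arr <- cube_data(cube)
  storage.mode(arr) <- "double"
  if (normalize == "global" && max(arr) > 0) arr <- arr / max(arr)
  d <- dim(arr)
  B <- d[3]
  L <- expanded_band_count(B)
  out <- array(0, c(d[1], d[2], L))
  labels <- data.frame(kind = character(L), i = integer(L), j = integer(L),
                       name = character(L), stringsAsFactors = FALSE)
  out[, , seq_len(B)] <- arr
  labels[seq_len(B), ] <- data.frame("original", seq_len(B), NA_integer_,
                                     sprintf("b%d", seq_len(B)))
  pos <- B
  for (i in seq_len(B)) {
    pos <- pos + 1L
    out[, , pos] <- arr[, , i] * arr[, , i]
    labels[pos, ] <- data.frame("auto", i, i, sprintf("b%dxb%d", i, i))
  }
  if (B >= 2) {
    for (i in seq_len(B - 1)) {
      for (j in (i + 1):B) {
        pos <- pos + 1L
        out[, , pos] <- arr[, , i] * arr[, , j]
        labels[pos, ] <- data.frame("cross", i, j, sprintf("b%dxb%d", i, j))
      }
    }
  }
  stopifnot(pos == L)
  if (normalize == "minmax") {
    for (l in seq_len(L)) {
      band <- out[, , l]
      rng <- range(band)
      out[, , l] <- if (rng[2] > rng[1]) {
        (band - rng[1]) / (rng[2] - rng[1])
      } else {
        band * 0
      }
    }
  }
  structure(list(data = out, band_labels = labels,
                 bvalues = if (is.array(cube)) NULL else cube$bvalues),
            class = "expanded_cube")
}

#' @export
print.expanded_cube <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(x$band_labels$kind)
  cat(sprintf("<expanded_cube> %d x %d pixels, %d bands (%s)\n",
              d[1], d[2], d[3],
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}
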