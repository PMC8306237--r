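#' Construct a b-value image cube
#'
#' The central container of the package: an H x W x B stack of
#' diffusion-weighted band images, one band per diffusion weighting
#' (b-value), ordered by increasing b with the unweighted (b = 0) image
#' first. Each pixel is then a length-B spectral vector, so the stack can
#' be treated as a multispectral image cube.
#'
#' @param data numeric H x W x B array of non-negative intensities.
#' @param bvalues numeric vector of length B, strictly increasing, with
#'   `bvalues[1] == 0` (s/mm^2).
#' @return An object of class `bvalue_cube`: a list with elements `data`
#'   and `bvalues`.
#' @examples
#' cube <- bvalue_cube(array(1, c(4, 4, 3)), c(0, 500, 1000))
#' n_bands(cube)
#' @export
bvalue_cube <- function(data, bvalues) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be an H x W x B array")
  }
  bvalues <- as.numeric(bvalues)
  if (dim(data)[3] != length(bvalues)) {
    stop(sprintf("band count (%d) does not match b-value count (%d)",
                 dim(data)[3], length(bvalues)))
  }
  if (length(bvalues) < 1 || any(diff(bvalues) <= 0)) {
    stop("b-values must be strictly increasing")
  }
  if (bvalues[1] != 0) stop("the first b-value must be 0")
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(data = data, bvalues = bvalues), class = "bvalue_cube")
}

#' @export
print.bvalue_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bvalue_cube> %d x %d pixels, %d bands (b = %s s/mm^2)\n",
              d[1], d[2], d[3],
              paste(format(x$bvalues, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Number of bands in a cube
#' @param cube a `bvalue_cube` or `expanded_cube`.
#' @return Integer band count.
#' @export
n_bands <- function(cube) dim(cube$data)[3]

# Pull the H x W x L array out of either cube flavour.
cube_data <- function(cube) {
  if (is.array(cube)) cube else cube$data
}

#' Flatten masked cube pixels into a spectral matrix
#'
#' @param cube a `bvalue_cube` or `expanded_cube`.
#' @param mask logical H x W matrix selecting pixels; `NULL` selects all.
#' @return List with `X`, an N x L matrix whose rows are pixel spectra,
#'   and `idx`, the column-major flat indices of those pixels in the
#'   H x W grid (used to scatter results back into images).
#' @export
cube_pixels <- function(cube, mask = NULL) {
  arr <- cube_data(cube)
  d <- dim(arr)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(mask), d[1:2]))
  idx <- which(mask)
  X <- matrix(arr, d[1] * d[2], d[3])[idx, , drop = FALSE]
  list(X = X, idx = idx)
}

# Scatter a per-masked-pixel vector back onto the H x W grid.
map_from_values <- function(values, idx, dim2, fill = 0) {
  out <- matrix(fill, dim2[1], dim2[2])
  out[idx] <- values
  out
}

#' Read a b-value cube from NIfTI plus a b-value text file
#'
#' The NIfTI volume may be H x W x B or H x W x 1 x B (one slice); the
#' side-car text file carries one b-value per line in band order.
#'
#' @param nifti_path path to a `.nii`/`.nii.gz` file.
#' @param bval_path path to a plain-text b-value file.
#' @return A [bvalue_cube()].
#' @export
read_cube <- function(nifti_path, bval_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4) {
    if (d[3] != 1) stop("4-D input must be a single slice (H x W x 1 x B)")
    arr <- array(arr, c(d[1], d[2], d[4]))
  } else if (length(d) != 3) {
    stop("NIfTI input must be 3-D or 4-D")
  }
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (length(bvals) != dim(arr)[3]) {
    stop(sprintf("NIfTI has %d bands but the b-value file lists %d values",
                 dim(arr)[3], length(bvals)))
  }
  bvalue_cube(arr, bvals)
}

#' Write a b-value cube to NIfTI plus a b-value text file
#'
#' @param cube a [bvalue_cube()].
#' @param nifti_path output NIfTI path; the cube is stored H x W x 1 x B
#'   with the fourth dimension indexing b.
#' @param bval_path output text path, one b-value per line.
#' @return Invisibly, the NIfTI path.
#' @export
write_cube <- function(cube, nifti_path, bval_path) {
  d <- dim(cube$data)
  arr <- array(cube$data, c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(arr, nifti_path)
  writeLines(format(cube$bvalues, trim = TRUE, scientific = FALSE),
             bval_path)
  invisible(nifti_path)
}

#' Write a binary mask as NIfTI
#' @param mask logical H x W matrix.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(array(as.integer(mask), dim(mask)), path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path NIfTI path holding a 2-D (or single-slice) volume.
#' @return Logical H x W matrix.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) > 2) arr <- array(arr, d[1:2])
  matrix(arr != 0, nrow(arr), ncol(arr))
}
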