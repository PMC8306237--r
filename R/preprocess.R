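#' Polynomial bias-field correction
#'
#' Estimates a smooth multiplicative intensity non-uniformity field by
#' robustly fitting a low-order 2-D polynomial to the log-intensity of
#' the b = 0 band over foreground pixels, then divides every band by the
#' exponentiated fit normalized to mean 1. The robust (bisquare) fit
#' keeps compact hyperintense structures such as lesions from bending the
#' estimated field. This is a deliberately simple stand-in for full
#' histogram-sharpening bias correction (N3/N4) and is matched to the
#' smooth polynomial non-uniformity the phantom generates.
#'
#' @param cube a [bvalue_cube()].
#' @param order polynomial order, 1..3 (default 2).
#' @return List with the corrected `cube` and the estimated `field`
#'   (H x W matrix, mean 1 over the foreground).
#' @export
correct_bias <- function(cube, order = 2) {
  stopifnot(order %in% 1:3)
  b0 <- cube$data[, , 1]
  if (!any(b0 > 0)) stop("no foreground: the b = 0 band is all zero")
  fg <- b0 > 0.05 * stats::quantile(b0[b0 > 0], 0.99)
  if (!any(fg)) stop("no foreground pixels above threshold")
  d <- dim(cube$data)
  G <- poly2d_design(d[1], d[2], order)
  y <- log(b0[fg])
  Gf <- G[which(fg), , drop = FALSE]
  coefs <- tryCatch(
    MASS::rlm(Gf, y, psi = MASS::psi.bisquare, maxit = 100)$coefficients,
    error = function(e) stats::lm.fit(Gf, y)$coefficients
  )
  coefs[!is.finite(coefs)] <- 0
  logf <- as.vector(G %*% coefs)
  field <- matrix(exp(logf - mean(logf[which(fg)])), d[1], d[2])
  field <- field / mean(field[fg])
  corrected <- cube$data / as.vector(field)
  list(cube = bvalue_cube(corrected, cube$bvalues), field = field)
}

#' Register bands by exhaustive integer-translation search
#'
#' For every band, finds the integer `(dy, dx)` within
#' `[-max_shift, max_shift]^2` that maximizes the correlation with the
#' previously registered neighbouring band and undoes it, so that all
#' bands end up in the frame of the b = 0 reference (which is never
#' moved). Matching each band against its b-neighbour rather than
#' directly against b = 0 matters at strong diffusion weighting, where
#' tissue contrast has decayed so far from the unweighted image that a
#' direct correlation surface is nearly flat; neighbouring b-values
#' share contrast and give a sharp peak. Correlations are scored on
#' lightly box-smoothed copies of the images, restricted to the
#' informative region of the anchor (its top intensity quartile), so
#' that the score is not diluted by the noise-only background; the
#' chosen shift is applied to the raw band. This corrects the in-plane
#' translational drift that breathing introduces between the band
#' acquisitions; rotation and subpixel motion are out of scope.
#'
#' @param cube a [bvalue_cube()].
#' @param reference reference band index (default 1, the b = 0 band).
#' @param max_shift search radius in pixels (default 5).
#' @return List with the registered `cube` and `shifts`, a B x 2 matrix of
#'   the estimated original displacements (so a phantom's applied shifts
#'   are recovered as-is; the reference row is `(0, 0)`).
#' @export
register_bands <- function(cube, reference = 1, max_shift = 5) {
  stopifnot(max_shift >= 0)
  B <- n_bands(cube)
  ref <- cube$data[, , reference]
  data <- cube$data
  est <- matrix(0L, B, 2)
  if (max_shift == 0) return(list(cube = cube, shifts = est))
  if (stats::sd(as.vector(ref)) == 0) {
    warning("reference band has zero variance; no registration applied")
    return(list(cube = cube, shifts = est))
  }
  offsets <- -max_shift:max_shift
  # visit bands outward from the reference so each is matched against an
  # already-registered neighbour of similar diffusion contrast
  order_out <- c(
    if (reference < B) (reference + 1):B,
    if (reference > 1) (reference - 1):1
  )
  prev <- reference
  for (j in order_out) {
    if (sign(j - reference) != sign(prev - reference)) prev <- reference
    anchor <- box_blur(data[, , prev])
    region <- anchor > stats::quantile(anchor, 0.75)
    anchor_v <- anchor[region]
    band <- data[, , j]
    if (stats::sd(as.vector(band)) == 0) {
      warning(sprintf("band %d is flat; assuming shift (0, 0)", j))
      prev <- j
      next
    }
    smoothed <- box_blur(band)
    best <- c(0L, 0L)
    best_score <- -Inf
    for (dy in offsets) {
      for (dx in offsets) {
        score <- stats::cor(shift_image(smoothed, dy, dx)[region],
                            anchor_v)
        if (is.finite(score) && score > best_score) {
          best_score <- score
          best <- c(dy, dx)
        }
      }
    }
    data[, , j] <- shift_image(band, best[1], best[2])
    est[j, ] <- -best  # displacement the band had relative to the reference
    prev <- j
  }
  list(cube = bvalue_cube(data, cube$bvalues), shifts = est)
}

#' Extract the breast region from a cube
#'
#' Thresholds the b = 0 band with Otsu's method, keeps the largest
#' connected foreground component, fills interior holes and erodes the
#' rim to discard the skin-line, yielding the pixel set every detector
#' operates on.
#'
#' @param cube a [bvalue_cube()].
#' @param erode_px rim erosion in pixels (default 1; 0 disables).
#' @return Logical H x W breast mask.
#' @export
extract_breast_mask <- function(cube, erode_px = 1) {
  b0 <- cube$data[, , 1]
  ot <- otsu_threshold(as.vector(b0))
  fg <- b0 > ot$threshold
  if (!any(fg)) stop("no foreground after thresholding")
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  m <- EBImage::fillHull(m)
  if (erode_px > 0) {
    m <- EBImage::erode(m, EBImage::makeBrush(2 * erode_px + 1, "diamond"))
  }
  mask <- matrix(as.logical(m > 0), nrow(b0), ncol(b0))
  if (!any(mask)) stop("breast mask is empty after morphology")
  mask
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: bias-field correction, then inter-band
#' registration, then breast-region extraction.
#'
#' @param cube a [bvalue_cube()].
#' @param bias_order polynomial order for [correct_bias()].
#' @param max_shift search radius for [register_bands()].
#' @param erode_px rim erosion for [extract_breast_mask()].
#' @return List with the preprocessed `cube`, estimated bias `field`,
#'   estimated `shifts` and the `breast_mask`.
#' @export
preprocess_cube <- function(cube, bias_order = 2, max_shift = 5,
                            erode_px = 1) {
  bc <- correct_bias(cube, order = bias_order)
  rg <- register_bands(bc$cube, max_shift = max_shift)
  mask <- extract_breast_mask(rg$cube, erode_px = erode_px)
  list(cube = rg$cube, field = bc$field, shifts = rg$shifts,
       breast_mask = mask)
}
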