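#' IVIM tissue parameter presets
#'
#' Per-class bi-exponential signal parameters used by the digital phantom.
#' Lesion rows (mass, non-mass, fibroadenoma, cyst) carry literature IVIM
#' values for those breast lesion types; the `normal` parenchyma row and
#' all `S0` baselines are package defaults chosen so that lesions are
#' hyperintense on diffusion-weighted images, as they typically are.
#' Background is signal-free (S0 = 0), so under Rician noise it becomes a
#' Rayleigh-distributed noise floor.
#'
#' @return A data.frame with columns `class`, `S0` (arbitrary units),
#'   `D` (mm^2/s), `Dstar` (mm^2/s) and `PF` (dimensionless fraction).
#' @examples
#' ivim_presets()
#' @export
ivim_presets <- function() {
  p <- data.frame(
    class = c("background", "normal", "mass", "nonmass", "fibroadenoma",
              "cyst"),
    S0    = c(0,    0.60, 1.00,    0.80,    1.00,    1.00),
    D     = c(0, 1.80e-3, 0.84e-3, 1.03e-3, 1.26e-3, 1.36e-3),
    Dstar = c(0, 1.00e-2, 6.10e-3, 7.53e-3, 4.09e-3, 4.38e-3),
    PF    = c(0,    0.05,    0.23,    0.31,    0.45,    0.52),
    stringsAsFactors = FALSE
  )
  stopifnot(all(p$PF >= 0 & p$PF <= 1), all(p$D >= 0), all(p$Dstar >= 0))
  p
}

#' Default acquisition b-values
#'
#' The 13 diffusion weightings of the breast protocol the package targets:
#' 0 to 2500 s/mm^2 with dense sampling at low b where perfusion dominates.
#'
#' @return Numeric vector of 13 b-values (s/mm^2).
#' @export
default_bvalues <- function() {
  c(0, 15, 30, 45, 60, 100, 200, 400, 600, 1000, 1500, 2000, 2500)
}

#' Bi-exponential IVIM signal
#'
#' Signal of the two-compartment IVIM model:
#' `S(b) = S0 * ((1 - PF) * exp(-b * D) + PF * exp(-b * Dstar))`,
#' where `D` is the pure diffusion coefficient, `Dstar` the
#' pseudo-diffusion coefficient of capillary perfusion and `PF` the
#' perfusion fraction.
#'
#' @param b b-value(s) (s/mm^2).
#' @param S0 baseline signal at b = 0.
#' @param D,Dstar diffusion and pseudo-diffusion coefficients (mm^2/s).
#' @param PF perfusion fraction in `[0, 1]`.
#' @return Signal value(s), same length as `b`.
#' @export
ivim_signal <- function(b, S0, D, Dstar, PF) {
  stopifnot(PF >= 0, PF <= 1, D >= 0, Dstar >= 0, S0 >= 0)
  S0 * ((1 - PF) * exp(-b * D) + PF * exp(-b * Dstar))
}

ellipse_mask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

#' Build a tissue label map for the phantom
#'
#' Lays out a background / normal-parenchyma / lesion label map on a pixel
#' grid: an elliptical "breast" region filled with normal tissue, inside
#' which the lesion is drawn either as a single ellipse (compact,
#' mass-like) or as several small blobs (scattered, non-mass-like).
#'
#' @param shape integer `(H, W)` grid size.
#' @param breast list with `center` `(row, col)` and `axes`
#'   `(semi-axis rows, semi-axis cols)`; default is a centered ellipse
#'   covering most of the grid.
#' @param lesion list describing the lesion: `type` `"ellipse"` (fields
#'   `center`, `axes`) or `"blobs"` (fields `n`, `radius`, optional
#'   `centers` as an n x 2 matrix, optional `seed` for random placement),
#'   plus `class`, one of `"mass"`, `"nonmass"`, `"fibroadenoma"`,
#'   `"cyst"`.
#' @return Integer H x W matrix with levels attribute
#'   `c("background", "normal", <lesion class>)`; values 1..3.
#' @export
make_label_map <- function(shape = c(64, 64),
                           breast = NULL,
                           lesion = list(type = "ellipse", class = "mass")) {
  shape <- as.integer(shape)
  if (is.null(breast)) {
    breast <- list(center = (shape + 1) / 2, axes = floor(shape * 0.42))
  }
  if (any(breast$center - breast$axes < 1) ||
      any(breast$center + breast$axes > shape)) {
    stop("breast region must lie inside the image grid")
  }
  cls <- lesion$class %||% "mass"
  if (!cls %in% c("mass", "nonmass", "fibroadenoma", "cyst")) {
    stop("unknown lesion class: ", cls)
  }
  breast_px <- ellipse_mask(shape, breast$center, breast$axes)

  type <- lesion$type %||% "ellipse"
  if (type == "ellipse") {
    center <- lesion$center %||% breast$center
    axes <- lesion$axes %||% c(5, 7)
    if (any(axes <= 0)) stop("lesion axes must be positive (empty lesion)")
    lesion_px <- ellipse_mask(shape, center, axes)
  } else if (type == "blobs") {
    n <- lesion$n %||% 4L
    radius <- lesion$radius %||% 3
    if (n < 1 || radius <= 0) stop("blob lesion needs n >= 1, radius > 0")
    centers <- lesion$centers
    if (is.null(centers)) {
      centers <- with_seed(lesion$seed %||% 1L, {
        # rejection-sample blob centers well inside the breast ellipse
        got <- matrix(0, 0, 2)
        while (nrow(got) < n) {
          cand <- c(
            breast$center[1] + round(stats::runif(1, -0.6, 0.6) * breast$axes[1]),
            breast$center[2] + round(stats::runif(1, -0.6, 0.6) * breast$axes[2]))
          if (nrow(got) == 0 ||
              all(sqrt(rowSums(sweep(got, 2, cand)^2)) > 2.5 * radius)) {
            got <- rbind(got, cand)
          }
        }
        got
      })
    }
    lesion_px <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(nrow(centers))) {
      lesion_px <- lesion_px |
        ellipse_mask(shape, centers[i, ], c(radius, radius))
    }
  } else {
    stop("unknown lesion type: ", type)
  }

  if (sum(lesion_px) == 0) stop("lesion is empty")
  if (any(lesion_px & !breast_px)) {
    stop("lesion must lie entirely inside the breast region")
  }
  labels <- matrix(1L, shape[1], shape[2])
  labels[breast_px] <- 2L
  labels[lesion_px] <- 3L
  attr(labels, "levels") <- c("background", "normal", cls)
  labels
}

label_classes <- function(labels) attr(labels, "levels")

#' Simulate a noisy b-value cube from a label map
#'
#' Every pixel's band profile follows the bi-exponential IVIM signal of
#' its tissue class ([ivim_signal()]). Optional Rician noise is applied as
#' the magnitude of the signal perturbed by two independent zero-mean
#' Gaussian components of scale `noise_sigma` (magnitude-MRI noise model).
#'
#' @param labels label map from [make_label_map()].
#' @param params data.frame of per-class parameters as in
#'   [ivim_presets()]; must contain every class present in `labels`.
#' @param bvalues b-value vector; default [default_bvalues()].
#' @param noise_sigma Rician noise scale in `S0` units (>= 0).
#' @param seed RNG seed for the noise draw; same seed, same cube.
#' @return List with `cube` ([bvalue_cube()]), `truth_mask` (logical
#'   lesion mask), `labels`, and `params` (rows actually used).
#' @export
simulate_cube <- function(labels, params = ivim_presets(),
                          bvalues = default_bvalues(),
                          noise_sigma = 0, seed = NULL) {
  stopifnot(noise_sigma >= 0)
  lv <- label_classes(labels)
  missing_cls <- setdiff(lv, params$class)
  if (length(missing_cls) > 0) {
    stop("no parameters for class(es): ", paste(missing_cls, collapse = ", "))
  }
  d <- c(dim(labels), length(bvalues))
  clean <- array(0, d)
  for (li in seq_along(lv)) {
    p <- params[params$class == lv[li], ]
    sig <- ivim_signal(bvalues, p$S0, p$D, p$Dstar, p$PF)
    sel <- labels == li
    for (j in seq_along(bvalues)) {
      band <- clean[, , j]
      band[sel] <- sig[j]
      clean[, , j] <- band
    }
  }
  data <- if (noise_sigma > 0) {
    with_seed(seed, {
      g1 <- array(stats::rnorm(length(clean), sd = noise_sigma), d)
      g2 <- array(stats::rnorm(length(clean), sd = noise_sigma), d)
      sqrt((clean + g1)^2 + g2^2)
    })
  } else clean
  list(cube = bvalue_cube(data, bvalues),
       truth_mask = labels == 3L,
       labels = labels,
       params = params[params$class %in% lv, ])
}

#' Apply a smooth multiplicative bias field to a cube
#'
#' Multiplies every band by the same smooth low-order polynomial field
#' with mean exactly 1 over the grid and peak relative deviation
#' `amplitude`, emulating coil-sensitivity intensity non-uniformity.
#'
#' @param cube a [bvalue_cube()].
#' @param amplitude peak `|field - 1|`, in `[0, 1)`.
#' @param seed RNG seed for the random polynomial coefficients.
#' @param order polynomial order of the field (default 2).
#' @return List with the biased `cube` and the applied `field` matrix.
#' @export
apply_bias_field <- function(cube, amplitude, seed = NULL, order = 2) {
  if (amplitude < 0 || amplitude >= 1) {
    stop("bias amplitude must be in [0, 1)")
  }
  d <- dim(cube$data)
  if (amplitude == 0) {
    return(list(cube = cube, field = matrix(1, d[1], d[2])))
  }
  G <- poly2d_design(d[1], d[2], order)[, -1, drop = FALSE]  # no intercept
  coefs <- with_seed(seed, stats::rnorm(ncol(G)))
  g <- as.vector(G %*% coefs)
  g <- g - mean(g)
  field <- matrix(1 + amplitude * g / max(abs(g)), d[1], d[2])
  data <- cube$data * as.vector(field)  # recycles over bands
  list(cube = bvalue_cube(data, cube$bvalues), field = field)
}

#' Translate individual bands of a cube
#'
#' Applies an integer `(dy, dx)` translation to each band, emulating
#' in-plane breathing drift between the acquisitions of different
#' diffusion weightings. The b = 0 band is the registration reference and
#' is never shifted. Vacated edge pixels take the background value.
#'
#' @param cube a [bvalue_cube()].
#' @param shifts integer B x 2 matrix of `(dy, dx)` per band.
#' @param fill fill value for vacated pixels (default 0).
#' @param max_shift shifts larger than this are clipped with a warning.
#' @return List with the shifted `cube` and the `shifts` actually applied.
#' @export
apply_shifts <- function(cube, shifts, fill = 0, max_shift = 5) {
  B <- n_bands(cube)
  shifts <- matrix(as.integer(round(shifts)), B, 2)
  if (any(shifts[1, ] != 0)) {
    warning("the b = 0 reference band is never shifted; ignoring its shift")
    shifts[1, ] <- 0L
  }
  if (any(abs(shifts) > max_shift)) {
    warning("shifts exceeding ", max_shift, " px were clipped")
    shifts <- pmin(pmax(shifts, -max_shift), max_shift)
  }
  data <- cube$data
  for (j in seq_len(B)) {
    if (any(shifts[j, ] != 0)) {
      data[, , j] <- shift_image(data[, , j], shifts[j, 1], shifts[j, 2],
                                 fill = fill)
    }
  }
  list(cube = bvalue_cube(data, cube$bvalues), shifts = shifts)
}

#' Generate a complete IVIM phantom
#'
#' One call that composes [make_label_map()], [simulate_cube()],
#' [apply_bias_field()] and [apply_shifts()] into a phantom slice with
#' known ground truth: lesion mask, tissue parameters, applied bias field
#' and applied per-band shifts.
#'
#' @param shape `(H, W)` grid (default 64 x 64).
#' @param lesion lesion descriptor as in [make_label_map()].
#' @param breast breast-region descriptor as in [make_label_map()].
#' @param params tissue parameter table; default [ivim_presets()].
#' @param bvalues b-values; default [default_bvalues()].
#' @param noise_sigma Rician noise scale (default 0.02, i.e. 2% of the
#'   lesion baseline signal).
#' @param bias_amplitude bias-field amplitude (default 0 = none).
#' @param shifts `NULL` for none, `"random"` for seeded random shifts in
#'   `[-3, 3]` px per band (b = 0 fixed), or an explicit B x 2 matrix.
#' @param seed master seed; sub-seeds for noise, bias and shifts are
#'   derived from it.
#' @return List with `cube`, `truth_mask`, `labels`, `field`, `shifts`,
#'   `params` and the generating `spec`.
#' @export
ivim_phantom <- function(shape = c(64, 64),
                         lesion = list(type = "ellipse", class = "mass"),
                         breast = NULL,
                         params = ivim_presets(),
                         bvalues = default_bvalues(),
                         noise_sigma = 0.02,
                         bias_amplitude = 0,
                         shifts = NULL,
                         seed = 1L) {
  seed <- as.integer(seed)
  labels <- make_label_map(shape, breast = breast, lesion = lesion)
  sim <- simulate_cube(labels, params, bvalues, noise_sigma, seed = seed)
  cube <- sim$cube
  field <- matrix(1, shape[1], shape[2])
  if (bias_amplitude > 0) {
    bf <- apply_bias_field(cube, bias_amplitude, seed = seed + 1L)
    cube <- bf$cube
    field <- bf$field
  }
  applied_shifts <- matrix(0L, length(bvalues), 2)
  if (!is.null(shifts)) {
    if (identical(shifts, "random")) {
      shifts <- with_seed(seed + 2L, {
        s <- matrix(sample(-3:3, 2 * length(bvalues), replace = TRUE),
                    ncol = 2)
        s[1, ] <- 0L
        s
      })
    }
    sh <- apply_shifts(cube, shifts)
    cube <- sh$cube
    applied_shifts <- sh$shifts
  }
  list(cube = cube,
       truth_mask = sim$truth_mask,
       labels = labels,
       field = field,
       shifts = applied_shifts,
       params = sim$params,
       spec = list(shape = shape, lesion = lesion, breast = breast,
                   bvalues = bvalues, noise_sigma = noise_sigma,
                   bias_amplitude = bias_amplitude, seed = seed))
}
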