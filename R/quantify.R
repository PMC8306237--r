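#' ROI-mean signal decay curve
#'
#' Mean intensity over the mask per band, normalized by the b = 0 mean,
#' giving the region's `S_b / S_0` decay profile.
#'
#' @param cube a [bvalue_cube()].
#' @param mask logical H x W region of interest, nonempty.
#' @return A data.frame of class `decay_curve` with columns `b` and
#'   `signal` (`signal[1] == 1`).
#' @export
roi_decay_curve <- function(cube, mask) {
  if (!any(mask)) stop("empty detection: the ROI mask has no pixels")
  B <- n_bands(cube)
  s <- vapply(seq_len(B), function(j) mean(cube$data[, , j][mask]),
              numeric(1))
  if (s[1] <= 0) stop("b = 0 mean signal must be positive")
  structure(data.frame(b = cube$bvalues, signal = s / s[1]),
            class = c("decay_curve", "data.frame"))
}

check_curve <- function(curve) {
  stopifnot(all(c("b", "signal") %in% names(curve)))
  if (nrow(curve) < 2) stop("need at least 2 b-values")
  invisible(curve)
}

#' Apparent diffusion coefficient (ADC) from a decay curve
#'
#' Mono-exponential fit `ln(S_b / S_0) = -b * ADC`: the least-squares
#' slope of log-signal against b, constrained through the origin (the
#' model has no intercept), negated. Equals `D` when the perfusion
#' fraction is 0, and exceeds `D` when perfusion contributes.
#'
#' @param curve a [roi_decay_curve()] result (or data.frame with `b`,
#'   `signal`).
#' @return ADC in mm^2/s.
#' @export
adc_fit <- function(curve) {
  check_curve(curve)
  if (any(curve$signal <= 0)) stop("signal values must be positive")
  y <- log(curve$signal)
  -sum(curve$b * y) / sum(curve$b^2)
}

#' Signal decay slope of a decay curve
#'
#' Ordinary least-squares slope of the normalized signal (linear, not
#' log) against b over all b-values. Negative for any decaying curve;
#' for normalized signal over b in 0..2500 s/mm^2 its magnitude is of
#' order 1e-4.
#'
#' @param curve a [roi_decay_curve()] result.
#' @return Slope per (s/mm^2).
#' @export
decay_slope <- function(curve) {
  check_curve(curve)
  unname(stats::coef(stats::lm(signal ~ b, data = curve))[2])
}

#' Bi-exponential IVIM fit of a decay curve
#'
#' Segmented fit: stage 1 fits `log(signal)` linearly over `b >= b_split`
#' (the perfusion-free regime), giving `D` from the slope and
#' `PF = 1 - exp(intercept)`; stage 2 (optional) refines `(D, Dstar, PF)`
#' by bounded Levenberg-Marquardt least squares on the full curve,
#' initialized from stage 1 with `Dstar = 10 * D`. Bounds:
#' `D` in `[0, 5e-3]`, `Dstar` in `[0, 0.5]`, `PF` in `[0, 1]`. If the
#' refinement fails to converge the stage-1 estimate is returned with
#' `refined = FALSE`.
#'
#' @param curve a [roi_decay_curve()] result.
#' @param b_split boundary between the perfusion-dominated and pure
#'   diffusion regimes (default 200 s/mm^2).
#' @param refine run the nonlinear refinement (default TRUE).
#' @return List with `D`, `Dstar`, `PF` and logical `refined`.
#' @export
ivim_fit <- function(curve, b_split = 200, refine = TRUE) {
  check_curve(curve)
  if (any(curve$signal <= 0)) stop("signal values must be positive")
  hi <- curve$b >= b_split
  if (sum(hi) < 2) {
    stop("fewer than 2 b-values at or above b_split = ", b_split)
  }
  fit1 <- stats::lm(log(signal) ~ b, data = curve[hi, ])
  D1 <- max(0, -unname(stats::coef(fit1)[2]))
  PF1 <- min(1, max(0, 1 - exp(unname(stats::coef(fit1)[1]))))
  Ds1 <- max(10 * D1, 1e-3)
  out <- list(D = D1, Dstar = Ds1, PF = PF1, refined = FALSE)
  if (!refine) return(out)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ (1 - PF) * exp(-b * D) + PF * exp(-b * Dstar),
      data = curve,
      start = list(D = min(D1, 5e-3), Dstar = min(Ds1, 0.5), PF = PF1),
      lower = c(0, 0, 0), upper = c(5e-3, 0.5, 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit2)) return(out)
  cf <- stats::coef(fit2)
  list(D = unname(cf["D"]), Dstar = unname(cf["Dstar"]),
       PF = unname(cf["PF"]), refined = TRUE)
}

#' Quantify a detected lesion
#'
#' Composes the ROI decay curve with the ADC, decay-slope and
#' bi-exponential IVIM fits, yielding the five-parameter
#' characterization (ADC, signal decay slope, D*, D, PF) reported per
#' detection method.
#'
#' @param cube a [bvalue_cube()].
#' @param mask logical lesion mask (e.g. a detector output).
#' @param method optional method label carried into the report row.
#' @param b_split,refine forwarded to [ivim_fit()].
#' @param per_pixel if TRUE, additionally fit every pixel curve in the
#'   mask and report the median of each parameter (noise-fragile; the
#'   ROI-mean fit remains the reported `params` row).
#' @return List with `params` (one-row data.frame: `method`, `ADC`,
#'   `decay_slope`, `Dstar`, `D`, `PF`, `refined`), `curve`, and, when
#'   `per_pixel` is set, `pixel_params` (per-pixel fit medians).
#' @export
quantify_detection <- function(cube, mask, method = NA_character_,
                               b_split = 200, refine = TRUE,
                               per_pixel = FALSE) {
  curve <- roi_decay_curve(cube, mask)
  fit <- ivim_fit(curve, b_split = b_split, refine = refine)
  params <- data.frame(method = method,
                       ADC = adc_fit(curve),
                       decay_slope = decay_slope(curve),
                       Dstar = fit$Dstar,
                       D = fit$D,
                       PF = fit$PF,
                       refined = fit$refined,
                       stringsAsFactors = FALSE)
  out <- list(params = params, curve = curve)
  if (per_pixel) {
    px <- cube_pixels(cube, mask)$X
    fits <- apply(px, 1, function(s) {
      if (s[1] <= 0 || any(s <= 0)) return(c(NA, NA, NA))
      cv <- data.frame(b = cube$bvalues, signal = s / s[1])
      f <- ivim_fit(cv, b_split = b_split, refine = refine)
      c(f$D, f$Dstar, f$PF)
    })
    out$pixel_params <- data.frame(
      D = stats::median(fits[1, ], na.rm = TRUE),
      Dstar = stats::median(fits[2, ], na.rm = TRUE),
      PF = stats::median(fits[3, ], na.rm = TRUE),
      n_pixels = ncol(fits))
  }
  out
}
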