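#' Detect a tumor with one of the four methods
#'
#' Dispatches to the method's flowchart: I-CEM and K-CEM run on the
#' BEP-expanded cube by default; K-means and FCM cluster the original
#' band spectra by default and identify the lesion cluster with ATGP
#' before Otsu binarization.
#'
#' @param cube a preprocessed [bvalue_cube()].
#' @param breast_mask logical H x W region to process.
#' @param method one of `"icem"`, `"kcem"`, `"kmeans"`, `"fcm"`.
#' @param bep apply the band expansion process; default TRUE for the CEM
#'   methods, FALSE for the clustering methods.
#' @param seed RNG seed.
#' @param k clusters for the clustering methods (default 3).
#' @param ... further arguments passed to [icem()], [kcem()],
#'   [kmeans_cluster()] or [fcm_cluster()].
#' @return List with `mask` (logical H x W) and method-specific `detail`.
#' @export
detect_tumor <- function(cube, breast_mask,
                         method = c("icem", "kcem", "kmeans", "fcm"),
                         bep = NULL, seed = 1L, k = 3, ...) {
  method <- match.arg(method)
  bep <- bep %||% (method %in% c("icem", "kcem"))
  if (method == "icem") {
    r <- icem(cube, breast_mask, bep = bep, seed = seed, ...)
    return(list(mask = r$mask, detail = r))
  }
  if (method == "kcem") {
    r <- kcem(cube, breast_mask, bep = bep, seed = seed, ...)
    return(list(mask = r$mask, detail = r))
  }
  work <- if (bep) expand_bands(cube) else cube
  X <- cube_pixels(work, breast_mask)$X
  cl <- if (method == "kmeans") {
    kmeans_cluster(X, k = k, seed = seed, ...)
  } else {
    fcm_cluster(X, c = k, seed = seed, ...)
  }
  mask <- pick_tumor_cluster(cl, X, cube, breast_mask)
  list(mask = mask, detail = cl)
}

#' Run the full detection pipeline
#'
#' Orchestrates phantom generation (or cube loading), preprocessing
#' (bias correction, band registration, breast extraction), detection by
#' one or more methods, lesion quantification and, when ground truth is
#' available, segmentation evaluation. All outputs are written under
#' `output_dir` with the seed recorded; a rerun with the same
#' configuration and seed reproduces the masks and tables bit for bit.
#'
#' @param config list with fields:
#'   * `phantom`: arguments for [ivim_phantom()] (mutually exclusive with
#'     `input`),
#'   * `input`: list with `cube` and `bvals` paths for [read_cube()],
#'   * `methods`: character vector from
#'     `c("icem", "kcem", "kmeans", "fcm")` (default all four),
#'   * `bep`: logical or NULL for per-method defaults,
#'   * `seed`: integer seed (default 1),
#'   * `preprocess`: optional arguments for [preprocess_cube()],
#'   * `output_dir`: where to write artifacts (`NULL` skips writing).
#' @return List with per-method `results` (mask, params, eval, timing),
#'   the combined `params` table, the preprocessing products and the
#'   `truth_mask` when a phantom was used.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$phantom) && !is.null(config$input)) {
    stop("configure exactly one input source: `phantom` or `input`")
  }
  seed <- as.integer(config$seed %||% 1L)
  methods <- config$methods %||% c("icem", "kcem", "kmeans", "fcm")
  bad <- setdiff(methods, c("icem", "kcem", "kmeans", "fcm"))
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))

  truth <- NULL
  if (!is.null(config$phantom)) {
    ph <- do.call(ivim_phantom, c(config$phantom, list(seed = seed)))
    cube <- ph$cube
    truth <- ph$truth_mask
  } else if (!is.null(config$input)) {
    cube <- read_cube(config$input$cube, config$input$bvals)
  } else {
    stop("no input source configured")
  }

  pp <- do.call(preprocess_cube,
                c(list(cube = cube), config$preprocess %||% list()))

  results <- list()
  params_rows <- list()
  for (mth in methods) {
    t0 <- proc.time()[["elapsed"]]
    det <- detect_tumor(pp$cube, pp$breast_mask, method = mth,
                        bep = config$bep, seed = seed)
    elapsed <- proc.time()[["elapsed"]] - t0
    q <- quantify_detection(pp$cube, det$mask, method = mth)
    ev <- if (!is.null(truth)) evaluate_mask(det$mask, truth) else NULL
    results[[mth]] <- list(mask = det$mask, params = q$params,
                           curve = q$curve, eval = ev, seconds = elapsed)
    params_rows[[mth]] <- q$params
  }
  params <- do.call(rbind, params_rows)
  rownames(params) <- NULL

  out <- list(results = results, params = params, cube = pp$cube,
              breast_mask = pp$breast_mask, field = pp$field,
              shifts = pp$shifts, truth_mask = truth, seed = seed)

  dir <- config$output_dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(params, file.path(dir, "parameters.csv"),
                     row.names = FALSE)
    write_mask(pp$breast_mask, file.path(dir, "breast_mask.nii.gz"))
    if (!is.null(truth)) {
      write_mask(truth, file.path(dir, "truth_mask.nii.gz"))
    }
    evals <- list()
    for (mth in methods) {
      write_mask(results[[mth]]$mask,
                 file.path(dir, sprintf("mask_%s.nii.gz", mth)))
      utils::write.csv(results[[mth]]$curve,
                       file.path(dir, sprintf("curve_%s.csv", mth)),
                       row.names = FALSE)
      if (!is.null(results[[mth]]$eval)) {
        evals[[mth]] <- results[[mth]]$eval[c("dice", "jaccard",
                                              "precision", "accuracy",
                                              "recall")]
      }
      evals[[mth]]$seconds <- results[[mth]]$seconds
    }
    log <- list(seed = seed, methods = methods,
                estimated_shifts = pp$shifts,
                evaluation = evals,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(log, file.path(dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
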