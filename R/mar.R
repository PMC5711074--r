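# Iterative sinogram-domain metal artifact reduction (O-MAR class).
#
# Each pass segments the current image into a metal-only and a tissue-
# classified image, forms a difference sinogram between the original image
# sinogram and the tissue estimate, masks it to the metal trace, and
# subtracts its reconstruction from the original image. The first pass uses
# linear interpolation across the metal trace as its tissue estimate (the
# classic inpainting step); later passes use the forward-projected
# tissue-classified image, which the iteration progressively cleans up.

#' HU segmentation thresholds
#'
#' @param metal_hu HU above which a pixel is classified as metal.
#' @param tissue_band HU interval `c(lo, hi)` counted as "close to zero"
#'   (soft tissue / water); must straddle 0 and lie below `metal_hu`. The
#'   default flattens only water-like pixels so denser real structure
#'   (acrylic, bone) survives in the tissue-classified prior.
#' @return Object of class `segmentation_thresholds`.
#' @export
segmentation_thresholds <- function(metal_hu = 2500,
                                    tissue_band = c(-100, 100)) {
  stopifnot(length(tissue_band) == 2, tissue_band[1] < 0, tissue_band[2] > 0,
            metal_hu > tissue_band[2])
  structure(list(metal_hu = metal_hu, tissue_band = tissue_band),
            class = "segmentation_thresholds")
}

#' MAR configuration
#'
#' @param thresholds A [segmentation_thresholds()].
#' @param max_iterations Maximum correction passes.
#' @param tolerance Relative L2 change (outside metal) below which the loop
#'   stops.
#' @param geometry Optional [projection_geometry()]; derived from the image
#'   when `NULL`.
#' @param filtered_correction Reconstruct the correction image by filtered
#'   back projection (default) so it lives on the image's quantitative
#'   scale; `FALSE` uses plain unfiltered back projection.
#' @return Object of class `mar_config`.
#' @export
mar_config <- function(thresholds = segmentation_thresholds(),
                       max_iterations = 8, tolerance = 1e-3,
                       geometry = NULL, filtered_correction = TRUE) {
  stopifnot(max_iterations >= 1, tolerance > 0)
  structure(list(thresholds = thresholds,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, geometry = geometry,
                 filtered_correction = isTRUE(filtered_correction)),
            class = "mar_config")
}

#' Segment an image into metal-only and tissue-classified images
#'
#' The metal-only image is zero except at metal pixels, where it keeps the
#' input HU. The tissue-classified image replaces every pixel inside the
#' tissue band with the global mean HU of those pixels; all remaining
#' (non-tissue) pixels keep their input values.
#'
#' @param image A [ct_image()] or HU matrix.
#' @param thresholds A [segmentation_thresholds()].
#' @return List: `metal_only`, `tissue_classified` (matrices), `metal_mask`
#'   (logical matrix), `tissue_mean`.
#' @export
classify_image <- function(image, thresholds = segmentation_thresholds()) {
  hu <- as_image_matrix(image)
  metal <- hu > thresholds$metal_hu
  in_band <- hu >= thresholds$tissue_band[1] & hu <= thresholds$tissue_band[2]
  if (!any(in_band)) {
    stop("no pixels inside the tissue band [",
         thresholds$tissue_band[1], ", ", thresholds$tissue_band[2],
         "] HU; widen the band thresholds", call. = FALSE)
  }
  metal_only <- matrix(0, nrow(hu), ncol(hu))
  metal_only[metal] <- hu[metal]
  tissue_mean <- mean(hu[in_band])
  tissue <- hu
  tissue[in_band] <- tissue_mean
  list(metal_only = metal_only, tissue_classified = tissue,
       metal_mask = metal, tissue_mean = tissue_mean)
}

#' Metal trace mask in the sinogram domain
#'
#' TRUE wherever the forward projection of the metal indicator image exceeds
#' a small epsilon (suppressing interpolation leakage).
#'
#' @param metal_only Metal-only image (matrix) or logical metal mask.
#' @param geometry A [projection_geometry()].
#' @param eps Threshold on the projected indicator (mm of metal path).
#' @return Logical n_angles x detector_count matrix.
#' @export
metal_trace_mask <- function(metal_only, geometry, eps = 1e-9) {
  ind <- (as_image_matrix(metal_only) != 0) * 1.0
  forward_project(ind, geometry)$values > eps
}

#' Inpaint the metal trace of a sinogram
#'
#' Masked detector runs in each view are replaced by 1-D linear interpolation
#' along the detector axis from their unmasked neighbours (nearest-value
#' extension at the detector edges). A fully masked view is replaced by the
#' nearest view with unmasked data, with a warning.
#'
#' @param sino A `sinogram` (or matrix).
#' @param mask Logical matrix from [metal_trace_mask()].
#' @return Object of the same type as `sino` with masked entries replaced.
#' @export
inpaint_metal_trace <- function(sino, mask) {
  values <- if (inherits(sino, "sinogram")) sino$values else sino
  stopifnot(all(dim(values) == dim(mask)))
  out <- values
  full <- which(apply(mask, 1, all))
  open <- which(!apply(mask, 1, all))
  if (length(full) > 0) {
    if (length(open) == 0) stop("all views fully masked", call. = FALSE)
    warning(length(full), " fully masked view(s) replaced by nearest view",
            call. = FALSE)
  }
  det <- seq_len(ncol(values))
  for (a in open) {
    m <- mask[a, ]
    if (!any(m)) next
    out[a, m] <- stats::approx(det[!m], values[a, !m], xout = det[m],
                               rule = 2)$y
  }
  for (a in full) {
    src <- open[which.min(abs(open - a))]
    out[a, ] <- out[src, ]
  }
  if (inherits(sino, "sinogram")) {
    sino$values <- out
    sino
  } else {
    out
  }
}

#' Iterative sinogram-domain metal artifact reduction
#'
#' See the module header for the loop structure. Metal pixels of the output
#' are restored bit-exactly from the input (the correction applies only
#' outside the metal objects), the correction is confined to the
#' reconstruction circle, and the loop stops when the relative L2 change of
#' the non-metal image falls below `config$tolerance` or after
#' `config$max_iterations` passes.
#'
#' @param image Input [ct_image()].
#' @param config A [mar_config()].
#' @return List: `corrected` ([ct_image()]), `diagnostics` (tibble with
#'   iteration and relative change), `no_metal` flag, `n_iterations`.
#' @export
omar_correct <- function(image, config = mar_config()) {
  stopifnot(inherits(image, "ct_image"))
  hu <- image$hu
  seg <- classify_image(hu, config$thresholds)
  if (!any(seg$metal_mask)) {
    return(list(corrected = image,
                diagnostics = tibble::tibble(iteration = integer(0),
                                             change = numeric(0)),
                no_metal = TRUE, n_iterations = 0L))
  }
  geometry <- config$geometry
  if (is.null(geometry)) {
    geometry <- default_geometry(hu, n_angles = 720,
                                 pixel_spacing = image$pixel_spacing)
  }
  s_orig <- forward_project(hu, geometry)$values
  trace <- metal_trace_mask(seg$metal_mask * 1.0, geometry)
  circle <- reconstruction_circle(geometry)
  outside_metal <- !seg$metal_mask

  reconstruct <- function(d) {
    if (config$filtered_correction) {
      fbp_reconstruct(d, geometry)
    } else {
      back_project(d, geometry) * (pi / geometry$n_angles) *
        geometry$detector_spacing / geometry$image_pixel_spacing^2
    }
  }

  current <- hu
  iters <- integer(0)
  changes <- numeric(0)
  for (k in seq_len(config$max_iterations)) {
    if (k == 1) {
      # first pass: the metal-trace data of the original sinogram are
      # replaced by interpolated values to emulate tissue
      s_cur <- s_orig
      estimate <- inpaint_metal_trace(s_orig, trace)
    } else {
      # later passes: the corrected image is the new input; its tissue
      # classification provides the trace estimate
      s_cur <- forward_project(current, geometry)$values
      tissue <- classify_image(current, config$thresholds)$tissue_classified
      estimate <- forward_project(tissue, geometry)$values
    }
    d <- s_cur - estimate
    d[!trace] <- 0
    correction <- reconstruct(d)
    correction[!circle] <- 0
    new_img <- current - correction
    new_img[seg$metal_mask] <- hu[seg$metal_mask]
    denom <- sqrt(sum(current[outside_metal]^2))
    change <- sqrt(sum((new_img[outside_metal] - current[outside_metal])^2)) /
      max(denom, .Machine$double.eps)
    iters <- c(iters, k)
    changes <- c(changes, change)
    current <- new_img
    if (change < config$tolerance) break
  }
  out <- image
  out$hu <- current
  out$meta$mar <- list(thresholds = config$thresholds,
                       n_iterations = length(iters))
  list(corrected = out,
       diagnostics = tibble::tibble(iteration = iters, change = changes),
       no_metal = FALSE, n_iterations = length(iters))
}
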