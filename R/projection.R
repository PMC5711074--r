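# Parallel-beam Radon transform, adjoint, and filtered back projection.
# These serve both the scan simulator (per-energy attenuation sinograms) and
# the MAR loop (reprojection of segmented images, correction reconstruction).

#' Parallel-beam projection geometry
#'
#' View angles are uniformly spaced over 180 degrees. The detector is a 1-D
#' array of `detector_count` bins spaced `detector_spacing` mm apart, centred
#' on the rotation axis.
#'
#' @param n_angles Number of view angles over 180 degrees.
#' @param detector_count Number of detector bins.
#' @param detector_spacing Detector bin spacing in mm.
#' @param image_pixel_spacing Image pixel spacing in mm.
#' @param image_dim Image dimensions `c(nrow, ncol)` the geometry is paired
#'   with (used by back projection and reconstruction).
#' @return Object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_angles, detector_count, detector_spacing,
                                image_pixel_spacing, image_dim) {
  stopifnot(n_angles >= 1, detector_count >= 2, detector_spacing > 0,
            image_pixel_spacing > 0, length(image_dim) == 2)
  structure(
    list(n_angles = as.integer(n_angles),
         detector_count = as.integer(detector_count),
         detector_spacing = detector_spacing,
         image_pixel_spacing = image_pixel_spacing,
         image_dim = as.integer(image_dim),
         angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]),
    class = "projection_geometry"
  )
}

#' Default geometry for an image
#'
#' Detector spacing equals the pixel spacing and the detector span covers the
#' image diagonal with a small margin.
#'
#' @param image Matrix (or `ct_image`) the geometry should cover.
#' @param n_angles Number of views over 180 degrees.
#' @param pixel_spacing Pixel spacing in mm (taken from a `ct_image` input).
#' @return A [projection_geometry()].
#' @export
default_geometry <- function(image, n_angles = 720,
                             pixel_spacing = attr(image, "pixel_spacing")) {
  m <- as_image_matrix(image)
  if (is.null(pixel_spacing) && inherits(image, "ct_image")) {
    pixel_spacing <- image$pixel_spacing
  }
  stopifnot(!is.null(pixel_spacing))
  diag_mm <- sqrt(sum(dim(m)^2)) * pixel_spacing
  n_det <- as.integer(ceiling(diag_mm / pixel_spacing)) + 4L
  projection_geometry(n_angles, n_det, pixel_spacing, pixel_spacing, dim(m))
}

# Accept a bare matrix or a ct_image for projection operators.
as_image_matrix <- function(x) {
  if (inherits(x, "ct_image")) return(x$hu)
  if (is.matrix(x)) return(x)
  stop("expected a matrix or ct_image", call. = FALSE)
}

.check_geom_image <- function(m, geometry) {
  if (!all(dim(m) == geometry$image_dim)) {
    stop("image dimensions ", paste(dim(m), collapse = "x"),
         " do not match geometry image_dim ",
         paste(geometry$image_dim, collapse = "x"), call. = FALSE)
  }
  diag_mm <- sqrt(sum(dim(m)^2)) * geometry$image_pixel_spacing
  span <- geometry$detector_count * geometry$detector_spacing
  if (span < diag_mm) {
    stop("detector span (", round(span), " mm) does not cover the image ",
         "diagonal (", round(diag_mm), " mm)", call. = FALSE)
  }
}

#' Forward projection (Radon transform)
#'
#' Each sinogram entry is the line integral of the image along the
#' corresponding parallel ray, in value x mm.
#'
#' @param image Matrix or `ct_image`.
#' @param geometry A [projection_geometry()] matching the image.
#' @return Object of class `sinogram`: list with `values`
#'   (n_angles x detector_count matrix) and `geometry`.
#' @export
forward_project <- function(image, geometry) {
  m <- as_image_matrix(image)
  .check_geom_image(m, geometry)
  values <- cpp_forward_project(m, geometry$angles, geometry$detector_count,
                                geometry$detector_spacing,
                                geometry$image_pixel_spacing)
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d bins (ds = %g mm)\n",
              nrow(x$values), ncol(x$values), x$geometry$detector_spacing))
  invisible(x)
}

#' Unfiltered back projection (adjoint of the forward projector)
#'
#' @param sino A `sinogram` (or bare matrix with `geometry` supplied).
#' @param geometry Geometry; defaults to the sinogram's own.
#' @return Image matrix of size `geometry$image_dim`.
#' @export
back_project <- function(sino, geometry = sino$geometry) {
  values <- if (inherits(sino, "sinogram")) sino$values else sino
  stopifnot(nrow(values) == geometry$n_angles,
            ncol(values) == geometry$detector_count)
  cpp_back_project(values, geometry$angles,
                   geometry$image_dim[1], geometry$image_dim[2],
                   geometry$detector_spacing, geometry$image_pixel_spacing)
}

# Frequency response of the reconstruction filter on an FFT grid of length L.
# The ramp (Ram-Lak) response is the DFT of the standard band-limited spatial
# kernel h[0] = 1/(4 ds^2), h[n odd] = -1/(pi^2 n^2 ds^2), h[n even] = 0,
# which avoids the DC bias of a naively sampled |f| ramp.
.filter_response <- function(L, ds, filter = c("ramp", "shepp-logan")) {
  filter <- match.arg(filter)
  h <- numeric(L)
  h[1] <- 1 / (4 * ds^2)
  n <- seq_len(L / 2)
  odd <- n[n %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2 * ds^2)
  h[L + 1 - odd] <- -1 / (pi^2 * odd^2 * ds^2)
  H <- Re(stats::fft(h))
  if (filter == "shepp-logan") {
    f <- c(seq(0, L / 2), seq(-L / 2 + 1, -1)) / L  # cycles per sample
    sinc <- ifelse(f == 0, 1, sin(pi * f) / (pi * f))
    H <- H * sinc
  }
  pmax(H, 0)
}

#' Filtered back projection reconstruction
#'
#' Ramp-filters each view (FFT convolution, zero-padded) and back-projects;
#' approximate inverse of [forward_project()] inside the reconstruction
#' circle.
#'
#' @param sino A `sinogram`.
#' @param geometry Geometry; defaults to the sinogram's own.
#' @param filter `"ramp"` (Ram-Lak) or `"shepp-logan"` (sinc-apodized ramp).
#' @return Reconstructed image matrix.
#' @export
fbp_reconstruct <- function(sino, geometry = sino$geometry,
                            filter = c("ramp", "shepp-logan")) {
  filter <- match.arg(filter)
  p <- if (inherits(sino, "sinogram")) sino$values else sino
  stopifnot(nrow(p) == geometry$n_angles,
            ncol(p) == geometry$detector_count)
  ds <- geometry$detector_spacing
  n_det <- geometry$detector_count
  L <- 2^ceiling(log2(2 * n_det))
  H <- .filter_response(L, ds, filter)
  pad <- matrix(0, nrow(p), L)
  pad[, seq_len(n_det)] <- p
  # filter all views at once: FFT along the detector axis
  fq <- t(stats::mvfft(t(pad)))
  fq <- sweep(fq, 2, H, `*`)
  q <- Re(t(stats::mvfft(t(fq), inverse = TRUE))) / L
  q <- q[, seq_len(n_det), drop = FALSE] * ds
  bp <- cpp_back_project(q, geometry$angles,
                         geometry$image_dim[1], geometry$image_dim[2],
                         ds, geometry$image_pixel_spacing)
  bp * (pi / geometry$n_angles) * ds / geometry$image_pixel_spacing^2
}

#' Mask of pixels inside the reconstruction circle
#'
#' @param geometry A [projection_geometry()].
#' @param radius_fraction Radius as a fraction of the inscribed half-width.
#' @return Logical matrix of size `geometry$image_dim`.
#' @export
reconstruction_circle <- function(geometry, radius_fraction = 1) {
  nr <- geometry$image_dim[1]; nc <- geometry$image_dim[2]
  ps <- geometry$image_pixel_spacing
  x <- (seq_len(nc) - (nc + 1) / 2) * ps
  y <- ((nr + 1) / 2 - seq_len(nr)) * ps
  r <- min(nr, nc) / 2 * ps * radius_fraction
  outer(y, x, function(yy, xx) xx^2 + yy^2) <= r^2
}

#' Write a sinogram as flat text + JSON sidecar
#'
#' @param sino A `sinogram`.
#' @param path Base path; writes `<path>.txt` (values) and `<path>.json`.
#' @return Base path, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  utils::write.table(sino$values, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  g <- sino$geometry
  jsonlite::write_json(
    list(n_angles = g$n_angles, detector_count = g$detector_count,
         detector_spacing = g$detector_spacing,
         image_pixel_spacing = g$image_pixel_spacing,
         image_dim = g$image_dim, angles = g$angles),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
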