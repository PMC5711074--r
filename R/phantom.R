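# Synthetic phantom and polychromatic CT acquisition simulator.
#
# The phantom emulates a 30 x 30 cm water tank filled to 23 cm with a PMMA
# slab on the bottom and one or two chromium-cobalt femoral-head inserts
# 20 cm apart resting on the slab. Acquisition is per-energy Beer-Lambert
# with Poisson counting noise; beam hardening and photon starvation produce
# the characteristic dark band between the implants and radial streaks.

#' CT image container
#'
#' @param hu Matrix of Hounsfield units (row 1 = top of the image).
#' @param pixel_spacing Pixel spacing in mm.
#' @param origin Offset (mm) of the grid corner; by default the grid is
#'   centred on the origin.
#' @param meta Optional named list of acquisition metadata.
#' @return Object of class `ct_image`.
#' @export
ct_image <- function(hu, pixel_spacing, origin = NULL, meta = list()) {
  stopifnot(is.matrix(hu), all(is.finite(hu)), pixel_spacing > 0)
  if (is.null(origin)) {
    origin <- -c(ncol(hu), nrow(hu)) / 2 * pixel_spacing
  }
  structure(list(hu = hu, pixel_spacing = pixel_spacing, origin = origin,
                 meta = meta),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d @ %g mm [%.0f, %.0f] HU\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing,
              min(x$hu), max(x$hu)))
  invisible(x)
}

# Pixel-centre physical coordinates (mm, image centre = origin of the frame):
# x increases with column (rightward), y decreases with row (row 1 = top).
image_axes <- function(image) {
  nr <- nrow(image$hu); nc <- ncol(image$hu); ps <- image$pixel_spacing
  list(x = (seq_len(nc) - (nc + 1) / 2) * ps,
       y = ((nr + 1) / 2 - seq_len(nr)) * ps)
}

#' Hip-prosthesis water phantom specification
#'
#' Geometry in mm, coordinates centred on the tank. The tank cross section is
#' `width` x `tank_height`; water fills it from the bottom to `water_depth`;
#' a PMMA slab of `slab_thickness` rests on the bottom; metallic inserts
#' (discs of `insert_radius`) rest on the slab, `separation` apart.
#'
#' @param n_inserts 0, 1 or 2 prosthesis inserts.
#' @param separation Centre-to-centre insert distance (mm, two-insert case).
#' @param insert_radius Femoral-head disc radius (mm).
#' @param insert_material Library name of the implant alloy.
#' @param slab_thickness PMMA slab thickness (mm).
#' @param width Tank inner width (mm).
#' @param water_depth Water fill depth (mm).
#' @param tank_height Tank inner height (mm).
#' @param inserts Optional explicit insert list overriding the defaults; each
#'   element is `list(shape = "disc"|"annulus", center = c(x, y),
#'   radii = r or c(r_in, r_out), material = <library name>)`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_inserts = 2, separation = 200, insert_radius = 22,
                         insert_material = "crco", slab_thickness = 20,
                         width = 300, water_depth = 230, tank_height = 300,
                         inserts = NULL) {
  stopifnot(n_inserts %in% 0:2, water_depth <= tank_height,
            slab_thickness < water_depth)
  bottom <- -tank_height / 2
  if (is.null(inserts)) {
    y0 <- bottom + slab_thickness + insert_radius
    # the unilateral variant keeps one prosthesis at its side position
    xs <- switch(as.character(n_inserts),
                 "0" = numeric(0),
                 "1" = -separation / 2,
                 "2" = c(-separation / 2, separation / 2))
    inserts <- lapply(xs, function(x) {
      list(shape = "disc", center = c(x, y0), radii = insert_radius,
           material = insert_material)
    })
  }
  if (length(inserts) == 2) {
    d <- sqrt(sum((inserts[[1]]$center - inserts[[2]]$center)^2))
    r12 <- max(inserts[[1]]$radii) + max(inserts[[2]]$radii)
    if (d <= r12) stop("insert separation must exceed the sum of radii",
                       call. = FALSE)
  }
  for (ins in inserts) {
    r <- max(ins$radii)
    if (abs(ins$center[1]) + r > width / 2 ||
        ins$center[2] - r < bottom ||
        ins$center[2] + r > bottom + water_depth) {
      stop("insert extends outside the water volume", call. = FALSE)
    }
  }
  structure(list(width = width, tank_height = tank_height,
                 water_depth = water_depth, slab_thickness = slab_thickness,
                 separation = separation, inserts = inserts,
                 slice_thickness_mm = 3),
            class = "phantom_spec")
}

#' Replace metal inserts by water
#'
#' Produces the reference-phantom specification: identical geometry with the
#' implant material swapped for water (the PMMA slab is retained).
#'
#' @param phantom A [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
metal_free <- function(phantom) {
  phantom$inserts <- lapply(phantom$inserts, function(ins) {
    ins$material <- "water"
    ins
  })
  phantom
}

#' Rasterize a phantom onto a pixel grid
#'
#' Nearest-material assignment at pixel centres (no partial volume).
#'
#' @param phantom A [phantom_spec()].
#' @param grid_dim Grid dimensions `c(nrow, ncol)`.
#' @param pixel_spacing Pixel spacing in mm.
#' @param library Material library.
#' @return List: `material` (integer matrix indexing into `materials`),
#'   `materials` (character vector of library names), `density` (g/cm^3
#'   matrix), plus the grid axes.
#' @export
rasterize_phantom <- function(phantom, grid_dim = c(512, 512),
                              pixel_spacing = 0.7,
                              library = material_library()) {
  nr <- grid_dim[1]; nc <- grid_dim[2]
  if (nr * pixel_spacing < phantom$tank_height ||
      nc * pixel_spacing < phantom$width) {
    stop("grid does not cover the phantom", call. = FALSE)
  }
  x <- (seq_len(nc) - (nc + 1) / 2) * pixel_spacing
  y <- ((nr + 1) / 2 - seq_len(nr)) * pixel_spacing
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  bottom <- -phantom$tank_height / 2
  surface <- bottom + phantom$water_depth

  materials <- c("air", "water", "pmma")
  lab <- matrix(1L, nr, nc)  # air everywhere
  in_tank <- abs(X) <= phantom$width / 2 & Y >= bottom & Y <= surface
  lab[in_tank] <- 2L
  slab <- in_tank & Y <= bottom + phantom$slab_thickness
  lab[slab] <- 3L
  for (ins in phantom$inserts) {
    if (!ins$material %in% materials) materials <- c(materials, ins$material)
    idx <- match(ins$material, materials)
    d2 <- (X - ins$center[1])^2 + (Y - ins$center[2])^2
    hit <- if (ins$shape == "annulus") {
      d2 >= min(ins$radii)^2 & d2 <= max(ins$radii)^2
    } else {
      d2 <= max(ins$radii)^2
    }
    lab[hit] <- idx
  }
  miss <- setdiff(materials, names(library))
  if (length(miss)) stop("materials not in library: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dens <- vapply(library[materials], `[[`, numeric(1), "rho")
  structure(list(material = lab, materials = materials,
                 density = matrix(dens[lab], nr, nc),
                 pixel_spacing = pixel_spacing, x = x, y = y),
            class = "phantom_raster")
}

#' Metal mask of a phantom on a grid
#'
#' @inheritParams rasterize_phantom
#' @return Logical matrix, TRUE on implant-metal pixels.
#' @export
phantom_metal_mask <- function(phantom, grid_dim = c(512, 512),
                               pixel_spacing = 0.7,
                               library = material_library()) {
  ras <- rasterize_phantom(phantom, grid_dim, pixel_spacing, library)
  matrix(ras$materials[ras$material] %in% c("crco", "titanium", "steel"),
         nrow(ras$material), ncol(ras$material))
}

#' X-ray spectrum model
#'
#' Discrete fluence-weighted energy bins approximating a filtered tube
#' spectrum.
#'
#' @param energy_kev Bin energies (keV), within [20, 150].
#' @param weight Fluence weights (normalized to sum to 1).
#' @return Object of class `spectrum_model`.
#' @export
spectrum_model <- function(energy_kev, weight = rep(1, length(energy_kev))) {
  stopifnot(length(energy_kev) == length(weight), all(weight > 0),
            all(energy_kev >= 20), all(energy_kev <= 150))
  structure(list(energy_kev = energy_kev, weight = weight / sum(weight)),
            class = "spectrum_model")
}

#' Default 120 kVp polychromatic spectrum
#'
#' Five-bin approximation of a filtered 120 kVp tube spectrum (mean energy
#' about 67 keV).
#'
#' @return A [spectrum_model()].
#' @export
spectrum_120kvp <- function() {
  spectrum_model(c(45, 60, 75, 90, 110), c(0.15, 0.30, 0.28, 0.17, 0.10))
}

#' Monochromatic spectrum
#'
#' @param energy_kev Single energy (keV).
#' @return A [spectrum_model()] with one bin.
#' @export
mono_spectrum <- function(energy_kev = 70) spectrum_model(energy_kev, 1)

# Klein-Nishina total cross-section per electron (cm^2), photon energy in keV.
.sigma_kn <- function(energy_kev) {
  re <- 2.8179403262e-13  # classical electron radius, cm
  a <- energy_kev / 510.99895
  2 * pi * re^2 * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
      log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  )
}

#' Linear photon attenuation coefficient
#'
#' Stoichiometric parameterization shared with the HU calibration:
#' Klein-Nishina Compton term plus photoelectric (~ Z~^3.62 E^-3.2) and
#' coherent (~ Z^^1.86 E^-1.9) terms anchored at the effective scanner energy
#' `e_ref`, so that monochromatic simulation at `e_ref` reproduces the
#' calibration's HU predictions.
#'
#' @param material A [material()].
#' @param energy_kev Photon energy in keV (vectorized), within [20, 150].
#' @param params [calibration_parameters()] giving the photoelectric and
#'   coherent weights at `e_ref`.
#' @param e_ref Effective scanner energy (keV).
#' @return Attenuation coefficient in 1/mm.
#' @export
attenuation_coefficient <- function(material, energy_kev,
                                    params = calibration_parameters(),
                                    e_ref = 70) {
  if (any(energy_kev < 20 | energy_kev > 150)) {
    stop("photon energy outside validity range [20, 150] keV", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  n_e <- material$rho * material$za_sum * avogadro  # electrons / cm^3
  lambda <- material$za / material$za_sum
  zph <- sum(lambda * material$Z^.P_PHOTO)
  zcoh <- sum(lambda * material$Z^.P_COH)
  s_ref <- .sigma_kn(e_ref)
  sigma <- .sigma_kn(energy_kev) +
    s_ref * (params$k_ph * zph * (energy_kev / e_ref)^(-3.2) +
               params$k_coh * zcoh * (energy_kev / e_ref)^(-1.9))
  n_e * sigma / 10  # 1/cm -> 1/mm
}

# Effective reconstructed attenuation of water for a spectrum+geometry+grid,
# obtained by running the identical simulation chain (noise-free) on a
# water-only tank and averaging a central ROI. Memoised per configuration.
.wetmar_cache <- new.env(parent = emptyenv())

.water_mu_eff <- function(phantom, spectrum, geometry, grid_dim,
                          pixel_spacing, params, library) {
  key <- rlang::hash(list(spectrum, geometry$n_angles,
                          geometry$detector_count, geometry$detector_spacing,
                          grid_dim, pixel_spacing, params,
                          phantom$width, phantom$tank_height,
                          phantom$water_depth))
  if (!is.null(.wetmar_cache[[key]])) return(.wetmar_cache[[key]])
  ph_w <- phantom_spec(n_inserts = 0, slab_thickness = 0,
                       width = phantom$width,
                       water_depth = phantom$water_depth,
                       tank_height = phantom$tank_height)
  ras <- rasterize_phantom(ph_w, grid_dim, pixel_spacing, library)
  mu_eff <- .effective_mu_image(ras, spectrum, geometry, params, library,
                                n0 = Inf, seed = NULL)$mu
  # central ROI well inside the water volume
  bottom <- -phantom$tank_height / 2
  cy <- bottom + phantom$water_depth / 2
  roi <- outer(ras$y, ras$x, function(yy, xx) (xx - 0)^2 + (yy - cy)^2) <= 50^2
  val <- mean(mu_eff[roi])
  .wetmar_cache[[key]] <- val
  val
}

# Core acquisition chain: per-energy Beer-Lambert line integrals, detected
# counts, optional Poisson noise, effective line integral, FBP.
.effective_mu_image <- function(ras, spectrum, geometry, params, library,
                                n0, seed) {
  n_clamped <- 0L
  mu_tab <- lapply(spectrum$energy_kev, function(E) {
    vapply(library[ras$materials], attenuation_coefficient, numeric(1),
           energy_kev = E, params = params)
  })
  dims <- dim(ras$material)
  intensity <- matrix(0, geometry$n_angles, geometry$detector_count)
  for (k in seq_along(spectrum$energy_kev)) {
    mu_img <- matrix(mu_tab[[k]][ras$material], dims[1], dims[2])
    p <- forward_project(mu_img, geometry)$values
    intensity <- intensity + spectrum$weight[k] * exp(-p)
  }
  if (is.finite(n0)) {
    counts <- intensity * n0
    noisy <- function() {
      matrix(stats::rpois(length(counts), counts), nrow(counts), ncol(counts))
    }
    counts <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
    n_clamped <- sum(counts < 1)
    counts[counts < 1] <- 1  # photon starvation floor
    p_eff <- log(n0 / counts)
  } else {
    p_eff <- -log(pmax(intensity, .Machine$double.xmin))
  }
  sino <- structure(list(values = p_eff, geometry = geometry),
                    class = "sinogram")
  list(mu = fbp_reconstruct(sino, geometry), n_clamped = n_clamped)
}

#' Simulate a CT scan of the phantom
#'
#' Per-energy Beer-Lambert transmission through the rasterized phantom,
#' Poisson counting noise, effective line integral -ln(I/I0), filtered back
#' projection, and HU scaling against a water-only calibration scan run
#' through the identical chain. Deterministic for a given `seed`.
#'
#' @param phantom A [phantom_spec()].
#' @param spectrum A [spectrum_model()]; polychromatic spectra produce beam
#'   hardening.
#' @param grid_dim Image dimensions `c(nrow, ncol)`.
#' @param pixel_spacing Pixel spacing (mm).
#' @param n_angles Views over 180 degrees.
#' @param n0 Incident photons per ray (`Inf` disables counting noise).
#' @param seed Integer seed for the counting noise (required when `n0` is
#'   finite and reproducibility is wanted).
#' @param params [calibration_parameters()] for the attenuation model.
#' @param library Material library.
#' @return A [ct_image()]; `meta` records seed, starved-ray count, spectrum
#'   and nominal slice thickness.
#' @export
simulate_scan <- function(phantom,
                          spectrum = spectrum_120kvp(),
                          grid_dim = c(512, 512),
                          pixel_spacing = 0.7,
                          n_angles = 720,
                          n0 = 1e5,
                          seed = NULL,
                          params = calibration_parameters(),
                          library = material_library()) {
  ras <- rasterize_phantom(phantom, grid_dim, pixel_spacing, library)
  geometry <- default_geometry(ras$material * 1.0, n_angles,
                               pixel_spacing = pixel_spacing)
  res <- .effective_mu_image(ras, spectrum, geometry, params, library,
                             n0 = n0, seed = seed)
  mu_w <- .water_mu_eff(phantom, spectrum, geometry, grid_dim, pixel_spacing,
                        params, library)
  hu <- 1000 * (res$mu / mu_w - 1)
  ct_image(hu, pixel_spacing,
           meta = list(seed = seed, n0 = n0, n_starved = res$n_clamped,
                       spectrum = spectrum, n_angles = n_angles,
                       slice_thickness_mm = phantom$slice_thickness_mm))
}

#' Simulate the metal-free reference scan
#'
#' Identical acquisition chain with implant metal replaced by water; the PMMA
#' slab is retained.
#'
#' @inheritParams simulate_scan
#' @return A [ct_image()].
#' @export
reference_scan <- function(phantom, spectrum = spectrum_120kvp(),
                           grid_dim = c(512, 512), pixel_spacing = 0.7,
                           n_angles = 720, n0 = 1e5, seed = NULL,
                           params = calibration_parameters(),
                           library = material_library()) {
  simulate_scan(metal_free(phantom), spectrum, grid_dim, pixel_spacing,
                n_angles, n0, seed, params, library)
}

#' Write a CT image as flat text + JSON sidecar
#'
#' @param image A [ct_image()].
#' @param path Base path; writes `<path>.txt` and `<path>.json`.
#' @return Base path, invisibly.
#' @export
write_ct_image <- function(image, path) {
  utils::write.table(image$hu, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(nrow = nrow(image$hu), ncol = ncol(image$hu),
         pixel_spacing = image$pixel_spacing, origin = image$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CT image written by [write_ct_image()]
#'
#' @param path Base path (without extension).
#' @return A [ct_image()].
#' @export
read_ct_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  hu <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(hu) <- NULL
  stopifnot(nrow(hu) == side$nrow, ncol(hu) == side$ncol)
  ct_image(hu, side$pixel_spacing, origin = unlist(side$origin))
}
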