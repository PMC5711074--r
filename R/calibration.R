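# Two-step stoichiometric HU -> proton RSP calibration.
#
# Step 1: fit the scanner-specific cross-section ratios k_ph = K^ph/K^KN and
# k_coh = K^coh/K^KN from measured HU of known insert materials.
# Step 2: predict HU of reference tissues from their composition with the
# fitted parameters, pair each with its relative stopping power, and
# interpolate linearly between these anchors.

.P_PHOTO <- 3.62  # photoelectric effective-Z exponent
.P_COH <- 1.86    # coherent-scatter effective-Z exponent

#' Stoichiometric calibration parameters
#'
#' @param k_ph Photoelectric-to-Klein-Nishina cross-section ratio at the
#'   scanner's effective energy (dimensionless).
#' @param k_coh Coherent-to-Klein-Nishina ratio (dimensionless).
#' @return Object of class `calibration_parameters`. Defaults are the fitted
#'   values for the pelvic protocol this package emulates.
#' @export
calibration_parameters <- function(k_ph = 2.86e-5, k_coh = 7.20e-4) {
  if (k_ph < 0 || k_coh < 0) stop("parameters must be >= 0", call. = FALSE)
  structure(list(k_ph = k_ph, k_coh = k_coh),
            class = "calibration_parameters")
}

# Attenuation bracket of the stoichiometric parameterization at the effective
# scanner energy: k_ph * Zph^3.62 + k_coh * Zcoh^1.86 + 1 (the trailing 1 is
# the Klein-Nishina Compton term all others are expressed relative to).
.stoich_bracket <- function(material, params) {
  lambda <- material$za / material$za_sum
  params$k_ph * sum(lambda * material$Z^.P_PHOTO) +
    params$k_coh * sum(lambda * material$Z^.P_COH) + 1
}

#' Theoretical Hounsfield unit of a material
#'
#' HU = 1000 (mu/mu_water - 1) with mu proportional to electron density times
#' the stoichiometric bracket k_ph*Z~^3.62 + k_coh*Z^^1.86 + 1 (effective
#' atomic numbers as electron-fraction power means). Water maps to exactly
#' 0 HU by construction.
#'
#' @param material A [material()].
#' @param params A [calibration_parameters()].
#' @param water Reference water material.
#' @return Predicted HU (scalar).
#' @export
theoretical_hu <- function(material, params = calibration_parameters(),
                           water = material_library()$water) {
  if (material$rho * material$za_sum <= 0) {
    stop("material has non-positive electron density", call. = FALSE)
  }
  mu_rel <- relative_electron_density(material, water) *
    .stoich_bracket(material, params) / .stoich_bracket(water, params)
  1000 * (mu_rel - 1)
}

#' Fit calibration parameters from insert measurements
#'
#' Least-squares fit of (k_ph, k_coh) to measured HU values of materials of
#' known composition (typically water, PMMA and CaCl2 solutions spanning a
#' range of effective atomic numbers). The HU model is a ratio of two terms
#' linear in the parameters; an exact linearized solve provides the starting
#' point and a bounded quasi-Newton refinement minimizes the actual HU
#' sum of squares.
#'
#' @param measurements List of `list(material = <material>, hu = <number>)`
#'   entries (or a 2-column data.frame with columns `material`, `hu`).
#' @param water Reference water material.
#' @return Fitted [calibration_parameters()].
#' @export
fit_calibration <- function(measurements, water = material_library()$water) {
  if (is.data.frame(measurements)) {
    measurements <- lapply(seq_len(nrow(measurements)), function(i) {
      list(material = measurements$material[[i]], hu = measurements$hu[[i]])
    })
  }
  if (length(measurements) < 3) {
    stop("need at least 3 insert measurements", call. = FALSE)
  }
  mats <- lapply(measurements, `[[`, "material")
  hu <- vapply(measurements, `[[`, numeric(1), "hu")

  a <- vapply(mats, function(m) {
    lambda <- m$za / m$za_sum
    sum(lambda * m$Z^.P_PHOTO)
  }, numeric(1))
  b <- vapply(mats, function(m) {
    lambda <- m$za / m$za_sum
    sum(lambda * m$Z^.P_COH)
  }, numeric(1))
  r <- vapply(mats, relative_electron_density, numeric(1), water = water)
  lw <- water$za / water$za_sum
  aw <- sum(lw * water$Z^.P_PHOTO)
  bw <- sum(lw * water$Z^.P_COH)

  # Linearized exact form: H*(k*aw + c*bw + 1) = r*(k*a + c*b + 1), H = hu/1000+1
  h <- hu / 1000 + 1
  X <- cbind(h * aw - r * a, h * bw - r * b)
  y <- r - h
  qx <- qr(X)
  if (qx$rank < 2) {
    stop("degenerate calibration design: insert materials do not span ",
         "distinct effective atomic numbers", call. = FALSE)
  }
  start <- pmax(as.numeric(qr.coef(qx, y)), 0)

  obj <- function(p) {
    pars <- calibration_parameters(p[1], p[2])
    sum((vapply(mats, theoretical_hu, numeric(1),
                params = pars, water = water) - hu)^2)
  }
  # parscale: the two ratios differ by an order of magnitude
  fit <- stats::optim(start, obj, method = "L-BFGS-B", lower = c(0, 0),
                      control = list(factr = 1e4, maxit = 500,
                                     parscale = c(1e-5, 1e-4)))
  calibration_parameters(fit$par[1], fit$par[2])
}

#' Build the HU -> RSP anchor table
#'
#' Pairs the theoretical HU of the anchor tissues (lung, adipose, muscle,
#' cartilage, cortical bone) with their relative stopping power at the
#' reference proton energy. Air is included as the lowest anchor, pinning the
#' conversion near (-1000 HU, ~0): dark reconstruction artifacts then map
#' onto the air-lung segment of the curve instead of an unbounded downward
#' extrapolation, which keeps the conversion non-negative in practice and
#' preserves the reference-cancellation property of WET differences under a
#' uniform calibration offset.
#'
#' @param params A [calibration_parameters()].
#' @param energy Proton energy (MeV) at which anchor RSPs are evaluated.
#' @param library Material library providing the anchor tissues and water.
#' @param tissues Names of the anchor tissues within `library`.
#' @return Object of class `hu_rsp_table`: a list with an `anchors` tibble
#'   (tissue, hu, rsp sorted by HU), the energy and the parameters.
#' @export
build_hu_rsp_table <- function(params = calibration_parameters(),
                               energy = 219,
                               library = material_library(),
                               tissues = c("air", "lung", "adipose", "muscle",
                                           "cartilage", "cortical_bone")) {
  stopifnot(all(tissues %in% names(library)), "water" %in% names(library))
  water <- library$water
  hu <- vapply(library[tissues], theoretical_hu, numeric(1),
               params = params, water = water)
  rsp <- vapply(library[tissues], relative_stopping_power, numeric(1),
                E = energy, water = water)
  ord <- order(hu)
  anchors <- tibble::tibble(tissue = tissues[ord], hu = unname(hu[ord]),
                            rsp = unname(rsp[ord]))
  if (nrow(anchors) < 2 || any(diff(anchors$hu) <= 0)) {
    stop("anchor HU values are not strictly increasing; ",
         "calibration parameters are pathological", call. = FALSE)
  }
  structure(list(anchors = anchors, energy = energy, params = params),
            class = "hu_rsp_table")
}

#' @export
print.hu_rsp_table <- function(x, ...) {
  cat(sprintf("<hu_rsp_table> %d anchors at %g MeV (k_ph = %.3g, k_coh = %.3g)\n",
              nrow(x$anchors), x$energy, x$params$k_ph, x$params$k_coh))
  print(x$anchors)
  invisible(x)
}

#' HU -> RSP lookup
#'
#' Piecewise-linear interpolation between anchors with linear extrapolation
#' beyond the outermost anchors on each side, floored at a small positive
#' minimum so WET line integrals stay non-negative. Input HU below the air
#' value are clamped to it before conversion: no material stops protons less
#' than vacuum, and reconstruction artifacts can undershoot -1000 HU.
#'
#' @param table A [build_hu_rsp_table()] result.
#' @param hu Hounsfield units (vectorized).
#' @param floor Minimum returned RSP.
#' @param hu_min Input clamp (HU of air).
#' @return RSP values, same length as `hu`.
#' @export
rsp_lookup <- function(table, hu, floor = 0.001, hu_min = -1000) {
  hu <- pmax(hu, hu_min)
  a <- table$anchors
  n <- nrow(a)
  out <- stats::approx(a$hu, a$rsp, xout = hu, rule = 2)$y
  lo <- hu < a$hu[1]
  if (any(lo)) {
    s <- (a$rsp[2] - a$rsp[1]) / (a$hu[2] - a$hu[1])
    out[lo] <- a$rsp[1] + s * (hu[lo] - a$hu[1])
  }
  hi <- hu > a$hu[n]
  if (any(hi)) {
    s <- (a$rsp[n] - a$rsp[n - 1]) / (a$hu[n] - a$hu[n - 1])
    out[hi] <- a$rsp[n] + s * (hu[hi] - a$hu[n])
  }
  pmax(out, floor)
}

#' Serialize a calibration to JSON
#'
#' @param table A [build_hu_rsp_table()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(table, path) {
  doc <- list(
    k_ph = table$params$k_ph,
    k_coh = table$params$k_coh,
    energy_MeV = table$energy,
    anchors = lapply(seq_len(nrow(table$anchors)), function(i) {
      list(tissue = table$anchors$tissue[i],
           hu = table$anchors$hu[i],
           rsp = table$anchors$rsp[i])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path File written by [write_calibration_json()].
#' @return A `hu_rsp_table`.
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path)
  anchors <- tibble::tibble(
    tissue = vapply(doc$anchors, `[[`, character(1), "tissue"),
    hu = vapply(doc$anchors, `[[`, numeric(1), "hu"),
    rsp = vapply(doc$anchors, `[[`, numeric(1), "rsp")
  )
  structure(list(anchors = anchors, energy = doc$energy_MeV,
                 params = calibration_parameters(doc$k_ph, doc$k_coh)),
            class = "hu_rsp_table")
}
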