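# Material definitions and proton stopping-power physics.

# Elemental data: atomic number Z, atomic mass A (g/mol), mean excitation
# energy I (eV). I-values follow the standard ICRU elemental recommendations.
.ELEMENTS <- local({
  tab <- rbind(
    H  = c(1,  1.008,   19.2),
    C  = c(6,  12.011,  78.0),
    N  = c(7,  14.007,  82.0),
    O  = c(8,  15.999,  95.0),
    Na = c(11, 22.990,  149),
    Mg = c(12, 24.305,  156),
    Si = c(14, 28.085,  173),
    P  = c(15, 30.974,  173),
    S  = c(16, 32.06,   180),
    Cl = c(17, 35.45,   174),
    Ar = c(18, 39.948,  188),
    K  = c(19, 39.098,  190),
    Ca = c(20, 40.078,  191),
    Ti = c(22, 47.867,  233),
    Cr = c(24, 51.996,  257),
    Mn = c(25, 54.938,  272),
    Fe = c(26, 55.845,  286),
    Co = c(27, 58.933,  297),
    Ni = c(28, 58.693,  311),
    Mo = c(42, 95.95,   424)
  )
  colnames(tab) <- c("Z", "A", "I")
  tab
})

# Physical constants (MeV units)
.K_BETHE <- 0.307075      # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.ME_C2 <- 0.51099895      # electron rest energy, MeV
.MP_C2 <- 938.2720882     # proton rest energy, MeV

#' Look up elemental data
#'
#' @param symbol Character vector of element symbols.
#' @return Matrix with columns `Z`, `A`, `I` (one row per symbol).
#' @keywords internal
element_data <- function(symbol) {
  miss <- setdiff(symbol, rownames(.ELEMENTS))
  if (length(miss) > 0) {
    stop("unknown element(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[symbol, , drop = FALSE]
}

#' Define a material
#'
#' A material is an elemental composition by mass, a mass density and a mean
#' excitation energy. The composition drives both the keV photon attenuation
#' model used for CT simulation/calibration and the MeV proton stopping power.
#'
#' @param name Label.
#' @param rho Mass density in g/cm^3.
#' @param composition Named numeric vector of elemental mass fractions
#'   (names are element symbols); must sum to 1 within 1e-6.
#' @param I Mean excitation energy in eV. If `NULL`, computed from the
#'   elemental I-values by the Bragg-additivity log-average over electron
#'   fractions.
#' @return An object of class `material`.
#' @export
#' @examples
#' water <- material("water", 1.0, c(H = 0.111894, O = 0.888106), I = 75)
material <- function(name, rho, composition, I = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  w <- as.numeric(composition)
  sym <- names(composition)
  if (is.null(sym) || any(!nzchar(sym))) {
    stop("composition must be a named vector of mass fractions", call. = FALSE)
  }
  if (any(w <= 0) || any(w > 1)) {
    stop("mass fractions must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  }
  el <- element_data(sym)
  # electrons per gram contribution of each element: w * Z / A
  za <- w * el[, "Z"] / el[, "A"]
  if (is.null(I)) {
    I <- exp(sum(za * log(el[, "I"])) / sum(za))
  }
  if (!is.numeric(I) || I <= 0) stop("I must be positive (eV)", call. = FALSE)
  structure(
    list(name = name, rho = rho, symbols = sym, w = w,
         Z = unname(el[, "Z"]), A = unname(el[, "A"]),
         I = unname(I), za_sum = sum(za), za = unname(za)),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho = %.4g g/cm^3, I = %.4g eV, Z/A = %.4f\n",
              x$name, x$rho, x$I, x$za_sum))
  cat("  ", paste(sprintf("%s=%.4g", x$symbols, x$w), collapse = " "), "\n")
  invisible(x)
}

#' Electron density relative to water
#'
#' @param material A [material()].
#' @param water The water material used as reference.
#' @return rho_e(material) / rho_e(water), dimensionless.
#' @export
relative_electron_density <- function(material, water = material_library()$water) {
  (material$rho * material$za_sum) / (water$rho * water$za_sum)
}

#' Effective atomic number (power mean over electron fractions)
#'
#' Z-hat = (sum_i lambda_i Z_i^p)^(1/p) with lambda_i the electron fraction of
#' element i. Exponents 3.62 (photoelectric) and 1.86 (coherent scatter) are
#' the standard stoichiometric-calibration values.
#'
#' @param material A [material()].
#' @param p Power-mean exponent.
#' @return Effective atomic number (dimensionless).
#' @export
effective_z <- function(material, p) {
  lambda <- material$za / material$za_sum
  sum(lambda * material$Z^p)^(1 / p)
}

#' Built-in material library
#'
#' Reference human tissues (compositions and densities from the standard
#' ICRP/ICRU tabulations), phantom materials (PMMA, chromium-cobalt implant
#' alloy) and calibration-insert CaCl2 solutions. Water carries the
#' conventional I = 75 eV; compound I-values are otherwise derived by Bragg
#' additivity.
#'
#' @param cacl2_concentrations Mass concentrations (fractions) of CaCl2
#'   dissolved in water for which insert materials are generated.
#' @return Named list of [material()] objects; always includes `water`.
#' @export
material_library <- function(cacl2_concentrations = c(0.02, 0.05, 0.10, 0.15, 0.20)) {
  lib <- list(
    water = material("water", 1.000,
                     c(H = 0.111894, O = 0.888106), I = 75),
    air = material("air", 0.0012048,
                   c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012828)),
    lung = material("lung", 0.26,
                    c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
                      P = 0.002, S = 0.003, Cl = 0.003, K = 0.002)),
    adipose = material("adipose", 0.95,
                       c(H = 0.114, C = 0.598, N = 0.007, O = 0.278,
                         Na = 0.001, S = 0.001, Cl = 0.001)),
    muscle = material("muscle", 1.05,
                      c(H = 0.102, C = 0.143, N = 0.034, O = 0.710,
                        Na = 0.001, P = 0.002, S = 0.003, Cl = 0.001,
                        K = 0.004)),
    cartilage = material("cartilage", 1.10,
                         c(H = 0.096, C = 0.099, N = 0.022, O = 0.744,
                           Na = 0.005, P = 0.022, S = 0.009, Cl = 0.003)),
    cortical_bone = material("cortical_bone", 1.92,
                             c(H = 0.034, C = 0.155, N = 0.042, O = 0.435,
                               Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003,
                               Ca = 0.225)),
    pmma = material("pmma", 1.19,
                    c(H = 0.080538, C = 0.599848, O = 0.319614), I = 74),
    crco = material("crco", 8.3,
                    c(Co = 0.63, Cr = 0.30, Mo = 0.06, Ni = 0.01))
  )
  for (conc in cacl2_concentrations) {
    m <- cacl2_solution(conc)
    lib[[m$name]] <- m
  }
  lib
}

#' CaCl2-in-water calibration insert
#'
#' @param concentration Mass fraction of dissolved CaCl2 (0 < c < 0.45).
#' @return A [material()] for the solution; density follows the usual
#'   near-linear concentration dependence rho = 1 + 0.84 c g/cm^3.
#' @export
cacl2_solution <- function(concentration) {
  stopifnot(concentration > 0, concentration < 0.45)
  a_ca <- 40.078; a_cl2 <- 2 * 35.45
  m_cacl2 <- a_ca + a_cl2
  comp <- c(
    Ca = concentration * a_ca / m_cacl2,
    Cl = concentration * a_cl2 / m_cacl2,
    H  = (1 - concentration) * 0.111894,
    O  = (1 - concentration) * 0.888106
  )
  material(sprintf("cacl2_%02.0fpct", 100 * concentration),
           1 + 0.84 * concentration, comp)
}

#' Read a material library from a plain-text table
#'
#' One material per line: `name density I element:fraction element:fraction ...`
#' Fields are whitespace-separated; `I` may be `NA` to request Bragg
#' additivity; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named list of [material()] objects.
#' @export
read_material_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lib <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 4) stop("malformed material line: ", ln, call. = FALSE)
    pairs <- strsplit(f[-(1:3)], ":", fixed = TRUE)
    comp <- vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
    names(comp) <- vapply(pairs, `[`, character(1), 1)
    I <- suppressWarnings(as.numeric(f[3]))
    lib[[f[1]]] <- material(f[1], as.numeric(f[2]), comp,
                            I = if (is.na(I)) NULL else I)
  }
  lib
}

#' Proton stopping-power model settings
#'
#' @param reference_energy Proton kinetic energy (MeV) at which the HU-to-RSP
#'   anchor table is evaluated; clinical convention here is 219 MeV.
#' @param valid_range Energy interval (MeV) over which the single-energy RSP
#'   is considered representative.
#' @return A list of class `stopping_power_model`.
#' @export
stopping_power_model <- function(reference_energy = 219,
                                 valid_range = c(50, 250)) {
  stopifnot(length(valid_range) == 2, valid_range[1] < reference_energy,
            reference_energy < valid_range[2])
  structure(list(reference_energy = reference_energy,
                 valid_range = valid_range),
            class = "stopping_power_model")
}

#' Proton mass stopping power (Bethe formula)
#'
#' First-order Bethe stopping power without shell, Barkas or density-effect
#' corrections; at therapeutic proton energies (50-250 MeV) in light media
#' these corrections are sub-percent and irrelevant for stopping-power
#' *ratios*.
#'
#' @param material A [material()].
#' @param E Proton kinetic energy in MeV (vectorized); must lie in [1, 300].
#' @return Mass stopping power in MeV cm^2 / g.
#' @export
#' @examples
#' mass_stopping_power(material_library()$water, 219)
mass_stopping_power <- function(material, E) {
  if (!inherits(material, "material")) stop("not a material", call. = FALSE)
  if (any(E < 1 | E > 300)) {
    stop("proton energy outside validity range [1, 300] MeV", call. = FALSE)
  }
  gamma <- 1 + E / .MP_C2
  beta2 <- 1 - 1 / gamma^2
  b2g2 <- beta2 * gamma^2
  i_mev <- material$I * 1e-6
  L <- log(2 * .ME_C2 * b2g2 / i_mev) - beta2
  .K_BETHE * material$za_sum * L / beta2
}

#' Relative proton stopping power (RSP)
#'
#' rho_s = rho_m (S/rho)_m / (rho_w (S/rho)_w): the ratio of the medium's
#' linear stopping power to water's. Identically 1 for water at any energy.
#'
#' @inheritParams mass_stopping_power
#' @param water Reference water material.
#' @return Dimensionless RSP (vectorized over `E`).
#' @export
relative_stopping_power <- function(material, E,
                                    water = material_library()$water) {
  (material$rho * mass_stopping_power(material, E)) /
    (water$rho * mass_stopping_power(water, E))
}

#' Energy stability of the RSP relative to a reference energy
#'
#' Maximum relative deviation of rho_s(E) from rho_s(E_ref) over an energy
#' grid spanning the model's validity range.
#'
#' @param material A [material()].
#' @param model A [stopping_power_model()].
#' @param step Grid step in MeV.
#' @param water Reference water material.
#' @return Maximum of |rho_s(E) - rho_s(E_ref)| / rho_s(E_ref), dimensionless.
#' @export
rsp_energy_stability <- function(material, model = stopping_power_model(),
                                 step = 5, water = material_library()$water) {
  grid <- seq(model$valid_range[1], model$valid_range[2], by = step)
  r <- relative_stopping_power(material, grid, water = water)
  r0 <- relative_stopping_power(material, model$reference_energy, water = water)
  max(abs(r - r0) / r0)
}
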