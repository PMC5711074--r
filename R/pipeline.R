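# Study orchestration: phantom simulation -> MAR -> calibration -> WET
# evaluation, for the one- and two-insert phantom variants.

#' Full study configuration
#'
#' @param phantom Two-insert [phantom_spec()] (the one-insert variant is
#'   derived from it).
#' @param spectrum Acquisition [spectrum_model()].
#' @param grid_dim Image dimensions `c(nrow, ncol)`.
#' @param pixel_spacing Pixel spacing (mm).
#' @param n_angles Views over 180 degrees.
#' @param n0 Incident photons per ray.
#' @param seed Integer seed for the counting noise.
#' @param mar A [mar_config()].
#' @param params [calibration_parameters()].
#' @param energy Proton energy (MeV) for the RSP anchors.
#' @param poi Point of interest (mm); `NULL` uses [default_poi()].
#' @param step_deg Angular step of the WET scan (degrees).
#' @param output_dir Output directory for [run_study()].
#' @return Object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_spec(),
                         spectrum = spectrum_120kvp(),
                         grid_dim = c(512, 512),
                         pixel_spacing = 0.7,
                         n_angles = 720,
                         n0 = 1e5,
                         seed = 101,
                         mar = mar_config(),
                         params = calibration_parameters(),
                         energy = 219,
                         poi = NULL,
                         step_deg = 4,
                         output_dir = NULL) {
  structure(list(phantom = phantom, spectrum = spectrum, grid_dim = grid_dim,
                 pixel_spacing = pixel_spacing, n_angles = n_angles, n0 = n0,
                 seed = as.integer(seed), mar = mar, params = params,
                 energy = energy, poi = poi, step_deg = step_deg,
                 output_dir = output_dir),
            class = "study_config")
}

# Simulate + correct + evaluate one phantom variant.
.run_variant <- function(phantom, config, table, library, seed) {
  uncorr <- simulate_scan(phantom, config$spectrum, config$grid_dim,
                          config$pixel_spacing, config$n_angles, config$n0,
                          seed = seed, params = config$params,
                          library = library)
  reference <- reference_scan(phantom, config$spectrum, config$grid_dim,
                              config$pixel_spacing, config$n_angles,
                              config$n0, seed = seed, params = config$params,
                              library = library)
  mar_cfg <- config$mar
  if (is.null(mar_cfg$geometry)) {
    mar_cfg$geometry <- default_geometry(uncorr$hu, config$n_angles,
                                         pixel_spacing = config$pixel_spacing)
  }
  corrected <- omar_correct(uncorr, mar_cfg)
  poi <- if (is.null(config$poi)) default_poi(phantom) else config$poi
  scan <- angular_scan(uncorr, corrected$corrected, reference, poi, table,
                       phantom = phantom, step_deg = config$step_deg)
  list(uncorr = uncorr, reference = reference,
       corrected = corrected$corrected,
       mar_diagnostics = corrected$diagnostics,
       scan = scan, summary = summarize_wet(scan), poi = poi)
}

#' Run the full study
#'
#' Simulates uncorrected and metal-free reference scans for the two-insert
#' and one-insert phantom variants, applies the MAR correction, builds the
#' HU-to-RSP calibration, runs the angular WET scan for each variant and
#' writes the output bundle (calibration JSON, WET CSVs, summary JSON,
#' optional figures and images). Fully reproducible from the configuration
#' and seed.
#'
#' @param config A [study_config()].
#' @param library Material library.
#' @param write_images Also write the six HU images as text + JSON sidecars.
#' @param plots Write angle-scan and profile figures (requires ggplot2).
#' @return List with per-variant results (`two_insert`, `one_insert`), the
#'   calibration `table`, the configuration hash and the output paths.
#' @export
run_study <- function(config = study_config(), library = material_library(),
                      write_images = FALSE, plots = FALSE) {
  table <- build_hu_rsp_table(config$params, config$energy, library)
  hash <- rlang::hash(config)

  two <- .run_variant(config$phantom, config, table, library, config$seed)
  one_phantom <- phantom_spec(
    n_inserts = 1, separation = config$phantom$separation,
    insert_radius = max(config$phantom$inserts[[1]]$radii),
    slab_thickness = config$phantom$slab_thickness,
    width = config$phantom$width, water_depth = config$phantom$water_depth,
    tank_height = config$phantom$tank_height)
  # one-insert variant keeps the POI of the two-insert geometry so the two
  # scans probe the same anatomical point
  cfg_one <- config
  cfg_one$poi <- if (is.null(config$poi)) default_poi(config$phantom) else config$poi
  one <- .run_variant(one_phantom, cfg_one, table, library,
                      config$seed + 1L)

  out <- list(two_insert = two, one_insert = one, table = table,
              config = config, config_hash = hash, paths = character(0))
  dir <- config$output_dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(dir, paste0(...))
    write_calibration_json(table, p("calibration.json"))
    write_wet_csv(two$scan, p("wet_two_insert.csv"))
    write_wet_csv(one$scan, p("wet_one_insert.csv"))
    utils::write.csv(as.data.frame(two$mar_diagnostics),
                     p("mar_diagnostics_two_insert.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           grid_dim = config$grid_dim, n_angles = config$n_angles,
           two_insert = two$summary, one_insert = one$summary),
      p("summary.json"), auto_unbox = TRUE, digits = NA)
    if (write_images) {
      write_ct_image(two$uncorr, p("two_insert_uncorrected"))
      write_ct_image(two$corrected, p("two_insert_corrected"))
      write_ct_image(two$reference, p("two_insert_reference"))
      write_ct_image(one$uncorr, p("one_insert_uncorrected"))
      write_ct_image(one$corrected, p("one_insert_corrected"))
      write_ct_image(one$reference, p("one_insert_reference"))
    }
    if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
      ggplot2::ggsave(p("wet_vs_angle_two_insert.png"),
                      plot_wet_vs_angle(two$scan), width = 7, height = 4,
                      dpi = 150)
      ggplot2::ggsave(p("wet_vs_angle_one_insert.png"),
                      plot_wet_vs_angle(one$scan), width = 7, height = 4,
                      dpi = 150)
      prof <- wet_profile(two$uncorr, two$corrected, two$reference, two$poi,
                          table, 180, phantom = config$phantom)
      ggplot2::ggsave(p("wet_profile_180deg.png"), plot_wet_profile(prof),
                      width = 7, height = 4, dpi = 150)
    }
    out$paths <- list.files(dir, full.names = TRUE)
  }
  out
}

# Load a slice argument: a ct_image, a write_ct_image() base path, or a
# single-slice NIfTI file.
.load_slice <- function(x, what) {
  if (is.null(x)) {
    stop("a ", what, " image is required", call. = FALSE)
  }
  if (inherits(x, "ct_image")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.nii(\\.gz)?$", x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("RNifti is required to read NIfTI slices", call. = FALSE)
      }
      img <- RNifti::readNifti(x)
      ps <- RNifti::pixdim(img)[1]
      return(ct_image(as.matrix(img[, , drop = TRUE]), ps))
    }
    return(read_ct_image(sub("\\.(txt|json)$", "", x)))
  }
  stop("cannot interpret ", what, " image argument", call. = FALSE)
}

#' Evaluate WET on externally acquired slices
#'
#' Skips simulation and MAR: takes three co-registered single slices (the
#' scanner's uncorrected and MAR-corrected reconstructions plus the
#' metal-free reference), runs the angular WET scan and returns the table
#' and summary. Metal exclusion is segmented from the uncorrected slice.
#'
#' @param uncorr,omar,reference [ct_image()] objects or file paths
#'   (text + JSON sidecar base path, or single-slice `.nii`/`.nii.gz`).
#' @param poi Point of interest `c(x, y)` in mm.
#' @param table A [build_hu_rsp_table()] result.
#' @param step_deg Angular step (degrees).
#' @param output_dir Optional directory for the WET CSV and summary JSON.
#' @return List: `scan` (the [angular_scan()] table) and `summary`.
#' @export
run_on_real_slices <- function(uncorr, omar, reference, poi,
                               table = build_hu_rsp_table(),
                               step_deg = 4, output_dir = NULL) {
  u <- .load_slice(uncorr, "uncorrected")
  o <- .load_slice(omar, "MAR-corrected")
  r <- .load_slice(reference, "reference")
  scan <- angular_scan(u, o, r, poi, table, phantom = NULL,
                       step_deg = step_deg)
  summary <- summarize_wet(scan)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_wet_csv(scan, file.path(output_dir, "wet_real_slices.csv"))
    jsonlite::write_json(summary,
                         file.path(output_dir, "summary_real_slices.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scan = scan, summary = summary)
}
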