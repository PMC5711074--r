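# Stoichiometric HU calibration and the HU -> RSP lookup.

test_that("theoretical HU anchors: water 0, air about -1000", {
  lib <- material_library()
  expect_identical(theoretical_hu(lib$water), 0)
  expect_equal(theoretical_hu(lib$air), -1000, tolerance = 5 / 1000)
})

test_that("theoretical HU agrees with an independent power-mean evaluation", {
  lib <- material_library()
  p <- calibration_parameters()
  hu_bone <- theoretical_hu(lib$cortical_bone, p)
  ref <- oracle_hu(lib$cortical_bone$symbols, lib$cortical_bone$w,
                   lib$cortical_bone$rho, p$k_ph, p$k_coh)
  expect_equal(hu_bone, ref, tolerance = 1e-10)
  expect_gt(hu_bone, 500)
  # frozen regression value for the default parameters
  expect_equal(hu_bone, 1446.24230, tolerance = 1e-7)
  # independent check for a soft tissue too
  expect_equal(theoretical_hu(lib$adipose, p),
               oracle_hu(lib$adipose$symbols, lib$adipose$w,
                         lib$adipose$rho, p$k_ph, p$k_coh),
               tolerance = 1e-10)
})

test_that("calibration fit recovers generating parameters from clean data", {
  lib <- material_library()
  truth <- calibration_parameters(2.86e-5, 7.20e-4)
  inserts <- lib[c("water", "pmma", "cacl2_02pct", "cacl2_05pct",
                   "cacl2_10pct", "cacl2_15pct", "cacl2_20pct")]
  meas <- lapply(inserts, function(m) {
    list(material = m, hu = theoretical_hu(m, truth))
  })
  fit <- fit_calibration(meas)
  expect_equal(fit$k_ph, truth$k_ph, tolerance = 1e-3)
  expect_equal(fit$k_coh, truth$k_coh, tolerance = 1e-3)
})

test_that("calibration fit tolerates measurement noise", {
  lib <- material_library()
  truth <- calibration_parameters()
  inserts <- lib[c("water", "pmma", "cacl2_02pct", "cacl2_05pct",
                   "cacl2_10pct", "cacl2_15pct", "cacl2_20pct")]
  withr::with_seed(11, {
    meas <- lapply(inserts, function(m) {
      list(material = m, hu = theoretical_hu(m, truth) + rnorm(1, sd = 2))
    })
  })
  fit <- fit_calibration(meas)
  expect_equal(fit$k_ph, truth$k_ph, tolerance = 0.05)
  expect_equal(fit$k_coh, truth$k_coh, tolerance = 0.05)
})

test_that("degenerate calibration designs are rejected", {
  lib <- material_library()
  same <- lapply(c(0, 10, -5), function(hu) list(material = lib$water, hu = hu))
  expect_error(fit_calibration(same), "degenerate")
  expect_error(fit_calibration(same[1:2]), "at least 3")
})

test_that("anchor table is ordered air -> lung -> bone, one anchor per tissue", {
  tab <- build_hu_rsp_table()
  expect_s3_class(tab, "hu_rsp_table")
  expect_equal(nrow(tab$anchors), 6)
  expect_equal(tab$anchors$tissue[1:2], c("air", "lung"))
  expect_equal(tab$anchors$tissue[6], "cortical_bone")
  expect_true(all(diff(tab$anchors$hu) > 0))
  expect_equal(tab$anchors$hu[1], -1000, tolerance = 5 / 1000)
  # anchor RSPs are exactly the stopping-power module's outputs
  lib <- material_library()
  for (i in seq_len(nrow(tab$anchors))) {
    expect_identical(tab$anchors$rsp[i],
                     relative_stopping_power(lib[[tab$anchors$tissue[i]]], 219))
  }
})

test_that("lookup interpolates through anchors and extrapolates linearly", {
  tab <- build_hu_rsp_table()
  a <- tab$anchors
  expect_identical(rsp_lookup(tab, a$hu), a$rsp)
  mid <- (a$hu[2] + a$hu[3]) / 2
  expect_equal(rsp_lookup(tab, mid), (a$rsp[2] + a$rsp[3]) / 2,
               tolerance = 1e-12)
  # beyond the last anchor: the line through the outermost two anchors
  n <- nrow(a)
  slope_hi <- (a$rsp[n] - a$rsp[n - 1]) / (a$hu[n] - a$hu[n - 1])
  expect_equal(rsp_lookup(tab, a$hu[n] + 100), a$rsp[n] + 100 * slope_hi,
               tolerance = 1e-12)
  # below the air anchor the input is clamped to -1000 HU
  expect_identical(rsp_lookup(tab, -1200), rsp_lookup(tab, -1000))
  slope_lo <- (a$rsp[2] - a$rsp[1]) / (a$hu[2] - a$hu[1])
  expect_equal(rsp_lookup(tab, -1000),
               pmax(a$rsp[1] + (-1000 - a$hu[1]) * slope_lo, 0.001),
               tolerance = 1e-9)
})

test_that("lookup is continuous, monotone over the span, and floored", {
  tab <- build_hu_rsp_table()
  grid <- seq(-1100, 2000, by = 1)
  v <- rsp_lookup(tab, grid)
  expect_true(all(is.finite(v)))
  expect_true(all(v > 0))
  span <- grid >= tab$anchors$hu[1] & grid <= tab$anchors$hu[5]
  expect_true(all(diff(v[span]) >= -1e-12))
  expect_true(all(abs(diff(v)) < 0.01))     # no jumps at 1-HU resolution
  expect_true(all(v >= 0.001))
  # the HU range observed in the study images maps to finite positive RSP
  expect_true(all(rsp_lookup(tab, c(-740, 1370)) > 0))
})

test_that("calibration JSON round-trips", {
  tab <- build_hu_rsp_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(tab, path)
  back <- read_calibration_json(path)
  expect_equal(back$anchors, tab$anchors, tolerance = 1e-12)
  expect_equal(back$energy, tab$energy)
  expect_equal(back$params$k_ph, tab$params$k_ph)
})
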