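# Ray tracing, WET integration and the angular WET-difference scan.

make_uniform_image <- function(hu_value, n = 100, ps = 1) {
  ct_image(matrix(hu_value, n, n), ps)
}

square_bounds <- function(half = 50) {
  list(xlim = c(-half, half), ylim = c(-half, half))
}

test_that("ray geometry follows the clockwise from-the-top convention", {
  img <- make_uniform_image(0)
  b <- square_bounds(50)
  r0 <- trace_ray(c(0, 0), 0, img, b)
  expect_equal(r0$entry, c(0, 50))              # from the top, straight down
  expect_equal(r0$length_mm, 50)
  r90 <- trace_ray(c(0, 0), 90, img, b)
  expect_equal(r90$entry, c(50, 0))             # from the right
  r180 <- trace_ray(c(0, 0), 180, img, b)
  expect_equal(r180$entry, c(0, -50), tolerance = 1e-9)
  # 0 and 180 degrees are collinear, opposite edges
  expect_equal(r0$entry + r180$entry, c(0, 0), tolerance = 1e-9)
  # off-centre POI: entry stays directly above for 0 degrees
  r <- trace_ray(c(13, -20), 0, img, b)
  expect_equal(r$entry, c(13, 50))
  expect_equal(r$length_mm, 70)
})

test_that("sample steps tile the entry-to-POI distance exactly", {
  img <- make_uniform_image(0)
  b <- square_bounds(50)
  for (a in c(0, 37, 90, 211, 304)) {
    r <- trace_ray(c(7, -11), a, img, b)
    expect_equal(nrow(r$samples) * r$ds, r$length_mm, tolerance = 1e-9)
    # last midpoint sample sits half a step short of the POI
    expect_equal(sqrt(sum((r$samples[nrow(r$samples), ] - c(7, -11))^2)),
                 r$ds / 2, tolerance = 1e-9)
    expect_lte(r$ds, img$pixel_spacing / 2 + 1e-12)
  }
  expect_error(trace_ray(c(100, 0), 0, img, b), "outside")
})

test_that("constant-HU images integrate to rho_s times the path length", {
  tab <- build_hu_rsp_table()
  adipose_hu <- tab$anchors$hu[tab$anchors$tissue == "adipose"]
  adipose_rsp <- tab$anchors$rsp[tab$anchors$tissue == "adipose"]
  img <- make_uniform_image(adipose_hu, n = 220, ps = 1)
  b <- square_bounds(100)
  ray <- trace_ray(c(0, 0), 0, img, b)   # length exactly 100 mm
  wet <- wet_to_poi(img, tab, ray)
  expect_equal(wet, adipose_rsp * 10, tolerance = 1e-12)
})

test_that("a 3-sample toy ray reproduces the hand-summed discrete integral", {
  tab <- build_hu_rsp_table()
  hu <- c(0, tab$anchors$hu[tab$anchors$tissue == "muscle"],
          tab$anchors$hu[tab$anchors$tissue == "cortical_bone"])
  # vertical ray sampled exactly at the three row centres (y = 1, 0, -1)
  ray <- structure(list(angle_deg = 0, entry = c(0, 2), poi = c(0, -1),
                        samples = cbind(0, c(1, 0, -1)), ds = 1,
                        length_mm = 3, cumulative_wet = NULL),
                   class = "ray_profile")
  # image: three one-mm rows carrying those HU values top to bottom
  img <- ct_image(matrix(hu, 3, 3), 1)
  filled <- wet_along_ray(img, tab, ray)
  expected <- cumsum(rsp_lookup(tab, hu)) * 1 / 10
  expect_equal(filled$cumulative_wet, expected, tolerance = 1e-12)
})

test_that("WET is additive over subpaths", {
  st <- ci_study()
  tab <- st$table
  img <- st$two_insert$reference
  b <- phantom_bounds(st$config$phantom)
  ray <- trace_ray(c(0, -108), 45, img, b)
  filled <- wet_along_ray(img, tab, ray)
  n <- length(filled$cumulative_wet)
  m <- floor(n / 2)
  # WET(entry -> POI) = WET(entry -> midpoint) + WET(midpoint -> POI), the
  # tail evaluated as an independent ray starting at the midpoint sample
  tail_ray <- structure(list(angle_deg = ray$angle_deg,
                             entry = ray$samples[m, ], poi = ray$poi,
                             samples = ray$samples[(m + 1):n, , drop = FALSE],
                             ds = ray$ds, length_mm = (n - m) * ray$ds,
                             cumulative_wet = NULL),
                        class = "ray_profile")
  tail_wet <- wet_to_poi(img, tab, tail_ray)
  expect_equal(filled$cumulative_wet[m] + tail_wet,
               filled$cumulative_wet[n], tolerance = 1e-9)
})

test_that("half-pixel sampling agrees with a 10x refined integration", {
  st <- ci_study()
  tab <- st$table
  img <- st$two_insert$reference
  b <- phantom_bounds(st$config$phantom)
  poi <- c(0, -108)
  withr::with_seed(21, angles <- runif(20, 0, 360))
  for (a in angles) {
    ray <- trace_ray(poi, a, img, b)
    wet <- wet_to_poi(img, tab, ray)
    expect_equal(wet, oracle_wet(img, tab, poi, a, b, refine = 10),
                 tolerance = 1e-3)
  }
})

test_that("resampled WET matches a voxel-intersection (Siddon) integral", {
  st <- ci_study()
  tab <- st$table
  img <- st$two_insert$reference
  b <- phantom_bounds(st$config$phantom)
  poi <- c(0, -108)
  for (a in c(0, 30, 120, 200, 333)) {
    ray <- trace_ray(poi, a, img, b)
    wet <- wet_to_poi(img, tab, ray)
    sid <- siddon_wet(img, tab, ray$entry, ray$poi)
    expect_equal(wet, sid, tolerance = 0.02)
  }
})

test_that("self-comparison yields identically zero differences", {
  st <- ci_study()
  img <- st$two_insert$reference
  sc <- angular_scan(img, img, img, c(0, -108), st$table,
                     phantom = st$config$phantom)
  keep <- !sc$excluded
  expect_true(any(keep))
  expect_true(all(sc$diff_uncorr_cm[keep] == 0))
  expect_true(all(sc$diff_omar_cm[keep] == 0))
  expect_true(all(sc$maxpath_diff_uncorr_cm[keep] == 0))
})

test_that("the angular grid and exclusion bookkeeping are correct", {
  st <- ci_study()
  sc <- st$two_insert$scan
  expect_equal(nrow(sc), 90)
  expect_equal(sc$angle_deg, seq(0, 356, by = 4))
  expect_true(all(is.na(sc$wet_ref_cm[sc$excluded])))
  keep <- !sc$excluded
  # the along-path maximum dominates the endpoint difference
  expect_true(all(sc$maxpath_diff_uncorr_cm[keep] >=
                    abs(sc$diff_uncorr_cm[keep]) - 1e-12))
  expect_true(all(sc$maxpath_diff_omar_cm[keep] >=
                    abs(sc$diff_omar_cm[keep]) - 1e-12))
  # rays through the implants are excluded: near-horizontal directions
  expect_true(all(c(88, 92, 268, 272) %in% sc$angle_deg[sc$excluded]))
})

test_that("mismatched grids are rejected", {
  a <- make_uniform_image(0, n = 64, ps = 1)
  b <- make_uniform_image(0, n = 32, ps = 1)
  tab <- build_hu_rsp_table()
  expect_error(angular_scan(a, b, a, c(0, 0), tab), "share grid")
  c2 <- make_uniform_image(0, n = 64, ps = 2)
  expect_error(angular_scan(a, c2, a, c(0, 0), tab), "share grid")
})

test_that("summaries reduce the table deterministically", {
  tab <- build_hu_rsp_table()
  res <- tibble::tibble(
    angle_deg = c(0, 90, 180), excluded = c(FALSE, TRUE, FALSE),
    wet_ref_cm = c(10, NA, 10), wet_uncorr_cm = c(10, NA, 11.3),
    wet_omar_cm = c(10, NA, 10.2),
    diff_uncorr_cm = c(0, NA, 1.3), diff_omar_cm = c(0, NA, 0.2),
    maxpath_diff_uncorr_cm = c(0, NA, 1.4),
    maxpath_diff_omar_cm = c(0, NA, 0.3))
  s <- summarize_wet(res)
  expect_equal(s$max_abs_diff_uncorr_cm, 1.3)
  expect_equal(s$angle_at_max_uncorr, 180)
  expect_equal(s$n_excluded, 1)
  all_ex <- res; all_ex$excluded <- TRUE
  expect_error(summarize_wet(all_ex), "excluded")
})

test_that("an anchor-wide RSP offset cancels in the WET differences", {
  st <- ci_study()
  tab <- st$table
  shifted <- tab
  shifted$anchors$rsp <- shifted$anchors$rsp + 0.02
  res <- st$two_insert
  poi <- res$poi
  base <- st$two_insert$scan
  alt <- angular_scan(res$uncorr, res$corrected, res$reference, poi, shifted,
                      phantom = st$config$phantom)
  keep <- !base$excluded
  for (col in c("diff_uncorr_cm", "diff_omar_cm")) {
    d0 <- base[[col]][keep]
    d1 <- alt[[col]][keep]
    expect_true(all(abs(d1 - d0) < 0.02 * abs(d0) + 1e-6))
  }
})
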