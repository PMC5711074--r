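# Radon forward/back projection and filtered back projection.

test_that("projectors are linear and vanish on zero input", {
  n <- 32
  g <- default_geometry(matrix(0, n, n), n_angles = 24, pixel_spacing = 1)
  z <- forward_project(matrix(0, n, n), g)
  expect_true(all(z$values == 0))
  expect_true(all(back_project(z) == 0))
  expect_true(all(fbp_reconstruct(z) == 0))
  withr::with_seed(3, {
    a <- matrix(rnorm(n * n), n, n)
    b <- matrix(rnorm(n * n), n, n)
  })
  sa <- forward_project(a, g)$values
  sb <- forward_project(b, g)$values
  sab <- forward_project(2 * a - 3 * b, g)$values
  expect_equal(sab, 2 * sa - 3 * sb, tolerance = 1e-10)
  # FBP linearity
  fa <- fbp_reconstruct(structure(list(values = sa, geometry = g),
                                  class = "sinogram"))
  fb <- fbp_reconstruct(structure(list(values = sb, geometry = g),
                                  class = "sinogram"))
  fab <- fbp_reconstruct(structure(list(values = 2 * sa - 3 * sb,
                                        geometry = g), class = "sinogram"))
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-8)
})

test_that("rotationally symmetric images project almost identically per view", {
  n <- 128; ps <- 1
  x <- (seq_len(n) - (n + 1) / 2) * ps
  blob <- outer(x, x, function(yy, xx) exp(-(xx^2 + yy^2) / (2 * 20^2)))
  g <- default_geometry(blob, n_angles = 90, pixel_spacing = ps)
  s <- forward_project(blob, g)$values
  spread <- max(apply(s, 2, function(v) diff(range(v))))
  expect_lt(spread / max(s), 0.01)
})

test_that("a single off-centre pixel traces a sinusoid matching brute force", {
  n <- 32; ps <- 1
  img <- matrix(0, n, n)
  img[10, 22] <- 1
  g <- default_geometry(img, n_angles = 36, pixel_spacing = ps)
  s <- forward_project(img, g)$values
  oracle <- march_sinogram(img, g, step = ps / 50)
  nd <- g$detector_count
  x <- (22 - (n + 1) / 2) * ps
  y <- ((n + 1) / 2 - 10) * ps
  for (a in seq_len(g$n_angles)) {
    t_true <- x * cos(g$angles[a]) + y * sin(g$angles[a])
    peak <- ((which.max(s[a, ]) - (nd + 1) / 2)) * g$detector_spacing
    expect_lt(abs(peak - t_true), ps)                   # sinusoidal trace
    expect_lt(abs(which.max(s[a, ]) - which.max(oracle[a, ])), 2)
    # exact mass preservation (the coarse-detector oracle only approximates it)
    expect_equal(sum(s[a, ]), 1 * ps^2 / g$detector_spacing, tolerance = 1e-12)
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  n <- 32
  withr::with_seed(5, {
    x <- matrix(rnorm(n * n), n, n)
    g <- default_geometry(x, n_angles = 48, pixel_spacing = 1.3)
    y <- matrix(rnorm(g$n_angles * g$detector_count),
                g$n_angles, g$detector_count)
  })
  lhs <- sum(forward_project(x, g)$values * y)
  rhs <- sum(x * back_project(y, g))
  expect_equal(lhs, rhs, tolerance = 1e-3)
})

test_that("one-view back projection is constant along the ray direction", {
  n <- 24
  g <- projection_geometry(1, 40, 1, 1, c(n, n))  # single view at 0 degrees
  sino <- matrix(seq_len(40) * 1.0, 1, 40)
  bp <- back_project(sino, g)
  # at angle 0 the detector coordinate is x: every column constant
  expect_equal(apply(bp, 2, function(col) diff(range(col))),
               rep(0, n), tolerance = 1e-12)
})

test_that("FBP inverts the forward projection of a smooth phantom", {
  n <- 256; ps <- 1
  x <- (seq_len(n) - (n + 1) / 2) * ps
  ph <- outer(x, x, function(yy, xx) {
    exp(-(xx^2 + yy^2) / (2 * 40^2)) +
      0.5 * exp(-((xx - 30)^2 + (yy + 20)^2) / (2 * 25^2))
  })
  g <- default_geometry(ph, n_angles = 360, pixel_spacing = ps)
  rec <- fbp_reconstruct(forward_project(ph, g))
  circ <- reconstruction_circle(g, 0.95)
  rel_rms <- sqrt(mean((rec[circ] - ph[circ])^2)) / sqrt(mean(ph[circ]^2))
  expect_lt(rel_rms, 0.05)
  # apodized filter reconstructs too, slightly smoother
  rec2 <- fbp_reconstruct(forward_project(ph, g), filter = "shepp-logan")
  rel_rms2 <- sqrt(mean((rec2[circ] - ph[circ])^2)) / sqrt(mean(ph[circ]^2))
  expect_lt(rel_rms2, 0.07)
})

test_that("each sinogram view conserves the image mass", {
  n <- 64; ps <- 0.8
  x <- (seq_len(n) - (n + 1) / 2) * ps
  disc <- outer(x, x, function(yy, xx) (xx^2 + yy^2 <= (0.3 * n * ps)^2) * 1.0)
  g <- default_geometry(disc, n_angles = 45, pixel_spacing = ps)
  expected <- sum(disc) * ps^2 / g$detector_spacing
  expect_equal(rowSums(forward_project(disc, g)$values),
               rep(expected, g$n_angles), tolerance = 1e-12)
})

test_that("geometry mismatches raise shape errors", {
  g <- projection_geometry(10, 50, 1, 1, c(32, 32))
  expect_error(forward_project(matrix(0, 16, 16), g), "do not match")
  expect_error(forward_project(matrix(0, 64, 64), g), "do not match")
  g_small <- projection_geometry(10, 10, 1, 1, c(32, 32))
  expect_error(forward_project(matrix(0, 32, 32), g_small), "diagonal")
  expect_error(back_project(matrix(0, 9, 50), g), "not")
})

test_that("sinograms serialize with a JSON sidecar", {
  n <- 16
  img <- diag(n) * 1.0
  g <- default_geometry(img, n_angles = 8, pixel_spacing = 2)
  s <- forward_project(img, g)
  base <- file.path(withr::local_tempdir(), "sino")
  write_sinogram(s, base)
  vals <- as.matrix(utils::read.table(paste0(base, ".txt")))
  dimnames(vals) <- NULL
  expect_equal(vals, s$values, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(side$n_angles, 8)
  expect_equal(side$detector_count, g$detector_count)
})
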