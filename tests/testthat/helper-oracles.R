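# Independent oracles and shared fixtures for the test suite.

# --- Brute-force ray-marching line integral -------------------------------
# Integrates a pixelated image along the ray with detector coordinate t and
# view angle theta (radians) by dense stepping; treats each pixel as a
# constant-valued square. Independent of the package's splatting projector.
march_line_integral <- function(img, ps, theta, t, step = ps / 20) {
  nr <- nrow(img); nc <- ncol(img)
  half <- sqrt(sum(dim(img)^2)) * ps / 2 + ps
  nstep <- ceiling(2 * half / step)
  s <- seq(-half, half, length.out = nstep)
  # ray: points at distance s along direction (-sin t?, ...): ray direction
  # is perpendicular to the detector axis (cos theta, sin theta)
  x <- t * cos(theta) - s * sin(theta)
  y <- t * sin(theta) + s * cos(theta)
  cc <- round(x / ps + (nc + 1) / 2)
  rr <- round((nr + 1) / 2 - y / ps)
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  if (!any(ok)) return(0)
  sum(img[cbind(rr[ok], cc[ok])]) * (s[2] - s[1])
}

# Full brute-force sinogram for small images.
march_sinogram <- function(img, geometry, step = geometry$image_pixel_spacing / 20) {
  nd <- geometry$detector_count
  tgrid <- (seq_len(nd) - (nd + 1) / 2) * geometry$detector_spacing
  out <- matrix(0, geometry$n_angles, nd)
  for (a in seq_len(geometry$n_angles)) {
    for (k in seq_len(nd)) {
      out[a, k] <- march_line_integral(img, geometry$image_pixel_spacing,
                                       geometry$angles[a], tgrid[k], step)
    }
  }
  out
}

# --- Independent stoichiometric HU (re-implementation for cross-checks) ---
# Computes HU from scratch given element tables, without using the package's
# theoretical_hu() internals.
oracle_hu <- function(symbols, w, rho, k_ph, k_coh) {
  ztab <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, Mg = 12, P = 15, S = 16,
            Cl = 17, Ar = 18, K = 19, Ca = 20, Cr = 24, Co = 27, Ni = 28,
            Mo = 42)
  atab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.99,
            Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
            K = 39.098, Ca = 40.078, Cr = 51.996, Co = 58.933, Ni = 58.693,
            Mo = 95.95)
  term <- function(sym, w, rho) {
    ne <- w * ztab[sym] / atab[sym]
    lam <- ne / sum(ne)
    rho * sum(ne) * (k_ph * sum(lam * ztab[sym]^3.62) +
                       k_coh * sum(lam * ztab[sym]^1.86) + 1)
  }
  mu_m <- term(symbols, w, rho)
  mu_w <- term(c("H", "O"), c(0.111894, 0.888106), 1.0)
  1000 * (mu_m / mu_w - 1)
}

# --- Dense-resampling WET oracle ------------------------------------------
# Cumulative WET by the same entry->POI geometry but a 10x finer step, done
# with plain R interpolation (bilinear, like the implementation, but written
# independently).
oracle_wet <- function(image, table, poi, angle_deg, bounds, refine = 10) {
  ps <- image$pixel_spacing
  a <- angle_deg * pi / 180
  d <- c(sin(a), cos(a))
  t_axis <- function(p, dd, lim) {
    if (abs(dd) < 1e-12) return(Inf)
    if (dd > 0) (lim[2] - p) / dd else (lim[1] - p) / dd
  }
  L <- min(t_axis(poi[1], d[1], bounds$xlim), t_axis(poi[2], d[2], bounds$ylim))
  entry <- poi + L * d
  n <- max(1L, ceiling(L / (ps / 2 / refine)))
  ds <- L / n
  s <- (seq_len(n) - 0.5) * ds
  px <- entry[1] - s * d[1]
  py <- entry[2] - s * d[2]
  m <- image$hu; nr <- nrow(m); nc <- ncol(m)
  cc <- px / ps + (nc + 1) / 2
  rr <- (nr + 1) / 2 - py / ps
  hu <- vapply(seq_along(cc), function(i) {
    if (rr[i] < 1 || rr[i] > nr || cc[i] < 1 || cc[i] > nc) return(NA_real_)
    r0 <- min(max(floor(rr[i]), 1), nr - 1); c0 <- min(max(floor(cc[i]), 1), nc - 1)
    fr <- rr[i] - r0; fc <- cc[i] - c0
    (1 - fr) * (1 - fc) * m[r0, c0] + (1 - fr) * fc * m[r0, c0 + 1] +
      fr * (1 - fc) * m[r0 + 1, c0] + fr * fc * m[r0 + 1, c0 + 1]
  }, numeric(1))
  rsp <- ifelse(is.na(hu), 0.001, rsp_lookup(table, ifelse(is.na(hu), 0, hu)))
  sum(rsp) * ds / 10
}

# --- Siddon-style voxel-intersection WET oracle ---------------------------
# Exact ray lengths through each crossed pixel, each pixel's HU mapped to RSP.
siddon_wet <- function(image, table, p0, p1) {
  ps <- image$pixel_spacing
  m <- image$hu; nr <- nrow(m); nc <- ncol(m)
  # param t in [0,1] along p0 -> p1; crossing times of all pixel edges
  xedges <- (c(0:nc) - nc / 2) * ps
  yedges <- (nr / 2 - c(0:nr)) * ps
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  tx <- if (abs(dx) > 1e-12) (xedges - p0[1]) / dx else numeric(0)
  ty <- if (abs(dy) > 1e-12) (yedges - p0[2]) / dy else numeric(0)
  tt <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
  L <- sqrt(dx^2 + dy^2)
  tot <- 0
  for (i in seq_len(length(tt) - 1)) {
    tm <- (tt[i] + tt[i + 1]) / 2
    x <- p0[1] + tm * dx; y <- p0[2] + tm * dy
    cc <- floor(x / ps + nc / 2) + 1
    rr <- floor(nr / 2 - y / ps) + 1
    seg <- (tt[i + 1] - tt[i]) * L
    rsp <- if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
      rsp_lookup(table, m[rr, cc])
    } else 0.001
    tot <- tot + rsp * seg
  }
  tot / 10
}

# --- 4-connected component count (for rasterizer tests) -------------------
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    queue <- list(c(i, j)); lab[i, j] <- comp
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- comp
          queue <- c(queue, list(q))
        }
      }
    }
  }
  comp
}

# --- Shared reduced-scale study fixture -----------------------------------
# One full two-insert + one-insert study at the reduced evaluation scale
# (256 x 256, 1.4 mm, 360 views), built once and reused across test files.
.fixtures <- new.env(parent = emptyenv())

ci_study <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  cfg <- study_config(grid_dim = c(256, 256), pixel_spacing = 1.4,
                      n_angles = 360)
  .fixtures$study <- run_study(cfg)
  .fixtures$study
}

# A small, fast phantom scan pair (128 grid, monochromatic option) for tests
# that only need plausible images, not evaluation-grade ones.
small_scan_pair <- function(seed = 7, mono = FALSE, n_inserts = 2) {
  key <- paste0("pair_", seed, "_", mono, "_", n_inserts)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  ph <- phantom_spec(n_inserts = n_inserts)
  sp <- if (mono) mono_spectrum(70) else spectrum_120kvp()
  un <- simulate_scan(ph, sp, grid_dim = c(128, 128), pixel_spacing = 2.8,
                      n_angles = 180, n0 = if (mono) Inf else 1e5,
                      seed = seed)
  rf <- reference_scan(ph, sp, grid_dim = c(128, 128), pixel_spacing = 2.8,
                       n_angles = 180, n0 = if (mono) Inf else 1e5,
                       seed = seed)
  .fixtures[[key]] <- list(phantom = ph, uncorr = un, reference = rf)
  .fixtures[[key]]
}
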