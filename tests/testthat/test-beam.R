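# A water slab with an on-axis voxel column (odd dims) for closed-form checks.
slab_geom <- grid_geometry(c(41, 41, 41), c(2, 2, 2), c(-40, -40, -40))
slab <- voxel_grid(array(1.0, c(41, 41, 41)), c(2, 2, 2), c(-40, -40, -40))
beam90 <- beam_geometry(90, 1000, c(0, 0, 0), c(5, 5), c(8, 8))  # axis +AP
dij_slab <- generate_dose_influence(slab, beam90, slab_geom, kernel_config())

test_that("central-axis dose follows exp(-mu * depth) in water", {
  ap <- mlc_aperture(rep(-20, 8), rep(20, 8), 1)
  d <- compute_aperture_dose(dij_slab, aperture_to_weights(ap, beam90), 1)
  prof <- d$data[21, , 21]                     # x = z = 0 column along AP
  ys <- -40 + (0:40) * 2
  sel <- ys > -32 & ys < 32                    # clear of edges and cutoff
  expected <- exp(-0.005 * (ys[sel] + 40))     # depth from slab entry at -40
  expect_equal(prof[sel] / prof[sel][1], expected / expected[1],
               tolerance = 1e-9)
  expect_true(all(diff(prof[sel]) < 0))        # monotone decrease past entry
})

test_that("the lateral 80-20 edge distance reproduces the 6.4 mm penumbra", {
  ap <- mlc_aperture(rep(0, 8), rep(20, 8), 1)   # field edge at BEV x = 0
  d <- compute_aperture_dose(dij_slab, aperture_to_weights(ap, beam90), 1)
  xs <- -40 + (0:40) * 2
  prof <- d$data[, 21, 21]
  open_lvl <- max(prof)
  sel <- xs >= -12 & xs <= 12                    # single monotone edge
  x80 <- approx(prof[sel], xs[sel], xout = 0.8 * open_lvl)$y
  x20 <- approx(prof[sel], xs[sel], xout = 0.2 * open_lvl)$y
  expect_equal(abs(x80 - x20), 6.4, tolerance = 0.2)
})

test_that("air gaps add no attenuation along the ray", {
  # slab with an air gap between entry and a deep water layer
  arr <- array(1.0, c(41, 41, 41))
  arr[, 11:20, ] <- 0                           # 20 mm air gap
  gap <- voxel_grid(arr, c(2, 2, 2), c(-40, -40, -40))
  dg <- generate_dose_influence(gap, beam90, slab_geom, kernel_config())
  ap <- mlc_aperture(rep(-20, 8), rep(20, 8), 1)
  d_gap <- compute_aperture_dose(dg, aperture_to_weights(ap, beam90), 1)
  d_full <- compute_aperture_dose(dij_slab, aperture_to_weights(ap, beam90), 1)
  # at a voxel beyond the gap the gap dose is higher by exp(+mu * 20 * 1.0)
  # (tolerance covers the ray-marching quadrature across the density kinks)
  ratio <- d_gap$data[21, 31, 21] / d_full$data[21, 31, 21]
  expect_equal(ratio, exp(0.005 * 20), tolerance = 1e-2)
})

test_that("aperture weights are fractional overlaps", {
  full <- mlc_aperture(rep(-20, 8), rep(20, 8), 1)
  expect_true(all(aperture_to_weights(full, beam90) == 1))
  closed <- mlc_aperture(rep(0, 8), rep(0, 8), 1)
  expect_true(all(aperture_to_weights(closed, beam90) == 0))
  # leaf edge bisecting a bixel: that bixel's weight is 0.5
  half <- mlc_aperture(rep(-2.5, 8), rep(20, 8), 1)   # -2.5 is a bixel center
  w <- aperture_to_weights(half, beam90)
  expect_equal(w[4, 1], 0.5)                           # bixel centred at -2.5
  expect_equal(w[5, 1], 1)
  # weight conservation: sum w = open area / bixel area for aligned apertures
  ap <- mlc_aperture(rep(-10, 8), rep(15, 8), 1)       # aligned to 5 mm grid
  expect_equal(sum(aperture_to_weights(ap, beam90)), 8 * 25 / 5)
  expect_warning(aperture_to_weights(mlc_aperture(rep(-50, 8), rep(50, 8), 1),
                                     beam90), "clip")
  expect_error(mlc_aperture(c(1, 0), c(0, 0)), "left")
})

test_that("aperture dose is linear in weights and MU", {
  set.seed(9)
  w1 <- matrix(runif(64), 8, 8)
  w2 <- matrix(runif(64), 8, 8)
  d1 <- compute_aperture_dose(dij_slab, w1, 1)$data
  d2 <- compute_aperture_dose(dij_slab, w2, 1)$data
  d12 <- compute_aperture_dose(dij_slab, w1 + w2, 1)$data
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
  expect_equal(compute_aperture_dose(dij_slab, w1, 2.5)$data, 2.5 * d1,
               tolerance = 1e-12)
  expect_equal(max(abs(compute_aperture_dose(dij_slab, matrix(0, 8, 8), 1)$data)), 0)
  # single bixel row of D recovered as a grid
  wb <- matrix(0, 8, 8); wb[4, 4] <- 1
  row_idx <- which(dij_slab$bixel_idx[, 1] == 3 & dij_slab$bixel_idx[, 2] == 3)
  db <- compute_aperture_dose(dij_slab, wb, 1)
  expect_equal(as.vector(db$data), as.numeric(dij_slab$D[row_idx, ]),
               tolerance = 1e-15)
  expect_error(compute_aperture_dose(dij_slab, wb, -1), "negative")
})

test_that("dose-influence entries are nonnegative and cutoff-sparse", {
  expect_gte(min(dij_slab$D@x), 0)
  # per-bixel max-relative cutoff honoured
  for (r in c(1, 20, 64)) {
    v <- as.numeric(dij_slab$D[r, ])
    nz <- v[v > 0]
    expect_gte(min(nz), 1e-4 * max(nz))
  }
  frac <- length(dij_slab$D@x) / prod(dim(dij_slab$D))
  expect_lt(frac, 0.5)
})

test_that("dose-influence stores round-trip through MatrixMarket", {
  dij <- structure(list(D = list(list(dij_slab)), beams = list(beam90),
                        geom_dose = slab_geom, kernel = kernel_config(),
                        n_phases = 1L), class = "dij_store")
  d <- tempfile()
  write_dij_store(dij, d)
  back <- read_dij_store(d)
  expect_equal(as.matrix(back$D[[1]][[1]]$D), as.matrix(dij_slab$D),
               tolerance = 1e-12)
  expect_equal(back$D[[1]][[1]]$bixel_idx, dij_slab$bixel_idx,
               ignore_attr = TRUE)
  expect_equal(back$beams[[1]]$gantry_deg, 90)
  expect_equal(back$kernel$sigma_mm, kernel_config()$sigma_mm)
  unlink(d, recursive = TRUE)
})

test_that("translating a homogeneous density leaves D columns invariant", {
  # rigid one-voxel translation of a *uniform* slab cannot change the kernel
  shifted <- voxel_grid(slab$data, slab$spacing, slab$origin + c(0, 0, 2))
  d2 <- generate_dose_influence(shifted, beam90, slab_geom, kernel_config())
  expect_equal(d2$D@x, dij_slab$D@x, tolerance = 1e-9)
})
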