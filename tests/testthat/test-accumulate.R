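small_geom <- grid_geometry(c(12, 12, 12), c(1, 1, 2), c(-5.5, -5.5, -11))

test_that("voxel mass is density times voxel volume", {
  d <- voxel_grid(array(1.0, c(4, 4, 4)), c(2, 2, 2))
  expect_equal(unique(as.vector(voxel_mass(d)$data)), 0.008)  # 1 g/cm3, 8 mm3
  z <- voxel_grid(array(0, c(4, 4, 4)), c(2, 2, 2))
  expect_true(all(voxel_mass(z)$data == 0))
  # rasterized 1 cm3 unit-density sphere: total mass 1 g up to rasterization
  r <- (3 / (4 * pi))^(1 / 3) * 10                       # mm, volume 1 cm3
  g <- grid_geometry(c(31, 31, 31), c(1, 1, 1), c(-15, -15, -15))
  sph <- dose4d:::ellipsoid_mask_array(g, c(0, 0, 0), rep(r, 3))
  dens <- voxel_grid(array(as.numeric(sph), g$dim), g$spacing, g$origin)
  expect_equal(sum(voxel_mass(dens)$data), 1, tolerance = 0.05)
  dn <- voxel_grid(array(1, c(2, 2, 2)), c(1, 1, 1))
  dn$data[1] <- -1
  expect_error(voxel_mass(dn), "negative")
})

test_that("push deposit: identity, uniform translation, and conservation", {
  set.seed(21)
  src <- array(runif(12^3), c(12, 12, 12))
  # identity field: exact no-op
  zero <- deformation_field(array(0, c(12, 12, 12, 3)), small_geom$spacing,
                            small_geom$origin)
  r <- dose4d:::cpp_push_deposit(src, c(12, 12, 12), small_geom$spacing,
                                 small_geom$origin, zero$vectors, c(12, 12, 12),
                                 zero$spacing, zero$origin, 4L,
                                 dose4d:::dvf_box(zero, small_geom))
  expect_identical(array(r$dep, dim(src)), src)
  expect_equal(r$lost, 0)
  # uniform one-voxel translation: grid translated, edge layer lost
  one <- deformation_field(array(rep(c(1, 0, 0), each = 12^3),
                                 c(12, 12, 12, 3)),
                           small_geom$spacing, small_geom$origin)
  r1 <- dose4d:::cpp_push_deposit(src, c(12, 12, 12), small_geom$spacing,
                                  small_geom$origin, one$vectors, c(12, 12, 12),
                                  one$spacing, one$origin, 4L,
                                  c(0L, 11L, 0L, 11L, 0L, 11L))
  dep <- array(r1$dep, dim(src))
  expect_equal(dep[2:12, , ], src[1:11, , ], tolerance = 1e-12)
  expect_equal(r1$lost, sum(src[12, , ]), tolerance = 1e-9)
  expect_equal(sum(dep) + r1$lost, sum(src), tolerance = 1e-12)
})

test_that("energy and mass are conserved for random smooth fields", {
  set.seed(31)
  src_mass <- voxel_grid(array(runif(12^3, 0.2, 1), c(12, 12, 12)),
                         small_geom$spacing, small_geom$origin)
  for (i in 1:100) {
    fld <- random_smooth_dvf(small_geom, amp_mm = runif(1, 0.5, 4))
    res <- dose4d:::cpp_push_deposit(src_mass$data, c(12, 12, 12),
                                     small_geom$spacing, small_geom$origin,
                                     fld$vectors, c(12, 12, 12), fld$spacing,
                                     fld$origin, 2L,
                                     c(0L, 11L, 0L, 11L, 0L, 11L))
    total <- sum(res$dep) + res$lost
    expect_equal(total, sum(src_mass$data), tolerance = 1e-9)
  }
})

test_that("EMT with an identity field multiplies dose and mass exactly", {
  set.seed(41)
  dose <- voxel_grid(array(runif(12^3, 0, 20), c(12, 12, 12)),
                     small_geom$spacing, small_geom$origin)
  mass <- voxel_grid(array(runif(12^3, 0.1, 1), c(12, 12, 12)),
                     small_geom$spacing, small_geom$origin)
  zero <- deformation_field(array(0, c(12, 12, 12, 3)), small_geom$spacing,
                            small_geom$origin)
  em <- emt_map(dose, mass, zero, 4L)
  expect_identical(em$energy$data, dose$data * mass$data)
  expect_equal(em$lost, 0)
  expect_equal(sum(em$energy$data) + em$lost, em$emitted)
})

test_that("uniform dose fields are EMT-invariant wherever mass remains", {
  dose0 <- voxel_grid(array(7.5, c(12, 12, 12)), small_geom$spacing,
                      small_geom$origin)
  mass <- voxel_grid(array(0.5, c(12, 12, 12)), small_geom$spacing,
                     small_geom$origin)
  set.seed(51)
  for (i in 1:5) {
    fld <- random_smooth_dvf(small_geom, amp_mm = 2)
    em <- emt_map(dose0, mass, fld, 4L)
    dm <- dose4d:::cpp_push_deposit(mass$data, c(12, 12, 12),
                                    small_geom$spacing, small_geom$origin,
                                    fld$vectors, c(12, 12, 12), fld$spacing,
                                    fld$origin, 4L,
                                    c(0L, 11L, 0L, 11L, 0L, 11L))
    dref <- emt_dose(em$energy, voxel_grid(array(dm$dep, c(12, 12, 12)),
                                           small_geom$spacing, small_geom$origin))
    got <- dref$data[dref$data > 0]
    expect_equal(got, rep(7.5, length(got)), tolerance = 1e-9)
    # conservation of the emitted energy
    expect_equal(sum(em$energy$data) + em$lost, sum(dose0$data * mass$data),
                 tolerance = 1e-9)
  }
})

test_that("EMT of a one-voxel rigid translation equals array translation", {
  set.seed(61)
  blob <- array(0, c(12, 12, 12))
  blob[4:7, 5:8, 4:7] <- runif(4 * 4 * 4, 5, 15)
  dose <- voxel_grid(blob, small_geom$spacing, small_geom$origin)
  mass <- voxel_grid(array(0.4, c(12, 12, 12)), small_geom$spacing,
                     small_geom$origin)
  one <- deformation_field(array(rep(c(0, 0, 2), each = 12^3), c(12, 12, 12, 3)),
                           small_geom$spacing, small_geom$origin)   # +1 voxel z
  em <- emt_map(dose, mass, one, 4L)
  dm <- dose4d:::cpp_push_deposit(mass$data, c(12, 12, 12), small_geom$spacing,
                                  small_geom$origin, one$vectors, c(12, 12, 12),
                                  one$spacing, one$origin, 4L,
                                  c(0L, 11L, 0L, 11L, 0L, 11L))
  dref <- emt_dose(em$energy, voxel_grid(array(dm$dep, c(12, 12, 12)),
                                         small_geom$spacing, small_geom$origin))
  expect_equal(dref$data[, , 2:12], dose$data[, , 1:11], tolerance = 1e-9)
})

test_that("DDM maps identity and uniform fields exactly", {
  set.seed(71)
  dose <- voxel_grid(array(runif(12^3, 0, 10), c(12, 12, 12)),
                     small_geom$spacing, small_geom$origin)
  zero <- deformation_field(array(0, c(12, 12, 12, 3)), small_geom$spacing,
                            small_geom$origin, direction = "pull")
  expect_equal(ddm_map(dose, zero)$data, dose$data, tolerance = 1e-12)
  u <- voxel_grid(array(4.2, c(12, 12, 12)), small_geom$spacing,
                  small_geom$origin)
  fld <- random_smooth_dvf(small_geom, 1.5, direction = "pull")
  mapped <- ddm_map(u, fld)
  inside <- mapped$data[3:10, 3:10, 3:10]
  expect_equal(inside, array(4.2, dim(inside)), tolerance = 1e-12)
  expect_error(ddm_map(dose, NULL), "absent")
})

test_that("EMT and DDM agree on means over uniform regions, differ locally", {
  # high-gradient dose edge under a compressive field
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1), c(-7.5, -7.5, -7.5))
  edge <- array(0, c(16, 16, 16)); edge[1:8, , ] <- 10
  dose <- voxel_grid(edge, g$spacing, g$origin)
  mass <- voxel_grid(array(0.5, c(16, 16, 16)), g$spacing, g$origin)
  pts <- grid_points(g)
  # compression toward the plane x = 0
  vec <- cbind(-0.35 * pts[, 1], 0, 0)
  push <- deformation_field(array(vec, c(16, 16, 16, 3)), g$spacing, g$origin)
  pull <- deformation_field(array(-vec / (1 - 0.35), c(16, 16, 16, 3)),
                            g$spacing, g$origin, direction = "pull")
  em <- emt_map(dose, mass, push, 4L)
  dm <- dose4d:::cpp_push_deposit(mass$data, c(16, 16, 16), g$spacing, g$origin,
                                  push$vectors, c(16, 16, 16), push$spacing,
                                  push$origin, 4L, c(0L, 15L, 0L, 15L, 0L, 15L))
  demt <- emt_dose(em$energy, voxel_grid(array(dm$dep, c(16, 16, 16)),
                                         g$spacing, g$origin))
  dddm <- ddm_map(dose, pull, g)
  # uniform high-dose side, far enough in that the expanded pull positions
  # stay inside the grid
  deep <- demt$data[4:6, 4:13, 4:13]
  expect_equal(mean(deep), mean(dddm$data[4:6, 4:13, 4:13]), tolerance = 0.01)
  # local differences near the moving dose edge are real
  expect_gt(max(abs(demt$data - dddm$data)), 0.1)
})

test_that("subvoxel refinement converges: s = 4 within 1% of s = 8", {
  ph <- build_phantom(small_phantom_spec())
  p <- 4L                                        # a moving phase
  mass <- voxel_mass(ph$density[[p]])
  # structured dose (SI ramp) so the push actually redistributes energy
  zramp <- rep(seq(0, 20, length.out = ph$geom_ct$dim[3]),
               each = prod(ph$geom_ct$dim[1:2]))
  dose <- voxel_grid(array(zramp, ph$geom_ct$dim), ph$geom_ct$spacing,
                     ph$geom_ct$origin)
  ds <- lapply(c(4L, 8L), function(s) {
    dm <- precompute_deformed_mass(ph, s)
    em <- emt_map(dose, mass, ph$dvf_push[[p]], s)
    emt_dose(em$energy, dm$phases[[p]]$mass)$data
  })
  ref <- max(ds[[2]])
  expect_lt(max(abs(ds[[1]] - ds[[2]])) / ref, 0.01)
})

test_that("per-tick accumulation matches the batched path", {
  ph <- build_phantom(small_phantom_spec())
  beams <- beam_set(3, iso_mm = ph$centroids[1, ], n_bixels = c(10, 10))
  dij <- precompute_dose_influence(ph, beams, kernel_config(),
                                   plan_bixel_set(ph, beams, 1))
  ptv <- expand_margin(build_mtv(ph$gtv, 0L), 1, "PTV")
  plan <- make_plan(ptv, ph, dij, name = "MTV+1")
  # shorten to a handful of ticks per beam for the per-tick loop
  for (b in seq_along(plan$segments))
    plan$segments[[b]][[1]]$mu <- 2.5
  fit <- fit_ellipse(ph$centroids[, c(3, 2)])
  traj <- bin_trajectory(generate_trajectory(fit, 5, 25, 40))
  del <- deliver(plan, traj, "untracked", ph, start_s = 12)
  dmass <- precompute_deformed_mass(ph, 2L)
  batched <- accumulate_delivery(del, ph, dij, dmass, 2L)
  state <- accumulate_init(ph, dmass, "untracked", 2L)
  for (i in seq_len(nrow(del$ticks)))
    state <- accumulate_tick(state, del, i, dij)
  expect_equal(state$dose$data, batched$dose$data, tolerance = 1e-9)
  expect_equal(sum(state$ledger$lost), sum(batched$ledger$lost),
               tolerance = 1e-9)
  # zero-MU ticks leave the state unchanged
  d0 <- del; d0$ticks$mu[1] <- 0
  s2 <- accumulate_tick(accumulate_init(ph, dmass, "untracked", 2L), d0, 1, dij)
  expect_true(all(s2$dose$data == 0))
  # global energy audit: deposited + lost equals emitted
  expect_equal(sum(batched$ledger$deposited) + sum(batched$ledger$lost),
               sum(batched$ledger$emitted), tolerance = 1e-9)
})
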