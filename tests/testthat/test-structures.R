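mk_mask <- function(arr, g, name = "m") roi_mask(arr, name, g$spacing, g$origin)

test_that("ITV union covers all phases and matches brute-force counts", {
  g <- grid_geometry(c(30, 12, 12), c(1, 1, 1), c(-5, -5, -5))
  sph <- function(cx) dose4d:::ellipsoid_mask_array(g, c(cx, 0, 0), rep(3, 3))
  masks <- lapply(c(0, 5, 10), function(cx) mk_mask(sph(cx), g))
  itv <- union_itv(masks)
  expect_identical(itv$mask, sph(0) | sph(5) | sph(10))
  expect_gt(sum(itv$mask), sum(masks[[1]]$mask))
  for (m in masks) expect_true(all(itv$mask[m$mask]))
  # identical masks -> ITV = mask; disjoint single voxels -> 2 voxels
  expect_identical(union_itv(list(masks[[1]], masks[[1]]))$mask, masks[[1]]$mask)
  a <- array(FALSE, g$dim); a[1, 1, 1] <- TRUE
  b <- array(FALSE, g$dim); b[5, 5, 5] <- TRUE
  expect_equal(sum(union_itv(list(mk_mask(a, g), mk_mask(b, g)))$mask), 2)
  g2 <- grid_geometry(c(30, 12, 12), c(2, 1, 1), c(-5, -5, -5))
  expect_error(union_itv(list(masks[[1]], mk_mask(a, g2))), "mismatch")
})

test_that("MTV equals the reference GTV for rigid translation", {
  g <- grid_geometry(c(30, 14, 14), c(1, 1, 1), c(-5, -6, -6))
  sph <- function(cx) dose4d:::ellipsoid_mask_array(g, c(cx, 0, 0), rep(3.2, 3))
  masks <- lapply(c(0, 4, 9, 13), function(cx) mk_mask(sph(cx), g))
  mtv <- build_mtv(masks, ref = 0L)
  # whole-voxel shifts: exact equality with the reference mask
  expect_identical(mtv$mask, masks[[1]]$mask)
  # identical masks all phases
  expect_identical(build_mtv(list(masks[[2]], masks[[2]]), 0L)$mask,
                   masks[[2]]$mask)
})

test_that("a single dilated phase propagates into the MTV", {
  g <- grid_geometry(c(30, 16, 16), c(1, 1, 1), c(-5, -7, -7))
  small <- mk_mask(dose4d:::ellipsoid_mask_array(g, c(0, 0, 0), rep(3, 3)), g)
  big <- mk_mask(dose4d:::ellipsoid_mask_array(g, c(8, 0, 0), rep(5, 3)), g)
  mtv <- build_mtv(list(small, small, big), ref = 0L)
  expect_equal(sum(mtv$mask), sum(big$mask))   # dilated phase dominates
  expect_gt(sum(mtv$mask), sum(small$mask))
})

test_that("MTV is no larger than ITV under nonzero centroid shifts", {
  ph <- build_phantom(small_phantom_spec())
  itv <- union_itv(ph$gtv)
  mtv <- build_mtv(ph$gtv, ph$ref_phase)
  expect_lt(sum(mtv$mask), sum(itv$mask))
  for (m in ph$gtv) expect_true(all(itv$mask[m$mask]))
})

test_that("margin expansion matches the exhaustive Euclidean oracle", {
  g <- grid_geometry(c(21, 21, 11), c(1, 1, 2), c(-10, -10, -10))
  one <- array(FALSE, g$dim); one[11, 11, 6] <- TRUE
  m <- mk_mask(one, g)
  ex <- expand_margin(m, 5)
  pts <- grid_points(g)
  center <- pts[(6 - 1) * 21 * 21 + (11 - 1) * 21 + 11, ]
  d <- sqrt(rowSums(sweep(pts, 2, center, "-")^2))
  expect_equal(sum(ex$mask), sum(d <= 5))
  expect_identical(as.vector(ex$mask), d <= 5)
  # margin 0 is the identity
  expect_identical(expand_margin(m, 0)$mask, m$mask)
  expect_error(expand_margin(m, -1), ">= 0")
})

test_that("margins nest and commute with whole-voxel translation", {
  g <- grid_geometry(c(24, 24, 16), c(1, 1, 2), c(0, 0, 0))
  base <- array(FALSE, g$dim); base[8:10, 8:9, 5:6] <- TRUE
  m <- mk_mask(base, g)
  e1 <- expand_margin(m, 1); e3 <- expand_margin(m, 3); e5 <- expand_margin(m, 5)
  expect_true(all(e3$mask[e1$mask]))
  expect_true(all(e5$mask[e3$mask]))
  expect_gt(sum(e3$mask), sum(e1$mask))
  shifted <- mk_mask(dose4d:::shift_mask_array(base, c(3, 2, 1)), g)
  expect_identical(expand_margin(shifted, 3)$mask,
                   dose4d:::shift_mask_array(expand_margin(m, 3)$mask, c(3, 2, 1)))
})

test_that("midV phase selection picks the time-weighted mean position", {
  # symmetric sinusoid: a mid-cycle phase, never an extreme one
  theta <- 2 * pi * (0:9) / 10
  cen <- cbind(LR = 0, AP = 0, SI = 7 * (1 - cos(theta)))
  mid <- select_midv_phase(cen)
  expect_false(mid %in% c(0L, 5L))
  expect_true(mid %in% c(2L, 3L, 7L, 8L))     # SI near the mean of the cycle
  # all centroids equal: tie resolves to phase 0
  expect_equal(select_midv_phase(matrix(1, 4, 3)), 0L)
  expect_error(select_midv_phase(matrix(1, 1, 3)), ">= 2")
  # asymmetric dwell: exhaustive nearest-to-weighted-mean check
  set.seed(5)
  cen2 <- matrix(rnorm(30), 10, 3)
  w <- runif(10); w <- w / sum(w)
  mean_pos <- colSums(cen2 * w)
  d <- sqrt(rowSums(sweep(cen2, 2, mean_pos, "-")^2))
  expect_equal(select_midv_phase(cen2, w), which.min(d) - 1L)
})

test_that("descriptors reproduce the cohort arithmetic from printed inputs", {
  # per-axis peak-to-peak and volume triplets of the four-patient cohort
  cohort <- list(
    p1 = list(pp = c(SI = 5.5, AP = 2.2, LR = 1.2), vol = c(9.7, 14.5, 9.7), pp3d = 6.0),
    p2 = list(pp = c(SI = 13.9, AP = 2.6, LR = 0.4), vol = c(2.7, 3.6, 3.3), pp3d = 14.1),
    p3 = list(pp = c(SI = 7.8, AP = 6.6, LR = 2.6), vol = c(23.6, 28.5, 25.6), pp3d = 10.5),
    p4 = list(pp = c(SI = 5.5, AP = 3.0, LR = 0.6), vol = c(8.4, 9.9, 8.6), pp3d = 6.3))
  theta <- 2 * pi * (0:9) / 10
  for (p in cohort) {
    cen <- cbind(LR = p$pp["LR"], AP = p$pp["AP"], SI = p$pp["SI"]) [rep(1, 10), ] / 2
    cen <- cen * (1 - cos(theta))
    vols <- c(p$vol[3], rep(p$vol[1], 4), p$vol[2], rep(p$vol[1], 4))
    md <- motion_descriptors(cen, ref = 0L, volumes_cm3 = vols)
    expect_equal(unname(md$pp_mm), unname(p$pp[c("LR", "AP", "SI")]), tolerance = 1e-9)
    expect_equal(round(md$pp3d_mm, 1), p$pp3d)      # 3D = norm of per-axis pp
    expect_gte(md$pp3d_mm, max(md$pp_mm))
  }
  # 49% deformation: volumes min 9.7 / max 14.5 / ref 9.7
  md1 <- motion_descriptors(matrix(0, 10, 3), ref = 0L,
                            volumes_cm3 = c(9.7, rep(9.7, 8), 14.5))
  expect_equal(round(md1$deformation_pct), 49)
  # zero motion: all peak-to-peaks vanish
  md0 <- motion_descriptors(matrix(3, 10, 3), ref = 0L, volumes_cm3 = rep(1, 10))
  expect_equal(unname(md0$pp_mm), c(0, 0, 0))
  expect_equal(md0$pp3d_mm, 0)
})
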