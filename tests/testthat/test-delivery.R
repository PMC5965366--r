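# Delivery fixtures on the small phantom: built once per file.
ph <- build_phantom(small_phantom_spec())
beams5 <- beam_set(9, iso_mm = ph$centroids[1, ], n_bixels = c(10, 10))
bx <- plan_bixel_set(ph, beams5, 3)
dij <- precompute_dose_influence(ph, beams5, kernel_config(), bx)
mtv <- build_mtv(ph$gtv, ph$ref_phase)
ptv <- expand_margin(mtv, 1, "PTV")
plan <- make_plan(ptv, ph, dij, name = "MTV+1")
fit <- fit_ellipse(ph$centroids[, c(3, 2)])
traj <- bin_trajectory(generate_trajectory(fit, 5, 25,
                                           plan_total_mu(plan) / (550 / 60) +
                                             40 + 9 * 2))

test_that("plan normalization pins D95(PTV) at the prescription", {
  dose <- dose4d:::plan_static_dose(plan, ph, dij)
  expect_equal(dose_at_volume(dvh(dose, ptv), 95), 18, tolerance = 1e-6)
  expect_equal(length(plan$beams), 9)
  expect_equal(plan$beams[[2]]$gantry_deg, 40)
})

test_that("larger margins open monotonically more bixels per beam", {
  open_count <- function(margin) {
    p <- expand_margin(mtv, margin, "P")
    sum(vapply(seq_along(beams5), function(b) {
      ap <- dose4d:::silhouette_bixels(p, beams5[[b]])
      sum(dose4d:::dilate_bixels(ap, 1L))
    }, numeric(1)))
  }
  counts <- vapply(c(1, 3, 5), open_count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("BEV projection follows the coplanar geometry", {
  b0 <- beam_geometry(0); b90 <- beam_geometry(90)
  # displacement parallel to the beam axis projects to zero
  expect_equal(unname(project_shift(b0$axis * 7, b0)), c(0, 0))
  # pure SI shift maps to the leaf-width axis at every gantry angle
  for (g in seq(0, 320, by = 40))
    expect_equal(unname(project_shift(c(0, 0, 4.2), beam_geometry(g))), c(0, 4.2))
  # pure AP shift: full at gantry 0, zero at gantry 90 in leaf travel
  expect_equal(abs(project_shift(c(0, 3, 0), b0)[["x"]]), 3)
  expect_equal(project_shift(c(0, 3, 0), b90)[["x"]], 0, tolerance = 1e-12)
})

test_that("aperture tracking shifts edges and re-indexes whole leaves", {
  beam <- beams5[[1]]
  ap <- mlc_aperture(c(0, -10, -10, -10, 0, 0, 0, 0, 0, 0),
                     c(0, 10, 12, 10, 0, 0, 0, 0, 0, 0), 3)
  # zero shift: identity
  t0 <- track_aperture(ap, c(0, 0), beam)
  expect_equal(t0$left, ap$left); expect_equal(t0$right, ap$right)
  # y-shift of exactly k leaf widths translates the pattern k pairs
  t2 <- track_aperture(ap, c(0, 2 * beam$bixel_mm[2]), beam)
  expect_equal(t2$left[3:6], ap$left[1:4])
  expect_equal(t2$right[3:6], ap$right[1:4])
  # continuous x shift applies to open pairs
  t1 <- track_aperture(ap, c(1.7, 0), beam)
  expect_equal(t1$left[2:4], ap$left[2:4] + 1.7)
  # tracked weights equal translated weights for integer-leaf shifts
  w0 <- aperture_to_weights(ap, beam)
  w2 <- aperture_to_weights(t2, beam)
  expect_equal(w2[, 3:10], w0[, 1:8])
  expect_true(all(w2[, 1:2] == 0))
  # an x-shift of one bixel translates weights one column
  tx <- track_aperture(ap, c(beam$bixel_mm[1], 0), beam)
  wx <- aperture_to_weights(tx, beam)
  expect_equal(wx[2:10, ], w0[1:9, ])
  # clamping beyond the travel range is flagged
  tc <- track_aperture(ap, c(60, 0), beam)
  expect_true(attr(tc, "clamped"))
})

test_that("tick streams conserve MU exactly at the 550 MU/min tick size", {
  del <- deliver(plan, traj, "static", ph)
  expect_equal(del$mu_tick, 550 / 60 / 25)       # 0.36667 MU per 40 ms tick
  for (b in seq_along(plan$beams)) {
    planned <- sum(vapply(plan$segments[[b]], function(s) s$mu, numeric(1)))
    expect_equal(sum(del$ticks$mu[del$ticks$beam == b]), planned,
                 tolerance = 1e-12)
  }
  # tick spacing is uniform at 40 ms within each segment
  expect_equal(unique(round(diff(del$ticks$time_s[del$ticks$beam == 1]), 9)),
               0.04)
  # static mode reports the planning phase and planned apertures
  expect_true(all(del$ticks$phase_bin == plan$planning_phase))
  expect_true(all(del$ticks$shift_x == 0 & del$ticks$shift_y == 0))
  i <- nrow(del$ticks) %/% 2
  ap <- dose4d:::tick_aperture(del, i)
  expect_equal(ap$left, plan$segments[[del$ticks$beam[i]]][[1]]$left)
})

test_that("tracked delivery degenerates to static for zero motion", {
  ph0 <- build_phantom(small_phantom_spec(amp_si = 0, amp_ap = 0))
  dij0 <- precompute_dose_influence(ph0, beams5, kernel_config(),
                                    plan_bixel_set(ph0, beams5, 1))
  ptv0 <- expand_margin(build_mtv(ph0$gtv, 0L), 1, "PTV")
  plan0 <- make_plan(ptv0, ph0, dij0, name = "MTV+1")
  # constant trajectory at the reference position, phases forced by stillness
  tr0 <- generate_trajectory(fit_ellipse(cbind(rep(0, 10), rep(0, 10)) +
                                           matrix(1e-9 * cos(2 * pi * (0:9) / 10),
                                                  10, 2)),
                             5, 25, plan_total_mu(plan0) / (550 / 60) + 40 + 18)
  tr0$SI_mm <- tr0$SI_mm * 0 + ph0$centroids[1, "SI"]
  tr0$AP_mm <- tr0$AP_mm * 0 + ph0$centroids[1, "AP"]
  tr0$phase_bin <- 0L
  class(tr0) <- c("trajectory", "data.frame")
  del_t <- deliver(plan0, tr0, "tracked", ph0)
  del_s <- deliver(plan0, tr0, "static", ph0)
  expect_equal(del_t$ticks$mu, del_s$ticks$mu)
  expect_true(all(del_t$ticks$shift_x == 0 & del_t$ticks$shift_y == 0))
  for (i in c(1, 50, nrow(del_t$ticks)))
    expect_equal(dose4d:::tick_aperture(del_t, i)$left,
                 dose4d:::tick_aperture(del_s, i)$left)
})

test_that("underrun trajectories and plan JSON round-trips are handled", {
  short <- traj[traj$time_s < 20, ]
  attr(short, "rate_hz") <- 25
  class(short) <- c("trajectory", "data.frame")
  expect_error(deliver(plan, short, "static", ph), "underrun")
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  p2 <- read_plan(f)
  expect_equal(plan_total_mu(p2), plan_total_mu(plan), tolerance = 1e-12)
  expect_equal(p2$segments[[3]][[1]]$left, plan$segments[[3]][[1]]$left)
  expect_equal(p2$beams[[4]]$gantry_deg, plan$beams[[4]]$gantry_deg)
  unlink(f)
})
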