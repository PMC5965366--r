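# Treatment-plan model, simplified conformal plan generation, centroid MLC
# tracking and the 25 Hz delivery stream for static/untracked/tracked modes.

#' Project a 3D target displacement into the beam's-eye-view
#'
#' Orthographic projection onto the isocenter plane perpendicular to the
#' beam axis (unit magnification): SI maps to the leaf-width (y) axis for
#' every gantry angle; the gantry-rotated LR/AP combination maps to leaf
#' travel (x). Displacement parallel to the beam axis projects to zero.
#'
#' @param displacement 3-vector mm (LR, AP, SI).
#' @param beam a `beam_geometry`.
#' @return named vector `c(x, y)` mm in the BEV frame.
#' @export
project_shift <- function(displacement, beam) {
  d <- as.numeric(displacement)
  c(x = sum(d * beam$xbev), y = sum(d * beam$ybev))
}

#' Shift an MLC aperture to follow a BEV target shift
#'
#' Leaf-travel (x) shifts are applied continuously to every open pair's
#' edges; leaf-width (y) shifts are quantized to whole leaves
#' (`round(shift / leaf_width)`) and applied by re-indexing the pairs,
#' closing vacated pairs. Shifts that would push edges beyond the leaf
#' travel range (the bixel grid) are clamped and flagged via attribute
#' `"clamped"`.
#'
#' @param aperture an `mlc_aperture`.
#' @param bev_shift `c(x, y)` mm from [project_shift()].
#' @param beam the `beam_geometry` (for leaf width and travel range).
#' @return the shifted `mlc_aperture`.
#' @export
track_aperture <- function(aperture, bev_shift, beam) {
  lw <- beam$bixel_mm[2]
  k <- as.integer(round(bev_shift[2] / lw))
  n <- length(aperture$left)
  l <- rep(NA_real_, n); r <- rep(NA_real_, n)
  src <- seq_len(n) - k                       # row i comes from planned row i-k
  ok <- src >= 1 & src <= n
  l[ok] <- aperture$left[src[ok]] + bev_shift[1]
  r[ok] <- aperture$right[src[ok]] + bev_shift[1]
  closed_at <- 0
  l[!ok] <- closed_at; r[!ok] <- closed_at
  # vacated or shifted-in rows that were closed stay closed at their position
  travel <- max(bixel_centers(beam)$x) + beam$bixel_mm[1] / 2
  clamped <- any(l < -travel - 1e-9) || any(r > travel + 1e-9)
  l <- pmin(pmax(l, -travel), travel)
  r <- pmin(pmax(r, -travel), travel)
  out <- mlc_aperture(l, r, aperture$mu)
  attr(out, "clamped") <- clamped
  out
}

# BEV silhouette of a mask for one beam: which bixels of the grid contain a
# projected mask voxel center (divergent projection to the isocenter plane).
silhouette_bixels <- function(mask, beam) {
  idx <- which(mask$mask, arr.ind = TRUE) - 1
  pts <- sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
  bev <- bev_coordinates(beam, pts)
  bc <- bixel_centers(beam)
  ix <- round((bev$x - bc$x[1]) / beam$bixel_mm[1])
  iy <- round((bev$y - bc$y[1]) / beam$bixel_mm[2])
  keep <- ix >= 0 & ix < beam$n_bixels[1] & iy >= 0 & iy < beam$n_bixels[2]
  open <- matrix(FALSE, beam$n_bixels[1], beam$n_bixels[2])
  open[unique(cbind(ix[keep], iy[keep])) + 1] <- TRUE
  open
}

dilate_bixels <- function(open, cells = 1L) {
  if (cells < 1L) return(open)
  d <- dim(open)
  out <- open
  for (dx in -cells:cells) for (dy in -cells:cells) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    out <- out | open[xs, ys]
  }
  out
}

#' Bixel subsets needed for a margin/tracking study
#'
#' Returns, per beam, the bixel indices covered by the all-phase GTV union
#' silhouette dilated by the largest margin, one bixel, and the tracking
#' overscan, so dose-influence data is generated only where any planned or
#' tracked aperture can open.
#'
#' @param phases a `phase4d`.
#' @param beams list of `beam_geometry`.
#' @param margin_max_mm largest planning margin to cover (mm).
#' @return list of integer (m x 2) 0-based bixel index matrices.
#' @export
plan_bixel_set <- function(phases, beams, margin_max_mm = 5) {
  itv <- union_itv(phases$gtv)
  lapply(beams, function(beam) {
    open <- silhouette_bixels(itv, beam)
    # the ITV silhouette already spans the motion, so planned apertures need
    # margin + 1 bixel beyond it and tracked excursions at most one more
    # bixel of sub-leaf rounding
    cells <- 2L + as.integer(ceiling(margin_max_mm / min(beam$bixel_mm)))
    open <- dilate_bixels(open, cells)
    which(open, arr.ind = TRUE) - 1L
  })
}

#' Generate a simplified conformal step-and-shoot plan
#'
#' One conformal segment per beam: the aperture follows the PTV's BEV
#' silhouette rounded out to bixels plus one bixel, with per-row leaf edges.
#' MU is split equally across beams, then a single global scale is applied
#' so the accumulated static dose on the planning phase satisfies the
#' prescription `D95(PTV) = prescription_gy` exactly.
#'
#' @param ptv the PTV `roi_mask` (CT grid).
#' @param phases the `phase4d` phantom.
#' @param dij a `dij_store` from [precompute_dose_influence()].
#' @param planning_phase 0-based phase the plan is designed on (default the
#'   reference phase).
#' @param prescription_gy D95 prescription per fraction (default 18).
#' @param dose_rate_mu_min delivery dose rate (default 550 MU/min).
#' @param name plan label.
#' @return Object of class `treatment_plan`: beams, one `mlc_aperture`
#'   segment per beam with MU, the prescription, and the planning phase.
#' @export
make_plan <- function(ptv, phases, dij, planning_phase = NULL,
                      prescription_gy = 18, dose_rate_mu_min = 550,
                      name = ptv$name) {
  if (sum(ptv$mask) == 0) stop("PTV is empty")
  planning_phase <- planning_phase %||% phases$ref_phase
  beams <- dij$beams
  segs <- vector("list", length(beams))
  any_open <- FALSE
  for (b in seq_along(beams)) {
    beam <- beams[[b]]
    open <- dilate_bixels(silhouette_bixels(ptv, beam), 1L)
    bc <- bixel_centers(beam)
    l <- r <- rep(0, beam$n_bixels[2])
    for (row in seq_len(beam$n_bixels[2])) {
      cols <- which(open[, row])
      if (length(cols) == 0) next
      l[row] <- bc$x[min(cols)] - beam$bixel_mm[1] / 2
      r[row] <- bc$x[max(cols)] + beam$bixel_mm[1] / 2
      any_open <- TRUE
    }
    segs[[b]] <- list(mlc_aperture(l, r, mu = 100))
  }
  if (!any_open) stop("PTV outside all beams' fields")
  plan <- structure(list(name = name, beams = beams, segments = segs,
                         prescription_gy = prescription_gy, ptv_name = ptv$name,
                         dose_rate_mu_min = dose_rate_mu_min,
                         planning_phase = as.integer(planning_phase)),
                    class = "treatment_plan")
  # global MU rescale: D95(PTV) on the planning phase = prescription. The
  # DVH inverse is piecewise linear in its fine bins, so a couple of
  # fixed-point passes pin the binned D95 at the prescription exactly.
  dose_ct <- plan_static_dose(plan, phases, dij)
  scale <- 1
  for (it in 1:5) {
    d95 <- dose_at_volume(dvh(voxel_grid(dose_ct$data * scale,
                                         dose_ct$spacing, dose_ct$origin),
                              ptv), 95)
    if (d95 <= 0) stop("planned dose is zero over the PTV")
    scale <- scale * prescription_gy / d95
    if (abs(d95 - prescription_gy) < 1e-9) break
  }
  for (b in seq_along(plan$segments))
    for (s in seq_along(plan$segments[[b]]))
      plan$segments[[b]][[s]]$mu <- plan$segments[[b]][[s]]$mu * scale
  plan
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> '%s': %d beams, %.1f MU total, D95 %g Gy to %s (phase %d)\n",
              x$name, length(x$beams), plan_total_mu(x), x$prescription_gy,
              x$ptv_name, x$planning_phase))
  invisible(x)
}

#' Total plan monitor units
#' @param plan a `treatment_plan`.
#' @export
plan_total_mu <- function(plan) {
  sum(vapply(plan$segments, function(ss)
    sum(vapply(ss, function(s) s$mu, numeric(1))), numeric(1)))
}

# Accumulated dose of the plan delivered statically on one phase, on the CT
# grid (the "planned" dose distribution).
plan_static_dose <- function(plan, phases, dij, phase = plan$planning_phase) {
  acc <- NULL
  for (b in seq_along(plan$beams)) {
    d <- dij$D[[b]][[phase + 1L]]
    for (ap in plan$segments[[b]]) {
      w <- aperture_to_weights(ap, plan$beams[[b]])
      dd <- compute_aperture_dose(d, w, ap$mu)
      acc <- if (is.null(acc)) dd$data else acc + dd$data
    }
  }
  dose_d <- voxel_grid(acc, dij$geom_dose$spacing, dij$geom_dose$origin)
  resample(dose_d, phases$geom_ct, "trilinear")
}

#' Write / read a treatment plan as JSON
#' @param plan a `treatment_plan`.
#' @param path JSON path.
#' @export
write_plan <- function(plan, path) {
  x <- list(name = plan$name, prescription_gy = plan$prescription_gy,
            ptv_name = plan$ptv_name, dose_rate_mu_min = plan$dose_rate_mu_min,
            planning_phase = plan$planning_phase,
            beams = lapply(plan$beams, function(b)
              list(gantry_deg = b$gantry_deg, sad_mm = b$sad_mm,
                   iso_mm = b$iso_mm, bixel_mm = b$bixel_mm,
                   n_bixels = b$n_bixels)),
            segments = lapply(plan$segments, function(ss)
              lapply(ss, function(s)
                list(left = s$left, right = s$right, mu = s$mu))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  beams <- lapply(x$beams, function(b)
    beam_geometry(b$gantry_deg, b$sad_mm, unlist(b$iso_mm),
                  unlist(b$bixel_mm), unlist(b$n_bixels)))
  segs <- lapply(x$segments, function(ss)
    lapply(ss, function(s) mlc_aperture(unlist(s$left), unlist(s$right),
                                        s$mu)))
  structure(list(name = x$name, beams = beams, segments = segs,
                 prescription_gy = x$prescription_gy, ptv_name = x$ptv_name,
                 dose_rate_mu_min = x$dose_rate_mu_min,
                 planning_phase = x$planning_phase), class = "treatment_plan")
}

#' Replay a plan delivery against a trajectory
#'
#' Segments are delivered beam by beam (gantry order) at the plan dose rate,
#' discretized into 40 ms ticks (`MU/tick = rate/60/25`, the last tick of a
#' segment carrying the remainder so MU is conserved exactly). Between
#' segments and beams a beam-off gap elapses (zero-MU stream for the phase
#' binner, no dose). Modes:
#' \describe{
#'   \item{static}{target positions ignored for delivery and accumulation;
#'     planned apertures.}
#'   \item{untracked}{(= conventional) planned apertures, but the reported
#'     online phase is attached for 4D accumulation.}
#'   \item{tracked}{planned apertures shifted by the projected
#'     (reported - planning) target displacement via [track_aperture()].}
#' }
#'
#' @param plan a `treatment_plan`.
#' @param traj a binned `trajectory` (see [bin_trajectory()]) at 25 Hz.
#' @param mode "static", "untracked" or "tracked".
#' @param phases the `phase4d` (provides the planning target position).
#' @param start_s delivery start time within the trajectory (default 12 s:
#'   past the phase-binner warm-up so every beam-on tick has a valid phase).
#' @param gap_s beam-off gap between segments/beams (default 2 s).
#' @return Object of class `delivery`: `ticks` data.frame (`time_s`, `beam`,
#'   `segment`, `mu`, `phase_bin`, `shift_x`, `shift_y` per beam), the plan
#'   and the mode.
#' @export
deliver <- function(plan, traj, mode = c("static", "untracked", "tracked"),
                    phases, start_s = 12, gap_s = 2) {
  mode <- match.arg(mode)
  rate <- attr(traj, "rate_hz")
  dt <- 1 / rate
  mu_tick <- plan$dose_rate_mu_min / 60 * dt
  ref_pos <- phases$centroids[plan$planning_phase + 1L, ]

  # tick schedule
  rows <- list(); ri <- 0L
  t <- start_s
  for (b in seq_along(plan$beams)) {
    for (s in seq_along(plan$segments[[b]])) {
      mu_left <- plan$segments[[b]][[s]]$mu
      while (mu_left > 1e-12) {
        mu <- min(mu_tick, mu_left)
        ri <- ri + 1L
        rows[[ri]] <- c(t, b, s, mu)
        mu_left <- mu_left - mu
        t <- t + dt
      }
      t <- t + gap_s
    }
  }
  tk <- do.call(rbind, rows)
  colnames(tk) <- c("time_s", "beam", "segment", "mu")
  tk <- as.data.frame(tk)
  idx <- as.integer(round(tk$time_s * rate)) + 1L
  if (max(idx) > nrow(traj))
    stop(sprintf("trajectory underrun: need %.1f s, have %.1f s",
                 max(tk$time_s), max(traj$time_s)))
  tk$phase_bin <- traj$phase_bin[idx]
  if (mode != "static" && anyNA(tk$phase_bin)) {
    if (max(traj$SI_mm) - min(traj$SI_mm) < 1e-6) {
      # degenerate motionless stream: no extrema to bin against, so every
      # sample sits in the planning (reference) phase
      tk$phase_bin[is.na(tk$phase_bin)] <- plan$planning_phase
    } else {
      stop("online phase undefined during beam-on; increase start_s")
    }
  }
  if (mode == "static") tk$phase_bin <- plan$planning_phase
  tk$SI_mm <- traj$SI_mm[idx]
  tk$AP_mm <- traj$AP_mm[idx]
  # reported displacement from the planning position; LR motion is ignored
  # (the trajectory reports AP/SI only, LR is identically zero)
  disp <- cbind(0, tk$AP_mm - ref_pos[2], tk$SI_mm - ref_pos[3])
  tk$shift_x <- 0; tk$shift_y <- 0
  if (mode == "tracked") {
    for (b in seq_along(plan$beams)) {
      sel <- tk$beam == b
      if (!any(sel)) next
      tk$shift_x[sel] <- as.numeric(disp[sel, , drop = FALSE] %*%
                                      plan$beams[[b]]$xbev)
      tk$shift_y[sel] <- as.numeric(disp[sel, , drop = FALSE] %*%
                                      plan$beams[[b]]$ybev)
    }
    # sub-nanometer shifts are fp noise from a motionless fit, not motion
    tk$shift_x[abs(tk$shift_x) < 1e-9] <- 0
    tk$shift_y[abs(tk$shift_y) < 1e-9] <- 0
  }
  structure(list(ticks = tk, plan = plan, mode = mode,
                 rate_hz = rate, mu_tick = mu_tick), class = "delivery")
}

#' @export
print.delivery <- function(x, ...) {
  cat(sprintf("<delivery> '%s' %s: %d beam-on ticks, %.1f MU, %.1f s beam-on\n",
              x$plan$name, x$mode, nrow(x$ticks), sum(x$ticks$mu),
              nrow(x$ticks) / x$rate_hz))
  invisible(x)
}

# The aperture actually set for one tick row.
tick_aperture <- function(delivery, i) {
  tk <- delivery$ticks[i, ]
  ap <- delivery$plan$segments[[tk$beam]][[tk$segment]]
  if (delivery$mode == "tracked" && (tk$shift_x != 0 || tk$shift_y != 0))
    ap <- track_aperture(ap, c(tk$shift_x, tk$shift_y),
                         delivery$plan$beams[[tk$beam]])
  ap
}

#' Write a delivery tick log CSV
#' @param delivery a `delivery`.
#' @param path CSV path.
#' @export
write_tick_log <- function(delivery, path) {
  write.csv(delivery$ticks, path, row.names = FALSE)
  invisible(path)
}
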