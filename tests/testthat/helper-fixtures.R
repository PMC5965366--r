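# Shared fixtures: small phantoms, random smooth deformation fields, and
# independent oracles used across the suite.

# A small phantom spec (coarse grids, small body) for fast end-to-end tests.
small_phantom_spec <- function(amp_si = 6, amp_ap = 1.5, ...) {
  phantom_spec(body_mm = c(72, 72, 72), ct_spacing = c(2, 2, 2),
               dose_spacing = c(4, 4, 4),
               lung_right = list(center = c(10, 0, 0), radii = c(24, 26, 33)),
               lung_left = list(center = c(-22, 0, 0), radii = c(12, 22, 30)),
               tumor_center_mm = c(10, 0, -3), tumor_radius_mm = 6,
               cord = list(center = c(0, 26), radius = 4),
               airways = list(center = c(-15, -4), radius = 4),
               amp_si_mm = amp_si, amp_ap_mm = amp_ap, shell_mm = 16, ...)
}

# Random smooth displacement field on a small grid: a few low-frequency
# sinusoidal modes per component, bounded amplitude.
random_smooth_dvf <- function(geom, amp_mm = 2, direction = "push") {
  g <- dose4d::grid_geometry(geom$dim, geom$spacing, geom$origin)
  pts <- dose4d::grid_points(g)
  ext <- g$dim * g$spacing
  vec <- sapply(1:3, function(c3) {
    v <- 0
    for (m in 1:2) {
      k <- runif(3, 0.5, 1.5) * 2 * pi / ext
      phi <- runif(3, 0, 2 * pi)
      v <- v + runif(1, -1, 1) *
        cos(pts[, 1] * k[1] + phi[1]) *
        cos(pts[, 2] * k[2] + phi[2]) *
        cos(pts[, 3] * k[3] + phi[3])
    }
    v
  })
  vec <- vec / max(sqrt(rowSums(vec^2)), 1e-9) * amp_mm
  dose4d::deformation_field(array(vec, c(g$dim, 3)), g$spacing, g$origin,
                            direction = direction)
}

# Offline phase-binning oracle: extrema from the full signal (same parabolic
# time refinement and tie-break convention), bins assigned within each
# exhale-to-exhale cycle directly.
offline_bins <- function(traj, n_phases = 10) {
  si <- traj$SI_mm; t <- traj$time_s
  dt <- t[2] - t[1]
  cand <- which(diff(sign(diff(si))) > 0) + 1L  # local minima (peak exhale)
  refine <- function(j) {
    vl <- si[j - 1]; v0 <- si[j]; vr <- si[j + 1]
    den <- vl - 2 * v0 + vr
    if (abs(den) < 1e-300) return(t[j])
    t[j] + max(min(0.5 * (vl - vr) / den, 0.5), -0.5) * dt
  }
  emin <- vapply(cand, refine, numeric(1))
  out <- rep(NA_integer_, length(t))
  for (c3 in seq_len(length(emin) - 1)) {
    sel <- t >= emin[c3] & t < emin[c3 + 1]
    frac <- (t[sel] - emin[c3]) / (emin[c3 + 1] - emin[c3])
    # same centred-bin convention as the online binner
    out[sel] <- as.integer(floor(n_phases * frac + 0.5 + 1e-9)) %% n_phases
  }
  out
}

# Brute-force trilinear interpolation oracle at one world point.
trilinear_oracle <- function(grid, p) {
  f <- (p - grid$origin) / grid$spacing
  i0 <- floor(f); tt <- f - i0
  v <- 0
  d <- dim(grid$data)
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    idx <- i0 + c(di, dj, dk)
    idx <- pmin(pmax(idx, 0), d - 1)            # clamped border
    wgt <- prod(ifelse(c(di, dj, dk) == 1, tt, 1 - tt))
    v <- v + wgt * grid$data[idx[1] + 1, idx[2] + 1, idx[3] + 1]
  }
  v
}

# erf for closed-form kernel checks.
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
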