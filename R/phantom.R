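# Synthetic 4D breathing phantom: per-phase density, ROI masks and exact
# analytic deformation fields emulating phase-binned 4DCT input.

#' Specify a synthetic breathing phantom
#'
#' Geometry is a soft-tissue elliptical-cylinder body containing two low
#' density lung ellipsoids, a spherical tumour inside the right lung, a
#' spinal cord cylinder and a proximal-airways tube. The tumour follows a
#' sinusoidal SI/AP cycle (LR motion is fixed at zero); all other structures
#' are static. Defaults emulate a peripherally located lower-lobe tumour with
#' large, mostly rigid SI motion (14 mm peak-to-peak SI, 2.6 mm AP).
#'
#' @param body_mm body extents (LR, AP, SI) in mm; the grids cover this box.
#' @param ct_spacing CT/DVF grid spacing mm (default 1 x 1 x 2).
#' @param dose_spacing dose grid spacing mm (default 2 x 2 x 2).
#' @param lung_right,lung_left lists with `center` and `radii` (mm) of the
#'   lung ellipsoids; the tumour lives in the right lung.
#' @param tumor_center_mm reference-phase (peak exhale) tumour center mm.
#' @param tumor_radius_mm tumour sphere radius mm.
#' @param cord list with `center` (LR, AP) and `radius` mm of the cord cylinder.
#' @param airways list with `center` (LR, AP) and `radius` mm of the airways tube.
#' @param amp_si_mm,amp_ap_mm peak-to-peak tumour motion (mm) along SI and AP.
#' @param ap_lag_rad phase lag of the AP sinusoid behind SI (radians);
#'   `pi/2` traces an axis-aligned hysteresis ellipse.
#' @param deform_coef per-phase isotropic tumour radius scaling coefficient;
#'   0 keeps the GTV rigid, positive values inflate it toward peak inhale.
#' @param n_phases number of respiratory phases (default 10).
#' @param shell_mm minimum width of the C1 smoothstep falloff shell around
#'   the tumour over which the displacement decays to zero; widened
#'   automatically to twice the peak displacement so the motion map stays
#'   invertible.
#' @param densities named list of tissue densities g/cm3.
#' @param seed integer seed recorded with the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_mm = c(128, 128, 128),
                         ct_spacing = c(1, 1, 2),
                         dose_spacing = c(2, 2, 2),
                         lung_right = list(center = c(22, 0, 0), radii = c(40, 42, 56)),
                         lung_left = list(center = c(-36, 0, 0), radii = c(21, 38, 52)),
                         tumor_center_mm = c(22, 0, -7),
                         tumor_radius_mm = 9,
                         cord = list(center = c(0, 44), radius = 5),
                         airways = list(center = c(-24, -5), radius = 6),
                         amp_si_mm = 14, amp_ap_mm = 2.6,
                         ap_lag_rad = pi / 2,
                         deform_coef = 0,
                         n_phases = 10,
                         shell_mm = 15,
                         densities = list(body = 1.0, lung = 0.26, tumor = 1.0,
                                          cord = 1.0, airways = 0.2),
                         seed = 1L) {
  if (amp_si_mm < 0 || amp_ap_mm < 0) stop("amplitudes must be >= 0")
  if (n_phases < 2) stop("n_phases must be >= 2")
  spec <- list(body_mm = body_mm, ct_spacing = ct_spacing,
               dose_spacing = dose_spacing, lung_right = lung_right,
               lung_left = lung_left, tumor_center_mm = tumor_center_mm,
               tumor_radius_mm = tumor_radius_mm, cord = cord,
               airways = airways, amp_si_mm = amp_si_mm,
               amp_ap_mm = amp_ap_mm, ap_lag_rad = ap_lag_rad,
               deform_coef = deform_coef, n_phases = as.integer(n_phases),
               shell_mm = shell_mm, densities = densities,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Read / write a phantom spec as JSON
#' @param path JSON file path.
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, x)
}

#' @param spec a `phantom_spec`.
#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Phase displacement of the tumour centroid relative to the reference
# (peak-exhale) phase 0: SI = (pp/2)(1 - cos theta), AP lagged, LR = 0.
phase_displacements <- function(spec) {
  p <- seq_len(spec$n_phases) - 1
  theta <- 2 * pi * p / spec$n_phases
  dsi <- spec$amp_si_mm / 2 * (1 - cos(theta))
  dap <- spec$amp_ap_mm / 2 * ((1 - cos(theta + spec$ap_lag_rad)) -
                                 (1 - cos(spec$ap_lag_rad)))
  cbind(LR = 0, AP = dap, SI = dsi)
}

smoothstep_falloff <- function(t, w) {
  tau <- pmin(pmax(t / w, 0), 1)
  1 - (3 * tau^2 - 2 * tau^3)
}

# Logical array of an axis-aligned ellipsoid on a geometry.
ellipsoid_mask_array <- function(geom, center, radii) {
  g <- geom_of(geom)
  ax <- ((g$origin[1] + (0:(g$dim[1] - 1)) * g$spacing[1] - center[1]) / radii[1])^2
  ay <- ((g$origin[2] + (0:(g$dim[2] - 1)) * g$spacing[2] - center[2]) / radii[2])^2
  az <- ((g$origin[3] + (0:(g$dim[3] - 1)) * g$spacing[3] - center[3]) / radii[3])^2
  outer(outer(ax, ay, "+"), az, "+") <= 1
}

# Partial-volume fraction of an ellipsoid per voxel (supersampled indicator):
# antialiases the tumour boundary so tissue mass varies smoothly as the
# tumour moves across the grid.
ellipsoid_fraction_array <- function(geom, center, radii, ss = 3L) {
  g <- geom_of(geom)
  acc <- array(0, g$dim)
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5)
  for (oz in offs) for (oy in offs) for (ox in offs) {
    sh <- grid_geometry(g$dim, g$spacing,
                        g$origin + c(ox, oy, oz) * g$spacing)
    acc <- acc + ellipsoid_mask_array(sh, center, radii)
  }
  acc / ss^3
}

cylinder_mask_array <- function(geom, center_xy, radius, zlim = c(-Inf, Inf)) {
  g <- geom_of(geom)
  ax <- (g$origin[1] + (0:(g$dim[1] - 1)) * g$spacing[1] - center_xy[1])^2
  ay <- (g$origin[2] + (0:(g$dim[2] - 1)) * g$spacing[2] - center_xy[2])^2
  zs <- g$origin[3] + (0:(g$dim[3] - 1)) * g$spacing[3]
  inz <- zs >= zlim[1] & zs <= zlim[2]
  r2 <- outer(ax, ay, "+") <= radius^2
  outer(r2, inz, "&")
}

phantom_geometries <- function(spec) {
  mk <- function(sp) {
    n <- pmax(1L, as.integer(round(spec$body_mm / sp)))
    grid_geometry(n, sp, origin = -(n - 1) / 2 * sp)
  }
  list(ct = mk(spec$ct_spacing), dose = mk(spec$dose_spacing))
}

#' Build the 4D phantom
#'
#' Rasterizes per-phase density and GTV masks, static lung/cord/airways
#' masks, and constructs the exact phase deformation fields: the pull field
#' (reference -> phase) is the rigid tumour displacement scaled by a C1
#' smoothstep of distance from the reference tumour surface over the falloff
#' shell, zero at the lung boundary and beyond; the push field
#' (phase -> reference) is its numerical inverse, computed at grid nodes by
#' fixed-point iteration and stored on the support sub-box.
#'
#' @param spec a `phantom_spec`.
#' @return Object of class `phase4d`: per-phase `density` grids, `gtv` masks,
#'   `dvf_push`/`dvf_pull` fields, static `lung`/`cord`/`airways` masks,
#'   analytic `centroids`, reference phase index 0 (peak exhale), and the
#'   grid pair (`geom_ct`, `geom_dose`).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geoms <- phantom_geometries(spec)
  gct <- geoms$ct
  disp <- phase_displacements(spec)
  dmax <- sqrt(max(rowSums(disp^2)))
  shell <- max(spec$shell_mm, 2 * dmax)
  r <- spec$tumor_radius_mm
  c0 <- spec$tumor_center_mm

  # static regions on the CT grid
  g <- gct
  ax <- ((g$origin[1] + (0:(g$dim[1] - 1)) * g$spacing[1]) / (spec$body_mm[1] / 2 - 1))^2
  ay <- ((g$origin[2] + (0:(g$dim[2] - 1)) * g$spacing[2]) / (spec$body_mm[2] / 2 - 1))^2
  body <- outer(outer(ax, ay, "+") <= 1, rep(TRUE, g$dim[3]), "&")
  lungR <- ellipsoid_mask_array(gct, spec$lung_right$center, spec$lung_right$radii)
  lungL <- ellipsoid_mask_array(gct, spec$lung_left$center, spec$lung_left$radii)
  airw <- cylinder_mask_array(gct, spec$airways$center, spec$airways$radius)
  cordm <- cylinder_mask_array(gct, spec$cord$center, spec$cord$radius)
  lungR <- lungR & body; lungL <- lungL & body
  airw <- airw & body; cordm <- cordm & body

  # the displacement support (tumour + falloff shell) must stay inside the
  # tumour-bearing lung: otherwise the tumour "leaves" the lung
  support <- ellipsoid_mask_array(gct, c0, rep(r + shell, 3))
  if (any(support & !lungR))
    stop(sprintf(paste("tumour motion support (radius %.1f mm) exceeds the",
                       "lung for amplitude %.1f mm"), r + shell, spec$amp_si_mm))

  n <- spec$n_phases
  dens <- vector("list", n); gtv <- vector("list", n)
  push <- vector("list", n); pull <- vector("list", n)
  d <- spec$densities
  gfac <- (1 - cos(2 * pi * (seq_len(n) - 1) / n)) / 2  # 0 at ref, 1 at inhale

  # DVF support sub-box, sampled at fine isotropic spacing (finer than the
  # CT grid in z) so that trilinear interpolation of the inverted push field
  # keeps the pull/push composition error well below 0.2 mm
  fsp <- pmin(gct$spacing, 1)
  lo <- pmax(gct$origin, c0 - (r + shell) - 2 * fsp)
  hi <- pmin(gct$origin + (gct$dim - 1) * gct$spacing, c0 + (r + shell) + 2 * fsp)
  bdim <- as.integer(ceiling((hi - lo) / fsp)) + 1L
  borg <- lo
  bpts <- grid_points(grid_geometry(bdim, fsp, borg))

  centroids <- sweep(disp, 2, c0, "+")
  for (p in seq_len(n)) {
    dp <- disp[p, ]
    cp <- c0 + dp
    rp <- r * (1 + spec$deform_coef * gfac[p])
    tum <- ellipsoid_mask_array(gct, cp, rep(rp, 3))
    tfrac <- ellipsoid_fraction_array(gct, cp, rep(rp, 3))
    arr <- array(0, gct$dim)
    arr[body] <- d$body
    arr[lungR | lungL] <- d$lung
    arr[airw] <- d$airways
    arr[cordm] <- d$cord
    arr <- arr * (1 - tfrac) + d$tumor * tfrac
    dens[[p]] <- voxel_grid(arr, gct$spacing, gct$origin)
    gtv[[p]] <- roi_mask(tum, sprintf("GTV_%d", p - 1), gct$spacing, gct$origin)

    if (all(dp == 0)) {
      zero <- array(0, c(bdim, 3))
      pull[[p]] <- deformation_field(zero, fsp, borg, "pull")
      push[[p]] <- deformation_field(zero, fsp, borg, "push")
    } else {
      # pull (ref -> phase): v(y) = d * S(|y - c0| - r)
      t_ref <- sqrt(rowSums(sweep(bpts, 2, c0, "-")^2)) - r
      s_ref <- smoothstep_falloff(t_ref, shell)
      pull_vec <- outer(s_ref, dp)
      pull[[p]] <- deformation_field(array(pull_vec, c(bdim, 3)), fsp,
                                     borg, "pull")
      # push (phase -> ref): invert y + d*S(|y-c0|-r) = x per node
      y <- bpts
      for (it in 1:80) {
        sv <- smoothstep_falloff(sqrt(rowSums(sweep(y, 2, c0, "-")^2)) - r, shell)
        ynew <- bpts - outer(sv, dp)
        delta <- max(abs(ynew - y))
        y <- ynew
        if (delta < 1e-7) break
      }
      push[[p]] <- deformation_field(array(y - bpts, c(bdim, 3)), fsp,
                                     borg, "push")
    }
  }

  structure(list(
    spec = spec, geom_ct = gct, geom_dose = geoms$dose, ref_phase = 0L,
    density = dens, gtv = gtv,
    lung = roi_mask((lungR | lungL) & !airw, "lung", gct$spacing, gct$origin),
    cord = roi_mask(cordm, "cord", gct$spacing, gct$origin),
    airways = roi_mask(airw, "airways", gct$spacing, gct$origin),
    dvf_push = push, dvf_pull = pull,
    centroids = centroids, displacements = disp,
    shell_mm = shell, deformed_mass = NULL), class = "phase4d")
}

#' @export
print.phase4d <- function(x, ...) {
  cat(sprintf("<phase4d> %d phases, CT grid %s, dose grid %s\n",
              x$spec$n_phases, paste(x$geom_ct$dim, collapse = "x"),
              paste(x$geom_dose$dim, collapse = "x")))
  cat(sprintf("  reference phase %d (peak exhale); SI pk-pk %.1f mm, AP %.1f mm\n",
              x$ref_phase, x$spec$amp_si_mm, x$spec$amp_ap_mm))
  invisible(x)
}

#' Per-phase GTV mask centroids
#'
#' Centroid = mean of the world coordinates of the voxel centers in the mask.
#'
#' @param phases a `phase4d` object, or a list of `roi_mask`.
#' @return numeric matrix (n_phases x 3) of mm centroids (LR, AP, SI).
#' @export
gtv_centroids <- function(phases) {
  masks <- if (inherits(phases, "phase4d")) phases$gtv else phases
  t(vapply(masks, mask_centroid, numeric(3)))
}

#' Partial-volume weighted tumour mass per phase
#'
#' Mass of the tumour region per phase, weighting boundary voxels by their
#' supersampled tumour volume fraction (the binary GTV mask alone jitters by
#' a few percent as the sphere moves across 2 mm slices). For rigid motion
#' (deformation coefficient 0) this is conserved across phases.
#'
#' @param phases a `phase4d`.
#' @return numeric vector of per-phase tumour mass (g).
#' @export
gtv_mass_g <- function(phases) {
  spec <- phases$spec
  disp <- phases$displacements
  gfac <- (1 - cos(2 * pi * (seq_len(spec$n_phases) - 1) / spec$n_phases)) / 2
  vol_cm3 <- prod(phases$geom_ct$spacing) / 1000
  vapply(seq_len(spec$n_phases), function(p) {
    rp <- spec$tumor_radius_mm * (1 + spec$deform_coef * gfac[p])
    frac <- ellipsoid_fraction_array(phases$geom_ct,
                                     spec$tumor_center_mm + disp[p, ],
                                     rep(rp, 3))
    sum(frac * phases$density[[p]]$data) * vol_cm3
  }, numeric(1))
}

mask_centroid <- function(m) {
  idx <- which(m$mask, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty mask: ", m$name)
  colMeans(sweep(sweep(idx, 2, m$spacing, "*"), 2, m$origin, "+"))
}

#' Write a built phantom to a directory of NIfTI grids plus a manifest
#' @param phases a `phase4d`.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(phases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- phases$spec$n_phases
  files <- list()
  for (p in seq_len(n)) {
    f <- file.path(dir, sprintf("density_phase%02d.nii.gz", p - 1))
    write_grid(phases$density[[p]], f)
    write_grid(phases$gtv[[p]], file.path(dir, sprintf("gtv_phase%02d.nii.gz", p - 1)))
    write_dvf(phases$dvf_push[[p]], file.path(dir, sprintf("dvf_push_phase%02d.nii.gz", p - 1)))
    write_dvf(phases$dvf_pull[[p]], file.path(dir, sprintf("dvf_pull_phase%02d.nii.gz", p - 1)))
  }
  for (nm in c("lung", "cord", "airways"))
    write_grid(phases[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  manifest <- list(n_phases = n, ref_phase = phases$ref_phase,
                   centroids = phases$centroids, shell_mm = phases$shell_mm,
                   spec = unclass(phases$spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
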