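# Beam geometry, bixel grid, analytic dose-influence generation, MLC
# aperture model and per-aperture dose.

#' Kernel configuration for analytic dose-influence generation
#'
#' The per-bixel dose kernel is `D_jv = A * exp(-mu * d_rad(v)) * E(r_perp)`:
#' exponential attenuation with radiological depth (density-scaled path
#' length from body entry, ~6 MV water attenuation by default) times an
#' error-function edge profile across the bixel aperture. The default
#' penumbra sigma makes the lateral 80-20 edge distance 6.4 mm
#' (sigma = 6.4 / 1.683), the reference photon penumbra for lung tissue.
#'
#' @param A kernel amplitude, Gy per MU per unit beamlet weight.
#' @param mu_per_mm linear attenuation per unit radiological depth
#'   (1/(g/cm3 * mm)); 0.005 approximates 6 MV in water.
#' @param sigma_mm penumbra width of the error-function edge profile (mm).
#' @param cutoff relative per-bixel cutoff below which entries are dropped.
#' @param step_mm ray-marching step for radiological depth (mm).
#' @return list of class `kernel_config`.
#' @export
kernel_config <- function(A = 0.01, mu_per_mm = 0.005,
                          sigma_mm = 6.4 / 1.683, cutoff = 1e-4,
                          step_mm = 1) {
  structure(list(A = A, mu_per_mm = mu_per_mm, sigma_mm = sigma_mm,
                 cutoff = cutoff, step_mm = step_mm), class = "kernel_config")
}

#' Coplanar isocentric beam geometry with a bixel grid
#'
#' The beam axis lies in the LR/AP plane: at gantry angle `g` (degrees) the
#' unit axis from source to isocenter is `(cos g, sin g, 0)`; the
#' beam's-eye-view (BEV) frame at the isocenter plane has x along leaf
#' travel (`(-sin g, cos g, 0)`) and y along leaf width = the SI axis.
#' Bixels are rectangles on that plane, y-size = MLC leaf width.
#'
#' @param gantry_deg gantry angle in degrees.
#' @param sad_mm source-axis distance (default 1000).
#' @param iso_mm isocenter world position mm.
#' @param bixel_mm bixel size (x: leaf travel, y: leaf width) mm.
#' @param n_bixels bixel counts (x, y); the grid is centred on the axis.
#' @return Object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_deg, sad_mm = 1000, iso_mm = c(0, 0, 0),
                          bixel_mm = c(5, 5), n_bixels = c(16, 16)) {
  g <- gantry_deg * pi / 180
  axis <- c(cos(g), sin(g), 0)
  xbev <- c(-sin(g), cos(g), 0)
  structure(list(gantry_deg = gantry_deg, sad_mm = sad_mm,
                 iso_mm = as.numeric(iso_mm), axis = axis, xbev = xbev,
                 ybev = c(0, 0, 1), source = as.numeric(iso_mm) - sad_mm * axis,
                 bixel_mm = as.numeric(bixel_mm),
                 n_bixels = as.integer(n_bixels)), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> gantry %g deg, SAD %g mm, %dx%d bixels of %gx%g mm\n",
              x$gantry_deg, x$sad_mm, x$n_bixels[1], x$n_bixels[2],
              x$bixel_mm[1], x$bixel_mm[2]))
  invisible(x)
}

#' Nine equidistant coplanar beams
#' @param n number of beams (default 9: gantry 0, 40, ..., 320).
#' @param ... passed to [beam_geometry()].
#' @export
beam_set <- function(n = 9, ...) {
  lapply(seq(0, 360 - 360 / n, by = 360 / n), beam_geometry, ...)
}

# Bixel center coordinates (x, y) mm in the isocenter-plane BEV frame.
bixel_centers <- function(beam) {
  bx <- (0:(beam$n_bixels[1] - 1) - (beam$n_bixels[1] - 1) / 2) * beam$bixel_mm[1]
  by <- (0:(beam$n_bixels[2] - 1) - (beam$n_bixels[2] - 1) / 2) * beam$bixel_mm[2]
  list(x = bx, y = by)
}

# Project world points into the divergent BEV frame scaled to the isocenter
# plane. Returns depth along axis from the source (mm) and (x, y) iso-plane mm.
bev_coordinates <- function(beam, pts) {
  rel <- sweep(as.matrix(pts), 2, beam$source, "-")
  zb <- rel %*% beam$axis
  mag <- beam$sad_mm / pmax(as.numeric(zb), 1e-6)
  list(z = as.numeric(zb),
       x = as.numeric(rel %*% beam$xbev) * mag,
       y = as.numeric(rel %*% beam$ybev) * mag)
}

#' Generate sparse dose-influence data for one beam on one phase
#'
#' For each bixel j and dose-grid voxel v the entry is
#' `A * exp(-mu * d_rad(v)) * E(r_perp(v))` where `d_rad` is the radiological
#' depth along the ray from the source (density from the phase CT grid,
#' trilinear), `r_perp` the lateral offset from the bixel's divergent pencil
#' axis scaled to the isocenter plane, and `E` the separable error-function
#' edge profile of the bixel rectangle. Entries below `cutoff` times the
#' per-bixel maximum are dropped.
#'
#' @param density phase density `voxel_grid` (CT grid).
#' @param beam a `beam_geometry`.
#' @param geom_dose dose-grid `grid_geometry` on which columns live.
#' @param kernel a `kernel_config`.
#' @param bixel_idx optional integer matrix (m x 2) of 0-based (ix, iy) bixel
#'   grid indices to generate (default: the full bixel grid).
#' @param voxel_subset optional integer vector of 1-based dose-grid voxel
#'   linear indices to restrict columns to.
#' @param voxel_keep optional logical vector over the dose grid further
#'   restricting columns (e.g. to body voxels).
#' @return Object of class `dose_influence`: sparse `D` (m bixels x n dose
#'   voxels, Gy per MU per unit weight), `bixel_idx`, the beam, geometry and
#'   kernel.
#' @export
generate_dose_influence <- function(density, beam, geom_dose,
                                    kernel = kernel_config(),
                                    bixel_idx = NULL, voxel_subset = NULL,
                                    voxel_keep = NULL) {
  bc <- bixel_centers(beam)
  if (is.null(bixel_idx)) {
    bixel_idx <- as.matrix(expand.grid(ix = 0:(beam$n_bixels[1] - 1),
                                       iy = 0:(beam$n_bixels[2] - 1)))
  }
  bix <- cbind(bc$x[bixel_idx[, 1] + 1], bc$y[bixel_idx[, 2] + 1])
  nv <- prod(geom_dose$dim)
  if (is.null(voxel_subset)) {
    # restrict to the corridor laterally reachable from the requested bixels
    pts_all <- grid_points(geom_dose)
    bev0 <- bev_coordinates(beam, pts_all)
    reach <- 0.5 * max(beam$bixel_mm) + 6 * kernel$sigma_mm
    keep <- bev0$x >= min(bix[, 1]) - reach & bev0$x <= max(bix[, 1]) + reach &
      bev0$y >= min(bix[, 2]) - reach & bev0$y <= max(bix[, 2]) + reach &
      bev0$z > 1
    if (!is.null(voxel_keep)) keep <- keep & voxel_keep
    voxel_subset <- which(keep)
    pts <- pts_all[voxel_subset, , drop = FALSE]
    bev <- list(x = bev0$x[voxel_subset], y = bev0$y[voxel_subset])
  } else {
    pts <- grid_points(geom_dose)[voxel_subset, , drop = FALSE]
    b <- bev_coordinates(beam, pts)
    bev <- list(x = b$x, y = b$y)
  }
  depth <- cpp_radiological_depth(density$data, dim(density$data),
                                  density$spacing, density$origin,
                                  beam$source, pts, kernel$step_mm)
  tri <- cpp_dose_influence(depth, cbind(bev$x, bev$y), bix,
                            beam$bixel_mm[1], beam$bixel_mm[2],
                            kernel$A, kernel$mu_per_mm, kernel$sigma_mm,
                            kernel$cutoff)
  D <- Matrix::sparseMatrix(i = tri$i, j = voxel_subset[tri$j], x = tri$x,
                            dims = c(nrow(bix), nv))
  structure(list(D = D, bixel_idx = bixel_idx, beam = beam,
                 geom_dose = geom_dose, kernel = kernel),
            class = "dose_influence")
}

#' An MLC aperture: per-leaf-pair openings plus monitor units
#'
#' Leaf edges are mm positions in the isocenter plane along leaf travel
#' (BEV x); row r corresponds to bixel-grid row r (leaf width = bixel
#' y-size). Closed pairs have `left == right`.
#'
#' @param left,right numeric vectors (one per leaf pair), `left <= right`.
#' @param mu monitor units carried by this segment/tick, >= 0.
#' @return Object of class `mlc_aperture`.
#' @export
mlc_aperture <- function(left, right, mu = 0) {
  if (length(left) != length(right)) stop("left/right length mismatch")
  if (any(left > right + 1e-9)) stop("left must be <= right for every pair")
  if (mu < 0) stop("MU must be >= 0")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 mu = as.numeric(mu)), class = "mlc_aperture")
}

#' @export
print.mlc_aperture <- function(x, ...) {
  open <- which(x$right - x$left > 1e-9)
  cat(sprintf("<mlc_aperture> %d/%d pairs open, area %.1f mm2 (iso plane), MU %.3f\n",
              length(open), length(x$left), sum(x$right - x$left), x$mu))
  invisible(x)
}

#' Convert an MLC aperture to beamlet weights
#'
#' Weight of bixel (ix, iy) is the fractional 1D overlap of the bixel's
#' x-extent with leaf pair iy's open interval (leaf width equals the bixel
#' y-size, so rows are all-or-nothing across y). Apertures reaching outside
#' the bixel grid are clipped with a warning.
#'
#' @param aperture an `mlc_aperture` with one pair per bixel-grid row.
#' @param beam the `beam_geometry` carrying the bixel grid.
#' @return numeric matrix (n_bixels_x x n_bixels_y) of weights in `[0, 1]`.
#' @export
aperture_to_weights <- function(aperture, beam) {
  nb <- beam$n_bixels
  if (length(aperture$left) != nb[2])
    stop("aperture must have one leaf pair per bixel-grid row")
  bc <- bixel_centers(beam)
  xe_lo <- bc$x - beam$bixel_mm[1] / 2
  xe_hi <- bc$x + beam$bixel_mm[1] / 2
  gmin <- min(xe_lo); gmax <- max(xe_hi)
  if (any(aperture$left < gmin - 1e-9 & aperture$right > gmin + 1e-9) ||
      any(aperture$right > gmax + 1e-9 & aperture$left < gmax - 1e-9))
    warning("aperture extends outside the bixel grid; clipping")
  w <- matrix(0, nb[1], nb[2])
  for (r in seq_len(nb[2])) {
    l <- max(aperture$left[r], gmin); u <- min(aperture$right[r], gmax)
    if (u <= l) next
    w[, r] <- pmax(0, pmin(xe_hi, u) - pmax(xe_lo, l)) / beam$bixel_mm[1]
  }
  w
}

# Weights for the rows of a dose_influence object (its bixel subset).
weights_for_dij <- function(w_full, dij) {
  w_full[cbind(dij$bixel_idx[, 1] + 1, dij$bixel_idx[, 2] + 1)]
}

#' Dose of one weighted aperture from dose-influence data
#'
#' `dose(v) = mu * sum_j w_j D_jv`, linear in both the weights and MU.
#'
#' @param dij a `dose_influence`.
#' @param w full bixel-grid weight matrix (from [aperture_to_weights()]) or
#'   a vector aligned with the rows of `dij$D`.
#' @param mu monitor units, >= 0.
#' @return dose `voxel_grid` on the dose grid, in the phase frame.
#' @export
compute_aperture_dose <- function(dij, w, mu = 1) {
  if (mu < 0) stop("negative MU")
  if (is.matrix(w) && nrow(dij$bixel_idx) < length(w)) {
    outside <- sum(w) - sum(weights_for_dij(w, dij))
    if (outside > 1e-9)
      warning(sprintf("%.3g bixel weight outside the dose-influence subset", outside))
  }
  wrow <- if (is.matrix(w)) weights_for_dij(w, dij) else as.numeric(w)
  v <- as.numeric(Matrix::crossprod(dij$D, wrow)) * mu
  voxel_grid(array(v, dij$geom_dose$dim), dij$geom_dose$spacing,
             dij$geom_dose$origin)
}

#' Precompute dose-influence data for all beams and phases
#'
#' @param phases a `phase4d` phantom.
#' @param beams list of `beam_geometry`.
#' @param kernel a `kernel_config`.
#' @param bixel_sets optional per-beam bixel index subsets (list of m x 2
#'   matrices), e.g. from [plan_bixel_set()].
#' @param verbose print progress.
#' @return Object of class `dij_store`: `D[[beam]][[phase]]` dose_influence
#'   objects plus the beams, geometry and kernel.
#' @export
precompute_dose_influence <- function(phases, beams, kernel = kernel_config(),
                                      bixel_sets = NULL, verbose = FALSE) {
  nb <- length(beams); np <- phases$spec$n_phases
  # restrict columns to body voxels (dose accumulation covers the patient
  # volume; vacuum outside the body carries no reportable dose)
  body_keep <- lapply(seq_len(np), function(p)
    as.vector(resample(phases$density[[p]], phases$geom_dose,
                       "nearest")$data >= 0.05))
  D <- vector("list", nb)
  for (b in seq_len(nb)) {
    D[[b]] <- vector("list", np)
    bi <- if (is.null(bixel_sets)) NULL else bixel_sets[[b]]
    for (p in seq_len(np)) {
      D[[b]][[p]] <- generate_dose_influence(phases$density[[p]], beams[[b]],
                                             phases$geom_dose, kernel, bi,
                                             voxel_keep = body_keep[[p]])
      if (verbose)
        message(sprintf("D_ij beam %d phase %d: %d nonzeros", b, p - 1,
                        length(D[[b]][[p]]$D@x)))
    }
  }
  structure(list(D = D, beams = beams, geom_dose = phases$geom_dose,
                 kernel = kernel, n_phases = np), class = "dij_store")
}

#' Persist / load a dose-influence store
#'
#' One MatrixMarket file per (beam, phase) plus a JSON manifest recording the
#' kernel configuration, bixel subsets and grid geometry for provenance.
#'
#' @param dij a `dij_store`.
#' @param dir output directory.
#' @export
write_dij_store <- function(dij, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_along(dij$D))
    for (p in seq_along(dij$D[[b]]))
      Matrix::writeMM(dij$D[[b]][[p]]$D,
                      file.path(dir, sprintf("dij_b%02d_p%02d.mtx", b, p - 1)))
  manifest <- list(
    kernel = unclass(dij$kernel), n_phases = dij$n_phases,
    geom_dose = list(dim = dij$geom_dose$dim, spacing = dij$geom_dose$spacing,
                     origin = dij$geom_dose$origin),
    beams = lapply(dij$beams, function(bm)
      list(gantry_deg = bm$gantry_deg, sad_mm = bm$sad_mm, iso_mm = bm$iso_mm,
           bixel_mm = bm$bixel_mm, n_bixels = bm$n_bixels)),
    bixel_idx = lapply(dij$D, function(bd) bd[[1]]$bixel_idx))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dij_store
#' @export
read_dij_store <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  geom <- grid_geometry(unlist(man$geom_dose$dim), unlist(man$geom_dose$spacing),
                        unlist(man$geom_dose$origin))
  kernel <- do.call(kernel_config, lapply(man$kernel, unlist))
  beams <- lapply(man$beams, function(bm)
    beam_geometry(bm$gantry_deg, bm$sad_mm, unlist(bm$iso_mm),
                  unlist(bm$bixel_mm), unlist(bm$n_bixels)))
  D <- vector("list", length(beams))
  for (b in seq_along(beams)) {
    bi <- do.call(rbind, lapply(man$bixel_idx[[b]], function(r)
      as.integer(unlist(r))))
    D[[b]] <- lapply(seq_len(man$n_phases), function(p) {
      m <- methods::as(Matrix::readMM(
        file.path(dir, sprintf("dij_b%02d_p%02d.mtx", b, p - 1))), "CsparseMatrix")
      structure(list(D = m, bixel_idx = bi, beam = beams[[b]],
                     geom_dose = geom, kernel = kernel),
                class = "dose_influence")
    })
  }
  structure(list(D = D, beams = beams, geom_dose = geom, kernel = kernel,
                 n_phases = man$n_phases), class = "dij_store")
}
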