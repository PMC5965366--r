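# Target volume construction (ITV, MTV, margins, midV phase selection) and
# cohort-style motion/volume descriptors.

check_mask_geometry <- function(masks) {
  g0 <- geom_of(masks[[1]])
  for (m in masks[-1])
    if (!same_geometry(m, g0)) stop("mask geometry mismatch")
  g0
}

#' Internal target volume: voxelwise union of per-phase GTVs
#'
#' @param gtv_masks list of per-phase `roi_mask` on a shared geometry.
#' @return `roi_mask` named "ITV".
#' @export
union_itv <- function(gtv_masks) {
  g <- check_mask_geometry(gtv_masks)
  acc <- gtv_masks[[1]]$mask
  for (m in gtv_masks[-1]) acc <- acc | m$mask
  roi_mask(acc, "ITV", g$spacing, g$origin)
}

# Translate a logical array by whole voxels, zero-filling vacated space.
shift_mask_array <- function(mask, shift) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else        { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Moving target volume: union of centroid-aligned per-phase GTVs
#'
#' Each phase GTV is rigidly translated onto the reference GTV centroid
#' (nearest-voxel shift of the centroid difference) before the union, so a
#' purely translating tumour yields an MTV equal to the reference GTV while
#' any shape change propagates into the MTV.
#'
#' @param gtv_masks list of per-phase `roi_mask`.
#' @param ref reference phase index (0-based, default 0 = peak exhale).
#' @return `roi_mask` named "MTV".
#' @export
build_mtv <- function(gtv_masks, ref = 0L) {
  g <- check_mask_geometry(gtv_masks)
  cref <- mask_centroid(gtv_masks[[ref + 1L]])
  acc <- array(FALSE, g$dim)
  for (m in gtv_masks) {
    shift <- as.integer(round((cref - mask_centroid(m)) / g$spacing))
    acc <- acc | shift_mask_array(m$mask, shift)
  }
  roi_mask(acc, "MTV", g$spacing, g$origin)
}

#' Isotropic Euclidean margin expansion of a mask
#'
#' A voxel is included iff its center lies within `margin_mm` of any source
#' voxel center (Euclidean distance in mm, anisotropic spacing respected).
#'
#' @param mask an `roi_mask`.
#' @param margin_mm isotropic margin in mm, >= 0.
#' @param name name of the result (default `<mask>+<margin>`).
#' @return expanded `roi_mask`.
#' @export
expand_margin <- function(mask, margin_mm, name = NULL) {
  if (margin_mm < 0) stop("margin must be >= 0")
  name <- name %||% sprintf("%s+%g", mask$name, margin_mm)
  if (margin_mm == 0)
    return(roi_mask(mask$mask, name, mask$spacing, mask$origin))
  sp <- mask$spacing
  rng <- floor(margin_mm / sp)
  offs <- as.matrix(expand.grid(i = -rng[1]:rng[1], j = -rng[2]:rng[2],
                                k = -rng[3]:rng[3]))
  keep <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
                 (offs[, 3] * sp[3])^2) <= margin_mm
  offs <- offs[keep, , drop = FALSE]
  d <- dim(mask$mask)
  idx <- which(mask$mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (q in seq_len(nrow(offs))) {
    sh <- idx
    sh[, 1] <- idx[, 1] + offs[q, 1]
    sh[, 2] <- idx[, 2] + offs[q, 2]
    sh[, 3] <- idx[, 3] + offs[q, 3]
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  roi_mask(out, name, mask$spacing, mask$origin)
}

#' Select the midventilation phase
#'
#' Returns the phase whose centroid is nearest (Euclidean) the time-weighted
#' mean centroid; ties break toward the lower phase index. With equal phase
#' durations (phase-binned 4DCT) the weights are uniform.
#'
#' @param centroids numeric matrix (n_phases x 3) mm.
#' @param weights optional per-phase dwell weights (default uniform).
#' @return 0-based phase index.
#' @export
select_midv_phase <- function(centroids, weights = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("need >= 2 phases")
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  mean_pos <- colSums(centroids * w)
  d <- sqrt(rowSums(sweep(centroids, 2, mean_pos, "-")^2))
  which.min(d) - 1L   # which.min takes the first (lowest index) minimum
}

#' Cohort-style motion and volume descriptors
#'
#' Per-axis peak-to-peak centroid motion, the 3D peak-to-peak as the
#' Euclidean norm of the per-axis values, GTV volume min/max/reference, and
#' the deformation percentage `(max - ref)/ref * 100`.
#'
#' @param centroids matrix (n_phases x 3) of GTV centroids, columns LR/AP/SI mm.
#' @param gtv_masks list of per-phase `roi_mask`, or `NULL` when `volumes_cm3`
#'   is given directly.
#' @param ref 0-based reference phase index.
#' @param volumes_cm3 optional per-phase GTV volumes (cm3) replacing the masks.
#' @return Object of class `motion_descriptors`: `pp_mm` (LR, AP, SI),
#'   `pp3d_mm`, `vol_min_cm3`, `vol_max_cm3`, `vol_ref_cm3`, `deformation_pct`.
#' @export
motion_descriptors <- function(centroids, gtv_masks = NULL, ref = 0L,
                               volumes_cm3 = NULL) {
  centroids <- as.matrix(centroids)
  pp <- apply(centroids, 2, function(v) max(v) - min(v))
  names(pp) <- c("LR", "AP", "SI")
  pp3d <- sqrt(sum(pp^2))
  if (is.null(volumes_cm3)) {
    if (is.null(gtv_masks)) stop("need gtv_masks or volumes_cm3")
    volumes_cm3 <- vapply(gtv_masks, mask_volume_cm3, numeric(1))
  }
  vref <- volumes_cm3[ref + 1L]
  structure(list(pp_mm = pp, pp3d_mm = pp3d,
                 vol_min_cm3 = min(volumes_cm3),
                 vol_max_cm3 = max(volumes_cm3),
                 vol_ref_cm3 = vref,
                 deformation_pct = (max(volumes_cm3) - vref) / vref * 100),
            class = "motion_descriptors")
}

#' @export
print.motion_descriptors <- function(x, ...) {
  cat(sprintf("<motion_descriptors> pp (LR %.1f, AP %.1f, SI %.1f) mm, 3D %.1f mm\n",
              x$pp_mm[1], x$pp_mm[2], x$pp_mm[3], x$pp3d_mm))
  cat(sprintf("  GTV vol min/max/ref %.1f/%.1f/%.1f cm3, deformation %.0f%%\n",
              x$vol_min_cm3, x$vol_max_cm3, x$vol_ref_cm3, x$deformation_pct))
  invisible(x)
}
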