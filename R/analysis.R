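# DVH computation, endpoint metrics (D98, D2, V20), dose normalization and
# mode-comparison reporting.

#' Cumulative dose-volume histogram
#'
#' Direct voxel counting over the masked voxels, cumulative ("volume
#' receiving >= dose"), with a fine fixed bin width (<= 0.01 Gy).
#'
#' @param dose dose `voxel_grid`.
#' @param mask `roi_mask` on the same geometry.
#' @param bin_gy bin width (default 0.01 Gy).
#' @return Object of class `dvh_result`: `dose_gy` bin edges, `volume_pct`
#'   (monotone non-increasing, 100% at 0 Gy), the structure `name`, and the
#'   raw masked `doses`.
#' @export
dvh <- function(dose, mask, bin_gy = 0.01) {
  if (!same_geometry(dose, mask)) stop("dose/mask geometry mismatch")
  d <- dose$data[mask$mask]
  if (length(d) == 0) stop("empty mask: ", mask$name)
  edges <- seq(0, max(d) + 2 * bin_gy, by = bin_gy)
  vol <- vapply(edges, function(x) 100 * mean(d >= x), numeric(1))
  structure(list(dose_gy = edges, volume_pct = vol, name = mask$name,
                 doses = d, bin_gy = bin_gy), class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("<dvh_result> '%s': %d voxels, D98 %.2f / D50 %.2f / D2 %.2f Gy\n",
              x$name, length(x$doses), dose_at_volume(x, 98),
              dose_at_volume(x, 50), dose_at_volume(x, 2)))
  invisible(x)
}

#' @param x a `dvh_result`.
#' @param ... further plot arguments.
#' @rdname dvh
#' @export
plot.dvh_result <- function(x, ...) {
  graphics::plot(x$dose_gy, x$volume_pct, type = "l", xlab = "Dose (Gy)",
                 ylab = "Volume (%)", main = x$name, ...)
  invisible(x)
}

#' Dose received by x% of the structure (D_x)
#'
#' Inverse of the cumulative curve with linear interpolation, evaluated on
#' the exact voxel-dose order statistics (the fine-bin limit of the binned
#' curve, so D_x is exactly linear under dose rescaling);
#' `D98 <= D50 <= D2` by construction.
#'
#' @param dvh a `dvh_result`.
#' @param x volume percentage, 0 < x < 100.
#' @return D_x in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (x <= 0 || x >= 100) stop("x must be in (0, 100)")
  if (max(dvh$doses) <= 0) return(0)
  ds <- sort(dvh$doses, decreasing = TRUE)
  n <- length(ds)
  c0 <- x / 100 * n
  if (c0 <= 1) return(ds[1])
  if (c0 >= n) return(ds[n])
  k <- floor(c0)
  ds[k] + (ds[k + 1] - ds[k]) * (c0 - k)
}

#' Volume receiving at least x Gy (V_x)
#'
#' Percent of the masked voxels with dose >= x, by direct count. For the
#' lung spill metric, pass the lung-minus-GTVref mask and scale the fraction
#' dose to the total course first (see [scale_to_course()]).
#'
#' @param dvh a `dvh_result`.
#' @param x dose threshold in Gy, >= 0.
#' @return volume percentage.
#' @export
volume_at_dose <- function(dvh, x) {
  if (x < 0) stop("x must be >= 0")
  100 * mean(dvh$doses >= x)
}

#' Scale a fraction dose to the total course
#' @param dose dose `voxel_grid` per fraction.
#' @param fractions number of fractions (default 3).
#' @export
scale_to_course <- function(dose, fractions = 3) {
  voxel_grid(dose$data * fractions, dose$spacing, dose$origin)
}

#' Mask subtraction helper (e.g. lung minus GTVref)
#' @param a,b `roi_mask`s on the same geometry.
#' @param name result name.
#' @export
mask_minus <- function(a, b, name = paste0(a$name, "-", b$name)) {
  if (!same_geometry(a, b)) stop("mask geometry mismatch")
  roi_mask(a$mask & !b$mask, name, a$spacing, a$origin)
}

#' Scale a dose distribution to a target GTV D98
#'
#' Multiplies the dose by `target / current D98(gtv)`; after scaling the
#' GTV D98 equals the target exactly (linearity). Used to compare OAR doses
#' at matched target coverage.
#'
#' @param dose dose `voxel_grid`.
#' @param gtv GTV `roi_mask`.
#' @param target_d98_gy target D98 in Gy.
#' @return scaled dose `voxel_grid`.
#' @export
normalize_to_reference <- function(dose, gtv, target_d98_gy) {
  cur <- dose_at_volume(dvh(dose, gtv), 98)
  if (cur <= 0) stop("current D98 is zero; cannot scale")
  voxel_grid(dose$data * target_d98_gy / cur, dose$spacing, dose$origin)
}

#' Endpoint metrics for one accumulated dose
#'
#' GTVref D98 (Gy/fraction), lung-minus-GTVref V20 (% of the total-course
#' dose, fraction dose x `fractions`), spinal cord D2 and proximal airways
#' D2 (Gy/fraction).
#'
#' @param dose reference-frame dose `voxel_grid` (per fraction).
#' @param masks list with `gtv`, `lung`, `cord`, `airways` `roi_mask`s
#'   (lung is taken minus the GTV internally).
#' @param fractions fractions for the V20 course scaling (default 3).
#' @return named numeric vector `d98_gtv`, `v20_lung`, `d2_cord`, `d2_airways`.
#' @export
endpoint_metrics <- function(dose, masks, fractions = 3) {
  lung_m <- mask_minus(masks$lung, masks$gtv, "lung-GTVref")
  c(d98_gtv = dose_at_volume(dvh(dose, masks$gtv), 98),
    v20_lung = volume_at_dose(dvh(scale_to_course(dose, fractions), lung_m), 20),
    d2_cord = dose_at_volume(dvh(dose, masks$cord), 2),
    d2_airways = dose_at_volume(dvh(dose, masks$airways), 2))
}

#' Compare delivery modes and margin strategies
#'
#' Builds the endpoint table for a set of accumulated doses and computes
#' dose differences against (a) each plan's own static (planned) delivery
#' and (b) a named conventional baseline (typically the conventionally
#' delivered ITV+5 plan), both unscaled and after scaling each entry's GTV
#' D98 to the baseline's (see [normalize_to_reference()]). Deltas are
#' recomputed from the stored entries, never stored independently.
#'
#' @param doses named list of reference-frame dose `voxel_grid`s; names are
#'   `"<plan>.<mode>"` (e.g. `"MTV+1.tracked"`).
#' @param masks list with `gtv`, `lung`, `cord`, `airways`.
#' @param baseline name of the conventional baseline entry
#'   (default `"ITV+5.untracked"`).
#' @param fractions V20 course scaling.
#' @return data.frame of class `comparison_report`: one row per entry with
#'   endpoints, deltas vs the same plan's static entry, deltas vs the
#'   baseline, and scaled OAR endpoints/deltas.
#' @export
compare_modes <- function(doses, masks, baseline = "ITV+5.untracked",
                          fractions = 3) {
  if (!baseline %in% names(doses)) stop("missing baseline: ", baseline)
  met <- t(vapply(doses, endpoint_metrics, numeric(4), masks = masks,
                  fractions = fractions))
  plans <- sub("\\.[^.]+$", "", names(doses))
  modes <- sub("^.*\\.", "", names(doses))
  base_d98 <- met[baseline, "d98_gtv"]
  rep <- data.frame(plan = plans, mode = modes, met,
                    row.names = names(doses), check.names = FALSE)
  # deltas vs the same plan's static entry
  rep$dd98_vs_static <- NA_real_
  for (i in seq_len(nrow(rep))) {
    st <- paste0(rep$plan[i], ".static")
    if (st %in% rownames(rep))
      rep$dd98_vs_static[i] <- rep$d98_gtv[i] - rep[st, "d98_gtv"]
  }
  # deltas vs the conventional baseline (unscaled)
  rep$dd98_vs_baseline <- rep$d98_gtv - base_d98
  rep$dv20_vs_baseline <- rep$v20_lung - met[baseline, "v20_lung"]
  rep$dd2_cord_vs_baseline <- rep$d2_cord - met[baseline, "d2_cord"]
  rep$dd2_airways_vs_baseline <- rep$d2_airways - met[baseline, "d2_airways"]
  # scaled variant: every entry rescaled to the baseline GTV D98
  sc <- t(vapply(names(doses), function(nm) {
    d <- normalize_to_reference(doses[[nm]], masks$gtv, base_d98)
    endpoint_metrics(d, masks, fractions)
  }, numeric(4)))
  rep$v20_lung_scaled <- sc[, "v20_lung"]
  rep$d2_cord_scaled <- sc[, "d2_cord"]
  rep$d2_airways_scaled <- sc[, "d2_airways"]
  rep$dv20_scaled_vs_baseline <- sc[, "v20_lung"] - met[baseline, "v20_lung"]
  rep$dd2_cord_scaled_vs_baseline <- sc[, "d2_cord"] - met[baseline, "d2_cord"]
  rep$dd2_airways_scaled_vs_baseline <- sc[, "d2_airways"] - met[baseline, "d2_airways"]
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' Write a DVH curve as CSV (`dose_gy`, `volume_pct`)
#' @param dvh a `dvh_result`.
#' @param path CSV path.
#' @export
write_dvh <- function(dvh, path) {
  write.csv(data.frame(dose_gy = dvh$dose_gy, volume_pct = dvh$volume_pct),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as CSV and JSON
#' @param report a `comparison_report`.
#' @param stem output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @export
write_report <- function(report, stem) {
  write.csv(as.data.frame(report), paste0(stem, ".csv"), row.names = TRUE)
  jsonlite::write_json(as.data.frame(report), paste0(stem, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(stem)
}
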