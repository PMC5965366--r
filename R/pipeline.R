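# End-to-end orchestration: phantom -> precompute -> plan -> deliver ->
# accumulate -> report, deterministic for a fixed seed.

#' Configuration for a full pipeline run
#'
#' @param phantom a `phantom_spec` (or path to a phantom-spec JSON).
#' @param margins_mm isotropic MTV margins to study (default 1, 3, 5).
#' @param modes named list mapping plan labels to delivery modes. The
#'   default covers the conventional reference (ITV+5 static/untracked),
#'   the full mode triplet for MTV+1, and tracked deliveries of the larger
#'   MTV margins.
#' @param midv logical: also plan/deliver a midventilation plan.
#' @param midv_margin_mm isotropic midV margin (config value; default 5).
#' @param period_s,rate_hz respiratory period and sampling rate (5 s, 25 Hz).
#' @param dose_rate_mu_min delivery dose rate (550 MU/min).
#' @param prescription_gy D95 prescription per fraction (18 Gy).
#' @param fractions course fractions for V20 scaling (3).
#' @param kernel a `kernel_config`.
#' @param subvoxels EMT subvoxel splits per axis (4).
#' @param start_s,gap_s delivery start time and beam-off gap (s).
#' @param n_beams number of equidistant beams (9).
#' @param seed integer seed fixing every stochastic choice.
#' @param out_dir output directory (NULL: keep results in memory only).
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       margins_mm = c(1, 3, 5),
                       modes = NULL, midv = FALSE, midv_margin_mm = 5,
                       period_s = 5, rate_hz = 25,
                       dose_rate_mu_min = 550, prescription_gy = 18,
                       fractions = 3, kernel = kernel_config(),
                       subvoxels = 4L, start_s = 12, gap_s = 2,
                       n_beams = 9, seed = 1L, out_dir = NULL) {
  if (is.character(phantom)) phantom <- read_phantom_spec(phantom)
  if (is.null(modes)) {
    modes <- c(list("ITV+5" = c("static", "untracked")),
               stats::setNames(lapply(sort(margins_mm), function(m)
                 if (m == min(margins_mm)) c("static", "untracked", "tracked")
                 else "tracked"),
                 sprintf("MTV+%g", sort(margins_mm))))
    if (midv) modes$midV <- c("static", "untracked")
  }
  structure(list(phantom = phantom, margins_mm = margins_mm, modes = modes,
                 midv = midv, midv_margin_mm = midv_margin_mm,
                 period_s = period_s, rate_hz = rate_hz,
                 dose_rate_mu_min = dose_rate_mu_min,
                 prescription_gy = prescription_gy, fractions = fractions,
                 kernel = kernel, subvoxels = as.integer(subvoxels),
                 start_s = start_s, gap_s = gap_s, n_beams = n_beams,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full dose-reconstruction pipeline
#'
#' Builds the phantom, precomputes deformed mass and dose-influence data,
#' constructs the target volumes and plans, replays every configured
#' delivery with online phase binning, accumulates each onto the reference
#' phase, and assembles the mode-comparison report. Deterministic for a
#' fixed config and seed. If `out_dir` is set, grids, logs and the report
#' are persisted with a manifest.
#'
#' @param config a `run_config`.
#' @param verbose print stage progress.
#' @return list: `phases`, `descriptors`, `trajectory`, `plans`, `results`
#'   (per `<plan>.<mode>` `accum_result`), `doses`, `masks`, `report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage phantom: building %d-phase phantom", config$phantom$n_phases)
  phases <- build_phantom(config$phantom)
  descriptors <- motion_descriptors(phases$centroids, phases$gtv,
                                    phases$ref_phase)

  say("stage precompute: deformed mass (s = %d)", config$subvoxels)
  dmass <- precompute_deformed_mass(phases, config$subvoxels)

  beams <- beam_set(config$n_beams, iso_mm = phases$centroids[1, ])
  bixels <- plan_bixel_set(phases, beams, max(config$margins_mm,
                                              config$midv_margin_mm))
  say("stage precompute: dose influence (%d beams x %d phases)",
      length(beams), config$phantom$n_phases)
  dij <- precompute_dose_influence(phases, beams, config$kernel, bixels)

  say("stage plan: target volumes and conformal plans")
  itv <- union_itv(phases$gtv)
  mtv <- build_mtv(phases$gtv, phases$ref_phase)
  ptvs <- list("ITV+5" = expand_margin(itv, 5, "PTV_ITV+5"))
  for (m in config$margins_mm)
    ptvs[[sprintf("MTV+%g", m)]] <- expand_margin(mtv, m, sprintf("PTV_MTV+%g", m))
  plan_phase <- stats::setNames(rep(phases$ref_phase, length(ptvs)), names(ptvs))
  if (config$midv) {
    midv_ph <- select_midv_phase(phases$centroids)
    ptvs$midV <- expand_margin(phases$gtv[[midv_ph + 1L]],
                               config$midv_margin_mm, "PTV_midV")
    plan_phase["midV"] <- midv_ph
  }
  plans <- lapply(names(config$modes), function(nm) {
    make_plan(ptvs[[nm]], phases, dij, planning_phase = plan_phase[[nm]],
              prescription_gy = config$prescription_gy,
              dose_rate_mu_min = config$dose_rate_mu_min, name = nm)
  })
  names(plans) <- names(config$modes)

  # one trajectory long enough for the longest delivery
  max_mu <- max(vapply(plans, plan_total_mu, numeric(1)))
  n_segs <- max(vapply(plans, function(p) sum(lengths(p$segments)), numeric(1)))
  duration <- config$start_s + max_mu / (config$dose_rate_mu_min / 60) +
    n_segs * config$gap_s + 3 * config$period_s
  say("stage motion: %0.f s trajectory at %g Hz", duration, config$rate_hz)
  fit <- fit_ellipse(phases$centroids[, c(3, 2)])
  traj <- generate_trajectory(fit, config$period_s, config$rate_hz, duration)
  traj <- bin_trajectory(traj, config$phantom$n_phases)

  masks <- list(gtv = phases$gtv[[phases$ref_phase + 1L]], lung = phases$lung,
                cord = phases$cord, airways = phases$airways)
  results <- list()
  for (nm in names(config$modes)) {
    for (mode in config$modes[[nm]]) {
      key <- paste0(nm, ".", mode)
      say("stage deliver/accumulate: %s", key)
      del <- deliver(plans[[nm]], traj, mode, phases,
                     start_s = config$start_s, gap_s = config$gap_s)
      results[[key]] <- accumulate_delivery(del, phases, dij, dmass,
                                            config$subvoxels)
      results[[key]]$delivery_ticks <- del$ticks
    }
  }
  doses <- lapply(results, function(r) r$dose)
  say("stage report")
  baseline <- if ("ITV+5.untracked" %in% names(doses)) "ITV+5.untracked"
              else names(doses)[1]
  report <- compare_modes(doses, masks, baseline = baseline,
                          fractions = config$fractions)

  out <- list(phases = phases, descriptors = descriptors, trajectory = traj,
              plans = plans, ptvs = ptvs, results = results, doses = doses,
              masks = masks, report = report, config = config)
  if (!is.null(config$out_dir)) persist_run(out, config$out_dir)
  out
}

persist_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(run$trajectory, file.path(dir, "trajectory.csv"))
  for (nm in names(run$plans))
    write_plan(run$plans[[nm]], file.path(dir, sprintf("plan_%s.json", gsub("\\+", "p", nm))))
  for (key in names(run$results)) {
    safe <- gsub("[+.]", "_", key)
    write_grid(run$results[[key]]$dose, file.path(dir, sprintf("dose_%s.nii.gz", safe)))
    write.csv(run$results[[key]]$delivery_ticks,
              file.path(dir, sprintf("ticks_%s.csv", safe)), row.names = FALSE)
    jsonlite::write_json(run$results[[key]]$ledger,
                         file.path(dir, sprintf("energy_%s.json", safe)),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  write_report(run$report, file.path(dir, "report"))
  manifest <- list(
    seed = run$config$seed,
    descriptors = unclass(run$descriptors),
    ptv_volumes_cm3 = lapply(run$ptvs, mask_volume_cm3),
    plan_mu = lapply(run$plans, plan_total_mu),
    runtime_ms = lapply(run$results, function(r) as.list(r$runtime_ms)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
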