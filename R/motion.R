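# Trajectory synthesis from per-phase GTV centroids and online respiratory
# phase binning. The respiratory cycle parameter theta runs 0..2*pi with
# theta = 0 at the reference (peak exhale) phase.

#' Least-squares ellipse fit to per-phase SI/AP centroid positions
#'
#' Models the phase-binned centroids as a 2D sinusoid pair
#' `SI(theta) = c_SI + a_SI cos(theta - phi_SI)`,
#' `AP(theta) = c_AP + a_AP cos(theta - phi_SI - phase_offset)`,
#' where the points are assumed to sample one respiratory cycle uniformly in
#' order (as phase-binned 4DCT centroids do), so the fit is linear least
#' squares in the cos/sin basis. `rms_error` is the per-coordinate RMS
#' residual of the points against the fitted curve at their assigned phases.
#'
#' @param points numeric matrix / data.frame (n x 2) of (SI, AP) mm, n >= 5.
#' @return Object of class `ellipse_fit` with fields `center` (SI, AP),
#'   `semi_axes` (a_SI, a_AP), `phase_si`, `phase_offset`, `rms_error_mm`
#'   and `degenerate` (TRUE when the points are collinear; a_AP is then 0
#'   for axis-aligned degeneracy).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5) stop("need at least 5 points")
  n <- nrow(pts)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  X <- cbind(1, cos(theta), sin(theta))
  coef <- qr.solve(X, pts)                     # 3 x 2
  fitted <- X %*% coef
  res <- pts - fitted
  rms <- sqrt(mean(res^2))                     # per-coordinate RMS residual
  amp <- sqrt(coef[2, ]^2 + coef[3, ]^2)
  amp[amp < 1e-9] <- 0                         # fp noise on constant input
  ph <- atan2(coef[3, ], coef[2, ])            # SI/AP phase angles
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  degenerate <- ev[1] <= 0 || ev[2] / ev[1] < 1e-12
  if (degenerate && stats::sd(pts[, 2]) < 1e-9 * max(stats::sd(pts[, 1]), 1e-300)) {
    amp[2] <- 0
    ph[2] <- ph[1]
  }
  off <- (ph[2] - ph[1] + pi) %% (2 * pi) - pi
  structure(list(center = c(SI = unname(coef[1, 1]), AP = unname(coef[1, 2])),
                 semi_axes = c(a_SI = unname(amp[1]), a_AP = unname(amp[2])),
                 phase_si = unname(ph[1]), phase_offset = off,
                 rms_error_mm = rms, degenerate = degenerate),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> a_SI %.2f mm, a_AP %.2f mm, offset %.2f rad, rms %.3g mm%s\n",
              x$semi_axes[1], x$semi_axes[2], x$phase_offset, x$rms_error_mm,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Generate a 2D sinusoid tumour trajectory from an ellipse fit
#'
#' SI and AP trace the fitted ellipse sinusoidally with the given respiratory
#' period, sampled at the acquisition rate; LR is identically zero. The cycle
#' starts at `theta = 0`, the reference (peak exhale) phase.
#'
#' @param fit an `ellipse_fit`.
#' @param period_s respiratory period in s (default 5).
#' @param rate_hz sampling rate in Hz (default 25).
#' @param duration_s trajectory length in s.
#' @param noise_sd_mm optional Gaussian position noise (mm) on SI and AP.
#' @return A data.frame of class `trajectory` with columns `time_s`, `LR_mm`,
#'   `AP_mm`, `SI_mm`; attributes `rate_hz` and `period_s`.
#' @export
generate_trajectory <- function(fit, period_s = 5, rate_hz = 25, duration_s,
                                noise_sd_mm = 0) {
  if (period_s <= 0 || rate_hz <= 0) stop("period and rate must be positive")
  if (duration_s < period_s)
    warning("trajectory shorter than one respiratory period; phase binning needs >= 1 cycle")
  t <- seq(0, duration_s, by = 1 / rate_hz)
  t <- t[t < duration_s + 1e-12]
  theta <- 2 * pi * t / period_s
  si <- fit$center[1] + fit$semi_axes[1] * cos(theta - fit$phase_si)
  ap <- fit$center[2] + fit$semi_axes[2] * cos(theta - fit$phase_si - fit$phase_offset)
  if (noise_sd_mm > 0) {
    si <- si + rnorm(length(t), 0, noise_sd_mm)
    ap <- ap + rnorm(length(t), 0, noise_sd_mm)
  }
  out <- data.frame(time_s = t, LR_mm = 0, AP_mm = as.numeric(ap),
                    SI_mm = as.numeric(si))
  attr(out, "rate_hz") <- rate_hz
  attr(out, "period_s") <- period_s
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Estimate the respiratory period by Fourier analysis
#'
#' Uses the last `window_s` seconds of the SI component: the dominant nonzero
#' spectral peak, refined by parabolic interpolation of the magnitude peak
#' (the 20 s window alone gives only 0.05 Hz resolution near a 0.2 Hz
#' breathing frequency).
#'
#' @param x numeric vector of SI samples, or a `trajectory`.
#' @param rate_hz sampling rate (taken from the trajectory if present).
#' @param window_s analysis window in s (default 20; shorter data is used whole).
#' @return Estimated period in s.
#' @export
estimate_period <- function(x, rate_hz = NULL, window_s = 20) {
  if (inherits(x, "trajectory")) {
    rate_hz <- rate_hz %||% attr(x, "rate_hz")
    x <- x$SI_mm
  }
  if (is.null(rate_hz)) stop("rate_hz required")
  n_win <- min(length(x), round(window_s * rate_hz))
  x <- x[(length(x) - n_win + 1):length(x)]
  x <- x - mean(x)
  if (sd(x) < 1e-12) stop("constant signal: period undefined")
  n <- length(x)
  # Hann window tames spectral leakage so the parabolic refinement of the
  # (log-magnitude) peak is accurate well below the raw bin resolution
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  mag <- Mod(fft(x * w))
  half <- floor(n / 2)
  b <- which.max(mag[2:(half + 1)])           # 0-based dominant nonzero bin
  m0 <- log(mag[b + 1])
  ml <- if (b >= 1) log(mag[b]) else m0
  mr <- if (b + 2 <= length(mag)) log(mag[b + 2]) else m0
  denom <- ml - 2 * m0 + mr
  delta <- if (is.finite(denom) && abs(denom) > 1e-300) 0.5 * (ml - mr) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  f <- (b + delta) * rate_hz / n
  1 / f
}

#' Create an online respiratory phase binner
#'
#' A causal stream processor: respiratory extrema ("peaks" and "valleys") are
#' detected on the SI component with a +/- `window_s` causal confirmation
#' window and a minimum prominence of `prominence` times the running
#' peak-to-peak range. Each sample is phase shifted back by one respiratory
#' cycle and binned relative to the last fully acquired exhale-to-exhale
#' branch pair: `n_phases` equal-duration half-open bins per cycle, centred
#' on the cycle's phase points with bin 0 centred on the exhale extremum
#' (the reference phase), mirroring how 4DCT phase binning centres its
#' reconstruction windows. Samples seen before the first complete cycle
#' report `NA` (warm-up).
#'
#' @param n_phases number of phase bins per cycle.
#' @param rate_hz sampling rate.
#' @param exhale whether peak exhale is the SI "min" (default) or "max".
#' @param prominence minimum extremum prominence as a fraction of the running
#'   peak-to-peak amplitude.
#' @param window_s half width of the causal extremum confirmation window (s).
#' @return A list with `add(si_mm, time_s)` returning the phase bin (0-based)
#'   or `NA` during warm-up, and `state()` returning detector internals
#'   (extrema times/types and the current cycle length).
#' @export
phase_binner <- function(n_phases = 10, rate_hz = 25, exhale = c("min", "max"),
                         prominence = 0.1, window_s = 0.5) {
  exhale <- match.arg(exhale)
  wlen <- max(1L, as.integer(round(window_s * rate_hz)))
  env <- new.env()
  env$si <- numeric(4096); env$tt <- numeric(4096); env$n <- 0L
  env$ex_t <- numeric(0); env$ex_v <- numeric(0); env$ex_type <- character(0)
  env$run_min <- Inf; env$run_max <- -Inf

  # parabolic sub-sample refinement of the extremum time (exact for a
  # noiseless sinusoid whose true extremum falls between samples)
  refine_t <- function(j) {
    if (j <= 1L || j >= env$n) return(env$tt[j])
    vl <- env$si[j - 1L]; v0 <- env$si[j]; vr <- env$si[j + 1L]
    den <- vl - 2 * v0 + vr
    if (abs(den) < 1e-300) return(env$tt[j])
    delta <- max(min(0.5 * (vl - vr) / den, 0.5), -0.5)
    env$tt[j] + delta * (env$tt[j + 1L] - env$tt[j])
  }

  try_extremum <- function(j) {
    lo <- max(1L, j - wlen); hi <- j + wlen
    w <- env$si[lo:hi]
    v <- env$si[j]
    if (max(w) == min(w)) return(invisible())
    # ties (e.g. two samples straddling the true extremum) are allowed; the
    # alternation rule below keeps only the first/most extreme of a run
    type <- if (v <= min(w)) "min"
            else if (v >= max(w)) "max" else return(invisible())
    k <- length(env$ex_type)
    if (k > 0L) {
      pp <- env$run_max - env$run_min
      if (env$ex_type[k] == type) {
        better <- if (type == "min") v < env$ex_v[k] else v > env$ex_v[k]
        if (better) { env$ex_v[k] <- v; env$ex_t[k] <- refine_t(j) }
        return(invisible())
      }
      if (abs(v - env$ex_v[k]) < prominence * pp) return(invisible())
    }
    env$ex_t <- c(env$ex_t, refine_t(j))
    env$ex_v <- c(env$ex_v, v)
    env$ex_type <- c(env$ex_type, type)
    invisible()
  }

  add <- function(si_mm, time_s) {
    n <- env$n + 1L
    if (n > length(env$si)) {
      env$si <- c(env$si, numeric(length(env$si)))
      env$tt <- c(env$tt, numeric(length(env$tt)))
    }
    env$si[n] <- si_mm; env$tt[n] <- time_s; env$n <- n
    env$run_min <- min(env$run_min, si_mm)
    env$run_max <- max(env$run_max, si_mm)
    if (n == wlen + 1L) try_extremum(1L)       # series start can be an extremum
    if (n > wlen) try_extremum(n - wlen)
    et <- env$ex_t[env$ex_type == exhale]
    if (length(et) < 2L) return(NA_integer_)
    e1 <- et[length(et) - 1L]; e2 <- et[length(et)]
    tc <- e2 - e1
    if (tc <= 0) return(NA_integer_)
    frac <- ((time_s - e2) / tc) %% 1
    # bins are centred on the n phase points of the cycle (as 4DCT phase
    # binning centres its reconstruction windows), half-open toward later
    # time; bin 0 is centred on the exhale extremum. The 1e-9 guard absorbs
    # fp jitter of samples landing exactly on a bin edge.
    as.integer(floor(n_phases * frac + 0.5 + 1e-9)) %% as.integer(n_phases)
  }

  state <- function() list(extrema_t = env$ex_t, extrema_type = env$ex_type,
                           cycle_s = {
                             et <- env$ex_t[env$ex_type == exhale]
                             if (length(et) >= 2) diff(utils::tail(et, 2)) else NA_real_
                           })
  list(add = add, state = state)
}

#' Annotate a trajectory with online phase bins and period estimates
#'
#' Runs the causal binner of [phase_binner()] over the samples in time order
#' and attaches the Fourier period estimate (updated once per second from the
#' trailing 20 s window).
#'
#' @param traj a `trajectory`.
#' @param n_phases bins per cycle.
#' @param exhale,prominence,window_s passed to [phase_binner()].
#' @return the trajectory with `phase_bin` (integer, `NA` = warm-up) and
#'   `period_s` columns added.
#' @export
bin_trajectory <- function(traj, n_phases = 10, exhale = "min",
                           prominence = 0.1, window_s = 0.5) {
  rate <- attr(traj, "rate_hz")
  pb <- phase_binner(n_phases, rate, exhale, prominence, window_s)
  n <- nrow(traj)
  bins <- integer(n); periods <- rep(NA_real_, n)
  upd <- max(1L, as.integer(rate))
  cur_period <- NA_real_
  for (i in seq_len(n)) {
    bins[i] <- pb$add(traj$SI_mm[i], traj$time_s[i])
    if (i %% upd == 0L && i >= 2 * rate) {
      cur_period <- tryCatch(estimate_period(traj$SI_mm[1:i], rate),
                             error = function(e) NA_real_)
    }
    periods[i] <- cur_period
  }
  traj$phase_bin <- bins
  traj$period_s <- periods
  traj
}

#' Write / read a trajectory CSV
#'
#' Columns: `time_s, LR_mm, AP_mm, SI_mm, phase_bin, period_s`.
#' @param traj a binned `trajectory`.
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  cols <- intersect(c("time_s", "LR_mm", "AP_mm", "SI_mm", "phase_bin", "period_s"),
                    names(traj))
  write.csv(as.data.frame(traj)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @param rate_hz sampling rate to attach (inferred from time steps if NULL).
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, rate_hz = NULL) {
  df <- read.csv(path)
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(df$time_s))
  attr(df, "rate_hz") <- rate_hz
  class(df) <- c("trajectory", "data.frame")
  df
}
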