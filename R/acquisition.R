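#' Acquisition parameters for a dynamic SPGR study
#'
#' Bundles the scanner and injection constants needed for relaxometry,
#' signal-to-concentration conversion and curve timing: repetition time,
#' flip angles, temporal resolution, frame counts, injection timing and the
#' contrast-agent relaxivity.
#'
#' Defaults describe a 1.5 T head-and-neck protocol: 60 dynamic frames at a
#' temporal resolution of 3.735 s, dynamic flip angle 12 degrees, a
#' variable-flip-angle (VFA) pre-contrast series at 2/5/10/15/25 degrees,
#' contrast injection starting a few frames into the dynamic series with the
#' four frames before bolus injection used as signal baseline, and gadoterate
#' relaxivity r1 = 3.1 /s/mM.
#'
#' @param tr Repetition time (s).
#' @param flip_angle_dyn Flip angle of the dynamic series (degrees).
#' @param flip_angles_vfa Flip angles of the pre-contrast VFA series (degrees).
#' @param dt Temporal resolution of the dynamic series (s).
#' @param n_frames Number of dynamic frames.
#' @param injection_frame 0-based index of the first post-injection frame.
#' @param baseline_frames Number of pre-injection frames averaged into S0.
#' @param r1 Longitudinal relaxivity of the contrast agent (/s/mM).
#'
#' @return An object of class \code{acq_params} (a validated list).
#' @export
acq_params <- function(tr = 0.0053,
                       flip_angle_dyn = 12,
                       flip_angles_vfa = c(2, 5, 10, 15, 25),
                       dt = 3.735,
                       n_frames = 60,
                       injection_frame = 4,
                       baseline_frames = 4,
                       r1 = 3.1) {
  stopifnot(is.numeric(tr), length(tr) == 1L, is.finite(tr))
  if (tr <= 0) stop("'tr' must be positive")
  if (dt <= 0) stop("'dt' must be positive")
  if (r1 <= 0) stop("'r1' must be positive")
  angles <- c(flip_angle_dyn, flip_angles_vfa)
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles > 90))
    stop("flip angles must lie in (0, 90] degrees")
  n_frames <- as.integer(n_frames)
  injection_frame <- as.integer(injection_frame)
  baseline_frames <- as.integer(baseline_frames)
  if (n_frames < injection_frame + 2L)
    stop("'n_frames' must be at least injection_frame + 2")
  if (baseline_frames < 1L || baseline_frames > injection_frame)
    stop("'baseline_frames' must be in [1, injection_frame]")
  structure(list(tr = tr,
                 flip_angle_dyn = flip_angle_dyn,
                 flip_angles_vfa = flip_angles_vfa,
                 dt = dt,
                 n_frames = n_frames,
                 injection_frame = injection_frame,
                 baseline_frames = baseline_frames,
                 r1 = r1),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("SPGR acquisition parameters\n")
  cat(sprintf("  TR %.4g s, dynamic flip %g deg, VFA angles %s deg\n",
              x$tr, x$flip_angle_dyn, paste(x$flip_angles_vfa, collapse = "/")))
  cat(sprintf("  %d frames at dt = %.3f s; injection frame %d, %d baseline frames\n",
              x$n_frames, x$dt, x$injection_frame, x$baseline_frames))
  cat(sprintf("  relaxivity r1 = %.2f /s/mM\n", x$r1))
  invisible(x)
}

#' Time axis of the dynamic series
#'
#' @param acq An \code{\link{acq_params}} object.
#' @return Numeric vector of frame mid times (s), starting at 0.
#' @export
acq_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  seq(0, by = acq$dt, length.out = acq$n_frames)
}

# Single point of unit conversion: all rate parameters cross the API in
# 1/min (the reporting convention in perfusion imaging) while internal time
# axes are in seconds.
per_min_to_per_s <- function(x) x / 60

per_s_to_per_min <- function(x) x * 60

deg_to_rad <- function(x) x * pi / 180
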