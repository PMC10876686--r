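# Pre-contrast T1 mapping (variable flip angle) and signal-to-concentration
# conversion for spoiled gradient-echo data.

#' Variable-flip-angle T10 estimation
#'
#' Estimates pre-contrast T1 from SPGR signals acquired at several flip
#' angles by the standard linearization: plotting S/sin(a) against
#' S/tan(a) gives a line with slope E1 = exp(-TR/T1). The nominal angles
#' are corrected by the transmit-field factor \code{b1} before use.
#'
#' Voxels with a degenerate or non-physical fit (slope outside (0, 1),
#' T1 outside \code{t1_bounds}, or all-zero signal) are flagged invalid
#' rather than raising an error, so whole maps can be fitted in one call.
#'
#' @param signals Numeric vector (one voxel) or matrix (voxels x angles) of
#'   SPGR signals, one column per flip angle.
#' @param flip_angles Nominal flip angles (degrees).
#' @param tr Repetition time (s).
#' @param b1 Relative flip-angle factor, scalar or one per voxel; default 1.
#' @param t1_bounds Acceptance interval for T10 (s); default c(0.05, 10).
#'
#' @return A data.frame with columns \code{t10} (s), \code{r_squared} of the
#'   linearized fit, and logical \code{valid}.
#' @export
fit_t10_vfa <- function(signals, flip_angles, tr, b1 = 1,
                        t1_bounds = c(0.05, 10)) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  n_vox <- nrow(signals)
  if (ncol(signals) != length(flip_angles))
    stop("one signal column per flip angle required")
  if (length(unique(flip_angles)) < 2L)
    stop("at least 2 distinct flip angles required")
  if (any(b1 <= 0)) stop("'b1' must be positive")
  b1 <- rep_len(b1, n_vox)

  t10 <- rep(NA_real_, n_vox)
  r2 <- rep(NA_real_, n_vox)
  valid <- rep(FALSE, n_vox)
  for (v in seq_len(n_vox)) {
    s <- signals[v, ]
    if (!all(is.finite(s)) || all(s == 0)) next
    if (stats::sd(s) == 0) next   # identical signal at all angles: no slope
    a <- deg_to_rad(flip_angles * b1[v])
    y <- s / sin(a)
    x <- s / tan(a)
    if (stats::sd(x) == 0) next
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2L]
    if (!is.finite(slope) || slope <= 0 || slope >= 1) next
    t1 <- -tr / log(slope)
    if (t1 < t1_bounds[1L] || t1 > t1_bounds[2L]) next
    ss_tot <- sum((y - mean(y))^2)
    t10[v] <- t1
    r2[v] <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
    valid[v] <- TRUE
  }
  data.frame(t10 = t10, r_squared = r2, valid = valid)
}

#' Convert an SPGR signal time course to contrast-agent concentration
#'
#' Inverts the steady-state SPGR signal equation. With the baseline signal
#' \eqn{S_0} (mean over the pre-injection frames) and the saturation factor
#' \eqn{k = (1 - E_{10}) / (1 - \cos\alpha\,E_{10})}, the signal ratio gives
#' \eqn{E_1(t) = (1 - y) / (1 - y\cos\alpha)} with
#' \eqn{y = k\,S(t)/S_0}, from which
#' \eqn{R_1(t) = -\ln E_1(t)/TR} and
#' \eqn{C(t) = (R_1(t) - 1/T_{10})/r_1}.
#'
#' Enhancement so strong that the inversion leaves no real solution
#' (\eqn{E_1 \le 0}) is clamped to \code{conc_ceiling} and flagged.
#'
#' @param signal Signal time course (arbitrary units).
#' @param t10 Pre-contrast T1 for this voxel/ROI (s).
#' @param acq An \code{\link{acq_params}} object.
#' @param b1 Relative flip-angle factor for the dynamic series; default 1.
#'   Whether the dynamic flip angle should receive the B1 correction is a
#'   protocol choice; pass \code{b1 = 1} to disable it.
#' @param s0 Baseline signal; default the mean of the first
#'   \code{acq$baseline_frames} samples.
#' @param conc_ceiling Clamp value (mM) for unphysical enhancement;
#'   default 20.
#'
#' @return A data.frame with columns \code{time} (s), \code{conc} (mM) and
#'   logical \code{clamped}.
#' @export
signal_to_concentration <- function(signal, t10, acq, b1 = 1, s0 = NULL,
                                    conc_ceiling = 20) {
  stopifnot(inherits(acq, "acq_params"))
  if (!is.finite(t10) || t10 <= 0) stop("'t10' must be positive")
  if (is.null(s0)) s0 <- mean(signal[seq_len(acq$baseline_frames)])
  if (!is.finite(s0) || s0 <= 0) stop("baseline signal S0 must be positive")
  alpha <- deg_to_rad(acq$flip_angle_dyn * b1)
  e10 <- exp(-acq$tr / t10)
  k <- (1 - e10) / (1 - cos(alpha) * e10)
  y <- k * signal / s0
  e1 <- (1 - y) / (1 - y * cos(alpha))
  # e1 must lie in (0, 1): <= 0 or >= 1 means enhancement beyond the
  # invertible range of the signal equation
  clamped <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  r1t <- rep(NA_real_, length(signal))
  r1t[!clamped] <- -log(e1[!clamped]) / acq$tr
  conc <- (r1t - 1 / t10) / acq$r1
  conc[clamped] <- conc_ceiling
  times <- seq(0, by = acq$dt, length.out = length(signal))
  data.frame(time = times, conc = conc, clamped = clamped)
}

#' Contrast-index (relative enhancement) curve
#'
#' \eqn{CI(t) = (S(t) - S_0) / S_0} with \eqn{S_0} the mean of the
#' pre-injection baseline frames.
#'
#' @param signal Signal time course.
#' @param acq An \code{\link{acq_params}} object (supplies baseline length
#'   and frame times).
#' @param s0 Baseline override; default mean of the baseline frames.
#'
#' @return A data.frame with columns \code{time} (s) and \code{ci}.
#' @export
contrast_index <- function(signal, acq, s0 = NULL) {
  stopifnot(inherits(acq, "acq_params"))
  if (is.null(s0)) s0 <- mean(signal[seq_len(acq$baseline_frames)])
  if (!is.finite(s0) || s0 <= 0) stop("baseline signal S0 must be positive")
  times <- seq(0, by = acq$dt, length.out = length(signal))
  data.frame(time = times, ci = (signal - s0) / s0)
}
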