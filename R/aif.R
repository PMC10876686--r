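# Arterial input function construction: individual AIF from an artery
# mask, population AIFs built from many arterial time-intensity curves
# under the six alignment x baseline-handling variants, and nonlinear
# least-squares fitting of the Parker functional form.

aif_variants <- c("individual", "pop", "pop_bl", "pop_pa", "pop_pa_bl",
                  "pop_wia", "pop_wia_bl")

new_measured_aif <- function(time, conc, variant, n_sources,
                             parker = NULL, fit_rmse = NA_real_) {
  variant <- match.arg(variant, aif_variants)
  if (variant == "individual" && n_sources != 1L)
    stop("individual AIF must have exactly one source")
  structure(list(time = time, conc = conc, variant = variant,
                 n_sources = as.integer(n_sources), parker = parker,
                 fit_rmse = fit_rmse),
            class = "measured_aif")
}

#' @export
print.measured_aif <- function(x, ...) {
  cat(sprintf("AIF [%s], %d source curve(s), %d samples, peak %.3g mM at %.1f s\n",
              x$variant, x$n_sources, length(x$conc),
              max(x$conc), x$time[which.max(x$conc)]))
  if (!is.null(x$parker))
    cat(sprintf("  Parker functional form attached (fit RMSE %.3g mM)\n",
                x$fit_rmse))
  invisible(x)
}

#' Detect the start of contrast wash-in in a time-intensity curve
#'
#' Returns the 0-based index of the first frame whose signal exceeds the
#' baseline mean by \code{k} baseline standard deviations (with a small
#' absolute floor for noiseless data) and that is followed by a further
#' increase. If the acquisition's injection frame is provided the onset is
#' never placed before it.
#'
#' @param signal Signal time course.
#' @param acq An \code{\link{acq_params}} object (baseline length,
#'   injection frame).
#' @param k Threshold in baseline SDs; default 3.
#' @param min_frame Earliest admissible onset (0-based); default the
#'   acquisition's injection frame.
#'
#' @return 0-based frame index of wash-in start.
#' @export
detect_washin_start <- function(signal, acq, k = 3,
                                min_frame = acq$injection_frame) {
  stopifnot(inherits(acq, "acq_params"))
  nb <- acq$baseline_frames
  if (length(signal) < nb + 2L) stop("curve too short for onset detection")
  bl <- signal[seq_len(nb)]
  thr <- mean(bl) + max(k * stats::sd(bl), 1e-6 * max(abs(mean(bl)), 1))
  n <- length(signal)
  for (i in seq(max(min_frame + 1L, nb + 1L), n - 1L)) {
    if (signal[i] > thr && signal[i + 1L] > signal[i]) return(i - 1L)
  }
  # allow an onset at the final frame if it clears the threshold
  if (signal[n] > thr) return(n - 1L)
  stop("no wash-in start found: curve never exceeds baseline + k*SD")
}

#' Extract an individual AIF from a delineated artery
#'
#' Ranks arterial voxels by their signal at the frame of maximum mean
#' arterial signal, averages the most enhanced fraction (default the top
#' 5 %) into a single time-intensity curve, and converts it to
#' concentration through the SPGR signal equation.
#'
#' @param dynamic_volume 4D signal array (x, y, z, t).
#' @param artery_mask 3D logical array.
#' @param t10_artery Blood pre-contrast T1 (s) used for conversion.
#' @param acq An \code{\link{acq_params}} object.
#' @param top_fraction Fraction of most-enhanced voxels to keep; default
#'   0.05.
#' @param b1 Flip-angle correction for the conversion: a scalar factor, or
#'   a 3D B1 map from which the median over the selected voxels is taken;
#'   default 1.
#'
#' @return A \code{measured_aif} with variant \code{"individual"}.
#' @export
extract_individual_aif <- function(dynamic_volume, artery_mask, t10_artery,
                                   acq, top_fraction = 0.05, b1 = 1) {
  stopifnot(inherits(acq, "acq_params"))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must lie in (0, 1]")
  idx <- which(artery_mask)
  if (length(idx) == 0L) stop("artery mask is empty")
  dm <- dim(dynamic_volume)
  nvox <- prod(dm[1:3])
  sig <- matrix(dynamic_volume, nrow = nvox)[idx, , drop = FALSE]
  peak_frame <- which.max(colMeans(sig))
  n_keep <- floor(top_fraction * length(idx))
  if (n_keep < 1L) {
    warning("top fraction selects no voxel; using the single most enhanced")
    n_keep <- 1L
  }
  ranking <- order(sig[, peak_frame], decreasing = TRUE)
  sel <- ranking[seq_len(n_keep)]
  tic <- colMeans(sig[sel, , drop = FALSE])
  b1_sel <- if (length(b1) > 1L) stats::median(b1[idx[sel]]) else b1
  cc <- signal_to_concentration(tic, t10_artery, acq, b1 = b1_sel)
  new_measured_aif(cc$time, cc$conc, "individual", 1L)
}

variant_tag <- function(alignment, baseline_mode) {
  tag <- switch(alignment, none = "pop", peak = "pop_pa", washin = "pop_wia")
  if (baseline_mode == "kept") tag <- paste0(tag, "_bl")
  tag
}

#' Build a population AIF from many arterial time-intensity curves
#'
#' Implements the six construction variants: curves are optionally aligned
#' by integer frame shifts (to the median peak frame or the median wash-in
#' start), the pre-onset baseline is either kept or removed, the shifted
#' curves are truncated to their common support and averaged framewise,
#' and the averaged signal curve is converted to concentration.
#'
#' Variant tags follow the alignment/baseline combination:
#' \code{pop}, \code{pop_bl}, \code{pop_pa}, \code{pop_pa_bl},
#' \code{pop_wia}, \code{pop_wia_bl} ("_bl" = baseline kept).
#'
#' @param tics List of arterial signal curves on a common temporal grid.
#' @param acq An \code{\link{acq_params}} object.
#' @param alignment "none", "peak" or "washin".
#' @param baseline_mode "removed" (drop pre-onset frames before averaging)
#'   or "kept".
#' @param t10_artery Representative blood T1 (s) used when converting the
#'   averaged curve; default 1.4.
#' @param b1 Conversion flip-angle factor; default 1.
#' @param min_overlap Minimum common-support length (frames); default 10.
#'
#' @return A \code{measured_aif} tagged with the variant.
#' @export
build_population_aif <- function(tics, acq,
                                 alignment = c("none", "peak", "washin"),
                                 baseline_mode = c("removed", "kept"),
                                 t10_artery = 1.4, b1 = 1,
                                 min_overlap = 10L) {
  alignment <- match.arg(alignment)
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(inherits(acq, "acq_params"))
  if (length(tics) < 2L) stop("at least 2 source curves required")
  lens <- vapply(tics, length, integer(1))

  # per-curve anchor frame (0-based): peak, wash-in start, or none
  anchors <- switch(alignment,
    none = rep(0L, length(tics)),
    peak = vapply(tics, function(s) which.max(s) - 1L, integer(1)),
    washin = vapply(tics, detect_washin_start, integer(1), acq = acq))
  ref <- as.integer(stats::median(anchors))
  shifts <- if (alignment == "none") rep(0L, length(tics)) else ref - anchors

  # baseline removal drops each curve's pre-onset frames without moving the
  # remaining samples on the common axis (removal is not an alignment)
  if (baseline_mode == "removed")
    onsets <- vapply(tics, detect_washin_start, integer(1), acq = acq)

  # each curve occupies [1 + shift, len + shift] on the common frame axis;
  # the common support is the intersection of the defined (post-removal)
  # windows of all curves
  starts <- integer(length(tics))
  ends <- integer(length(tics))
  for (i in seq_along(tics)) {
    first_kept <- if (baseline_mode == "removed") onsets[i] + 1L else 1L
    starts[i] <- first_kept + shifts[i]
    ends[i] <- lens[i] + shifts[i]
  }
  common_start <- max(starts)
  common_end <- min(ends)
  n_common <- common_end - common_start + 1L
  if (n_common < min_overlap)
    stop(sprintf("aligned curves overlap on only %d frames (need >= %d)",
                 n_common, min_overlap))
  mat <- vapply(seq_along(tics), function(i) {
    frames <- (common_start:common_end) - shifts[i]   # original frame index
    tics[[i]][frames]
  }, numeric(n_common))
  avg <- rowMeans(mat)

  tag <- variant_tag(alignment, baseline_mode)
  # S0 from the source-curve baselines (robust to removal/shift trimming)
  s0 <- mean(vapply(tics, function(s) mean(s[seq_len(acq$baseline_frames)]),
                    numeric(1)))
  cc <- signal_to_concentration(avg, t10_artery, acq, b1 = b1, s0 = s0)
  times <- (common_start - 1L + seq_len(n_common) - 1L) * acq$dt
  new_measured_aif(times, cc$conc, tag, length(tics))
}

#' Fit the Parker functional form to a measured AIF
#'
#' Bounded Levenberg-Marquardt least squares of the bi-Gaussian +
#' sigmoidal-washout form against a measured concentration curve. The
#' starting point is derived from the curve itself (peak position/height
#' for the first Gaussian, a secondary bump for the second, tail log-slope
#' for the washout), making the fit deterministic.
#'
#' @param aif A \code{measured_aif}, or a list with \code{time} (s) and
#'   \code{conc} (mM).
#' @param t0 Bolus arrival time (s) fixed during the fit; default the time
#'   of the curve's wash-in start estimated as the last sample below 5 %
#'   of peak before the peak.
#'
#' @return A \code{measured_aif} identical to the input but with
#'   \code{parker} (a \code{\link{parker_params}}) and \code{fit_rmse}
#'   filled in.
#' @export
fit_parker <- function(aif, t0 = NULL) {
  time <- aif$time
  conc <- aif$conc
  pk <- max(conc)
  ipk <- which.max(conc)
  pre <- conc[seq_len(max(ipk - 1L, 1L))]
  if (pk <= 3 * mean(pmax(pre, 0)))
    stop("no discernible peak: max must exceed 3x the pre-peak mean")
  if (is.null(t0)) {
    below <- which(conc[seq_len(ipk)] < 0.05 * pk)
    t0 <- if (length(below)) time[max(below)] else time[1]
  }
  tm <- (time - t0) / 60          # minutes since arrival
  use <- tm >= 0
  tmu <- tm[use]; cu <- conc[use]

  # initialization from curve geometry
  ipk_u <- which.max(cu)
  t_pk <- tmu[ipk_u]
  half <- cu >= pk / 2
  fwhm <- if (sum(half) >= 2) diff(range(tmu[half])) else 0.1
  sg1 <- max(fwhm / 2.355, 0.02)
  tail_i <- tmu > t_pk + 1.5 * sg1 & cu > 0
  beta0 <- if (sum(tail_i) >= 3) {
    sl <- stats::coef(stats::lm(log(cu[tail_i]) ~ tmu[tail_i]))[2]
    max(min(-sl, 5), 0.01)
  } else 0.17
  tail_lvl <- if (sum(tail_i) >= 1) stats::median(cu[tail_i]) else pk / 5
  start <- c(a1 = pk * sg1 * sqrt(2 * pi) * 0.8, a2 = pk * sg1 * sqrt(2 * pi) * 0.3,
             t1 = t_pk, t2 = t_pk * 2.1,
             sigma1 = sg1, sigma2 = 2.3 * sg1,
             alpha_w = max(tail_lvl, 1e-3), beta_w = beta0,
             s_sig = 38, tau_sig = t_pk * 2.8)
  lower <- c(0, 0, 0, 0, 5e-3, 5e-3, 0, 0, 1, 0)
  upper <- c(20, 20, 5, 5, 2, 2, 10, 5, 200, 5)

  model <- function(p, t) {
    pp <- parker_params(p[1], p[2], p[3], p[4], pmax(p[5], 5e-3),
                        pmax(p[6], 5e-3), p[7], pmax(p[8], 0), p[9], p[10])
    parker_aif(pp, t * 60)
  }
  res_fn <- function(p) model(p, tmu) - cu
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 5, 9))
    stop(sprintf("Parker fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message))
  p <- fit$par
  params <- parker_params(p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8],
                          p[9], p[10])
  rmse <- sqrt(mean(res_fn(p)^2))
  out <- aif
  out$parker <- params
  out$parker_t0 <- t0
  out$fit_rmse <- rmse
  out
}

#' Evaluate an AIF on a time axis
#'
#' Returns the concentration course of an AIF either in measured form
#' (sample values, linearly interpolated if the axes differ) or through
#' its fitted Parker functional form.
#'
#' @param aif A \code{measured_aif}.
#' @param times Target time axis (s).
#' @param form "measured" or "parker".
#' @return Concentration (mM) at \code{times}.
#' @export
eval_aif <- function(aif, times, form = c("measured", "parker")) {
  form <- match.arg(form)
  if (form == "parker") {
    if (is.null(aif$parker)) stop("AIF has no fitted Parker form")
    t0 <- if (!is.null(aif$parker_t0)) aif$parker_t0 else 0
    parker_aif(aif$parker, times, t0 = t0)
  } else {
    stats::approx(aif$time, aif$conc, xout = times, rule = 2)$y
  }
}
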