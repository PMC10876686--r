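# Semi-quantitative perfusion metrics: areas under the contrast-index
# curve (Simpson's rule) and time-to-half-peak.

# composite Simpson on a uniform grid; a trailing odd interval is handled
# by the trapezoid rule on the final interval
simpson_uniform <- function(y, h) {
  n <- length(y) - 1L            # number of intervals
  if (n < 1L) return(0)
  total <- 0
  n_simp <- if (n %% 2L == 0L) n else n - 1L
  if (n_simp >= 2L) {
    i <- seq(1L, n_simp - 1L, by = 2L)   # 0-based odd nodes
    j <- seq(2L, n_simp - 2L, by = 2L)
    s <- y[1L] + y[n_simp + 1L] + 4 * sum(y[i + 1L]) +
      2 * (if (n_simp >= 4L) sum(y[j + 1L]) else 0)
    total <- total + h / 3 * s
  }
  if (n %% 2L == 1L)
    total <- total + h / 2 * (y[n] + y[n + 1L])
  total
}

#' Area under the contrast-index curve
#'
#' Integrates CI(t) by composite Simpson's rule over the first
#' \code{window_s} seconds after contrast arrival in the lesion. The
#' sampling grid (e.g. 3.735 s) never divides the window exactly, so the
#' curve is linearly interpolated at the exact window end before
#' integration; an odd interval count is closed with a trapezoid on the
#' final interval.
#'
#' @param ci Data.frame with columns \code{time} (s) and \code{ci}, as
#'   returned by \code{\link{contrast_index}}, or a numeric CI vector.
#' @param arrival_frame 0-based frame of contrast arrival in the lesion.
#' @param window_s Integration window (s); conventionally 60, 90 or 120.
#' @param dt Temporal resolution (s); required when \code{ci} is a bare
#'   vector.
#'
#' @return The integral (dimensionless CI times seconds).
#' @export
auc_ci <- function(ci, arrival_frame, window_s, dt = NULL) {
  if (is.data.frame(ci)) {
    times <- ci$time
    vals <- ci$ci
    dt <- times[2] - times[1]
  } else {
    if (is.null(dt)) stop("'dt' required for a bare CI vector")
    vals <- ci
    times <- seq(0, by = dt, length.out = length(ci))
  }
  t_start <- arrival_frame * dt
  t_end <- t_start + window_s
  if (t_end > max(times) + 1e-9)
    stop(sprintf("curve too short: window ends at %.1f s but curve stops at %.1f s",
                 t_end, max(times)))
  keep <- which(times >= t_start - 1e-9 & times <= t_end + 1e-9)
  y <- vals[keep]
  t <- times[keep]
  # interpolated terminal point when the window end falls between samples
  if (max(t) < t_end - 1e-9) {
    y_end <- stats::approx(times, vals, xout = t_end)$y
    # Simpson on the uniform part, trapezoid on the fractional tail
    return(simpson_uniform(y, dt) +
             (t_end - max(t)) / 2 * (y[length(y)] + y_end))
  }
  simpson_uniform(y, dt)
}

#' Time to half peak of a signal curve
#'
#' Time from contrast injection until the signal reaches half its maximum,
#' computed from the straight line through the two samples bracketing
#' \eqn{S_{max}/2} on the rising limb:
#' \deqn{TTHP = \frac{S_{max}/2 - intercept}{slope}}
#' The bracketing pair is the last upward crossing of \eqn{S_{max}/2}
#' before the (earliest) global peak.
#'
#' @param signal Signal time course.
#' @param times Sample times (s).
#' @param injection_time_s Time of contrast injection (s); subtracted from
#'   the crossing time.
#'
#' @return A list with \code{tthp} (s) and logical \code{flagged}
#'   (TRUE when the half-maximum precedes the first post-injection sample,
#'   in which case \code{tthp} is 0).
#' @export
tthp <- function(signal, times, injection_time_s = 0) {
  stopifnot(length(signal) == length(times))
  smax <- max(signal)
  ipk <- which.max(signal)            # earliest peak on ties
  half <- smax / 2
  if (diff(range(signal)) < .Machine$double.eps * max(abs(signal), 1))
    stop("flat curve: TTHP undefined")
  rising <- seq_len(ipk)
  below <- which(signal[rising] < half)
  if (length(below) == 0L)
    return(list(tthp = 0, flagged = TRUE))
  i <- max(below)                     # last sample below half before peak
  if (i == ipk)
    return(list(tthp = 0, flagged = TRUE))
  slope <- (signal[i + 1L] - signal[i]) / (times[i + 1L] - times[i])
  intercept <- signal[i] - slope * times[i]
  t_half <- (half - intercept) / slope
  list(tthp = t_half - injection_time_s, flagged = FALSE)
}

#' Semi-quantitative metrics for one lesion curve
#'
#' Computes AUC60/AUC90/AUC120 of the contrast-index curve (windows start
#' at contrast arrival in the lesion, detected on the curve itself) and
#' the time-to-half-peak (measured from contrast injection).
#'
#' @param signal Lesion mean signal time course.
#' @param acq An \code{\link{acq_params}}.
#' @param arrival_frame Optional 0-based arrival frame; default detected
#'   with \code{\link{detect_washin_start}}.
#' @param windows AUC windows (s); default c(60, 90, 120).
#'
#' @return A one-row data.frame: auc60, auc90, auc120, tthp (s),
#'   tthp_flagged, arrival_frame.
#' @export
semiquant_metrics <- function(signal, acq, arrival_frame = NULL,
                              windows = c(60, 90, 120)) {
  stopifnot(inherits(acq, "acq_params"))
  if (is.null(arrival_frame))
    arrival_frame <- detect_washin_start(signal, acq)
  ci <- contrast_index(signal, acq)
  aucs <- vapply(windows, function(w) auc_ci(ci, arrival_frame, w),
                 numeric(1))
  tt <- tthp(signal, acq_times(acq),
             injection_time_s = acq$injection_frame * acq$dt)
  out <- as.data.frame(as.list(stats::setNames(aucs, paste0("auc", windows))))
  out$tthp <- tt$tthp
  out$tthp_flagged <- tt$flagged
  out$arrival_frame <- arrival_frame
  out
}
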