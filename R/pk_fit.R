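# Nonlinear least-squares fitting of the Tofts, extended Tofts and Brix
# models. All fits use bounded Levenberg-Marquardt minimization from a
# fixed multi-start grid (log-spaced over the rate bounds), so results are
# deterministic: no RNG is involved anywhere in fitting.

pk_bounds <- list(
  ktrans = c(0, 5),        # /min
  ve = c(1e-3, 1),
  vp = c(0, 0.5),
  a_brix = c(0, 50),
  kep = c(1e-3, 10),       # /min
  kel = c(0, 10))          # /min

# lowest-RMSE bounded LM fit over a fixed start grid
multistart_lm <- function(res_fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(par = fit$par, rss = rss, info = fit$info,
                   message = fit$message)
  }
  best
}

new_tofts_fit <- function(ktrans, ve, vp, rmse, converged, model,
                          aif_variant = NA_character_, flags = character()) {
  structure(list(model = model, ktrans = ktrans, ve = ve,
                 vp = if (model == "ETM") vp else NULL,
                 kep = ktrans / ve, rmse = rmse, converged = converged,
                 aif_variant = aif_variant, flags = flags),
            class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf("%s fit%s: Ktrans = %.4g /min, ve = %.4g%s, Kep = %.4g /min\n",
              x$model,
              if (!is.na(x$aif_variant)) paste0(" (AIF ", x$aif_variant, ")") else "",
              x$ktrans, x$ve,
              if (!is.null(x$vp)) sprintf(", vp = %.4g", x$vp) else "",
              x$kep))
  cat(sprintf("  RMSE %.4g, converged: %s%s\n", x$rmse, x$converged,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Fit the Tofts model to a tissue concentration curve
#'
#' Least-squares estimation of \eqn{K^{trans}} and \eqn{v_e} in
#' \eqn{C_t(t) = K^{trans}\int_0^t C_a(u) e^{-K^{trans}/v_e (t-u)} du},
#' with the arterial input supplied either as a measured curve or through
#' a fitted Parker functional form. The derived rate constant
#' \eqn{K_{ep} = K^{trans}/v_e} is always populated.
#'
#' @param conc Tissue concentration course (mM) at \code{times}.
#' @param aif A \code{measured_aif}, or a numeric vector of arterial
#'   concentrations already sampled at \code{times}.
#' @param times Sample times (s).
#' @param aif_form "measured" or "parker" (ignored for a numeric AIF).
#'
#' @return A \code{tofts_fit}.
#' @export
fit_tofts <- function(conc, aif, times, aif_form = c("measured", "parker")) {
  aif_form <- match.arg(aif_form)
  ca <- resolve_aif(aif, times, aif_form)
  variant <- if (inherits(aif, "measured_aif")) aif$variant else NA_character_
  flags <- character()
  if (all(abs(conc) < 1e-12)) {
    return(new_tofts_fit(0, pk_bounds$ve[1], 0, 0, TRUE, "TM", variant,
                         "ve_unidentifiable"))
  }
  res_fn <- function(p)
    tissue_conc_tofts(p[1], p[2], 0, ca, times) - conc
  starts <- make_starts(list(ktrans = c(0.02, 0.2, 1), ve = c(0.1, 0.3, 0.7)))
  best <- multistart_lm(res_fn, starts,
                        lower = c(pk_bounds$ktrans[1], pk_bounds$ve[1]),
                        upper = c(pk_bounds$ktrans[2], pk_bounds$ve[2]))
  finish_tofts(best, conc, "TM", variant, flags)
}

#' Fit the extended Tofts model
#'
#' As \code{\link{fit_tofts}} with the additional plasma-volume term
#' \eqn{v_p C_a(t)}.
#'
#' @inheritParams fit_tofts
#' @param fix_vp Optional value at which to pin the plasma volume fraction
#'   (e.g. 0 to recover the plain Tofts solution); default NULL (free).
#' @return A \code{tofts_fit} with \code{vp} populated.
#' @export
fit_extended_tofts <- function(conc, aif, times,
                               aif_form = c("measured", "parker"),
                               fix_vp = NULL) {
  aif_form <- match.arg(aif_form)
  ca <- resolve_aif(aif, times, aif_form)
  variant <- if (inherits(aif, "measured_aif")) aif$variant else NA_character_
  if (all(abs(conc) < 1e-12)) {
    return(new_tofts_fit(0, pk_bounds$ve[1], 0, 0, TRUE, "ETM", variant,
                         "ve_unidentifiable"))
  }
  if (!is.null(fix_vp)) {
    res_fn <- function(p)
      tissue_conc_tofts(p[1], p[2], fix_vp, ca, times) - conc
    starts <- make_starts(list(ktrans = c(0.02, 0.2, 1), ve = c(0.1, 0.3, 0.7)))
    best <- multistart_lm(res_fn, starts,
                          lower = c(pk_bounds$ktrans[1], pk_bounds$ve[1]),
                          upper = c(pk_bounds$ktrans[2], pk_bounds$ve[2]))
    if (!is.null(best)) best$par <- c(best$par, fix_vp)
    return(finish_tofts(best, conc, "ETM", variant, "vp_fixed"))
  }
  res_fn <- function(p)
    tissue_conc_tofts(p[1], p[2], p[3], ca, times) - conc
  starts <- make_starts(list(ktrans = c(0.02, 0.2, 1), ve = c(0.1, 0.3, 0.7),
                             vp = c(0, 0.03, 0.1)))
  best <- multistart_lm(res_fn, starts,
                        lower = c(pk_bounds$ktrans[1], pk_bounds$ve[1],
                                  pk_bounds$vp[1]),
                        upper = c(pk_bounds$ktrans[2], pk_bounds$ve[2],
                                  pk_bounds$vp[2]))
  finish_tofts(best, conc, "ETM", variant, character())
}

#' Fit the Brix model to a relative signal curve
#'
#' Fits amplitude A and the rates \eqn{k_{ep}}, \eqn{k_{el}} of the
#' AIF-free two-compartment infusion model to S(t)/S0. The constraint
#' \eqn{k_{ep} \ge k_{el}} breaks the label-swap symmetry of the closed
#' form (exchange is fast relative to elimination).
#'
#' @param signal Signal time course (raw units; normalized internally by
#'   the baseline mean) or already-relative S/S0 if \code{s0 = 1}.
#' @param times Sample times (s), with \code{t = 0} at contrast injection.
#' @param tau_inj Infusion duration (s).
#' @param acq Optional \code{\link{acq_params}}; supplies the baseline
#'   length for S0 when \code{s0} is NULL.
#' @param s0 Baseline signal; default mean of the baseline frames.
#'
#' @return A \code{brix_fit} list: \code{a_brix}, \code{kep}, \code{kel}
#'   (/min), \code{rmse}, \code{converged}.
#' @export
fit_brix <- function(signal, times, tau_inj, acq = NULL, s0 = NULL) {
  if (tau_inj <= 0) stop("'tau_inj' must be positive")
  if (is.null(s0)) {
    nb <- if (!is.null(acq)) acq$baseline_frames else max(sum(times <= 0), 1L)
    s0 <- mean(signal[seq_len(nb)])
  }
  if (!is.finite(s0) || s0 <= 0) stop("baseline signal S0 must be positive")
  rel <- signal / s0
  if (max(abs(rel - 1)) < 1e-12) {
    return(structure(list(a_brix = 0, kep = pk_bounds$kep[1], kel = 0,
                          rmse = 0, converged = TRUE, flags = "flat_curve"),
                     class = "brix_fit"))
  }
  res_fn <- function(p) {
    kep <- max(p[2], p[3])   # enforce kep >= kel by ordering
    kel <- min(p[2], p[3])
    brix_enhancement(p[1], kep, kel, tau_inj, times) - rel
  }
  starts <- make_starts(list(a = c(0.3, 1, 3),
                             kep = c(0.1, 0.6, 3), kel = c(0.01, 0.05, 0.3)))
  best <- multistart_lm(res_fn, starts,
                        lower = c(pk_bounds$a_brix[1], pk_bounds$kep[1],
                                  pk_bounds$kel[1]),
                        upper = c(pk_bounds$a_brix[2], pk_bounds$kep[2],
                                  pk_bounds$kel[2]))
  if (is.null(best))
    return(structure(list(a_brix = NA_real_, kep = NA_real_, kel = NA_real_,
                          rmse = NA_real_, converged = FALSE,
                          flags = "optimizer_failure"), class = "brix_fit"))
  p <- best$par
  structure(list(a_brix = p[1], kep = max(p[2], p[3]), kel = min(p[2], p[3]),
                 rmse = sqrt(best$rss / length(rel)), converged = TRUE,
                 flags = character()),
            class = "brix_fit")
}

#' @export
print.brix_fit <- function(x, ...) {
  cat(sprintf("Brix fit: A = %.4g, kep = %.4g /min, kel = %.4g /min\n",
              x$a_brix, x$kep, x$kel))
  cat(sprintf("  RMSE %.4g, converged: %s\n", x$rmse, x$converged))
  invisible(x)
}

resolve_aif <- function(aif, times, aif_form) {
  if (inherits(aif, "measured_aif")) {
    eval_aif(aif, times, form = aif_form)
  } else if (inherits(aif, "parker_params")) {
    parker_aif(aif, times)
  } else if (is.numeric(aif)) {
    stopifnot(length(aif) == length(times))
    aif
  } else stop("unsupported AIF object")
}

make_starts <- function(grid) {
  g <- do.call(expand.grid, grid)
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}

finish_tofts <- function(best, conc, model, variant, flags) {
  if (is.null(best))
    return(new_tofts_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                         model, variant, c(flags, "optimizer_failure")))
  p <- best$par
  new_tofts_fit(p[1], p[2], if (length(p) > 2) p[3] else 0,
                sqrt(best$rss / length(conc)), TRUE, model, variant, flags)
}

#' ROI-mean pharmacokinetic analysis of one lesion
#'
#' Averages the lesion voxels' signal into one time-intensity curve first,
#' then converts the mean curve to concentration, then fits the requested
#' models (this order matters: fit of the mean, not mean of the fits).
#' The Tofts-family models are fitted once per supplied AIF; the Brix
#' model is fitted to the relative mean signal and needs no AIF.
#'
#' @param dynamic_volume 4D signal array.
#' @param lesion_mask 3D logical array.
#' @param t10_lesion Representative lesion T10 (s) for conversion.
#' @param acq An \code{\link{acq_params}}.
#' @param aifs A single \code{measured_aif} or a list of them (e.g. the
#'   individual AIF plus six population variants).
#' @param models Character subset of c("TM", "ETM", "Brix").
#' @param tau_inj Infusion duration for Brix (s); default 6.
#' @param aif_form_population Evaluate population AIFs through their Parker
#'   functional form when available ("parker") or as measured curves;
#'   default "parker" with fallback to measured.
#'
#' @return A list of fit objects; Tofts-family entries are named
#'   \code{<model>.<variant>}.
#' @export
fit_roi_mean <- function(dynamic_volume, lesion_mask, t10_lesion, acq,
                         aifs = NULL, models = c("TM", "ETM", "Brix"),
                         tau_inj = 6,
                         aif_form_population = c("parker", "measured")) {
  aif_form_population <- match.arg(aif_form_population)
  models <- match.arg(models, several.ok = TRUE)
  idx <- which(lesion_mask)
  if (length(idx) == 0L) stop("lesion mask is empty")
  dm <- dim(dynamic_volume)
  sig <- matrix(dynamic_volume, nrow = prod(dm[1:3]))[idx, , drop = FALSE]
  mean_tic <- colMeans(sig)
  times <- acq_times(acq)

  fits <- list()
  if (any(c("TM", "ETM") %in% models)) {
    if (is.null(aifs)) stop("Tofts-family models require an AIF")
    if (inherits(aifs, "measured_aif")) aifs <- list(aifs)
    cc <- signal_to_concentration(mean_tic, t10_lesion, acq)
    for (a in aifs) {
      form <- if (a$variant == "individual" || is.null(a$parker) ||
                  aif_form_population == "measured") "measured" else "parker"
      if ("TM" %in% models)
        fits[[paste0("TM.", a$variant)]] <-
          fit_tofts(cc$conc, a, times, aif_form = form)
      if ("ETM" %in% models)
        fits[[paste0("ETM.", a$variant)]] <-
          fit_extended_tofts(cc$conc, a, times, aif_form = form)
    }
  }
  if ("Brix" %in% models) {
    # t = 0 at the last pre-enhancement frame (detected onset is the first
    # elevated frame); falls back to the injection frame if undetectable
    origin <- tryCatch(max(detect_washin_start(mean_tic, acq) - 1L, 0L),
                       error = function(e) acq$injection_frame)
    fits[["Brix"]] <- fit_brix(mean_tic, times - origin * acq$dt, tau_inj,
                               acq = acq)
  }
  fits
}

#' Voxel-wise pharmacokinetic parameter maps
#'
#' Fits one model independently in every voxel of a lesion mask. Voxels
#' whose fit fails (degenerate signal, optimizer failure) are flagged in
#' the failure mask and excluded from summaries, never imputed.
#'
#' @inheritParams fit_roi_mean
#' @param model One of "TM", "ETM", "Brix".
#' @param aif AIF for the Tofts-family models.
#' @param t10_map 3D array of per-voxel T10 (s), or a scalar.
#' @param b1_map 3D array of per-voxel flip-angle factors, or a scalar;
#'   default 1.
#'
#' @return A list with per-parameter 3D maps (NA outside the mask and at
#'   failures), \code{failure_mask}, and \code{failure_fraction}.
#' @export
fit_voxelwise <- function(dynamic_volume, lesion_mask, t10_map, acq,
                          model = c("TM", "ETM", "Brix"), aif = NULL,
                          tau_inj = 6, b1_map = 1) {
  model <- match.arg(model)
  idx <- which(lesion_mask)
  if (length(idx) == 0L) stop("lesion mask is empty")
  dm <- dim(dynamic_volume)
  sig <- matrix(dynamic_volume, nrow = prod(dm[1:3]))[idx, , drop = FALSE]
  times <- acq_times(acq)
  t10v <- if (length(t10_map) == 1L) rep(t10_map, length(idx)) else t10_map[idx]
  b1v <- if (length(b1_map) == 1L) rep(b1_map, length(idx)) else b1_map[idx]

  par_names <- switch(model, TM = c("ktrans", "ve", "kep"),
                      ETM = c("ktrans", "ve", "vp", "kep"),
                      Brix = c("a_brix", "kep", "kel"))
  maps <- lapply(par_names, function(p) array(NA_real_, dim = dm[1:3]))
  names(maps) <- par_names
  failure <- array(FALSE, dim = dm[1:3])

  ca <- if (model != "Brix") {
    if (is.null(aif)) stop("Tofts-family models require an AIF")
    resolve_aif(aif, times,
                if (inherits(aif, "measured_aif") && !is.null(aif$parker) &&
                    aif$variant != "individual") "parker" else "measured")
  } else NULL

  for (j in seq_along(idx)) {
    s <- sig[j, ]
    fit <- tryCatch({
      if (model == "Brix") {
        t_inj <- times - acq$injection_frame * acq$dt
        fit_brix(s, t_inj, tau_inj, acq = acq)
      } else {
        if (!all(is.finite(s)) || all(s == 0)) stop("degenerate voxel signal")
        cc <- signal_to_concentration(s, t10v[j], acq, b1 = b1v[j])
        if (model == "TM") fit_tofts(cc$conc, ca, times)
        else fit_extended_tofts(cc$conc, ca, times)
      }
    }, error = function(e) NULL)
    v <- idx[j]
    if (is.null(fit) || !isTRUE(fit$converged)) {
      failure[v] <- TRUE
    } else {
      for (p in par_names) maps[[p]][v] <- fit[[p]]
    }
  }
  list(maps = maps, failure_mask = failure,
       failure_fraction = mean(failure[idx]), model = model)
}
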