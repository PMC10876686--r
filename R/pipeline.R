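# End-to-end orchestration: run a whole (synthetic or file-based) study
# through relaxometry, AIF construction, model fitting, semi-quantitative
# metrics and the agreement statistics, producing one tidy results table.

#' Run the full analysis on a study
#'
#' Executes the complete pipeline on a \code{synthetic_study} (or an
#' equivalent list read back with \code{\link{read_study}}):
#' \enumerate{
#'   \item T10 mapping from the VFA volumes with B1 correction;
#'   \item individual AIF extraction from the artery mask;
#'   \item six population-AIF variants built from per-source arterial
#'     curves (here: resampled subsets of artery voxels), each with a
#'     fitted Parker functional form;
#'   \item ROI-mean model fits per lesion: the Tofts model against the
#'     individual AIF (measured form) and each population AIF (functional
#'     form), plus extended Tofts and Brix against the individual AIF;
#'   \item semi-quantitative metrics per lesion;
#'   \item the agreement report (ICC across population variants, CCC of
#'     population vs individual AIF).
#' }
#'
#' @param study A \code{synthetic_study}.
#' @param models Models to fit; default c("TM", "ETM", "Brix").
#' @param aif_variants AIF variants to use for the Tofts model; default
#'   all seven (individual + six population).
#' @param voxelwise Also compute voxel-wise maps (TM only); default FALSE.
#' @param n_population Number of pseudo-source arterial curves used to
#'   build the population AIFs; default 10.
#' @param tau_inj Brix infusion duration (s); default 6.
#'
#' @return A list: \code{records} (tidy data.frame, one row per lesion x
#'   model x AIF variant), \code{aifs}, \code{t1fit} summary,
#'   \code{agreement} (when >= 2 lesions and TM fitted),
#'   \code{voxelwise} (optional), \code{log}.
#' @export
run_study <- function(study, models = c("TM", "ETM", "Brix"),
                      aif_variants = c("individual", "pop", "pop_bl",
                                       "pop_pa", "pop_pa_bl", "pop_wia",
                                       "pop_wia_bl"),
                      voxelwise = FALSE, n_population = 10, tau_inj = 6) {
  stopifnot(inherits(study, "synthetic_study") || is.list(study))
  known_models <- c("TM", "ETM", "Brix")
  if (!all(models %in% known_models))
    stop("unknown model(s): ", paste(setdiff(models, known_models),
                                     collapse = ", "))
  if (!all(aif_variants %in% aif_variants_all()))
    stop("unknown AIF variant(s): ",
         paste(setdiff(aif_variants, aif_variants_all()), collapse = ", "))
  acq <- study$acq
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  # --- T10 mapping from VFA volumes ---------------------------------------
  dm <- dim(study$dynamic_volume)[1:3]
  vfa_mat <- vapply(study$vfa_volumes, as.vector, numeric(prod(dm)))
  t1fit <- fit_t10_vfa(vfa_mat, acq$flip_angles_vfa, acq$tr,
                       b1 = as.vector(study$b1_map))
  t10_map <- array(t1fit$t10, dim = dm)
  say("t1map: %d/%d voxels valid", sum(t1fit$valid), nrow(t1fit))

  # representative tissue T10s from the fitted map
  t10_artery <- stats::median(t10_map[study$artery_mask], na.rm = TRUE)
  b1_artery <- stats::median(study$b1_map[study$artery_mask])

  # --- AIFs ----------------------------------------------------------------
  aifs <- list()
  if ("individual" %in% aif_variants || any(c("TM", "ETM") %in% models)) {
    aifs$individual <- extract_individual_aif(
      study$dynamic_volume, study$artery_mask, t10_artery, acq,
      b1 = study$b1_map)
    say("aif: individual AIF extracted (peak %.2f mM)",
        max(aifs$individual$conc))
  }
  pop_wanted <- setdiff(aif_variants, "individual")
  if (length(pop_wanted) > 0 && any(c("TM", "ETM") %in% models)) {
    tics <- arterial_source_tics(study, n_population)
    combos <- list(pop = c("none", "removed"), pop_bl = c("none", "kept"),
                   pop_pa = c("peak", "removed"), pop_pa_bl = c("peak", "kept"),
                   pop_wia = c("washin", "removed"),
                   pop_wia_bl = c("washin", "kept"))
    for (v in pop_wanted) {
      co <- combos[[v]]
      a <- build_population_aif(tics, acq, alignment = co[1],
                                baseline_mode = co[2],
                                t10_artery = t10_artery, b1 = b1_artery)
      aifs[[v]] <- tryCatch(fit_parker(a), error = function(e) {
        say("aif: Parker fit failed for %s (%s); measured form kept",
            v, conditionMessage(e))
        a
      })
    }
    say("aif: %d population variants built from %d source curves",
        length(pop_wanted), length(tics))
  }

  # --- per-lesion fits and metrics ----------------------------------------
  records <- list()
  voxmaps <- list()
  for (li in seq_along(study$lesion_masks)) {
    mask <- study$lesion_masks[[li]]
    t10_lesion <- stats::median(t10_map[mask], na.rm = TRUE)
    b1_lesion <- stats::median(study$b1_map[mask])
    rec <- tryCatch({
      sig <- matrix(study$dynamic_volume, nrow = prod(dm))[which(mask), ,
                                                           drop = FALSE]
      mean_tic <- colMeans(sig)
      sq <- semiquant_metrics(mean_tic, acq)
      rows <- list()
      if (any(c("TM", "ETM") %in% models)) {
        use_aifs <- aifs[intersect(aif_variants, names(aifs))]
        tm_aifs <- if ("TM" %in% models) use_aifs else aifs["individual"]
        for (a in tm_aifs) {
          if ("TM" %in% models) {
            f <- one_roi_fit(mean_tic, t10_lesion, acq, a, "TM",
                             b1 = b1_lesion)
            rows[[length(rows) + 1L]] <- fit_row(li, "TM", a$variant, f, sq)
          }
        }
        if ("ETM" %in% models) {
          f <- one_roi_fit(mean_tic, t10_lesion, acq, aifs$individual,
                           "ETM", b1 = b1_lesion)
          rows[[length(rows) + 1L]] <- fit_row(li, "ETM", "individual", f, sq)
        }
      }
      if ("Brix" %in% models) {
        times <- acq_times(acq)
        # t = 0 at the last pre-enhancement frame of this lesion's curve
        # (the detected onset is the first elevated frame)
        origin <- max(sq$arrival_frame - 1L, 0L) * acq$dt
        f <- fit_brix(mean_tic, times - origin, tau_inj, acq = acq)
        rows[[length(rows) + 1L]] <- fit_row(li, "Brix", NA_character_, f, sq)
      }
      do.call(rbind, rows)
    }, error = function(e) {
      say("lesion %d failed: %s", li, conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    if (voxelwise) {
      voxmaps[[li]] <- fit_voxelwise(study$dynamic_volume, mask, t10_map,
                                     acq, model = "TM",
                                     aif = aifs$individual,
                                     b1_map = study$b1_map)
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  say("fits: %d records across %d lesions",
      if (is.null(records)) 0L else nrow(records),
      length(study$lesion_masks))

  agreement <- NULL
  if (!is.null(records) && "TM" %in% models &&
      length(unique(records$lesion)) >= 2 &&
      length(setdiff(aif_variants, "individual")) >= 2) {
    tm <- records[records$model == "TM", ]
    agreement <- tryCatch(
      parameter_agreement_report(tm, params = c("ktrans", "ve")),
      error = function(e) {
        say("agreement report failed: %s", conditionMessage(e)); NULL
      })
  }

  list(records = records, aifs = aifs,
       t1fit = list(valid_fraction = mean(t1fit$valid), t10_map = t10_map),
       agreement = agreement,
       voxelwise = if (voxelwise) voxmaps else NULL,
       log = log)
}

aif_variants_all <- function()
  c("individual", "pop", "pop_bl", "pop_pa", "pop_pa_bl", "pop_wia",
    "pop_wia_bl")

# deterministic split of the artery into pseudo-source curves: voxels are
# dealt round-robin into n groups and each group's mean TIC is one source
arterial_source_tics <- function(study, n) {
  idx <- which(study$artery_mask)
  dm <- dim(study$dynamic_volume)[1:3]
  sig <- matrix(study$dynamic_volume, nrow = prod(dm))[idx, , drop = FALSE]
  groups <- rep(seq_len(n), length.out = length(idx))
  lapply(seq_len(n), function(g) colMeans(sig[groups == g, , drop = FALSE]))
}

one_roi_fit <- function(mean_tic, t10_lesion, acq, aif, model, b1 = 1) {
  cc <- signal_to_concentration(mean_tic, t10_lesion, acq, b1 = b1)
  times <- acq_times(acq)
  form <- if (aif$variant != "individual" && !is.null(aif$parker))
    "parker" else "measured"
  if (model == "TM") fit_tofts(cc$conc, aif, times, aif_form = form)
  else fit_extended_tofts(cc$conc, aif, times, aif_form = form)
}

fit_row <- function(lesion, model, variant, fit, sq) {
  data.frame(lesion = lesion, model = model, aif_variant = variant,
             ktrans = if (!is.null(fit$ktrans)) fit$ktrans else NA_real_,
             ve = if (!is.null(fit$ve)) fit$ve else NA_real_,
             vp = if (!is.null(fit$vp)) fit$vp else NA_real_,
             kep = fit$kep,
             kel = if (!is.null(fit$kel)) fit$kel else NA_real_,
             a_brix = if (!is.null(fit$a_brix)) fit$a_brix else NA_real_,
             rmse = fit$rmse, converged = fit$converged,
             auc60 = sq$auc60, auc90 = sq$auc90, auc120 = sq$auc120,
             tthp = sq$tthp, stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk
#'
#' Emits the study in standard formats: NIfTI volumes (dynamic 4D, one 3D
#' per VFA angle, B1 map, true T10 map, artery and lesion masks) and a
#' JSON sidecar with the acquisition parameters, ground-truth lesion
#' parameters, Parker parameters and seed.
#'
#' @param study A \code{synthetic_study}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  paths <- character()
  wr <- function(arr, name) {
    f <- p(paste0(name, ".nii.gz"))
    RNifti::writeNifti(arr * 1, f)      # *1 coerces logical masks to numeric
    paths <<- c(paths, f)
  }
  wr(study$dynamic_volume, "dynamic")
  for (nm in names(study$vfa_volumes)) wr(study$vfa_volumes[[nm]], paste0("vfa_", nm))
  wr(study$b1_map, "b1")
  wr(study$t10_map_truth, "t10_truth")
  wr(study$artery_mask, "mask_artery")
  for (i in seq_along(study$lesion_masks))
    wr(study$lesion_masks[[i]], sprintf("mask_lesion%02d", i))
  meta <- list(
    acq = unclass(study$acq),
    seed = study$seed,
    arrival_frame = study$truth$arrival_frame,
    parker = unclass(study$truth$parker),
    lesions = lapply(study$truth$lesions, unclass))
  f <- p("study.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, f)
  invisible(paths)
}

#' Read a study written by \code{\link{write_study}}
#'
#' @param dir Directory containing the study files.
#' @return A \code{synthetic_study}-compatible list (without the full
#'   generator config).
#' @export
read_study <- function(dir) {
  p <- function(...) file.path(dir, ...)
  meta <- jsonlite::read_json(p("study.json"), simplifyVector = TRUE)
  acq <- do.call(acq_params, meta$acq)
  rd <- function(name) {
    arr <- RNifti::readNifti(p(paste0(name, ".nii.gz")))
    a <- array(as.numeric(arr), dim = dim(arr))
    a
  }
  dyn <- rd("dynamic")
  check_shape <- function(a, name) {
    if (!identical(dim(a), dim(dyn)[1:3]))
      stop(sprintf("grid mismatch: %s is %s but dynamic is %s", name,
                   paste(dim(a), collapse = "x"),
                   paste(dim(dyn)[1:3], collapse = "x")))
    a
  }
  if (dim(dyn)[4] != acq$n_frames)
    stop(sprintf("dynamic volume has %d frames but acquisition says %d",
                 dim(dyn)[4], acq$n_frames))
  vfa_files <- list.files(dir, pattern = "^vfa_.*\\.nii\\.gz$")
  vfa_names <- sub("^vfa_(.*)\\.nii\\.gz$", "\\1", vfa_files)
  vfa <- lapply(vfa_names, function(nm) check_shape(rd(paste0("vfa_", nm)), nm))
  names(vfa) <- vfa_names
  vfa <- vfa[paste0("fa", acq$flip_angles_vfa)]
  lesion_files <- sort(list.files(dir, pattern = "^mask_lesion.*\\.nii\\.gz$"))
  lesions <- lapply(lesion_files, function(f) {
    nm <- sub("\\.nii\\.gz$", "", f)
    check_shape(rd(nm), nm) > 0.5
  })
  truth_lesions <- lapply(seq_len(nrow(meta$lesions)), function(i) {
    l <- as.list(meta$lesions[i, ])
    lesion_truth(l$model_tag, ktrans = l$ktrans, ve = l$ve, vp = l$vp,
                 a_brix = l$a_brix, kep_brix = l$kep, kel = l$kel,
                 tau_inj = l$tau_inj, t10 = l$t10)
  })
  structure(list(
    dynamic_volume = dyn,
    vfa_volumes = vfa,
    b1_map = check_shape(rd("b1"), "b1"),
    t10_map_truth = check_shape(rd("t10_truth"), "t10_truth"),
    artery_mask = check_shape(rd("mask_artery"), "mask_artery") > 0.5,
    lesion_masks = lesions,
    truth = list(lesions = truth_lesions,
                 parker = do.call(parker_params, as.list(meta$parker)),
                 arrival_frame = meta$arrival_frame),
    acq = acq,
    config = NULL,
    seed = meta$seed), class = "synthetic_study")
}

#' Write pipeline results to disk
#'
#' @param result A \code{\link{run_study}} result bundle.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(result$records)) {
    f <- file.path(dir, "records.csv")
    utils::write.csv(result$records, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(result$agreement)) {
    f <- file.path(dir, "agreement.csv")
    utils::write.csv(result$agreement, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  for (v in names(result$aifs)) {
    a <- result$aifs[[v]]
    f <- file.path(dir, sprintf("aif_%s.csv", v))
    utils::write.csv(data.frame(time = a$time, conc = a$conc), f,
                     row.names = FALSE)
    paths <- c(paths, f)
    if (!is.null(a$parker)) {
      f2 <- file.path(dir, sprintf("aif_%s_parker.json", v))
      jsonlite::write_json(
        c(unclass(a$parker), list(t0 = a$parker_t0, fit_rmse = a$fit_rmse,
                                  variant = a$variant)),
        f2, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, f2)
    }
  }
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(c(paths, file.path(dir, "run.log")))
}
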