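# Synthetic DCE-MRI study generation: forward-model phantoms with known
# ground truth, emulating a 1.5 T SPGR head-and-neck acquisition (60 frames
# at 3.735 s). Stands in for a clinical cohort in tests and examples.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Ground-truth pharmacokinetic parameters for one synthetic lesion
#'
#' @param model_tag One of "TM", "ETM", "Brix".
#' @param ktrans,ve,vp Tofts-family parameters (/min, -, -); \code{vp} is
#'   used by ETM only.
#' @param a_brix,kep_brix,kel Brix parameters (-, /min, /min).
#' @param tau_inj Infusion duration for Brix synthesis (s).
#' @param t10 Pre-contrast T1 of the lesion tissue (s).
#'
#' @return A \code{lesion_truth} list; \code{kep = ktrans/ve} is derived
#'   for Tofts-family lesions.
#' @export
lesion_truth <- function(model_tag = c("TM", "ETM", "Brix"),
                         ktrans = 0.25, ve = 0.4, vp = 0.05,
                         a_brix = 1.2, kep_brix = 0.8, kel = 0.05,
                         tau_inj = 6, t10 = 1.0) {
  model_tag <- match.arg(model_tag)
  if (model_tag != "Brix") {
    if (ve <= 0 || ve > 1) stop("'ve' must lie in (0, 1]")
    if (ktrans < 0) stop("'ktrans' must be non-negative")
    if (vp < 0 || vp >= 1) stop("'vp' must lie in [0, 1)")
  } else {
    if (kep_brix < 0 || kel < 0) stop("Brix rates must be non-negative")
    if (tau_inj <= 0) stop("'tau_inj' must be positive")
  }
  structure(list(model_tag = model_tag, ktrans = ktrans, ve = ve,
                 vp = if (model_tag == "ETM") vp else 0,
                 kep = if (model_tag == "Brix") kep_brix else ktrans / ve,
                 a_brix = a_brix, kel = kel, tau_inj = tau_inj, t10 = t10),
            class = "lesion_truth")
}

#' Configuration for a synthetic DCE-MRI study
#'
#' @param dim Spatial grid (x, y, z); default c(16, 16, 4).
#' @param acq \code{\link{acq_params}}; defaults emulate the reference
#'   protocol (60 frames, dt 3.735 s).
#' @param parker Arterial Parker parameters; default
#'   \code{\link{parker_reference_params}}.
#' @param arrival_frame Frame at which the bolus reaches the artery
#'   (0-based); default 5.
#' @param n_artery Number of arterial voxels; default 100.
#' @param artery_jitter SD of the per-voxel multiplicative amplitude jitter
#'   on arterial curves; default 0.05.
#' @param lesions List of \code{\link{lesion_truth}} objects; each lesion
#'   occupies one z-slice block.
#' @param lesion_size Voxels per lesion (placed as a compact box);
#'   default 64.
#' @param t10_background,t10_artery Pre-contrast T1 (s) outside lesions and
#'   in blood.
#' @param b1_range Transmit-field factor range, ramped linearly along x;
#'   default c(0.95, 1.05).
#' @param noise_snr Baseline signal-to-noise ratio of the Rician noise;
#'   \code{Inf} (default) for noiseless data.
#' @param noise_model "rician" (magnitude MRI) or "gaussian".
#' @param s0_scale Proton-density/gain scale; default 1000.
#'
#' @return A validated \code{study_config} list.
#' @export
study_config <- function(dim = c(16, 16, 4),
                         acq = acq_params(),
                         parker = parker_reference_params(),
                         arrival_frame = 5,
                         n_artery = 100,
                         artery_jitter = 0.05,
                         lesions = list(
                           lesion_truth("TM", ktrans = 0.25, ve = 0.4),
                           lesion_truth("ETM", ktrans = 0.15, ve = 0.3, vp = 0.05),
                           lesion_truth("Brix", a_brix = 1.2, kep_brix = 0.8,
                                        kel = 0.05)),
                         lesion_size = 64,
                         t10_background = 0.8,
                         t10_artery = 1.4,
                         b1_range = c(0.95, 1.05),
                         noise_snr = Inf,
                         noise_model = c("rician", "gaussian"),
                         s0_scale = 1000) {
  stopifnot(inherits(acq, "acq_params"), inherits(parker, "parker_params"))
  noise_model <- match.arg(noise_model)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 2L)) stop("'dim' must be 3 positive extents")
  if (arrival_frame < acq$injection_frame)
    stop("bolus cannot arrive before the injection frame")
  if (!all(vapply(lesions, inherits, logical(1), "lesion_truth")))
    stop("'lesions' must be a list of lesion_truth objects")
  n_needed <- n_artery + length(lesions) * lesion_size
  if (n_needed > prod(dim) / 2)
    stop("grid too small for the requested artery and lesions")
  structure(list(dim = dim, acq = acq, parker = parker,
                 arrival_frame = as.integer(arrival_frame),
                 n_artery = as.integer(n_artery),
                 artery_jitter = artery_jitter,
                 lesions = lesions, lesion_size = as.integer(lesion_size),
                 t10_background = t10_background, t10_artery = t10_artery,
                 b1_range = b1_range, noise_snr = noise_snr,
                 noise_model = noise_model, s0_scale = s0_scale),
            class = "study_config")
}

# compact box of n voxels starting at linear offset within a z-slab
carve_box <- function(dim, n, origin) {
  side <- ceiling(sqrt(n))
  if (origin[1] + side - 1 > dim[1] || origin[2] + side - 1 > dim[2])
    stop("region does not fit the grid")
  idx <- expand.grid(x = origin[1] + seq_len(side) - 1,
                     y = origin[2] + seq_len(side) - 1,
                     z = origin[3])
  as.matrix(idx[seq_len(n), , drop = FALSE])
}

#' Generate a synthetic DCE-MRI study with known ground truth
#'
#' Builds a 4D dynamic SPGR volume plus the pre-contrast variable-flip-angle
#' volumes, a B1 map, a true T10 map, an artery mask and one mask per
#' lesion. Arterial voxels carry a Parker-form concentration course with a
#' small per-voxel amplitude jitter (so selecting the most enhanced voxels
#' is non-trivial); Tofts-family lesions carry the convolution forward
#' model driven by the same arterial course; Brix lesions carry the
#' two-compartment infusion signal course. Magnitude (Rician) noise is
#' added at the configured baseline SNR.
#'
#' @param config A \code{\link{study_config}}.
#' @param seed Integer RNG seed; the same config and seed give a
#'   bit-identical study.
#'
#' @return A \code{synthetic_study} list: \code{dynamic_volume} (4D array),
#'   \code{vfa_volumes} (list of 3D arrays, one per VFA angle),
#'   \code{b1_map}, \code{t10_map_truth}, \code{artery_mask},
#'   \code{lesion_masks} (list of 3D logical arrays), \code{truth}
#'   (per-lesion parameters and the Parker parameters), \code{acq},
#'   \code{config}, \code{seed}.
#' @export
generate_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  acq <- config$acq
  dm <- config$dim
  times <- acq_times(acq)
  arrival_t <- config$arrival_frame * acq$dt

  # region layout: artery in slice 1, lesions in successive slices
  artery_idx <- carve_box(dm, config$n_artery, c(1L, 1L, 1L))
  lesion_idx <- list()
  z <- 2L
  for (i in seq_along(config$lesions)) {
    if (z > dm[3]) stop("not enough slices for all lesions")
    lesion_idx[[i]] <- carve_box(dm, config$lesion_size, c(1L, 1L, z))
    z <- z + 1L
  }
  all_idx <- rbind(artery_idx, do.call(rbind, lesion_idx))
  if (anyDuplicated(all_idx)) stop("artery and lesion regions overlap")

  # true T10 and B1 maps
  t10_map <- array(config$t10_background, dim = dm)
  t10_map[artery_idx] <- config$t10_artery
  for (i in seq_along(config$lesions))
    t10_map[lesion_idx[[i]]] <- config$lesions[[i]]$t10
  b1_ramp <- seq(config$b1_range[1], config$b1_range[2], length.out = dm[1])
  b1_map <- array(rep(b1_ramp, times = dm[2] * dm[3]), dim = dm)

  arterial_conc <- parker_aif(config$parker, times, t0 = arrival_t)

  with_seed(seed, {
    dyn <- array(0, dim = c(dm, acq$n_frames))
    nvox <- prod(dm)
    # baseline (pre-contrast) signal everywhere, voxel by voxel
    vox <- arrayInd(seq_len(nvox), dm)
    noiseless <- matrix(0, nrow = nvox, ncol = acq$n_frames)
    lin <- function(ijk) (ijk[, 3] - 1) * dm[1] * dm[2] +
      (ijk[, 2] - 1) * dm[1] + ijk[, 1]
    for (v in seq_len(nvox)) {
      i <- vox[v, 1]
      noiseless[v, ] <- spgr_signal(rep(0, acq$n_frames), t10_map[vox[v, , drop = FALSE]],
                                    acq, s0_scale = config$s0_scale,
                                    b1 = b1_map[vox[v, , drop = FALSE]])
    }
    # arterial voxels: jittered Parker course
    art_lin <- lin(artery_idx)
    jit <- 1 + stats::rnorm(length(art_lin), 0, config$artery_jitter)
    for (j in seq_along(art_lin)) {
      v <- art_lin[j]
      conc <- pmax(arterial_conc * jit[j], 0)
      noiseless[v, ] <- spgr_signal(conc, config$t10_artery, acq,
                                    s0_scale = config$s0_scale,
                                    b1 = b1_map[artery_idx[j, , drop = FALSE]])
    }
    # lesion voxels: model forward curves
    for (i in seq_along(config$lesions)) {
      tr_i <- config$lesions[[i]]
      les_lin <- lin(lesion_idx[[i]])
      if (tr_i$model_tag == "Brix") {
        rel <- brix_enhancement(tr_i$a_brix, tr_i$kep, tr_i$kel, tr_i$tau_inj,
                                times - arrival_t)
        for (j in seq_along(les_lin)) {
          v <- les_lin[j]
          s0v <- spgr_signal(0, tr_i$t10, acq, s0_scale = config$s0_scale,
                             b1 = b1_map[lesion_idx[[i]][j, , drop = FALSE]])
          noiseless[v, ] <- s0v * rel
        }
      } else {
        conc <- tissue_conc_tofts(tr_i$ktrans, tr_i$ve, tr_i$vp,
                                  arterial_conc, times)
        for (j in seq_along(les_lin)) {
          v <- les_lin[j]
          noiseless[v, ] <- spgr_signal(conc, tr_i$t10, acq,
                                        s0_scale = config$s0_scale,
                                        b1 = b1_map[lesion_idx[[i]][j, , drop = FALSE]])
        }
      }
    }
    # noise: sigma from the mean baseline signal and the requested SNR
    baseline_mean <- mean(noiseless[, seq_len(acq$baseline_frames)])
    sigma <- if (is.finite(config$noise_snr) && config$noise_snr > 0)
      baseline_mean / config$noise_snr else 0
    noisy <- noiseless
    if (sigma > 0) {
      if (config$noise_model == "rician") {
        noisy <- matrix(rician(as.vector(noiseless), sigma),
                        nrow = nvox)
      } else {
        noisy <- noiseless + matrix(stats::rnorm(length(noiseless), 0, sigma),
                                    nrow = nvox)
      }
    }
    dyn <- array(noisy, dim = c(dm, acq$n_frames))

    # VFA pre-contrast volumes (same noise model)
    vfa <- lapply(acq$flip_angles_vfa, function(ang) {
      acq_a <- acq
      acq_a$flip_angle_dyn <- ang
      vol <- array(0, dim = dm)
      for (v in seq_len(nvox)) {
        s <- spgr_signal(0, t10_map[vox[v, , drop = FALSE]], acq_a,
                         s0_scale = config$s0_scale,
                         b1 = b1_map[vox[v, , drop = FALSE]])
        vol[v] <- s
      }
      if (sigma > 0) {
        vol <- if (config$noise_model == "rician")
          array(rician(as.vector(vol), sigma), dim = dm)
        else vol + array(stats::rnorm(nvox, 0, sigma), dim = dm)
      }
      vol
    })
    names(vfa) <- paste0("fa", acq$flip_angles_vfa)

    mask_from_idx <- function(idx) {
      m <- array(FALSE, dim = dm)
      m[idx] <- TRUE
      m
    }
    structure(list(
      dynamic_volume = dyn,
      vfa_volumes = vfa,
      b1_map = b1_map,
      t10_map_truth = t10_map,
      artery_mask = mask_from_idx(artery_idx),
      lesion_masks = lapply(lesion_idx, mask_from_idx),
      truth = list(lesions = config$lesions, parker = config$parker,
                   arrival_frame = config$arrival_frame),
      acq = acq,
      config = config,
      seed = as.integer(seed)),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  dm <- dim(x$dynamic_volume)
  cat(sprintf("Synthetic DCE-MRI study: %dx%dx%d grid, %d frames (dt %.3f s)\n",
              dm[1], dm[2], dm[3], dm[4], x$acq$dt))
  cat(sprintf("  %d arterial voxels, %d lesion(s): %s\n",
              sum(x$artery_mask), length(x$lesion_masks),
              paste(vapply(x$truth$lesions, `[[`, "", "model_tag"),
                    collapse = ", ")))
  cat(sprintf("  baseline SNR %s, seed %d\n",
              format(x$config$noise_snr), x$seed))
  invisible(x)
}
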