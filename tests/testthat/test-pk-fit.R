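# Model fitting: parameter recovery, nested-model behaviour, determinism.

pk_times <- function(n = 60, dt = 3.735) seq(0, by = dt, length.out = n)

pk_aif <- function(times, t0 = 15)
  parker_aif(parker_reference_params(), times, t0 = t0)

test_that("Tofts fit recovers noiseless parameters over a grid", {
  times <- pk_times()
  ca <- pk_aif(times)
  grid <- expand.grid(ktrans = c(0.05, 0.25, 0.8), ve = c(0.15, 0.4, 0.7))
  for (i in seq_len(nrow(grid))) {
    kt <- grid$ktrans[i]; ve <- grid$ve[i]
    conc <- tissue_conc_tofts(kt, ve, 0, ca, times)
    fit <- fit_tofts(conc, ca, times)
    expect_true(fit$converged)
    expect_lt(abs(fit$ktrans - kt) / kt, 0.005)
    expect_lt(abs(fit$ve - ve) / ve, 0.005)
    expect_equal(fit$kep, fit$ktrans / fit$ve)   # exact identity
  }
})

test_that("extended Tofts recovers ktrans, ve and vp noiselessly", {
  times <- pk_times()
  ca <- pk_aif(times)
  grid <- expand.grid(ktrans = c(0.1, 0.3), ve = c(0.2, 0.5),
                      vp = c(0.02, 0.08))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    conc <- tissue_conc_tofts(p$ktrans, p$ve, p$vp, ca, times)
    fit <- fit_extended_tofts(conc, ca, times)
    expect_lt(abs(fit$ktrans - p$ktrans) / p$ktrans, 0.01)
    expect_lt(abs(fit$ve - p$ve) / p$ve, 0.01)
    expect_lt(abs(fit$vp - p$vp) / p$vp, 0.01)
  }
})

test_that("ETM on vp-free data matches the TM fit (nested models)", {
  times <- pk_times()
  ca <- pk_aif(times)
  conc <- tissue_conc_tofts(0.25, 0.4, 0, ca, times)
  tm <- fit_tofts(conc, ca, times)
  etm <- fit_extended_tofts(conc, ca, times)
  expect_lt(etm$vp, 0.01)
  expect_lt(abs(etm$ktrans - tm$ktrans) / tm$ktrans, 0.01)
  expect_lt(abs(etm$ve - tm$ve) / tm$ve, 0.01)
  # with vp pinned at zero the ETM residual equals the TM residual
  etm0 <- fit_extended_tofts(conc, ca, times, fix_vp = 0)
  expect_lt(abs(etm0$rmse - tm$rmse), 1e-9)
  expect_equal(etm0$vp, 0)
})

test_that("pure plasma curve yields ktrans ~ 0 and vp ~ fraction", {
  times <- pk_times()
  ca <- pk_aif(times)
  fit <- fit_extended_tofts(0.05 * ca, ca, times)
  expect_lt(fit$ktrans, 0.005)
  expect_equal(fit$vp, 0.05, tolerance = 0.01)
})

test_that("null tissue curve gives ktrans 0 with flagged ve", {
  times <- pk_times()
  ca <- pk_aif(times)
  fit <- fit_tofts(rep(0, length(times)), ca, times)
  expect_equal(fit$ktrans, 0)
  expect_true("ve_unidentifiable" %in% fit$flags)
})

test_that("Brix fit recovers noiseless parameters and orders the rates", {
  times <- pk_times() - 4 * 3.735
  grid <- expand.grid(a = c(0.6, 1.2), kep = c(0.3, 0.8, 2),
                      kel = c(0.02, 0.1))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    rel <- brix_enhancement(p$a, p$kep, p$kel, 6, times)
    fit <- fit_brix(rel, times, 6, s0 = 1)
    expect_lt(abs(fit$a_brix - p$a) / p$a, 0.01)
    expect_lt(abs(fit$kep - p$kep) / p$kep, 0.01)
    expect_lt(abs(fit$kel - p$kel) / p$kel, 0.01)
    expect_gte(fit$kep, fit$kel)
  }
  # label-swapped generator parameters land on the same constrained optimum
  rel_sw <- brix_enhancement(1.2, 0.05, 0.8, 6, times)  # kep < kel in truth
  fit_sw <- fit_brix(rel_sw, times, 6, s0 = 1)
  expect_gte(fit_sw$kep, fit_sw$kel)
  expect_lt(fit_sw$rmse, 1e-6)    # same RMSE at the swapped optimum
})

test_that("flat signal gives zero Brix amplitude", {
  times <- pk_times() - 4 * 3.735
  fit <- fit_brix(rep(123.4, length(times)), times, 6, s0 = 123.4)
  expect_equal(fit$a_brix, 0)
})

test_that("fits are deterministic and AIF-form change shifts ktrans < 2 %", {
  times <- pk_times()
  ca <- pk_aif(times)
  conc <- tissue_conc_tofts(0.25, 0.4, 0, ca, times)
  f1 <- fit_tofts(conc, ca, times)
  f2 <- fit_tofts(conc, ca, times)
  expect_identical(f1[c("ktrans", "ve", "kep", "rmse")],
                   f2[c("ktrans", "ve", "kep", "rmse")])

  # measured vs fitted-Parker functional form of the same AIF
  aif_m <- list(time = times, conc = ca, variant = "pop")
  aif_p <- fit_parker(aif_m)
  class(aif_p) <- "measured_aif"
  fm <- fit_tofts(conc, aif_p, times, aif_form = "measured")
  fp <- fit_tofts(conc, aif_p, times, aif_form = "parker")
  expect_lt(abs(fm$ktrans - fp$ktrans) / fm$ktrans, 0.02)
})

test_that("noisy replicates keep the median estimates within 5 %", {
  set.seed(31)
  acq <- acq_params()
  times <- acq_times(acq)
  ca <- pk_aif(times, t0 = 5 * acq$dt)
  kt_true <- 0.25; ve_true <- 0.4
  conc <- tissue_conc_tofts(kt_true, ve_true, 0, ca, times)
  sig <- spgr_signal(conc, 1.0, acq)
  sigma <- mean(sig[1:4]) / 50
  est <- t(vapply(seq_len(200), function(i) {
    noisy <- sqrt((sig + rnorm(length(sig), 0, sigma))^2 +
                    rnorm(length(sig), 0, sigma)^2)
    cc <- signal_to_concentration(noisy, 1.0, acq)
    f <- fit_tofts(cc$conc, ca, times)
    c(f$ktrans, f$ve)
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) - kt_true) / kt_true, 0.05)
  expect_lt(abs(median(est[, 2]) - ve_true) / ve_true, 0.05)
})

test_that("ROI-mean fitting equals the single-voxel fit on homogeneous data", {
  st <- generate_study(tiny_config(b1_range = c(1, 1), lesions = list(
    lesion_truth("TM", ktrans = 0.2, ve = 0.35))), seed = 5)
  acq <- st$acq
  aif <- extract_individual_aif(st$dynamic_volume, st$artery_mask, 1.4, acq,
                                b1 = st$b1_map)
  mask <- st$lesion_masks[[1]]
  fits <- fit_roi_mean(st$dynamic_volume, mask, 1.0, acq, aifs = aif,
                       models = "TM")
  f_roi <- fits[["TM.individual"]]
  # single voxel from the homogeneous lesion (b1 varies across x, so take a
  # voxel and correct with its own b1 via the ROI call on a 1-voxel mask)
  one <- array(FALSE, dim = dim(mask))
  ix <- which(mask, arr.ind = TRUE)[1, , drop = FALSE]
  one[ix] <- TRUE
  f_vox <- fit_roi_mean(st$dynamic_volume, one, 1.0, acq, aifs = aif,
                        models = "TM")[["TM.individual"]]
  expect_lt(abs(f_roi$ktrans - f_vox$ktrans) / f_vox$ktrans, 0.02)
  expect_lt(abs(f_roi$ve - f_vox$ve) / f_vox$ve, 0.02)
})

test_that("seven AIFs produce exactly seven Tofts fits", {
  st <- generate_study(tiny_config(), seed = 8)
  res <- run_study(st, models = "TM")
  tm1 <- res$records[res$records$lesion == 1 & res$records$model == "TM", ]
  expect_equal(nrow(tm1), 7L)
  expect_setequal(tm1$aif_variant,
                  c("individual", "pop", "pop_bl", "pop_pa", "pop_pa_bl",
                    "pop_wia", "pop_wia_bl"))
})

test_that("voxelwise maps recover truth and flag degenerate voxels", {
  st <- generate_study(tiny_config(lesions = list(
    lesion_truth("TM", ktrans = 0.3, ve = 0.45))), seed = 6)
  acq <- st$acq
  aif <- extract_individual_aif(st$dynamic_volume, st$artery_mask, 1.4, acq,
                                b1 = st$b1_map)
  mask <- st$lesion_masks[[1]]
  # zero out one voxel to create a degenerate curve
  dyn <- st$dynamic_volume
  bad <- which(mask, arr.ind = TRUE)[3, ]
  dyn[bad[1], bad[2], bad[3], ] <- 0
  pm <- fit_voxelwise(dyn, mask, st$t10_map_truth, acq, model = "TM",
                      aif = aif, b1_map = st$b1_map)
  expect_true(pm$failure_mask[bad[1], bad[2], bad[3]])
  ok <- !is.na(pm$maps$ktrans)
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(pm$maps$ktrans[ok] - 0.3) / 0.3), 0.02)
  expect_lt(max(abs(pm$maps$ve[ok] - 0.45) / 0.45), 0.02)
  expect_true(is.na(pm$maps$ktrans[bad[1], bad[2], bad[3]]))
})
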