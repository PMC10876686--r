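# dcequant

Quantitative and semi-quantitative pharmacokinetic analysis of dynamic
contrast-enhanced MRI (DCE-MRI), aimed at perfusion studies of head-and-neck
tumours and at methodological questions around the arterial input function
(AIF): how much do fitted parameters change when the individual, per-patient
AIF is replaced by one of several population-averaged AIFs?

The package is written for imaging scientists who have dynamic SPGR series,
pre-contrast variable-flip-angle (VFA) volumes, a B1 map and delineated
artery/lesion masks — or who want a fully synthetic, ground-truth-bearing
study to validate a fitting chain.

## What it computes

**Relaxometry and conversion.** Pre-contrast T1 (T10) maps from VFA SPGR
data via the linearized fit (S/sin α against S/tan α) with B1 correction of
the nominal flip angles, and conversion of signal time courses to
gadolinium concentration by inverting the steady-state SPGR equation: with
the saturation factor k = (1 − E10)/(1 − cos α · E10) and y = k·S(t)/S0,

    E1(t) = (1 − y) / (1 − y cos α),   R1(t) = −ln E1(t) / TR,
    C(t)  = (R1(t) − 1/T10) / r1,      r1 = 3.1 /s/mM by default.

**Arterial input functions.** The individual AIF from the most enhanced
5 % of artery-mask voxels at the frame of maximum mean arterial signal;
six population AIF variants built from many arterial curves (no alignment,
peak alignment, or wash-in alignment × baseline kept or removed); and
nonlinear least-squares fitting of the Parker population functional form
(two Gaussians plus a sigmoid-modulated exponential washout).

**Pharmacokinetic models.** Bounded, multi-start, deterministic
least-squares fits of

- the Tofts model (TM): C_t(t) = K^trans ∫ C_a(u) e^(−K^trans/v_e (t−u)) du,
- the extended Tofts model (ETM): TM plus a plasma term v_p·C_a(t),
- the Brix model: an AIF-free two-compartment constant-infusion signal
  model S(t)/S0 = 1 + A·f(t; k_ep, k_el, τ),

ROI-mean and voxel-wise, with K_ep = K^trans/v_e always derived. The
convolution kernel is integrated analytically over each sampling interval
(piecewise-linear arterial input), which keeps the discretization error of
the ~3.7 s dynamic grid far below fitting noise.

**Semi-quantitative metrics.** AUC60/90/120 of the contrast-index curve
CI(t) = (S(t) − S0)/S0 by composite Simpson integration from lesion
contrast arrival, and time-to-half-peak (TTHP) from the two samples
bracketing S_max/2 on the rising limb.

**Agreement statistics.** ICC(A,1) (two-way model, single measures,
absolute agreement), Lin's concordance correlation coefficient, Pearson
correlation with p-values, and the Mann-Whitney U test.

**Synthetic studies.** `generate_study()` builds a 4D SPGR phantom — a
Parker-shaped artery, lesions following TM/ETM/Brix dynamics with known
parameters, VFA volumes, a B1 ramp and Rician noise at a configurable
baseline SNR — so every stage of the chain can be validated against ground
truth.

## Worked example

```r
library(dcequant)

study <- generate_study(study_config(noise_snr = 50), seed = 42)
study
#> Synthetic DCE-MRI study: 16x16x4 grid, 60 frames (dt 3.735 s)
#>   100 arterial voxels, 3 lesion(s): TM, ETM, Brix
#>   baseline SNR 50, seed 42

result <- run_study(study)
subset(result$records, lesion == 1 & model == "TM",
       select = c(model, aif_variant, ktrans, ve, kep))
#>   model aif_variant ktrans    ve   kep
#> 1    TM  individual  0.225 0.373 0.603
#> 2    TM         pop  0.251 0.402 0.623
#> 3    TM      pop_bl  0.251 0.402 0.623
#> 4    TM      pop_pa  0.251 0.402 0.623
#> 5    TM   pop_pa_bl  0.251 0.402 0.623
#> 6    TM     pop_wia  0.262 0.400 0.654
#> 7    TM  pop_wia_bl  0.262 0.400 0.654

result$agreement
#>   parameter icc_population ccc_pop_vs_individual n_lesions
#> 1    ktrans          0.999                 0.978         3
#> 2        ve          0.999                 0.973         3
```

Lesion 1 was generated with K^trans = 0.25 /min and v_e = 0.4. The seven
rows are the seven AIF choices (individual + six population variants); the
fitted K^trans stays within a few percent of truth under the SNR-50 noise,
and the agreement table summarizes the spread: ICC(A,1) of each parameter
across the population variants, and CCC between the plain population AIF
and the individual AIF.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/dcequant-cli.R simulate --seed 3 --snr 50 --out-dir study/
Rscript inst/scripts/dcequant-cli.R run --study-dir study/ --out-dir results/
```

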