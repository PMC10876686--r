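---
title: "Models and methods behind dcequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcequant)
```

# The measurement chain

DCE-MRI pharmacokinetics turns a dynamic T1-weighted image series into rate
constants describing contrast-agent exchange between blood plasma and the
extravascular extracellular space (EES). The chain implemented here is:

1. pre-contrast T1 (T10) mapping from variable-flip-angle (VFA) SPGR data,
   with B1 (transmit-field) correction;
2. conversion of signal time courses to gadolinium concentration through
   the steady-state SPGR signal equation;
3. an arterial input function (AIF), either individual (from an artery
   mask) or a population average, optionally represented by the Parker
   functional form;
4. nonlinear least-squares fitting of compartment models — Tofts (TM),
   extended Tofts (ETM) and Brix — ROI-mean or voxel-wise;
5. semi-quantitative metrics (AUC of the contrast-index curve,
   time-to-half-peak);
6. agreement statistics comparing parameters across AIF choices.

Everything runs equally on real NIfTI inputs and on the built-in synthetic
studies, which carry exact ground truth.

## Units

Internally every time axis is in seconds, starting at acquisition start.
Rate parameters cross the user-facing API in min^-1, the reporting
convention in perfusion imaging; the conversion lives in a single helper
so no formula mixes units. Relaxivity r1 is in /s/mM (default 3.1, the
gadoterate value at 1.5 T), concentrations in mM, T1 in seconds.

# Signal model and relaxometry

The spoiled gradient-echo steady-state signal at flip angle $\alpha$ and
repetition time $TR$ is

$$S = S_{sc}\,\sin\alpha\,\frac{1-E_1}{1-\cos\alpha\,E_1},
  \qquad E_1 = e^{-TR\cdot R_1},$$

with $R_1(t) = 1/T_{10} + r_1 C(t)$ once contrast is present.

**VFA T10 fitting** uses the standard linearization — $S/\sin\alpha$
regressed on $S/\tan\alpha$ has slope $E_1$ — with the nominal angles
multiplied by the per-voxel B1 factor. Fits with slope outside $(0,1)$ or
T10 outside $[0.05, 10]$ s, all-zero signal, or an identical signal at all
angles are flagged invalid rather than raising an error, so whole maps fit
in one pass. The linearized estimator is fast and, at the SNR levels
simulated here (bias < 0.1 % at SNR 100), entirely adequate; an
iteratively reweighted variant was not needed.

**Signal-to-concentration conversion** inverts the ratio of the dynamic
signal to its own pre-injection baseline $S_0$ (the mean of the baseline
frames, four by default). Writing the baseline saturation factor
$k = (1-E_{10})/(1-\cos\alpha\,E_{10})$ and $y = k\,S(t)/S_0$,

$$E_1(t) = \frac{1-y}{1-y\cos\alpha}, \qquad
  R_1(t) = -\frac{\ln E_1(t)}{TR}, \qquad
  C(t) = \frac{R_1(t) - 1/T_{10}}{r_1}.$$

This is the unique inversion consistent with the forward model above, and
the two are verified to be mutual inverses to below $10^{-6}$ mM over
0–5 mM in the tests. Enhancement outside the invertible range
($E_1 \le 0$ or $E_1 \ge 1$, i.e. signal beyond saturation) is clamped to
a configurable concentration ceiling and flagged, never silently dropped.

**B1 and the dynamic series.** B1 maps are routinely applied to VFA T1
mapping; whether the dynamic-series flip angle should also be corrected
is less standardised. Correcting it is the physically consistent choice
and is the default here (`b1` arguments throughout); passing `b1 = 1`
disables it. The individual-AIF extractor accepts the full B1 map and
uses the median over the voxels it actually selects, since the selection
is itself signal-ranked and therefore B1-biased.

# Arterial input functions

**Individual AIF.** Voxels in the artery mask are ranked by their signal
at the frame of maximum mean arterial signal, the top 5 % (configurable)
are averaged into one curve, and the curve is converted to concentration.
If the fraction selects no voxel the single most enhanced one is used,
with a warning.

**Population AIFs.** Six variants arise from crossing three alignment
modes (none, by peak frame, by wash-in start) with two baseline policies
(kept, removed). Design choices the construction needed but the
literature leaves open:

- *Integer-frame alignment.* Curves are shifted by whole frames to the
  median peak (or onset) frame; no sub-frame interpolation, which would
  add an unstated resampling model.
- *Baseline removal without realignment.* Removing a curve's pre-onset
  frames masks them out in place — the surviving samples keep their
  position on the common frame axis. Removal is therefore not a hidden
  second alignment; the averaged window is the intersection of the
  surviving supports, and an error is raised if fewer than 10 frames
  overlap.
- *Conversion T10 and S0.* The averaged signal curve is converted once,
  using a representative arterial T10 (median of the fitted map over the
  artery by default) and an $S_0$ taken from the source curves' own
  baselines — necessary because the "removed" variants have no baseline
  frames left, and harmless for the "kept" variants.

**Wash-in detection** returns the first frame exceeding the baseline mean
by $k$ baseline SDs (default $k = 3$, with a small absolute floor so
noiseless curves work) that is followed by a further increase; it never
fires before the injection frame.

**Parker functional form.** The population AIF shape used throughout is
the two-Gaussian + sigmoid-modulated-exponential form

$$C_b(t) = \sum_{i=1}^{2}\frac{A_i}{\sigma_i\sqrt{2\pi}}
  e^{-(t-T_i)^2/2\sigma_i^2}
  + \frac{\alpha e^{-\beta t}}{1+e^{-s(t-\tau)}}$$

with $t$ in minutes; `parker_reference_params()` carries the published
population-average values (peak ≈ 6.07 mM shortly after 10 s on a dense
grid). `fit_parker()` estimates all ten parameters by bounded
Levenberg–Marquardt least squares. The starting point is derived from the
curve itself (peak height/position, FWHM, tail log-slope), making the fit
deterministic; the bolus-arrival time is estimated as the last sample
below 5 % of peak before the peak and held fixed.

# Pharmacokinetic models

**Tofts and extended Tofts.**

$$C_t(t) = K^{trans}\int_0^t C_a(u)\,
  e^{-\frac{K^{trans}}{v_e}(t-u)}\,du \;[+\; v_p\,C_a(t)]$$

$K^{trans}$ (min^-1) is the plasma→EES volume transfer constant, $v_e$
the EES volume fraction, $v_p$ the plasma volume fraction (ETM only), and
$K_{ep} = K^{trans}/v_e$ is derived — the identity is enforced at
construction, never re-fitted.

*Discretization.* At a temporal resolution of 3.735 s, rectangle or
trapezoid quadrature of the convolution biases $K^{trans}$ by several
percent. The package instead treats $C_a$ as piecewise linear between
samples and integrates the exponential kernel analytically over each
interval (with a series expansion when $K_{ep}\Delta t$ is tiny, to avoid
cancellation). The synthetic generator and the fitter use the same
scheme, so discretization does not masquerade as fitting bias; the scheme
itself is validated against 10 ms brute-force quadrature of the same
piecewise-linear input (< 0.5 % everywhere, in practice ~10^-5 %).

**Brix model.** The AIF-free two-compartment constant-infusion model.
From the plasma/tissue system (unit-rate infusion of duration $\tau$,
elimination $k_{el}$, exchange $k_{ep}$), the closed form with
$t' = \min(t, \tau)$ is

$$\frac{S(t)}{S_0} = 1 + \frac{A}{k_{ep}-k_{el}}\left[
  \frac{(e^{k_{el}t'}-1)e^{-k_{el}t}}{k_{el}} -
  \frac{(e^{k_{ep}t'}-1)e^{-k_{ep}t}}{k_{ep}}\right].$$

Because published renderings of this expression vary (and are easily
mangled typographically), the implementation was derived from the ODE
system directly and is verified against `deSolve` integration to ~10^-10
relative error in the tests. The degenerate case $k_{ep}=k_{el}$ uses the
analytic limit, guarded by a relative-difference threshold of $10^{-9}$;
the double limit $k_{ep}=k_{el}\to 0$ is also closed-form. The model is
fitted in the signal domain on $S(t)/S_0$ — no concentration conversion —
matching its conventional use.

*Identifiability.* The closed form is symmetric under swapping
$(k_{ep}, k_{el})$ with a compensating amplitude change. The fit enforces
$k_{ep} \ge k_{el}$ (exchange fast, elimination slow — the physiological
ordering) by parameter ordering inside the objective, which removes the
label-swap ambiguity; a generator curve with swapped labels is recovered
at the equivalent ordered optimum with identical residual.

*Time origin.* The Brix curve is pinned to $t=0$ at contrast arrival.
With a 6 s infusion sampled every 3.7 s, a one-frame origin error is the
single largest error source, so the pipeline sets the origin at the last
pre-enhancement frame of the lesion curve (the detected onset is the
first *elevated* frame); it can be overridden to the injection frame.

**Optimization.** All fits use `minpack.lm` bounded Levenberg–Marquardt
from a fixed multi-start grid (3 points per parameter, log-spaced for
rates), keeping the basin search deterministic — no RNG exists anywhere
in fitting. Bounds: $K^{trans}\in[0,5]$ min^-1, $v_e\in(10^{-3},1]$,
$v_p\in[0,0.5]$, $k_{ep},k_{el}\in[0,10]$ min^-1, chosen as generous
physiological ranges that stop runaway fits on flat curves. A tissue
curve that is identically zero short-circuits to $K^{trans}=0$ with
$v_e$ at its lower bound and an explicit `ve_unidentifiable` flag.

**ROI-mean order of operations.** For ROI analysis the voxel signals are
averaged *first*, the mean curve converted *second*, and the model fitted
*third*. Because the signal→concentration map is nonlinear, this is not
the same as averaging concentrations or parameters; the ROI fit of a
heterogeneous lesion is a property of the mean curve, and the
voxelwise/ROI consistency tests use homogeneous lesions for that reason.

# Semi-quantitative metrics

The contrast index is $CI(t)=(S(t)-S_0)/S_0$. AUC60/90/120 integrate
$CI$ by composite Simpson's rule over the first 60/90/120 s after
contrast arrival in the lesion (detected on the lesion mean curve). The
3.735 s grid never divides those windows exactly: the curve is linearly
interpolated at the exact window end, an odd interval count is closed
with a trapezoid on the final interval, and the interpolated tail is
integrated as a trapezoid. Against a 1 ms trapezoid oracle on smooth
curves this stays well within 0.1 %.

TTHP is computed on the rising limb: find $S_{max}$ (earliest frame on
ties), take the last upward crossing of $S_{max}/2$ before the peak, put
a straight line through the two bracketing samples, and report the
crossing time minus the injection time,
$TTHP = (S_{max}/2 - \text{intercept})/\text{slope}$. If the curve never
drops below $S_{max}/2$ before the peak — typical when baseline signal
already exceeds half of peak, as in modestly enhancing tissue — TTHP is
reported as 0 with an explicit flag rather than a fabricated crossing.

# Agreement statistics

- **ICC(A,1)**: two-way model, single measures, absolute agreement,
  computed from the two-way ANOVA mean squares
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$.
  Lesions are subjects, AIF variants raters. The estimate is capped at 1
  to absorb floating-point overshoot in the zero-error-variance limit.
- **CCC**: Lin's concordance coefficient with population ($1/n$)
  denominators — the original definition; the sample-variance convention
  changes the value noticeably at small $n$, so the choice is pinned and
  documented.
- **Pearson r** with the two-sided t-test p-value ($n-2$ df), and
  **Mann-Whitney U** via `wilcox.test` (exact null distribution for small
  tie-free samples, normal approximation with tie correction otherwise).
- No multiple-testing correction is applied anywhere; p-values are
  reported raw and compared at the 5 % level, matching common reporting
  practice in this literature. Users running many comparisons should
  adjust downstream.

`parameter_agreement_report()` packages the two headline summaries: the
ICC of each Tofts parameter across the six population variants, and the
CCC of the plain population AIF against the individual AIF.

# The synthetic study generator

`generate_study()` emulates a 1.5 T head-and-neck SPGR protocol: 60
dynamic frames at 3.735 s, dynamic flip angle 12°, VFA angles
2/5/10/15/25°, TR 5.3 ms, contrast injection starting at frame 4 with the
four preceding frames as baseline and arterial bolus arrival at frame 5,
r1 = 3.1 /s/mM. The phantom contains

- an arterial block carrying the Parker reference curve, with optional
  per-voxel amplitude jitter (5 % SD by default) so that "top 5 %"
  selection is non-trivial;
- one lesion per z-slice following TM, ETM or Brix dynamics with known
  parameters (defaults: TM $K^{trans}=0.25$, $v_e=0.4$; ETM
  $K^{trans}=0.15$, $v_e=0.3$, $v_p=0.05$; Brix $A=1.2$,
  $k_{ep}=0.8$, $k_{el}=0.05$ min^-1, $\tau=6$ s — mid-range tumour-like
  values);
- background tissue (T10 0.8 s), arterial blood (T10 1.4 s), a linear B1
  ramp (0.95–1.05 by default);
- Rician noise on the magnitude signal at a configurable baseline SNR
  (Gaussian available for debugging), because magnitude MRI noise is
  Rician; `noise_snr = Inf` gives bit-exact forward-model data.

The infusion duration $\tau$ for Brix synthesis is a free configuration
parameter (default 6 s, a bolus-like value for typical injected volumes
at 3 ml/s) since a per-phantom dose is not modelled.

What the phantom deliberately does **not** contain: k-space effects,
motion, B0 inhomogeneity, partial-volume mixing, bolus dispersion or
delay differences between artery and tissue, or T2* effects. Passing
tests on these phantoms therefore demonstrates correctness of the
numerical chain under its own assumptions, not robustness to every
real-data artefact.

Population-AIF construction needs multiple "patients"; a single synthetic
study provides pseudo-sources by dealing the artery voxels round-robin
into groups (10 by default) and using each group's mean curve. With
per-voxel jitter these sources differ realistically in amplitude; their
onsets coincide, so the six variants agree more closely here than across
a real cohort — the agreement statistics on synthetic cohorts are
accordingly near their degenerate upper end, and are reported as such.

# Problem sizes and determinism

The shipped tests and the acceptance script use 16×16×4 grids (1024
voxels, 60 frames), 100-voxel arteries, 25–64-voxel lesions, a 12-lesion
cohort for the agreement statistics, 200 noise replicates at SNR 50 for
recovery medians, 1000–1200 voxels for the T10-bias estimate, and 2000
null replicates for the type-I-error check — sizes chosen so the whole
chain, including every oracle comparison, runs in well under a minute per
file on one CPU while keeping Monte-Carlo error comfortably below the
tolerances being asserted. A study is bit-reproducible from its
configuration and seed; all fitting is RNG-free, so a full pipeline rerun
writes byte-identical CSVs.

# Known limitations

- The individual-AIF "top 5 %" selection is order-statistics-biased
  upward in the presence of voxel jitter or noise — a faithful rendering
  of how the procedure behaves on real data, visible in the worked
  example as a slightly low $K^{trans}$ with the individual AIF.
- No hematocrit correction is applied to arterial concentrations; AIFs
  are used as measured (or as fitted), so $K^{trans}$ is defined with
  respect to blood rather than plasma concentration unless the user
  scales the AIF.
- The Parker fit estimates ten parameters from ~60 samples; on curves
  without a clear second bolus pass the two Gaussians can trade
  amplitude. The fit is validated on reconstructed-curve fidelity (peak
  height/time, RMSE), not on per-parameter identifiability.
- Voxel-wise fitting is plain R looping over voxels; at the phantom sizes
  used it is fast, but whole-organ maps at clinical resolution would
  deserve vectorization or compiled code.
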