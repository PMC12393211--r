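# echoshift

Macroscopic magnetic field gradients (MFGs) in the phase-encode direction
displace a voxel's echo in k-space during an EPI readout. For asymmetric
spin-echo (ASE) acquisitions — the workhorse of quantitative BOLD (qBOLD)
mapping of R2′, deoxygenated blood volume (DBV) and oxygen extraction
fraction (OEF) — this means the k-space center is not read at the nominal
spin-echo offset τ but at an effective offset

    τ_eff = (τ − k0,y / v) / (1 + γ·Gy / v),

where v is the k-space velocity of the EPI train in the phase-encode
direction and k0,y a baseline phase-gradient (e.g. from y-shimming or eddy
currents). The measured signal becomes

    S_shift(τ) = S0 · exp(−R2·TE) · exp(−R2·(τ_eff − τ)) · f(τ_eff),

an R2-contaminated version of the static-dephasing qBOLD kernel

    f(t) = exp(−DBV ∫₀¹ (2+u)√(1−u)/(3u²) · [1 − J0(1.5·δω·t·u)] du),
    δω = (4/3)π·γ·B0·Δχ0·Hct·OEF.

`echoshift` is an R package for scientists simulating or analysing ASE-EPI
data. It provides:

* the signal model (`qbold_f`, `ase_signal_shifted`, `ase_trajectory`) and
  its closed-form consequences — apparent R2′ and DBV under echo shift
  (`apparent_r2prime`, `apparent_dbv`) and the reversed-phase-encode
  log-ratio predictions (`predict_ln_ratio_from_taueff`,
  `predict_ln_ratio_from_gy`);
* the log-linear qBOLD fitter (`fit_qbold`, with `tidy()`/`glance()`);
* a complex k-space phantom that emulates per-voxel echo displacement on an
  EPI grid, plus B0-map tooling (`phantom_object`, `forward_epi_acquisition`,
  `acquire_stack`, `make_b0_field`, `compute_mfg`), with NIfTI/CSV/JSON I/O;
* the "simulated signal dropout" estimator of τ_eff from complex images
  (`estimate_tau_eff`);
* the phase-encode-reversal analysis — voxelwise ln(S/S_rev), Theil–Sen
  regression with 95% CI, slope-vs-τ tables (`ln_ratio_map`,
  `theil_sen_fit`, `slope_vs_tau_table`) — and the mitigation operators
  `correction_factor`, `geometric_mean_combine`, `rms_combine`.

## Worked example

Healthy gray matter at 3 T (DBV 0.03, OEF 0.4, Hct 0.4, Δχ0 0.264 ppm,
R2 10 1/s), 64-line EPI with 224 mm FOV, TE 74 ms, v = 0.077 rad/(mm·ms),
under a 50 µT/m phase-encode MFG:

```r
library(echoshift)

tis <- tissue_params()
ro  <- epi_readout(v = 0.077)          # warns: printed v vs geometry differ ~3%
compute_delta_omega(tis)               # 141.9952  rad/s
r2prime(tis)                           # 4.259857  1/s
tau_eff(48, field_state(Gy = 50), ro)  # 40.89604  ms  (echo read 7 ms early)

traj <- ase_trajectory(tis, ro, field_state(Gy = 50))
fit  <- fit_qbold(traj, tis)
glance(fit)
#>   r2prime_hat dbv_hat oef_hat intercept_ln n_points valid
#> 1        2.09  0.0265   0.223       -0.714      500  TRUE
apparent_r2prime(tis$R2, r2prime(tis), 50, ro$v)
#> [1] 2.14941
```

The fitted R2′ of 2.09 1/s — half the true 4.26 1/s — is the predicted
echo-shift bias (closed form 2.15 1/s): the gradient tilts the ln-signal
slope by −R2·γGy/v and the fitted OEF collapses from 0.40 to 0.22. With
`Gy = 0` the same pipeline recovers DBV 0.0297 and OEF 0.404.

`plot_trajectories()`, `autoplot()` methods for sweeps, τ_eff maps and
slope tables, and the vignette (`vignettes/echo-shift-model.Rmd`) show the
standard figures: trajectory fans over Gy and k0,y, apparent-parameter
curves, and slope-vs-τ plots with CI whiskers.

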