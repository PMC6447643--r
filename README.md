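# fpact

Quantitative myocardial perfusion from **low-dose first-pass analysis (FPA)
dynamic CT** — the two-volume-scan technique in which a whole-heart volume
scan is acquired at the *base* (V1) and another at the *peak* (V2) of the
aortic enhancement, and voxel-wise perfusion is derived from the enhancement
change between them. The package is aimed at researchers developing or
validating CT perfusion acquisition protocols: it provides the curve
analysis, the acquisition timing rule, a bolus-tracking protocol simulator,
the perfusion computation, CT dosimetry, and the agreement statistics used
to validate such protocols — plus a synthetic dynamic-CT phantom generator
with known ground truth so the whole pipeline is testable without scanner
data.

## The model

**Aortic bolus shape.** An aortic time-density curve is modeled as a
gamma variate

&nbsp;&nbsp;&nbsp;&nbsp;E(t) = A · (u/τ)^b · e^{b(1−u/τ)} + C,&nbsp;&nbsp;u = t − t₀,

which peaks at u = τ with value A + C over the pre-contrast baseline C. The
*base* of the enhancement is the maximum of the curve's second derivative
before the peak; the base-to-peak interval **T_g** depends only on (τ, b)
and scales linearly in τ.

**Timing rule.** Because dispersion broadens mainly the edges of an
(approximately square) injected bolus, the time from base to peak is
predicted by half the injection time plus a fixed dispersion delay:

&nbsp;&nbsp;&nbsp;&nbsp;T_p = T_i/2 + T_d,&nbsp;&nbsp;T_i = contrast volume / injection rate.

The synthetic generator constructs curves whose landmark interval equals
T_i/2 + T_d exactly (default T_d = 2.3 s), so the regression of fitted T_g
on T_i/2 must recover the configured delay.

**Perfusion.** With the myocardium as a single compartment and no venous
outflow during the first pass, mean perfusion is the rate of contrast mass
entry normalized by the arterial input level C_in and tissue mass M_T; the
voxel map redistributes the mean by each voxel's enhancement change ΔHU:

&nbsp;&nbsp;&nbsp;&nbsp;P_AVE = 60·ΔHU_AVE / (ρ · C_in · (t₂−t₁)) [mL/min/g],&nbsp;&nbsp;P_v = P_AVE · ΔHU_v / ΔHU_AVE.

**Dose.** SSDE = f₃₂(d)·CTDIvol with f₃₂(d) = 3.704369·e^(−0.03671937·d)
(32-cm phantom size conversion), and effective dose E = k·CTDIvol·L.

## Worked example

```r
library(fpact)
spec <- acquisition_spec(weight = 45, condition = "rest", seed = 7)
spec
#> Acquisition: 45.0 kg rest, HR 84.9 bpm, T_i = 9.00 s (45 mL @ 5 mL/s)

gen <- generate_aortic_curve(spec)   # noisy synthetic aortic curve
fit <- fit_gamma(gen$curve)
timing_landmarks(fit)
#> Timing landmarks: base 6.955 s, peak 13.921 s, T_g = 6.965 s
```

T_i/2 + 2.3 s = 6.8 s; the fitted interval 6.97 s differs only through the
10-HU curve noise. Simulate the prospective protocol (trigger at +140 HU,
V2 at T_i/2 + 1 s after V1) and compute perfusion on a phantom with true
perfusion 1.5 mL/min/g:

```r
prot <- run_protocol(list(curve = gen$curve, spec = spec, fit = fit),
                     protocol_config(dispersion_delay_d = 1))
prot
#> Protocol: trigger 8.31 s, V1 9.01 s, V2 14.67 s, ideal peak 13.92 s, offset +1 beats

ser <- generate_dynamic_phantom(spec,
         phantom_spec(grid_shape = c(16L, 16L, 8L), true_perfusion = 1.5))
reference_retrospective(ser, fitted = fit)
#> FPA perfusion map: 1056 voxels, global mean 1.443 mL/min/g
#>   M_T = 1.11 g, C_in = 367.3 HU, dHU_AVE = 65.57 HU, dMc/dt = 9.793 HU*mL/s

dose_report(9.2, 23, 16)
#> CTDIvol(32) 9.2 mGy -> SSDE 14.6 mGy; E 2.1 mSv, size-specific E 3.3 mSv
```

The reference map recovers the true 1.5 mL/min/g to within the 10-HU phantom
noise (1.44); on a noiseless phantom recovery is exact to 1e−6 relative. The
dose chain converts the protocol's CTDIvol of 9.2 mGy into an SSDE of
14.6 mGy (23-cm effective diameter) and effective doses of 2.1 / 3.3 mSv
(16-cm coverage, k = 0.014).

A full experiment (cohort generation → fitting → timing regression →
dispersion sweep → low-dose vs reference perfusion agreement → dose report)
is one call:

```r
ex <- run_experiment(experiment_config(n_subjects = 28, seed = 1),
                     outdir = "exp_out")
```

There is also a CLI (`inst/cli/fpact`) with subcommands `simulate`, `fit`,
`sweep`, `perfusion`, `agree`, `dose`, `run-all` operating on YAML configs
and CSV/JSON artifacts.

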