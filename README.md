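# ctpcalib

Calibration of CT-perfusion (CTP) stroke-lesion thresholds between
deconvolution algorithms, using a digital perfusion phantom.

## The problem

CTP triage of acute ischemic stroke segments the **ischemic core** (relative
CBF below a threshold, classically CBF < 30% of normally perfused brain) and
the **penumbra** (Tmax > 6 s) from perfusion maps, and decides treatment
eligibility from the *target mismatch profile* (core < 70 ml, penumbra
≥ 15 ml, mismatch ratio ≥ 1.8). But CBF and Tmax are not measured — they are
estimated by deconvolving the arterial input function C_a(t) from each tissue
time–density curve Q(t) under the indicator-dilution model

    Q(t) = C_a(t) ⊗ R_F(t),      R_F(t) = F · R(t)

where R(t) is the impulse residue function (IRF), CBF is the peak of the
flow-scaled IRF, CBV its area (Central Volume Principle, CBV = CBF·MTT), and
Tmax its time-to-maximum. Different deconvolution algorithms — the
model-independent regularized Fourier method used in clinically validated
software, plug-flow model fitting, or Johnson–Wilson–Lee (JWL) model fitting —
return systematically different CBF for the same tissue, so a threshold
validated for one algorithm is wrong for another.

`ctpcalib` implements a systematic fix: simulate a **digital perfusion
phantom** (gamma-variate flow-scaled IRFs over a wide grid of ground-truth
T0 × MTT × CBV, convolved with an arterial curve, with σ = 1.5 HU Gaussian
noise, 1024 realizations per combination), regress each engine's estimates
against ground truth (estimate = α·truth + β), and map the reference
thresholds through the closed forms

    R_MB     = [α_MB (α_MI·N_GT + β_MI) R_MI + α_MI β_MB − α_MB β_MI]
               / [α_MI (α_MB·N_GT + β_MB)]
    Tmax_MB  = (γ_MB/γ_MI) Tmax_MI + (γ_MI δ_MB − γ_MB δ_MI)/γ_MI

with N_GT = 50 ml/min/100 g the assumed normal-brain CBF. The downstream
pipeline turns 4D dynamic volumes into parameter maps, segments
hypoperfusion / core / penumbra with morphological post-processing, and
compares engines with Pearson correlation, Bland–Altman limits, Cohen's
kappa and classification metrics.

## Worked example

Phantom calibration of the plug-flow (model-dependent, "md") engine against
the Fourier (model-independent, "mi") reference, at a reduced 128
realizations per combination:

```r
library(ctpcalib)
ph  <- build_phantom(phantom_config(n_real = 128L), seed = 1L)
rep <- calibrate_phantom(ph, target = "md")
print(rep)
#> <calibration_report> reference mi vs target md
#>   CBF fits:  mi slope 0.295 int 5.761 | md slope 0.737 int 6.565
#>   Tmax fits: mi slope 1.054 int 1.634 | md slope 1.113 int 1.373
#>   calibrated: relative CBF 17.4% -> 15%, Tmax 5.99 s -> 6 s
```

Reading this: the Fourier engine recovers only ~0.30 of a true CBF increment
(its Wiener-regularized IRF peak is strongly flattened) while the plug-flow
engine recovers ~0.74; both engines' Tmax track truth with slope ~1.1. A
relative-CBF 30% core threshold on the Fourier maps therefore corresponds to
roughly a 15% threshold on plug-flow maps, while the Tmax 6 s penumbra
threshold carries over unchanged — the same qualitative conclusion as with
the published patient-derived arterial curve.

End-to-end on the built-in synthetic 4D study (64×64×4 voxels × 30 frames),
reference thresholds for "mi", calibrated for "md":

```r
study <- make_synthetic_study(seed = 1L)
vol   <- smooth_dynamic(study$volume)           # 2.4 mm Gaussian
print(segment_lesions(compute_maps(vol, "mi"), rcbf_thresh = 0.30))
#> <lesion_report> core 8.7 ml, penumbra 29.9 ml, mismatch ratio 3.4 -> favourable
print(segment_lesions(compute_maps(vol, "md"), rcbf_thresh = 0.15))
#> <lesion_report> core 10.8 ml, penumbra 32.3 ml, mismatch ratio 3.0 -> favourable
```

(Ground truth for this fixture: core 9.7 ml, penumbra 24.6 ml.) Both engines
agree on the favourable verdict once the model-dependent core threshold is
calibrated.

A command-line front end covers the same workflows
(`phantom`, `calibrate`, `synth`, `maps`, `lesions`, `agree`):

```sh
Rscript -e 'quit(status = ctpcalib::ctp_cli())' calibrate --seed 1 --out report.json
```

## Layout

- `R/phantom.R` — arterial curve, gamma-variate IRFs, phantom builder
- `R/deconv.R` — Fourier ("mi"), plug-flow ("md"), JWL ("jwl") engines
- `R/calibration.R` — regressions and the closed-form threshold calibration
- `R/lesions.R` — smoothing, maps, segmentation, morphology, mismatch rules
- `R/stats.R` — Bland–Altman, Cohen's kappa, classification metrics
- `R/nifti.R`, `R/synthetic.R`, `R/config.R`, `R/cli.R` — I/O, the 4D
  fixture generator, configuration, command line
- `vignettes/ctpcalib-methods.Rmd` — the model, numerical choices, what the
  phantom does and does not establish
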