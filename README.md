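# fmrdi

Fast MR dispersion imaging (fMRDI) for dynamic contrast-enhanced MRI:
pharmacokinetic modelling with a dispersion-weighted arterial input function,
and a two-stage (neural network → nonlinear least squares) parameter
estimator.

## The problem

Quantitative DCE-MRI analysis fits a pharmacokinetic model to the
contrast-agent concentration curve of every voxel. The standard Tofts model

    Ct(t) = ∫₀ᵗ Cp(τ − t0) · Ktrans e^(−kep (t − τ)) dτ

assumes one population arterial input function (AIF) `Cp` for all voxels,
ignoring how the vascular tree disperses the bolus on its way to the tissue.
Dispersion is diagnostic in the prostate: tumor neovasculature passes the
bolus fast (little dispersion), normal tissue slowly (strong dispersion).
The fMRDI model makes the local AIF a convex combination of a fast and a
slow local-density-random-walk (LDRW) dilution basis,

    C̄p(t) = λ·Cp_fast(t − t0) + (1 − λ)·Cp_slow(t − t0),    λ ∈ [0, 1],

so one affine weight λ spans the dispersion continuum (λ → 1 in clinically
significant prostate cancer, λ → 0 in normal tissue). The estimand per voxel
is P = {Ktrans, kep, t0, λ}.

Because voxelwise nonlinear least squares (NLLS) from random starts is slow
and initialization-sensitive, the package estimates P in two stages: a small
transformer network, trained purely on synthetic curves, produces a coarse
estimate from the preprocessed curve (a multiscale time-series pyramid
followed by bounded sinusoidal normalization), and 20 iterations of bounded
Levenberg–Marquardt (or a guarded fixed-step gradient rule) refine it. A
digital-reference-object (DRO) benchmark measures robustness to noise.

## Worked example

```r
library(fmrdi)

grid <- time_grid()                      # 75 frames, 5 s apart

# forward model: a tumor-like voxel
pk <- pk_params(ktrans = 0.25, kep = 1.0, t0 = 0.03, lambda_weight = 0.8)
ct <- fmrdi_forward(pk, grid)
round(range(ct), 4)
#> [1] 0.00 0.83

# train a coarse estimator on synthetic curves (reduced desk-scale run)
model <- build_model(model_config(d_model = 32, n_heads = 2, ffn_width = 64),
                     seed = 11)
model <- train_model(model, tc = train_config(iterations = 450,
                                              learning_rate = 1e-3,
                                              batch_size = 48, seed = 7))
# a few minutes on one core

# two-stage fit of a noisy observation of the same voxel
noisy <- add_noise(ct, noise_config(10, 10), seed = 1)
fit <- two_stage_fit(model, noisy, grid, fit_config(seed = 1))
fit
#> <fit_result> fmrdi: ktrans=0.2566, kep=1.008, t0=0.02927, lambda_weight=0.8118 |
#>   residual 0.056255, 3 iteration(s), converged (init: nn)
```

The fitted `ktrans` (0.257 /min), `kep` (1.01 /min) and dispersion weight
(0.81) recover the generating values (0.25, 1.0, 0.8) to a few percent from
a single noisy curve; `residual` is the squared fitting error against the
observation and `init: nn` records that the refinement started from the
network estimate.

Voxelwise maps from a 4D NIfTI series:

```r
vol  <- read_dynamic_volume("dce.nii.gz")          # (x, y, z, t), dt from header
maps <- fit_volume(vol, model, fit_config(seed = 1))
write_parameter_maps(maps, "maps/")                # ktrans/kep/t0/lambda/residual/converged + provenance.json
```

A thin command-line front end over the same functions ships in
`inst/cli/fmrdi.R` (subcommands `simulate`, `synth`, `train`, `fit`,
`dro-bench`, `maps`).

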