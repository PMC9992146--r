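# ganst

Accelerated, quantitative chemical exchange saturation transfer (CEST) and
semisolid magnetization transfer (MT) MR fingerprinting, reconstructed by a
conditional generative adversarial network — as a fully self-contained,
desk-scale R package.

## The problem

Saturation-transfer MRF acquires M pseudo-randomly saturation-encoded
images and estimates, per voxel, the exchangeable-proton volume fraction
f_s and the proton exchange rate k_sw (Hz) by comparing each voxel's
signal trajectory against Bloch-McConnell simulations. Quantification
classically needs the full-length schedule (M = 30) plus dictionary
matching or a pixelwise neural quantifier. This package implements the
accelerated alternative: a conditional GAN (U-Net generator, conditional
patch discriminator, composite loss
L_total = λ₁L₁ + λ₂L_adv + λ₃L_tv + λ₄L_p) that maps the *first N = 9*
raw images — a 70% scan-time reduction; only the schedule tail may be
dropped, because spin history accrues — directly to the quantitative maps
of a full-length reference quantifier.

It is aimed at quantitative-MRI methods researchers who want to study the
truncation/reconstruction trade-off without scanner data: everything from
the two-pool Bloch-McConnell physics (matrix-exponential propagation,
Lorentzian/super-Lorentzian semisolid lineshapes) through schedules,
dictionaries, dot-product matching, the dictionary-trained fully connected
reference network, digital phantoms (L-arginine vials at 25–100 mM and
pH 4–6; procedural brain-like MT scenes), the GAN, and the evaluation
statistics (NRMSE, SSIM, Pearson r, ICC) is generated and validated in
code.

## Worked example

Simulate a vial of 50 mM L-arginine at pH 5, quantify it three ways, and
check the numbers against the ground truth
(f_s = 3·50/111000 ≈ 1.35e-3, k_sw = 25 + 400·10^(5−6) = 65 Hz):

```r
library(ganst)

sched <- generate_pseudorandom_schedule(30, "cest_3ppm", seed = 11)
tissue <- tissue_parameters(
  water  = pool_parameters(t1 = 2.5, t2 = 1.0),
  solute = pool_parameters(t1 = 1.0, t2 = 0.02, chemical_shift = 3,
                           exchange_rate = larg_exchange_rate(5.0),
                           volume_fraction = fs_from_concentration(50)))
traj <- abs(simulate_schedule(tissue, sched))   # magnitude trajectory

grid <- parameter_grid(list(
  volume_fraction = seq(1e-4, 3.5e-3, length.out = 41),
  exchange_rate   = seq(10, 1400, length.out = 41)))
base <- tissue_parameters(pool_parameters(2.5, 1.0),
                          pool_parameters(1.0, 0.02, chemical_shift = 3))
dict <- generate_dictionary(grid, sched, base)

# 1. classical brute-force dictionary matching
dot_product_match(traj, dict)[, c("volume_fraction", "exchange_rate")]
#>   volume_fraction exchange_rate
#> 1         0.00112          79.5

# 2. the dictionary-trained reference network
fcn <- train_reference_fcn(dict, fcn_config(
  30, output_scaling = list(volume_fraction = c(1e-4, 3.5e-3),
                            exchange_rate   = c(10, 1400)),
  noise_sigma = 2e-4, seed = 3))
predict(fcn, traj)
#>      volume_fraction exchange_rate
#> [1,]     0.001360729      67.96815
```

The matcher snaps to a nearby grid point (grid steps are 8.5e-5 and
34.75 Hz, and the slow-exchange corner of the grid trades f_s against
k_sw); the network interpolates off-grid and lands within ~1% of the
true volume fraction and ~3 Hz of the true exchange rate. Training the
N = 9 GAN on rendered scenes is the same pattern at pipeline scale — see
`run_larg_pipeline()` (or the `demo` subcommand of `inst/cli/ganst`),
which synthesizes scenes, renders raw stacks, trains the reference FCN
and the GAN, and reports held-out agreement.

## Package tour

| Area | Entry points |
| --- | --- |
| Physics | `propagate_interval`, `simulate_schedule`, `simulate_schedule_rk4`, `apply_semisolid_lineshape` |
| Schedules | `generate_pseudorandom_schedule`, `truncate_schedule`, `read_schedule`/`write_schedule` |
| Dictionary | `parameter_grid`, `generate_dictionary`, `dot_product_match` |
| Phantoms | `make_larg_scene`, `make_brain_scene`, `inject_b0_artifact`, `render_raw_stack`, `segment_vials`, `augment_pairs` |
| Reference quantifier | `fcn_config`, `train_reference_fcn`, `quantify_stack` |
| GAN | `gan_config`, `loss_weights`, `train_gan`, `reconstruct_volume`, `retarget_to_direct_quantities` |
| Metrics | `nrmse`, `ssim`, `pearson_and_icc`, `evaluation_report` |
| Pipeline / IO / CLI | `run_larg_pipeline`, `run_config`, NIfTI/TSV/JSON readers and writers, `run_cli` |

The methods vignette (`vignettes/ganst-methods.Rmd`) documents the model
assumptions, the synthetic-world constants, the numerical choices and the
known limitations.
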