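# gaitkd

Physics-guided knowledge distillation for estimating lower-limb joint
torques (N·m/kg) from single-cycle IMU signals.

## Who this is for

Researchers in wearable biomechanics and rehabilitation engineering who
need torque estimates on-device: a high-fidelity network consuming 2D
continuous-wavelet-transform (CWT) scalograms is too heavy for embedded
inference, while a lightweight recurrent network on raw 1D signals loses
spectral observability. `gaitkd` distills the former (the *teacher*) into
the latter (the *student*) without relying on feature-space similarity —
the two architectures are too heterogeneous for that — using two
complementary consistency pathways.

## The method

**Path I — parameter-manifold alignment.** The teacher's anchor
projection W<sub>T</sub> (D<sub>T</sub>×D<sub>a</sub>) and the student's
linear dimensional adapter W<sub>S</sub> (D<sub>S</sub>×D<sub>a</sub>)
land in a shared D<sub>a</sub>-dimensional anchor space. Their Gram
matrices G = WᵀW are shape-compatible regardless of D<sub>T</sub> ≠
D<sub>S</sub>, and the student is trained to match the teacher's Gram
structure through

- a Fisher-weighted row discrepancy
  L<sub>Fisher</sub> = Σ<sub>k</sub> F<sub>kk</sub> ‖G<sub>S,k</sub> − G<sub>T,k</sub>‖²,
  with F<sub>kk</sub> = E[(∂L/∂z<sub>k</sub>)²] the teacher's diagonal
  Fisher information over its anchor activation, and
- a principal-subspace term
  L<sub>subspace</sub> = ‖P(G<sub>S</sub> − G<sub>T</sub>)‖²<sub>F</sub>,
  P = U<sub>k</sub>U<sub>k</sub>ᵀ from the top-k eigenvectors of
  G<sub>T</sub>.

**Path II — physics-guided compensation.** A Newton–Euler residual

τ ≈ I<sub>eff</sub> ω̇ + ω × (I<sub>eff</sub> ω) + G(θ)

regularizes the student's torque trajectories. The equivalent inertia
I<sub>eff</sub> = LLᵀ is learned through a Cholesky factor with
softplus-positive diagonal — symmetric positive definite for *every*
parameter value — and ω is smoothed/differentiated by a Savitzky–Golay
filter (exact on cubics, robust to sensor noise). The gravity term is
a<sub>sin</sub> sin θ + a<sub>cos</sub> cos θ with learnable coefficients.

The composite objective is
L = L<sub>data</sub> + α L<sub>KD</sub> + β L<sub>Fisher</sub> +
δ L<sub>subspace</sub> + γ L<sub>phy</sub>
(defaults α = 0.5, β = 0.1, δ = 0.1, γ = 0.05), optimized with AdamW,
linear warm-up, and gradient clipping. Ablation presets M0–M3 switch the
terms on cumulatively.

Because no public gait corpus ships with the package, a synthetic
rigid-body gait simulator (`build_dataset()`) generates structurally
matching data — periodic Fourier kinematics with analytic derivatives,
6-axis IMU per segment, hip/knee/ankle torque labels that are exactly
dynamically consistent with the physics module, 101-step cycles, 7:2:1
cycle-level splits, all randomness from one seed.

## Worked example

```r
library(gaitkd)

cfg <- gait_sim_config(n_subjects = 2, n_cycles_per_subject = 30, seed = 11)
ds  <- build_dataset(cfg)
ds
#> <gait_dataset 60 cycles (test=6 train=42 val=12), 3 joints, seed=11>

tstate <- train_teacher(ds, teacher_config("test"),
                        train_config(epochs = 40, batch_size = 14, seed = 5),
                        joint = "hip")
student <- distill(tstate, ds, student_config("test"),
                   train_config(epochs = 150, batch_size = 14, seed = 5),
                   ablation_weights("M3"), joint = "hip")
evaluate_student(student, ds, split = "test")
#>   joint split n_cycles        r2      rmse nrmse_pct     pcc       pce peak_error
#> 1   hip  test        6 0.9862816 0.1497812  2.842618 0.99533 0.2962318  0.1943287

student$physics$inertia
#> <inertia_cholesky> I_eff (kg m^2/kg):
#>         [,1]    [,2]    [,3]
#> [1,] 0.11303 0.01146 0.00780
#> [2,] 0.01146 0.09535 0.01011
#> [3,] 0.00780 0.01011 0.04656
#> eigenvalues: 0.12046 0.09038 0.04410
```

Reading the output: the distilled student explains 98.6% of the held-out
sagittal torque variance (R² 0.986) with an RMSE of 0.15 N·m/kg — 2.8% of
the torque range (NRMSE) — while using 1,345 trainable parameters against
the teacher's 78,099 (1.7%). The physical-consistency error (PCE, the RMS
Newton–Euler residual under the model's own learned physics parameters)
is 0.30, and the learned equivalent inertia has converged close to the
simulator's generating tensor diag(0.12, 0.10, 0.05) + 0.01
off-diagonals. Peak error is the absolute deviation at the torque
extrema of each cycle, the safety-critical points of the trajectory.

At the `"paper"` scale presets the teacher instantiates ~31.1 M
parameters and the student ~0.16 M — a 99.5% reduction, comfortably
inside the ≥98% compression regime the framework is designed for:

```r
100 * (1 - count_parameters(student_model(student_config("paper"))) /
           count_parameters(teacher_model(teacher_config("paper"))))
#> [1] 99.489
```

## Command line

A thin CLI over the same functions lives at `inst/cli/gaitkd.R`:

```sh
Rscript inst/cli/gaitkd.R simulate      --seed 7 --out runs
Rscript inst/cli/gaitkd.R train-teacher --data runs/<dir> --seed 7 --out runs
Rscript inst/cli/gaitkd.R distill       --data runs/<dir> --teacher runs/<dir>/teacher.rds --preset M3 --out runs
Rscript inst/cli/gaitkd.R evaluate      --data runs/<dir> --student runs/<dir>/student.rds --out runs
Rscript inst/cli/gaitkd.R ablate        --data runs/<dir> --teacher runs/<dir>/teacher.rds --preset M0,M1,M2,M3 --out runs
Rscript inst/cli/gaitkd.R noise-sweep   --data runs/<dir> --student runs/<dir>/student.rds --sigma-list 0,0.1,0.2,0.5,1.0 --out runs
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/anchor_align.R` | Gram anchor space, Fisher weighting, subspace projector |
| `R/physics.R` | SG differentiation, Cholesky SPD inertia, Newton–Euler loss, inertia fitting |
| `R/models.R` | Morlet CWT, teacher (conv + attention), student (GRU + adapter) |
| `R/nn.R` | Matrix-op neural-network primitives with hand-written backprop, AdamW |
| `R/trainer.R` | Composite objective, teacher training, distillation loop, presets |
| `R/gait_sim.R` | Synthetic rigid-body gait simulator |
| `R/metrics.R` | R², RMSE, NRMSE, PCC, PCE, peak error, CV, noise sweep |
| `R/cli_io.R` | Dataset TSV format, checkpoints, config files, CLI |
| `vignettes/` | Methods vignette: model, assumptions, design choices, limitations |
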