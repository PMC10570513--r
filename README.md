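# imugait

Wearable-IMU gait analysis in R: identify hip/knee/ankle hinge-joint
geometry from raw gyroscope and accelerometer streams, estimate
flexion/extension angles by complementary-filter sensor fusion, detect gait
events, and estimate the body-weight-normalized vertical ground reaction
force (vGRF) with random-forest and feedforward-network regressors — plus
the full evaluation suite (RMSE, NRMSE, Pearson ρ, loading/mid-stance/
terminal-stance peak magnitude and timing errors, permutation feature
importance) and a synthetic-data generator with exact ground truth.

It is written for movement scientists and biomechanical engineers who want
force-plate-style outcome measures from body-worn sensors, and for anyone who
needs a fully reproducible, simulation-backed implementation of this sensor
pipeline to build on.

## The method in brief

**Calibration.** Two sensors across a hinge joint measure angular rates
g₁, g₂ and specific forces a₁, a₂ in their own frames. The axis coordinates
j₁, j₂ satisfy ‖g₁ × j₁‖ = ‖g₂ × j₂‖ at every sample; parameterizing each
axis by inclination/azimuth (φᵢ, θᵢ) and minimizing the summed squared
residuals identifies them from a walking segment. The joint-centre offsets
o₁, o₂ satisfy ‖a₁ − Γ_g₁(o₁)‖ = ‖a₂ − Γ_g₂(o₂)‖ with
Γ_g(o) = g×(g×o) + ġ×o, minimized over R⁶ from a circling segment. Both are
least-squares fits (Levenberg–Marquardt, four deterministic restarts for the
axes); the offsets are reported with the unidentifiable axis-parallel
component projected out.

**Angles.** A gyro angle, ∫(g₁·j₁ − g₂·j₂)dt, and an accelerometer angle
(polar-angle difference of the joint-plane projections of the shifted
accelerations ãᵢ = aᵢ − Γ_gᵢ(oᵢ)) are fused per sample by
α(t) = λ·α_acc(t) + (1−λ)·(α(t−Δt) + α_gyr(t) − α_gyr(t−Δt)), λ = 0.02 at
60 Hz: drift-free like the accelerometer, smooth like the gyro.

**vGRF estimation.** Contacts are detected from the 2 Hz-filtered hip
anteroposterior acceleration (IMU side) and from 0.03 BW onsets of the force
signal; every stride is mapped to a 101-point 0–100% cycle grid; each row
(six kinematic features, C7 vertical acceleration, cycle percent) carries a
vGRF label in BW. A random forest (170 trees, depth ≤ 35, log₂ feature
sampling) and a 5×10 ReLU feedforward network (Adam, RMSE loss, dropout 0.2,
max-norm 4) are trained on min–max-scaled inputs with an 80/20 split of the
training subjects plus fully held-out test subjects.

## Worked example

```r
library(imugait)

# --- calibrate one joint from simulated walking + circling segments -------
j1 <- c(0.15, 0.95, 0.27) / sqrt(sum(c(0.15, 0.95, 0.27)^2))
walk <- simulate_hinge(hinge_sim_config(
  duration = 30, motion = "walking", seed = 1,
  true_axis_1 = j1, true_axis_2 = c(0, 1, 0),
  gyro_noise_sd = 0.01, accel_noise_sd = 0.1))
circ <- simulate_hinge(hinge_sim_config(
  duration = 30, motion = "circling", seed = 2,
  true_axis_1 = j1, true_axis_2 = c(0, 1, 0),
  gyro_noise_sd = 0.01, accel_noise_sd = 0.1))
geo <- calibrate_joint(walk$stream1, walk$stream2,
                       circ$stream1, circ$stream2, joint = "knee")
geo
#> <joint_geometry> knee
#>   j1: [+0.1512 +0.9506 +0.2710]   j2: [+0.0004 +1.0000 +0.0006]
#>   o1: [+0.1419 -0.0121 -0.0368] m  o2: [-0.1206 +0.0000 +0.0204] m
#>   residual RMS: axis 0.0145 rad/s, centre 0.1606 m/s^2
```

The recovered axes match the configured ones (true j₁ ≈ (0.150, 0.951,
0.270), j₂ = (0, 1, 0)) to a fraction of a degree despite gyro noise of
0.01 rad/s; the residual RMS values are the per-sample misfits of the two
hinge constraints in their native units.

```r
# --- fused flexion/extension angle for that sensor pair -------------------
ang <- joint_angles(walk$stream1, walk$stream2, geo)
ang
#> <angle_series> knee: 1800 samples, fused range [-16.2, 29.8] deg

# --- a small synthetic cohort, end to end ---------------------------------
study <- run_gait_study(gait_sim_config(n_subjects = 5,
                                        strides_per_speed = 5, seed = 42),
                        n_inter = 1, models = "rf", seed = 1)
study
#> <gait_study> 6060 rows, 5 subjects (1 held out), models: rf_kinematics, rf_c7
#>   rf_kinematics  validation: RMSE 0.014 BW, NRMSE 0.0129, rho 0.9994
#>   rf_c7          validation: RMSE 0.013 BW, NRMSE 0.0122, rho 0.9995

round(study$results$rf_c7$importance, 4)
#>      hip_angle     knee_angle    ankle_angle   hip_velocity  knee_velocity
#>         0.0075         0.0322         0.0009         0.1284         0.0890
#> ankle_velocity         a_vert      cycle_pct
#>         0.1160         0.0326         0.3836
```

The study report gives, per model and feature set, the validation-partition
RMSE (in body weights), the range-normalized RMSE and the Pearson correlation
between measured and estimated vGRF; the permutation importances say how much
the validation RMSE rises when one input is shuffled — the gait-cycle percent
dominates, and the trunk vertical acceleration contributes little, consistent
with the vGRF being primarily a function of gait phase.

A thin command-line front end over the same functions is installed at
`inst/cli/imugait.R` (subcommands `simulate`, `calibrate`, `angles`,
`vertaccel`, `events`, `evaluate`, `run`; all accept `--seed`).

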