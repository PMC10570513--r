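---
title: "Estimating joint kinematics and vertical ground reaction force from wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating joint kinematics and vertical ground reaction force from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Treadmill-embedded force plates measure the vertical ground reaction force
(vGRF) — the dominant external load during walking — but confine the analysis
to the lab. `imugait` implements a wearable alternative: five
inertial measurement units (pelvis/hip, thigh, shank, foot, and one over the
C7 vertebra) provide hip, knee and ankle flexion/extension angles, angular
velocities and trunk vertical acceleration, and a regression model maps those,
together with the instant of the gait cycle, to the body-weight-normalized
vGRF. The package covers the whole chain: sensor-to-segment calibration, angle
estimation, gait-event detection, dataset assembly, model training and a
waveform/peak evaluation suite, plus a synthetic-data generator with exact
ground truth used throughout the tests.

## Hinge-joint calibration

Two sensors on the segments of a (near-)hinge joint measure angular rates
$g_1(t), g_2(t)$ and specific forces $a_1(t), a_2(t)$ in their own frames. The
joint axis has fixed local coordinates $j_1, j_2$ in the two frames, and the
rates differ only by the joint angular velocity about that axis, so
$\lVert g_1 \times j_1\rVert = \lVert g_2 \times j_2\rVert$ at every sample.
Parameterizing each axis by inclination and azimuth
$(\phi_i, \theta_i)$ keeps the axes unit-length, and the axes are identified
by least squares over the per-sample residuals
(`estimate_joint_axes()`). Because the objective is invariant to flipping
either axis, four deterministic starts are used and the lowest sum of squares
kept; `resolve_axis_sign()` then makes the reported solution unique (largest
component of $j_1$ positive; sign of $j_2$ chosen so the axis-projected rates
correlate positively).

The joint-centre offsets $o_1, o_2$ (sensor position relative to the joint
centre, in local coordinates) satisfy a second constraint: removing each
sensor's own rotational acceleration about the centre,
$\Gamma_g(o) = g \times (g \times o) + \dot g \times o$, leaves the
joint-centre acceleration, whose norm is frame-independent:
$\lVert a_1 - \Gamma_{g_1}(o_1)\rVert = \lVert a_2 - \Gamma_{g_2}(o_2)\rVert$.
`estimate_joint_centers()` minimizes these residuals over
$(o_1, o_2) \in \mathbb{R}^6$. Note the direction convention: with $o$
pointing from the *centre to the sensor* the subtraction above recovers the
centre acceleration exactly (the package's simulator verifies this to machine
precision); with the opposite convention the sign of $\Gamma$ flips.

Two numerical choices matter here:

* $\dot g$ is computed by central differences (one-sided at the endpoints).
  On noise-free data this leaves $O(\Delta t^2)$ residuals; the simulator also
  exports the analytic derivative so that exactness can be asserted in tests.
* The centre solution is degenerate under a *common* slide along the axis,
  $(o_1 + s\,j_1,\; o_2 + s\,j_2)$ — both offsets pointing at another point of
  the same axis. (A one-sided slide is *not* a degeneracy once the base of
  the joint rotates in space; we verified this numerically.) The reported
  offsets have the axis-parallel component projected out, a canonical
  representative that is invariant under the common slide.

Calibration data routing follows the intended use: axis identification from a
walking segment (strong flexion/extension excitation), centre identification
from a circling segment (rich angular acceleration). Fits with a
gyro-magnitude standard deviation below 0.2 rad/s are refused as
under-excited. The optimizer is Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the residual vectors; any least-squares method
works for this small, smooth problem.

## Flexion/extension angles

Two independent angle estimates are formed per joint:

* **Gyro angle**: the cumulative trapezoidal integral of
  $g_1 \cdot j_1 - g_2 \cdot j_2$. Smooth, but any relative gyro bias $b$
  drifts it by roughly $b\,t$.
* **Accelerometer angle**: shift both accelerations to the joint centre
  ($\tilde a_i = a_i - \Gamma_{g_i}(o_i)$), project them onto the joint plane
  using the basis $x_i = j_i \times c$, $y_i = j_i \times x_i$, and take the
  difference of the two polar angles (two-argument arctangent). Drift-free but
  noisy, and undefined when the joint-centre acceleration is parallel to the
  axis. The reference vector $c$ may be anything not parallel to the axis;
  `"auto"` picks the standard basis vector minimizing $|j \cdot e|$. The
  resulting angle is independent of $c$ up to a constant. The subtraction
  order is fixed so that both sources share the same sign convention (the
  complementary filter requires it; the opposite order yields the negated
  angle, as the exact simulator shows).

The two are blended by a complementary filter,
$$\alpha(t) = \lambda\,\alpha_{acc}(t) + (1-\lambda)\,
  \bigl(\alpha(t-\Delta t) + \alpha_{gyr}(t) - \alpha_{gyr}(t-\Delta t)\bigr),$$
with $\lambda = 0.02$ and $\Delta t = 0.016$ s (60 Hz) as defaults: an
effective first-order high-pass on the gyro path and low-pass on the
accelerometer path with time constant $\Delta t/\lambda \approx 0.8$ s. The
filter is initialized at the first valid accelerometer angle; samples with a
degenerate accelerometer angle propagate on the gyro increment alone; the
accelerometer angle is unwrapped before fusion.

Two conventions are unobservable from the data and standard practice resolves
them against a reference: the *sign* of the angle (the hinge constraint is
sign-blind) and its *zero offset* (a constant depending on mounting and $c$).
`align_angle_convention()` applies exactly this sign-by-correlation and
offset-by-mean alignment before validation errors are computed — the same
role anatomical calibration plays in real studies. It cannot manufacture
accuracy: all shape and drift errors remain.

Angular velocities are obtained by zero-phase low-pass filtering the fused
angle (second-order Butterworth, 6 Hz cutoff, applied forward and backward —
effectively fourth order) and central differencing. Filtering *then*
differentiating was chosen over the reverse order; in the passband the two
differ negligibly. The trunk vertical acceleration uses the C7 device
quaternions: rotate the specific force to the global frame, add gravity back,
keep the Z component.

## Gait events and the cycle dataset

Foot contacts are detected twice. In the IMU stream, the hip anteroposterior
acceleration is zero-phase low-pass filtered at 2 Hz and prominent local
maxima (above the mean plus 0.2 standard deviations, separated by at least
0.4 of the median inter-peak interval, away from the filter's edge
transients) are contacts; on real data every second maximum would be taken as
the right foot, while the simulator generates right-contact maxima only. In
the force signal, a contact is a rising crossing of 0.03 BW sustained for 3
samples (exact on step edges; at most one sample late on waveforms that are
exactly zero at contact), and the falling crossing is the toe-off.

Each inter-contact interval is mapped to the fixed 101-point 0–100% cycle
grid by linear interpolation, each modality from its own contacts on the
shared clock (never by time-domain resampling across rates); strides outside
[0.5 s, 3 s] are dropped and counted. The two modalities are paired contact
by contact (nearest-time matching with a tolerance of 0.3 median stride;
count mismatches beyond one stride are an error), and each grid point of each
stride becomes one dataset row: six kinematic features, vertical
acceleration, cycle percent, and the vGRF label in BW.

## vGRF regression

Inputs are min–max scaled to [0, 1] using *training* minima/maxima only; test
data transformed with the training scaler may leave [0, 1] and is not
clipped. Two feature sets are supported: `kinematics` (6 kinematic features +
cycle percent) and `c7` (plus vertical acceleration, 8 inputs). Data from the
training subjects are split 80/20 uniformly at random (unstratified) into
training and validation; held-out subjects form the test partition.

* **Random forest** (`ranger`): 170 trees, maximum depth 35, minimum of one
  sample per leaf and two to split, $\lfloor\log_2 p\rfloor$ candidate
  features per split. Note `ranger` declares nodes of size
  `min.node.size` terminal, so "may split nodes with ≥ 2 samples" maps to
  `min.node.size = 1` together with `min.bucket = 1`.
* **Feedforward network** (implemented in base R): 5 hidden ReLU layers of 10
  units, linear output, Adam, RMSE loss, inverted dropout 0.2 after each
  hidden layer, and a max-norm constraint of 4 on each unit's incoming
  weights, re-applied after every update. Batch size 128, at most 200 epochs
  with early stopping (patience 30) on validation RMSE, best weights
  restored. The learning rate, unstated in the training recipes this design
  follows, is 3e-3: the RMSE loss scales the mean-squared-error gradient by
  $1/(2\,\mathrm{RMSE})$, so steps shrink while the error is large and 1e-3
  leaves this small network visibly under-trained within the epoch budget.
  All stochastic pieces (initialization, shuffling, dropout masks) run off
  one seed, making training bit-reproducible.

Permutation feature importance is the increase in prediction RMSE when one
column of the evaluation matrix is shuffled, averaged over repeats.

## Evaluation

Per-stride RMSE (BW), NRMSE (RMSE divided by the range of the *measured*
signal, computed per grouping), Pearson correlation, and the three
characteristic peaks of the walking vGRF waveform: loading peak (LP) as the
maximum over the first half of stance, terminal-stance peak (TP) as the
maximum over the second half, mid-stance minimum (MP) strictly between them —
"halves" being the simplest reading of the first/second period of foot
support, configurable via the stance bound. Peak magnitude errors are
reported as absolute values; timing errors are signed (positive = estimated
peak later). A stance without an interior minimum raises an error rather
than fabricating peaks.

## The synthetic-data generator

No public recording of the five-sensor/force-plate protocol exists, so the
`simulate` module is a first-class component:

* `simulate_hinge()` builds an exact rigid two-segment hinge: analytic base
  rotation (two-axis sinusoids), analytic joint waveform (sinusoid or a
  two-harmonic flexion-like "gait" profile), translating joint centre, and
  sensors at arbitrary requested axis/centre coordinates. Gyro signals and
  specific forces are closed-form, so both calibration constraints hold to
  machine precision at zero noise — the foundation for every exactness test.
  The base frame is tilted so the hinge axis is near-horizontal, as
  flexion/extension axes are in gait; gravity then lies in the joint plane
  and carries angle information, without which accelerometer angles are
  noise-dominated (as they would be on a real vertical-axis joint). White
  noise and constant bias are configurable; the bias applies to one sensor
  because only the relative bias drifts the integrated angle.
* `simulate_gait()` walks a planar sagittal chain (pelvis–thigh–shank–foot,
  mediolateral hinge axes) at per-speed cadences, with smooth periodic
  joint-angle splines loosely shaped like normal hip/knee/ankle curves and
  mildly scaled with speed, per-subject randomized mounting poses and
  waveform variability, a contact-locked anteroposterior pelvis
  acceleration bump, a vertical pelvis oscillation at twice the stride
  frequency, and a C7 sensor with quaternions. The right-foot vGRF is a
  monotone cubic Hermite double bump through (0,0), LP, MP, TP,
  (stance end, 0) — zero slope at the three peaks (so they are exact, unique
  stance extrema), secant slope at the stance boundaries (crisp loading), and
  exactly zero in swing; plate noise, when enabled, is added in stance only.
  Default study conditions mirror a treadmill protocol: 12 subjects, speeds
  1.5/2.5/3.5/4.5 km/h, cadences 35–53 strides/min, LP 1.02–1.15 BW around
  13–14%, MP 0.70–0.88 BW at 30%, TP 1.00–1.12 BW at 46–47%, stance ending
  at 61–64%, IMUs at 60 Hz, force at 100 Hz.

What the generator does *not* emulate — soft-tissue artifact, non-hinge joint
laxity, left/right asymmetry, double-support force sharing, magnetometer
effects, non-stationary cadence — bounds what green tests mean: they validate
the algorithms under the stated model, not the hardware or human variability
of a real study.

## Problem sizes and numerical choices in the test suite

The accuracy studies run at sizes chosen to exercise the full chain while
keeping the suite quick: the angle experiment uses 20 seeds per joint preset
with 30 s calibration segments and 60 s measurement records at 60 Hz (gyro
noise 0.01 rad/s, bias 0.005 rad/s, accelerometer noise 0.1 m/s²,
evaluation over the final 50 s); the end-to-end study uses 12 simulated
subjects (10 intra, 2 held out), four speeds and 6 strides per speed.
`scripts/acceptance.R` re-runs the angle experiment from scratch at those
conditions. Zero-noise exactness is asserted at 1e-12 or tighter; oracle
equivalence (residuals, Γ, RMSE, NRMSE, permutation importance against
independent reimplementations) at 1e-12.

## Known limitations

* Axis sign and angle offset are reported in the package's own convention;
  mapping to anatomical flexion-positive angles needs a reference pose or
  system, exactly as with any sensor-to-segment calibration.
* The centre fit needs genuinely three-dimensional "circling" excitation;
  planar motion leaves components weakly identified (the axis-parallel one is
  unidentifiable by construction).
* Linear resampling of a 100 Hz force signal onto the cycle grid is exact to
  a few thousandths of a BW except within ~2 grid points of the contact and
  toe-off kinks, where the waveform's slope changes discontinuously.
* The regressors interpolate within the training distribution; the held-out
  subject partition exists precisely to expose the (expected) degradation on
  unseen subjects, and random forests in particular fit training subjects
  much more tightly than new ones.
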