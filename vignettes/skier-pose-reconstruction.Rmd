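---
title: "Reconstructing a skier's center of mass and ski trajectories from a single GNSS antenna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a skier's center of mass and ski trajectories from a single GNSS antenna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipose)
```

## The problem

High-grade differential GNSS gives centimetre-accurate positions of a single
point — an antenna worn behind the skier's neck — at 20 Hz. Coaches and
biomechanists, however, care about the skier's center of mass (COM) and the
ski trajectories, neither of which is directly measured. `skipose` implements
two families of solutions to this single-point-to-pose problem:

1. **A dynamic inverted-pendulum (IP) estimator.** The skier is reduced to a
   rigid bar pivoting at the snow contact, kept dynamically balanced by
   gravity and the radial force of the turn. From the antenna track alone it
   reconstructs the lean angle, the bar length, the COM (at fraction `k` of
   the bar) and the ground-contact point.
2. **Learned pose models.** A 3-D *query* — radial acceleration `a_r`, speed
   `v` and tangent-plane skiing angle `alpha` — is mapped to the 9-D
   antenna-relative pose (COM, left ski, right ski) by either a locally
   weighted regression model with Gaussian receptive fields (`lwpr_fit()`)
   or a feedforward neural network (`mlp_fit()`). These require reference
   training data but are not constrained by the pendulum's rigid-balance
   assumption.

A third, equally important component is a **synthetic run generator**
(`make_course()`, `make_run()`, `make_study()`, `degrade_to_gnss()`): every
estimator in the package can be validated by parameter recovery on data whose
ground truth is known exactly.

## The balance model

With `theta` the lean angle from the global vertical, `l_g = k l` the COM
height along the bar, `(a_r, a_z)` the radial and vertical COM accelerations
and `g` gravity, the dynamically balanced bar satisfies

$$ l_g \ddot\theta + a_r \cos\theta - (a_z + g) \sin\theta = 0 . $$

The driving torque is taken as zero (the GNSS setup cannot observe it) and
the pendulum inertia as a point mass at the COM. `solve_theta()` solves this
equation for `theta` in closed form via the tangent half-angle substitution,
which turns it into a quadratic in `tan(theta/2)`; of the two roots the one
with `|theta| < pi/2` and the smaller residual is returned. For
`theta_ddot = 0` it reduces to the static lean `atan(a_r / (a_z + g))`.

The antenna sits at the *top* of the bar, so the measured accelerations are
not the COM accelerations. Differentiating the rigid kinematics of a point at
fraction `k` of a bar whose lean plane rotates at the turn rate `omega` gives
the transfer implemented in `com_accel_from_antenna()`:

$$ a_r = a_r^* + (k-1)\left[\sin\theta\,(\ddot l - l\dot\theta^2 - l\omega^2)
   + \cos\theta\,(l\ddot\theta + 2\dot l\dot\theta)\right] $$
$$ a_z = a_z^* + (k-1)\left[\cos\theta\,(\ddot l - l\dot\theta^2)
   - \sin\theta\,(l\ddot\theta + 2\dot l\dot\theta)\right] $$

This transfer is *derived*, not transcribed: it is validated in the test
suite against second finite differences of exactly-placed antenna and COM
points on an analytic scene (agreement better than $10^{-3}\,\mathrm{m/s^2}$
at 120 Hz). Note the factor `k - 1`: the COM-minus-antenna offset is
`(k - 1) l` along the bar, which is what the finite-difference oracle forces.

## The estimation loop, and why it is solved implicitly

`estimate_ip()` follows the classic fixed-point scheme: compute antenna
features (three-point circumradius curvature, `a_r^* = v_h^2/r`, turn rate
`omega = v_h/r`, vertical acceleration by central differences); take the
antenna accelerations as the first COM approximation; solve for `theta`;
intersect the lean ray with the slope mesh to get the bar length `l`;
transfer the accelerations to the COM; repeat until the angle update falls
below `tol` (default $10^{-3}$ rad, `max_iter = 20`).

One numerical point deserves emphasis. Updating `theta` sample-by-sample with
the closed form, feeding back a smoothed `theta_ddot`, is an *explicit*
treatment of the angular-acceleration coupling. Its loop gain is roughly
$(l_g/g)\,\omega^2$ per iteration for an angle perturbation at frequency
$\omega$ — greater than one above about 1.8 Hz for human proportions — so any
angle estimate that carries genuine dynamics diverges geometrically. The
package therefore performs each angle update as one quasi-Newton step on the
full discrete balance system: `theta_ddot` is the tight central second
difference, treated implicitly, and the COM-transfer feedback (whose
linearization is another `(k-1) l D^2` second-difference operator) is folded
into the same tridiagonal Jacobian, giving weight `l (2k - 1)/dt^2`. The
residual that is driven to zero is the exact nonlinear one; only the
Jacobian is approximated. On the default synthetic course this converges in
2 iterations on clean data and 5–6 under GNSS noise, inside the 5–10 range
typical for this estimator class. Kalman smoothing (`kalman_theta()`, a
constant-acceleration forward filter plus Rauch–Tung–Striebel pass) remains
in two roles: smoothing the ray-cast length series before differentiation —
raw per-sample lengths carry cast jitter that finite differencing amplifies
by $1/dt^2$ — and producing the reported `theta_dot`/`theta_ddot` series.

Two further numerical choices: the antenna track is smoothed with
per-coordinate cross-validated smoothing splines before differentiation
(`smooth = TRUE`; see *Noise* below), and the two outermost samples at each
end stay at the quasi-static solution, since one-sided differencing supports
no stable angular-acceleration estimate there.

## The query and the learned models

`build_query()` computes per sample: the curvature radius `r` as the
circumradius of the circle through three adjacent horizontal projections
(collinear samples give `r = Inf`), `a_r = v_h^2/r` signed positive in
left-hand (counter-clockwise) turns, the absolute speed `v`, and the skiing
angle `alpha` of the tangent-plane-projected velocity measured from the
local fall line. A printed formula for the radial acceleration of the form
"`omega * r`" is dimensionally a velocity; the package uses
$v_h^2/r~(= \omega^2 r)$ throughout, which is what enters the balance
equation against `g`.

**LWPR-style model.** Queries are z-scored, and Gaussian receptive fields
with a fixed metric `D` cover the query space incrementally: a field is
created wherever the best activation falls below `w_gen = 0.2`, and every
sufficiently activated field updates a local linear map by weighted
recursive least squares. Prediction is the activation-weighted convex
combination of local models. Design choices made here:

* `D` is interpreted in *standardized* query units so its meaning is stable
  across runs and unit systems; the default `4 * I` gives fields of roughly
  half a standard deviation radius and a few dozen local models at study
  scale. A much smaller metric (e.g. `0.1 * I` on standardized features)
  leaves 3 fields and a grossly underfit model; metrics quoted on raw
  physical scales make the radian-valued angle feature essentially invisible.
  The field count is a property of the data scales, not a target in itself.
* Training makes `passes = 2` sweeps: one placement pass plus one
  update-only sweep, so fields created late still see the whole data. With a
  strict single pass the accuracy was erratic in `D`; one extra sweep makes
  it stable without changing the incremental character of the algorithm.
* Local models are ridge-regularized (`1e-6`) plain linear regressions in
  the 3-D query; with three inputs, partial-least-squares projections would
  add nothing.

**Neural network.** `mlp_fit()` is a tanh-hidden/identity-output network
(default one hidden layer of 30 units) trained by seeded mini-batch gradient
descent on standardized inputs and targets. Backpropagation is verified
against central finite differences to $10^{-5}$ relative error. Defaults
(`epochs = 1000`, `lr = 0.05`, batch 32) are sized so the default study
problems train to a loss plateau in a few seconds.

Both models serialize to plain JSON (`save_model()`/`load_model()`), and
`predict_pose()` adds predicted offsets back to the antenna track to give
absolute COM and ski trajectories.

## What the generator emulates — and what it does not

`make_course()` builds an inclined plane with pitch `atan(drop/length)`
(defaults 99 m over 350 m, about 15.8 degrees) and 12 gates at equal
along-slope spacing with alternating lateral offsets (default 4 m, giving
turn radii around 25 m). `make_run()` threads a cubic-spline line through
per-run jittered gate positions, advances the mid-ski point with a smooth
monotone speed ramp (8 to 16 m/s, 60 m e-folding, small smooth seeded pacing
variation), and erects the skier on it.

For a **balanced** skier the lean angle is solved so the balance equation
holds *for the COM path that the lean itself generates*, using exactly the
discrete operators the estimator uses (three-point circumradius, central
differences). This self-consistency is a banded nonlinear system solved by
the same implicit quasi-Newton scheme as the estimator; the returned runs
satisfy the balance equation to better than $10^{-8}$ at interior samples.
That makes balanced runs the IP estimator's own model class, so estimator
accuracy on them is a genuine parameter-recovery measurement.

**Styled** (unbalanced) skiers add: a lean bias following the turn direction
through a smooth `tanh` ramp, a fore-aft COM offset along the direction of
travel, turn-synchronous flexion shortening the antenna height, and smooth
stochastic wobble of the COM (1 cm) and each ski (3 cm) that is
unpredictable from the trajectory. The wobble amplitudes encode the
real-world fact that skis move more, relative to the antenna, than the COM
does; they set the irreducible error floor of any pose model and produce the
COM-below-ski error ordering. Distinct style parameter draws act as distinct
subjects for cross-validation (`make_study()`: five skiers, 4+4+4+3+3 = 18
runs by default). GNSS measurement is emulated by decimation to 20 Hz plus
i.i.d. Gaussian noise with per-axis SD 3.5 mm horizontal / 8 mm vertical —
read off 95% error bounds of 7 and 16 mm as two sigma.

What the generator does **not** emulate: real terrain relief (the mesh is a
plane, though all mesh code is written for general bilinear grids),
ski–snow interaction forces, air drag, turn-phase structure beyond what the
gate geometry induces, upper-body articulation, GNSS outages or multipath,
and the pose-measurement error of a real motion-capture reference. Passing
recovery tests on synthetic runs therefore demonstrates correctness of the
estimation machinery under its stated assumptions, not field accuracy on
real athletes.

## Noise, rates and smoothing

The reference pose rate is 120 Hz and GNSS is 20 Hz; `upsample_spline()`
bridges the two with cubic interpolation (Forsythe–Malcolm–Moler boundary
conditions, exact on cubic paths). `sync_by_squat()` aligns the two clocks
by the bottom of the pre-run squat — the upward zero-crossing of vertical
velocity nearest the global height minimum, linearly interpolated.

At RTK noise levels, raw three-point curvature is useless at GNSS rates: the
sagitta of a 25 m-radius turn over a 0.75 m chord is about 2.8 mm, the same
order as the 3.5 mm horizontal noise. All pipelines therefore smooth the
antenna track first (`smooth_trajectory()`), with per-coordinate smoothing
splines whose smoothness is chosen by generalized cross-validation — on
clean tracks GCV selects near-interpolation, so the step is harmless there.

## Evaluation protocol

Errors are per-sample Euclidean distances (`pose_error()`); the pendulum's
single ground point is scored against the mid-point of the two reference
skis under the equal-weighting assumption (`ip_ground_error()`). For
aggregation across runs, each run's error series is resampled onto a common
path-fraction grid `s` in [0, 1] defined by cumulative horizontal arc length
(`path_normalize()`, 200 points by default; a duration-based `by = "time"`
option is provided — the two coincide only at constant speed), then averaged
pointwise (`aggregate_runs()`).

`cross_validate()` trains one model per skier on that skier's runs and
evaluates every model on every run: rows are (skier, run), columns are
model-training skiers, cells are mean (SD) error over the run's samples.
With distinct synthetic styles the row minima fall on the own-skier diagonal.
The two methods are compared by a paired t-test (`paired_t_test()`, verified
against `stats::t.test` to $10^{-10}$) over the off-diagonal cells only —
predictions made with a model trained on a different subject. An 18-run,
5-model layout gives 90 − 18 = 72 paired cases, hence 71 degrees of freedom.

## Problem sizes and determinism

The packaged experiments run at the full default study scale: ~26 s runs at
120 Hz (about 3100 samples), 20 Hz training queries (~500 samples per run),
18-run cross-validation studies. Every stochastic step — path jitter, speed
pacing, style wobble, GNSS noise, weight initialization, batch shuffling —
is driven by explicit seeds, and equal seeds give bit-identical artifacts.

## Known limitations

* The IP estimator's lean plane is the vertical plane through the horizontal
  radial direction of the *antenna* path; the simulator's balanced skier is
  defined on the COM path's radial direction. The residual mismatch is
  second-order and is absorbed into the recovery error (millimetres on clean
  data).
* The balance solve holds the outermost two samples quasi-static; the first
  and last fraction of a second of a run should not be over-interpreted.
* `lwpr_fit()` fixes the distance metric; it does not adapt `D` per field or
  implement forgetting factors, and its local models are plain ridge
  regressions rather than incremental PLS.
* The generator's style model (bias, fore-aft, flexion, wobble) spans a
  plausible but low-dimensional family of techniques; real inter-subject
  differences are richer.
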