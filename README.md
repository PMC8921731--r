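# antkin

Whole-body kinematic modeling of ant locomotion: constrained multibody
models built from fitted joint geometry, marker-based inverse kinematics
over a gait cycle, and Monte Carlo propagation of model-parameter
uncertainties into joint angles.

## Who this is for

Researchers doing marker-based motion analysis of small arthropods (or
any multi-legged animal at millimeter scale), where two questions
dominate: *can a rigid multibody model track the markers at all*, and
*how much of the computed joint-angle signal survives the uncertainties
in marker placement and joint-geometry digitization*? `antkin` answers
both with a pipeline that runs entirely in R (compiled kernels for the
hot path) and a synthetic hexapod generator that makes every stage
testable against known ground truth.

## The method

**Joint geometry.** Articular surfaces segmented from µ-CT are point
clouds; a ball-and-socket center is the center of a least-squares sphere
fit (algebraic Coope start + Gauss–Newton refinement), a hinge axis the
line through two fitted condyle-sphere centers, the sagittal plane the
perpendicular bisector plane of the propodeal-spiracle centers. Segment
coordinate systems follow the anatomical conventions (y anterior /
proximal, z along hinge axes pointing medially, right-handed, validated
to 1e-10).

**Inverse kinematics.** Per frame, the pose vector q (65 DOF on the
reference ant topology) minimizes the weighted least-squares marker
distance

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>q</sub> Σᵢ wᵢ ‖xᵢ<sup>obs</sup> − xᵢ<sup>model</sup>(q)‖²&nbsp;&nbsp;s.t.&nbsp;&nbsp;q ∈ [q<sub>min</sub>, q<sub>max</sub>]

under range-of-motion bounds, solved by a projected Levenberg–Marquardt
with active-set reduction and an analytic rigid-body Jacobian. Frame 0
is multi-started; later frames warm-start.

**Uncertainty propagation.** Two Monte Carlo simulations perturb (a)
model marker placements inside uniform balls of radius 0.4 mm and (b)
joint geometrical parameters — ball centers and hinge condyle points —
inside uniform zones of radius 0.2 mm, re-solving the whole trial each
iteration. Per DOF: mean trajectory θ̄(t), coverage width Δθ(t) = 2σ(t),
and the sensitivity statistic

&nbsp;&nbsp;&nbsp;&nbsp;SNR = P<sub>s</sub> / P<sub>n</sub>, &nbsp; P<sub>s</sub> = max<sub>t</sub> θ̄ − min<sub>t</sub> θ̄, &nbsp; P<sub>n</sub> = max<sub>t</sub> Δθ(t),

with group averages over body sides, leg positions and anatomical
joints.

## Worked example

```r
library(antkin)

model <- make_synthetic_hexapod()
model
#> <kinematic_model> 40 segments, 65 free DOF (8 locked), 80 markers

trial <- render_marker_trial(model,
  make_gait_trajectories(model, synthetic_gait_spec()))
trial
#> <marker_trial> 139 frames x 80 markers at 100 Hz (1.380 s), 0 missing samples

ik <- solve_ik_trial(model, trial, ik_settings(multi_start = 8),
                     body_length_mm = 6.6)
ik
#> <ik_result> 65 DOF x 139 frames; 139 converged, 0 flagged; average marker RMSE 3.735e-12 mm
#>   normalized RMSE: 0.00 % of body length
```

A noiseless synthetic trial is recovered to numerical precision — the
marker RMSE is the residual of the solver, and every generated joint
angle comes back to below 0.5°. Ranges of motion (max − min over the
cycle, degrees):

```r
head(subset(range_of_motion(ik), segment %in% c("head", "fr_ti"))[,
     c("segment", "joint_label", "dof", "rom")])
#>    segment joint_label               dof      rom
#> 7     head thorax/head         abduction 11.99921
#> 8     head thorax/head internal_rotation 11.99923
#> 9     head thorax/head           flexion 11.99919
#> 21   fr_ti       fe/ti           flexion 54.53385
```

Marker-placement uncertainty (uniform ball, radius 0.4 mm, 50
iterations on the cycle sampled at 10 Hz):

```r
g10 <- make_gait_trajectories(model, synthetic_gait_spec(rate = 10))
mc <- run_monte_carlo(model, render_marker_trial(model, g10),
                      ik_settings(multi_start = 2, max_iter = 600),
                      perturbation_spec("model_markers", radius = 0.4,
                                        n_iterations = 50, seed = 42))
head(summarize_snr(compute_snr(mc)), 6)
#>                    group n_dof       snr
#> 1             all joints    59 0.9321432
#> 2 right-hand side joints    26 0.9866314
#> 3  left-hand side joints    26 1.0390673
#> 4      front legs joints    20 0.8188630
#> 5     middle legs joints    16 1.1574910
#> 6       rear legs joints    16 1.1106907
```

An SNR near 1 says the joint-angle signal and the uncertainty band have
comparable size for this geometry and perturbation radius: on a ~6.6 mm
body, 0.4 mm of marker-placement uncertainty is a serious fraction of
every segment's length, and the sensitivity analysis quantifies exactly
which joints survive it best (here, as in real data, the femur/tibia
joint fares best; see `compute_snr()` per-DOF output).

I/O: `read_c3d()` / `write_c3d()`, `read_trc()` / `write_trc()`,
`write_trajectory_csv()`, `write_ik_csv()`, plus `lowpass_filter()`
(zero-phase Butterworth), `resample_trial()` and `crop_cycle()` for the
standard conditioning chain.

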