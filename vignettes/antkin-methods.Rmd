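---
title: "Whole-body kinematic modeling of ant locomotion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body kinematic modeling of ant locomotion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antkin)
```

## The problem

Marker-based motion analysis of walking insects works at the edge of what
optical systems resolve: a ~6.6 mm ant tracked in a calibrated volume a
few centimeters across, with roughly 3 % spatial resolution per dimension.
Whole-body inverse kinematics on a constrained multibody model makes such
data usable — segment lengths cannot drift, joints cannot dislocate — but
it also inherits every uncertainty in the model itself: where the virtual
markers sit on the segments, and where the joint centers and axes were
placed when the exoskeleton geometry was digitized.

`antkin` implements that pipeline end to end and quantifies how both
sources of uncertainty propagate into joint angles:

1. **joint geometry** — least-squares sphere fits of articular surfaces
   give ball-joint centers; pairs of condyle spheres give hinge axes;
2. **model construction** — a rigid-segment tree with typed joints,
   anatomical coordinate systems and range-of-motion (ROM) limits;
3. **signal conditioning** — C3D/TRC input, zero-phase Butterworth
   low-pass filtering, resampling, gait-cycle cropping;
4. **scaling and inverse kinematics** — per-segment scale factors from
   inter-marker distances, then per-frame bounded weighted least squares;
5. **Monte Carlo uncertainty propagation** — repeated re-solution of the
   whole trial under uniform perturbations of marker placements or joint
   geometry, summarized as coverage intervals and a per-DOF
   signal-to-noise ratio (SNR).

A synthetic-data module generates fully known hexapod models, gaits and
trials, so every stage is testable against ground truth without any
external downloads.

## Joint geometry

`fit_sphere()` uses the algebraic (Coope) linear least-squares
formulation — writing $\lVert p\rVert^2 = 2\,p\cdot c + (r^2 -
\lVert c\rVert^2)$ turns sphere fitting into one linear solve — followed
by Gauss–Newton refinement of the orthogonal-distance criterion. The
algebraic stage is closed-form and deterministic; the refinement corrects
the mild bias the algebraic criterion has under radial noise. Point
clouds whose design matrix has a smallest singular value below $10^{-9}$
of the largest are rejected as coplanar: a circle in a plane constrains a
sphere only up to a one-parameter family.

A hinge axis is the line through two fitted condyle centers
(`fit_hinge_axis()`); its midpoint is the joint origin. The sagittal
plane is perpendicular to the segment joining the two propodeal-spiracle
sphere centers, through their midpoint (`define_sagittal_plane()`).

Coordinate systems follow the anatomical conventions:

* **thorax**: origin midway between the thorax/head and thorax/abdomen
  joint centers, $y$ anterior along that segment, $x$ the common
  perpendicular to the sagittal normal and $y$, $z$ completing a
  right-handed triad;
* **hinge joints**: origin at the axis midpoint, $z$ along the axis
  pointing medially, $y$ perpendicular to $z$ toward the previous
  segment's origin;
* **ball joints**: origin at the sphere center, $y$ toward the previous
  segment's origin (proximal), $x$ the common perpendicular to the
  sagittal normal and $y$.

Two signs are left free by these definitions and fixed here once:
the *medial* direction of a hinge $z$-axis is the sign whose dot product
with the vector from the axis midpoint to its orthogonal projection on
the sagittal plane is positive (this resolves consistently for both body
sides); the $x$-axis of thorax/ball frames is $\hat n \times \hat y$
normalized, with a `flip_x` switch for the opposite convention. All
frame constructors validate orthonormality and a $+1$ determinant to
$10^{-10}$ and are equivariant under rigid motion of their inputs, which
the tests exercise directly.

## The multibody model

Segments are rigid; joints have no clearance. Joint types are `free6`
(floating base: three translations plus three rotations), `ball3`
(intrinsic $x$–$y$–$z$ rotations named abduction, internal rotation,
flexion — matching the convention that abduction is positive about $x$,
internal rotation positive about $y$, and extension positive / flexion
negative about $z$), `hinge1` (flexion about the joint $z$) and
`locked0`. The intrinsic $x$–$y$–$z$ sequence is a choice: the
anatomical convention fixes signs and axis names but not an Euler order,
and this order applies the named rotations in the order the names are
listed.

A pose of the child segment is
$X_\text{child} = X_\text{parent}\, F_p\, J(q)\, F_c^{-1}$, with $F_p$
the joint frame in the parent, $J(q)$ the joint transform and $F_c$ the
joint frame in the child (identity by default: the child's body frame
*is* the joint frame at the reference pose). The coordinate layout is
deterministic — pre-order traversal of the tree, translations before
rotations, rotations in abduction/internal-rotation/flexion order — so a
pose vector has one well-defined meaning. Locked DOFs (for example
coxa/trochanter abduction and internal rotation on middle and rear legs)
exist in the model description, are reported as `NA` in ranges of motion,
and contribute no optimization variables.

ROM limits are given as a single maximum allowable span per DOF.
A span $R$ is interpreted as the neutral-centered interval
$[-R/2, +R/2]$: the least-informative reading of a single number, and
explicit min/max overrides are accepted wherever a joint is specified.
Limits are closed intervals; a value exactly at a limit is feasible.

Forward kinematics and the solver internals are compiled (Rcpp). The
analytic rigid-body Jacobian — $\partial x_k/\partial q_j = a_j \times
(x_k - o_j)$ for a rotational coordinate with instantaneous axis $a_j$
through $o_j$ on the marker's kinematic chain — is assembled directly
into Gauss–Newton normal equations, exploiting the tree sparsity. A
central-difference Jacobian is kept as an independent oracle and the two
are compared in the tests.

## Signal conditioning

Filtering is a fourth-order Butterworth low-pass at 5 Hz applied
forward–backward per coordinate channel. Zero-phase filtering is
standard in gait analysis because phase lag would bias joint-angle
timing; the documented side effect is that the effective order doubles
and the magnitude response squares. Edges use odd-reflection padding of
$3 \times$ the filter order with steady-state initial conditions, so
constants pass through exactly. Missing-data gaps of at most 10 frames
are linearly interpolated before filtering; channels with longer gaps
are flagged entirely missing and thereby excluded from IK (weight 0
behavior). Video-based tracking pipelines rarely document whether
their filtering is zero-phase; treating it as zero-phase is an explicit
assumption here.

Resampling is decimation when the rate ratio is an integer (300 to
100 Hz keeps every third sample — exact, given the signal is already
low-passed) and linear interpolation otherwise. Gait-cycle cropping
takes manually supplied half-open frame windows; automatic foot-off
detection is out of scope because cycle events come from video
inspection.

C3D support is a minimal reader/writer pair written here (no R package
for the format exists in this stack): Intel processor type, float or
scaled-integer point data, the POINT parameter group, units normalized
to mm, and invalid samples (negative residual words) mapped to missing
flags. TRC and a flat CSV complete the interchange surface.

## Scaling and inverse kinematics

Scale factors are per segment: the mean over frames and marker pairs of
the experimental inter-marker distance divided by the model's reference
distance; segments without measurable pairs inherit the parent's factor.
Scaling multiplies marker local positions and joint placement
translations (a placement is a length of the parent segment, so it uses
the parent's factor); rotations and ROM limits are untouched. The
field's workflows usually delegate scaling to external tools without
reporting parameters, so this distance-ratio definition is an assumption
the tests pin down on synthetic subjects with known factors.

Per-frame IK minimizes $\sum_i w_i \lVert x_i^{obs} -
x_i^{model}(q)\rVert^2$ subject to ROM bounds, with equal weights by
default. The solver is a projected Levenberg–Marquardt with an
active-set reduction: coordinates pinned at a bound with an outward
gradient are frozen and the damped step is solved in the free subspace
(plain clipping of full steps stalls at active bounds). Steps are
accepted only if the cost does not increase, so the cost is
non-increasing by construction. Stopping: zero cost (noiseless data), a
vanishing projected gradient, relative cost reduction below `ftol`
($10^{-10}$ by default) on two successive steps, or a *plateau* — mean
relative reduction below $10^{-5}$ over ten iterations. The plateau rule
exists because with two markers per segment some DOF combinations are
only marginally identifiable: the cost surface has near-degenerate
valleys along which a strict-tolerance solver would creep for thousands
of iterations while the fit itself is stationary at far below
measurement resolution. The solver reports the stopping reason, and an
observability warning is raised whenever the Gauss–Newton Hessian has an
eigenvalue below $10^{-8}$ of its largest. The default iteration budget
is 200 per frame; the Monte Carlo analyses raise it to 600, at which
point every perturbed iteration in the shipped analyses converges.

Frame 0 is solved with multi-start (the neutral pose plus seeded random
ROM-respecting offsets, each start first translating the base to align
marker centroids); subsequent frames warm-start from the previous
solution. The per-frame marker RMSE is $\sqrt{\sum_i w_i\lVert
\cdot\rVert^2 / \sum_i w_i}$ over non-missing markers; the *average
RMSE* is its arithmetic mean over frames, optionally normalized by a
body length supplied by the user. Range of motion is max minus min of
each DOF trajectory over the cycle.

## Monte Carlo uncertainty propagation

Two simulations, each propagating one source of model-parameter
uncertainty:

* **marker placement**: every model marker's local position is offset by
  an independent draw from the uniform distribution over a solid ball of
  radius 0.4 mm (a typical camera-calibration residual at this scale).
  "Uniform over a spherical zone" is read as uniform over the ball, not
  its surface: a zone is a region. Draws are made once per iteration and
  held fixed over the trial — this models placement/identification
  error, not per-frame tracking noise (a per-frame noise switch exists
  in the trial generator for exploration).
* **joint geometry**: ball-joint centers are offset by uniform-ball
  draws of radius 0.2 mm; hinge joints have their two axis-defining
  condyle points offset independently by uniform-ball draws of the same
  radius, which keeps the perturbed axis inside a cylinder of that
  radius around the nominal axis. Joint frames are then rebuilt from the
  perturbed geometry with the same constructors used at model-building
  time, so both the location and the orientation of each joint change.
  Realizing a cylindrical uncertainty zone through two endpoint balls
  is a design choice: a cylinder constraint alone leaves the sampling
  mechanism unspecified, and endpoint balls are the construction that
  both respects the cylinder bound and perturbs orientation.

Each iteration re-solves IK over the whole trial, warm-started from the
unperturbed baseline solution. Iterations that fail to converge on any
frame are dropped and logged, never imputed. Per-iteration substream
seeds derive deterministically from the master seed, so a given (seed,
inputs) pair yields bit-identical results. Per DOF and time step the
mean $\bar\theta(t)$ and standard deviation $\sigma(t)$ across
iterations are accumulated (Welford), and the coverage interval is the
band width $\Delta\theta(t) = 2\sigma(t)$. A coverage interval defined as twice the standard
deviation is ambiguous between a full band width of $2\sigma$ and
$\pm 2\sigma$; the default multiplier 2 (full width) is exposed as
`coverage_multiplier` so the alternative reading costs one argument. A
running group-mean SNR is recorded at twenty checkpoints so users can
judge stabilization of the averages — the criterion that justifies any
particular iteration count, including the 1000-iteration default.

The sensitivity statistic per DOF is
$\mathrm{SNR} = P_s / P_n$ with $P_s$ the peak-to-peak amplitude of
$\bar\theta(t)$ over the cycle and $P_n = \max_t \Delta\theta(t)$.
Locked DOFs and the six floating-base coordinates are excluded; a DOF
with $P_n = 0$ is reported as undefined (`NA`), never infinite.
`summarize_snr()` averages over the standard groups: all joints, body
sides, leg positions, and one row per anatomical joint.

## The synthetic hexapod and what it does (not) show

`make_synthetic_hexapod()` builds a 40-segment, 65-DOF floating-base
model in the ant's topology: thorax (free base), head and abdomen on
ball joints, a petiole hinge, and six legs of coxa (ball), trochanter
(ball, with abduction and internal rotation locked on middle and rear
legs), then femur, tibia, metatarsus and tarsus on hinges. The DOF
count decomposes as 6 (base) + 3 (head) + 1 (petiole) + 3 (abdomen) +
2×10 (front legs) + 4×8 (middle and rear legs) = 65. The petiole joint
is modeled as a hinge with a 40° span because its type and allowable
range are not covered by the reference ROM tables; whether the petiole
counts as a segment of its own changes the segment tally (39 versus
this fixture's 40), and the fixture does not claim fidelity on that
point. The metatarsus/tarsus joint is a hinge whose
center comes from a sphere fit, consistent with treating its flexion as
the single mobile DOF.

Geometric defaults are chosen once for anatomical plausibility at a
~6.6 mm body, typical of a medium-caste *Messor barbarus* worker — the
scale at which sub-millimeter uncertainty radii are meaningful
fractions of segment lengths: segment lengths 0.45/0.35/1.55/1.45/0.9/0.55 mm from coxa to
tarsus, legs splayed outward with the femur rising and the tibia
descending so the feet rest just above the ground plane, hinge condyle
separations of 0.44 mm (a realistic joint width at this body size — and
comfortably above twice the 0.2 mm perturbation radius, which keeps the
worst-case axis tilt $\arcsin(2r/L)$ finite), and two markers per
segment placed at roughly 30 % and 92 % of each segment with small
perpendicular offsets so that no segment's markers are collinear with
its joint center.

Gait trajectories are sums of sines: each leg DOF oscillates at the
cycle fundamental (default 1.39 s cycle, 100 Hz sampling) with a 30 %
second harmonic, amplitude a fraction (default 0.3) of its ROM
half-span, with the canonical tripod phasing — right-front, left-middle
and right-rear legs in phase, the opposite tripod delayed by half a
cycle; trunk joints oscillate at small amplitude (6°) and the base
translates forward at 3.4 mm/s, a realistic mean walking speed for a
freely foraging ant of this size, with a small vertical bounce tied to
the oscillation
amplitude so that a zero-amplitude specification is exactly static.
Generated series are validated against the ROM limits and rejected if
any frame violates them.

What passing tests on this generator demonstrate: the estimators and
the pipeline are correct — geometry fits recover their generators,
noiseless gaits are recovered to below 0.5° per DOF, coverage grows
monotonically with the perturbation radius, the SNR statistic matches
its closed forms, and the whole chain is deterministic under seeding.
What they do not demonstrate: fidelity to real ant data. The synthetic
gait has no foot-ground contact, no soft-tissue or exoskeleton
compliance, no tracking-loss patterns, and marker noise is isotropic.
Absolute SNR magnitudes are geometry-dependent; on this synthetic
geometry the group-average SNR under joint-parameter perturbation
(0.2 mm) comes out *below* the marker-perturbation SNR (0.4 mm),
whereas sensitivity analyses on real ant recordings at these radii have
reported joint perturbation to be markedly less influential than marker
perturbation. The divergence is unsurprising: at this body scale the
induced joint-frame orientation noise scales like (perturbation ÷
condyle separation), so the outcome hinges on joint widths and on how a
given implementation realizes location-and-orientation perturbations.
The package therefore treats the direction of that comparison as
data-dependent, not as an invariant.

## Numerical choices and degenerate inputs

* Sphere fits require ≥ 4 points and reject near-coplanar clouds
  (relative singular-value threshold $10^{-9}$).
* Coincident condyle or spiracle centers (< $10^{-9}$ mm apart) are
  degenerate; inside the Monte Carlo, a perturbation that collapses the
  two hinge points is resampled and counted.
* Frame constructors refuse y-directions parallel to the sagittal
  normal (angle below ~$10^{-6}$ rad) and previous origins on a hinge
  axis.
* The hinge medial sign is indeterminate when the axis midpoint lies on
  the sagittal plane or the axis is exactly perpendicular to the medial
  direction; the axis direction is then kept as given.
* IK needs at least enough non-missing markers for $3n \ge$ DOF count;
  under-determined frames are flagged and excluded from averages rather
  than solved.
* Internal angles are radians; every user-facing table and trajectory
  is degrees (mm for translations), converted only at the reporting
  boundary.

## Problem sizes in the shipped analyses

The test suite runs the full 139-frame, 65-DOF noiseless recovery; the
Monte Carlo properties use the same cycle sampled at 10 Hz (13 frames)
with 100 iterations over 10 seeds — a deliberate desk-scale reduction
of the full 1000-iteration design whose stabilization the running
SNR diagnostic makes checkable. `scripts/acceptance.R` reproduces the
whole pipeline at 300 Hz acquisition, 5 Hz filtering, resampling to
100 Hz, a 139-frame cycle, and both Monte Carlo simulations (radii
0.4 mm and 0.2 mm) with 100 iterations on the cycle resampled to 25 Hz.

## Known limitations

* No dynamics: no masses, forces, contacts or muscle models.
* No `.osim`/NMSBuilder interchange; models are built in R.
* Marker weights are equal by default and the scaling rule is an
  assumption (see above); both are explicit settings so sensitivity to
  them can be probed.
* The C3D support covers the marker-trajectory subset of the format
  only (no analog channels, no events, Intel byte order).
* With two markers per segment, marginal identifiability is intrinsic;
  the observability warning and the plateau stopping reason make it
  visible rather than hiding it.
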