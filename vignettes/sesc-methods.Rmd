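---
title: "Methods: statically equivalent serial chain CoM estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statically equivalent serial chain CoM estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sescom)
```

## The model

A human body is approximated as nine rigid segments: torso (with head and
neck merged in), left and right upper arms, forearms (with hands merged),
thighs, and shanks (with feet merged). The whole-body center of mass is
the mass-weighted mean of the segment CoM positions,

$$ C = \frac{1}{M}\sum_{i=1}^{9} m_i \left(A_i c_i + d_i\right), $$

with $A_i$ the global orientation of segment $i$, $c_i$ its local CoM
offset, $d_i$ its frame origin and $M$ the total mass. Because the frame
origins are themselves affine functions of the orientations (chained
through fixed attachment offsets), the sum telescopes into the end
effector of an open serial chain rooted at the torso:

$$ C = d_1 + A_1 r_1 + \sum_{i \ne 1} a_i\, r_i, $$

where $a_i$ is the third column of $A_i$ (the longitudinal segment axis)
and the $r$ parameters are fixed combinations of masses and geometry. Two
assumptions reduce the chain to seven unknowns:

* **on-axis limb CoMs** — each limb segment's CoM lies on the line joining
  its two joints, so its parameter is a scalar along $a_i$;
* **bilateral symmetry** — left and right limbs share masses and geometry,
  so mirror pairs share one parameter and the regressor sums their axes.

The reduced parameter vector is $R = (r_{1x}, r_{1y}, r_{1z}, r_2, r_3,
r_6, r_7)$: a torso 3-vector (in torso-local axes, so it is constant while
the subject moves) and one scalar per limb-pair level (upper arm,
forearm+hand, thigh, shank+foot). In closed form, with $\ell$ the
proximal segment length and $d_{1j}$ the attachment offsets in the torso
frame,

$$ r_1 = \tfrac{1}{M}\big(c_1 m_1 + d_{12}(m_2{+}m_3) + d_{14}(m_4{+}m_5)
        + d_{16}(m_6{+}m_7) + d_{18}(m_8{+}m_9)\big), $$
$$ r_2 = \tfrac{c_2 m_2 + \ell_2 m_3}{M},\quad
   r_3 = \tfrac{c_3 m_3}{M},\quad
   r_6 = \tfrac{c_6 m_6 + \ell_6 m_7}{M},\quad
   r_7 = \tfrac{c_7 m_7}{M}. $$

Each proximal attachment must carry the *distal chain's* mass
($m_2{+}m_3$ at the shoulder, not the torso's own): `sescom` verifies this
grouping with an exact equivalence test — `estimate_com()` on
`true_sesc_from_model()` must reproduce `whole_body_com_direct()` to
below $10^{-9}$ m for arbitrary symmetric bodies and postures, and the
alternative grouping fails that test by orders of magnitude.

### Frame conventions

The global frame has $x$ anterior, $y$ medio-lateral pointing toward the
subject's right, $z$ vertical up; the ground plane is $z = 0$. Each
segment's local $z$-axis runs from its proximal to its distal joint, so
limb CoM offsets are $(0, 0, c_z)$. The model root is the mid-hip point;
the torso frame takes $z$ from mid-hip toward the neck and $y$ along the
left-hip-to-right-hip direction. Users mapping depth-camera "torso"
joints should remap their root to mid-hip accordingly.

## Identification

During calibration the subject holds a set of static postures on a force
platform. At rest the center of pressure equals the CoM ground
projection, so each static window supplies the $x$ and $y$ components of
$C - d_1$. Per window, the regressor block is $2 \times 7$: the $x,y$
rows of $A_1$, then the $x,y$ components of the four limb-pair axis sums.
Stacking $m$ windows (all $x$ rows, then all $y$ rows) gives
$y = D R$, solved by the Moore–Penrose pseudo-inverse. Only ground-plane
rows are observed, yet $r_{1z}$ and the limb scalars are identified
because tilted postures rotate vertical axes into the ground plane.

Numerical choices:

* the pseudo-inverse uses SVD with a relative singular-value cutoff of
  $10^{-10}$; numerical rank below 7 raises an error naming the rank and
  condition number (the postures did not excite all parameters), with an
  explicit override returning the minimum-norm solution;
* window averaging precedes regressor construction; averaged orientation
  matrices are re-orthonormalized by nearest-rotation (SVD Procrustes)
  projection, with the determinant sign corrected so the result is a
  proper rotation;
* measurements are kept in meters internally; reports are in millimeters.

A practical note on how many postures to collect: rank 7 is reachable
from four generic postures (two rows each), and conservative
rules of thumb in the calibration literature ask for considerably more
(orders of 10–40) to average down noise. The implementation enforces the
rank condition, not a posture count; more varied postures always help
conditioning.

## Identification quality

With $W = D$, $r$ rows and $c = 7$ columns, the package reports:

* `cond(D)` $= \sigma_{\max}/\sigma_{\min}$ — excitation/conditioning
  indicator; the grading threshold defaults to 20, chosen to bound the
  range observed on well-executed 40-posture calibrations (roughly 5–13)
  with margin;
* $\sigma_\rho^2 = \lVert y - D\hat R\rVert^2 / (r - c)$ — residual
  variance; the degrees of freedom use rows minus columns, i.e. $2m - 7$;
* $C_{\hat R} = \sigma_\rho^2 (D^\top D)^{-1}$ (via SVD), per-parameter
  $\sigma_j$, relative standard deviations $100\,\sigma_j/|\hat R_j|$ and
  their ratios $k_j$ to the smallest one — $k_j > 10$ flags a poorly
  identified parameter;
* a two-sided $t$-test of $\hat R_j = 0$ with $r - c$ degrees of freedom
  (the standard linear-regression coefficient test, which is the natural
  reading of "a t-test on the identified parameters"); $p > 0.01$ flags
  insignificance. A zero estimate with nonzero $\sigma$ reports an
  infinite relative standard deviation and is flagged rather than
  dropped.

Relative standard deviations are meaningful relative to each other; only
the $k > 10$ and $p > 0.01$ rules are absolute decisions. On simulated
noisy calibrations the forearm parameter $r_3$ systematically shows the
largest $k$: it weighs an order of magnitude less than the thigh
parameter, so the same absolute uncertainty is relatively much larger —
the test suite asserts this as a median-$k$ ordering over 100 replicates.

## Preprocessing

Real streams arrive time-stamped on independent clocks.
`resample_series()` linearly interpolates every channel onto a shared
uniform grid (15 Hz default) over the overlapping span. Linear
interpolation is exact for affine signals and adequate for postural
signals a decade below the grid rate; it is *not* band-limited
reconstruction, and the suite checks its fidelity on a 0.25 Hz sine
sampled at a jittered 24 Hz (max deviation $<10^{-3}$ of amplitude),
which brackets the quasi-static content the method relies on.

`zero_phase_lowpass()` applies a second-order Butterworth filter (5 Hz
cutoff default) forward and backward (`signal::filtfilt`), giving zero
net phase and a squared magnitude response (gain $1/2$ at the cutoff).
The input is extended by odd-symmetric reflection — $10/f_c$ seconds per
end — so startup transients decay outside the retained span; without
padding, a constant stream would show edge bias.

`detect_static_windows()` slides a 1-s window one sample at a time. A
window is static when the per-axis CoP standard deviation is strictly
below 3 mm *and* every segment's orientation dispersion — the standard
deviation of the geodesic angle to the window's mean rotation — is
strictly below 5°. Overlapping static windows are merged; a settle margin
(0.5 s default) is trimmed from both ends of each merged interval before
averaging, because the beginning and end of a hold pass under the
dispersion thresholds while the subject is still drifting into position;
merged intervals shorter than one window after trimming are dropped. The
CoP threshold is applied per axis (configurable), and thresholds act on
dispersion, never absolute position, so detection is
translation-invariant.

`joints_to_posture()` reconstructs orientations from 15 named skeleton
joint positions: limb $z$-axes from proximal→distal bone vectors,
completed to rotations by deterministic Gram–Schmidt against the global
vertical (global $x$ as fallback for vertical bones); the torso frame as
described above. Coincident joints raise an error naming the bone. Only
bone directions matter downstream: the regressor uses limb $z$-axes and
the full torso orientation, both of which the reconstruction recovers
exactly for consistent data.

## The literature comparator

`winter_body_model()` scales a shipped anthropometric table (Winter's
segment mass fractions, segment-length fractions of stature, and CoM
fractions) to a subject's height and mass; `literature_sesc()` converts
it to height-normalized SESC parameters, which are mass-independent
because mass fractions cancel. Merging choices that pin the shipped
constants:

* the foot is a point mass (1.45% of body mass) at the ankle; this
  reproduces the published shank+foot parameter $r_7 = 0.0085$, whereas
  placing the combined leg-foot CoM at 0.606 of shank length yields
  0.0091 and was rejected;
* the forearm+hand row (2.2% mass, CoM at 0.682 of forearm length)
  reproduces $r_3 = 0.0022$, and the thigh row reproduces $r_6 = 0.0256$;
* the upper-arm constants give $r_2 = 0.00636$, which rounds to 0.0064
  against a published 0.0063 — a rounding/length-convention discrepancy
  in the source that we document rather than absorb by tuning; $r_2$ is
  therefore not used as an exact check;
* the torso geometry (torso length 0.288 of stature, trunk+head CoM at
  0.626 of torso length, shoulder span 0.259, hip span 0.191) is needed
  only for the torso parameter and the simulator's skeleton; it yields
  $r_{1z} \approx 0.133$, close to the published 0.1342, whose exact
  torso-frame conventions are not recoverable — the computed value is
  reported, not asserted.

## The virtual-subject simulator

`generate_subject()` perturbs each merged-segment mass fraction and CoM
fraction by $1 + \delta u$, $u \sim U(-1,1)$ (left/right tied, fractions
renormalized), emulating subjects who depart from the tables;
$\delta = 0.2$ produces clearly subject-specific bodies.
`generate_session()` renders stratified static holds — hold families
rotate between arm-dominant, leg-dominant, trunk-lean and mixed ranges,
emulating an examiner guiding varied calibration postures — each held 5 s
at 15 Hz by default, joined by 1-s smoothstep transitions. Consecutive
holds are redrawn until at least one segment changes orientation by 60°
or more, mirroring the protocol requirement that every segment's
orientation be varied; this also guarantees that transitions register as
movement to the static detector. The true CoM is computed per sample by
direct mass-weighted summation; the CoP equals its ground projection plus
noise.

Noise presets: `"vicon_like"` (0.5° orientation, 1 mm CoP, 2 mm root) and
`"kinect_like"` (5°, 3 mm, 15 mm). Orientation noise is a per-sample
random rotation with angle $|N(0, \sigma)|$ and uniform axis. What the
generator does **not** emulate: temporally correlated sensor error,
depth-camera occlusion and skeleton-swap artifacts, balance-board
load-dependent bias, and the physiological CoP–CoM difference (which is
proportional to CoM acceleration and nonzero even in careful holds). By
construction the CoP is exactly the CoM projection during noiseless
holds, so passing tests validate the estimation pipeline, not the CoP≈CoM
approximation on real subjects; published whole-session errors on real
hardware (tens of millimeters for depth-camera tables) are larger than
the simulator's, and the package reproduces their *ordering*, not their
absolute magnitudes.

All randomness derives from one session seed through named Lehmer
sub-streams, so posture scripts and noise can be regenerated
independently and fixture bundles are byte-stable.

## Evaluation protocol

`split_identification_validation()` makes a seeded disjoint split (40
identification windows by default). `evaluate_estimates()` reports the
planar rmse (root mean square of residual norms, so
$\text{rmse}^2 = \text{AP}^2 + \text{ML}^2$), per-axis AP/ML rmse, and
$R^2$ computed per axis against the CoP and averaged across the two axes
(a min-axis alternative is available; the aggregation is configurable
because a single published $R^2$ does not determine it). $R^2$ is not
clamped: estimators worse than the CoP mean go negative.
`compare_methods()` runs the full protocol on a virtual session using the
generator's per-hold labels to form windows — the same per-posture
averaging the sliding-window detector produces, keyed to ground truth,
which keeps 100-seed Monte Carlo studies fast while the detector itself
is exercised end-to-end by the noiseless-recovery and overlap tests.
Where several sessions are compared, per-session rmse values are averaged
(rather than pooling postures across sessions).

## Problem sizes and runtime choices

The shipped checks use: 1000 random bodies/postures for the chain
identity; one 40-hold noiseless session through full sliding-window
detection for end-to-end recovery; 100 virtual subjects × two noise
presets × 80-hold sessions (40/40 split) for the subject-specificity
ordering; 80×7 systems against the `lm()` oracle for diagnostics; and
100 25-hold replicates for the $k$-ordering property. These sizes give
stable Monte Carlo fractions (the ordering holds in ≥95% of seeds) while
the whole suite completes in a few minutes on one CPU.

## Known limitations

* Static, kinematic model only: no inertia tensors, no dynamics, no
  multi-surface identification for restricted-mobility protocols.
* Batch identification; no online/recursive update.
* The bilateral-symmetry and on-axis assumptions are structural: subjects
  with strongly asymmetric mass distributions (e.g. unilateral
  amputation) violate the 7-parameter reduction.
* Anthropometric tables ship without age/sex/fitness adjustment; the
  package's answer to that bias is calibration, not table correction.
* The simulator's noise is i.i.d. per sample; real depth-camera error is
  temporally correlated, so real calibrations need more postures than the
  simulator suggests for the same parameter uncertainty.
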