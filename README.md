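# sescom

Subject-specific whole-body center-of-mass (CoM) estimation via the
statically equivalent serial chain (SESC).

## The problem

The trajectory of the whole-body CoM is a standard metric of postural
stability: during quiet stance and functional reach, its ground projection
must stay inside the base of support. The classical way to compute it — the
segmentation (kinematic) method — mass-averages per-segment CoM positions
using anthropometric tables compiled from cadavers and young, fit adults.
Those tables misrepresent elderly, obese, or neurologically impaired
subjects, and the resulting CoM error is exactly where clinical assessment
needs accuracy most.

`sescom` implements a calibration-based alternative. For any rigid
multi-body chain, the CoM can be written as the end effector of an open
serial chain attached to one root segment (here the torso), whose constant
parameter vector encodes the subject's true mass distribution:

    C = d1 + A1 r1 + (a2 + a4) r2 + (a3 + a5) r3 + (a6 + a8) r6 + (a7 + a9) r7

where `d1` and `A1` are the torso origin and orientation, `a_i` is the
global direction of segment *i*'s longitudinal axis, and
`R = (r1, r2, r3, r6, r7)` collects seven constants (a 3-vector for the
torso, scalars for the upper-arm, forearm+hand, thigh and shank+foot
left/right pairs, assuming on-axis limb CoMs and bilateral symmetry).
During a short calibration the subject holds a series of static postures on
a force platform; each static window contributes two rows relating the
measured center of pressure (CoP, which equals the CoM ground projection at
rest) to the segment orientations:

    CoP_xy - d1_xy = D R

and `R` is identified by Moore–Penrose least squares. After calibration the
CoM follows from orientations alone — no force plate, arbitrary (including
dynamic) movement, and it works with low-cost skeleton sensors (depth
cameras) as well as marker-based capture.

The package provides the nine-segment body model and forward kinematics,
the SESC reduction/identification/estimation chain, identification-quality
diagnostics (regressor condition number, per-parameter relative standard
deviations, k-ratios, significance t-tests), sensor-stream preprocessing
(resampling, zero-phase Butterworth filtering, static-window detection,
skeleton-joint-to-orientation conversion), a Winter anthropometric-table
comparator, a virtual-subject simulator with marker-grade
(`"vicon_like"`) and depth-camera-grade (`"kinect_like"`) noise presets,
and a cross-validation evaluation protocol.

## Worked example

Simulate a subject whose mass distribution deviates 20% from the
anthropometric tables, calibrate from 60 static holds, and compare the
identified estimator with the table-based one on 20 held-out postures:

```r
library(sescom)

subject <- generate_subject(seed = 42, height = 1.76, mass = 76.1,
                            deviation = 0.2)
session <- generate_session(subject, n_holds = 80,
                            noise = noise_profile("kinect_like"), seed = 42)

cmp <- compare_methods(session, n_identify = 60, split_seed = 42)
cmp$reports$sesc_identified
#> <evaluation_report> n = 20: rmse 3.36 mm (AP 2.59, ML 2.15), R^2 = 0.997
cmp$reports$literature
#> <evaluation_report> n = 20: rmse 14.34 mm (AP 13.13, ML 5.76), R^2 = 0.953

cmp$diagnostics
#> <identification_diagnostics> cond(D) = 11.11, sigma_rho = 0.001984 m, dof = 113
#>  parameter   estimate     sigma rel_std_pct       k    p_value
#>       r1_x -0.0009650 0.0006669     69.1100 115.200  1.507e-01
#>       r1_y  0.0004246 0.0002648     62.3500 104.000  1.116e-01
#>       r1_z  0.2057000 0.0012330      0.5998   1.000 4.880e-137
#>         r2  0.0132400 0.0004148      3.1330   5.224  2.310e-58
#>         r3  0.0059660 0.0003156      5.2910   8.821  8.797e-37
#>         r6  0.0450300 0.0005895      1.3090   2.183  4.258e-99
#>         r7  0.0158600 0.0006030      3.8010   6.337  5.300e-50
#>               flag
#>  poorly identified
#>  poorly identified
```

The identified estimator cuts the validation error of the literature table
roughly four-fold even under depth-camera-grade noise; the regressor is
well conditioned (`cond(D)` ≈ 11, below the warning threshold of 20); and
the vertical torso and thigh parameters — which dominate the CoM — are
identified with about 1% relative uncertainty, while the two horizontal
torso components (true values near zero for a bilaterally centered trunk)
are flagged as poorly identified and fail the significance t-test, exactly
the behavior the k-ratio and p-value diagnostics exist to expose.

With real recordings the same workflow runs from CSV streams, either in R
(`cmd_identify()`, `cmd_estimate()`) or from a shell via the thin wrapper:

```sh
Rscript exec/sesc simulate --out session/ --n-holds 40 --noise kinect_like
Rscript exec/sesc identify --skeleton session/skeleton.csv \
    --cop session/cop.csv --out params.json --report report.json
Rscript exec/sesc estimate --params params.json \
    --skeleton session/skeleton.csv --out com.csv
```

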