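# adaptahrs

Orientation estimation from 9-axis inertial measurement units (IMUs) in
movement that is hostile to the usual sensor-fusion assumptions —
wheelchair sports being the motivating case, where every push produces
linear accelerations of a large fraction of gravity and the chair carries
magnetized material that disturbs the local field.

## Who this is for

Biomechanists and sports scientists who estimate body-segment orientation
(here: trunk inclination relative to the wheelchair) from one IMU per
segment, validate against optical motion capture, and need the estimate to
survive sprints, turns and collisions rather than only quiet standing.

## The method

The core estimator is the gradient-descent complementary (Madgwick) MARG
filter. Per sample,

    q_t = normalize( q_{t-1} + (dq_gyro,t - beta * dq_am,t) * dt )

where `dq_gyro = 0.5 q (x) (0, omega)` integrates the gyroscope and
`dq_am` is one gradient-descent step toward the orientation implied by the
measured gravity and magnetic-field directions, normalized to unit
magnitude so the gain `beta` alone sets the correction size.

The package's contribution-level machinery makes `beta` *adaptive*: a
classifier trained on raw IMU signals predicts, per sample, whether the
accelerometer/magnetometer-implied ("earth-frame") orientation is
currently trustworthy. Predictions decode to `beta_high = 0.9635`
(snap to the earth frame, killing drift) or `beta_low = 0.0015`
(essentially gyro-only, ignoring the corrupted earth frame). Around this
sit:

* pre-processing: hard-iron sphere calibration, startup gyro-bias zeroing,
  spline resampling to 100 Hz, marker-gap interpolation, cluster frames,
  cross-correlation time alignment of IMU and optical systems;
* kinematics: signed helical trunk-inclination angle relative to a
  neutral pose (flexion positive);
* trust-label generation (`EFcorrect`, `EFcorrect_S5`), leave-one-
  subject-out feature ranking, the 4-algorithm × 2-label × 5-feature-set
  model grid, validation-based model selection and gain grid search;
* agreement analysis (mean error, MAE, RMSE, Pearson r, Bland–Altman
  limits) partitioned into fixed- and free-wheelchair conditions;
* a seeded two-sensor session simulator with exact ground truth, so the
  whole pipeline is testable without any recordings.

## Worked example

```r
library(adaptahrs)

session <- generate_session(session_config(seed = 42))  # synthetic two-sensor session
prep    <- prepare_session(session)                     # calibrate, resample, align, label
prep
#> <prepared_session> S01: 6951 aligned samples, lag 48, threshold 1.93 deg, 48.1% trusted

cfg   <- adaptive_config()                              # beta_high 0.9635, beta_low 0.0015
orig  <- session_inclination(prep, beta = 0.033)        # fixed-gain filter
sched <- decode_beta(prep$labels$efcorrect, cfg)        # oracle-label gain schedule
ext   <- session_inclination(prep, beta = sched)        # adaptive filter

masks <- partition_masks(prep$annotations)[c("fixed_wheelchair", "free_wheelchair")]
agreement_table(list(original = orig, extended = ext), prep$ref, masks)
#>          condition   filter    n mean_error  mae rmse pearson_r ba_loa_low ba_loa_high
#> 1 fixed_wheelchair original 4151      1.147 1.43 3.14     0.975      -4.58        6.87
#> 2 fixed_wheelchair extended 4151      0.258 1.05 1.26     0.996      -2.17        2.68
#> 3  free_wheelchair original 2739      1.859 8.11 9.54     0.360     -16.48       20.20
#> 4  free_wheelchair extended 2739      1.798 2.15 2.91     0.763      -2.69        6.28
```

Reading the table: while the wheelchair is fixed (wheels blocked) the two
filters are close; while it moves freely the fixed-gain filter is dragged
by the corrupted earth-frame estimate (RMSE 9.5°, correlation 0.36 with
the optical reference) whereas the adaptive schedule stays at 2.9° RMSE —
the qualitative signature the method is built around. The `lag` is the
recovered inter-system clock offset (samples at 100 Hz); the labelling
threshold is `1° + noise` with the noise estimated from the 20-s neutral
pose.

Classifier training end to end (cohort directories written by
`cmd_simulate`, model selection on validation subjects) is available both
as R functions (`train_trust_classifier()`) and through the thin CLI in
`inst/cli/adaptahrs` (`simulate`, `filter`, `train`, `evaluate`
subcommands).

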