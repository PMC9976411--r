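# needlenav

Registration, guidance geometry and Monte-Carlo accuracy simulation for
fiducial-based augmented-reality (AR) needle navigation.

## The problem

Transperineal prostate procedures (biopsy, focal ablation, brachytherapy
seed placement) traditionally guide needles through a rigid grid
template, which restricts trajectories to parallel paths at fixed
spacing. AR head-mounted displays remove that constraint: annotated
anatomy and needle plans from preprocedural MRI/CT are superimposed on
the patient through a tracked, fiducial-bearing *patient reference
frame*, and a tracked *needle reference frame* makes the needle itself a
live digital object. The accuracy of such a system rests on a chain of
rigid transforms

```
T_image->device  =  T_image->frame  x  T_frame->device
```

where `T_image->frame` comes from point-to-point rigid registration of
fiducial markers localized in the volumetric image against their
caliper-measured frame coordinates, and the frame and needle poses are
tracked optically.

`needlenav` implements that computational core for desk-scale analysis:

* **geometry** — rigid transforms between named coordinate spaces
  (IMAGE, PATIENT_FRAME, NEEDLE_FRAME, WORLD, CAMERA, SNAPSHOT_2D),
  composition, inversion, JSON serialization.
* **registration** — the least-squares (Kabsch/Umeyama SVD) rigid fit
  as a classed model object, the fiducial registration error
  `FRE = sqrt(mean(||T x_i - y_i||^2))`, the fiducial localization
  error inversion `FLE = FRE * sqrt(N/(N-2))` from
  `E[FRE^2] = (1 - 2/N) FLE^2`, and target registration error (TRE)
  prediction by the closed-form
  `TRE^2(r) = FLE^2/N * (1 + (1/3) * sum_k d_k^2/f_k^2)` or Monte
  Carlo (the default — the frame's fiducials are coplanar, where the
  closed form is ill-conditioned).
* **scene** — physical models of the 7-fiducial patient frame
  (95x70 mm window, 90x80 mm plate at 60 deg), the 20-cm needle with
  its 50x50 mm plate at 45 deg, bead phantoms and insertion plans.
* **guidance** — the planned-path and free-hand guidance methods as
  pure state machines (tip-target distance, angular deviation,
  predicted miss, depth remaining, 5-mm proximity display states).
* **simulator** — seeded Monte-Carlo reproductions of three phantom
  accuracy experiments: image overlay error, visual needle-targeting
  error and needle-placement error, with every noise source (fiducial
  localization, caliper, frame/needle tracking, operator) an explicit
  sigma.
* **stats** — the accompanying analysis plan: Shapiro-Wilk-gated
  Student's t / Mann-Whitney comparisons, one-way ANOVA, and t-tests
  recomputed from printed summary statistics.

## Worked example

Register the patient frame's caliper coordinates to noisy localized
marker positions, budget the induced target error, and simulate a
placement session:

```r
library(needlenav)
frame <- build_patient_frame()

set.seed(1)
t_true <- rigid_transform(rotation_axis_angle(c(0.2, 1, 0.1), 25),
                          c(40, -12, 8), "PATIENT_FRAME", "WORLD")
measured <- fiducial_set(frame$fiducials$labels,
                         transform_points(t_true, frame$fiducials$points) +
                           matrix(rnorm(21, 0, 0.55), 7, 3),
                         "WORLD")
fit <- register_fiducials(frame$fiducials, measured)
summary(fit)
#> Rigid point-to-point registration (PATIENT_FRAME -> WORLD)
#>   fiducials: 7  FRE: 0.7435 mm
#>   rotation 24.832 deg, translation 42.559 mm
#>   FLE estimated from FRE: 0.8797 mm
#>   per-fiducial residuals (mm):
#>     F1     F2     F3     F4     F5     F6     F7
#> 0.2987 0.6384 0.7013 1.2738 0.2938 0.5660 0.9228
```

The fit recovers the simulated 25-degree pose; the 0.74-mm FRE is the
RMS residual over the seven markers, and the FLE estimate inverts the
`(1 - 2/N)` identity. A prostate-depth target 80 mm behind the working
window then carries:

```r
predict_tre(frame$fiducials, estimate_fle_from_fre(fit$fre_mm, 7),
            c(0, 35, 80), method = "MONTE_CARLO", n_reps = 5000, seed = 2)
#> Predicted TRE (MONTE_CARLO): 1.1970 mm RMS at (0, 35, 80) mm, FLE 0.8797 mm
```

i.e. registration alone displaces that target by about 1.2 mm RMS.
A full simulated placement session (3 operators, 4 targets, both
guidance methods, the calibrated full-chain noise model):

```r
tr <- run_simulate("placement", default_run_config(), seed = 11)
summarize_values(tr$error_mm[tr$method == "PLANNED_PATH"])
#> 3.96 +/- 1.93 (n = 12)
summarize_values(tr$error_mm[tr$method == "FREE_HAND"])
#> 3.42 +/- 1.42 (n = 12)
```

Placement errors land around 3.5-4 mm: the system error (~1-2 mm) plus
the simulated operator's aiming and depth-decision noise.

A command-line wrapper is installed at `inst/cli/needlenav` with
subcommands `register`, `simulate`, `calibrate-fle`, `stats` and
`make-scene`.

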