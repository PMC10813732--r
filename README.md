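# drinksense

Hierarchical fluid-intake assessment from inertial sensors, for
researchers comparing **wrist-worn** and **smart-container** (cup-mounted)
IMU placements. The package implements the full analysis chain —
drinking-gesture recognition followed by intake-volume estimation — and a
seeded synthetic session generator that emulates the 12-participant
drinking protocol (7 fill levels × 3 sip sizes × 4 repetitions = 1008
events at 128 Hz) on which such pipelines are studied.

## The method

**Gesture recognition.** Tri-axial acceleration a, angular velocity ω,
angular acceleration ω̇ (central differences) and per-axis inclination
θᵢ = arccos(aᵢ/‖a‖) are segmented by sliding windows (sizes 16–56
samples, overlaps 25–87.5 %). Each window yields 96 features (8 statistics
× 12 channels) classified by an RBF-kernel SVM into the five phases
*grasp → pre-sip → sip → post-sip → release* (three container-side
phases). A run-length postprocessor rewrites any interior run of ≤ 2
fragments flanked by agreeing neighbors to the preceding label.

**Volume estimation.** From the recognized *sip* segment, 64 features
(duration, per-direction average/maximum/integral of inclination, and
threshold-exceedance counts at 10°–90° and at 10–90 % of the segment
maximum) feed ε-SVR models (linear and Gaussian kernels): one *general*
model, or three *sip-size-dependent* models (small/medium/large), each
with or without the fill level as a 65th feature. The fill level itself is
regressed from the *pre-sip*..*post-sip* span. Everything is scored by
leave-one-subject-out (LOSO) cross-validation with sensitivity, precision,
F1 and accuracy for classification and MAPE, MAD, RMSE and R² for
regression.

## Worked example

```r
library(drinksense)
study <- run_full_study(drink_protocol(seed = 11))   # ~3 min, 1 CPU
print(study)
```

```
Fluid-intake assessment study: 1008 events, seed 11
  wrist gesture accuracy: 0.9426 raw, 0.9448 postprocessed
  container gesture accuracy: 0.9566 raw, 0.9570 postprocessed
  wrist fill level (linear SVR): MAPE 10.80% | MAD 22.43 g | RMSE 28.42 g | R2 0.919 | n = 1008
  container fill level (linear SVR): MAPE 8.95% | MAD 19.12 g | RMSE 25.63 g | R2 0.934 | n = 1008
  wrist volume general: MAD 9.12 g RMSE 12.16 g
  wrist volume by_size: MAD 2.87 g RMSE 4.07 g
  container volume general: MAD 8.68 g RMSE 10.94 g
  container volume by_size: MAD 2.80 g RMSE 3.84 g
```

Reading this: both placements recognize gestures at comparable accuracy,
with postprocessing helping the noisier wrist arm more; the
container-mounted sensor estimates the fill level better than the wrist
(its tilt directly encodes how far an emptier cup must be tipped); and
sip-size-dependent regressors cut the volume error to roughly a third of
the general model's MAD — the sip-size information, not the kernel, is
what matters. `study$combination` additionally crosses true vs recognized
sip segments with true vs estimated fill levels and shows recognition
errors propagating into slightly larger volume errors.

Datasets serialize to plain text (`write_dataset()`/`read_dataset()`:
one CSV per sensor stream, one JSON per event), and
`inst/cli/drinksense.R` wraps generation, the full study and the
window/overlap grid study for shell use:

```sh
Rscript inst/cli/drinksense.R generate --out data/ --seed 7
Rscript inst/cli/drinksense.R run --out reports/ --seed 7
```

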