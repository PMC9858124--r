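# tremorclass

Binary detection of pathological tremor — *Tremor* vs *No Tremor* — from
one-second windows of wearable-sensor signal, with no hand-crafted
features. The package targets the detection stage of closed-loop
peripheral electrical stimulation (PES) systems, where a stimulator must
decide, second by second, whether an essential-tremor patient's wrist is
currently trembling.

Three input modalities are supported, mirroring a typical recording setup
(hand + forearm IMUs, bipolar surface EMG on the wrist flexor FCR and
extensor ECR):

| modality | rate | window | derivation |
|---|---|---|---|
| wrist flexion–extension angle | 50 Hz | 50 samples | relative IMU quaternion, intrinsic X-Y′-Z″ Euler |
| EMG envelope | 50 Hz | 50 samples | rectify → 4–10 Hz zero-lag Butterworth → downsample |
| raw EMG | 510 Hz | 510 samples | anti-aliased downsampling from 2042 Hz |

Windows are auto-labelled by a tremor-band power-spectral-density rule:
a window is *Tremor* iff the maximum of its Hann periodogram over 4–10 Hz
strictly exceeds a threshold calibrated as the 99th percentile of the
no-tremor peak-power distribution,

```
label(w) = Tremor  ⇔  max_{4 ≤ f ≤ 10} PSD_w(f) > q_0.99(no-tremor peaks).
```

Four classifier families are trained on the flat window samples:
distance-weighted KNN, RBF-kernel SVM and random forests (tuned by
stratified 10-fold cross-validated grid search on mean F1), and a
two-layer LSTM (hidden sizes 20/35/50, Adam, binary cross-entropy,
validation-loss checkpointing) whose linear readout consumes the last
hidden state of the second layer — implemented from scratch in
RcppArmadillo with gradients verified against finite differences.
Evaluation reports precision, recall, specificity, accuracy and F1
(Tremor positive).

Because no public dataset exists for this task, the package ships a
first-class synthetic cohort generator (12 patients, 11 controls, 60-s
postural trials) with known ground truth: kinematic tremor as a jittered
4–10 Hz sinusoid of 2–8° over postural drift, EMG as amplitude-modulated
band-limited Gaussian noise with antiphase FCR/ECR burst trains, an
8–12 Hz physiological-tremor distractor in controls, and matched RMS
levels so no trivial power cue separates the classes. Real recordings
with the same schema enter through CSV readers.

## Worked example

```r
library(tremorclass)
cfg <- cohort_config(seed = 42)          # 12 patients, 11 controls, 60-s trials
cohort <- generate_cohort(cfg, "kinematics")
kin <- build_kinematics_dataset(cohort)  # angle windows + PSD-threshold labels
print(kin$threshold)
#> Tremor labelling threshold: 0.08839 (q0.99 of 660 no-tremor peak powers)
print(kin)
#> <labeled_window_set/window_set> 1380 windows of 50 samples (50 Hz, kinematic-angle)
#> no_tremor    tremor
#>       653       727

mean((kin$labels == "tremor") == (kin$design_label == "tremor"))
#> agreement with design labels: 99.5%

bal <- assemble_balanced(kin, 600, seed = 42)
res <- evaluate_modality(bal, "kinematics", families = c("knn", "lstm"),
                         seed = 42)
print(res$reports$knn)
#> Metrics [knn / kinematics]: precision 0.994  recall 0.978  specificity 0.994  accuracy 0.986  f1 0.986
print(res$reports$lstm)
#> Metrics [lstm / kinematics]: precision 1.000  recall 0.989  specificity 1.000  accuracy 0.994  f1 0.994
```

The threshold sits just above the strongest healthy-control windows (the
8–12 Hz physiological distractor overlaps the top of the labelling band),
so ~1 % of control windows are labelled *Tremor* by construction and the
remaining disagreement with ground truth is exactly that calibration
rate. `run_tremor_study()` runs the full pipeline — cohort generation,
preprocessing, labelling, balanced assembly (up to 9000 windows per class
for kinematics, 4000 per EMG modality), 70/30 and 70/15/15 stratified
splits, all four families on all three modalities — and returns the
model × modality comparison (`compare_reports()`, `plot_metric_bars()`).

## Layout

- `R/` — cohort simulation, quaternion kinematics, EMG preprocessing,
  PSD labelling, datasets/splits, models, evaluation, CSV/JSON I/O
- `src/lstm.cpp` — LSTM forward/BPTT/Adam and a Chebyshev distance kernel
- `vignettes/tremor-detection-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations
- `tests/testthat/` — unit, property and acceptance suites
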