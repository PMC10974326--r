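# bedbeat

Heartbeat detection from bed-mounted accelerometers, for researchers in
unobtrusive vital-sign monitoring (ballistocardiography, sleep sensing,
digital health).

A 3-axis accelerometer fixed to a bed frame records the micro-recoil of
the body at every heartbeat, strongest along the head–foot (X) axis; a
finger photoplethysmograph (PPG) recorded in parallel marks the true beat
times. `bedbeat` implements the full analysis pipeline around this setup:

1. **Simulation** — multi-participant synthetic studies (per-participant
   heart rate, four lying positions, beat transients, respiration, noise,
   and a co-registered pulse channel with known ground truth), since no
   public dataset exists for this problem.
2. **Preprocessing** — zero-phase Butterworth bandpass, 0.5–20 Hz, on all
   four channels; rectified first differences Δ = |x[i+1] − x[i]|.
3. **Windowing and features** — non-overlapping 125-sample windows (0.5 s
   at 250 Sa/s); 12 features per window (sum / population std / max per
   axis, plus the same statistics of the X first-difference magnitude).
4. **Labels** — window *w* is positive iff a PPG peak (prominence-filtered
   local maximum with a 0.3 s refractory separation) falls inside it.
5. **Model comparison** — LR, LDA, KNN, CART, naive Bayes, RBF-SVM, a
   100-tree random forest and a 12→9→9→1 ReLU/sigmoid MLP (SGD, learning
   rate 0.1, 100 epochs, batch 10), all behind one fit/predict contract,
   under stratified 10-fold cross-validation with a shared fold
   assignment, plus leave-one-subject-out per-participant evaluation.

Metrics follow the standard binary-classification definitions: per-class
precision `TP/(TP+FP)` and recall `TP/(TP+FN)`, per-class
F1 `2PR/(P+R)`, the macro average `(F1⁻ + F1⁺)/2`, the support-weighted
average, and accuracy.

A full study follows the geometry 10 participants × 4 positions × 180 s at
250 Sa/s: 45,000 samples per recording and
`250·180·4·10 / 125 = 14,400` windows in the pooled design matrix.

## Worked example

```r
library(bedbeat)

ds    <- simulate_dataset(n_participants = 3, duration_s = 60, seed = 42)
feats <- build_feature_matrix(ds)
nrow(feats)        # 1440 windows (3 people x 4 positions x 120 windows)
mean(feats$label)  # 0.654  — fraction of windows holding a beat

cv <- kfold_compare(feats, specs = default_model_specs(seed = 42)[c("LR", "CART", "RF")],
                    k = 5, seed = 42)
cv
#>  Model MeanAccuracy     Std FoldTimeSeconds
#>     LR        0.888 0.00291          0.0088
#>   CART        0.888 0.00994          0.0294
#>     RF        0.919 0.01285          0.1016
```

`MeanAccuracy` and `Std` are the mean and standard deviation of the five
fold accuracies (every model sees the identical folds), and
`FoldTimeSeconds` is the mean wall-clock time to train and test one fold
on this machine. The random forest separates beat from no-beat windows at
~92% accuracy on this small clean simulation, well above the 65%
majority-class baseline.

```r
pp <- per_person_eval(feats, spec = model_spec("RF"), seed = 42)
pp[, c("Person", "PrecisionHeartBeating", "RecallHeartBeating", "Accuracy")]
#>  Person PrecisionHeartBeating RecallHeartBeating Accuracy
#>      P1                  0.91               0.95      0.9
#>      P2                  0.91               0.95      0.9
#>      P3                  0.86               0.96      0.9
#>    Mean                    NA                 NA      0.9
```

Each row holds one participant evaluated on their own 480 windows by a
forest trained on everyone else (leave-one-subject-out); the `Mean` row is
the average accuracy across participants.

Reports are written with `write_comparison_csv()`, `write_per_person_csv()`
and `write_run_manifest()`; a thin command-line front end lives at
`inst/cli/bedbeat.R` (`simulate`, `compare`, `per-person`).

See the methods vignette (`vignettes/methods.Rmd`) for the signal model
behind the simulator, every pinned hyperparameter, and the package's
numerical conventions.

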