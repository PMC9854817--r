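# ramandx

Serum Raman spectroscopy is a label-free probe of blood biochemistry: the
positions and relative intensities of its peaks report on carotenoids,
proteins, lipids and nucleic acids, and disease shifts those relative
intensities. `ramandx` implements a complete diagnostic pipeline for
classifying serum spectra into three groups — healthy controls (HC), breast
cancer (BC) and ductal carcinoma in situ (DCIS) — for spectroscopists and
biostatisticians who want a tested, reproducible reference implementation
they can run end to end without access to restricted patient data.

The pipeline has four stages:

1. **Synthetic data** — `generate_dataset()` emulates a serum cohort:
   Lorentzian peaks at the eleven canonical serum Raman positions (593–2662
   cm⁻¹, strongest at the β-carotene bands 1154 and 1514 cm⁻¹) with
   class-dependent amplitudes, a smooth cubic fluorescence background,
   per-peak lognormal amplitude jitter, and five noisy replicate
   acquisitions averaged per sample, on a 1698-point 400–4000 cm⁻¹ axis.
2. **Preprocessing** — `preprocess_set()` applies, per spectrum,
   Savitzky–Golay smoothing, airPLS baseline subtraction and min–max
   scaling. The airPLS baseline *z* solves the weighted Whittaker system

   (Wₜ + λ DᵀD) z = Wₜ y

   with D the second-difference operator; points above the running
   baseline (Raman peaks) get weight 0 while points below it are
   re-weighted as wᵢ = exp(t·|dᵢ|/|d⁻|), iterating until the negative
   residual mass |d⁻| falls below `ratio`·‖y‖₁.
3. **Models** — `raman_train()` fits one of four families: a 1D CNN
   (conv(8, k=3) → batch-norm → tanh → conv(16, k=3) → tanh → max-pool(3) →
   flatten(9024) → dense(3) → softmax, trained with Adam on categorical
   cross-entropy, batch 16, learning rate 0.001), or KNN / random-forest /
   RBF-SVM baselines tuned by stratified 5-fold cross-validated grid
   search.
4. **Evaluation** — `run_full_experiment()` makes a stratified 7:3 split,
   evaluates all families three-class and on every class pair, and reports
   confusion matrices, accuracy, misdiagnosis counts,
   sensitivity/specificity and one-vs-rest macro-averaged ROC/AUC.

## Worked example

```r
library(ramandx)

cfg <- generator_config(seed = 11)        # 241 HC / 463 BC / 100 DCIS
raw <- generate_dataset(cfg)              # 804 x 1698 spectra
pp  <- preprocess_set(raw)                # smooth -> airPLS -> min-max

sp    <- stratified_split(pp$labels, 0.7, seed = 2)
train <- pp[sp$train_indices]
test  <- pp[sp$test_indices]
sp$per_class_counts
#>        HC  BC DCIS
#> train 168 324   70
#> test   73 139   30

cnn  <- train_cnn(build_cnn(cnn_spec(epochs = 15)), train, seed = 3)
pred <- predict(cnn, test)
cm   <- confusion(test$labels, pred, class_order = levels(pp$labels))
print(metrics_from_cm(cm))
#> accuracy 98.76%, 3 misdiagnose(s)
roc_auc(predict(cnn, test, type = "prob"), test$labels)$auc
#> [1] 0.9997729
```

The split table shows each class contributing ⌊0.7·n⌋ samples to training
(562 train / 242 test in total). The metrics line reads: of 242 held-out
synthetic spectra, 3 were assigned to the wrong diagnostic group; the
macro-averaged one-vs-rest AUC close to 1 means the class scores rank
almost every positive above every negative. Values vary with the seeds.

A command-line front end wrapping the same stages
(`raman-dx synth|preprocess|train|evaluate|run-all`) is installed at
`system.file("scripts", "raman-dx", package = "ramandx")`.

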