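# g4melt

Prediction of DNA G-quadruplex (G4) melting temperatures from primary
sequence and ionic conditions.

G4s are four-stranded structures that fold in guanine-rich DNA; their
thermodynamic stability — the melting temperature Tm at which half the
population is unfolded — shapes their regulatory roles and their value
as drug targets. Stability depends on the sequence (G-tract lengths,
loop lengths and composition) *and* on the buffer: K+ stabilises the
G-tetrad channel more than Na+, which beats Li+/NH4+, and pH matters at
the margins. `g4melt` is for researchers who need quantitative Tm
estimates for arbitrary G4-forming sequences under arbitrary
monovalent-cation conditions — without hand-specifying structural
features.

At its core is a four-branch neural regressor:

* one-hot sequence matrix (4 × 100, symmetric zero padding) through two
  convolution/max-pool/dropout blocks and dense layers;
* 340 k-mer counts (k = 1–4, laid into a 20 × 17 matrix) through two
  bidirectional LSTM layers and dense layers;
* the (K+, Na+, Li+/NH4+) concentration triple (min-max scaled) and
* the pH, each through small dense branches;

merged by fully connected layers into one linear unit emitting Tm in
°C. Training uses the Nadam optimiser (η = 1.55e-4, β₁ = 0.995,
β₂ = 0.9915, decoupled weight decay λ = 4e-5) with MSE loss, seeded
shuffling and early stopping on a validation split. Around the model
sit a dataset reader/validator/deduplicator, a repeated-k-fold
cross-validation harness with error stratification, an ensemble
predictor reporting mean ± SEM, motif-family stability scans, and
genome-scale profiling of eG4 tables under ionic presets (`normal`
100 mM K+; `moderate` 50 mM K+; `sodium` 100 mM Na+; `cancer` 70 mM
K+/30 mM Na+). A synthetic-data module generates oracle-labelled
training sets and eG4 tables so the whole pipeline is testable without
external downloads.

## Worked example

Train on synthetic oracle data (the package's generator with its
documented toy thermodynamic ground truth; ~10 min on one CPU) and
predict the human telomeric repeat under potassium and sodium:

```r
library(g4melt)

ds  <- generateG4Records(synthConfig(n_records = 2000, rng_seed = 101))
rec <- g4Records(ds)
set.seed(7); idx <- sample(2000)
fit <- trainRegressor(
  modelConfig(epochs = 600, patience = 100, learning_rate = 1e-3,
              rng_seed = 11),
  G4Dataset(rec[idx[1:1500], ]),
  validation = G4Dataset(rec[idx[1501:1700], ]))

tel <- "AGGGTTAGGGTTAGGGTTAGGGT"
predictTm(fit, tel, conditionPreset("normal"))   # 100 mM K+
predictTm(fit, tel, conditionPreset("sodium"))   # 100 mM Na+
```

```
[1] 60.78594
[1] 57.2909
```

The model, trained only on generated records, recovers the expected
cation hierarchy: the same sequence is predicted ~3.5 °C more stable
in 100 mM K+ than in 100 mM Na+. Held-out accuracy of this run:

```r
test <- rec[idx[1701:2000], ]
computeMetrics(test$tm_celsius, predict(fit, test))
```

```
RMSE 4.546 degC | MAE 3.516 degC | R^2 0.824 | within 5 degC 72.0% | n=300
```

The RMSE is 4.5 °C against a 2 °C generative noise floor: the network
captures most, not all, of the oracle's structure (the methods
vignette quantifies the gap). Scanning a motif family under the
potassium preset:

```r
tab <- scanStability(loopLengthGrid(bases = "T", n = 1:7),
                     list(conditionPreset("normal")), fit)
round(tab$tm_mean, 1)
```

```
[1] 64.8 65.1 63.5 60.4 59.6 60.9 61.4
```

Predicted stability falls by ~3.4 °C from one-base to seven-base
loops — the canonical inverse loop-length law, recovered as a trend. A
command-line interface wrapping the same functions is installed at
`inst/scripts/g4melt`
(`g4melt synth|validate|summarize|train|cv|ensemble-train|predict|scan|genome`).

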