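# Shared fixtures: everything is generated in code, nothing is stored.

# A deliberately small network configuration so unit tests train in
# seconds; architecture shape (two conv blocks, two BiLSTM layers,
# four branches) is unchanged.
tinyModelConfig <- function(epochs = 5L, rng_seed = 1L, ...) {
  modelConfig(conv_filters = c(4L, 6L), conv_kernel = 5L,
              conv_dense = c(8L, 6L), lstm_units = c(4L, 3L),
              kmer_dense = c(6L, 4L, 3L), cond_dense = c(4L, 3L),
              ph_dense = c(3L, 2L), head_dense = c(8L, 6L),
              epochs = epochs, rng_seed = rng_seed, ...)
}

# Random A/C/G/T sequence of a given length (for property tests).
randomDna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# A small valid records data.frame without going through the generator.
madeRecords <- function(n = 6L) {
  data.frame(
    sequence = c("GGGTTAGGGTTAGGGTTAGGG", "GGGAGGGAGGGAGGG",
                 "GGTTGGTTGGTTGG", "GGGGCCGGGGCCGGGGCCGGGG",
                 "GGGTGGGTGGGTGGG", "AATTGGGTTGGGTTGGGTTGGG")[seq_len(n)],
    tm_celsius = c(62, 71.5, 48, 80, 66, 58)[seq_len(n)],
    conc_k = c(100, 0, 50, 10, 100, 0)[seq_len(n)],
    conc_na = c(0, 100, 0, 0, 0, 70)[seq_len(n)],
    conc_li_nh4 = c(0, 0, 0, 25, 0, 0)[seq_len(n)],
    ph = c(7, 7.2, 7, 6.5, 7, 7.4)[seq_len(n)],
    stringsAsFactors = FALSE
  )
}

# Train-once cache for tests that need a real (small) fitted model.
.test_model_env <- new.env(parent = emptyenv())

tinyTrainedModel <- function() {
  if (is.null(.test_model_env$model)) {
    ds <- generateG4Records(synthConfig(n_records = 160L, rng_seed = 42L))
    rec <- g4Records(ds)
    .test_model_env$model <- trainRegressor(
      tinyModelConfig(epochs = 8L, rng_seed = 5L),
      G4Dataset(rec[1:130, ]),
      validation = G4Dataset(rec[131:160, ]))
  }
  .test_model_env$model
}
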