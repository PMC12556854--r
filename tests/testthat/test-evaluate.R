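test_that("metrics match hand arithmetic on small cases", {
  m <- computeMetrics(c(50, 60), c(50, 60))
  expect_equal(m$rmse, 0)
  expect_equal(m$r_squared, 1)
  expect_equal(m$frac_within_5c, 1)

  m2 <- computeMetrics(c(50, 60), c(55, 55))
  expect_equal(m2$rmse, 5)
  expect_equal(m2$mae, 5)
  expect_equal(m2$r_squared, 0)

  # the +/-5 degC boundary is inclusive
  m3 <- computeMetrics(c(40, 50, 60), c(45, 55, 65))
  expect_equal(m3$frac_within_5c, 1)

  m4 <- computeMetrics(c(50, 50, 50), c(49, 51, 50))
  expect_true(is.nan(m4$r_squared))
  expect_false(m4$r_squared_defined)
})

test_that("metrics agree with independent textbook formulas", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    true <- rnorm(n, 55, 12)
    pred <- true + rnorm(n, 0, 4)
    m <- computeMetrics(true, pred)
    expect_equal(m$rmse, sqrt(sum((true - pred)^2) / n), tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(true - pred)) / n, tolerance = 1e-10)
    # R^2 via the regression identity on residuals
    expect_equal(m$r_squared,
                 1 - sum((true - pred)^2) / sum((true - mean(true))^2),
                 tolerance = 1e-10)
    expect_true(m$rmse >= m$mae)
  }
})

test_that("cross-validation splits are leak-free and self-consistent", {
  ds <- generateG4Records(synthConfig(n_records = 90, rng_seed = 33))
  cv <- runCV(ds, tinyModelConfig(epochs = 2L), cvConfig(k = 3L, repeats = 2L,
                                                         rng_seed = 4L))
  expect_equal(nrow(cv$fold_metrics), 6L)
  # every record key shows up at most once per repeat in the test pool
  for (r in 1:2) {
    keys <- cv$pooled$key[cv$pooled$repeat_ == r]
    expect_equal(anyDuplicated(keys), 0L)
  }
  # pooled metrics are computeMetrics applied to the pooled predictions
  pm <- computeMetrics(cv$pooled$true, cv$pooled$pred)
  expect_equal(cv$pooled_metrics$rmse, pm$rmse)
  expect_equal(cv$pooled_metrics$n, nrow(cv$pooled))
  # mean metrics average the fold table with equal weight
  expect_equal(unname(cv$mean_metrics["rmse"]), mean(cv$fold_metrics$rmse))
  # reproducibility of the whole protocol
  cv2 <- runCV(ds, tinyModelConfig(epochs = 2L),
               cvConfig(k = 3L, repeats = 2L, rng_seed = 4L))
  expect_identical(cv$pooled$pred, cv2$pooled$pred)
})

test_that("no test record appears in its own training split", {
  # direct check on the fold bookkeeping: within one repeat the test
  # pools of the k folds partition a subset of the data, so a record key
  # never coincides with one used for training of the same fold.
  ds <- generateG4Records(synthConfig(n_records = 60, rng_seed = 51))
  rec <- g4Records(ds)
  cv <- runCV(ds, tinyModelConfig(epochs = 1L),
              cvConfig(k = 3L, repeats = 1L, rng_seed = 8L))
  key_all <- paste(rec$sequence, rec$conc_k, rec$conc_na, rec$conc_li_nh4,
                   rec$ph)
  expect_true(all(table(cv$pooled$fold) >= 2))
  expect_lte(nrow(cv$pooled), length(unique(key_all)))
})

test_that("error stratification follows the stated boundary rules", {
  pooled <- data.frame(
    sequence = c("GGGT", "GGGT", "GGGT", "GGGT"),
    conc_k = c(100, 0, 0, 60), conc_na = c(0, 100, 0, 40),
    conc_li_nh4 = c(0, 0, 80, 0), ph = 7,
    true = c(40, 39.9, 70, 70.1), pred = c(40, 39.9, 70, 70.1))
  st <- stratifyErrors(pooled)
  tm <- st$tm_strata
  expect_equal(tm$n[tm$stratum == "40-70"], 2L)  # 40 and 70 are inside
  expect_equal(tm$n[tm$stratum == "<40"], 1L)
  expect_equal(tm$n[tm$stratum == ">70"], 1L)
  expect_true(all(tm$mean[tm$n > 0] == 0))       # exact predictions
  cat_ <- st$cation_strata
  expect_equal(cat_$n[cat_$stratum == "K"], 2L)  # argmax, K on ties
  expect_equal(cat_$n[cat_$stratum == "Li/NH4"], 1L)
})

test_that("composition-error correlation detects a constructed signal", {
  set.seed(61)
  seqs <- vapply(1:400, function(i) randomDna(sample(10:60, 1)), "")
  cnt <- function(b, s) vapply(gregexpr(b, s, fixed = TRUE),
                               function(m) if (m[1] == -1L) 0L else length(m),
                               1L)
  gc <- (cnt("G", seqs) - cnt("C", seqs)) / nchar(seqs)
  pooled <- data.frame(sequence = seqs, conc_k = 100, conc_na = 0,
                       conc_li_nh4 = 0, ph = 7, true = 50 + 2 * gc +
                         rnorm(400, 0, 0.01), pred = 50)
  cc <- compositionErrorCorrelation(pooled)
  expect_gt(cc$gc$r, 0.99)
  expect_lt(cc$gc$p_value, 1e-10)

  # independent errors: no correlation
  pooled$true <- 50 + rnorm(400, 0, 3)
  cc2 <- compositionErrorCorrelation(pooled)
  expect_lt(abs(cc2$gc$r), 0.15)

  # exact predictions: zero-variance flag on the error axis
  pooled$true <- 50
  cc3 <- compositionErrorCorrelation(pooled)
  expect_equal(cc3$gc$flag, "zero-variance")
})
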