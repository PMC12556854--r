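#' Cross-validation configuration
#'
#' The reference protocol is 5-fold cross-validation repeated with fresh
#' fold shuffles and model reinitialisation; within each repeat the held
#' -out fold is split 50/50 into a final test half and a validation half
#' used only to monitor training (early stopping). Repeats are seeded
#' from one master seed so the whole experiment is a single reproducible
#' stream.
#'
#' @param k fold count (default 5).
#' @param repeats number of reinitialised repeats.
#' @param test_fraction_of_fold fraction of the held-out fold kept for
#'   final testing (the rest is the validation set).
#' @param rng_seed master seed.
#' @return a classed list (`CVConfig`).
#' @export
cvConfig <- function(k = 5L, repeats = 1L, test_fraction_of_fold = 0.5,
                     rng_seed = 1L) {
  stopifnot(k >= 2, repeats >= 1,
            test_fraction_of_fold > 0, test_fraction_of_fold < 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 test_fraction_of_fold = test_fraction_of_fold,
                 rng_seed = as.integer(rng_seed)), class = "CVConfig")
}

#' Regression metrics for Tm prediction
#'
#' RMSE = sqrt(mean(dT^2)), MAE = mean(|dT|), R^2 = 1 - SSres/SStot with
#' SStot about the mean of the true values, and the fraction of
#' predictions within +/-5 degC (boundary inclusive). A constant true
#' vector makes R^2 undefined; it is reported as NaN with
#' `r_squared_defined = FALSE`.
#'
#' @param true,pred numeric vectors of equal length >= 2.
#' @return list of class `MetricsReport`: `rmse`, `mae`, `r_squared`,
#'   `frac_within_5c`, `n`, `r_squared_defined`.
#' @export
computeMetrics <- function(true, pred) {
  stopifnot(length(true) == length(pred), length(true) >= 2L)
  d <- true - pred
  ss_tot <- sum((true - mean(true))^2)
  defined <- ss_tot > 0
  list(
    rmse = sqrt(mean(d^2)),
    mae = mean(abs(d)),
    r_squared = if (defined) 1 - sum(d^2) / ss_tot else NaN,
    frac_within_5c = mean(abs(d) <= 5),
    n = length(true),
    r_squared_defined = defined
  ) -> out
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("RMSE %.3f degC | MAE %.3f degC | R^2 %.3f | within 5 degC %.1f%% | n=%d\n",
              x$rmse, x$mae, x$r_squared, 100 * x$frac_within_5c, x$n))
  invisible(x)
}

#' Repeated k-fold cross-validation of the Tm regressor
#'
#' For every repeat the records are reshuffled into `k` folds; for every
#' fold a freshly initialised model is trained on the other k-1 folds
#' (scalers and normalisation statistics refitted on that training split
#' only — no leakage), the held-out fold is split into test and
#' validation halves, and the test-half predictions are retained with
#' their record keys for stratified analyses.
#'
#' @param dataset a [G4Dataset-class].
#' @param model_config a [modelConfig()] (its `rng_seed` is overridden
#'   per fold from the CV master seed).
#' @param cv_config a [cvConfig()].
#' @param verbose print fold progress.
#' @return list with `fold_metrics` (one row per repeat x fold),
#'   `mean_metrics` (metrics averaged over folds/repeats with equal
#'   weight), `pooled` (data.frame: key, sequence, conditions, true,
#'   pred, repeat_, fold), and `pooled_metrics` (metrics of the pooled
#'   predictions).
#' @export
runCV <- function(dataset, model_config = modelConfig(),
                  cv_config = cvConfig(), verbose = FALSE) {
  stopifnot(is(dataset, "G4Dataset"))
  rec <- g4Records(dataset)
  n <- nrow(rec)
  k <- cv_config$k
  if (floor(n / k) < 4L)
    .stopf("dataset too small for %d-fold CV with test/validation split", k)
  key <- .dedup_key(rec)
  fold_rows <- list(); pooled <- list()
  for (r in seq_len(cv_config$repeats)) {
    set.seed(deriveSeed(cv_config$rng_seed, r))
    fold_of <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      hold <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      n_test <- max(2L, round(cv_config$test_fraction_of_fold * length(hold)))
      if (length(hold) - n_test < 1L || n_test < 2L)
        .stopf("fold %d has too few records (%d) for the test/validation split",
               f, length(hold))
      shuf <- sample(hold)
      test_idx <- shuf[seq_len(n_test)]
      val_idx <- shuf[(n_test + 1L):length(shuf)]
      cfg <- model_config
      cfg$rng_seed <- deriveSeed(cv_config$rng_seed, r * 10000L + f)
      fit <- trainRegressor(cfg,
                            G4Dataset(rec[train_idx, , drop = FALSE]),
                            validation = G4Dataset(rec[val_idx, , drop = FALSE]))
      pred <- predict(fit, rec[test_idx, , drop = FALSE])
      m <- computeMetrics(rec$tm_celsius[test_idx], pred)
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, rmse = m$rmse, mae = m$mae,
                   r_squared = m$r_squared, frac_within_5c = m$frac_within_5c,
                   n = m$n)
      pooled[[length(pooled) + 1L]] <- cbind(
        data.frame(key = key[test_idx], stringsAsFactors = FALSE),
        rec[test_idx, c("sequence", .cation_names, "ph"), drop = FALSE],
        data.frame(true = rec$tm_celsius[test_idx], pred = pred,
                   repeat_ = r, fold = f))
      if (verbose)
        message(sprintf("repeat %d fold %d: RMSE %.2f R2 %.3f", r, f,
                        m$rmse, m$r_squared))
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  pooled <- do.call(rbind, pooled)
  rownames(pooled) <- NULL
  list(
    fold_metrics = fold_metrics,
    mean_metrics = c(rmse = mean(fold_metrics$rmse),
                     mae = mean(fold_metrics$mae),
                     r_squared = mean(fold_metrics$r_squared),
                     frac_within_5c = mean(fold_metrics$frac_within_5c)),
    pooled = pooled,
    pooled_metrics = computeMetrics(pooled$true, pooled$pred)
  )
}

#' Stratify prediction errors by Tm range, cation class and length
#'
#' Errors are dT = Ttrue - Tpred. Tm strata: below 40 degC (strict),
#' 40-70 degC (closed on both ends), above 70 degC (strict). Cation
#' strata use the dominant-cation rule ([dominantCation()]). A
#' per-length RMSE profile over 5-99 nt is included. Empty strata are
#' reported with n = 0 and no statistics.
#'
#' @param pooled the `pooled` data.frame from [runCV()] (columns
#'   `true`, `pred`, `sequence`, `conc_k`, `conc_na`, `conc_li_nh4`).
#' @return list with `tm_strata`, `cation_strata`, `length_profile`
#'   data.frames.
#' @export
stratifyErrors <- function(pooled) {
  d <- pooled$true - pooled$pred
  tm_stratum <- cut(pooled$true, breaks = c(-Inf, 40, 70, Inf),
                    labels = c("<40", "40-70", ">70"), right = TRUE)
  # cut(right=TRUE) puts 40 in "<40"; the convention here closes [40,70]
  tm_stratum[pooled$true == 40] <- "40-70"
  strat_stats <- function(groups) {
    lv <- levels(groups)
    do.call(rbind, lapply(lv, function(g) {
      dd <- d[groups == g]
      data.frame(stratum = g, n = length(dd),
                 mean = if (length(dd)) mean(dd) else NA_real_,
                 sd = if (length(dd) > 1) sd(dd) else NA_real_)
    }))
  }
  cation <- dominantCation(pooled$conc_k, pooled$conc_na, pooled$conc_li_nh4)
  L <- nchar(pooled$sequence)
  lengths_present <- sort(unique(L))
  length_profile <- do.call(rbind, lapply(lengths_present, function(l) {
    dd <- d[L == l]
    data.frame(length = l, n = length(dd), rmse = sqrt(mean(dd^2)))
  }))
  list(tm_strata = strat_stats(tm_stratum),
       cation_strata = strat_stats(cation),
       length_profile = length_profile)
}

#' Correlation between sequence composition and prediction error
#'
#' Pearson tests (two-sided) of (G-C)/L and (A-T)/L against
#' dT = Ttrue - Tpred. A zero-variance axis is flagged and yields
#' NA correlations rather than an error.
#'
#' @param pooled as in [stratifyErrors()].
#' @return list with `gc` and `at`, each `list(r, p_value, flag)`.
#' @export
compositionErrorCorrelation <- function(pooled) {
  stopifnot(nrow(pooled) >= 3L)
  d <- pooled$true - pooled$pred
  L <- nchar(pooled$sequence)
  cnt <- function(b) vapply(gregexpr(b, pooled$sequence, fixed = TRUE),
                            function(m) if (m[1] == -1L) 0L else length(m), 1L)
  gc <- (cnt("G") - cnt("C")) / L
  at <- (cnt("A") - cnt("T")) / L
  one <- function(x) {
    if (sd(x) == 0 || sd(d) == 0)
      return(list(r = NA_real_, p_value = NA_real_, flag = "zero-variance"))
    ct <- stats::cor.test(x, d, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p_value = ct$p.value, flag = "ok")
  }
  list(gc = one(gc), at = one(at))
}
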