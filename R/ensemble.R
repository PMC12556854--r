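#' Ensemble configuration
#'
#' The reference protocol trains 100 models of identical architecture,
#' each from different random initial weights and on a random subset of
#' the training data; here a subset is an 80% subsample drawn without
#' replacement (fraction configurable and recorded in the artifact).
#'
#' @param n_models ensemble size (default 100).
#' @param subsample_fraction fraction of training records per member.
#' @param rng_seed master seed; member seeds are derived from it.
#' @return a classed list (`EnsembleConfig`).
#' @export
ensembleConfig <- function(n_models = 100L, subsample_fraction = 0.8,
                           rng_seed = 1L) {
  stopifnot(n_models >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(n_models = as.integer(n_models),
                 subsample_fraction = subsample_fraction,
                 rng_seed = as.integer(rng_seed)), class = "EnsembleConfig")
}

#' Train an ensemble of independently initialised Tm regressors
#'
#' Each member gets a distinct derived seed (initial weights, shuffling,
#' dropout) and a distinct subsample of the records; member scalers and
#' normalisation statistics are fitted on that member's subsample. The
#' result is independent of the order in which members are trained.
#'
#' @param dataset a [G4Dataset-class].
#' @param model_config a [modelConfig()]; its seed is replaced by each
#'   member's derived seed.
#' @param ens_config an [ensembleConfig()].
#' @param verbose print member progress.
#' @return a [TmEnsemble-class].
#' @export
trainEnsemble <- function(dataset, model_config = modelConfig(),
                          ens_config = ensembleConfig(), verbose = FALSE) {
  stopifnot(is(dataset, "G4Dataset"))
  rec <- g4Records(dataset)
  n <- nrow(rec)
  n_sub <- max(2L, floor(ens_config$subsample_fraction * n))
  if (n_sub < model_config$batch_size)
    .stopf("member subsample (%d) is smaller than one batch (%d)",
           n_sub, model_config$batch_size)
  members <- vector("list", ens_config$n_models)
  for (m in seq_len(ens_config$n_models)) {
    seed_m <- deriveSeed(ens_config$rng_seed, m)
    set.seed(seed_m)
    idx <- sample.int(n, n_sub)
    cfg <- model_config
    cfg$rng_seed <- seed_m
    members[[m]] <- trainRegressor(cfg, G4Dataset(rec[idx, , drop = FALSE]))
    if (verbose) message(sprintf("member %d/%d trained", m,
                                 ens_config$n_models))
  }
  new("TmEnsemble", members = members, config = unclass(ens_config))
}

#' Ensemble prediction: mean Tm and its standard error
#'
#' Every query is processed by all members; the reported Tm is the
#' arithmetic mean over members and the uncertainty is the SEM: the
#' sample standard deviation (n-1 denominator) over member predictions
#' divided by sqrt(n_models). With a single member the SEM is 0. The
#' mean is invariant to member order.
#'
#' @param object a [TmEnsemble-class].
#' @param newdata query data.frame as in the [TmRegressor-class] predict
#'   method.
#' @param members if TRUE, attach the full member-by-query prediction
#'   matrix as attribute `"member_matrix"`.
#' @param ... ignored.
#' @return data.frame with `tm_mean`, `tm_sem`, `n_models`.
#' @export
setMethod("predict", "TmEnsemble",
  function(object, newdata, members = FALSE, ...) {
    M <- length(object@members)
    preds <- vapply(object@members, function(mod) predict(mod, newdata),
                    numeric(nrow(as.data.frame(newdata))))
    preds <- matrix(preds, ncol = M)  # queries x members
    tm_mean <- rowMeans(preds)
    tm_sem <- if (M == 1L) rep(0, nrow(preds))
              else apply(preds, 1L, sd) / sqrt(M)
    out <- data.frame(tm_mean = tm_mean, tm_sem = tm_sem, n_models = M)
    if (members) attr(out, "member_matrix") <- preds
    out
  })

#' Persist / restore an ensemble artifact
#'
#' A directory of member artifacts (`member_001`, ...) plus a manifest
#' with the ensemble configuration and member seeds. Loading fails,
#' naming the index, if a member directory is missing.
#'
#' @param ensemble a [TmEnsemble-class].
#' @param dir artifact directory.
#' @return `saveEnsemble`: `dir` invisibly; `loadEnsemble`: a
#'   [TmEnsemble-class].
#' @export
saveEnsemble <- function(ensemble, dir) {
  stopifnot(is(ensemble, "TmEnsemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- length(ensemble@members)
  for (m in seq_len(M))
    saveRegressor(ensemble@members[[m]],
                  file.path(dir, sprintf("member_%03d", m)))
  jsonlite::write_json(
    c(ensemble@config, list(n_members_saved = M)),
    file.path(dir, "ensemble_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  mf <- file.path(dir, "ensemble_manifest.json")
  if (!file.exists(mf)) .stopf("no ensemble manifest in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  M <- manifest$n_members_saved
  members <- vector("list", M)
  for (m in seq_len(M)) {
    mdir <- file.path(dir, sprintf("member_%03d", m))
    if (!dir.exists(mdir)) .stopf("ensemble member %d missing (%s)", m, mdir)
    members[[m]] <- loadRegressor(mdir)
  }
  cfg <- manifest[c("n_models", "subsample_fraction", "rng_seed")]
  new("TmEnsemble", members = members, config = cfg)
}
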