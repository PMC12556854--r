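#' G4Dataset: a curated G-quadruplex thermodynamic dataset
#'
#' Container for melting-temperature observations of G-quadruplex-forming
#' DNA oligonucleotides. Each record holds the primary sequence (5'->3',
#' A/C/G/T only, at most 100 nt), the measured melting temperature Tm in
#' degrees Celsius, the monovalent-cation composition of the buffer
#' (K+, Na+, and pooled Li+/NH4+, in mM) and the pH.
#'
#' @slot records data.frame with columns `sequence`, `tm_celsius`,
#'   `conc_k`, `conc_na`, `conc_li_nh4`, `ph`, `source`, `method`.
#' @slot provenance list: source path and parse report (`n_parsed`,
#'   `n_rejected`, `rejects` data.frame of row numbers and reasons).
#' @slot dedupReport list: `n_removed` and the duplicate keys, filled by
#'   [deduplicate()].
#'
#' @seealso [readG4Dataset()], [deduplicate()], [summary,G4Dataset-method]
#' @export
setClass("G4Dataset",
  representation(
    records = "data.frame",
    provenance = "list",
    dedupReport = "list"
  ),
  prototype(
    records = data.frame(),
    provenance = list(),
    dedupReport = list(n_removed = 0L, duplicate_keys = character(0))
  )
)

.g4_columns <- c("sequence", "tm_celsius", "conc_k", "conc_na",
                 "conc_li_nh4", "ph", "source", "method")

setValidity("G4Dataset", function(object) {
  rec <- object@records
  msgs <- character(0)
  if (nrow(rec)) {
    missing <- setdiff(.g4_columns, names(rec))
    if (length(missing))
      return(paste("records missing columns:", paste(missing, collapse = ", ")))
    if (!all(validDnaSequence(rec$sequence)))
      msgs <- c(msgs, "sequences must be non-empty over {A,C,G,T}")
    if (any(nchar(rec$sequence) > 100))
      msgs <- c(msgs, "sequences longer than 100 nt are not representable")
    if (any(rec$conc_k < 0 | rec$conc_na < 0 | rec$conc_li_nh4 < 0))
      msgs <- c(msgs, "cation concentrations must be >= 0 mM")
    if (any(rec$ph < 0 | rec$ph > 14))
      msgs <- c(msgs, "pH must lie in [0, 14]")
    if (any(rec$tm_celsius < 0 | rec$tm_celsius > 120))
      msgs <- c(msgs, "Tm must lie in [0, 120] degC")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a G4Dataset from a records data.frame
#'
#' @param records data.frame with at least `sequence`, `tm_celsius`,
#'   `conc_k`, `conc_na`, `conc_li_nh4`, `ph`; optional `source`, `method`.
#' @param provenance optional list describing where the records came from.
#' @return a validated [G4Dataset-class] object.
#' @export
G4Dataset <- function(records, provenance = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$source))
    records$source <- rep(NA_character_, nrow(records))
  if (is.null(records$method))
    records$method <- rep(NA_character_, nrow(records))
  records$sequence <- toupper(as.character(records$sequence))
  records <- records[, .g4_columns, drop = FALSE]
  rownames(records) <- NULL
  new("G4Dataset", records = records, provenance = provenance)
}

#' @describeIn G4Dataset number of records
#' @param x a `G4Dataset`.
#' @export
setMethod("length", "G4Dataset", function(x) nrow(x@records))

#' Accessors for G4Dataset
#'
#' `g4Records()` returns the records data.frame; `g4Sequences()` the
#' sequences as a [Biostrings::DNAStringSet]; `dedupReport()` the
#' deduplication report.
#'
#' @param x a [G4Dataset-class].
#' @return see individual descriptions.
#' @export
g4Records <- function(x) {
  stopifnot(is(x, "G4Dataset"))
  x@records
}

#' @rdname g4Records
#' @export
g4Sequences <- function(x) {
  stopifnot(is(x, "G4Dataset"))
  Biostrings::DNAStringSet(x@records$sequence)
}

#' @rdname g4Records
#' @export
dedupReport <- function(x) {
  stopifnot(is(x, "G4Dataset"))
  x@dedupReport
}

setMethod("show", "G4Dataset", function(object) {
  rec <- object@records
  cat("G4Dataset with", nrow(rec), "records\n")
  if (nrow(rec)) {
    cat(sprintf("  sequence length: %d-%d nt | Tm: %.1f-%.1f degC\n",
                min(nchar(rec$sequence)), max(nchar(rec$sequence)),
                min(rec$tm_celsius), max(rec$tm_celsius)))
  }
  if (!is.null(object@provenance$path))
    cat("  source:", object@provenance$path, "\n")
  if ((object@dedupReport$n_removed %||% 0L) > 0L)
    cat("  deduplicated:", object@dedupReport$n_removed, "records removed\n")
  invisible(NULL)
})

#' FeatureScalers: min-max scaling parameters for buffer conditions
#'
#' Per-channel minima and maxima for the three cation concentrations and
#' pH, fitted on a training split and applied unchanged at prediction
#' time (no leakage). A degenerate channel (min == max) maps every value
#' to 0.
#'
#' @slot mins,maxs named numeric vectors over
#'   `c("conc_k","conc_na","conc_li_nh4","ph")`.
#' @seealso [fitScalers()], [scaleConditions()]
#' @export
setClass("FeatureScalers",
  representation(mins = "numeric", maxs = "numeric"))

setValidity("FeatureScalers", function(object) {
  chans <- c(.cation_names, "ph")
  if (!identical(names(object@mins), chans) ||
      !identical(names(object@maxs), chans))
    return("mins/maxs must be named over conc_k, conc_na, conc_li_nh4, ph")
  if (any(object@maxs < object@mins)) return("max < min in some channel")
  TRUE
})

setMethod("show", "FeatureScalers", function(object) {
  cat("FeatureScalers (min-max, [0,1])\n")
  for (ch in names(object@mins))
    cat(sprintf("  %-12s [%g, %g]\n", ch, object@mins[ch], object@maxs[ch]))
  invisible(NULL)
})

#' TmRegressor: a trained (or untrained) four-branch Tm network
#'
#' Holds the network parameters, the input-standardisation statistics,
#' the condition [FeatureScalers-class] in force when the model was
#' fitted, the full configuration, and the per-epoch training history.
#'
#' @slot params list of weight matrices/vectors, named by layer.
#' @slot config list from [modelConfig()].
#' @slot scalers a [FeatureScalers-class] or NULL before fitting.
#' @slot normStats list of per-branch standardisation means/sds.
#' @slot history data.frame with `epoch`, `train_mse`, `val_mse`.
#' @slot trained logical.
#' @export
setClass("TmRegressor",
  representation(
    params = "list",
    config = "list",
    scalers = "ANY",
    normStats = "list",
    history = "data.frame",
    trained = "logical"
  ),
  prototype(trained = FALSE, history = data.frame(), normStats = list(),
            scalers = NULL)
)

setMethod("show", "TmRegressor", function(object) {
  nw <- sum(vapply(object@params, length, 1L))
  cat("TmRegressor:", if (object@trained) "trained" else "untrained",
      "| parameters:", nw, "\n")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  epochs run: %d | final train MSE: %.3f", last$epoch,
                last$train_mse))
    if (!is.na(last$val_mse)) cat(sprintf(" | val MSE: %.3f", last$val_mse))
    cat("\n")
  }
  invisible(NULL)
})

#' TmEnsemble: an ensemble of independently trained Tm regressors
#'
#' Members share the architecture but differ in random initialisation and
#' in the (subsampled) training data. Prediction returns the arithmetic
#' mean over members and its standard error (sd over members / sqrt(N)).
#'
#' @slot members list of [TmRegressor-class].
#' @slot config list from [ensembleConfig()].
#' @export
setClass("TmEnsemble",
  representation(members = "list", config = "list"))

setValidity("TmEnsemble", function(object) {
  if (!length(object@members)) return("ensemble needs at least one member")
  if (!all(vapply(object@members, is, TRUE, "TmRegressor")))
    return("all members must be TmRegressor objects")
  TRUE
})

setMethod("show", "TmEnsemble", function(object) {
  cat("TmEnsemble with", length(object@members), "members",
      sprintf("(subsample fraction %.2f)\n",
              object@config$subsample_fraction %||% NA_real_))
  invisible(NULL)
})

#' @rdname g4Records
#' @export
ensembleMembers <- function(x) {
  stopifnot(is(x, "TmEnsemble"))
  x@members
}
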