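#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats median sd predict runif rnorm quantile IQR setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing so that independent components (folds,
#' ensemble members, repeats) each get a distinct, reproducible seed that
#' stays within R's 32-bit integer range.
#'
#' @param master integer master seed.
#' @param index positive integer component index.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
deriveSeed <- function(master, index) {
  # multiplicative hash mod a prime below 2^31
  p <- 2147483629
  x <- (as.numeric(master) %% p)
  x <- (x * 48271 + as.numeric(index) * 16807 + 12345) %% p
  as.integer(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check a vector of DNA sequences against the model alphabet
#' @param x character vector.
#' @return logical vector: TRUE where `x` is a non-empty A/C/G/T string.
#' @keywords internal
validDnaSequence <- function(x) {
  nzchar(x) & !is.na(x) & grepl("^[ACGT]+$", x)
}

.cation_names <- c("conc_k", "conc_na", "conc_li_nh4")
.cation_labels <- c(conc_k = "K", conc_na = "Na", conc_li_nh4 = "Li/NH4")

#' Dominant cation class of a record
#'
#' The stratification label used for error analyses: argmax of the three
#' monovalent concentrations, ties broken in the order K > Na > Li/NH4.
#'
#' @param conc_k,conc_na,conc_li_nh4 numeric vectors of concentrations (mM).
#' @return factor with levels `K`, `Na`, `Li/NH4`.
#' @export
dominantCation <- function(conc_k, conc_na, conc_li_nh4) {
  m <- cbind(conc_k, conc_na, conc_li_nh4)
  idx <- apply(m, 1L, which.max)  # which.max takes first on ties: K > Na > Li/NH4
  factor(unname(.cation_labels[idx]), levels = unname(.cation_labels))
}

#' @useDynLib g4melt, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
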