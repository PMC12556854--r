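#' Read a G-quadruplex thermodynamic dataset from delimited text
#'
#' Reads a TSV or CSV file with header columns `sequence, tm_celsius,
#' k_mM, na_mM, li_nh4_mM, ph, source` (case-insensitive; `source` and
#' `method` optional). Every row is validated against the record
#' invariants: non-empty A/C/G/T sequence of at most 100 nt,
#' non-negative concentrations, pH in 0-14, Tm in 0-120 degC.
#' Invalid rows are rejected individually and recorded, with reasons, in
#' the parse report; a missing required column is fatal.
#'
#' Sequences are uppercased. `U` is not mapped to `T`: the model is
#' DNA-only and an RNA residue is an alphabet error. Records in which all
#' three cation concentrations are zero are accepted with a warning
#' (physically dubious, but they should not silently vanish).
#'
#' @param path path to the dataset file.
#' @param sep field separator; by default inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return a [G4Dataset-class]; `provenance(x)$parse_report` holds
#'   `n_parsed`, `n_rejected` and a `rejects` data.frame (file row
#'   number, reason).
#' @export
readG4Dataset <- function(path, sep = NULL) {
  if (!file.exists(path)) .stopf("dataset file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  colmap <- c(sequence = "sequence", tm_celsius = "tm_celsius",
              conc_k = "k_mm", conc_na = "na_mm", conc_li_nh4 = "li_nh4_mm",
              ph = "ph", source = "source", method = "method")
  required <- colmap[setdiff(names(colmap), c("source", "method"))]
  missing <- required[!(required %in% names(raw))]
  if (length(missing))
    .stopf("required column(s) missing from %s: %s", path,
           paste(missing, collapse = ", "))

  n <- nrow(raw)
  rec <- data.frame(
    sequence = toupper(trimws(as.character(raw[["sequence"]]))),
    tm_celsius = suppressWarnings(as.numeric(raw[["tm_celsius"]])),
    conc_k = suppressWarnings(as.numeric(raw[["k_mm"]])),
    conc_na = suppressWarnings(as.numeric(raw[["na_mm"]])),
    conc_li_nh4 = suppressWarnings(as.numeric(raw[["li_nh4_mm"]])),
    ph = suppressWarnings(as.numeric(raw[["ph"]])),
    source = if ("source" %in% names(raw)) as.character(raw[["source"]])
             else NA_character_,
    method = if ("method" %in% names(raw)) as.character(raw[["method"]])
             else NA_character_,
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n)
  bad_seq <- !validDnaSequence(rec$sequence)
  reason[bad_seq] <- "invalid alphabet"
  too_long <- !bad_seq & nchar(rec$sequence) > 100
  reason[too_long] <- "sequence exceeds model window (100 nt)"
  bad_tm <- is.na(reason) & (is.na(rec$tm_celsius) | rec$tm_celsius < 0 |
                             rec$tm_celsius > 120)
  reason[bad_tm] <- "non-numeric or out-of-range Tm"
  conc <- as.matrix(rec[, .cation_names])
  bad_conc <- is.na(reason) & (rowSums(is.na(conc)) > 0 | rowSums(conc < 0) > 0)
  reason[bad_conc] <- "negative or non-numeric concentration"
  bad_ph <- is.na(reason) & (is.na(rec$ph) | rec$ph < 0 | rec$ph > 14)
  reason[bad_ph] <- "non-numeric or out-of-range pH"

  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  kept <- rec[keep, , drop = FALSE]
  n_zero_salt <- sum(rowSums(as.matrix(kept[, .cation_names])) == 0)
  if (n_zero_salt > 0)
    .warnf("%d record(s) have all cation concentrations = 0 mM", n_zero_salt)

  report <- list(n_rows = n, n_parsed = nrow(kept), n_rejected = nrow(rejects),
                 rejects = rejects)
  G4Dataset(kept, provenance = list(path = path, parse_report = report))
}

#' Write a G4Dataset back to TSV
#'
#' Inverse of [readG4Dataset()]: writes the external schema
#' `sequence, tm_celsius, k_mM, na_mM, li_nh4_mM, ph, source, method`,
#' so that read -> write -> read is the identity on records.
#'
#' @param x a [G4Dataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeG4Dataset <- function(x, path) {
  stopifnot(is(x, "G4Dataset"))
  out <- x@records
  names(out) <- c("sequence", "tm_celsius", "k_mM", "na_mM", "li_nh4_mM",
                  "ph", "source", "method")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a parse or deduplication report as JSON
#' @param report a list (e.g. `provenance(x)$parse_report` or
#'   [dedupReport()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

.dedup_key <- function(rec) {
  paste(rec$sequence, format(rec$conc_k, digits = 15),
        format(rec$conc_na, digits = 15),
        format(rec$conc_li_nh4, digits = 15),
        format(rec$ph, digits = 15), sep = "|")
}

#' Remove duplicate measurements
#'
#' Duplicates on the key (sequence, K+, Na+, Li/NH4+, pH) would bias
#' training weight and inflate cross-validation scores, so all but the
#' first occurrence are dropped. The operation is idempotent and
#' order-preserving on the survivors; removed keys are recorded in the
#' report.
#'
#' @param x a [G4Dataset-class].
#' @return a deduplicated [G4Dataset-class]; see [dedupReport()].
#' @export
deduplicate <- function(x) {
  stopifnot(is(x, "G4Dataset"))
  rec <- x@records
  if (!nrow(rec)) {
    x@dedupReport <- list(n_removed = 0L, duplicate_keys = character(0))
    return(x)
  }
  key <- .dedup_key(rec)
  dup <- duplicated(key)
  out <- x
  out@records <- rec[!dup, , drop = FALSE]
  rownames(out@records) <- NULL
  out@dedupReport <- list(n_removed = sum(dup),
                          duplicate_keys = unique(key[dup]))
  validObject(out)
  out
}

#' Summary statistics of a G4 dataset
#'
#' Computes the dataset characterisation used throughout: sequence-length
#' statistics (mean/median/sd/IQR, plus the fraction shorter than 21 nt
#' and the count longer than 50 nt), Tm statistics (mean/sd/span), the
#' per-record normalised composition differences (G-C)/L and (A-T)/L,
#' the fraction of records at each distinct pH, and record counts per
#' dominant cation class.
#'
#' @param object a [G4Dataset-class] with at least one record.
#' @param ... ignored.
#' @return a list of class `G4DatasetSummary` with elements `n_records`,
#'   `length_stats`, `tm_stats`, `composition` (data.frame `gc_diff`,
#'   `at_diff`), `ph_table`, `cation_table`.
#' @export
setMethod("summary", "G4Dataset", function(object, ...) {
  rec <- object@records
  if (!nrow(rec)) .stopf("no records")
  L <- nchar(rec$sequence)
  base_counts <- function(b) {
    vapply(gregexpr(b, rec$sequence, fixed = TRUE),
           function(m) if (m[1] == -1L) 0L else length(m), 1L)
  }
  g <- base_counts("G"); c_ <- base_counts("C")
  a <- base_counts("A"); t_ <- base_counts("T")
  comp <- data.frame(gc_diff = (g - c_) / L, at_diff = (a - t_) / L)
  ph_tab <- table(rec$ph) / nrow(rec)
  out <- list(
    n_records = nrow(rec),
    length_stats = c(mean = mean(L), median = median(L), sd = sd(L),
                     iqr = IQR(L),
                     frac_below_21 = mean(L < 21), n_above_50 = sum(L > 50)),
    tm_stats = c(mean = mean(rec$tm_celsius), sd = sd(rec$tm_celsius),
                 span = diff(range(rec$tm_celsius)),
                 min = min(rec$tm_celsius), max = max(rec$tm_celsius)),
    composition = comp,
    ph_table = setNames(as.numeric(ph_tab), names(ph_tab)),
    cation_table = table(dominantCation(rec$conc_k, rec$conc_na,
                                        rec$conc_li_nh4))
  )
  class(out) <- "G4DatasetSummary"
  out
})

#' @export
print.G4DatasetSummary <- function(x, ...) {
  cat("G4 dataset summary:", x$n_records, "records\n")
  cat(sprintf("  length (nt): mean %.1f, median %.1f, sd %.1f, IQR %.1f\n",
              x$length_stats["mean"], x$length_stats["median"],
              x$length_stats["sd"], x$length_stats["iqr"]))
  cat(sprintf("  Tm (degC): mean %.1f, sd %.1f, span %.1f\n",
              x$tm_stats["mean"], x$tm_stats["sd"], x$tm_stats["span"]))
  cat("  dominant cation:",
      paste(sprintf("%s=%d", names(x$cation_table),
                    as.integer(x$cation_table)), collapse = ", "), "\n")
  invisible(x)
}
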