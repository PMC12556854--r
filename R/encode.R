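.BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence into a 4 x width matrix
#'
#' Sequences are centred in a fixed window of `width` positions
#' (default 100) by symmetric zero padding: `floor((width - L)/2)` all-zero
#' columns on the left, the remainder on the right. Rows are the channels
#' A, C, G, T in that order; each real-base column sums to 1 and each
#' padding column to 0, so the matrix total equals the sequence length.
#'
#' @param sequence a single A/C/G/T string, 1 to `width` nt.
#' @param width window size in nucleotides (default 100).
#' @return a `4 x width` binary matrix with rownames A, C, G, T.
#' @examples
#' m <- encodeOneHot("ACGT")
#' sum(m)              # 4
#' which(m["A", ] == 1)  # column 49
#' @export
encodeOneHot <- function(sequence, width = 100L) {
  sequence <- toupper(sequence)
  if (length(sequence) != 1L || !validDnaSequence(sequence))
    .stopf("sequence must be a single non-empty A/C/G/T string")
  L <- nchar(sequence)
  if (L > width) .stopf("sequence exceeds model window (%d > %d nt)", L, width)
  m <- matrix(0, nrow = 4L, ncol = width, dimnames = list(.BASES, NULL))
  left <- (width - L) %/% 2L
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m[cbind(match(chars, .BASES), left + seq_len(L))] <- 1
  m
}

#' All k-mers of length k in lexicographic A < C < G < T order
#' @param k word length.
#' @return character vector of the 4^k words.
#' @keywords internal
kmerAlphabet <- function(k) {
  grids <- rev(rep(list(.BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Count overlapping k-mers for k = 1..4
#'
#' Counts are taken on the raw, unpadded sequence with overlapping
#' windows, so for each k the counts sum to `max(L - k + 1, 0)`. The 340
#' features (4 + 16 + 64 + 256) are ordered k-ascending and
#' lexicographically (A < C < G < T) within each k.
#'
#' @param sequence a single A/C/G/T string.
#' @return named integer vector of length 340.
#' @seealso [countKmers()] for the 20 x 17 matrix layout.
#' @export
kmerCounts <- function(sequence) {
  sequence <- toupper(sequence)
  if (length(sequence) != 1L || !validDnaSequence(sequence))
    .stopf("sequence must be a single non-empty A/C/G/T string")
  L <- nchar(sequence)
  out <- vector("list", 4L)
  for (k in 1:4) {
    words <- kmerAlphabet(k)
    n <- max(L - k + 1L, 0L)
    subs <- if (n > 0L) substring(sequence, seq_len(n), seq_len(n) + k - 1L)
            else character(0)
    out[[k]] <- table(factor(subs, levels = words))
  }
  v <- unlist(lapply(out, as.integer))
  names(v) <- unlist(lapply(1:4, kmerAlphabet))
  v
}

#' Lay the 340 k-mer counts into a 20 x 17 matrix
#'
#' The feature vector from [kmerCounts()] is filled row-major into a
#' 20 x 17 grid (20 * 17 = 340). The layout is a fixed storage
#' convention for the recurrent branch of the network; any fixed order
#' is equally learnable, fixing one makes artifacts portable.
#'
#' @param sequence a single A/C/G/T string.
#' @return a 20 x 17 integer matrix.
#' @export
countKmers <- function(sequence) {
  matrix(kmerCounts(sequence), nrow = 20L, ncol = 17L, byrow = TRUE)
}

#' Fit min-max condition scalers on a training split
#'
#' Per-channel minima and maxima of the three cation concentrations and
#' pH over the training records. Scaling maps each channel onto the unit interval;
#' a degenerate channel (min == max) maps every value to 0. Scalers are
#' fitted on the training split only and persisted with the model, so
#' validation/test folds are transformed with training statistics and
#' never refitted (no leakage).
#'
#' @param x a [G4Dataset-class] or a records data.frame.
#' @return a [FeatureScalers-class].
#' @export
fitScalers <- function(x) {
  rec <- if (is(x, "G4Dataset")) x@records else as.data.frame(x)
  if (!nrow(rec)) .stopf("cannot fit scalers on an empty dataset")
  chans <- c(.cation_names, "ph")
  mins <- vapply(chans, function(ch) min(rec[[ch]]), 0)
  maxs <- vapply(chans, function(ch) max(rec[[ch]]), 0)
  new("FeatureScalers", mins = mins, maxs = maxs)
}

#' Apply (or invert) fitted min-max scalers
#'
#' @param scalers a [FeatureScalers-class].
#' @param conditions data.frame with columns `conc_k`, `conc_na`,
#'   `conc_li_nh4`, `ph` (raw units for `scaleConditions`, scaled unit-interval
#'   values for `unscaleConditions`).
#' @param clip if TRUE, scaled values outside the unit interval (conditions outside
#'   the training range) are clipped with a warning.
#' @return data.frame of the same shape.
#' @export
scaleConditions <- function(scalers, conditions, clip = FALSE) {
  stopifnot(is(scalers, "FeatureScalers"))
  chans <- c(.cation_names, "ph")
  out <- conditions[, chans, drop = FALSE]
  clipped <- FALSE
  for (ch in chans) {
    rng <- scalers@maxs[ch] - scalers@mins[ch]
    if (rng <= 0) {
      out[[ch]] <- rep(0, nrow(out))
    } else {
      v <- (conditions[[ch]] - scalers@mins[ch]) / rng
      if (clip && any(v < 0 | v > 1)) {
        clipped <- TRUE
        v <- pmin(pmax(v, 0), 1)
      }
      out[[ch]] <- v
    }
  }
  if (clipped)
    .warnf("condition values outside the training range were clipped to [0,1]")
  out
}

#' @rdname scaleConditions
#' @export
unscaleConditions <- function(scalers, conditions) {
  stopifnot(is(scalers, "FeatureScalers"))
  chans <- c(.cation_names, "ph")
  out <- conditions[, chans, drop = FALSE]
  for (ch in chans) {
    rng <- scalers@maxs[ch] - scalers@mins[ch]
    out[[ch]] <- if (rng <= 0) rep(scalers@mins[ch], nrow(out))
                 else conditions[[ch]] * rng + scalers@mins[ch]
  }
  out
}

#' Encode records into the four network inputs
#'
#' Produces the feature bundle consumed by the regressor: the one-hot
#' sequence array, the k-mer array (17 timesteps of 20 features for the
#' recurrent branch), the scaled cation matrix, and the scaled pH
#' column. Encoding is deterministic: the same records and scalers give
#' bit-identical arrays.
#'
#' @param records data.frame with `sequence`, `conc_k`, `conc_na`,
#'   `conc_li_nh4`, `ph` (a [G4Dataset-class] is also accepted).
#' @param scalers a fitted [FeatureScalers-class].
#' @param clip passed to [scaleConditions()]; use TRUE at prediction
#'   time so out-of-range conditions are clipped rather than
#'   extrapolated.
#' @return list with `onehot` (`n x 100 x 4` array), `kmer`
#'   (`n x 17 x 20` array), `cond` (`n x 3` matrix), `ph` (`n x 1`
#'   matrix) and `n`.
#' @export
encodeRecords <- function(records, scalers, clip = FALSE) {
  rec <- if (is(records, "G4Dataset")) records@records
         else as.data.frame(records)
  n <- nrow(rec)
  if (!n) .stopf("no records to encode")
  onehot <- array(0, dim = c(n, 100L, 4L))
  kmer <- array(0, dim = c(n, 17L, 20L))
  for (i in seq_len(n)) {
    onehot[i, , ] <- t(encodeOneHot(rec$sequence[i]))
    kmer[i, , ] <- t(countKmers(rec$sequence[i]))
  }
  sc <- scaleConditions(scalers, rec, clip = clip)
  list(onehot = onehot, kmer = kmer,
       cond = as.matrix(sc[, .cation_names]),
       ph = matrix(sc$ph, ncol = 1L), n = n)
}
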