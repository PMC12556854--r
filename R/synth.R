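#' Structural features of a putative G4 sequence used by the toy oracle
#'
#' Maximal runs of G are taken as candidate G-tracts; the four longest
#' (ties broken by earlier position) form the stem. Loops are the
#' subsequences between consecutive chosen tracts (flanks outside the
#' first/last tract are not loops). Reported are the shortest tract
#' length among the chosen (0 if fewer than four tracts exist), the mean
#' loop length (0 if fewer than two tracts), and the fraction of A among
#' loop bases (0 if there are no loop bases).
#'
#' @param sequence a single A/C/G/T string.
#' @return list with `min_tract`, `mean_loop`, `frac_a_loop`,
#'   `n_tracts`.
#' @export
g4StructuralFeatures <- function(sequence) {
  sequence <- toupper(sequence)
  if (!validDnaSequence(sequence)) .stopf("invalid sequence")
  m <- gregexpr("G+", sequence)[[1]]
  if (m[1] == -1L)
    return(list(min_tract = 0, mean_loop = 0, frac_a_loop = 0, n_tracts = 0L))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ord <- order(-lens, starts)
  chosen <- sort(starts[ord[seq_len(min(4L, length(starts)))]])
  chosen_len <- lens[match(chosen, starts)]
  min_tract <- if (length(chosen) >= 4L) min(chosen_len) else 0
  if (length(chosen) >= 2L) {
    loop_start <- chosen[-length(chosen)] + chosen_len[-length(chosen)]
    loop_end <- chosen[-1] - 1L
    loop_len <- loop_end - loop_start + 1L
    loops <- substring(sequence, loop_start, loop_end)
    loop_seq <- paste(loops, collapse = "")
    nb <- nchar(loop_seq)
    frac_a <- if (nb > 0) {
      am <- gregexpr("A", loop_seq, fixed = TRUE)[[1]]
      (if (am[1] == -1L) 0L else length(am)) / nb
    } else 0
    list(min_tract = min_tract, mean_loop = mean(loop_len),
         frac_a_loop = frac_a, n_tracts = length(starts))
  } else {
    list(min_tract = 0, mean_loop = 0, frac_a_loop = 0,
         n_tracts = length(starts))
  }
}

#' Toy thermodynamic oracle for synthetic G4 melting temperatures
#'
#' A deliberately simple additive ground truth used to generate testable
#' synthetic data (it is a test instrument, not a biophysical claim):
#'
#' \deqn{T_m = \beta_0 + \beta_1 \cdot \mathrm{minTract}
#'   - \beta_2 \cdot \mathrm{meanLoop} - \beta_3 \cdot \mathrm{fracA}
#'   + \beta_4 \log_{10}(1 + [K^+] + 0.5 [Na^+] + 0.25 [Li/NH_4^+])}
#'
#' with defaults beta = (20, 8, 1.2, 4, 12). By construction Tm is
#' monotone increasing in K+, monotone decreasing in mean loop length,
#' and K+ stabilises more than Na+ at equal molarity — the qualitative
#' determinants a trained model must recover.
#'
#' @param sequence character vector of A/C/G/T strings.
#' @param conc_k,conc_na,conc_li_nh4 concentrations in mM (recycled).
#' @param ph pH (present for interface symmetry; the default oracle does
#'   not use it).
#' @param beta numeric length-5 coefficient vector (beta0..beta4).
#' @return numeric vector of noise-free melting temperatures (degC).
#' @export
oracleTm <- function(sequence, conc_k, conc_na, conc_li_nh4, ph = 7,
                     beta = c(20, 8, 1.2, 4, 12)) {
  stopifnot(length(beta) == 5L)
  feats <- lapply(sequence, g4StructuralFeatures)
  mt <- vapply(feats, `[[`, 0, "min_tract")
  ml <- vapply(feats, `[[`, 0, "mean_loop")
  fa <- vapply(feats, `[[`, 0, "frac_a_loop")
  ion <- log10(1 + conc_k + 0.5 * conc_na + 0.25 * conc_li_nh4)
  beta[1] + beta[2] * mt - beta[3] * ml - beta[4] * fa + beta[5] * ion
}

#' Configuration for the synthetic G4 dataset generator
#'
#' Defaults define the study conditions used throughout testing:
#' guanine-tract-rich sequences of 12-60 nt built from 4 G-tracts
#' (length 2-5) joined by loops (length 1-7) of A/T/C bases, conditions
#' drawn from grids over 0-200 mM with one dominant cation per record,
#' pH a point mass at 7.0 plus spread over nearby values, and observed
#' Tm = oracle + Gaussian noise with sd 2 degC.
#'
#' @param n_records number of records to generate.
#' @param length_range allowed sequence length range (nt).
#' @param tract_lengths candidate G-tract lengths.
#' @param loop_lengths candidate loop lengths.
#' @param loop_base_probs named probabilities for loop bases A/T/C.
#' @param conc_grid candidate concentrations (mM) for the dominant
#'   cation.
#' @param ph_values,ph_probs pH support and probabilities.
#' @param beta oracle coefficients, see [oracleTm()].
#' @param noise_sd Gaussian noise sd on observed Tm (degC).
#' @param rng_seed integer seed.
#' @return a classed list (`SynthConfig`).
#' @export
synthConfig <- function(n_records = 2000L,
                        length_range = c(12L, 60L),
                        tract_lengths = 2:5,
                        loop_lengths = 1:7,
                        loop_base_probs = c(A = 0.35, T = 0.45, C = 0.20),
                        conc_grid = c(0, 1, 5, 10, 25, 50, 70, 100, 150, 200),
                        ph_values = c(6.5, 7.0, 7.2, 7.4, 8.0),
                        ph_probs = c(0.05, 0.60, 0.15, 0.15, 0.05),
                        beta = c(20, 8, 1.2, 4, 12),
                        noise_sd = 2,
                        rng_seed = 1L) {
  stopifnot(n_records >= 1, length(length_range) == 2L,
            length_range[1] >= 5L, length_range[2] <= 99L,
            abs(sum(loop_base_probs) - 1) < 1e-8,
            abs(sum(ph_probs) - 1) < 1e-8, noise_sd >= 0)
  structure(as.list(environment()), class = "SynthConfig")
}

.synth_sequence <- function(config) {
  repeat {
    nt <- 4L
    tl <- sample(config$tract_lengths, nt, replace = TRUE)
    ll <- sample(config$loop_lengths, nt - 1L, replace = TRUE)
    loops <- vapply(ll, function(n) {
      paste(sample(names(config$loop_base_probs), n, replace = TRUE,
                   prob = config$loop_base_probs), collapse = "")
    }, "")
    # occasional short non-G flanks, as in curated oligos
    flank <- function() {
      n <- sample(0:2, 1L)
      if (n == 0L) "" else
        paste(sample(c("A", "T", "C"), n, replace = TRUE), collapse = "")
    }
    parts <- character(2L * nt - 1L)
    parts[seq(1L, 2L * nt - 1L, by = 2L)] <- strrep("G", tl)
    parts[seq(2L, 2L * nt - 2L, by = 2L)] <- loops
    s <- paste0(flank(), paste(parts, collapse = ""), flank())
    L <- nchar(s)
    if (L >= config$length_range[1] && L <= config$length_range[2]) return(s)
  }
}

.synth_condition <- function(config) {
  dominant <- sample(1:3, 1L, prob = c(0.55, 0.3, 0.15))
  conc <- c(0, 0, 0)
  conc[dominant] <- sample(config$conc_grid, 1L)
  # occasionally a mixed buffer (e.g. cancer-like K+/Na+ mixtures)
  if (runif(1) < 0.2) {
    other <- sample(setdiff(1:3, dominant), 1L)
    conc[other] <- sample(config$conc_grid[config$conc_grid <= conc[dominant]],
                          1L)
  }
  conc
}

#' Generate a synthetic G4 thermodynamic dataset
#'
#' Seeded and reproducible. Observed Tm is the [oracleTm()] value plus
#' Gaussian noise (clipped into the representable 0-120 degC range);
#' the noise-free ground truth is returned as a sidecar attribute (and
#' written to a separate file by the CLI) so that recovery tests can
#' compare against it without any pipeline stage consuming it by
#' accident.
#'
#' @param config a [synthConfig()].
#' @return a [G4Dataset-class]; `attr(x, "tm_true")` holds the
#'   noise-free oracle values, aligned with the records.
#' @export
generateG4Records <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$rng_seed)
  n <- config$n_records
  seqs <- character(n)
  conc <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    seqs[i] <- .synth_sequence(config)
    conc[i, ] <- .synth_condition(config)
  }
  ph <- sample(config$ph_values, n, replace = TRUE, prob = config$ph_probs)
  tm_true <- oracleTm(seqs, conc[, 1], conc[, 2], conc[, 3], ph,
                      beta = config$beta)
  tm_obs <- pmin(pmax(tm_true + rnorm(n, 0, config$noise_sd), 0), 120)
  ds <- G4Dataset(
    data.frame(sequence = seqs, tm_celsius = tm_obs,
               conc_k = conc[, 1], conc_na = conc[, 2],
               conc_li_nh4 = conc[, 3], ph = ph,
               source = "synthetic-oracle", method = NA_character_,
               stringsAsFactors = FALSE),
    provenance = list(path = NA_character_,
                      generator = "g4melt::generateG4Records",
                      rng_seed = config$rng_seed)
  )
  attr(ds, "tm_true") <- tm_true
  ds
}

.EG4_CHROMS <- c(as.character(1:22), "X", "Y", "M")

#' Generate a synthetic eG4 genomic table
#'
#' Emulates the shape of genome-wide experimentally-validated G4 tables:
#' id, chromosome, 0-based half-open coordinates, strand, gene-type
#' label and sequence. Positions are uniform per chromosome unless
#' `hotspot` names a (chrom, start_mb) pair, in which case an extra
#' `hotspot_fraction` of records is concentrated in that 1-Mb bin.
#'
#' @param n number of rows.
#' @param config a [synthConfig()] (used for sequence generation and the
#'   seed).
#' @param chrom_length_mb chromosome length (Mb) used for uniform
#'   placement (single value, applied to every chromosome).
#' @param gene_type_probs named categorical distribution of gene types.
#' @param hotspot optional `list(chrom=, start_mb=)` 1-Mb hotspot.
#' @param hotspot_fraction fraction of rows placed in the hotspot bin.
#' @return data.frame with columns `id, chrom, start, end, strand,
#'   gene_type, sequence` (write with [writeEG4Table()]).
#' @export
generateEG4Table <- function(n = 5000L, config = synthConfig(),
                             chrom_length_mb = 50,
                             gene_type_probs = c(protein_coding = 0.60,
                                                 lncRNA = 0.14,
                                                 pseudogene = 0.10,
                                                 lincRNA = 0.05,
                                                 miRNA = 0.04,
                                                 snoRNA = 0.03,
                                                 snRNA = 0.02,
                                                 IG_C = 0.02),
                             hotspot = NULL, hotspot_fraction = 0.2) {
  stopifnot(inherits(config, "SynthConfig"),
            abs(sum(gene_type_probs) - 1) < 1e-8)
  set.seed(deriveSeed(config$rng_seed, 104729L))
  seqs <- vapply(seq_len(n), function(i) .synth_sequence(config), "")
  chrom <- sample(.EG4_CHROMS, n, replace = TRUE,
                  prob = c(rep(1, 22), 0.6, 0.3, 0.1) / sum(c(rep(1, 22), 0.6, 0.3, 0.1)))
  max_start <- chrom_length_mb * 1e6
  start <- floor(runif(n, 0, max_start))
  if (!is.null(hotspot)) {
    n_hot <- round(hotspot_fraction * n)
    idx <- seq_len(n_hot)
    chrom[idx] <- hotspot$chrom
    start[idx] <- floor(runif(n_hot, hotspot$start_mb * 1e6,
                              (hotspot$start_mb + 1) * 1e6))
  }
  data.frame(
    id = sprintf("eG4_%06d", seq_len(n)),
    chrom = chrom,
    start = start,
    end = start + nchar(seqs),
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_type = sample(names(gene_type_probs), n, replace = TRUE,
                       prob = gene_type_probs),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic (or any) eG4 table as TSV
#' @param x data.frame in the eG4 schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEG4Table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
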