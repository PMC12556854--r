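#' Ionic-condition presets and constructor
#'
#' `ionicCondition()` builds a named (K+, Na+, Li+/NH4+) concentration
#' triple in mM. `conditionPreset()` returns one of the four standard
#' presets: `normal` (100, 0, 0) — the potassium-rich in vitro standard
#' approximating intracellular conditions; `moderate` (50, 0, 0);
#' `sodium` (0, 100, 0); `cancer` (70, 30, 0) — the elevated Na+/K+
#' ratio (30/70 ~ 0.43) observed across several cancer types.
#'
#' @param name condition label.
#' @param conc_k,conc_na,conc_li_nh4 concentrations in mM, all >= 0.
#' @return a classed list (`IonicCondition`).
#' @export
ionicCondition <- function(name, conc_k, conc_na, conc_li_nh4 = 0) {
  stopifnot(conc_k >= 0, conc_na >= 0, conc_li_nh4 >= 0)
  structure(list(name = name, conc_k = conc_k, conc_na = conc_na,
                 conc_li_nh4 = conc_li_nh4), class = "IonicCondition")
}

.PRESETS <- list(
  normal = c(100, 0, 0),
  moderate = c(50, 0, 0),
  sodium = c(0, 100, 0),
  cancer = c(70, 30, 0)
)

#' @rdname ionicCondition
#' @export
conditionPreset <- function(name) {
  if (!name %in% names(.PRESETS))
    .stopf("unknown condition preset '%s' (use %s)", name,
           paste(names(.PRESETS), collapse = ", "))
  v <- .PRESETS[[name]]
  ionicCondition(name, v[1], v[2], v[3])
}

#' @rdname ionicCondition
#' @export
conditionPresets <- function() {
  setNames(lapply(names(.PRESETS), conditionPreset), names(.PRESETS))
}

#' Read a genome-wide eG4 table
#'
#' Parses a TSV with header `id, chrom, start, end, strand, gene_type,
#' sequence` (optional `phastCons`, `phyloP`); coordinates are 0-based
#' half-open. Rows with `end <= start`, a sequence whose length differs
#' from `end - start`, an invalid strand or an invalid alphabet are
#' rejected and logged. Coordinates are normalised into a
#' [GenomicRanges::GRanges] (1-based closed, as usual for GRanges);
#' width therefore equals the sequence length.
#'
#' @param path TSV path.
#' @return a `GRanges` with mcols `id`, `gene_type`, `sequence` (and
#'   conservation scores when present); `S4Vectors::metadata()` carries
#'   the parse report.
#' @export
readEG4 <- function(path) {
  if (!file.exists(path)) .stopf("eG4 table not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "strand", "gene_type", "sequence")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    .stopf("eG4 table missing column(s): %s", paste(missing, collapse = ", "))
  raw$start <- suppressWarnings(as.numeric(raw$start))
  raw$end <- suppressWarnings(as.numeric(raw$end))
  raw$sequence <- toupper(raw$sequence)

  reason <- rep(NA_character_, nrow(raw))
  bad_coord <- is.na(raw$start) | is.na(raw$end) | raw$end <= raw$start |
    raw$start < 0
  reason[bad_coord] <- "malformed coordinates (need end > start >= 0)"
  bad_strand <- is.na(reason) & !(raw$strand %in% c("+", "-"))
  reason[bad_strand] <- "invalid strand"
  bad_seq <- is.na(reason) & !validDnaSequence(raw$sequence)
  reason[bad_seq] <- "invalid alphabet"
  bad_len <- is.na(reason) & (nchar(raw$sequence) != raw$end - raw$start)
  reason[bad_len] <- "sequence length != end - start"

  keep <- is.na(reason)
  kept <- raw[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = kept$chrom,
    ranges = IRanges::IRanges(start = kept$start + 1L, end = kept$end),
    strand = kept$strand)
  S4Vectors::mcols(gr)$id <- kept$id
  S4Vectors::mcols(gr)$gene_type <- kept$gene_type
  S4Vectors::mcols(gr)$sequence <- kept$sequence
  for (sc in intersect(c("phastCons", "phyloP"), names(kept)))
    S4Vectors::mcols(gr)[[sc]] <- kept[[sc]]
  S4Vectors::metadata(gr) <- list(parse_report = list(
    n_rows = nrow(raw), n_parsed = nrow(kept), n_rejected = sum(!keep),
    rejects = data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)))
  gr
}

#' Predict Tm of eG4 sequences under a set of ionic conditions
#'
#' Streams the table through the predictor in chunks so memory is
#' bounded by `chunk_size`, not table size. Sequences longer than the
#' 100-nt model window are recorded as unpredictable and excluded from
#' downstream summaries (the count is reported).
#'
#' @param g4s a `GRanges` from [readEG4()] or a data.frame in the eG4
#'   schema.
#' @param conditions list of [ionicCondition()] objects (default: the
#'   four presets).
#' @param predictor a trained [TmRegressor-class] or
#'   [TmEnsemble-class].
#' @param ph pH applied to every prediction.
#' @param chunk_size sequences per prediction chunk.
#' @return data.frame `id, condition, tm_mean, tm_sem` (one row per
#'   predictable sequence x condition), with attribute `"excluded"`
#'   (data.frame of unpredictable ids and reasons).
#' @export
profileConditions <- function(g4s, conditions = conditionPresets(),
                              predictor, ph = 7, chunk_size = 1000L) {
  df <- .eg4AsFrame(g4s)
  ok <- nchar(df$sequence) <= 100L & validDnaSequence(df$sequence)
  excluded <- data.frame(id = df$id[!ok],
                         reason = ifelse(nchar(df$sequence[!ok]) > 100L,
                                         "sequence exceeds model window",
                                         "invalid alphabet")[seq_len(sum(!ok))],
                         stringsAsFactors = FALSE)
  df <- df[ok, , drop = FALSE]
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    res <- vector("list", ceiling(nrow(df) / chunk_size))
    for (s in seq_len(length(res))) {
      idx <- ((s - 1L) * chunk_size + 1L):min(s * chunk_size, nrow(df))
      qd <- data.frame(sequence = df$sequence[idx], conc_k = cond$conc_k,
                       conc_na = cond$conc_na,
                       conc_li_nh4 = cond$conc_li_nh4, ph = ph,
                       stringsAsFactors = FALSE)
      pr <- predict(predictor, qd)
      res[[s]] <- if (is.data.frame(pr))
        data.frame(id = df$id[idx], condition = cond$name,
                   tm_mean = pr$tm_mean, tm_sem = pr$tm_sem,
                   stringsAsFactors = FALSE)
      else
        data.frame(id = df$id[idx], condition = cond$name, tm_mean = pr,
                   tm_sem = NA_real_, stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.eg4AsFrame <- function(g4s) {
  if (is(g4s, "GRanges")) {
    data.frame(id = S4Vectors::mcols(g4s)$id,
               chrom = as.character(GenomicRanges::seqnames(g4s)),
               start = GenomicRanges::start(g4s) - 1L,
               end = GenomicRanges::end(g4s),
               strand = as.character(GenomicRanges::strand(g4s)),
               gene_type = S4Vectors::mcols(g4s)$gene_type,
               sequence = S4Vectors::mcols(g4s)$sequence,
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(g4s, stringsAsFactors = FALSE)
  }
}

.skewness <- function(x) {
  # moment skewness g1 = m3 / m2^(3/2) (biased moments)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

.cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Kruskal-Wallis effect size eta-squared
#'
#' The convention eta2 = (H - k + 1) / (n - k), with H the
#' Kruskal-Wallis statistic, k the group count and n the total sample
#' size.
#'
#' @param H Kruskal-Wallis chi-squared statistic.
#' @param k number of groups.
#' @param n total observations.
#' @return eta-squared.
#' @export
kruskalEta2 <- function(H, k, n) (H - k + 1) / (n - k)

.shapiroW <- function(x) {
  # shapiro.test accepts 3..5000 values; larger vectors are reduced to a
  # deterministic evenly-spaced subsample of 5000
  if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p_value = st$p.value,
       n_used = length(x))
}

#' Compare Tm profiles between two ionic conditions
#'
#' Produces the genome-scale comparison summary: 1-degC left-closed
#' histograms per condition; per-chromosome mean/median/sd; per-gene-
#' type statistics restricted to types with at least `min_gene_type_n`
#' G4s; counts inside the physiological window (36-42 degC, closed on
#' both ends) overall, per chromosome and per gene type, with the
#' fold change `count_b / count_a` (flagged undefined when the
#' reference count is zero); and a statistics block: Shapiro-Wilk W and
#' skewness per condition, Levene W (Brown-Forsythe, median-centred),
#' Welch t with df and 95% CI of the mean difference (a - b), Cohen's d
#' (pooled sd), Kruskal-Wallis H with eta-squared on the per-record Tm
#' shifts (a - b, paired by id) across gene types, and a Fisher exact
#' test on physiological-window counts (protein-coding vs other) by
#' condition.
#'
#' @param profile output of [profileConditions()].
#' @param condition_a,condition_b condition names present in `profile`
#'   (`a` is the reference, e.g. `"normal"`; `b` the comparison, e.g.
#'   `"cancer"`).
#' @param g4s the `GRanges`/data.frame the profile was computed from
#'   (source of chromosome and gene-type labels).
#' @param min_gene_type_n minimum G4 count for a gene type to enter the
#'   per-type tables (default 100).
#' @return a list of class `GenomeSummary`.
#' @export
compareConditions <- function(profile, condition_a, condition_b, g4s,
                              min_gene_type_n = 100L) {
  stopifnot(all(c(condition_a, condition_b) %in% profile$condition))
  meta <- .eg4AsFrame(g4s)[, c("id", "chrom", "gene_type")]
  a <- profile[profile$condition == condition_a, c("id", "tm_mean")]
  b <- profile[profile$condition == condition_b, c("id", "tm_mean")]
  m <- merge(merge(a, b, by = "id", suffixes = c("_a", "_b")), meta,
             by = "id")
  if (!nrow(m)) .stopf("no shared ids between conditions")
  ta <- m$tm_mean_a; tb <- m$tm_mean_b

  hist1c <- function(x) {
    lo <- floor(min(x)); hi <- ceiling(max(x))
    if (hi == lo) hi <- lo + 1
    breaks <- lo:hi
    cnt <- integer(length(breaks) - 1L)
    bin <- pmin(pmax(floor(x), lo), hi - 1L) - lo + 1L
    tb_ <- table(bin)
    cnt[as.integer(names(tb_))] <- as.integer(tb_)
    data.frame(bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1L], count = cnt)
  }

  per_group <- function(x, g) {
    do.call(rbind, lapply(split(x, g), function(v)
      data.frame(n = length(v), mean = mean(v), median = median(v),
                 sd = if (length(v) > 1) sd(v) else NA_real_)))
  }
  chrom_a <- per_group(ta, m$chrom); chrom_a$chrom <- rownames(chrom_a)
  chrom_b <- per_group(tb, m$chrom); chrom_b$chrom <- rownames(chrom_b)

  type_counts <- table(m$gene_type)
  big_types <- names(type_counts)[type_counts >= min_gene_type_n]
  dropped_types <- setdiff(names(type_counts), big_types)
  mt <- m[m$gene_type %in% big_types, , drop = FALSE]
  gene_type_stats <- NULL
  if (nrow(mt)) {
    gt_a <- per_group(mt$tm_mean_a, mt$gene_type)
    gt_b <- per_group(mt$tm_mean_b, mt$gene_type)
    gene_type_stats <- data.frame(
      gene_type = rownames(gt_a), n = gt_a$n,
      mean_a = gt_a$mean, sd_a = gt_a$sd,
      mean_b = gt_b$mean, sd_b = gt_b$sd,
      mean_shift = gt_a$mean - gt_b$mean, row.names = NULL)
    # descending total abundance, the standard ordering for these tables
    gene_type_stats <- gene_type_stats[order(-gene_type_stats$n), ]
  }

  in_win <- function(x) x >= 36 & x <= 42
  win_a <- in_win(ta); win_b <- in_win(tb)
  fold <- if (sum(win_a) == 0) NA_real_ else sum(win_b) / sum(win_a)
  tab_count <- function(w, g) {
    lv <- sort(unique(g))
    cnt <- table(factor(g[w], levels = lv))
    data.frame(group = lv, count = as.integer(cnt), row.names = NULL)
  }
  window_counts <- list(
    total_a = sum(win_a), total_b = sum(win_b),
    fold_change = fold,
    fold_change_defined = sum(win_a) > 0,
    per_chrom = merge(setNames(tab_count(win_a, m$chrom), c("chrom", "count_a")),
                      setNames(tab_count(win_b, m$chrom), c("chrom", "count_b")),
                      by = "chrom"),
    per_gene_type = merge(
      setNames(tab_count(win_a, m$gene_type), c("gene_type", "count_a")),
      setNames(tab_count(win_b, m$gene_type), c("gene_type", "count_b")),
      by = "gene_type"))

  tt <- stats::t.test(ta, tb)  # Welch by default
  lev <- car::leveneTest(c(ta, tb),
                         factor(rep(c("a", "b"), c(length(ta), length(tb)))))
  shift <- ta - tb
  stats_block <- list(
    shapiro_a = .shapiroW(ta), shapiro_b = .shapiroW(tb),
    skewness_a = .skewness(ta), skewness_b = .skewness(tb),
    levene = list(W = lev$`F value`[1], p_value = lev$`Pr(>F)`[1]),
    welch = list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_diff = mean(ta) - mean(tb),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2]),
    cohens_d = .cohensD(ta, tb),
    mean_shift = mean(shift), median_shift = median(shift)
  )
  if (length(unique(m$gene_type)) >= 2L) {
    kw <- stats::kruskal.test(shift, factor(m$gene_type))
    stats_block$kruskal_shift <- list(
      H = unname(kw$statistic), p_value = kw$p.value,
      eta_squared = kruskalEta2(unname(kw$statistic),
                                length(unique(m$gene_type)), length(shift)))
  }
  pc <- m$gene_type == "protein_coding"
  fisher_tab <- matrix(c(sum(win_a & pc), sum(win_a & !pc),
                         sum(win_b & pc), sum(win_b & !pc)), nrow = 2L)
  ft <- stats::fisher.test(fisher_tab)
  stats_block$fisher_window <- list(p_value = ft$p.value,
                                    table = fisher_tab)

  out <- list(
    condition_a = condition_a, condition_b = condition_b,
    n = nrow(m),
    histogram_a = hist1c(ta), histogram_b = hist1c(tb),
    per_chrom_a = chrom_a[, c("chrom", "n", "mean", "median", "sd")],
    per_chrom_b = chrom_b[, c("chrom", "n", "mean", "median", "sd")],
    gene_type_stats = gene_type_stats,
    dropped_gene_types = dropped_types,
    window_counts = window_counts,
    stats = stats_block)
  class(out) <- "GenomeSummary"
  out
}

#' @export
print.GenomeSummary <- function(x, ...) {
  cat(sprintf("GenomeSummary: %s vs %s over %d G4s\n", x$condition_a,
              x$condition_b, x$n))
  cat(sprintf("  mean shift (a - b): %.2f degC | Cohen's d %.3f\n",
              x$stats$mean_shift, x$stats$cohens_d))
  cat(sprintf("  physiological window (36-42 degC): %d -> %d (fold %s)\n",
              x$window_counts$total_a, x$window_counts$total_b,
              ifelse(x$window_counts$fold_change_defined,
                     sprintf("%.2f", x$window_counts$fold_change),
                     "undefined")))
  invisible(x)
}

#' Positional G4 density in fixed genomic bins
#'
#' Bins are half-open `[k * size, (k+1) * size)` in 0-based
#' coordinates; a G4 is assigned by its start, so one sitting exactly on
#' a boundary opens the right-hand bin. Counts (and mean Tm when a
#' profile is supplied) are reported per chromosome, strand and bin.
#'
#' @param g4s `GRanges` or eG4 data.frame.
#' @param bin_size bin width in bp (default 1 Mb).
#' @param profile optional [profileConditions()] output.
#' @param condition condition name to take Tm values from (required
#'   with `profile`).
#' @return data.frame `chrom, strand, bin, bin_start, count[, mean_tm]`.
#' @export
positionalDensity <- function(g4s, bin_size = 1e6, profile = NULL,
                              condition = NULL) {
  df <- .eg4AsFrame(g4s)
  df$bin <- df$start %/% bin_size
  if (!is.null(profile)) {
    stopifnot(!is.null(condition))
    pp <- profile[profile$condition == condition, c("id", "tm_mean")]
    df <- merge(df, pp, by = "id", all.x = TRUE)
  }
  key <- interaction(df$chrom, df$strand, df$bin, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(s)
    data.frame(chrom = s$chrom[1], strand = s$strand[1], bin = s$bin[1],
               bin_start = s$bin[1] * bin_size, count = nrow(s),
               mean_tm = if (!is.null(s$tm_mean)) mean(s$tm_mean)
                         else NA_real_,
               stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$strand, out$bin), ]
  rownames(out) <- NULL
  out
}
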