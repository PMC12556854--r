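#' Generate a G4 motif sequence from a family and its parameters
#'
#' Three canonical motif families are supported:
#' \describe{
#'   \item{`loop_length`}{`G3 Bn G3 Bn G3 Bn G3` — four G3 tracts joined
#'     by three loops of base `loop_base` (A or T) and length
#'     `loop_length` in 1..7.}
#'   \item{`tract_grid`}{`(Gn Tx)4` — four repeats of a G-tract of
#'     length `tract_length` (2..7) followed by a thymine stretch of
#'     length `t_stretch` (1..7).}
#'   \item{`central_loop`}{`A G3 L G3 (TTA)n G3 L G3 T` with flank loop
#'     `L` in TTA/TTT and central repeat count `n` in 1, 3, ..., 25.}
#' }
#' Family ranges are soft limits: out-of-range parameters are allowed
#' with a warning. Every generated sequence matches its defining
#' regular expression ([motifPattern()]).
#'
#' @param family one of `"loop_length"`, `"tract_grid"`,
#'   `"central_loop"`.
#' @param loop_base,loop_length loop base and length (`loop_length`
#'   family).
#' @param tract_length,t_stretch G-tract length and T-stretch
#'   (`tract_grid` family).
#' @param flank_loop,central_repeats flank loop (TTA/TTT) and central
#'   (TTA)n repeat count (`central_loop` family).
#' @return a single DNA sequence string.
#' @examples
#' generateMotif("tract_grid", tract_length = 3, t_stretch = 1)
#' # "GGGTGGGTGGGTGGGT"
#' @export
generateMotif <- function(family = c("loop_length", "tract_grid",
                                     "central_loop"),
                          loop_base = "T", loop_length = 1L,
                          tract_length = 3L, t_stretch = 1L,
                          flank_loop = "TTA", central_repeats = 1L) {
  family <- match.arg(family)
  g3 <- strrep("G", 3L)
  switch(family,
    loop_length = {
      if (!loop_base %in% c("A", "T"))
        .stopf("loop_base must be A or T")
      if (loop_length < 1 || loop_length > 7)
        .warnf("loop_length %d outside the canonical 1..7 range", loop_length)
      loop <- strrep(loop_base, loop_length)
      paste0(g3, loop, g3, loop, g3, loop, g3)
    },
    tract_grid = {
      if (tract_length < 2 || tract_length > 7)
        .warnf("tract_length %d outside the canonical 2..7 range",
               tract_length)
      if (t_stretch < 1 || t_stretch > 7)
        .warnf("t_stretch %d outside the canonical 1..7 range", t_stretch)
      strrep(paste0(strrep("G", tract_length), strrep("T", t_stretch)), 4L)
    },
    central_loop = {
      if (!flank_loop %in% c("TTA", "TTT"))
        .stopf("flank_loop must be TTA or TTT")
      if (central_repeats < 1 || central_repeats > 25)
        .warnf("central_repeats %d outside the canonical 1..25 range",
               central_repeats)
      paste0("A", g3, flank_loop, g3, strrep("TTA", central_repeats),
             g3, flank_loop, g3, "T")
    })
}

#' Defining regular expression of a motif family instance
#' @inheritParams generateMotif
#' @return a regex string anchored at both ends.
#' @export
motifPattern <- function(family, loop_base = "T", loop_length = 1L,
                         tract_length = 3L, t_stretch = 1L,
                         flank_loop = "TTA", central_repeats = 1L) {
  switch(family,
    loop_length = sprintf("^GGG(%s{%d}GGG){3}$", loop_base, loop_length),
    tract_grid = sprintf("^(G{%d}T{%d}){4}$", tract_length, t_stretch),
    central_loop = sprintf("^AGGG%sGGG(TTA){%d}GGG%sGGGT$",
                           flank_loop, central_repeats, flank_loop),
    .stopf("unknown motif family: %s", family))
}

#' Standard motif grids for the stability scans
#'
#' `loopLengthGrid()`: A and T loops, lengths 1..7. `tractGrid()`:
#' G-tract lengths 2..7 crossed with T-stretches 1..7.
#' `centralLoopGrid()`: TTA and TTT flank loops, central repeats
#' 1, 3, ..., 25.
#'
#' @param bases,n,x,flanks grid ranges (see defaults).
#' @return data.frame of motif specs with `motif_id`, `family`,
#'   parameter columns and `sequence`.
#' @export
loopLengthGrid <- function(bases = c("A", "T"), n = 1:7) {
  g <- expand.grid(loop_base = bases, loop_length = n,
                   stringsAsFactors = FALSE)
  data.frame(
    motif_id = sprintf("loop_%s%d", g$loop_base, g$loop_length),
    family = "loop_length", g,
    sequence = mapply(function(b, l) generateMotif("loop_length",
                                                   loop_base = b,
                                                   loop_length = l),
                      g$loop_base, g$loop_length, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' @rdname loopLengthGrid
#' @export
tractGrid <- function(n = 2:7, x = 1:7) {
  g <- expand.grid(tract_length = n, t_stretch = x)
  data.frame(
    motif_id = sprintf("tract_G%dT%d", g$tract_length, g$t_stretch),
    family = "tract_grid", g,
    sequence = mapply(function(tl, ts) generateMotif("tract_grid",
                                                     tract_length = tl,
                                                     t_stretch = ts),
                      g$tract_length, g$t_stretch, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' @rdname loopLengthGrid
#' @export
centralLoopGrid <- function(flanks = c("TTA", "TTT"), n = seq(1L, 25L, 2L)) {
  g <- expand.grid(flank_loop = flanks, central_repeats = n,
                   stringsAsFactors = FALSE)
  data.frame(
    motif_id = sprintf("central_%s_n%02d", g$flank_loop, g$central_repeats),
    family = "central_loop", g,
    sequence = mapply(function(fl, cr) generateMotif("central_loop",
                                                     flank_loop = fl,
                                                     central_repeats = cr),
                      g$flank_loop, g$central_repeats, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Default ionic-condition grid for motif scans
#'
#' The four physiological presets plus a 1 mM / 100 mM K+-vs-Na+ grid;
#' pH is fixed at 7.0 (the most common dataset value) unless overridden
#' in [scanStability()].
#' @return named list of [ionicCondition()] objects.
#' @export
scanConditions <- function() {
  c(conditionPresets(),
    list(K_1mM = ionicCondition("K_1mM", 1, 0, 0),
         Na_1mM = ionicCondition("Na_1mM", 0, 1, 0),
         Na_100mM = ionicCondition("Na_100mM", 0, 100, 0)))
}

#' Tabulate predicted stability of motif grids across ionic conditions
#'
#' One row per (motif, condition); output is a pure function of the
#' specs, the conditions and the predictor artifact. With an ensemble
#' predictor the SEM column is filled; with a single regressor it is
#' NA.
#'
#' @param specs motif spec data.frame from [loopLengthGrid()],
#'   [tractGrid()], [centralLoopGrid()], or any data.frame with
#'   `motif_id`, `family`, parameter columns and `sequence`.
#' @param conditions list of [ionicCondition()] objects.
#' @param predictor a trained [TmRegressor-class] or
#'   [TmEnsemble-class].
#' @param ph pH applied to every prediction (default 7).
#' @return `StabilityScanTable` data.frame: spec columns plus
#'   `condition`, `conc_k`, `conc_na`, `conc_li_nh4`, `ph`, `tm_mean`,
#'   `tm_sem`.
#' @export
scanStability <- function(specs, conditions = scanConditions(), predictor,
                          ph = 7) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1L, length(conditions) >= 1L)
  rows <- lapply(conditions, function(cond) {
    qd <- data.frame(sequence = specs$sequence, conc_k = cond$conc_k,
                     conc_na = cond$conc_na, conc_li_nh4 = cond$conc_li_nh4,
                     ph = ph, stringsAsFactors = FALSE)
    pr <- predict(predictor, qd)
    if (is.data.frame(pr)) {
      tm_mean <- pr$tm_mean; tm_sem <- pr$tm_sem
    } else {
      tm_mean <- pr; tm_sem <- NA_real_
    }
    cbind(specs,
          data.frame(condition = cond$name, conc_k = cond$conc_k,
                     conc_na = cond$conc_na, conc_li_nh4 = cond$conc_li_nh4,
                     ph = ph, tm_mean = tm_mean, tm_sem = tm_sem,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("StabilityScanTable", "data.frame")
  out
}

.scan_param_col <- c(loop_length = "loop_length", tract_grid = "tract_length",
                     central_loop = "central_repeats")

#' Derived-effect summary of a stability scan
#'
#' Per family and condition: the mean Tm change per unit of the family's
#' primary parameter (loop length, G-tract length, or central repeat
#' count). Per K+/Na+ condition pair at matched concentration: the mean
#' stabilisation difference Tm(K+) - Tm(Na+). For the `loop_length`
#' family, a simple interaction effect: the difference-of-differences
#' between A and T loops across the two cations. Insufficient coverage
#' yields a partial report with `flags`.
#'
#' @param table a `StabilityScanTable` from [scanStability()].
#' @return list with `slopes`, `cation_diff`, `interaction`, `flags`.
#' @export
trendReport <- function(table) {
  stopifnot(inherits(table, "data.frame"))
  flags <- character(0)
  slopes <- NULL
  for (fam in intersect(unique(table$family), names(.scan_param_col))) {
    pc <- .scan_param_col[[fam]]
    sub <- table[table$family == fam, ]
    grp_cols <- switch(fam,
                       loop_length = c("condition", "loop_base"),
                       tract_grid = c("condition", "t_stretch"),
                       central_loop = c("condition", "flank_loop"))
    sp <- do.call(rbind, lapply(split(sub, sub[grp_cols]), function(s) {
      s <- s[order(s[[pc]]), ]
      if (nrow(s) < 2L) return(NULL)
      data.frame(family = fam,
                 s[1L, grp_cols, drop = FALSE],
                 slope = mean(diff(s$tm_mean) / diff(s[[pc]])),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    slopes <- rbind(slopes, sp)
  }
  if (is.null(slopes)) flags <- c(flags, "no family with >= 2 parameter values")

  # matched-concentration K vs Na stabilisation difference
  kc <- table[table$conc_na == 0 & table$conc_li_nh4 == 0 & table$conc_k > 0, ]
  nac <- table[table$conc_k == 0 & table$conc_li_nh4 == 0 & table$conc_na > 0, ]
  cation_diff <- NULL
  if (nrow(kc) && nrow(nac)) {
    shared <- intersect(unique(kc$conc_k), unique(nac$conc_na))
    cation_diff <- do.call(rbind, lapply(shared, function(cm) {
      a <- kc[kc$conc_k == cm, c("motif_id", "tm_mean")]
      b <- nac[nac$conc_na == cm, c("motif_id", "tm_mean")]
      m <- merge(a, b, by = "motif_id", suffixes = c("_k", "_na"))
      if (!nrow(m)) return(NULL)
      data.frame(conc_mM = cm, mean_k_minus_na = mean(m$tm_mean_k - m$tm_mean_na),
                 n_motifs = nrow(m))
    }))
  }
  if (is.null(cation_diff))
    flags <- c(flags, "no matched K+/Na+ concentration pair")

  interaction <- NA_real_
  ll <- table[table$family == "loop_length", ]
  if (nrow(ll) && length(unique(ll$loop_base)) == 2L &&
      !is.null(cation_diff)) {
    shared <- intersect(unique(kc$conc_k), unique(nac$conc_na))
    if (length(shared)) {
      cm <- max(shared)
      cell <- function(base, cond_is_k) {
        s <- if (cond_is_k) ll[ll$conc_k == cm & ll$conc_na == 0, ]
             else ll[ll$conc_na == cm & ll$conc_k == 0, ]
        mean(s$tm_mean[s$loop_base == base])
      }
      interaction <- (cell("A", TRUE) - cell("A", FALSE)) -
                     (cell("T", TRUE) - cell("T", FALSE))
    }
  }
  list(slopes = slopes, cation_diff = cation_diff,
       interaction = interaction, flags = flags)
}
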