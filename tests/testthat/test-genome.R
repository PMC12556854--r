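test_that("condition presets carry the stated concentrations", {
  p <- conditionPresets()
  expect_equal(unlist(p$normal[c("conc_k", "conc_na", "conc_li_nh4")]),
               c(conc_k = 100, conc_na = 0, conc_li_nh4 = 0))
  expect_equal(p$moderate$conc_k, 50)
  expect_equal(p$sodium$conc_na, 100)
  expect_equal(unlist(p$cancer[c("conc_k", "conc_na")]),
               c(conc_k = 70, conc_na = 30))
  expect_equal(p$cancer$conc_na / p$cancer$conc_k, 30 / 70)
  expect_error(conditionPreset("seawater"), "unknown")
})

test_that("eG4 parsing validates rows and normalises coordinates", {
  tab <- generateEG4Table(n = 10, config = synthConfig(rng_seed = 41))
  f <- tempfile(fileext = ".tsv")
  writeEG4Table(tab, f)
  gr <- readEG4(f)
  expect_equal(length(gr), 10L)

  tab$end[3] <- tab$start[3]          # end <= start
  tab$strand[5] <- "*"
  tab$sequence[7] <- "GGNNGG"
  writeEG4Table(tab, f)
  gr2 <- readEG4(f)
  rep_ <- S4Vectors::metadata(gr2)$parse_report
  expect_equal(length(gr2), 7L)
  expect_equal(rep_$n_rejected, 3L)
  expect_setequal(rep_$rejects$row, c(3L, 5L, 7L))
})

test_that("profiles are locus-blind and cover every condition", {
  fit <- tinyTrainedModel()
  tab <- generateEG4Table(n = 6, config = synthConfig(rng_seed = 43))
  tab$sequence[2] <- tab$sequence[1]  # same sequence, different locus
  prof <- profileConditions(tab, conditionPresets(), fit)
  expect_equal(nrow(prof), 6L * 4L)
  expect_setequal(unique(prof$condition),
                  c("normal", "moderate", "sodium", "cancer"))
  for (cn in unique(prof$condition)) {
    sub <- prof[prof$condition == cn, ]
    expect_equal(sub$tm_mean[sub$id == tab$id[1]],
                 sub$tm_mean[sub$id == tab$id[2]])
  }
  # one sequence x the four presets -> 4 rows
  prof1 <- profileConditions(tab[1, ], conditionPresets(), fit)
  expect_equal(nrow(prof1), 4L)
})

test_that("over-long sequences are excluded and counted, not dropped silently", {
  fit <- tinyTrainedModel()
  tab <- generateEG4Table(n = 4, config = synthConfig(rng_seed = 47))
  tab$sequence[2] <- strrep("G", 120)
  tab$end[2] <- tab$start[2] + 120
  prof <- profileConditions(tab, list(conditionPreset("normal")), fit)
  expect_equal(nrow(prof), 3L)
  excl <- attr(prof, "excluded")
  expect_equal(excl$id, tab$id[2])
  expect_match(excl$reason, "window")
})

# A constructed profile: condition b is exactly a -2.4 degC, plus known
# window counts, so every summary number has a brute-force expectation.
.constructedProfile <- function(n = 5000L, seed = 71L) {
  set.seed(seed)
  tab <- generateEG4Table(n = n, config = synthConfig(rng_seed = seed))
  # background Tm kept >= 46 degC so neither condition's background can
  # enter the 36-42 window (b = a - 2.4 >= 43.6)
  tm_a <- pmin(pmax(rnorm(n, 62, 7), 46), 95)
  # plant known physiological-window counts: 2 in a, 27 in b
  tm_a[1] <- 36.5                        # in window for a, out for b (34.1)
  tm_a[2] <- 41.5                        # in window for both (b: 39.1)
  tm_a[3:28] <- runif(26, 39.61, 41.5) + 2.4  # out for a (>42), in for b
  tm_b <- tm_a - 2.4                     # the shift is uniform everywhere
  stopifnot(sum(tm_a >= 36 & tm_a <= 42) == 2,
            sum(tm_b >= 36 & tm_b <= 42) == 27)
  prof <- rbind(
    data.frame(id = tab$id, condition = "normal", tm_mean = tm_a,
               tm_sem = 0),
    data.frame(id = tab$id, condition = "cancer", tm_mean = tm_b,
               tm_sem = 0))
  list(tab = tab, prof = prof, tm_a = tm_a, tm_b = tm_b)
}

test_that("a uniform -2.4 degC shift is summarised exactly", {
  cp <- .constructedProfile()
  cmp <- compareConditions(cp$prof, "normal", "cancer", cp$tab)
  expect_equal(cmp$n, 5000L)
  expect_equal(cmp$stats$mean_shift, 2.4, tolerance = 1e-9)
  # histogram totals equal the number of predictable sequences
  expect_equal(sum(cmp$histogram_a$count), 5000L)
  expect_equal(sum(cmp$histogram_b$count), 5000L)
  # brute-force 1 degC bins, left-closed
  brute_bin <- table(floor(cp$tm_a))
  got <- cmp$histogram_a$count[match(as.integer(names(brute_bin)),
                                     cmp$histogram_a$bin_left)]
  expect_equal(got, unname(as.integer(brute_bin)))
  # closed physiological window and fold-change arithmetic
  expect_equal(cmp$window_counts$total_a, 2L)
  expect_equal(cmp$window_counts$total_b, 27L)
  expect_equal(cmp$window_counts$fold_change, 13.5)
  # Welch machinery on the constructed shift
  expect_equal(cmp$stats$welch$mean_diff, 2.4, tolerance = 1e-9)
  expect_equal(cmp$stats$cohens_d,
               2.4 / sqrt((var(cp$tm_a) + var(cp$tm_b)) / 2),
               tolerance = 1e-6)
})

test_that("comparing a condition against itself yields null effects", {
  cp <- .constructedProfile(n = 800, seed = 73)
  prof <- cp$prof
  prof$tm_mean[prof$condition == "cancer"] <-
    prof$tm_mean[prof$condition == "normal"]
  cmp <- compareConditions(prof, "normal", "cancer", cp$tab)
  expect_equal(cmp$stats$welch$t, 0, tolerance = 1e-12)
  expect_equal(cmp$stats$mean_shift, 0)
  expect_equal(cmp$stats$cohens_d, 0)
  fc <- cmp$window_counts$fold_change
  expect_true(is.na(fc) || fc == 1)
})

test_that("the statistics block matches reference implementations", {
  set.seed(83)
  a <- rnorm(400, 60, 8); b <- rnorm(400, 58, 7)
  tab <- generateEG4Table(n = 400, config = synthConfig(rng_seed = 83))
  prof <- rbind(data.frame(id = tab$id, condition = "normal", tm_mean = a,
                           tm_sem = 0),
                data.frame(id = tab$id, condition = "cancer", tm_mean = b,
                           tm_sem = 0))
  cmp <- compareConditions(prof, "normal", "cancer", tab)
  tt <- t.test(a, b)
  expect_equal(cmp$stats$welch$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(cmp$stats$welch$df, unname(tt$parameter), tolerance = 1e-8)
  expect_equal(cmp$stats$welch$ci_low, tt$conf.int[1], tolerance = 1e-8)
  sw <- shapiro.test(a)
  expect_equal(cmp$stats$shapiro_a$W, unname(sw$statistic), tolerance = 1e-8)
  lev <- car::leveneTest(c(a, b), factor(rep(c("a", "b"), each = 400)))
  expect_equal(cmp$stats$levene$W, lev$`F value`[1], tolerance = 1e-8)
  # moment skewness against its definition
  expect_equal(cmp$stats$skewness_a,
               mean((a - mean(a))^3) / mean((a - mean(a))^2)^1.5,
               tolerance = 1e-10)
  # Kruskal-Wallis on shifts across gene types + eta^2 convention
  kw <- kruskal.test(a - b, factor(tab$gene_type))
  expect_equal(cmp$stats$kruskal_shift$H, unname(kw$statistic),
               tolerance = 1e-8)
  k <- length(unique(tab$gene_type))
  expect_equal(cmp$stats$kruskal_shift$eta_squared,
               (unname(kw$statistic) - k + 1) / (400 - k), tolerance = 1e-10)
})

test_that("eta-squared follows its convention on a worked example", {
  # H = 6.5 over k = 3 groups and n = 50: (6.5 - 3 + 1) / (50 - 3)
  expect_equal(kruskalEta2(6.5, 3, 50), 4.5 / 47)
})

test_that("gene types below the abundance floor are dropped and logged", {
  cp <- .constructedProfile(n = 1000, seed = 79)
  cmp <- compareConditions(cp$prof, "normal", "cancer", cp$tab,
                           min_gene_type_n = 100L)
  tt <- table(cp$tab$gene_type)
  expect_setequal(cmp$gene_type_stats$gene_type, names(tt)[tt >= 100])
  expect_setequal(cmp$dropped_gene_types, names(tt)[tt < 100])
  # ordering is by descending abundance
  expect_false(is.unsorted(rev(cmp$gene_type_stats$n)))
})

test_that("positional density bins are half-open on 1-Mb boundaries", {
  tab <- data.frame(
    id = c("a", "b", "c", "d"), chrom = "1",
    start = c(228500000, 229000000, 228999999, 0),
    end = c(228500021, 229000021, 229000020, 21),
    strand = c("+", "+", "-", "+"), gene_type = "protein_coding",
    sequence = strrep("G", 21))
  dens <- positionalDensity(tab, bin_size = 1e6)
  expect_equal(dens$bin[dens$count == 1 & dens$strand == "-"], 228)
  bins_plus <- dens$bin[dens$strand == "+"]
  expect_setequal(bins_plus, c(0, 228, 229))  # boundary opens bin 229
})

test_that("uniform positions give near-uniform bin counts", {
  set.seed(97)
  n <- 10000
  tab <- data.frame(
    id = sprintf("g%05d", 1:n), chrom = "7",
    start = floor(runif(n, 0, 10e6)), strand = "+",
    gene_type = "protein_coding", sequence = "GGGTTAGGGTTAGGGTTAGGG")
  tab$end <- tab$start + 21
  dens <- positionalDensity(tab, bin_size = 1e6)
  expect_equal(sum(dens$count), n)
  p <- 1 / 10
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(dens$count - n * p) < sd3))
})
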