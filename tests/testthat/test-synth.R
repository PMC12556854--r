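test_that("oracle Tm evaluates its stated formula", {
  # hand evaluation: 20 + 8*3 - 1.2*1 - 4*0 + 12*log10(101)
  expect_equal(oracleTm("GGGTGGGTGGGTGGGT", 100, 0, 0),
               20 + 8 * 3 - 1.2 * 1 - 4 * 0 + 12 * log10(101),
               tolerance = 1e-12)
  expect_equal(oracleTm("GGGTGGGTGGGTGGGT", 100, 0, 0), 66.85186,
               tolerance = 1e-6)
  # loops of the human telomeric repeat contain 1/3 A
  f <- g4StructuralFeatures("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(f$min_tract, 3)
  expect_equal(f$mean_loop, 3)
  expect_equal(f$frac_a_loop, 1 / 3)
})

test_that("oracle embeds its three monotonicities by construction", {
  s <- "GGGTTAGGGTTAGGGTTAGGG"
  kgrid <- c(0, 1, 5, 25, 100, 200)
  tm_k <- oracleTm(rep(s, length(kgrid)), kgrid, 0, 0)
  expect_true(all(diff(tm_k) > 0))                     # increasing in K+
  expect_gt(oracleTm(s, 100, 0, 0), oracleTm(s, 0, 100, 0))  # K+ > Na+
  loops <- vapply(1:7, function(n)
    generateMotif("loop_length", loop_base = "T", loop_length = n), "")
  tm_loop <- oracleTm(loops, 100, 0, 0)
  expect_true(all(diff(tm_loop) < 0))                  # decreasing in loop
})

test_that("record generation is seeded, valid, and carries its sidecar", {
  cfg <- synthConfig(n_records = 120, rng_seed = 7)
  d1 <- generateG4Records(cfg)
  d2 <- generateG4Records(cfg)
  expect_identical(g4Records(d1), g4Records(d2))
  expect_identical(attr(d1, "tm_true"), attr(d2, "tm_true"))
  rec <- g4Records(d1)
  L <- nchar(rec$sequence)
  expect_true(all(L >= 12 & L <= 60))
  expect_true(all(grepl("^[ACGT]+$", rec$sequence)))
  # zero rejections when re-read through dataio
  f <- tempfile(fileext = ".tsv")
  writeG4Dataset(d1, f)
  ds <- suppressWarnings(readG4Dataset(f))
  expect_equal(ds@provenance$parse_report$n_rejected, 0L)
  expect_equal(length(ds), 120L)
})

test_that("zero noise makes observed Tm equal the oracle", {
  d <- generateG4Records(synthConfig(n_records = 60, noise_sd = 0,
                                     rng_seed = 3))
  rec <- g4Records(d)
  tm_true <- oracleTm(rec$sequence, rec$conc_k, rec$conc_na,
                      rec$conc_li_nh4, rec$ph)
  expect_equal(rec$tm_celsius, tm_true, tolerance = 1e-12)
  expect_equal(attr(d, "tm_true"), tm_true, tolerance = 1e-12)
})

test_that("synthetic eG4 tables parse loss-free and match their schema", {
  tab <- generateEG4Table(n = 400, config = synthConfig(rng_seed = 9))
  expect_equal(nrow(tab), 400L)
  f <- tempfile(fileext = ".tsv")
  writeEG4Table(tab, f)
  gr <- readEG4(f)
  expect_equal(length(gr), 400L)
  expect_equal(S4Vectors::metadata(gr)$parse_report$n_rejected, 0L)
  expect_identical(S4Vectors::mcols(gr)$sequence, tab$sequence)
  expect_equal(GenomicRanges::start(gr) - 1L, tab$start)  # 0-based in file
  expect_equal(GenomicRanges::width(gr), nchar(tab$sequence))
})

test_that("gene-type marginals stay within multinomial 3 sigma", {
  probs <- c(protein_coding = 0.60, lncRNA = 0.14, pseudogene = 0.10,
             lincRNA = 0.05, miRNA = 0.04, snoRNA = 0.03, snRNA = 0.02,
             IG_C = 0.02)
  n <- 4000
  tab <- generateEG4Table(n = n, config = synthConfig(rng_seed = 21),
                          gene_type_probs = probs)
  cnt <- table(factor(tab$gene_type, levels = names(probs)))
  for (g in names(probs)) {
    sd3 <- 3 * sqrt(n * probs[g] * (1 - probs[g]))
    expect_lt(abs(cnt[g] - n * probs[g]), sd3 + 1)
  }
})

test_that("a clustered hotspot is recovered as the densest 1-Mb bin", {
  tab <- generateEG4Table(n = 2000, config = synthConfig(rng_seed = 13),
                          hotspot = list(chrom = "1", start_mb = 17),
                          hotspot_fraction = 0.25)
  dens <- positionalDensity(tab, bin_size = 1e6)
  agg <- aggregate(count ~ chrom + bin, data = dens, sum)
  top <- agg[which.max(agg$count), ]
  expect_equal(top$chrom, "1")
  expect_equal(top$bin, 17)
})
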