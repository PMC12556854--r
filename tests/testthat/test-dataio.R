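test_that("well-formed rows round-trip through read/write", {
  rec <- madeRecords()
  f <- tempfile(fileext = ".tsv")
  writeG4Dataset(G4Dataset(rec), f)
  ds <- readG4Dataset(f)
  expect_s4_class(ds, "G4Dataset")
  expect_equal(length(ds), nrow(rec))
  got <- g4Records(ds)
  expect_identical(got$sequence, rec$sequence)
  expect_equal(got$tm_celsius, rec$tm_celsius)
  expect_equal(got$conc_k, rec$conc_k)
  expect_equal(ds@provenance$parse_report$n_rejected, 0L)
  # a second write/read cycle is the identity
  f2 <- tempfile(fileext = ".tsv")
  writeG4Dataset(ds, f2)
  expect_identical(g4Records(readG4Dataset(f2)), got)
})

test_that("invalid rows are rejected individually with reasons", {
  rec <- madeRecords(4)
  rec$sequence[2] <- "GGGXTTGGG"     # alphabet
  rec$conc_na[3] <- -5               # negative concentration
  f <- tempfile(fileext = ".tsv")
  writeG4Dataset(G4Dataset(madeRecords(4)), f)
  # rebuild the file with the bad values (G4Dataset would refuse them)
  tab <- read.delim(f)
  tab$sequence[2] <- "GGGXTTGGG"
  tab$na_mM[3] <- -5
  tab$tm_celsius[4] <- "not_a_number"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- readG4Dataset(f)
  rep_ <- ds@provenance$parse_report
  expect_equal(length(ds), 1L)
  expect_equal(rep_$n_rejected, 3L)
  expect_setequal(rep_$rejects$row, c(2L, 3L, 4L))
  expect_match(rep_$rejects$reason[rep_$rejects$row == 2], "alphabet")
  expect_match(rep_$rejects$reason[rep_$rejects$row == 3], "concentration")
  expect_match(rep_$rejects$reason[rep_$rejects$row == 4], "Tm")
})

test_that("a missing required column is fatal and names the column", {
  f <- tempfile(fileext = ".tsv")
  writeG4Dataset(G4Dataset(madeRecords(3)), f)
  tab <- read.delim(f)
  tab$ph <- NULL
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readG4Dataset(f), "ph")
})

test_that("all-zero salt records are kept with a warning", {
  rec <- madeRecords(2)
  rec$conc_k <- c(0, 100); rec$conc_na <- 0; rec$conc_li_nh4 <- 0
  f <- tempfile(fileext = ".tsv")
  suppressWarnings(writeG4Dataset(G4Dataset(rec), f))
  expect_warning(ds <- readG4Dataset(f), "0 mM")
  expect_equal(length(ds), 2L)
})

test_that("deduplication keeps first occurrences and is idempotent", {
  rec <- madeRecords(4)
  rec2 <- rbind(rec, rec[c(2, 2, 4), ])            # byte-identical dups
  same_seq <- rec[1, ]; same_seq$conc_k <- 50      # key differs: kept
  rec2 <- rbind(rec2, same_seq)
  ds <- G4Dataset(rec2)
  dd <- deduplicate(ds)
  expect_equal(length(dd), 5L)
  expect_equal(dedupReport(dd)$n_removed, 3L)
  # first occurrence retained, order preserved
  expect_identical(g4Records(dd)$sequence[1:4], rec$sequence)
  expect_identical(deduplicate(dd)@records, dd@records)
  # empty input passes through
  expect_equal(length(deduplicate(G4Dataset(rec[0, ]))), 0L)
})

test_that("dedup agrees with brute-force pairwise comparison", {
  set.seed(31)
  for (trial in 1:5) {
    n <- sample(50:200, 1)
    base <- madeRecords(6)
    rec <- base[sample(6, n, replace = TRUE), ]
    # random concentration jitter on some rows creates distinct keys
    jit <- sample(n, n %/% 3)
    rec$conc_k[jit] <- rec$conc_k[jit] + sample(0:3, length(jit), TRUE) * 10
    rownames(rec) <- NULL
    dd <- g4Records(deduplicate(G4Dataset(rec)))
    # brute force: quadratic scan keeping the first of each key
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (!keep[i]) next
      for (j in seq_len(i - 1)) {
        if (keep[j] &&
            rec$sequence[i] == rec$sequence[j] &&
            rec$conc_k[i] == rec$conc_k[j] &&
            rec$conc_na[i] == rec$conc_na[j] &&
            rec$conc_li_nh4[i] == rec$conc_li_nh4[j] &&
            rec$ph[i] == rec$ph[j]) { keep[i] <- FALSE; break }
      }
    }
    brute <- rec[keep, ]; rownames(brute) <- NULL
    expect_equal(dd$sequence, brute$sequence)
    expect_equal(dd$conc_k, brute$conc_k)
  }
})

test_that("summary statistics match brute-force recomputation", {
  s <- summary(G4Dataset(data.frame(
    sequence = "GGGG", tm_celsius = 50, conc_k = 100, conc_na = 0,
    conc_li_nh4 = 0, ph = 7)))
  expect_equal(unname(s$length_stats["mean"]), 4)
  expect_equal(s$composition$gc_diff, 1.0)
  expect_equal(s$composition$at_diff, 0.0)
  expect_equal(unname(s$tm_stats["span"]), 0)

  s2 <- summary(G4Dataset(data.frame(
    sequence = "AATT", tm_celsius = 20, conc_k = 100, conc_na = 0,
    conc_li_nh4 = 0, ph = 7)))
  expect_equal(s2$composition$gc_diff, 0)
  expect_equal(s2$composition$at_diff, 0)

  ds <- generateG4Records(synthConfig(n_records = 300, rng_seed = 8))
  s3 <- summary(ds)
  rec <- g4Records(ds)
  L <- nchar(rec$sequence)
  expect_equal(unname(s3$length_stats[c("mean", "median", "sd", "iqr")]),
               c(mean(L), median(L), sd(L), IQR(L)))
  expect_equal(unname(s3$tm_stats["mean"]), mean(rec$tm_celsius))
  expect_equal(unname(s3$tm_stats["span"]),
               max(rec$tm_celsius) - min(rec$tm_celsius))
  expect_true(all(abs(s3$composition$gc_diff) <= 1))
  expect_true(all(abs(s3$composition$at_diff) <= 1))
  expect_equal(sum(s3$ph_table), 1)
  expect_equal(sum(s3$cation_table), 300)
  expect_error(summary(G4Dataset(rec[0, ])), "no records")
})

test_that("dominant cation uses argmax with K > Na > Li/NH4 tie-break", {
  got <- dominantCation(c(100, 0, 50, 0, 0), c(0, 100, 50, 0, 70),
                        c(0, 0, 0, 0, 70))
  expect_equal(as.character(got), c("K", "Na", "K", "K", "Na"))
})
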