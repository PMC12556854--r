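test_that("one-hot encoding follows the symmetric padding rule", {
  m <- encodeOneHot("ACGT")
  expect_equal(dim(m), c(4L, 100L))
  expect_equal(sum(m), 4)
  expect_equal(unname(m[, 49:52]), diag(4))   # left pad floor((100-4)/2)=48
  expect_equal(sum(m[, c(1:48, 53:100)]), 0)

  s100 <- randomDna(100)
  m100 <- encodeOneHot(s100)
  expect_equal(sum(m100), 100)
  expect_true(all(colSums(m100) == 1))

  s99 <- randomDna(99)
  m99 <- encodeOneHot(s99)                    # left pad 0, right pad 1
  expect_equal(sum(m99[, 100]), 0)
  expect_equal(sum(colSums(m99[, 1:99]) == 1), 99L)

  expect_error(encodeOneHot(paste(rep("G", 101), collapse = "")),
               "exceeds model window")
  expect_error(encodeOneHot("ACGU"), "A/C/G/T")
})

test_that("one-hot agrees with a brute-force re-implementation", {
  set.seed(101)
  for (i in 1:250) {
    L <- sample(1:100, 1)
    s <- randomDna(L)
    m <- encodeOneHot(s)
    left <- (100 - L) %/% 2
    brute <- matrix(0, 4, 100, dimnames = list(c("A", "C", "G", "T"), NULL))
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(L)) brute[ch[j], left + j] <- 1
    expect_identical(m, brute)
  }
})

test_that("k-mer counts obey the enumeration and sum rules", {
  v <- kmerCounts("GGGG")
  expect_equal(unname(v[c("G", "GG", "GGG", "GGGG")]), c(4, 3, 2, 1))
  expect_equal(sum(v), 10)
  expect_equal(sum(v != 0), 4L)

  v3 <- kmerCounts("ACG")          # L=3: no 4-mers
  k_of <- nchar(names(v3))
  expect_equal(sum(v3[k_of == 1]), 3)
  expect_equal(sum(v3[k_of == 2]), 2)
  expect_equal(sum(v3[k_of == 3]), 1)
  expect_equal(sum(v3[k_of == 4]), 0)

  expect_length(v, 340)            # 4 + 16 + 64 + 256
  expect_equal(dim(countKmers("ACG")), c(20L, 17L))
  # row-major layout: the first 17 vector entries fill matrix row 1
  expect_equal(unname(countKmers("GGGG")[1, ]), unname(v[1:17]))
})

test_that("k-mer counting matches Biostrings on random sequences", {
  set.seed(202)
  for (i in 1:250) {
    s <- randomDna(sample(1:100, 1))
    v <- kmerCounts(s)
    ref <- unlist(lapply(1:4, function(k)
      Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), k)))
    expect_equal(unname(v), unname(as.numeric(ref)))
    expect_identical(names(v), names(ref))
    L <- nchar(s)
    for (k in 1:4)
      expect_equal(sum(v[nchar(names(v)) == k]), max(L - k + 1, 0))
  }
})

test_that("min-max scalers fit, apply, invert, and handle degeneracy", {
  rec <- data.frame(conc_k = c(0, 50, 100), conc_na = c(0, 0, 0),
                    conc_li_nh4 = c(0, 10, 20), ph = c(7, 7, 7))
  sc <- fitScalers(rec)
  out <- scaleConditions(sc, rec)
  expect_equal(out$conc_k, c(0, 0.5, 1))
  expect_equal(out$conc_na, c(0, 0, 0))       # degenerate channel -> 0
  expect_equal(out$ph, c(0, 0, 0))            # constant pH -> 0
  back <- unscaleConditions(sc, out)
  expect_equal(back$conc_k, rec$conc_k)

  # round-trip property on many random records
  set.seed(55)
  big <- data.frame(conc_k = runif(1000, 0, 200), conc_na = runif(1000, 0, 150),
                    conc_li_nh4 = runif(1000, 0, 50), ph = runif(1000, 5, 9))
  sc2 <- fitScalers(big)
  rt <- unscaleConditions(sc2, scaleConditions(sc2, big))
  expect_lt(max(abs(as.matrix(rt) - as.matrix(big))), 1e-9)
})

test_that("out-of-range conditions are clipped with a warning", {
  rec <- data.frame(conc_k = c(0, 100), conc_na = 0, conc_li_nh4 = 0,
                    ph = c(6, 8))
  sc <- fitScalers(rec)
  probe <- data.frame(conc_k = 150, conc_na = 0, conc_li_nh4 = 0, ph = 7)
  expect_warning(out <- scaleConditions(sc, probe, clip = TRUE), "clipped")
  expect_equal(out$conc_k, 1)
})

test_that("record encoding is deterministic and assembles all four parts", {
  rec <- madeRecords(3)
  sc <- fitScalers(data.frame(conc_k = c(0, 100), conc_na = c(0, 100),
                              conc_li_nh4 = c(0, 100), ph = c(6, 8)))
  e1 <- encodeRecords(rec, sc)
  e2 <- encodeRecords(rec, sc)
  expect_identical(e1, e2)
  expect_equal(dim(e1$onehot), c(3L, 100L, 4L))
  expect_equal(dim(e1$kmer), c(3L, 17L, 20L))
  expect_equal(dim(e1$cond), c(3L, 3L))
  # one-hot slice total equals sequence length
  expect_equal(sum(e1$onehot[1, , ]), nchar(rec$sequence[1]))

  # cancer-like mixture under 0-100 mM scalers
  cancer <- data.frame(sequence = "GGGTTAGGGTTAGGGTTAGGG",
                       conc_k = 70, conc_na = 30, conc_li_nh4 = 0, ph = 7)
  ec <- encodeRecords(cancer, sc)
  expect_equal(unname(ec$cond[1, ]), c(0.7, 0.3, 0))
})
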