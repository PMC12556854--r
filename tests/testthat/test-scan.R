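test_that("motif generation matches the family patterns exactly", {
  expect_equal(generateMotif("tract_grid", tract_length = 3, t_stretch = 1),
               "GGGTGGGTGGGTGGGT")
  expect_equal(generateMotif("loop_length", loop_base = "T",
                             loop_length = 2),
               "GGGTTGGGTTGGGTTGGG")
  expect_equal(generateMotif("central_loop", flank_loop = "TTA",
                             central_repeats = 1),
               "AGGGTTAGGGTTAGGGTTAGGGT")
  expect_equal(nchar(generateMotif("central_loop", flank_loop = "TTT",
                                   central_repeats = 3)), 29L)
  expect_warning(generateMotif("loop_length", loop_length = 9), "range")
  expect_error(generateMotif("loop_length", loop_base = "C"), "A or T")
})

test_that("every grid sequence verifies against its family regex", {
  for (grid in list(loopLengthGrid(), tractGrid(), centralLoopGrid())) {
    ok <- vapply(seq_len(nrow(grid)), function(i) {
      r <- grid[i, ]
      pat <- motifPattern(r$family,
                          loop_base = r$loop_base %||% "T",
                          loop_length = r$loop_length %||% 1L,
                          tract_length = r$tract_length %||% 3L,
                          t_stretch = r$t_stretch %||% 1L,
                          flank_loop = r$flank_loop %||% "TTA",
                          central_repeats = r$central_repeats %||% 1L)
      grepl(pat, r$sequence)
    }, TRUE)
    expect_true(all(ok))
  }
  expect_equal(nrow(loopLengthGrid()), 14L)   # 2 bases x 7 lengths
  expect_equal(nrow(tractGrid()), 42L)        # 6 tracts x 7 stretches
  expect_equal(nrow(centralLoopGrid()), 26L)  # 2 flanks x 13 repeats
})

test_that("scan output has one row per motif-condition pair", {
  fit <- tinyTrainedModel()
  specs <- loopLengthGrid()                    # 14 motifs
  conds <- list(conditionPreset("normal"), conditionPreset("moderate"),
                conditionPreset("sodium"), conditionPreset("cancer"))
  tab <- scanStability(specs, conds, fit)
  expect_equal(nrow(tab), 56L)                 # 2 x 7 x 4
  expect_true(all(is.finite(tab$tm_mean)))
  # duplicate specs give duplicate rows with identical Tm
  tab2 <- scanStability(rbind(specs[1, ], specs[1, ]),
                        list(conditionPreset("normal")), fit)
  expect_equal(tab2$tm_mean[1], tab2$tm_mean[2])
  # pure function of inputs
  tab3 <- scanStability(specs, conds, fit)
  expect_identical(tab$tm_mean, tab3$tm_mean)
})

test_that("trend report recovers constructed slopes and differences", {
  # constructed table: Tm exactly linear in loop length with slope -3
  specs <- loopLengthGrid(bases = "T", n = 1:5)
  tab <- do.call(rbind, lapply(c("K_100mM", "Na_100mM"), function(cn) {
    data.frame(specs, condition = cn,
               conc_k = if (cn == "K_100mM") 100 else 0,
               conc_na = if (cn == "Na_100mM") 100 else 0,
               conc_li_nh4 = 0, ph = 7,
               tm_mean = 70 - 3 * specs$loop_length +
                 if (cn == "K_100mM") 5 else 0,
               tm_sem = 0)
  }))
  class(tab) <- c("StabilityScanTable", "data.frame")
  tr <- trendReport(tab)
  expect_equal(tr$slopes$slope, c(-3, -3), tolerance = 1e-12)
  expect_equal(tr$cation_diff$mean_k_minus_na, 5, tolerance = 1e-12)

  # identical Tm across conditions -> all condition differences zero
  tab$tm_mean <- 60
  tr0 <- trendReport(tab)
  expect_equal(tr0$cation_diff$mean_k_minus_na, 0)
  expect_equal(tr0$slopes$slope, c(0, 0))
})

test_that("a model trained on oracle data recovers the loop-length trend", {
  fit <- tinyTrainedModel()
  specs <- loopLengthGrid(bases = "T", n = 1:7)
  tab <- scanStability(specs, list(ionicCondition("K_100mM", 100, 0, 0)),
                       fit)
  tab <- tab[order(tab$loop_length), ]
  # trend-level check: overall decrease from n=1 to n=7
  expect_lt(tab$tm_mean[7], tab$tm_mean[1])
  tr <- trendReport(tab)
  expect_lt(tr$slopes$slope[1], 0)
})
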