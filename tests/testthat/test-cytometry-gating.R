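# Phenotype gating, frequency enumeration, enrichment/rank-sum statistics
# and the multi-cell cooperation analysis.

test_that("quadrant gating follows the thresholds and partitions records", {
  cfg <- gate_config(cd16_threshold = 300, cd56_positive_threshold = 50,
                     cd56_dim_bright_threshold = 2000)
  expect_identical(gate_phenotype(500, 600, cfg), "CD56dim_CD16pos")
  expect_identical(gate_phenotype(100, 6000, cfg), "CD56bright_CD16neg")
  expect_identical(gate_phenotype(100, 600, cfg), "CD56dim_CD16neg")
  expect_identical(gate_phenotype(500, 6000, cfg), "CD56bright_CD16pos")
  expect_identical(gate_phenotype(500, 10, cfg), "ungated")
  expect_warning(out <- gate_phenotype(NA, 600, cfg), "missing")
  expect_identical(out, "ungated")
  # partition: exactly one label each; order invariance
  set.seed(5)
  cd16 <- rlnorm(500, log(500), 1); cd56 <- rlnorm(500, log(800), 1)
  lab <- gate_phenotype(cd16, cd56, cfg)
  expect_true(all(lab %in% c("CD56dim_CD16pos", "CD56bright_CD16neg",
                             "CD56dim_CD16neg", "CD56bright_CD16pos",
                             "ungated")))
  perm <- sample(500)
  expect_identical(gate_phenotype(cd16[perm], cd56[perm], cfg), lab[perm])
})

test_that("a 90% CD56dim/CD16+ mixture is recovered by gating", {
  occ <- tibble::tibble(well_id = sprintf("W%06d", 1:5000),
                        n_cells = 1L, n_beads = 0L)
  sc <- sample_cells(occ, donor_profile(), seed = 21)
  gated <- gate_cells(sc$cells, gate_config())
  frac <- mean(gated$phenotype_label == "CD56dim_CD16pos")
  expect_lt(abs(frac - 0.9), 0.02)
  # data-driven thresholds land between the population modes
  est <- estimate_gate_thresholds(sc$cells)
  expect_gt(est$cd16_threshold, 120); expect_lt(est$cd16_threshold, 1500)
  expect_gt(est$cd56_dim_bright_threshold, 900)
  expect_lt(est$cd56_dim_bright_threshold, 5500)
})

test_that("frequency enumeration uses single-cell wells and the LoD floor", {
  wells <- tibble::tibble(
    well_id = sprintf("W%06d", 1:10200),
    n_cells = rep(c(1L, 2L, 1L), c(10000, 100, 100)),
    n_beads = rep(c(1L, 1L, 0L), c(10000, 100, 100))
  )
  pos <- wells$well_id[1:40]
  calls <- tibble::tibble(well_id = pos, is_secretor = TRUE)
  fr <- enumerate_frequency(wells, calls)
  expect_equal(fr$frequency, 0.004)
  expect_equal(fr$n_eligible, 10000)  # 2-cell and bead-free wells excluded
  expect_false(fr$below_lod)
  expect_identical(fr$display, "0.40%")
  # zero positives floor at the limit of detection
  fr0 <- enumerate_frequency(wells, calls[0, ])
  expect_true(fr0$below_lod)
  expect_identical(fr0$display, "< 0.01%")
  # invariance to row order and extra bead-free wells
  fr2 <- enumerate_frequency(wells[sample(nrow(wells)), ], calls)
  expect_equal(fr2$frequency, fr$frequency)
  und <- enumerate_frequency(wells[wells$n_beads == 0, ], calls)
  expect_identical(und$status, "undefined")
})

test_that("enrichment test matches its exact-test oracle on fixed tables", {
  # equal proportions: no enrichment
  eq <- enrichment_test(rep(c(TRUE, FALSE), c(10, 10)),
                        rep(c(TRUE, FALSE), c(50, 50)), method = "fisher")
  expect_equal(eq$odds_ratio, 1)
  expect_equal(eq$p_value, 1)
  eq_mid <- enrichment_test(rep(c(TRUE, FALSE), c(10, 10)),
                            rep(c(TRUE, FALSE), c(50, 50)))
  expect_gt(eq_mid$p_value, 0.8)
  # the stated strong-enrichment table
  strong <- enrichment_test(rep(c(TRUE, FALSE), c(90, 10)),
                            rep(c(TRUE, FALSE), c(500, 500)))
  oracle <- fisher.test(rbind(c(90, 10), c(500, 500)))$p.value
  expect_lt(strong$p_value, 1e-4)
  expect_lt(oracle, 1e-4)
  expect_lt(abs(log10(strong$p_value) - log10(oracle)), 1)
  # zero cell: Haldane-corrected odds ratio stays finite
  z <- enrichment_test(rep(TRUE, 20), rep(c(TRUE, FALSE), c(50, 50)))
  expect_true(is.finite(z$odds_ratio))
  expect_error(enrichment_test(logical(0), TRUE), "non-empty")
})

test_that("rank-sum comparison handles ties and detects shifts", {
  x <- c(1, 2, 3, 4, 5)
  expect_gt(compare_groups(x, x)$p_value, 0.99)
  expect_equal(compare_groups(rep(3, 5), rep(3, 6))$p_value, 1)
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50, mean = 1)
  expect_lt(compare_groups(a, b)$p_value, 0.001)
  expect_error(compare_groups(1:2, 1:10), "at least 3")
})

test_that("expected multi-cell frequency is the independence closure", {
  expect_equal(expected_multi_cell_frequency(0.1, 2), 0.19)
  expect_equal(expected_multi_cell_frequency(0, 5), 0)
  expect_equal(expected_multi_cell_frequency(1, 3), 1)
  expect_equal(expected_multi_cell_frequency(0.3, 1), 0.3)
  # monotone in both arguments
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(expected_multi_cell_frequency(0.2, 1:6)) > 0))
  expect_true(all(diff(sapply(p, expected_multi_cell_frequency, k = 3)) >= 0))
  expect_error(expected_multi_cell_frequency(1.2, 2), "probability")
})

test_that("cooperation test is quiet under independence and loud under synergy", {
  # p1 = 0: nothing expected, nothing observed
  z <- make_null_wells(200, 50, p1 = 0, seed = 3)
  ct0 <- cooperation_test(z$wells, z$calls, ks = 2)
  expect_equal(ct0$p1, 0)
  expect_equal(ct0$table$observed_freq, 0)
  expect_equal(ct0$table$expected_freq, 0)
  # independent secretion: observed near expected, not significant
  z1 <- make_null_wells(10000, 500, p1 = 0.2, seed = 17)
  ct1 <- cooperation_test(z1$wells, z1$calls, ks = 2)
  expect_equal(ct1$table$observed_freq, 0.36, tolerance = 0.15)
  expect_gt(ct1$table$p_value, 0.05)
  # doubled per-cell probability in multi-cell wells is detected
  z2 <- make_null_wells(10000, 500, p1 = 0.2, synergy = 2, seed = 17)
  ct2 <- cooperation_test(z2$wells, z2$calls, ks = 2)
  expect_gt(ct2$table$observed_freq, ct2$table$expected_freq)
  expect_lt(ct2$table$p_value, 0.05)
  # no single-cell wells -> p1 cannot be estimated
  w2 <- z1$wells[z1$wells$n_cells == 2, ]
  expect_error(cooperation_test(w2, z1$calls), "single-cell")
})
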