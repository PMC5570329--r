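# Synthetic-data generator: loading statistics, ground-truth consistency,
# trace construction and seed determinism.

test_that("Poisson loading reproduces the single-cell fraction", {
  lay <- array_layout(n_wells = 1e5, cell_load_mean = 0.5)
  occ <- sample_occupancy(lay, 42)
  expect_equal(mean(occ$n_cells == 1), 0.5 * exp(-0.5), tolerance = 0.017)
  expect_true(all(occ$n_cells <= lay$max_count))
  # zero load -> all empty
  occ0 <- sample_occupancy(array_layout(n_wells = 100, cell_load_mean = 0,
                                        bead_load_mean = 0), 1)
  expect_true(all(occ0$n_cells == 0) && all(occ0$n_beads == 0))
})

test_that("generators are pure functions of (config, seed)", {
  lay <- array_layout(n_wells = 300)
  expect_identical(sample_occupancy(lay, 7), sample_occupancy(lay, 7))
  d1 <- generate_dataset(lay, seed = 7)
  d2 <- generate_dataset(lay, seed = 7)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$traces, d2$traces)
  d3 <- generate_dataset(lay, seed = 8)
  expect_false(identical(d1$traces, d3$traces))
})

test_that("phenotype mixture and secretor probabilities are honoured", {
  occ <- tibble::tibble(well_id = sprintf("W%06d", 1:5000),
                        n_cells = 1L, n_beads = 0L)
  donor <- donor_profile(
    phenotype_mix = c(CD56dim_CD16pos = 0.9, CD56bright_CD16neg = 0.1,
                      CD56dim_CD16neg = 0, CD56bright_CD16pos = 0))
  sc <- sample_cells(occ, donor, seed = 2)
  frac <- prop.table(table(sc$truth$phenotype))
  expect_lt(abs(frac[["CD56dim_CD16pos"]] - 0.9), 0.02)
  expect_lt(abs(frac[["CD56bright_CD16neg"]] - 0.1), 0.02)
  # no secretors when every probability is zero
  none <- donor_profile(secretor_prob = c(CD56dim_CD16pos = 0,
                                          CD56bright_CD16neg = 0,
                                          CD56dim_CD16neg = 0,
                                          CD56bright_CD16pos = 0))
  sc0 <- sample_cells(occ, none, seed = 2)
  expect_false(any(sc0$truth$is_secretor))
})

test_that("onset-time presets are positively skewed with the stated means", {
  set.seed(3)
  for (cfg in list(c(donor = 1, mean = 62), c(donor = 2, mean = 70))) {
    d <- donor_profile_preset(cfg["donor"])
    x <- rlnorm(20000, d$t_secrete_meanlog, d$t_secrete_sdlog)
    expect_equal(mean(x), cfg[["mean"]], tolerance = 0.03)
    expect_gt(e1071::skewness(x), 0)
    mode_est <- exp(d$t_secrete_meanlog - d$t_secrete_sdlog^2)
    expect_gt(mode_est, 45); expect_lt(mode_est, 60)
  }
})

test_that("noise-free traces equal the ground-truth curves", {
  ch <- make_cohort(40, noise = noise_model(0, 0), seed = 5)
  expect_true(all(table(ch$traces$bead_id) == 37))
  expect_equal(sort(unique(ch$traces$time_min)), seq(0, 360, 10))
  donor <- donor_profile()
  for (w in unique(ch$traces$well_id)) {
    tr <- ch$traces[ch$traces$well_id == w, ]
    tru <- ch$truth[ch$truth$well_id == w, ]
    expected <- rep(donor$baseline, 37)
    if (isTRUE(tru$is_secretor)) {
      expected <- expected + four_param_logistic(seq(0, 360, 10), 0,
                                                 tru$top, tru$ec50, tru$hill)
    }
    expect_equal(tr$mfi, expected, tolerance = 1e-12)
  }
})

test_that("the manifest is consistent with the emitted tables", {
  ds <- generate_dataset(array_layout(n_wells = 500), seed = 9)
  # every cell/bead belongs to a well with matching occupancy
  occ <- ds$occupancy
  cell_counts <- table(ds$cells$well_id)
  expect_true(all(occ$n_cells[match(names(cell_counts), occ$well_id)] ==
                    as.integer(cell_counts)))
  bead_counts <- table(ds$beads$well_id)
  expect_true(all(occ$n_beads[match(names(bead_counts), occ$well_id)] ==
                    as.integer(bead_counts)))
  expect_setequal(unique(ds$traces$bead_id), ds$beads$bead_id)
  expect_identical(ds$cells$cell_id, ds$truth$cell_id)
  # secretor frequency among single-cell wells tracks the configured rate
  single <- occ$well_id[occ$n_cells == 1]
  p_hat <- mean(ds$truth$is_secretor[ds$truth$well_id %in% single])
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / length(single)))
})
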