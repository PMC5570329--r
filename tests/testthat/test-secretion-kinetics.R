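# 4PL fitting, secretor classification and onset-time summaries.

test_that("noiseless 4PL samples are recovered to numerical precision", {
  set.seed(101)
  cases <- replicate(12, {
    bottom <- runif(1, 0, 500)
    c(bottom = bottom, top = bottom + runif(1, 500, 5000),
      ec50 = runif(1, 20, 300), hill = runif(1, 1, 8))
  })
  for (j in seq_len(ncol(cases))) {
    p <- cases[, j]
    fit <- fit_four_param_logistic(
      make_4pl_trace(p["bottom"], p["top"], p["ec50"], p["hill"]))
    expect_true(fit$converged)
    expect_equal(fit$bottom, unname(p["bottom"]), tolerance = 1e-6)
    expect_equal(fit$top, unname(p["top"]), tolerance = 1e-6)
    expect_equal(fit$ec50, unname(p["ec50"]), tolerance = 1e-6)
    expect_equal(fit$hill, unname(p["hill"]), tolerance = 1e-6)
  }
})

test_that("the reference parameter set is recovered from 37 frames", {
  fit <- fit_four_param_logistic(make_4pl_trace(200, 2200, 90, 5))
  expect_equal(fit$bottom, 200, tolerance = 1e-6)
  expect_equal(fit$top, 2200, tolerance = 1e-6)
  expect_equal(fit$ec50, 90, tolerance = 1e-6)
  expect_equal(fit$hill, 5, tolerance = 1e-6)
  # EC50 is the half-rise time of the fitted curve
  mid <- four_param_logistic(fit$ec50, fit$bottom, fit$top, fit$ec50,
                             fit$hill)
  expect_equal(mid, (fit$bottom + fit$top) / 2, tolerance = 1e-9)
  # positive-slope fits are non-decreasing in time
  curve <- four_param_logistic(seq(0, 360, 5), fit$bottom, fit$top,
                               fit$ec50, fit$hill)
  expect_true(all(diff(curve) >= 0))
})

test_that("degenerate and short traces are handled without crashes", {
  flat <- bead_trace(seq(0, 360, 10), rep(500, 37))
  fit <- fit_four_param_logistic(flat)
  expect_true(fit$converged)
  expect_equal(fit$top - fit$bottom, 0)
  expect_false(isTRUE(classify_secretor(flat, fit = fit)))
  expect_error(fit_four_param_logistic(bead_trace(c(0, 10, 20), c(1, 2, 3))),
               "at least 5")
  short <- bead_trace(c(0, 10, 20, 30), c(1, 2, 3, 4))
  call <- classify_secretor(short)
  expect_true(is.na(call))
  expect_identical(attr(call, "status"), "uncallable")
})

test_that("EC50 recovery bias stays below one frame at 2% noise", {
  set.seed(202)
  errs <- replicate(60, {
    tr <- make_4pl_trace(200, 2200, 60, 4, noise_sd = 0.02 * 2000)
    fit_four_param_logistic(tr)$ec50 - 60
  })
  expect_lt(median(abs(errs)), 5)
  expect_lt(abs(mean(errs)), 10)   # bias under one frame interval
})

test_that("classification separates clear secretors from background", {
  up <- make_4pl_trace(200, 2000, 90, 4)          # 10x rise
  expect_true(isTRUE(classify_secretor(up)))
  noisy_flat <- make_4pl_trace(200, 200, 90, 4, noise_sd = 5, seed = 7)
  expect_false(isTRUE(classify_secretor(noisy_flat)))
})

test_that("secretion metrics follow their definitions", {
  fit <- fit_four_param_logistic(make_4pl_trace(200, 2200, 90, 5))
  m <- secretion_metrics(fit)
  expect_equal(m$mfi_ratio, 11, tolerance = 0.05)
  expect_equal(m$t_secrete, 90, tolerance = 1e-6)
  expect_true(m$immediate)
  fit2 <- fit_four_param_logistic(make_4pl_trace(200, 2200, 200, 5))
  expect_false(secretion_metrics(fit2)$immediate)
  # non-converged fit carries no kinetics
  nc <- structure(list(converged = FALSE), class = "logistic_fit")
  expect_true(is.na(secretion_metrics(nc)$t_secrete))
})

test_that("early/late split at the mean sends ties to late", {
  sp <- split_early_late(c(50, 60, 70, 100))
  expect_equal(sort(sp$early), c(50, 60))
  expect_equal(sort(sp$late), c(70, 100))
  same <- split_early_late(rep(80, 5))
  expect_length(same$early, 0)
  expect_length(same$late, 5)
  expect_warning(split_early_late(numeric(0)), "fewer than two")
  # positive skew puts the majority below the mean
  set.seed(11)
  x <- rlnorm(500, 4, 0.5)
  sp2 <- split_early_late(x)
  expect_gt(length(sp2$early), length(sp2$late))
})

test_that("distribution summaries report moments and the normal overlay", {
  s <- distribution_summary(c(40, 50, 60, 50))
  expect_equal(s$skewness, 0, tolerance = 1e-12)
  expect_identical(s$overlay_mean, s$mean)
  expect_identical(s$overlay_sd, s$sd)
  set.seed(12)
  s2 <- distribution_summary(rlnorm(1000, 4, 0.5))
  expect_gt(s2$skewness, 0)
  expect_true(is.na(distribution_summary(c(1, 2))$skewness))
})

test_that("cohort-level calling recovers generator ground truth", {
  ch <- make_cohort(250, seed = 31)
  calls <- fit_secretion_table(ch$traces)
  truth <- ch$truth
  m <- merge(calls, truth[, c("well_id", "is_secretor", "ec50")],
             by = "well_id", suffixes = c("", "_true"))
  tp <- sum(m$is_secretor & m$is_secretor_true)
  expect_gte(tp / max(sum(m$is_secretor), 1), 0.9)        # precision
  expect_gte(tp / max(sum(m$is_secretor_true), 1), 0.9)   # recall
  hit <- m$is_secretor & m$is_secretor_true
  expect_lt(median(abs(m$t_secrete_min[hit] - m$ec50[hit])), 5)
})
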