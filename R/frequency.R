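# Secretor frequencies, phenotype enrichment, group comparison and the
# multi-cell cooperation analysis.

.well_positive <- function(wells, calls) {
  pos_wells <- unique(calls$well_id[calls$is_secretor %in% TRUE])
  wells$secretion_positive <- wells$well_id %in% pos_wells
  wells
}

#' Secretor frequency among single-cell wells
#'
#' The per-cell secretion frequency is estimated from nanowells containing
#' exactly one cell and at least one bead: a well is positive when any of its
#' beads is called secretion-positive. Frequencies below the assay's limit of
#' detection (default 0.01%) are flagged and displayed as below the floor.
#'
#' @param wells Occupancy table with `well_id`, `n_cells`, `n_beads`.
#' @param calls Bead call table with `well_id`, `is_secretor` (see
#'   [fit_secretion_table()]).
#' @param lod Reporting floor as a fraction (default `1e-4`, i.e. 0.01%).
#' @return A list: `frequency`, `n_positive`, `n_eligible`, `below_lod`,
#'   `lod`, `display` (formatted percentage, `"< 0.01%"` when floored) and
#'   `status` (`"ok"` or `"undefined"` when no eligible wells exist).
#' @export
enumerate_frequency <- function(wells, calls, lod = 1e-4) {
  stopifnot(all(c("well_id", "n_cells", "n_beads") %in% names(wells)),
            all(c("well_id", "is_secretor") %in% names(calls)))
  wells <- .well_positive(wells, calls)
  elig <- wells$n_cells == 1 & wells$n_beads >= 1
  n_eligible <- sum(elig)
  if (n_eligible == 0) {
    return(list(frequency = NA_real_, n_positive = 0L, n_eligible = 0L,
                below_lod = NA, lod = lod, display = NA_character_,
                status = "undefined"))
  }
  n_positive <- sum(wells$secretion_positive[elig])
  freq <- n_positive / n_eligible
  below <- freq < lod
  display <- if (below) sprintf("< %g%%", lod * 100) else
    sprintf("%.2f%%", freq * 100)
  list(frequency = freq, n_positive = n_positive, n_eligible = n_eligible,
       below_lod = below, lod = lod, display = display, status = "ok")
}

#' CD16 positivity from phenotype labels
#'
#' @param labels Phenotype labels from [gate_phenotype()].
#' @return Logical vector, `TRUE` for CD16-positive quadrants.
#' @export
cd16_positive <- function(labels) {
  labels %in% c("CD56dim_CD16pos", "CD56bright_CD16pos")
}

#' Phenotype enrichment among secretors
#'
#' Two-sided exact test on the 2x2 table (secretor group vs comparison
#' population) x (marker-positive vs marker-negative). The default is the
#' mid-p exact test (probability method on the conditional hypergeometric
#' support, counting the observed table with weight one half), which is
#' calibrated - its null p-values are close to uniform - where the classical
#' Fisher test is conservative; `method = "fisher"` gives the classical
#' variant. The odds ratio is the sample cross-product ratio with a Haldane
#' correction (+0.5 to every cell) whenever a cell is zero, so it is always
#' finite.
#'
#' @param secretor_marker Logical marker positivity of the secretor group.
#' @param parent_marker Logical marker positivity of the comparison group
#'   (the full parent population in the assay's headline comparison).
#' @param method `"midp"` (default) or `"fisher"`.
#' @return List with `odds_ratio`, `p_value`, `table` and `method`.
#' @export
enrichment_test <- function(secretor_marker, parent_marker,
                            method = c("midp", "fisher")) {
  method <- match.arg(method)
  if (length(secretor_marker) == 0 || length(parent_marker) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  tab <- rbind(
    secretor = c(pos = sum(secretor_marker), neg = sum(!secretor_marker)),
    parent = c(pos = sum(parent_marker), neg = sum(!parent_marker))
  )
  p <- if (method == "fisher") {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    .midp_2x2(tab)
  }
  ct <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  list(odds_ratio = unname(or), p_value = p, table = tab,
       method = paste0("two-sided ", if (method == "midp") "mid-p " else "",
                       "exact test, Haldane-corrected odds ratio"))
}

# two-sided mid-p for a 2x2 table, probability method on the hypergeometric
# support conditional on the margins
.midp_2x2 <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]; n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]; x <- tab[1, 1]
  supp <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(pr[pr < p_obs * (1 + 1e-7)]) - 0.5 * p_obs
  min(max(p, 0), 1)
}

#' Two-sided rank-sum comparison of two groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test: exact for small tie-free samples,
#' normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b Numeric samples, each with at least 3 values.
#' @return List with `p_value`, `statistic`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 finite values", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  p <- wt$p.value
  # fully tied data: zero-variance normal approximation -> no evidence
  if (is.nan(p)) p <- 1
  list(p_value = p, statistic = unname(wt$statistic),
       method = wt$method)
}

#' Expected positive-well frequency under independent secretion
#'
#' If each of `k` cells in a well secretes independently with probability
#' `p1`, the well is positive with probability `1 - (1 - p1)^k`. This is the
#' null model against which multi-cell well frequencies are compared to look
#' for cooperation.
#'
#' @param p1 Single-cell secretion probability in `[0, 1]`.
#' @param k Number of cells in the well (`>= 1`), may be a vector.
#' @return Expected positive-well probability.
#' @export
expected_multi_cell_frequency <- function(p1, k) {
  if (!is.numeric(p1) || length(p1) != 1 || is.na(p1) || p1 < 0 || p1 > 1)
    stop("`p1` must be a probability in [0, 1]", call. = FALSE)
  if (any(k < 1)) stop("`k` must be >= 1", call. = FALSE)
  1 - (1 - p1)^k
}

#' Test for cooperation in multi-cell wells
#'
#' Estimates the single-cell secretion probability `p1` from wells with
#' exactly one cell (and at least one bead), predicts the positive-well
#' frequency for wells with `k` cells under independence via
#' [expected_multi_cell_frequency()], and compares the observed positive
#' count with an exact two-sided binomial test. Observed frequencies above
#' the expectation indicate synergy; at or below it, no cooperation.
#'
#' @param wells Occupancy table (`well_id`, `n_cells`, `n_beads`).
#' @param calls Bead call table (`well_id`, `is_secretor`).
#' @param ks Cell counts to test (default `c(2, 3)`).
#' @return A `cooperation_result` list: `p1`, `n_single` and `table`
#'   (tibble with `k`, `n_wells`, `observed_freq`, `expected_freq`,
#'   `p_value`).
#' @export
cooperation_test <- function(wells, calls, ks = c(2, 3)) {
  wells <- .well_positive(wells, calls)
  single <- wells$n_cells == 1 & wells$n_beads >= 1
  if (!any(single))
    stop("no single-cell wells available to estimate p1", call. = FALSE)
  p1 <- mean(wells$secretion_positive[single])
  rows <- lapply(ks, function(k) {
    sel <- wells$n_cells == k & wells$n_beads >= 1
    n <- sum(sel)
    if (n == 0) {
      return(tibble::tibble(k = k, n_wells = 0L, observed_freq = NA_real_,
                            expected_freq = expected_multi_cell_frequency(p1, k),
                            p_value = NA_real_))
    }
    x <- sum(wells$secretion_positive[sel])
    expc <- expected_multi_cell_frequency(p1, k)
    pv <- stats::binom.test(x, n, p = expc,
                            alternative = "two.sided")$p.value
    tibble::tibble(k = k, n_wells = n, observed_freq = x / n,
                   expected_freq = expc, p_value = pv)
  })
  structure(list(p1 = p1, n_single = sum(single),
                 table = dplyr::bind_rows(rows)),
            class = "cooperation_result")
}

#' @export
print.cooperation_result <- function(x, ...) {
  cat(sprintf("single-cell secretion probability p1 = %.4f (n = %d wells)\n",
              x$p1, x$n_single))
  print(x$table)
  invisible(x)
}
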