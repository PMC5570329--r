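# Population summaries of secretion onset times.

#' Split secretors into early and late groups at the mean onset time
#'
#' Early secretors have `t_secrete` strictly below the group mean; values at
#' or above the mean (including exact ties with it) go to the late group.
#' With a positively skewed onset distribution the early group is the larger
#' one, since more than half of the mass lies below the mean.
#'
#' @param t_secrete Numeric onset times (min), or a calls table from
#'   [fit_secretion_table()] (its secretor rows are used).
#' @return A list with `early`, `late` (numeric vectors) and `mean`.
#' @export
split_early_late <- function(t_secrete) {
  if (is.data.frame(t_secrete)) {
    t_secrete <- t_secrete$t_secrete_min[t_secrete$is_secretor %in% TRUE]
  }
  t_secrete <- t_secrete[is.finite(t_secrete)]
  if (length(t_secrete) < 2) {
    warning("fewer than two secretors; returning empty early/late groups")
    return(list(early = numeric(0), late = numeric(0), mean = NA_real_))
  }
  m <- mean(t_secrete)
  list(early = t_secrete[t_secrete < m],
       late = t_secrete[t_secrete >= m],
       mean = m)
}

#' Moments of an onset-time distribution with its normal overlay
#'
#' Returns mean, SD and sample skewness of the onset times, plus the
#' parameters of the normal curve conventionally overlaid on the histogram
#' (same mean and SD as the sample). Skewness is the moment ratio
#' `g1 = m3 / m2^(3/2)` and requires at least 3 values.
#'
#' @param t_values Numeric onset times (min).
#' @return A list with `n`, `mean`, `sd`, `skewness`, `overlay_mean`,
#'   `overlay_sd`. `skewness` is `NA` when `n < 3`.
#' @export
distribution_summary <- function(t_values) {
  t_values <- t_values[is.finite(t_values)]
  n <- length(t_values)
  m <- mean(t_values)
  s <- stats::sd(t_values)
  skew <- if (n >= 3) e1071::skewness(t_values, type = 1) else NA_real_
  list(n = n, mean = m, sd = s, skewness = skew,
       overlay_mean = m, overlay_sd = s)
}
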