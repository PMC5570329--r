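# Four-parameter logistic (4PL) secretion kinetics.
#
# Bead fluorescence versus time follows a sigmoid once the cell starts
# secreting. The time-domain 4PL
#   MFI(t) = Bottom + (Top - Bottom) * t^h / (t^h + EC50^h)
# is fitted to every bead trace; EC50 is the time at which the MFI reaches
# halfway between Bottom and Top and is reported as the secretion onset time
# t_Secrete. The formula gives exactly Bottom at t = 0, so the first frame is
# used in the fit like any other point (no log-time transform).

#' Evaluate the time-domain four-parameter logistic
#'
#' @param t Times (min, `>= 0`).
#' @param bottom,top Low/high plateaus (MFI units).
#' @param ec50 Half-rise time (min, `> 0`).
#' @param hill Hill slope (`> 0` for a rising trace).
#' @return MFI values at `t`.
#' @export
four_param_logistic <- function(t, bottom, top, ec50, hill) {
  th <- ifelse(t > 0, t^hill, 0)
  bottom + (top - bottom) * th / (th + ec50^hill)
}

#' A single bead fluorescence time series
#'
#' @param bead_id,well_id Identifiers.
#' @param times Acquisition times (min), strictly increasing, first frame at 0.
#' @param mfi Background-corrected mean fluorescence intensities.
#' @return A `bead_trace` object.
#' @export
bead_trace <- function(times, mfi, bead_id = NA_character_,
                       well_id = NA_character_) {
  times <- as.numeric(times); mfi <- as.numeric(mfi)
  if (length(times) != length(mfi))
    stop("`times` and `mfi` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(mfi)))
    stop("`mfi` must be finite", call. = FALSE)
  structure(list(bead_id = bead_id, well_id = well_id,
                 times = times, mfi = mfi),
            class = "bead_trace")
}

.as_bead_trace <- function(trace) {
  if (inherits(trace, "bead_trace")) return(trace)
  if (is.data.frame(trace)) {
    tcol <- intersect(c("time_min", "times", "time"), names(trace))[1]
    if (is.na(tcol) || !"mfi" %in% names(trace))
      stop("trace table needs a time column and `mfi`", call. = FALSE)
    return(bead_trace(trace[[tcol]], trace$mfi,
                      bead_id = trace$bead_id[1] %||% NA_character_,
                      well_id = trace$well_id[1] %||% NA_character_))
  }
  stop("`trace` must be a bead_trace or a data frame", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the four-parameter logistic to a bead trace
#'
#' Bounded Levenberg-Marquardt least squares over (Bottom, Top, EC50, h),
#' using every available point including t = 0. Starting values: Bottom/Top
#' at the data extremes, EC50 at the first mid-range crossing, h = 4. Bounds:
#' plateaus within the data range +/- 50% of its width, EC50 in (0, 2 t_end],
#' h in (0, 50]. Non-convergence is reported via `converged = FALSE`, never
#' as an error; an exactly flat trace returns a converged degenerate fit with
#' `top == bottom`.
#'
#' @param trace A [bead_trace()] or data frame with time and `mfi` columns.
#' @return A `logistic_fit` list: `bottom`, `top`, `ec50`, `hill`,
#'   `residual_norm` (root-mean-square residual), `converged`, `t_end`,
#'   `n_points`.
#' @export
fit_four_param_logistic <- function(trace) {
  tr <- .as_bead_trace(trace)
  t <- tr$times; y <- tr$mfi
  n <- length(t)
  if (n < 5) stop("at least 5 timepoints are required for a 4PL fit", call. = FALSE)
  t_end <- max(t)
  rng <- diff(range(y))
  fit0 <- list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
               hill = NA_real_, residual_norm = NA_real_, converged = FALSE,
               t_end = t_end, n_points = n,
               bead_id = tr$bead_id, well_id = tr$well_id)

  if (rng == 0) {
    fit0$bottom <- fit0$top <- y[1]
    fit0$ec50 <- max(t_end / 2, 1e-6)
    fit0$hill <- 1
    fit0$residual_norm <- 0
    fit0$converged <- TRUE
    return(structure(fit0, class = "logistic_fit"))
  }

  mid <- min(y) + rng / 2
  cross <- which(y >= mid & t > 0)
  ec50_0 <- if (length(cross)) t[cross[1]] else t_end / 2
  start <- list(bottom = min(y), top = max(y),
                ec50 = min(max(ec50_0, 1e-3), 2 * t_end), hill = 4)
  lower <- c(bottom = min(y) - 0.5 * rng, top = min(y) - 0.5 * rng,
             ec50 = 1e-6, hill = 1e-3)
  upper <- c(bottom = max(y) + 0.5 * rng, top = max(y) + 0.5 * rng,
             ec50 = 2 * t_end, hill = 50)

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ four_param_logistic(t, bottom, top, ec50, hill),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(structure(fit0, class = "logistic_fit"))
  cf <- stats::coef(fit)
  out <- fit0
  out$bottom <- unname(cf["bottom"]); out$top <- unname(cf["top"])
  out$ec50 <- unname(cf["ec50"]); out$hill <- unname(cf["hill"])
  out$residual_norm <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- TRUE
  structure(out, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("4PL fit:", if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  bottom %.4g  top %.4g  EC50 %.4g min  hill %.4g  rms %.4g\n",
              x$bottom, x$top, x$ec50, x$hill, x$residual_norm))
  invisible(x)
}

#' Secretor-calling policy
#'
#' A bead is called secretion-positive when its smoothed peak intensity is at
#' least `fold_threshold` times the baseline (mean of the first
#' `baseline_frames` frames) and the 4PL fit converged with an amplitude
#' (`top - bottom`) above the noise floor `min_amplitude`.
#'
#' @param fold_threshold Fold change over baseline (default 2).
#' @param min_amplitude Minimum fitted amplitude in MFI units (default 100).
#' @param baseline_frames Frames averaged for the baseline (default 3).
#' @param smooth_k Running-median window for the peak estimate (odd, default 5).
#' @param min_points Minimum trace length to attempt a call (default 5).
#' @return A `secretor_policy` list.
#' @export
secretor_policy <- function(fold_threshold = 2, min_amplitude = 100,
                            baseline_frames = 3, smooth_k = 5,
                            min_points = 5) {
  stopifnot(fold_threshold >= 1, min_amplitude >= 0, baseline_frames >= 1,
            smooth_k %% 2 == 1, min_points >= 5)
  structure(list(fold_threshold = fold_threshold,
                 min_amplitude = min_amplitude,
                 baseline_frames = baseline_frames,
                 smooth_k = smooth_k, min_points = min_points),
            class = "secretor_policy")
}

#' Classify a bead trace as secretor / non-secretor
#'
#' @param trace A [bead_trace()] or data frame.
#' @param policy A [secretor_policy()].
#' @param fit Optional precomputed [fit_four_param_logistic()] result.
#' @return Logical flag (`TRUE` = secretor); `NA` with attribute
#'   `status = "uncallable"` when the trace is too short.
#' @export
classify_secretor <- function(trace, policy = secretor_policy(), fit = NULL) {
  tr <- .as_bead_trace(trace)
  if (length(tr$times) < policy$min_points) {
    return(structure(NA, status = "uncallable"))
  }
  if (is.null(fit)) fit <- fit_four_param_logistic(tr)
  k <- min(policy$smooth_k, length(tr$mfi) - (1 - length(tr$mfi) %% 2))
  sm <- stats::runmed(tr$mfi, k)
  base <- mean(tr$mfi[seq_len(min(policy$baseline_frames, length(tr$mfi)))])
  fold <- max(sm) / max(base, .Machine$double.eps)
  flag <- isTRUE(fit$converged) &&
    fold >= policy$fold_threshold &&
    (fit$top - fit$bottom) >= policy$min_amplitude
  structure(flag, status = "called", fold = fold)
}

#' Kinetic metrics of a secretion-positive fit
#'
#' `t_secrete` is the fitted EC50; `mfi_ratio` is the maximum over minimum of
#' the fitted curve across the observation window (a proxy for the total
#' amount secreted); `hill` reflects the secretion rate; `immediate` flags
#' `t_secrete <= cutoff` (default 180 min).
#'
#' @param fit A converged `logistic_fit`.
#' @param immediate_cutoff Immediate-secretor cutoff (min).
#' @return A list with `t_secrete`, `hill_slope`, `mfi_ratio`, `immediate`.
#' @export
secretion_metrics <- function(fit, immediate_cutoff = 180) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    return(list(t_secrete = NA_real_, hill_slope = NA_real_,
                mfi_ratio = NA_real_, immediate = FALSE))
  }
  tt <- seq(0, fit$t_end, length.out = 721)
  curve <- four_param_logistic(tt, fit$bottom, fit$top, fit$ec50, fit$hill)
  lo <- min(curve); hi <- max(curve)
  ratio <- if (lo > 0) hi / lo else Inf
  list(t_secrete = fit$ec50, hill_slope = fit$hill, mfi_ratio = ratio,
       immediate = fit$ec50 <= immediate_cutoff)
}

#' Fit and call every bead trace in a table
#'
#' @param traces A data frame with columns `bead_id`, `well_id`, `time_min`,
#'   `mfi` (one row per bead per frame).
#' @param policy A [secretor_policy()].
#' @param immediate_cutoff Immediate-secretor cutoff in minutes.
#' @return A tibble with one row per bead: `bead_id`, `well_id`,
#'   `is_secretor`, `t_secrete_min`, `hill`, `mfi_ratio`, `immediate`,
#'   `residual`, `converged`. Kinetic values are `NA` for non-secretors.
#' @export
fit_secretion_table <- function(traces, policy = secretor_policy(),
                                immediate_cutoff = 180) {
  stopifnot(all(c("bead_id", "well_id", "time_min", "mfi") %in% names(traces)))
  parts <- split(traces, traces$bead_id)
  rows <- lapply(parts, function(df) {
    df <- df[order(df$time_min), ]
    tr <- bead_trace(df$time_min, df$mfi, bead_id = df$bead_id[1],
                     well_id = df$well_id[1])
    fit <- fit_four_param_logistic(tr)
    flag <- classify_secretor(tr, policy, fit = fit)
    sec <- isTRUE(flag)
    m <- if (sec) secretion_metrics(fit, immediate_cutoff) else
      list(t_secrete = NA_real_, hill_slope = NA_real_,
           mfi_ratio = NA_real_, immediate = FALSE)
    tibble::tibble(
      bead_id = df$bead_id[1], well_id = df$well_id[1],
      is_secretor = sec,
      t_secrete_min = m$t_secrete, hill = m$hill_slope,
      mfi_ratio = m$mfi_ratio, immediate = m$immediate,
      residual = fit$residual_norm, converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}
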