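# Imaging-cytometry style phenotype gating on CD16/CD56 intensities.
#
# NK cells are classified into the four quadrants of the CD16 x CD56 plane.
# Cells whose CD56 signal is below the positivity threshold are not NK cells
# and stay ungated. The dim/bright boundary subdivides CD56-positive cells.

.PHENOTYPE_LABELS <- c("CD56dim_CD16pos", "CD56bright_CD16neg",
                       "CD56dim_CD16neg", "CD56bright_CD16pos", "ungated")

#' Numeric gate thresholds for CD16/CD56 classification
#'
#' @param cd16_threshold CD16 positivity threshold (MFI units).
#' @param cd56_positive_threshold CD56 level below which a cell is not an NK
#'   cell (ungated).
#' @param cd56_dim_bright_threshold Boundary between CD56^dim and CD56^bright;
#'   must exceed `cd56_positive_threshold`.
#' @return A `gate_config` object.
#' @export
gate_config <- function(cd16_threshold = 300,
                        cd56_positive_threshold = 50,
                        cd56_dim_bright_threshold = 2000) {
  stopifnot(cd16_threshold > 0, cd56_positive_threshold > 0,
            cd56_dim_bright_threshold > cd56_positive_threshold)
  structure(list(cd16_threshold = cd16_threshold,
                 cd56_positive_threshold = cd56_positive_threshold,
                 cd56_dim_bright_threshold = cd56_dim_bright_threshold),
            class = "gate_config")
}

#' Estimate gate thresholds from the data
#'
#' Fits a two-component Gaussian mixture to log10 intensity per channel and
#' places the threshold at the posterior cross-over (the valley between the
#' negative and positive populations). The CD56 positivity threshold is set
#' a decade below the dim population unless given.
#'
#' @param cells Data frame with `cd16_mfi` and `cd56_mfi` columns.
#' @param cd56_positive_threshold Optional fixed CD56 positivity threshold.
#' @return A [gate_config()].
#' @export
estimate_gate_thresholds <- function(cells, cd56_positive_threshold = NULL) {
  stopifnot(all(c("cd16_mfi", "cd56_mfi") %in% names(cells)))
  valley <- function(x) {
    mclustBIC <- mclust::mclustBIC   # Mclust() looks this up in the caller
    lx <- log10(pmax(x, 1e-3))
    fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    grid <- seq(min(mu), max(mu), length.out = 512)
    pr <- predict(fit, grid)$z
    lo <- which.min(mu)
    cross <- grid[which(pr[, lo] < 0.5)[1]]
    10^cross
  }
  cd16_thr <- valley(cells$cd16_mfi)
  cd56_db <- valley(cells$cd56_mfi)
  cd56_pos <- cd56_positive_threshold %||%
    max(min(cells$cd56_mfi) * 0.5, cd56_db / 40)
  gate_config(cd16_threshold = cd16_thr,
              cd56_positive_threshold = cd56_pos,
              cd56_dim_bright_threshold = cd56_db)
}

#' Assign phenotype labels from channel intensities
#'
#' Deterministic quadrant assignment: CD56 below the positivity threshold is
#' `ungated`; otherwise CD56 dim/bright is split at the dim/bright threshold
#' and CD16 +/- at the CD16 threshold.
#'
#' @param cd16_mfi,cd56_mfi Numeric background-corrected intensities
#'   (vectors of equal length).
#' @param config A [gate_config()].
#' @return Character vector of labels (`CD56dim_CD16pos`,
#'   `CD56bright_CD16neg`, `CD56dim_CD16neg`, `CD56bright_CD16pos`,
#'   `ungated`).
#' @export
gate_phenotype <- function(cd16_mfi, cd56_mfi, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"),
            length(cd16_mfi) == length(cd56_mfi))
  out <- rep("ungated", length(cd16_mfi))
  bad <- !is.finite(cd16_mfi) | !is.finite(cd56_mfi)
  if (any(bad)) warning("missing channel intensities; affected cells ungated")
  nk <- !bad & cd56_mfi >= config$cd56_positive_threshold
  bright <- cd56_mfi >= config$cd56_dim_bright_threshold
  pos16 <- cd16_mfi >= config$cd16_threshold
  out[nk & !bright & pos16] <- "CD56dim_CD16pos"
  out[nk & !bright & !pos16] <- "CD56dim_CD16neg"
  out[nk & bright & pos16] <- "CD56bright_CD16pos"
  out[nk & bright & !pos16] <- "CD56bright_CD16neg"
  out
}

#' Gate a cell table
#'
#' @param cells Data frame with `cd16_mfi`, `cd56_mfi`.
#' @param config A [gate_config()], or `NULL` to estimate thresholds from the
#'   data with [estimate_gate_thresholds()].
#' @return `cells` with a `phenotype_label` column added.
#' @export
gate_cells <- function(cells, config = gate_config()) {
  if (is.null(config)) config <- estimate_gate_thresholds(cells)
  cells$phenotype_label <- gate_phenotype(cells$cd16_mfi, cells$cd56_mfi,
                                          config)
  cells
}
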