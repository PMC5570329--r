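# Generative configuration for synthetic nanowell experiments.

#' Donor-level generative parameters
#'
#' Describes one donor's NK-cell population: the phenotype mixture over the
#' four CD16/CD56 gate quadrants, the per-phenotype probability of secreting
#' upon activation, and log-normal distributions for the secretion kinetics
#' (onset time `t_secrete` in minutes, Hill slope, and trace amplitude
#' `top - bottom` in MFI units). Channel intensities are drawn log-normally
#' around per-quadrant centers. `synergy_factor` multiplies the per-cell
#' secretion probability in wells holding more than one cell (1 = independent
#' secretion, the null).
#'
#' Defaults describe a peripheral-blood-like population dominated (90%) by
#' CD56^dim CD16^+ cells, an overall secretion probability of ~10% that is
#' mildly enriched in CD16^+ cells, and a positively skewed onset-time
#' distribution with mean ~62 min and mode ~52 min.
#'
#' @param phenotype_mix Named probabilities over the four gate labels,
#'   summing to 1.
#' @param secretor_prob Named per-phenotype secretion probabilities.
#' @param t_secrete_meanlog,t_secrete_sdlog Log-normal parameters of the
#'   onset time (min).
#' @param hill_meanlog,hill_sdlog Log-normal parameters of the Hill slope.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of the
#'   trace amplitude (MFI units).
#' @param baseline Baseline bead MFI.
#' @param synergy_factor Secretion-probability multiplier in multi-cell wells.
#' @param channel_centers Named list of `c(cd16 =, cd56 =)` intensity centers
#'   per phenotype label.
#' @param channel_sdlog Log-normal spread of channel intensities.
#' @return A `donor_profile` object.
#' @export
donor_profile <- function(
    phenotype_mix = c(CD56dim_CD16pos = 0.90, CD56bright_CD16neg = 0.06,
                      CD56dim_CD16neg = 0.03, CD56bright_CD16pos = 0.01),
    secretor_prob = c(CD56dim_CD16pos = 0.105, CD56bright_CD16neg = 0.06,
                      CD56dim_CD16neg = 0.05, CD56bright_CD16pos = 0.05),
    t_secrete_meanlog = 4.068, t_secrete_sdlog = 0.342,
    hill_meanlog = log(4), hill_sdlog = 0.3,
    amplitude_meanlog = log(2000), amplitude_sdlog = 0.5,
    baseline = 200, synergy_factor = 1,
    channel_centers = list(
      CD56dim_CD16pos = c(cd16 = 2000, cd56 = 600),
      CD56bright_CD16neg = c(cd16 = 80, cd56 = 6000),
      CD56dim_CD16neg = c(cd16 = 80, cd56 = 600),
      CD56bright_CD16pos = c(cd16 = 2000, cd56 = 6000)
    ),
    channel_sdlog = 0.35) {
  labs <- names(channel_centers)
  stopifnot(setequal(names(phenotype_mix), labs),
            setequal(names(secretor_prob), labs))
  if (abs(sum(phenotype_mix) - 1) > 1e-8)
    stop("`phenotype_mix` must sum to 1", call. = FALSE)
  if (any(secretor_prob < 0 | secretor_prob > 1))
    stop("`secretor_prob` entries must be probabilities", call. = FALSE)
  stopifnot(t_secrete_sdlog > 0, hill_sdlog > 0, amplitude_sdlog > 0,
            baseline > 0, synergy_factor >= 0)
  structure(
    list(phenotype_mix = phenotype_mix[labs],
         secretor_prob = secretor_prob[labs],
         t_secrete_meanlog = t_secrete_meanlog,
         t_secrete_sdlog = t_secrete_sdlog,
         hill_meanlog = hill_meanlog, hill_sdlog = hill_sdlog,
         amplitude_meanlog = amplitude_meanlog,
         amplitude_sdlog = amplitude_sdlog,
         baseline = baseline, synergy_factor = synergy_factor,
         channel_centers = channel_centers, channel_sdlog = channel_sdlog),
    class = "donor_profile"
  )
}

#' Donor presets with distinct mean onset times
#'
#' Two presets mirroring two donors with population mean onset times of 62
#' and 70 minutes (both positively skewed, modes near 50-55 min); donor 2
#' additionally secretes larger amounts at lower Hill slopes.
#'
#' @param donor 1 or 2.
#' @return A [donor_profile()].
#' @export
donor_profile_preset <- function(donor = 1) {
  switch(as.character(donor),
    "1" = donor_profile(),
    "2" = donor_profile(t_secrete_meanlog = 4.168, t_secrete_sdlog = 0.401,
                        amplitude_meanlog = log(3000),
                        hill_meanlog = log(3)),
    stop("`donor` must be 1 or 2", call. = FALSE)
  )
}

#' Nanowell array layout and loading parameters
#'
#' @param n_wells Number of wells.
#' @param well_pitch Center-to-center pitch (um), default 100.
#' @param well_size Well side (um), default 50.
#' @param cell_load_mean,bead_load_mean Poisson means of cells/beads per well.
#' @param max_count Truncation of the Poisson draws (occupancies above this
#'   are resampled as `max_count`).
#' @return An `array_layout` object.
#' @export
array_layout <- function(n_wells = 5000, well_pitch = 100, well_size = 50,
                         cell_load_mean = 0.5, bead_load_mean = 1,
                         max_count = 5) {
  stopifnot(n_wells >= 1, well_pitch > 0, well_size > 0,
            well_size <= well_pitch,
            cell_load_mean >= 0, bead_load_mean >= 0, max_count >= 1)
  structure(list(n_wells = as.integer(n_wells), well_pitch = well_pitch,
                 well_size = well_size, cell_load_mean = cell_load_mean,
                 bead_load_mean = bead_load_mean,
                 max_count = as.integer(max_count)),
            class = "array_layout")
}

#' Measurement noise model for bead traces
#'
#' Per-frame noise is Gaussian with standard deviation
#' `multiplicative_sigma * (trace dynamic range) + 0`, plus independent
#' additive Gaussian noise of SD `additive_sigma`, plus a linear background
#' drift of `background_drift` MFI units per hour.
#'
#' @param multiplicative_sigma Noise SD as a fraction of each trace's dynamic
#'   range (default 0.02).
#' @param additive_sigma Additive noise SD in MFI units (default 5).
#' @param background_drift Drift in MFI units per hour (default 0).
#' @return A `noise_model` object.
#' @export
noise_model <- function(multiplicative_sigma = 0.02, additive_sigma = 5,
                        background_drift = 0) {
  stopifnot(multiplicative_sigma >= 0, additive_sigma >= 0,
            background_drift >= 0)
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 additive_sigma = additive_sigma,
                 background_drift = background_drift),
            class = "noise_model")
}

#' Time-lapse acquisition schedule
#'
#' @param start First frame time (min).
#' @param interval Frame spacing (min), default 10.
#' @param duration Total duration (min), default 360 (6 h, 37 frames).
#' @return Numeric vector of frame times in minutes.
#' @export
trace_schedule <- function(start = 0, interval = 10, duration = 360) {
  stopifnot(interval > 0, duration >= interval)
  seq(start, start + duration, by = interval)
}
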