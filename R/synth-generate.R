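# Seeded generators for synthetic nanowell experiments. Every generator is a
# pure function of (config, seed): the same seed reproduces identical tables.

#' Sample well occupancies by Poisson loading
#'
#' Cells and beads load independently and Poisson per well (the standard null
#' for gravity loading of a suspension over an open array), truncated at
#' `layout$max_count`.
#'
#' @param layout An [array_layout()].
#' @param seed Integer RNG seed.
#' @return Tibble `well_id`, `n_cells`, `n_beads`.
#' @export
sample_occupancy <- function(layout, seed) {
  stopifnot(inherits(layout, "array_layout"))
  set.seed(seed)
  n <- layout$n_wells
  tibble::tibble(
    well_id = sprintf("W%06d", seq_len(n)),
    n_cells = pmin(stats::rpois(n, layout$cell_load_mean), layout$max_count),
    n_beads = pmin(stats::rpois(n, layout$bead_load_mean), layout$max_count)
  )
}

.sample_positions <- function(n, well_size, radius, seed_offset_state = NULL) {
  # rejection sampling for non-overlapping in-well positions
  lo <- radius; hi <- well_size - radius
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
      if (i == 1 || all((x - xs[seq_len(i - 1)])^2 +
                        (y - ys[seq_len(i - 1)])^2 >= (2 * radius)^2)) break
    }
    xs[i] <- x; ys[i] <- y
  }
  list(x = xs, y = ys)
}

#' Sample cells, phenotypes and secretion ground truth
#'
#' Each cell draws a phenotype from the donor mixture, a secretor flag from
#' that phenotype's probability (multiplied by `synergy_factor` in wells with
#' more than one cell), channel intensities consistent with its gate
#' quadrant, an in-well position, and - for secretors - true 4PL kinetics.
#'
#' @param occupancy Occupancy table from [sample_occupancy()].
#' @param donor A [donor_profile()].
#' @param seed Integer RNG seed.
#' @param well_size Well side (um) for position sampling.
#' @return A list: `cells` (tibble `cell_id`, `well_id`, `cd16_mfi`,
#'   `cd56_mfi`, `x_um`, `y_um`) and `truth` (per-cell manifest with
#'   `phenotype`, `is_secretor` and true `bottom`, `top`, `ec50`, `hill`).
#' @export
sample_cells <- function(occupancy, donor, seed, well_size = 50) {
  stopifnot(inherits(donor, "donor_profile"))
  set.seed(seed)
  labs <- names(donor$phenotype_mix)
  wells <- occupancy[occupancy$n_cells > 0, ]
  n_tot <- sum(wells$n_cells)
  if (n_tot == 0) {
    empty <- tibble::tibble(cell_id = character(0), well_id = character(0),
                            cd16_mfi = numeric(0), cd56_mfi = numeric(0),
                            x_um = numeric(0), y_um = numeric(0))
    truth <- tibble::tibble(cell_id = character(0), well_id = character(0),
                            phenotype = character(0), is_secretor = logical(0),
                            bottom = numeric(0), top = numeric(0),
                            ec50 = numeric(0), hill = numeric(0))
    return(list(cells = empty, truth = truth))
  }
  well_id <- rep(wells$well_id, wells$n_cells)
  n_in_well <- rep(wells$n_cells, wells$n_cells)
  cell_id <- sprintf("%s_C%d", well_id,
                     unlist(lapply(wells$n_cells, seq_len)))
  phen <- sample(labs, n_tot, replace = TRUE, prob = donor$phenotype_mix)
  p_sec <- pmin(donor$secretor_prob[phen] *
                  ifelse(n_in_well > 1, donor$synergy_factor, 1), 1)
  is_sec <- stats::runif(n_tot) < p_sec
  ec50 <- stats::rlnorm(n_tot, donor$t_secrete_meanlog, donor$t_secrete_sdlog)
  hill <- stats::rlnorm(n_tot, donor$hill_meanlog, donor$hill_sdlog)
  amp <- stats::rlnorm(n_tot, donor$amplitude_meanlog, donor$amplitude_sdlog)
  centers <- do.call(rbind, donor$channel_centers[phen])
  cd16 <- stats::rlnorm(n_tot, log(centers[, "cd16"]), donor$channel_sdlog)
  cd56 <- stats::rlnorm(n_tot, log(centers[, "cd56"]), donor$channel_sdlog)
  pos_x <- numeric(n_tot); pos_y <- numeric(n_tot)
  idx <- split(seq_len(n_tot), well_id)
  for (ii in idx) {
    p <- .sample_positions(length(ii), well_size, radius = 4)
    pos_x[ii] <- p$x; pos_y[ii] <- p$y
  }
  cells <- tibble::tibble(cell_id = cell_id, well_id = well_id,
                          cd16_mfi = cd16, cd56_mfi = cd56,
                          x_um = pos_x, y_um = pos_y)
  truth <- tibble::tibble(
    cell_id = cell_id, well_id = well_id, phenotype = phen,
    is_secretor = is_sec,
    bottom = ifelse(is_sec, 0, NA_real_),
    top = ifelse(is_sec, amp, NA_real_),
    ec50 = ifelse(is_sec, ec50, NA_real_),
    hill = ifelse(is_sec, hill, NA_real_)
  )
  list(cells = cells, truth = truth)
}

#' Generate noisy bead traces from the ground truth
#'
#' Every bead in a well reports the well's analyte signal: the donor baseline
#' plus one 4PL component per secreting cell in that well (amplitude `top`,
#' onset `ec50`, slope `hill`), sampled on the acquisition schedule with the
#' noise model applied. Wells without secreting cells give flat baseline
#' traces.
#'
#' @param occupancy Occupancy table (wells with `n_beads >= 1` get traces).
#' @param truth Per-cell truth table from [sample_cells()].
#' @param donor The [donor_profile()] (for the baseline).
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed.
#' @param schedule Frame times in minutes, see [trace_schedule()].
#' @param well_size Well side (um) for bead position sampling.
#' @return A list: `traces` (tibble `bead_id`, `well_id`, `time_min`, `mfi`)
#'   and `beads` (tibble `bead_id`, `well_id`, `x_um`, `y_um`).
#' @export
generate_traces <- function(occupancy, truth, donor, noise = noise_model(),
                            seed = 1, schedule = trace_schedule(),
                            well_size = 50) {
  stopifnot(inherits(noise, "noise_model"), inherits(donor, "donor_profile"))
  set.seed(seed)
  wells <- occupancy[occupancy$n_beads > 0, ]
  n_beads <- sum(wells$n_beads)
  if (n_beads == 0) {
    return(list(
      traces = tibble::tibble(bead_id = character(0), well_id = character(0),
                              time_min = numeric(0), mfi = numeric(0)),
      beads = tibble::tibble(bead_id = character(0), well_id = character(0),
                             x_um = numeric(0), y_um = numeric(0))))
  }
  bead_well <- rep(wells$well_id, wells$n_beads)
  bead_id <- sprintf("%s_B%d", bead_well,
                     unlist(lapply(wells$n_beads, seq_len)))
  pos_x <- numeric(n_beads); pos_y <- numeric(n_beads)
  for (ii in split(seq_len(n_beads), bead_well)) {
    p <- .sample_positions(length(ii), well_size, radius = 2.5)
    pos_x[ii] <- p$x; pos_y[ii] <- p$y
  }
  beads <- tibble::tibble(bead_id = bead_id, well_id = bead_well,
                          x_um = pos_x, y_um = pos_y)

  sec <- truth[truth$is_secretor %in% TRUE, ]
  sec_by_well <- split(sec, sec$well_id)
  nt <- length(schedule)
  drift <- noise$background_drift * schedule / 60
  rows <- vector("list", n_beads)
  for (b in seq_len(n_beads)) {
    w <- bead_well[b]
    curve <- rep(donor$baseline, nt)
    sw <- sec_by_well[[w]]
    if (!is.null(sw) && nrow(sw) > 0) {
      for (s in seq_len(nrow(sw))) {
        curve <- curve + four_param_logistic(schedule, 0, sw$top[s],
                                             sw$ec50[s], sw$hill[s])
      }
    }
    rng <- diff(range(curve))
    sd_t <- noise$multiplicative_sigma * rng
    eps <- if (sd_t > 0 || noise$additive_sigma > 0) {
      stats::rnorm(nt, 0, sd_t) + stats::rnorm(nt, 0, noise$additive_sigma)
    } else 0
    rows[[b]] <- tibble::tibble(bead_id = bead_id[b], well_id = w,
                                time_min = schedule,
                                mfi = curve + drift + eps)
  }
  list(traces = dplyr::bind_rows(rows), beads = beads)
}

#' Generate a complete synthetic nanowell dataset
#'
#' Runs [sample_occupancy()], [sample_cells()] and [generate_traces()] with
#' seeds derived from `seed`, bundling the results with the configuration as
#' a ground-truth manifest. Regenerating with the same configuration and
#' seed reproduces identical tables.
#'
#' @param layout An [array_layout()].
#' @param donor A [donor_profile()].
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed.
#' @param schedule Frame times (min).
#' @return A `nanowell_dataset` list: `occupancy`, `cells`, `truth`, `beads`,
#'   `traces`, `schedule`, `seed`, and the three config objects.
#' @export
generate_dataset <- function(layout = array_layout(),
                             donor = donor_profile(),
                             noise = noise_model(), seed = 1,
                             schedule = trace_schedule()) {
  occ <- sample_occupancy(layout, seed)
  sc <- sample_cells(occ, donor, seed + 1L, well_size = layout$well_size)
  tr <- generate_traces(occ, sc$truth, donor, noise, seed + 2L, schedule,
                        well_size = layout$well_size)
  structure(
    list(occupancy = occ, cells = sc$cells, truth = sc$truth,
         beads = tr$beads, traces = tr$traces, schedule = schedule,
         seed = seed, layout = layout, donor = donor, noise = noise),
    class = "nanowell_dataset"
  )
}
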