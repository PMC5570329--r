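# Shared fixtures. All data are generated in code; no files are read.

# 40 um well presets at coarse/medium resolution for fast solver tests
geo40 <- function(h = 2) well_geometry_preset("sim40", voxel_size = h)

# a placement whose bead stays resolved down to 4 um voxels (sphere centers
# near voxel centers of the h = 4 grid)
plc_aligned <- function() {
  placement(cell_center = c(14, 20, 4), bead_center = c(26, 18, 2.5))
}

kin_theta <- function(theta0, ...) binding_kinetics(theta0 = theta0, ...)

# noiseless samples of the 4PL on the standard 37-frame/10-min schedule
make_4pl_trace <- function(bottom, top, ec50, hill, times = seq(0, 360, 10),
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- four_param_logistic(times, bottom, top, ec50, hill)
  if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
  bead_trace(times, y, bead_id = "B1", well_id = "W1")
}

# minimal occupancy/call tables for the frequency and cooperation statistics:
# n1 single-cell wells (positive with probability p1), n2 two-cell and n3
# three-cell wells positive under independence (or with a synergy multiplier
# on the per-cell probability)
make_null_wells <- function(n1, n2 = 0, n3 = 0, p1 = 0.2, synergy = 1,
                            seed = 1) {
  set.seed(seed)
  n_cells <- rep(c(1L, 2L, 3L), c(n1, n2, n3))
  n <- length(n_cells)
  p_cell <- pmin(p1 * ifelse(n_cells > 1, synergy, 1), 1)
  p_well <- 1 - (1 - p_cell)^n_cells
  pos <- stats::runif(n) < p_well
  wells <- tibble::tibble(well_id = sprintf("W%06d", seq_len(n)),
                          n_cells = n_cells, n_beads = 1L)
  calls <- tibble::tibble(well_id = wells$well_id[pos],
                          is_secretor = TRUE)
  list(wells = wells, calls = calls)
}

# a cohort of single-cell single-bead wells driven by the donor profile
make_cohort <- function(n_wells, donor = donor_profile(),
                        noise = noise_model(), seed = 1) {
  occ <- tibble::tibble(well_id = sprintf("W%06d", seq_len(n_wells)),
                        n_cells = 1L, n_beads = 1L)
  sc <- sample_cells(occ, donor, seed)
  tr <- generate_traces(occ, sc$truth, donor, noise, seed + 1L)
  list(occupancy = occ, cells = sc$cells, truth = sc$truth,
       traces = tr$traces)
}
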