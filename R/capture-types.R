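#' Nanowell geometry for the capture simulator
#'
#' Describes one open nanowell: a square cross-section well of side
#' `well_width` and depth `well_depth`, topped by a buffer region of height
#' `buffer_height` that stands in for the bulk medium above the well mouth.
#' The computational domain is the well plus buffer, discretised into cubic
#' voxels of edge `voxel_size`.
#'
#' @param well_width Side of the square well cross-section (um).
#' @param well_depth Depth of the well (um).
#' @param buffer_height Height of the medium column above the well mouth (um);
#'   must be at least `well_depth`.
#' @param voxel_size Voxel edge length (um); must divide `well_width` and
#'   `well_depth + buffer_height` to within one voxel.
#' @return A `well_geometry` object.
#' @examples
#' well_geometry()                 # 50 x 50 x 60 um fabrication geometry
#' well_geometry_preset("sim40")  # 40 um well used for simulation snapshots
#' @export
well_geometry <- function(well_width = 50, well_depth = 60,
                          buffer_height = well_depth, voxel_size = 2) {
  stopifnot(is.numeric(well_width), is.numeric(well_depth),
            is.numeric(buffer_height), is.numeric(voxel_size))
  if (any(c(well_width, well_depth, buffer_height, voxel_size) <= 0)) {
    stop("all geometry lengths must be > 0", call. = FALSE)
  }
  if (buffer_height < well_depth) {
    stop("`buffer_height` must be >= `well_depth` (the buffer stands in for bulk medium)",
         call. = FALSE)
  }
  height <- well_depth + buffer_height
  divides <- function(len) abs(len / voxel_size - round(len / voxel_size)) < 1e-9
  if (!divides(well_width) || !divides(height)) {
    stop("`voxel_size` must divide `well_width` and the total domain height",
         call. = FALSE)
  }
  structure(
    list(well_width = well_width, well_depth = well_depth,
         buffer_height = buffer_height, voxel_size = voxel_size),
    class = "well_geometry"
  )
}

#' @rdname well_geometry
#' @param name Preset name: `"fab50"` (50 x 50 x 60 um fabrication dimensions)
#'   or `"sim40"` (40 um well).
#' @param voxel_size Voxel edge (um), passed through to [well_geometry()].
#' @export
well_geometry_preset <- function(name = c("fab50", "sim40"), voxel_size = 2) {
  name <- match.arg(name)
  switch(name,
    fab50 = well_geometry(50, 60, 60, voxel_size),
    sim40 = well_geometry(40, 40, 40, voxel_size)
  )
}

#' Cell and bead placement inside a nanowell
#'
#' Positions of the secreting cell and the capture bead, both modelled as
#' spheres. Coordinates are in um with the origin at one bottom corner of the
#' well; z increases upward. Both spheres must lie fully inside the well
#' (below the mouth) and must not overlap.
#'
#' @param cell_center,bead_center Numeric length-3 (x, y, z) in um.
#' @param cell_radius Cell radius (um); default 4 (an 8 um lymphocyte).
#' @param bead_radius Bead radius (um); default 2.5 (5 um sensor bead).
#' @return A `placement` object.
#' @export
placement <- function(cell_center, bead_center,
                      cell_radius = 4, bead_radius = 2.5) {
  as_pt <- function(p, what) {
    p <- as.numeric(p)
    if (length(p) != 3 || any(!is.finite(p)))
      stop(sprintf("`%s` must be a finite (x, y, z) triple", what), call. = FALSE)
    p
  }
  cell_center <- as_pt(cell_center, "cell_center")
  bead_center <- as_pt(bead_center, "bead_center")
  stopifnot(cell_radius > 0, bead_radius > 0)
  d <- sqrt(sum((cell_center - bead_center)^2))
  if (d < cell_radius + bead_radius) {
    stop("cell and bead spheres overlap", call. = FALSE)
  }
  structure(
    list(cell_center = cell_center, cell_radius = cell_radius,
         bead_center = bead_center, bead_radius = bead_radius),
    class = "placement"
  )
}

#' Default side-by-side placement at the well floor
#'
#' Cell and bead resting on the well floor, offset symmetrically about the
#' well center along x with a small clearance between them.
#'
#' @param geometry A [well_geometry()].
#' @param gap Clearance between sphere surfaces (um).
#' @inheritParams placement
#' @return A `placement` object.
#' @export
placement_default <- function(geometry, cell_radius = 4, bead_radius = 2.5,
                              gap = 1) {
  w <- geometry$well_width
  half <- (cell_radius + bead_radius + gap) / 2
  placement(
    cell_center = c(w / 2 - half, w / 2, cell_radius),
    bead_center = c(w / 2 + half, w / 2, bead_radius),
    cell_radius = cell_radius, bead_radius = bead_radius
  )
}

#' Systematic placements varying the bead-cell distance
#'
#' Keeps the cell at the well floor near one side and slides the bead along
#' the floor from adjacent to the far side, giving `n` placements with
#' systematically increasing separation. Used for position-sensitivity sweeps.
#'
#' @inheritParams placement_default
#' @param n Number of placements (>= 2).
#' @return List of `placement` objects, ordered near to far.
#' @export
placement_axial_set <- function(geometry, n = 3, cell_radius = 4,
                                bead_radius = 2.5, gap = 1) {
  stopifnot(n >= 2)
  w <- geometry$well_width
  cell_x <- cell_radius + gap
  x_min <- cell_x + cell_radius + bead_radius + gap
  x_max <- w - bead_radius - gap
  if (x_max <= x_min) stop("well too small for an axial placement set", call. = FALSE)
  xs <- seq(x_min, x_max, length.out = n)
  lapply(xs, function(x) {
    placement(c(cell_x, w / 2, cell_radius), c(x, w / 2, bead_radius),
              cell_radius = cell_radius, bead_radius = bead_radius)
  })
}

#' Analyte transport and surface-binding kinetics
#'
#' Physical constants of the analyte and the capture chemistry. The surface
#' mass balance on the bead is Langmuir binding,
#' `dCs/dt = k_on C (theta0 - Cs) - k_off Cs`, with surface diffusion of the
#' bound analyte neglected. Defaults describe a small cytokine captured by a
#' high-affinity antibody and are assumptions, not measured values; override
#' them when the chemistry is known.
#'
#' @param D Analyte diffusion coefficient in medium (m^2/s).
#' @param k_on Association rate (1/M/s).
#' @param k_off Dissociation rate (1/s).
#' @param theta0 Capture-antibody site density on the bead (mol/m^2).
#' @param secretion_rate Constant secretion rate of the cell (molecules/s).
#' @return A `binding_kinetics` object.
#' @export
binding_kinetics <- function(D = 1e-10, k_on = 1e6, k_off = 1e-5,
                             theta0 = 1e-8, secretion_rate = 10) {
  stopifnot(is.numeric(D), is.numeric(k_on), is.numeric(k_off),
            is.numeric(theta0), is.numeric(secretion_rate))
  if (D <= 0) stop("`D` must be > 0", call. = FALSE)
  if (k_on < 0 || k_off < 0 || theta0 < 0 || secretion_rate < 0) {
    stop("rates and densities must be >= 0", call. = FALSE)
  }
  structure(
    list(D = D, k_on = k_on, k_off = k_off, theta0 = theta0,
         secretion_rate = secretion_rate),
    class = "binding_kinetics"
  )
}

#' Time-integration settings for the capture simulator
#'
#' @param t_end Simulated duration (h); default 6 h.
#' @param output_interval Output spacing (min); default 10 min.
#' @param dt_max Largest macro time step (s). The solver ramps from 1 s steps
#'   over the first minute, through 5 s steps to 10 min, then `dt_max`;
#'   `dt_max` must divide `output_interval` so outputs fall on step
#'   boundaries.
#' @param picard_tol Relative convergence tolerance of the per-step surface
#'   coupling iteration.
#' @param open_top If `TRUE`, the top of the buffer is an absorbing
#'   (zero-concentration) face modelling escape to a far-field sink; if
#'   `FALSE` (default) the buffer is a finite reservoir with a no-flux top.
#' @return A `sim_settings` object.
#' @export
sim_settings <- function(t_end = 6, output_interval = 10, dt_max = 30,
                         picard_tol = 1e-10, open_top = FALSE) {
  stopifnot(t_end > 0, output_interval > 0, dt_max > 0, picard_tol > 0)
  if (output_interval > t_end * 60) {
    stop("`output_interval` must be <= `t_end`", call. = FALSE)
  }
  out_s <- output_interval * 60
  if (abs(out_s / dt_max - round(out_s / dt_max)) > 1e-9) {
    stop("`dt_max` must divide `output_interval`", call. = FALSE)
  }
  structure(
    list(t_end = t_end, output_interval = output_interval, dt_max = dt_max,
         picard_tol = picard_tol, open_top = isTRUE(open_top)),
    class = "sim_settings"
  )
}
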