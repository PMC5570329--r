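# Capture time series container -----------------------------------------

#' Build a capture time-series table
#'
#' One row per output time. Columns: `time_min`, `frac_occupancy` (bead-mean
#' fraction of antibody sites bound), `captured_density_per_um2`
#' (bound molecules per um^2 of bead surface), `bound`, `free`, `escaped`,
#' `secreted` (molecule counts) and `residual` (relative mass-balance
#' residual, see [mass_balance_residual()]).
#'
#' @keywords internal
#' @noRd
new_capture_series <- function(time_min, frac_occupancy, captured_density,
                               bound, free, escaped, secreted, residual,
                               meta = list()) {
  out <- tibble::tibble(
    time_min = time_min,
    frac_occupancy = frac_occupancy,
    captured_density_per_um2 = captured_density,
    bound = bound, free = free, escaped = escaped,
    secreted = secreted, residual = residual
  )
  attr(out, "capture_meta") <- meta
  class(out) <- c("capture_series", class(out))
  out
}

#' Relative mass-balance residual of a capture simulation
#'
#' At the final output time, `|secreted - free - bound - escaped| /
#' max(secreted, 1)`. For the finite-volume solver `escaped` is accumulated
#' with a boundary-flux quadrature that is independent of the scheme's own
#' bookkeeping, so the residual measures real discretization error and
#' shrinks under grid refinement.
#'
#' @param series A capture time series from [simulate_capture()] or
#'   [wellmixed_oracle()].
#' @return Relative residual at the final time (dimensionless).
#' @export
mass_balance_residual <- function(series) {
  stopifnot(inherits(series, "capture_series") || all(
    c("secreted", "free", "bound", "escaped") %in% names(series)))
  n <- nrow(series)
  with(series[n, ], abs(secreted - free - bound - escaped) / max(secreted, 1))
}

# Well-mixed two-compartment oracle --------------------------------------

#' Well-mixed Langmuir capture oracle
#'
#' Spatially homogeneous limit of the open-well capture model: a single
#' well-mixed fluid compartment (well + buffer volume, minus the cell and
#' bead spheres) fed by the cell at `secretion_rate`, exchanging with the
#' bead surface by Langmuir kinetics, and (optionally) leaking to a zero
#' far-field through a diffusive conductance at the top. This is a
#' closed-form-checkable reference used to verify the spatial solver in its
#' high-diffusivity limit; it is not the production model.
#'
#' @param geometry A [well_geometry()].
#' @param kinetics A [binding_kinetics()].
#' @param sealed If `TRUE` (default) no analyte leaves the compartment.
#' @param settings A [sim_settings()]; only `t_end`/`output_interval` used.
#' @param fixed_C_molar Optional: hold the free concentration at this value
#'   (mol/L) instead of evolving it; then only the surface evolves and the
#'   long-time occupancy is the Langmuir isotherm `C/(C + Kd)`.
#' @param bead_radius,cell_radius Sphere radii (um) used for the compartment
#'   volume and bead area; defaults match [placement_default()].
#' @return A capture time-series table (see [mass_balance_residual()]).
#' @export
wellmixed_oracle <- function(geometry, kinetics, sealed = TRUE,
                             settings = sim_settings(),
                             fixed_C_molar = NULL,
                             bead_radius = 2.5, cell_radius = 4) {
  stopifnot(inherits(geometry, "well_geometry"),
            inherits(kinetics, "binding_kinetics"))
  H <- geometry$well_depth + geometry$buffer_height
  W <- geometry$well_width
  r_b <- bead_radius
  r_c <- cell_radius
  V <- W^2 * H - 4 / 3 * pi * (r_b^3 + r_c^3)   # um^3
  A <- 4 * pi * r_b^2                            # um^2
  th <- convert_site_density(kinetics$theta0)    # molecules/um^2
  kon <- .kon_to_internal(kinetics$k_on)         # um^3/(molecule s)
  koff <- kinetics$k_off
  S <- kinetics$secretion_rate
  D <- .D_to_internal(kinetics$D)
  G <- if (sealed) 0 else D * W^2 / (H / 2)      # escape conductance um^3/s

  hold <- !is.null(fixed_C_molar)
  C_hold <- if (hold) fixed_C_molar * .molar_to_per_um3 else NA_real_

  times <- seq(0, settings$t_end * 3600, by = settings$output_interval * 60)
  rhs <- function(t, y, parms) {
    N <- y[1]; Cs <- y[2]
    C <- if (hold) C_hold else N / V
    r <- kon * C * (th - Cs) - koff * Cs
    dN <- if (hold) 0 else S - A * r - G * C
    list(c(dN, r, G * C))
  }
  sol <- deSolve::ode(y = c(N = 0, Cs = 0, E = 0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  N <- sol[, "N"]; Cs <- sol[, "Cs"]; E <- sol[, "E"]
  secreted <- if (hold) NA_real_ else S * times
  bound <- Cs * A
  occ <- if (th > 0) Cs / th else rep(0, length(Cs))
  resid <- if (hold) rep(NA_real_, length(times)) else
    abs(secreted - N - bound - E) / pmax(secreted, 1)
  new_capture_series(
    time_min = times / 60, frac_occupancy = occ, captured_density = Cs,
    bound = bound, free = N, escaped = E, secreted = secreted,
    residual = resid,
    meta = list(model = "wellmixed", volume_um3 = V, bead_area_um2 = A,
                sealed = sealed)
  )
}
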