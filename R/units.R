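# Internal unit system for the transport solver: lengths in um, time in s,
# free analyte in molecules/um^3, surface analyte in molecules/um^2.

#' Avogadro constant (1/mol)
#' @keywords internal
#' @noRd
AVOGADRO <- 6.02214076e23

#' Convert an antibody site density from mol/m^2 to molecules/um^2
#'
#' Capture-antibody surface densities are conventionally quoted in mol/m^2;
#' the solver and all per-bead bookkeeping count molecules per um^2. The
#' conversion is `theta0 * N_A * 1e-12`.
#'
#' @param theta0 Site density in mol/m^2 (scalar or vector, all `>= 0`).
#' @return Site density in molecules/um^2.
#' @examples
#' convert_site_density(1e-9) # ~602 molecules/um^2
#' @export
convert_site_density <- function(theta0) {
  if (!is.numeric(theta0) || any(!is.finite(theta0)) || any(theta0 < 0)) {
    stop("`theta0` must be a finite non-negative site density in mol/m^2",
         call. = FALSE)
  }
  theta0 * AVOGADRO * 1e-12
}

# mol/L (M) -> molecules/um^3 multiplier, and its inverse for k_on.
.molar_to_per_um3 <- AVOGADRO / 1e15

# k_on in 1/M/s -> um^3/(molecule s)
.kon_to_internal <- function(k_on) k_on / .molar_to_per_um3

# D in m^2/s -> um^2/s
.D_to_internal <- function(D) D * 1e12
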