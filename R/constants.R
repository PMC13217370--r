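# Physical constants (CODATA 2018, SI) and the unit conversions used
# throughout the package.  All other modules work in kJ/mol and Angstrom at
# their interfaces and convert here, in one place.

#' Physical constants used by the package
#'
#' A named list of CODATA 2018 values in SI units: `R` (gas constant,
#' J mol^-1 K^-1), `kB` (Boltzmann, J/K), `N_A` (Avogadro, mol^-1),
#' `e` (elementary charge, C), `eps0` (vacuum permittivity, F/m),
#' `h` (Planck, J s).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' phys_constants()$R
phys_constants <- function() {
  list(
    R    = 8.314462618,     # J mol^-1 K^-1
    kB   = 1.380649e-23,    # J K^-1
    N_A  = 6.02214076e23,   # mol^-1
    e    = 1.602176634e-19, # C
    eps0 = 8.8541878128e-12,# F m^-1
    h    = 6.62607015e-34   # J s
  )
}

.const <- phys_constants()

# kJ/mol -> J/mol
.kj_to_j <- function(x) x * 1e3

# Angstrom -> metre
.ang_to_m <- function(x) x * 1e-10

# m^3 mol^-1 s^-1 (SI bimolecular rate) -> M^-1 s^-1 (litre-based)
.si_rate_to_molar <- function(k) k * 1e3

# mol/L -> number density per m^3
.molar_to_number_density <- function(c0) c0 * 1e3 * .const$N_A

.stopifnot_finite <- function(..., .msg = "inputs must be finite numbers") {
  vals <- c(...)
  if (!is.numeric(vals) || any(!is.finite(vals))) stop(.msg, call. = FALSE)
  invisible(TRUE)
}

#' Solvent dielectric constant at temperature
#'
#' Linear interpolation between the two anchors used for the binding
#' free-energy calculations: water at 298 K (eps_r = 78.36) and the
#' temperature-corrected value at 333 K (eps_r = 66.77).  Temperatures
#' outside the anchor interval are linearly extrapolated.
#'
#' @param T_K Temperature in kelvin.
#' @return Dimensionless relative permittivity.
#' @export
#' @examples
#' water_dielectric(298)
#' water_dielectric(333)
water_dielectric <- function(T_K) {
  .stopifnot_finite(T_K)
  if (any(T_K <= 0)) stop("temperature must be positive", call. = FALSE)
  78.36 + (T_K - 298) * (66.77 - 78.36) / (333 - 298)
}
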