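# Free-energy profiles of the probe-ion binding coordinate: construction,
# file I/O, Gibbs composition, translational entropy, and extraction of the
# well depth / barrier height that drive all downstream kinetics.

#' Free-energy profile along the binding coordinate
#'
#' Constructs a validated `free_energy_profile` object: tabulated free energy
#' `G(r)` (kJ/mol, referenced to the separated state at large `r`) on a
#' strictly increasing separation grid `r` (Angstrom), together with the
#' temperature the profile describes and the minimum binding distance `a`
#' used as the lower limit of rate integrals.
#'
#' @param r Numeric vector of separations, Angstrom, strictly increasing,
#'   length >= 3.
#' @param G Numeric vector of free energies, kJ/mol, same length as `r`.
#'   `G[length(G)]` must be within `ref_tol` of 0 (separated-state reference).
#' @param T_K Temperature the profile describes, K.
#' @param a Minimum binding distance (lower integration limit), Angstrom.
#'   Must satisfy `min(r) <= a < max(r)`.
#' @param ref_tol Tolerance on the separated-state reference, kJ/mol.
#' @return Object of class `free_energy_profile` with fields `r`, `G`,
#'   `T_K`, `a`.
#' @export
#' @examples
#' p <- free_energy_profile(r = c(2, 10, 40), G = c(-40, 5, 0), T_K = 298, a = 2)
free_energy_profile <- function(r, G, T_K = 298, a = min(r), ref_tol = 1e-6) {
  .stopifnot_finite(r, G, T_K, a)
  if (length(r) != length(G) || length(r) < 3)
    stop("r and G must have equal length >= 3", call. = FALSE)
  if (any(diff(r) <= 0))
    stop("separation grid r must be strictly increasing", call. = FALSE)
  if (abs(G[length(G)]) > ref_tol)
    stop("G at the largest separation must be ~0 (separated-state reference)",
         call. = FALSE)
  if (T_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (a < r[1] || a >= r[length(r)])
    stop("minimum binding distance a must lie within the grid", call. = FALSE)
  structure(list(r = as.numeric(r), G = as.numeric(G),
                 T_K = as.numeric(T_K), a = as.numeric(a)),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile> %d points, r in [%.3g, %.3g] A, T = %.6g K, a = %.3g A\n",
    length(x$r), x$r[1], x$r[length(x$r)], x$T_K, x$a))
  cat(sprintf("  min G = %.4g kJ/mol, max G = %.4g kJ/mol\n",
              min(x$G), max(x$G)))
  invisible(x)
}

#' Gibbs free energy from its electronic-structure components
#'
#' Composes a Gibbs free energy as `G = E + ZPE + Hth - TS`: electronic
#' energy plus zero-point energy plus thermal enthalpy correction minus the
#' entropy term (temperature times entropy).  All terms in kJ/mol.
#'
#' @param E Electronic energy, kJ/mol.
#' @param ZPE Zero-point energy, kJ/mol.
#' @param Hth Thermal enthalpy correction, kJ/mol.
#' @param TS Entropy term (T times S), kJ/mol.
#' @return Free energy, kJ/mol.
#' @export
#' @examples
#' gibbs_from_components(E = -100, ZPE = 10, Hth = 5, TS = 20)  # -105
gibbs_from_components <- function(E, ZPE = 0, Hth = 0, TS = 0) {
  .stopifnot_finite(E, ZPE, Hth, TS)
  E + ZPE + Hth - TS
}

#' Sackur-Tetrode translational entropy
#'
#' Standard molar translational entropy of an ideal gas of particles of mass
#' `mass` at temperature `T_K`, at the molar volume implied by a standard-state
#' concentration (1 M corresponds to a molar volume of 1 L/mol).  Used for
#' the translational-entropy correction of the ion separation process.
#'
#' S/R = ln[(2 pi m kB T / h^2)^{3/2} * Vm / NA] + 5/2
#'
#' @param mass Particle mass, kg.
#' @param T_K Temperature, K.
#' @param concentration Standard-state concentration, mol/L; sets the molar
#'   volume `Vm = 1e-3 / concentration` m^3/mol.
#' @return Molar translational entropy, J mol^-1 K^-1.
#' @export
#' @examples
#' # argon at 298.15 K at the 1 atm ideal-gas molar volume (~0.04087 M)
#' sackur_tetrode_entropy(6.6335e-26, 298.15, 0.0408740)
sackur_tetrode_entropy <- function(mass, T_K, concentration = 1) {
  .stopifnot_finite(mass, T_K, concentration)
  if (mass <= 0 || T_K <= 0 || concentration <= 0)
    stop("mass, temperature and concentration must be positive", call. = FALSE)
  k <- .const
  Vm <- 1e-3 / concentration                       # m^3 per mole
  lambda_term <- (2 * pi * mass * k$kB * T_K / k$h^2)^1.5
  k$R * (log(lambda_term * Vm / k$N_A) + 2.5)
}

#' Build a synthetic free-energy profile from its scalar features
#'
#' Constructs a smooth well-plus-barrier profile whose extracted well depth
#' equals `dG0` and whose barrier height (measured from the separated state)
#' equals `Ea`.  The shape is a sum of two narrow Gaussian features centred
#' at `r_well` and `r_barrier` (width one eighth of their separation, so
#' cross-contamination of the two extrema is below 1e-9 kJ/mol), decaying to
#' the zero reference at large separation.  Only the two scalar features
#' enter any downstream rate; the shape between them is a modelling choice.
#'
#' @param dG0 Well depth (standard binding free energy), kJ/mol, usually
#'   negative.
#' @param Ea Barrier height above the separated state, kJ/mol, >= 0.
#' @param r_well Position of the bound-state minimum, Angstrom.
#' @param r_barrier Position of the barrier maximum, Angstrom; must exceed
#'   `r_well`.
#' @param r_max Largest separation on the grid, Angstrom.
#' @param a Minimum binding distance (grid start), Angstrom; `a <= r_well`.
#' @param n_points Grid size before inserting the feature positions.
#' @param T_K Temperature tag for the profile, K.
#' @return A [free_energy_profile].
#' @export
#' @examples
#' p <- build_profile(dG0 = -43.84, Ea = 76.32)
#' extract_thermo(p)
build_profile <- function(dG0, Ea, r_well = 2.2, r_barrier = 6, r_max = 40,
                          a = 1, n_points = 400, T_K = 298) {
  .stopifnot_finite(dG0, Ea, r_well, r_barrier, r_max, a)
  if (Ea < 0) stop("barrier height Ea must be >= 0", call. = FALSE)
  if (!(a <= r_well && r_well < r_barrier && r_barrier < r_max))
    stop("require a <= r_well < r_barrier < r_max", call. = FALSE)
  w <- (r_barrier - r_well) / 8
  r <- sort(unique(c(seq(a, r_max, length.out = n_points), r_well, r_barrier)))
  G <- dG0 * exp(-(r - r_well)^2 / (2 * w^2)) +
       Ea  * exp(-(r - r_barrier)^2 / (2 * w^2))
  # tails are below machine noise at r_max for any sane geometry; snap to the
  # separated-state reference exactly
  G[length(G)] <- 0
  free_energy_profile(r = r, G = G, T_K = T_K, a = a)
}

#' Extract thermodynamic scalars from a free-energy profile
#'
#' Reads the well depth and the barrier height off the grid: `dG0` is the
#' minimum of `G`; `Ea` is the maximum of `G` at separations beyond the well
#' (both relative to the separated-state zero).  A profile with no interior
#' minimum is flagged unbound (`dG0 = 0`).  No interpolation beyond the grid
#' is performed.
#'
#' @param p A [free_energy_profile].
#' @param T_K Temperature for the returned state, K; defaults to the
#'   profile's own temperature.
#' @param eps_r Solvent dielectric constant; defaults to
#'   [water_dielectric]`(T_K)`.
#' @return A list of class `thermo_state`: `T_K`, `dG0` (kJ/mol), `Ea`
#'   (kJ/mol), `eps_r`, `bound` (logical).
#' @export
#' @examples
#' extract_thermo(build_profile(-43.84, 76.32))
extract_thermo <- function(p, T_K = p$T_K, eps_r = water_dielectric(T_K)) {
  stopifnot(inherits(p, "free_energy_profile"))
  i_min <- which.min(p$G)
  interior_min <- i_min > 1 && i_min < length(p$G) && p$G[i_min] < 0
  if (interior_min) {
    dG0 <- p$G[i_min]
    Ea  <- max(0, max(p$G[i_min:length(p$G)]))
  } else {
    dG0 <- 0
    Ea  <- if (i_min == length(p$G)) 0 else max(0, max(p$G))
  }
  structure(list(T_K = T_K, dG0 = dG0, Ea = Ea, eps_r = eps_r,
                 bound = interior_min),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %.6g K: dG0 = %.4f kJ/mol, Ea = %.4f kJ/mol, eps_r = %.4g%s\n",
              x$T_K, x$dG0, x$Ea, x$eps_r,
              if (x$bound) "" else " (unbound)"))
  invisible(x)
}

#' Read a free-energy profile from a two-column text file
#'
#' Whitespace- or tab-separated text with separation (Angstrom) in the first
#' column and free energy (kJ/mol) in the second; lines starting with `#`
#' are comments.  The grid is validated as strictly increasing.
#'
#' @param path File path.
#' @param T_K Temperature tag, K.
#' @param a Minimum binding distance, Angstrom; defaults to the smallest
#'   tabulated separation.
#' @return A [free_energy_profile].
#' @export
#' @examples
#' f <- system.file("extdata", "profile_pb_probe_298K_synthetic.tsv",
#'                  package = "pulsefet")
#' extract_thermo(read_profile(f))
read_profile <- function(path, T_K = 298, a = NULL) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("r", "G"),
                           colClasses = "numeric")
  if (is.null(a)) a <- min(tab$r)
  free_energy_profile(r = tab$r, G = tab$G, T_K = T_K, a = a)
}

#' Write a free-energy profile to a two-column text file
#'
#' @param p A [free_energy_profile].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "free_energy_profile"))
  header <- sprintf("# free-energy profile: T = %g K, a = %g A\n# r_A  G_kJ_per_mol",
                    p$T_K, p$a)
  writeLines(c(header, sprintf("%.10g\t%.10g", p$r, p$G)), path)
  invisible(path)
}
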