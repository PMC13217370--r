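# Electric-double-layer and transistor transduction: Gouy-Chapman-Stern
# capacitances, Debye screening, the Grahame charge-potential relation, the
# capacitive gate-voltage shift from bound charge, the small-signal drain
# current, and the ionic-strength (salt) response factor.

#' Electric-double-layer interface parameters
#'
#' @param eps_r_stern Stern-layer relative permittivity (water is strongly
#'   ordered in the compact layer; the common textbook value ~6 is the
#'   default).
#' @param l_stern Stern-layer thickness, m (default 0.5 nm, about one
#'   hydrated-ion diameter).
#' @param eps_r_diff Diffuse-layer relative permittivity (bulk water at the
#'   operating temperature by default).
#' @param area Electrode area, m^2 (default a 450 um x 450 um pad).
#' @param c0 Bulk electrolyte concentration as 1:1-equivalent ionic
#'   strength, M.
#' @param T_K Temperature, K.
#' @return Object of class `edl_params`.
#' @export
#' @examples
#' edl_params(c0 = pbs_ionic_strength(0.02))
edl_params <- function(eps_r_stern = 6, l_stern = 5e-10,
                       eps_r_diff = 78.36, area = 4.5e-4^2,
                       c0 = 3.254e-3, T_K = 298) {
  .stopifnot_finite(eps_r_stern, l_stern, eps_r_diff, area, c0, T_K)
  if (min(eps_r_stern, l_stern, eps_r_diff, area, c0, T_K) <= 0)
    stop("all EDL parameters must be positive", call. = FALSE)
  structure(list(eps_r_stern = eps_r_stern, l_stern = l_stern,
                 eps_r_diff = eps_r_diff, area = area, c0 = c0, T_K = T_K),
            class = "edl_params")
}

#' Transistor device parameters
#'
#' @param gm Transconductance at the operating point, S (default the
#'   128.3 mS maximum near Vg = 3 V at Vd = 3.5 V).
#' @param Vg Applied gate bias, V.
#' @param Vd Drain bias, V.
#' @param Id_baseline Baseline drain current, A.
#' @return Object of class `device_params`.
#' @export
device_params <- function(gm = 0.1283, Vg = 3, Vd = 3.5, Id_baseline = 0) {
  .stopifnot_finite(gm, Vg, Vd, Id_baseline)
  if (gm <= 0) stop("transconductance gm must be positive", call. = FALSE)
  structure(list(gm = gm, Vg = Vg, Vd = Vd, Id_baseline = Id_baseline),
            class = "device_params")
}

#' PBS dilution to 1:1-equivalent ionic strength
#'
#' Maps an nX phosphate-buffered-saline dilution to ionic strength, taking
#' 1X PBS as 162.7 mM 1:1-equivalent and scaling linearly with the dilution
#' factor.
#'
#' @param dilution PBS strength as a fraction of 1X (e.g. 0.02 for 0.02X).
#' @param full_strength Ionic strength of 1X PBS, M.
#' @return Ionic strength, M.
#' @export
#' @examples
#' pbs_ionic_strength(0.02)
pbs_ionic_strength <- function(dilution, full_strength = 0.1627) {
  .stopifnot_finite(dilution, full_strength)
  if (any(dilution <= 0)) stop("dilution must be positive", call. = FALSE)
  dilution * full_strength
}

#' Debye screening length
#'
#' `lambda_D = sqrt(eps0 eps_r kB T / (2 NA e^2 c0 * 1e3))` for a
#' 1:1-equivalent ionic strength `c0` in mol/L.
#'
#' @param c0 Ionic strength, M.
#' @param eps_r Relative permittivity of the solution.
#' @param T_K Temperature, K.
#' @return Debye length, m.
#' @export
#' @examples
#' debye_length(0.150, 78.36, 298)  # ~0.78 nm
debye_length <- function(c0, eps_r = 78.36, T_K = 298) {
  .stopifnot_finite(c0, eps_r, T_K)
  if (any(c0 <= 0)) stop("ionic strength must be positive", call. = FALSE)
  k <- .const
  sqrt(k$eps0 * eps_r * k$kB * T_K /
         (2 * .molar_to_number_density(c0) * k$e^2))
}

#' Stern-layer capacitance
#'
#' `C_St = eps0 eps_r,st A / l_st`.
#'
#' @param p An [edl_params].
#' @return Capacitance, F.
#' @export
stern_capacitance <- function(p) {
  stopifnot(inherits(p, "edl_params"))
  .const$eps0 * p$eps_r_stern * p$area / p$l_stern
}

#' Diffuse-layer capacitance
#'
#' `C_diff = eps0 eps_r A / l_diff` with the diffuse-layer thickness taken
#' as the Debye screening length at the bulk ionic strength.
#'
#' @param p An [edl_params].
#' @return Capacitance, F.
#' @export
diffuse_capacitance <- function(p) {
  stopifnot(inherits(p, "edl_params"))
  .const$eps0 * p$eps_r_diff * p$area /
    debye_length(p$c0, p$eps_r_diff, p$T_K)
}

#' Total electric-double-layer capacitance
#'
#' Series combination `1/C_EDL = 1/C_St + 1/C_diff`.
#'
#' @param p An [edl_params].
#' @return Capacitance, F.
#' @export
#' @examples
#' edl_capacitance(edl_params())
edl_capacitance <- function(p) {
  cs <- stern_capacitance(p)
  cd <- diffuse_capacitance(p)
  cs * cd / (cs + cd)
}

#' Grahame charge-potential relation
#'
#' Surface charge density balancing the diffuse-layer charge at a given
#' Stern-plane potential in a symmetric 1:1 electrolyte:
#' `sigma = sqrt(8 c0 NA 1e3 eps eps0 kB T) * sinh(e phi / (2 kB T))`.
#' The relation is odd and strictly increasing in the potential and reduces
#' to the linear Debye capacitor `eps eps0 phi / lambda_D` for small
#' potentials.
#'
#' The `"linearized"` form returns that small-potential limit explicitly.
#' The `"literal"` form evaluates the bare prefactor `8 eps eps0 kB T`
#' without the bulk-concentration factor or the square root; it is
#' dimensionally inconsistent and provided only to compare against the
#' standard form.
#'
#' @param phi_stern Stern-plane potential, V (vectorized).
#' @param c0 Bulk ionic strength, M.
#' @param eps_r Relative permittivity of the solution.
#' @param T_K Temperature, K.
#' @param form `"standard"` (default), `"linearized"`, or `"literal"`.
#' @return Charge density, C/m^2 (`"literal"`: arbitrary units).
#' @export
#' @examples
#' grahame_charge(0.025, c0 = 0.01)
grahame_charge <- function(phi_stern, c0, eps_r = 78.36, T_K = 298,
                           form = c("standard", "linearized", "literal")) {
  form <- match.arg(form)
  .stopifnot_finite(phi_stern)
  if (any(c0 <= 0)) stop("ionic strength must be positive", call. = FALSE)
  k <- .const
  if (form == "linearized")
    return(k$eps0 * eps_r * phi_stern / debye_length(c0, eps_r, T_K))
  if (form == "literal")
    return(8 * eps_r * k$eps0 * k$kB * T_K *
             sinh(k$e * phi_stern / (2 * k$kB * T_K)))
  pref <- sqrt(8 * .molar_to_number_density(c0) * k$eps0 * eps_r * k$kB * T_K)
  pref * sinh(k$e * phi_stern / (2 * k$kB * T_K))
}

#' Gate-voltage shift from a change in bound interfacial charge
#'
#' Capacitive division of added interfacial charge:
#' `delta_Vg = delta_sigma * A / C_EDL`.
#'
#' @param delta_sigma Change in bound charge density, C/m^2 (vectorized).
#' @param p An [edl_params].
#' @return Gate-voltage shift, V.
#' @export
gate_shift_from_binding <- function(delta_sigma, p) {
  .stopifnot_finite(delta_sigma)
  C <- edl_capacitance(p)
  if (C <= 0) stop("EDL capacitance must be positive", call. = FALSE)
  delta_sigma * p$area / C
}

#' Small-signal drain-current response
#'
#' `delta_Id = gm * delta_Vg` at the device operating point.
#'
#' @param delta_Vg Gate-voltage shift, V (vectorized).
#' @param d A [device_params].
#' @return Drain-current change, A.
#' @export
#' @examples
#' current_response(1e-3, device_params(gm = 0.1283))  # 0.1283 mA
current_response <- function(delta_Vg, d) {
  stopifnot(inherits(d, "device_params"))
  .stopifnot_finite(delta_Vg)
  d$gm * delta_Vg
}

#' Salt-dependent response factor
#'
#' Dimensionless multiplier on the binding-derived signal as a function of
#' ionic strength, the product of two effects:
#'
#' * screening: the capacitive-division factor `C_St / C_EDL(c0)`
#'   (the gate shift per unit bound charge, normalized to its
#'   high-salt Stern-only limit), which falls as `c0` rises because the
#'   diffuse layer compresses;
#' * hydration: a phenomenological logistic roll-off in `log10(c0)` below
#'   `hydration_scale` representing the loss of direct ion-ligand
#'   coordination when thick hydration shells form at low ionic strength.
#'
#' The product is unimodal in `c0`: the signal is attenuated both at high
#' salt (ion screening) and at very low salt (hydration), with an interior
#' optimum at moderate ionic strength.
#'
#' @param c0 Ionic strength, M (vectorized).
#' @param hydration_scale Midpoint of the hydration roll-off, M.  The
#'   default 3e-4 M (about 0.002X PBS) places the net optimum at moderate
#'   ionic strength, around a 0.01X PBS assay buffer.
#' @param p An [edl_params] supplying the Stern-layer constants; its own
#'   `c0` field is overridden by the `c0` argument.
#' @param hydration_width Width of the roll-off in decades of `c0`.
#' @return Dimensionless response factor.
#' @export
#' @examples
#' salt_response_factor(pbs_ionic_strength(c(0.1, 0.01, 1e-4)))
salt_response_factor <- function(c0, hydration_scale = 3e-4,
                                 p = edl_params(), hydration_width = 0.4) {
  .stopifnot_finite(c0)
  if (any(c0 <= 0)) stop("ionic strength must be positive", call. = FALSE)
  screening <- vapply(c0, function(ci) {
    pi_ <- p; pi_$c0 <- ci
    stern_capacitance(pi_) / edl_capacitance(pi_)
  }, numeric(1))
  hydration <- if (hydration_scale <= 0) rep(1, length(c0)) else
    stats::plogis((log10(c0) - log10(hydration_scale)) / hydration_width)
  screening * hydration
}
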