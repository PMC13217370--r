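# Rate constants from free-energy profiles and thermodynamic scalars:
# diffusion-limited association over a potential of mean force, Arrhenius
# rates, detailed-balance reverse rates, and the rate-ratio ordering that
# rationalizes the pulsed-temperature protocol.

#' Temperature-stamped rate set
#'
#' Bundles a forward (association) rate constant, a reverse (dissociation)
#' rate constant and the dissociation constant at one temperature, enforcing
#' detailed balance `Kd = kr / kf`.
#'
#' @param T_K Temperature, K.
#' @param kf Forward rate constant, M^-1 s^-1, > 0.
#' @param kr Reverse rate constant, s^-1, >= 0.
#' @param Kd Dissociation constant, M; defaults to `kr / kf` and must agree
#'   with it to 1e-9 relative if supplied.
#' @return Object of class `rate_set`.
#' @export
#' @examples
#' rate_set(298, kf = 5.33e4, kr = 1.1e-3)
rate_set <- function(T_K, kf, kr, Kd = kr / kf) {
  .stopifnot_finite(T_K, kf, kr, Kd)
  if (T_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (kf <= 0) stop("forward rate kf must be > 0", call. = FALSE)
  if (kr < 0 || Kd < 0) stop("kr and Kd must be >= 0", call. = FALSE)
  if (abs(Kd - kr / kf) > 1e-9 * max(Kd, kr / kf, .Machine$double.xmin))
    stop("detailed balance violated: Kd must equal kr/kf", call. = FALSE)
  structure(list(T_K = T_K, kf = kf, kr = kr, Kd = Kd), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> T = %.6g K: kf = %.4g /M/s, kr = %.4g /s, Kd = %.4g M\n",
              x$T_K, x$kf, x$kr, x$Kd))
  invisible(x)
}

# integrate exp(G(r)/RT)/r^2 piecewise between knots so kinks and steps in
# G(r) never cross a quadrature panel
.pmf_integral <- function(Gfun, a, r_max, T_K, breaks = NULL,
                          rel_tol = 1e-10) {
  RT <- .const$R * T_K / 1e3   # kJ/mol
  integrand <- function(r) exp(Gfun(r) / RT) / r^2
  knots <- sort(unique(c(a, r_max, breaks[breaks > a & breaks < r_max])))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    piece <- stats::integrate(integrand, knots[i], knots[i + 1L],
                              rel.tol = rel_tol, abs.tol = 0,
                              subdivisions = 500L)
    if (!is.finite(piece$value))
      stop("divergent Smoluchowski integrand", call. = FALSE)
    total <- total + piece$value
  }
  total
}

#' Diffusion-limited association rate over a free-energy profile
#'
#' Evaluates `kf = 4 pi D N_A / integral_a^inf exp(G(r)/RT) / r^2 dr`, the
#' diffusion-controlled association rate for two partners with combined
#' diffusion coefficient `D` approaching along a potential of mean force
#' `G(r)`.  The integral runs from the minimum binding distance `a` to the
#' end of the tabulated grid; beyond the grid `G = 0` and the remaining tail
#' `integral r^-2 dr = 1/r_max` is added analytically.  Evaluated in SI and
#' converted to M^-1 s^-1 in one place.
#'
#' For a flat profile this collapses to the classic Smoluchowski limit
#' `4 pi D N_A a`.
#'
#' @param p A [free_energy_profile], or a function `G(r)` (Angstrom ->
#'   kJ/mol); a function is taken as exact between `a` and `r_max`.
#' @param D Sum of the diffusion coefficients of the partners, m^2/s.
#' @param a Minimum binding distance, Angstrom; defaults to the profile's.
#' @param T_K Temperature, K; defaults to the profile's.
#' @param r_max End of the profiled region, Angstrom (required when `p` is a
#'   function).
#' @param breaks Optional interior break points (Angstrom) where `G` is
#'   non-smooth; profile grids supply their own knots automatically.
#' @param rel_tol Quadrature relative tolerance per panel.
#' @return Forward rate constant, M^-1 s^-1.
#' @export
#' @examples
#' flat <- free_energy_profile(r = seq(10, 40, length.out = 5),
#'                             G = rep(0, 5), a = 10)
#' smoluchowski_rate(flat, D = 1e-9)  # ~ 4 pi D NA a
smoluchowski_rate <- function(p, D, a = NULL, T_K = NULL, r_max = NULL,
                              breaks = NULL, rel_tol = 1e-10) {
  .stopifnot_finite(D)
  if (D <= 0) stop("diffusion coefficient must be positive", call. = FALSE)
  if (inherits(p, "free_energy_profile")) {
    if (is.null(a)) a <- p$a
    if (is.null(T_K)) T_K <- p$T_K
    r_max <- p$r[length(p$r)]
    if (a < p$r[1] || a >= r_max)
      stop("minimum binding distance a lies outside the profile grid",
           call. = FALSE)
    Gfun <- stats::approxfun(p$r, p$G, rule = 2)
    breaks <- unique(c(breaks, p$r))
  } else if (is.function(p)) {
    if (is.null(a) || is.null(T_K) || is.null(r_max))
      stop("a, T_K and r_max are required when G is given as a function",
           call. = FALSE)
    Gfun <- p
  } else stop("p must be a free_energy_profile or a function", call. = FALSE)
  I_ang <- .pmf_integral(Gfun, a, r_max, T_K, breaks, rel_tol) +
           1 / r_max                       # analytic G = 0 tail
  I_si <- I_ang / .ang_to_m(1)             # A^-1 -> m^-1
  .si_rate_to_molar(4 * pi * D * .const$N_A / I_si)
}

#' Arrhenius rate constant
#'
#' `k = A exp(-Ea / (R T))`: a rate constant from a pre-exponential factor
#' and an activation barrier.
#'
#' @param A Pre-exponential factor, same units as the returned rate.
#' @param Ea Activation energy, kJ/mol.
#' @param T_K Temperature, K (vectorized).
#' @return Rate constant(s), same units as `A`.
#' @export
#' @examples
#' arrhenius_rate(1e10, 76.32, 298)
arrhenius_rate <- function(A, Ea, T_K) {
  .stopifnot_finite(A, Ea, T_K)
  if (any(T_K <= 0)) stop("temperature must be positive", call. = FALSE)
  A * exp(-.kj_to_j(Ea) / (.const$R * T_K))
}

#' Dissociation constant from the binding free energy
#'
#' `Kd = exp(+dG0 / (R T))` against the 1 M standard state, where `dG0` is
#' the (negative, for spontaneous binding) standard free-energy change of
#' the association direction.  The sign convention is fixed by detailed
#' balance: `Kd = kr / kf` must be small for a strongly bound complex.
#'
#' @param dG0 Standard binding free energy, kJ/mol.
#' @param T_K Temperature, K.
#' @return Dissociation constant, M.
#' @export
#' @examples
#' dissociation_constant(-43.84, 298)  # ~2.07e-8 M
dissociation_constant <- function(dG0, T_K) {
  .stopifnot_finite(dG0, T_K)
  if (any(T_K <= 0)) stop("temperature must be positive", call. = FALSE)
  exp(.kj_to_j(dG0) / (.const$R * T_K))
}

#' Reverse (dissociation) rate constant via detailed balance
#'
#' `kr = kf * Kd(dG0, T)`: the dissociation rate implied by a forward rate
#' and the standard binding free energy.
#'
#' @param kf Forward rate constant, M^-1 s^-1, > 0.
#' @param dG0 Standard binding free energy, kJ/mol.
#' @param T_K Temperature, K.
#' @return Reverse rate constant, s^-1.
#' @export
#' @examples
#' reverse_rate(5.33e4, -43.84, 298)   # ~1.1e-3 /s
#' reverse_rate(1.22e5, -35.65, 333)   # ~3e-1 /s
reverse_rate <- function(kf, dG0, T_K) {
  .stopifnot_finite(kf)
  if (any(kf <= 0)) stop("forward rate kf must be > 0", call. = FALSE)
  kf * dissociation_constant(dG0, T_K)
}

#' Rate-ratio ordering across the pulsed protocol
#'
#' For rate sets at room temperature (`rt`) and at the hot spike
#' temperature (`hot`), computes the three forward/reverse ratios that rank
#' the operating modes: pulsed operation (hot forward rate against the
#' room-temperature reverse rate, `hot$kf / rt$kr`), isothermal room
#' temperature (`rt$kf / rt$kr`), and sustained heating
#' (`hot$kf / hot$kr`), and reports whether the strict ordering
#' pulsed > isothermal > sustained-hot holds.
#'
#' @param rt [rate_set] at the base (room) temperature.
#' @param hot [rate_set] at the spike temperature.
#' @return List with `ratios` (named numeric: `pulsed`, `isothermal_rt`,
#'   `sustained_hot`) and `ordered` (logical).
#' @export
#' @examples
#' rt  <- rate_set(298, 5.33e4, 1.1e-3)
#' hot <- rate_set(333, 1.22e5, 3e-1)
#' rate_ratio_ordering(rt, hot)
rate_ratio_ordering <- function(rt, hot) {
  stopifnot(inherits(rt, "rate_set"), inherits(hot, "rate_set"))
  if (rt$kr == 0 || hot$kr == 0)
    stop("reverse rates must be non-zero to form ratios", call. = FALSE)
  ratios <- c(pulsed        = hot$kf / rt$kr,
              isothermal_rt = rt$kf / rt$kr,
              sustained_hot = hot$kf / hot$kr)
  list(ratios = ratios,
       ordered = ratios[["pulsed"]] > ratios[["isothermal_rt"]] &&
                 ratios[["isothermal_rt"]] > ratios[["sustained_hot"]])
}

#' Effective-Arrhenius interpolation between two rate anchors
#'
#' Fits `A` and `Ea` of an Arrhenius law through two (rate, temperature)
#' anchor points; used to interpolate both the forward and the reverse rate
#' between the two temperatures at which they are known.
#'
#' @param k1,T1 Rate and temperature of the first anchor.
#' @param k2,T2 Rate and temperature of the second anchor.
#' @return List with `A` (units of `k`) and `Ea` (kJ/mol); `Ea` may be
#'   negative if the rate decreases with temperature.
#' @export
arrhenius_fit <- function(k1, T1, k2, T2) {
  .stopifnot_finite(k1, T1, k2, T2)
  if (min(k1, k2) <= 0 || min(T1, T2) <= 0 || T1 == T2)
    stop("anchors must have positive rates and distinct positive temperatures",
         call. = FALSE)
  Ea_j <- .const$R * log(k1 / k2) / (1 / T2 - 1 / T1)
  list(A = k1 * exp(Ea_j / (.const$R * T1)), Ea = Ea_j / 1e3)
}

#' Temperature-dependent rate interpolator from two anchor rate sets
#'
#' Builds a function `T -> rate_set` by effective-Arrhenius interpolation of
#' `kf` and `kr` between two anchors (typically room temperature and the hot
#' spike temperature).  Temperatures outside the anchor interval are clamped
#' to it with a warning: the anchors are the only measured constraints, and
#' hot extrapolation is not modelled.
#'
#' @param rt [rate_set] at the lower anchor temperature.
#' @param hot [rate_set] at the upper anchor temperature.
#' @param clamp Clamp temperatures to the anchor interval (default TRUE).
#' @return Function of `T_K` returning a [rate_set].
#' @export
#' @examples
#' fn <- rate_interpolator(rate_set(298, 5.33e4, 1.1e-3),
#'                         rate_set(333, 1.22e5, 3e-1))
#' fn(315)
rate_interpolator <- function(rt, hot, clamp = TRUE) {
  stopifnot(inherits(rt, "rate_set"), inherits(hot, "rate_set"))
  if (rt$T_K >= hot$T_K) stop("anchors must satisfy rt$T_K < hot$T_K",
                              call. = FALSE)
  if (rt$kr <= 0 || hot$kr <= 0)
    stop("anchor reverse rates must be positive for interpolation",
         call. = FALSE)
  fit_f <- arrhenius_fit(rt$kf, rt$T_K, hot$kf, hot$T_K)
  fit_r <- arrhenius_fit(rt$kr, rt$T_K, hot$kr, hot$T_K)
  lo <- rt$T_K; hi <- hot$T_K
  warned <- FALSE
  function(T_K) {
    if (clamp && (T_K < lo || T_K > hi)) {
      if (!warned) {
        warning(sprintf("temperature %.4g K outside anchor range [%g, %g]; clamped",
                        T_K, lo, hi), call. = FALSE)
        warned <<- TRUE
      }
      T_K <- min(max(T_K, lo), hi)
    }
    kf <- arrhenius_rate(fit_f$A, fit_f$Ea, T_K)
    kr <- arrhenius_rate(fit_r$A, fit_r$Ea, T_K)
    rate_set(T_K, kf, kr)
  }
}

#' Tabulate interpolated rates over temperatures
#'
#' @param rates_fn Function `T_K -> rate_set`, e.g. from
#'   [rate_interpolator].
#' @param T_K Numeric vector of temperatures, K.
#' @return data.frame with columns `T_K`, `kf`, `kr`, `Kd`.
#' @export
rate_table <- function(rates_fn, T_K) {
  rows <- lapply(T_K, function(Ti) {
    rs <- rates_fn(Ti)
    data.frame(T_K = rs$T_K, kf = rs$kf, kr = rs$kr, Kd = rs$Kd)
  })
  do.call(rbind, rows)
}
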