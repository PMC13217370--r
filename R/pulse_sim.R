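# Two-state probe-ion complexation under arbitrary temperature protocols:
# protocol construction (isothermal / hot-sample injection), deterministic
# ODE integration of site occupancy, and protocol comparison.

#' Piecewise temperature protocol
#'
#' A protocol is an ordered list of contiguous segments, each either
#' constant temperature or an exponential relaxation toward a base
#' temperature.  Segments are supplied as a data.frame with columns
#' `t0`, `t1` (s), `type` (`"constant"` or `"relax"`), `T0` (segment
#' temperature, or the starting temperature of a relaxation, K), and for
#' relaxation segments `T_base` (K) and `tau` (s).
#'
#' @param segments data.frame as described above.
#' @return Object of class `temperature_protocol`.
#' @export
#' @examples
#' isothermal_protocol(294, 600)
temperature_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("t0", "t1", "type", "T0") %in% names(segments)))
  if (!all(segments$type %in% c("constant", "relax")))
    stop("segment type must be 'constant' or 'relax'", call. = FALSE)
  if (any(segments$t1 <= segments$t0))
    stop("segment times must be increasing", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(abs(segments$t0[-1] - segments$t1[-nrow(segments)]) > 1e-12))
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  Ts <- c(segments$T0, segments$T_base[segments$type == "relax"])
  if (any(!is.finite(Ts)) || any(Ts <= 273) || any(Ts >= 380))
    stop("temperatures must lie in (273, 380) K", call. = FALSE)
  structure(list(segments = segments), class = "temperature_protocol")
}

#' Constant-temperature protocol
#'
#' @param T_K Temperature, K.
#' @param duration Protocol length, s.
#' @param t0 Start time, s.
#' @return A [temperature_protocol].
#' @export
isothermal_protocol <- function(T_K, duration, t0 = 0) {
  temperature_protocol(data.frame(t0 = t0, t1 = t0 + duration,
                                  type = "constant", T0 = T_K,
                                  T_base = NA_real_, tau = NA_real_))
}

#' Protocol for a hot-sample injection spike
#'
#' Injecting a fraction `injected_fraction` of preheated sample into the
#' chamber raises the temperature instantaneously to the enthalpy-mixing
#' value `T_mix = (1 - f) T_base + f T_sample` (ideal dilute solutions of
#' equal heat capacity), after which the chamber relaxes exponentially back
#' to `T_base` with time constant `relax_tau`.
#'
#' @param T_base Chamber base temperature, K.
#' @param T_sample Temperature of the injected sample, K.
#' @param injected_fraction Volume fraction injected, in (0, 1).
#' @param relax_tau Thermal relaxation time constant, s.  Default 15 s lets
#'   the spike decay within about a minute.
#' @param duration Protocol length, s.
#' @param t0 Start time, s.
#' @return A [temperature_protocol] with one relaxation segment.
#' @export
#' @examples
#' # 10 % of a 60 C sample into a 21 C chamber: ~4 K spike
#' protocol_from_injection(294, 333, 0.10, relax_tau = 15, duration = 300)
protocol_from_injection <- function(T_base, T_sample, injected_fraction,
                                    relax_tau = 15, duration = 300, t0 = 0) {
  .stopifnot_finite(T_base, T_sample, injected_fraction, relax_tau, duration)
  if (injected_fraction <= 0 || injected_fraction >= 1)
    stop("injected_fraction must lie in (0, 1)", call. = FALSE)
  if (relax_tau <= 0) stop("relax_tau must be positive", call. = FALSE)
  T_mix <- (1 - injected_fraction) * T_base + injected_fraction * T_sample
  temperature_protocol(data.frame(t0 = t0, t1 = t0 + duration,
                                  type = "relax", T0 = T_mix,
                                  T_base = T_base, tau = relax_tau))
}

#' Evaluate a protocol's temperature at given times
#'
#' @param protocol A [temperature_protocol].
#' @param t Numeric vector of times, s; times outside the protocol are
#'   clamped to its ends.
#' @return Temperatures, K.
#' @export
protocol_temperature <- function(protocol, t) {
  stopifnot(inherits(protocol, "temperature_protocol"))
  seg <- protocol$segments
  t <- pmin(pmax(t, seg$t0[1]), seg$t1[nrow(seg)])
  idx <- findInterval(t, seg$t0, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  relax <- seg$type[idx] == "relax"
  out <- seg$T0[idx]
  if (any(relax)) {
    i <- idx[relax]
    out[relax] <- seg$T_base[i] + (seg$T0[i] - seg$T_base[i]) *
      exp(-(t[relax] - seg$t0[i]) / seg$tau[i])
  }
  out
}

#' Protocol time span
#' @param protocol A [temperature_protocol].
#' @return Numeric length-2 vector `c(t0, t1)` in seconds.
#' @export
protocol_span <- function(protocol) {
  seg <- protocol$segments
  c(seg$t0[1], seg$t1[nrow(seg)])
}

#' Simulate two-state binding under a temperature protocol
#'
#' Integrates the site-occupancy kinetics
#' `d theta / dt = kf(T(t)) C_free (1 - theta) - kr(T(t)) theta` with free
#' ion concentration `C_free = C0 - site_density * theta` (well-mixed mass
#' balance), using adaptive integration (lsoda) at relative tolerance 1e-10.
#'
#' @param protocol A [temperature_protocol].
#' @param rates_fn Function `T_K -> rate_set`, e.g. [rate_interpolator].
#' @param C0 Total ion concentration, M.
#' @param site_density Total probe site concentration, M.  The trace-site
#'   default keeps `C_free` essentially equal to `C0`.
#' @param theta0 Initial occupancy in `[0, 1]`.
#' @param n_out Number of output time points.
#' @return Object of class `binding_trajectory`: data.frame with columns
#'   `t`, `T_K`, `theta`, `C_free`.
#' @export
#' @examples
#' fn <- rate_interpolator(rate_set(298, 5.33e4, 1.1e-3),
#'                         rate_set(333, 1.22e5, 3e-1))
#' simulate_binding(isothermal_protocol(298, 600), fn, C0 = 1e-8)
simulate_binding <- function(protocol, rates_fn, C0,
                             site_density = 1e-12, theta0 = 0,
                             n_out = 201) {
  stopifnot(inherits(protocol, "temperature_protocol"))
  .stopifnot_finite(C0, site_density, theta0)
  if (C0 < 0 || site_density < 0) stop("concentrations must be >= 0",
                                       call. = FALSE)
  if (theta0 < 0 || theta0 > 1) stop("theta0 must lie in [0, 1]",
                                     call. = FALSE)
  if (site_density * theta0 > C0 + 1e-30)
    stop("initially bound ions exceed the total ion concentration",
         call. = FALSE)
  span <- protocol_span(protocol)
  times <- sort(unique(c(seq(span[1], span[2], length.out = n_out),
                         protocol$segments$t0, protocol$segments$t1)))
  # pre-tabulate the rate laws on a fine temperature grid so the ODE
  # right-hand side stays cheap and smooth
  seg <- protocol$segments
  T_range <- range(c(seg$T0, seg$T_base), na.rm = TRUE)
  if (diff(T_range) < 1e-9) {
    rs <- rates_fn(T_range[1])
    kf_of_T <- function(T_K) rs$kf
    kr_of_T <- function(T_K) rs$kr
  } else {
    T_grid <- seq(T_range[1], T_range[2], length.out = 200)
    tab <- rate_table(rates_fn, T_grid)
    kf_of_T <- stats::approxfun(tab$T_K, tab$kf, rule = 2)
    kr_of_T <- stats::approxfun(tab$T_K, tab$kr, rule = 2)
  }
  rhs <- function(t, y, parms) {
    T_now <- protocol_temperature(protocol, t)
    theta <- min(max(y[1], 0), 1)
    C_free <- max(C0 - site_density * theta, 0)
    list(kf_of_T(T_now) * C_free * (1 - theta) - kr_of_T(T_now) * theta)
  }
  sol <- deSolve::ode(y = c(theta = theta0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  theta <- pmin(pmax(sol[, "theta"], 0), 1)
  out <- data.frame(t = sol[, "time"],
                    T_K = protocol_temperature(protocol, sol[, "time"]),
                    theta = theta,
                    C_free = C0 - site_density * theta)
  class(out) <- c("binding_trajectory", "data.frame")
  out
}

#' Compare final occupancy across temperature protocols
#'
#' Runs [simulate_binding] for each protocol over a shared time horizon and
#' summarizes: final occupancy, peak occupancy, and the time at which the
#' trajectory first reaches 90 % of its final value.
#'
#' @param protocols Named list of [temperature_protocol] objects sharing the
#'   same time span.
#' @param rates_fn,C0,site_density,theta0,n_out Passed to
#'   [simulate_binding].
#' @return data.frame with one row per protocol: `protocol`, `final_theta`,
#'   `peak_theta`, `t90`.
#' @export
compare_protocols <- function(protocols, rates_fn, C0,
                              site_density = 1e-12, theta0 = 0,
                              n_out = 201) {
  stopifnot(is.list(protocols), length(protocols) >= 1)
  spans <- vapply(protocols, protocol_span, numeric(2))
  if (max(abs(spans[1, ] - spans[1, 1])) > 1e-9 ||
      max(abs(spans[2, ] - spans[2, 1])) > 1e-9)
    stop("protocols must share the same time horizon", call. = FALSE)
  nms <- names(protocols)
  if (is.null(nms)) nms <- paste0("protocol_", seq_along(protocols))
  rows <- lapply(seq_along(protocols), function(i) {
    tr <- simulate_binding(protocols[[i]], rates_fn, C0,
                           site_density, theta0, n_out)
    final <- tr$theta[nrow(tr)]
    t90 <- tr$t[which(tr$theta >= 0.9 * final)[1]]
    data.frame(protocol = nms[i], final_theta = final,
               peak_theta = max(tr$theta), t90 = t90)
  })
  do.call(rbind, rows)
}

#' Equilibrium (Langmuir) occupancy at constant temperature
#'
#' In the trace-site limit the stationary point of the binding ODE is the
#' Langmuir isotherm `theta_eq = C0 / (C0 + Kd)`.
#'
#' @param C0 Free ion concentration, M (vectorized).
#' @param rates A [rate_set] (its `Kd` is used) or a numeric `Kd` in M.
#' @return Equilibrium occupancy in `[0, 1]`.
#' @export
#' @examples
#' langmuir_occupancy(1e-8, rate_set(298, 5.33e4, 1.1e-3))
langmuir_occupancy <- function(C0, rates) {
  Kd <- if (inherits(rates, "rate_set")) rates$Kd else rates
  .stopifnot_finite(C0, Kd)
  if (any(C0 < 0) || Kd < 0) stop("C0 and Kd must be >= 0", call. = FALSE)
  C0 / (C0 + Kd)
}
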