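# Seeded synthetic sensing runs with the statistical structure the analysis
# assumes: stepwise current increases at timed analyte additions, baseline
# drift, injection artifacts, and Gaussian noise whose variance grows with
# solution temperature.

#' Noise model for synthetic traces
#'
#' @param sigma_ref Baseline current-noise standard deviation at `T_ref`,
#'   mA.
#' @param T_ref Reference temperature for the noise scale, K.
#' @param temp_exponent Exponent of the temperature scaling of the noise SD
#'   (`sd = sigma_ref * (T / T_ref)^temp_exponent`); the default 0.5 is the
#'   Johnson-noise square-root law.
#' @param drift_rate Linear baseline drift, mA/s.
#' @param spike_amplitude Amplitude of the brief injection artifact, mA.
#' @param spike_tau Decay time of the injection artifact, s.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_ref = 0.067, T_ref = 298, temp_exponent = 0.5,
                        drift_rate = 0, spike_amplitude = 0,
                        spike_tau = 5) {
  .stopifnot_finite(sigma_ref, T_ref, temp_exponent, drift_rate,
                    spike_amplitude, spike_tau)
  if (sigma_ref < 0) stop("sigma_ref must be >= 0", call. = FALSE)
  if (T_ref <= 0 || spike_tau <= 0)
    stop("T_ref and spike_tau must be positive", call. = FALSE)
  structure(list(sigma_ref = sigma_ref, T_ref = T_ref,
                 temp_exponent = temp_exponent, drift_rate = drift_rate,
                 spike_amplitude = spike_amplitude, spike_tau = spike_tau),
            class = "noise_model")
}

#' Sensing-run scenario
#'
#' Ground-truth description of a synthetic run: the addition schedule and
#' chamber volume, the temperature mode, the binding kinetics, and the
#' transduction constants mapping occupancy to current.
#'
#' @param additions An [addition_schedule].
#' @param initial_volume Chamber volume before the first addition, uL.
#' @param T_base Chamber base temperature, K.
#' @param mode `"pulsed"` (each addition injects a hot aliquot causing a
#'   temperature spike) or `"isothermal"` (chamber stays at `T_base`).
#' @param relax_tau Thermal relaxation time after an injection, s.
#' @param rates_fn Function `T_K -> rate_set`; defaults to the
#'   [rate_interpolator] through the printed room-temperature and 60 C rate
#'   anchors.
#' @param site_density Probe site concentration, M (trace level by
#'   default).
#' @param sigma_site Interfacial charge density at full occupancy, C/m^2.
#' @param edl An [edl_params].
#' @param device A [device_params].
#' @param t_end Run length, s; defaults to one inter-addition spacing past
#'   the last addition.
#' @param dt Sampling interval, s (default 0.1 s).
#' @return Object of class `sensing_scenario`.
#' @export
sensing_scenario <- function(additions = standard_additions(),
                             initial_volume = 50, T_base = 298,
                             mode = c("pulsed", "isothermal"),
                             relax_tau = 15,
                             rates_fn = default_rates_fn(),
                             site_density = 1e-12,
                             sigma_site = 6e-4,
                             edl = edl_params(),
                             device = device_params(),
                             t_end = NULL, dt = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(additions, "addition_schedule"))
  .stopifnot_finite(initial_volume, T_base, relax_tau, site_density,
                    sigma_site, dt)
  if (is.null(t_end)) {
    gaps <- diff(additions$time)
    t_end <- additions$time[nrow(additions)] +
      if (length(gaps)) gaps[length(gaps)] else 120
  }
  if (t_end <= additions$time[nrow(additions)])
    stop("t_end must lie beyond the last addition", call. = FALSE)
  structure(list(additions = additions, initial_volume = initial_volume,
                 T_base = T_base, mode = mode, relax_tau = relax_tau,
                 rates_fn = rates_fn, site_density = site_density,
                 sigma_site = sigma_site, edl = edl, device = device,
                 t_end = t_end, dt = dt),
            class = "sensing_scenario")
}

#' Rate interpolator through the printed rate anchors
#'
#' Convenience constructor for the effective-Arrhenius interpolation
#' through the room-temperature anchor (kf = 5.33e4 /M/s, kr = 1.1e-3 /s at
#' 298 K) and the 60 C anchor (kf = 1.22e5 /M/s, kr = 3e-1 /s at 333 K).
#'
#' @return Function `T_K -> rate_set`.
#' @export
default_rates_fn <- function() {
  rate_interpolator(rate_set(298, 5.33e4, 1.1e-3),
                    rate_set(333, 1.22e5, 3e-1))
}

# deterministic part of a run: temperature trace, occupancy, current
.deterministic_trace <- function(sc) {
  add <- sc$additions
  n_add <- nrow(add)
  conc <- dilution_series(sc$initial_volume, add)
  vols <- sc$initial_volume + cumsum(add$volume)
  t <- seq(0, sc$t_end, by = sc$dt)
  bounds <- c(add$time, sc$t_end)
  theta <- numeric(length(t))
  T_K <- rep(sc$T_base, length(t))
  th0 <- 0
  for (i in seq_len(n_add)) {
    dur <- bounds[i + 1] - bounds[i]
    prot <- if (sc$mode == "pulsed") {
      f <- add$volume[i] / vols[i]
      protocol_from_injection(sc$T_base, add$sample_temperature[i], f,
                              relax_tau = sc$relax_tau, duration = dur,
                              t0 = bounds[i])
    } else isothermal_protocol(sc$T_base, dur, t0 = bounds[i])
    n_seg <- max(31L, ceiling(dur / sc$dt) + 1L)
    tr <- simulate_binding(prot, sc$rates_fn, C0 = conc[i],
                           site_density = sc$site_density, theta0 = th0,
                           n_out = n_seg)
    sel <- t >= bounds[i] & t <= bounds[i + 1]
    theta[sel] <- stats::approx(tr$t, tr$theta, xout = t[sel], rule = 2)$y
    T_K[sel] <- protocol_temperature(prot, t[sel])
    th0 <- tr$theta[nrow(tr)]
  }
  dVg <- gate_shift_from_binding(theta * sc$sigma_site, sc$edl)
  Id_mA <- (sc$device$Id_baseline + current_response(dVg, sc$device)) * 1e3
  list(t = t, T_K = T_K, theta = theta, Id_mA = Id_mA, conc = conc)
}

#' Generate a seeded synthetic sensing run
#'
#' Produces a timestamped drain-current trace:
#' `Id(t) = baseline + gm * dVg(theta(t)) + drift * t + noise + spikes`,
#' where occupancy `theta(t)` follows the two-state binding kinetics under
#' the scenario's temperature protocol, the gate shift comes from the EDL
#' capacitive division, Gaussian noise has standard deviation
#' `sigma_ref * (T(t)/T_ref)^temp_exponent`, and each addition leaves a
#' brief exponentially decaying current artifact.  The output is
#' deterministic given the seed.
#'
#' @param scenario A [sensing_scenario].
#' @param noise A [noise_model].
#' @param seed Integer seed.
#' @return Object of class `sensing_run`: list with `t` (s), `Id` (mA),
#'   `T_K`, `additions`, `concentrations` (chamber concentration after each
#'   addition, M), `theta` (true occupancy), and `meta` (seed, noise model,
#'   scenario).
#' @export
#' @examples
#' run <- generate_trace(sensing_scenario(dt = 1), noise_model(0.02), seed = 1)
generate_trace <- function(scenario, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(scenario, "sensing_scenario"),
            inherits(noise, "noise_model"))
  det <- .deterministic_trace(scenario)
  n <- length(det$t)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  sd_t <- noise$sigma_ref * (det$T_K / noise$T_ref)^noise$temp_exponent
  eps <- stats::rnorm(n, 0, 1) * sd_t
  spikes <- numeric(n)
  if (noise$spike_amplitude != 0) {
    for (ta in scenario$additions$time) {
      idx <- det$t >= ta
      spikes[idx] <- spikes[idx] +
        noise$spike_amplitude * exp(-(det$t[idx] - ta) / noise$spike_tau)
    }
  }
  Id <- det$Id_mA + noise$drift_rate * det$t + eps + spikes
  structure(list(t = det$t, Id = Id, T_K = det$T_K,
                 additions = scenario$additions,
                 concentrations = det$conc, theta = det$theta,
                 meta = list(seed = seed, noise = noise,
                             scenario = scenario)),
            class = "sensing_run")
}

#' @export
print.sensing_run <- function(x, ...) {
  cat(sprintf("<sensing_run> %d samples over %.6g s, %d additions, seed %d\n",
              length(x$t), x$t[length(x$t)], nrow(x$additions),
              x$meta$seed))
  invisible(x)
}

#' Extract per-addition step heights from a sensing run
#'
#' For each addition, the signal change is the mean current over the settle
#' window just before the next addition (or the end of the run) minus the
#' mean over the settle window just before this addition, paired with the
#' chamber concentration established by the addition.
#'
#' @param run A [generate_trace] output (`sensing_run`).
#' @param settle_window Averaging window length, s; must not reach back
#'   across a previous addition.
#' @return data.frame with columns `concentration` (M) and `signal` (mA).
#' @export
extract_step_heights <- function(run, settle_window = 30) {
  stopifnot(inherits(run, "sensing_run"))
  .stopifnot_finite(settle_window)
  if (settle_window <= 0) stop("settle_window must be positive", call. = FALSE)
  t_add <- run$additions$time
  bounds <- c(t_add, run$t[length(run$t)])
  gaps <- c(t_add[1] - run$t[1], diff(bounds))
  if (settle_window > min(gaps))
    stop("settle_window overlaps an addition; shorten it", call. = FALSE)
  win_mean <- function(t_end_w) {
    sel <- run$t >= (t_end_w - settle_window) & run$t < t_end_w
    mean(run$Id[sel])
  }
  pre  <- vapply(bounds[-length(bounds)], win_mean, numeric(1))
  post <- vapply(bounds[-1], win_mean, numeric(1))
  data.frame(concentration = run$concentrations, signal = post - pre)
}
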