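# Serial-dilution bookkeeping, calibration-curve fitting, 3-sigma/S limit
# of detection, and real-sample back-calculation.

#' Addition-event schedule
#'
#' Builds a validated data.frame of analyte additions: time of addition,
#' added volume, stock concentration, and the temperature of the injected
#' sample.
#'
#' @param time Addition times, s.
#' @param volume Added volumes, uL, > 0.
#' @param stock_concentration Stock concentrations, M, >= 0.
#' @param sample_temperature Temperatures of the injected aliquots, K.
#' @return data.frame of class `addition_schedule`.
#' @export
#' @examples
#' standard_additions()
addition_schedule <- function(time, volume, stock_concentration,
                              sample_temperature = 333) {
  .stopifnot_finite(time, volume, stock_concentration, sample_temperature)
  if (any(volume <= 0)) stop("addition volumes must be positive", call. = FALSE)
  if (any(stock_concentration < 0))
    stop("stock concentrations must be >= 0", call. = FALSE)
  if (any(diff(time) <= 0)) stop("addition times must be increasing",
                                 call. = FALSE)
  out <- data.frame(time = time, volume = volume,
                    stock_concentration = rep_len(stock_concentration,
                                                  length(time)),
                    sample_temperature = rep_len(sample_temperature,
                                                 length(time)))
  class(out) <- c("addition_schedule", "data.frame")
  out
}

#' The six-step decade addition schedule
#'
#' The standard serial-addition protocol: 5.55, 6.17, 6.85, 7.62, 8.40 and
#' 9.40 uL of stocks at 1e-10 ... 1e-5 M into an initial 50 uL chamber,
#' chosen so each addition raises the chamber concentration to the next
#' decade (1e-11 ... 1e-6 M).
#'
#' @param spacing Time between additions, s.
#' @param t_first Time of the first addition, s.
#' @param sample_temperature Temperature of the injected aliquots, K.
#' @return An [addition_schedule].
#' @export
standard_additions <- function(spacing = 120, t_first = 120,
                               sample_temperature = 333) {
  addition_schedule(time = t_first + spacing * (0:5),
                    volume = c(5.55, 6.17, 6.85, 7.62, 8.40, 9.40),
                    stock_concentration = 10^(-10:-5),
                    sample_temperature = sample_temperature)
}

#' Concentration after each serial addition
#'
#' Exact mole/volume bookkeeping: after each addition the chamber
#' concentration is `(moles so far + V_add * C_stock) / (volume so far +
#' V_add)`.  Moles are conserved exactly.
#'
#' @param initial_volume Starting chamber volume, uL.
#' @param additions An [addition_schedule] (or data.frame with `volume` and
#'   `stock_concentration` columns).
#' @param initial_concentration Analyte concentration already present, M.
#' @return Numeric vector of post-addition concentrations, M.
#' @export
#' @examples
#' dilution_series(50, standard_additions())  # ~1e-11 ... ~1e-6 M
dilution_series <- function(initial_volume, additions,
                            initial_concentration = 0) {
  .stopifnot_finite(initial_volume, initial_concentration)
  if (initial_volume <= 0) stop("initial volume must be positive",
                                call. = FALSE)
  vol <- initial_volume
  moles <- initial_volume * initial_concentration   # uL * M (consistent units)
  out <- numeric(nrow(additions))
  for (i in seq_len(nrow(additions))) {
    moles <- moles + additions$volume[i] * additions$stock_concentration[i]
    vol <- vol + additions$volume[i]
    out[i] <- moles / vol
  }
  out
}

#' Fit a log-concentration calibration line
#'
#' Ordinary least squares of signal change (mA) against `log10` of
#' concentration (M).  The slope is the sensitivity in mA per decade.
#'
#' @param concentration Concentrations, M, > 0; at least two distinct
#'   values.
#' @param signal Signal changes, mA.
#' @param sigma_blank Standard deviation of the blank signal, mA; defaults
#'   to the residual standard deviation of the fit.
#' @param C_ref Reference concentration (M) mapping the calibration
#'   intercept to the concentration axis, used by [lod].
#' @return Object of class `calibration_curve`: `slope` (mA/decade),
#'   `intercept` (mA), `sigma_blank`, `C_ref`, `points` (data.frame of
#'   `logC`, `signal`), `fit` (the underlying `lm`).
#' @export
#' @examples
#' fit_calibration(10^(-11:-6), c(0.35, 0.61, 0.98, 1.28, 1.59, 1.91))
fit_calibration <- function(concentration, signal, sigma_blank = NULL,
                            C_ref = 2.43e-13) {
  .stopifnot_finite(concentration, signal)
  if (length(concentration) != length(signal) || length(signal) < 2)
    stop("need matched concentration/signal vectors of length >= 2",
         call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be positive for a log fit", call. = FALSE)
  logC <- log10(concentration)
  if (diff(range(logC)) < 1e-12)
    stop("concentrations are degenerate: at least two distinct values needed",
         call. = FALSE)
  fit <- stats::lm(signal ~ logC)
  # a perfect (e.g. two-point) fit is a legitimate input here
  smry <- suppressWarnings(summary(fit))
  if (is.null(sigma_blank)) {
    sigma_blank <- if (length(signal) > 2) smry$sigma else 0
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = smry$coefficients[2, 2],
                 sigma_blank = sigma_blank,
                 C_ref = C_ref,
                 points = data.frame(logC = logC, signal = signal),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d points: signal = %.4g + %.4g * log10(C)\n",
              nrow(x$points), x$intercept, x$slope))
  cat(sprintf("  sigma_blank = %.4g mA, C_ref = %.4g M\n",
              x$sigma_blank, x$C_ref))
  invisible(x)
}

#' Limit of detection from blank noise and calibration slope
#'
#' `LOD = 3 sigma / S` in decades of concentration, converted to molarity
#' through the calibration reference concentration:
#' `LOD_M = 10^(3 sigma / S) * C_ref`.
#'
#' @param sigma_blank Standard deviation of the blank signal, mA.
#' @param slope Calibration slope, mA per decade, > 0.
#' @param C_ref Reference concentration at the calibration intercept, M.
#' @return List with `lod_decades` and `lod_molar` (M).
#' @export
#' @examples
#' lod(0.067, 0.307, 2.43e-13)
lod <- function(sigma_blank, slope, C_ref) {
  .stopifnot_finite(sigma_blank, slope, C_ref)
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (sigma_blank < 0) stop("sigma_blank must be >= 0", call. = FALSE)
  decades <- 3 * sigma_blank / slope
  list(lod_decades = decades, lod_molar = 10^decades * C_ref)
}

#' Molarity to mass concentration (ppb)
#'
#' @param conc_M Concentration, mol/L.
#' @param molar_mass Molar mass, g/mol (lead: 207.2).
#' @return Concentration in ug/L (ppb).
#' @export
molar_to_ppb <- function(conc_M, molar_mass = 207.2) {
  .stopifnot_finite(conc_M, molar_mass)
  conc_M * molar_mass * 1e6
}

#' Mass concentration (ppb) to molarity
#'
#' @param ppb Concentration, ug/L.
#' @param molar_mass Molar mass, g/mol.
#' @return Concentration, mol/L.
#' @export
ppb_to_molar <- function(ppb, molar_mass = 207.2) {
  .stopifnot_finite(ppb, molar_mass)
  ppb * 1e-6 / molar_mass
}

#' Total dilution factor of the certified-river-water workflow
#'
#' The real-sample pretreatment dilutes the certified reference water
#' 4-fold after pH adjustment and then introduces one part in ten into the
#' sensing chamber, a 40-fold total dilution.
#'
#' @return Numeric scalar, 40.
#' @export
slrs_dilution_factor <- function() 4 * 10

#' Back-calculate a sample concentration from a measured signal
#'
#' Inverts the calibration line to `log10 C`, multiplies the chamber
#' concentration back through the sample dilution factor, and converts to
#' ppb via the molar mass.  Signals outside the fitted concentration range
#' trigger an extrapolation warning.
#'
#' @param signal Measured signal change, mA.
#' @param curve A [calibration_curve].
#' @param dilution_factor Total dilution between the original sample and
#'   the sensing chamber, >= 1.
#' @param molar_mass Molar mass of the analyte, g/mol.
#' @return List with `conc_chamber_M`, `conc_sample_M`, `conc_sample_ppb`.
#' @export
#' @examples
#' curve <- fit_calibration(10^(-11:-6), 0.3 * (1:6))
#' quantify(0.9, curve)
quantify <- function(signal, curve, dilution_factor = 1,
                     molar_mass = 207.2) {
  stopifnot(inherits(curve, "calibration_curve"))
  .stopifnot_finite(signal, dilution_factor)
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  logC <- (signal - curve$intercept) / curve$slope
  rng <- range(curve$points$logC)
  if (logC < rng[1] || logC > rng[2])
    warning("signal lies outside the calibrated concentration range; extrapolating",
            call. = FALSE)
  conc_chamber <- 10^logC
  conc_sample <- conc_chamber * dilution_factor
  list(conc_chamber_M = conc_chamber,
       conc_sample_M = conc_sample,
       conc_sample_ppb = molar_to_ppb(conc_sample, molar_mass))
}

#' Relative deviation from a certified value
#'
#' @param measured Measured concentration (any unit).
#' @param certified Certified concentration (same unit).
#' @return Relative deviation in percent.
#' @export
#' @examples
#' relative_deviation(0.182, 0.170)  # ~7 %
relative_deviation <- function(measured, certified) {
  .stopifnot_finite(measured, certified)
  if (certified == 0) stop("certified value must be non-zero", call. = FALSE)
  100 * abs(measured - certified) / abs(certified)
}
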