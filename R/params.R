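#' @keywords internal
"_PACKAGE"

# Boltzmann constant in pN.um/K (1 J = 1e18 pN.um)
.kB <- 1.380649e-05

#' Viscoelastic medium parameters
#'
#' Describes the medium a 1 um-radius probe bead is embedded in, as seen by
#' the bead: a Kelvin-Voigt element (elastic stiffness `kappa_m` in parallel
#' with a dashpot of drag `gamma`), optionally generalized to a power-law
#' medium through `msd_exponent`. Thermal energy `kBT` is derived from
#' `temperature`.
#'
#' Units follow the package convention: lengths um, forces pN, stiffness
#' pN/um, drag pN.s/um, energy pN.um.
#'
#' @param kappa_m Elastic stiffness seen by the bead (pN/um), `>= 0`.
#' @param gamma Drag coefficient (pN.s/um), `> 0`.
#' @param temperature Absolute temperature (K). Default 310.15 K (37 C).
#' @param msd_exponent Optional power-law exponent in `[0, 1]` for
#'   fractional media; `NULL` for the plain Kelvin-Voigt element.
#' @return An object of class `medium_params`.
#' @examples
#' medium_params(kappa_m = 50, gamma = 0.01)
#' @export
medium_params <- function(kappa_m, gamma, temperature = 310.15,
                          msd_exponent = NULL) {
  stopifnot(is.numeric(kappa_m), length(kappa_m) == 1L, is.finite(kappa_m))
  if (kappa_m < 0) stop("kappa_m must be >= 0")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(temperature) || temperature < 0)
    stop("temperature must be >= 0")
  if (!is.null(msd_exponent)) {
    if (!is.numeric(msd_exponent) || msd_exponent < 0 || msd_exponent > 1)
      stop("msd_exponent must lie in [0, 1]")
  }
  structure(list(kappa_m = kappa_m, gamma = gamma,
                 temperature = temperature,
                 kBT = .kB * temperature,
                 msd_exponent = msd_exponent),
            class = "medium_params")
}

#' Optical trap and detection parameters
#'
#' Parameters of the oscillating optical trap and of the two quadrant
#' photodiodes (detQPD follows the bead, trapQPD follows the trapping beam).
#'
#' @param k_trap Trap stiffness (pN/um), `> 0`.
#' @param amplitude Drive amplitude (nm). Default 60 nm.
#' @param frequency Drive frequency (Hz). Default 50 Hz.
#' @param axis_angle Oscillation axis in degrees, one of 0, 45, 90, 135.
#' @param volts_per_um_det,volts_per_um_trap QPD gains (V/um), non-zero.
#' @return An object of class `trap_params`.
#' @export
trap_params <- function(k_trap = 100, amplitude = 60, frequency = 50,
                        axis_angle = 0, volts_per_um_det = 5,
                        volts_per_um_trap = 5) {
  if (!is.numeric(k_trap) || k_trap <= 0) stop("k_trap must be > 0")
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop("amplitude must be > 0")
  if (!is.numeric(frequency) || frequency <= 0)
    stop("frequency must be > 0")
  if (!axis_angle %in% c(0, 45, 90, 135))
    stop("axis_angle must be one of 0, 45, 90, 135 degrees")
  if (volts_per_um_det == 0 || volts_per_um_trap == 0)
    stop("QPD gains must be non-zero")
  structure(list(k_trap = k_trap, amplitude = amplitude,
                 frequency = frequency, axis_angle = axis_angle,
                 volts_per_um_det = volts_per_um_det,
                 volts_per_um_trap = volts_per_um_trap),
            class = "trap_params")
}

#' Generative trend of a peri-cellular stiffness field
#'
#' Log-scale linear trend of bead stiffness on distance to the cell outline,
#' folded angular position and experimental condition, the generative twin
#' of the multivariate exponential regression fitted by [mer_fit()].
#' Per-axis stiffness is drawn as
#' `LogNormal(beta0 + beta_distance*d + beta_theta*theta + beta_condition[cond],
#' sigma_log)`.
#'
#' @param beta0 Log-stiffness intercept (log pN/um).
#' @param beta_distance Coefficient per um of distance.
#' @param beta_theta Coefficient per degree of folded angle.
#' @param beta_condition Named numeric vector of condition coefficients;
#'   exactly one entry (the reference level) must be 0.
#' @param sigma_log Log-scale noise SD, `>= 0`.
#' @return An object of class `field_trend`.
#' @examples
#' field_trend(beta0 = log(20), beta_distance = -0.01, beta_theta = -0.002,
#'             beta_condition = c("1.0T1C" = 0, "2.0T1C" = 0.5))
#' @export
field_trend <- function(beta0, beta_distance = 0, beta_theta = 0,
                        beta_condition = c("1.0T1C" = 0), sigma_log = 0) {
  stopifnot(is.numeric(beta0), is.numeric(beta_distance),
            is.numeric(beta_theta), is.numeric(beta_condition))
  if (is.null(names(beta_condition)) || any(names(beta_condition) == ""))
    stop("beta_condition must be a fully named vector")
  if (sum(beta_condition == 0) != 1L)
    stop("exactly one condition (the reference level) must have coefficient 0")
  if (!is.numeric(sigma_log) || sigma_log < 0)
    stop("sigma_log must be >= 0")
  structure(list(beta0 = beta0, beta_distance = beta_distance,
                 beta_theta = beta_theta, beta_condition = beta_condition,
                 reference = names(beta_condition)[beta_condition == 0],
                 sigma_log = sigma_log),
            class = "field_trend")
}

#' @export
print.medium_params <- function(x, ...) {
  cat("Medium: kappa_m =", x$kappa_m, "pN/um, gamma =", x$gamma,
      "pN.s/um, T =", x$temperature, "K (kBT =",
      format(x$kBT, digits = 4), "pN.um)\n")
  if (!is.null(x$msd_exponent))
    cat("  power-law exponent:", x$msd_exponent, "\n")
  invisible(x)
}

#' @export
print.trap_params <- function(x, ...) {
  cat("Trap: k_trap =", x$k_trap, "pN/um, drive", x$amplitude, "nm @",
      x$frequency, "Hz, axis", x$axis_angle, "deg\n")
  invisible(x)
}
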