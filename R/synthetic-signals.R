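# Synthetic QPD signals and bead trajectories with known ground truth.
#
# The per-axis bead dynamics are 1-D and overdamped (bead Reynolds number
# << 1, no inertia):
#   gamma dx = [-kappa_m x + k_trap (x_T(t) - x)] dt + sqrt(2 kBT gamma) dW
# with x_T(t) = A sin(2 pi f t). Because the SDE is linear, it is integrated
# with the exact exponential (Ornstein-Uhlenbeck) one-step update rather
# than Euler-Maruyama: the update is exact in distribution at any step size,
# so stiff parameter combinations (large kappa/gamma) need no step-size
# guard and the sampled path equals the continuous solution at the sample
# times.

#' Construct a QPD time series
#'
#' @param samples Numeric vector of QPD voltages.
#' @param sampling_rate Sampling rate (Hz), `> 0`.
#' @param channel `"detQPD"` (bead position) or `"trapQPD"` (trap position).
#' @param axis_angle Oscillation axis (degrees).
#' @param bead_id Optional bead identifier, used to enforce that a
#'   calibration and a measurement belong to the same bead.
#' @return An object of class `qpd_series`.
#' @export
qpd_series <- function(samples, sampling_rate, channel = c("detQPD", "trapQPD"),
                       axis_angle = 0, bead_id = NULL) {
  channel <- match.arg(channel)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, channel = channel,
                 axis_angle = axis_angle, bead_id = bead_id),
            class = "qpd_series")
}

#' @export
print.qpd_series <- function(x, ...) {
  cat(sprintf("<qpd_series> %s, %d samples @ %g Hz, axis %g deg\n",
              x$channel, length(x$samples), x$sampling_rate, x$axis_angle))
  invisible(x)
}

# Exact one-step forcing integral of the driven OU equation:
# (k_trap A / gamma) * Int_0^h exp(-lambda (h-s)) sin(w (t_n + s)) ds,
# evaluated for all step start times t_n at once.
.ou_forcing <- function(t_n, h, lambda, w, prefac) {
  z <- complex(real = lambda, imaginary = w)
  kern <- (exp(complex(imaginary = w * h)) - exp(-lambda * h)) / z
  prefac * Im(exp(complex(imaginary = w * t_n)) * kern)
}

#' Generate synthetic AMR trap/detection QPD signals
#'
#' Simulates a probe bead in a Kelvin-Voigt medium driven by a sinusoidally
#' oscillating optical trap and returns the two QPD records an active
#' microrheology acquisition would produce: `trapQPD` encoding the trap
#' position `x_T(t) = A sin(2 pi f t)` and `detQPD` encoding the bead
#' position from the overdamped Langevin dynamics. The ground-truth complex
#' stiffness `kappa*(w) = kappa_m + i w gamma` is stored in the
#' `ground_truth` attribute.
#'
#' @param medium A [medium_params()] object.
#' @param trap A [trap_params()] object.
#' @param duration Record length (s); must cover at least 10 drive cycles.
#' @param sampling_rate Sampling rate (Hz), at least 10x the drive frequency.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param thermal If `FALSE`, thermal noise is suppressed (equivalently
#'   `temperature = 0`) so closed-form checks can run noise-free.
#' @param bead_id Optional bead identifier propagated to both series.
#' @return A list with elements `trapQPD` and `detQPD` (class
#'   [qpd_series()]) and attribute `ground_truth` (list with `kappa_star`,
#'   the parameters and the seed).
#' @examples
#' sig <- gen_amr_signals(medium_params(50, 0.01, temperature = 0),
#'                        trap_params(), duration = 0.5, seed = 1)
#' attr(sig, "ground_truth")$kappa_star
#' @export
gen_amr_signals <- function(medium, trap, duration = 1, sampling_rate = 1e4,
                            seed = 1, thermal = TRUE, bead_id = NULL) {
  stopifnot(inherits(medium, "medium_params"), inherits(trap, "trap_params"))
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be > 0")
  if (sampling_rate < 10 * trap$frequency)
    stop("sampling_rate must be at least 10x the drive frequency")
  if (duration * trap$frequency < 10)
    stop("record must cover at least 10 drive cycles")

  h <- 1 / sampling_rate
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1L) * h
  w <- 2 * pi * trap$frequency
  A <- trap$amplitude / 1000            # nm -> um
  x_trap <- A * sin(w * t)

  kappa_tot <- medium$kappa_m + trap$k_trap
  lambda <- kappa_tot / medium$gamma
  a <- exp(-lambda * h)
  forcing <- .ou_forcing(t[-n], h, lambda, w,
                         prefac = trap$k_trap * A / medium$gamma)

  kBT <- if (thermal) medium$kBT else 0
  if (kBT > 0) {
    set.seed(seed)
    sd_step <- sqrt(kBT / kappa_tot * (1 - a^2))
    noise <- stats::rnorm(n - 1L, sd = sd_step)
    x0 <- stats::rnorm(1L, sd = sqrt(kBT / kappa_tot))
  } else {
    noise <- numeric(n - 1L)
    x0 <- 0
  }
  incr <- forcing + noise
  x <- c(x0, a^seq_len(n - 1L) * x0 +
           as.numeric(stats::filter(incr, a, method = "recursive")))

  gt <- list(kappa_star = complex(real = medium$kappa_m,
                                  imaginary = w * medium$gamma),
             medium = medium, trap = trap, seed = seed,
             duration = duration, sampling_rate = sampling_rate,
             thermal = thermal, position_um = x, trap_position_um = x_trap)
  out <- list(
    trapQPD = qpd_series(x_trap * trap$volts_per_um_trap, sampling_rate,
                         "trapQPD", trap$axis_angle, bead_id),
    detQPD = qpd_series(x * trap$volts_per_um_det, sampling_rate,
                        "detQPD", trap$axis_angle, bead_id))
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a passive-microrheology bead trajectory
#'
#' Free (trap off) thermal trajectory of a bead in a Kelvin-Voigt medium,
#' `gamma dx = -kappa_m x dt + sqrt(2 kBT gamma) dW`, integrated with the
#' exact OU update (or as a Wiener path when `kappa_m = 0`). The analytic
#' mean-square displacement `MSD(tau) = 2 kBT/kappa_m (1 - exp(-kappa_m
#' tau/gamma))` (or `2 D tau` with `D = kBT/gamma` for `kappa_m = 0`) is
#' recorded in the `analytic_msd` attribute as a function of lag.
#'
#' @param medium A [medium_params()] object (`kappa_m >= 0`).
#' @param duration Record length (s). Default 30 s.
#' @param sampling_rate Sampling rate (Hz). Default 10 kHz.
#' @param seed Integer seed.
#' @return An object of class `trajectory`: list with `position` (um),
#'   `sampling_rate`, `duration`; attribute `analytic_msd` is a function of
#'   lag tau (s) returning the exact 1-D MSD (um^2), and `ground_truth`
#'   stores the parameters.
#' @export
gen_pmr_trajectory <- function(medium, duration = 30, sampling_rate = 1e4,
                               seed = 1) {
  stopifnot(inherits(medium, "medium_params"))
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be > 0")
  h <- 1 / sampling_rate
  n <- round(duration * sampling_rate)
  set.seed(seed)
  if (medium$kBT == 0) {
    x <- numeric(n)
  } else if (medium$kappa_m == 0) {
    D <- medium$kBT / medium$gamma
    x <- c(0, cumsum(stats::rnorm(n - 1L, sd = sqrt(2 * D * h))))
  } else {
    lambda <- medium$kappa_m / medium$gamma
    a <- exp(-lambda * h)
    var_stat <- medium$kBT / medium$kappa_m
    x0 <- stats::rnorm(1L, sd = sqrt(var_stat))
    incr <- stats::rnorm(n - 1L, sd = sqrt(var_stat * (1 - a^2)))
    x <- c(x0, a^seq_len(n - 1L) * x0 +
             as.numeric(stats::filter(incr, a, method = "recursive")))
  }
  kBT <- medium$kBT; km <- medium$kappa_m; g <- medium$gamma
  msd_fun <- if (km == 0) {
    function(tau) 2 * (kBT / g) * tau
  } else {
    function(tau) 2 * kBT / km * (1 - exp(-km * tau / g))
  }
  structure(list(position = x, sampling_rate = sampling_rate,
                 duration = duration),
            analytic_msd = msd_fun,
            ground_truth = list(medium = medium, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples @ %g Hz (%.3g s)\n",
              length(x$position), x$sampling_rate, x$duration))
  invisible(x)
}

#' Generate a synthetic QPD calibration sweep
#'
#' Emulates the in-situ calibration in which the stage moves the bead a
#' fixed span across the detection beam at constant velocity while detQPD
#' voltage is recorded. The central region responds linearly at the given
#' gain; beyond it the response saturates smoothly (sigmoidal tails), as a
#' real QPD does.
#'
#' @param volts_per_um True central gain (V/um).
#' @param span_nm Total sweep span (nm). Default 200 nm.
#' @param velocity_nm_s Stage velocity (nm/s). Default 100 nm/s.
#' @param sampling_rate Sampling rate of the recorded sweep (Hz).
#' @param noise_sd Voltage noise SD (V).
#' @param linear_fraction Fraction of the span over which the response is
#'   linear. Default 0.8.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param bead_id,axis_angle Identifiers propagated to the sweep.
#' @return An object of class `calibration_sweep`: list with
#'   `stage_position` (nm, strictly monotone) and `detqpd_volts`.
#' @export
gen_calibration_sweep <- function(volts_per_um, span_nm = 200,
                                  velocity_nm_s = 100, sampling_rate = 100,
                                  noise_sd = 0, linear_fraction = 0.8,
                                  seed = 1, bead_id = NULL, axis_angle = 0) {
  n <- max(21L, round(span_nm / velocity_nm_s * sampling_rate) + 1L)
  pos <- seq(-span_nm / 2, span_nm / 2, length.out = n)     # nm
  half_lin <- linear_fraction * span_nm / 2
  # linear core with tanh saturation outside the linear region
  v <- ifelse(abs(pos) <= half_lin,
              pos,
              sign(pos) * (half_lin + (span_nm / 2 - half_lin) *
                             tanh((abs(pos) - half_lin) /
                                    (span_nm / 2 - half_lin))))
  volts <- v / 1000 * volts_per_um                          # nm -> um
  if (noise_sd > 0) {
    set.seed(seed)
    volts <- volts + stats::rnorm(n, sd = noise_sd)
  }
  structure(list(stage_position = pos, detqpd_volts = volts,
                 bead_id = bead_id, axis_angle = axis_angle,
                 true_gain = volts_per_um),
            class = "calibration_sweep")
}
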