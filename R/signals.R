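# QPD calibration, displacement conversion and drive-frequency lock-in.

#' Fit the voltage-to-um conversion factor from a calibration sweep
#'
#' Least-squares slope of detQPD voltage against stage position over the
#' central linear region of the sweep (central 60% by default; a QPD's
#' response is sigmoidal towards the sweep edges). The sign of the slope is
#' preserved.
#'
#' @param sweep A `calibration_sweep` (see [gen_calibration_sweep()]) or a
#'   list with `stage_position` (nm, strictly monotone) and `detqpd_volts`.
#' @param central_fraction Fraction of the ramp used for the fit.
#' @return Object of class `conversion_factor`: list with `volts_per_um`,
#'   `fit_r2`, `low_r2` flag (`fit_r2 < 0.9`, reported with a warning) and
#'   the bead/axis identifiers of the sweep.
#' @examples
#' sw <- gen_calibration_sweep(volts_per_um = 2)
#' fit_conversion_factor(sw)$volts_per_um
#' @export
fit_conversion_factor <- function(sweep, central_fraction = 0.6) {
  pos <- sweep$stage_position; v <- sweep$detqpd_volts
  if (length(pos) != length(v)) stop("position and voltage lengths differ")
  if (length(pos) < 20L) stop("need at least 20 sweep samples")
  if (any(diff(pos) <= 0) && any(diff(pos) >= 0) &&
      !(all(diff(pos) > 0) || all(diff(pos) < 0)))
    stop("stage position must be strictly monotone")
  span <- abs(pos[length(pos)] - pos[1])
  if (span < 100) stop("sweep must span at least 100 nm")
  if (stats::var(pos) == 0) stop("degenerate sweep: zero position variance")
  if (stats::var(v) == 0) stop("degenerate sweep: constant voltage")
  mid <- (min(pos) + max(pos)) / 2
  keep <- abs(pos - mid) <= central_fraction * span / 2
  x <- pos[keep] / 1000            # nm -> um
  y <- v[keep]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  yhat <- mean(y) + slope * (x - mean(x))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - yhat)^2) / sst
  if (slope == 0) stop("degenerate sweep: zero slope")
  low <- r2 < 0.9
  if (low) warning("calibration fit r2 below 0.9")
  structure(list(volts_per_um = slope, fit_r2 = r2, low_r2 = low,
                 bead_id = sweep$bead_id, axis_angle = sweep$axis_angle),
            class = "conversion_factor")
}

#' Convert a QPD voltage series to displacement
#'
#' Elementwise division by the conversion factor, then mean-centering.
#' When both the series and the factor carry bead/axis identifiers they
#' must agree (a calibration is valid only for its own bead and axis).
#'
#' @param ts A [qpd_series()].
#' @param cf A `conversion_factor` from [fit_conversion_factor()], or a
#'   bare number (V/um).
#' @param center Mean-center the result (default `TRUE`).
#' @return Numeric displacement series (um) with the sampling rate as
#'   attribute.
#' @export
volts_to_displacement <- function(ts, cf, center = TRUE) {
  stopifnot(inherits(ts, "qpd_series"))
  if (inherits(cf, "conversion_factor")) {
    if (!is.null(cf$bead_id) && !is.null(ts$bead_id) &&
        !identical(cf$bead_id, ts$bead_id))
      stop("conversion factor belongs to a different bead")
    if (!is.null(cf$axis_angle) && !is.null(ts$axis_angle) &&
        !identical(cf$axis_angle, ts$axis_angle))
      stop("conversion factor belongs to a different axis")
    g <- cf$volts_per_um
  } else g <- cf
  if (g == 0) stop("conversion factor must be non-zero")
  x <- ts$samples / g
  if (center) x <- x - mean(x)
  attr(x, "sampling_rate") <- ts$sampling_rate
  x
}

#' Lock-in extraction of the drive-frequency Fourier component
#'
#' Projects a displacement (or force) record onto `exp(-i w t)` over an
#' integer number of drive cycles and reports the complex amplitude with
#' phase referenced to the drive: for `x(t) = B sin(w t + delta)` against a
#' reference `sin(w t)`, the result is `B exp(i delta)` — a positive real
#' part means in phase with the drive. The first `discard_cycles` cycles
#' are dropped as the overdamped settling transient.
#'
#' @param x Numeric record (um or pN).
#' @param reference Drive reference record of the same length and sampling
#'   (e.g. the trap displacement).
#' @param frequency Drive frequency (Hz).
#' @param sampling_rate Sampling rate (Hz); taken from the record's
#'   attribute if absent.
#' @param discard_cycles Leading drive cycles to drop (default 2).
#' @return Complex scalar amplitude; attributes `omega` (rad/s) and
#'   `n_cycles` used.
#' @export
lockin_extract <- function(x, reference, frequency,
                           sampling_rate = attr(x, "sampling_rate"),
                           discard_cycles = 2) {
  if (is.null(sampling_rate)) stop("sampling_rate must be given")
  if (length(x) != length(reference))
    stop("record and reference lengths differ")
  spc <- sampling_rate / frequency           # samples per cycle
  n_cyc <- floor((length(x) - discard_cycles * spc) / spc)
  if (n_cyc < 2) stop("record too short: fewer than 2 resolvable drive cycles")
  if (n_cyc < 10)
    warning("fewer than 10 integer drive cycles after truncation")
  i0 <- round(discard_cycles * spc)
  idx <- i0 + seq_len(round(n_cyc * spc))
  t <- (idx - 1) / sampling_rate
  w <- 2 * pi * frequency
  e <- exp(complex(imaginary = -w * t))
  zx <- 2 * mean(x[idx] * e)
  zr <- 2 * mean(reference[idx] * e)
  if (Mod(zr) == 0) stop("reference has no component at the drive frequency")
  out <- zx * Conj(zr) / Mod(zr)
  attr(out, "omega") <- w
  attr(out, "n_cycles") <- n_cyc
  out
}

#' Optical force exerted by a linear trap
#'
#' `F(t) = k_trap * (x_trap(t) - x_bead(t))`.
#'
#' @param trap_displacement,bead_displacement Equal-length series (um).
#' @param k_trap Trap stiffness (pN/um), `> 0`.
#' @return Force series (pN) with the sampling-rate attribute preserved.
#' @export
optical_force <- function(trap_displacement, bead_displacement, k_trap) {
  if (k_trap <= 0) stop("k_trap must be > 0")
  if (length(trap_displacement) != length(bead_displacement))
    stop("series lengths differ")
  f <- k_trap * (trap_displacement - bead_displacement)
  attr(f, "sampling_rate") <- attr(bead_displacement, "sampling_rate")
  f
}

#' Lock-in components of bead displacement and optical force
#'
#' Composes the calibration, conversion, force and lock-in steps for one
#' AMR record: converts both QPD channels to displacement, forms the
#' optical force, and extracts the drive-frequency Fourier components of
#' bead displacement `X` and force `F`, phase-referenced to the trap
#' drive.
#'
#' @param signals List with `trapQPD` and `detQPD` [qpd_series()] (as
#'   returned by [gen_amr_signals()]).
#' @param trap A [trap_params()] object (trap stiffness, drive frequency,
#'   trapQPD gain).
#' @param cf_det `conversion_factor` (or V/um scalar) for the detQPD
#'   channel; defaults to the trap's nominal gain.
#' @param discard_cycles Passed to [lockin_extract()].
#' @return List of class `lockin_components`: `X` (um, complex), `F` (pN,
#'   complex), `omega` (rad/s), `frequency`, `axis_angle`, `bead_id`.
#' @export
amr_lockin <- function(signals, trap, cf_det = trap$volts_per_um_det,
                       discard_cycles = 2) {
  stopifnot(inherits(trap, "trap_params"))
  x_bead <- volts_to_displacement(signals$detQPD, cf_det)
  x_trap <- volts_to_displacement(signals$trapQPD, trap$volts_per_um_trap)
  f <- optical_force(x_trap, x_bead, trap$k_trap)
  X <- lockin_extract(x_bead, x_trap, trap$frequency,
                      signals$detQPD$sampling_rate, discard_cycles)
  Fc <- lockin_extract(f, x_trap, trap$frequency,
                       signals$detQPD$sampling_rate, discard_cycles)
  structure(list(X = as.complex(X), F = as.complex(Fc),
                 omega = 2 * pi * trap$frequency,
                 frequency = trap$frequency,
                 axis_angle = trap$axis_angle,
                 bead_id = signals$detQPD$bead_id),
            class = "lockin_components")
}
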