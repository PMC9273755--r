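# Complex stiffness from AMR lock-in components, shear moduli via the
# generalized Stokes relation, and passive microrheology via MSD plus the
# generalized Stokes-Einstein (GSER) inversion.

#' Complex material stiffness from lock-in components
#'
#' The material response obeys `X = alpha*(w) F`, so the complex compliance
#' is `alpha* = X/F` and the complex stiffness `kappa* = F/X`. The reported
#' stiffness is the real (elastic) part `kappa' = Re(kappa*)`; the
#' imaginary (viscous) part is retained in the record but not used as the
#' reported stiffness.
#'
#' @param X Complex bead-displacement component (um), or a
#'   `lockin_components` object (then `F` and `omega` are taken from it).
#' @param F_ Complex optical-force component (pN).
#' @param omega Angular drive frequency (rad/s).
#' @param bead_id,axis_angle Optional identifiers.
#' @return Object of class `complex_response`: `alpha_star` (um/pN),
#'   `kappa_star` (pN/um), `kappa_prime` (pN/um), `omega`, identifiers and
#'   a `flagged` field (TRUE for non-physical `kappa_prime <= 0`, which is
#'   excluded from maps but kept in tables).
#' @examples
#' compute_kappa(complex(real = 0.01), complex(real = 1), omega = 2 * pi * 50)
#' @export
compute_kappa <- function(X, F_ = NULL, omega = NULL, bead_id = NULL,
                          axis_angle = NULL) {
  if (inherits(X, "lockin_components")) {
    li <- X
    X <- li$X; F_ <- li$F; omega <- li$omega
    bead_id <- li$bead_id; axis_angle <- li$axis_angle
  }
  if (Mod(F_) == 0) stop("force component has zero magnitude")
  if (Mod(X) == 0)
    stop("displacement component is zero (stiffness beyond detection); bead flagged")
  ks <- F_ / X
  kp <- Re(ks)
  structure(list(alpha_star = X / F_, kappa_star = ks, kappa_prime = kp,
                 omega = omega, bead_id = bead_id, axis_angle = axis_angle,
                 flagged = kp <= 0),
            class = "complex_response")
}

#' @export
print.complex_response <- function(x, ...) {
  cat(sprintf("<complex_response> kappa' = %.4g pN/um (kappa'' = %.3g) at %.3g rad/s%s\n",
              x$kappa_prime, Im(x$kappa_star), x$omega,
              if (isTRUE(x$flagged)) " [flagged: non-physical]" else ""))
  invisible(x)
}

#' Shear modulus from complex stiffness (generalized Stokes relation)
#'
#' `G*(w) = kappa*(w) / (6 pi r)`. With `r` in um and `kappa` in pN/um the
#' result is in Pa (1 Pa = 1 pN/um^2).
#'
#' @param kappa_star Complex stiffness (pN/um) or a `complex_response`.
#' @param radius Bead radius (um), `> 0`. Default 1 um.
#' @param frequency Ordinary frequency (Hz), carried into the record.
#' @param source `"AMR"` or `"PMR"`.
#' @return One-row data.frame with `G_prime` (Pa), `G_doubleprime` (Pa),
#'   `frequency`, `source`, `bead_radius`.
#' @examples
#' generalized_stokes(complex(real = 6 * pi), radius = 1)  # G' = 1 Pa
#' @export
generalized_stokes <- function(kappa_star, radius = 1, frequency = NA,
                               source = "AMR") {
  if (inherits(kappa_star, "complex_response")) {
    if (is.na(frequency)) frequency <- kappa_star$omega / (2 * pi)
    kappa_star <- kappa_star$kappa_star
  }
  if (radius <= 0) stop("radius must be > 0")
  g <- kappa_star / (6 * pi * radius)
  data.frame(G_prime = Re(g), G_doubleprime = Im(g),
             frequency = frequency, source = source, bead_radius = radius)
}

#' Mean-square displacement of a trajectory
#'
#' `MSD(tau) = mean over start times of (x(t + tau) - x(t))^2` (1-D
#' convention), evaluated at log-spaced lags from one sample to a quarter
#' of the record.
#'
#' @param traj A `trajectory` (see [gen_pmr_trajectory()]) or numeric
#'   position vector with a `sampling_rate` attribute.
#' @param n_lags Number of log-spaced lags (`>= 2`).
#' @return Object of class `msd_curve`: list with `lags` (s, strictly
#'   increasing), `msd` (um^2), `sampling_rate`.
#' @export
compute_msd <- function(traj, n_lags = 40) {
  if (inherits(traj, "trajectory")) {
    x <- traj$position; fs <- traj$sampling_rate
  } else {
    x <- as.numeric(traj); fs <- attr(traj, "sampling_rate")
  }
  if (is.null(fs)) stop("sampling rate unknown")
  n <- length(x)
  if (n < 100L) stop("trajectory must have at least 100 samples")
  if (n_lags < 2L) stop("n_lags must be >= 2")
  max_lag <- floor(n / 4)
  lag_samples <- unique(round(exp(seq(log(1), log(max_lag),
                                      length.out = n_lags))))
  msd <- vapply(lag_samples, function(L) {
    d <- x[(1L + L):n] - x[1:(n - L)]
    mean(d * d)
  }, numeric(1))
  structure(list(lags = lag_samples / fs, msd = msd, sampling_rate = fs),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, tau in [%.3g, %.3g] s\n",
              length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

#' GSER inversion of an MSD curve (local power-law method)
#'
#' Mason's local power-law estimator: the logarithmic slope
#' `alpha(tau) = d ln MSD / d ln tau` is obtained from a quadratic fit in
#' log-log coordinates over a centered 5-point window and clipped to
#' `[0, 1]`; then, with the 1-D MSD convention
#' (`<Dr^2>_3D = 3 MSD_1D`),
#' `|G*(w)| = kBT / (3 pi r MSD(1/w) Gamma(1 + alpha))` at `w = 1/tau`,
#' and `G' = |G*| cos(pi alpha / 2)`, `G'' = |G*| sin(pi alpha / 2)`.
#'
#' @param msd An `msd_curve` (strictly positive on the used lags).
#' @param radius Bead radius (um). Default 1 um.
#' @param temperature Temperature (K). Default 310.15 K.
#' @return data.frame with `frequency` (Hz, = 1/(2 pi tau)), `omega`
#'   (rad/s), `tau` (s), `alpha`, `G_prime`, `G_doubleprime`, `source =
#'   "PMR"`, `bead_radius`. Non-positive MSD points are dropped with a
#'   warning.
#' @export
gser_invert <- function(msd, radius = 1, temperature = 310.15) {
  stopifnot(inherits(msd, "msd_curve"))
  keep <- msd$msd > 0
  if (!all(keep)) warning("dropping ", sum(!keep), " non-positive MSD points")
  tau <- msd$lags[keep]; m <- msd$msd[keep]
  if (length(tau) < 5L) stop("need at least 5 positive MSD points")
  lt <- log(tau); lm <- log(m)
  n <- length(tau)
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, min(i - 2L, n - 4L)) + 0:4
    fit <- stats::lm.fit(cbind(1, lt[j], lt[j]^2), lm[j])
    alpha[i] <- fit$coefficients[2] + 2 * fit$coefficients[3] * lt[i]
  }
  alpha <- pmin(1, pmax(0, alpha))
  kBT <- .kB * temperature
  Gmod <- kBT / (3 * pi * radius * m * gamma(1 + alpha))
  data.frame(frequency = 1 / (2 * pi * tau), omega = 1 / tau, tau = tau,
             alpha = alpha,
             G_prime = Gmod * cos(pi * alpha / 2),
             G_doubleprime = Gmod * sin(pi * alpha / 2),
             source = "PMR", bead_radius = radius)
}

#' Paired comparison of AMR and PMR shear moduli
#'
#' Interpolates the PMR storage modulus onto the AMR frequencies (log-log
#' interpolation within the overlapping frequency support) and reports the
#' per-frequency paired differences together with a Wilcoxon signed-rank
#' test. Purely descriptive.
#'
#' @param amr,pmr data.frames with columns `frequency` and `G_prime` (as
#'   produced by [generalized_stokes()] / [gser_invert()]).
#' @return List with `table` (frequency, G_prime_amr, G_prime_pmr,
#'   difference, ratio), `median_difference`, `median_ratio`, `wilcoxon`
#'   (the [wilcox_signed()] result).
#' @export
amr_pmr_compare <- function(amr, pmr) {
  lo <- max(min(amr$frequency), min(pmr$frequency))
  hi <- min(max(amr$frequency), max(pmr$frequency))
  if (!is.finite(lo) || !is.finite(hi) || lo > hi)
    stop("no overlapping frequency support")
  a <- amr[amr$frequency >= lo & amr$frequency <= hi, , drop = FALSE]
  if (nrow(a) == 0L) stop("no AMR frequencies in the overlap")
  gp <- exp(stats::approx(log(pmr$frequency), log(pmax(pmr$G_prime, 1e-300)),
                          xout = log(a$frequency), rule = 2)$y)
  tab <- data.frame(frequency = a$frequency, G_prime_amr = a$G_prime,
                    G_prime_pmr = gp, difference = a$G_prime - gp,
                    ratio = a$G_prime / gp)
  wt <- if (nrow(tab) >= 2 && any(tab$difference != 0))
    wilcox_signed(tab$G_prime_amr, tab$G_prime_pmr) else NULL
  list(table = tab,
       median_difference = stats::median(tab$difference),
       median_ratio = stats::median(tab$ratio),
       wilcoxon = wt)
}
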