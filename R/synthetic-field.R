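# Synthetic peri-cellular stiffness fields and an elliptical test cell.

#' Elliptical cell outline as a cell_geometry
#'
#' Convenience constructor for synthetic experiments: an ellipse with
#' semi-axes `a` (along `orientation_deg`) and `b`, rasterized as a
#' polygon.
#'
#' @param a,b Semi-axes (um), `a >= b`.
#' @param center Length-2 center (um).
#' @param orientation_deg Long-axis angle (degrees, counterclockwise).
#' @param n_vertices Number of polygon vertices.
#' @param ... Passed to [cell_geometry()] (e.g. `mode`, `front_sign`).
#' @return A [cell_geometry()] object.
#' @export
make_ellipse_cell <- function(a = 40, b = 15, center = c(0, 0),
                              orientation_deg = 0, n_vertices = 72, ...) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-1L]
  phi <- orientation_deg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  boundary <- cbind(center[1] + x * cos(phi) - y * sin(phi),
                    center[2] + x * sin(phi) + y * cos(phi))
  cg <- cell_geometry(boundary, validate = FALSE, ...)
  # analytic orientation beats the polygonal moment estimate
  if (a != b) {
    cg$orientation_deg <- orientation_deg %% 180
    if (cg$mode == "long_axis") {
      u <- .axis_unit(cg$orientation_deg)
      cg$front_direction <- sign(sum(cg$front_direction * u)) * u
    }
  }
  cg
}

#' Generate a synthetic peri-cellular stiffness field
#'
#' Scatters beads uniformly over the annular region outside the cell
#' outline up to `max_distance` from it, and draws a per-axis elastic
#' stiffness for each bead from the log-normal generative model
#' `log kappa' ~ N(beta0 + beta_d * d + beta_theta * theta + beta_cond,
#' sigma_log)`, where `d` is the shortest distance to the outline (um) and
#' `theta` the folded angular position (degrees). The true coefficients
#' are stored in the `truth` attribute for recovery tests.
#'
#' @param cell A [cell_geometry()] object.
#' @param trend A [field_trend()] object.
#' @param n_beads Number of beads, `>= 1`.
#' @param max_distance Outer radius of the probed region (um), `> 0`.
#' @param condition Condition label for all beads; must be a name of
#'   `trend$beta_condition`.
#' @param axes Oscillation axes sampled per bead (degrees).
#' @param seed Integer seed.
#' @return A data.frame of bead records, one row per bead x axis:
#'   `bead_id`, `x`, `y`, `distance`, `theta_deg`, `axis_angle_deg`,
#'   `condition`, `kappa_prime`; attribute `truth` holds the trend and
#'   seed, attribute `cell` the geometry.
#' @examples
#' cg <- make_ellipse_cell()
#' tr <- field_trend(beta0 = log(20), sigma_log = 0.3)
#' head(gen_stiffness_field(cg, tr, n_beads = 50, seed = 1))
#' @export
gen_stiffness_field <- function(cell, trend, n_beads, max_distance = 150,
                                condition = trend$reference,
                                axes = c(0, 45, 90, 135), seed = 1) {
  stopifnot(inherits(cell, "cell_geometry"), inherits(trend, "field_trend"))
  if (n_beads < 1L) stop("n_beads must be >= 1")
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (!condition %in% names(trend$beta_condition))
    stop("unknown condition: ", condition)
  if (nrow(cell$boundary) <= 400L && !.is_simple_polygon(cell$boundary))
    stop("cell outline is not a simple polygon")
  set.seed(seed)
  lo <- apply(cell$boundary, 2, min) - max_distance
  hi <- apply(cell$boundary, 2, max) + max_distance
  xs <- numeric(0); ys <- numeric(0); ds <- numeric(0)
  while (length(xs) < n_beads) {
    m <- max(2L * (n_beads - length(xs)), 100L)
    cx <- stats::runif(m, lo[1], hi[1])
    cy <- stats::runif(m, lo[2], hi[2])
    d <- shortest_distance(cbind(cx, cy), cell$boundary)
    keep <- !attr(d, "inside") & d > 0 & d <= max_distance
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep]); ds <- c(ds, d[keep])
  }
  xs <- xs[seq_len(n_beads)]; ys <- ys[seq_len(n_beads)]
  ds <- ds[seq_len(n_beads)]
  th <- angular_position(cbind(xs, ys), cell)
  mu <- trend$beta0 + trend$beta_distance * ds + trend$beta_theta * th +
    trend$beta_condition[[condition]]
  k <- length(axes)
  out <- data.frame(
    bead_id = rep(seq_len(n_beads), each = k),
    x = rep(xs, each = k), y = rep(ys, each = k),
    distance = rep(ds, each = k), theta_deg = rep(th, each = k),
    axis_angle_deg = rep(axes, times = n_beads),
    condition = condition,
    kappa_prime = exp(rep(mu, each = k) +
                        stats::rnorm(n_beads * k, sd = trend$sigma_log)),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(trend = trend, seed = seed,
                             condition = condition,
                             max_distance = max_distance)
  attr(out, "cell") <- cell
  out
}
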