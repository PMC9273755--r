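# The twenty-annular-bin peri-cellular stiffness landscape and per-cell
# anisotropy / peri-vs-distal summaries.

#' Annular bin grid around a cell
#'
#' Default edges give the 20-bin landscape: four radial annuli at
#' 0-25-50-100-150 um (the first annulus is the peri-cellular region) by
#' five 36-degree sectors of the folded angle.
#'
#' @param radial_edges Strictly increasing distances (um), first edge 0.
#' @param angular_edges Strictly increasing folded angles (degrees),
#'   spanning [0, 180].
#' @return Object of class `bin_grid`.
#' @export
bin_grid <- function(radial_edges = c(0, 25, 50, 100, 150),
                     angular_edges = c(0, 36, 72, 108, 144, 180)) {
  if (radial_edges[1] != 0) stop("first radial edge must be 0")
  if (any(diff(radial_edges) <= 0) || any(diff(angular_edges) <= 0))
    stop("edges must be strictly increasing")
  structure(list(radial_edges = radial_edges, angular_edges = angular_edges,
                 n_radial = length(radial_edges) - 1L,
                 n_angular = length(angular_edges) - 1L),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d radial x %d angular = %d bins\n",
              x$n_radial, x$n_angular, x$n_radial * x$n_angular))
  cat("  radial edges (um):", paste(x$radial_edges, collapse = ", "), "\n")
  cat("  angular edges (deg):", paste(x$angular_edges, collapse = ", "), "\n")
  invisible(x)
}

#' Assign beads to annular bins
#'
#' Intervals are half-open `[lo, hi)` on both axes, with the top edges
#' (outermost radius and 180 degrees) closed. Beads beyond the outermost
#' radial edge are out of range (`NA` bins).
#'
#' @param distance,theta_deg Numeric vectors (um / degrees, `distance >=
#'   0`, `theta_deg` in [0, 180]).
#' @param grid A [bin_grid()].
#' @return data.frame with `radial_bin`, `angular_bin` (1-based, `NA` when
#'   out of range) and `bin` (single index, radial-major).
#' @examples
#' assign_bin(c(10, 25, 160), c(20, 180, 90), bin_grid())
#' @export
assign_bin <- function(distance, theta_deg, grid = bin_grid()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(distance < 0, na.rm = TRUE)) stop("distance must be >= 0")
  if (any(theta_deg < 0 | theta_deg > 180, na.rm = TRUE))
    stop("theta_deg must lie in [0, 180]")
  re <- grid$radial_edges; ae <- grid$angular_edges
  rb <- findInterval(distance, re, rightmost.closed = TRUE)
  rb[distance > re[length(re)]] <- NA_integer_
  rb[rb == 0L] <- NA_integer_   # below first edge cannot happen (edge 0)
  ab <- findInterval(theta_deg, ae, rightmost.closed = TRUE)
  ab[theta_deg < ae[1]] <- NA_integer_
  data.frame(radial_bin = rb, angular_bin = ab,
             bin = (rb - 1L) * grid$n_angular + ab)
}

#' Build the binned stiffness landscape
#'
#' Per-bin median stiffness over the beads falling in each annular bin,
#' optionally restricted to one oscillation axis. Beads flagged as inside
#' the cell, with non-finite or non-positive stiffness, or beyond the
#' grid are excluded from the map (but counted in the accounting).
#'
#' @param beads data.frame with columns `distance`, `theta_deg`,
#'   `kappa_prime` and optionally `axis_angle_deg` and `inside`.
#' @param grid A [bin_grid()].
#' @param axis_filter Optional single axis (degrees) to restrict to.
#' @return Object of class `stiffness_map`: `median` and `count` matrices
#'   (radial x angular; `NA` median marks an empty bin), `grid`,
#'   `axis_filter`, `bin_beads` (list of row indices per bin) and
#'   `accounting` (in_range / out_of_range / inside / flagged counts).
#' @export
build_map <- function(beads, grid = bin_grid(), axis_filter = NULL) {
  if (nrow(beads) == 0L) stop("empty bead table")
  b <- beads
  if (!is.null(axis_filter) && "axis_angle_deg" %in% names(b))
    b <- b[b$axis_angle_deg == axis_filter, , drop = FALSE]
  if (nrow(b) == 0L) stop("no beads on the requested axis")
  inside <- if ("inside" %in% names(b)) as.logical(b$inside) else
    rep(FALSE, nrow(b))
  flagged <- !is.finite(b$kappa_prime) | b$kappa_prime <= 0
  asn <- assign_bin(b$distance, b$theta_deg, grid)
  out_of_range <- is.na(asn$bin) & !inside
  usable <- !inside & !flagged & !is.na(asn$bin)
  med <- matrix(NA_real_, grid$n_radial, grid$n_angular)
  cnt <- matrix(0L, grid$n_radial, grid$n_angular)
  bin_beads <- vector("list", grid$n_radial * grid$n_angular)
  for (idx in which(usable)) {
    i <- asn$radial_bin[idx]; j <- asn$angular_bin[idx]
    bin_beads[[(i - 1L) * grid$n_angular + j]] <-
      c(bin_beads[[(i - 1L) * grid$n_angular + j]], idx)
  }
  for (i in seq_len(grid$n_radial)) for (j in seq_len(grid$n_angular)) {
    rows <- bin_beads[[(i - 1L) * grid$n_angular + j]]
    cnt[i, j] <- length(rows)
    if (length(rows)) med[i, j] <- stats::median(b$kappa_prime[rows])
  }
  structure(list(median = med, count = cnt, grid = grid,
                 axis_filter = axis_filter, bin_beads = bin_beads,
                 accounting = c(total = nrow(b), in_range = sum(usable),
                                out_of_range = sum(out_of_range & !flagged),
                                inside = sum(inside),
                                flagged = sum(flagged & !inside &
                                                !out_of_range))),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d bins, %d beads in range",
              x$grid$n_radial, x$grid$n_angular, x$accounting["in_range"]))
  if (!is.null(x$axis_filter)) cat(", axis", x$axis_filter, "deg")
  cat("\nper-bin median kappa' (pN/um), radial x angular:\n")
  print(round(x$median, 3))
  invisible(x)
}

#' Polar-wedge plot of a stiffness landscape
#'
#' Draws the folded half-annulus bins shaded by median stiffness.
#'
#' @param x A `stiffness_map`.
#' @param palette Color ramp function (values low to high).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stiffness_map <- function(x, palette = grDevices::hcl.colors, ...) {
  re <- x$grid$radial_edges; ae <- x$grid$angular_edges
  rmax <- max(re)
  vals <- x$median
  rng <- range(vals, na.rm = TRUE)
  cols <- palette(64)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(0, rmax), asp = 1,
                 xlab = "um (front at 0 deg, right)", ylab = "um", ...)
  for (i in seq_len(x$grid$n_radial)) for (j in seq_len(x$grid$n_angular)) {
    v <- vals[i, j]
    col <- if (is.na(v)) "grey90" else
      cols[1 + round(63 * (v - rng[1]) / max(rng[2] - rng[1], 1e-12))]
    th <- seq(ae[j], ae[j + 1], length.out = 20) * pi / 180
    xx <- c(re[i] * cos(th), re[i + 1] * cos(rev(th)))
    yy <- c(re[i] * sin(th), re[i + 1] * sin(rev(th)))
    graphics::polygon(xx, yy, col = col, border = "white")
  }
  invisible(x)
}

#' Split beads into peri-cellular and distal subsets
#'
#' Peri-cellular: shortest distance below the cutoff (default 25 um, the
#' inner annulus); distal: at or beyond it.
#'
#' @param beads data.frame with a `distance` column.
#' @param cutoff Distance cutoff (um).
#' @return List with `peri` and `distal` data.frames.
#' @export
pericellular_split <- function(beads, cutoff = 25) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  list(peri = beads[beads$distance < cutoff, , drop = FALSE],
       distal = beads[beads$distance >= cutoff, , drop = FALSE])
}

#' Stiffness anisotropy across oscillation axes
#'
#' Reshapes per-bead, per-axis stiffness into a blocked matrix (one row
#' per bead, one column per axis) and applies the blocked Friedman
#' comparison; beads lacking any axis are dropped with a warning.
#'
#' @param beads data.frame with `bead_id`, `axis_angle_deg`,
#'   `kappa_prime`.
#' @param axes Axes expected for every bead.
#' @return The [friedman_axes()] result, with the per-axis medians as its
#'   effect summary.
#' @export
anisotropy_summary <- function(beads, axes = c(0, 45, 90, 135)) {
  need <- c("bead_id", "axis_angle_deg", "kappa_prime")
  if (!all(need %in% names(beads)))
    stop("beads must have columns ", paste(need, collapse = ", "))
  b <- beads[beads$axis_angle_deg %in% axes, , drop = FALSE]
  mat <- matrix(NA_real_, length(unique(b$bead_id)), length(axes),
                dimnames = list(NULL, paste0("axis", axes)))
  ids <- unique(b$bead_id)
  for (j in seq_along(axes)) {
    sub <- b[b$axis_angle_deg == axes[j], , drop = FALSE]
    mat[match(sub$bead_id, ids), j] <- sub$kappa_prime
  }
  friedman_axes(mat)
}
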