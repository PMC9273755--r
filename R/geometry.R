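# Cell-centric coordinate system: traced outline, centroid, long axis,
# front/rear assignment, per-bead shortest distance and folded angle.
#
# Coordinate convention: all geometry is done in physical coordinates
# (um, y axis pointing up). Image masks (origin top-left, y down) are
# converted on entry; angles are counterclockwise in the physical frame.

# polygon signed area, centroid and second central moments via the
# shoelace-based area integrals
.poly_moments <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100) stop("polygon has zero area")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum(cr * (x^2 + x * x2 + x2^2)) / 12    # integral of x^2 dA
  Iyy <- sum(cr * (y^2 + y * y2 + y2^2)) / 12    # integral of y^2 dA
  Ixy <- sum(cr * (x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y)) / 24
  list(area = abs(A),
       centroid = c(cx, cy),
       mu20 = Ixx / A - cx^2, mu02 = Iyy / A - cy^2,
       mu11 = Ixy / A - cx * cy)
}

# canonical long-axis unit vector: positive x component (positive y when
# the axis is vertical), so the numerically equivalent orientations 0 and
# 180 - eps give the same axis direction
.axis_unit <- function(orientation_deg) {
  u <- c(cos(orientation_deg * pi / 180), sin(orientation_deg * pi / 180))
  if (u[1] < -1e-12 || (abs(u[1]) <= 1e-12 && u[2] < 0)) u <- -u
  u
}

.orientation_from_mu <- function(mu20, mu02, mu11, tol = 1e-09) {
  scale <- max(mu20, mu02, abs(mu11), tol)
  degenerate <- abs(mu20 - mu02) < tol * scale && abs(mu11) < tol * scale
  ang <- if (degenerate) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ang <- ang %% 180
  list(orientation_deg = ang, degenerate = degenerate)
}

# O(n^2) segment-intersection test for polygon simplicity (small polygons)
.is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]))
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      if (ccw(a, c, d) * ccw(b, c, d) < 0 && ccw(a, b, c) * ccw(a, b, d) < 0)
        return(FALSE)
    }
  }
  TRUE
}

#' Cell geometry: outline, centroid, long axis and front direction
#'
#' @param boundary Closed simple polygon as an n x 2 matrix of vertices
#'   (um, physical coordinates, y up); the closing vertex need not be
#'   repeated.
#' @param mode How the reference (front) axis is defined: `"long_axis"`
#'   (front along the cell's long axis, the default for elongated,
#'   migrating cells), `"image_axis"` (front = image right, the convention
#'   for rounded non-migrating cells) or `"lysis_axis"` (front = away from
#'   a supplied direction of enzymatic matrix breakdown).
#' @param front_sign For `mode = "long_axis"`: +1 or -1, selecting which
#'   end of the long axis is the front (e.g. from [migration_front()]).
#' @param lysis_direction For `mode = "lysis_axis"`: length-2 vector
#'   pointing towards the degraded region; the front is the opposite
#'   direction.
#' @param validate Check polygon simplicity (O(n^2); skipped automatically
#'   for outlines with more than 400 vertices).
#' @return An object of class `cell_geometry` with fields `boundary`,
#'   `centroid`, `orientation_deg` (in [0, 180)), `front_direction`
#'   (unit vector), `mode`, and flags `degenerate` (isotropic shape).
#' @examples
#' cg <- make_ellipse_cell(a = 20, b = 10)
#' cg$orientation_deg
#' @export
cell_geometry <- function(boundary, mode = c("long_axis", "image_axis",
                                             "lysis_axis"),
                          front_sign = 1, lysis_direction = NULL,
                          validate = TRUE) {
  mode <- match.arg(mode)
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2L || nrow(boundary) < 3L)
    stop("boundary must be an n x 2 matrix with n >= 3")
  # drop explicit closing vertex
  n <- nrow(boundary)
  if (all(boundary[1, ] == boundary[n, ])) boundary <- boundary[-n, , drop = FALSE]
  if (validate && nrow(boundary) <= 400L && !.is_simple_polygon(boundary))
    stop("cell outline is not a simple polygon")
  m <- .poly_moments(boundary)
  ori <- .orientation_from_mu(m$mu20, m$mu02, m$mu11)
  if (!.point_in_polygon(m$centroid[1], m$centroid[2], boundary))
    stop("polygon centroid falls outside the polygon (non-convex artefact?)")

  front <- switch(mode,
    long_axis = {
      (if (front_sign >= 0) 1 else -1) * .axis_unit(ori$orientation_deg)
    },
    image_axis = c(1, 0),
    lysis_axis = {
      if (is.null(lysis_direction))
        stop("mode 'lysis_axis' requires lysis_direction")
      v <- -as.numeric(lysis_direction)
      v / sqrt(sum(v^2))
    })
  structure(list(boundary = boundary, centroid = m$centroid,
                 orientation_deg = ori$orientation_deg,
                 front_direction = front, mode = mode,
                 area = m$area, degenerate = ori$degenerate),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(paste0("<cell_geometry> %d vertices, centroid (%.2f, %.2f) um,",
                     " long axis %.1f deg, mode %s\n"),
              nrow(x$boundary), x$centroid[1], x$centroid[2],
              x$orientation_deg, x$mode))
  invisible(x)
}

# even-odd rule; px, py vectors
.point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (e in seq_along(x)) {
    crosses <- ((y[e] > py) != (y2[e] > py))
    if (any(crosses)) {
      xint <- x[e] + (py[crosses] - y[e]) / (y2[e] - y[e]) * (x2[e] - x[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Estimate centroid and long-axis orientation from a binary mask
#'
#' Centroid from first moments and orientation from the major principal
#' axis of the second central moments of the foreground pixels, the
#' standard regionprops-style shape orientation. The mask must contain
#' exactly one connected foreground component of at least 50 pixels.
#'
#' @param mask Binary matrix (rows = image y, top-left origin) or anything
#'   coercible; nonzero = foreground.
#' @param pixel_size Pixel size (um). All outputs are in um.
#' @param mode,front_sign,lysis_direction Passed to [cell_geometry()].
#' @return A [cell_geometry()] object; its boundary is the sub-pixel
#'   0.5-level contour of the mask. The `degenerate` flag is set for
#'   isotropic shapes (a circle), whose orientation is reported as 0.
#' @export
orientation_from_mask <- function(mask, pixel_size = 1, mode = "long_axis",
                                  front_sign = 1, lysis_direction = NULL) {
  m <- (as.matrix(mask) != 0) * 1L
  if (sum(m) == 0L) stop("mask has zero foreground area")
  lab <- EBImage::bwlabel(m)
  if (max(lab) != 1L) stop("mask must contain exactly one connected component")
  if (sum(m) < 50L) stop("foreground component smaller than 50 pixels")
  idx <- which(m == 1L, arr.ind = TRUE)
  # physical frame: x right, y up
  xs <- idx[, 2] * pixel_size
  ys <- (nrow(m) - idx[, 1] + 1L) * pixel_size
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  ori <- .orientation_from_mu(mu20, mu02, mu11, tol = 1e-03)

  cl <- grDevices::contourLines(
    x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m, levels = 0.5)
  if (length(cl) == 0L) stop("could not trace mask outline")
  len <- vapply(cl, function(ct) length(ct$x), integer(1))
  ct <- cl[[which.max(len)]]
  boundary <- cbind(ct$y * pixel_size,                    # image col -> x
                    (nrow(m) - ct$x + 1L) * pixel_size)   # image row -> y up
  cg <- cell_geometry(boundary, mode = mode, front_sign = front_sign,
                      lysis_direction = lysis_direction, validate = FALSE)
  cg$centroid <- c(cx, cy)
  cg$orientation_deg <- ori$orientation_deg
  cg$degenerate <- ori$degenerate
  if (cg$mode == "long_axis") {
    cg$front_direction <-
      (if (front_sign >= 0) 1 else -1) * .axis_unit(ori$orientation_deg)
  }
  cg
}

#' Shortest distance from bead positions to the cell outline
#'
#' Minimum point-to-segment Euclidean distance over all boundary edges.
#' Beads lying inside the polygon are reported with distance 0 and flagged.
#'
#' @param bead_xy Numeric length-2 vector or n x 2 matrix of positions (um).
#' @param boundary Simple polygon (n x 2 matrix, um) or a
#'   [cell_geometry()] object.
#' @return Numeric vector of distances (um) with attribute `inside`
#'   (logical vector).
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' shortest_distance(c(15, 5), sq)   # 5
#' @export
shortest_distance <- function(bead_xy, boundary) {
  if (inherits(boundary, "cell_geometry")) boundary <- boundary$boundary
  p <- if (is.null(dim(bead_xy))) matrix(bead_xy, ncol = 2) else as.matrix(bead_xy)
  ax <- boundary[, 1]; ay <- boundary[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  dmin <- rep(Inf, nrow(p))
  for (e in seq_along(ax)) {
    if (len2[e] == 0) {
      d2 <- (p[, 1] - ax[e])^2 + (p[, 2] - ay[e])^2
    } else {
      tt <- ((p[, 1] - ax[e]) * dx[e] + (p[, 2] - ay[e]) * dy[e]) / len2[e]
      tt <- pmin(1, pmax(0, tt))
      d2 <- (p[, 1] - (ax[e] + tt * dx[e]))^2 +
        (p[, 2] - (ay[e] + tt * dy[e]))^2
    }
    dmin <- pmin(dmin, d2)
  }
  d <- sqrt(dmin)
  inside <- .point_in_polygon(p[, 1], p[, 2], boundary)
  d[inside] <- 0
  attr(d, "inside") <- inside
  d
}

#' Folded angular position of a bead about the cell centroid
#'
#' Signed angle between the centroid-to-bead vector and the cell's front
#' direction, folded across the long axis into `[0, 180]` degrees under the
#' assumption of mirror symmetry: 0 = cell front, 180 = cell rear.
#'
#' @param bead_xy Length-2 vector or n x 2 matrix of positions (um).
#' @param cell A [cell_geometry()] object.
#' @return Numeric vector of folded angles in degrees.
#' @export
angular_position <- function(bead_xy, cell) {
  stopifnot(inherits(cell, "cell_geometry"))
  p <- if (is.null(dim(bead_xy))) matrix(bead_xy, ncol = 2) else as.matrix(bead_xy)
  vx <- p[, 1] - cell$centroid[1]
  vy <- p[, 2] - cell$centroid[2]
  if (any(vx == 0 & vy == 0)) stop("bead coincides with the cell centroid")
  f <- cell$front_direction
  ang <- atan2(vx * f[2] - vy * f[1], vx * f[1] + vy * f[2]) * 180 / pi
  abs(ang)    # fold across the axis: [-180, 180] -> [0, 180]
}

#' Determine the cell front from migration relative to fiducial beads
#'
#' Beads distal to the cell do not move between the two acquisitions and
#' serve as fiducial markers: the rigid field translation (stage drift) is
#' estimated from the matched bead lists by least squares and subtracted
#' from the centroid displacement. The front direction is the long-axis
#' direction onto which the residual displacement projects positively. If
#' the drift-corrected displacement projects by less than `threshold` um,
#' the cell is deemed non-migrating and the image-axis convention (front =
#' image right) is returned as a fallback.
#'
#' @param mask_before,mask_after Binary masks of the cell at the two times.
#' @param beads_before,beads_after Matched n x 2 matrices of fiducial bead
#'   positions (um), `n >= 3`.
#' @param pixel_size Pixel size (um) for the masks.
#' @param threshold Minimum drift-corrected projected displacement (um).
#' @return List with `front_direction` (unit vector), `mode`
#'   (`"long_axis"` or fallback `"image_axis"`), `residual` (drift-corrected
#'   centroid displacement, um) and `drift` (estimated field translation).
#' @export
migration_front <- function(mask_before, mask_after, beads_before,
                            beads_after, pixel_size = 1, threshold = 0.5) {
  bb <- as.matrix(beads_before); ba <- as.matrix(beads_after)
  if (!all(dim(bb) == dim(ba))) stop("bead lists must be matched (same size)")
  if (nrow(bb) < 3L) stop("need at least 3 matched fiducial beads")
  drift <- colMeans(ba - bb)   # least-squares rigid translation
  g0 <- orientation_from_mask(mask_before, pixel_size)
  g1 <- orientation_from_mask(mask_after, pixel_size)
  residual <- (g1$centroid - g0$centroid) - drift
  u <- .axis_unit(g0$orientation_deg)
  proj <- sum(residual * u)
  if (abs(proj) < threshold) {
    list(front_direction = c(1, 0), mode = "image_axis",
         residual = residual, drift = drift)
  } else {
    list(front_direction = sign(proj) * u, mode = "long_axis",
         residual = residual, drift = drift)
  }
}
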