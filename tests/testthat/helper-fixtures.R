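# Shared fixtures and independent oracles used across the test files.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

rotate_xy <- function(p, deg) {
  a <- deg * pi / 180
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  cbind(cos(a) * p[, 1] - sin(a) * p[, 2],
        sin(a) * p[, 1] + cos(a) * p[, 2])
}

# dense boundary-sampling oracle for point-to-polygon distance
dense_distance_oracle <- function(bead, poly, pts_per_edge = 500) {
  nv <- nrow(poly)
  dense <- do.call(rbind, lapply(seq_len(nv), function(i) {
    j <- if (i == nv) 1L else i + 1L
    tt <- seq(0, 1, length.out = pts_per_edge)
    cbind(poly[i, 1] + tt * (poly[j, 1] - poly[i, 1]),
          poly[i, 2] + tt * (poly[j, 2] - poly[i, 2]))
  }))
  min(sqrt((dense[, 1] - bead[1])^2 + (dense[, 2] - bead[2])^2))
}

random_star_polygon <- function(nv = 20, rmin = 5, rmax = 20) {
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- stats::runif(nv, rmin, rmax)
  cbind(rad * cos(ang), rad * sin(ang))
}

# Friedman chi-square statistic from first principles (rank formula)
friedman_stat_oracle <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
}

# rasterized ellipse mask (rows = image y), orientation counterclockwise
# in the physical (y-up) frame
ellipse_mask <- function(n = 201, a = 40, b = 20, deg = 0) {
  ctr <- (n + 1) / 2
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  phi <- deg * pi / 180
  xr <- (idx$c - ctr) * cos(phi) + (-(idx$r - ctr)) * sin(phi)
  yr <- -(idx$c - ctr) * sin(phi) + (-(idx$r - ctr)) * cos(phi)
  matrix(xr^2 / a^2 + yr^2 / b^2 <= 1, n, n)
}
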