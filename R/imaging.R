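# Image-derived quantities: 3-D pore sizing by distance-transform watershed,
# and per-cell immunofluorescence metrics from multi-channel stacks.
#
# The 3-D Euclidean distance transform uses the separable lower-envelope
# (parabola) algorithm; the watershed floods quantized distance levels from
# regional-maximum seeds (the h-maxima of the distance map, realized as
# regional maxima after quantizing the map in steps of h).

# exact 1-D squared distance transform (lower envelope of parabolas);
# f: squared-distance samples, w: grid spacing
.dt1d <- function(f, w) {
  n <- length(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  w2 <- w * w
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + w2 * q * q) - (f[vk] + w2 * vk * vk)) /
        (2 * w2 * (q - vk))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    vk <- v[k]
    d[q] <- w2 * (q - vk) * (q - vk) + f[vk]
  }
  d
}

# 3-D Euclidean distance transform: distance from each voxel of `mask`
# (TRUE = region of interest) to the nearest FALSE voxel, in physical units
.edt3d <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  # pass 1 (binary): nearest-zero distance along axis 1 by two scans
  d1 <- array(Inf, dm)
  d1[!mask] <- 0
  for (i in 2:dm[1]) {
    d1[i, , ] <- pmin(d1[i, , ], d1[i - 1L, , ] + spacing[1])
  }
  for (i in (dm[1] - 1L):1L) {
    d1[i, , ] <- pmin(d1[i, , ], d1[i + 1L, , ] + spacing[1])
  }
  f <- d1^2
  big <- sum((dm * spacing)^2)       # finite stand-in for Inf
  f[!is.finite(f)] <- big
  for (k in seq_len(dm[3]))          # pass 2: axis 2 (parabolas)
    for (i in seq_len(dm[1]))
      f[i, , k] <- .dt1d(f[i, , k], spacing[2])
  for (j in seq_len(dm[2]))          # pass 3: axis 3
    for (i in seq_len(dm[1]))
      f[i, j, ] <- .dt1d(f[i, j, ], spacing[3])
  sqrt(f)
}

# index shifts of the 6 face neighbors for an array of dim dm, as a matrix
# of linear-index offsets plus a validity test done by padding
.shift_arr <- function(a, d, dm, fill) {
  # shift array a by one voxel along axis d in direction sign(d)
  out <- array(fill, dm)
  if (d == 1L) out[2:dm[1], , ] <- a[1:(dm[1] - 1L), , ]
  if (d == -1L) out[1:(dm[1] - 1L), , ] <- a[2:dm[1], , ]
  if (d == 2L) out[, 2:dm[2], ] <- a[, 1:(dm[2] - 1L), ]
  if (d == -2L) out[, 1:(dm[2] - 1L), ] <- a[, 2:dm[2], ]
  if (d == 3L) out[, , 2:dm[3]] <- a[, , 1:(dm[3] - 1L)]
  if (d == -3L) out[, , 1:(dm[3] - 1L)] <- a[, , 2:dm[3]]
  out
}

# label connected components of a 3-D logical array by simultaneous
# max-label propagation (components get the largest initial index they
# contain; renumbered consecutively afterwards)
.label3d <- function(mask, box = FALSE) {
  dm <- dim(mask)
  lab <- array(0, dm)
  lab[mask] <- seq_len(sum(mask))
  shifts <- if (box) NULL else c(1L, -1L, 2L, -2L, 3L, -3L)
  repeat {
    new <- lab
    if (box) {
      new <- .boxmax(new, dm, fill = 0)
    } else {
      for (s in shifts) new <- pmax(new, .shift_arr(lab, s, dm, 0))
    }
    new[!mask] <- 0
    if (all(new == lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, dm)
  out[mask] <- match(lab[mask], ids)
  out
}

# grayscale geodesic reconstruction of `marker` under `f` by iterative
# 6-neighbor dilation (both with -Inf outside mask)
.reconstruct <- function(marker, f, dm) {
  R <- marker
  repeat {
    Rn <- R
    for (s in c(1L, -1L, 2L, -2L, 3L, -3L))
      Rn <- pmax(Rn, .shift_arr(R, s, dm, -Inf))
    Rn <- pmin(Rn, f)
    if (isTRUE(all(Rn == R | (is.infinite(Rn) & is.infinite(R))))) break
    R <- Rn
  }
  R
}

# 26-neighborhood (3x3x3 box) maximum filter, separable by axis
.boxmax <- function(a, dm, fill = -Inf) {
  for (ax in c(1L, 2L, 3L))
    a <- pmax(a, .shift_arr(a, ax, dm, fill), .shift_arr(a, -ax, dm, fill))
  a
}

# seeded watershed on a distance map: seeds are the regional maxima of the
# h-maxima transform (geodesic reconstruction of dist - h under dist), so
# maxima shallower than h merge with their neighbors; flooding then
# descends quantized distance levels, never creating new regions
.watershed3d <- function(dist, mask, h = 1) {
  dm <- dim(dist)
  f <- dist; f[!mask] <- -Inf
  R <- .reconstruct(f - h, f, dm)
  seeds <- mask & R >= .boxmax(R, dm)
  lab <- .label3d(seeds, box = TRUE)
  qstep <- h / 2
  q <- floor(dist / qstep)
  q[!mask] <- -1
  for (lev in sort(unique(q[mask & lab == 0]), decreasing = TRUE)) {
    front <- mask & q == lev & lab == 0L
    repeat {
      assigned <- FALSE
      for (s in c(1L, -1L, 2L, -2L, 3L, -3L)) {
        nb <- .shift_arr(lab, s, dm, 0L)
        take <- front & lab == 0L & nb > 0L
        if (any(take)) { lab[take] <- nb[take]; assigned <- TRUE }
      }
      front <- front & lab == 0L
      if (!assigned || !any(front)) break
    }
  }
  # voxels on plateaus that had no labeled neighbor when their level was
  # flooded: attach to the nearest labeled region
  while (any(un <- mask & lab == 0L)) {
    progress <- FALSE
    for (s in c(1L, -1L, 2L, -2L, 3L, -3L)) {
      nb <- .shift_arr(lab, s, dm, 0L)
      take <- un & nb > 0L
      if (any(take)) { lab[take] <- nb[take]; progress <- TRUE }
    }
    if (!progress) {  # isolated component without a seed (should not occur)
      sub <- .label3d(un)
      lab[un] <- sub[un] + max(lab)
      break
    }
    un <- mask & lab == 0L
    if (!any(un)) break
  }
  lab
}

#' Pore-size distribution of a fibrous volume
#'
#' Identifies individual pores of a binary fiber network by a 3-D
#' distance-transform watershed and reports, for each pore, the maximum
#' diameter of an inscribed sphere: the Euclidean distance transform of
#' the pore phase is computed in physical units, pores are split by
#' flooding the (negated) distance map from its regional maxima (h-maxima
#' seeds with merge tolerance `h`), and each pore's diameter is twice the
#' largest distance-transform value it contains. Pores touching the volume
#' border are excluded because their inscribed sphere is truncated.
#'
#' @param stack 3-D binary array; foreground (nonzero) = fiber phase.
#' @param voxel_size Voxel size (um); scalar or length-3 for anisotropic
#'   voxels.
#' @param h Watershed merge tolerance in voxel units (default 1).
#' @return Object of class `pore_sizes`: list with `diameters` (um, sorted
#'   decreasing), `n_pores`, `voxel_size`; attribute `labels` holds the
#'   pore label array.
#' @examples
#' v <- gen_fiber_stack(c(32, 32, 32), n_fibers = 0, voxel_size = 1,
#'                      cavities = list(list(center = c(16, 16, 16),
#'                                           diameter = 10)))
#' pore_size_distribution(v, voxel_size = 1)$diameters
#' @export
pore_size_distribution <- function(stack, voxel_size = attr(stack, "voxel_size"),
                                   h = 1) {
  if (is.null(voxel_size)) voxel_size <- 1
  spacing <- if (length(voxel_size) == 1L) rep(voxel_size, 3) else voxel_size
  vol <- array(as.integer(stack != 0), dim(stack))
  pore <- vol == 0L
  if (!any(pore))
    return(structure(list(diameters = numeric(0), n_pores = 0L,
                          voxel_size = voxel_size), class = "pore_sizes"))
  if (all(pore)) stop("volume contains no fiber phase")
  dist <- .edt3d(pore, spacing)
  lab <- .watershed3d(dist, pore, h = h * min(spacing))
  dm <- dim(vol)
  border <- array(FALSE, dm)
  border[c(1L, dm[1]), , ] <- TRUE
  border[, c(1L, dm[2]), ] <- TRUE
  border[, , c(1L, dm[3])] <- TRUE
  exclude <- unique(lab[border & lab > 0L])
  keep <- setdiff(sort(unique(lab[lab > 0L])), exclude)
  diams <- vapply(keep, function(l) 2 * max(dist[lab == l]), numeric(1))
  structure(list(diameters = sort(diams, decreasing = TRUE),
                 n_pores = length(diams), voxel_size = voxel_size),
            labels = lab, class = "pore_sizes")
}

#' @export
print.pore_sizes <- function(x, ...) {
  cat(sprintf("<pore_sizes> %d pores, median diameter %.3g um\n",
              x$n_pores, if (x$n_pores) stats::median(x$diameters) else NA))
  invisible(x)
}

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack 3-D array (rows x cols x planes) or a 2-D matrix (a
#'   single plane, returned unchanged).
#' @return 2-D matrix of voxelwise maxima over z.
#' @export
max_intensity_projection <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  stopifnot(length(dim(zstack)) == 3L, dim(zstack)[3] >= 1L)
  do.call(pmax, lapply(seq_len(dim(zstack)[3]), function(z) zstack[, , z]))
}

.otsu_mask <- function(img, channel, sigma = 1) {
  rng <- range(img)
  if (diff(rng) == 0)
    stop("channel '", channel, "' is empty (constant intensity)")
  x <- (img - rng[1]) / diff(rng)
  xs <- if (sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma)) else x
  xs > EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
}

.largest_cc <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1L))
  if (max(lab) <= 1L) return(matrix(as.logical(mask), nrow(lab), ncol(lab)))
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Segment nucleus, F-actin and fibronectin channels
#'
#' Gaussian smoothing (sigma = 1 px) followed by Otsu thresholding for the
#' extended nucleus and F-actin structures; the punctate fibronectin
#' channel is Otsu-thresholded without smoothing, which would dilute
#' single-pixel puncta below threshold and bias the partition. The
#' F-actin and nucleus masks are reduced to their largest connected
#' component and the nucleus mask is intersected with the filled F-actin
#' mask so the nucleus lies within the cell.
#'
#' @param mip_nucleus,mip_actin,mip_fibronectin 2-D intensity images of
#'   identical size (maximum-intensity projections).
#' @param sigma Smoothing SD (px) for the nucleus/actin channels.
#' @return List of logical masks `nucleus`, `actin`, `fibronectin`.
#' @export
segment_channels <- function(mip_nucleus, mip_actin, mip_fibronectin,
                             sigma = 1) {
  if (!all(dim(mip_nucleus) == dim(mip_actin)) ||
      !all(dim(mip_actin) == dim(mip_fibronectin)))
    stop("channel images must have identical dimensions")
  actin <- .largest_cc(.otsu_mask(mip_actin, "actin", sigma))
  actin_filled <- as.matrix(EBImage::fillHull(actin * 1L)) > 0
  nucleus <- .largest_cc(.otsu_mask(mip_nucleus, "nucleus", sigma)) &
    actin_filled
  fibro <- .otsu_mask(mip_fibronectin, "fibronectin", sigma = 0)
  list(nucleus = nucleus, actin = actin, fibronectin = fibro)
}

#' Nuclear/cytoplasmic YAP ratio
#'
#' Mean YAP intensity inside the nucleus divided by mean YAP intensity in
#' the cytoplasm (the F-actin support minus the nucleus).
#'
#' @param yap_mip 2-D YAP intensity image.
#' @param nucleus_mask,actin_mask Logical masks (nucleus is intersected
#'   with the actin support).
#' @return Dimensionless ratio.
#' @export
yap_ratio <- function(yap_mip, nucleus_mask, actin_mask) {
  nuc <- nucleus_mask & actin_mask
  cyto <- actin_mask & !nuc
  if (!any(cyto)) stop("cytoplasm mask is empty")
  if (!any(nuc)) stop("nucleus mask is empty")
  mean(yap_mip[nuc]) / mean(yap_mip[cyto])
}

#' Fibronectin partition outside the cell
#'
#' Percentage of fibronectin-positive pixels found outside the F-actin
#' mask: `100 * (1 - |fn intersect actin| / |fn|)`.
#'
#' @param fn_mask,actin_mask Logical masks.
#' @return Percentage in `[0, 100]`.
#' @export
fibronectin_partition <- function(fn_mask, actin_mask) {
  n_fn <- sum(fn_mask)
  if (n_fn == 0) stop("fibronectin mask is empty")
  100 * (1 - sum(fn_mask & actin_mask) / n_fn)
}

#' Cell shape metrics: circularity and solidity
#'
#' Area from the pixel count; perimeter from the sub-pixel 0.5-level
#' contour of the lightly smoothed mask (pixel-edge counting would bias a
#' disk's circularity by tens of percent); convex area from the convex
#' hull of the contour. Circularity = `4 * pi * Area / Perimeter^2`,
#' solidity = `Area / ConvexArea`.
#'
#' @param mask Logical or 0/1 matrix with a single connected foreground
#'   component.
#' @param pixel_size Pixel size (um).
#' @return List with `circularity`, `solidity`, `area` (um^2),
#'   `perimeter` (um), `convex_area` (um^2).
#' @export
shape_metrics <- function(mask, pixel_size = 1) {
  m <- (as.matrix(mask) != 0) * 1
  if (sum(m) == 0) stop("mask is empty")
  if (max(EBImage::bwlabel(m)) != 1L)
    stop("mask must contain a single connected component")
  area <- sum(m) * pixel_size^2
  pad <- 4L
  mp <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mp), sigma = 1))
  cl <- grDevices::contourLines(seq_len(nrow(mp)), seq_len(ncol(mp)), sm,
                                levels = 0.5)
  if (length(cl) == 0L) stop("could not trace mask contour")
  lens <- vapply(cl, function(ct) {
    sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2))
  }, numeric(1))
  ct <- cl[[which.max(lens)]]
  perim <- max(lens) * pixel_size
  hull_idx <- grDevices::chull(ct$x, ct$y)
  hx <- ct$x[hull_idx]; hy <- ct$y[hull_idx]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 *
    pixel_size^2
  list(circularity = 4 * pi * area / perim^2,
       solidity = min(1, area / hull_area),
       area = area, perimeter = perim, convex_area = hull_area)
}
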