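# Synthetic fiber-network volumes and immunofluorescence stacks.

#' Generate a synthetic fibrous binary volume
#'
#' Random line-segment fibers spanning the volume, dilated to
#' `fiber_radius`; optional spherical cavities of known diameter carved out
#' of the fiber phase so pore-sizing can be validated against ground truth.
#' Foreground (1) is the fiber phase, background (0) the pore phase.
#'
#' @param shape Integer length-3 volume size in voxels, each `>= 32`.
#' @param n_fibers Number of fibers (`>= 0`).
#' @param fiber_radius Fiber radius in voxels; must be `< min(shape)/2`.
#' @param voxel_size Isotropic voxel size (um).
#' @param cavities Optional list of `list(center = c(x, y, z), diameter)`
#'   (voxel units) spheres carved out (set to pore phase) after fiber
#'   placement.
#' @param seed Integer seed.
#' @return 3-D integer array (0/1) with attributes `voxel_size`, `cavities`
#'   (with diameters in voxels and um) and `seed`.
#' @examples
#' v <- gen_fiber_stack(c(32, 32, 32), n_fibers = 0, voxel_size = 0.5,
#'                      cavities = list(list(center = c(16, 16, 16),
#'                                           diameter = 10)), seed = 1)
#' @export
gen_fiber_stack <- function(shape = c(48, 48, 48), n_fibers = 30,
                            fiber_radius = 1.5, voxel_size = 0.2,
                            cavities = NULL, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must be three dimensions, each >= 32 voxels")
  if (fiber_radius >= min(shape) / 2)
    stop("fiber_radius must be < min(shape)/2")
  set.seed(seed)
  # with no fibers the volume is a solid block, the fixture mode in which
  # carved cavities are the only pores
  vol <- array(if (n_fibers == 0L) 1L else 0L, shape)
  if (n_fibers > 0) {
    # integer offsets of the dilation ball
    r <- fiber_radius
    rng <- -ceiling(r):ceiling(r)
    off <- as.matrix(expand.grid(dx = rng, dy = rng, dz = rng))
    off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
    diag_len <- sqrt(sum(shape^2))
    for (i in seq_len(n_fibers)) {
      p0 <- stats::runif(3) * shape
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      tt <- seq(-diag_len, diag_len, by = 0.5)
      pts <- cbind(p0[1] + tt * u[1], p0[2] + tt * u[2], p0[3] + tt * u[3])
      keep <- pts[, 1] >= 1 & pts[, 1] <= shape[1] &
        pts[, 2] >= 1 & pts[, 2] <= shape[2] &
        pts[, 3] >= 1 & pts[, 3] <= shape[3]
      pts <- round(pts[keep, , drop = FALSE])
      if (nrow(pts) == 0L) next
      vox <- pts[rep(seq_len(nrow(pts)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(pts)), , drop = FALSE]
      ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
        vox[, 2] >= 1 & vox[, 2] <= shape[2] &
        vox[, 3] >= 1 & vox[, 3] <= shape[3]
      vol[vox[ok, , drop = FALSE]] <- 1L
    }
  }
  carved <- list()
  if (!is.null(cavities)) {
    ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
    for (cv in cavities) {
      ctr <- cv$center; rad <- cv$diameter / 2
      ix <- ax[abs(ax - ctr[1]) <= rad]
      iy <- ay[abs(ay - ctr[2]) <= rad]
      iz <- az[abs(az - ctr[3]) <= rad]
      g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
      d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
      vol[g[d2 <= rad^2, , drop = FALSE]] <- 0L
      carved[[length(carved) + 1L]] <-
        list(center = ctr, diameter_vox = cv$diameter,
             diameter_um = cv$diameter * voxel_size)
    }
  }
  attr(vol, "voxel_size") <- voxel_size
  attr(vol, "cavities") <- carved
  attr(vol, "seed") <- seed
  vol
}

#' Generate a synthetic 4-channel immunofluorescence z-stack
#'
#' Builds a cell as an outer ellipse (F-actin support) containing an inner
#' elliptical nucleus, with per-channel intensities constructed so that the
#' ground-truth readouts hold exactly before noise: mean YAP intensity in
#' the nucleus divided by mean YAP intensity in the cytoplasm equals
#' `yap_ratio_true`, and the stated fraction of fibronectin-positive voxels
#' lies outside the F-actin support.
#'
#' @param shape_params List with elements `size` (c(rows, cols, planes)),
#'   `cell_radii` (outer semi-axes, px), `nucleus_radii` (px),
#'   `orientation_deg`, optional `center` (row, col; default image center)
#'   and `nucleus_offset` (px).
#' @param yap_ratio_true Nuclear/cytoplasmic YAP ratio, `> 0`.
#' @param fn_outside_frac_true Fraction of fibronectin voxels outside the
#'   cell, in `[0, 1]`.
#' @param noise_sd Gaussian noise SD added to every channel (intensity
#'   units; foreground intensity is 200, cytoplasmic YAP 100).
#' @param n_fn Number of fibronectin-positive voxels per plane.
#' @param seed Integer seed.
#' @return Named list of 3-D arrays `nucleus`, `actin`, `yap`,
#'   `fibronectin`, with attribute `truth` (generative masks and values).
#' @export
gen_cell_image <- function(shape_params = list(), yap_ratio_true = 1.5,
                           fn_outside_frac_true = 0.3, noise_sd = 0,
                           n_fn = 300, seed = 1) {
  sp <- utils::modifyList(
    list(size = c(96, 96, 3), cell_radii = c(35, 18),
         nucleus_radii = c(12, 8), orientation_deg = 0,
         center = NULL, nucleus_offset = c(0, 0)), shape_params)
  if (yap_ratio_true <= 0) stop("yap_ratio_true must be > 0")
  if (fn_outside_frac_true < 0 || fn_outside_frac_true > 1)
    stop("fn_outside_frac_true must lie in [0, 1]")
  nr <- sp$size[1]; nc <- sp$size[2]; nz <- sp$size[3]
  ctr <- if (is.null(sp$center)) c(nr, nc) / 2 else sp$center
  phi <- sp$orientation_deg * pi / 180
  gr <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  rel_r <- gr$r - ctr[1]; rel_c <- gr$c - ctr[2]
  # rotate into the ellipse frame (columns = x, rows = y)
  ex <- rel_c * cos(phi) + rel_r * sin(phi)
  ey <- -rel_c * sin(phi) + rel_r * cos(phi)
  cell2d <- matrix((ex / sp$cell_radii[1])^2 + (ey / sp$cell_radii[2])^2 <= 1,
                   nr, nc)
  nctr <- ctr + sp$nucleus_offset
  nex <- (gr$c - nctr[2]) * cos(phi) + (gr$r - nctr[1]) * sin(phi)
  ney <- -(gr$c - nctr[2]) * sin(phi) + (gr$r - nctr[1]) * cos(phi)
  nuc2d <- matrix((nex / sp$nucleus_radii[1])^2 +
                    (ney / sp$nucleus_radii[2])^2 <= 1, nr, nc)
  if (any(nuc2d & !cell2d))
    stop("nucleus is not contained in the cell shape")
  cyto2d <- cell2d & !nuc2d

  bg <- 10; fg <- 200; yap_cyto <- 100
  mk <- function(fg_mask, fg_val) {
    pl <- matrix(bg, nr, nc); pl[fg_mask] <- fg_val
    array(rep(pl, nz), c(nr, nc, nz))
  }
  nucleus <- mk(nuc2d, fg)
  actin <- mk(cell2d, fg)
  yap <- mk(cyto2d, yap_cyto)
  for (z in seq_len(nz)) yap[, , z][nuc2d] <- yap_cyto * yap_ratio_true

  set.seed(seed)
  # one punctate 2-D pattern replicated across z, so the MIP preserves the
  # constructed inside/outside pixel counts exactly
  out_idx <- which(!cell2d); in_idx <- which(cell2d)
  n_out <- round(n_fn * fn_outside_frac_true); n_in <- n_fn - n_out
  pl <- matrix(0, nr, nc)
  if (n_out > 0) pl[sample(out_idx, min(n_out, length(out_idx)))] <- fg
  if (n_in > 0) pl[sample(in_idx, min(n_in, length(in_idx)))] <- fg
  fn <- array(rep(pl, nz), c(nr, nc, nz))
  if (noise_sd > 0) {
    nvox <- nr * nc * nz
    nucleus <- nucleus + stats::rnorm(nvox, sd = noise_sd)
    actin <- actin + stats::rnorm(nvox, sd = noise_sd)
    yap <- yap + stats::rnorm(nvox, sd = noise_sd)
    fn <- fn + stats::rnorm(nvox, sd = noise_sd)
  }
  out <- list(nucleus = nucleus, actin = actin, yap = yap, fibronectin = fn)
  attr(out, "truth") <- list(yap_ratio = yap_ratio_true,
                             fn_outside_frac = fn_outside_frac_true,
                             nucleus_mask = nuc2d, cell_mask = cell2d,
                             noise_sd = noise_sd, seed = seed)
  out
}
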