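# Columnar signal files with JSON sidecars, geometry JSON, map output and
# TIFF stacks. Every writer stores the generating parameters and seed so
# ground truth round-trips unchanged.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".json")

.medium_to_list <- function(m)
  list(kappa_m = m$kappa_m, gamma = m$gamma, temperature = m$temperature,
       msd_exponent = m$msd_exponent)

.medium_from_list <- function(l)
  medium_params(l$kappa_m, l$gamma, l$temperature,
                if (is.null(l$msd_exponent)) NULL else l$msd_exponent)

#' Write / read AMR QPD signals as CSV plus JSON sidecar
#'
#' The CSV holds `time_s`, `trapQPD_V`, `detQPD_V`; the sidecar holds the
#' sampling metadata, the generating parameters, the seed and the
#' ground-truth complex stiffness, so synthetic records round-trip with
#' their truth intact.
#'
#' @param signals List with `trapQPD`/`detQPD` [qpd_series()] (see
#'   [gen_amr_signals()]).
#' @param path CSV file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_amr_signals <- function(signals, path) {
  ts <- signals$detQPD
  n <- length(ts$samples)
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1) / ts$sampling_rate,
    trapQPD_V = signals$trapQPD$samples,
    detQPD_V = ts$samples), path, row.names = FALSE)
  gt <- attr(signals, "ground_truth")
  meta <- list(sampling_rate = ts$sampling_rate, axis_angle = ts$axis_angle,
               bead_id = ts$bead_id)
  if (!is.null(gt)) {
    meta$ground_truth <- list(
      kappa_star_re = Re(gt$kappa_star), kappa_star_im = Im(gt$kappa_star),
      medium = .medium_to_list(gt$medium),
      trap = unclass(gt$trap)[c("k_trap", "amplitude", "frequency",
                                "axis_angle", "volts_per_um_det",
                                "volts_per_um_trap")],
      seed = gt$seed, thermal = gt$thermal)
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = 17, null = "null")
  invisible(path)
}

#' @rdname write_amr_signals
#' @export
read_amr_signals <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  bead_id <- if (is.null(meta$bead_id)) NULL else meta$bead_id
  out <- list(
    trapQPD = qpd_series(d$trapQPD_V, meta$sampling_rate, "trapQPD",
                         meta$axis_angle, bead_id),
    detQPD = qpd_series(d$detQPD_V, meta$sampling_rate, "detQPD",
                        meta$axis_angle, bead_id))
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    attr(out, "ground_truth") <- list(
      kappa_star = complex(real = g$kappa_star_re,
                           imaginary = g$kappa_star_im),
      medium = .medium_from_list(g$medium),
      trap = do.call(trap_params, g$trap),
      seed = g$seed, thermal = g$thermal,
      sampling_rate = meta$sampling_rate)
  }
  out
}

#' Write / read a PMR trajectory as CSV plus JSON sidecar
#'
#' @param traj A `trajectory` (see [gen_pmr_trajectory()]).
#' @param path CSV file path.
#' @return `path`, invisibly; `read_trajectory` returns the `trajectory`
#'   with its analytic-MSD attribute rebuilt from the stored parameters.
#' @export
write_trajectory <- function(traj, path) {
  n <- length(traj$position)
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1) / traj$sampling_rate,
    position_um = traj$position), path, row.names = FALSE)
  gt <- attr(traj, "ground_truth")
  jsonlite::write_json(
    list(sampling_rate = traj$sampling_rate, duration = traj$duration,
         medium = .medium_to_list(gt$medium), seed = gt$seed),
    .sidecar_path(path), auto_unbox = TRUE, digits = 17, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  medium <- .medium_from_list(meta$medium)
  kBT <- medium$kBT; km <- medium$kappa_m; g <- medium$gamma
  msd_fun <- if (km == 0) {
    function(tau) 2 * (kBT / g) * tau
  } else {
    function(tau) 2 * kBT / km * (1 - exp(-km * tau / g))
  }
  structure(list(position = d$position_um,
                 sampling_rate = meta$sampling_rate,
                 duration = meta$duration),
            analytic_msd = msd_fun,
            ground_truth = list(medium = medium, seed = meta$seed),
            class = "trajectory")
}

#' Serialize cell geometry to JSON
#'
#' @param cell A [cell_geometry()].
#' @param path JSON path.
#' @return `path` invisibly; `read_cell_geometry` reconstructs the object.
#' @export
write_cell_geometry <- function(cell, path) {
  jsonlite::write_json(
    list(boundary = unname(as.matrix(cell$boundary)),
         centroid = cell$centroid,
         orientation_deg = cell$orientation_deg,
         front_direction = cell$front_direction,
         mode = cell$mode, degenerate = cell$degenerate),
    path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}

#' @rdname write_cell_geometry
#' @export
read_cell_geometry <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  cg <- cell_geometry(l$boundary, mode = l$mode,
                      lysis_direction = if (l$mode == "lysis_axis")
                        -l$front_direction else NULL,
                      validate = FALSE)
  cg$centroid <- l$centroid
  cg$orientation_deg <- l$orientation_deg
  cg$front_direction <- l$front_direction
  cg$degenerate <- l$degenerate
  cg
}

#' Write a stiffness map as JSON plus a tidy long-format CSV
#'
#' @param map A `stiffness_map`.
#' @param path_json,path_csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the long-format data.frame.
#' @export
write_map <- function(map, path_json = NULL, path_csv = NULL) {
  g <- map$grid
  long <- expand.grid(radial_bin = seq_len(g$n_radial),
                      angular_bin = seq_len(g$n_angular))
  long$radial_lo <- g$radial_edges[long$radial_bin]
  long$radial_hi <- g$radial_edges[long$radial_bin + 1L]
  long$angular_lo <- g$angular_edges[long$angular_bin]
  long$angular_hi <- g$angular_edges[long$angular_bin + 1L]
  long$count <- map$count[cbind(long$radial_bin, long$angular_bin)]
  long$median_kappa <- map$median[cbind(long$radial_bin, long$angular_bin)]
  long <- long[order(long$radial_bin, long$angular_bin), ]
  if (!is.null(path_json))
    jsonlite::write_json(
      list(radial_edges = g$radial_edges, angular_edges = g$angular_edges,
           axis_filter = map$axis_filter, accounting = as.list(map$accounting),
           bins = long),
      path_json, auto_unbox = TRUE, digits = 17, null = "null", na = "null")
  if (!is.null(path_csv))
    utils::write.csv(long, path_csv, row.names = FALSE)
  invisible(long)
}

#' Write / read a 3-D stack as multi-page TIFF
#'
#' Values are scaled to [0, 1] for storage; the scale and voxel size go
#' into a JSON sidecar so intensities round-trip.
#'
#' @param stack 3-D numeric array.
#' @param path TIFF path.
#' @param voxel_size Voxel size (um), scalar or length 3.
#' @return `path` invisibly; `read_stack` returns the array with
#'   `voxel_size` attribute.
#' @export
write_stack <- function(stack, path, voxel_size = attr(stack, "voxel_size")) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output")
  mx <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(z) pmax(stack[, , z] / mx, 0))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = mx, voxel_size = voxel_size,
                            dim = dim(stack)),
                       .sidecar_path(path), auto_unbox = TRUE, digits = 17,
                       null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input")
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, meta$dim)
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]] * meta$scale
  attr(arr, "voxel_size") <- meta$voxel_size
  arr
}
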