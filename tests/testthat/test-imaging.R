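# Pore sizing, projections, segmentation and per-cell metrics.

test_that("inscribed-sphere diameters are recovered from carved volumes", {
  v <- gen_fiber_stack(c(32, 32, 32), n_fibers = 0, voxel_size = 1,
                       cavities = list(list(center = c(16, 16, 16),
                                            diameter = 10)))
  p <- pore_size_distribution(v, voxel_size = 1)
  expect_equal(p$n_pores, 1L)
  expect_lt(abs(p$diameters - 10), 1)
  # two spheres split by the watershed despite a thin wall
  v2 <- gen_fiber_stack(c(40, 40, 40), n_fibers = 0, voxel_size = 1,
                        cavities = list(list(center = c(12, 20, 20),
                                             diameter = 8),
                                        list(center = c(27, 20, 20),
                                             diameter = 12)))
  p2 <- pore_size_distribution(v2, voxel_size = 1)
  expect_equal(p2$n_pores, 2L)
  expect_lt(abs(sort(p2$diameters)[1] - 8), 1)
  expect_lt(abs(sort(p2$diameters)[2] - 12), 1)
  # solid block: no pores; all-pore volume: rejected
  solid <- gen_fiber_stack(c(32, 32, 32), n_fibers = 0)
  expect_equal(pore_size_distribution(solid, 1)$n_pores, 0L)
  expect_error(pore_size_distribution(array(0L, c(32, 32, 32)), 1),
               "no fiber")
  # physical units: diameters scale with voxel size
  p_half <- pore_size_distribution(v, voxel_size = 0.5)
  expect_equal(p_half$diameters, p$diameters * 0.5)
})

test_that("pore diameters stay below the carved truth plus one voxel", {
  # fibers dense enough that the carved cavity is the largest pore
  v <- gen_fiber_stack(c(40, 40, 40), n_fibers = 60, fiber_radius = 1.5,
                       voxel_size = 1, seed = 2,
                       cavities = list(list(center = c(20, 20, 20),
                                            diameter = 12)))
  p <- pore_size_distribution(v, voxel_size = 1)
  expect_lte(max(p$diameters), 12 + 1)
})

test_that("maximum-intensity projection equals the brute-force loop", {
  set.seed(8)
  st <- array(stats::rnorm(20 * 15 * 6), c(20, 15, 6))
  mip <- max_intensity_projection(st)
  oracle <- matrix(0, 20, 15)
  for (i in 1:20) for (j in 1:15) oracle[i, j] <- max(st[i, j, ])
  expect_equal(mip, oracle)
  expect_equal(max_intensity_projection(st[, , 1, drop = TRUE]),
               st[, , 1])
  expect_true(all(max_intensity_projection(array(0, c(5, 5, 3))) == 0))
})

test_that("channel segmentation recovers the generative supports", {
  img <- gen_cell_image(yap_ratio_true = 1.5, fn_outside_frac_true = 0.3,
                        noise_sd = 0, seed = 1)
  m <- segment_channels(max_intensity_projection(img$nucleus),
                        max_intensity_projection(img$actin),
                        max_intensity_projection(img$fibronectin))
  truth <- attr(img, "truth")
  expect_gt(jaccard(m$actin, truth$cell_mask), 0.98)
  expect_gt(jaccard(m$nucleus, truth$nucleus_mask), 0.95)
  # bimodal synthetic channel: mask equals the foreground support
  bi <- matrix(10, 40, 40); bi[10:20, 10:20] <- 200
  mb <- segment_channels(bi, bi, bi)
  expect_identical(unname(mb$actin), unname(bi == 200))
  expect_error(segment_channels(matrix(1, 5, 5), matrix(1, 5, 5),
                                matrix(1, 5, 5)), "actin")
  expect_error(segment_channels(bi, bi, matrix(1, 4, 4)), "dimensions")
  # 10% noise: Jaccard against truth at least 0.9 across seeds
  jac <- vapply(1:10, function(s) {
    im <- gen_cell_image(noise_sd = 20, seed = s)
    ms <- segment_channels(max_intensity_projection(im$nucleus),
                           max_intensity_projection(im$actin),
                           max_intensity_projection(im$fibronectin))
    jaccard(ms$actin, attr(im, "truth")$cell_mask)
  }, numeric(1))
  expect_gt(min(jac), 0.9)
})

test_that("YAP ratio and fibronectin partition behave as constructed", {
  img <- gen_cell_image(yap_ratio_true = 2, noise_sd = 0, seed = 1)
  tr <- attr(img, "truth")
  yap <- max_intensity_projection(img$yap)
  expect_equal(yap_ratio(yap, tr$nucleus_mask, tr$cell_mask), 2)
  expect_equal(yap_ratio(matrix(7, 96, 96), tr$nucleus_mask, tr$cell_mask),
               1)
  # intensity-scale invariance
  expect_equal(yap_ratio(3.7 * yap, tr$nucleus_mask, tr$cell_mask), 2)
  expect_error(yap_ratio(yap, tr$cell_mask, tr$cell_mask), "cytoplasm")
  # partition by construction: 30 of 100 pixels outside -> 30%
  actin <- matrix(FALSE, 50, 50); actin[11:40, 11:40] <- TRUE
  fn <- matrix(FALSE, 50, 50)
  fn[cbind(rep(1:10, 3), rep(1:3, each = 10))] <- TRUE   # 30 outside
  fn[cbind(rep(15:24, 7), rep(15:21, each = 10))] <- TRUE # 70 inside
  expect_equal(fibronectin_partition(fn, actin), 30)
  expect_equal(fibronectin_partition(actin, actin), 0)
  expect_equal(fibronectin_partition(!actin, actin), 100)
  expect_error(fibronectin_partition(fn & FALSE, actin), "empty")
})

test_that("shape metrics are accurate and rotation invariant", {
  n <- 128; idx <- expand.grid(r = 1:n, c = 1:n)
  disk <- matrix((idx$r - 64.5)^2 + (idx$c - 64.5)^2 <= 50^2, n, n)
  sd_ <- shape_metrics(disk)
  expect_gt(sd_$circularity, 0.98); expect_lt(sd_$circularity, 1.02)
  expect_gte(sd_$solidity, 0.99)
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  ss <- shape_metrics(sq)
  expect_lt(abs(ss$circularity - pi / 4), 0.02)
  expect_gt(ss$solidity, 0.98)
  # 5-point star: solidity well below 1 (hull-area oracle on the polygon)
  th <- seq(0, 2 * pi, length.out = 11)[-11] - pi / 2
  rad <- rep(c(55, 30), 5)
  star_poly <- cbind(70 + rad * cos(th), 70 + rad * sin(th))
  idx140 <- expand.grid(r = 1:140, c = 1:140)
  star <- matrix(FALSE, 140, 140)
  star[as.matrix(idx140)[stiffmap:::.point_in_polygon(idx140$c, idx140$r,
                                                      star_poly), ]] <- TRUE
  expect_lt(shape_metrics(star)$solidity, 0.8)
  # rotation invariance within rasterization tolerance
  e0 <- shape_metrics(ellipse_mask(n = 161, a = 50, b = 25, deg = 0))
  e40 <- shape_metrics(ellipse_mask(n = 161, a = 50, b = 25, deg = 40))
  expect_lt(abs(e0$circularity - e40$circularity) / e0$circularity, 0.02)
  expect_lt(abs(e0$solidity - e40$solidity) / e0$solidity, 0.02)
  expect_error(shape_metrics(matrix(FALSE, 10, 10)), "empty")
  multi <- matrix(FALSE, 60, 60); multi[5:10, 5:10] <- TRUE
  multi[40:45, 40:45] <- TRUE
  expect_error(shape_metrics(multi), "single connected")
  # pixel size scales area/perimeter but not the dimensionless metrics
  s2 <- shape_metrics(disk, pixel_size = 0.5)
  expect_equal(s2$circularity, sd_$circularity)
  expect_equal(s2$area, sd_$area * 0.25)
})
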