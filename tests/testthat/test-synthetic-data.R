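# Generators: determinism, ground-truth fidelity, support constraints.

test_that("parameter constructors validate their domains", {
  expect_error(medium_params(-1, 0.01), "kappa_m")
  expect_error(medium_params(10, 0), "gamma")
  expect_error(medium_params(10, 0.01, msd_exponent = 1.5), "msd_exponent")
  expect_error(trap_params(k_trap = 0), "k_trap")
  expect_error(trap_params(axis_angle = 30), "axis_angle")
  expect_error(field_trend(1, beta_condition = c(a = 0.5, b = 1)),
               "reference")
  expect_equal(medium_params(10, 0.01, temperature = 310.15)$kBT,
               1.380649e-05 * 310.15)
})

test_that("AMR signal generator is deterministic and carries exact truth", {
  med <- medium_params(50, 0.01)
  tr <- trap_params()
  s1 <- gen_amr_signals(med, tr, duration = 1, seed = 42)
  s2 <- gen_amr_signals(med, tr, duration = 1, seed = 42)
  expect_identical(s1$detQPD$samples, s2$detQPD$samples)
  expect_identical(s1$trapQPD$samples, s2$trapQPD$samples)
  s3 <- gen_amr_signals(med, tr, duration = 1, seed = 43)
  expect_false(identical(s1$detQPD$samples, s3$detQPD$samples))
  gt <- attr(s1, "ground_truth")
  expect_equal(gt$kappa_star, complex(real = 50,
                                      imaginary = 2 * pi * 50 * 0.01))
  expect_error(gen_amr_signals(med, tr, duration = 0.1), "10 drive cycles")
  expect_error(gen_amr_signals(med, tr, sampling_rate = 200), "10x")
})

test_that("noise-free AMR signals match the closed-form steady state", {
  med <- medium_params(50, 0.01, temperature = 0)
  tr <- trap_params(frequency = 50)
  sig <- gen_amr_signals(med, tr, duration = 1, seed = 1, thermal = FALSE)
  kp <- compute_kappa(amr_lockin(sig, tr))
  expect_lt(abs(kp$kappa_prime - 50) / 50, 0.005)
  # pure fluid limit: Re ~ 0, Im ~ w*gamma
  med0 <- medium_params(0, 0.01, temperature = 0)
  sig0 <- gen_amr_signals(med0, tr, duration = 1, seed = 1, thermal = FALSE)
  kp0 <- compute_kappa(amr_lockin(sig0, tr))
  expect_lt(abs(kp0$kappa_prime), 1e-6)
  expect_equal(Im(kp0$kappa_star), 2 * pi * 50 * 0.01, tolerance = 1e-6)
})

test_that("PMR trajectory reproduces the analytic MSD", {
  # zero temperature: identically zero
  med0 <- medium_params(10, 0.01, temperature = 0)
  tr0 <- gen_pmr_trajectory(med0, duration = 1, sampling_rate = 1e3, seed = 1)
  expect_true(all(tr0$position == 0))
  # free diffusion: fitted MSD slope within 5% of 2D over 3 decades
  medf <- medium_params(0, 0.01)
  trf <- gen_pmr_trajectory(medf, duration = 30, sampling_rate = 1e4,
                            seed = 2)
  m <- compute_msd(trf, n_lags = 40)
  band <- m$lags <= 0.1                 # 1e-4 .. 1e-1 s: three decades
  expect_gt(max(m$lags[band]) / min(m$lags[band]), 999)
  slope_fit <- exp(mean(log(m$msd[band]) - log(m$lags[band])))
  D2 <- 2 * medf$kBT / medf$gamma
  expect_lt(abs(slope_fit - D2) / D2, 0.05)
  # trapped bead: long-lag plateau at 2 kBT / kappa within 5%
  medk <- medium_params(20, 0.001)
  trk <- gen_pmr_trajectory(medk, duration = 30, sampling_rate = 1e4,
                            seed = 3)
  mk <- compute_msd(trk, n_lags = 40)
  plateau <- 2 * medk$kBT / medk$kappa_m
  expect_lt(abs(stats::median(utils::tail(mk$msd, 10)) - plateau) / plateau,
            0.05)
  expect_error(gen_pmr_trajectory(medium_params(10, 0.01), duration = -1),
               "duration")
  expect_identical(gen_pmr_trajectory(medf, 1, 1e3, seed = 9)$position,
                   gen_pmr_trajectory(medf, 1, 1e3, seed = 9)$position)
})

test_that("stiffness fields honor their generative trend and support", {
  cg <- make_ellipse_cell()
  # no noise, intercept only: kappa constant
  tr0 <- field_trend(beta0 = log(7), sigma_log = 0)
  b0 <- gen_stiffness_field(cg, tr0, n_beads = 30, seed = 1)
  expect_equal(b0$kappa_prime, rep(7, nrow(b0)))
  # support: 0 < d <= max_distance, theta in [0, 180]
  tr <- field_trend(beta0 = log(20), beta_distance = -0.01, sigma_log = 0.3)
  b <- gen_stiffness_field(cg, tr, n_beads = 400, max_distance = 80,
                           seed = 2)
  expect_true(all(b$distance > 0 & b$distance <= 80))
  expect_true(all(b$theta_deg >= 0 & b$theta_deg <= 180))
  # distance slope recovered by OLS within its 95% CI
  b5 <- gen_stiffness_field(cg, tr, n_beads = 5000, seed = 3, axes = 0)
  fit <- stats::lm(log(kappa_prime) ~ distance + theta_deg, data = b5)
  ci <- stats::confint(fit)["distance", ]
  expect_gt(-0.01, ci[1])
  expect_lt(-0.01, ci[2])
  expect_identical(gen_stiffness_field(cg, tr, 50, seed = 4)$kappa_prime,
                   gen_stiffness_field(cg, tr, 50, seed = 4)$kappa_prime)
  cg_bad <- cg
  cg_bad$boundary <- rbind(c(0, 0), c(10, 0), c(2, 8), c(8, 8))
  expect_error(gen_stiffness_field(cg_bad, tr, 10), "simple polygon")
})

test_that("fiber volumes are deterministic with valid cavities", {
  v1 <- gen_fiber_stack(c(32, 32, 32), n_fibers = 12, seed = 5)
  v2 <- gen_fiber_stack(c(32, 32, 32), n_fibers = 12, seed = 5)
  expect_identical(v1, v2)
  expect_error(gen_fiber_stack(c(16, 32, 32)), "32")
  expect_error(gen_fiber_stack(c(32, 32, 32), fiber_radius = 20),
               "fiber_radius")
  vc <- gen_fiber_stack(c(32, 32, 32), n_fibers = 0, voxel_size = 0.5,
                        cavities = list(list(center = c(16, 16, 16),
                                             diameter = 10)))
  expect_equal(attr(vc, "cavities")[[1]]$diameter_um, 5)
  expect_true(all(vc %in% c(0L, 1L)))
})

test_that("synthetic cell images encode their ground truth exactly", {
  img <- gen_cell_image(yap_ratio_true = 2, fn_outside_frac_true = 0.3,
                        noise_sd = 0, seed = 1)
  tr <- attr(img, "truth")
  mip <- max_intensity_projection(img$yap)
  expect_equal(yap_ratio(mip, tr$nucleus_mask, tr$cell_mask), 2)
  img1 <- gen_cell_image(yap_ratio_true = 1, noise_sd = 0, seed = 1)
  tr1 <- attr(img1, "truth")
  expect_equal(yap_ratio(max_intensity_projection(img1$yap),
                         tr1$nucleus_mask, tr1$cell_mask), 1)
  expect_error(gen_cell_image(yap_ratio_true = 0), "yap_ratio_true")
  expect_error(gen_cell_image(fn_outside_frac_true = 2), "fn_outside")
  expect_error(gen_cell_image(shape_params = list(nucleus_radii = c(40, 40))),
               "nucleus")
})
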