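# Complex stiffness, generalized Stokes, MSD and GSER inversion.

test_that("complex stiffness follows from the lock-in components", {
  cr <- compute_kappa(complex(real = 0.01), complex(real = 1),
                      omega = 2 * pi * 50)
  expect_equal(cr$kappa_prime, 100)
  expect_equal(cr$alpha_star, complex(real = 0.01))
  # phase arithmetic: X lagging 45 deg
  X <- 0.01 * exp(complex(imaginary = -pi / 4))
  cr2 <- compute_kappa(X, complex(real = 1), omega = 1)
  expect_equal(cr2$kappa_star, 100 * exp(complex(imaginary = pi / 4)))
  expect_equal(cr2$kappa_prime, 100 * cos(pi / 4))
  expect_error(compute_kappa(complex(real = 0), complex(real = 1), 1),
               "flagged")
  expect_error(compute_kappa(complex(real = 1), complex(real = 0), 1),
               "force")
  cr3 <- compute_kappa(complex(real = -0.01), complex(real = 1), omega = 1)
  expect_true(cr3$flagged)
})

test_that("generalized Stokes relation has the exact unit identity", {
  g <- generalized_stokes(complex(real = 6 * pi), radius = 1)
  expect_identical(g$G_prime, 1)
  expect_identical(g$G_doubleprime, 0)
  g2 <- generalized_stokes(complex(imaginary = 6 * pi), radius = 1)
  expect_equal(g2$G_prime, 0)
  expect_equal(g2$G_doubleprime, 1)
  ks <- complex(real = 3, imaginary = 2)
  expect_equal(generalized_stokes(2 * ks, 1)$G_prime,
               2 * generalized_stokes(ks, 1)$G_prime)
  expect_error(generalized_stokes(ks, radius = 0), "radius")
})

test_that("MSD matches brute-force and closed-form oracles", {
  fs <- 100
  # alternating sequence: lag 1 -> 1, lag 2 -> 0 (brute-force over pairs)
  x <- rep(c(0, 1), 60)
  attr(x, "sampling_rate") <- fs
  m <- compute_msd(x, n_lags = 10)
  expect_equal(m$msd[m$lags == 1 / fs], 1)
  expect_equal(m$msd[m$lags == 2 / fs], 0)
  # ballistic: MSD = v^2 tau^2 exactly
  v <- 3
  xb <- v * (0:999) / fs
  attr(xb, "sampling_rate") <- fs
  mb <- compute_msd(xb, n_lags = 15)
  expect_equal(mb$msd, v^2 * mb$lags^2, tolerance = 1e-12)
  # constant: identically zero
  xc <- rep(2, 500); attr(xc, "sampling_rate") <- fs
  expect_true(all(compute_msd(xc, n_lags = 5)$msd == 0))
  expect_error(compute_msd(xc, n_lags = 1), "n_lags")
  expect_true(all(diff(mb$lags) > 0))
})

test_that("GSER inversion recovers analytic media", {
  kBT <- 1.380649e-05 * 310.15
  r <- 1
  lags <- exp(seq(log(1e-3), log(1), length.out = 40))
  # Newtonian: MSD = 2 D tau -> G' = 0, G'' = gamma w / (6 pi r)
  gam <- 0.002
  mN <- structure(list(lags = lags, msd = 2 * (kBT / gam) * lags,
                       sampling_rate = 1e3), class = "msd_curve")
  gN <- gser_invert(mN, radius = r)
  mid <- seq(10, 30)
  expect_lt(max(abs(gN$G_doubleprime[mid] / gN$omega[mid] -
                      gam / (6 * pi * r)) / (gam / (6 * pi * r))), 0.02)
  expect_true(all(gN$G_prime[mid] < 0.01 * gN$G_doubleprime[mid]))
  # Kelvin-Voigt plateau: G' -> kappa / (6 pi r)
  km <- 30
  mK <- structure(list(lags = lags,
                       msd = rep(2 * kBT / km, length(lags)),
                       sampling_rate = 1e3), class = "msd_curve")
  gK <- gser_invert(mK, radius = r)
  expect_lt(max(abs(gK$G_prime[mid] - km / (6 * pi * r)) /
                  (km / (6 * pi * r))), 0.05)
  # half-power medium: G' = G'' everywhere (phase pi/4)
  mH <- structure(list(lags = lags, msd = 1e-4 * sqrt(lags),
                       sampling_rate = 1e3), class = "msd_curve")
  gH <- gser_invert(mH, radius = r)
  expect_equal(gH$G_prime[mid], gH$G_doubleprime[mid], tolerance = 1e-6)
})

test_that("estimated |kappa*| grows with frequency in a viscous medium", {
  med <- medium_params(50, 0.02, temperature = 0)
  kap <- vapply(c(20, 50, 200), function(f) {
    tr <- trap_params(frequency = f)
    sig <- gen_amr_signals(med, tr, 1, 1e4, seed = 1, thermal = FALSE)
    Mod(compute_kappa(amr_lockin(sig, tr))$kappa_star)
  }, numeric(1))
  expect_true(all(diff(kap) > 0))
})

test_that("AMR-PMR comparison reports paired differences", {
  amr <- data.frame(frequency = c(1, 10, 50), G_prime = c(2, 2.2, 2.4))
  ident <- amr_pmr_compare(amr, amr)
  expect_true(all(ident$table$difference == 0))
  up <- amr; up$G_prime <- up$G_prime * 1.1
  shifted <- amr_pmr_compare(up, amr)
  expect_equal(shifted$median_ratio, 1.1, tolerance = 1e-10)
  expect_error(amr_pmr_compare(amr,
                               data.frame(frequency = c(100, 200),
                                          G_prime = c(1, 1))),
               "overlap")
})

test_that("trap-on passive recording inflates the apparent modulus", {
  # a bead held by the trap fluctuates as if in a stiffer medium: the
  # naive GSER readout must exceed the medium-only modulus
  km <- 5; gam <- 0.001; ktrap <- 50
  med_only <- medium_params(km, gam)
  trap_on <- medium_params(km + ktrap, gam)   # trap adds to the spring
  g1 <- gser_invert(compute_msd(gen_pmr_trajectory(med_only, 10, 5e3, 1)),
                    radius = 1)
  g2 <- gser_invert(compute_msd(gen_pmr_trajectory(trap_on, 10, 5e3, 1)),
                    radius = 1)
  long <- utils::tail(seq_len(min(nrow(g1), nrow(g2))), 10)
  expect_true(all(g2$G_prime[long] > g1$G_prime[long]))
})
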