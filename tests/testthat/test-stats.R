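# MER regression and the nonparametric battery against independent oracles.

test_that("MER reproduces the closed-form least-squares solution", {
  set.seed(20)
  n <- 200
  d <- data.frame(distance = stats::runif(n, 0, 150),
                  theta_deg = stats::runif(n, 0, 180),
                  condition = sample(c("1.0T1C", "2.0T1C"), n, TRUE),
                  axis_angle_deg = sample(c(0, 45, 90, 135), n, TRUE))
  d$kappa_prime <- exp(3 - 0.01 * d$distance - 0.002 * d$theta_deg +
                         0.5 * (d$condition == "2.0T1C") +
                         stats::rnorm(n, sd = 0.3))
  fit <- mer_fit(d)
  # independent oracle: stats::lm on the log scale
  lmfit <- stats::lm(log(kappa_prime) ~ distance + theta_deg +
                       I(condition == "2.0T1C") + I(axis_angle_deg == 45) +
                       I(axis_angle_deg == 90) + I(axis_angle_deg == 135),
                     data = d)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-10)
  expect_equal(fit$variance_explained, summary(lmfit)$r.squared,
               tolerance = 1e-10)
  expect_equal(fit$reference_levels$condition, "1.0T1C")
  expect_equal(fit$reference_levels$axis_angle_deg, "0")
  # predict returns exp of the linear predictor
  expect_equal(predict(fit, d[1:5, ]),
               exp(unname(predict(lmfit, d[1:5, ]))), tolerance = 1e-10)
})

test_that("MER handles exact, constant and invalid responses", {
  set.seed(30)
  d <- data.frame(distance = stats::runif(50, 0, 100),
                  theta_deg = stats::runif(50, 0, 180))
  d$kappa_prime <- exp(2 - 0.02 * d$distance + 0.001 * d$theta_deg)
  fit <- mer_fit(d)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), c(2, -0.02, 0.001), tolerance = 1e-8)
  dconst <- d; dconst$kappa_prime <- 5
  fitc <- mer_fit(dconst)
  expect_equal(unname(coef(fitc)[-1]), c(0, 0), tolerance = 1e-10)
  expect_equal(fitc$variance_explained, 0)
  dbad <- d; dbad$kappa_prime[3] <- -1
  expect_error(mer_fit(dbad), "rows: 3")
  dalias <- d; dalias$distance <- dalias$theta_deg
  expect_error(mer_fit(dalias), "aliased")
})

test_that("MER residual and simulation methods are consistent", {
  cg <- make_ellipse_cell()
  tr <- field_trend(beta0 = log(20), beta_distance = -0.01,
                    sigma_log = 0.3)
  b <- gen_stiffness_field(cg, tr, n_beads = 300, seed = 5)
  fit <- mer_fit(b)
  expect_equal(length(residuals(fit)), nrow(b))
  expect_lt(abs(fit$sigma - 0.3), 0.05)
  sim <- simulate(fit, nsim = 2, seed = 1, newdata = b[1:10, ])
  expect_equal(dim(sim), c(10L, 2L))
  expect_true(all(sim > 0))
  ci <- confint(fit)
  expect_true(ci["distance", 1] < coef(fit)["distance"])
})

test_that("Friedman wrapper matches the exhaustive permutation oracle", {
  set.seed(21)
  y <- matrix(stats::rnorm(15), 5, 3)
  ft <- friedman_axes(y)
  expect_equal(ft$statistic, friedman_stat_oracle(y), tolerance = 1e-12)
  # exact permutation null over all 6^5 within-block orderings
  pm <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
              c(3, 1, 2), c(3, 2, 1))
  perms <- as.matrix(expand.grid(rep(list(1:6), 5)))
  null_stats <- apply(perms, 1, function(ix) {
    m2 <- y
    for (i in 1:5) m2[i, ] <- y[i, pm[ix[i], ]]
    friedman_stat_oracle(m2)
  })
  p_exact <- mean(null_stats >= ft$statistic - 1e-12)
  # the chi-square approximation at 5 blocks is rough; the exact reference
  # must still be in its neighborhood
  expect_lt(abs(ft$p_value - p_exact), 0.15)
  # identical columns: statistic 0, p 1
  eq <- friedman_axes(matrix(rep(stats::rnorm(10), 4), 10, 4))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # power: one axis shifted by 3 SD on 50 blocks
  sh <- matrix(stats::rnorm(200), 50, 4); sh[, 2] <- sh[, 2] + 3
  expect_lt(friedman_axes(sh)$p_value, 0.01)
  expect_warning(friedman_axes(rbind(sh, c(NA, 1, 2, 3))), "missing")
})

test_that("Kruskal-Wallis plus rank post hoc isolates the shifted group", {
  set.seed(22)
  same <- stats::rnorm(20)
  kw0 <- kruskal_wallis_posthoc(list(a = same, b = same, c = same))
  expect_equal(kw0$statistic, 0, tolerance = 1e-10)
  expect_gt(kw0$p_value, 0.999)
  expect_false(any(kw0$posthoc$significant))
  g <- list(a = stats::rnorm(30), b = stats::rnorm(30),
            c = stats::rnorm(30) + 5)
  kw <- kruskal_wallis_posthoc(g)
  expect_lt(kw$p_value, 1e-6)
  ph <- kw$posthoc
  expect_true(all(ph$significant[ph$group_a == "c" | ph$group_b == "c"]))
  expect_false(any(ph$significant[ph$group_a == "a" & ph$group_b == "b"]))
  # two groups: H equals the squared standardized rank-sum statistic
  x1 <- stats::rnorm(15); x2 <- stats::rnorm(12) + 1
  kw2 <- kruskal_wallis_posthoc(list(a = x1, b = x2))
  N <- 27; r <- rank(c(x1, x2)); R1 <- sum(r[1:15])
  z <- (R1 - 15 * (N + 1) / 2) / sqrt(15 * 12 * (N + 1) / 12)
  expect_equal(kw2$statistic, z^2, tolerance = 1e-6)
  expect_error(kruskal_wallis_posthoc(list(a = 1:5)), "2 groups")
})

test_that("Ansari-Bradley exact p equals the enumeration oracle", {
  a <- c(1.1, 2.3, 0.5, 3.3); b <- c(1.9, 2.0, 1.5, 2.6)
  ab <- ansari_bradley(a, b)
  # oracle: all choose(8, 4) assignments of the pooled folded scores
  s <- stiffmap:::.ab_scores(c(a, b))
  combs <- utils::combn(8, 4)
  null_stats <- colSums(matrix(s[combs], nrow = 4))
  obs <- sum(s[1:4])
  p_oracle <- min(1, 2 * min(mean(null_stats <= obs),
                             mean(null_stats >= obs)))
  expect_equal(ab$statistic, obs)
  expect_equal(ab$p_value, p_oracle)
  # agreement with the reference implementation
  bt <- stats::ansari.test(a, b, exact = TRUE)
  expect_equal(ab$statistic, unname(bt$statistic))
  expect_equal(ab$p_value, bt$p.value, tolerance = 1e-12)
  # identical samples: no dispersion difference detectable
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_gte(ansari_bradley(x, x)$p_value, 0.99)
  # strong dispersion alternative at n = 50 per group
  set.seed(23)
  base <- stats::rnorm(50)
  wide <- 10 * (base - stats::median(base)) + stats::median(base)
  expect_lt(ansari_bradley(wide, stats::rnorm(50))$p_value, 0.01)
})

test_that("Pearson correlation matches the covariance formula", {
  expect_equal(pearson_rho(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_equal(pearson_rho(1:10, -(1:10))$statistic, -1)
  x <- c(1, 2, 3, 4); y <- c(4, 3, 3, 1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_rho(x, y)$statistic, r_oracle, tolerance = 1e-12)
  expect_error(pearson_rho(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("the KS screen is conservative with estimated parameters", {
  set.seed(24)
  # null with estimated parameters: rejection at the 0.01 screen is rare
  rej <- mean(vapply(1:100, function(i)
    ks_normality(stats::rnorm(500))$p_value < 0.01, logical(1)))
  expect_lt(rej, 0.05)
  # log-normal alternative: overwhelmingly rejected
  rej_alt <- mean(vapply(1:50, function(i)
    ks_normality(exp(stats::rnorm(500)))$p_value < 0.01, logical(1)))
  expect_gte(rej_alt, 0.95)
  deg <- ks_normality(rep(2, 10))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0.5)
  expect_error(ks_normality(1:3), "at least 5")
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(25)
  x <- matrix(stats::rlnorm(80), 20, 4)
  expect_equal(friedman_axes(x)$p_value, friedman_axes(log(x))$p_value)
  g1 <- stats::rlnorm(20); g2 <- stats::rlnorm(25) * 2
  expect_equal(kruskal_wallis_posthoc(list(a = g1, b = g2))$p_value,
               kruskal_wallis_posthoc(list(a = log(g1),
                                           b = log(g2)))$p_value)
})
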