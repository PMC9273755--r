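# Statistical layer: the multivariate exponential regression (MER) of
# stiffness on distance, angle and dummy-coded condition/axis covariates,
# and the accompanying nonparametric tests. The MER is fitted by the
# package's own QR least squares on the log scale; the standard tests
# delegate to base R's implementations behind this module's interface,
# except the Ansari-Bradley p-value (own exact enumeration for small
# samples, finite-population normal approximation otherwise) and the
# rank-based Tukey-Kramer post hoc (not available in base R).

.test_result <- function(test_name, statistic, p_value, n, effect = NULL,
                         ...) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = n, effect = effect, ...),
            class = "stiffmap_test")
}

#' @export
print.stiffmap_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (!is.null(x$effect)) {
    cat("  effect summary:\n")
    print(x$effect)
  }
  invisible(x)
}

#' Multivariate exponential regression of stiffness
#'
#' Fits the exponential-mean model
#' `kappa' = exp(b0 + b_d * distance + b_theta * theta + sum b_level)`
#' as ordinary least squares of `log(kappa')` on the covariates, with
#' discrete covariates (condition, oscillation axis) dummy-coded against
#' declared reference levels. Variance explained is the R^2 of the
#' log-scale fit.
#'
#' @param data data.frame of bead records with strictly positive response.
#' @param response Name of the stiffness column (pN/um). Default
#'   `"kappa_prime"`.
#' @param distance,theta Names of the continuous covariate columns; set to
#'   `NULL` to omit. Defaults `"distance"` (um) and `"theta_deg"`
#'   (degrees).
#' @param condition,axis Names of the discrete covariate columns; set to
#'   `NULL` to omit (a column absent from `data` is omitted as well).
#' @param reference_condition,reference_axis Reference levels for the
#'   dummy coding; defaults: `"1.0T1C"` when present (else the first
#'   level), and axis `0` (oscillation along the reference axis).
#' @param min_per_level Minimum rows per condition level (default 10).
#' @return Object of class `mer_fit` with components `coefficients`,
#'   `se`, `t_value`, `p_value`, `variance_explained`,
#'   `reference_levels`, `residuals` (log scale), `fitted_log`, `df`,
#'   `n`, `sigma`, `cov_unscaled`, `terms_info`. Methods: `print`,
#'   `summary`, `coef`, `confint`, `predict`, `residuals`, `simulate`.
#' @examples
#' cg <- make_ellipse_cell()
#' tr <- field_trend(beta0 = log(20), beta_distance = -0.01, sigma_log = 0.3)
#' beads <- gen_stiffness_field(cg, tr, n_beads = 500, seed = 2)
#' fit <- mer_fit(beads)
#' coef(fit)
#' @export
mer_fit <- function(data, response = "kappa_prime", distance = "distance",
                    theta = "theta_deg", condition = "condition",
                    axis = "axis_angle_deg", reference_condition = NULL,
                    reference_axis = NULL, min_per_level = 10) {
  y_raw <- data[[response]]
  if (is.null(y_raw)) stop("response column '", response, "' not found")
  bad <- which(!(y_raw > 0) | !is.finite(y_raw))
  if (length(bad))
    stop("non-positive stiffness in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  y <- log(y_raw)
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  refs <- list()
  add_cont <- function(X, nm) {
    if (!is.null(nm) && nm %in% names(data))
      X <- cbind(X, stats::setNames(data.frame(data[[nm]]), nm))
    X
  }
  X <- as.matrix(add_cont(as.data.frame(X), distance))
  X <- as.matrix(add_cont(as.data.frame(X), theta))
  add_dummies <- function(X, nm, ref) {
    if (is.null(nm) || !nm %in% names(data)) return(X)
    f <- as.character(data[[nm]])
    lev <- unique(f)
    if (length(lev) < 2L) return(X)
    counts <- table(f)
    if (nm == condition && any(counts < min_per_level))
      stop("fewer than ", min_per_level, " rows in condition level(s): ",
           paste(names(counts)[counts < min_per_level], collapse = ", "))
    if (is.null(ref)) {
      ref <- if (nm == condition && "1.0T1C" %in% lev) "1.0T1C"
      else if (nm == axis && "0" %in% lev) "0"
      else sort(lev)[1]
    }
    ref <- as.character(ref)
    if (!ref %in% lev) stop("reference level '", ref, "' absent from ", nm)
    refs[[nm]] <<- ref
    lev_sorted <- if (!anyNA(suppressWarnings(as.numeric(lev))))
      lev[order(as.numeric(lev))] else sort(lev)
    for (l in setdiff(lev_sorted, ref)) {
      d <- as.numeric(f == l)
      X <- cbind(X, d)
      colnames(X)[ncol(X)] <- paste0(nm, l)
    }
    X
  }
  X <- add_dummies(X, condition, reference_condition)
  X <- add_dummies(X, axis, reference_axis)

  qrX <- qr(X)
  p <- ncol(X); n <- nrow(X)
  if (qrX$rank < p)
    stop("rank-deficient design; aliased column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(0, diag(XtXinv) * sigma2))
  tval <- beta / ifelse(se > 0, se, NA)
  pval <- 2 * stats::pt(-abs(tval), df)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else max(0, min(1, 1 - sum(res^2) / sst))
  structure(list(coefficients = beta, se = se, t_value = tval,
                 p_value = pval, variance_explained = r2,
                 reference_levels = refs, residuals = res,
                 fitted_log = fitted, df = df, n = n,
                 sigma = sqrt(sigma2), cov_unscaled = XtXinv,
                 terms_info = list(response = response, distance = distance,
                                   theta = theta, condition = condition,
                                   axis = axis),
                 call = match.call()),
            class = "mer_fit")
}

#' @export
print.mer_fit <- function(x, ...) {
  cat("Multivariate exponential regression (log-linear least squares)\n")
  cat(sprintf("  n = %d, variance explained (log-scale R^2) = %.1f%%\n",
              x$n, 100 * x$variance_explained))
  if (length(x$reference_levels))
    cat("  reference levels:",
        paste(names(x$reference_levels), unlist(x$reference_levels),
              sep = " = ", collapse = ", "), "\n")
  cat("Coefficients (log pN/um scale):\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.mer_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t_value, `Pr(>|t|)` = object$p_value)
  out <- list(coefficients = tab,
              variance_explained = object$variance_explained,
              sigma = object$sigma, df = object$df, n = object$n,
              reference_levels = object$reference_levels)
  class(out) <- "summary.mer_fit"
  out
}

#' @export
print.summary.mer_fit <- function(x, ...) {
  cat("Multivariate exponential regression\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual SD (log scale): %.4g on %d df\n", x$sigma, x$df))
  cat(sprintf("Variance explained: %.1f%%\n", 100 * x$variance_explained))
  invisible(x)
}

#' @export
coef.mer_fit <- function(object, ...) object$coefficients

#' @export
residuals.mer_fit <- function(object, ...) object$residuals

#' @export
confint.mer_fit <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, object$df)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

.mer_design <- function(object, data) {
  ti <- object$terms_info
  nm <- names(object$coefficients)
  X <- matrix(1, nrow(data), 1)
  colnames(X) <- "(Intercept)"
  for (cn in setdiff(nm, "(Intercept)")) {
    if (!is.null(ti$distance) && cn == ti$distance) {
      X <- cbind(X, data[[cn]])
    } else if (!is.null(ti$theta) && cn == ti$theta) {
      X <- cbind(X, data[[cn]])
    } else {
      hit <- FALSE
      for (fac in c(ti$condition, ti$axis)) {
        if (!is.null(fac) && startsWith(cn, fac) && fac %in% names(data)) {
          lev <- substring(cn, nchar(fac) + 1L)
          X <- cbind(X, as.numeric(as.character(data[[fac]]) == lev))
          hit <- TRUE
          break
        }
      }
      if (!hit) stop("cannot rebuild design column ", cn)
    }
    colnames(X)[ncol(X)] <- cn
  }
  X
}

#' Predict stiffness from a fitted MER model
#'
#' @param object A `mer_fit`.
#' @param newdata data.frame with the model's covariate columns.
#' @param type `"kappa"` for stiffness on the natural scale (the
#'   conditional median, `exp(X b)`) or `"log"` for the linear predictor.
#' @param ... Unused.
#' @export
predict.mer_fit <- function(object, newdata, type = c("kappa", "log"), ...) {
  type <- match.arg(type)
  eta <- drop(.mer_design(object, newdata) %*% object$coefficients)
  if (type == "kappa") exp(eta) else eta
}

#' @export
simulate.mer_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- drop(.mer_design(object, newdata) %*% object$coefficients)
  out <- replicate(nsim,
                   exp(eta + stats::rnorm(length(eta), sd = object$sigma)))
  as.data.frame(out)
}

#' Friedman test across oscillation axes
#'
#' Blocked (per-bead) rank comparison of stiffness across oscillation
#' axes: within-block average ranks with a chi-square approximation.
#' Blocks containing missing values are dropped with a warning.
#'
#' @param mat Numeric matrix, blocks (beads) x treatments (axes).
#' @return A `stiffmap_test` with the statistic, p-value, per-axis medians
#'   and the number of blocks used.
#' @export
friedman_axes <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 treatments")
  ok <- stats::complete.cases(mat)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " block(s) with missing axis measurements")
    mat <- mat[ok, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("need at least 2 complete blocks")
  ht <- stats::friedman.test(mat)
  medians <- apply(mat, 2, stats::median)
  if (all(apply(mat, 1, function(r) length(unique(r)) == 1L))) {
    # all treatments identical within every block: no evidence at all
    return(.test_result("Friedman", 0, 1, nrow(mat), effect = medians,
                        df = ncol(mat) - 1L))
  }
  .test_result("Friedman", unname(ht$statistic), ht$p.value, nrow(mat),
               effect = medians, df = unname(ht$parameter))
}

#' Kruskal-Wallis test with rank-based Tukey-Kramer post hoc
#'
#' Kruskal-Wallis H (tie-corrected) across groups, followed by pairwise
#' comparisons of group mean ranks using the studentized-range
#' (Tukey-Kramer) critical value, the rank-based multiple-comparison
#' procedure conventionally paired with Kruskal-Wallis.
#'
#' @param groups Named list of numeric samples (each `n >= 2`), or a
#'   numeric vector together with `g`.
#' @param g Optional grouping factor when `groups` is a vector.
#' @param alpha Familywise significance level for the post hoc flags.
#' @return A `stiffmap_test` with an added `posthoc` data.frame
#'   (`group_a`, `group_b`, `diff_mean_rank`, `p_value`, `significant`).
#' @export
kruskal_wallis_posthoc <- function(groups, g = NULL, alpha = 0.05) {
  if (!is.list(groups)) {
    stopifnot(!is.null(g))
    groups <- split(as.numeric(groups), g)
  }
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  gg <- factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups))
  ht <- stats::kruskal.test(x, gg)
  N <- length(x); k <- nlevels(gg)
  r <- rank(x)
  rbar <- tapply(r, gg, mean)
  nn <- tabulate(gg)
  # tie-corrected rank variance
  ties <- table(x)
  s2 <- (N * (N + 1) / 12) - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  ph <- data.frame(
    group_a = levels(gg)[pairs[1, ]], group_b = levels(gg)[pairs[2, ]],
    diff_mean_rank = rbar[pairs[1, ]] - rbar[pairs[2, ]])
  sed <- sqrt(s2 * (1 / nn[pairs[1, ]] + 1 / nn[pairs[2, ]]))
  qstat <- sqrt(2) * abs(ph$diff_mean_rank) / sed
  ph$p_value <- stats::ptukey(qstat, k, Inf, lower.tail = FALSE)
  ph$significant <- ph$p_value < alpha
  rownames(ph) <- NULL
  out <- .test_result("Kruskal-Wallis", unname(ht$statistic), ht$p.value,
                      nn, effect = vapply(groups, stats::median, numeric(1)),
                      df = unname(ht$parameter))
  out$posthoc <- ph
  out
}

# Ansari-Bradley scores of a pooled sample
.ab_scores <- function(x) {
  N <- length(x)
  r <- rank(x)
  pmin(r, N + 1 - r)
}

#' Ansari-Bradley test for difference in dispersion
#'
#' Scores the pooled sample by folded ranks (`min(rank, N + 1 - rank)`)
#' and sums the scores of the first sample. The null distribution is
#' obtained by exact enumeration of all assignments when `n_a + n_b <= 20`
#' (ties handled naturally by enumerating the realized scores), and by a
#' finite-population normal approximation otherwise. Small values of the
#' statistic indicate the first sample is more dispersed.
#'
#' @param sample_a,sample_b Numeric samples (each `n >= 2`).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   default chooses exact for `n_a + n_b <= 20`.
#' @return A `stiffmap_test` (two-sided p).
#' @export
ansari_bradley <- function(sample_a, sample_b, exact = NULL) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  N <- length(a) + length(b)
  s <- .ab_scores(c(a, b))
  ab <- sum(s[seq_along(a)])
  if (is.null(exact)) exact <- N <= 20L
  if (exact) {
    combs <- utils::combn(N, length(a))
    stat_null <- colSums(matrix(s[combs], nrow = length(a)))
    p <- min(1, 2 * min(mean(stat_null <= ab), mean(stat_null >= ab)))
    method <- "exact enumeration"
  } else {
    mu <- length(a) * mean(s)
    v <- length(a) * length(b) * sum((s - mean(s))^2) / (N * (N - 1))
    z <- (ab - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  .test_result("Ansari-Bradley", ab, p, c(length(a), length(b)),
               effect = c(iqr_a = stats::IQR(a), iqr_b = stats::IQR(b)),
               method = method)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, non-degenerate.
#' @return A `stiffmap_test`; the statistic is the sample correlation rho.
#' @export
pearson_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in input")
  ht <- stats::cor.test(x, y, method = "pearson")
  .test_result("Pearson", unname(ht$estimate), ht$p.value, length(x),
               effect = c(t = unname(ht$statistic)))
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of a sample against a normal distribution. By
#' default (the pragmatic screen) the normal's mean and SD are the
#' sample's own estimates; note that estimating the parameters from the
#' same sample inflates the p-value (the test becomes conservative). Pass
#' fixed `mean`/`sd` for a fully specified null, under which the nominal
#' level is exact.
#'
#' @param sample Numeric sample, `n >= 5`.
#' @param mean,sd Optional fixed null parameters.
#' @return A `stiffmap_test` with fields `estimated_params` and, for a
#'   zero-variance sample, `degenerate = TRUE` (D = 0.5 against the
#'   limiting point mass, p undefined).
#' @export
ks_normality <- function(sample, mean = NULL, sd = NULL) {
  x <- as.numeric(sample)
  if (length(x) < 5L) stop("need at least 5 observations")
  estimated <- is.null(mean) || is.null(sd)
  m <- if (is.null(mean)) base::mean(x) else mean
  s <- if (is.null(sd)) stats::sd(x) else sd
  if (s == 0) {
    out <- .test_result("Kolmogorov-Smirnov", 0.5, NA_real_, length(x),
                        estimated_params = estimated)
    out$degenerate <- TRUE
    return(out)
  }
  ht <- suppressWarnings(stats::ks.test(x, "pnorm", m, s))
  out <- .test_result("Kolmogorov-Smirnov", unname(ht$statistic),
                      ht$p.value, length(x), estimated_params = estimated)
  out$degenerate <- FALSE
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' @param x,y Paired numeric vectors.
#' @return A `stiffmap_test`.
#' @export
wilcox_signed <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  .test_result("Wilcoxon signed-rank", unname(ht$statistic), ht$p.value,
               length(x), effect = c(median_diff = stats::median(x - y)))
}
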