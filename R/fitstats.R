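#' Monte-Carlo uncertainty-expanded ordinary least squares
#'
#' Each of the N data points (x, y +/- y_sem) is expanded into `m` draws
#' from Normal(y, y_sem) at its x, and an ordinary least squares line is
#' fitted to the resulting n = N * m cloud. P-value_1 tests the null that a
#' constant (horizontal) line fits the data as well as the sloped line;
#' P-value_2 (computed when N > 3) tests the x^2 coefficient of a quadratic
#' fit, rejecting linearity below 0.1. Both use t-tests whose standard
#' errors and degrees of freedom are based on the N empirical points, not
#' the N * m pseudo-replicates, so the expansion widens the residual
#' variance without inflating significance. The 68.2% confidence band is
#' the pointwise central interval of the m per-draw fitted lines (cloud
#' quantiles).
#'
#' x values are treated as exact; only y uncertainty is expanded.
#'
#' @param x,y,y_sem numeric vectors of equal length N (y_sem >= 0; zeros
#'   reduce the expansion to exact replication, so with all zeros the fit
#'   equals plain OLS on the N points).
#' @param m draws per point (default 1000).
#' @param seed RNG seed for the expansion.
#' @param band_x x values at which to evaluate the confidence band
#'   (default: 50 points spanning the x range).
#' @return object of class `mc_fit`: slope, intercept, slope_se, r_squared,
#'   rmse, p_value_1, p_value_2 (NA when N <= 3), df, n, m and `cb68`
#'   (data.frame x, fit, lower, upper).
#' @export
mc_ols <- function(x, y, y_sem = rep(0, length(y)), m = 1000, seed = NULL,
                   band_x = NULL) {
  stopifnot(length(x) == length(y), length(y) == length(y_sem),
            all(y_sem >= 0), m >= 1)
  N <- length(x)
  if (N < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate fit: x values are constant")
  if (!is.null(seed)) set.seed(seed)

  z <- matrix(stats::rnorm(N * m), N, m)
  Y <- y + y_sem * z                      # N x m cloud
  ybar <- rowMeans(Y)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)

  # cloud OLS == OLS of the per-point draw means (x repeats m times)
  slope <- sum(xc * (ybar - mean(ybar))) / Sxx
  intercept <- mean(ybar) - slope * mean(x)
  fitted_pt <- intercept + slope * x
  sse <- sum((Y - fitted_pt)^2)
  sst <- sum((Y - mean(Y))^2)
  n_cloud <- N * m
  r2 <- if (sst > 0) 1 - sse / sst else 1
  rmse <- sqrt(sse / n_cloud)

  df1 <- N - 2
  sigma2 <- sse / max(n_cloud - 2, 1)
  slope_se <- sqrt(sigma2 / Sxx)          # SE on the N-point scale
  t1 <- slope / slope_se
  p1 <- 2 * stats::pt(-abs(t1), df = df1)

  p2 <- NA_real_
  if (N > 3) {
    X <- cbind(1, x, x^2)
    XtXinv <- solve(crossprod(X))
    beta <- XtXinv %*% crossprod(X, ybar)
    fit2 <- as.numeric(X %*% beta)
    sse2 <- sum((Y - fit2)^2)
    sigma2_q <- sse2 / max(n_cloud - 3, 1)
    se_c2 <- sqrt(sigma2_q * XtXinv[3, 3])
    p2 <- 2 * stats::pt(-abs(beta[3] / se_c2), df = N - 3)
  }

  if (is.null(band_x)) band_x <- seq(min(x), max(x), length.out = 50)
  # per-draw fits (one line per MC replicate)
  sl_j <- colSums(xc * sweep(Y, 2, colMeans(Y))) / Sxx
  ic_j <- colMeans(Y) - sl_j * mean(x)
  lines_j <- outer(band_x, sl_j) + rep(ic_j, each = length(band_x))
  qs <- apply(lines_j, 1, stats::quantile, probs = c(0.159, 0.841),
              names = FALSE)
  cb68 <- data.frame(x = band_x, fit = intercept + slope * band_x,
                     lower = pmin(qs[1, ], intercept + slope * band_x),
                     upper = pmax(qs[2, ], intercept + slope * band_x))

  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 r_squared = r2, rmse = rmse, p_value_1 = p1, p_value_2 = p2,
                 df = df1, n = N, m = m, cb68 = cb68),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("MC-expanded OLS (N = %d, m = %d): y = %.4g + %.4g x\n",
              x$n, x$m, x$intercept, x$slope))
  cat(sprintf("  R2 = %.3f  RMSE = %.4g  P1 = %.3g  P2 = %s (df = %d)\n",
              x$r_squared, x$rmse, x$p_value_1,
              ifelse(is.na(x$p_value_2), "NA", sprintf("%.3g", x$p_value_2)),
              x$df))
  invisible(x)
}

#' Null-model regression by pairing-destroying resampling
#'
#' Builds the no-association reference fit for an (X, Y) relationship:
#' K samplings each draw `ceiling(sample_frac * size)` X values and,
#' independently, as many Y values (both without replacement), destroying
#' the pairing. The pooled draws are fitted by OLS; because the pool
#' over-represents the original points, p-values use degrees of freedom
#' `size - C` (C = 2 for a line) and a standard error rescaled to `size`
#' effective points. K defaults to `max_size / (sample_frac * size)`.
#'
#' @param x,y paired observations.
#' @param sample_frac fraction drawn per sampling (default 0.05).
#' @param max_size pooled-size cap setting K (default 45980 / 2).
#' @param seed RNG seed.
#' @return list: slope, intercept, slope_se, r_squared, p_value, df,
#'   n_pooled, k_samplings, fallback (TRUE when size < 20 forced a single
#'   full permutation).
#' @export
null_model_fit <- function(x, y, sample_frac = 0.05, max_size = 45980 / 2,
                           seed = NULL) {
  stopifnot(length(x) == length(y))
  size <- length(x)
  if (!is.null(seed)) set.seed(seed)
  fallback <- size < 20
  if (fallback) {
    px <- sample(x); py <- sample(y)
    k <- 1L
  } else {
    s <- ceiling(sample_frac * size)
    k <- max(1L, floor(max_size / (sample_frac * size)))
    px <- unlist(lapply(seq_len(k), function(i) x[sample.int(size, s)]))
    py <- unlist(lapply(seq_len(k), function(i) y[sample.int(size, s)]))
  }
  n_pooled <- length(px)
  xc <- px - mean(px)
  Sxx <- sum(xc^2)
  if (Sxx == 0) stop("degenerate null model: constant x after sampling")
  slope <- sum(xc * (py - mean(py))) / Sxx
  intercept <- mean(py) - slope * mean(px)
  res <- py - intercept - slope * px
  sse <- sum(res^2)
  sst <- sum((py - mean(py))^2)
  df <- size - 2
  sigma2 <- sse / max(n_pooled - 2, 1)
  # rescale to `size` effective points: Sxx grows with the pooled n
  slope_se <- sqrt(sigma2 / (Sxx * size / n_pooled))
  p <- 2 * stats::pt(-abs(slope / slope_se), df = df)
  list(slope = slope, intercept = intercept, slope_se = slope_se,
       r_squared = if (sst > 0) 1 - sse / sst else 0,
       p_value = p, df = df, n_pooled = n_pooled, k_samplings = k,
       fallback = fallback)
}

.logistic4 <- function(t, a, c, t0, k) a + (c - a) / (1 + exp(-k * (t - t0)))

.logistic_start <- function(t, y) {
  a <- min(y); c <- max(y)
  if (c - a < .Machine$double.eps) c <- a + 1e-6
  mid <- (a + c) / 2
  above <- which(y >= mid)
  t0 <- if (length(above)) t[above[1]] else stats::median(t)
  k <- 4 / max(diff(range(t)) / 4, .Machine$double.eps)
  increasing <- stats::cor(t, y) >= 0
  if (!increasing) { tmp <- a; a <- c; c <- tmp }
  list(a = a, c = c, t0 = t0, k = k)
}

#' Monte-Carlo sigmoid (4-parameter logistic) fit
#'
#' Fits y(t) = a + (c - a) / (1 + exp(-k (t - t0))) to a time series with
#' per-point SEMs. On each iteration every point is resampled from
#' Normal(y, y_sem) and the logistic is fitted by Levenberg-Marquardt
#' least squares; the final parameters and curve are the iteration means,
#' with 68.2% confidence bands from the central interval over iterations.
#' Non-convergent iterations are dropped and counted; more than 50%
#' failures is an error.
#'
#' @param t,y,y_sem time series (>= 5 points; y_sem >= 0).
#' @param iterations Monte-Carlo iterations (default 1000).
#' @param seed RNG seed.
#' @param curve_x times at which to evaluate the fitted curve (default:
#'   100 points spanning t).
#' @return object of class `sigmoid_fit`: `parameters` (a, c, t0, k),
#'   `param_cb68` (matrix with lower/upper rows), `curve` (data.frame t,
#'   fit, lower, upper), `n_failed`, `iterations`.
#' @export
sigmoid_mc_fit <- function(t, y, y_sem = rep(0, length(y)),
                           iterations = 1000, seed = NULL, curve_x = NULL) {
  stopifnot(length(t) == length(y), length(y) == length(y_sem),
            all(y_sem >= 0))
  if (length(t) < 5) stop("need at least 5 timepoints")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(curve_x)) curve_x <- seq(min(t), max(t), length.out = 100)

  fit_once <- function(yy) {
    st <- .logistic_start(t, yy)
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ a + (c - a) / (1 + exp(-k * (tt - t0))),
                        data = data.frame(tt = t, yy = yy),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(NULL)
    stats::coef(fit)
  }

  noiseless <- all(y_sem == 0)
  n_iter <- if (noiseless) 1L else iterations
  draws <- matrix(NA_real_, n_iter, 4,
                  dimnames = list(NULL, c("a", "c", "t0", "k")))
  for (i in seq_len(n_iter)) {
    yy <- if (noiseless) y else stats::rnorm(length(y), y, y_sem)
    co <- fit_once(yy)
    if (!is.null(co)) draws[i, ] <- co[c("a", "c", "t0", "k")]
  }
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > 0.5) {
    stop("sigmoid fit failed in ", sum(!ok), "/", n_iter, " iterations")
  }
  draws <- draws[ok, , drop = FALSE]
  params <- colMeans(draws)
  qs <- apply(draws, 2, stats::quantile, probs = c(0.159, 0.841),
              names = FALSE)
  rownames(qs) <- c("lower", "upper")

  curves <- apply(draws, 1, function(p) {
    .logistic4(curve_x, p["a"], p["c"], p["t0"], p["k"])
  })
  curves <- matrix(curves, nrow = length(curve_x))
  cq <- apply(curves, 1, stats::quantile, probs = c(0.159, 0.841),
              names = FALSE)
  curve <- data.frame(t = curve_x, fit = rowMeans(curves),
                      lower = cq[1, ], upper = cq[2, ])
  structure(list(parameters = params, param_cb68 = qs, curve = curve,
                 n_failed = sum(!ok), iterations = n_iter),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "MC sigmoid fit (%d iterations, %d failed): a=%.4g c=%.4g t0=%.4g k=%.4g\n",
    x$iterations, x$n_failed, p["a"], p["c"], p["t0"], p["k"]))
  invisible(x)
}

#' ANCOVA comparison of two fitted lines
#'
#' Tests whether two (x, y) groups share slope and intercept: the slope
#' p-value is the t-test on the group-by-x interaction in
#' `y ~ x * group`; the intercept p-value is the t-test on the group term
#' in the parallel-slopes model `y ~ x + group`. Rejection at 0.1.
#'
#' @param x_a,y_a first group (>= 3 pairs).
#' @param x_b,y_b second group (>= 3 pairs).
#' @return list: p_slope, p_intercept, reject_slope, reject_intercept.
#' @export
ancova_compare <- function(x_a, y_a, x_b, y_b) {
  stopifnot(length(x_a) == length(y_a), length(x_b) == length(y_b),
            length(x_a) >= 3, length(x_b) >= 3)
  d <- data.frame(x = c(x_a, x_b), y = c(y_a, y_b),
                  g = factor(rep(c("A", "B"), c(length(x_a), length(x_b)))))
  full <- stats::lm(y ~ x * g, data = d)
  cf <- summary(full)$coefficients
  p_slope <- if ("x:gB" %in% rownames(cf)) cf["x:gB", 4] else 1
  para <- stats::lm(y ~ x + g, data = d)
  cp <- summary(para)$coefficients
  p_int <- if ("gB" %in% rownames(cp)) cp["gB", 4] else 1
  # exactly duplicated groups give 0/0 t-statistics; equality is not rejected
  if (is.nan(p_slope)) p_slope <- 1
  if (is.nan(p_int)) p_int <- 1
  list(p_slope = p_slope, p_intercept = p_int,
       reject_slope = p_slope < 0.1, reject_intercept = p_int < 0.1)
}

#' Basic two-sample and one-sample hypothesis tests
#'
#' Thin wrappers at the pipeline's 10% significance level: Welch two-sample
#' t-test, two-sample Kolmogorov-Smirnov test, one-sample Z-test against an
#' externally supplied Normal(m, sigma) (in practice estimated from the
#' K_TF = 0 genes), and the two-sided Fisher exact test on a 2x2 table.
#'
#' @param x,y numeric samples (y unused for the Z-test).
#' @param m,sigma reference Normal parameters for the Z-test.
#' @param tab 2x2 contingency table for the Fisher test.
#' @return each: list(statistic, p_value, reject) with reject at p < 0.10.
#' @name basic_tests
NULL

#' @rdname basic_tests
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) > 1, length(y) > 1)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       reject = ht$p.value < 0.10)
}

#' @rdname basic_tests
#' @export
two_sample_ks <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ht <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       reject = ht$p.value < 0.10)
}

#' @rdname basic_tests
#' @export
one_sample_z <- function(x, m, sigma) {
  stopifnot(length(x) > 0, sigma > 0)
  z <- (mean(x) - m) / (sigma / sqrt(length(x)))
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = z, p_value = p, reject = p < 0.10)
}

#' @rdname basic_tests
#' @export
fisher_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  list(statistic = unname(ht$estimate), p_value = ht$p.value,
       reject = ht$p.value < 0.10)
}

#' Concentration relative to control from abundance and cell-area ratios
#'
#' Mean reporter abundance over mean cell area (a proxy for cell volume),
#' both relative to the control condition; SEMs combine by first-order
#' error propagation.
#'
#' @param abundance_rel,abundance_sem relative abundance and its SEM.
#' @param area_rel,area_sem relative mean cell area (> 0) and its SEM.
#' @return list(value, sem).
#' @export
relative_concentration <- function(abundance_rel, area_rel,
                                   abundance_sem = 0, area_sem = 0) {
  if (any(area_rel <= 0)) stop("relative area must be positive")
  value <- abundance_rel / area_rel
  sem <- sqrt((abundance_sem / area_rel)^2 +
                (abundance_rel * area_sem / area_rel^2)^2)
  list(value = value, sem = sem)
}
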