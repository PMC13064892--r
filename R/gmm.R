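#' Construct a two-component univariate Gaussian mixture
#'
#' Components are stored sorted by ascending mean. Useful for building a
#' mixture directly (e.g. to derive a threshold from known parameters);
#' [fit_gmm_em()] returns the same class.
#'
#' @param weights,means,variances Length-2 numerics; weights positive and
#'   summing to 1, variances positive.
#' @param log_likelihood,n_iter,converged Optional fit metadata.
#' @param fit_scale `"linear"` or `"log"`: the scale the mixture lives on.
#' @return An object of class `gmm1d`.
#' @export
gmm1d <- function(weights, means, variances, log_likelihood = NA_real_,
                  n_iter = 0L, converged = NA, fit_scale = "linear") {
  stopifnot(length(weights) == 2, length(means) == 2,
            length(variances) == 2, all(weights > 0),
            abs(sum(weights) - 1) < 1e-9, all(variances > 0))
  o <- order(means)
  structure(list(weights = weights[o], means = means[o],
                 variances = variances[o],
                 log_likelihood = log_likelihood, n_iter = n_iter,
                 converged = converged, fit_scale = fit_scale),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("2-component Gaussian mixture (", x$fit_scale, " scale)\n", sep = "")
  cat(sprintf("  weights:   %.4f  %.4f\n", x$weights[1], x$weights[2]))
  cat(sprintf("  means:     %.4g  %.4g\n", x$means[1], x$means[2]))
  cat(sprintf("  sd:        %.4g  %.4g\n", sqrt(x$variances[1]),
              sqrt(x$variances[2])))
  cat(sprintf("  logLik %.4g after %d iterations (converged: %s)\n",
              x$log_likelihood, x$n_iter, x$converged))
  invisible(x)
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization with log-sum-exp responsibilities.
#' Initialization places the component means at the 25th and 75th
#' percentiles (default), at k-means centres, or at two random data
#' points (seeded). Iteration stops when the log-likelihood improves by
#' less than `tol` or after `max_iter` iterations. A variance floor of
#' `var_floor_frac * var(x)` prevents singular collapse onto a single
#' point. The per-iteration log-likelihood trace is retained
#' (`ll_trace`) and is non-decreasing, as EM guarantees.
#'
#' @param values Numeric vector; at least 4 finite values with nonzero
#'   spread are required.
#' @param max_iter,tol EM stopping rule.
#' @param init `"quantile"` (default), `"kmeans"`, or `"random"`.
#' @param seed Seed used only by the stochastic initializers.
#' @param var_floor_frac Variance floor as a fraction of the data
#'   variance.
#' @param fit_scale Fit on `"linear"` intensity (default) or on `"log"`
#'   intensity (all values must then be positive).
#' @return A [gmm1d()] with components sorted by mean and an `ll_trace`
#'   element.
#' @export
fit_gmm_em <- function(values, max_iter = 500, tol = 1e-8,
                       init = c("quantile", "kmeans", "random"),
                       seed = NULL, var_floor_frac = 1e-6,
                       fit_scale = c("linear", "log")) {
  init <- match.arg(init)
  fit_scale <- match.arg(fit_scale)
  x <- values[is.finite(values)]
  if (fit_scale == "log") {
    if (any(x <= 0)) stop("log-scale fit requires strictly positive values")
    x <- log(x)
  }
  if (length(x) < 4)
    stop("need at least 4 finite values to fit a 2-component mixture")
  vx <- stats::var(x)
  if (vx == 0)
    stop("values have no spread; no mixture structure to fit")
  floor_var <- var_floor_frac * vx

  if (!is.null(seed)) set.seed(seed)
  mu <- switch(init,
    quantile = as.numeric(stats::quantile(x, c(0.25, 0.75))),
    kmeans = sort(stats::kmeans(x, centers = 2, nstart = 5)$centers[, 1]),
    random = sort(sample(x, 2)))
  if (diff(mu) == 0) mu <- mu + c(-1, 1) * sqrt(vx) / 2
  sig2 <- rep(max(vx / 4, floor_var), 2)
  w <- c(0.5, 0.5)

  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## E step (log domain)
    lg <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sqrt(sig2[1]),
                                         log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], sqrt(sig2[2]),
                                         log = TRUE))
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r1 <- exp(lg[, 1] - lse)
    ## M step
    n1 <- sum(r1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sig2 <- c(sum(r1 * (x - mu[1])^2) / n1,
              sum((1 - r1) * (x - mu[2])^2) / n2)
    sig2 <- pmax(sig2, floor_var)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  g <- gmm1d(w, mu, sig2, log_likelihood = ll_trace[length(ll_trace)],
             n_iter = it, converged = converged, fit_scale = fit_scale)
  g$ll_trace <- ll_trace
  g
}

#' Derive a positivity threshold from a fitted mixture by grid scan
#'
#' Evaluates the maximum-posterior component assignment on a uniform grid
#' of `grid_points` values spanning the interval between the two
#' component means; the threshold is the smallest grid value assigned to
#' the higher-mean component. Restricting the scan to between the means
#' guarantees a unique crossing for two components (outside this interval
#' assignments can revert when variances are unequal).
#'
#' @param gmm A [gmm1d()] with distinct means.
#' @param grid_points Number of grid values (default 1000).
#' @return A list of class `gate_threshold` with `threshold` (on the fit
#'   scale), `threshold_intensity` (back on the intensity scale if the
#'   fit was on log intensity), `grid_step`, and `fit_scale`.
#' @export
find_threshold <- function(gmm, grid_points = 1000) {
  stopifnot(inherits(gmm, "gmm1d"), grid_points >= 2)
  if (gmm$means[1] == gmm$means[2])
    stop("component means are identical; the threshold is undefined")
  grid <- seq(gmm$means[1], gmm$means[2], length.out = grid_points)
  post_hi <- log(gmm$weights[2]) +
    stats::dnorm(grid, gmm$means[2], sqrt(gmm$variances[2]), log = TRUE) -
    (log(gmm$weights[1]) +
       stats::dnorm(grid, gmm$means[1], sqrt(gmm$variances[1]),
                    log = TRUE))
  hi <- post_hi >= 0
  if (!any(hi))
    stop("no grid value is assigned to the high component; ",
         "increase grid_points")
  thr <- grid[which(hi)[1]]
  structure(list(
    threshold = thr,
    threshold_intensity = if (gmm$fit_scale == "log") exp(thr) else thr,
    grid_step = diff(grid[1:2]),
    fit_scale = gmm$fit_scale), class = "gate_threshold")
}

#' Classify cells as EdU-positive or -negative
#'
#' Compares each cell's mean nuclear EdU intensity to the threshold
#' (values at or above the threshold are positive; the tie direction is
#' fixed for determinism). Cells without an EdU measurement are left
#' unlabelled and excluded from the percentage.
#'
#' @param cell_records A data frame with a `mean_nuclear_edu` column
#'   (e.g. from [measure_cells()]).
#' @param threshold Numeric threshold on the intensity scale, or a
#'   `gate_threshold` from [find_threshold()].
#' @return A list of class `gate_result`: `cells` (input plus an
#'   `edu_label` column), `threshold`, `percent_positive`.
#' @export
classify_cells <- function(cell_records, threshold) {
  if (inherits(threshold, "gate_threshold"))
    threshold <- threshold$threshold_intensity
  stopifnot(is.finite(threshold))
  v <- cell_records$mean_nuclear_edu
  if (is.null(v) || all(is.na(v)))
    stop("no cells with EdU measurements to classify")
  lab <- ifelse(is.na(v), NA_character_,
                ifelse(v >= threshold, "positive", "negative"))
  cell_records$edu_label <- lab
  structure(list(
    cells = cell_records,
    threshold = threshold,
    percent_positive = 100 * sum(lab == "positive", na.rm = TRUE) /
      sum(!is.na(lab))), class = "gate_result")
}
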