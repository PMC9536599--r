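# Distribution-level statistics: Freedman-Diaconis histograms,
# least-squares fits of the three empirical regression models
# (two-Gaussian mixture, single Gaussian, lognormal; baseline fixed at 0),
# width-to-sigma conversion, percent-abnormal quantification with the
# proportion standard error, fold changes with Taylor-approximation errors,
# and coefficients of variation.
#
# The Gaussian models use the width parameterisation
# y = k * exp(-((x - x1)/width)^2), so sigma = width / sqrt(2).

#' Freedman-Diaconis histogram bins
#'
#' Bin width `2 * IQR / n^(1/3)`; edges span the data range.
#'
#' @param values numeric data (n >= 4).
#' @return list `(bin_width, n_bins, edges)`.
#' @export
fd_bins <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 values for FD binning")
  iqr <- IQR(values, type = 7)
  if (iqr <= 0) {
    stop("IQR is zero (near-constant data); supply explicit bins instead")
  }
  bw <- 2 * iqr / length(values)^(1 / 3)
  lo <- min(values)
  n_bins <- max(1L, ceiling((max(values) - lo) / bw))
  edges <- lo + bw * 0:n_bins
  if (edges[length(edges)] <= max(values)) {
    edges <- c(edges, edges[length(edges)] + bw)
    n_bins <- n_bins + 1L
  }
  list(bin_width = bw, n_bins = n_bins, edges = edges)
}

model_fun <- function(model) {
  switch(model,
    two_gaussian = function(p, x) {
      p["k1"] * exp(-((x - p["x1"]) / p["width1"])^2) +
        p["k2"] * exp(-((x - p["x2"]) / p["width2"])^2)
    },
    gaussian = function(p, x) p["k1"] * exp(-((x - p["x1"]) / p["width1"])^2),
    lognormal = function(p, x) {
      ifelse(x > 0, p["k1"] * exp(-(log(x / p["x1"]) / p["width1"])^2), 0)
    },
    stop("unknown model: ", model))
}

model_start <- function(model, values, mids, counts) {
  pk <- max(counts)
  switch(model,
    two_gaussian = {
      med <- median(values)
      lo <- values[values <= med]; hi <- values[values > med]
      c(k1 = pk, x1 = mean(lo), width1 = max(sd(lo), 1e-6) * sqrt(2),
        k2 = pk / 4, x2 = mean(hi), width2 = max(sd(hi), 1e-6) * sqrt(2))
    },
    gaussian = c(k1 = pk, x1 = mean(values),
                 width1 = max(sd(values), 1e-6) * sqrt(2)),
    lognormal = {
      lv <- log(values[values > 0])
      c(k1 = pk, x1 = exp(mean(lv)), width1 = max(sd(lv), 1e-6) * sqrt(2))
    })
}

#' Least-squares histogram fit
#'
#' Bins `values` with the Freedman-Diaconis rule and fits the chosen model
#' to the bin counts by unweighted least squares with the baseline fixed
#' at zero. Goodness of fit is reported as chi-square per degree of
#' freedom with Poisson variances floored at 1.
#'
#' @param values numeric sample.
#' @param model `"two_gaussian"`, `"gaussian"` or `"lognormal"`.
#' @param start optional named start vector overriding the data-driven
#'   initial guesses.
#' @return a `histogram_fit` list `(model, params, chi2_per_df, bin_width,
#'   n, mids, counts)`. For Gaussian components `sigma = width / sqrt(2)`.
#' @export
fit_histogram <- function(values, model = c("two_gaussian", "gaussian",
                                            "lognormal"), start = NULL) {
  model <- match.arg(model)
  values <- values[is.finite(values)]
  if (length(values) < 8L) stop("too few values to fit a histogram model")
  h <- fd_bins(values)
  hh <- graphics::hist(values, breaks = h$edges, plot = FALSE)
  counts <- hh$counts
  mids <- hh$mids
  if (sum(counts) == 0L) stop("empty histogram")
  f <- model_fun(model)
  p0 <- start %||% model_start(model, values, mids, counts)
  obj <- function(p) {
    names(p) <- names(p0)
    sum((counts - f(abs(p), mids))^2)
  }
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  par <- abs(fit$par)
  names(par) <- names(p0)
  if (!is.finite(fit$value)) {
    stop("histogram fit did not converge; initial guesses were: ",
         paste(sprintf("%s=%.4g", names(p0), p0), collapse = ", "))
  }
  if (model == "two_gaussian" && par["x1"] > par["x2"]) {
    par <- par[c("k2", "x2", "width2", "k1", "x1", "width1")]
    names(par) <- c("k1", "x1", "width1", "k2", "x2", "width2")
  }
  resid <- counts - f(par, mids)
  dfree <- max(1L, length(counts) - length(par))
  chi2 <- sum(resid^2 / pmax(f(par, mids), 1)) / dfree
  structure(list(model = model, params = par, chi2_per_df = chi2,
                 bin_width = h$bin_width, n = length(values),
                 mids = mids, counts = counts),
            class = "histogram_fit")
}

#' Convert a fitted Gaussian width to sigma
#'
#' The models use `exp(-((x - x1)/width)^2)`, so `sigma = width/sqrt(2)`
#' (e.g. a fitted width of 179 gives sigma = 179/1.414 = 127).
#'
#' @param width1 fitted width (> 0).
#' @return sigma.
#' @export
sigma_from_width <- function(width1) {
  if (any(width1 <= 0)) stop("width must be positive")
  width1 / sqrt(2)
}

# model mass outside [lo, hi] as a fraction of total mass (closed forms)
model_tail_fraction <- function(fit_or_params, model, lo, hi) {
  p <- if (inherits(fit_or_params, "histogram_fit")) fit_or_params$params else fit_or_params
  if (inherits(fit_or_params, "histogram_fit")) model <- fit_or_params$model
  comp_mass <- function(k, x1, width) k * width * sqrt(pi)
  comp_inside <- function(k, x1, width) {
    s <- width / sqrt(2)
    comp_mass(k, x1, width) * (pnorm(hi, x1, s) - pnorm(lo, x1, s))
  }
  if (model == "gaussian") {
    total <- comp_mass(p["k1"], p["x1"], p["width1"])
    inside <- comp_inside(p["k1"], p["x1"], p["width1"])
  } else if (model == "two_gaussian") {
    total <- comp_mass(p["k1"], p["x1"], p["width1"]) +
      comp_mass(p["k2"], p["x2"], p["width2"])
    inside <- comp_inside(p["k1"], p["x1"], p["width1"]) +
      comp_inside(p["k2"], p["x2"], p["width2"])
  } else if (model == "lognormal") {
    # integral of k exp(-(ln(x/x1)/w)^2) dx over (0, inf):
    #   k x1 w sqrt(pi) exp(w^2/4); the integrand in log-space is Gaussian
    # with mean ln(x1) + w^2/2 and sd w/sqrt(2)
    w <- p["width1"]
    m <- log(p["x1"]) + w^2 / 2
    s <- w / sqrt(2)
    total <- 1
    inside <- pnorm(log(max(hi, 1e-300)), m, s) -
      pnorm(log(max(lo, 1e-300)), m, s)
  } else stop("unknown model")
  unname(1 - inside / total)
}

#' Percent of distribution mass outside the normal band
#'
#' Fraction of the fitted tumor density lying outside
#' `[mu - k sigma, mu + k sigma]` of the diploid normal Gaussian, relative
#' to the total area under the fitted curve; the standard error treats the
#' fraction as a proportion over `n` cells: `sqrt(p(1-p)/n)`.
#'
#' @param tumor_fit a `histogram_fit` for the tumor distribution.
#' @param normal_2n c(mu, sigma) of the diploid normal Gaussian.
#' @param region_k half-width of the normal band in sigma units (default 2).
#' @param n number of cells behind the estimate (defaults to the fit's n).
#' @return list `(fraction, se, region)`.
#' @export
percent_abnormal <- function(tumor_fit, normal_2n, region_k = 2, n = NULL) {
  stopifnot(inherits(tumor_fit, "histogram_fit"), length(normal_2n) == 2L)
  lo <- normal_2n[1L] - region_k * normal_2n[2L]
  hi <- normal_2n[1L] + region_k * normal_2n[2L]
  p <- model_tail_fraction(tumor_fit, tumor_fit$model, lo, hi)
  p <- min(max(p, 0), 1)
  n <- n %||% tumor_fit$n
  list(fraction = p, se = proportion_se(p, n), region = c(lo, hi),
       region_k = region_k)
}

#' Standard error of a proportion
#' @param p proportion in [0, 1].
#' @param n count.
#' @return `sqrt(p (1 - p) / n)`.
#' @export
proportion_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Population summary
#'
#' @param values numeric sample (or supply `mean`, `sd`, `n` directly).
#' @param mean,sd,n explicit summary statistics.
#' @return a `population_summary` list `(mean, sd, n, cv)`.
#' @export
population_summary <- function(values = NULL, mean = NULL, sd = NULL,
                               n = NULL) {
  if (!is.null(values)) {
    values <- values[is.finite(values)]
    mean <- base::mean(values)
    sd <- stats::sd(values)
    n <- length(values)
  }
  if (is.null(n)) n <- 1L
  stopifnot(n >= 1)
  structure(list(mean = mean, sd = sd, n = n,
                 cv = if (mean != 0) sd / mean else NA_real_),
            class = "population_summary")
}

#' Fold change with Taylor-approximation error
#'
#' `fold = xbar / ybar` with variance
#' `Var(X/Y) ~ sx^2 / ybar^2 + xbar^2 sy^2 / ybar^4` (independence assumed,
#' covariance dropped). The default standard error follows the source
#' convention `se = sqrt(var / (nx^2 + ny^2))`; `method = "conventional"`
#' uses the delta-method `se = sqrt(sx^2/(nx ybar^2) + xbar^2 sy^2/(ny
#' ybar^4))`. Both are returned in the result for transparency.
#'
#' @param x_summary,y_summary `population_summary` objects (x = tumor,
#'   y = normal reference).
#' @param method `"literal"` or `"conventional"`.
#' @return a `fold_change` list.
#' @export
fold_change <- function(x_summary, y_summary,
                        method = c("literal", "conventional")) {
  method <- match.arg(method)
  xb <- x_summary$mean; yb <- y_summary$mean
  sx <- x_summary$sd; sy <- y_summary$sd
  nx <- x_summary$n; ny <- y_summary$n
  if (yb == 0) stop("reference mean is zero")
  var_taylor <- sx^2 / yb^2 + xb^2 * sy^2 / yb^4
  se_literal <- sqrt(var_taylor / (nx^2 + ny^2))
  se_conventional <- sqrt(sx^2 / (nx * yb^2) + xb^2 * sy^2 / (ny * yb^4))
  structure(list(xbar = xb, ybar = yb, sx = sx, sy = sy, nx = nx, ny = ny,
                 fold = xb / yb, var_taylor = var_taylor,
                 se = if (method == "literal") se_literal else se_conventional,
                 se_literal = se_literal, se_conventional = se_conventional,
                 method = method),
            class = "fold_change")
}

#' Coefficient of variation
#' @param summary a `population_summary` (or list with mean and sd).
#' @return `sd / mean`.
#' @export
coefficient_of_variation <- function(summary) {
  if (summary$mean == 0) stop("mean is zero")
  summary$sd / summary$mean
}
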