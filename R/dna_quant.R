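# Brightness-calibrated nuclear thresholding and image-cytometric ploidy
# estimation. The calibration model couples two linear behaviours of the
# DNA content d inside an isosurface: d falls linearly as the DNA threshold
# t rises (d = beta_t - m_t * t), and rises linearly as a lamin-based
# envelope is dilated by l (d = beta_l + m_l * l). The working point is the
# 90% content d90 = 0.1*beta_l + 0.9*beta_t, reached at threshold
# t90 = 0.1*(beta_t - beta_l)/m_t; t90 varies with overall stack brightness
# I (DNA-histogram centre of mass) as t(I) = 0.6 + k1*exp(k2*I).

#' Calibration curve for one stack
#'
#' @param I DNA-channel histogram centre of mass (intensity units).
#' @param beta_t content intercept at zero threshold (intensity x voxels).
#' @param m_t magnitude of the content-vs-threshold slope (> 0).
#' @param beta_l content inside the undilated lamin envelope;
#'   `beta_l < beta_t`.
#' @param m_l content-vs-dilation slope (> 0, per micrometre).
#' @return a `calibration_curve` list.
#' @export
calibration_curve <- function(I, beta_t, m_t, beta_l, m_l) {
  if (!(beta_t > beta_l)) stop("beta_t must exceed beta_l")
  if (m_t <= 0 || m_l <= 0) stop("slopes m_t and m_l must be positive")
  structure(list(I = I, beta_t = beta_t, m_t = m_t, beta_l = beta_l,
                 m_l = m_l), class = "calibration_curve")
}

#' DNA-histogram centre of mass
#'
#' Computed over the nonzero voxels of the (background-subtracted) DNA
#' channel: `sum(v * h(v)) / sum(h(v))`, i.e. the intensity-weighted mean.
#'
#' @param dna 3D DNA-channel array.
#' @return scalar intensity.
#' @export
histogram_center_of_mass <- function(dna) {
  v <- dna[dna > 0]
  if (length(v) == 0L) stop("DNA channel is empty (all zero)")
  mean(v)
}

#' Sweep the DNA threshold and fit d(t)
#'
#' For each nucleus, computes the DNA content inside the isosurface at each
#' threshold (sum of DNA over voxels above threshold inside the nucleus
#' neighbourhood) and regresses content on threshold; slopes/intercepts are
#' averaged across nuclei.
#'
#' @param stack an [image_stack()] with a DNA channel.
#' @param nucleus_mask 3D label array of nuclei to fit.
#' @param thresholds numeric vector (>= 3 values).
#' @return list `(beta_t, m_t, per_nucleus)`.
#' @export
sweep_threshold <- function(stack, nucleus_mask, thresholds) {
  if (length(thresholds) < 3L) stop("need at least 3 thresholds")
  dna <- get_channel(stack, "DNA")
  ids <- setdiff(sort(unique(as.vector(nucleus_mask))), 0L)
  if (length(ids) == 0L) stop("nucleus mask is empty")
  coefs <- t(vapply(ids, function(i) {
    m <- nucleus_mask == i
    d_t <- vapply(thresholds, function(t0) sum(dna[m & dna >= t0]), 1)
    fit_content_line(thresholds, d_t, decreasing = TRUE)
  }, c(0, 0)))
  list(beta_t = mean(coefs[, 1L]), m_t = mean(coefs[, 2L]),
       per_nucleus = data.frame(id = ids, beta_t = coefs[, 1L],
                                m_t = coefs[, 2L]))
}

#' Fit the d(t) line for one nucleus from a measured sweep
#'
#' Linear regression of DNA content on threshold, returning the intercept
#' `beta_t` and slope magnitude `m_t`. Errors if the content is not
#' non-increasing in the threshold (the calibration model requires it).
#'
#' @param thresholds numeric thresholds.
#' @param contents DNA contents at those thresholds.
#' @return c(beta_t, m_t).
#' @export
fit_threshold_sweep <- function(thresholds, contents) {
  b <- fit_content_line(thresholds, contents, decreasing = TRUE)
  c(beta_t = b[1L], m_t = b[2L])
}

fit_content_line <- function(x, y, decreasing) {
  if (decreasing && (!all(diff(y) <= 0) || all(diff(y) == 0))) {
    stop("DNA content must decrease with threshold; calibration model violated")
  }
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  c(b[1L], abs(b[2L]))
}

#' Sweep lamin-envelope dilation and fit d(l)
#'
#' Dilates the lamin surface by each distance (via the Euclidean distance
#' transform), sums DNA content inside, and fits the linear model
#' `d = beta_l + m_l * l`.
#'
#' @param stack an [image_stack()] with a DNA channel.
#' @param lamin_surface 3D 0/1 mask of the undilated envelope interior.
#' @param dilations dilation distances in micrometres (>= 3, including 0
#'   recommended).
#' @return list `(beta_l, m_l, contents)`.
#' @export
sweep_dilation <- function(stack, lamin_surface, dilations) {
  if (length(dilations) < 3L) stop("need at least 3 dilation distances")
  dna <- get_channel(stack, "DNA")
  d <- dim(dna)
  voxel <- stack$voxel_size
  # distance of background voxels to the envelope
  edt <- sqrt(array(cpp_edt_sq(as.integer(!(lamin_surface > 0)),
                               as.integer(d), as.numeric(voxel)), dim = d))
  contents <- vapply(dilations, function(l) {
    sum(dna[lamin_surface > 0 | edt <= l])
  }, 1)
  fit <- lm(contents ~ dilations)
  b <- unname(coef(fit))
  list(beta_l = b[1L], m_l = abs(b[2L]), contents = contents)
}

#' Target DNA content d90
#'
#' `0.1 * beta_l + 0.9 * beta_t`: 90% of the way from the lamin-envelope
#' content to the theoretical zero-threshold maximum.
#'
#' @param curve a [calibration_curve()].
#' @return content in intensity x voxel units.
#' @export
target_content <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  0.1 * curve$beta_l + 0.9 * curve$beta_t
}

#' Threshold (and dilation) reaching the target content
#'
#' `t90 = 0.1 * (beta_t - beta_l) / m_t` (algebraic simplification of the
#' printed two-term form), and `L90 = 0.9 * (beta_t - beta_l) / m_l`.
#'
#' @param curve a [calibration_curve()].
#' @return list `(t90, L90)`.
#' @export
target_threshold <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  span <- curve$beta_t - curve$beta_l
  list(t90 = 0.1 * span / curve$m_t, L90 = 0.9 * span / curve$m_l)
}

#' Threshold-vs-brightness model t(I) = 0.6 + k1 exp(k2 I)
#'
#' @param k1,k2 fitted coefficients (> 0); the published fit on the
#'   calibration stacks gives k1 = 0.219, k2 = 0.0665.
#' @param base fixed floor 0.6 (segmentation breaks down below it).
#' @return a `threshold_model` list.
#' @export
threshold_model <- function(k1 = 0.219, k2 = 0.0665, base = 0.6) {
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive")
  structure(list(base = base, k1 = k1, k2 = k2), class = "threshold_model")
}

#' Evaluate a threshold model at brightness I
#' @param model a [threshold_model()].
#' @param I histogram centre of mass.
#' @return threshold value.
#' @export
predict_threshold <- function(model, I) {
  stopifnot(inherits(model, "threshold_model"))
  model$base + model$k1 * exp(model$k2 * I)
}

#' Fit the threshold-brightness curve
#'
#' Nonlinear least squares for k1, k2 with the 0.6 base fixed.
#'
#' @param points data.frame with columns `I` and `t90` (>= 3 rows).
#' @param base fixed threshold floor.
#' @return a [threshold_model()].
#' @export
fit_threshold_curve <- function(points, base = 0.6) {
  stopifnot(all(c("I", "t90") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 calibration points")
  y <- points$t90 - base
  if (any(y <= 0)) stop("t90 values at or below the base threshold")
  # log-linear start, then direct least squares in t (two-stage optim:
  # nls chokes on zero-residual synthetic calibrations)
  st <- lm(log(y) ~ points$I)
  start <- c(k1 = exp(unname(coef(st)[1L])), k2 = unname(coef(st)[2L]))
  obj <- function(p) {
    sum((points$t90 - (base + abs(p[1L]) * exp(p[2L] * points$I)))^2)
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  if (!is.finite(fit$value) || any(!is.finite(fit$par))) {
    stop("threshold-curve fit did not converge; start was k1=",
         signif(start[1L], 4), ", k2=", signif(start[2L], 4),
         "; residual SS ", signif(obj(start), 4))
  }
  threshold_model(k1 = abs(unname(fit$par[1L])), k2 = unname(fit$par[2L]),
                  base = base)
}

#' Segment one nucleus with the calibrated threshold
#'
#' Applies `t(I)` to the masked, smoothed DNA channel, keeps the largest
#' connected component, fills cavities slice by slice, and reports the
#' filled volume along with the fill-only volume delta.
#'
#' @param stack an [image_stack()] with a DNA channel (background already
#'   subtracted).
#' @param cell_mask 3D logical/0-1 mask of the cell body.
#' @param model a [threshold_model()].
#' @param smoothing Gaussian smoothing, micrometres.
#' @param I optional precomputed histogram centre of mass (defaults to the
#'   masked DNA channel's).
#' @return list `(mask, volume, fill_delta, threshold, I)`; volumes in fL.
#' @export
segment_nucleus <- function(stack, cell_mask, model, smoothing = 0.3,
                            I = NULL) {
  dna <- get_channel(stack, "DNA")
  d <- dim(dna)
  voxel <- stack$voxel_size
  masked <- dna * (cell_mask > 0)
  if (is.null(I)) I <- histogram_center_of_mass(dna)
  t_use <- predict_threshold(model, I)
  sm <- gauss3d(masked, voxel, smoothing)
  fg <- sm >= t_use
  if (!any(fg)) {
    return(list(mask = array(0L, dim = d), volume = 0, fill_delta = 0,
                threshold = t_use, I = I))
  }
  lab <- array(cpp_label6(as.integer(fg), as.integer(d)), dim = d)
  main <- which.max(tabulate(lab[lab > 0L], nbins = max(lab)))
  fg <- lab == main
  filled <- array(cpp_fill_holes_slices(as.integer(fg), as.integer(d)),
                  dim = d)
  v_raw <- sum(fg) * prod(voxel)
  v_fill <- sum(filled) * prod(voxel)
  list(mask = filled, volume = v_fill, fill_delta = v_fill - v_raw,
       threshold = t_use, I = I)
}

#' Stromal diploid DNA baseline
#'
#' Background-subtracted DNA totals per stromal nucleus, with the diploid
#' mode taken from a single-Gaussian fit to the totals (fitted centre, not
#' histogram argmax). Warns below the 20-nucleus minimum of the protocol.
#'
#' @param stroma_labels 3D label array of stromal nuclei.
#' @param stack an [image_stack()] with a DNA channel.
#' @param background per-voxel background level subtracted from each
#'   nucleus total.
#' @return a `stromal_baseline` list `(totals, gaussian_mode, gaussian_sd)`.
#' @export
stromal_baseline <- function(stroma_labels, stack, background = 0) {
  dna <- get_channel(stack, "DNA")
  n <- max(stroma_labels)
  if (n == 0L) stop("no stromal nuclei in label volume")
  totals <- vapply(seq_len(n), function(i) {
    m <- stroma_labels == i
    sum(dna[m]) - sum(m) * background
  }, 1)
  totals <- totals[totals > 0]
  baseline_from_totals(totals)
}

#' Build a stromal baseline from DNA totals
#'
#' @param totals numeric vector of background-subtracted per-nucleus DNA
#'   sums.
#' @return a `stromal_baseline` list.
#' @export
baseline_from_totals <- function(totals) {
  if (length(totals) < 20L) {
    warning(sprintf("only %d stromal nuclei; at least 20 are recommended for the diploid baseline",
                    length(totals)))
  }
  fit <- fit_gaussian_mode(totals)
  structure(list(totals = totals, gaussian_mode = fit$mode,
                 gaussian_sd = fit$sd), class = "stromal_baseline")
}

# single-Gaussian least-squares fit to a histogram of totals; returns the
# fitted centre (the "mode") and sd. Robust start from median/MAD so a
# minority of polyploid contaminants does not drag the centre.
fit_gaussian_mode <- function(x) {
  if (length(unique(x)) == 1L) return(list(mode = x[1L], sd = 0))
  if (length(x) < 8L || IQR(x) <= 0) {
    # too few nuclei to fit a histogram; fall back to robust location
    return(list(mode = median(x), sd = sd(x)))
  }
  h <- fd_bins(x)
  counts <- graphics::hist(x, breaks = h$edges, plot = FALSE)$counts
  mids <- (h$edges[-1L] + h$edges[-length(h$edges)]) / 2
  start_mu <- median(x)
  start_sd <- max(stats::mad(x), diff(range(x)) / 20)
  obj <- function(p) {
    k <- p[1L]; mu <- p[2L]; s <- abs(p[3L]) + 1e-9
    sum((counts - k * exp(-((mids - mu) / (s * sqrt(2)))^2))^2)
  }
  fit <- optim(c(max(counts), start_mu, start_sd), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(mode = fit$par[2L], sd = abs(fit$par[3L]))
}

#' Estimate ploidy from a nucleus DNA total
#'
#' `dna_number = total / stromal mode` (how many normal genomes' worth of
#' DNA signal the nucleus holds); `estimated_ploidy = 2 * dna_number`;
#' near-euploid when ploidy lies in the inclusive interval [1.6, 4.4].
#'
#' @param nucleus_total background-subtracted DNA sum of the nucleus.
#' @param baseline a `stromal_baseline` (or list with `gaussian_mode`).
#' @return a `ploidy_estimate` list `(dna_number, estimated_ploidy,
#'   near_euploid)`.
#' @export
estimate_ploidy <- function(nucleus_total, baseline) {
  mode <- baseline$gaussian_mode
  if (!is.finite(mode) || mode <= 0) stop("stromal baseline mode must be positive")
  dna_number <- nucleus_total / mode
  ploidy <- 2 * dna_number
  structure(list(dna_number = dna_number, estimated_ploidy = ploidy,
                 near_euploid = ploidy >= 1.6 & ploidy <= 4.4),
            class = "ploidy_estimate")
}
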