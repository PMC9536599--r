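# dna_quant: calibration sweeps, target content/threshold algebra, the
# threshold-brightness model, nucleus segmentation, baselines and ploidy.

test_that("threshold sweep fits d(t) lines and rejects invalid input", {
  t <- seq(1, 10)
  expect_equal(unname(fit_threshold_sweep(t, 1000 - 20 * t)), c(1000, 20),
               tolerance = 1e-9)
  expect_error(fit_threshold_sweep(t, rep(500, 10)), "decrease")
  expect_error(fit_threshold_sweep(t, 500 + t), "decrease")
  # noisy line: recovered within the regression CI
  set.seed(1)
  y <- 1000 - 20 * t + rnorm(10, 0, 5)
  y <- cummin(y)  # keep monotone
  b <- fit_threshold_sweep(t, y)
  fit <- lm(y ~ t)
  ci <- confint(fit)
  expect_gte(b[1], ci[1, 1]); expect_lte(b[1], ci[1, 2])
  expect_gte(b[2], -ci[2, 2]); expect_lte(b[2], -ci[2, 1])
})

test_that("dilation sweep measures content growth and plateaus at beta_t", {
  shape <- c(32L, 48L, 48L); voxel <- 0.5
  ph <- generate_phantom_stack(phantom_spec(
    shape, voxel,
    list(cell_truth((shape - 1) * voxel / 2, 900, 300, 2, cell_class = "tumor")),
    background_level = 0, noise_sd = 0, rng_seed = 5))
  d <- dim(ph$nucleus_labels)
  nuc <- ph$nucleus_labels == 1
  edt <- array(cytovol3d:::cpp_edt_sq(as.integer(nuc), as.integer(d),
                                      rep(voxel, 3)), d)
  lamin <- edt > 0.75^2  # inner envelope under-estimating the nucleus
  dl <- sweep_dilation(ph$stack, lamin, seq(0, 0.75, 0.25))
  dna <- get_channel(ph$stack, "DNA")
  expect_equal(dl$contents[1], sum(dna[lamin]))  # l = 0 content by definition
  expect_gt(dl$m_l, 0)
  # far beyond the nucleus extent the content plateaus at the total
  far <- sweep_dilation(ph$stack, lamin, c(3, 4, 5))
  expect_rel_equal(far$contents[3], sum(dna[ph$nucleus_labels == 1]), 0.02)
  expect_error(sweep_dilation(ph$stack, lamin, c(0, 1)), "at least 3")
})

test_that("target content and threshold follow the calibration algebra", {
  cv <- calibration_curve(I = 30, beta_t = 1000, m_t = 20, beta_l = 800,
                          m_l = 50)
  expect_equal(target_content(cv), 980)
  expect_equal(target_threshold(cv)$t90, 1)
  expect_equal(target_threshold(cv)$L90, 0.9 * 200 / 50)
  # beta_l -> beta_t collapses the band
  eps <- 1e-9
  cv2 <- calibration_curve(30, 1000, 20, 1000 - eps, 50)
  expect_equal(target_content(cv2), 1000, tolerance = 1e-6)
  expect_lt(target_threshold(cv2)$t90, 1e-9)
  cv3 <- calibration_curve(30, 1, 20, 0, 50)
  expect_equal(target_content(cv3), 0.9)
  # doubling m_t halves t90
  cv4 <- calibration_curve(30, 1000, 40, 800, 50)
  expect_equal(target_threshold(cv4)$t90, 0.5)
  expect_error(calibration_curve(30, 800, 20, 1000, 50), "exceed")
  expect_error(calibration_curve(30, 1000, -2, 800, 50), "positive")
})

test_that("threshold-brightness model fits and evaluates per the published form", {
  I <- c(10, 18, 25, 32, 40, 47)
  pts <- data.frame(I = I, t90 = 0.6 + 0.219 * exp(0.0665 * I))
  fit <- fit_threshold_curve(pts)
  expect_rel_equal(fit$k1, 0.219, 0.01)
  expect_rel_equal(fit$k2, 0.0665, 0.01)
  # closed-form evaluation of the published fit at I = 40
  pub <- threshold_model()
  expect_equal(predict_threshold(pub, 40), 0.6 + 0.219 * exp(2.66),
               tolerance = 1e-9)
  expect_equal(round(predict_threshold(pub, 40), 2), 3.73)
  expect_equal(predict_threshold(pub, 0), 0.6 + 0.219)
  expect_error(fit_threshold_curve(data.frame(I = 1:2, t90 = c(1, 2))),
               "at least 3")
  expect_error(fit_threshold_curve(data.frame(I = 1:3, t90 = c(0.5, 1, 2))),
               "base")
})

test_that("nucleus segmentation fills cavities and records the delta", {
  shape <- c(40L, 56L, 88L); voxel <- 0.5
  extent <- (shape - 1) * voxel
  mk <- function(x_frac, cav) cell_truth(extent * c(0.5, 0.5, x_frac), 1500,
                                         500, 2, cell_class = "tumor",
                                         has_cavity = cav)
  ph <- generate_phantom_stack(phantom_spec(shape, voxel,
                                            list(mk(0.27, TRUE), mk(0.73, FALSE)),
                                            background_level = 0, noise_sd = 0,
                                            rng_seed = 12, dna_density_2n = 40))
  model <- threshold_model()
  I <- histogram_center_of_mass(get_channel(ph$stack, "DNA"))
  with_cav <- segment_nucleus(ph$stack, ph$cell_labels == 1, model, I = I)
  without <- segment_nucleus(ph$stack, ph$cell_labels == 2, model, I = I)
  # filled cavity nucleus matches its cavity-free twin within 5%
  expect_rel_equal(with_cav$volume, without$volume, 0.05)
  expect_gt(with_cav$fill_delta, 0)
  expect_lt(without$fill_delta / without$volume, 0.01)
})

test_that("stromal baseline uses the Gaussian-fit mode and warns when sparse", {
  b1 <- suppressWarnings(baseline_from_totals(rep(1e6, 25)))
  expect_equal(b1$gaussian_mode, 1e6)

  set.seed(7)
  totals <- c(rnorm(180, 1e5, 8e3), rnorm(20, 2e5, 8e3))  # 10% 4n contaminants
  b2 <- baseline_from_totals(totals)
  expect_rel_equal(b2$gaussian_mode, 1e5, 0.05)

  expect_warning(baseline_from_totals(rnorm(5, 1e5, 1e3)), "at least 20")
})

test_that("ploidy estimation follows the stromal-mode arithmetic", {
  bl <- list(gaussian_mode = 1e5)
  p1 <- estimate_ploidy(2e5, bl)
  expect_equal(p1$estimated_ploidy, 4)
  expect_true(p1$near_euploid)
  p2 <- estimate_ploidy(0.7e5, bl)
  expect_equal(p2$estimated_ploidy, 1.4)
  expect_false(p2$near_euploid)
  p3 <- estimate_ploidy(2.2e5, bl)
  expect_equal(p3$estimated_ploidy, 4.4)
  expect_true(p3$near_euploid)  # inclusive upper bound
  expect_true(estimate_ploidy(0.8e5, bl)$near_euploid)  # 1.6n inclusive
  expect_error(estimate_ploidy(1e5, list(gaussian_mode = 0)), "positive")
})
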