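# cytometry_gating: signal gates, size bins, area model, yields.

test_that("signal gates filter sequentially with logged counts", {
  pops <- data.frame(area = 276, ploidy = 2, live = TRUE, epcam = TRUE,
                     fraction = 1)
  ev <- generate_flow_events(1000, pops, rng_seed = 5)
  # a wide-open DNA gate lets the whole all-pass population through
  gates <- gate_set(live_max = 800, epcam_min = 300, dna_max_multiplier = 3)
  g <- apply_signal_gates(ev, gates)
  expect_equal(nrow(g$events), 1000L)  # all-pass population

  # an event at 1.6x the DNA mode is excluded by the 1.5x gate
  ev2 <- ev[1:10, ]
  ev2$draq5 <- g$dna_mode * c(rep(1, 9), 1.6)
  g2 <- apply_signal_gates(ev2, gate_set(live_max = 800, epcam_min = 300,
                                         dna_mode = g$dna_mode))
  expect_equal(nrow(g2$events), 9L)

  # 30% dead with perfect separation: the live gate removes exactly those
  pops3 <- data.frame(area = 276, ploidy = 2, live = c(TRUE, FALSE),
                      epcam = TRUE, fraction = c(0.7, 0.3))
  ev3 <- generate_flow_events(2000, pops3, rng_seed = 6)
  g3 <- apply_signal_gates(ev3, gate_set(live_max = 500, epcam_min = 1000))
  expect_equal(g3$counts[["live"]], sum(ev3$true_live))

  # gate order invariance for the independent live/EPCAM gates
  manual <- ev3[ev3$epcam >= 1000, ]
  manual <- manual[manual$zombie_red <= 500, ]
  direct <- ev3[ev3$zombie_red <= 500, ]
  direct <- direct[direct$epcam >= 1000, ]
  expect_identical(rownames(manual), rownames(direct))
})

test_that("data-driven calibration lands between the populations", {
  pops <- data.frame(area = c(276, 276, 276), ploidy = c(2, 2, 2),
                     live = c(TRUE, FALSE, TRUE),
                     epcam = c(TRUE, TRUE, FALSE),
                     fraction = c(0.6, 0.2, 0.2))
  ev <- generate_flow_events(4000, pops, rng_seed = 9)
  gates <- calibrate_gates(ev, gate_set())
  # cutoffs land between the population modes (live ~100, dead ~3000;
  # EPCAM- ~120, EPCAM+ ~3000)
  expect_gt(gates$live_max, 100)
  expect_lt(gates$live_max, 3000)
  expect_gt(gates$epcam_min, 120)
  expect_lt(gates$epcam_min, 3000)
  # heuristic cutoffs on overlapping lognormal populations: high but not
  # perfect purity
  g <- apply_signal_gates(ev, gates)
  expect_gt(mean(g$events$true_live), 0.95)
  expect_gt(mean(g$events$true_epcam), 0.95)
})

test_that("size bins follow the published SSC-W ranges within the SSC-H trim", {
  gates <- gate_set()
  ev <- data.frame(ssc_h = c(100, 100, 100, 100, 250, 100, 100),
                   ssc_w = c(70, 100, 90, 105, 70, 120, 50))
  bins <- assign_size_bin(ev, gates)
  expect_identical(bins,
                   c("G1", "none", "G2", "G3", "none", "G4", "none"))
  expect_error(gate_set(size_bins = list(G1 = c(64, 90), G2 = c(84, 99))),
               "non-overlapping")
})

test_that("the area model predicts, inverts and fits per the printed line", {
  m <- area_model()
  expect_equal(predict_area(100, m), 276)
  expect_lt(abs(-m$intercept / m$slope - 36.6), 0.1)
  expect_warning(predict_area(36.6 - 5, m), "below zero|at or below")

  pairs <- data.frame(ssc_w = c(70, 90, 105, 120),
                      area = -159 + 4.35 * c(70, 90, 105, 120))
  # exact points: lm warns that the fit is perfect, which is the point
  fit <- suppressWarnings(fit_area_model(pairs))
  expect_equal(fit$intercept, -159, tolerance = 1e-9)
  expect_equal(fit$slope, 4.35, tolerance = 1e-9)
  expect_error(fit_area_model(pairs[1:2, ]), "at least 3")

  set.seed(4)
  noisy <- data.frame(ssc_w = seq(60, 130, 5))
  noisy$area <- -159 + 4.35 * noisy$ssc_w + rnorm(nrow(noisy), 0, 8)
  nf <- fit_area_model(noisy)
  expect_lt(abs(nf$slope - 4.35), 2.5 * nf$slope_se)
  expect_lt(abs(nf$intercept + 159), 2.5 * nf$intercept_se)
})

test_that("yield reports divide by the gated total with a none remainder", {
  gates <- gate_set()
  set.seed(8)
  ev <- data.frame(ssc_h = runif(5000, 60, 190), ssc_w = runif(5000, 64, 113))
  bins <- assign_size_bin(ev, gates)
  yr <- yield_report(bins, gates)
  expect_equal(sum(yr), 1, tolerance = 1e-12)
  # uniform SSC-W over 64-113: G2 mass ~ its interval share of the in-bin mass
  expect_rel_equal(yr[["G2"]] / (yr[["G1"]] + yr[["G2"]] + yr[["G3"]]),
                   15 / (15 + 15 + 12), 0.15)

  expect_equal(sum(yield_report(character(0), gates)), 0)
  all3 <- data.frame(ssc_h = rep(100, 50), ssc_w = rep(105, 50))
  expect_equal(yield_report(assign_size_bin(all3, gates), gates)[["G3"]], 1)
})
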