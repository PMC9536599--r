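# synthetic_data: phantom stacks, measurement tables, flow events,
# annotation pairs.

test_that("phantom rasterisation recovers stated geometry and is deterministic", {
  vol <- 4 / 3 * pi * 5^3  # r = 5 um sphere, ~523.6 fL
  ct <- cell_truth(c(16, 16, 16), vol, 150, 2, cell_class = "tumor")
  spec <- phantom_spec(c(32L, 32L, 32L), 1, list(ct), background_level = 0,
                       noise_sd = 0)
  ph <- generate_phantom_stack(spec)
  expect_rel_equal(ph$truth$cell_voxels, vol, 0.02)

  ph2 <- generate_phantom_stack(spec)
  expect_identical(ph$stack$channels, ph2$stack$channels)
  expect_identical(ph$cell_labels, ph2$cell_labels)
  expect_identical(ph$nucleus_labels, ph2$nucleus_labels)
})

test_that("phantom DNA follows the linear attenuation model along z", {
  mk <- function(z) cell_truth(c(z, 16, 16), 900, 400, 2, cell_class = "tumor")
  spec <- phantom_spec(c(33L, 32L, 32L), 1, list(mk(7), mk(25)),
                       attenuation_factor = 2, background_level = 0,
                       noise_sd = 0, dna_density_2n = 40)
  ph <- generate_phantom_stack(spec)
  dna <- get_channel(ph$stack, "DNA")
  m_top <- mean(dna[ph$nucleus_labels == 1 & dna > 0])
  m_bot <- mean(dna[ph$nucleus_labels == 2 & dna > 0])
  # linear scale: s(z) = 1 - 0.5 z / (nz - 1); identical nuclei centred at
  # z = 6 and z = 26 should show the corresponding mean ratio; the extreme
  # planes themselves are dimmed exactly 2-fold by construction
  s <- function(z) 1 - 0.5 * z / 32
  expect_rel_equal(m_bot / m_top, s(25) / s(7), 0.04)

  spec1 <- phantom_spec(c(33L, 32L, 32L), 1, list(mk(16)),
                        attenuation_factor = 2, background_level = 0,
                        noise_sd = 0, dna_density_2n = 40)
  ph1 <- generate_phantom_stack(spec1)
  dna1 <- get_channel(ph1$stack, "DNA")
  prof <- vapply(1:33, function(z) sum(dna1[z, , ]), 1)
  # per-plane totals of a symmetric nucleus follow s(z) times the
  # unattenuated symmetric profile: ratio of mirror planes = s ratio
  mid <- 17
  for (k in c(2, 3)) {
    expect_rel_equal(prof[mid + k] / prof[mid - k],
                     s(mid + k - 1) / s(mid - k - 1), 0.04)
  }
})

test_that("integrated DNA is proportional to ploidy before noise", {
  mk <- function(y, pl, nv) cell_truth(c(12, y, 12), 3 * nv, nv, pl,
                                       cell_class = "tumor")
  # same nuclear volume, different ploidy, and different volume same ploidy
  spec <- phantom_spec(c(25L, 72L, 25L), 1,
                       list(mk(12, 2, 202), mk(36, 4, 202), mk(60, 2, 404)),
                       background_level = 0, noise_sd = 0,
                       dna_density_2n = 30)
  ph <- generate_phantom_stack(spec)
  dna <- get_channel(ph$stack, "DNA")
  tot <- vapply(1:3, function(i) sum(dna[ph$nucleus_labels == i]), 1)
  expect_rel_equal(tot[2] / tot[1], 2, 0.02)   # 4n vs 2n
  expect_rel_equal(tot[3] / tot[1], 1, 0.02)   # ploidy, not volume, sets total
})

test_that("phantom invariants: containment, bounds checks, collisions", {
  ph <- tumor_phantom(4)
  for (i in seq_len(nrow(ph$truth))) {
    nuc <- sum(ph$nucleus_labels == i)
    cell <- sum(ph$cell_labels == i)
    expect_lte(nuc, cell)
    expect_gte(sum(ph$cell_labels[ph$nucleus_labels == i] == i) / nuc, 0.999)
  }
  expect_error(
    phantom_spec(c(16L, 16L, 16L), 1,
                 list(cell_truth(c(40, 8, 8), 100, 50, 2, cell_class = "tumor"))),
    "outside stack bounds")
  expect_error(generate_phantom_stack(phantom_spec(
    c(24L, 24L, 24L), 1,
    list(cell_truth(c(12, 12, 10), 500, 100, 2, cell_class = "tumor"),
         cell_truth(c(12, 12, 14), 500, 100, 2, cell_class = "tumor")))),
    "overlap beyond tolerance.*cell 2")
})

test_that("measurement tables reproduce the stated populations", {
  spec <- population_spec(n_normal = 1e4, n_tumor = 0, n_stromal = 0,
                          rng_seed = 2)
  tab <- generate_measurement_table(spec)
  peak1 <- tab$cell_volume[tab$true_ploidy == 2]
  se <- 127 / sqrt(length(peak1))
  expect_lt(abs(mean(peak1) - 582), 3 * se)
  expect_true(all(tab$cell_class %in% c("AT2")))

  tab2 <- generate_measurement_table(population_spec(
    n_normal = 50, n_tumor = 0, n_stromal = 10, rng_seed = 3))
  expect_true(all(tab2$cell_class %in% c("AT2", "stromal")))

  # supraproportional mode with 2x slope: >90% classify supra downstream
  tab3 <- generate_measurement_table(population_spec(
    n_tumor = 2000, n_normal = 0, n_stromal = 0,
    proportionality_mode = "supra", rng_seed = 4))
  cls <- classify_cell(tab3$cell_volume, tab3$estimated_ploidy)
  expect_gt(mean(cls == "supra"), 0.9)

  # DNA totals: ploidy/2 x stromal mode x noise
  expect_rel_equal(mean(tab3$dna_total / (tab3$true_ploidy / 2 * 1e5)), 1, 0.01)
})

test_that("flow events invert the area model and respect gate truths", {
  pops <- data.frame(area = 276, ploidy = 2, live = TRUE, epcam = TRUE,
                     fraction = 1)
  ev <- generate_flow_events(500, pops, rng_seed = 1, sscw_noise_sd = 0)
  expect_equal(unique(ev$ssc_w), 100, tolerance = 1e-12)

  pops2 <- data.frame(area = c(276, 276), ploidy = c(2, 2),
                      live = c(FALSE, FALSE), epcam = c(TRUE, FALSE),
                      fraction = c(0.5, 0.5))
  ev2 <- generate_flow_events(400, pops2, rng_seed = 2)
  gated <- apply_signal_gates(ev2, gate_set(live_max = 500, epcam_min = 1000))
  expect_equal(gated$counts[["live"]], 0L)

  pops3 <- data.frame(area = c(276, 276), ploidy = c(2, 8),
                      live = TRUE, epcam = TRUE, fraction = c(0.7, 0.3))
  ev3 <- generate_flow_events(2000, pops3, rng_seed = 3)
  g3 <- apply_signal_gates(ev3, gate_set(live_max = 500, epcam_min = 1000))
  expect_true(all(g3$events$true_ploidy == 2))  # 8n beyond 1.5x mode
})

test_that("annotation pairs mark 1-px label interfaces on populated slices", {
  ph <- tumor_phantom(1, noise_sd = 0, shape = c(32L, 48L, 48L))
  prs <- generate_annotation_pairs(ph$stack, ph$cell_labels)
  zs <- vapply(prs, `[[`, 1L, "z")
  pop <- which(apply(ph$cell_labels, 1, function(m) any(m > 0)))
  expect_identical(zs, pop)

  # equatorial slice of a single cell: mask is the 2D boundary of the disc
  eq <- prs[[which.max(vapply(prs, function(p) sum(p$mask), 1))]]
  sl <- ph$cell_labels[eq$z, , ]
  oracle <- matrix(0L, nrow(sl), ncol(sl))
  for (y in seq_len(nrow(sl))) for (x in seq_len(ncol(sl))) {
    if (sl[y, x] == 0) next
    nb <- c(if (y > 1) sl[y - 1, x] else -1L,
            if (y < nrow(sl)) sl[y + 1, x] else -1L,
            if (x > 1) sl[y, x - 1] else -1L,
            if (x < ncol(sl)) sl[y, x + 1] else -1L)
    if (any(nb != sl[y, x])) oracle[y, x] <- 1L
  }
  expect_identical(unname(eq$mask), unname(oracle))

  # two touching cells: interface voxels marked on both contours
  two <- generate_phantom_stack(phantom_spec(
    c(24L, 48L, 32L), 1,
    list(cell_truth(c(12, 16, 16), 500, 100, 2, cell_class = "tumor"),
         cell_truth(c(12, 25.6, 16), 500, 100, 2, cell_class = "tumor")),
    background_level = 0, noise_sd = 0, overlap_tolerance = 0.2))
  prs2 <- generate_annotation_pairs(two$stack, two$cell_labels)
  eq2 <- prs2[[which(vapply(prs2, `[[`, 1L, "z") == 12L)]]
  sl2 <- two$cell_labels[12, , ]
  # adjacency oracle: pixels of label 1 with a 4-neighbour of label 2 (and
  # vice versa) must be marked
  for (lab in 1:2) {
    other <- 3 - lab
    w <- which(sl2 == lab, arr.ind = TRUE)
    touching <- w[apply(w, 1, function(p) {
      y <- p[1]; x <- p[2]
      any(c(if (y > 1) sl2[y - 1, x], if (y < nrow(sl2)) sl2[y + 1, x],
            if (x > 1) sl2[y, x - 1], if (x < ncol(sl2)) sl2[y, x + 1]) == other)
    }), , drop = FALSE]
    expect_gt(nrow(touching), 0)
    expect_true(all(eq2$mask[touching] == 1))
  }

  expect_error(generate_annotation_pairs(ph$stack, array(0L, dim(ph$cell_labels))),
               "empty")
})
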