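# segmentation: seeds, tumor-cell watershed, AT2 pipeline, stromal nuclei,
# QC rules.

test_that("seeds_from_marks finds centroids and radius classes", {
  d <- c(32L, 48L, 48L)
  marks <- array(0L, d)
  centers <- list(c(8, 12, 12), c(8, 36, 12), c(20, 24, 36))
  for (ct in centers) marks <- marks | digitize_ball(d, ct, 5)
  seeds <- seeds_from_marks(marks, voxel_size = 0.15)
  expect_equal(nrow(seeds$centroids), 3L)
  got <- seeds$centroids[order(seeds$centroids[, 3]), ]
  want <- do.call(rbind, centers)[c(1, 2, 3), ]
  want <- (want - 1) * 0.15
  expect_lt(max(abs(got - want[order(want[, 3]), ])), 0.15)
  # 5 px at 0.15 um maps to the 1.6 um class
  expect_equal(seeds$seed_radius, 1.6)

  # three normal marks plus one merged pair of touching marks
  touching <- marks | digitize_ball(d, c(28, 24, 20), 5) |
    digitize_ball(d, c(28, 24, 27), 5)
  expect_warning(s2 <- seeds_from_marks(touching * 1L, 0.15), "merged")
  expect_equal(nrow(s2$centroids), 4L)
})

test_that("seeded watershed recovers phantom volumes and flags edge cases", {
  ph <- tumor_phantom(2, noise_sd = 1, seed = 17)
  conf <- ridge_boundary_confidence(ph$stack)
  seeds <- seed_set(as.matrix(ph$truth[, c("center_z", "center_y", "center_x")]))
  seg <- segment_tumor_cells(conf, seeds, ph$stack$voxel_size)
  vols <- tabulate(seg$labels[seg$labels > 0], nrow(ph$truth)) *
    prod(ph$stack$voxel_size)
  err <- abs(vols - ph$truth$cell_volume) / ph$truth$cell_volume
  expect_lt(max(err), 0.06)

  # pairwise disjoint by construction; nuclei contained in own cell
  for (i in seq_len(nrow(ph$truth))) {
    nm <- ph$nucleus_labels == i
    expect_gte(sum(seg$labels[nm] == i) / sum(nm), 0.9)
  }

  # degenerate: one seed in a zero-confidence volume fills to max_radius
  zero <- array(0, c(40, 40, 40))
  s1 <- seed_set(matrix(c(19.5, 19.5, 19.5), 1))
  seg0 <- segment_tumor_cells(zero, s1, 1, max_radius = 8)
  v <- sum(seg0$labels == 1)
  expect_rel_equal(v, 4 / 3 * pi * 8^3, 0.1)
  expect_true(seg0$flags$capped[1])

  expect_error(segment_tumor_cells(zero, seed_set(rbind(c(2, 2, 2), c(2, 2, 2))), 1),
               "duplicate")
  expect_error(segment_tumor_cells(zero, seed_set(matrix(c(99, 2, 2), 1)), 1),
               "outside")
})

test_that("AT2 segmentation recovers cell bodies within tolerance", {
  shape <- c(48L, 80L, 80L); voxel <- 0.5
  extent <- (shape - 1) * voxel
  cells <- list(
    cell_truth(extent * c(0.5, 0.3, 0.3), 582, 202, 2, cell_class = "AT2"),
    cell_truth(extent * c(0.5, 0.7, 0.3), 582, 202, 2, cell_class = "AT2"),
    cell_truth(extent * c(0.5, 0.5, 0.75), 582, 202, 2, cell_class = "AT2"))
  ph <- generate_phantom_stack(phantom_spec(shape, voxel, cells,
                                            background_level = 1, noise_sd = 1,
                                            rng_seed = 4))
  seg <- segment_at2_cells(ph$stack, spc_threshold = 12, erosion = 0.85)
  expect_equal(seg$n_cells, 3L)
  sizes <- tabulate(seg$labels[seg$labels > 0], 3) * voxel^3
  expect_true(all(abs(sizes - 582) / 582 < 0.1))

  expect_warning(s0 <- segment_at2_cells(ph$stack, spc_threshold = 300),
                 "no voxels above threshold")
  expect_equal(max(s0$labels), 0L)
})

test_that("erosion never increases neighbour contamination", {
  shape <- c(40L, 72L, 48L); voxel <- 0.5
  extent <- (shape - 1) * voxel
  # abutting pair: centres 10.4 um apart, radii ~5.18 um
  cells <- list(
    cell_truth(extent * c(0.5, 0.36, 0.5), 582, 202, 2, cell_class = "AT2"),
    cell_truth(extent * c(0.5, 0.36, 0.5) + c(0, 10.4, 0), 582, 202, 2,
               cell_class = "AT2"))
  ph <- generate_phantom_stack(phantom_spec(shape, voxel, cells,
                                            background_level = 1, noise_sd = 1,
                                            rng_seed = 8))
  contam <- function(ero) {
    seg <- segment_at2_cells(ph$stack, spc_threshold = 9, erosion = ero)
    if (max(seg$labels) == 0) return(0L)
    total <- 0L
    for (i in seq_len(max(seg$labels))) {
      inside <- ph$nucleus_labels[seg$labels == i]
      tb <- table(inside[inside > 0])
      if (!length(tb)) next
      own <- as.integer(names(which.max(tb)))
      total <- total + sum(inside > 0 & inside != own)
    }
    total
  }
  expect_gte(contam(0), contam(0.85))
})

test_that("stromal nuclei are filtered by edge distance and CK7", {
  shape <- c(40L, 64L, 64L); voxel <- 0.5
  extent <- (shape - 1) * voxel
  cells <- list(
    # interior CK7-negative stromal nucleus -> kept
    cell_truth(extent * c(0.5, 0.5, 0.3), 200, 150, 2, cell_class = "stromal"),
    # nucleus hugging a face (< 4 um margin) -> dropped
    cell_truth(c(3.2, extent[2] * 0.5, extent[3] * 0.72), 200, 150, 2,
               cell_class = "stromal"),
    # CK7-positive (tumor) nucleus -> dropped
    cell_truth(extent * c(0.5, 0.8, 0.72), 600, 150, 2, cell_class = "tumor"))
  ph <- generate_phantom_stack(phantom_spec(shape, voxel, cells,
                                            background_level = 1, noise_sd = 1,
                                            rng_seed = 6))
  seg <- segment_stromal_nuclei(ph$stack, dna_threshold = 10, edge_margin = 4,
                                ck7_max = 15)
  expect_equal(seg$n_nuclei, 1L)
  expect_length(seg$totals, 1L)
  # the survivor is the interior stromal nucleus
  w <- which(seg$labels == 1, arr.ind = TRUE)
  ctr <- (colMeans(w) - 1) * voxel
  expect_lt(sqrt(sum((ctr - extent * c(0.5, 0.5, 0.3))^2)), 2)
  expect_gt(seg$totals, 0)
})

test_that("QC applies the 10% edge/overlap rules and decile review", {
  d <- c(24L, 40L, 40L)
  cells <- array(0L, d); nuclei <- array(0L, d)
  # cell 1: clean interior
  cells[8:16, 8:16, 8:16] <- 1L
  nuclei[10:14, 10:14, 10:14] <- 1L
  # cell 2: clipped by the z face (many voxels on the face layer)
  cells[1:6, 24:34, 8:18] <- 2L
  nuclei[2:5, 26:32, 10:16] <- 2L
  # cell 3 overlaps most of cell 1's... a foreign nucleus 4
  cells[8:16, 24:36, 24:36] <- 3L
  nuclei[9:13, 25:29, 25:29] <- 4L  # foreign nucleus fully inside cell 3
  rep1 <- qc_cells(cells, nuclei)
  expect_true(rep1$pass[1])
  expect_true(rep1$edge_clipped[2])
  expect_false(rep1$pass[2])
  expect_true(rep1$nucleus_overlap_violation[3])
  expect_false(rep1$pass[3])

  # decile review is a flag, not a failure
  nc <- c(0.5, 0.52, 0.48)
  rep2 <- qc_cells(cells, nuclei, nc_ratio = nc)
  expect_true(any(rep2$nc_ratio_extreme))
  expect_true(rep2$pass[1])

  # fused double nuclei are retained; separated ones are fatal
  cells2 <- array(0L, d); nuclei2 <- array(0L, d)
  cells2[4:20, 4:20, 4:20] <- 1L
  nuclei2[6:10, 6:12, 6:12] <- 1L
  nuclei2[11:15, 6:12, 6:12] <- 1L  # touching blocks (fused)
  repf <- qc_cells(cells2, nuclei2)
  expect_false(repf$multinucleate[1])  # contiguous, so a single component
  nuclei2[11:15, , ] <- 0L
  nuclei2[14:18, 6:12, 6:12] <- 1L    # now separated by a gap
  reps <- qc_cells(cells2, nuclei2)
  expect_true(reps$multinucleate[1])
  expect_false(reps$pass[1])
})
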