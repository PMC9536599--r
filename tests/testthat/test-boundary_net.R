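# boundary_net: loss, training-set preparation, training behaviour,
# slice-wise prediction.

test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-12)
  # clamping keeps the loss finite at exact 0/1 predictions
  expect_true(is.finite(bce_loss(1, 0)))
  expect_error(bce_loss(c(1, 0), 0.5), "shape mismatch")
})

test_that("training-set preparation crops, normalises, augments and splits", {
  imgs <- lapply(1:6, function(i) matrix(runif(48 * 48, 0, 255), 48, 48))
  msks <- lapply(1:6, function(i) matrix(rbinom(48 * 48, 1, 0.1), 48, 48))
  cfg <- training_config(crop_size = 32L, target_train_size = 186L,
                         val_fraction = 0.2, rng_seed = 9L)
  sets <- prepare_training_set(imgs, msks, cfg)
  # 6 images x 4 corner crops = 24 base crops, augmented x (186/24) to 186,
  # split 20% validation
  n_val <- round(0.2 * 186)
  expect_length(sets$val, n_val)
  expect_length(sets$train, 186 - n_val)
  # normalisation: /255 and mean-centred per crop
  for (pr in sets$train[1:5]) {
    expect_lt(abs(mean(pr$image)), 1e-9)
    expect_lt(max(pr$image), 1)
    expect_true(all(pr$mask %in% c(0, 1)))
  }
  # deterministic given the seed
  sets2 <- prepare_training_set(imgs, msks, cfg)
  expect_identical(sets$train[[3]], sets2$train[[3]])

  expect_error(prepare_training_set(imgs[1], msks[1],
                                    training_config(crop_size = 64L)),
               "crop_size exceeds")
  expect_error(prepare_training_set(imgs, lapply(msks, t)[c(2:6, 1)], cfg),
               NA)  # same shapes still fine
  bad <- msks; bad[[2]] <- matrix(0, 12, 12)
  expect_error(prepare_training_set(imgs, bad, cfg), "mismatch")
})

test_that("the published augmentation arithmetic holds", {
  # 40 annotated slices -> 4 corner crops each -> 160 base crops;
  # augmentation to 4960 means 31 variants per base crop; a 0.2 validation
  # fraction of 4960 is 992 items
  expect_identical(40L * 4L, 160L)
  expect_equal(4960 / 160, 31)
  expect_identical(round(0.2 * 4960), 992)
  cfg <- training_config()
  expect_identical(cfg$crop_size, 448L)
  expect_identical(cfg$target_train_size, 4960L)
  expect_identical(cfg$val_fraction, 0.2)
  expect_identical(cfg$loss_threshold, 0.001)
})

test_that("training is seed-deterministic, stoppable, and flags edge cases", {
  crops <- normalize_crops(boundary_crops(10, seed = 21))
  cfg <- training_config(crop_size = 64L, max_epochs = 3L, lr = 5e-3,
                         base_channels = 4L, batch_size = 4L,
                         dropout_rate = 0, rng_seed = 13L)
  m1 <- train_boundary_net(cfg, crops[1:8], crops[9:10])
  m2 <- train_boundary_net(cfg, crops[1:8], crops[9:10])
  expect_identical(m1$train_loss, m2$train_loss)
  expect_identical(m1$val_loss, m2$val_loss)
  expect_length(m1$train_loss, 3L)
  expect_true(all(diff(m1$train_loss) < 0))

  cfg0 <- training_config(crop_size = 64L, max_epochs = 0L)
  m0 <- train_boundary_net(cfg0, crops[1:4])
  expect_false(m0$trained)
  ph <- tumor_phantom(1, shape = c(8L, 64L, 64L))
  expect_error(predict_boundaries(m0, ph$stack), "untrained")
})

test_that("prediction yields bounded confidence with ridge contrast", {
  crops <- normalize_crops(boundary_crops(12, seed = 31))
  cfg <- training_config(crop_size = 64L, max_epochs = 8L, lr = 5e-3,
                         base_channels = 6L, batch_size = 6L,
                         dropout_rate = 0, rng_seed = 3L)
  model <- train_boundary_net(cfg, crops)
  ph <- tumor_phantom(1, voxel = 1, shape = c(10L, 64L, 64L), noise_sd = 2,
                      vol_range = c(700, 900))
  conf <- predict_boundaries(model, ph$stack)
  expect_true(all(conf >= 0 & conf <= 1))
  iface <- array(cytovol3d:::cpp_label_boundary(
    as.integer(ph$cell_labels), as.integer(dim(ph$cell_labels)), FALSE),
    dim = dim(ph$cell_labels)) > 0
  expect_gt(mean(conf[iface]) - mean(conf[!iface]), 0.3)

  blank <- image_stack(list(CK7 = array(3, c(4L, 64L, 64L)),
                            DNA = array(0, c(4L, 64L, 64L))), 1)
  cb <- predict_boundaries(model, blank)
  expect_lt(diff(range(cb)), 0.25)   # near-uniform
  expect_lt(mean(cb), 0.5)           # and low

  # tiled prediction on a larger slice stays bounded and near the
  # untiled prediction away from borders
  big <- image_stack(list(CK7 = array(runif(1 * 96 * 96, 0, 255), c(1L, 96L, 96L)),
                          DNA = array(0, c(1L, 96L, 96L))), 1)
  cb2 <- predict_boundaries(model, big)
  expect_true(all(cb2 >= 0 & cb2 <= 1))
})

test_that("the classical fallback predictor honours the same contract", {
  ph <- tumor_phantom(2, noise_sd = 1, shape = c(32L, 64L, 64L))
  conf <- ridge_boundary_confidence(ph$stack)
  expect_true(all(conf >= 0 & conf <= 1))
  blank <- image_stack(list(CK7 = array(5, c(4, 8, 8)), DNA = array(0, c(4, 8, 8))), 1)
  expect_true(all(ridge_boundary_confidence(blank) == 0))
})
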