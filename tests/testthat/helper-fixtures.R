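# Shared fixtures: small phantoms, digitised shapes, synthetic boundary
# crops. Everything is generated in code at test time.

# digitised ball: 1 inside radius r (voxel units), centred in a dim^3 array
digitize_ball <- function(dim3, center, r) {
  a <- array(0L, dim = dim3)
  for (z in seq_len(dim3[1L])) {
    for (y in seq_len(dim3[2L])) {
      a[z, y, ] <- as.integer((z - center[1L])^2 + (y - center[2L])^2 +
                                (seq_len(dim3[3L]) - center[3L])^2 <= r^2)
    }
  }
  a
}

# small well-separated tumor phantom used by several suites
tumor_phantom <- function(n = 4, voxel = 0.5, seed = 11, noise_sd = 1,
                          vol_range = c(600, 1800), ploidy = 2,
                          shape = c(48L, 96L, 96L), ...) {
  extent <- (shape - 1) * voxel
  pos <- expand.grid(z = extent[1L] / 2,
                     y = extent[2L] * seq(0.25, 0.75, length.out = 2),
                     x = extent[3L] * seq(0.25, 0.75, length.out = 2))
  cells <- with_seed(seed + 1L, lapply(seq_len(min(n, nrow(pos))), function(i) {
    vol <- runif(1, vol_range[1L], vol_range[2L])
    cell_truth(as.numeric(pos[i, ]), vol, 0.35 * vol,
               ploidy = if (length(ploidy) > 1) sample(ploidy, 1) else ploidy,
               cell_class = "tumor")
  }))
  generate_phantom_stack(phantom_spec(shape, voxel, cells,
                                      noise_sd = noise_sd, rng_seed = seed,
                                      ...))
}

# synthetic 64x64 boundary-annotation crops: bright rings on dim discs
boundary_crops <- function(n, seed = 5, size = 64L) {
  with_seed(seed, replicate(n, {
    img <- matrix(0, size, size)
    msk <- matrix(0, size, size)
    for (k in seq_len(sample(2:4, 1))) {
      cy <- runif(1, 12, size - 12); cx <- runif(1, 12, size - 12)
      r <- runif(1, 7, 14)
      yy <- outer(seq_len(size), rep(1, size))
      xx <- t(yy)
      d <- sqrt((yy - cy)^2 + (xx - cx)^2)
      img[d <= r] <- pmax(img[d <= r], 60)
      band <- abs(d - r) <= 1.2
      img[band] <- 200
      msk[band] <- 1
    }
    img <- pmin(pmax(img + rnorm(size * size, 0, 8), 0), 255)
    list(image = matrix(img, size, size), mask = msk)
  }, simplify = FALSE))
}

# normalise crops the way prepare_training_set does
normalize_crops <- function(crops) {
  lapply(crops, function(cr) {
    im <- cr$image / 255
    list(image = im - mean(im), mask = cr$mask)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
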