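# Synthetic-data generators: labelled 3D phantom stacks, measurement tables
# shaped like the per-cell spreadsheet exports, boundary-annotation training
# pairs, and flow-cytometry event tables. Everything is seeded and returns
# ground truth so downstream stages can be tested without real acquisitions.

#' Ground truth for one phantom cell
#'
#' @param center physical coordinates (z, y, x) of the cell centre in
#'   micrometres (voxel index 0 sits at 0 um).
#' @param cell_volume cell body volume in fL (1 fL = 1 um^3).
#' @param nuclear_volume nuclear volume in fL; must be < `cell_volume`.
#' @param ploidy genome copy number in haploid units (2 = diploid).
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param axis_ratio relative semi-axis ratios (z, y, x) for ellipsoids.
#' @param cell_class `"AT2"`, `"tumor"` or `"stromal"`.
#' @param has_cavity if TRUE the nucleus contains a DNA-poor central void
#'   (10% of nuclear volume), emulating cavitated tumor nuclei.
#' @return a `cell_truth` list.
#' @export
cell_truth <- function(center, cell_volume, nuclear_volume, ploidy = 2,
                       shape = c("sphere", "ellipsoid"),
                       axis_ratio = c(1, 1, 1),
                       cell_class = c("tumor", "AT2", "stromal"),
                       has_cavity = FALSE) {
  shape <- match.arg(shape)
  cell_class <- match.arg(cell_class)
  stopifnot(length(center) == 3L, cell_volume > 0, nuclear_volume > 0,
            ploidy > 0)
  if (nuclear_volume >= cell_volume) {
    stop("nuclear_volume must be smaller than cell_volume")
  }
  structure(list(center = as.numeric(center), cell_volume = cell_volume,
                 nuclear_volume = nuclear_volume, ploidy = ploidy,
                 shape = shape, axis_ratio = as.numeric(axis_ratio),
                 cell_class = cell_class, has_cavity = isTRUE(has_cavity)),
            class = "cell_truth")
}

#' Phantom stack specification
#'
#' Describes a synthetic multi-channel acquisition: geometry of the cells,
#' depth attenuation, background and noise. Attenuation is linear in z: a
#' voxel at depth z is scaled by `1 + (1/attenuation_factor - 1) * z/(nz-1)`,
#' so `attenuation_factor = 2` dims the bottom plane 2-fold relative to the
#' top, matching the two-point correction scheme used downstream. DNA signal
#' integrates (before attenuation/noise/quantisation) to
#' `ploidy/2 * dna_total_2n` per nucleus; the proSPC-like channel is punctate
#' AT2 cytoplasm, the CK7-like channel a membrane-width band centred on the
#' true cell surface plus weak cytoplasm.
#'
#' @param stack_shape integer (nz, ny, nx) voxel counts.
#' @param voxel_size micrometres per voxel (z, y, x); scalar recycled.
#' @param cells list of [cell_truth()] objects.
#' @param attenuation_factor ratio of top/bottom brightness (>= 1 dims with
#'   depth); applied to CK7, DNA and LMN, not to SPC (the 488 nm channel
#'   shows no attenuation in this protocol).
#' @param background_level additive background intensity (8-bit units).
#' @param noise_sd additive Gaussian noise SD (8-bit units).
#' @param noise_cv multiplicative lognormal noise CV applied voxelwise to
#'   the signal before background/additive noise (the intensity-to-ploidy
#'   coupling is exactly linear before this noise).
#' @param rng_seed integer seed; all randomness in the generator flows
#'   through it.
#' @param dna_density_2n DNA-channel intensity per voxel for a diploid
#'   nucleus of the reference 202 fL volume; per-cell density is scaled so
#'   integrated intensity is exactly proportional to ploidy.
#' @param dna_edge_softness width (um) of the graded DNA fall-off just
#'   inside the nuclear surface (the stain is not a hard disc; the content
#'   inside an isosurface must decrease smoothly with threshold for the
#'   calibration sweeps to be meaningful). 0 gives hard-edged nuclei.
#' @param include_lamin add an `LMN` channel (nuclear-envelope band).
#' @param overlap_tolerance allowed overlapping-voxel fraction (of the
#'   smaller cell) before generation fails.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(stack_shape, voxel_size, cells,
                         attenuation_factor = 1, background_level = 2,
                         noise_sd = 0, noise_cv = 0, rng_seed = 1,
                         dna_density_2n = 80, dna_edge_softness = 0.75,
                         include_lamin = FALSE, overlap_tolerance = 0) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 4),
            all(voxel_size > 0), attenuation_factor > 0,
            background_level >= 0, noise_sd >= 0)
  extent <- (as.numeric(stack_shape) - 1) * voxel_size
  for (ct in cells) {
    if (any(ct$center < 0) || any(ct$center > extent)) {
      stop("cell center outside stack bounds: ",
           paste(signif(ct$center, 4), collapse = ", "))
    }
  }
  structure(list(stack_shape = as.integer(stack_shape),
                 voxel_size = voxel_size, cells = cells,
                 attenuation_factor = attenuation_factor,
                 background_level = background_level, noise_sd = noise_sd,
                 noise_cv = noise_cv,
                 rng_seed = as.integer(rng_seed),
                 dna_density_2n = dna_density_2n,
                 dna_edge_softness = dna_edge_softness,
                 include_lamin = isTRUE(include_lamin),
                 overlap_tolerance = overlap_tolerance),
            class = "phantom_spec")
}

# semi-axes (z, y, x) in um for a given volume and axis ratios
ellipsoid_semiaxes <- function(volume, axis_ratio) {
  s <- (3 * volume / (4 * pi * prod(axis_ratio)))^(1 / 3)
  s * axis_ratio
}

# normalised ellipsoid radius u(p) = sqrt(sum(((p - c)/a)^2)) on the voxel
# grid restricted to a bounding box; returns list(idx cube indices, u)
ellipsoid_field <- function(shape, voxel, center, axes, pad = 0) {
  lo <- pmax(1L, floor((center - axes - pad) / voxel) + 1L)
  hi <- pmin(shape, ceiling((center + axes + pad) / voxel) + 1L)
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  uz <- ((zi - 1) * voxel[1L] - center[1L]) / axes[1L]
  uy <- ((yi - 1) * voxel[2L] - center[2L]) / axes[2L]
  ux <- ((xi - 1) * voxel[3L] - center[3L]) / axes[3L]
  u2 <- outer(outer(uz^2, uy^2, "+"), ux^2, "+")
  list(zi = zi, yi = yi, xi = xi, u = sqrt(u2))
}

#' Generate a labelled phantom stack
#'
#' Rasterises the cells of a [phantom_spec()] into a multi-channel
#' [image_stack()] plus ground-truth cell and nucleus label volumes.
#' Integrated DNA intensity per nucleus (before attenuation, noise and
#' 8-bit quantisation) is exactly proportional to ploidy.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` ([image_stack()]), `cell_labels`,
#'   `nucleus_labels` (3D integer arrays) and `truth` (data.frame of
#'   per-cell ground truth incl. rasterised voxel counts).
#' @export
generate_phantom_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$stack_shape
  voxel <- spec$voxel_size
  nz <- shape[1L]
  cell_lab <- array(0L, dim = shape)
  nuc_lab <- array(0L, dim = shape)
  spc <- array(0, dim = shape)
  ck7 <- array(0, dim = shape)
  dna <- array(0, dim = shape)
  lmn <- if (spec$include_lamin) array(0, dim = shape) else NULL
  band_hw <- max(voxel)  # CK7 membrane band half-width, um

  truth <- data.frame(cell_id = integer(), cell_class = character(),
                      ploidy = numeric(), cell_volume = numeric(),
                      nuclear_volume = numeric(), cell_voxels = integer(),
                      nucleus_voxels = integer(), has_cavity = logical(),
                      center_z = numeric(), center_y = numeric(),
                      center_x = numeric())

  with_seed(spec$rng_seed, {
    for (i in seq_along(spec$cells)) {
      ct <- spec$cells[[i]]
      ratio <- if (ct$shape == "sphere") c(1, 1, 1) else ct$axis_ratio
      axes_c <- ellipsoid_semiaxes(ct$cell_volume, ratio)
      axes_n <- ellipsoid_semiaxes(ct$nuclear_volume, ratio)
      f <- ellipsoid_field(shape, voxel, ct$center, axes_c, pad = 2 * band_hw)
      inside <- f$u <= 1
      block <- cell_lab[f$zi, f$yi, f$xi]
      clash <- inside & block != 0L
      if (any(clash)) {
        n_clash <- sum(clash)
        other <- unique(block[clash])
        vol_vox <- min(sum(inside), sum(cell_lab == other[1L]))
        if (n_clash > spec$overlap_tolerance * vol_vox) {
          stop(sprintf("phantom cells overlap beyond tolerance: cell %d with cell(s) %s (%d voxels)",
                       i, paste(other, collapse = ", "), n_clash))
        }
        inside <- inside & block == 0L
      }
      block[inside] <- i
      cell_lab[f$zi, f$yi, f$xi] <- block

      # CK7 membrane band centred on the true surface, approx physical width
      u_hw <- band_hw / (prod(axes_c))^(1 / 3)
      band <- abs(f$u - 1) <= u_hw
      ck7_blk <- ck7[f$zi, f$yi, f$xi]
      if (ct$cell_class == "tumor") {
        ck7_blk[inside] <- pmax(ck7_blk[inside], 60)
        ck7_blk[band] <- 200
      } else if (ct$cell_class == "AT2") {
        ck7_blk[band] <- pmax(ck7_blk[band], 40)  # alveolar wall, weak in body
      }
      ck7[f$zi, f$yi, f$xi] <- ck7_blk

      # nucleus + optional cavity; DNA density normalised to ploidy
      fn <- ellipsoid_field(shape, voxel, ct$center, axes_n)
      nin <- fn$u <= 1
      nblk <- nuc_lab[fn$zi, fn$yi, fn$xi]
      nin <- nin & (cell_lab[fn$zi, fn$yi, fn$xi] == i)  # stay inside own cell
      nblk[nin] <- i
      nuc_lab[fn$zi, fn$yi, fn$xi] <- nblk
      cav <- rep(FALSE, length(nin))
      if (ct$has_cavity) {
        axes_cav <- ellipsoid_semiaxes(0.1 * ct$nuclear_volume, ratio)
        cav <- array(FALSE, dim = dim(fn$u))
        fc <- ellipsoid_field(shape, voxel, ct$center, axes_cav)
        # cavity box is inside nucleus box; mark via coordinates
        cz <- match(fc$zi, fn$zi); cy <- match(fc$yi, fn$yi)
        cx <- match(fc$xi, fn$xi)
        cav[cz, cy, cx] <- fc$u <= 1
        cav <- cav & nin
      }
      # DNA weights: flat core with a graded fall-off reaching zero at the
      # nuclear surface (u = 1); cavity voxels carry no DNA. Total is
      # renormalised so integrated intensity is exactly ploidy-proportional.
      r_gn <- (prod(axes_n))^(1 / 3)
      u0 <- max(0, 1 - 2 * spec$dna_edge_softness / r_gn)
      wgt <- ifelse(fn$u <= u0, 1,
                    ifelse(fn$u < 1, (1 - fn$u) / (1 - u0), 0))
      wgt[!nin] <- 0
      wgt[cav] <- 0
      if (sum(wgt) > 0) {
        ref_vox <- 202 / prod(voxel)  # diploid reference nucleus, voxels
        total <- (ct$ploidy / 2) * spec$dna_density_2n * ref_vox
        dblk <- dna[fn$zi, fn$yi, fn$xi]
        sel <- wgt > 0
        dblk[sel] <- total * wgt[sel] / sum(wgt)
        dna[fn$zi, fn$yi, fn$xi] <- dblk
      }
      if (!is.null(lmn)) {
        n_hw <- band_hw / (prod(axes_n))^(1 / 3)
        nband <- abs(fn$u - 1) <= n_hw
        lblk <- lmn[fn$zi, fn$yi, fn$xi]
        lblk[nband] <- 150
        lmn[fn$zi, fn$yi, fn$xi] <- lblk
      }
      # SPC puncta in AT2 cytoplasm
      if (ct$cell_class == "AT2") {
        cyto <- which(inside & !(fn_to_cell_mask(f, fn, dim(f$u))))
        sblk <- spc[f$zi, f$yi, f$xi]
        sblk[inside] <- pmax(sblk[inside], 30)
        if (length(cyto) > 0) {
          k <- max(1L, round(0.2 * length(cyto)))
          pick <- sample(cyto, k)
          sblk[pick] <- 180
        }
        spc[f$zi, f$yi, f$xi] <- sblk
      }
      truth <- rbind(truth, data.frame(
        cell_id = i, cell_class = ct$cell_class, ploidy = ct$ploidy,
        cell_volume = ct$cell_volume, nuclear_volume = ct$nuclear_volume,
        cell_voxels = sum(cell_lab == i), nucleus_voxels = sum(nuc_lab == i),
        has_cavity = ct$has_cavity, center_z = ct$center[1L],
        center_y = ct$center[2L], center_x = ct$center[3L]))
    }

    # attenuation (not SPC), background, noise, 8-bit quantisation
    att <- 1 + (1 / spec$attenuation_factor - 1) * (seq_len(nz) - 1) / (nz - 1)
    for (nm in c("ck7", "dna", "lmn")) {
      a <- switch(nm, ck7 = ck7, dna = dna, lmn = lmn)
      if (is.null(a)) next
      for (z in seq_len(nz)) a[z, , ] <- a[z, , ] * att[z]
      assign(nm, a)
    }
    finish <- function(a) {
      if (spec$noise_cv > 0) {
        a <- a * array(lnoise(length(a), spec$noise_cv), dim = dim(a))
      }
      a <- a + spec$background_level
      if (spec$noise_sd > 0) {
        a <- a + array(rnorm(length(a), 0, spec$noise_sd), dim = dim(a))
      }
      array(pmin(pmax(round(a), 0), 255), dim = dim(a))
    }
    spc <- finish(spc); ck7 <- finish(ck7); dna <- finish(dna)
    if (!is.null(lmn)) lmn <- finish(lmn)
  })

  channels <- list(SPC = spc, CK7 = ck7, DNA = dna)
  if (!is.null(lmn)) channels$LMN <- lmn
  list(stack = image_stack(channels, voxel, sprintf("phantom-%d", spec$rng_seed)),
       cell_labels = cell_lab, nucleus_labels = nuc_lab, truth = truth)
}

# helper: nucleus mask of cell i expressed on the cell bounding box grid
fn_to_cell_mask <- function(f, fn, dims) {
  m <- array(FALSE, dim = dims)
  zi <- match(fn$zi, f$zi); yi <- match(fn$yi, f$yi); xi <- match(fn$xi, f$xi)
  ok_z <- !is.na(zi); ok_y <- !is.na(yi); ok_x <- !is.na(xi)
  m[zi[ok_z], yi[ok_y], xi[ok_x]] <- (fn$u <= 1)[ok_z, ok_y, ok_x]
  m
}

#' Population specification for measurement tables
#'
#' The normal AT2 population is a two-Gaussian mixture in cell volume
#' (defaults: 2n peak 582 +/- 127 fL, 4n peak 1164 +/- 180 fL, 4n fraction
#' 0.17 so the mixture mean matches the observed overall AT2 mean of
#' ~682 fL); tumor populations are long-tailed lognormal by default
#' (moment-matched to the near-euploid tumor summary 1086 +/- 755.6 fL).
#'
#' @param n_normal,n_tumor,n_stromal population sizes.
#' @param normal_peak1,normal_peak2 c(mean, sd) of the AT2 cell-volume
#'   mixture components, fL.
#' @param peak2_fraction mixing fraction of the 4n component.
#' @param tumor_model `"lognormal"` or `"gaussian"`.
#' @param tumor_params for lognormal: c(meanlog, sdlog); for gaussian:
#'   c(mean, sd) in fL.
#' @param ploidy_mix data.frame with columns `ploidy`, `fraction` (sums
#'   to 1) for tumor cells.
#' @param proportionality_mode NULL (volumes independent of ploidy, drawn
#'   from `tumor_model`) or one of `"sub"`, `"proportional"`, `"supra"`:
#'   tumor volume = slope_mult * (582/2) * ploidy * lognormal noise, with
#'   slope multipliers 0.5 / 1 / 2.
#' @param slope_mult override the mode's slope multiplier.
#' @param stromal_mode_dna DNA intensity-sum at the diploid stromal mode.
#' @param dna_cv multiplicative lognormal CV of DNA totals.
#' @param rng_seed integer seed.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_normal = 0, n_tumor = 0, n_stromal = 30,
                            normal_peak1 = c(582, 127),
                            normal_peak2 = c(1164, 180),
                            peak2_fraction = 0.17,
                            tumor_model = c("lognormal", "gaussian"),
                            tumor_params = NULL,
                            ploidy_mix = data.frame(
                              ploidy = c(2, 4, 5, 6, 8),
                              fraction = c(0.45, 0.20, 0.15, 0.10, 0.10)),
                            proportionality_mode = NULL,
                            slope_mult = NULL,
                            stromal_mode_dna = 1e5, dna_cv = 0.05,
                            rng_seed = 1) {
  tumor_model <- match.arg(tumor_model)
  if (is.null(tumor_params)) {
    tumor_params <- if (tumor_model == "lognormal") {
      # moment match to 1086 +/- 755.6 fL
      cv2 <- (755.6 / 1086)^2
      c(meanlog = log(1086) - log(1 + cv2) / 2, sdlog = sqrt(log(1 + cv2)))
    } else {
      c(mean = 1086, sd = 755.6)
    }
  }
  stopifnot(n_normal >= 0, n_tumor >= 0, n_stromal >= 0,
            peak2_fraction >= 0, peak2_fraction <= 1)
  if (abs(sum(ploidy_mix$fraction) - 1) > 1e-8) {
    stop("ploidy_mix fractions must sum to 1")
  }
  if (!is.null(proportionality_mode)) {
    proportionality_mode <- match.arg(proportionality_mode,
                                      c("sub", "proportional", "supra"))
    if (is.null(slope_mult)) {
      slope_mult <- c(sub = 0.5, proportional = 1, supra = 2)[[proportionality_mode]]
    }
  }
  structure(list(n_normal = n_normal, n_tumor = n_tumor,
                 n_stromal = n_stromal, normal_peak1 = normal_peak1,
                 normal_peak2 = normal_peak2, peak2_fraction = peak2_fraction,
                 tumor_model = tumor_model, tumor_params = tumor_params,
                 ploidy_mix = ploidy_mix,
                 proportionality_mode = proportionality_mode,
                 slope_mult = slope_mult, stromal_mode_dna = stromal_mode_dna,
                 dna_cv = dna_cv, rng_seed = as.integer(rng_seed)),
            class = "population_spec")
}

# lognormal multiplicative noise with unit mean and given CV
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

sphere_surface <- function(v) pi^(1 / 3) * (6 * v)^(2 / 3)

#' Generate a per-cell measurement table
#'
#' Draws a population of normal AT2, tumor and stromal cells with known
#' generating distributions and fills the per-cell record schema used by
#' the whole pipeline. DNA totals are `ploidy/2 * stromal_mode *
#' multiplicative lognormal noise`.
#'
#' @param spec a [population_spec()].
#' @return data.frame of cell records (one row per cell).
#' @export
generate_measurement_table <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$rng_seed, {
    rows <- list()
    if (spec$n_normal > 0) {
      comp <- rbinom(spec$n_normal, 1, spec$peak2_fraction)
      mu <- ifelse(comp == 1, spec$normal_peak2[1], spec$normal_peak1[1])
      sdv <- ifelse(comp == 1, spec$normal_peak2[2], spec$normal_peak1[2])
      v <- rnorm(spec$n_normal, mu, sdv)
      v <- pmax(v, 60)
      nv <- ifelse(comp == 1, rnorm(spec$n_normal, 404, 68.4),
                   rnorm(spec$n_normal, 202, 34.2))
      nv <- pmin(pmax(nv, 30), 0.9 * v)
      ploidy <- ifelse(comp == 1, 4, 2)
      rows$normal <- data.frame(cell_class = "AT2", cell_volume = v,
                                nuclear_volume = nv, true_ploidy = ploidy)
    }
    if (spec$n_tumor > 0) {
      idx <- sample.int(nrow(spec$ploidy_mix), spec$n_tumor, replace = TRUE,
                        prob = spec$ploidy_mix$fraction)
      ploidy <- spec$ploidy_mix$ploidy[idx]
      if (!is.null(spec$proportionality_mode)) {
        v <- spec$slope_mult * (582 / 2) * ploidy * lnoise(spec$n_tumor, 0.15)
      } else if (spec$tumor_model == "lognormal") {
        v <- rlnorm(spec$n_tumor, spec$tumor_params[1], spec$tumor_params[2])
      } else {
        v <- pmax(rnorm(spec$n_tumor, spec$tumor_params[1],
                        spec$tumor_params[2]), 60)
      }
      nv <- pmin(0.42 * v * lnoise(spec$n_tumor, 0.2), 0.9 * v)
      rows$tumor <- data.frame(cell_class = "tumor", cell_volume = v,
                               nuclear_volume = nv, true_ploidy = ploidy)
    }
    if (spec$n_stromal > 0) {
      nv <- pmax(rnorm(spec$n_stromal, 150, 20), 40)
      rows$stroma <- data.frame(cell_class = "stromal",
                                cell_volume = nv * 1.3, nuclear_volume = nv,
                                true_ploidy = 2)
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab) || nrow(tab) == 0L) stop("empty population spec")
    n <- nrow(tab)
    tab$cell_id <- seq_len(n)
    tab$patient_id <- "synthetic"
    tab$genotype <- ifelse(tab$cell_class == "tumor", "KRAS", "normal")
    tab$stage <- ifelse(tab$cell_class == "tumor", 2L, 0L)
    tab$stack_id <- sprintf("pop-%d", spec$rng_seed)
    tab$dna_total <- tab$true_ploidy / 2 * spec$stromal_mode_dna *
      lnoise(n, spec$dna_cv)
    tab$background <- 0
    tab$stromal_mode <- spec$stromal_mode_dna
    tab$dna_number <- tab$dna_total / spec$stromal_mode_dna
    tab$estimated_ploidy <- 2 * tab$dna_number
    tab$cell_surface <- sphere_surface(tab$cell_volume) / 0.8  # mildly aspherical
    tab$nuclear_surface <- sphere_surface(tab$nuclear_volume) / 0.9
    tab$sphericity <- sphere_surface(tab$cell_volume) / tab$cell_surface
    tab$ellipticity_prolate <- 0.25
    tab$ellipticity_oblate <- 0.15
    tab$n_nuclei <- 1L
    tab$cytoplasm_volume <- tab$cell_volume - tab$nuclear_volume
    tab$nc_ratio <- tab$nuclear_volume / tab$cytoplasm_volume
    tab$cell_sv_ratio <- tab$cell_surface / tab$cell_volume
    tab$elongation <- tab$ellipticity_prolate / tab$ellipticity_oblate
    tab$genome_concentration <- tab$estimated_ploidy / tab$nuclear_volume
    tab$cv_over_n <- tab$cell_volume / tab$estimated_ploidy
    rownames(tab) <- NULL
    tab
  })
}

#' Generate synthetic flow-cytometry events
#'
#' Events are drawn from a mixture of groups with known cell area, ploidy,
#' viability and EPCAM status. SSC-W is generated by inverting the linear
#' area model `A = intercept + slope * SSC-W` (defaults -159, 4.35) plus
#' Gaussian noise; the DNA channel is proportional to ploidy.
#'
#' @param n number of events.
#' @param populations data.frame with columns `area` (um^2), `ploidy`,
#'   `live` (logical), `epcam` (logical), `fraction` (sums to 1).
#' @param rng_seed integer seed.
#' @param sscw_noise_sd Gaussian SD on SSC-W.
#' @param dna_mode_2n DRAQ5 intensity at the diploid mode.
#' @param area_model c(intercept, slope) of the area model to invert.
#' @return data.frame of events (`ssc_h`, `ssc_w`, `fsc_a`, `ssc_a`,
#'   `zombie_red`, `epcam`, `draq5`, plus generating-truth columns
#'   `true_area`, `true_ploidy`, `true_live`, `true_epcam`, `group`).
#' @export
generate_flow_events <- function(n, populations, rng_seed = 1,
                                 sscw_noise_sd = 0, dna_mode_2n = 1000,
                                 area_model = c(-159, 4.35)) {
  stopifnot(n > 0, all(c("area", "ploidy", "live", "epcam", "fraction")
                       %in% names(populations)))
  if (abs(sum(populations$fraction) - 1) > 1e-8) {
    stop("population fractions must sum to 1")
  }
  with_seed(rng_seed, {
    g <- sample.int(nrow(populations), n, replace = TRUE,
                    prob = populations$fraction)
    area <- populations$area[g]
    ploidy <- populations$ploidy[g]
    live <- as.logical(populations$live[g])
    epc <- as.logical(populations$epcam[g])
    ssc_w <- (area - area_model[1]) / area_model[2]
    if (sscw_noise_sd > 0) ssc_w <- ssc_w + rnorm(n, 0, sscw_noise_sd)
    draq5 <- ploidy / 2 * dna_mode_2n * lnoise(n, 0.08)
    zr <- ifelse(live, 100 * lnoise(n, 0.3), 3000 * lnoise(n, 0.3))
    ep <- ifelse(epc, 3000 * lnoise(n, 0.3), 120 * lnoise(n, 0.3))
    data.frame(ssc_h = runif(n, 80, 180), ssc_w = ssc_w,
               fsc_a = 50 + 2 * area * lnoise(n, 0.1),
               ssc_a = 30 + 1.5 * area * lnoise(n, 0.1),
               zombie_red = zr, epcam = ep, draq5 = draq5,
               true_area = area, true_ploidy = ploidy, true_live = live,
               true_epcam = epc, group = g)
  })
}

#' Extract boundary-annotation training pairs from a labelled stack
#'
#' For every z-slice containing at least one labelled cell, emits the CK7
#' image slice together with a 1-pixel-wide boundary mask marking label
#' interfaces (cell-cell and cell-background) in that slice.
#'
#' @param stack an [image_stack()] with a CK7 channel.
#' @param cell_labels 3D integer label array matching the stack.
#' @return list of `list(image, mask, z)`; `mask` is 0/1.
#' @export
generate_annotation_pairs <- function(stack, cell_labels) {
  stopifnot(inherits(stack, "image_stack"),
            all(dim(stack) == dim(cell_labels)))
  if (all(cell_labels == 0L)) stop("label volume is empty")
  ck7 <- get_channel(stack, "CK7")
  out <- list()
  d <- dim(cell_labels)
  for (z in seq_len(d[1L])) {
    sl <- cell_labels[z, , ]
    if (all(sl == 0L)) next
    m <- slice_boundary_mask(sl)
    out[[length(out) + 1L]] <- list(image = matrix(ck7[z, , ], nrow = d[2L]),
                                    mask = m, z = z)
  }
  out
}

# 2D label-interface mask: labelled pixel with a 4-neighbour of a different
# value (other label or background)
slice_boundary_mask <- function(sl) {
  ny <- nrow(sl); nx <- ncol(sl)
  m <- matrix(0L, ny, nx)
  diff_n <- matrix(FALSE, ny, nx)
  diff_n[-1, ] <- diff_n[-1, ] | (sl[-1, ] != sl[-ny, ])
  diff_n[-ny, ] <- diff_n[-ny, ] | (sl[-ny, ] != sl[-1, ])
  diff_n[, -1] <- diff_n[, -1] | (sl[, -1] != sl[, -nx])
  diff_n[, -nx] <- diff_n[, -nx] | (sl[, -nx] != sl[, -1])
  m[sl != 0L & diff_n] <- 1L
  m
}
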