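# 3D cell-body and nucleus segmentation: marker-controlled watershed on the
# boundary-confidence landscape for tumor cells, the masked-threshold /
# erosion pipeline for normal AT2 cells, DNA-thresholded stromal nuclei,
# and the automated QC rules that replace manual curation.

#' Seed set for marker-controlled segmentation
#'
#' @param centroids matrix with one row per seed, physical (z, y, x)
#'   micrometre coordinates.
#' @param seed_radius seed radius class in micrometres (1.6 um for 5-px
#'   marks, 2.75 um for 10-px marks at the 0.15 um acquisition).
#' @return a `seed_set` list.
#' @export
seed_set <- function(centroids, seed_radius = 1.6) {
  centroids <- matrix(as.numeric(centroids), ncol = 3L)
  stopifnot(seed_radius > 0)
  structure(list(centroids = centroids, seed_radius = seed_radius),
            class = "seed_set")
}

#' Derive seeds from idealised nuclear marks
#'
#' One centroid per connected component of the mark volume; the radius
#' class (1.6 vs 2.75 um) is inferred from the median component size.
#' Touching marks merge into a single component and produce one seed with
#' a warning.
#'
#' @param mark_volume 3D 0/1 (or intensity) array of nuclear marks.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @return a [seed_set()].
#' @export
seeds_from_marks <- function(mark_volume, voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  fg <- array(as.integer(mark_volume > 0), dim = dim(mark_volume))
  lab <- array(cpp_label6(as.integer(fg), as.integer(dim(fg))), dim = dim(fg))
  n <- max(lab)
  if (n == 0L) stop("mark volume contains no marks")
  cent <- matrix(0, n, 3L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  for (i in seq_len(n)) {
    w <- which(lab == i, arr.ind = TRUE)
    cent[i, ] <- (colMeans(w) - 1) * voxel_size
  }
  # mark radius class: 5-px marks (0.75 um at the 0.15 um raster) map to
  # the 1.6 um object radius, 10-px marks (1.5 um) to the 2.75 um object;
  # the midpoint 1.125 um separates the two classes
  med_vol <- median(sizes) * prod(voxel_size)
  r_eq <- (3 * med_vol / (4 * pi))^(1 / 3)
  radius <- if (r_eq <= 1.125) 1.6 else 2.75
  big <- sizes > 1.8 * median(sizes)
  if (any(big)) {
    warning(sprintf("%d mark component(s) look like merged touching marks",
                    sum(big)))
  }
  seed_set(cent, radius)
}

#' Segment tumor cells by seeded watershed on boundary confidence
#'
#' Grows one label per seed over the smoothed confidence landscape
#' (priority flooding from low confidence upward). The volume border acts
#' as an implicit background marker so labels settle on confidence ridges;
#' growth is additionally capped at `max_radius` from each seed. Labels
#' touching the stack faces are flagged.
#'
#' @param confidence 3D array in `[0, 1]` (e.g. [predict_boundaries()] or
#'   [ridge_boundary_confidence()]).
#' @param seeds a [seed_set()].
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param smoothing Gaussian smoothing of the landscape, micrometres.
#' @param max_radius growth cap per seed, micrometres.
#' @param background_seed add the implicit border background marker.
#' @return list with `labels` (3D integer array; 0 background) and
#'   `flags` (data.frame: label, edge_touch, capped).
#' @export
segment_tumor_cells <- function(confidence, seeds, voxel_size,
                                smoothing = 0.3, max_radius = 20,
                                background_seed = TRUE) {
  stopifnot(inherits(seeds, "seed_set"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  d <- dim(confidence)
  cent <- seeds$centroids
  if (nrow(cent) < 1L) stop("at least one seed is required")
  vox <- sweep(cent, 2L, voxel_size, "/")
  vi <- round(vox) + 1
  if (any(vi < 1) || any(sweep(vi, 2L, d, ">"))) {
    bad <- which(apply(vi, 1L, function(r) any(r < 1) || any(r > d)))
    stop("seed(s) outside the volume: ", paste(bad, collapse = ", "))
  }
  lin <- vi[, 1L] + d[1L] * ((vi[, 2L] - 1) + d[2L] * (vi[, 3L] - 1))
  if (anyDuplicated(lin)) {
    stop("duplicate seeds at the same voxel: ",
         paste(which(duplicated(lin)), collapse = ", "))
  }
  elev <- gauss3d(confidence, voxel_size, smoothing)
  n_seed <- nrow(cent)
  markers <- array(0L, dim = d)
  markers[lin] <- seq_len(n_seed)
  bg_label <- n_seed + 1L
  if (background_seed) {
    markers[1, , ] <- ifelse(markers[1, , ] == 0L, bg_label, markers[1, , ])
    markers[d[1L], , ] <- ifelse(markers[d[1L], , ] == 0L, bg_label, markers[d[1L], , ])
    markers[, 1, ] <- ifelse(markers[, 1, ] == 0L, bg_label, markers[, 1, ])
    markers[, d[2L], ] <- ifelse(markers[, d[2L], ] == 0L, bg_label, markers[, d[2L], ])
    markers[, , 1] <- ifelse(markers[, , 1] == 0L, bg_label, markers[, , 1])
    markers[, , d[3L]] <- ifelse(markers[, , d[3L]] == 0L, bg_label, markers[, , d[3L]])
  }
  # `centers` has one row per real seed only, so the background label
  # (bg_label > nrow(centers)) floods without a radius cap
  lab <- cpp_watershed(as.numeric(elev), as.integer(markers),
                       rep(1L, prod(d)), as.integer(d),
                       as.numeric(voxel_size), cent, max_radius)
  lab <- array(lab, dim = d)
  lab[lab == bg_label] <- 0L
  flags <- data.frame(label = seq_len(n_seed), edge_touch = FALSE,
                      capped = FALSE)
  for (i in seq_len(n_seed)) {
    m <- lab == i
    if (!any(m)) next
    w <- which(m, arr.ind = TRUE)
    flags$edge_touch[i] <- any(w == 1L) || any(sweep(w, 2L, d, "=="))
    # capped if some voxels sit at the max_radius shell
    dist2 <- colSums((t(sweep(w, 2L, c(1, 1, 1), "-")) * voxel_size -
                        cent[i, ])^2)
    flags$capped[i] <- max(sqrt(dist2)) > 0.95 * max_radius
  }
  list(labels = lab, flags = flags)
}

#' Segment normal AT2 cell bodies
#'
#' Automated version of the masked-threshold pipeline: coarse SPC
#' isosurface (threshold 7-12) at 1 um smoothing, 3D erosion by
#' 0.7-1 um via the distance transform, removal of process-scale
#' fragments, and splitting of touching bodies with 5 um seed points
#' (watershed on the negative distance transform).
#'
#' @param stack an [image_stack()] with an SPC channel.
#' @param spc_threshold isovolume threshold on SPC (7-12).
#' @param erosion 3D erosion depth, micrometres (0.7-1).
#' @param split_seed_diameter seed-point diameter for splitting, um.
#' @param smoothing coarse smoothing, um.
#' @param min_volume minimum retained fragment volume, fL.
#' @return list with `labels` and `n_cells`.
#' @export
segment_at2_cells <- function(stack, spc_threshold = 9, erosion = 0.85,
                              split_seed_diameter = 5, smoothing = 1,
                              min_volume = 150) {
  spc <- get_channel(stack, "SPC")
  d <- dim(spc)
  voxel <- stack$voxel_size
  sm <- gauss3d(spc, voxel, smoothing)
  fg <- sm >= spc_threshold
  if (!any(fg)) {
    warning("SPC channel has no voxels above threshold; empty labels")
    return(list(labels = array(0L, dim = d), n_cells = 0L))
  }
  if (erosion > 0) {
    edt <- array(cpp_edt_sq(as.integer(fg), as.integer(d), as.numeric(voxel)),
                 dim = d)
    fg <- edt > erosion^2
    if (!any(fg)) {
      warning("erosion removed all foreground; empty labels")
      return(list(labels = array(0L, dim = d), n_cells = 0L))
    }
  }
  labs <- split_binary(fg, voxel, split_seed_diameter)
  # drop process-scale fragments
  labs <- drop_small_labels(labs, min_voxels = ceiling(min_volume / prod(voxel)))
  list(labels = labs, n_cells = max(labs))
}

# watershed split of a binary mask using distance-transform maxima
# separated by at least `seed_diameter`
split_binary <- function(fg, voxel, seed_diameter) {
  d <- dim(fg)
  edt <- array(cpp_edt_sq(as.integer(fg), as.integer(d), as.numeric(voxel)),
               dim = d)
  edt <- sqrt(edt)
  peaks <- cpp_local_maxima(as.numeric(edt), as.integer(d),
                            as.numeric(voxel), seed_diameter,
                            min(voxel) * 0.5)
  if (length(peaks) == 0L) {
    return(array(cpp_label6(as.integer(fg), as.integer(d)), dim = d))
  }
  # greedy suppression: peaks are sorted by depth; keep those farther than
  # seed_diameter from any kept peak
  coords <- arrayInd(peaks, d)
  phys <- sweep(coords - 1, 2L, voxel, "*")
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dmin <- min(sqrt(colSums((t(phys[keep, , drop = FALSE]) - phys[i, ])^2)))
    if (dmin >= seed_diameter) keep[i] <- TRUE
  }
  markers <- array(0L, dim = d)
  markers[peaks[keep]] <- seq_len(sum(keep))
  lab <- cpp_watershed(as.numeric(-edt), as.integer(markers),
                       as.integer(fg), as.integer(d), as.numeric(voxel),
                       matrix(0, 0, 3), -1)
  array(lab, dim = d)
}

drop_small_labels <- function(labs, min_voxels) {
  n <- max(labs)
  if (n == 0L) return(labs)
  sizes <- tabulate(labs[labs > 0L], nbins = n)
  keep <- which(sizes >= min_voxels)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- labs
  out[labs > 0L] <- remap[labs[labs > 0L]]
  array(as.integer(out), dim = dim(labs))
}

#' Segment stromal (normal control) nuclei
#'
#' DNA-thresholded nuclei, split with 3 um seed points, filtered to be
#' CK7-negative and at least `edge_margin` from every stack face.
#'
#' @param stack an [image_stack()] with DNA (and optionally CK7) channels.
#' @param dna_threshold isovolume threshold on the DNA channel.
#' @param edge_margin minimum distance from stack faces, micrometres.
#' @param ck7_max mean-CK7 cutoff above which a nucleus is CK7-positive.
#' @param split_seed_diameter seed diameter for splitting, um.
#' @param min_volume minimum nucleus volume, fL.
#' @return list with `labels`, `n_nuclei` and `totals` (DNA intensity sums
#'   per retained nucleus).
#' @export
segment_stromal_nuclei <- function(stack, dna_threshold = 20, edge_margin = 4,
                                   ck7_max = 15, split_seed_diameter = 3,
                                   min_volume = 40) {
  dna <- get_channel(stack, "DNA")
  ck7 <- get_channel(stack, "CK7", required = FALSE)
  d <- dim(dna)
  voxel <- stack$voxel_size
  sm <- gauss3d(dna, voxel, 0.3)
  fg <- sm >= dna_threshold
  if (!any(fg)) return(list(labels = array(0L, dim = d), n_nuclei = 0L,
                            totals = numeric(0)))
  labs <- split_binary(fg, voxel, split_seed_diameter)
  labs <- drop_small_labels(labs, ceiling(min_volume / prod(voxel)))
  n <- max(labs)
  if (n == 0L) return(list(labels = labs, n_nuclei = 0L, totals = numeric(0)))
  keep <- logical(n)
  totals <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(labs == i, arr.ind = TRUE)
    phys <- sweep(w - 1, 2L, voxel, "*")
    extent <- sweep(matrix(d - 1, nrow(w), 3L, byrow = TRUE), 2L, voxel, "*")
    margin <- min(phys, extent - phys)
    ck7_mean <- if (is.null(ck7)) 0 else mean(ck7[labs == i])
    keep[i] <- margin >= edge_margin && ck7_mean <= ck7_max
    totals[i] <- sum(dna[labs == i])
  }
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  out <- labs
  out[labs > 0L] <- remap[labs[labs > 0L]]
  list(labels = array(as.integer(out), dim = d), n_nuclei = sum(keep),
       totals = totals[keep])
}

#' Automated segmentation quality control
#'
#' Replaces the manual curation rounds with their quantified rules: a cell
#' fails if more than 10% of its voxels lie on the stack faces
#' (edge-clipped), or if it overlaps more than 10% of any foreign nucleus.
#' N:C ratios in the top or bottom decile are flagged for review (warning,
#' not fatal). Multinucleate cells are fatal unless their nuclei are
#' 6-adjacent (fused envelopes).
#'
#' @param cells,nuclei 3D label arrays (matched ids where applicable).
#' @param edge_fraction,overlap_fraction fatal thresholds (default 0.1).
#' @param nc_ratio optional numeric vector of N:C ratios indexed by cell
#'   label, used for the decile review flag.
#' @return data.frame QC report with per-label flags and `pass`.
#' @export
qc_cells <- function(cells, nuclei, nc_ratio = NULL,
                     edge_fraction = 0.1, overlap_fraction = 0.1) {
  d <- dim(cells)
  n <- max(cells)
  if (n == 0L) {
    return(data.frame(label = integer(), edge_clipped = logical(),
                      nucleus_overlap_violation = logical(),
                      nc_ratio_extreme = logical(), multinucleate = logical(),
                      pass = logical()))
  }
  face <- array(FALSE, dim = d)
  face[1, , ] <- TRUE; face[d[1L], , ] <- TRUE
  face[, 1, ] <- TRUE; face[, d[2L], ] <- TRUE
  face[, , 1] <- TRUE; face[, , d[3L]] <- TRUE
  nuc_sizes <- if (max(nuclei) > 0) tabulate(nuclei[nuclei > 0], max(nuclei)) else integer(0)
  rep_out <- data.frame(label = seq_len(n), edge_clipped = FALSE,
                        nucleus_overlap_violation = FALSE,
                        nc_ratio_extreme = FALSE, multinucleate = FALSE,
                        fused_ok = FALSE)
  for (i in seq_len(n)) {
    m <- cells == i
    vol <- sum(m)
    if (vol == 0L) next
    rep_out$edge_clipped[i] <- sum(m & face) / vol > edge_fraction
    inside <- nuclei[m]
    foreign <- setdiff(unique(inside[inside > 0L]), i)
    for (f in foreign) {
      if (sum(inside == f) / nuc_sizes[f] > overlap_fraction) {
        rep_out$nucleus_overlap_violation[i] <- TRUE
      }
    }
    own <- nuclei == i & m
    # multinucleate: own nucleus label splits into several components
    if (any(own)) {
      comp <- cpp_label6(as.integer(own), as.integer(d))
      ncomp <- max(comp)
      if (ncomp > 1L) {
        rep_out$multinucleate[i] <- TRUE
        rep_out$fused_ok[i] <- nuclei_adjacent(array(comp, dim = d))
      }
    }
  }
  if (!is.null(nc_ratio)) {
    qs <- quantile(nc_ratio, c(0.1, 0.9), na.rm = TRUE)
    idx <- seq_len(min(n, length(nc_ratio)))
    rep_out$nc_ratio_extreme[idx] <- nc_ratio[idx] < qs[1L] | nc_ratio[idx] > qs[2L]
  }
  rep_out$pass <- !rep_out$edge_clipped & !rep_out$nucleus_overlap_violation &
    (!rep_out$multinucleate | rep_out$fused_ok)
  rep_out
}

# are the connected components of a nucleus mask 6-adjacent (within 1
# voxel of each other)?
nuclei_adjacent <- function(comp) {
  d <- dim(comp)
  # dilate component 1 by one voxel and test intersection with others
  m1 <- comp == 1L
  edt <- array(cpp_edt_sq(as.integer(!m1), as.integer(d), c(1, 1, 1)),
               dim = d)
  near <- edt <= 1
  any(comp > 1L & near)
}
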