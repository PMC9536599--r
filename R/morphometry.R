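# Per-cell and per-nucleus feature extraction: volumes (voxel count times
# voxel volume), surfaces (marching-tetrahedra isosurface on the lightly
# smoothed binary mask), sphericity, inertia-tensor ellipticities, derived
# record columns, nuclear-shell DNA enrichment, the Ki-67 retention
# cascade, and 2D long-axis measurement.

#' Measure one label: volume, surface, sphericity, ellipticities
#'
#' Volume is exact voxel arithmetic (`count * voxel volume`). Surface area
#' comes from a marching-tetrahedra mesh of the 0.5-isosurface of the
#' smoothed binary mask, which tracks the physical surface of digitised
#' spheres to about a percent. Sphericity `pi^(1/3) (6V)^(2/3) / A` is
#' clamped at 1 (the mesh can undercount the area of a digitised sphere by
#' a fraction of a percent). Ellipticities use the inertia-tensor semi-axes
#' a >= b >= c of the equivalent ellipsoid with the package convention
#' `prolate = (2a - b - c) / (2a)` and `oblate = (a + b - 2c) / (a + b)`
#' (both 0 for a sphere; prolate dominates for cigar shapes, oblate for
#' discs; only their ratio, the elongation, is consumed downstream).
#'
#' @param mask 3D logical/0-1 array for one label.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param smooth_vox pre-mesh smoothing sigma in voxels.
#' @return list `(volume, surface, sphericity, ellipticity_prolate,
#'   ellipticity_oblate, centroid)`; volume fL, surface um^2.
#' @export
measure_label <- function(mask, voxel_size, smooth_vox = 0.7) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  d <- dim(mask)
  m <- array(as.numeric(mask > 0), dim = d)
  nvox <- sum(m)
  if (nvox == 0L) stop("empty label")
  volume <- nvox * prod(voxel_size)
  sm <- if (smooth_vox > 0) {
    array(cpp_gauss_smooth(as.numeric(m), as.integer(d),
                           rep(smooth_vox, 3L)), dim = d)
  } else m
  surface <- cpp_mesh_area(as.numeric(sm), as.integer(d),
                           as.numeric(voxel_size), 0.5)
  sphericity <- min(1, pi^(1 / 3) * (6 * volume)^(2 / 3) / surface)

  w <- which(m > 0, arr.ind = TRUE)
  phys <- sweep(w - 1, 2L, voxel_size, "*")
  ctr <- colMeans(phys)
  cc <- sweep(phys, 2L, ctr, "-")
  cov3 <- crossprod(cc) / nvox + diag(voxel_size^2 / 12)  # voxel extent term
  ev <- sort(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  semi <- sqrt(5 * pmax(ev, 0))  # uniform-ellipsoid relation
  a <- semi[1L]; b <- semi[2L]; c3 <- semi[3L]
  list(volume = volume, surface = surface, sphericity = sphericity,
       ellipticity_prolate = (2 * a - b - c3) / (2 * a),
       ellipticity_oblate = (a + b - 2 * c3) / (a + b),
       centroid = ctr)
}

#' Assemble a full cell record
#'
#' Combines cell and nucleus features with a ploidy estimate into the
#' per-cell record schema, filling all derived columns. When nuclear
#' measurements are absent the DNA-derived columns are NA ("not measured").
#'
#' @param cell list from [measure_label()] for the cell body.
#' @param nucleus list from [measure_label()] for the nucleus, or NULL.
#' @param ploidy a `ploidy_estimate` from [estimate_ploidy()], or NULL.
#' @param meta named list of identifiers (patient_id, genotype, stage,
#'   stack_id, cell_id) and optionally dna_total, background, stromal_mode,
#'   n_nuclei.
#' @return one-row data.frame.
#' @export
derive_record <- function(cell, nucleus = NULL, ploidy = NULL, meta = list()) {
  v <- cell$volume
  nv <- if (is.null(nucleus)) NA_real_ else nucleus$volume
  if (!is.na(nv) && nv >= v) {
    stop("nuclear volume must be smaller than cell volume")
  }
  est <- if (is.null(ploidy)) NA_real_ else ploidy$estimated_ploidy
  cyto <- if (is.na(nv)) NA_real_ else v - nv
  data.frame(
    patient_id = meta$patient_id %||% NA_character_,
    genotype = meta$genotype %||% NA_character_,
    stage = meta$stage %||% NA_integer_,
    stack_id = meta$stack_id %||% NA_character_,
    cell_id = meta$cell_id %||% NA_integer_,
    cell_volume = v,
    cell_surface = cell$surface,
    cytoplasm_volume = cyto,
    sphericity = cell$sphericity,
    ellipticity_prolate = cell$ellipticity_prolate,
    ellipticity_oblate = cell$ellipticity_oblate,
    nuclear_volume = nv,
    nuclear_surface = if (is.null(nucleus)) NA_real_ else nucleus$surface,
    n_nuclei = meta$n_nuclei %||% (if (is.null(nucleus)) 0L else 1L),
    dna_total = meta$dna_total %||% NA_real_,
    background = meta$background %||% NA_real_,
    stromal_mode = meta$stromal_mode %||% NA_real_,
    dna_number = if (is.null(ploidy)) NA_real_ else ploidy$dna_number,
    estimated_ploidy = est,
    near_euploid = if (is.null(ploidy)) NA else ploidy$near_euploid,
    nc_ratio = if (is.na(cyto) || cyto <= 0) NA_real_ else nv / cyto,
    cell_sv_ratio = cell$surface / v,
    elongation = cell$ellipticity_prolate / cell$ellipticity_oblate,
    genome_concentration = if (is.na(nv)) NA_real_ else est / nv,
    cv_over_n = v / est,
    stringsAsFactors = FALSE
  )
}

#' DNA enrichment in the nuclear-envelope shell
#'
#' The shell is the nucleus minus its erosion by `shell_width` (distance
#' transform); enrichment is the shell's mean DNA density divided by the
#' whole-nucleus mean density (the core-referenced variant divides by the
#' eroded-core density instead). Invariant under global DNA intensity
#' scaling. If erosion leaves no core the shell equals the whole nucleus
#' (enrichment 1) and a warning is emitted.
#'
#' @param nucleus_mask 3D logical/0-1 nucleus mask.
#' @param dna 3D DNA-channel array.
#' @param voxel_size micrometres per voxel.
#' @param shell_width erosion depth in micrometres (1.5).
#' @param reference `"whole"` (default) or `"core"`.
#' @return list `(shell_density, whole_density, enrichment, shell_voxels)`.
#' @export
shell_enrichment <- function(nucleus_mask, dna, voxel_size,
                             shell_width = 1.5, reference = c("whole", "core")) {
  reference <- match.arg(reference)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  d <- dim(nucleus_mask)
  m <- nucleus_mask > 0
  if (!any(m)) stop("empty nucleus mask")
  edt <- sqrt(array(cpp_edt_sq(as.integer(m), as.integer(d),
                               as.numeric(voxel_size)), dim = d))
  core <- m & edt > shell_width
  shell <- m & !core
  whole_density <- sum(dna[m]) / sum(m)
  if (!any(core)) {
    warning("nucleus thinner than 2x shell width everywhere; shell equals whole nucleus")
    return(list(shell_density = whole_density, whole_density = whole_density,
                enrichment = 1, shell_voxels = sum(shell)))
  }
  shell_density <- sum(dna[shell]) / sum(shell)
  ref_density <- if (reference == "whole") whole_density else
    sum(dna[core]) / sum(core)
  list(shell_density = shell_density, whole_density = whole_density,
       enrichment = shell_density / ref_density, shell_voxels = sum(shell))
}

#' Ki-67 proliferation retention cascade
#'
#' Retains nuclei that are CK7-positive (total CK7 >= 3e4, the cut below
#' which nuclei were always outside the tumor envelope) and pass the
#' proliferation filter: total Ki-67 strictly > 2e4, sphericity > 0.5 and
#' volume > 150 um^3.
#'
#' @param records data.frame with columns `sphericity` and `volume` (or
#'   `nuclear_volume`).
#' @param ck7_totals,ki67_totals numeric vectors aligned with `records`.
#' @param ck7_min,ki67_min,sphericity_min,volume_min cascade thresholds.
#' @return the retained subset of `records`.
#' @export
ki67_filter <- function(records, ck7_totals, ki67_totals,
                        ck7_min = 3e4, ki67_min = 2e4,
                        sphericity_min = 0.5, volume_min = 150) {
  vol <- records$volume %||% records$nuclear_volume
  stopifnot(length(ck7_totals) == nrow(records),
            length(ki67_totals) == nrow(records))
  keep <- ck7_totals >= ck7_min &
    ki67_totals > ki67_min &
    records$sphericity > sphericity_min &
    vol > volume_min
  records[keep, , drop = FALSE]
}

#' 2D long axis of a nucleus
#'
#' Longest axis of the best-fit ellipse of the z-projection (principal
#' component analysis of projected voxel coordinates; full axis length =
#' 4 sd along the major direction, exact for a filled ellipse).
#'
#' @param nucleus_mask 3D logical/0-1 mask.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @return long axis length in micrometres.
#' @export
long_axis_2d <- function(nucleus_mask, voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  m <- nucleus_mask > 0
  if (!any(m)) stop("empty label")
  proj <- apply(m, c(2L, 3L), any)
  w <- which(proj, arr.ind = TRUE)
  phys <- sweep(w - 1, 2L, voxel_size[2:3], "*")
  cc <- sweep(phys, 2L, colMeans(phys), "-")
  cov2 <- crossprod(cc) / nrow(cc) + diag(voxel_size[2:3]^2 / 12)
  ev <- max(eigen(cov2, symmetric = TRUE, only.values = TRUE)$values)
  4 * sqrt(ev)  # uniform filled ellipse: axis = 4 sd
}
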