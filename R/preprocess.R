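# Raw-data corrections applied before segmentation: two-point depth
# attenuation correction and Gaussian high-pass background subtraction.

# Gaussian smoothing of a 3D array with sigma in micrometres (isotropic in
# physical space, converted per axis to voxel units).
gauss3d <- function(arr, voxel_size, sigma_um) {
  if (sigma_um <= 0) return(arr)
  d <- dim(arr)
  s <- sigma_um / voxel_size
  out <- cpp_gauss_smooth(as.numeric(arr), as.integer(d), as.numeric(s))
  array(out, dim = d)
}

#' Two-point attenuation model
#'
#' Mean reference intensities of a uniformly staining structure measured
#' near the top and bottom of the stack; the correction gain is linear in z
#' between the two reference planes (and extrapolated beyond them).
#'
#' @param top_reference,bottom_reference mean intensities (> 0).
#' @param top_z,bottom_z 1-based z indices of the reference planes;
#'   `top_z < bottom_z`.
#' @return an `attenuation_model` list.
#' @export
attenuation_model <- function(top_reference, bottom_reference, top_z, bottom_z) {
  if (top_reference <= 0 || bottom_reference <= 0) {
    stop("attenuation references must be positive")
  }
  if (top_z >= bottom_z) stop("top_z must be smaller than bottom_z")
  structure(list(top_reference = top_reference,
                 bottom_reference = bottom_reference,
                 top_z = as.integer(top_z), bottom_z = as.integer(bottom_z)),
            class = "attenuation_model")
}

#' Correct depth attenuation on one channel
#'
#' Multiplies each z-plane by a gain interpolated linearly in z so that the
#' corrected bottom reference equals the top reference: the gain is 1 at
#' `top_z` and `top_reference/bottom_reference` at `bottom_z`. The
#' correction commutes with global intensity scaling.
#'
#' @param stack an [image_stack()].
#' @param channel channel role to correct.
#' @param model an [attenuation_model()] measured on that channel.
#' @return the stack with the corrected (floating point) channel.
#' @export
correct_attenuation <- function(stack, channel, model) {
  stopifnot(inherits(stack, "image_stack"), inherits(model, "attenuation_model"))
  a <- get_channel(stack, channel)
  nz <- dim(a)[1L]
  g_bottom <- model$top_reference / model$bottom_reference
  z <- seq_len(nz)
  gain <- 1 + (g_bottom - 1) * (z - model$top_z) / (model$bottom_z - model$top_z)
  gain <- pmax(gain, 0)
  for (i in z) a[i, , ] <- a[i, , ] * gain[i]
  stack$channels[[channel]] <- a
  stack
}

#' Background subtraction (Gaussian high-pass)
#'
#' Estimates the smooth background as a Gaussian blur with
#' `sigma = filter_width / 2` and subtracts it, clipping at zero. Constant
#' images map to zero; structures much smaller than the filter width pass
#' through nearly unchanged. The default width matches the standard 33.7 um
#' filter of the acquisition software this reimplements.
#'
#' @param stack an [image_stack()].
#' @param channels channel roles to process (default: all).
#' @param filter_width filter width in micrometres; must exceed the voxel
#'   size.
#' @return the stack with background-subtracted channels.
#' @export
subtract_background <- function(stack, channels = names(stack$channels),
                                filter_width = 33.7) {
  stopifnot(inherits(stack, "image_stack"))
  if (filter_width <= max(stack$voxel_size)) {
    stop("filter_width must be larger than the voxel size")
  }
  sigma <- filter_width / 2
  for (ch in channels) {
    a <- get_channel(stack, ch)
    bg <- gauss3d(a, stack$voxel_size, sigma)
    stack$channels[[ch]] <- pmax(a - bg, 0)
  }
  stack
}
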