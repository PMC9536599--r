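#' Multi-channel 3D image stack
#'
#' Container for a multi-channel confocal volume. Each channel is a 3D
#' numeric array with dimensions `(z, y, x)`; all channels share a shape and
#' a physical voxel size in micrometres per axis. Channel roles follow the
#' acquisition convention of the study: `SPC` (proSPC-like AT2 cytoplasm
#' marker), `CK7` (epithelial boundary marker), `DNA` (DNA stain) and
#' optionally `LMN` (lamin A/C). Intensities use an 8-bit scale (0-255);
#' values become floating point after attenuation correction or background
#' subtraction and are only quantised back to 8 bits at I/O.
#'
#' @param channels named list of 3D arrays, dims `(z, y, x)`.
#' @param voxel_size numeric length-3, micrometres per voxel along
#'   `(z, y, x)`. All components must be > 0.
#' @param stack_id character scalar identifying the stack.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size, stack_id = "stack") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("all channels must be 3D arrays with dim (z, y, x)")
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same shape")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (z, y, x) in micrometres")
  }
  structure(
    list(channels = channels, voxel_size = voxel_size,
         stack_id = as.character(stack_id)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf(
    "<image_stack '%s'> %d x %d x %d voxels (z,y,x), %s um, channels: %s\n",
    x$stack_id, d[1], d[2], d[3],
    paste(signif(x$voxel_size, 3), collapse = " x "),
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

# Physical voxel volume in femtolitres (1 fL = 1 um^3).
voxel_volume_fl <- function(stack_or_voxel) {
  v <- if (inherits(stack_or_voxel, "image_stack")) {
    stack_or_voxel$voxel_size
  } else {
    stack_or_voxel
  }
  prod(v)
}

#' Fetch one channel by role
#'
#' @param stack an [image_stack()].
#' @param role channel name, e.g. `"DNA"`.
#' @param required error (TRUE) or return NULL (FALSE) when absent.
#' @return the 3D array for that channel, or NULL.
#' @export
get_channel <- function(stack, role, required = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channels)) {
    if (required) {
      stop(sprintf(
        "channel '%s' not present; expected roles among: SPC, CK7, DNA, LMN (have: %s)",
        role, paste(names(stack$channels), collapse = ", ")))
    }
    return(NULL)
  }
  stack$channels[[role]]
}
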