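# Minimal baseline TIFF codec (little-endian, uncompressed, grayscale,
# single strip per page, 8- or 16-bit unsigned). No R TIFF package is
# available in the target environment, so the subset of the format the
# pipeline needs is implemented here. Stack metadata (channel roles, voxel
# size, stack id) travels in the ImageDescription tag of the first page as
# JSON, OME-sidecar style. Pages are ordered channel-major, z within
# channel; page rows are y, columns are x.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L
TIFF_ASCII <- 2L

tiff_pack_u <- function(value, width) {
  # little-endian unsigned integer of `width` bytes as raw
  out <- raw(width)
  v <- value
  for (i in seq_len(width)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(tiff_pack_u(tag, 2L), tiff_pack_u(type, 2L), tiff_pack_u(count, 4L),
    value_raw4)
}

tiff_inline_short <- function(v) c(tiff_pack_u(v, 2L), raw(2L))
tiff_inline_long <- function(v) tiff_pack_u(v, 4L)

write_tiff_pages <- function(path, pages, bits = 8L, description = NULL) {
  stopifnot(bits %in% c(8L, 16L), length(pages) >= 1L)
  bytes_pp <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))

  n <- length(pages)
  heights <- vapply(pages, nrow, 1L)
  widths <- vapply(pages, ncol, 1L)
  strip_sizes <- heights * widths * bytes_pp
  strip_offsets <- 8L + c(0L, cumsum(strip_sizes))[seq_len(n)]
  desc_raw <- if (!is.null(description)) {
    c(charToRaw(description), as.raw(0L))
  } else {
    raw(0)
  }
  desc_offset <- 8L + sum(strip_sizes)
  ifd_start <- desc_offset + length(desc_raw)
  n_entries <- function(i) if (i == 1L && length(desc_raw)) 10L else 9L
  ifd_sizes <- vapply(seq_len(n), function(i) 2L + 12L * n_entries(i) + 4L, 1L)
  ifd_offsets <- ifd_start + c(0L, cumsum(ifd_sizes))[seq_len(n)]

  # header
  writeBin(charToRaw("II"), con)
  writeBin(tiff_pack_u(42L, 2L), con)
  writeBin(tiff_pack_u(ifd_offsets[1L], 4L), con)

  # strips: row-major (row = y)
  for (p in pages) {
    v <- as.integer(round(t(p)))  # transpose -> row-major order
    if (bits == 8L) {
      writeBin(as.raw(pmin(pmax(v, 0L), 255L)), con)
    } else {
      v <- pmin(pmax(v, 0L), 65535L)
      lo <- as.raw(v %% 256L)
      hi <- as.raw(v %/% 256L)
      inter <- raw(2L * length(v))
      inter[seq(1L, by = 2L, length.out = length(v))] <- lo
      inter[seq(2L, by = 2L, length.out = length(v))] <- hi
      writeBin(inter, con)
    }
  }
  if (length(desc_raw)) writeBin(desc_raw, con)

  for (i in seq_len(n)) {
    entries <- list(
      tiff_entry(256L, TIFF_LONG, 1L, tiff_inline_long(widths[i])),
      tiff_entry(257L, TIFF_LONG, 1L, tiff_inline_long(heights[i])),
      tiff_entry(258L, TIFF_SHORT, 1L, tiff_inline_short(bits)),
      tiff_entry(259L, TIFF_SHORT, 1L, tiff_inline_short(1L)),
      tiff_entry(262L, TIFF_SHORT, 1L, tiff_inline_short(1L))
    )
    if (i == 1L && length(desc_raw)) {
      entries <- c(entries, list(tiff_entry(
        270L, TIFF_ASCII, length(desc_raw), tiff_inline_long(desc_offset))))
    }
    entries <- c(entries, list(
      tiff_entry(273L, TIFF_LONG, 1L, tiff_inline_long(strip_offsets[i])),
      tiff_entry(277L, TIFF_SHORT, 1L, tiff_inline_short(1L)),
      tiff_entry(278L, TIFF_LONG, 1L, tiff_inline_long(heights[i])),
      tiff_entry(279L, TIFF_LONG, 1L, tiff_inline_long(strip_sizes[i]))
    ))
    writeBin(tiff_pack_u(length(entries), 2L), con)
    for (e in entries) writeBin(e, con)
    next_off <- if (i < n) ifd_offsets[i + 1L] else 0L
    writeBin(tiff_pack_u(next_off, 4L), con)
  }
  invisible(path)
}

tiff_read_u <- function(raw_vec, offset, width) {
  # offset is 0-based
  b <- as.integer(raw_vec[offset + seq_len(width)])
  sum(b * 256^(seq_len(width) - 1L))
}

read_tiff_pages <- function(path) {
  raw_vec <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw_vec[1:2]) != "II" || tiff_read_u(raw_vec, 2L, 2L) != 42L) {
    stop("not a little-endian TIFF file: ", path)
  }
  ifd <- tiff_read_u(raw_vec, 4L, 4L)
  pages <- list()
  description <- NULL
  while (ifd != 0L) {
    n_ent <- tiff_read_u(raw_vec, ifd, 2L)
    tags <- list()
    for (k in seq_len(n_ent)) {
      base <- ifd + 2L + 12L * (k - 1L)
      tag <- tiff_read_u(raw_vec, base, 2L)
      type <- tiff_read_u(raw_vec, base + 2L, 2L)
      count <- tiff_read_u(raw_vec, base + 4L, 4L)
      width <- switch(as.character(type), "3" = 2L, "4" = 4L, "2" = 1L, 1L)
      inline_size <- width * count
      if (inline_size <= 4L) {
        vals <- vapply(seq_len(count), function(j) {
          tiff_read_u(raw_vec, base + 8L + width * (j - 1L), width)
        }, 1)
      } else {
        off <- tiff_read_u(raw_vec, base + 8L, 4L)
        vals <- vapply(seq_len(count), function(j) {
          tiff_read_u(raw_vec, off + width * (j - 1L), width)
        }, 1)
      }
      tags[[as.character(tag)]] <- list(type = type, values = vals)
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    w <- tags[["256"]]$values[1L]
    h <- tags[["257"]]$values[1L]
    bits <- tags[["258"]]$values[1L]
    if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth: ", bits)
    if (!is.null(tags[["259"]]) && tags[["259"]]$values[1L] != 1) {
      stop("compressed TIFF not supported")
    }
    if ("270" %in% names(tags) && is.null(description)) {
      dvals <- tags[["270"]]$values
      dvals <- dvals[dvals != 0]
      description <- rawToChar(as.raw(dvals))
    }
    offs <- tags[["273"]]$values
    cnts <- tags[["279"]]$values
    data <- integer(w * h)
    pos <- 0L
    for (s in seq_along(offs)) {
      nb <- cnts[s]
      bytes <- as.integer(raw_vec[offs[s] + seq_len(nb)])
      if (bits == 8) {
        vals <- bytes
      } else {
        vals <- bytes[seq(1L, nb, 2L)] + 256L * bytes[seq(2L, nb, 2L)]
      }
      data[pos + seq_along(vals)] <- vals
      pos <- pos + length(vals)
    }
    pages[[length(pages) + 1L]] <- t(matrix(data, nrow = w, ncol = h))
    ifd <- tiff_read_u(raw_vec, ifd + 2L + 12L * n_ent, 4L)
  }
  list(pages = pages, description = description)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...)
#' and carry channel roles, voxel size and stack id in the first page's
#' ImageDescription as JSON. Intensities are stored as 8-bit unsigned;
#' values are rounded (with a warning if they were not already integral)
#' and clipped to 0-255.
#'
#' @param stack an [image_stack()]; must contain a `DNA` channel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  get_channel(stack, "DNA")  # errors listing expected roles when missing
  d <- dim(stack)
  pages <- list()
  nonint <- FALSE
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    if (max(abs(a - round(a))) > 1e-9 || min(a) < 0 || max(a) > 255) {
      nonint <- TRUE
    }
    for (z in seq_len(d[1L])) {
      pages[[length(pages) + 1L]] <- matrix(a[z, , ], nrow = d[2L])
    }
  }
  if (nonint) {
    warning("stack values quantised to the 8-bit range 0-255 at I/O")
  }
  meta <- jsonlite::toJSON(list(
    format = "cytovol3d-stack", shape = d, channels = names(stack$channels),
    voxel_size_um = stack$voxel_size, stack_id = stack$stack_id
  ), auto_unbox = TRUE, digits = NA)
  write_tiff_pages(path, pages, bits = 8L, description = as.character(meta))
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF file path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- read_tiff_pages(path)
  if (is.null(tf$description)) stop("TIFF lacks stack metadata description")
  meta <- jsonlite::fromJSON(tf$description)
  shape <- as.integer(meta$shape)
  chs <- as.character(meta$channels)
  if (!"DNA" %in% chs) {
    stop("stack metadata lacks DNA channel; expected roles among SPC, CK7, DNA, LMN")
  }
  stopifnot(length(tf$pages) == shape[1L] * length(chs))
  channels <- list()
  p <- 0L
  for (ch in chs) {
    a <- array(0, dim = shape)
    for (z in seq_len(shape[1L])) {
      p <- p + 1L
      a[z, , ] <- tf$pages[[p]]
    }
    channels[[ch]] <- a
  }
  image_stack(channels, as.numeric(meta$voxel_size_um),
              as.character(meta$stack_id))
}

#' Write a 3D label volume as 16-bit multi-page TIFF
#'
#' @param labels 3D integer array, dims `(z, y, x)`, 0 = background.
#' @param path output file path.
#' @param voxel_size voxel size in micrometres `(z, y, x)`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(labels)) == 3L, min(labels) >= 0)
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored as 16-bit")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1L]), function(z) matrix(labels[z, , ], nrow = d[2L]))
  meta <- jsonlite::toJSON(list(
    format = "cytovol3d-labels", shape = d, voxel_size_um = voxel_size
  ), auto_unbox = TRUE, digits = NA)
  write_tiff_pages(path, pages, bits = 16L, description = as.character(meta))
}

#' Read a label volume written by [write_labels()]
#'
#' @param path TIFF file path.
#' @return list with `labels` (3D integer array) and `voxel_size`.
#' @export
read_labels <- function(path) {
  tf <- read_tiff_pages(path)
  meta <- jsonlite::fromJSON(tf$description)
  shape <- as.integer(meta$shape)
  a <- array(0L, dim = shape)
  for (z in seq_len(shape[1L])) a[z, , ] <- as.integer(tf$pages[[z]])
  list(labels = a, voxel_size = as.numeric(meta$voxel_size_um))
}
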