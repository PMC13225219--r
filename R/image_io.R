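# Reading and writing stacks, masks and measurement tables.

# Minimal uncompressed 32-bit float multipage TIFF writer (little-endian).
# tiff::readTIFF reads float TIFFs back with exact float32 values; no
# installed R package writes them, hence this writer. One strip per page.
write_float_tiff <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  # header: II, magic 42, offset of first IFD (filled in as we go)
  w(charToRaw("II"), 1L)
  w(42L, 2L)
  first_ifd_pos <- 4L
  w(0L, 4L)  # placeholder
  pos <- 8L
  ifd_offsets <- integer(length(pages))
  data_offsets <- integer(length(pages))
  # write pixel data blocks first
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    data_offsets[i] <- pos
    # TIFF rows are written top-to-bottom, row-major
    vals <- as.numeric(t(m))
    w(vals, 4L)
    pos <- pos + 4L * length(vals)
  }
  n_tags <- 9L
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); wd <- ncol(m)
    ifd_offsets[i] <- pos
    tag <- function(id, type, count, value) {
      w(as.integer(id), 2L); w(as.integer(type), 2L); w(as.integer(count), 4L)
      w(as.integer(value), 4L)
    }
    w(n_tags, 2L)
    tag(256, 4, 1, wd)                      # ImageWidth
    tag(257, 4, 1, h)                       # ImageLength
    tag(258, 3, 1, 32)                      # BitsPerSample
    tag(259, 3, 1, 1)                       # Compression: none
    tag(262, 3, 1, 1)                       # Photometric: BlackIsZero
    tag(273, 4, 1, data_offsets[i])         # StripOffsets
    tag(278, 4, 1, h)                       # RowsPerStrip
    tag(279, 4, 1, 4L * h * wd)             # StripByteCounts
    tag(339, 3, 1, 3)                       # SampleFormat: IEEE float
    # offset of next IFD (0 for last)
    next_off <- if (i < length(pages)) pos + 2L + n_tags * 12L + 4L else 0L
    w(next_off, 4L)
    pos <- pos + 2L + n_tags * 12L + 4L
  }
  # back-patch first IFD offset
  seek(con, first_ifd_pos, origin = "start", rw = "write")
  w(ifd_offsets[1], 4L)
  invisible(path)
}

#' Write an image stack to a 32-bit float TIFF
#'
#' Pages are ordered with time slowest, then z, then channel fastest, the
#' order [read_stack()] assumes. Intensities are stored as IEEE float32, so
#' round trips are bit-exact at float32 precision (exact for integer-valued
#' intensities below 2^24).
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  pages <- list()
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$pixels[t, z, c, , ], d[4], d[5])
  }
  write_float_tiff(pages, path)
  invisible(path)
}

#' Read a TIFF file into an image stack
#'
#' Single- and multi-page grayscale TIFFs (integer or float) are supported.
#' A plain multi-page file carries no axis metadata, so the page count must
#' be factored into `(t, z, c)` by the caller via `shape`; with the default
#' all pages are taken as z slices. Pages are assumed ordered time-slowest,
#' channel-fastest (the order written by [write_stack()]).
#'
#' @param path a readable TIFF file.
#' @param shape optional integer `(t, z, c)` page layout; the product must
#'   equal the page count.
#' @param pixel_size_um,z_step_um,time_interval_s physical metadata. TIFF
#'   tags do not carry these reliably; when left `NULL` they default to 1
#'   with a warning.
#' @param channel_names optional channel labels.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, shape = NULL, pixel_size_um = NULL,
                       z_step_um = NULL, time_interval_s = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read TIFF: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L]
      else stop("multi-sample TIFF pages are not supported; store channels as separate pages")
    }
    p
  })
  n <- length(pages)
  if (is.null(shape)) shape <- c(1L, n, 1L)
  shape <- as.integer(shape)
  if (length(shape) != 3L || prod(shape) != n) {
    stop(sprintf("`shape` (t,z,c) must multiply to the page count (%d)", n))
  }
  h <- nrow(pages[[1]]); wd <- ncol(pages[[1]])
  px <- array(0, dim = c(shape, h, wd))
  k <- 0L
  for (t in seq_len(shape[1])) for (z in seq_len(shape[2])) for (c in seq_len(shape[3])) {
    k <- k + 1L
    if (!all(dim(pages[[k]]) == c(h, wd))) stop("TIFF pages differ in size")
    px[t, z, c, , ] <- pages[[k]]
  }
  if (any(px < 0)) stop("negative intensities are not allowed")
  if (is.null(pixel_size_um) || is.null(z_step_um) || is.null(time_interval_s)) {
    warning("physical metadata missing; defaulting pixel size / z step / time interval to 1")
  }
  image_stack(px,
              pixel_size_um = pixel_size_um %||% c(1, 1),
              z_step_um = z_step_um %||% 1,
              time_interval_s = time_interval_s %||% 1,
              channel_names = channel_names)
}

#' Read and write binary masks as PNG
#'
#' Masks are stored as 8-bit PNG with 0 = excluded and 255 = included.
#'
#' @param mask logical `(y, x)` matrix.
#' @param path file path.
#' @return `read_mask` returns a logical matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask: %s", path))
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Read and write measurement tables
#'
#' Long-format CSV tables (comma separator, header row, UTF-8) carrying
#' measurements plus their grouping columns, e.g. attachment-site lengths
#' with `length`, `genotype`, `sample`, `image`.
#'
#' @param records a data.frame.
#' @param path file path.
#' @param required_columns character vector of columns that must be present
#'   on read; a missing column is a format error.
#' @return `read_table` returns a data.frame; `write_table` returns `path`
#'   invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, required_columns = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read table: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_columns, names(df))
  if (length(missing)) {
    stop(sprintf("table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  df
}
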