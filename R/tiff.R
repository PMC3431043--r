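# Minimal baseline TIFF support: multi-page, single-channel grayscale,
# 8- or 16-bit, uncompressed. This is deliberately narrow -- it covers the
# stack format the toolkit exchanges and nothing else (no LSM/CZI, no RGB,
# no compression). Both byte orders are read; little-endian is written.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

tiff_type_size <- function(type) {
  # BYTE ASCII SHORT LONG RATIONAL SBYTE UNDEF SSHORT SLONG SRATIONAL FLOAT DOUBLE
  sizes <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  if (type < 1 || type > 12) return(NA_integer_)
  sizes[type]
}

rd_uint <- function(raw, off, size, n, endian) {
  v <- readBin(raw[(off + 1):(off + size * n)], what = "integer", n = n,
               size = size, signed = if (size < 4) FALSE else TRUE,
               endian = endian)
  if (size == 4) v[v < 0] <- NA  # >2^31 offsets unsupported
  v
}

tiff_read_entry_values <- function(raw, entry_off, endian) {
  tag <- rd_uint(raw, entry_off, 2, 1, endian)
  type <- rd_uint(raw, entry_off + 2, 2, 1, endian)
  count <- rd_uint(raw, entry_off + 4, 4, 1, endian)
  size <- tiff_type_size(type)
  if (is.na(size) || !(type %in% c(1L, 3L, 4L)))
    return(list(tag = tag, values = NULL))
  nbytes <- size * count
  voff <- if (nbytes <= 4) entry_off + 8 else rd_uint(raw, entry_off + 8, 4, 1, endian)
  list(tag = tag, values = rd_uint(raw, voff, size, count, endian))
}

#' Read a multi-page grayscale TIFF stack
#'
#' Reads uncompressed single-channel 8/16-bit baseline TIFF (either byte
#' order) into an [image_stack]. Voxel spacing is **never** taken from TIFF
#' tags: it comes from the `spacing` argument, or from a JSON sidecar
#' (`<path>.json` with fields `spacing` and optionally `origin`) written by
#' [write_stack], or falls back to the (2, 1, 1) um default.
#'
#' @param path TIFF file path.
#' @param spacing `(dz, dy, dx)` um, overriding any sidecar.
#' @param origin `(z0, y0, x0)` um.
#' @return an `image_stack` with integer-valued voxels.
#' @export
read_stack <- function(path, spacing = NULL, origin = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (rd_uint(raw, 2, 2, 1, endian) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd_uint(raw, 4, 4, 1, endian)
  if (is.na(ifd_off) || ifd_off == 0) stop("empty TIFF (no image directory): ", path)

  pages <- list()
  shape <- NULL
  while (!is.na(ifd_off) && ifd_off != 0) {
    n_entries <- rd_uint(raw, ifd_off, 2, 1, endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      ent <- tiff_read_entry_values(raw, ifd_off + 2 + (e - 1) * 12, endian)
      tags[[as.character(ent$tag)]] <- ent$values
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- g(258, 1L)
    if (length(bits) > 1L || g(277, 1L) != 1L || g(262, 1L) >= 2L)
      stop("unsupported TIFF: only single-channel grayscale pages are readable")
    if (!bits %in% c(8L, 16L))
      stop("unsupported TIFF bit depth: ", bits)
    if (g(259, 1L) != 1L) stop("unsupported TIFF: compressed data")
    if (g(339, 1L) != 1L) stop("unsupported TIFF: non-unsigned sample format")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs) || is.null(cnts)) stop("TIFF page missing strip layout")
    if (!is.null(shape) && !identical(shape, c(h, w)))
      stop("TIFF pages differ in size (", h, "x", w, " vs ",
           shape[1], "x", shape[2], ")")
    shape <- c(h, w)
    data_raw <- raw[unlist(mapply(function(o, ct) (o + 1):(o + ct), offs, cnts,
                                  SIMPLIFY = FALSE))]
    px <- readBin(data_raw, "integer", n = w * h, size = bits / 8,
                  signed = FALSE, endian = endian)
    pages[[length(pages) + 1L]] <- px
    ifd_off <- rd_uint(raw, ifd_off + 2 + n_entries * 12, 4, 1, endian)
  }
  nz <- length(pages)
  vox <- array(0, dim = c(nz, shape[1], shape[2]))
  for (k in seq_len(nz))
    vox[k, , ] <- matrix(pages[[k]], nrow = shape[1], byrow = TRUE)

  sidecar <- paste0(path, ".json")
  if (is.null(spacing) || is.null(origin)) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(spacing) && !is.null(meta$spacing)) spacing <- meta$spacing
      if (is.null(origin) && !is.null(meta$origin)) origin <- meta$origin
    }
  }
  image_stack(vox, spacing = if (is.null(spacing)) c(2, 1, 1) else spacing,
              origin = if (is.null(origin)) c(0, 0, 0) else origin)
}

#' Write a stack as multi-page grayscale TIFF
#'
#' Writes uncompressed little-endian baseline TIFF, one page per z-slice.
#' Voxel values must already be integers within the chosen bit depth;
#' nothing is rescaled, so write-then-read is bit-identical. A JSON sidecar
#' (`<path>.json`) records spacing and origin for [read_stack].
#'
#' @param stack an `image_stack` with integer-valued voxels.
#' @param path output path.
#' @param bits 8 or 16.
#' @param sidecar write the spacing/origin sidecar (default `TRUE`).
#' @export
write_stack <- function(stack, path, bits = 8L, sidecar = TRUE) {
  stopifnot_stack(stack)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  v <- stack$voxels
  if (any(v != round(v)) || min(v) < 0 || max(v) > 2^bits - 1)
    stop(sprintf("voxel values must be integers in [0, %d] for %d-bit TIFF",
                 2^bits - 1, bits))
  d <- dim(v)
  nz <- d[1]; h <- d[2]; w <- d[3]
  bpp <- bits / 8L
  nbytes <- w * h * bpp
  pad <- nbytes %% 2L
  ifd_size <- 2L + 9L * 12L + 4L
  page_size <- ifd_size + nbytes + pad
  ifd_off <- 8L + (seq_len(nz) - 1L) * page_size
  data_off <- ifd_off + ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")
  wr_entry <- function(tag, type, count, value) {
    writeBin(as.integer(c(tag, type)), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT packed into 4-byte field
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(raw(2), con)
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (k in seq_len(nz)) {
    writeBin(9L, con, size = 2L, endian = "little")
    wr_entry(256L, 4L, 1L, w)
    wr_entry(257L, 4L, 1L, h)
    wr_entry(258L, 3L, 1L, bits)
    wr_entry(259L, 3L, 1L, 1L)
    wr_entry(262L, 3L, 1L, 1L)
    wr_entry(273L, 4L, 1L, data_off[k])
    wr_entry(277L, 3L, 1L, 1L)
    wr_entry(278L, 4L, 1L, h)
    wr_entry(279L, 4L, 1L, nbytes)
    writeBin(if (k < nz) as.integer(ifd_off[k + 1L]) else 0L,
             con, size = 4L, endian = "little")
    px <- as.integer(t(matrix(v[k, , ], nrow = h)))
    writeBin(px, con, size = bpp, endian = "little")
    if (pad) writeBin(raw(1), con)
  }
  if (sidecar)
    jsonlite::write_json(list(spacing = stack$spacing, origin = stack$origin),
                         paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
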