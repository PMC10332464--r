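## Minimal baseline TIFF support (little-endian, uncompressed, single-channel
## grayscale, 8- or 16-bit, multi-page).  No TIFF reader ships with the
## supported dependency set, so the subset of baseline TIFF 6.0 needed for
## monochrome camera stacks is implemented here and round-trip tested against
## an independent reader.

.tiff_type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)

.u16le <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

.u32le <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256
  b1 <- (x %/% 256) %% 256
  b2 <- (x %/% 65536) %% 256
  b3 <- (x %/% 16777216) %% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

# one 12-byte IFD entry; `value` must fit inline (count * size <= 4)
.ifd_entry <- function(tag, type, count, value) {
  val <- switch(as.character(type),
    `3` = .u16le(value),
    `4` = .u32le(value),
    stop("unsupported IFD type"))
  val <- c(val, rep(as.raw(0), 4L - length(val)))
  c(.u16le(tag), .u16le(type), .u32le(count), val)
}

#' Write a multi-page 16-bit grayscale TIFF
#'
#' Writes one page per z-slice, uncompressed, little-endian, one strip per
#' page.  Intensities are rounded and clamped to the 16-bit range.
#'
#' @param voxels 3-D numeric array indexed `[slice, row, col]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff_stack <- function(voxels, path) {
  d <- dim(voxels)
  if (length(d) != 3L) stop("'voxels' must be a 3-D array [slice, row, col]")
  nz <- d[1]; h <- d[2]; w <- d[3]
  page_bytes <- 2 * h * w
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_start <- 8
  ifd_start <- data_start + nz * page_bytes

  v <- round(voxels)
  v[v < 0] <- 0
  v[v > 65535] <- 65535

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .u16le(42L), .u32le(ifd_start)), con)
  for (z in seq_len(nz)) {
    page <- as.vector(t(matrix(v[z, , ], h, w)))  # row-major scan order
    writeBin(.u16le(page), con)
  }
  for (z in seq_len(nz)) {
    strip_off <- data_start + (z - 1) * page_bytes
    next_ifd <- if (z < nz) ifd_start + z * ifd_size else 0
    ifd <- c(
      .u16le(n_entries),
      .ifd_entry(256L, 4L, 1L, w),            # ImageWidth
      .ifd_entry(257L, 4L, 1L, h),            # ImageLength
      .ifd_entry(258L, 3L, 1L, 16L),          # BitsPerSample
      .ifd_entry(259L, 3L, 1L, 1L),           # Compression: none
      .ifd_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
      .ifd_entry(273L, 4L, 1L, strip_off),    # StripOffsets
      .ifd_entry(277L, 3L, 1L, 1L),           # SamplesPerPixel
      .ifd_entry(278L, 4L, 1L, h),            # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, page_bytes),   # StripByteCounts
      .ifd_entry(339L, 3L, 1L, 1L),           # SampleFormat: unsigned int
      .u32le(next_ifd)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a 3-D array
#'
#' Supports the baseline subset written by [write_tiff_stack()] plus common
#' single-channel exports: little-endian, uncompressed, 8- or 16-bit unsigned,
#' one sample per pixel, any strip layout.
#'
#' @param path TIFF file path.
#' @return 3-D numeric array `[slice, row, col]`.
#' @keywords internal
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", file.size(path))
  int <- as.integer(raw)
  u16 <- function(off) int[off + 1L] + 256L * int[off + 2L]  # off is 0-based
  u32 <- function(off) {
    int[off + 1L] + 256 * int[off + 2L] + 65536 * int[off + 3L] +
      16777216 * int[off + 4L]
  }
  if (!(raw[1] == 0x49 && raw[2] == 0x49)) {
    stop("unsupported TIFF: only little-endian ('II') files are handled")
  }
  if (u16(2) != 42L) stop("not a TIFF file")

  read_tag_values <- function(off, type, count) {
    size <- .tiff_type_size[as.character(type)]
    if (is.na(size)) return(NULL)  # skip tag types we do not need
    vals_off <- if (count * size <= 4) off + 8 else u32(off + 8)
    reader <- switch(as.character(type),
      `1` = function(k) int[vals_off + k],
      `3` = function(k) u16(vals_off + (k - 1L) * 2L),
      `4` = function(k) u32(vals_off + (k - 1L) * 4L))
    vapply(seq_len(count), reader, numeric(1))
  }

  pages <- list()
  ifd_off <- u32(4)
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      off <- ifd_off + 2 + (i - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      tags[[as.character(tag)]] <- read_tag_values(off, type, count)
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- g(258, 1)
    if ((g(277, 1)[1] != 1) || length(bits) != 1) {
      stop("single-channel required: multi-sample (RGB/multichannel) TIFF")
    }
    if (g(259, 1) != 1) stop("unsupported TIFF: compressed data")
    if (g(339, 1) != 1) stop("unsupported TIFF: non-integer sample format")
    if (!bits %in% c(8, 16)) stop("unsupported TIFF: bits per sample ", bits)
    offs <- g(273); counts <- g(279)
    bytes <- unlist(lapply(seq_along(offs), function(s) {
      int[(offs[s] + 1):(offs[s] + counts[s])]
    }))
    px <- if (bits == 16) {
      bytes[c(TRUE, FALSE)] + 256 * bytes[c(FALSE, TRUE)]
    } else {
      bytes
    }
    if (length(px) != w * h) stop("TIFF strip data does not match dimensions")
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  nz <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, c(nz, h, w))
  for (z in seq_len(nz)) out[z, , ] <- pages[[z]]
  out
}
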