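#' Minimal 16-bit grayscale TIFF I/O
#'
#' The scan renderer stores images as plain baseline TIFF (little
#' endian, uncompressed, 16-bit unsigned, one strip per page; line-scans
#' are a single page with rows = time, frame series one page per
#' frame). No TIFF library ships with the target R environment, so this
#' reader/writer implements exactly that baseline subset; it is
#' validated against an independent TIFF implementation in the test
#' suite.
#'
#' @param x numeric matrix (single page) or 3-D array `page x y x x`;
#'   values are rounded and clamped to 0..65535.
#' @param path file path.
#' @return `write_tiff16` returns `path` invisibly. `read_tiff16`
#'   returns a matrix for single-page files, otherwise a
#'   `page x y x x` array.
#' @export
write_tiff16 <- function(x, path) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3L)
  n_pages <- dim(x)[1L]
  h <- dim(x)[2L]
  w <- dim(x)[3L]
  vals <- pmin(pmax(round(x), 0), 65535)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")

  page_bytes <- 2L * h * w
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + n_pages * page_bytes

  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  w4(ifd_start) # first IFD after all pixel data

  for (p in seq_len(n_pages)) {
    # TIFF is row-major: emit each image row in turn
    w2(as.vector(t(vals[p, , ])))
  }
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (p in seq_len(n_pages)) {
    w2(n_tags)
    tag(256L, 4L, 1L, w)                                  # ImageWidth
    tag(257L, 4L, 1L, h)                                  # ImageLength
    tag(258L, 3L, 1L, 16L)                                # BitsPerSample
    tag(259L, 3L, 1L, 1L)                                 # no compression
    tag(262L, 3L, 1L, 1L)                                 # BlackIsZero
    tag(273L, 4L, 1L, data_start + (p - 1L) * page_bytes) # StripOffsets
    tag(277L, 3L, 1L, 1L)                                 # SamplesPerPixel
    tag(278L, 4L, 1L, h)                                  # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)                         # StripByteCounts
    w4(if (p < n_pages) ifd_start + p * ifd_size else 0L) # next IFD
  }
  invisible(path)
}

#' @rdname write_tiff16
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  }
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1L])) +
      256 * as.integer(raw[off + 2L]) +
      65536 * as.integer(raw[off + 3L]) +
      16777216 * as.integer(raw[off + 4L])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L) {
    stop("not a little-endian TIFF", call. = FALSE)
  }
  ifd_off <- u32(4L)
  pages <- list()
  while (ifd_off != 0) {
    n_tags <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      id <- u16(e)
      type <- u16(e + 2L)
      tags[[as.character(id)]] <- if (type == 3L) u16(e + 8L) else u32(e + 8L)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("missing required TIFF tags", call. = FALSE)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      stop("compressed TIFF not supported", call. = FALSE)
    }
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16L) {
      stop("only 16-bit TIFF supported", call. = FALSE)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]
    npx <- h * w
    bytes <- raw[(off + 1L):(off + 2L * npx)]
    lo <- as.integer(bytes[seq(1L, 2L * npx, by = 2L)])
    hi <- as.integer(bytes[seq(2L, 2L * npx, by = 2L)])
    pages[[length(pages) + 1L]] <- matrix(lo + 256L * hi, nrow = h,
                                          ncol = w, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2L + n_tags * 12L)
  }
  if (length(pages) == 1L) return(pages[[1L]])
  out <- array(0L, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (p in seq_along(pages)) out[p, , ] <- pages[[p]]
  out
}
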