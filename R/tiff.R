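# Minimal baseline TIFF codec: uncompressed, single-channel (greyscale),
# 8- or 16-bit, little-endian, multi-page. No preinstalled R package reads
# TIFF in this stack, and the pipeline's on-disk exchange format is multi-page
# TIFF, so this small reader/writer covers exactly the subset the pipeline
# emits. It is not a general TIFF implementation.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a multi-page greyscale TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page.
#'
#' @param pages list of numeric matrices (or a 3-D array sliced along dim 1),
#'   values in `[0, 2^bits - 1]`; they are rounded to integers.
#' @param path output file path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 8L) {
  if (is.array(pages) && length(dim(pages)) == 3L) {
    pages <- lapply(seq_len(dim(pages)[1L]), function(i) pages[i, , ])
  }
  stopifnot(is.list(pages), length(pages) >= 1L, bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pages)
  bytes_per <- bits %/% 8L
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: header | page data (word-aligned) | chained IFDs
  sizes <- vapply(pages, function(p) length(p) * bytes_per, 0)
  padded <- sizes + sizes %% 2L
  data_off <- 8L + c(0, cumsum(padded))[seq_len(n)]
  ifd0 <- 8L + sum(padded)
  ifd_off <- ifd0 + (seq_len(n) - 1L) * ifd_size
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1L]), con, size = 4, endian = "little")
  for (p in seq_len(n)) {
    vals <- as.integer(round(pmax(0, pmin(2^bits - 1, t(pages[[p]])))))  # row-major
    writeBin(vals, con, size = bytes_per, endian = "little")
    if (sizes[p] %% 2L == 1L) writeBin(as.raw(0L), con)
  }
  for (p in seq_len(n)) {
    img <- pages[[p]]
    h <- nrow(img); w <- ncol(img)
    entries <- list(
      c(256L, 3L, 1L, w),                     # ImageWidth
      c(257L, 3L, 1L, h),                     # ImageLength
      c(258L, 3L, 1L, bits),                  # BitsPerSample
      c(259L, 3L, 1L, 1L),                    # Compression = none
      c(262L, 3L, 1L, 1L),                    # Photometric = BlackIsZero
      c(273L, 4L, 1L, as.integer(data_off[p])),  # StripOffsets
      c(277L, 3L, 1L, 1L),                    # SamplesPerPixel
      c(278L, 3L, 1L, h),                     # RowsPerStrip
      c(279L, 4L, 1L, as.integer(sizes[p]))   # StripByteCounts
    )
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      e <- as.integer(e)
      writeBin(e[1L], con, size = 2, endian = "little")
      writeBin(e[2L], con, size = 2, endian = "little")
      writeBin(e[3L], con, size = 4, endian = "little")
      if (e[2L] == 3L) {  # SHORT padded to 4 bytes
        writeBin(e[4L], con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(e[4L], con, size = 4, endian = "little")
      }
    }
    next_off <- if (p < n) as.integer(ifd_off[p + 1L]) else 0L
    writeBin(next_off, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page greyscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed single-channel baseline TIFF (8/16-bit, either byte
#' order, one or more strips).
#'
#' @param path file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  rd_int <- function(off, size, endian) {
    b <- as.integer(raw[(off + 1L):(off + size)])
    if (endian == "big") b <- rev(b)
    sum(b * 256^(seq_len(size) - 1L))
  }
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (rd_int(2L, 2L, endian) != 42L) stop("bad TIFF magic in ", path)
  ifd <- rd_int(4L, 4L, endian)
  pages <- list()
  while (ifd != 0L) {
    nent <- rd_int(ifd, 2L, endian)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- rd_int(e, 2L, endian)
      typ <- rd_int(e + 2L, 2L, endian)
      cnt <- rd_int(e + 4L, 4L, endian)
      tsz <- .tiff_type_size[as.character(typ)]
      vsz <- if (is.na(tsz)) 4L else tsz
      vals <- if (vsz * cnt <= 4L) {
        vapply(seq_len(cnt), function(j) rd_int(e + 8L + (j - 1L) * vsz, vsz, endian), 0)
      } else {
        voff <- rd_int(e + 8L, 4L, endian)
        vapply(seq_len(cnt), function(j) rd_int(voff + (j - 1L) * vsz, vsz, endian), 0)
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(t) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) stop("TIFF tag ", t, " missing in ", path)
      v
    }
    w <- need(256L); h <- need(257L)
    bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]][1L]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1L]
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]][1L]
    if (comp != 1L) stop("only uncompressed TIFF supported (compression=", comp, ")")
    if (spp != 1L) stop("only single-channel TIFF supported")
    offs <- need(273L); cnts <- need(279L)
    bytes_per <- bits %/% 8L
    vals <- integer(0)
    for (s in seq_along(offs)) {
      nv <- cnts[s] %/% bytes_per
      seg <- raw[(offs[s] + 1L):(offs[s] + cnts[s])]
      v <- readBin(seg, "integer", n = nv, size = bytes_per,
                   signed = FALSE, endian = endian)
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- rd_int(ifd + 2L + nent * 12L, 4L, endian)
  }
  pages
}
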