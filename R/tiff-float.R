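# Minimal writer for uncompressed 32-bit IEEE-float TIFF.
#
# The tiff package (libtiff) reads float TIFFs transparently but its writer
# only emits integer sample formats, which cannot represent the negative
# excursions of mixed Poisson-Gaussian noisy images. This writer emits the
# small subset of baseline TIFF needed for lossless float round-trips:
# little-endian, single strip, contiguous planar config, 1 or 3 samples
# per pixel, SampleFormat = IEEE floating point.

writeFloatTIFF <- function(arr, path) {
  d <- dim(arr)
  nr <- d[1]; nc <- d[2]
  nch <- if (length(d) == 3L) d[3] else 1L
  stopifnot(nch %in% c(1L, 3L))

  # pixel data: row-major, channels interleaved
  px <- if (nch == 1L) as.vector(t(arr))
        else as.vector(aperm(arr, c(3, 2, 1)))
  dataBytes <- writeBin(as.numeric(px), raw(), size = 4L,
                        endian = "little")

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "little")
  # IFD entry: tag, type (3 = SHORT, 4 = LONG), count, value/offset
  entry <- function(tag, type, count, value) {
    val <- if (type == 3L && count == 1L) c(u16(value), u16(0L))
           else u32(value)
    c(u16(tag), u16(type), u32(count), val)
  }

  header <- c(charToRaw("II"), u16(42L), u32(8L))  # IFD at offset 8
  nEntries <- 11L
  ifdSize <- 2L + nEntries * 12L + 4L
  # layout: header (8) | IFD | [bits/sampleformat arrays for 3ch] | data
  extraOff <- 8L + ifdSize
  extra <- raw(0)
  if (nch == 3L) {
    bitsOff <- extraOff
    extra <- c(extra, u16(32L), u16(32L), u16(32L))
    sfOff <- extraOff + 6L
    extra <- c(extra, u16(3L), u16(3L), u16(3L))
    extraOff <- extraOff + 12L
  }
  dataOff <- extraOff

  entries <- c(
    entry(256L, 4L, 1L, nc),                 # ImageWidth
    entry(257L, 4L, 1L, nr),                 # ImageLength
    if (nch == 3L) entry(258L, 3L, 3L, bitsOff)
    else entry(258L, 3L, 1L, 32L),           # BitsPerSample
    entry(259L, 3L, 1L, 1L),                 # Compression: none
    entry(262L, 3L, 1L, if (nch == 3L) 2L else 1L),  # Photometric
    entry(273L, 4L, 1L, dataOff),            # StripOffsets
    entry(277L, 3L, 1L, nch),                # SamplesPerPixel
    entry(278L, 4L, 1L, nr),                 # RowsPerStrip
    entry(279L, 4L, 1L, length(dataBytes)),  # StripByteCounts
    entry(284L, 3L, 1L, 1L),                 # PlanarConfig: contiguous
    if (nch == 3L) entry(339L, 3L, 3L, sfOff)
    else entry(339L, 3L, 1L, 3L))            # SampleFormat: IEEE float

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, u16(nEntries), entries, u32(0L), extra, dataBytes),
           con)
  invisible(path)
}
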