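# Minimal single-band GeoTIFF support: uncompressed IEEE-float strips with
# ModelPixelScale/ModelTiepoint georeferencing and the GDAL_NODATA tag.
# No installed package provides georeferenced TIFF, so the byte layout is
# handled here directly. Limitations (by design): one sample per pixel,
# Compression = 1 only, geographic (lon/lat) grids only.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

read_geotiff <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short)", call. = FALSE)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark)", call. = FALSE)
  rd_int <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], what = "integer", n = n,
            size = size, signed = size >= 4L, endian = endian)
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("not a TIFF file (bad magic number)", call. = FALSE)
  ifd_off <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd_off, 2L)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e_off <- ifd_off + 2L + (k - 1L) * 12L
    tag <- rd_int(e_off, 2L)
    type <- rd_int(e_off + 2L, 2L)
    count <- rd_int(e_off + 4L, 4L)
    tsz <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(tsz)) next
    nbytes <- tsz * count
    voff <- if (nbytes <= 4L) e_off + 8L else rd_int(e_off + 8L, 4L)
    vals <- switch(as.character(type),
      `1` = rd_int(voff, 1L, count),
      `2` = {
        b <- raw[(voff + 1L):(voff + count)]
        rawToChar(b[b != as.raw(0L)])
      },
      `3` = rd_int(voff, 2L, count),
      `4` = rd_int(voff, 4L, count),
      `11` = readBin(raw[(voff + 1L):(voff + nbytes)], "double", n = count,
                     size = 4L, endian = endian),
      `12` = readBin(raw[(voff + 1L):(voff + nbytes)], "double", n = count,
                     size = 8L, endian = endian))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, what) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop(sprintf("GeoTIFF missing required tag: %s", what),
                         call. = FALSE)
    v
  }
  nc <- need(256, "ImageWidth"); nr <- need(257, "ImageLength")
  bits <- need(258, "BitsPerSample")
  comp <- tags[["259"]] %||% 1L
  if (comp != 1L)
    stop("only uncompressed GeoTIFF is supported (Compression = 1)",
         call. = FALSE)
  fmt <- tags[["339"]] %||% 1L
  if (fmt != 3L || !(bits %in% c(32L, 64L)))
    stop("only IEEE-float GeoTIFF samples (32/64-bit) are supported",
         call. = FALSE)
  spp <- tags[["277"]] %||% 1L
  if (spp != 1L) stop("only single-band GeoTIFF is supported", call. = FALSE)
  offs <- need(273, "StripOffsets"); cnts <- need(279, "StripByteCounts")
  body <- raw(0)
  for (i in seq_along(offs))
    body <- c(body, raw[(offs[i] + 1L):(offs[i] + cnts[i])])
  v <- readBin(body, "double", n = nr * nc, size = bits %/% 8L,
               endian = endian)
  if (length(v) != nr * nc)
    stop(sprintf("GeoTIFF pixel data has %d samples, expected %d",
                 length(v), nr * nc), call. = FALSE)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- tags[["42113"]]
  if (!is.null(nodata)) {
    nodata <- suppressWarnings(as.numeric(trimws(nodata)))
    if (!is.na(nodata)) m[m == nodata] <- NA_real_
  }
  scale <- need(33550, "ModelPixelScaleTag")
  tie <- need(33922, "ModelTiepointTag")
  if (abs(tie[1]) > 1e-9 || abs(tie[2]) > 1e-9)
    stop("GeoTIFF tiepoint must anchor raster origin (0,0)", call. = FALSE)
  if (abs(scale[1] - scale[2]) > 1e-9 * max(scale[1], scale[2]))
    stop("GeoTIFF must have square cells (pixel scale x = y)", call. = FALSE)
  env_grid(m, origin_lon = tie[4], origin_lat = tie[5], cellsize = scale[1])
}

write_geotiff <- function(grid, path, nodata = -9999, bits = 64L) {
  stopifnot(inherits(grid, "env_grid"), bits %in% c(32L, 64L))
  m <- grid$values
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  bytes_per <- bits %/% 8L
  data_len <- nr * nc * bytes_per
  nodata_str <- c(charToRaw(formatC(nodata, format = "g", digits = 17)),
                  as.raw(0L))
  # GeoKeyDirectory: geographic model, pixel-is-area, WGS84
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,
                          1025, 0, 1, 1,
                          2048, 0, 1, 4326))
  data_off <- 8L
  ifd_off <- data_off + data_len
  n_tags <- 14L
  after_ifd <- ifd_off + 2L + n_tags * 12L + 4L
  scale_off <- after_ifd
  tie_off <- scale_off + 24L
  geokey_off <- tie_off + 48L
  nodata_off <- geokey_off + length(geokeys) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wle(42L, 2L)
  wle(ifd_off, 4L)
  # pixel data: north row first, row-major
  writeBin(as.numeric(t(m)), con, size = bytes_per, endian = "little")
  # IFD
  wle(n_tags, 2L)
  entry <- function(tag, type, count, value, inline_size = 4L) {
    wle(tag, 2L); wle(type, 2L); wle(count, 4L)
    if (type == 3L && count == 1L) { wle(value, 2L); wle(0L, 2L) }
    else wle(value, 4L)
  }
  entry(256L, 4L, 1L, nc)                 # ImageWidth
  entry(257L, 4L, 1L, nr)                 # ImageLength
  entry(258L, 3L, 1L, bits)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                 # Compression = none
  entry(262L, 3L, 1L, 1L)                 # Photometric = BlackIsZero
  entry(273L, 4L, 1L, data_off)           # StripOffsets (single strip)
  entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
  entry(278L, 4L, 1L, nr)                 # RowsPerStrip
  entry(279L, 4L, 1L, data_len)           # StripByteCounts
  entry(339L, 3L, 1L, 3L)                 # SampleFormat = IEEE float
  entry(33550L, 12L, 3L, scale_off)       # ModelPixelScaleTag
  entry(33922L, 12L, 6L, tie_off)         # ModelTiepointTag
  entry(34735L, 3L, length(geokeys), geokey_off)  # GeoKeyDirectoryTag
  entry(42113L, 2L, length(nodata_str), nodata_off)  # GDAL_NODATA
  wle(0L, 4L)                             # next IFD: none
  writeBin(c(grid$cellsize, grid$cellsize, 0), con, size = 8L,
           endian = "little")
  writeBin(c(0, 0, 0, grid$origin_lon, grid$origin_lat, 0), con, size = 8L,
           endian = "little")
  wle(geokeys, 2L)
  writeBin(nodata_str, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
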