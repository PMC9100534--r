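#' Read a raster grid from file
#'
#' Supports single-band GeoTIFF and ESRI ASCII grid. The format is inferred
#' from the file extension (`.tif`/`.tiff` vs `.asc`/`.txt`) unless given.
#'
#' @param path File path.
#' @param format `"geotiff"`, `"esri_ascii"`, or `"auto"`.
#' @return An [env_grid()] with no-data cells masked as `NA`.
#' @export
read_grid <- function(path, format = c("auto", "geotiff", "esri_ascii")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "geotiff",
      asc = , txt = "esri_ascii",
      stop(sprintf("cannot infer grid format from extension '.%s'", ext),
           call. = FALSE))
  }
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format,
         geotiff = read_geotiff(path),
         esri_ascii = read_esri_ascii(path))
}

#' Write a raster grid to file
#'
#' @param grid An [env_grid()].
#' @param path Output path.
#' @param format `"geotiff"`, `"esri_ascii"`, or `"auto"` (from extension).
#' @param nodata No-data sentinel written to file (default -9999).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("auto", "geotiff", "esri_ascii"),
                       nodata = -9999) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "geotiff",
      asc = , txt = "esri_ascii",
      stop(sprintf("cannot infer grid format from extension '.%s'", ext),
           call. = FALSE))
  }
  switch(format,
         geotiff = write_geotiff(grid, path, nodata = nodata),
         esri_ascii = write_esri_ascii(grid, path, nodata = nodata))
  invisible(path)
}

# ESRI ASCII grid: 6-line header (ncols, nrows, xllcorner, yllcorner,
# cellsize, NODATA_value) then nrows lines of ncols values, north first.
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z_]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed ESRI ASCII header line: '%s'", lines[i]),
           call. = FALSE)
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]]) || is.na(hdr[[key]]))
      stop(sprintf("ESRI ASCII header missing or invalid field: %s", key),
           call. = FALSE)
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ESRI ASCII body has %d values, expected nrows*ncols = %d",
                 length(vals), nr * nc), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  env_grid(m,
           origin_lon = hdr$xllcorner,
           origin_lat = hdr$yllcorner + nr * hdr$cellsize,
           cellsize = hdr$cellsize)
}

write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "env_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin_lon),
    sprintf("yllcorner %.17g", grid$origin_lat - nr * grid$cellsize),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", nodata))
  # 17 significant digits guarantee exact double round-trip through text
  body <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read aligned raster layers into a stack
#'
#' @param paths Character vector of grid files; layer names default to the
#'   file stems.
#' @param names Optional layer names.
#' @return A [grid_stack()].
#' @export
read_stack <- function(paths, names = NULL) {
  if (is.null(names))
    names <- tools::file_path_sans_ext(basename(paths))
  layers <- lapply(paths, read_grid)
  names(layers) <- names
  grid_stack(layers)
}
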