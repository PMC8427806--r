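#' Elevation raster container
#'
#' A minimal georeferenced single-band raster: a numeric matrix (row 1 is the
#' northernmost row, as in image formats and ESRI ASCII grids), a square pixel
#' size in meters, and the map coordinates of the lower-left corner of the
#' grid. `NA` is the in-memory nodata sentinel. The `kind` field tracks what
#' the values mean: a surface model above sea level (`"DSM_ASL"`), a
#' bare-earth model (`"DEM_ASL"`), or normalized above-ground heights
#' (`"HEIGHT_AGL"`, constrained non-negative).
#'
#' Coordinates are planar projected meters. Rasters whose georeference looks
#' geographic (|coordinates| ≤ 360 with sub-meter "pixels" expressed in
#' degrees) cannot be detected reliably, so callers must project before use;
#' `pixel_size` is always interpreted as meters.
#'
#' @param values numeric matrix of elevations/heights (m); `NA` = nodata.
#' @param pixel_size pixel edge length in meters (> 0, square pixels).
#' @param xll,yll map coordinates (m) of the lower-left corner of the grid.
#' @param kind one of `"DSM_ASL"`, `"DEM_ASL"`, `"HEIGHT_AGL"`.
#' @return an object of class `elev_raster`.
#' @export
#' @examples
#' r <- elev_raster(matrix(100, 4, 5), pixel_size = 0.5)
#' dim(r$values)
elev_raster <- function(values, pixel_size, xll = 0, yll = 0,
                        kind = c("DSM_ASL", "DEM_ASL", "HEIGHT_AGL")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (m/px)")
  if (kind == "HEIGHT_AGL" && any(values < 0, na.rm = TRUE))
    stop("HEIGHT_AGL rasters must be non-negative where defined")
  structure(
    list(values = values, pixel_size = pixel_size,
         xll = xll, yll = yll, kind = kind),
    class = "elev_raster"
  )
}

#' @export
print.elev_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elev_raster %s: %d x %d px @ %g m/px, origin (%g, %g)>\n",
              x$kind, nrow(v), ncol(v), x$pixel_size, x$xll, x$yll))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g] m, %d nodata px\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.elev_raster <- function(x) dim(x$values)

is_elev_raster <- function(x) inherits(x, "elev_raster")

#' Map coordinates of pixel centers
#'
#' @param r an [elev_raster()].
#' @return a list with `x` (length ncol, west→east) and `y` (length nrow,
#'   north→south, matching matrix row order).
#' @export
raster_xy <- function(r) {
  stopifnot(is_elev_raster(r))
  nr <- nrow(r$values); nc <- ncol(r$values); px <- r$pixel_size
  list(
    x = r$xll + (seq_len(nc) - 0.5) * px,
    y = r$yll + (nr - seq_len(nr) + 0.5) * px
  )
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header, rows north→south). `cellsize` must be
#' square and is taken as meters.
#'
#' @param path file path.
#' @param kind raster kind tag to attach on read (see [elev_raster()]).
#' @return `read_asc()` returns an [elev_raster()]; `write_asc()` returns the
#'   path invisibly.
#' @export
read_asc <- function(path, kind = "DSM_ASL") {
  lines <- readLines(path, n = 6)
  known <- c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
             "yllcenter", "cellsize", "nodata_value")
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(kv[1])
    if (!key %in% known) break  # first data row ends the header
    hdr[[key]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, skip = length(hdr), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body size does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  elev_raster(m, pixel_size = hdr$cellsize,
              xll = hdr$xllcorner, yll = hdr$yllcorner, kind = kind)
}

#' @rdname read_asc
#' @param r an [elev_raster()] to write.
#' @param nodata numeric sentinel written for `NA` pixels.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(is_elev_raster(r))
  m <- r$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$pixel_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  write.table(format(m, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
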