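#' Lightweight single-band raster
#'
#' An in-memory raster: a numeric or integer matrix with square cells, an
#' origin, and `NA` as the nodata value. Row 1 is the northernmost row
#' (origin top-left), matching the usual image convention of remote-sensing
#' rasters. Georeferencing is minimal on purpose: a cell size in metres and
#' the coordinates of the lower-left corner, which is all the analysis needs
#' to convert cell counts into areas.
#'
#' @param values numeric or integer matrix; `NA` marks nodata cells.
#' @param cellsize side length of a cell in metres (default 30, a Landsat
#'   pixel).
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param categorical logical; `TRUE` for class-coded rasters (land use,
#'   zones), `FALSE` for continuous fields (NDVI, drivers).
#' @return an object of class `oasis_raster`.
#' @export
new_raster <- function(values, cellsize = 30, xll = 0, yll = 0,
                       categorical = FALSE) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have positive dimensions", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll),
         categorical = isTRUE(categorical)),
    class = "oasis_raster"
  )
}

#' @export
is_raster <- function(x) inherits(x, "oasis_raster")

#' @export
dim.oasis_raster <- function(x) dim(x$values)

#' @export
print.oasis_raster <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (x$categorical) "categorical" else "continuous"
  cat(sprintf("<oasis_raster> %d x %d cells, %s, cellsize %g m\n",
              d[1], d[2], kind, x$cellsize))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    if (x$categorical) {
      tb <- table(v)
      cat("  classes:", paste(names(tb), collapse = " "), "\n")
    } else {
      cat(sprintf("  range: [%.4g, %.4g]\n", min(v), max(v)))
    }
  }
  cat(sprintf("  nodata cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.oasis_raster <- function(x, main = "", ...) {
  # image() wants x ascending and transposed; flip rows so north is up
  m <- t(x$values[nrow(x$values):1, , drop = FALSE])
  graphics::image(m, main = main, useRaster = TRUE, axes = FALSE, ...)
  invisible(x)
}

#' Cell area in square kilometres
#' @param raster an `oasis_raster`.
#' @export
cell_area_km2 <- function(raster) {
  stopifnot(is_raster(raster))
  (raster$cellsize / 1000)^2
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ArcInfo ASCII raster format (`ncols`/`nrows` header,
#' optional `nodata_value`, rows listed north to south). `xllcenter`/
#' `yllcenter` headers are converted to corner coordinates.
#'
#' @param path file path.
#' @param categorical logical; store values as integer class codes.
#' @return an `oasis_raster`.
#' @export
read_ascii_grid <- function(path, categorical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header must define ncols, nrows and cellsize",
         call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (categorical) storage.mode(m) <- "integer"
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else 0
  new_raster(m, cellsize = hdr$cellsize, xll = xll, yll = yll,
             categorical = categorical)
}

#' Write an ESRI ASCII grid
#'
#' Integer rasters round-trip exactly; continuous rasters are written with
#' full double precision (`%.17g`).
#'
#' @param raster an `oasis_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(is_raster(raster))
  m <- raster$values
  nodata <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cellsize),
    sprintf("NODATA_value %d", nodata)
  )
  fmt <- if (is.integer(m) || raster$categorical) "%d" else "%.17g"
  mm <- m
  mm[is.na(mm)] <- nodata
  if (fmt == "%d") storage.mode(mm) <- "integer"
  rows <- apply(mm, 1L, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
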