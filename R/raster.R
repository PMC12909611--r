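#' Lightweight gridded raster
#'
#' A minimal single-band raster on a regular grid in projected metre
#' coordinates: a numeric matrix plus an origin and a cell size. Row 1 of the
#' matrix is the northernmost row (the convention of the ESRI ASCII grid
#' format used for I/O). `NA` cells are outside the study area (no data).
#'
#' @param values numeric matrix; row 1 = top (north) row.
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param cellsize cell edge length in metres; must be > 0.
#' @return an object of class `sea_raster`.
#' @export
sea_raster <- function(values, xll = 0, yll = 0, cellsize = 25) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "sea_raster"
  )
}

#' @export
print.sea_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<sea_raster> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
    nrow(v), ncol(v), x$cellsize, x$xll, x$yll
  ))
  cat(sprintf(
    "  data cells: %d / %d; range [%g, %g]\n",
    sum(!is.na(v)), length(v),
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE))
  ))
  invisible(x)
}

#' @export
dim.sea_raster <- function(x) dim(x$values)

#' Cell-centre coordinates
#'
#' @param r a [sea_raster].
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south, matching matrix row order).
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  list(
    x = r$xll + (seq_len(nc) - 0.5) * cs,
    y = r$yll + (nr - seq_len(nr) + 0.5) * cs
  )
}

#' Locate the cell containing a point
#'
#' @param r a [sea_raster].
#' @param x,y point coordinates (metres), vectorised.
#' @return integer matrix with columns `row`, `col`; NA for points off-grid.
#' @export
cell_at <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  col <- floor((x - r$xll) / cs) + 1L
  row <- nr - floor((y - r$yll) / cs)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at points
#'
#' @inheritParams cell_at
#' @return numeric vector of cell values (NA off-grid or no-data).
#' @export
raster_extract <- function(r, x, y) {
  rc <- cell_at(r, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1L])
  out[ok] <- r$values[rc[ok, , drop = FALSE]]
  out
}

#' Do two rasters share a grid?
#'
#' Same dimensions, cell size and origin (to 1e-6 m).
#' @param a,b [sea_raster] objects.
#' @return logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) < 1e-6 &&
    abs(a$xll - b$xll) < 1e-6 && abs(a$yll - b$yll) < 1e-6
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard 6-line header; `NA` cells are written
#' as the NODATA value.
#'
#' @param r a [sea_raster].
#' @param path output file path.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE, digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path of a `.asc` grid.
#' @return a [sea_raster]; NODATA cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z_]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) stop("malformed ASCII grid header: missing ", key)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body has ", length(vals), " values; header implies ",
         hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  sea_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner, cellsize = hdr$cellsize)
}
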