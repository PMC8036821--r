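#' Binary raster surfaces
#'
#' A `binary_raster` is the measurement substrate of the landscape metrics:
#' a rectangular grid of 0/1 cells (tree canopy present/absent, greenspace
#' present/absent) with a square cell size and a planar origin. Row 1 of the
#' grid is the northernmost row, matching the on-disk layout of the ESRI
#' ASCII raster dialect used for serialization.
#'
#' @param grid matrix of 0/1 values (integer or numeric).
#' @param cell_size edge length of one cell in planar units; must be > 0.
#' @param origin numeric length-2, planar coordinates `(x0, y0)` of the
#'   lower-left corner of the grid.
#' @return an object of class `binary_raster` with fields `grid`,
#'   `cell_size`, `origin`.
#' @examples
#' r <- binary_raster(matrix(c(0, 1, 1, 0), 2, 2), cell_size = 2)
#' cover <- sum(r$grid) / length(r$grid)
#' @export
binary_raster <- function(grid, cell_size = 1, origin = c(0, 0)) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  if (anyNA(grid) || !all(grid == 0L | grid == 1L)) {
    stopf("binary_raster values must be exactly 0 or 1")
  }
  storage.mode(grid) <- "integer"
  cell_size <- check_positive(cell_size, "cell_size")
  if (!is.numeric(origin) || length(origin) != 2L || anyNA(origin)) {
    stopf("origin must be numeric length 2")
  }
  structure(
    list(grid = grid, cell_size = cell_size, origin = as.numeric(origin)),
    class = "binary_raster"
  )
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf(
    "<binary_raster> %d x %d cells, cell_size %g, origin (%g, %g), cover %.3f\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, x$origin[1], x$origin[2],
    mean(x$grid)
  ))
  invisible(x)
}

#' @export
dim.binary_raster <- function(x) dim(x$grid)

# planar x coordinate of column centers / y coordinate of row centers
# (row 1 = top row)
cell_center_x <- function(raster, col) {
  raster$origin[1] + (col - 0.5) * raster$cell_size
}

cell_center_y <- function(raster, row) {
  raster$origin[2] + (nrow(raster$grid) - row + 0.5) * raster$cell_size
}

#' Write a binary raster as an ESRI ASCII grid
#'
#' Plain-text serialization (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header followed by rows from north to south), readable by standard GIS
#' tooling and by [read_ascii_grid()].
#'
#' @param raster a [binary_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "binary_raster"))
  g <- raster$grid
  header <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999"
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a binary raster
#'
#' @param path path to an ASCII grid file with 0/1 cell values.
#' @return a [binary_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stopf("ASCII grid header missing '%s'", key)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stopf("ASCII grid body has %d values, expected %d", length(vals), nr * nc)
  }
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  binary_raster(grid,
                cell_size = hdr$cellsize,
                origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}
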