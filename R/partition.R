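#' Regular tract partitions
#'
#' The unit of analysis is the census tract. For synthetic studies the tract
#' partition is a regular `n_rows` x `n_cols` grid of square tracts, each
#' `tract_cells` x `tract_cells` raster cells: queen/rook adjacency is then
#' analytically known, which is what the estimator tests need. Tract ids are
#' assigned row-major from the northwest corner.
#'
#' @param n_rows,n_cols number of tract rows/columns.
#' @param tract_cells raster cells per tract edge.
#' @param cell_size raster cell edge length in planar units.
#' @param origin planar coordinates of the lower-left corner.
#' @return a list with elements `partition` (a `tract_partition`) and
#'   `raster` (an all-zero [binary_raster()] covering the study area).
#' @examples
#' sp <- simulate_partition(2, 2, 10, 1)
#' sp$partition$n          # 4 tracts
#' tract_areas(sp$partition)  # all 100
#' @export
simulate_partition <- function(n_rows, n_cols, tract_cells, cell_size = 1,
                               origin = c(0, 0)) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  tract_cells <- check_count(tract_cells, "tract_cells")
  cell_size <- check_positive(cell_size, "cell_size")
  n <- n_rows * n_cols
  partition <- structure(
    list(
      n = n,
      n_rows = n_rows,
      n_cols = n_cols,
      tract_cells = tract_cells,
      cell_size = cell_size,
      origin = as.numeric(origin),
      tract_id = sprintf("T%04d", seq_len(n))
    ),
    class = "tract_partition"
  )
  empty <- binary_raster(
    matrix(0L, nrow = n_rows * tract_cells, ncol = n_cols * tract_cells),
    cell_size = cell_size, origin = origin
  )
  list(partition = partition, raster = empty)
}

#' @export
print.tract_partition <- function(x, ...) {
  cat(sprintf(
    "<tract_partition> %d x %d tracts (%d), %d cells/edge, cell_size %g\n",
    x$n_rows, x$n_cols, x$n, x$tract_cells, x$cell_size
  ))
  invisible(x)
}

#' Planar area of each tract
#'
#' @param partition a `tract_partition`.
#' @return named numeric vector of tract areas.
#' @export
tract_areas <- function(partition) {
  a <- (partition$tract_cells * partition$cell_size)^2
  stats::setNames(rep(a, partition$n), partition$tract_id)
}

# raster row/col ranges of tract t (row-major index)
tract_block <- function(partition, t) {
  tr <- (t - 1L) %/% partition$n_cols + 1L
  tc <- (t - 1L) %% partition$n_cols + 1L
  k <- partition$tract_cells
  list(rows = ((tr - 1L) * k + 1L):(tr * k),
       cols = ((tc - 1L) * k + 1L):(tc * k))
}

# check a raster and a partition share the same frame
check_frame <- function(partition, raster) {
  ok <- nrow(raster$grid) == partition$n_rows * partition$tract_cells &&
    ncol(raster$grid) == partition$n_cols * partition$tract_cells &&
    isTRUE(all.equal(raster$cell_size, partition$cell_size)) &&
    isTRUE(all.equal(raster$origin, partition$origin))
  if (!ok) stopf("raster and partition are not in the same coordinate frame")
  invisible(TRUE)
}

# polygon ring (closed, counter-clockwise) of tract t in planar coordinates
tract_ring <- function(partition, t) {
  tr <- (t - 1L) %/% partition$n_cols + 1L
  tc <- (t - 1L) %% partition$n_cols + 1L
  side <- partition$tract_cells * partition$cell_size
  x0 <- partition$origin[1] + (tc - 1L) * side
  # tract row 1 is the northernmost band
  y0 <- partition$origin[2] + (partition$n_rows - tr) * side
  rbind(
    c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side),
    c(x0, y0)
  )
}

#' Write a tract partition as GeoJSON polygons
#'
#' Each tract becomes a `Polygon` feature carrying a `tract_id` property.
#'
#' @param partition a `tract_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition_geojson <- function(partition, path) {
  stopifnot(inherits(partition, "tract_partition"))
  features <- lapply(seq_len(partition$n), function(t) {
    ring <- tract_ring(partition, t)
    list(
      type = "Feature",
      properties = list(tract_id = partition$tract_id[t]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) ring[i, ]))
      )
    )
  })
  obj <- list(
    type = "FeatureCollection",
    properties = list(
      n_rows = partition$n_rows, n_cols = partition$n_cols,
      tract_cells = partition$tract_cells, cell_size = partition$cell_size,
      origin = partition$origin
    ),
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tract partition from GeoJSON
#'
#' Only regular square-grid partitions (as written by
#' [write_partition_geojson()]) are supported; irregular polygon sets are
#' refused.
#'
#' @param path GeoJSON file path.
#' @return a `tract_partition`.
#' @export
read_partition_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- obj$properties
  if (is.null(pr$n_rows) || is.null(pr$tract_cells)) {
    stopf("GeoJSON lacks the regular-grid metadata; only regular partitions are supported")
  }
  sp <- simulate_partition(pr$n_rows, pr$n_cols, pr$tract_cells,
                           pr$cell_size, unlist(pr$origin))
  ids <- obj$features$properties$tract_id
  if (!is.null(ids) && length(ids) == sp$partition$n) {
    sp$partition$tract_id <- as.character(ids)
  }
  sp$partition
}
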