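#' Connected-component labelling of a binary grid
#'
#' Labels maximal connected sets of 1-cells (tree patches) under 4- or
#' 8-neighbour connectivity using union-find with path halving. The default
#' is 8-neighbour: crowns touching diagonally read as one canopy.
#'
#' @param grid 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 for background, patch labels
#'   1..K for foreground, labels numbered in row-major order of first
#'   occurrence.
#' @export
label_components <- function(grid, connectivity = 8) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  nr <- nrow(grid)
  nc <- ncol(grid)
  ones <- which(grid == 1L)
  m <- length(ones)
  out <- matrix(0L, nr, nc)
  if (m == 0L) return(out)
  id <- matrix(0L, nr, nc)
  id[ones] <- seq_len(m)
  parent <- seq_len(m)

  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]   # path halving
      x <- parent[x]
    }
    x
  }

  # edges between each 1-cell and its already-visited neighbour directions
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  }
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a > 0L & b > 0L)
    if (length(hit) == 0L) next
    ea <- a[hit]; eb <- b[hit]
    for (k in seq_along(ea)) {
      ra <- find_root(ea[k])
      rb <- find_root(eb[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(m), find_root, integer(1))
  # stable labels: 1..K in row-major order of first appearance
  # `ones` is column-major; recover row-major order of the compact ids
  rows <- (ones - 1L) %% nr + 1L
  cols <- (ones - 1L) %/% nr + 1L
  ord <- order(rows, cols)
  labels <- integer(m)
  nxt <- 0L
  seen <- integer(m)
  for (k in ord) {
    r <- roots[k]
    if (seen[r] == 0L) {
      nxt <- nxt + 1L
      seen[r] <- nxt
    }
    labels[k] <- seen[r]
  }
  out[ones] <- labels
  out
}

#' Extract tree patches within one tract
#'
#' Every canopy cell whose center falls in the tract belongs to exactly one
#' patch; patches are maximal connected components delineated within the
#' tract independently (a canopy spanning a tract boundary is split, since
#' all metrics are defined per tract).
#'
#' @param raster a [binary_raster()] canopy layer.
#' @param partition a `tract_partition` in the same frame.
#' @param tract tract index (1-based, row-major) or tract id.
#' @param connectivity 4 or 8 (default) neighbour rule.
#' @return a list of patches, each a list with `n_cells`, `area`
#'   (cells x cell_size^2), `centroid` (planar `(x, y)` mean of member cell
#'   centers) and `cells` (2-column matrix of raster row/col). Empty
#'   intersection yields an empty list.
#' @export
extract_patches <- function(raster, partition, tract, connectivity = 8) {
  check_frame(partition, raster)
  if (is.character(tract)) tract <- match(tract, partition$tract_id)
  t <- check_count(tract, "tract")
  if (t > partition$n) stopf("tract index out of range")
  blk <- tract_block(partition, t)
  sub <- raster$grid[blk$rows, blk$cols, drop = FALSE]
  lab <- label_components(sub, connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  cell_area <- raster$cell_size^2
  lapply(seq_len(k), function(j) {
    idx <- which(lab == j, arr.ind = TRUE)
    rows <- blk$rows[idx[, 1]]
    cols <- blk$cols[idx[, 2]]
    list(
      n_cells = nrow(idx),
      area = nrow(idx) * cell_area,
      centroid = c(x = mean(cell_center_x(raster, cols)),
                   y = mean(cell_center_y(raster, rows))),
      cells = cbind(row = rows, col = cols)
    )
  })
}

#' Canopy cover fraction of a tract
#'
#' @param raster a [binary_raster()] canopy layer.
#' @param partition a `tract_partition` in the same frame.
#' @param tract tract index or id.
#' @return fraction of tract area under canopy, in `[0, 1]`.
#' @export
tree_cover_fraction <- function(raster, partition, tract) {
  check_frame(partition, raster)
  if (is.character(tract)) tract <- match(tract, partition$tract_id)
  t <- check_count(tract, "tract")
  blk <- tract_block(partition, t)
  mean(raster$grid[blk$rows, blk$cols])
}

#' Median patch size
#'
#' The per-tract patch-size summary is the median (patch-size distributions
#' are right-skewed, so the median is preferred to the mean); an even count
#' returns the mean of the two central order statistics.
#'
#' @param patches list of patches from [extract_patches()], or a numeric
#'   vector of patch areas.
#' @return median patch area; `NA` with a flag attribute if no patches.
#' @export
median_patch_size <- function(patches) {
  areas <- if (is.numeric(patches)) patches
  else vapply(patches, function(p) p$area, numeric(1))
  if (length(areas) == 0L) {
    return(structure(NA_real_, flag = "no_patches"))
  }
  stats::median(areas)
}

#' Average nearest-neighbor index of a point set
#'
#' NNI = observed mean nearest-neighbor distance / expected mean distance
#' under complete spatial randomness over the same area,
#' `0.5 / sqrt(n / area)`. Values below 1 indicate clustering, above 1
#' dispersion. No edge correction is applied (the conventional
#' average-nearest-neighbor formula); this carries a small upward
#' small-sample bias near boundaries.
#'
#' @param centroids 2-column matrix (or list of length-2 points) of planar
#'   coordinates.
#' @param area planar area of the enclosing region; must be > 0.
#' @return dimensionless ratio >= 0; `NA` with a flag attribute for fewer
#'   than 2 points.
#' @examples
#' pts <- cbind(runif(50), runif(50))
#' nearest_neighbor_index(pts, area = 1)
#' @export
nearest_neighbor_index <- function(centroids, area) {
  if (is.list(centroids) && !is.data.frame(centroids)) {
    centroids <- do.call(rbind, lapply(centroids, function(p) {
      if (!is.null(p$centroid)) p$centroid else unlist(p)
    }))
  }
  centroids <- as.matrix(centroids)
  area <- check_positive(area, "area")
  n <- nrow(centroids)
  if (n < 2L) {
    return(structure(NA_real_, flag = "fewer_than_two_points"))
  }
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  d_obs <- mean(apply(d, 1L, min))
  d_exp <- 0.5 / sqrt(n / area)
  d_obs / d_exp
}

#' Stratify greenspace area by land-use tenure within a tract
#'
#' Overlays the binary greenspace raster with the land-use map: each green
#' cell contributes its area to exactly one tenure class — private
#' (residential, commercial, office, industrial), semi-public (golf,
#' education, cemetery, agriculture), or public (parks and recreation).
#' Green cells in unmapped categories are counted as unclassified and
#' reported, never silently dropped.
#'
#' @param green a [binary_raster()] greenspace layer.
#' @param landuse a [land_use_map()] in the same frame.
#' @param partition a `tract_partition` in the same frame.
#' @param tract tract index or id.
#' @return named numeric vector `c(PrvtGrn, SemiGrn, GrnRec, UnclGrn)` of
#'   fractions of total tract area.
#' @export
classify_greenspace <- function(green, landuse, partition, tract) {
  check_frame(partition, green)
  check_landuse_frame(partition, landuse)
  if (is.character(tract)) tract <- match(tract, partition$tract_id)
  t <- check_count(tract, "tract")
  blk <- tract_block(partition, t)
  g <- green$grid[blk$rows, blk$cols]
  lab <- landuse$labels[blk$rows, blk$cols]
  tenure <- landuse_tenure()[landuse$categories[lab[g == 1L]]]
  tenure[is.na(tenure)] <- "unclassified"
  ncell <- length(g)
  counts <- table(factor(tenure,
                         levels = c("private", "semi_public", "public",
                                    "unclassified")))
  c(PrvtGrn = unname(counts["private"]) / ncell,
    SemiGrn = unname(counts["semi_public"]) / ncell,
    GrnRec = unname(counts["public"]) / ncell,
    UnclGrn = unname(counts["unclassified"]) / ncell)
}

#' Per-tract landscape metrics table
#'
#' Assembles the six tree/greenspace variables for every tract: canopy
#' cover (`TreeCov`), median tree-patch size (`TreeClus`, in squared raster
#' units), nearest-neighbor index of patch centroids (`TreeAgr`), and the
#' three tenure-stratified greenspace fractions (`PrvtGrn`, `SemiGrn`,
#' `GrnRec`). Tracts where `TreeClus`/`TreeAgr` are undefined (no patches,
#' or a single patch for the NNI) carry a non-empty `flags` entry; the
#' pipeline's filtering stage drops them.
#'
#' @param canopy a [binary_raster()] canopy layer.
#' @param green a [binary_raster()] greenspace layer.
#' @param landuse a [land_use_map()].
#' @param partition a `tract_partition`; all layers share its frame.
#' @param connectivity patch connectivity, 4 or 8 (default).
#' @return data.frame with one row per tract: `tract_id`, the six metrics,
#'   `UnclGrn`, `n_patches` and a `flags` character column
#'   (semicolon-separated reasons, empty when all metrics are defined).
#' @export
compute_tract_metrics <- function(canopy, green, landuse, partition,
                                  connectivity = 8) {
  check_frame(partition, canopy)
  check_frame(partition, green)
  check_landuse_frame(partition, landuse)
  areas <- tract_areas(partition)
  n <- partition$n
  out <- data.frame(
    tract_id = partition$tract_id,
    TreeCov = numeric(n), TreeClus = numeric(n), TreeAgr = numeric(n),
    PrvtGrn = numeric(n), SemiGrn = numeric(n), GrnRec = numeric(n),
    UnclGrn = numeric(n), n_patches = integer(n),
    flags = character(n),
    stringsAsFactors = FALSE
  )
  for (t in seq_len(n)) {
    patches <- extract_patches(canopy, partition, t, connectivity)
    flags <- character(0)
    out$TreeCov[t] <- tree_cover_fraction(canopy, partition, t)
    out$n_patches[t] <- length(patches)
    med <- median_patch_size(patches)
    if (is.na(med)) {
      flags <- c(flags, "undefined TreeClus")
      out$TreeClus[t] <- NA_real_
    } else {
      out$TreeClus[t] <- med
    }
    if (length(patches) >= 2L) {
      cent <- do.call(rbind, lapply(patches, function(p) p$centroid))
      out$TreeAgr[t] <- nearest_neighbor_index(cent, areas[t])
    } else {
      flags <- c(flags, "undefined TreeAgr")
      out$TreeAgr[t] <- NA_real_
    }
    gr <- classify_greenspace(green, landuse, partition, t)
    out$PrvtGrn[t] <- gr["PrvtGrn"]
    out$SemiGrn[t] <- gr["SemiGrn"]
    out$GrnRec[t] <- gr["GrnRec"]
    out$UnclGrn[t] <- gr["UnclGrn"]
    out$flags[t] <- paste(flags, collapse = ";")
  }
  out
}
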