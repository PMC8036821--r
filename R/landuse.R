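#' Land-use maps and greenspace tenure classes
#'
#' Land use is represented as a label grid in the same frame as the rasters:
#' every cell carries exactly one category. Categories follow the parcel
#' classes relevant to greenspace tenure: private urban uses (residential,
#' commercial, office, industrial), semi-public uses with restricted access
#' (golf courses, educational facilities, cemeteries, agriculture), public
#' recreational space (parks), and a residual `other` class.
#'
#' @name land_use_map
NULL

#' Recognized land-use categories
#'
#' @return character vector of category names.
#' @export
landuse_categories <- function() {
  c("residential", "commercial", "office", "industrial",
    "golf", "education", "cemetery", "agriculture",
    "park_recreation", "other")
}

# tenure class of each land-use category: which of the three greenspace
# variables a green cell in that category feeds
landuse_tenure <- function() {
  c(residential = "private", commercial = "private", office = "private",
    industrial = "private",
    golf = "semi_public", education = "semi_public",
    cemetery = "semi_public", agriculture = "semi_public",
    park_recreation = "public",
    other = "unclassified")
}

#' Construct a land-use map from a label grid
#'
#' @param labels integer matrix of category codes (indices into `categories`).
#' @param categories character vector of category names; defaults to
#'   [landuse_categories()].
#' @param cell_size,origin raster frame, as in [binary_raster()].
#' @return an object of class `land_use_map`.
#' @export
land_use_map <- function(labels, categories = landuse_categories(),
                         cell_size = 1, origin = c(0, 0)) {
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 1L) || any(labels > length(categories))) {
    stopf("land-use labels must index into the category vector")
  }
  structure(
    list(labels = labels, categories = as.character(categories),
         cell_size = check_positive(cell_size, "cell_size"),
         origin = as.numeric(origin)),
    class = "land_use_map"
  )
}

#' @export
print.land_use_map <- function(x, ...) {
  tab <- table(factor(x$categories[x$labels], levels = x$categories))
  cat(sprintf("<land_use_map> %d x %d cells, %d categories\n",
              nrow(x$labels), ncol(x$labels), length(x$categories)))
  print(tab[tab > 0])
  invisible(x)
}

# frame check mirroring check_frame() for rasters
check_landuse_frame <- function(partition, landuse) {
  ok <- nrow(landuse$labels) == partition$n_rows * partition$tract_cells &&
    ncol(landuse$labels) == partition$n_cols * partition$tract_cells &&
    isTRUE(all.equal(landuse$cell_size, partition$cell_size)) &&
    isTRUE(all.equal(landuse$origin, partition$origin))
  if (!ok) stopf("land-use map and partition are not in the same frame")
  invisible(TRUE)
}

#' Per-tract share of area in a land-use category
#'
#' Used by the tract-filtering stage to identify tracts without residential
#' land (the synthetic analogue of park/forest-only tracts).
#'
#' @param landuse a [land_use_map()].
#' @param partition a `tract_partition` in the same frame.
#' @param category category name, e.g. `"residential"`.
#' @return named numeric vector of per-tract fractions in `[0, 1]`.
#' @export
landuse_share <- function(landuse, partition, category = "residential") {
  check_landuse_frame(partition, landuse)
  code <- match(category, landuse$categories)
  if (is.na(code)) stopf("unknown land-use category '%s'", category)
  out <- numeric(partition$n)
  for (t in seq_len(partition$n)) {
    blk <- tract_block(partition, t)
    lab <- landuse$labels[blk$rows, blk$cols]
    out[t] <- mean(lab == code)
  }
  stats::setNames(out, partition$tract_id)
}
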