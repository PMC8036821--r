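#' Contiguity spatial weights
#'
#' The weight matrix W enters the spatial lag model (as the lag `Wy`), the
#' spatial error model (as the error autoregression), and Moran's I. Weights
#' are built as binary first-order contiguity on the tract grid — queen
#' (shared edge or corner) by default, rook (shared edge) optionally — and
#' are row-standardized before estimation so that `Wy` is a neighbor
#' average. The binary adjacency is retained inside the object: the
#' eigenvalue machinery exploits its symmetry.
#'
#' @param partition a `tract_partition`.
#' @param type `"queen"` or `"rook"` contiguity.
#' @return an object of class `spatial_weights` with fields `n`, `ids`,
#'   `neighbours` (adjacency lists of integer indices), `weights`
#'   (per-neighbour values), `style` (`"B"` binary or `"W"`
#'   row-standardized) and `islands` (indices with no neighbours).
#' @examples
#' p <- simulate_partition(3, 3, 5)$partition
#' W <- row_standardize(build_queen_weights(p))
#' lengths(W$neighbours)[5]  # the center tract of a 3x3 grid has 8 neighbours
#' @export
build_queen_weights <- function(partition, type = c("queen", "rook")) {
  stopifnot(inherits(partition, "tract_partition"))
  type <- match.arg(type)
  nr <- partition$n_rows
  nc <- partition$n_cols
  n <- nr * nc
  offs <- if (type == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  neighbours <- vector("list", n)
  for (t in seq_len(n)) {
    r <- (t - 1L) %/% nc + 1L
    c_ <- (t - 1L) %% nc + 1L
    rr <- r + offs[, "dr"]
    cc <- c_ + offs[, "dc"]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    neighbours[[t]] <- sort(as.integer((rr[ok] - 1L) * nc + cc[ok]))
  }
  new_spatial_weights(partition$tract_id, neighbours,
                      lapply(neighbours, function(nb) rep(1, length(nb))),
                      style = "B")
}

new_spatial_weights <- function(ids, neighbours, weights, style) {
  islands <- which(lengths(neighbours) == 0L)
  structure(
    list(n = length(ids), ids = as.character(ids), neighbours = neighbours,
         weights = weights, style = style, islands = islands),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf(
    "<spatial_weights> n = %d, style = %s, avg neighbours %.2f, islands %d\n",
    x$n, x$style, mean(lengths(x$neighbours)), length(x$islands)
  ))
  invisible(x)
}

#' Row-standardize a spatial weights object
#'
#' Divides each row of weights by its sum so that non-island rows sum to 1.
#' Island rows (no neighbours) are left all-zero and a warning is emitted;
#' estimation functions refuse islands. Idempotent.
#'
#' @param W a `spatial_weights` object.
#' @return the row-standardized `spatial_weights` (style `"W"`).
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(W$islands) > 0L) {
    warnf("%d island tract(s) have no neighbours; their rows stay zero",
          length(W$islands))
  }
  W$weights <- lapply(W$weights, function(w) {
    s <- sum(w)
    if (s > 0) w / s else w
  })
  W$style <- "W"
  W
}

#' Dense matrix form of a spatial weights object
#'
#' @param W a `spatial_weights` object.
#' @return an `n` x `n` numeric matrix with zero diagonal.
#' @export
weights_matrix <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  m <- matrix(0, W$n, W$n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(W$n)) {
    m[i, W$neighbours[[i]]] <- W$weights[[i]]
  }
  m
}

#' Eigenvalue spectrum and bounds of a row-standardized W
#'
#' For W derived from a symmetric binary adjacency B by row standardization,
#' W = D^-1 B is similar to the symmetric matrix D^-1/2 B D^-1/2, so its
#' spectrum is real and is computed with a symmetric eigensolver. The
#' admissible interval for the spatial parameter of the lag/error models is
#' `(1/min(values), 1/max(values))`; for a connected row-standardized W the
#' maximum eigenvalue is 1. Island rows contribute zero eigenvalues.
#'
#' @param W a `spatial_weights` object built from symmetric binary adjacency.
#' @return list with `values` (sorted ascending), `min`, `max`.
#' @export
eigenvalue_bounds <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  deg <- lengths(W$neighbours)
  keep <- which(deg > 0L)
  if (length(keep) == 0L) stopf("all tracts are islands; W has no spectrum")
  # symmetric similarity transform on the non-island block
  idx <- match(seq_len(W$n), keep)
  d <- sqrt(deg[keep])
  m <- matrix(0, length(keep), length(keep))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    nb <- W$neighbours[[i]]
    jj <- idx[nb]
    if (anyNA(jj)) stopf("adjacency is not symmetric (island with incoming edge)")
    m[ii, jj] <- 1 / (d[ii] * d[jj])
  }
  if (max(abs(m - t(m))) > 1e-12) stopf("adjacency is not symmetric")
  vals <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (length(keep) < W$n) vals <- c(vals, rep(0, W$n - length(keep)))
  vals <- sort(vals)
  list(values = vals, min = vals[1], max = vals[length(vals)])
}

#' Restrict a spatial weights object to a subset of tracts
#'
#' Used after tract filtering: the retained tracts keep their mutual
#' adjacency (the subgraph), and the result is re-standardized if the input
#' was.
#'
#' @param W a `spatial_weights` object.
#' @param keep integer indices or tract ids to retain.
#' @return a `spatial_weights` on the retained tracts.
#' @export
subset_weights <- function(W, keep) {
  stopifnot(inherits(W, "spatial_weights"))
  if (is.character(keep)) keep <- match(keep, W$ids)
  keep <- as.integer(keep)
  if (anyNA(keep) || any(keep < 1L | keep > W$n)) stopf("invalid subset indices")
  pos <- match(seq_len(W$n), keep)
  neighbours <- lapply(W$neighbours[keep], function(nb) {
    nb2 <- pos[nb]
    sort(nb2[!is.na(nb2)])
  })
  out <- new_spatial_weights(
    W$ids[keep], neighbours,
    lapply(neighbours, function(nb) rep(1, length(nb))),
    style = "B"
  )
  if (W$style == "W") out <- suppressWarnings(row_standardize(out))
  out
}

#' Write spatial weights in GAL neighbour-list format
#'
#' First line gives the number of units; then, for each unit, a line
#' `id  n_neighbours` followed by a line of neighbour ids. Ordering is the
#' object's deterministic tract-id order. Binary adjacency only (the GAL
#' dialect carries no weights); re-standardize after reading.
#'
#' @param W a `spatial_weights` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(W, path) {
  stopifnot(inherits(W, "spatial_weights"))
  lines <- character(1L + 2L * W$n)
  lines[1] <- as.character(W$n)
  for (i in seq_len(W$n)) {
    lines[2 * i] <- sprintf("%s %d", W$ids[i], length(W$neighbours[[i]]))
    lines[2 * i + 1] <- paste(W$ids[W$neighbours[[i]]], collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read spatial weights from a GAL neighbour-list file
#'
#' @param path GAL file path.
#' @return a binary-style `spatial_weights` object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  ids <- character(n)
  raw_nbs <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- strsplit(trimws(lines[2 * i]), "\\s+")[[1]]
    ids[i] <- hdr[1]
    k <- as.integer(hdr[2])
    raw_nbs[[i]] <- if (k > 0L) {
      strsplit(trimws(lines[2 * i + 1]), "\\s+")[[1]]
    } else character(0)
  }
  neighbours <- lapply(raw_nbs, function(nb) sort(match(nb, ids)))
  if (anyNA(unlist(neighbours))) stopf("GAL file references unknown ids")
  new_spatial_weights(ids, neighbours,
                      lapply(neighbours, function(nb) rep(1, length(nb))),
                      style = "B")
}
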