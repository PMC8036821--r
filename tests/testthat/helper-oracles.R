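# Independent oracles and fixture builders used across the suite.

# brute-force flood fill (stack-based), independent of label_components
flood_fill_label <- function(grid, connectivity = 8) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (sc in seq_len(nc)) for (sr in seq_len(nr)) {
    if (grid[sr, sc] != 1L || lab[sr, sc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(sr, sc))
    lab[sr, sc] <- nxt
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        r <- cur[1] + offs[o, 1]
        c_ <- cur[2] + offs[o, 2]
        if (r >= 1L && r <= nr && c_ >= 1L && c_ <= nc &&
            grid[r, c_] == 1L && lab[r, c_] == 0L) {
          lab[r, c_] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c_)
        }
      }
    }
  }
  lab
}

# random 0/1 matrix
rand_grid <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# partition + row-standardized lattice weights in one call
lattice_weights <- function(n_rows, n_cols, type = "queen") {
  p <- simulate_partition(n_rows, n_cols, 2)$partition
  suppressWarnings(row_standardize(build_queen_weights(p, type)))
}

# hand-worked single-tract 10x10 fixture; expected values computed by hand
# from the cell coordinates (see test-metrics.R for the arithmetic)
hand_fixture <- function() {
  sp <- simulate_partition(1, 1, 10, cell_size = 1)
  canopy <- sp$raster$grid
  canopy[2:3, 2:3] <- 1L       # patch A, 4 cells, centroid (2.0, 8.0)
  canopy[2, 8] <- 1L           # patch B, 1 cell,  centroid (7.5, 8.5)
  canopy[7:9, 2:4] <- 1L       # patch C, 9 cells, centroid (2.5, 2.5)
  labels <- matrix(0L, 10, 10)
  labels[, 1:5] <- match("residential", landuse_categories())
  labels[, 6:8] <- match("golf", landuse_categories())
  labels[, 9:10] <- match("park_recreation", landuse_categories())
  green <- sp$raster$grid
  green[5:6, 1:2] <- 1L        # 4 residential green cells
  green[5, 6] <- 1L            # 1 golf green cell
  green[5:6, 9:10] <- 1L       # 4 park green cells
  list(
    partition = sp$partition,
    canopy = binary_raster(canopy),
    green = binary_raster(green),
    landuse = land_use_map(labels),
    expected = list(
      TreeCov = 14 / 100,
      TreeClus = 4,
      TreeAgr = sqrt(30.5) / (0.5 * sqrt(100 / 3)),
      PrvtGrn = 0.04,
      SemiGrn = 0.01,
      GrnRec = 0.04
    )
  )
}

# simulate a lag/error outcome directly from the model equations with a
# precomputed inverse (fast path for replication loops)
make_dgp <- function(W, k = 2, par = 0.5, process = "lag", sigma = 1,
                     beta = NULL) {
  n <- W$n
  Wm <- weights_matrix(W)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  if (is.null(beta)) beta <- c(1, rep(c(2, -1), length.out = k))
  Ainv <- if (process %in% c("lag", "error")) {
    solve(diag(n) - par * Wm)
  } else {
    diag(n)
  }
  xb <- drop(cbind(1, X) %*% beta)
  draw <- function() {
    innov <- rnorm(n, 0, sigma)
    if (process == "lag") drop(Ainv %*% (xb + innov))
    else if (process == "error") xb + drop(Ainv %*% innov)
    else xb + innov
  }
  list(X = X, beta = beta, draw = draw, Wm = Wm)
}
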