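#' Seeded patch-growth canopy simulator
#'
#' Generates a clustered binary canopy raster with known per-tract cover.
#' Within each tract, seed cells are placed uniformly at random
#' (`patch_intensity` seeds per unit of planar area) and patches are grown
#' by stochastic dilation — each iteration converts a random fraction
#' (`patch_growth`) of the current patch frontier — until the tract's
#' target cell count is reached exactly. Fewer seeds at the same cover
#' therefore yield larger, more aggregated patches (lower NNI); realized
#' cover differs from `target_cover` only by cell-count rounding, i.e. at
#' most half a cell per tract.
#'
#' @param partition a `tract_partition`.
#' @param target_cover canopy cover fraction in `[0, 1)`; scalar or one
#'   value per tract.
#' @param patch_intensity expected patch seeds per unit planar area; scalar
#'   or per tract. At least one seed is always placed when cover > 0, and
#'   never more seeds than target cells.
#' @param patch_growth fraction of the patch frontier converted per growth
#'   step, in `(0, 1]`; smaller values give rougher, more dendritic patches.
#' @param seed integer RNG seed; identical inputs give bit-identical rasters.
#' @return a [binary_raster()] canopy layer over the partition's frame.
#' @export
simulate_canopy <- function(partition, target_cover, patch_intensity,
                            patch_growth = 0.5, seed = 1L) {
  stopifnot(inherits(partition, "tract_partition"))
  n <- partition$n
  target_cover <- rep_len(as.numeric(target_cover), n)
  patch_intensity <- rep_len(as.numeric(patch_intensity), n)
  if (any(target_cover < 0 | target_cover >= 1)) {
    stopf("target_cover must lie in [0, 1)")
  }
  if (any(patch_intensity <= 0)) stopf("patch_intensity must be > 0")
  if (patch_growth <= 0 || patch_growth > 1) {
    stopf("patch_growth must lie in (0, 1]")
  }
  k <- partition$tract_cells
  area <- (k * partition$cell_size)^2
  grid <- matrix(0L, partition$n_rows * k, partition$n_cols * k)
  with_seed(seed, {
    for (t in seq_len(n)) {
      n_target <- round(target_cover[t] * k * k)
      if (n_target == 0L) next
      n_seeds <- max(1L, min(n_target, round(patch_intensity[t] * area)))
      block <- grow_patches(k, n_target, n_seeds, patch_growth)
      blk <- tract_block(partition, t)
      grid[blk$rows, blk$cols] <- block
    }
  })
  binary_raster(grid, cell_size = partition$cell_size,
                origin = partition$origin)
}

# stochastic dilation inside one k x k tract block
grow_patches <- function(k, n_target, n_seeds, patch_growth) {
  canopy <- matrix(FALSE, k, k)
  canopy[sample.int(k * k, n_seeds)] <- TRUE
  need <- n_target - sum(canopy)
  while (need > 0L) {
    fr <- which(dilate8(canopy) & !canopy)
    if (length(fr) == 0L) break  # unreachable while need > 0 and cover < 1
    n_add <- min(need, max(1L, round(patch_growth * length(fr))))
    add <- if (length(fr) <= n_add) fr else sample(fr, n_add)
    canopy[add] <- TRUE
    need <- need - length(add)
  }
  matrix(as.integer(canopy), k, k)
}

# 8-neighbour binary dilation of a logical matrix
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
    c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
    out[r_dst, c_dst] <- out[r_dst, c_dst] | m[r_dst - dr, c_dst - dc]
  }
  out
}

#' Simulate a land-use map and its greenspace raster
#'
#' Each tract is subdivided into contiguous vertical land-use strips whose
#' widths follow `class_shares` (the strip order is randomly permuted per
#' tract); within each strip, greenspace fills a contiguous block of cells
#' at that class's configured green share. The overlay inverse —
#' [classify_greenspace()] — recovers the configured shares up to cell
#' rounding at block boundaries.
#'
#' @param partition a `tract_partition`.
#' @param class_shares named fractions over [landuse_categories()] summing
#'   to 1; either one vector for all tracts or a matrix with one row per
#'   tract.
#' @param green_share_by_class named fractions in `[0, 1]`: share of each
#'   class's area that is green. Missing categories default to 0.
#' @param seed integer RNG seed.
#' @return list with `landuse` (a [land_use_map()]) and `green`
#'   (a [binary_raster()]).
#' @export
simulate_landuse_and_green <- function(partition, class_shares,
                                       green_share_by_class, seed = 1L) {
  stopifnot(inherits(partition, "tract_partition"))
  cats <- landuse_categories()
  shares <- normalize_shares(class_shares, partition$n, cats)
  gs <- stats::setNames(rep(0, length(cats)), cats)
  if (length(green_share_by_class)) {
    bad <- setdiff(names(green_share_by_class), cats)
    if (length(bad)) stopf("unknown land-use categories: %s",
                           paste(bad, collapse = ", "))
    gs[names(green_share_by_class)] <- as.numeric(green_share_by_class)
  }
  if (any(gs < 0 | gs > 1)) stopf("green shares must lie in [0, 1]")
  k <- partition$tract_cells
  labels <- matrix(1L, partition$n_rows * k, partition$n_cols * k)
  green <- matrix(0L, partition$n_rows * k, partition$n_cols * k)
  with_seed(seed, {
    for (t in seq_len(partition$n)) {
      blk <- tract_block(partition, t)
      ord <- sample.int(length(cats))
      sh <- shares[t, ord]
      cuts <- round(cumsum(sh) * k)
      widths <- diff(c(0L, cuts))
      col0 <- 0L
      for (j in seq_along(ord)) {
        w <- widths[j]
        if (w <= 0L) next
        cols <- blk$cols[(col0 + 1L):(col0 + w)]
        labels[blk$rows, cols] <- ord[j]
        n_green <- round(gs[ord[j]] * k * w)
        if (n_green > 0L) {
          strip <- matrix(0L, k, w)
          strip[seq_len(n_green)] <- 1L   # contiguous column-major fill
          green[blk$rows, cols] <- strip
        }
        col0 <- col0 + w
      }
    }
  })
  list(
    landuse = land_use_map(labels, cats, partition$cell_size,
                           partition$origin),
    green = binary_raster(green, partition$cell_size, partition$origin)
  )
}

normalize_shares <- function(class_shares, n, cats) {
  if (is.matrix(class_shares) || is.data.frame(class_shares)) {
    m <- as.matrix(class_shares)
    if (nrow(m) != n) stopf("class share matrix needs one row per tract")
  } else {
    m <- matrix(as.numeric(class_shares), nrow = n,
                ncol = length(class_shares), byrow = TRUE,
                dimnames = list(NULL, names(class_shares)))
  }
  if (is.null(colnames(m))) stopf("class shares must be named")
  bad <- setdiff(colnames(m), cats)
  if (length(bad)) stopf("unknown land-use categories: %s",
                         paste(bad, collapse = ", "))
  out <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  out[, colnames(m)] <- m
  if (any(out < 0 | out > 1)) stopf("class shares must lie in [0, 1]")
  if (any(abs(rowSums(out) - 1) > 1e-8)) stopf("class shares must sum to 1")
  out
}

#' Simulate correlated tract-level covariates
#'
#' Draws the socio-demographic and air-quality covariate block (poverty
#' rate, educational attainment, Black population share, child and senior
#' population shares, PM2.5, ozone) from a Gaussian copula-free multivariate
#' normal with configurable correlation, then maps each margin to its
#' documented location/scale and clips percentages to `[0, 100]` and
#' concentrations to be non-negative. Sample correlations converge to the
#' requested matrix as `n` grows (clipping aside).
#'
#' @param n_tracts number of tracts; must be >= 1.
#' @param correlation correlation matrix over the seven covariates (order of
#'   [covariate_names()]); defaults to [default_covariate_correlation()].
#'   Must be symmetric positive semi-definite with unit diagonal.
#' @param means,sds per-covariate location and scale; defaults mimic the
#'   dispersion printed for the Los Angeles County study region.
#' @param seed integer RNG seed.
#' @return data.frame with columns [covariate_names()].
#' @export
simulate_covariates <- function(n_tracts,
                                correlation = default_covariate_correlation(),
                                means = NULL, sds = NULL, seed = 1L) {
  n_tracts <- check_count(n_tracts, "n_tracts")
  vars <- covariate_names()
  p <- length(vars)
  mu <- c(PovRt = 18.82, EduAtn = 40.0, EtnGrp = 8.17, ChldPop = 12.80,
          SnrPop = 11.02, PM25 = 11.53, Ozone = 0.05)
  sg <- c(PovRt = 13.01, EduAtn = 21.90, EtnGrp = 13.08, ChldPop = 4.26,
          SnrPop = 6.05, PM25 = 1.28, Ozone = 0.01)
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sg[names(sds)] <- sds
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(dim(correlation), c(p, p))) ||
      max(abs(correlation - t(correlation))) > 1e-10 ||
      any(abs(diag(correlation) - 1) > 1e-10)) {
    stopf("correlation must be a symmetric %dx%d matrix with unit diagonal", p, p)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("correlation matrix is not positive semi-definite")
  z <- with_seed(seed,
                 MASS::mvrnorm(n_tracts, mu = rep(0, p), Sigma = correlation))
  z <- matrix(z, nrow = n_tracts, ncol = p)
  out <- as.data.frame(sweep(sweep(z, 2, sg[vars], `*`), 2, mu[vars], `+`))
  names(out) <- vars
  pct <- c("PovRt", "EduAtn", "EtnGrp", "ChldPop", "SnrPop")
  out[pct] <- lapply(out[pct], function(x) pmin(pmax(x, 0), 100))
  out[c("PM25", "Ozone")] <- lapply(out[c("PM25", "Ozone")],
                                    function(x) pmax(x, 0))
  out
}

#' Covariate column order used throughout the package
#' @return character vector of the seven covariate names.
#' @export
covariate_names <- function() {
  c("PovRt", "EduAtn", "EtnGrp", "ChldPop", "SnrPop", "PM25", "Ozone")
}

#' Default covariate correlation structure
#'
#' The source data's covariance among covariates is not published, so the
#' default encodes a mild, sociologically plausible structure (poverty with
#' lower attainment and more children; the two pollution measures positively
#' related). Any positive semi-definite matrix may be supplied instead.
#'
#' @return 7x7 correlation matrix in [covariate_names()] order.
#' @export
default_covariate_correlation <- function() {
  vars <- covariate_names()
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("PovRt", "EduAtn", 0.50)
  set_r("PovRt", "EtnGrp", 0.25)
  set_r("PovRt", "ChldPop", 0.30)
  set_r("EduAtn", "ChldPop", 0.30)
  set_r("ChldPop", "SnrPop", -0.25)
  set_r("PM25", "Ozone", 0.40)
  set_r("PovRt", "PM25", 0.20)
  R
}

#' Record the ground truth of a synthetic outcome process
#'
#' @param process `"lag"` (spatially lagged outcome), `"error"` (spatially
#'   autocorrelated errors) or `"none"` (independent errors).
#' @param rho,lambda spatial parameter for the lag/error process; exactly
#'   the one matching `process` must be supplied.
#' @param beta coefficient vector including the intercept.
#' @param sigma innovation standard deviation; must be >= 0.
#' @param seed integer RNG seed used when drawing the outcome.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(process = c("lag", "error", "none"),
                            rho = NULL, lambda = NULL, beta, sigma = 1,
                            seed = 1L) {
  process <- match.arg(process)
  if (process == "lag" && is.null(rho)) stopf("process 'lag' needs rho")
  if (process == "error" && is.null(lambda)) stopf("process 'error' needs lambda")
  if (!is.numeric(sigma) || sigma < 0) stopf("sigma must be >= 0")
  structure(
    list(process = process, rho = rho, lambda = lambda,
         beta = as.numeric(beta), beta_names = names(beta),
         sigma = as.numeric(sigma), seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  par <- switch(x$process,
                lag = sprintf("rho = %g", x$rho),
                error = sprintf("lambda = %g", x$lambda),
                none = "no spatial parameter")
  cat(sprintf("<synthetic_truth> process = %s, %s, sigma = %g, seed = %d\n",
              x$process, par, x$sigma, x$seed))
  invisible(x)
}

#' Draw an outcome vector from a known spatial process
#'
#' Implements the three data-generating processes the estimators are tested
#' against, given a design matrix and a row-standardized weight matrix:
#' \describe{
#'   \item{lag}{`y = (I - rho W)^-1 (X beta + eps)`, `eps ~ N(0, sigma^2 I)`}
#'   \item{error}{`y = X beta + (I - lambda W)^-1 u`, `u ~ N(0, sigma^2 I)`}
#'   \item{none}{`y = X beta + eps`}
#' }
#' The spatial parameter must lie strictly inside the admissible interval
#' `(1/min(omega), 1/max(omega))` of W's eigenvalue spectrum.
#'
#' @param X design matrix including the intercept column; one row per tract.
#' @param W a row-standardized, island-free `spatial_weights` object.
#' @param truth a [synthetic_truth()] whose `beta` matches `ncol(X)`.
#' @return numeric outcome vector of length `nrow(X)`.
#' @export
simulate_outcome <- function(X, W, truth) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(W, "spatial_weights"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != W$n) stopf("X and W disagree on the number of tracts")
  if (ncol(X) != length(truth$beta)) {
    stopf("beta has length %d but X has %d columns",
          length(truth$beta), ncol(X))
  }
  xb <- drop(X %*% truth$beta)
  if (truth$process == "none") {
    return(with_seed(truth$seed, unname(xb + stats::rnorm(n, 0, truth$sigma))))
  }
  par <- if (truth$process == "lag") truth$rho else truth$lambda
  ev <- eigenvalue_bounds(W)
  if (par <= 1 / ev$min || par >= 1 / ev$max) {
    stopf("spatial parameter %g outside the admissible interval (%g, %g)",
          par, 1 / ev$min, 1 / ev$max)
  }
  A <- diag(n) - par * weights_matrix(W)
  with_seed(truth$seed, {
    innov <- stats::rnorm(n, 0, truth$sigma)
    if (truth$process == "lag") {
      unname(drop(solve(A, xb + innov)))
    } else {
      unname(xb + drop(solve(A, innov)))
    }
  })
}

#' Simulate a complete synthetic study landscape
#'
#' Bundles the generator stages into one seeded call: a regular tract
#' partition; per-tract canopy cover and patch intensity drawn from
#' documented distributions (Beta-distributed cover, log-uniform seed
#' intensity) so the tree metrics vary across tracts; per-tract land-use
#' composition drawn from a Dirichlet around a base mix; greenspace by
#' class; and the covariate table. The outcome is *not* drawn here — the
#' pipeline first filters tracts and builds W on the retained set, then
#' calls [simulate_outcome()] so that the recorded truth refers to the
#' estimation weights.
#'
#' @param n_rows,n_cols,tract_cells,cell_size partition geometry.
#' @param cover_mean,cover_sd mean/sd of per-tract canopy cover (Beta law).
#' @param patch_intensity_range range of per-tract seed intensity (seeds per
#'   unit area), sampled log-uniformly.
#' @param patch_growth frontier fraction per growth step.
#' @param class_base_shares base land-use mix (named, sums to 1).
#' @param class_concentration Dirichlet concentration around the base mix;
#'   larger is more homogeneous.
#' @param green_share_by_class per-class green fractions.
#' @param correlation covariate correlation matrix.
#' @param n_no_residential number of tracts forced to a no-residential
#'   composition (parks/open space only), emulating uninhabited tracts.
#' @param seed master integer seed; all stage seeds derive from it.
#' @return list with `partition`, `canopy`, `green`, `landuse`,
#'   `covariates`, `residential_share`, and the per-tract generator draws
#'   (`target_cover`, `patch_intensity`).
#' @export
simulate_dataset <- function(n_rows = 15, n_cols = 15, tract_cells = 20,
                             cell_size = 1,
                             cover_mean = 0.11, cover_sd = 0.06,
                             patch_intensity_range = c(0.01, 0.05),
                             patch_growth = 0.5,
                             class_base_shares = default_class_shares(),
                             class_concentration = 50,
                             green_share_by_class = default_green_shares(),
                             correlation = default_covariate_correlation(),
                             n_no_residential = 0,
                             seed = 1L) {
  sp <- simulate_partition(n_rows, n_cols, tract_cells, cell_size)
  partition <- sp$partition
  n <- partition$n
  draws <- with_seed(derive_seed(seed, 1L), {
    v <- max(cover_sd^2, 1e-8)
    m <- min(max(cover_mean, 1e-3), 0.9)
    common <- m * (1 - m) / v - 1
    common <- max(common, 0.1)
    cover <- stats::rbeta(n, m * common, (1 - m) * common)
    cover <- pmin(cover, 0.95 - 1e-9)
    lo <- log10(patch_intensity_range[1])
    hi <- log10(patch_intensity_range[2])
    intensity <- 10^stats::runif(n, lo, hi)
    shares <- t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(class_base_shares),
                         shape = class_concentration * class_base_shares)
      g / sum(g)
    }, numeric(length(class_base_shares))))
    colnames(shares) <- names(class_base_shares)
    nores <- if (n_no_residential > 0) {
      sample.int(n, min(n_no_residential, n))
    } else integer(0)
    list(cover = cover, intensity = intensity, shares = shares,
         nores = nores)
  })
  if (length(draws$nores)) {
    draws$shares[draws$nores, ] <- 0
    draws$shares[draws$nores, "park_recreation"] <- 0.6
    draws$shares[draws$nores, "other"] <- 0.4
    draws$cover[draws$nores] <- pmax(draws$cover[draws$nores], 0.2)
  }
  canopy <- simulate_canopy(partition, draws$cover, draws$intensity,
                            patch_growth, seed = derive_seed(seed, 2L))
  lg <- simulate_landuse_and_green(partition, draws$shares,
                                   green_share_by_class,
                                   seed = derive_seed(seed, 3L))
  covariates <- simulate_covariates(n, correlation,
                                    seed = derive_seed(seed, 4L))
  covariates <- cbind(tract_id = partition$tract_id, covariates,
                      stringsAsFactors = FALSE)
  list(
    partition = partition, canopy = canopy, green = lg$green,
    landuse = lg$landuse, covariates = covariates,
    residential_share = landuse_share(lg$landuse, partition, "residential"),
    target_cover = draws$cover, patch_intensity = draws$intensity
  )
}

#' Default synthetic land-use mix
#' @return named shares over [landuse_categories()] summing to 1.
#' @export
default_class_shares <- function() {
  c(residential = 0.50, commercial = 0.08, office = 0.04, industrial = 0.06,
    golf = 0.04, education = 0.05, cemetery = 0.02, agriculture = 0.03,
    park_recreation = 0.08, other = 0.10)
}

#' Default per-class green shares
#' @return named fractions in `[0, 1]`.
#' @export
default_green_shares <- function() {
  c(residential = 0.25, commercial = 0.08, office = 0.08, industrial = 0.03,
    golf = 0.85, education = 0.30, cemetery = 0.60, agriculture = 0.70,
    park_recreation = 0.70, other = 0)
}
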