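test_that("canopy simulator hits target cover and is seed-deterministic", {
  p <- simulate_partition(3, 3, 20)$partition
  covers <- c(0, 0.05, 0.1, 0.2, 0.4, 0.1, 0.3, 0.15, 0.25)
  r1 <- simulate_canopy(p, covers, patch_intensity = 0.01, seed = 11)
  r2 <- simulate_canopy(p, covers, patch_intensity = 0.01, seed = 11)
  expect_identical(r1$grid, r2$grid)
  r3 <- simulate_canopy(p, covers, patch_intensity = 0.01, seed = 12)
  expect_false(identical(r1$grid, r3$grid))
  # realized cover is exact up to cell rounding (half a cell per tract)
  for (t in seq_len(p$n)) {
    realized <- tree_cover_fraction(r1, p, t)
    expect_equal(realized, round(covers[t] * 400) / 400, tolerance = 1e-12)
  }
  expect_true(all(simulate_canopy(p, 0, 0.01, seed = 1)$grid == 0L))
  expect_error(simulate_canopy(p, 1.0, 0.01), "\\[0, 1\\)")
})

test_that("fewer seeds at equal cover produce larger patches", {
  p <- simulate_partition(1, 1, 50)$partition
  area <- unname(tract_areas(p))
  med_of <- function(intensity, seed) {
    r <- simulate_canopy(p, 0.2, intensity, seed = seed)
    median_patch_size(extract_patches(r, p, 1))
  }
  set.seed(31)
  seeds <- sample.int(1e6, 30)
  few <- vapply(seeds, function(s) med_of(5 / area, s), numeric(1))
  many <- vapply(seeds, function(s) med_of(500 / area, s + 1), numeric(1))
  expect_gt(mean(few), mean(many))
})

test_that("land-use/greenspace simulator round-trips configured shares", {
  p <- simulate_partition(2, 3, 30)$partition
  shares <- c(residential = 0.5, golf = 0.2, park_recreation = 0.2,
              other = 0.1)
  gs <- c(residential = 0.3, golf = 0.8, park_recreation = 0.6)
  lg <- simulate_landuse_and_green(p, shares, gs, seed = 5)
  lg2 <- simulate_landuse_and_green(p, shares, gs, seed = 5)
  expect_identical(lg$landuse$labels, lg2$landuse$labels)
  expect_identical(lg$green$grid, lg2$green$grid)
  for (t in seq_len(p$n)) {
    fr <- classify_greenspace(lg$green, lg$landuse, p, t)
    # expected per-tenure fractions; discretization tolerance of one cell
    # row per class block boundary
    tol <- 2 * 30 / 900
    expect_equal(unname(fr["PrvtGrn"]), 0.5 * 0.3, tolerance = tol)
    expect_equal(unname(fr["SemiGrn"]), 0.2 * 0.8, tolerance = tol)
    expect_equal(unname(fr["GrnRec"]), 0.2 * 0.6, tolerance = tol)
    expect_equal(unname(fr["UnclGrn"]), 0)
  }
  # all-zero green shares give an all-zero greenspace raster
  lg0 <- simulate_landuse_and_green(p, shares, c(residential = 0), seed = 5)
  expect_true(all(lg0$green$grid == 0L))
  expect_error(simulate_landuse_and_green(p, c(residential = 0.5), gs),
               "sum to 1")
})

test_that("single-class tract attributes all green to that tenure", {
  p <- simulate_partition(1, 1, 20)$partition
  lg <- simulate_landuse_and_green(p, c(residential = 1),
                                   c(residential = 0.3), seed = 2)
  fr <- classify_greenspace(lg$green, lg$landuse, p, 1)
  expect_equal(unname(fr["PrvtGrn"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(fr["SemiGrn"] + fr["GrnRec"] + fr["UnclGrn"]), 0)
})

test_that("covariate simulator respects the correlation specification", {
  ident <- diag(7)
  x <- simulate_covariates(10000, correlation = ident, seed = 99)
  r <- cor(as.matrix(x))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  x2 <- simulate_covariates(10000, correlation = ident, seed = 99)
  expect_identical(x, x2)
  pct <- x[c("PovRt", "EduAtn", "EtnGrp", "ChldPop", "SnrPop")]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_error(simulate_covariates(0), "positive integer")
  bad <- diag(7); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(simulate_covariates(10, correlation = bad),
               "positive semi-definite")
})

test_that("outcome generator honours the stated processes", {
  W <- lattice_weights(5, 5)
  set.seed(3)
  X <- cbind(Constant = 1, x1 = rnorm(25))
  beta <- c(2, 1.5)
  # sigma = 0, no spatial process: y = X beta exactly
  tr0 <- synthetic_truth("none", beta = beta, sigma = 0, seed = 1)
  expect_equal(simulate_outcome(X, W, tr0), drop(X %*% beta))
  # rho = 0 lag process equals the independent process draw-for-draw
  trl <- synthetic_truth("lag", rho = 0, beta = beta, sigma = 2, seed = 7)
  trn <- synthetic_truth("none", beta = beta, sigma = 2, seed = 7)
  expect_equal(simulate_outcome(X, W, trl), simulate_outcome(X, W, trn),
               tolerance = 1e-10)
  # inadmissible spatial parameter errors
  trb <- synthetic_truth("lag", rho = 1.2, beta = beta, sigma = 1, seed = 1)
  expect_error(simulate_outcome(X, W, trb), "admissible")
})

test_that("lag DGP analytic mean matches the empirical mean", {
  W <- lattice_weights(4, 4)
  Wm <- weights_matrix(W)
  set.seed(8)
  X <- cbind(Constant = 1, x1 = rnorm(16))
  beta <- c(1, 2)
  rho <- 0.6
  mu <- drop(solve(diag(16) - rho * Wm, X %*% beta))
  ys <- vapply(1:400, function(b) {
    tr <- synthetic_truth("lag", rho = rho, beta = beta, sigma = 1, seed = b)
    simulate_outcome(X, W, tr)
  }, numeric(16))
  emp <- rowMeans(ys)
  mc_se <- apply(ys, 1, sd) / sqrt(400)
  expect_true(all(abs(emp - mu) < 4 * mc_se + 1e-8))
})

test_that("simulate_dataset is deterministic and spans the study layers", {
  ds1 <- simulate_dataset(n_rows = 4, n_cols = 4, tract_cells = 15,
                          n_no_residential = 3, seed = 21)
  ds2 <- simulate_dataset(n_rows = 4, n_cols = 4, tract_cells = 15,
                          n_no_residential = 3, seed = 21)
  expect_identical(ds1$canopy$grid, ds2$canopy$grid)
  expect_identical(ds1$covariates, ds2$covariates)
  expect_identical(ds1$landuse$labels, ds2$landuse$labels)
  expect_equal(sum(ds1$residential_share == 0), 3)
  expect_equal(nrow(ds1$covariates), 16)
})
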