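test_that("patch extraction follows the connectivity definition", {
  sp <- simulate_partition(1, 1, 6)
  g <- sp$raster$grid
  g[2, 2] <- 1L
  r <- binary_raster(g)
  patches <- extract_patches(r, sp$partition, 1)
  expect_length(patches, 1)
  expect_equal(patches[[1]]$area, 1)
  expect_equal(unname(patches[[1]]$centroid), c(1.5, 4.5))

  # two diagonally touching cells: split under 4-, joined under 8-connectivity
  g2 <- sp$raster$grid
  g2[3, 3] <- 1L
  g2[4, 4] <- 1L
  r2 <- binary_raster(g2)
  expect_length(extract_patches(r2, sp$partition, 1, connectivity = 4), 2)
  expect_length(extract_patches(r2, sp$partition, 1, connectivity = 8), 1)

  expect_length(extract_patches(binary_raster(sp$raster$grid),
                                sp$partition, 1), 0)
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(42)
  for (conn in c(4, 8)) {
    for (i in 1:25) {
      g <- rand_grid(50, 50, p = runif(1, 0.2, 0.6))
      lab <- label_components(g, conn)
      oracle <- flood_fill_label(g, conn)
      expect_equal(max(lab), max(oracle))
      # identical partitions of the foreground, label names aside
      expect_true(all((lab > 0) == (oracle > 0)))
      for (j in seq_len(max(lab))) {
        expect_equal(length(unique(oracle[lab == j])), 1L)
      }
    }
  }
})

test_that("patch areas sum to canopy area within a tract", {
  set.seed(9)
  sp <- simulate_partition(2, 2, 25)
  r <- binary_raster(rand_grid(50, 50, 0.35), cell_size = 1)
  for (t in 1:4) {
    patches <- extract_patches(r, sp$partition, t)
    expect_equal(sum(vapply(patches, function(p) p$area, numeric(1))),
                 tree_cover_fraction(r, sp$partition, t) *
                   unname(tract_areas(sp$partition)[t]))
  }
})

test_that("tree cover fraction matches closed forms", {
  sp <- simulate_partition(1, 1, 8)
  zero <- binary_raster(sp$raster$grid)
  ones <- binary_raster(matrix(1L, 8, 8))
  checker <- binary_raster(outer(1:8, 1:8, function(i, j) (i + j) %% 2L))
  expect_equal(tree_cover_fraction(zero, sp$partition, 1), 0)
  expect_equal(tree_cover_fraction(ones, sp$partition, 1), 1)
  expect_equal(tree_cover_fraction(checker, sp$partition, 1), 0.5)
})

test_that("median patch size uses the mid-mean convention", {
  expect_equal(median_patch_size(c(4)), 4)
  expect_equal(median_patch_size(c(1, 9, 100)), 9)
  expect_equal(median_patch_size(c(1, 3, 5, 100)), 4)
  out <- median_patch_size(list())
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "no_patches")
})

test_that("nearest-neighbor index matches its closed forms", {
  # coincident points
  expect_equal(nearest_neighbor_index(rbind(c(1, 1), c(1, 1), c(1, 1)), 10), 0)
  # two points at distance d in area A
  d <- 3.7; A <- 42
  pts <- rbind(c(0, 0), c(d, 0))
  expect_equal(nearest_neighbor_index(pts, A), d / (0.5 * sqrt(A / 2)),
               tolerance = 1e-12)
  # fewer than two points is flagged undefined
  out <- nearest_neighbor_index(rbind(c(1, 2)), 5)
  expect_true(is.na(out))
  expect_error(nearest_neighbor_index(pts, 0), "positive")
})

test_that("NNI is invariant under rigid motion and uniform rescaling", {
  set.seed(12)
  pts <- cbind(runif(40), runif(40))
  base <- nearest_neighbor_index(pts, 1)
  theta <- 0.7
  Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- sweep(pts %*% Rot, 2, c(5, -3), `+`)
  expect_equal(nearest_neighbor_index(moved, 1), base, tolerance = 1e-12)
  expect_equal(nearest_neighbor_index(pts * 10, 100), base, tolerance = 1e-12)
})

test_that("greenspace classification handles edge cases", {
  fx <- hand_fixture()
  none <- binary_raster(matrix(0L, 10, 10))
  expect_equal(unname(classify_greenspace(none, fx$landuse, fx$partition, 1)),
               c(0, 0, 0, 0))
  # green on an unmapped ('other') category is reported as unclassified
  labs <- matrix(match("other", landuse_categories()), 10, 10)
  lu <- land_use_map(labs)
  fr <- classify_greenspace(fx$green, lu, fx$partition, 1)
  expect_equal(unname(fr["UnclGrn"]), 0.09)
  expect_equal(unname(fr["PrvtGrn"] + fr["SemiGrn"] + fr["GrnRec"]), 0)
})

test_that("hand-worked fixture reproduces all six metrics exactly", {
  fx <- hand_fixture()
  tab <- compute_tract_metrics(fx$canopy, fx$green, fx$landuse, fx$partition)
  expect_equal(nrow(tab), 1)
  for (v in names(fx$expected)) {
    expect_equal(tab[[v]], fx$expected[[v]], tolerance = 1e-12, label = v)
  }
  expect_equal(tab$flags, "")
  expect_equal(tab$n_patches, 3L)
})

test_that("metrics table flags undefined values and survives relabeling", {
  sp <- simulate_partition(2, 2, 10)
  empty <- binary_raster(sp$raster$grid)
  lg <- simulate_landuse_and_green(sp$partition, c(residential = 1),
                                   c(residential = 0.2), seed = 1)
  tab <- compute_tract_metrics(empty, lg$green, lg$landuse, sp$partition)
  expect_true(all(tab$TreeCov == 0))
  expect_true(all(is.na(tab$TreeClus)))
  expect_true(all(grepl("undefined TreeClus", tab$flags)))
  expect_true(all(grepl("undefined TreeAgr", tab$flags)))

  # permutation invariance of tract ids
  set.seed(2)
  canopy <- simulate_canopy(sp$partition, 0.2, 0.02, seed = 3)
  t1 <- compute_tract_metrics(canopy, lg$green, lg$landuse, sp$partition)
  p2 <- sp$partition
  p2$tract_id <- rev(p2$tract_id)
  t2 <- compute_tract_metrics(canopy, lg$green, lg$landuse, p2)
  expect_equal(t2[, -1], t1[, -1])
})

test_that("adding canopy cells never decreases cover", {
  set.seed(5)
  sp <- simulate_partition(1, 1, 12)
  g <- rand_grid(12, 12, 0.3)
  before <- tree_cover_fraction(binary_raster(g), sp$partition, 1)
  g2 <- g
  g2[sample(which(g == 0L), 5)] <- 1L
  after <- tree_cover_fraction(binary_raster(g2), sp$partition, 1)
  expect_gte(after, before)
})
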