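test_that("per-class cutoffs label cells as the survey maps do", {
  # one cell: rock p=0.30 (cutoff 0.25), mud p=0.05 (cutoff 0.1)
  ct <- data.frame(class = c("rock", "mud"), hard = c(TRUE, FALSE),
                   cutoff = c(0.25, 0.1), softness = c(0.25, 0.8),
                   depth_pref = NA_real_)
  s <- substratum_raster(list(rock = matrix(0.30, 1, 1),
                              mud = matrix(0.05, 1, 1)), ct)
  pm <- classify_patches(s)
  expect_true(pm$labels[1, 1, "rock"])
  expect_false(pm$labels[1, 1, "mud"])
  expect_equal(pm$classes[pm$dominant[1, 1]], "rock")

  # mud 0.4, sand 0.2, both cutoff 0.1: both labelled, mud dominant
  ct2 <- data.frame(class = c("mud", "sand"), hard = FALSE, cutoff = 0.1,
                    softness = 0.8, depth_pref = NA_real_)
  s2 <- substratum_raster(list(mud = matrix(0.4, 1, 1),
                               sand = matrix(0.2, 1, 1)), ct2)
  pm2 <- classify_patches(s2)
  expect_true(all(pm2$labels[1, 1, ]))
  expect_equal(pm2$classes[pm2$dominant[1, 1]], "mud")

  # all probabilities below cutoff: empty label set, no dominant class
  s3 <- substratum_raster(list(mud = matrix(0.05, 1, 1),
                               sand = matrix(0.05, 1, 1)), ct2)
  pm3 <- classify_patches(s3)
  expect_false(any(pm3$labels))
  expect_true(is.na(pm3$dominant[1, 1]))

  expect_error(classify_patches(s2, cutoffs = c(mud = 0.1)), "sand")
})

test_that("raising a cutoff never adds cells to a class", {
  s <- random_subst(15, 20, K = 3, seed = 4)
  lo <- classify_patches(s, cutoffs = c(c1 = 0.2, c2 = 0.3, c3 = 0.4))
  hi <- classify_patches(s, cutoffs = c(c1 = 0.5, c2 = 0.3, c3 = 0.4))
  expect_true(all(lo$labels[, , "c1"] | !hi$labels[, , "c1"]))
  expect_true(sum(hi$labels[, , "c1"]) <= sum(lo$labels[, , "c1"]))
})

test_that("boundary mask matches hand constructions and a brute-force scan", {
  # uniform single class: no boundary anywhere
  uni <- subst_from_dominant(matrix(1L, 6, 8), classes = c("a", "b"))
  expect_false(any(classify_patches(uni)$boundary))
  # two half-planes split between columns 4|5: the two facing columns
  dom <- matrix(1L, 6, 8); dom[, 5:8] <- 2L
  pm <- classify_patches(subst_from_dominant(dom))
  expect_true(all(pm$boundary[, 4:5]))
  expect_false(any(pm$boundary[, c(1:3, 6:8)]))
  # random fuzzy rasters against the exhaustive neighbour scan
  for (seed in 1:6) {
    s <- random_subst(12, 14, K = 3, seed = seed, mask_frac = 0.1)
    pmr <- classify_patches(s)
    expect_identical(pmr$boundary, oracle_boundary_mask(pmr))
  }
})

test_that("boundary distance is exact against the exhaustive scan", {
  dom <- matrix(1L, 10, 12); dom[, 7:12] <- 2L
  pm <- classify_patches(subst_from_dominant(dom))  # boundary at cols 6,7
  # a deployment on a boundary cell
  expect_equal(distance_to_boundary(pm, 6 * 25 - 12.5, 112.5), 0)
  # 4 cells perpendicular from the facing column (col 2 centre -> col 6 centre)
  expect_equal(distance_to_boundary(pm, 25 * 2 - 12.5, 112.5), 100)
  for (seed in 1:5) {
    s <- random_subst(11, 13, K = 3, seed = 10 + seed)
    pmr <- classify_patches(s)
    x <- runif(3, 0, 13 * 25); y <- runif(3, 0, 11 * 25)
    got <- distance_to_boundary(pmr, x, y)
    want <- vapply(1:3, function(i) {
      oracle_min_dist(pmr$boundary, pmr, x[i], y[i])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(
    distance_to_boundary(classify_patches(uni <- subst_from_dominant(
      matrix(1L, 4, 4), classes = c("a", "b"))), 10, 10),
    "no patch boundary"
  )
})

test_that("surrounding patch diversity matches closed forms and hand counts", {
  # homogeneous circle: H = 0
  pm1 <- classify_patches(subst_from_dominant(matrix(1L, 9, 9),
                                              classes = c("a", "b")))
  ctr <- c(4.5 * 25, 4.5 * 25)
  expect_equal(shannon_diversity(pm1, ctr[1], ctr[2], 100), 0)
  # two classes at exactly equal proportions: H = ln 2
  dom2 <- matrix(1L, 10, 10); dom2[, 6:10] <- 2L
  pm2 <- classify_patches(subst_from_dominant(dom2))
  expect_equal(shannon_diversity(pm2, 5 * 25, 5 * 25, 1000), log(2),
               tolerance = 1e-12)
  # four equal quadrants: H = ln 4
  dom4 <- matrix(1L, 10, 10)
  dom4[1:5, 6:10] <- 2L; dom4[6:10, 1:5] <- 3L; dom4[6:10, 6:10] <- 4L
  pm4 <- classify_patches(subst_from_dominant(dom4))
  expect_equal(shannon_diversity(pm4, 5 * 25, 5 * 25, 1000), log(4),
               tolerance = 1e-12)
  # arbitrary circles equal the brute-force hand count
  for (seed in 1:5) {
    s <- random_subst(12, 12, K = 4, seed = 20 + seed, mask_frac = 0.15)
    pmr <- classify_patches(s)
    x <- runif(2, 50, 250); y <- runif(2, 50, 250)
    for (i in 1:2) {
      want <- oracle_shannon(pmr, x[i], y[i], 120)
      if (is.na(want)) next
      expect_equal(shannon_diversity(pmr, x[i], y[i], 120), want,
                   tolerance = 1e-12)
    }
  }
  # H bounded by ln(number of classes)
  expect_lte(shannon_diversity(pm4, 5 * 25, 5 * 25, 80), log(4))
  expect_error(shannon_diversity(pm1, -1e6, -1e6, 30), "no eligible cells")
})

test_that("H cannot rise when the circle shrinks onto a homogeneous core", {
  # class-1 core large enough that it holds the majority at every radius
  # tried (entropy then falls monotonically as the circle shrinks onto it)
  dom <- matrix(2L, 20, 20); dom[7:13, 7:13] <- 1L
  pm <- classify_patches(subst_from_dominant(dom))
  ctr <- (20 - 10 + 0.5) * 25  # centre of the core cell (10, 10)
  hs <- vapply(c(130, 100, 60), function(r) {
    shannon_diversity(pm, 9.5 * 25, ctr, r)
  }, numeric(1))
  expect_true(all(diff(hs) <= 1e-12))
  expect_equal(hs[3], 0)
})

test_that("slope and aspect follow Horn differences on the depth surface", {
  # planar ramp: depth increases by 0.1 per metre eastward
  nx <- 12; ny <- 10; cs <- 25
  xs <- (seq_len(nx) - 0.5) * cs
  ramp <- matrix(rep(xs * 0.1, each = ny), ny, nx)
  sa <- slope_aspect(sea_raster(ramp, cellsize = cs))
  interior <- sa$slope$values[2:(ny - 1), 2:(nx - 1)]
  expect_equal(interior, matrix(atan(0.1) * 180 / pi, ny - 2, nx - 2),
               tolerance = 1e-9)
  # downslope (deepening) direction is east = 90 degrees
  expect_equal(sa$aspect$values[5, 5], 90, tolerance = 1e-9)
  # flat surface: slope 0, aspect undefined
  fl <- slope_aspect(sea_raster(matrix(7, 5, 5), cellsize = cs))
  expect_equal(fl$slope$values[3, 3], 0)
  expect_true(is.na(fl$aspect$values[3, 3]))
  # random smooth surface: Horn gradient close to central differences
  set.seed(3)
  z <- matrix(rnorm(30 * 30), 30, 30)
  z <- gauss_smooth_for_tests(z, 3)
  sa2 <- slope_aspect(sea_raster(z, cellsize = cs))
  r <- 15; c <- 15
  dzdx <- (z[r, c + 1] - z[r, c - 1]) / (2 * cs)
  dzdy <- (z[r - 1, c] - z[r + 1, c]) / (2 * cs)
  want <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  expect_equal(sa2$slope$values[r, c], want, tolerance = 0.3)
})

test_that("shore distance matches the exhaustive scan and grows seaward", {
  v <- matrix(50, 10, 12)
  v[1:2, ] <- NA  # land strip along the north edge
  b <- sea_raster(v, cellsize = 25)
  # deployment in the first sea row, adjacent to shoreline cells
  expect_lte(distance_to_shore(b, 6 * 25 - 12.5, (10 - 3 + 0.5) * 25), 25)
  # exhaustive-scan equality at random points
  set.seed(8)
  x <- runif(5, 0, 300); y <- runif(5, 0, 175)
  shoreline <- matrix(FALSE, 10, 12); shoreline[2, ] <- TRUE
  want <- vapply(1:5, function(i) {
    oracle_min_dist(shoreline, b, x[i], y[i])
  }, numeric(1))
  expect_equal(distance_to_shore(b, x, y), want, tolerance = 1e-12)
  # moving seaward along the normal increases the distance
  ys <- (10 - c(3, 5, 7, 9) + 0.5) * 25
  d <- distance_to_shore(b, rep(150, 4), ys)
  expect_true(all(diff(d) > 0))
  expect_error(distance_to_shore(sea_raster(matrix(1, 4, 4)), 10, 10),
               "no land")
})

test_that("depth strata follow the printed design bands", {
  expect_equal(assign_depth_stratum(9.9), 1L)
  expect_equal(assign_depth_stratum(10.0), 2L)
  expect_equal(assign_depth_stratum(c(0, 18.9, 19, 29.9, 30, 37.9, 38,
                                      49.9, 50, 116)),
               c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L))
  expect_error(assign_depth_stratum(116.1), "deepest")
  expect_error(assign_depth_stratum(-1), "negative")
})
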