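test_that("windowed H agrees with the point-wise definition at cell centres", {
  s <- random_subst(14, 16, K = 3, seed = 31, mask_frac = 0.1)
  pm <- classify_patches(s)
  H <- window_shannon(pm, 90)
  cc_x <- pm$xll + (seq_len(pm$ncol) - 0.5) * pm$cellsize
  cc_y <- pm$yll + (pm$nrow - seq_len(pm$nrow) + 0.5) * pm$cellsize
  set.seed(1)
  for (i in 1:12) {
    r <- sample(pm$nrow, 1); c <- sample(pm$ncol, 1)
    want <- oracle_shannon(pm, cc_x[c], cc_y[r], 90)
    if (is.na(want)) {
      expect_true(is.na(H[r, c]))
    } else {
      expect_equal(H[r, c], want, tolerance = 1e-12)
    }
  }
})

test_that("percent area present follows the occurrence rule", {
  r10 <- sea_raster(matrix(10, 5, 5))
  expect_equal(as.numeric(percent_area_present(r10)), 100)
  r0 <- sea_raster(matrix(0.01, 5, 5))
  expect_equal(as.numeric(percent_area_present(r0)), 0)
  # half the cells above the threshold
  v <- matrix(0.01, 4, 5); v[1:2, ] <- 10
  expect_equal(as.numeric(percent_area_present(sea_raster(v))), 50)
  # monotone under intensity inflation
  set.seed(2)
  v2 <- matrix(rexp(30), 5, 6)
  p1 <- as.numeric(percent_area_present(sea_raster(v2)))
  p2 <- as.numeric(percent_area_present(sea_raster(2 * v2)))
  expect_gte(p2, p1)
  expect_error(percent_area_present(sea_raster(matrix(NA_real_, 2, 2))),
               "empty")
  expect_match(attr(percent_area_present(r10), "rule"), "exp")
})

test_that("gridded prediction reduces to exp(alpha) for a null model", {
  sc <- tiny_seascape()
  spec <- model_spec(terms = c("substratum", "depth"), n_factors = 0)
  d <- build_design_matrix(sc$feats, spec)
  set.seed(4)
  y <- matrix(rpois(nrow(sc$feats) * 2, 2), ncol = 2,
              dimnames = list(sc$feats$deployment_id, c("a", "b")))
  post <- sample_posterior(y, d, settings = quick_settings(iterations = 300,
                                                           burnin = 100))
  # zero out every draw: lambda-hat must be exactly 1 everywhere
  for (ch in seq_along(post$chains)) {
    post$chains[[ch]]$B[] <- 0
    post$chains[[ch]]$eps_site[] <- 0
    post$chains[[ch]]$eps_year[] <- 0
  }
  pred <- predict_grid(post, sc$pm, sc$bathy, site = "A", year = 2021,
                       max_draws = 10)
  vals <- pred$lambda$a$values
  expect_equal(unique(vals[!is.na(vals)]), 1)
  expect_s3_class(pred$lambda$b, "sea_raster")
})

test_that("prediction at a training deployment matches the draws", {
  sc <- tiny_seascape()
  spec <- model_spec(terms = c("depth", "boundary"), n_factors = 0)
  d <- build_design_matrix(sc$feats, spec)
  set.seed(8)
  y <- matrix(rpois(nrow(sc$feats), 3), ncol = 1,
              dimnames = list(sc$feats$deployment_id, "sp"))
  post <- sample_posterior(y, d, settings = quick_settings(
    chains = 2, iterations = 400, burnin = 150))
  i <- 5
  lam <- seajsdm:::predict_lambda(post, d$X[i, , drop = FALSE],
                                  site = sc$feats$site[i],
                                  year = sc$feats$year[i])
  # recompute the posterior-mean fitted intensity from raw draws
  want <- 0
  for (ch in seq_along(post$chains)) {
    for (dr in seq_len(post$nkeep)) {
      B <- matrix(post$chains[[ch]]$B[dr, , ], post$p, post$J)
      eS <- matrix(post$chains[[ch]]$eps_site[dr, , ], ncol = post$J)
      eY <- matrix(post$chains[[ch]]$eps_year[dr, , ], ncol = post$J)
      want <- want + exp(d$X[i, , drop = FALSE] %*% B +
                           eS[post$si[i], ] + eY[post$yi[i], ])
    }
  }
  want <- want / (2 * post$nkeep)
  expect_equal(as.numeric(lam), as.numeric(want), tolerance = 1e-10)
})

test_that("doubling a positive coefficient raises predictions where its covariate is positive", {
  n <- 20
  X <- cbind("(Intercept)" = rep(1, n), z = seq(-2, 2, length.out = n))
  B1 <- matrix(c(0.5, 0.4), 2, 1)
  B2 <- matrix(c(0.5, 0.8), 2, 1)
  p1 <- constant_posterior(B1, n)
  p2 <- constant_posterior(B2, n)
  l1 <- seajsdm:::predict_lambda(p1, X)
  l2 <- seajsdm:::predict_lambda(p2, X)
  pos <- X[, "z"] > 0
  expect_true(all(l2[pos, 1] > l1[pos, 1]))
})

test_that("response curves respect closed forms and observed ranges", {
  sc <- tiny_seascape()
  spec <- model_spec(terms = "depth", n_factors = 0)
  d <- build_design_matrix(sc$feats, spec)
  set.seed(10)
  y <- matrix(rpois(nrow(sc$feats), 2), ncol = 1,
              dimnames = list(sc$feats$deployment_id, "sp"))
  post <- sample_posterior(y, d, settings = quick_settings(iterations = 400,
                                                           burnin = 150))
  # all beta = 0: flat curve at exp(alpha)
  flat <- post
  for (ch in seq_along(flat$chains)) {
    flat$chains[[ch]]$B[, 2, ] <- 0
    flat$chains[[ch]]$eps_site[] <- 0
    flat$chains[[ch]]$eps_year[] <- 0
  }
  rc <- response_curve(flat, sc$feats, "depth", n_points = 7)
  expect_equal(diff(range(rc$sp_mean)), 0, tolerance = 1e-12)
  want <- mean(exp(posterior_draws(flat, "B")[, 1]))
  expect_equal(unique(round(rc$sp_mean, 10)), round(want, 10))
  # curve values equal exp(alpha + beta z) averaged over draws
  rc2 <- response_curve(post, sc$feats, "depth", n_points = 5)
  Bd <- posterior_draws(post, "B")
  eSd <- posterior_draws(post, "eps_site")
  eYd <- posterior_draws(post, "eps_year")
  z <- (rc2$value - post$constants$center$depth) / post$constants$scale$depth
  want2 <- vapply(z, function(zz) {
    mean(exp(Bd[, 1] + Bd[, 2] * zz))
  }, numeric(1))
  expect_equal(rc2$sp_mean, want2, tolerance = 1e-10)
  # endpoints stay inside the observed range; extrapolation is refused
  expect_gte(min(rc2$value), min(sc$feats$depth_m))
  expect_lte(max(rc2$value), max(sc$feats$depth_m))
  expect_error(response_curve(post, sc$feats, "depth",
                              to = max(sc$feats$depth_m) + 50),
               "extrapolate")
  expect_error(response_curve(post, sc$feats, "boundary"), "model")
})
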