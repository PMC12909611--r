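test_that("WAIC collapses correctly for a degenerate posterior", {
  # all draws identical: p_waic = 0, WAIC = -2 * total log likelihood
  n <- 6; J <- 2
  X <- cbind("(Intercept)" = rep(1, n))
  B <- matrix(log(c(2, 4)), 1, J)
  set.seed(7)
  y <- matrix(rpois(n * J, 3), n, J)
  post <- constant_posterior(B, n, nkeep = 3L)
  w <- waic(post, y, X)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  ll <- log_likelihood(y, eta = X %*% B)
  expect_equal(w$waic, -2 * ll, tolerance = 1e-10)
  expect_equal(w$lppd, ll, tolerance = 1e-10)
})

test_that("WAIC equals the hand computation on a 2-draw toy posterior", {
  # 2 deployments x 1 species, two distinct draws
  y <- matrix(c(1L, 3L), 2, 1)
  X <- cbind("(Intercept)" = c(1, 1), z = c(0, 1))
  B1 <- matrix(c(0.2, 0.5), 2, 1)
  B2 <- matrix(c(0.4, 0.1), 2, 1)
  post <- constant_posterior(B1, n = 2, nkeep = 2L)
  post$chains[[1]]$B[2, , ] <- B2
  w <- waic(post, y, X)
  lp <- function(B) dpois(y, exp(X %*% B), log = TRUE)
  lp1 <- lp(B1); lp2 <- lp(B2)
  lppd <- sum(log((exp(lp1) + exp(lp2)) / 2))
  p_waic <- sum(apply(cbind(as.vector(lp1), as.vector(lp2)), 1, var))
  expect_equal(w$lppd, lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-12)
  # single draw: the variance penalty is undefined
  post1 <- constant_posterior(B1, n = 2, nkeep = 1L)
  expect_error(waic(post1, y, X), "at least 2")
})

test_that("WAIC is invariant to deployment reordering", {
  set.seed(9)
  f <- fake_features(50)
  d <- build_design_matrix(f, model_spec(terms = "depth", n_factors = 0,
                                         random = character(0)))
  y <- matrix(rpois(100, 2), 50, 2, dimnames = list(f$deployment_id,
                                                    c("a", "b")))
  post <- sample_posterior(y, d, settings = quick_settings(iterations = 400,
                                                           burnin = 100))
  w1 <- waic(post, y, d$X)$waic
  perm <- sample(50)
  post$si <- post$si[perm]; post$yi <- post$yi[perm]
  w2 <- waic(post, y[perm, ], d$X[perm, , drop = FALSE])$waic
  expect_equal(w1, w2, tolerance = 1e-10)
})

test_that("VIF matches its closed form and flags exact collinearity", {
  # orthogonal columns: all VIF = 1
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(vif(X), c(a = 1, b = 1), tolerance = 1e-12)
  # exact correlation 0.9: VIF = 1/(1 - 0.81) = 5.263...
  u <- c(1, 1, -1, -1) / 2; v <- c(1, -1, 1, -1) / 2
  X2 <- cbind(a = u, b = 0.9 * u + sqrt(1 - 0.81) * v)
  expect_equal(unname(vif(X2)), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_equal(unname(round(vif(X2)[1], 3)), 5.263)
  # random design against a per-column regression oracle
  set.seed(13)
  Z <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  Z[, 3] <- Z[, 1] * 0.7 + rnorm(20, 0, 0.5)
  got <- vif(Z)
  want <- vapply(1:3, function(k) {
    1 / (1 - summary(stats::lm(Z[, k] ~ Z[, -k]))$r.squared)
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-9)
  # exact collinearity
  X3 <- cbind(a = u, b = 2 * u, c = v)
  expect_equal(unname(vif(X3)[1:2]), c(Inf, Inf))
  expect_error(vif(cbind(a = u)), "at least 2")
})

test_that("relative RMSE reproduces the survey's worked percentages", {
  expect_equal(rmse_relative(1.633, 0, 24), 6.8)
  expect_equal(rmse_relative(1.875, 0, 25), 7.5)
  expect_equal(rmse_relative(6.596, 0, 48), 13.7)
  expect_equal(rmse_relative(0, 0, 10), 0)
  expect_error(rmse_relative(1, 5, 5), "range")
})

test_that("variance partitioning honours closed-form splits", {
  n <- 40
  set.seed(3)
  # two orthonormal standardized columns, beta = (1, 1): 50/50
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(stats::residuals(stats::lm(rnorm(n) ~ z1)))[, 1]
  X <- cbind("(Intercept)" = 1, a = z1, b = z2)
  B <- matrix(c(0.5, 1, 1), 3, 1)
  rownames(B) <- colnames(X)
  design <- list(X = X, terms = c("(Intercept)", "a", "b"))
  class(design) <- "design_matrix"
  post <- constant_posterior(B, n)
  post$terms <- design$terms
  vp <- variance_partition(post, design)
  expect_equal(unname(vp[1, ]), c(50, 50), tolerance = 1e-9)
  expect_equal(sum(vp[1, ]), 100, tolerance = 1e-9)
  # single group takes 100%
  vp1 <- variance_partition(post, design,
                            groups = list(env = c("a", "b")))
  expect_equal(unname(vp1[1, "env"]), 100, tolerance = 1e-9)
  # 3:1 variance ratio -> 75/25
  B31 <- matrix(c(0, sqrt(3), 1), 3, 1); rownames(B31) <- colnames(X)
  post31 <- constant_posterior(B31, n)
  vp31 <- variance_partition(post31, design)
  expect_equal(unname(vp31[1, ]), c(75, 25), tolerance = 1e-9)
  expect_error(variance_partition(post, design,
                                  groups = list(g1 = "a", g2 = c("a", "b"))),
               "overlap")
})

test_that("a generative 3:1 variance split is recovered from a real fit", {
  set.seed(17)
  n <- 250
  f <- fake_features(n)
  d <- build_design_matrix(f, model_spec(terms = c("depth", "boundary"),
                                         n_factors = 0,
                                         random = character(0)))
  # var(X beta) ratio depth:boundary = 3:1 by construction
  b_depth <- 0.6 * sqrt(3); b_bnd <- 0.6
  eta <- 1.5 + b_depth * d$X[, "depth"] + b_bnd * d$X[, "boundary"]
  y <- matrix(rpois(n, exp(eta)), n, 1, dimnames = list(f$deployment_id, "s"))
  post <- sample_posterior(y, d, settings = mcmc_settings(
    chains = 2, iterations = 2000, burnin = 600, seed = 4))
  vp <- variance_partition(post, d)
  ratio_true <- 100 * c(b_depth^2 * var(d$X[, "depth"]),
                        b_bnd^2 * var(d$X[, "boundary"]))
  ratio_true <- ratio_true / sum(ratio_true) * 100
  expect_lt(max(abs(vp[1, c("depth", "boundary")] - ratio_true)), 5)
})

test_that("cross-validation partitions deployments and reports honest errors", {
  sc <- tiny_seascape()
  f <- sc$feats
  set.seed(2)
  d0 <- build_design_matrix(f, model_spec(terms = "depth", n_factors = 0))
  eta <- 0.8 + 0.7 * d0$X[, "depth"]
  y <- matrix(rpois(nrow(f), exp(eta)), ncol = 1,
              dimnames = list(f$deployment_id, "sp"))
  cv <- kfold_cv(y, f, model_spec(terms = "depth", n_factors = 0), k = 4,
                 settings = quick_settings(iterations = 500, burnin = 200),
                 seed = 11)
  # folds are an exact partition
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_equal(length(cv$folds), nrow(f))
  # reported RMSE equals recomputation from the stored predictions
  expect_equal(unname(cv$rmse),
               sqrt(mean((cv$predictions - y)^2)), tolerance = 1e-12)
  # relative RMSE consistent with the response range
  expect_equal(unname(cv$relative_rmse),
               rmse_relative(unname(cv$rmse), min(y), max(y)))
  expect_true(all(cv$rmse >= 0))
})

test_that("radius selection obeys its tie and singleton rules", {
  sc <- tiny_seascape()
  f <- sc$feats
  f$H_1000 <- f$H_500  # identical covariates at both radii
  set.seed(5)
  y <- matrix(rpois(nrow(f) * 2, 2), ncol = 2,
              dimnames = list(f$deployment_id, c("a", "b")))
  r <- select_diversity_radius(y, f, radii = c(1000, 500),
                               settings = quick_settings(iterations = 300,
                                                         burnin = 100),
                               seed = 2)
  expect_equal(as.numeric(r), 500)  # tie -> smallest radius
  expect_true(attr(r, "tie"))
  r1 <- select_diversity_radius(y, f, radii = 500,
                                settings = quick_settings(iterations = 300,
                                                          burnin = 100),
                                seed = 2)
  expect_equal(as.numeric(r1), 500)
})

test_that("stepwise search is reproducible and assembles a valid trace", {
  sc <- tiny_seascape()
  f <- sc$feats[stats::complete.cases(sc$feats), ]
  set.seed(23)
  d0 <- build_design_matrix(f, model_spec(terms = "depth", n_factors = 0))
  eta <- 0.7 + 0.8 * d0$X[, "depth"]
  y <- matrix(rpois(nrow(f), exp(eta)), ncol = 1,
              dimnames = list(f$deployment_id, "sp"))
  st <- quick_settings(iterations = 400, burnin = 150)
  s1 <- stepwise_select(c("depth", "aspect"), y, f, settings = st, seed = 7)
  s2 <- stepwise_select(c("depth", "aspect"), y, f, settings = st, seed = 7)
  expect_identical(s1$trace, s2$trace)
  expect_s3_class(s1$trace, "data.frame")
  # accepted WAICs strictly decrease along the trace
  acc <- s1$trace[which(s1$trace$accepted), ]
  expect_true(all(diff(acc$waic) < 0))
})
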