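#' Widely applicable information criterion
#'
#' WAIC = -2 (lppd - p_waic), with the log pointwise predictive density
#' lppd = sum_cells log mean_draws p(y | lambda) and the effective-parameter
#' penalty p_waic = sum_cells var_draws log p(y | lambda), evaluated over
#' every deployment-by-species cell using the draw-level linear predictors
#' (fixed effects + random intercepts + latent term).
#'
#' @param post a `posterior_samples` fit (with latent scores stored when the
#'   model has factors).
#' @param counts the count matrix the model was fitted to.
#' @param X design matrix used for the fit; defaults to the training one if
#'   supplied, otherwise must be given.
#' @return list of class `waic`: `waic`, `lppd`, `p_waic`, `n_draws`.
#' @export
waic <- function(post, counts, X) {
  y <- as.matrix(counts)
  ndraws <- length(post$chains) * post$nkeep
  if (ndraws < 2L) stop("p_waic needs at least 2 posterior draws")
  if (post$q > 0L && is.null(post$chains[[1L]]$U)) {
    stop("latent scores were not stored; refit with store_u = TRUE")
  }
  # online logsumexp + Welford accumulation over draws, per cell
  mx <- matrix(-Inf, post$n, post$J)
  sm <- matrix(0, post$n, post$J)
  mean_lp <- matrix(0, post$n, post$J)
  m2 <- matrix(0, post$n, post$J)
  lgy <- lgamma(y + 1)
  cnt <- 0L
  for (ch in seq_along(post$chains)) {
    for (d in seq_len(post$nkeep)) {
      eta <- draw_eta(post, ch, d, X)
      lp <- y * eta - exp(eta) - lgy
      newmx <- pmax(mx, lp)
      sm <- sm * exp(mx - newmx) + exp(lp - newmx)
      mx <- newmx
      cnt <- cnt + 1L
      delta <- lp - mean_lp
      mean_lp <- mean_lp + delta / cnt
      m2 <- m2 + delta * (lp - mean_lp)
    }
  }
  lppd <- sum(mx + log(sm) - log(ndraws))
  p_waic <- sum(m2 / (ndraws - 1))
  structure(list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
                 n_draws = ndraws),
            class = "waic")
}

#' @export
print.waic <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, p_waic %.2f, %d draws)\n",
              x$waic, x$lppd, x$p_waic, x$n_draws))
  invisible(x)
}

# Fit a term set and return its WAIC (used by the selection searches).
fit_and_waic <- function(terms, counts, features, spec_args, priors,
                         settings, seed) {
  spec <- do.call(model_spec, c(list(terms = terms), spec_args))
  design <- build_design_matrix(features, spec)
  st <- settings; st$seed <- seed
  post <- sample_posterior(counts, design, priors, st)
  list(waic = waic(post, counts, design$X)$waic, post = post,
       design = design, spec = spec)
}

#' Forward-backward stepwise model selection by WAIC
#'
#' Starting from the intercept-only model, alternately adds the candidate
#' term that lowers WAIC the most and drops the term whose removal lowers
#' WAIC the most, until no move improves. Interaction terms are only
#' entertained once their main effects are in the model, and a main effect
#' is not dropped while one of its interactions remains. Search fits use
#' the (typically reduced) `settings` supplied; every fit's seed derives
#' deterministically from `seed`.
#'
#' @param pool candidate terms (see [model_spec()]).
#' @param counts count matrix.
#' @param features `deployment_features` for the same deployments.
#' @param priors a [prior_spec()].
#' @param settings reduced [mcmc_settings()] for the search fits.
#' @param seed master seed for the search.
#' @param min_delta smallest WAIC decrease accepted as an improvement.
#' @param spec_args extra arguments passed to [model_spec()] (factors,
#'   random terms, diversity radius, ...).
#' @return list of class `selection_trace`: `terms` (selected set), `waic`,
#'   `trace` (data.frame of every candidate evaluated).
#' @export
stepwise_select <- function(pool, counts, features, priors = prior_spec(),
                            settings = mcmc_settings(chains = 2,
                                                     iterations = 1500,
                                                     burnin = 500),
                            seed = 1, min_delta = 0,
                            spec_args = list(n_factors = 0, random = character(0))) {
  fit_no <- 0L
  trace <- list()
  eval_terms <- function(terms, move, candidate) {
    fit_no <<- fit_no + 1L
    w <- fit_and_waic(terms, counts, features, spec_args, priors, settings,
                      seed = chain_seed(seed, fit_no))$waic
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, move = move, candidate = candidate,
      terms = paste(sort(terms), collapse = "+"), waic = w,
      accepted = NA
    )
    w
  }
  current <- character(0)
  best_waic <- eval_terms(current, "start", "(intercept)")
  trace[[length(trace)]]$accepted <- TRUE
  repeat {
    improved <- FALSE
    # forward: addable terms whose main effects are present
    addable <- setdiff(pool, current)
    addable <- addable[vapply(addable, function(tm) {
      mains <- setdiff(strsplit(tm, ":")[[1L]], tm)
      all(mains %in% current)
    }, logical(1L))]
    if (length(addable)) {
      ws <- vapply(addable, function(tm) {
        eval_terms(c(current, tm), "add", tm)
      }, numeric(1L))
      if (min(ws) < best_waic - min_delta) {
        tm <- addable[which.min(ws)]
        current <- c(current, tm)
        best_waic <- min(ws)
        trace[[length(trace) - length(addable) + which.min(ws)]]$accepted <- TRUE
        improved <- TRUE
      }
    }
    # backward: droppable terms with no dependent interaction in the model
    droppable <- current[vapply(current, function(tm) {
      !any(vapply(setdiff(current, tm), function(other) {
        tm %in% strsplit(other, ":")[[1L]]
      }, logical(1L)))
    }, logical(1L))]
    if (length(droppable)) {
      ws <- vapply(droppable, function(tm) {
        eval_terms(setdiff(current, tm), "drop", tm)
      }, numeric(1L))
      if (length(ws) && min(ws) < best_waic - min_delta) {
        tm <- droppable[which.min(ws)]
        current <- setdiff(current, tm)
        best_waic <- min(ws)
        trace[[length(trace) - length(droppable) + which.min(ws)]]$accepted <- TRUE
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(
    list(terms = current, waic = best_waic, trace = do.call(rbind, trace)),
    class = "selection_trace"
  )
}

#' Choose the surrounding patch diversity radius
#'
#' Fits the single-covariate diversity model at each candidate radius and
#' returns the radius with the lowest WAIC; ties go to the smallest radius.
#'
#' @param counts count matrix.
#' @param features `deployment_features` holding an `H_<radius>` column per
#'   candidate.
#' @param radii candidate radii (m).
#' @param priors,settings,seed as in [stepwise_select()].
#' @param spec_args extra [model_spec()] arguments.
#' @return chosen radius, with attribute `waic` (named vector per radius)
#'   and `tie` flag.
#' @export
select_diversity_radius <- function(counts, features,
                                    radii = c(500, 1000, 1500),
                                    priors = prior_spec(),
                                    settings = mcmc_settings(chains = 2,
                                                             iterations = 1500,
                                                             burnin = 500),
                                    seed = 1,
                                    spec_args = list(n_factors = 0,
                                                     random = character(0))) {
  stopifnot(length(radii) >= 1L)
  radii <- sort(radii)
  # common random numbers across candidates: a paired comparison, and an
  # exact tie when two radii carry identical covariates
  ws <- vapply(seq_along(radii), function(i) {
    args <- c(list(terms = "diversity"), spec_args)
    args$diversity_radius <- radii[i]
    spec <- do.call(model_spec, args)
    design <- build_design_matrix(features, spec)
    st <- settings; st$seed <- chain_seed(seed, 1L)
    post <- sample_posterior(counts, design, priors, st)
    waic(post, counts, design$X)$waic
  }, numeric(1L))
  names(ws) <- radii
  best <- which(ws == min(ws))
  structure(radii[best[1L]], waic = ws, tie = length(best) > 1L)
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) from regressing each non-intercept design column
#' on all the others; exact collinearity is reported as `Inf`.
#'
#' @param design a `design_matrix` or plain numeric matrix (intercept column
#'   allowed and ignored).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  icpt <- colnames(X) %in% "(Intercept)" |
    apply(X, 2L, function(v) stats::sd(v) == 0)
  X <- X[, !icpt, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 non-intercept columns")
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X))
}

# Posterior-mean lambda for new rows: fixed effects plus the site/year
# random-intercept draws at the given levels; latent term at its marginal
# expectation (score 0). Unseen levels get effect 0 (with a warning).
predict_lambda <- function(post, newX, site = NULL, year = NULL) {
  nnew <- nrow(newX)
  map_idx <- function(values, levels, label) {
    if (is.null(values) || is.null(levels)) return(rep(NA_integer_, nnew))
    idx <- match(as.character(values), levels)
    if (anyNA(idx)) {
      warning(label, " level(s) unseen in training; random effect set to 0")
    }
    idx
  }
  si <- map_idx(site, levels(post$site), "site")
  yi <- map_idx(year, levels(post$year), "year")
  acc <- matrix(0, nnew, post$J)
  nd <- 0L
  for (ch in seq_along(post$chains)) {
    cobj <- post$chains[[ch]]
    for (d in seq_len(post$nkeep)) {
      B <- matrix(cobj$B[d, , ], post$p, post$J)
      eta <- newX %*% B
      eS <- matrix(cobj$eps_site[d, , ], ncol = post$J)
      eY <- matrix(cobj$eps_year[d, , ], ncol = post$J)
      ok <- !is.na(si)
      if (any(ok)) eta[ok, ] <- eta[ok, ] + eS[si[ok], , drop = FALSE]
      ok <- !is.na(yi)
      if (any(ok)) eta[ok, ] <- eta[ok, ] + eY[yi[ok], , drop = FALSE]
      acc <- acc + exp(eta)
      nd <- nd + 1L
    }
  }
  acc / nd
}

#' k-fold cross-validation
#'
#' Randomly partitions deployments into k folds (seeded), refits the model
#' on each training remainder, predicts the held-out deployments with the
#' posterior-mean Poisson mean (random effects at their site/year draws —
#' levels are shared across folds — and the latent term at its marginal
#' expectation), and reports per-species RMSE over all held-out cells,
#' plus RMSE as a percentage of each species' observed response range.
#'
#' @param counts count matrix.
#' @param features `deployment_features`.
#' @param spec a [model_spec()].
#' @param k number of folds (>= 2).
#' @param priors,settings,seed fitting controls; each fold's fit derives its
#'   seed from `seed`.
#' @return list of class `cv_result`: `rmse` (per species), `relative_rmse`
#'   (% of range), `range` (2 x J), `folds`, `predictions`.
#' @export
kfold_cv <- function(counts, features, spec, k = 5, priors = prior_spec(),
                     settings = mcmc_settings(chains = 2, iterations = 1500,
                                              burnin = 500),
                     seed = 1) {
  y <- as.matrix(counts)
  n <- nrow(y)
  stopifnot(k >= 2, n >= 2 * k)
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(k), length.out = n))
  pred <- matrix(NA_real_, n, ncol(y), dimnames = dimnames(y))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train_feat <- features[-test, , drop = FALSE]
    design <- build_design_matrix(train_feat, spec)
    st <- settings; st$seed <- chain_seed(seed, f)
    post <- sample_posterior(y[-test, , drop = FALSE], design, priors, st)
    if ("substratum" %in% spec$terms) {
      unseen <- !(features$substratum[test] %in% design$constants$subst_levels)
      if (any(unseen)) {
        warning("fold ", f, ": ", sum(unseen), " deployment(s) with a ",
                "substratum class absent from the training folds left ",
                "unpredicted")
        test <- test[!unseen]
      }
    }
    test_design <- build_design_matrix(features[test, , drop = FALSE], spec,
                                       constants = design$constants)
    pred[test, ] <- predict_lambda(post, test_design$X,
                                   site = features$site[test],
                                   year = features$year[test])
  }
  rmse <- sqrt(colMeans((pred - y)^2, na.rm = TRUE))
  rng <- apply(y, 2L, range)
  rel <- vapply(seq_along(rmse), function(j) {
    rmse_relative(rmse[j], rng[1L, j], rng[2L, j])
  }, numeric(1L))
  structure(
    list(rmse = rmse, relative_rmse = stats::setNames(rel, names(rmse)),
         range = rng, folds = folds, predictions = pred),
    class = "cv_result"
  )
}

#' RMSE as a percentage of the response range
#'
#' @param rmse root-mean-square error (>= 0).
#' @param response_min,response_max observed response range.
#' @return 100 * rmse / (max - min), rounded to 1 decimal.
#' @export
rmse_relative <- function(rmse, response_min, response_max) {
  if (response_max <= response_min) stop("response range must be positive")
  round(100 * rmse / (response_max - response_min), 1)
}

#' Variance partitioning over covariate groups and random effects
#'
#' For every posterior draw and species, computes the variance over
#' deployments of each covariate group's partial linear predictor
#' X_g beta_g, together with the realized site, year and latent-factor
#' contributions, normalizes them to percentages summing to 100, and
#' averages over draws.
#'
#' @param post a `posterior_samples` fit (latent scores stored).
#' @param design the training `design_matrix`.
#' @param groups named list mapping group name -> character vector of term
#'   labels (as in `design$terms`); groups must be disjoint and cover all
#'   non-intercept terms. Default: one group per term.
#' @return matrix (species x components) of mean percentages.
#' @export
variance_partition <- function(post, design, groups = NULL) {
  X <- design$X
  terms <- design$terms
  fixed_terms <- setdiff(unique(terms), "(Intercept)")
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(fixed_terms), fixed_terms)
  }
  all_terms <- unlist(groups)
  if (anyDuplicated(all_terms)) stop("groups overlap")
  if (!setequal(all_terms, fixed_terms)) {
    stop("groups must cover exactly the non-intercept terms")
  }
  cols_of <- lapply(groups, function(g) which(terms %in% g))
  comp_names <- c(names(groups),
                  if (post$use_site) "site", if (post$use_year) "year",
                  if (post$q > 0L) "latent")
  acc <- matrix(0, post$J, length(comp_names),
                dimnames = list(post$species, comp_names))
  nd <- 0L
  for (ch in seq_along(post$chains)) {
    cobj <- post$chains[[ch]]
    for (d in seq_len(post$nkeep)) {
      B <- matrix(cobj$B[d, , ], post$p, post$J)
      parts <- matrix(0, post$J, length(comp_names))
      ci <- 0L
      for (g in seq_along(groups)) {
        ci <- ci + 1L
        cols <- cols_of[[g]]
        pg <- X[, cols, drop = FALSE] %*% B[cols, , drop = FALSE]
        parts[, ci] <- apply(pg, 2L, stats::var)
      }
      if (post$use_site) {
        ci <- ci + 1L
        eS <- matrix(cobj$eps_site[d, , ], ncol = post$J)
        parts[, ci] <- apply(eS[post$si, , drop = FALSE], 2L, stats::var)
      }
      if (post$use_year) {
        ci <- ci + 1L
        eY <- matrix(cobj$eps_year[d, , ], ncol = post$J)
        parts[, ci] <- apply(eY[post$yi, , drop = FALSE], 2L, stats::var)
      }
      if (post$q > 0L) {
        ci <- ci + 1L
        U <- matrix(cobj$U[d, , ], post$n, post$q)
        V <- matrix(cobj$V[d, , ], post$J, post$q)
        parts[, ci] <- apply(U %*% t(V), 2L, stats::var)
      }
      tot <- rowSums(parts)
      tot[tot == 0] <- 1
      acc <- acc + 100 * parts / tot
      nd <- nd + 1L
    }
  }
  acc / nd
}
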