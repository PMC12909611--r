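#' Model specification
#'
#' Declares which seascape covariates enter the joint model's linear
#' predictor, the random-effect groupings, and the latent-factor rank.
#' Interaction terms require their main effects; exactly one surrounding
#' patch diversity radius is active at a time.
#'
#' @param terms character vector drawn from `"substratum"`, `"depth"`,
#'   `"boundary"` (distance to patch boundary), `"diversity"` (surrounding
#'   patch diversity H), `"shore"`, `"slope"`, `"aspect"`,
#'   `"depth:substratum"`, `"boundary:substratum"`, `"depth:diversity"`.
#'   May be empty (intercept-only model).
#' @param n_factors latent-factor rank (>= 0); default 2.
#' @param random random-intercept groupings, subset of c("site", "year").
#' @param diversity_radius radius (m) of the active H covariate.
#' @param reference substratum reference level; default alphabetically first.
#' @param overdispersion add a deployment-level normal residual (off by
#'   default).
#' @param spatial placeholder for a spatially structured random effect; only
#'   `"none"` is implemented.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(terms = c("substratum", "depth", "boundary",
                                 "diversity", "depth:substratum",
                                 "boundary:substratum", "depth:diversity"),
                       n_factors = 2, random = c("site", "year"),
                       diversity_radius = 500, reference = NULL,
                       overdispersion = FALSE, spatial = "none") {
  known <- c("substratum", "depth", "boundary", "diversity", "shore",
             "slope", "aspect", "depth:substratum", "boundary:substratum",
             "depth:diversity")
  bad <- setdiff(terms, known)
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  for (tm in grep(":", terms, value = TRUE)) {
    mains <- strsplit(tm, ":")[[1L]]
    if (!all(mains %in% terms)) {
      stop("interaction ", tm, " requires its main effects")
    }
  }
  if (!identical(spatial, "none")) {
    stop("spatially structured random effects are not implemented")
  }
  stopifnot(n_factors >= 0, length(diversity_radius) == 1L)
  structure(
    list(terms = terms, n_factors = n_factors, random = random,
         diversity_radius = diversity_radius, reference = reference,
         overdispersion = overdispersion),
    class = "model_spec"
  )
}

#' Build the design matrix
#'
#' Reference-codes the substratum factor (C classes -> C-1 dummies),
#' standardizes continuous covariates to mean 0 / SD 1 (storing the
#' constants so prediction uses the training scale), and forms interaction
#' columns as products of the coded columns.
#'
#' @param features a `deployment_features` data.frame (or any data.frame
#'   with the needed columns).
#' @param spec a [model_spec()].
#' @param constants standardization constants and factor levels from a
#'   previously built design, for prediction-time reuse.
#' @return list of class `design_matrix`: `X` (n x p, intercept first),
#'   `terms` (term label per column), `constants`, `spec`, `site`, `year`,
#'   `deployment_id`.
#' @export
build_design_matrix <- function(features, spec, constants = NULL) {
  n <- nrow(features)
  cont_col <- c(depth = "depth_m", boundary = "dist_boundary_m",
                diversity = paste0("H_", spec$diversity_radius),
                shore = "dist_shore_m", slope = "slope_deg",
                aspect = "aspect_deg")
  std <- function(name) {
    col <- cont_col[[name]]
    if (is.null(features[[col]])) stop("feature column ", col, " missing")
    v <- features[[col]]
    if (anyNA(v)) {
      stop("covariate ", col, " has missing values (e.g. undefined aspect ",
           "on flat cells); drop or impute those deployments first")
    }
    if (is.null(constants)) {
      ctr <- mean(v); scl <- stats::sd(v)
      if (!is.finite(scl) || scl == 0) scl <- 1
    } else {
      ctr <- constants$center[[name]]; scl <- constants$scale[[name]]
    }
    list(z = (v - ctr) / scl, center = ctr, scale = scl)
  }
  X <- matrix(1, n, 1L, dimnames = list(features$deployment_id, "(Intercept)"))
  term_of <- "(Intercept)"
  centers <- list(); scales <- list()
  subst_dum <- NULL; subst_levels <- NULL
  if ("substratum" %in% spec$terms) {
    if (is.null(constants)) {
      subst_levels <- sort(unique(features$substratum))
      if (!is.null(spec$reference)) {
        subst_levels <- c(spec$reference,
                          setdiff(subst_levels, spec$reference))
      }
    } else {
      subst_levels <- constants$subst_levels
      unseen <- setdiff(unique(features$substratum), subst_levels)
      if (length(unseen)) {
        stop("substratum level(s) not in the training design: ",
             paste(unseen, collapse = ", "))
      }
    }
    f <- factor(features$substratum, levels = subst_levels)
    if (nlevels(f) > 1L) {
      subst_dum <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(subst_dum) <- paste0("substratum", subst_levels[-1L])
      X <- cbind(X, subst_dum)
      term_of <- c(term_of, rep("substratum", ncol(subst_dum)))
    }
  }
  zs <- list()
  for (nm in c("depth", "boundary", "diversity", "shore", "slope", "aspect")) {
    if (nm %in% spec$terms) {
      s <- std(nm)
      zs[[nm]] <- s$z; centers[[nm]] <- s$center; scales[[nm]] <- s$scale
      X <- cbind(X, s$z)
      colnames(X)[ncol(X)] <- nm
      term_of <- c(term_of, nm)
    }
  }
  add_inter <- function(X, term_of, tm) {
    parts <- strsplit(tm, ":")[[1L]]
    if ("substratum" %in% parts) {
      cont <- setdiff(parts, "substratum")
      if (!is.null(subst_dum)) {
        cols <- subst_dum * zs[[cont]]
        colnames(cols) <- paste0(cont, ":", colnames(subst_dum))
        X <- cbind(X, cols)
        term_of <- c(term_of, rep(tm, ncol(cols)))
      }
    } else {
      X <- cbind(X, zs[[parts[1L]]] * zs[[parts[2L]]])
      colnames(X)[ncol(X)] <- tm
      term_of <- c(term_of, tm)
    }
    list(X = X, term_of = term_of)
  }
  for (tm in grep(":", spec$terms, value = TRUE)) {
    r <- add_inter(X, term_of, tm)
    X <- r$X; term_of <- r$term_of
  }
  if (is.null(constants)) {
    # prediction-time designs keep the training layout even if a column is
    # constant in the new rows
    nonconst <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                              function(v) stats::sd(v) > 0))
    if (any(!nonconst)) {
      warning("dropping constant column(s): ",
              paste(colnames(X)[!nonconst], collapse = ", "))
      X <- X[, nonconst, drop = FALSE]
      term_of <- term_of[nonconst]
    }
  }
  structure(
    list(X = X, terms = term_of,
         constants = list(center = centers, scale = scales,
                          subst_levels = subst_levels),
         spec = spec,
         site = if (!is.null(features$site)) factor(features$site),
         year = if (!is.null(features$year)) factor(features$year),
         deployment_id = features$deployment_id),
    class = "design_matrix"
  )
}

#' Poisson log likelihood
#'
#' Total log likelihood sum_ij (y log lambda - lambda - log y!) of a count
#' matrix under cellwise Poisson means, given on the log-link scale.
#'
#' @param counts count matrix y.
#' @param eta linear predictor (log lambda), same shape as `counts`.
#' @param lambda alternatively the means themselves; must be > 0.
#' @return scalar total log likelihood.
#' @export
log_likelihood <- function(counts, eta = NULL, lambda = NULL) {
  if (is.null(lambda)) {
    if (is.null(eta)) stop("supply eta or lambda")
    lambda <- exp(eta)
  }
  if (any(lambda <= 0)) stop("lambda must be positive under the log link")
  if (!all(dim(as.matrix(counts)) == dim(as.matrix(lambda)))) {
    stop("shape mismatch between counts and means")
  }
  sum(counts * log(lambda) - lambda - lgamma(counts + 1))
}

#' Prior specification
#'
#' Fixed effects get independent normal priors (mean 0, variance 10^4);
#' the precisions of the site, year and latent-loading variance components
#' get Gamma(shape 0.1, rate 0.1) priors (conjugate; equivalently an
#' inverse-gamma prior on each variance).
#'
#' @param beta_mean,beta_var normal prior moments for intercepts and slopes.
#' @param shape,rate Gamma prior parameters for the precisions.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(beta_mean = 0, beta_var = 1e4, shape = 0.1, rate = 0.1) {
  stopifnot(beta_var > 0, shape > 0, rate > 0)
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 shape = shape, rate = rate),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains number of chains.
#' @param iterations iterations per chain (including burn-in).
#' @param burnin transient iterations discarded per chain.
#' @param thin thinning interval for retained draws.
#' @param seed master seed; each chain derives its own stream.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, iterations = 3000, burnin = 1000,
                          thin = 1, seed = 1) {
  stopifnot(chains >= 1, burnin >= 0, burnin < iterations, thin >= 1)
  structure(list(chains = chains, iterations = iterations, burnin = burnin,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Retained-draw arithmetic of an MCMC schedule
#'
#' @param settings an [mcmc_settings()].
#' @return list with `per_chain` and `total` retained draw counts.
#' @export
mcmc_schedule <- function(settings) {
  kept <- settings$iterations - settings$burnin
  if (kept %% settings$thin != 0) {
    warning("(iterations - burnin) not divisible by thin; flooring")
  }
  per_chain <- kept %/% settings$thin
  list(per_chain = per_chain, total = settings$chains * per_chain)
}

chain_seed <- function(master, chain) {
  (as.integer(master) %% 2000000000L) + 7919L * as.integer(chain)
}

#' Fit the latent-factor Poisson joint species distribution model
#'
#' Samples the posterior of the hierarchical model
#' y_ij ~ Poisson(lambda_ij),
#' log lambda_ij = alpha_j + x_i' beta_j + eps\[site,j\] + eps\[year,j\] +
#' u_i' v_j, by blocked Metropolis-within-Gibbs MCMC: adaptive random-walk
#' Metropolis updates vectorised over conditionally independent blocks
#' (species for intercepts/slopes/loadings, deployments for latent scores,
#' level-by-species cells for the random intercepts) and conjugate Gamma
#' draws for the precision components. Step sizes adapt towards 44%
#' acceptance during the first half of burn-in and are frozen afterwards, so
#' retained draws come from a fixed kernel.
#'
#' @param counts n x J count matrix (deployments x species).
#' @param design a `design_matrix` from [build_design_matrix()].
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param prior_only if TRUE the likelihood is disabled and the sampler
#'   draws each block's conditional under the priors alone (exact Gibbs).
#' @param store_u keep the latent score draws (needed for draw-level linear
#'   predictors, WAIC, variance partitioning).
#' @param verbose print progress.
#' @return object of class `posterior_samples`: per-chain arrays of kept
#'   draws for `B` (p x J coefficients, intercept row first), `eps_site`,
#'   `eps_year`, `U`, `V`, variance components and total log likelihood,
#'   plus metadata (species, column names, settings, acceptance rates).
#' @export
sample_posterior <- function(counts, design, priors = prior_spec(),
                             settings = mcmc_settings(), prior_only = FALSE,
                             store_u = TRUE, verbose = FALSE) {
  y <- as.matrix(counts)
  X <- design$X
  n <- nrow(X); p <- ncol(X); J <- ncol(y)
  if (nrow(y) != n) stop("count rows must match design rows")
  spec <- design$spec
  q <- spec$n_factors
  use_site <- "site" %in% spec$random && !is.null(design$site) &&
    nlevels(design$site) > 1L
  use_year <- "year" %in% spec$random && !is.null(design$year) &&
    nlevels(design$year) > 1L
  si <- if (use_site) as.integer(design$site) else rep(1L, n)
  yi <- if (use_year) as.integer(design$year) else rep(1L, n)
  nS <- max(si); nY <- max(yi)
  sched <- suppressWarnings(mcmc_schedule(settings))
  nkeep <- sched$per_chain
  bsd <- sqrt(priors$beta_var)
  adapt_end <- max(50L, settings$burnin %/% 2L)
  batch <- 50L
  ySgrp <- rowsum(y, si); yYgrp <- rowsum(y, yi)
  lgy <- sum(lgamma(y + 1))
  ytX <- crossprod(y, X)                     # J x p; colSums(y * outer(x_k, d)) = d * ytX[, k]
  nz <- lapply(seq_len(p), function(k) which(X[, k] != 0))
  Xnz <- lapply(seq_len(p), function(k) X[nz[[k]], k])

  run_chain <- function(ch) {
    set.seed(chain_seed(settings$seed, ch))
    B <- matrix(0, p, J)
    B[1L, ] <- log(colMeans(y) + 0.1) + stats::rnorm(J, 0, 0.1)
    if (p > 1L) B[-1L, ] <- stats::rnorm((p - 1L) * J, 0, 0.1)
    eS <- matrix(0, nS, J); eY <- matrix(0, nY, J)
    U <- if (q > 0L) matrix(stats::rnorm(n * q, 0, 0.1), n, q) else NULL
    V <- if (q > 0L) matrix(stats::rnorm(J * q, 0, 0.1), J, q) else NULL
    tauS <- 1; tauY <- 1; tauV <- 1
    stepB <- matrix(0.15, p, J); stepS <- matrix(0.2, nS, J)
    stepY <- matrix(0.2, nY, J)
    stepU <- if (q > 0L) matrix(0.4, n, q) else NULL
    stepV <- if (q > 0L) matrix(0.2, J, q) else NULL
    accB <- matrix(0, p, J); accS <- matrix(0, nS, J); accY <- matrix(0, nY, J)
    accU <- if (q > 0L) matrix(0, n, q) else NULL
    accV <- if (q > 0L) matrix(0, J, q) else NULL
    totB <- 0; rateB <- 0  # post-adaptation acceptance bookkeeping
    Eta <- X %*% B + eS[si, , drop = FALSE] + eY[yi, , drop = FALSE]
    if (q > 0L) Eta <- Eta + U %*% t(V)
    expEta <- exp(Eta)
    keep <- list(
      B = array(NA_real_, c(nkeep, p, J)),
      eps_site = array(NA_real_, c(nkeep, nS, J)),
      eps_year = array(NA_real_, c(nkeep, nY, J)),
      U = if (q > 0L && store_u) array(NA_real_, c(nkeep, n, q)) else NULL,
      V = if (q > 0L) array(NA_real_, c(nkeep, J, q)) else NULL,
      sigma = matrix(NA_real_, nkeep, 3,
                     dimnames = list(NULL, c("site", "year", "loading"))),
      loglik = numeric(nkeep)
    )
    kidx <- 0L
    adapt <- function(step, acc) {
      rate <- acc / batch
      step * exp(0.3 * ifelse(rate > 0.44, 1, -1) *
                   pmin(1, abs(rate - 0.44) / 0.2))
    }
    for (it in seq_len(settings$iterations)) {
      if (prior_only) {
        # with the likelihood disabled every conditional is its prior
        B[] <- stats::rnorm(p * J, priors$beta_mean, bsd)
        eS[] <- stats::rnorm(nS * J, 0, 1 / sqrt(tauS))
        eY[] <- stats::rnorm(nY * J, 0, 1 / sqrt(tauY))
        if (q > 0L) {
          U[] <- stats::rnorm(n * q)
          V[] <- stats::rnorm(J * q, 0, 1 / sqrt(tauV))
        }
        tauS <- stats::rgamma(1, priors$shape + nS * J / 2,
                              priors$rate + sum(eS^2) / 2)
        tauY <- stats::rgamma(1, priors$shape + nY * J / 2,
                              priors$rate + sum(eY^2) / 2)
        if (q > 0L) tauV <- stats::rgamma(1, priors$shape + J * q / 2,
                                          priors$rate + sum(V^2) / 2)
      } else {
        # --- coefficients, one design column at a time, all species at once
        # (only the column's nonzero rows contribute to the likelihood ratio)
        for (k in seq_len(p)) {
          delta <- stats::rnorm(J, 0, stepB[k, ])
          rows <- nz[[k]]
          D <- outer(Xnz[[k]], delta)
          expD <- exp(D)
          logr <- delta * ytX[, k] -
            colSums(expEta[rows, , drop = FALSE] * (expD - 1)) +
            stats::dnorm(B[k, ] + delta, priors$beta_mean, bsd, log = TRUE) -
            stats::dnorm(B[k, ], priors$beta_mean, bsd, log = TRUE)
          acc <- log(stats::runif(J)) < logr
          if (any(acc)) {
            B[k, acc] <- B[k, acc] + delta[acc]
            Eta[rows, acc] <- Eta[rows, acc] + D[, acc]
            expEta[rows, acc] <- expEta[rows, acc] * expD[, acc]
          }
          accB[k, ] <- accB[k, ] + acc
          if (it > adapt_end) { totB <- totB + J; rateB <- rateB + sum(acc) }
        }
        # --- site random intercepts (level x species cells independent)
        if (use_site) {
          D <- matrix(stats::rnorm(nS * J, 0, stepS), nS, J)
          grpExp <- rowsum(expEta, si)
          sdS <- 1 / sqrt(tauS)
          logr <- ySgrp * D - grpExp * (exp(D) - 1) +
            stats::dnorm(eS + D, 0, sdS, log = TRUE) -
            stats::dnorm(eS, 0, sdS, log = TRUE)
          acc <- matrix(log(stats::runif(nS * J)) < logr, nS, J)
          Dacc <- D * acc
          eS <- eS + Dacc
          Eta <- Eta + Dacc[si, , drop = FALSE]
          expEta <- expEta * exp(Dacc[si, , drop = FALSE])
          accS <- accS + acc
          tauS <- stats::rgamma(1, priors$shape + nS * J / 2,
                                priors$rate + sum(eS^2) / 2)
        }
        # --- year random intercepts
        if (use_year) {
          D <- matrix(stats::rnorm(nY * J, 0, stepY), nY, J)
          grpExp <- rowsum(expEta, yi)
          sdY <- 1 / sqrt(tauY)
          logr <- yYgrp * D - grpExp * (exp(D) - 1) +
            stats::dnorm(eY + D, 0, sdY, log = TRUE) -
            stats::dnorm(eY, 0, sdY, log = TRUE)
          acc <- matrix(log(stats::runif(nY * J)) < logr, nY, J)
          Dacc <- D * acc
          eY <- eY + Dacc
          Eta <- Eta + Dacc[yi, , drop = FALSE]
          expEta <- expEta * exp(Dacc[yi, , drop = FALSE])
          accY <- accY + acc
          tauY <- stats::rgamma(1, priors$shape + nY * J / 2,
                                priors$rate + sum(eY^2) / 2)
        }
        # --- latent scores and loadings, factor by factor
        if (q > 0L) {
          for (f in seq_len(q)) {
            d <- stats::rnorm(n, 0, stepU[, f])
            D <- outer(d, V[, f])
            expD <- exp(D)
            logr <- d * as.vector(y %*% V[, f]) -
              rowSums(expEta * (expD - 1)) +
              stats::dnorm(U[, f] + d, log = TRUE) -
              stats::dnorm(U[, f], log = TRUE)
            acc <- log(stats::runif(n)) < logr
            if (any(acc)) {
              U[acc, f] <- U[acc, f] + d[acc]
              Eta[acc, ] <- Eta[acc, ] + D[acc, , drop = FALSE]
              expEta[acc, ] <- expEta[acc, ] * expD[acc, , drop = FALSE]
            }
            accU[, f] <- accU[, f] + acc
            e <- stats::rnorm(J, 0, stepV[, f])
            D <- outer(U[, f], e)
            expD <- exp(D)
            sdV <- 1 / sqrt(tauV)
            logr <- e * as.vector(crossprod(y, U[, f])) -
              colSums(expEta * (expD - 1)) +
              stats::dnorm(V[, f] + e, 0, sdV, log = TRUE) -
              stats::dnorm(V[, f], 0, sdV, log = TRUE)
            acc <- log(stats::runif(J)) < logr
            if (any(acc)) {
              V[acc, f] <- V[acc, f] + e[acc]
              Eta[, acc] <- Eta[, acc] + D[, acc, drop = FALSE]
              expEta[, acc] <- expEta[, acc] * expD[, acc, drop = FALSE]
            }
            accV[, f] <- accV[, f] + acc
          }
          tauV <- stats::rgamma(1, priors$shape + J * q / 2,
                                priors$rate + sum(V^2) / 2)
        }
        # --- step-size adaptation (first half of burn-in only)
        if (it <= adapt_end && it %% batch == 0L) {
          stepB <- adapt(stepB, accB); accB[] <- 0
          if (use_site) { stepS <- adapt(stepS, accS); accS[] <- 0 }
          if (use_year) { stepY <- adapt(stepY, accY); accY[] <- 0 }
          if (q > 0L) {
            stepU <- adapt(stepU, accU); accU[] <- 0
            stepV <- adapt(stepV, accV); accV[] <- 0
          }
        }
      }
      if (it > settings$burnin &&
          (it - settings$burnin) %% settings$thin == 0L) {
        kidx <- kidx + 1L
        if (kidx <= nkeep) {
          keep$B[kidx, , ] <- B
          keep$eps_site[kidx, , ] <- eS
          keep$eps_year[kidx, , ] <- eY
          if (q > 0L) {
            if (store_u) keep$U[kidx, , ] <- U
            keep$V[kidx, , ] <- V
          }
          keep$sigma[kidx, ] <- c(1 / sqrt(tauS), 1 / sqrt(tauY),
                                  1 / sqrt(tauV))
          keep$loglik[kidx] <- if (prior_only) NA_real_ else
            sum(y * Eta) - sum(expEta) - lgy
        }
      }
      if (verbose && it %% 1000L == 0L) {
        message("chain ", ch, ": iteration ", it)
      }
    }
    keep$accept_rate <- if (totB > 0) rateB / totB else NA_real_
    keep
  }

  chains <- lapply(seq_len(settings$chains), run_chain)
  rates <- vapply(chains, `[[`, numeric(1L), "accept_rate")
  if (!prior_only && any(!is.na(rates) & (rates < 0.05 | rates > 0.95))) {
    warning("post-adaptation acceptance rate outside [0.05, 0.95] (",
            paste(sprintf("%.2f", rates), collapse = ", "),
            "); mixing may be poor")
  }
  structure(
    list(chains = chains, species = colnames(y), n = n, p = p, J = J, q = q,
         colnames = colnames(X), terms = design$terms,
         site = design$site, year = design$year,
         use_site = use_site, use_year = use_year,
         si = si, yi = yi, constants = design$constants, spec = spec,
         settings = settings, priors = priors, nkeep = nkeep,
         accept_rate = rates),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "<posterior_samples> %d species, %d deployments, %d columns, %d factor(s)\n",
    x$J, x$n, x$p, x$q
  ))
  cat(sprintf("  %d chains x %d kept draws (%d total)\n",
              length(x$chains), x$nkeep, length(x$chains) * x$nkeep))
  invisible(x)
}

#' Flatten posterior draws of a parameter block
#'
#' @param post a `posterior_samples` object.
#' @param param one of "B", "eps_site", "eps_year", "U", "V", "sigma",
#'   "loglik".
#' @return matrix (total kept draws x flattened parameters); chains stacked
#'   in order, with a `chain` attribute.
#' @export
posterior_draws <- function(post, param = "B") {
  grab <- function(ch) {
    a <- ch[[param]]
    if (is.null(a)) stop("block ", param, " was not stored")
    if (is.matrix(a)) a else if (is.array(a)) {
      matrix(a, nrow = dim(a)[1L])
    } else matrix(a, ncol = 1L)
  }
  out <- do.call(rbind, lapply(post$chains, grab))
  attr(out, "chain") <- rep(seq_along(post$chains),
                            each = nrow(out) / length(post$chains))
  out
}

# Reconstruct the linear predictor (n x J) of stored draw d of chain ch.
draw_eta <- function(post, ch, d, X) {
  cobj <- post$chains[[ch]]
  B <- matrix(cobj$B[d, , ], post$p, post$J)
  Eta <- X %*% B +
    matrix(cobj$eps_site[d, , ], ncol = post$J)[post$si, , drop = FALSE] +
    matrix(cobj$eps_year[d, , ], ncol = post$J)[post$yi, , drop = FALSE]
  if (post$q > 0L && !is.null(cobj$U)) {
    U <- matrix(cobj$U[d, , ], post$n, post$q)
    V <- matrix(cobj$V[d, , ], post$J, post$q)
    Eta <- Eta + U %*% t(V)
  }
  Eta
}

#' Split potential scale reduction factor (rank-normalized)
#'
#' R-hat computed on rank-normalized draws after splitting each chain in
#' half; values near 1 (typically < 1.1) indicate the chains agree. Constant
#' input returns 1 by convention, and estimates falling fractionally below 1
#' (pure sampling noise in the variance ratio) are floored at 1.
#'
#' @param x draws: matrix (iterations x chains), or a vector (one chain).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 draws per chain")
  if (stats::sd(as.vector(x)) == 0) return(1)
  half <- nrow(x) %/% 2L
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(nrow(x) - half + 1L):nrow(x), j])
  }))
  r <- matrix(rank(splits, ties.method = "average"), nrow(splits))
  z <- stats::qnorm((r - 3 / 8) / (length(splits) + 1 / 4))
  m <- ncol(z); nn <- nrow(z)
  means <- colMeans(z)
  W <- mean(apply(z, 2L, stats::var))
  if (W == 0) return(1)
  Bn <- nn * stats::var(means)
  max(1, sqrt(((nn - 1) / nn * W + Bn / nn) / W))
}

#' Effective sample size
#'
#' Autocorrelation-based ESS pooled over chains, with Geyer's initial
#' positive sequence truncation of the autocorrelation sum. Constant chains
#' are degenerate: the total draw count is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param x draws: matrix (iterations x chains) or vector.
#' @return scalar ESS (possibly with a `degenerate` attribute).
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  nn <- nrow(x); m <- ncol(x)
  if (nn < 4L) stop("need at least 4 draws per chain")
  if (stats::sd(as.vector(x)) == 0) {
    return(structure(nn * m, degenerate = TRUE))
  }
  acov <- function(v) {
    v <- v - mean(v)
    nv <- length(v)
    f <- stats::fft(c(v, rep(0, nv)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(nv)]
    ac / (2 * nv * nv) * nv  # biased autocovariance (divides by n)
  }
  acovs <- vapply(seq_len(m), function(j) acov(x[, j]), numeric(nn))
  acovs <- matrix(acovs, nrow = nn)
  mean_ac <- rowMeans(acovs)
  W <- mean(acovs[1L, ]) * nn / (nn - 1)
  var_plus <- W * (nn - 1) / nn
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- 1 - (W - mean_ac) / var_plus
  rho[1L] <- 1
  # Geyer initial positive sequence on paired sums
  tmax <- nn - 2L
  tau <- 0; t <- 1L
  repeat {
    if (t + 1L > tmax) break
    pair <- rho[t + 1L] + rho[t + 2L]
    if (pair < 0) break
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * nn / (1 + 2 * tau)
  max(1, min(ess, m * nn))
}

#' Convergence summary for a fitted model
#'
#' R-hat and ESS for every coefficient and the variance components.
#'
#' @param post a `posterior_samples` object.
#' @return data.frame with `parameter`, `rhat`, `ess`.
#' @export
diagnose_posterior <- function(post) {
  nk <- post$nkeep; nch <- length(post$chains)
  Bd <- posterior_draws(post, "B")
  sd_ <- posterior_draws(post, "sigma")
  labs <- c(as.vector(outer(post$colnames, post$species, paste, sep = "|")),
            paste0("sigma_", colnames(sd_)))
  mats <- c(lapply(seq_len(ncol(Bd)), function(j) matrix(Bd[, j], nk, nch)),
            lapply(seq_len(ncol(sd_)), function(j) matrix(sd_[, j], nk, nch)))
  data.frame(
    parameter = labs,
    rhat = vapply(mats, gelman_rubin, numeric(1L)),
    ess = vapply(mats, function(m) as.numeric(effective_sample_size(m)),
                 numeric(1L))
  )
}
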