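#' Windowed Shannon diversity raster
#'
#' Surrounding patch diversity H computed at every cell centre, using the
#' same definition as [shannon_diversity()] (dominant-class proportions
#' among labelled in-area cells whose centres lie within the radius),
#' accumulated with an offset scan of the circular window.
#'
#' @param pm a `patch_map`.
#' @param radius_m window radius (m).
#' @return matrix of H values (NA where no eligible cell falls in the
#'   window).
#' @export
window_shannon <- function(pm, radius_m) {
  nr <- pm$nrow; nc <- pm$ncol; cs <- pm$cellsize
  K <- length(pm$classes)
  m <- floor(radius_m / cs)
  offs <- expand.grid(dr = -m:m, dc = -m:m)
  offs <- offs[(offs$dr^2 + offs$dc^2) * cs^2 <= radius_m^2, ]
  counts <- array(0, c(nr, nc, K))
  shift_sum <- function(acc, ind, dr, dc) {
    rs <- seq_len(nr) + dr; csq <- seq_len(nc) + dc
    vr <- which(rs >= 1L & rs <= nr); vc <- which(csq >= 1L & csq <= nc)
    acc[vr, vc] <- acc[vr, vc] + ind[rs[vr], csq[vc]]
    acc
  }
  dom <- pm$dominant
  for (k in seq_len(K)) {
    ind <- matrix(0, nr, nc)
    ind[!is.na(dom) & dom == k] <- 1
    ck <- matrix(0, nr, nc)
    for (o in seq_len(nrow(offs))) {
      ck <- shift_sum(ck, ind, offs$dr[o], offs$dc[o])
    }
    counts[, , k] <- ck
  }
  tot <- apply(counts, c(1L, 2L), sum)
  H <- matrix(NA_real_, nr, nc)
  ok <- tot > 0
  Hsum <- matrix(0, nr, nc)
  for (k in seq_len(K)) {
    p <- counts[, , k] / ifelse(tot > 0, tot, 1)
    term <- ifelse(p > 0, -p * log(p), 0)
    Hsum <- Hsum + term
  }
  H[ok] <- Hsum[ok]
  H
}

#' Per-cell covariates for gridded prediction
#'
#' Builds the model covariates for every predictable cell (in the study
#' area, with a dominant substratum class) with the same operations used
#' for deployment features, so training and prediction use one definition.
#'
#' @param pm a `patch_map`.
#' @param bathy depth [sea_raster].
#' @param radius_m diversity radius (m) of the active model term.
#' @return data.frame with one row per predictable cell: `cell` (index into
#'   the raster matrix), `x`, `y`, `depth_m`, `substratum`,
#'   `dist_boundary_m`, `dist_shore_m`, `slope_deg`, `aspect_deg`, and the
#'   `H_<radius>` column.
#' @export
cell_features <- function(pm, bathy, radius_m = 500) {
  dom <- pm$dominant
  ok <- which(!is.na(dom) & !is.na(bathy$values))
  nr <- pm$nrow
  rows <- ((ok - 1L) %% nr) + 1L
  cols <- ((ok - 1L) %/% nr) + 1L
  cs <- pm$cellsize
  x <- pm$xll + (cols - 0.5) * cs
  y <- pm$yll + (nr - rows + 0.5) * cs
  H <- window_shannon(pm, radius_m)
  sa <- slope_aspect(bathy)
  out <- data.frame(
    cell = ok, x = x, y = y,
    depth_m = bathy$values[ok],
    substratum = pm$classes[dom[ok]],
    dist_boundary_m = distance_to_boundary(pm, x, y),
    dist_shore_m = distance_to_shore(bathy, x, y),
    slope_deg = sa$slope$values[ok],
    aspect_deg = sa$aspect$values[ok],
    stringsAsFactors = FALSE
  )
  out[[paste0("H_", radius_m)]] <- H[ok]
  out
}

#' Predict expected relative abundance over the seascape
#'
#' Posterior-mean expected MaxN per cell and species, with the site and
#' year random intercepts fixed at the requested conditioning levels and
#' the latent term at its marginal expectation (score 0). Cells without a
#' dominant substratum class, or whose class was absent from training, are
#' masked (the count of the latter is recorded).
#'
#' @param post a `posterior_samples` fit.
#' @param pm,bathy the seascape rasters.
#' @param site,year conditioning levels for the random intercepts.
#' @param max_draws cap on the number of (evenly thinned) draws used for
#'   the posterior mean; NULL for all draws.
#' @return list of class `prediction_raster`: `lambda` (named list of
#'   per-species [sea_raster]), `conditioning`, `n_unseen_class` (masked
#'   cell count).
#' @export
predict_grid <- function(post, pm, bathy, site = NULL, year = NULL,
                         max_draws = 200) {
  feats <- cell_features(pm, bathy, radius_m = post$spec$diversity_radius)
  known <- post$constants$subst_levels
  unseen <- 0L
  if (!is.null(known) && "substratum" %in% post$spec$terms) {
    drop <- !(feats$substratum %in% known)
    unseen <- sum(drop)
    feats <- feats[!drop, , drop = FALSE]
  }
  feats <- feats[stats::complete.cases(feats), , drop = FALSE]
  design <- build_design_matrix(feats, post$spec, constants = post$constants)
  p2 <- thin_posterior(post, max_draws)
  lam <- predict_lambda(
    p2, design$X,
    site = if (!is.null(site)) rep(site, nrow(feats)),
    year = if (!is.null(year)) rep(year, nrow(feats))
  )
  nr <- pm$nrow; nc <- pm$ncol
  rasters <- lapply(seq_len(post$J), function(j) {
    v <- matrix(NA_real_, nr, nc)
    v[feats$cell] <- lam[, j]
    sea_raster(v, pm$xll, pm$yll, pm$cellsize)
  })
  names(rasters) <- post$species
  structure(
    list(lambda = rasters, conditioning = list(site = site, year = year),
         n_unseen_class = unseen),
    class = "prediction_raster"
  )
}

# Evenly thin the kept draws of every chain down to about max_draws total.
thin_posterior <- function(post, max_draws) {
  if (is.null(max_draws)) return(post)
  per_chain <- max(1L, ceiling(max_draws / length(post$chains)))
  if (post$nkeep <= per_chain) return(post)
  idx <- unique(round(seq(1L, post$nkeep, length.out = per_chain)))
  post$chains <- lapply(post$chains, function(ch) {
    for (nm in c("B", "eps_site", "eps_year", "U", "V")) {
      if (!is.null(ch[[nm]])) {
        ch[[nm]] <- ch[[nm]][idx, , , drop = FALSE]
      }
    }
    ch$sigma <- ch$sigma[idx, , drop = FALSE]
    ch$loglik <- ch$loglik[idx]
    ch
  })
  post$nkeep <- length(idx)
  post
}

#' Response curve along one covariate
#'
#' Expected MaxN (posterior mean and equal-tailed interval) along a grid of
#' one covariate, with the other covariates fixed at their observed means,
#' the substratum fixed at a chosen class (or one curve per class), random
#' intercepts at the conditioning levels, and the latent term at 0. The
#' grid must stay inside the observed covariate range unless
#' `extrapolate = TRUE`.
#'
#' @param post a `posterior_samples` fit.
#' @param features the training `deployment_features` (source of observed
#'   means and ranges).
#' @param varying one of "depth", "boundary", "diversity", "shore",
#'   "slope", "aspect".
#' @param substratum substratum class(es) for the curve; default the
#'   training classes in turn.
#' @param site,year conditioning levels.
#' @param n_points grid length.
#' @param from,to grid limits; default the observed range.
#' @param level interval level.
#' @param extrapolate allow limits beyond the observed range.
#' @param max_draws draw cap as in [predict_grid()].
#' @return data.frame of class `response_curve`: `covariate`, `value`,
#'   `substratum`, species columns `<sp>_mean`, `<sp>_lower`, `<sp>_upper`.
#' @export
response_curve <- function(post, features, varying, substratum = NULL,
                           site = NULL, year = NULL, n_points = 50,
                           from = NULL, to = NULL, level = 0.95,
                           extrapolate = FALSE, max_draws = 400) {
  cont_col <- c(depth = "depth_m", boundary = "dist_boundary_m",
                diversity = paste0("H_", post$spec$diversity_radius),
                shore = "dist_shore_m", slope = "slope_deg",
                aspect = "aspect_deg")
  if (!varying %in% names(cont_col) || !varying %in% post$spec$terms) {
    stop("varying covariate must be a continuous term of the model")
  }
  obs <- features[[cont_col[[varying]]]]
  lo <- if (is.null(from)) min(obs) else from
  hi <- if (is.null(to)) max(obs) else to
  if (!extrapolate && (lo < min(obs) - 1e-9 || hi > max(obs) + 1e-9)) {
    stop("requested range extends beyond the observed range; set extrapolate = TRUE to override")
  }
  grid <- seq(lo, hi, length.out = n_points)
  if (is.null(substratum)) {
    substratum <- if ("substratum" %in% post$spec$terms) {
      post$constants$subst_levels
    } else NA_character_
  }
  p2 <- thin_posterior(post, max_draws)
  a <- (1 - level) / 2
  out <- list()
  for (cl in substratum) {
    newf <- data.frame(deployment_id = sprintf("G%03d", seq_along(grid)))
    for (nm in names(cont_col)) {
      col <- cont_col[[nm]]
      if (!is.null(features[[col]])) {
        newf[[col]] <- if (nm == varying) grid else mean(features[[col]])
      }
    }
    if (!is.na(cl)) newf$substratum <- cl
    design <- build_design_matrix(newf, post$spec, constants = post$constants)
    ld <- lambda_draws(p2, design$X,
                       site = if (!is.null(site)) rep(site, n_points),
                       year = if (!is.null(year)) rep(year, n_points))
    df <- data.frame(covariate = varying, value = grid,
                     substratum = cl, stringsAsFactors = FALSE)
    for (j in seq_len(post$J)) {
      sp <- post$species[j]
      df[[paste0(sp, "_mean")]] <- colMeans(ld[, , j])
      df[[paste0(sp, "_lower")]] <- apply(ld[, , j], 2L, stats::quantile, a)
      df[[paste0(sp, "_upper")]] <- apply(ld[, , j], 2L, stats::quantile, 1 - a)
    }
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  class(res) <- c("response_curve", "data.frame")
  res
}

# Per-draw lambda for new rows (draws x rows x species), random effects at
# the given levels, latent term at 0.
lambda_draws <- function(post, newX, site = NULL, year = NULL) {
  nnew <- nrow(newX)
  nd <- length(post$chains) * post$nkeep
  out <- array(NA_real_, c(nd, nnew, post$J))
  si <- if (!is.null(site)) match(as.character(site), levels(post$site))
  yi <- if (!is.null(year)) match(as.character(year), levels(post$year))
  d0 <- 0L
  for (ch in seq_along(post$chains)) {
    cobj <- post$chains[[ch]]
    for (d in seq_len(post$nkeep)) {
      B <- matrix(cobj$B[d, , ], post$p, post$J)
      eta <- newX %*% B
      if (!is.null(si) && !anyNA(si)) {
        eS <- matrix(cobj$eps_site[d, , ], ncol = post$J)
        eta <- eta + eS[si, , drop = FALSE]
      }
      if (!is.null(yi) && !anyNA(yi)) {
        eY <- matrix(cobj$eps_year[d, , ], ncol = post$J)
        eta <- eta + eY[yi, , drop = FALSE]
      }
      out[d0 + d, , ] <- exp(eta)
    }
    d0 <- d0 + post$nkeep
  }
  out
}

#' Percent of the study area where a species is predicted present
#'
#' Share (%) of unmasked prediction cells satisfying a presence rule.
#' The default rule calls a cell present when the Poisson occurrence
#' probability at the posterior-mean intensity, 1 - exp(-lambda), is at
#' least 0.5; the rule used is recorded on the result.
#'
#' @param pred a per-species [sea_raster] of predicted lambda, or a
#'   `prediction_raster` (then a named vector is returned).
#' @param rule function(lambda) -> logical; the presence rule.
#' @param rule_label description stored with the result.
#' @return percentage(s) of in-mask cells predicted present, attribute
#'   `rule` attached.
#' @export
percent_area_present <- function(pred,
                                 rule = function(l) 1 - exp(-l) >= 0.5,
                                 rule_label = "P(occurrence) = 1 - exp(-lambda) >= 0.5") {
  one <- function(r) {
    v <- r$values[!is.na(r$values)]
    if (length(v) == 0L) stop("prediction mask is empty")
    100 * mean(rule(v))
  }
  out <- if (inherits(pred, "prediction_raster")) {
    vapply(pred$lambda, one, numeric(1L))
  } else {
    one(pred)
  }
  structure(out, rule = rule_label)
}
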