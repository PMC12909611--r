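#' Default substratum class table
#'
#' Six seabed classes: four soft-sediment classes whose patches grade into one
#' another over wide "fuzzy" transition zones (classification cutoff 0.1), and
#' two hard classes with crisp edges (cutoff 0.25). `softness` controls the
#' width of the probability transition at patch edges (larger = fuzzier);
#' `depth_pref` is the depth (m) at which the class is most likely, used by
#' the generator to give each class a plausible bathymetric niche.
#'
#' @return data.frame with columns `class`, `hard`, `cutoff`, `softness`,
#'   `depth_pref`.
#' @export
default_class_table <- function() {
  data.frame(
    class = c("cobble_boulder", "gravel", "mud", "muddy_sand", "rock", "sand"),
    hard = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    cutoff = c(0.25, 0.1, 0.1, 0.1, 0.25, 0.1),
    softness = c(0.25, 0.8, 0.8, 0.8, 0.25, 0.8),
    depth_pref = c(15, 35, 90, 60, 8, 25),
    stringsAsFactors = FALSE
  )
}

#' Depth stratum boundaries
#'
#' The six survey design bands in metres (positive downward):
#' 0-9.9, 10-18.9, 19-29.9, 30-37.9, 38-49.9 and 50-116.
#' @return numeric vector of 7 band edges.
#' @export
default_strata <- function() c(0, 10, 19, 30, 38, 50, 116)

#' Configuration for the synthetic seascape generator
#'
#' Bundles the raster geometry, substratum class table, depth-stratified
#' deployment design and seed for [generate_bathymetry()],
#' [generate_substratum_probabilities()] and [sample_deployments()].
#'
#' @param nx,ny raster dimensions (columns, rows).
#' @param cellsize cell edge (m); default 25.
#' @param depth_max deepest in-design depth (m); default 116.
#' @param classes substratum class table, see [default_class_table()].
#' @param strata depth band edges (m), strictly increasing.
#' @param n_per_stratum deployments per depth stratum per site-year group.
#' @param site_years data.frame with columns `site`, `year` — one row per
#'   site-year survey; default two sites and up to three years.
#' @param field_sigma smoothing length (cells) of the generator's random
#'   fields.
#' @param seed master seed; per-stage substreams are derived from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(nx = 120, ny = 80, cellsize = 25, depth_max = 116,
                             classes = default_class_table(),
                             strata = default_strata(),
                             n_per_stratum = 20,
                             site_years = data.frame(
                               site = c("A", "A", "B", "B", "A"),
                               year = c(2021, 2022, 2022, 2023, 2023)
                             ),
                             field_sigma = 6, seed = 1) {
  stopifnot(nx >= 8, ny >= 8, cellsize > 0, depth_max > 0,
            n_per_stratum >= 1, nrow(classes) >= 1)
  if (any(diff(strata) <= 0)) stop("strata edges must be strictly increasing")
  if (strata[1] != 0) stop("strata must start at depth 0")
  structure(
    list(nx = nx, ny = ny, cellsize = cellsize, depth_max = depth_max,
         classes = classes, strata = strata, n_per_stratum = n_per_stratum,
         site_years = site_years, field_sigma = field_sigma, seed = seed),
    class = "synthetic_config"
  )
}

# Fixed offsets expanding the master seed into independent substreams so each
# stage can be regenerated on its own.
substream_seed <- function(master, stage) {
  offs <- c(bathy = 11L, subst = 23L, deploy = 37L, counts = 53L)
  (as.integer(master) %% 2000000000L) + offs[[stage]]
}

# Gaussian-smoothed white noise with edge replication, standardised to
# mean 0 / sd 1. sigma in cells.
smooth_noise <- function(nr, nc, sigma) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  m <- gauss_smooth(m, sigma)
  (m - mean(m)) / stats::sd(m)
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1L], half), v, rep(v[length(v)], half))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(m, 1L, pad_conv))
}

#' Generate a synthetic bathymetry raster
#'
#' A smooth depth field (m, positive downward) deepening away from a
#' shoreline along the northern edge, with low-pass-filtered noise
#' superimposed. Cells shallower than the waterline are land (`NA`), giving a
#' study-area mask with a shoreline. The field spans the full design depth
#' range so that every depth stratum is populated.
#'
#' @param config a [synthetic_config()].
#' @return a [sea_raster] of depth; `NA` = land / outside study area.
#' @export
generate_bathymetry <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "bathy"))
  nr <- config$ny; nc <- config$nx
  # fraction of the way from the north (shore) edge to the south edge
  frac <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
  noise <- smooth_noise(nr, nc, config$field_sigma)
  # waterline offset pushes the top rows above water -> land strip
  depth <- config$depth_max * 1.12 * frac^1.25 +
    0.06 * config$depth_max * noise - 0.03 * config$depth_max
  depth[depth < 0] <- NA_real_
  depth[depth > config$depth_max] <- config$depth_max
  if (all(is.na(depth[1L, ]) == FALSE)) {
    # guarantee some land so a shoreline exists
    depth[1L, ] <- NA_real_
  }
  r <- sea_raster(depth, xll = 0, yll = 0, cellsize = config$cellsize)
  n_strata <- length(config$strata) - 1L
  counts <- tabulate(assign_depth_stratum(depth[!is.na(depth)],
                                          strata = config$strata), n_strata)
  if (any(counts == 0L)) {
    stop("extent too small: depth stratum ", which(counts == 0L)[1L],
         " contains no cells")
  }
  r
}

#' Generate fuzzy substratum probability rasters
#'
#' One probability surface per substratum class on the bathymetry grid. Each
#' class gets a smooth spatial potential (smoothed noise plus an affinity for
#' its preferred depth); per cell the potential is compared with the
#' second-highest potential among classes and squashed through a logistic
#' whose width is the class `softness`. The locally strongest one or two
#' classes therefore carry high probability while the rest fall away, classes
#' overlap in transition zones, and soft-sediment classes (large softness)
#' show wide fuzzy edges while rock/cobble edges are crisp. Probabilities do
#' not sum to 1 across classes.
#'
#' @param bathy bathymetry [sea_raster] from [generate_bathymetry()].
#' @param config the same [synthetic_config()].
#' @return list of class `substratum_raster`: `classes` (class table),
#'   `probs` (named list of [sea_raster]), `bathy` grid geometry.
#' @export
generate_substratum_probabilities <- function(bathy, config) {
  stopifnot(inherits(config, "synthetic_config"))
  cls <- config$classes
  if (nrow(cls) == 0L) stop("class list is empty")
  set.seed(substream_seed(config$seed, "subst"))
  nr <- nrow(bathy$values); nc <- ncol(bathy$values)
  depth <- bathy$values
  dscale <- config$depth_max
  pot <- vector("list", nrow(cls))
  for (k in seq_len(nrow(cls))) {
    aff <- -((depth - cls$depth_pref[k]) / (0.45 * dscale))^2
    aff[is.na(aff)] <- 0
    pot[[k]] <- 3 * smooth_noise(nr, nc, config$field_sigma) + 1.5 * aff
  }
  # each class is squashed against the strongest of the OTHER classes, so the
  # locally best class sits above 0.5 and the rest fall away from boundaries
  K <- nrow(cls)
  best <- pot[[1L]]; best_k <- matrix(1L, nr, nc); second_best <- matrix(-Inf, nr, nc)
  if (K > 1L) {
    for (k in 2L:K) {
      upd <- pot[[k]] > best
      second_best[upd] <- best[upd]
      second_best[!upd] <- pmax(second_best[!upd], pot[[k]][!upd])
      best[upd] <- pot[[k]][upd]
      best_k[upd] <- k
    }
  }
  probs <- vector("list", K)
  names(probs) <- cls$class
  for (k in seq_len(K)) {
    other_max <- best
    own_best <- best_k == k
    other_max[own_best] <- second_best[own_best]
    p <- stats::plogis((pot[[k]] - other_max) / cls$softness[k])
    p[is.na(depth)] <- NA_real_
    probs[[k]] <- sea_raster(p, xll = bathy$xll, yll = bathy$yll,
                             cellsize = bathy$cellsize)
  }
  structure(list(classes = cls, probs = probs), class = "substratum_raster")
}

#' Sample a depth-stratified deployment design
#'
#' Places baited-video deployments by drawing, for every site-year survey and
#' every depth stratum, an equal number of in-mask cells whose depth falls in
#' the stratum band (without replacement within a survey). Sites are the west
#' (A) and east (B) halves of the raster.
#'
#' @param bathy bathymetry [sea_raster].
#' @param config a [synthetic_config()].
#' @return data.frame of class `deployment_table`: `deployment_id`, `site`,
#'   `year`, `x`, `y`, `depth_m`, `stratum`.
#' @export
sample_deployments <- function(bathy, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "deploy"))
  v <- bathy$values
  nr <- nrow(v); nc <- ncol(v)
  cc <- cell_centres(bathy)
  half <- ceiling(nc / 2)
  site_of_col <- ifelse(seq_len(nc) <= half, "A", "B")
  n_strata <- length(config$strata) - 1L
  ok <- which(!is.na(v))
  rows <- ((ok - 1L) %% nr) + 1L
  cols <- ((ok - 1L) %/% nr) + 1L
  strat <- assign_depth_stratum(v[ok], strata = config$strata)
  out <- list()
  for (g in seq_len(nrow(config$site_years))) {
    site <- config$site_years$site[g]
    year <- config$site_years$year[g]
    in_site <- site_of_col[cols] == site
    for (s in seq_len(n_strata)) {
      cand <- which(in_site & strat == s)
      if (length(cand) < config$n_per_stratum) {
        stop("stratum ", s, " (site ", site, ", year ", year, ") has only ",
             length(cand), " eligible cells; ", config$n_per_stratum,
             " deployments requested")
      }
      pick <- sample(cand, config$n_per_stratum)
      out[[length(out) + 1L]] <- data.frame(
        site = site, year = year,
        x = cc$x[cols[pick]], y = cc$y[rows[pick]],
        depth_m = v[ok[pick]], stratum = s,
        stringsAsFactors = FALSE
      )
    }
  }
  d <- do.call(rbind, out)
  d <- cbind(deployment_id = sprintf("D%04d", seq_len(nrow(d))), d,
             stringsAsFactors = FALSE)
  class(d) <- c("deployment_table", "data.frame")
  d
}

#' Ground-truth parameters for the count simulator
#'
#' @param species character vector of species names (length J).
#' @param alpha per-species log-scale intercepts (length J).
#' @param beta coefficient matrix, columns per species (p x J), rows matching
#'   the non-intercept columns of the design matrix the counts will be
#'   simulated from; may have 0 rows for an intercept-only truth.
#' @param sd_site,sd_year standard deviations (log scale, >= 0) of the
#'   species-specific site and year random intercepts.
#' @param V latent-factor loading matrix (J x q); NULL or 0 columns for no
#'   residual factor.
#' @return list of class `true_parameters`.
#' @export
true_parameters <- function(species, alpha, beta = NULL, sd_site = 0,
                            sd_year = 0, V = NULL) {
  J <- length(species)
  stopifnot(length(alpha) == J, sd_site >= 0, sd_year >= 0)
  if (is.null(beta)) beta <- matrix(0, 0, J)
  beta <- as.matrix(beta)
  if (ncol(beta) != J) stop("beta must have one column per species")
  if (!is.null(V)) {
    V <- as.matrix(V)
    if (nrow(V) != J) stop("V must have one row per species")
  }
  structure(list(species = species, alpha = alpha, beta = beta,
                 sd_site = sd_site, sd_year = sd_year, V = V),
            class = "true_parameters")
}

#' Simulate Poisson counts from the joint model
#'
#' Draws MaxN-style counts y_ij ~ Poisson(lambda_ij) with
#' log lambda_ij = alpha_j + x_i' beta_j + eps_site + eps_year + u_i' v_j.
#' Site/year random intercepts (species-specific) and latent scores are drawn
#' fresh for each call from their generative distributions.
#'
#' @param design a `design_matrix` from [build_design_matrix()] (its
#'   non-intercept columns must match `params$beta` rows) or a plain numeric
#'   matrix of covariates.
#' @param params a [true_parameters()] object.
#' @param site,year factors of length n giving each deployment's grouping;
#'   taken from the design's deployment table if omitted.
#' @param seed integer seed for this replicate.
#' @return n x J integer count matrix (deployments x species) with attributes
#'   `eta` (linear predictor), `lambda`, `eps_site`, `eps_year`, `U`, `site`,
#'   `year`.
#' @export
simulate_counts <- function(design, params, site = NULL, year = NULL,
                            seed = 1) {
  X <- design_covariates(design)
  n <- nrow(X)
  J <- length(params$species)
  if (nrow(params$beta) != ncol(X)) {
    stop("design has ", ncol(X), " covariate columns but beta has ",
         nrow(params$beta), " rows")
  }
  if (is.null(site)) site <- factor(rep("A", n)) else site <- factor(site)
  if (is.null(year)) year <- factor(rep(1L, n)) else year <- factor(year)
  set.seed(as.integer(seed))
  eta <- matrix(rep(params$alpha, each = n), n, J)
  if (ncol(X) > 0L) eta <- eta + X %*% params$beta
  eS <- matrix(stats::rnorm(nlevels(site) * J, 0, params$sd_site),
               nlevels(site), J)
  eY <- matrix(stats::rnorm(nlevels(year) * J, 0, params$sd_year),
               nlevels(year), J)
  eta <- eta + eS[as.integer(site), , drop = FALSE] +
    eY[as.integer(year), , drop = FALSE]
  U <- NULL
  if (!is.null(params$V) && ncol(params$V) > 0L) {
    q <- ncol(params$V)
    U <- matrix(stats::rnorm(n * q), n, q)
    eta <- eta + U %*% t(params$V)
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  lambda <- exp(eta)
  if (any(!is.finite(lambda))) {
    stop("non-finite intensity: linear predictor overflows exp()")
  }
  y <- matrix(stats::rpois(n * J, lambda), n, J)
  dimnames(y) <- list(rownames(X), params$species)
  structure(y, eta = eta, lambda = lambda, eps_site = eS, eps_year = eY,
            U = U, site = site, year = year)
}

# Covariate matrix (no intercept column) from a design_matrix or plain matrix.
design_covariates <- function(design) {
  if (inherits(design, "design_matrix")) {
    X <- design$X[, design$terms != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(design)
  }
  X
}
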