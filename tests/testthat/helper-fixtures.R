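# Shared fixtures, all generated in code.

# A small but fully-featured seascape: rasters, patch map, deployments and
# per-deployment covariates. Memoised per (seed, n_per_stratum) because
# several test files reuse the same seascape.
.seascape_cache <- new.env(parent = emptyenv())
tiny_seascape <- function(seed = 7, n_per_stratum = 4, nx = 60, ny = 40,
                          radii = 500) {
  key <- paste(seed, n_per_stratum, nx, ny, paste(radii, collapse = "_"),
               sep = "|")
  if (!is.null(.seascape_cache[[key]])) return(.seascape_cache[[key]])
  cfg <- synthetic_config(
    nx = nx, ny = ny, n_per_stratum = n_per_stratum,
    site_years = data.frame(site = c("A", "A", "B"),
                            year = c(2021, 2022, 2022)),
    seed = seed
  )
  bathy <- generate_bathymetry(cfg)
  subst <- generate_substratum_probabilities(bathy, cfg)
  pm <- classify_patches(subst)
  deps <- sample_deployments(bathy, cfg)
  feats <- deployment_features(deps, pm, bathy, radii = radii)
  out <- list(config = cfg, bathy = bathy, subst = subst, pm = pm,
              deps = deps, feats = feats)
  .seascape_cache[[key]] <- out
  out
}

quick_settings <- function(seed = 1, chains = 1, iterations = 800,
                           burnin = 300) {
  mcmc_settings(chains = chains, iterations = iterations, burnin = burnin,
                seed = seed)
}

# Random single-label substratum surfaces over a given dominant-class map:
# the chosen class gets probability 0.95, the rest 0.01, so classification
# is known by construction.
subst_from_dominant <- function(dom, classes = letters[seq_len(max(dom, na.rm = TRUE))],
                                cellsize = 25) {
  probs <- lapply(seq_along(classes), function(k) {
    p <- matrix(0.01, nrow(dom), ncol(dom))
    p[!is.na(dom) & dom == k] <- 0.95
    p[is.na(dom)] <- NA_real_
    p
  })
  names(probs) <- classes
  ct <- data.frame(class = classes, hard = FALSE, cutoff = 0.1,
                   softness = 0.8, depth_pref = NA_real_)
  substratum_raster(probs, ct, cellsize = cellsize)
}

# Random fuzzy surfaces (possibly multi-label after cutoffs).
random_subst <- function(nr, nc, K = 3, seed = 1, cellsize = 25,
                         mask_frac = 0) {
  set.seed(seed)
  probs <- lapply(seq_len(K), function(k) {
    matrix(runif(nr * nc), nr, nc)
  })
  if (mask_frac > 0) {
    drop <- matrix(runif(nr * nc) < mask_frac, nr, nc)
    probs <- lapply(probs, function(p) { p[drop] <- NA_real_; p })
  }
  names(probs) <- paste0("c", seq_len(K))
  ct <- data.frame(class = names(probs), hard = FALSE,
                   cutoff = runif(K, 0.3, 0.6), softness = 0.8,
                   depth_pref = NA_real_)
  substratum_raster(probs, ct, cellsize = cellsize)
}

# Plain feature table (no rasters) for design-matrix level tests.
fake_features <- function(n = 60, classes = c("mud", "rock", "sand"),
                          seed = 1) {
  set.seed(seed)
  data.frame(
    deployment_id = sprintf("d%03d", seq_len(n)),
    site = sample(c("A", "B"), n, replace = TRUE),
    year = sample(2021:2022, n, replace = TRUE),
    depth_m = runif(n, 1, 110),
    substratum = sample(classes, n, replace = TRUE),
    dist_boundary_m = rexp(n, 1 / 80),
    dist_shore_m = runif(n, 25, 2000),
    slope_deg = runif(n, 0, 15),
    aspect_deg = runif(n, 0, 360),
    H_500 = runif(n, 0, log(4)),
    H_1000 = runif(n, 0, log(4)),
    stringsAsFactors = FALSE
  )
}

# Minimal hand-built posterior container with constant draws, for
# closed-form WAIC / variance-partition / prediction checks.
constant_posterior <- function(B, n, si = rep(1L, n), yi = rep(1L, n),
                               nkeep = 2L, species = NULL, V = NULL,
                               U = NULL, spec = NULL, constants = NULL,
                               site = NULL, year = NULL) {
  p <- nrow(B); J <- ncol(B)
  q <- if (is.null(V)) 0L else ncol(V)
  nS <- max(si); nY <- max(yi)
  rep_arr <- function(m, d1, d2) {
    a <- array(NA_real_, c(nkeep, d1, d2))
    for (d in seq_len(nkeep)) a[d, , ] <- m
    a
  }
  ch <- list(
    B = rep_arr(B, p, J),
    eps_site = rep_arr(matrix(0, nS, J), nS, J),
    eps_year = rep_arr(matrix(0, nY, J), nY, J),
    U = if (q > 0L) rep_arr(U, n, q) else NULL,
    V = if (q > 0L) rep_arr(V, J, q) else NULL,
    sigma = matrix(1, nkeep, 3,
                   dimnames = list(NULL, c("site", "year", "loading"))),
    loglik = rep(NA_real_, nkeep)
  )
  structure(
    list(chains = list(ch), species = species %||% paste0("sp", seq_len(J)),
         n = n, p = p, J = J, q = q, colnames = rownames(B),
         terms = rownames(B) %||% rep("", p),
         site = site, year = year,
         use_site = FALSE, use_year = FALSE, si = si, yi = yi,
         constants = constants, spec = spec,
         settings = NULL, priors = NULL, nkeep = nkeep,
         accept_rate = NA_real_),
    class = "posterior_samples"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gauss_smooth_for_tests <- function(m, sigma) seajsdm:::gauss_smooth(m, sigma)

# Brute-force oracles -------------------------------------------------------

oracle_boundary_mask <- function(pm) {
  nr <- pm$nrow; nc <- pm$ncol
  dom <- pm$dominant
  nlab <- apply(pm$labels, c(1, 2), sum)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dom[r, c])) next
    if (nlab[r, c] >= 2) { out[r, c] <- TRUE; next }
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!pm$mask[r2, c2]) next
      if (is.na(dom[r2, c2]) || dom[r2, c2] != dom[r, c]) {
        out[r, c] <- TRUE
        break
      }
    }
  }
  out
}

oracle_min_dist <- function(cells_mask, geom, x, y) {
  nr <- if (!is.null(geom$nrow)) geom$nrow else nrow(geom$values)
  cs <- geom$cellsize
  idx <- which(cells_mask)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  cx <- geom$xll + (cols - 0.5) * cs
  cy <- geom$yll + (nr - rows + 0.5) * cs
  best <- Inf
  for (i in seq_along(cx)) {
    best <- min(best, sqrt((cx[i] - x)^2 + (cy[i] - y)^2))
  }
  best
}

oracle_shannon <- function(pm, x, y, radius) {
  nr <- pm$nrow; nc <- pm$ncol; cs <- pm$cellsize
  cnt <- integer(length(pm$classes))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- pm$dominant[r, c]
    if (is.na(k)) next
    cx <- pm$xll + (c - 0.5) * cs
    cy <- pm$yll + (nr - r + 0.5) * cs
    if ((cx - x)^2 + (cy - y)^2 <= radius^2) cnt[k] <- cnt[k] + 1
  }
  if (sum(cnt) == 0) return(NA_real_)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}
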