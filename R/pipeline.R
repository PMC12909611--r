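#' Read aligned substratum probability rasters
#'
#' @param paths named character vector (class name -> ASCII grid file) or a
#'   data.frame with columns `class`, `path`.
#' @param class_table class metadata table (see [default_class_table()]);
#'   rows are matched to `paths` by class name.
#' @return a `substratum_raster`.
#' @export
read_substratum_rasters <- function(paths, class_table = default_class_table()) {
  if (is.data.frame(paths)) paths <- stats::setNames(paths$path, paths$class)
  cls <- class_table[class_table$class %in% names(paths), , drop = FALSE]
  missing <- setdiff(names(paths), cls$class)
  if (length(missing)) stop("classes missing from class table: ",
                            paste(missing, collapse = ", "))
  probs <- lapply(cls$class, function(cl) read_asc(paths[[cl]]))
  names(probs) <- cls$class
  ref <- probs[[1L]]
  for (cl in cls$class) {
    if (!same_grid(probs[[cl]], ref)) {
      stop("raster for class ", cl, " (", paths[[cl]],
           ") is not aligned with ", paths[[1L]])
    }
    v <- probs[[cl]]$values
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("probabilities outside [0,1] in ", paths[[cl]])
    }
  }
  structure(list(classes = cls, probs = probs), class = "substratum_raster")
}

#' Read and validate a deployment table
#'
#' @param path CSV with columns deployment_id, site, year, x, y, depth_m
#'   (stratum optional).
#' @return a `deployment_table` data.frame.
#' @export
read_deployments <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deployment_id", "site", "year", "x", "y", "depth_m")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("deployment table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$deployment_id)) stop("duplicate deployment ids")
  if (any(d$depth_m < 0)) stop("negative depths")
  class(d) <- c("deployment_table", "data.frame")
  d
}

#' Read and validate a MaxN count matrix
#'
#' @param path CSV: first column `deployment_id`, one column per species.
#' @return integer matrix (deployments x species) with rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "deployment_id") {
    stop("first column must be deployment_id")
  }
  if (anyDuplicated(d$deployment_id)) stop("duplicate deployment ids")
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(m < 0)) stop("negative MaxN counts")
  if (any(m != floor(m))) stop("non-integer MaxN counts")
  storage.mode(m) <- "integer"
  rownames(m) <- d$deployment_id
  m
}

#' Write a count matrix as CSV
#'
#' @param counts matrix with deployment rownames.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(deployment_id = rownames(counts), counts,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration, fills defaults, and validates that every
#' referenced input file exists (so a bad path fails at load, not
#' mid-run).
#'
#' @param path YAML file, or a list with the same structure.
#' @return list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    seed = 1,
    simulate = list(enabled = TRUE, nx = 90, ny = 60, cellsize = 25,
                    n_per_stratum = 8, n_species = 6, n_years = 2),
    inputs = list(),
    radii = c(500, 1000, 1500),
    filter = list(fraction = 0.10, mode = "any"),
    model = list(terms = c("substratum", "depth", "boundary", "diversity"),
                 n_factors = 2, random = c("site", "year"),
                 diversity_radius = 500),
    priors = list(beta_var = 1e4, shape = 0.1, rate = 0.1),
    mcmc = list(chains = 2, iterations = 2000, burnin = 800, thin = 2),
    evaluate = list(cv_folds = 0, select_radius = FALSE),
    predict = list(enabled = TRUE, site = NULL, year = NULL, max_draws = 100)
  )
  merge_in <- function(def, got) {
    for (nm in names(got)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(got[[nm]])) {
        merge_in(def[[nm]], got[[nm]])
      } else got[[nm]]
    }
    def
  }
  cfg <- merge_in(defaults, cfg)
  if (!isTRUE(cfg$simulate$enabled)) {
    need <- c("bathymetry", "deployments", "counts")
    for (nm in need) {
      f <- cfg$inputs[[nm]]
      if (is.null(f)) stop("config inputs$", nm, " required when not simulating")
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
    for (f in unlist(cfg$inputs$substratum)) {
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
  }
  structure(cfg, class = "run_config")
}

#' Plausible ground-truth parameters for a synthetic community
#'
#' Draws species intercepts around typical baited-video MaxN levels, modest
#' covariate responses, small site/year intercept SDs, and latent loadings
#' of mixed sign, for a design's column layout.
#'
#' @param design a `design_matrix`.
#' @param species species names.
#' @param n_factors latent rank of the truth.
#' @param seed RNG seed.
#' @return a [true_parameters()] object.
#' @export
default_true_parameters <- function(design, species, n_factors = 2, seed = 1) {
  set.seed(as.integer(seed))
  J <- length(species)
  pnb <- sum(design$terms != "(Intercept)")
  true_parameters(
    species = species,
    alpha = stats::rnorm(J, log(1.5), 0.5),
    beta = matrix(stats::rnorm(pnb * J, 0, 0.35), pnb, J),
    sd_site = 0.25, sd_year = 0.3,
    V = if (n_factors > 0) matrix(stats::rnorm(J * n_factors, 0, 0.5),
                                  J, n_factors) else NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end — simulate (optional), seascape metrics,
#' rarity filter, radius selection (optional), fit, diagnostics,
#' cross-validation (optional), residual associations, gridded prediction —
#' writing each stage's artifact (CSV / ASCII grid) plus a JSON manifest
#' with the seeds, settings and config hash to the output directory. A
#' rerun with the same config reproduces every artifact.
#'
#' @param config a [run_config()] (or path to one).
#' @param outdir output directory (created if needed).
#' @param verbose log stage progress.
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage ", name, " done")
    out
  }
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  artifacts <- character(0)
  mark <- function(path) artifacts <<- c(artifacts, path)

  if (isTRUE(config$simulate$enabled)) {
    sim <- stage("simulate", {
      sy <- data.frame(
        site = rep(c("A", "B"), each = config$simulate$n_years),
        year = rep(2021 + seq_len(config$simulate$n_years) - 1L, 2)
      )
      sc <- synthetic_config(
        nx = config$simulate$nx, ny = config$simulate$ny,
        cellsize = config$simulate$cellsize,
        n_per_stratum = config$simulate$n_per_stratum,
        site_years = sy, seed = config$seed
      )
      bathy <- generate_bathymetry(sc)
      subst <- generate_substratum_probabilities(bathy, sc)
      deps <- sample_deployments(bathy, sc)
      list(sc = sc, bathy = bathy, subst = subst, deps = deps)
    })
    bathy <- sim$bathy; subst <- sim$subst; deps <- sim$deps
    write_asc(bathy, file.path(outdir, "bathymetry.asc")); mark("bathymetry.asc")
    for (cl in names(subst$probs)) {
      f <- paste0("substratum_", cl, ".asc")
      write_asc(subst$probs[[cl]], file.path(outdir, f)); mark(f)
    }
  } else {
    bathy <- read_asc(config$inputs$bathymetry)
    subst <- read_substratum_rasters(unlist(config$inputs$substratum))
    deps <- read_deployments(config$inputs$deployments)
  }

  pm <- stage("metrics", classify_patches(subst))
  feats <- stage("features",
                 deployment_features(deps, pm, bathy, radii = config$radii))
  utils::write.csv(feats, file.path(outdir, "deployment_features.csv"),
                   row.names = FALSE)
  mark("deployment_features.csv")

  spec <- do.call(model_spec, config$model)
  if (isTRUE(config$simulate$enabled)) {
    counts <- stage("counts", {
      design0 <- build_design_matrix(feats, spec)
      truth <- default_true_parameters(
        design0, species = paste0("species_", seq_len(config$simulate$n_species)),
        n_factors = spec$n_factors, seed = substream_seed(config$seed, "counts")
      )
      simulate_counts(design0, truth, site = feats$site, year = feats$year,
                      seed = substream_seed(config$seed, "counts"))
    })
    write_counts(counts, file.path(outdir, "counts.csv")); mark("counts.csv")
  } else {
    counts <- read_counts(config$inputs$counts)
    counts <- counts[deps$deployment_id, , drop = FALSE]
  }

  filt <- stage("filter", filter_rare_species(
    counts, site = feats$site, year = feats$year,
    fraction = config$filter$fraction, mode = config$filter$mode
  ))
  utils::write.csv(filt$report, file.path(outdir, "rarity_filter.csv"),
                   row.names = FALSE)
  mark("rarity_filter.csv")
  say("retained ", length(filt$retained), " of ", ncol(counts), " species")
  counts <- filt$counts
  if (ncol(counts) < 2L) stop("fewer than 2 species survive the rarity filter")

  accum <- stage("accumulation",
                 species_accumulation(counts, n_permutations = 50,
                                      seed = config$seed))
  utils::write.csv(
    data.frame(n = accum$n, mean_richness = accum$mean_richness,
               exact = accum$exact),
    file.path(outdir, "species_accumulation.csv"), row.names = FALSE
  )
  mark("species_accumulation.csv")

  priors <- prior_spec(beta_var = config$priors$beta_var,
                       shape = config$priors$shape, rate = config$priors$rate)
  settings <- mcmc_settings(chains = config$mcmc$chains,
                            iterations = config$mcmc$iterations,
                            burnin = config$mcmc$burnin,
                            thin = config$mcmc$thin, seed = config$seed)

  if (isTRUE(config$evaluate$select_radius)) {
    rad <- stage("select_radius", select_diversity_radius(
      counts, feats, radii = config$radii, priors = priors,
      settings = mcmc_settings(chains = 1,
                               iterations = max(600, settings$iterations %/% 2),
                               burnin = max(200, settings$burnin %/% 2),
                               seed = config$seed),
      seed = config$seed
    ))
    spec$diversity_radius <- as.numeric(rad)
    say("selected diversity radius ", spec$diversity_radius, " m")
  }

  design <- build_design_matrix(feats, spec)
  if (sum(design$terms != "(Intercept)") >= 2L) {
    v <- stage("vif", vif(design))
    utils::write.csv(data.frame(column = names(v), vif = v),
                     file.path(outdir, "vif.csv"), row.names = FALSE)
    mark("vif.csv")
  }

  post <- stage("fit", sample_posterior(counts, design, priors, settings))
  for (blk in c("B", "V", "sigma")) {
    if (blk == "V" && post$q == 0L) next
    d <- posterior_draws(post, blk)
    utils::write.csv(as.data.frame(d),
                     file.path(outdir, paste0("draws_", blk, ".csv")),
                     row.names = FALSE)
    mark(paste0("draws_", blk, ".csv"))
  }

  diag_df <- stage("diagnostics", diagnose_posterior(post))
  utils::write.csv(diag_df, file.path(outdir, "diagnostics.csv"),
                   row.names = FALSE)
  mark("diagnostics.csv")

  w <- stage("waic", waic(post, counts, design$X))
  vp <- stage("variance_partition", variance_partition(post, design))
  utils::write.csv(data.frame(species = rownames(vp), vp, check.names = FALSE),
                   file.path(outdir, "variance_partition.csv"),
                   row.names = FALSE)
  mark("variance_partition.csv")

  cv <- NULL
  if (config$evaluate$cv_folds >= 2L) {
    cv <- stage("cv", kfold_cv(
      counts, feats, spec, k = config$evaluate$cv_folds, priors = priors,
      settings = mcmc_settings(chains = 1,
                               iterations = max(600, settings$iterations %/% 2),
                               burnin = max(200, settings$burnin %/% 2),
                               seed = config$seed),
      seed = config$seed
    ))
    utils::write.csv(
      data.frame(species = names(cv$rmse), rmse = cv$rmse,
                 range_min = cv$range[1L, ], range_max = cv$range[2L, ],
                 relative_rmse = cv$relative_rmse),
      file.path(outdir, "cv_rmse.csv"), row.names = FALSE
    )
    mark("cv_rmse.csv")
  }

  assoc <- NULL
  if (post$q > 0L) {
    assoc <- stage("associations", {
      R <- residual_correlation_draws(post)
      screen_associations(R)
    })
    utils::write.csv(association_table(assoc),
                     file.path(outdir, "associations.csv"), row.names = FALSE)
    mark("associations.csv")
  }

  pred <- NULL
  if (isTRUE(config$predict$enabled)) {
    cond_site <- config$predict$site %||% levels(design$site)[1L]
    cond_year <- config$predict$year %||% levels(design$year)[1L]
    pred <- stage("predict", predict_grid(
      post, pm, bathy, site = cond_site, year = cond_year,
      max_draws = config$predict$max_draws
    ))
    area <- percent_area_present(pred)
    utils::write.csv(
      data.frame(species = names(area), percent_area = as.numeric(area),
                 rule = attr(area, "rule")),
      file.path(outdir, "percent_area_present.csv"), row.names = FALSE
    )
    mark("percent_area_present.csv")
    for (sp in names(pred$lambda)) {
      f <- paste0("prediction_", sp, ".asc")
      write_asc(pred$lambda[[sp]], file.path(outdir, f)); mark(f)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("seajsdm")),
    r_version = R.version.string,
    seed = config$seed,
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    mcmc = config$mcmc,
    chain_seeds = vapply(seq_len(settings$chains), chain_seed,
                         integer(1L), master = settings$seed),
    species = post$species,
    waic = w$waic,
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: ", length(artifacts), " artifacts")
  invisible(list(bathy = bathy, subst = subst, patch_map = pm,
                 features = feats, counts = counts, filter = filt,
                 accumulation = accum, design = design, posterior = post,
                 waic = w, variance_partition = vp, cv = cv,
                 associations = assoc, prediction = pred))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
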