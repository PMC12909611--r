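#' Bundle aligned probability surfaces into a substratum raster
#'
#' @param probs named list of [sea_raster] probability surfaces (one per
#'   class, values in \[0,1\]) or bare matrices sharing a grid.
#' @param class_table class metadata with at least `class` and `cutoff`
#'   columns; defaults to [default_class_table()] rows matching `probs`.
#' @param xll,yll,cellsize grid geometry used when `probs` holds bare
#'   matrices.
#' @return object of class `substratum_raster`.
#' @export
substratum_raster <- function(probs, class_table = NULL, xll = 0, yll = 0,
                              cellsize = 25) {
  stopifnot(length(probs) >= 1L, !is.null(names(probs)))
  probs <- lapply(probs, function(p) {
    if (inherits(p, "sea_raster")) p else sea_raster(p, xll, yll, cellsize)
  })
  if (is.null(class_table)) {
    dft <- default_class_table()
    class_table <- dft[match(names(probs), dft$class), , drop = FALSE]
    if (anyNA(class_table$class)) {
      class_table <- data.frame(class = names(probs), hard = FALSE,
                                cutoff = 0.1, softness = 0.8,
                                depth_pref = NA_real_)
    }
  }
  ref <- probs[[1L]]
  for (nm in names(probs)) {
    if (!same_grid(probs[[nm]], ref)) stop("misaligned grid for class ", nm)
    v <- probs[[nm]]$values
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("probabilities outside [0,1] for class ", nm)
    }
  }
  class_table <- class_table[match(names(probs), class_table$class), ,
                             drop = FALSE]
  structure(list(classes = class_table, probs = probs),
            class = "substratum_raster")
}

#' Classify substratum patches from probability surfaces
#'
#' Applies per-class probability cutoffs to fuzzy substratum surfaces: a cell
#' is labelled with every class whose probability meets its cutoff (0.25 for
#' hard-edged rock/cobble, 0.1 for soft-sediment classes by default, so that
#' gradual "fuzzy" transitions between soft classes survive classification),
#' and its dominant class is the labelled class of highest probability.
#'
#' @param subst a `substratum_raster` (see
#'   [generate_substratum_probabilities()] / [read_substratum_rasters()]).
#' @param cutoffs named numeric vector of per-class cutoffs in (0,1);
#'   defaults to the `cutoff` column of the class table.
#' @return list of class `patch_map`: `labels` (nr x nc x K logical array),
#'   `dominant` (integer matrix, NA where no class passes its cutoff or
#'   outside the study area), `boundary` (logical matrix from
#'   [patch_boundary_cells()]), `classes`, `cutoffs`, and the grid geometry
#'   (`xll`, `yll`, `cellsize`, `mask`).
#' @export
classify_patches <- function(subst, cutoffs = NULL) {
  cls <- subst$classes$class
  if (is.null(cutoffs)) {
    cutoffs <- stats::setNames(subst$classes$cutoff, cls)
  }
  missing <- setdiff(cls, names(cutoffs))
  if (length(missing)) stop("missing cutoff for class: ", paste(missing, collapse = ", "))
  if (any(cutoffs[cls] <= 0 | cutoffs[cls] >= 1)) stop("cutoffs must lie in (0,1)")
  g <- subst$probs[[1L]]
  nr <- nrow(g$values); nc <- ncol(g$values); K <- length(cls)
  labels <- array(FALSE, c(nr, nc, K), dimnames = list(NULL, NULL, cls))
  best_p <- matrix(-Inf, nr, nc)
  dominant <- matrix(NA_integer_, nr, nc)
  mask <- !is.na(g$values)
  for (k in seq_len(K)) {
    p <- subst$probs[[cls[k]]]$values
    if (!same_grid(subst$probs[[cls[k]]], g)) stop("misaligned grid for class ", cls[k])
    lab <- !is.na(p) & p >= cutoffs[[cls[k]]]
    labels[, , k] <- lab
    upd <- lab & p > best_p
    best_p[upd] <- p[upd]
    dominant[upd] <- k
  }
  pm <- structure(
    list(labels = labels, dominant = dominant, boundary = NULL,
         classes = cls, cutoffs = cutoffs[cls], mask = mask,
         xll = g$xll, yll = g$yll, cellsize = g$cellsize,
         nrow = nr, ncol = nc),
    class = "patch_map"
  )
  pm$boundary <- patch_boundary_cells(pm)
  pm
}

#' Patch boundary cells
#'
#' A labelled cell is a boundary cell iff it touches (4-neighbourhood) an
#' in-study-area cell with a different dominant class or with an empty label
#' set, or its own label set holds two or more classes (an overlap / fuzzy
#' transition zone). Cells outside the study area never create boundaries:
#' the shoreline is not a patch boundary.
#'
#' @param pm a `patch_map` from [classify_patches()].
#' @return logical matrix, TRUE at boundary cells.
#' @export
patch_boundary_cells <- function(pm) {
  dom <- pm$dominant
  nr <- pm$nrow; nc <- pm$ncol
  labelled <- !is.na(dom)
  n_labels <- apply(pm$labels, c(1L, 2L), sum)
  bnd <- labelled & n_labels >= 2L
  # dominant code with distinct sentinels: NA-outside-mask vs empty-label-set
  code <- dom
  code[!pm$mask] <- -1L          # outside study area: ignored
  code[pm$mask & is.na(dom)] <- 0L  # in-area, unlabelled: counts as different
  shift <- function(m, dr, dc) {
    out <- matrix(-1L, nr, nc)   # off-grid behaves like outside the area
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    vr <- rs >= 1L & rs <= nr; vc <- cs >= 1L & cs <= nc
    out[vr, vc] <- m[rs[vr], cs[vc]]
    out
  }
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shift(code, d[1L], d[2L])
    differs <- labelled & nb != -1L & nb != code
    bnd <- bnd | differs
  }
  dimnames(bnd) <- NULL
  bnd
}

# Centre coordinates of TRUE cells of a logical matrix on a patch_map or
# raster-like geometry (fields xll, yll, cellsize, nrow/ncol).
true_cell_coords <- function(geom, mask) {
  idx <- which(mask)
  nr <- if (!is.null(geom$nrow)) geom$nrow else nrow(geom$values)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cs <- geom$cellsize
  cbind(x = geom$xll + (cols - 0.5) * cs,
        y = geom$yll + (nr - rows + 0.5) * cs)
}

# Vectorised min Euclidean distance from query points to target points.
min_dist_to <- function(x, y, targets) {
  vapply(seq_along(x), function(i) {
    sqrt(min((targets[, 1L] - x[i])^2 + (targets[, 2L] - y[i])^2))
  }, numeric(1L))
}

#' Distance to the nearest patch boundary
#'
#' Planar Euclidean distance (m) from each location to the nearest
#' boundary-cell centre; 0 when the location's own cell is a boundary cell.
#'
#' @param pm a `patch_map`.
#' @param x,y location coordinates (projected metres), vectorised.
#' @return numeric vector of distances (m).
#' @export
distance_to_boundary <- function(pm, x, y) {
  if (!any(pm$boundary)) stop("no patch boundary present")
  tg <- true_cell_coords(pm, pm$boundary)
  min_dist_to(x, y, tg)
}

#' Distance to shore
#'
#' Planar Euclidean distance (m) to the centre of the nearest land cell
#' (out-of-study-area cell edge-adjacent to an in-area cell). The shoreline
#' is a separate covariate, never a patch boundary.
#'
#' @param mask logical matrix (TRUE = in study area) or a [sea_raster] whose
#'   `NA` cells are land.
#' @param x,y location coordinates (m), vectorised.
#' @param geom grid geometry when `mask` is a bare matrix: list with `xll`,
#'   `yll`, `cellsize`.
#' @return numeric vector of distances (m).
#' @export
distance_to_shore <- function(mask, x, y, geom = NULL) {
  if (inherits(mask, "sea_raster")) {
    geom <- mask
    mask <- !is.na(mask$values)
  } else if (is.null(geom)) {
    stop("geom required when mask is a bare matrix")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    vr <- rs >= 1L & rs <= nr; vc <- cs >= 1L & cs <= nc
    out[vr, vc] <- m[rs[vr], cs[vc]]
    out
  }
  land <- !mask
  touches_sea <- pad(mask, -1L, 0L) | pad(mask, 1L, 0L) |
    pad(mask, 0L, -1L) | pad(mask, 0L, 1L)
  shoreline <- land & touches_sea
  if (!any(shoreline)) stop("mask has no land/sea transition")
  g <- list(xll = geom$xll, yll = geom$yll, cellsize = geom$cellsize, nrow = nr)
  tg <- true_cell_coords(g, shoreline)
  min_dist_to(x, y, tg)
}

#' Shannon diversity of surrounding substratum patches
#'
#' The Shannon index H = -sum p_c log p_c (nats) of dominant-class
#' proportions among in-study-area, labelled cells whose centres fall within
#' `radius_m` of the location. Cells outside the study area or with no class
#' above its cutoff are excluded from the denominator, so a circle clipped by
#' the shoreline uses only its in-area part.
#'
#' @param pm a `patch_map`.
#' @param x,y location coordinates (m), vectorised.
#' @param radius_m circle radius in metres (e.g. 500, 1000, 1500).
#' @param weighted if TRUE, proportions are probability-weighted by each
#'   class's surface instead of hard dominant-class counts (off by default).
#' @param subst the `substratum_raster`, required when `weighted = TRUE`.
#' @return numeric vector of H values (nats).
#' @export
shannon_diversity <- function(pm, x, y, radius_m, weighted = FALSE,
                              subst = NULL) {
  stopifnot(radius_m > 0)
  nr <- pm$nrow; nc <- pm$ncol; cs <- pm$cellsize
  cx <- pm$xll + (seq_len(nc) - 0.5) * cs
  cy <- pm$yll + (nr - seq_len(nr) + 0.5) * cs
  dom <- pm$dominant
  K <- length(pm$classes)
  if (weighted && is.null(subst)) stop("weighted H needs the substratum surfaces")
  vapply(seq_along(x), function(i) {
    dx2 <- outer(rep(1, nr), (cx - x[i])^2)
    dy2 <- outer((cy - y[i])^2, rep(1, nc))
    inside <- (dx2 + dy2) <= radius_m^2
    if (weighted) {
      w <- vapply(pm$classes, function(cl) {
        p <- subst$probs[[cl]]$values
        sum(p[inside & !is.na(p)])
      }, numeric(1L))
      if (sum(w) <= 0) stop("no eligible cells within ", radius_m, " m of (",
                            x[i], ", ", y[i], ")")
      p <- w / sum(w)
    } else {
      d <- dom[inside]
      d <- d[!is.na(d)]
      if (length(d) == 0L) stop("no eligible cells within ", radius_m,
                                " m of (", x[i], ", ", y[i], ")")
      p <- tabulate(d, K) / length(d)
    }
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1L))
}

#' Slope and aspect from bathymetry
#'
#' Slope gradient (degrees) and downslope aspect (compass degrees) by Horn's
#' 3x3 weighted finite differences on the depth surface (depth positive
#' downward; aspect is the bearing of steepest seafloor descent). Edge cells,
#' cells with a missing neighbour, and flat cells get `NA` aspect; flat cells
#' have slope 0.
#'
#' @param bathy depth [sea_raster].
#' @return list with `slope` and `aspect` [sea_raster]s; aspect `NA` where
#'   undefined (flat).
#' @export
slope_aspect <- function(bathy) {
  z <- -bathy$values   # elevation
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("need at least a 3x3 grid")
  cs <- bathy$cellsize
  # missing neighbours (grid edge or land) take the centre value, a
  # zero-gradient fallback so nearshore cells still get a defined slope
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs2 <- seq_len(nc) + dc
    vr <- rs >= 1L & rs <= nr; vc <- cs2 >= 1L & cs2 <= nc
    out[vr, vc] <- z[rs[vr], cs2[vc]]
    miss <- is.na(out)
    out[miss] <- z[miss]
    out
  }
  a <- sh(-1L, -1L); b <- sh(-1L, 0L); cc <- sh(-1L, 1L)
  d <- sh(0L, -1L);                    f <- sh(0L, 1L)
  g <- sh(1L, -1L);  h <- sh(1L, 0L);  i <- sh(1L, 1L)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # +y = north
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  flat <- !is.na(slope) & sqrt(dzdx^2 + dzdy^2) < 1e-12
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360  # bearing of steepest descent
  aspect[flat] <- NA_real_
  slope[is.na(bathy$values)] <- NA_real_
  aspect[is.na(bathy$values)] <- NA_real_
  list(
    slope = sea_raster(slope, bathy$xll, bathy$yll, bathy$cellsize),
    aspect = sea_raster(aspect, bathy$xll, bathy$yll, bathy$cellsize)
  )
}

#' Assign a depth stratum
#'
#' Maps depths (m, positive downward) to the survey's six design bands,
#' boundaries closed on the left: [0, 10), [10, 19), [19, 30), [30, 38),
#' [38, 50), [50, 116].
#'
#' @param depth_m numeric vector of depths, >= 0.
#' @param strata band edges, see [default_strata()].
#' @return integer vector of stratum indices (1-based).
#' @export
assign_depth_stratum <- function(depth_m, strata = default_strata()) {
  if (any(depth_m < 0, na.rm = TRUE)) stop("negative depth")
  if (any(depth_m > strata[length(strata)], na.rm = TRUE)) {
    stop("depth exceeds the deepest design stratum (",
         strata[length(strata)], " m)")
  }
  findInterval(depth_m, strata, rightmost.closed = TRUE)
}

#' Derive per-deployment seascape covariates
#'
#' Computes, for every deployment, the covariates used in modelling: depth,
#' map-derived dominant substratum class, distance to the nearest patch
#' boundary, surrounding patch diversity H at each radius, distance to
#' shore, slope, aspect, and depth stratum.
#'
#' @param deployments a `deployment_table`.
#' @param pm a `patch_map`.
#' @param bathy bathymetry [sea_raster].
#' @param radii H radii in metres; default c(500, 1000, 1500).
#' @return data.frame of class `deployment_features` keyed by
#'   `deployment_id`, with one `H_<radius>` column per radius.
#' @export
deployment_features <- function(deployments, pm, bathy,
                                radii = c(500, 1000, 1500)) {
  d <- deployments
  rc <- cell_at(bathy, d$x, d$y)
  dom <- pm$dominant[rc]
  sa <- slope_aspect(bathy)
  out <- data.frame(
    deployment_id = d$deployment_id,
    site = d$site, year = d$year,
    depth_m = raster_extract(bathy, d$x, d$y),
    substratum = ifelse(is.na(dom), NA_character_, pm$classes[dom]),
    dist_boundary_m = distance_to_boundary(pm, d$x, d$y),
    dist_shore_m = distance_to_shore(bathy, d$x, d$y),
    slope_deg = raster_extract(sa$slope, d$x, d$y),
    aspect_deg = raster_extract(sa$aspect, d$x, d$y),
    stringsAsFactors = FALSE
  )
  for (r in radii) {
    out[[paste0("H_", r)]] <- shannon_diversity(pm, d$x, d$y, r)
  }
  out$stratum <- assign_depth_stratum(out$depth_m)
  class(out) <- c("deployment_features", "data.frame")
  out
}
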