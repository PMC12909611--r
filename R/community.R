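#' Filter rarely-encountered species
#'
#' Removes species that occur in fewer than a given fraction of deployments
#' within site-year survey groups (occurrence = MaxN > 0). By default a
#' species is retained when at least one site-year group meets the
#' occurrence threshold `ceiling(fraction * group size)`; ties at exactly
#' the fraction are retained ("fewer than" is strict). Set `mode = "all"` to
#' require the criterion in every group, or `min_occurrence` to use an
#' absolute per-group occurrence floor instead of the fraction.
#'
#' @param counts n x J count matrix (deployments x species).
#' @param site,year grouping labels per deployment; taken from attributes of
#'   `counts` if present.
#' @param fraction occurrence fraction in (0,1); default 0.10.
#' @param min_occurrence optional absolute occurrence threshold overriding
#'   the fraction.
#' @param mode `"any"` (default: retained if any group qualifies) or
#'   `"all"`.
#' @return list with `counts` (filtered matrix), `retained`, `removed`
#'   (character vectors) and `report` (per-species per-group occurrences).
#' @export
filter_rare_species <- function(counts, site = attr(counts, "site"),
                                year = attr(counts, "year"),
                                fraction = 0.10, min_occurrence = NULL,
                                mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (is.null(counts) || length(counts) == 0L || ncol(counts) == 0L) {
    stop("empty count matrix")
  }
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(site)) site <- rep("S1", nrow(counts))
  if (is.null(year)) year <- rep(1L, nrow(counts))
  grp <- interaction(site, year, drop = TRUE)
  pres <- counts > 0
  occ <- rowsum(pres + 0, grp)                     # groups x species
  n_g <- as.vector(table(grp)[rownames(occ)])
  thr <- if (is.null(min_occurrence)) ceiling(fraction * n_g) else
    rep(min_occurrence, length(n_g))
  qual <- occ >= thr                               # groups x species
  keep <- if (mode == "any") colSums(qual) > 0 else colSums(qual) == nrow(qual)
  report <- data.frame(
    species = rep(colnames(counts), each = nrow(occ)),
    group = rep(rownames(occ), ncol(occ)),
    occurrences = as.vector(occ),
    group_size = rep(n_g, ncol(occ)),
    threshold = rep(thr, ncol(occ)),
    retained = rep(keep, each = nrow(occ))
  )
  list(
    counts = counts[, keep, drop = FALSE],
    retained = colnames(counts)[keep],
    removed = colnames(counts)[!keep],
    report = report
  )
}

#' Species accumulation curve
#'
#' Mean cumulative species richness against the number of deployments
#' sampled, estimated by random permutations of deployment order, with the
#' final gradient (new species per additional sample) as the sampling
#' adequacy statistic. The exact expectation
#' E[S_n] = sum_j (1 - C(N - F_j, n) / C(N, n)), with F_j the occupancy of
#' species j, is returned alongside for verification.
#'
#' @param counts n x J count matrix.
#' @param n_permutations number of random orderings; >= 1.
#' @param seed RNG seed.
#' @return list of class `species_accum`: `n`, `mean_richness`,
#'   `sd_richness`, `exact` (closed-form E[S_n]), `gradient`.
#' @export
species_accumulation <- function(counts, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  N <- nrow(counts)
  if (N < 2L) stop("need at least 2 deployments")
  pres <- counts > 0
  set.seed(as.integer(seed))
  acc <- matrix(0, n_permutations, N)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(N)
    seen <- apply(pres[ord, , drop = FALSE], 2L, cummax)
    acc[p, ] <- rowSums(seen)
  }
  Fj <- colSums(pres)
  exact <- vapply(seq_len(N), function(n) {
    sum(1 - exp(lchoose(N - Fj, n) - lchoose(N, n)))
  }, numeric(1L))
  mean_r <- colMeans(acc)
  structure(
    list(n = seq_len(N), mean_richness = mean_r,
         sd_richness = apply(acc, 2L, stats::sd), exact = exact,
         gradient = mean_r[N] - mean_r[N - 1L]),
    class = "species_accum"
  )
}
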