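#' Residual correlation draws from latent-factor loadings
#'
#' For each posterior draw, forms the residual species covariance
#' Omega = V V' implied by the latent-factor loadings and converts it to a
#' correlation matrix. Omega is invariant to orthogonal rotation of the
#' factors, so these draws do not depend on the (unidentified) rotation of
#' the loadings. Species whose loading norm is zero in a draw have
#' undefined correlations (NA) for that draw; species with zero loadings in
#' every draw are excluded with a warning.
#'
#' @param x a `posterior_samples` fit with at least one latent factor, or a
#'   draws-by-species-by-factor array of loadings.
#' @param species species names (taken from the fit when available).
#' @return array (draws x J x J) of residual correlations.
#' @export
residual_correlation_draws <- function(x, species = NULL) {
  if (inherits(x, "posterior_samples")) {
    if (x$q < 1L) stop("model has no latent factor")
    Vd <- posterior_draws(x, "V")                  # draws x (J*q)
    nd <- nrow(Vd); J <- x$J; q <- x$q
    if (is.null(species)) species <- x$species
    Varr <- array(Vd, c(nd, J, q))
  } else {
    Varr <- x
    if (length(dim(Varr)) == 2L) Varr <- array(Varr, c(dim(Varr), 1L))
    nd <- dim(Varr)[1L]; J <- dim(Varr)[2L]; q <- dim(Varr)[3L]
  }
  if (is.null(species)) species <- paste0("sp", seq_len(J))
  R <- array(NA_real_, c(nd, J, J), dimnames = list(NULL, species, species))
  zero_norm <- matrix(FALSE, nd, J)
  for (d in seq_len(nd)) {
    V <- matrix(Varr[d, , ], J, q)
    omega <- V %*% t(V)
    nrm <- sqrt(diag(omega))
    zero <- nrm == 0
    zero_norm[d, ] <- zero
    Rd <- omega / outer(nrm, nrm)
    Rd[zero, ] <- NA_real_; Rd[, zero] <- NA_real_
    diag(Rd)[!zero] <- 1
    R[d, , ] <- Rd
  }
  dead <- colSums(!zero_norm) == 0
  if (any(dead)) {
    warning("species with zero loadings in every draw excluded: ",
            paste(species[dead], collapse = ", "))
    R <- R[, !dead, !dead, drop = FALSE]
  }
  attr(R, "n_undefined") <- colSums(zero_norm)
  R
}

#' Screen residual species associations by credible interval
#'
#' Summarizes per-pair residual correlation draws by the posterior mean and
#' equal-tailed credible bounds, and flags a pair as supported only when the
#' interval excludes zero (both bounds share a sign) — unsupported pairs are
#' the "blank" cells of the rendered matrix. Draws where a pair's
#' correlation is undefined (zero loading norm) are dropped pairwise.
#'
#' @param R draws x J x J correlation array from
#'   [residual_correlation_draws()].
#' @param level credible level; default 0.95 (equal-tailed 2.5%/97.5%).
#' @return list of class `association_matrix`: `mean`, `lower`, `upper`
#'   (J x J), `supported` (logical J x J; diagonal TRUE), `level`,
#'   `n_dropped` (per pair).
#' @export
screen_associations <- function(R, level = 0.95) {
  stopifnot(level > 0, level < 1)
  nd <- dim(R)[1L]; J <- dim(R)[2L]
  need <- ceiling(2 / (1 - level))
  if (nd < need) {
    stop("need at least ", need, " draws for a stable ", level * 100,
         "% interval; got ", nd)
  }
  a <- (1 - level) / 2
  mean_m <- lower <- upper <- matrix(NA_real_, J, J,
                                     dimnames = dimnames(R)[c(2L, 3L)])
  dropped <- matrix(0L, J, J)
  for (j in seq_len(J)) {
    for (k in j:J) {
      v <- R[, j, k]
      bad <- is.na(v)
      v <- v[!bad]
      dropped[j, k] <- dropped[k, j] <- sum(bad)
      if (length(v) == 0L) next
      qs <- stats::quantile(v, c(a, 1 - a), names = FALSE)
      mean_m[j, k] <- mean_m[k, j] <- mean(v)
      lower[j, k] <- lower[k, j] <- qs[1L]
      upper[j, k] <- upper[k, j] <- qs[2L]
    }
  }
  supported <- !is.na(lower) & (lower > 0 | upper < 0)
  diag(supported) <- TRUE
  structure(
    list(mean = mean_m, lower = lower, upper = upper, supported = supported,
         level = level, n_dropped = dropped),
    class = "association_matrix"
  )
}

#' @export
print.association_matrix <- function(x, digits = 2, ...) {
  J <- nrow(x$mean)
  cat(sprintf("<association_matrix> %d species, %g%% equal-tailed intervals\n",
              J, x$level * 100))
  shown <- ifelse(x$supported, format(round(x$mean, digits)), ".")
  diag(shown) <- "1"
  print(as.data.frame(shown), ...)
  invisible(x)
}

#' Tabulate an association matrix pair by pair
#'
#' @param x an `association_matrix`.
#' @return data.frame with one row per unordered species pair: mean, lower,
#'   upper, supported.
#' @export
association_table <- function(x) {
  J <- nrow(x$mean)
  sp <- rownames(x$mean)
  idx <- which(upper.tri(x$mean), arr.ind = TRUE)
  data.frame(
    species_1 = sp[idx[, 1L]], species_2 = sp[idx[, 2L]],
    mean = x$mean[idx], lower = x$lower[idx], upper = x$upper[idx],
    supported = x$supported[idx]
  )
}

#' Heat map of screened associations
#'
#' Renders the association matrix with blue positive / red negative cells
#' and blanks where the credible interval straddles zero.
#'
#' @param x an `association_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.association_matrix <- function(x, ...) {
  J <- nrow(x$mean)
  m <- x$mean
  m[!x$supported] <- NA
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(99)
  graphics::image(seq_len(J), seq_len(J), t(m[J:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(J), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(J), rev(rownames(m)), las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
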