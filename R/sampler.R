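# Rank-correlated uniform sampling of the parameter space.
#
# Marginals are exactly uniform on each parameter's [low, high]; the
# assumed pairwise rank correlations are induced by the Iman-Conover
# method: independently drawn uniforms are reordered column by column to
# follow the rank pattern of a correlated multivariate-normal reference
# sample.  The method is distribution-free, so the uniform marginals are
# untouched.

#' Assemble a correlation matrix from pairwise assumptions
#'
#' Builds the symmetric unit-diagonal matrix over `columns` from a pair
#' list, then repairs it to the nearest positive semidefinite correlation
#' matrix by eigenvalue clipping if needed (negative eigenvalues are
#' raised to a small positive floor and the result rescaled to unit
#' diagonal).  Any repair is flagged: the returned matrix carries
#' attributes `adjusted` (logical) and `max_adjustment` (largest absolute
#' entry change).
#'
#' @param spec Data frame with columns `a`, `b`, `rho` (each unordered
#'   pair listed once); pairs naming identifiers outside `columns` are
#'   dropped (they correspond to constants, which carry no rank).
#' @param columns Character vector of parameter identifiers.
#' @return A `length(columns)` square correlation matrix.
#' @examples
#' build_correlation_matrix(data.frame(a = "x", b = "y", rho = 0.7),
#'                          c("x", "y", "z"))
#' @export
build_correlation_matrix <- function(spec, columns) {
  p <- length(columns)
  R <- diag(p)
  dimnames(R) <- list(columns, columns)
  if (!is.null(spec) && nrow(spec) > 0) {
    if (any(abs(spec$rho) > 1)) {
      stop("correlations must lie in [-1, 1]", call. = FALSE)
    }
    keep <- spec$a %in% columns & spec$b %in% columns
    spec <- spec[keep, , drop = FALSE]
    for (i in seq_len(nrow(spec))) {
      a <- spec$a[i]; b <- spec$b[i]
      if (a == b) next
      if (R[a, b] != 0 && R[a, b] != spec$rho[i]) {
        stop(sprintf("conflicting correlations for pair (%s, %s)", a, b),
             call. = FALSE)
      }
      R[a, b] <- spec$rho[i]
      R[b, a] <- spec$rho[i]
    }
  }
  nearest_psd_correlation(R)
}

#' Nearest positive semidefinite correlation matrix
#'
#' Eigenvalue-clipping repair: eigenvalues below a small floor are
#' raised to it, the matrix is recomposed and rescaled to unit diagonal.
#' A no-op (up to the attributes) for matrices that are already PSD.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor.  Kept distinctly positive so the
#'   repaired matrix stays comfortably full-rank (a Cholesky factor of
#'   it, and of sample correlations drawn under it, must exist).
#' @return Repaired matrix with attributes `adjusted` and
#'   `max_adjustment`.
#' @export
nearest_psd_correlation <- function(R, eps = 1e-3) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) {
    attr(R, "adjusted") <- FALSE
    attr(R, "max_adjustment") <- 0
    return(R)
  }
  lam <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2 <- (R2 + t(R2)) / 2
  dimnames(R2) <- dimnames(R)
  attr(R2, "adjusted") <- TRUE
  attr(R2, "max_adjustment") <- max(abs(R2 - R))
  R2
}

# Spearman rank correlation target -> Pearson correlation of the normal
# scores that induces it under a Gaussian copula.
.spearman_to_pearson <- function(R) {
  P <- 2 * sin(pi * R / 6)
  diag(P) <- 1
  P
}

#' Draw correlated uniform parameter realizations
#'
#' Samples `n_draws` realizations of every catalog parameter: each
#' uncertain parameter is uniform on its [low, high]; degenerate
#' parameters (low = high) are constant columns.  The catalog's pairwise
#' rank correlations are imposed by Iman-Conover reordering against a
#' multivariate-normal reference sample whose Pearson correlations are
#' chosen to induce the (PSD-repaired) Spearman targets.  Fully
#' reproducible for a given (seed, n_draws, catalog).
#'
#' @param catalog A `stove_catalog`.
#' @param n_draws Number of realizations (>= 2).
#' @param seed Integer RNG seed.
#' @return A data frame with one column per parameter id and attributes
#'   `seed`, `target_spearman` (the repaired rank-correlation targets
#'   over uncertain columns) and `correlation_adjusted`.
#' @examples
#' d <- sample_draws(default_catalog(), 100, seed = 1)
#' range(d$chi)   # within [0.2, 0.8]
#' @export
sample_draws <- function(catalog, n_draws, seed) {
  stopifnot(n_draws >= 2)
  pt <- param_table(catalog)
  uncertain <- pt$low < pt$high
  ids <- pt$id[uncertain]

  set.seed(as.integer(seed))
  n <- as.integer(n_draws)
  p <- length(ids)
  U <- matrix(stats::runif(n * p), nrow = n)

  Rs <- if (p > 0) build_correlation_matrix(catalog$correlations, ids)
        else matrix(numeric(0), 0, 0)
  if (p > 0 && any(Rs[upper.tri(Rs)] != 0)) {
    adjusted <- isTRUE(attr(Rs, "adjusted"))
    P <- nearest_psd_correlation(.spearman_to_pearson(Rs))
    adjusted <- adjusted || isTRUE(attr(P, "adjusted"))
    Z <- matrix(stats::rnorm(n * p), nrow = n) %*% chol(P)
    if (n > p + 1) {
      # Iman-Conover correction: remove the sampling error of the
      # reference scores so their realized correlation is exactly P
      Z <- Z %*% solve(chol(stats::cor(Z))) %*% chol(P)
    }
    for (j in seq_len(p)) {
      U[, j] <- sort(U[, j])[rank(Z[, j], ties.method = "first")]
    }
    # rank correlation actually induced by the (repaired) normal copula
    Rs <- 6 / pi * asin(P / 2)
    diag(Rs) <- 1
    dimnames(Rs) <- list(ids, ids)
    attr(Rs, "adjusted") <- adjusted
  }

  out <- matrix(NA_real_, nrow = n, ncol = nrow(pt),
                dimnames = list(NULL, pt$id))
  out[, ids] <- rep(pt$low[uncertain], each = n) +
    U * rep(pt$high[uncertain] - pt$low[uncertain], each = n)
  if (any(!uncertain)) {
    out[, pt$id[!uncertain]] <- rep(pt$mid[!uncertain], each = n)
  }
  df <- as.data.frame(out)
  attr(df, "seed") <- as.integer(seed)
  attr(df, "target_spearman") <- Rs
  attr(df, "correlation_adjusted") <- isTRUE(attr(Rs, "adjusted"))
  df
}

#' Export a draw matrix to CSV
#'
#' Writes the draws with a header row of parameter identifiers, for
#' audit and replay.
#'
#' @param draws A draw matrix from [sample_draws()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  utils::write.csv(draws, path, row.names = FALSE)
  invisible(path)
}
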