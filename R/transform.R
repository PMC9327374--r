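#' Eigendecomposition of the GRM
#'
#' Computes the symmetric eigendecomposition `A = Q diag(phi) Q'` of the
#' genomic-relationship matrix, with eigenvalues sorted in descending order.
#' The decomposition costs O(N^3) but is needed only once per dataset, and
#' every subsequent model fit reuses it; numerically negative eigenvalues
#' (a GRM is positive semidefinite up to rounding) are clipped to zero with a
#' warning.
#'
#' @param grm a [grm_data] object.
#' @return An object of class `grm_eigen` with elements `ids`, `Q`
#'   (orthonormal eigenvectors, columns matching `phi`) and `phi`
#'   (eigenvalues, descending).
#' @export
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm_data"))
  if (!all(is.finite(grm$A))) stop("GRM contains non-finite entries")
  e <- eigen(grm$A, symmetric = TRUE)
  phi <- e$values
  if (any(phi < 0)) {
    if (min(phi) < -1e-6 * max(abs(phi)))
      warning("GRM has substantially negative eigenvalues (min ",
              format(min(phi), digits = 3), "); clipping to zero")
    phi <- pmax(phi, 0)
  }
  structure(list(ids = grm$ids, Q = e$vectors, phi = phi),
            class = "grm_eigen")
}

#' @export
print.grm_eigen <- function(x, ...) {
  cat("GRM eigendecomposition:", length(x$phi), "individuals\n")
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$phi, 5), digits = 4), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Rotate phenotypes and covariates into the GRM eigenbasis
#'
#' The multivariate GREML covariance `V_G (x) A + V_E (x) I` is dense, but in
#' the basis of GRM eigenvectors it becomes block diagonal: after projecting
#' on the `n = N - L` eigenvectors whose eigenvalues are not among the L
#' largest, observation block j has covariance `V_j = d_j V_G + V_E` with
#' `d_j` the j-th retained eigenvalue. Dropping the L leading principal
#' components removes their contribution from the likelihood entirely, which
#' corrects for population stratification without spending fixed-effect
#' covariates (default L = 20).
#'
#' An intercept applying to every trait is appended to the covariates by
#' default, since trait means are otherwise unmodelled.
#'
#' @param eig a [grm_eigen] object.
#' @param pheno a [pheno_data] object aligned with `eig` (same individuals,
#'   same order; see [align_samples]).
#' @param covar optional aligned [covar_data].
#' @param L number of leading principal components to drop.
#' @param intercept add a constant covariate applying to all traits.
#' @return An object of class `mv_transformed` with elements `d` (retained
#'   eigenvalues), `Ystar` (T x n rotated traits), `Xstar` (n x k rotated
#'   covariates), `trait_map` (binary T x k), `traits`, `covars`, `L`, `n`,
#'   `N`.
#' @export
canonical_transform <- function(eig, pheno, covar = NULL, L = 20L,
                                intercept = TRUE) {
  stopifnot(inherits(eig, "grm_eigen"), inherits(pheno, "pheno_data"))
  if (!identical(.id_key(eig$ids), .id_key(pheno$ids)))
    stop("'eig' and 'pheno' are not aligned; run align_samples() first")
  if (!is.null(covar) && !identical(.id_key(eig$ids), .id_key(covar$ids)))
    stop("'eig' and 'covar' are not aligned; run align_samples() first")
  n_tot <- length(eig$phi)
  tt <- ncol(pheno$Y)
  k_user <- if (is.null(covar)) 0L else ncol(covar$X)
  k <- k_user + as.integer(intercept)
  L <- as.integer(L)
  if (L < 0L || L >= n_tot - tt - k)
    stop("'L' must satisfy 0 <= L < N - T - k = ", n_tot - tt - k)
  keep <- seq.int(L + 1L, n_tot)        # eigenvalues are sorted descending
  P <- eig$Q[, keep, drop = FALSE]
  d <- eig$phi[keep]
  X <- matrix(numeric(0), nrow = n_tot, ncol = 0)
  covars <- character(0)
  tmap <- matrix(numeric(0), nrow = tt, ncol = 0)
  if (intercept) {
    X <- cbind(X, rep(1, n_tot))
    covars <- c(covars, "intercept")
    tmap <- cbind(tmap, rep(1, tt))
  }
  if (k_user > 0L) {
    X <- cbind(X, covar$X)
    covars <- c(covars, covar$covars)
    user_map <- covar$trait_map
    if (is.null(user_map)) user_map <- matrix(1, tt, k_user)
    tmap <- cbind(tmap, user_map)
  }
  colnames(tmap) <- covars
  rownames(tmap) <- pheno$traits
  Xstar <- if (k > 0L) crossprod(P, X) else matrix(numeric(0), length(d), 0)
  colnames(Xstar) <- covars
  structure(list(
    d = d,
    Ystar = crossprod(pheno$Y, P),       # T x n
    Xstar = Xstar,
    trait_map = tmap,
    traits = pheno$traits,
    covars = covars,
    L = L, n = length(d), N = n_tot
  ), class = "mv_transformed")
}

#' @export
print.mv_transformed <- function(x, ...) {
  cat("Transformed dataset:", x$N, "individuals,", x$L,
      "leading PCs dropped ->", x$n, "blocks of", length(x$traits),
      "traits\n")
  cat("  covariates:",
      if (length(x$covars)) paste(x$covars, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
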