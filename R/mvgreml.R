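#' Multivariate GREML with genetic and environmental factor models
#'
#' Fits the multivariate linear mixed model
#' \deqn{y \sim N(Z\beta,\; V_G \otimes A + V_E \otimes I_N)}
#' by restricted maximum likelihood, where `A` is a genomic-relationship
#' matrix over N unrelated individuals and `V_G`, `V_E` are the T x T genetic
#' and environmental variance matrices of the traits. Both variance matrices
#' are parameterized through factor models `V = C C'` with user-specified
#' binary patterns of free loadings ([factor_model]); by default both are
#' saturated (lower-triangular), which can represent any positive
#' semidefinite variance matrix. The parameterization guarantees valid
#' (positive semidefinite) genetic and environmental correlation matrices.
#'
#' Estimation proceeds in the GRM eigenbasis, where the covariance is block
#' diagonal and one likelihood or gradient evaluation costs O(N T^2). The L
#' leading principal components of the GRM are removed from the likelihood
#' (default L = 20), absorbing population stratification without additional
#' fixed effects. The free coefficients are estimated by BFGS with a
#' golden-section line search; standard errors of heritabilities and
#' correlations come from the inverse average-information matrix through the
#' delta method, and fixed effects are estimated by GLS at the fitted
#' variance components.
#'
#' @param pheno phenotypes: a [pheno_data] object or a file path readable by
#'   [read_pheno].
#' @param grm the relatedness input: a [grm_data] object, a GCTA binary GRM
#'   path prefix, or a precomputed [grm_eigen] (in which case `pheno` and
#'   `covar` must already be aligned to it and `adjust_pcs` applies to its
#'   eigenvalues).
#' @param covar optional covariates: a [covar_data] object or file path.
#' @param genetic_model,environment_model [factor_model]s (or specification
#'   file paths); both default to saturated models.
#' @param adjust_pcs number L of leading GRM principal components to drop.
#' @param intercept add an intercept covariate applying to every trait.
#' @param se compute the average-information matrix and delta-method standard
#'   errors after convergence (can be switched off; the AI matrix is the
#'   expensive step).
#' @param control a [mvgreml_control] list.
#' @param theta0 optional starting coefficients (advanced use).
#' @return An object of class `mvgreml`; see [summary.mvgreml]. Key elements:
#'   `h2` (SNP heritabilities), `rhoG`/`rhoE` (correlation matrices), `VG`,
#'   `VE`, `CG`, `CE`, `loglik`, `beta` (GLS fixed effects), `theta`,
#'   `theta_cov`, `converged`, `trace`.
#' @seealso [anova.mvgreml] for likelihood-ratio tests between nested fits.
#' @export
mvgreml <- function(pheno, grm, covar = NULL,
                    genetic_model = NULL, environment_model = NULL,
                    adjust_pcs = 20L, intercept = TRUE, se = TRUE,
                    control = mvgreml_control(), theta0 = NULL) {
  cl <- match.call()
  if (is.character(pheno)) pheno <- read_pheno(pheno)
  if (is.character(covar)) covar <- read_covar(covar)
  if (is.character(grm)) grm <- read_grm(grm)
  if (inherits(grm, "grm_data")) {
    al <- align_samples(grm, pheno, covar)
    eig <- grm_eigen(al$grm)
    pheno <- al$pheno
    covar <- al$covar
  } else if (inherits(grm, "grm_eigen")) {
    eig <- grm
  } else stop("'grm' must be a grm_data, grm_eigen, or GRM path prefix")
  traits <- pheno$traits
  if (is.character(genetic_model))
    genetic_model <- read_factor_model(genetic_model, traits)
  if (is.character(environment_model))
    environment_model <- read_factor_model(environment_model, traits)
  if (is.null(genetic_model)) genetic_model <- saturated_factor_model(traits)
  if (is.null(environment_model))
    environment_model <- saturated_factor_model(traits)
  if (!identical(genetic_model$traits, traits) ||
      !identical(environment_model$traits, traits))
    stop("factor model trait labels must match the phenotype traits")

  ident <- check_identification(genetic_model, environment_model,
                                seed = control$seed)
  if (!ident$identified)
    stop("the factor models are not identified:\n  ",
         paste(ident$problems, collapse = "\n  "))

  td <- canonical_transform(eig, pheno, covar, L = adjust_pcs,
                            intercept = intercept)
  fit <- .fit_theta(td, genetic_model, environment_model, control,
                    theta0 = theta0)
  if (!fit$converged)
    warning("BFGS did not converge in ", control$max_iter,
            " iterations (RMS gradient criterion ",
            format(sqrt(mean(fit$gradient^2)) / td$n, digits = 3), ")")

  theta <- .fix_loading_signs(fit$theta, genetic_model, environment_model,
                              fit$index)
  vs <- .implied_variance(theta, genetic_model, environment_model, fit$index)
  hc <- .h2_and_correlations(vs$VG, vs$VE, traits)
  kb <- .reml_kernel(td, vs, fit$index, want = "gls")

  ai <- NULL
  theta_cov <- NULL
  ses <- NULL
  if (se) {
    ai <- .reml_kernel(td, vs, fit$index, want = "ai")$ai
    theta_cov <- .invert_information(ai)
    ses <- .delta_method_ses(theta, theta_cov, genetic_model,
                             environment_model, fit$index)
  }

  beta <- NULL
  if (length(kb$beta)) {
    beta <- data.frame(
      term = names(kb$beta),
      estimate = as.vector(kb$beta),
      se = sqrt(pmax(diag(kb$beta_cov), 0)),
      row.names = NULL
    )
  }

  structure(list(
    call = cl, traits = traits,
    genetic_model = genetic_model, environment_model = environment_model,
    theta = theta, index = fit$index,
    loglik = fit$loglik, converged = fit$converged, n_iter = fit$n_iter,
    gradient = fit$gradient, trace = fit$trace,
    CG = vs$CG, CE = vs$CE, VG = vs$VG, VE = vs$VE,
    h2 = hc$h2, rhoG = hc$rhoG, rhoE = hc$rhoE,
    ai = ai, theta_cov = theta_cov, se = ses,
    beta = beta,
    N = td$N, n = td$n, L = td$L, T = length(traits),
    k = length(td$covars), covars = td$covars,
    identification = ident, control = control
  ), class = "mvgreml")
}

# Sign convention for reporting: V = C C' is invariant to negating a factor
# column, so the first free loading of each factor is made nonnegative.
.fix_loading_signs <- function(theta, spec_g, spec_e, index) {
  for (tag in c("G", "E")) {
    spec <- if (tag == "G") spec_g else spec_e
    for (f_ in seq_len(ncol(spec$pattern))) {
      rows <- which(index$mat == tag & index$f == f_)
      if (length(rows) == 0L) next
      lead <- rows[which.min(index$t[rows])]
      if (theta[lead] < 0) theta[rows] <- -theta[rows]
    }
  }
  theta
}

# h2_t = sigma_G,tt / (sigma_G,tt + sigma_E,tt); correlations are the
# variance-normalized covariances. Traits with zero genetic variance have
# undefined genetic correlations and are reported as NA, never as 0.
.h2_and_correlations <- function(VG, VE, traits = NULL) {
  vg <- diag(VG)
  ve <- diag(VE)
  tot <- vg + ve
  if (any(tot <= 0))
    stop("trait with zero total variance; the model cannot be summarized")
  h2 <- vg / tot
  corr_of <- function(V) {
    v <- diag(V)
    defined <- v > 0
    r <- matrix(NA_real_, nrow(V), ncol(V))
    if (any(defined)) {
      s <- sqrt(v[defined])
      r[defined, defined] <- V[defined, defined] / tcrossprod(s)
      r[cbind(which(defined), which(defined))] <- 1
    }
    dimnames(r) <- list(traits, traits)
    r
  }
  names(h2) <- traits
  list(h2 = h2, rhoG = corr_of(VG), rhoE = corr_of(VE))
}

# Invert the AI matrix to get the coefficient covariance; fall back to a
# pseudo-inverse (with a warning) when badly conditioned.
.invert_information <- function(ai) {
  e <- eigen((ai + t(ai)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  if (!all(pos))
    warning("AI matrix is singular or indefinite (condition number > 1e12); ",
            "using a pseudo-inverse for coefficient covariance")
  v <- ifelse(pos, 1 / e$values, 0)
  cv <- e$vectors %*% (v * t(e$vectors))
  (cv + t(cv)) / 2
}

# --- delta-method standard errors -----------------------------------------

# Analytic Jacobians of h2, rhoG, rhoE with respect to theta, chained
# through V = C C' (dV_i known in closed form), then SE = sqrt(J Sigma J').
.summary_jacobians <- function(theta, spec_g, spec_e, index) {
  vs <- .implied_variance(theta, spec_g, spec_e, index)
  tt <- nrow(vs$VG)
  p <- nrow(index)
  vg <- diag(vs$VG)
  ve <- diag(vs$VE)
  tot <- vg + ve
  J_h2 <- matrix(0, tt, p)
  npair <- tt * (tt - 1) / 2
  J_rg <- matrix(0, npair, p)
  J_re <- matrix(0, npair, p)
  pair_idx <- which(lower.tri(vs$VG), arr.ind = TRUE)
  for (i in seq_len(p)) {
    dv <- .variance_derivative(i, vs, index)
    if (dv$mat == "G") {
      dVG <- dv$dV
      dVE <- matrix(0, tt, tt)
    } else {
      dVG <- matrix(0, tt, tt)
      dVE <- dv$dV
    }
    dvg <- diag(dVG)
    dve <- diag(dVE)
    J_h2[, i] <- (dvg * ve - vg * dve) / tot^2
    if (npair > 0) {
      t1 <- pair_idx[, 1L]
      t2 <- pair_idx[, 2L]
      # d rho_ts = dV_ts / sqrt(v_t v_s) - rho_ts/2 (dv_t/v_t + dv_s/v_s)
      rg_ok <- vg[t1] > 0 & vg[t2] > 0
      re_ok <- ve[t1] > 0 & ve[t2] > 0
      den_g <- sqrt(vg[t1] * vg[t2])
      den_e <- sqrt(ve[t1] * ve[t2])
      rg <- ifelse(rg_ok, vs$VG[pair_idx] / den_g, NA_real_)
      re <- ifelse(re_ok, vs$VE[pair_idx] / den_e, NA_real_)
      J_rg[, i] <- ifelse(rg_ok,
        dVG[pair_idx] / den_g -
          0.5 * rg * (dvg[t1] / vg[t1] + dvg[t2] / vg[t2]), NA_real_)
      J_re[, i] <- ifelse(re_ok,
        dVE[pair_idx] / den_e -
          0.5 * re * (dve[t1] / ve[t1] + dve[t2] / ve[t2]), NA_real_)
    }
  }
  list(h2 = J_h2, rhoG = J_rg, rhoE = J_re, pair_idx = pair_idx)
}

# Central-finite-difference cross-check of the analytic summary Jacobians.
.summary_jacobians_fd <- function(theta, spec_g, spec_e, index, h = 1e-6) {
  tt <- nrow(spec_g$pattern)
  summ <- function(th) {
    vs <- .implied_variance(th, spec_g, spec_e, index)
    hc <- .h2_and_correlations(vs$VG, vs$VE)
    c(hc$h2, hc$rhoG[lower.tri(hc$rhoG)], hc$rhoE[lower.tri(hc$rhoE)])
  }
  p <- length(theta)
  base <- summ(theta)
  J <- matrix(NA_real_, length(base), p)
  for (i in seq_len(p)) {
    e <- numeric(p)
    e[i] <- h
    J[, i] <- (summ(theta + e) - summ(theta - e)) / (2 * h)
  }
  npair <- tt * (tt - 1) / 2
  list(h2 = J[seq_len(tt), , drop = FALSE],
       rhoG = J[tt + seq_len(npair), , drop = FALSE],
       rhoE = J[tt + npair + seq_len(npair), , drop = FALSE])
}

.delta_method_ses <- function(theta, theta_cov, spec_g, spec_e, index) {
  J <- .summary_jacobians(theta, spec_g, spec_e, index)
  tt <- nrow(spec_g$pattern)
  se_of <- function(jac) {
    out <- rep(NA_real_, nrow(jac))
    ok <- stats::complete.cases(jac)
    if (any(ok)) {
      jj <- jac[ok, , drop = FALSE]
      out[ok] <- sqrt(pmax(rowSums((jj %*% theta_cov) * jj), 0))
    }
    out
  }
  h2_se <- se_of(J$h2)
  rg_se_v <- se_of(J$rhoG)
  re_se_v <- se_of(J$rhoE)
  tomat <- function(v) {
    m <- matrix(NA_real_, tt, tt)
    m[J$pair_idx] <- v
    m[J$pair_idx[, c(2, 1), drop = FALSE]] <- v
    diag(m) <- 0
    m
  }
  list(h2_se = h2_se, rhoG_se = tomat(rg_se_v), rhoE_se = tomat(re_se_v))
}

# --- likelihood-ratio test ------------------------------------------------

#' Likelihood-ratio test between nested multivariate GREML fits
#'
#' Computes `LRT = 2 (ell_A - ell_0)` for a main fit and a fit of a model
#' nested within it, with degrees of freedom equal to the difference in free
#' factor-loading counts, and the upper-tail chi-square p-value. The fits
#' must be on the same data; nestedness of the factor models is the user's
#' assertion (the free-coefficient counts are checked for consistency).
#'
#' When a fitted coefficient of the main model lies on the boundary of the
#' parameter space (a loading estimated at ~0), the chi-square reference can
#' be conservative; the standard chi-square p-value is still reported.
#'
#' @param object the main (larger) `mvgreml` fit.
#' @param nested the nested `mvgreml` fit. Order is checked by free counts
#'   and swapped with a message if reversed.
#' @param ... unused.
#' @return An object of class `mvgreml_lrt` with `statistic`, `df`,
#'   `p_value`, `ell_main`, `ell_nested`.
#' @export
anova.mvgreml <- function(object, nested, ...) {
  if (missing(nested) || !inherits(nested, "mvgreml"))
    stop("supply two mvgreml fits: anova(main_fit, nested_fit)")
  main <- object
  cA <- n_free(main$genetic_model) + n_free(main$environment_model)
  c0 <- n_free(nested$genetic_model) + n_free(nested$environment_model)
  if (c0 > cA) {
    message("second fit has more free coefficients; treating it as the main model")
    tmp <- main; main <- nested; nested <- tmp
  }
  df <- lrt_df(list(genetic = main$genetic_model,
                    environment = main$environment_model),
               list(genetic = nested$genetic_model,
                    environment = nested$environment_model))
  lrt(main$loglik, nested$loglik, df)
}

#' @param ell_main,ell_nested restricted log-likelihoods of the main and
#'   nested models.
#' @param df degrees of freedom from [lrt_df].
#' @rdname anova.mvgreml
#' @export
lrt <- function(ell_main, ell_nested, df) {
  stat <- 2 * (ell_main - ell_nested)
  if (stat < -1e-6)
    stop("main model fits worse than the nested model (LRT = ",
         format(stat, digits = 4),
         "); models may not be nested, or the optimizer failed")
  if (stat < 0) {
    warning("tiny negative LRT statistic (", format(stat, digits = 3),
            ") clipped to 0")
    stat <- 0
  }
  df <- as.integer(df)
  if (df < 0L) stop("'df' must be nonnegative")
  p <- if (df == 0L) as.numeric(stat <= 0) else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 ell_main = ell_main, ell_nested = ell_nested),
            class = "mvgreml_lrt")
}

#' @export
print.mvgreml_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of nested factor models\n")
  cat(sprintf("  ell(main) = %.4f, ell(nested) = %.4f\n",
              x$ell_main, x$ell_nested))
  cat(sprintf("  LRT = %.4f, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# --- methods --------------------------------------------------------------

#' @export
print.mvgreml <- function(x, digits = 4, ...) {
  cat("Multivariate GREML fit:", x$T, "traits,", x$N, "individuals (",
      x$L, "leading PCs removed )\n")
  cat("  genetic model:", ncol(x$CG), "factors,", n_free(x$genetic_model),
      "free loadings;  environmental model:", ncol(x$CE), "factors,",
      n_free(x$environment_model), "free loadings\n")
  cat("  restricted log-likelihood:", format(x$loglik, digits = 10),
      if (!x$converged) " (NOT converged)", "\n")
  cat("  SNP heritability estimates:\n")
  h <- format(round(x$h2, digits))
  if (!is.null(x$se)) h <- paste0(h, " (", format(round(x$se$h2_se, digits)),
                                  ")")
  names(h) <- x$traits
  print(h, quote = FALSE)
  invisible(x)
}

#' Summarize a multivariate GREML fit
#'
#' @param object an `mvgreml` fit.
#' @param ... unused.
#' @return A list of class `summary.mvgreml` with the heritability table,
#'   genetic and environmental correlation matrices (and their standard
#'   errors when available), the GLS fixed-effect table and fit diagnostics.
#' @export
summary.mvgreml <- function(object, ...) {
  h2_tab <- data.frame(trait = object$traits, h2 = as.vector(object$h2),
                       se = if (is.null(object$se)) NA_real_ else
                         object$se$h2_se,
                       row.names = NULL)
  structure(list(
    call = object$call,
    h2 = h2_tab,
    rhoG = object$rhoG, rhoG_se = object$se$rhoG_se,
    rhoE = object$rhoE, rhoE_se = object$se$rhoE_se,
    beta = object$beta,
    loglik = object$loglik, converged = object$converged,
    n_iter = object$n_iter, N = object$N, L = object$L, T = object$T
  ), class = "summary.mvgreml")
}

#' @export
print.summary.mvgreml <- function(x, digits = 4, ...) {
  cat("Multivariate GREML:", x$T, "traits,", x$N, "individuals, L =", x$L,
      "\n")
  cat("Restricted log-likelihood:", format(x$loglik, digits = 10), "(",
      x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n\n")
  cat("SNP heritability:\n")
  print(x$h2, digits = digits, row.names = FALSE)
  cat("\nGenetic correlations:\n")
  print(round(x$rhoG, digits))
  if (!is.null(x$rhoG_se)) {
    cat("\nSE of genetic correlations:\n")
    print(round(x$rhoG_se, digits))
  }
  cat("\nEnvironmental correlations:\n")
  print(round(x$rhoE, digits))
  if (!is.null(x$beta)) {
    cat("\nGLS fixed effects:\n")
    print(x$beta, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mvgreml <- function(object, type = c("beta", "theta"), ...) {
  type <- match.arg(type)
  if (type == "theta") {
    th <- object$theta
    names(th) <- paste0(object$index$mat, "[",
                        object$traits[object$index$t], ",",
                        object$index$f, "]")
    return(th)
  }
  if (is.null(object$beta)) return(numeric(0))
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
logLik.mvgreml <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n * object$T, class = "logLik")
}

#' @export
vcov.mvgreml <- function(object, ...) {
  if (is.null(object$theta_cov))
    stop("fit was run without standard errors (se = FALSE)")
  object$theta_cov
}

#' Extract SNP-heritability estimates
#'
#' @param object an `mvgreml` fit.
#' @return Data frame with one row per trait: estimate and (if computed)
#'   delta-method standard error.
#' @export
heritability <- function(object) {
  stopifnot(inherits(object, "mvgreml"))
  data.frame(trait = object$traits, h2 = as.vector(object$h2),
             se = if (is.null(object$se)) NA_real_ else object$se$h2_se,
             row.names = NULL)
}

#' Extract genetic or environmental correlation matrices
#'
#' @param object an `mvgreml` fit.
#' @param type `"genetic"` or `"environmental"`.
#' @return The correlation matrix, with the matching standard-error matrix
#'   attached as attribute `"se"` when available. Entries involving a trait
#'   with zero genetic variance are `NA` (undefined), never 0.
#' @export
correlations <- function(object, type = c("genetic", "environmental")) {
  stopifnot(inherits(object, "mvgreml"))
  type <- match.arg(type)
  if (type == "genetic")
    structure(object$rhoG, se = object$se$rhoG_se)
  else structure(object$rhoE, se = object$se$rhoE_se)
}
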