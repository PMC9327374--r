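#' Genetic and environmental factor models
#'
#' A factor model for T traits and F factors is a binary T x F pattern: entry
#' (t, f) is 1 when factor f has a free path coefficient (loading) to trait t
#' and 0 when that loading is constrained to zero. The implied variance matrix
#' is `V = C C'` with `C` the T x F loading matrix carrying free coefficients
#' at the pattern's ones, so `V` is positive semidefinite by construction and
#' the implied correlation matrices are always valid. Factors are orthogonal
#' with unit variance; equality constraints between loadings are not
#' supported.
#'
#' @param pattern binary T x F matrix (values 0/1). A T x 0 matrix encodes a
#'   model with no factors (zero variance), e.g. a null genetic model.
#' @param traits trait labels; defaults to the pattern's row names.
#' @param factors factor labels; defaults to the pattern's column names.
#' @return An object of class `factor_model` with elements `traits`,
#'   `factors` and `pattern`.
#' @examples
#' saturated_factor_model(c("height", "bmi"))
#' factor_model(cbind(shared = c(1, 1)), traits = c("height", "bmi"))
#' @export
factor_model <- function(pattern, traits = rownames(pattern),
                         factors = colnames(pattern)) {
  pattern <- as.matrix(pattern)
  if (nrow(pattern) < 1L) stop("a factor model needs at least one trait")
  suppressWarnings(storage.mode(pattern) <- "double")
  if (anyNA(pattern) || !all(pattern %in% c(0, 1)))
    stop("factor model pattern must be binary (0/1)")
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(pattern)))
  if (is.null(factors) && ncol(pattern) > 0L)
    factors <- paste0("factor", seq_len(ncol(pattern)))
  if (length(traits) != nrow(pattern)) stop("trait labels do not match rows")
  if (length(factors) != ncol(pattern)) stop("factor labels do not match columns")
  if (anyDuplicated(traits)) stop("duplicate trait labels")
  if (ncol(pattern) > 0L && any(colSums(pattern) == 0))
    stop("every factor must load on at least one trait")
  dimnames(pattern) <- list(traits, factors)
  structure(list(traits = as.character(traits),
                 factors = as.character(factors),
                 pattern = pattern),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model:", nrow(x$pattern), "traits,", ncol(x$pattern),
      "factors,", n_free(x), "free loadings\n")
  if (ncol(x$pattern) > 0L && nrow(x$pattern) <= 20L)
    print(x$pattern)
  invisible(x)
}

#' @param x a `factor_model`.
#' @rdname factor_model
#' @export
n_free <- function(x) {
  stopifnot(inherits(x, "factor_model"))
  as.integer(sum(x$pattern))
}

#' Saturated factor model
#'
#' The default model: a T x T lower-triangular pattern of ones, with
#' T(T+1)/2 free loadings. A saturated model can represent any positive
#' semidefinite T x T variance matrix, hence any proper correlation matrix
#' (with T(T-1)/2 distinct correlations).
#'
#' @param traits trait labels (or a single integer T, in which case traits
#'   are labelled `trait1..traitT`).
#' @return A `factor_model` with lower-triangular pattern.
#' @export
saturated_factor_model <- function(traits) {
  if (is.numeric(traits) && length(traits) == 1L) {
    if (traits < 1) stop("need at least one trait")
    traits <- paste0("trait", seq_len(traits))
  }
  tt <- length(traits)
  pat <- matrix(0, tt, tt)
  pat[lower.tri(pat, diag = TRUE)] <- 1
  factor_model(pat, traits = traits, factors = paste0("factor", seq_len(tt)))
}

#' Null factor model
#'
#' A model with no factors at all: the implied variance matrix is zero and
#' there are no free coefficients. Used as the nested genetic model when
#' testing whether traits have any genetic variance.
#'
#' @inheritParams saturated_factor_model
#' @export
null_factor_model <- function(traits) {
  if (is.numeric(traits) && length(traits) == 1L)
    traits <- paste0("trait", seq_len(traits))
  factor_model(matrix(0, length(traits), 0), traits = traits,
               factors = character(0))
}

#' Read a factor model specification file
#'
#' The on-disk form is a labelled binary matrix: one header row of factor
#' labels, one leading column of trait labels, cells 0 or 1. Rows are matched
#' to `traits` by label (any row order is accepted) and reordered.
#'
#' @param path path to the specification file.
#' @param traits trait labels fixing the row order.
#' @return A [factor_model].
#' @export
read_factor_model <- function(path, traits) {
  m <- .read_labeled_binary(path)
  if (nrow(m) != length(traits) || !setequal(rownames(m), traits))
    stop("factor model rows in ", path,
         " must be a permutation of the trait labels")
  factor_model(m[traits, , drop = FALSE], traits = traits,
               factors = colnames(m))
}

#' Write a factor model specification file
#'
#' @param x a [factor_model].
#' @param path output path.
#' @export
write_factor_model <- function(x, path) {
  stopifnot(inherits(x, "factor_model"))
  tab <- data.frame(Trait = x$traits, x$pattern, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- free-coefficient bookkeeping -----------------------------------------

# theta holds all genetic loadings first (row-major over the pattern), then
# all environmental loadings; the index records (matrix, trait, factor) per
# entry so any fixed order could be swapped in without touching the kernel
.theta_index <- function(spec_g, spec_e) {
  one <- function(spec, tag) {
    w <- which(spec$pattern == 1, arr.ind = TRUE)
    if (nrow(w) == 0L)
      return(data.frame(mat = character(0), t = integer(0), f = integer(0)))
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
    data.frame(mat = tag, t = as.integer(w[, 1L]), f = as.integer(w[, 2L]))
  }
  idx <- rbind(one(spec_g, "G"), one(spec_e, "E"))
  rownames(idx) <- NULL
  idx
}

# place free coefficients into C_G / C_E and form V = C C'
.implied_variance <- function(theta, spec_g, spec_e, index = NULL) {
  if (is.null(index)) index <- .theta_index(spec_g, spec_e)
  if (length(theta) != nrow(index))
    stop("theta has length ", length(theta), " but the patterns imply ",
         nrow(index), " free coefficients")
  tt <- nrow(spec_g$pattern)
  cg <- matrix(0, tt, ncol(spec_g$pattern))
  ce <- matrix(0, tt, ncol(spec_e$pattern))
  ig <- index$mat == "G"
  cg[cbind(index$t[ig], index$f[ig])] <- theta[ig]
  ce[cbind(index$t[!ig], index$f[!ig])] <- theta[!ig]
  dimnames(cg) <- dimnames(spec_g$pattern)
  dimnames(ce) <- dimnames(spec_e$pattern)
  list(CG = cg, CE = ce, VG = tcrossprod(cg), VE = tcrossprod(ce))
}

# d V / d theta_i for V = C C': rank-<=2 matrix e_t c_f' + c_f e_t'
# returned with the generating vectors alongside the dense matrix
.variance_derivative <- function(i, vs, index) {
  t_ <- index$t[i]
  f_ <- index$f[i]
  cmat <- if (index$mat[i] == "G") vs$CG else vs$CE
  tt <- nrow(cmat)
  cf <- cmat[, f_]
  et <- numeric(tt)
  et[t_] <- 1
  dv <- tcrossprod(et, cf)
  dv <- dv + t(dv)
  list(mat = index$mat[i], t = t_, f = f_, e = et, c = cf, dV = dv)
}

#' Check identification of a factor-model pair
#'
#' Applies the standard structural-equation-model identification conditions
#' numerically: (a) neither matrix may carry more free coefficients than the
#' T(T+1)/2 entries of a symmetric variance matrix; (b) the Jacobian of the
#' half-vectorized implied (V_G, V_E) with respect to the free coefficients
#' must have full column rank at random interior points (local
#' identification); (c) duplicated factor columns within a matrix are flagged
#' (they are never identified, by permutation symmetry).
#'
#' @param spec_g,spec_e genetic and environmental [factor_model]s over the
#'   same traits.
#' @param n_draws number of random evaluation points for the rank check.
#' @param seed seed for the random draws.
#' @return A list of class `identification_report` with logical `identified`,
#'   the free counts, the observed Jacobian rank, and diagnostic `problems`.
#' @export
check_identification <- function(spec_g, spec_e, n_draws = 3L, seed = 1L) {
  stopifnot(inherits(spec_g, "factor_model"), inherits(spec_e, "factor_model"))
  tt <- nrow(spec_g$pattern)
  if (nrow(spec_e$pattern) != tt)
    stop("genetic and environmental models disagree on the trait count")
  problems <- character(0)
  max_free <- tt * (tt + 1) / 2
  cg <- n_free(spec_g)
  ce <- n_free(spec_e)
  if (cg > max_free)
    problems <- c(problems, sprintf(
      "genetic model has %d free loadings; a %d-trait variance matrix supports at most %d",
      cg, tt, max_free))
  if (ce > max_free)
    problems <- c(problems, sprintf(
      "environmental model has %d free loadings; at most %d are identifiable",
      ce, max_free))
  dup <- function(spec, lab) {
    if (ncol(spec$pattern) < 2L) return(character(0))
    d <- duplicated(t(spec$pattern))
    if (any(d)) sprintf("%s model has duplicated factor columns (%s)", lab,
                        paste(spec$factors[d], collapse = ", "))
    else character(0)
  }
  problems <- c(problems, dup(spec_g, "genetic"), dup(spec_e, "environmental"))

  index <- .theta_index(spec_g, spec_e)
  p <- nrow(index)
  rank_obs <- 0L
  if (p > 0L) {
    lt <- which(lower.tri(matrix(0, tt, tt), diag = TRUE))
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    for (r in seq_len(n_draws)) {
      theta <- stats::runif(p, 0.5, 1.5) * sample(c(-1, 1), p, replace = TRUE)
      vs <- .implied_variance(theta, spec_g, spec_e, index)
      jac <- vapply(seq_len(p), function(i) {
        dv <- .variance_derivative(i, vs, index)
        out <- numeric(2 * length(lt))
        if (dv$mat == "G") out[seq_along(lt)] <- dv$dV[lt]
        else out[length(lt) + seq_along(lt)] <- dv$dV[lt]
        out
      }, numeric(2 * length(lt)))
      rank_obs <- max(rank_obs, qr(jac)$rank)
    }
    if (rank_obs < p)
      problems <- c(problems, sprintf(
        "model is not locally identified: Jacobian rank %d < %d free coefficients",
        rank_obs, p))
  }
  structure(list(identified = length(problems) == 0L,
                 n_free_genetic = cg, n_free_environment = ce,
                 jacobian_rank = rank_obs, n_parameters = p,
                 problems = problems),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Identification check:",
      if (x$identified) "passed" else "FAILED", "\n")
  cat("  free loadings: genetic", x$n_free_genetic, ", environmental",
      x$n_free_environment, "\n")
  cat("  Jacobian rank:", x$jacobian_rank, "of", x$n_parameters,
      "parameters\n")
  for (pb in x$problems) cat("  problem:", pb, "\n")
  invisible(x)
}

#' Degrees of freedom of a likelihood-ratio test between nested factor models
#'
#' The test statistic comparing a main model A against a model nested within
#' it is chi-square distributed with degrees of freedom equal to the
#' difference in free-coefficient counts,
#' `(C_GA + C_EA) - (C_G0 + C_E0)`.
#'
#' @param main,nested lists with components `genetic` and `environment`, each
#'   a [factor_model] (a single `factor_model` is also accepted and counted
#'   on its own).
#' @return Integer degrees of freedom.
#' @export
lrt_df <- function(main, nested) {
  count <- function(m) {
    if (inherits(m, "factor_model")) return(n_free(m))
    if (!all(c("genetic", "environment") %in% names(m)))
      stop("expected a list with 'genetic' and 'environment' factor models")
    n_free(m$genetic) + n_free(m$environment)
  }
  df <- count(main) - count(nested)
  if (df < 0L)
    stop("the nested model has more free coefficients than the main model; ",
         "the models cannot be nested as given")
  as.integer(df)
}

# save/restore .Random.seed so internal draws do not disturb user RNG state
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
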