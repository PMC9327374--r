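#' Phenotype and covariate tables
#'
#' Phenotype and covariate files are whitespace-delimited text with a header
#' row; the first two columns are the family and individual identifiers
#' (`FID`, `IID`) and the remaining columns are labelled traits or covariates.
#'
#' @param path path to the file.
#' @return For `read_pheno`, a `pheno_data` object with elements `ids`,
#'   `traits` (labels) and `Y` (N x T numeric matrix). For `read_covar`, a
#'   `covar_data` object with `ids`, `covars` and `X` (N x k), plus a
#'   `trait_map` slot that defaults to all covariates applying to all traits
#'   (set from a covariate model file via [read_covar_model]).
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("phenotype file needs FID, IID and >= 1 trait")
  ids <- .as_id_frame(tab[, 1:2])
  Y <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(Y) <- "double"
  pheno_data(ids, Y)
}

#' @param ids sample identifiers (see [grm_data]).
#' @param Y numeric N x T matrix with unique column names (trait labels).
#' @rdname read_pheno
#' @export
pheno_data <- function(ids, Y) {
  ids <- .as_id_frame(ids)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  if (nrow(Y) != nrow(ids)) stop("'Y' and 'ids' disagree on N")
  if (anyDuplicated(colnames(Y))) stop("duplicate trait labels")
  structure(list(ids = ids, traits = colnames(Y), Y = Y),
            class = "pheno_data")
}

#' @export
print.pheno_data <- function(x, ...) {
  cat("Phenotypes:", nrow(x$Y), "individuals x", ncol(x$Y), "traits\n")
  cat("  traits:", paste(utils::head(x$traits, 8), collapse = ", "),
      if (length(x$traits) > 8) "...", "\n")
  invisible(x)
}

#' @rdname read_pheno
#' @export
read_covar <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("covariate file needs FID, IID and >= 1 covariate")
  ids <- .as_id_frame(tab[, 1:2])
  X <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  covar_data(ids, X)
}

#' @param X numeric N x k covariate matrix with unique column names.
#' @param trait_map binary T x k matrix; entry (t, j) is 1 when covariate j
#'   applies to trait t. `NULL` means every covariate applies to every trait.
#' @rdname read_pheno
#' @export
covar_data <- function(ids, X, trait_map = NULL) {
  ids <- .as_id_frame(ids)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("covar", seq_len(ncol(X)))
  if (nrow(X) != nrow(ids)) stop("'X' and 'ids' disagree on N")
  if (anyDuplicated(colnames(X))) stop("duplicate covariate labels")
  if (!is.null(trait_map)) {
    trait_map <- as.matrix(trait_map)
    if (ncol(trait_map) != ncol(X))
      stop("'trait_map' columns must match covariates")
    if (!all(trait_map %in% c(0, 1)))
      stop("'trait_map' must be binary")
    if (any(rowSums(trait_map) == 0))
      stop("every trait must have at least one applicable covariate ",
           "when a covariate model is used")
  }
  structure(list(ids = ids, covars = colnames(X), X = X,
                 trait_map = trait_map), class = "covar_data")
}

#' Read a covariate-to-trait model
#'
#' A covariate model file is a labelled binary matrix: one header row of
#' covariate labels, one leading column of trait labels, cells 1 (covariate
#' applies to that trait) or 0. Rows are matched to `traits` by label.
#'
#' @param path path to the covariate model file.
#' @param covar a `covar_data` object the map applies to.
#' @param traits character vector of trait labels fixing the row order.
#' @return `covar` with its `trait_map` slot filled in.
#' @export
read_covar_model <- function(path, covar, traits) {
  m <- .read_labeled_binary(path)
  if (!setequal(rownames(m), traits) || nrow(m) != length(traits))
    stop("covariate model rows must be a permutation of the trait labels")
  if (!setequal(colnames(m), covar$covars) || ncol(m) != length(covar$covars))
    stop("covariate model columns must match the covariate labels")
  covar_data(covar$ids, covar$X,
             trait_map = m[traits, covar$covars, drop = FALSE])
}

# whitespace-delimited labelled 0/1 matrix: header row of column labels,
# leading column of row labels
.read_labeled_binary <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           row.names = 1L, colClasses = "character")
  m <- as.matrix(tab)
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("format error in ", path, ": entries must all be 0 or 1")
  m
}

#' Restrict GRM, phenotypes and covariates to common samples
#'
#' Restricts all inputs, in identical order, to the individuals present in
#' every table, and drops individuals with a missing value in any trait or in
#' any covariate that applies to at least one trait. Sample order follows the
#' GRM. The operation is idempotent.
#'
#' @param grm a [grm_data] object.
#' @param pheno a [pheno_data] object.
#' @param covar optional [covar_data] object.
#' @return A list with elements `grm`, `pheno` and `covar` (the latter `NULL`
#'   when not supplied).
#' @export
align_samples <- function(grm, pheno, covar = NULL) {
  stopifnot(inherits(grm, "grm_data"), inherits(pheno, "pheno_data"))
  kg <- .id_key(grm$ids)
  kp <- .id_key(pheno$ids)
  common <- intersect(kg, kp)
  if (!is.null(covar)) common <- intersect(common, .id_key(covar$ids))
  if (length(common) == 0L)
    stop("no individuals shared between the GRM and the phenotype",
         if (!is.null(covar)) "/covariate", " tables")
  # complete cases across traits and applicable covariates
  pi <- match(common, kp)
  ok <- stats::complete.cases(pheno$Y[pi, , drop = FALSE])
  if (!is.null(covar)) {
    used <- if (is.null(covar$trait_map)) rep(TRUE, ncol(covar$X)) else
      colSums(covar$trait_map) > 0
    ci <- match(common, .id_key(covar$ids))
    ok <- ok & stats::complete.cases(covar$X[ci, used, drop = FALSE])
  }
  common <- common[ok]
  if (length(common) == 0L)
    stop("no individuals left after removing missing values")
  keep <- sort(match(common, kg))          # preserve GRM order
  key <- kg[keep]
  n <- length(key)
  tt <- length(pheno$traits)
  k <- if (is.null(covar)) 0L else ncol(covar$X)
  if (n < tt + k + 1L)
    stop("only ", n, " individuals remain; too few for ", tt, " traits and ",
         k, " covariates")
  grm_out <- grm_data(grm$ids[keep, ], grm$A[keep, keep],
                      grm$n_pairs[keep, keep])
  pi <- match(key, kp)
  ph_out <- pheno_data(pheno$ids[pi, ], pheno$Y[pi, , drop = FALSE])
  cv_out <- NULL
  if (!is.null(covar)) {
    ci <- match(key, .id_key(covar$ids))
    cv_out <- covar_data(covar$ids[ci, ], covar$X[ci, , drop = FALSE],
                         covar$trait_map)
  }
  list(grm = grm_out, pheno = ph_out, covar = cv_out)
}
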