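#' Simulation designs for multivariate GREML
#'
#' Three stock designs generate genotypes, a GRM and multivariate polygenic
#' phenotypes under the GREML model, for validating estimation and inference
#' without any external data:
#'
#' * design 1 - T = 10 traits, SNP heritability 0.5 for every trait, one
#'   uniform genetic correlation `rho` across all trait pairs;
#' * design 2 - two clusters of traits (default two clusters of five),
#'   random genetic correlations within clusters (drawn through a random
#'   single-factor structure, which keeps the matrix positive semidefinite)
#'   and exactly zero between clusters;
#' * design 3 - T = 50 independent traits (`rho = 0`), heritability 0.5.
#'
#' Defaults are full-scale (`N = 20000` individuals, `M = 20000` SNPs); every
#' field can be overridden for desk-scale runs.
#'
#' @param design 1, 2 or 3.
#' @param N individuals.
#' @param M SNPs (all causal, infinitesimal effects).
#' @param T_traits trait count; defaults to 10 (designs 1-2) or 50 (design 3).
#' @param h2 target SNP heritability, recycled to T traits.
#' @param rho uniform genetic correlation (design 1 only).
#' @param rho_E uniform environmental correlation (default 0).
#' @param cluster_sizes design 2: sizes of the two clusters (default splits
#'   the traits in half).
#' @param maf_range allele-frequency bounds, within (0, 0.5].
#' @param n_replicates replicate count carried in the design.
#' @param seed master seed; each replicate derives its own stream from
#'   (seed, replicate).
#' @return A list of class `sim_design`.
#' @export
simulation_design <- function(design = 1, N = 20000, M = 20000,
                              T_traits = NULL, h2 = 0.5, rho = 0.3,
                              rho_E = 0, cluster_sizes = NULL,
                              maf_range = c(0.01, 0.5),
                              n_replicates = if (design == 3) 1 else 100,
                              seed = 1L) {
  design <- as.integer(design)
  if (!design %in% 1:3) stop("'design' must be 1, 2 or 3")
  if (is.null(T_traits)) T_traits <- if (design == 3) 50L else 10L
  T_traits <- as.integer(T_traits)
  h2 <- rep_len(h2, T_traits)
  if (any(h2 < 0 | h2 > 1)) stop("'h2' must lie in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("'maf_range' must lie within (0, 0.5]")
  if (design == 1 && T_traits > 1 && (rho <= -1 / (T_traits - 1) || rho > 1))
    stop("uniform correlation rho = ", rho, " is not positive semidefinite ",
         "for ", T_traits, " traits")
  if (design == 3) rho <- 0
  if (design == 2) {
    if (is.null(cluster_sizes))
      cluster_sizes <- c(ceiling(T_traits / 2), floor(T_traits / 2))
    if (sum(cluster_sizes) != T_traits)
      stop("'cluster_sizes' must sum to the trait count")
  }
  structure(list(design = design, N = as.integer(N), M = as.integer(M),
                 T_traits = T_traits, h2 = h2, rho = rho, rho_E = rho_E,
                 cluster_sizes = cluster_sizes, maf_range = maf_range,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design", x$design, ": N =", x$N, ", M =", x$M,
      ", T =", x$T_traits, "\n")
  cat("  target h2:", paste(unique(x$h2), collapse = ", "),
      switch(x$design,
             paste(" uniform rho_G =", x$rho),
             paste(" two clusters of", paste(x$cluster_sizes, collapse = "/"),
                   "traits, rho_G = 0 between"),
             " rho_G = 0"), "\n")
  invisible(x)
}

# independent replicate streams derived from (master seed, replicate);
# kept below 2^31 so the value is a valid R integer seed
.replicate_seed <- function(seed, replicate) {
  as.integer((as.double(seed) * 48271 + as.double(replicate) * 69621 + 11)
             %% 2147483647)
}

# symmetric PSD square root via eigendecomposition (chol would reject the
# rank-deficient targets such as rho = 1)
.psd_sqrt <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# target variance matrices for a design; design 2 draws its within-cluster
# correlations from the replicate stream (loadings uniform on [-1, 1])
.target_variances <- function(design) {
  tt <- design$T_traits
  h2 <- design$h2
  R <- diag(tt)
  if (design$design == 1) {
    R[] <- design$rho
    diag(R) <- 1
  } else if (design$design == 2) {
    off <- 0L
    for (cs in design$cluster_sizes) {
      idx <- off + seq_len(cs)
      u <- stats::runif(cs, -1, 1)
      blk <- tcrossprod(u)
      diag(blk) <- 1
      R[idx, idx] <- blk
      off <- off + cs
    }
  }
  sd_g <- sqrt(h2)
  VG <- R * tcrossprod(sd_g)
  RE <- diag(tt)
  if (design$rho_E != 0) {
    RE[] <- design$rho_E
    diag(RE) <- 1
  }
  sd_e <- sqrt(1 - h2)
  VE <- RE * tcrossprod(sd_e)
  list(VG = VG, VE = VE)
}

#' Simulate a multivariate GREML dataset
#'
#' Draws allele frequencies uniform on the design's range, genotypes as
#' binomial(2, p) counts standardized in-sample, per-SNP effects jointly
#' normal across traits with covariance `V_G / M` (so genetic values have
#' covariance `V_G (x) A` with `A` the realized GRM), and environmental
#' residuals jointly normal with covariance `V_E`. Total per-trait variance
#' is 1, so `diag(V_G)` equals the target heritabilities. Deterministic
#' given (design seed, replicate).
#'
#' @param design a [simulation_design].
#' @param replicate replicate number (1-based).
#' @return A list of class `sim_dataset` with elements `grm` ([grm_data]),
#'   `pheno` ([pheno_data]), `true_VG`, `true_VE`, `genetic_values`,
#'   `realized_h2`, `replicate`.
#' @export
simulate_dataset <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.replicate_seed(design$seed, replicate))
  n <- design$N
  m <- design$M
  tt <- design$T_traits
  tv <- .target_variances(design)   # design-2 draws happen on this stream
  p <- stats::runif(m, design$maf_range[1], design$maf_range[2])
  G012 <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  G <- standardize_genotypes(G012)
  m_eff <- ncol(G)
  if (m_eff == 0L) stop("all simulated SNPs were monomorphic; increase N or the allele-frequency bounds")
  ids <- data.frame(FID = sprintf("FAM%06d", seq_len(n)),
                    IID = sprintf("ID%06d", seq_len(n)))
  grm <- compute_grm(G, ids)
  sq_g <- .psd_sqrt(tv$VG)
  sq_e <- .psd_sqrt(tv$VE)
  B <- matrix(stats::rnorm(m_eff * tt), m_eff, tt) %*% sq_g / sqrt(m_eff)
  gval <- G %*% B
  eval_ <- matrix(stats::rnorm(n * tt), n, tt) %*% sq_e
  Y <- gval + eval_
  colnames(Y) <- paste0("trait", seq_len(tt))
  vg_real <- apply(gval, 2L, stats::var)
  vy_real <- apply(Y, 2L, stats::var)
  structure(list(grm = grm, pheno = pheno_data(ids, Y),
                 true_VG = tv$VG, true_VE = tv$VE,
                 genetic_values = gval,
                 realized_h2 = vg_real / vy_real,
                 replicate = as.integer(replicate), M_effective = m_eff),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset (replicate", x$replicate, "):",
      nrow(x$pheno$Y), "individuals x", ncol(x$pheno$Y), "traits,",
      x$M_effective, "SNPs\n")
  cat("  realized h2:",
      paste(format(utils::head(x$realized_h2, 6), digits = 3),
            collapse = ", "),
      if (length(x$realized_h2) > 6) "...", "\n")
  invisible(x)
}

#' Write a simulated dataset as analysis-ready fixture files
#'
#' Emits the GCTA binary GRM triple, a whitespace-delimited phenotype file,
#' and plain-text truth tables (`prefix.true_VG.txt`, `prefix.true_VE.txt`,
#' `prefix.realized_h2.txt`) for downstream assertions.
#'
#' @param ds a `sim_dataset`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "sim_dataset"))
  write_grm(ds$grm, prefix)
  ph <- data.frame(FID = ds$pheno$ids$FID, IID = ds$pheno$ids$IID,
                   ds$pheno$Y, check.names = FALSE)
  utils::write.table(format(ph, digits = 10, trim = TRUE),
                     paste0(prefix, ".pheno.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wr <- function(m, suffix) {
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       paste0(prefix, ".", suffix, ".txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  wr(ds$true_VG, "true_VG")
  wr(ds$true_VE, "true_VE")
  wr(matrix(ds$realized_h2, nrow = 1), "realized_h2")
  invisible(prefix)
}
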