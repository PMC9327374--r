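# Shared fixture builders: everything is generated in code at test time.

make_ids <- function(n) {
  data.frame(FID = sprintf("f%03d", seq_len(n)),
             IID = sprintf("i%03d", seq_len(n)))
}

# small positive-definite GRM from random genotypes (M >= N so A is PD a.s.)
make_grm <- function(n, m = n + 20, maf = 0.3) {
  G <- standardize_genotypes(matrix(rbinom(n * m, 2, maf), n, m))
  compute_grm(G, make_ids(n))
}

make_pheno <- function(n, t, ids = make_ids(n)) {
  Y <- matrix(rnorm(n * t), n, t)
  colnames(Y) <- paste0("t", seq_len(t))
  pheno_data(ids, Y)
}

# random coefficients for a spec pair, bounded away from zero so V_E is PD
random_theta <- function(spec_g, spec_e) {
  idx <- mvgreml:::.theta_index(spec_g, spec_e)
  runif(nrow(idx), 0.4, 1.2) * sample(c(-1, 1), nrow(idx), replace = TRUE)
}

# a complete small random REML instance on transformed data (L = 0)
make_instance <- function(n, t, m = n + 20, covar = FALSE) {
  grm <- make_grm(n, m)
  ph <- make_pheno(n, t, grm$ids)
  cv <- NULL
  if (covar) {
    X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "age"))
    cv <- covar_data(grm$ids, X)
  }
  sg <- saturated_factor_model(ph$traits)
  se_ <- saturated_factor_model(ph$traits)
  idx <- mvgreml:::.theta_index(sg, se_)
  theta <- runif(nrow(idx), 0.4, 1.2)
  vs <- mvgreml:::.implied_variance(theta, sg, se_, idx)
  eig <- grm_eigen(grm)
  td <- canonical_transform(eig, ph, cv, L = 0)
  list(grm = grm, pheno = ph, covar = cv, spec_g = sg, spec_e = se_,
       index = idx, theta = theta, vs = vs, eig = eig, td = td)
}

# the 10-trait height/BMI factor pattern used in the worked examples:
# five height waves loading on factors 1 and 3, five BMI waves on 2 and 3
height_bmi_traits <- c(paste0("height", 7:11), paste0("bmi", 7:11))

height_bmi_model <- function(shared = TRUE) {
  pat <- cbind(G_height = rep(c(1, 0), each = 5),
               G_bmi = rep(c(0, 1), each = 5))
  if (shared) pat <- cbind(pat, G_shared = rep(1, 10))
  factor_model(pat, traits = height_bmi_traits)
}
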