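test_that("heritability and correlations follow the variance-component ratios", {
  hc <- mvgreml:::.h2_and_correlations(diag(c(1, 1)), diag(c(1, 1)))
  expect_equal(unname(hc$h2), c(0.5, 0.5))
  expect_equal(hc$rhoG, diag(2), ignore_attr = TRUE)
  VG <- matrix(c(1, 0.5, 0.5, 4), 2, 2)
  hc2 <- mvgreml:::.h2_and_correlations(VG, diag(2))
  expect_equal(hc2$rhoG[1, 2], 0.25)
  expect_error(mvgreml:::.h2_and_correlations(matrix(0, 1, 1),
                                              matrix(0, 1, 1)),
               "zero total variance")
})

test_that("zero-genetic-variance traits get NA correlations, never 0", {
  VG <- diag(c(1, 0, 2))
  hc <- mvgreml:::.h2_and_correlations(VG, diag(3))
  expect_true(is.na(hc$rhoG[1, 2]))
  expect_true(is.na(hc$rhoG[2, 2]))
  expect_equal(hc$rhoG[1, 3], 0)
  expect_equal(hc$rhoG[3, 3], 1)
})

test_that("fitted genetic correlation matrices are PSD with unit diagonal", {
  set.seed(41)
  d <- simulation_design(1, N = 400, M = 500, T_traits = 3, rho = 0.6,
                         seed = 2)
  ds <- simulate_dataset(d, 1)
  fit <- mvgreml(ds$pheno, ds$grm, adjust_pcs = 0, se = FALSE)
  expect_equal(diag(fit$rhoG), rep(1, 3), ignore_attr = TRUE)
  expect_gte(min(eigen(fit$rhoG, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_true(all(abs(fit$rhoG) <= 1 + 1e-10))
})

test_that("delta-method Jacobians agree with finite differences", {
  set.seed(42)
  sg <- saturated_factor_model(3)
  se_ <- saturated_factor_model(3)
  idx <- mvgreml:::.theta_index(sg, se_)
  for (r in 1:5) {
    th <- random_theta(sg, se_)
    an <- mvgreml:::.summary_jacobians(th, sg, se_, idx)
    fd <- mvgreml:::.summary_jacobians_fd(th, sg, se_, idx)
    expect_lt(max(abs(an$h2 - fd$h2)), 1e-6)
    expect_lt(max(abs(an$rhoG - fd$rhoG)), 1e-6)
    expect_lt(max(abs(an$rhoE - fd$rhoE)), 1e-6)
  }
})

test_that("delta-method SEs propagate the coefficient covariance exactly", {
  set.seed(48)
  sg <- saturated_factor_model(2)
  idx <- mvgreml:::.theta_index(sg, sg)
  th <- random_theta(sg, sg)
  p <- length(th)
  L <- matrix(rnorm(p * p), p) / p
  theta_cov <- tcrossprod(L) + diag(1e-3, p)
  ses <- mvgreml:::.delta_method_ses(th, theta_cov, sg, sg, idx)
  J <- mvgreml:::.summary_jacobians_fd(th, sg, sg, idx)
  expect_equal(ses$h2_se,
               sqrt(diag(J$h2 %*% theta_cov %*% t(J$h2))),
               tolerance = 1e-6)
  expect_equal(ses$rhoG_se[2, 1],
               sqrt((J$rhoG %*% theta_cov %*% t(J$rhoG))[1, 1]),
               tolerance = 1e-6)
})

test_that("reported SEs track the spread of estimates across replicates", {
  set.seed(43)
  d <- simulation_design(1, N = 500, M = 500, T_traits = 2, rho = 0.5,
                         seed = 77)
  h2_est <- matrix(NA_real_, 8, 2)
  h2_se <- matrix(NA_real_, 8, 2)
  for (r in 1:8) {
    ds <- simulate_dataset(d, r)
    fit <- mvgreml(ds$pheno, ds$grm, adjust_pcs = 0)
    h2_est[r, ] <- fit$h2
    h2_se[r, ] <- fit$se$h2_se
  }
  ratio <- mean(h2_se) / sd(as.vector(h2_est))
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.7)
})

test_that("GLS fixed effects reduce to OLS under identity covariance", {
  set.seed(44)
  n <- 30
  ids <- make_ids(n)
  grm <- make_grm(n, 60)
  ph <- make_pheno(n, 2, ids)
  cv <- covar_data(ids, matrix(rnorm(n), n, 1, dimnames = list(NULL, "x")))
  td <- canonical_transform(grm_eigen(grm), ph, cv, L = 0)
  sg <- null_factor_model(ph$traits)
  se_ <- factor_model(diag(2), traits = ph$traits)   # V_E = I at theta = 1
  idx <- mvgreml:::.theta_index(sg, se_)
  vs <- mvgreml:::.implied_variance(c(1, 1), sg, se_, idx)
  kb <- mvgreml:::.reml_kernel(td, vs, idx, want = "gls")
  for (t_ in 1:2) {
    ols <- coef(lm(ph$Y[, t_] ~ cv$X[, 1]))
    blk <- kb$beta[grepl(paste0("^t", t_, ":"), names(kb$beta))]
    expect_equal(unname(blk), unname(ols), tolerance = 1e-8)
  }
})

test_that("GLS recovers a known intercept and matches the dense oracle", {
  set.seed(45)
  d <- simulation_design(1, N = 600, M = 600, T_traits = 2, rho = 0.3,
                         seed = 11)
  ds <- simulate_dataset(d, 1)
  Y <- ds$pheno$Y
  Y[, 1] <- Y[, 1] + 5.0
  fit <- mvgreml(pheno_data(ds$pheno$ids, Y), ds$grm, adjust_pcs = 0)
  b1 <- fit$beta[fit$beta$term == "trait1:intercept", ]
  expect_lt(abs(b1$estimate - 5.0), 3 * b1$se)
  # dense-oracle GLS agreement at test scale
  inst <- make_instance(25, 2, covar = TRUE)
  kb <- mvgreml:::.reml_kernel(inst$td, inst$vs, inst$index, want = "gls")
  o <- mvgreml:::.dense_reml_oracle(inst$grm, inst$pheno, inst$covar,
                                    inst$vs)
  expect_lt(max(abs(kb$beta - o$beta)), 1e-8)
  expect_lt(max(abs(kb$beta_cov - o$beta_cov)), 1e-8)
})

test_that("likelihood-ratio tests reproduce the worked chi-square arithmetic", {
  r1 <- lrt(ell_main = 0, ell_nested = -72.03 / 2, df = 10)
  expect_equal(r1$statistic, 72.03)
  expect_equal(r1$p_value, 1.79e-11, tolerance = 5e-3)
  r2 <- lrt(ell_main = 0, ell_nested = -11.11 / 2, df = 10)
  expect_equal(r2$p_value, 0.349, tolerance = 5e-3)
  r0 <- lrt(ell_main = -5, ell_nested = -5, df = 3)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(lrt(-10, -5, 2), "fits worse")
})

test_that("anova on two fits computes the LRT with pattern-based df", {
  set.seed(46)
  d <- simulation_design(1, N = 300, M = 400, T_traits = 2, rho = 0.5,
                         seed = 23)
  ds <- simulate_dataset(d, 1)
  eig <- grm_eigen(ds$grm)
  main <- mvgreml(ds$pheno, eig, adjust_pcs = 0, se = FALSE)
  nested <- mvgreml(ds$pheno, eig, adjust_pcs = 0, se = FALSE,
                    genetic_model = factor_model(diag(2),
                                                 traits = ds$pheno$traits))
  out <- anova(main, nested)
  expect_s3_class(out, "mvgreml_lrt")
  expect_equal(out$df, 1L)
  expect_gte(out$statistic, 0)
  expect_equal(out$statistic, 2 * (main$loglik - nested$loglik))
  # reversed argument order is detected and swapped
  expect_message(out2 <- anova(nested, main), "main model")
  expect_equal(out2$statistic, out$statistic)
})
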