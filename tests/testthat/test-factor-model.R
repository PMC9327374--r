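test_that("specification files parse, reorder by trait label, and validate", {
  m <- height_bmi_model()
  path <- file.path(tempdir(), "fm.txt")
  write_factor_model(m, path)
  back <- read_factor_model(path, height_bmi_traits)
  expect_equal(back$pattern, m$pattern)
  expect_equal(n_free(back), 20L)

  # rows in scrambled order are matched by label
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  write.table(tab[sample(nrow(tab)), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_factor_model(path, height_bmi_traits)$pattern, m$pattern)

  # non-binary entry is a format error, unknown trait an input error
  tab2 <- tab
  tab2[1, 2] <- "2"
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_factor_model(path, height_bmi_traits), "0 or 1")
  write_factor_model(m, path)
  expect_error(read_factor_model(path, c("height7", "nope")), "permutation")
  expect_error(factor_model(matrix(c(1, 0, 0, 0), 2, 2)),
               "load on at least one trait")
})

test_that("saturated models have T(T+1)/2 loadings and T(T-1)/2 correlations", {
  expect_equal(n_free(saturated_factor_model(3)), 6L)
  expect_equal(n_free(saturated_factor_model(1)), 1L)
  s50 <- saturated_factor_model(50)
  expect_equal(n_free(s50), 1275L)
  expect_equal(sum(lower.tri(matrix(0, 50, 50))), 1225L)  # distinct rho_G
  expect_true(all(s50$pattern[upper.tri(s50$pattern)] == 0))
  expect_error(saturated_factor_model(0), "at least one trait")
})

test_that("implied variance matrices are C C' with zeros at constrained cells", {
  sg <- saturated_factor_model(2)
  se_ <- saturated_factor_model(2)
  idx <- mvgreml:::.theta_index(sg, se_)
  # all-zero coefficients give zero matrices
  vs0 <- mvgreml:::.implied_variance(rep(0, 6), sg, se_, idx)
  expect_equal(vs0$VG, matrix(0, 2, 2), ignore_attr = TRUE)
  # theta_G = (1, 0.5, 1) lower-triangular
  vs <- mvgreml:::.implied_variance(c(1, 0.5, 1, 1, 0, 1), sg, se_, idx)
  expect_equal(vs$VG, matrix(c(1, 0.5, 0.5, 1.25), 2, 2),
               ignore_attr = TRUE)
  expect_error(mvgreml:::.implied_variance(rep(1, 4), sg, se_, idx),
               "free coefficients")
})

test_that("implied V_G and V_E are PSD for arbitrary coefficients", {
  set.seed(19)
  for (r in 1:25) {
    tt <- sample(2:5, 1)
    sg <- saturated_factor_model(tt)
    se_ <- saturated_factor_model(tt)
    th <- random_theta(sg, se_)
    vs <- mvgreml:::.implied_variance(th, sg, se_)
    expect_gte(min(eigen(vs$VG, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    expect_gte(min(eigen(vs$VE, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    expect_identical(vs$VG, t(vs$VG))
  }
})

test_that("analytic variance derivatives match central finite differences", {
  # single loading: d(gamma^2)/dgamma = 2 gamma
  sg1 <- saturated_factor_model(1)
  idx1 <- mvgreml:::.theta_index(sg1, sg1)
  vs1 <- mvgreml:::.implied_variance(c(2, 1), sg1, sg1, idx1)
  expect_equal(mvgreml:::.variance_derivative(1, vs1, idx1)$dV,
               matrix(4, 1, 1))
  # T=2 saturated, derivative w.r.t. gamma_21 at theta_G = (1, 0.5, 1)
  sg <- saturated_factor_model(2)
  idx <- mvgreml:::.theta_index(sg, sg)
  vs <- mvgreml:::.implied_variance(c(1, 0.5, 1, 1, 0.3, 1), sg, sg, idx)
  expect_equal(mvgreml:::.variance_derivative(2, vs, idx)$dV,
               matrix(c(0, 1, 1, 1), 2, 2))
  # property: FD agreement over random draws at T=4
  set.seed(4)
  sg4 <- saturated_factor_model(4)
  idx4 <- mvgreml:::.theta_index(sg4, sg4)
  for (r in 1:50) {
    th <- random_theta(sg4, sg4)
    vs4 <- mvgreml:::.implied_variance(th, sg4, sg4, idx4)
    i <- sample(nrow(idx4), 1)
    h <- 1e-6
    e <- numeric(length(th)); e[i] <- h
    vp <- mvgreml:::.implied_variance(th + e, sg4, sg4, idx4)
    vm <- mvgreml:::.implied_variance(th - e, sg4, sg4, idx4)
    fd <- if (idx4$mat[i] == "G") (vp$VG - vm$VG) / (2 * h) else
      (vp$VE - vm$VE) / (2 * h)
    an <- mvgreml:::.variance_derivative(i, vs4, idx4)
    expect_lt(max(abs(an$dV - fd)), 1e-6)
    # the rank-<=2 generators reproduce the dense matrix
    expect_equal(tcrossprod(an$e, an$c) + tcrossprod(an$c, an$e), an$dV)
  }
})

test_that("identification check accepts standard models and flags broken ones", {
  s3 <- saturated_factor_model(3)
  rep3 <- check_identification(s3, s3)
  expect_true(rep3$identified)
  expect_equal(rep3$jacobian_rank, 12L)

  # two identical single-trait factor columns are never identified
  bad <- factor_model(cbind(a = c(1, 0), b = c(1, 0)),
                      traits = c("x", "y"))
  env2 <- saturated_factor_model(c("x", "y"))
  repb <- check_identification(bad, env2)
  expect_false(repb$identified)
  expect_true(any(grepl("duplicated", repb$problems)))

  # the worked 10x3 model with saturated environment is identified
  m <- height_bmi_model()
  env10 <- saturated_factor_model(height_bmi_traits)
  expect_true(check_identification(m, env10)$identified)

  # over-parameterized: more loadings than T(T+1)/2
  over <- factor_model(matrix(1, 2, 4), traits = c("x", "y"))
  expect_false(check_identification(over, env2)$identified)
})

test_that("LRT degrees of freedom equal the free-count difference", {
  env <- saturated_factor_model(height_bmi_traits)
  m1 <- null_factor_model(height_bmi_traits)
  m2 <- height_bmi_model(shared = FALSE)
  m3 <- height_bmi_model(shared = TRUE)
  expect_equal(lrt_df(list(genetic = m2, environment = env),
                      list(genetic = m1, environment = env)), 10L)
  expect_equal(lrt_df(list(genetic = m3, environment = env),
                      list(genetic = m2, environment = env)), 10L)
  expect_equal(lrt_df(list(genetic = m3, environment = env),
                      list(genetic = m3, environment = env)), 0L)
  expect_error(lrt_df(list(genetic = m1, environment = env),
                      list(genetic = m3, environment = env)),
               "cannot be nested")
})
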