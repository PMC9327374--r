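# Restricted-likelihood kernel in the GRM eigenbasis.
#
# After the canonical transform the model is y_j ~ N(Z_j beta, V_j) with
# V_j = d_j V_G + V_E over j = 1..n independent T-variate blocks, and the
# restricted log-likelihood (constant omitted) is
#   ell = -1/2 ( log|V| + log|Z' V^-1 Z| + y' M y ),
#   M   = V^-1 - V^-1 Z (Z' V^-1 Z)^-1 Z' V^-1.
# One simultaneous diagonalization of (V_G, V_E) per parameter value gives a
# whitening W with W V_E W' = I and W V_G W' = diag(lam), so every block
# inverse and log-determinant becomes a diagonal operation:
#   V_j^-1 = W' diag(1 / (d_j lam + 1)) W,
#   log|V_j| = log|V_E| + sum_t log(d_j lam_t + 1).
# All block sums below are vectorized over j; M is never formed densely.

# Whitening transform for the pair (V_G, V_E): Cholesky of V_E followed by a
# symmetric eigensolve. V_E must be positive definite; one shot of jitter
# (1e-8 * mean diagonal) is tried before giving up, since in intended use the
# environmental model is (near-)saturated and V_E is well-conditioned.
.diagonalize_pair <- function(VG, VE) {
  tt <- nrow(VE)
  Lc <- tryCatch(t(chol(VE)), error = function(e) NULL)
  if (is.null(Lc)) {
    jit <- 1e-8 * mean(diag(VE))
    if (is.finite(jit) && jit > 0)
      Lc <- tryCatch(t(chol(VE + diag(jit, tt))), error = function(e) NULL)
    if (is.null(Lc))
      stop("environmental variance matrix is singular; specify an ",
           "environmental factor model closer to saturated")
  }
  # Lc^-1 VG Lc^-T, then symmetric EVD
  S <- forwardsolve(Lc, t(forwardsolve(Lc, VG)))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  U <- e$vectors
  W <- crossprod(U, forwardsolve(Lc, diag(tt)))   # U' Lc^-1
  list(W = W, lam = lam, logdet_VE = 2 * sum(log(diag(Lc))))
}

# Evaluate the restricted log-likelihood and, on request, its gradient, the
# average-information matrix and the GLS fixed effects, in one pass.
#
# td:     mv_transformed dataset
# vs:     list(CG, CE, VG, VE) from .implied_variance
# index:  theta index (required for gradient/AI)
# want:   subset of c("gradient", "ai", "gls")
.reml_kernel <- function(td, vs, index = NULL, want = character(0)) {
  tt <- length(td$traits)
  n <- td$n
  d <- td$d
  k <- length(td$covars)
  dg <- .diagonalize_pair(vs$VG, vs$VE)
  W <- dg$W
  lam <- dg$lam
  Den <- 1 + outer(lam, d)                    # T x n
  if (any(Den <= 1e-12))
    stop("a covariance block is numerically singular (d_j lam_t + 1 <= 1e-12)")
  iDen <- 1 / Den
  Yt <- W %*% td$Ystar                        # whitened traits, T x n
  logdetV <- n * dg$logdet_VE + sum(log(Den))
  Rv <- crossprod(W, Yt * iDen)               # V_j^-1 y_j, T x n

  # per-trait design blocks and the (t, s) inner-weight vectors
  # omega_ts(j) = sum_u W[u,t] W[u,s] / (d_j lam_u + 1)
  beta <- numeric(0)
  beta_cov <- NULL
  logdet_gram <- 0
  Fit <- 0
  B <- NULL
  Xt_list <- NULL
  koff <- NULL
  OmFlat <- NULL
  if (k > 0L) {
    map <- td$trait_map > 0
    Xt_list <- lapply(seq_len(tt), function(t_)
      td$Xstar[, map[t_, ], drop = FALSE])
    kt <- vapply(Xt_list, ncol, 0L)
    if (any(kt == 0L))
      stop("trait '", td$traits[which(kt == 0L)[1L]],
           "' has no applicable covariate")
    koff <- c(0L, cumsum(kt))
    ktot <- koff[tt + 1L]
    # all T^2 omega vectors at once: column (t,s) of Mw is W[,t]*W[,s]
    Mw <- W[, rep(seq_len(tt), times = tt), drop = FALSE] *
      W[, rep(seq_len(tt), each = tt), drop = FALSE]
    OmFlat <- crossprod(Mw, iDen)             # T^2 x n, row (t,s) = t + (s-1)T
    gram <- matrix(0, ktot, ktot)
    xtvy <- numeric(ktot)
    for (s in seq_len(tt)) {
      bs <- seq.int(koff[s] + 1L, koff[s + 1L])
      xtvy[bs] <- crossprod(Xt_list[[s]], Rv[s, ])
      for (s2 in s:tt) {
        bs2 <- seq.int(koff[s2] + 1L, koff[s2 + 1L])
        om <- OmFlat[s + (s2 - 1L) * tt, ]
        blk <- crossprod(Xt_list[[s]], om * Xt_list[[s2]])
        gram[bs, bs2] <- blk
        if (s2 > s) gram[bs2, bs] <- t(blk)
      }
    }
    ch <- tryCatch(chol(gram), error = function(e) NULL)
    if (is.null(ch)) {
      bad <- which(abs(diag(gram)) < 1e-10 * max(abs(diag(gram)), 1))
      hint <- if (length(bad)) {
        lab <- unlist(lapply(seq_len(tt), function(t_)
          paste(td$traits[t_], colnames(Xt_list[[t_]]), sep = ":")))
        paste("; suspect columns:", paste(lab[bad], collapse = ", "))
      } else ""
      stop("fixed-effect design Z' V^-1 Z is rank deficient ",
           "(collinear covariates?)", hint)
    }
    logdet_gram <- 2 * sum(log(diag(ch)))
    beta <- backsolve(ch, backsolve(ch, xtvy, transpose = TRUE))
    B <- chol2inv(ch)
    Fit <- matrix(0, tt, n)
    for (t_ in seq_len(tt)) {
      bt <- seq.int(koff[t_] + 1L, koff[t_ + 1L])
      Fit[t_, ] <- Xt_list[[t_]] %*% beta[bt]
    }
    if ("gls" %in% want) {
      beta_cov <- B
      names(beta) <- unlist(lapply(seq_len(tt), function(t_)
        paste(td$traits[t_], colnames(Xt_list[[t_]]), sep = ":")))
    }
  }

  E <- td$Ystar - Fit                         # residuals, trait coords
  Rres <- crossprod(W, (W %*% E) * iDen)      # blocks of M y, T x n
  quad <- sum(E * Rres)
  loglik <- -0.5 * (logdetV + logdet_gram + quad)

  out <- list(loglik = loglik, logdetV = logdetV,
              logdet_gram = logdet_gram, quad = quad,
              beta = beta, beta_cov = beta_cov,
              W = W, lam = lam)

  need_grad <- "gradient" %in% want
  need_ai <- "ai" %in% want
  if (!need_grad && !need_ai) return(out)
  if (is.null(index)) stop("gradient/AI evaluation needs the theta index")

  if (need_grad) {
    # Each partial derivative of V is block diagonal with block
    # c_j (e_t a' + a e_t'), c_j = d_j (genetic) or 1 (environmental), a a
    # column of C. Since (e_t, a) are block-constant, all partials follow
    # from four aggregated T x T matrices:
    #   sum_j c_j M_jj (trace term) and sum_j c_j r_j r_j' (quadratic term),
    # read off against C columns: d ell / d theta = -[(Sc - Rc) C]_{t,f}.
    sg <- as.vector(iDen %*% d)
    se <- rowSums(iDen)
    VinvG <- crossprod(W, sg * W)             # sum_j d_j V_j^-1
    VinvE <- crossprod(W, se * W)
    Rg <- Rres %*% (t(Rres) * d)
    Re <- tcrossprod(Rres)
    Ag <- matrix(0, tt, tt)
    Ae <- matrix(0, tt, tt)
    if (k > 0L) {
      # A_j = V_j^-1 Z_j B Z_j' V_j^-1 = Om_j Phi_j Om_j with
      # Phi_j[s,s2] = x_js' B[bs,bs2] x_js2; aggregate over j per (s, s2)
      for (s in seq_len(tt)) {
        bs <- seq.int(koff[s] + 1L, koff[s + 1L])
        Om_s <- OmFlat[seq.int((s - 1L) * tt + 1L, s * tt), , drop = FALSE]
        for (s2 in s:tt) {
          bs2 <- seq.int(koff[s2] + 1L, koff[s2 + 1L])
          Om_s2 <- OmFlat[seq.int((s2 - 1L) * tt + 1L, s2 * tt), ,
                          drop = FALSE]
          phi <- rowSums((Xt_list[[s]] %*% B[bs, bs2, drop = FALSE]) *
                           Xt_list[[s2]])
          M1g <- Om_s %*% (t(Om_s2) * (d * phi))
          M1e <- Om_s %*% (t(Om_s2) * phi)
          if (s2 == s) {
            Ag <- Ag + M1g
            Ae <- Ae + M1e
          } else {
            Ag <- Ag + M1g + t(M1g)
            Ae <- Ae + M1e + t(M1e)
          }
        }
      }
    }
    ScG <- VinvG - Ag - Rg
    ScE <- VinvE - Ae - Re
    gmat_g <- -(ScG %*% vs$CG)
    gmat_e <- -(ScE %*% vs$CE)
    ig <- index$mat == "G"
    grad <- numeric(nrow(index))
    if (any(ig)) grad[ig] <- gmat_g[cbind(index$t[ig], index$f[ig])]
    if (any(!ig)) grad[!ig] <- gmat_e[cbind(index$t[!ig], index$f[!ig])]
    out$gradient <- grad
  }

  if (need_ai) {
    # AI_ij = 1/2 u_i' M u_j with u_i = (dV_i) M y; each u_i is assembled
    # blockwise from the rank-<=2 derivative structure, and M is applied as
    # an operator (V^-1 minus the fixed-effect projection)
    p <- nrow(index)
    apply_Vinv <- function(U) crossprod(W, (W %*% U) * iDen)
    apply_M <- function(U) {
      VU <- apply_Vinv(U)
      if (k == 0L) return(VU)
      cvec <- numeric(koff[tt + 1L])
      for (s in seq_len(tt)) {
        bs <- seq.int(koff[s] + 1L, koff[s + 1L])
        cvec[bs] <- crossprod(Xt_list[[s]], VU[s, ])
      }
      bc <- B %*% cvec
      Fc <- matrix(0, tt, n)
      for (t_ in seq_len(tt)) {
        bt <- seq.int(koff[t_] + 1L, koff[t_ + 1L])
        Fc[t_, ] <- Xt_list[[t_]] %*% bc[bt]
      }
      VU - apply_Vinv(Fc)
    }
    Ulist <- vector("list", p)
    for (i in seq_len(p)) {
      cmat <- if (index$mat[i] == "G") vs$CG else vs$CE
      a <- cmat[, index$f[i]]
      wj <- if (index$mat[i] == "G") d else rep(1, n)
      sf <- as.vector(crossprod(a, Rres))     # a' r_j over j
      U <- a %o% (wj * Rres[index$t[i], ])
      U[index$t[i], ] <- U[index$t[i], ] + wj * sf
      Ulist[[i]] <- U
    }
    MU <- lapply(Ulist, apply_M)
    ai <- matrix(0, p, p)
    for (i in seq_len(p))
      for (j in i:p) {
        ai[i, j] <- 0.5 * sum(Ulist[[i]] * MU[[j]])
        ai[j, i] <- ai[i, j]
      }
    out$ai <- ai
  }
  out
}

# Restricted log-likelihood of a variance structure on transformed data.
.reml_loglik <- function(td, vs) .reml_kernel(td, vs)$loglik

# Analytic gradient with respect to the free coefficients.
.reml_gradient <- function(td, vs, index)
  .reml_kernel(td, vs, index, want = "gradient")$gradient

# Average-information matrix at the given coefficients.
.average_information <- function(td, vs, index)
  .reml_kernel(td, vs, index, want = "ai")$ai

# Dense-matrix REML evaluation on untransformed data: materializes the full
# NT x NT covariance V_G (x) A + V_E (x) I and the block-diagonal design.
# Test-scale equivalence oracle for the transformed kernel (L = 0); also
# returns the GLS fixed effects. Guarded to small problems.
.dense_reml_oracle <- function(grm, pheno, covar = NULL, vs,
                               intercept = TRUE) {
  n <- nrow(pheno$Y)
  tt <- ncol(pheno$Y)
  if (n * tt > 400)
    stop("dense oracle is restricted to N*T <= 400")
  V <- kronecker(vs$VG, grm$A) + kronecker(vs$VE, diag(n))
  y <- as.vector(pheno$Y)                     # traits stacked: y_1, ..., y_T
  X <- matrix(numeric(0), n, 0)
  tmap <- matrix(numeric(0), tt, 0)
  if (intercept) {
    X <- cbind(X, rep(1, n))
    tmap <- cbind(tmap, rep(1, tt))
  }
  if (!is.null(covar)) {
    X <- cbind(X, covar$X)
    um <- covar$trait_map
    if (is.null(um)) um <- matrix(1, tt, ncol(covar$X))
    tmap <- cbind(tmap, um)
  }
  Xt_list <- lapply(seq_len(tt), function(t_) X[, tmap[t_, ] > 0, drop = FALSE])
  kt <- vapply(Xt_list, ncol, 0L)
  ktot <- sum(kt)
  Z <- matrix(0, n * tt, ktot)
  off <- 0L
  for (t_ in seq_len(tt)) {
    if (kt[t_] > 0L)
      Z[seq.int((t_ - 1L) * n + 1L, t_ * n), off + seq_len(kt[t_])] <-
        Xt_list[[t_]]
    off <- off + kt[t_]
  }
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  if (ktot > 0L) {
    Vinv_Z <- backsolve(ch, backsolve(ch, Z, transpose = TRUE))
    gram <- crossprod(Z, Vinv_Z)
    chg <- chol(gram)
    logdet_gram <- 2 * sum(log(diag(chg)))
    beta <- backsolve(chg, backsolve(chg, crossprod(Z, Vinv_y),
                                     transpose = TRUE))
    quad <- sum(y * Vinv_y) - sum(crossprod(Z, Vinv_y) * beta)
    beta_cov <- chol2inv(chg)
  } else {
    logdet_gram <- 0
    beta <- numeric(0)
    beta_cov <- NULL
    quad <- sum(y * Vinv_y)
  }
  list(loglik = -0.5 * (logdetV + logdet_gram + quad),
       beta = as.vector(beta), beta_cov = beta_cov)
}
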