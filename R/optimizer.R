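#' Control parameters for multivariate GREML fitting
#'
#' @param grad_tol convergence threshold: the fit stops when the root mean
#'   square of the gradient, divided by the number of retained blocks n, drops
#'   below this value.
#' @param max_iter iteration cap; exceeding it returns an unconverged fit
#'   rather than an error.
#' @param gss_tol absolute interval tolerance of the golden-section line
#'   search (relative to the current bracket scale).
#' @param gss_max_bracket maximum number of geometric bracket expansions.
#' @param reset_patience consecutive unstable iterations (failed line search,
#'   non-finite values, loss of ascent) before the inverse-Hessian
#'   approximation is reinitialized.
#' @param ai_after_resets consecutive reinitializations before a single
#'   damped Newton step using the average-information matrix.
#' @param seed seed for any randomized component (identification draws).
#' @param verbose print one line per iteration.
#' @return A list of class `mvgreml_control`.
#' @export
mvgreml_control <- function(grad_tol = 1e-5, max_iter = 300L,
                            gss_tol = 1e-6, gss_max_bracket = 30L,
                            reset_patience = 2L, ai_after_resets = 2L,
                            seed = 1L, verbose = FALSE) {
  stopifnot(grad_tol > 0, max_iter >= 1, gss_tol > 0, gss_max_bracket >= 1,
            reset_patience >= 1, ai_after_resets >= 1)
  structure(list(grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 gss_tol = gss_tol,
                 gss_max_bracket = as.integer(gss_max_bracket),
                 reset_patience = as.integer(reset_patience),
                 ai_after_resets = as.integer(ai_after_resets),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "mvgreml_control")
}

# Golden-section line search maximizing f over step lengths s > 0.
# The bracket is grown geometrically (x2) from s0 while the objective keeps
# improving, then contracted by the golden ratio to the requested tolerance.
# Non-finite objective values are treated as -Inf. Returns ok = FALSE when no
# step improves on f(0).
.golden_section <- function(f, f0, s0 = 1, tol = 1e-6, max_bracket = 30L) {
  safe <- function(s) {
    v <- tryCatch(f(s), error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  }
  s <- s0
  fs <- safe(s)
  halvings <- 0L
  while (fs <= f0 && halvings < 40L) {       # shrink until some step ascends
    s <- s / 2
    fs <- safe(s)
    halvings <- halvings + 1L
  }
  if (fs <= f0)
    return(list(step = 0, value = f0, ok = FALSE, n_eval = halvings + 1L))
  n_eval <- halvings + 1L
  lo <- s / 2
  hi <- 2 * s
  fhi <- safe(hi)
  n_eval <- n_eval + 1L
  expansions <- 0L
  while (fhi > fs && expansions < max_bracket) {   # grow while improving
    lo <- s
    s <- hi
    fs <- fhi
    hi <- 2 * hi
    fhi <- safe(hi)
    n_eval <- n_eval + 1L
    expansions <- expansions + 1L
  }
  # contract [lo, hi] around the interior maximum
  gr <- (sqrt(5) - 1) / 2
  a <- lo
  b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- safe(x1)
  f2 <- safe(x2)
  n_eval <- n_eval + 2L
  best_s <- s
  best_f <- fs
  while ((b - a) > tol * max(1, abs(best_s))) {
    if (f1 < f2) {
      a <- x1
      x1 <- x2
      f1 <- f2
      x2 <- a + gr * (b - a)
      f2 <- safe(x2)
    } else {
      b <- x2
      x2 <- x1
      f2 <- f1
      x1 <- b - gr * (b - a)
      f1 <- safe(x1)
    }
    n_eval <- n_eval + 1L
    if (f1 > best_f) { best_f <- f1; best_s <- x1 }
    if (f2 > best_f) { best_f <- f2; best_s <- x2 }
  }
  if (best_f <= f0)
    return(list(step = 0, value = f0, ok = FALSE, n_eval = n_eval))
  list(step = best_s, value = best_f, ok = TRUE, n_eval = n_eval)
}

# Starting coefficients: a 50/50 genetic/environmental variance split.
# For each trait, the first free loading in its row gets sqrt(0.5 * var),
# remaining free loadings 0.1 * sd (nonzero, to break factor symmetry).
.theta_init <- function(td, spec_g, spec_e, index) {
  vt <- apply(td$Ystar, 1L, stats::var)
  vt[vt <= 0 | !is.finite(vt)] <- 1
  fill <- function(spec) {
    pat <- spec$pattern
    th <- matrix(0, nrow(pat), ncol(pat))
    for (t_ in seq_len(nrow(pat))) {
      free <- which(pat[t_, ] == 1)
      if (length(free) == 0L) next
      th[t_, free[1L]] <- sqrt(0.5 * vt[t_])
      if (length(free) > 1L)
        th[t_, free[-1L]] <- 0.1 * sqrt(vt[t_])
    }
    th
  }
  thg <- fill(spec_g)
  the <- fill(spec_e)
  ig <- index$mat == "G"
  theta <- numeric(nrow(index))
  theta[ig] <- thg[cbind(index$t[ig], index$f[ig])]
  theta[!ig] <- the[cbind(index$t[!ig], index$f[!ig])]
  theta
}

# BFGS ascent on the restricted log-likelihood with golden-section line
# search. The inverse-Hessian approximation starts at a scaled identity, so
# the first iteration is a gradient-ascent step. On instability (failed line
# search, non-finite values, or a search direction that is not an ascent
# direction) the approximation is reinitialized after `reset_patience`
# consecutive failures; after `ai_after_resets` consecutive resets a single
# damped Newton step using the average-information matrix is taken, then
# BFGS resumes.
.fit_theta <- function(td, spec_g, spec_e, control = mvgreml_control(),
                       theta0 = NULL) {
  index <- .theta_index(spec_g, spec_e)
  p <- nrow(index)
  if (p == 0L) stop("the model has no free coefficients")
  n <- td$n
  eval_ll <- function(theta) {
    vs <- .implied_variance(theta, spec_g, spec_e, index)
    out <- tryCatch(.reml_kernel(td, vs)$loglik, error = function(e) -Inf)
    if (!is.finite(out)) -Inf else out
  }
  eval_both <- function(theta) {
    vs <- .implied_variance(theta, spec_g, spec_e, index)
    tryCatch(.reml_kernel(td, vs, index, want = "gradient"),
             error = function(e) NULL)
  }
  theta <- if (is.null(theta0)) .theta_init(td, spec_g, spec_e, index)
           else as.numeric(theta0)
  kb <- eval_both(theta)
  if (is.null(kb) || !is.finite(kb$loglik))
    stop("restricted likelihood is not finite at the starting coefficients")
  ll <- kb$loglik
  g <- kb$gradient
  crit <- function(g) sqrt(mean(g^2)) / n
  H <- diag(1 / max(1, sqrt(sum(g^2))), p)    # first step ~ gradient ascent
  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      grad_norm = numeric(0), step = numeric(0),
                      event = character(0))
  push <- function(iter, ll, g, step, event)
    rbind(trace, data.frame(iter = iter, loglik = ll,
                            grad_norm = sqrt(sum(g^2)), step = step,
                            event = event))
  converged <- crit(g) < control$grad_tol
  fails <- 0L
  resets <- 0L
  iter <- 0L
  trace <- push(0L, ll, g, NA_real_, "init")
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1L
    dir <- as.vector(H %*% g)
    unstable <- FALSE
    event <- "bfgs"
    if (!all(is.finite(dir)) || sum(dir * g) <= 0) {
      unstable <- TRUE
      event <- "bad-direction"
    } else {
      ls <- .golden_section(function(s) eval_ll(theta + s * dir), ll,
                            s0 = 1, tol = control$gss_tol,
                            max_bracket = control$gss_max_bracket)
      if (!ls$ok) {
        unstable <- TRUE
        event <- "line-search-failed"
      } else {
        theta_new <- theta + ls$step * dir
        kb <- eval_both(theta_new)
        if (is.null(kb) || !is.finite(kb$loglik) ||
            !all(is.finite(kb$gradient))) {
          unstable <- TRUE
          event <- "non-finite"
        } else {
          sk <- theta_new - theta
          yk <- g - kb$gradient             # minimization convention on -ell
          theta <- theta_new
          ll <- kb$loglik
          g <- kb$gradient
          sy <- sum(sk * yk)
          if (sy > 1e-12 * sqrt(sum(sk^2) * sum(yk^2))) {
            rho <- 1 / sy
            Hy <- H %*% yk
            H <- H - rho * (sk %*% t(Hy) + Hy %*% t(sk)) +
              rho * (1 + rho * sum(yk * Hy)) * (sk %*% t(sk))
          } else {
            event <- "bfgs-skip"            # curvature condition failed
          }
          fails <- 0L
          resets <- 0L
          trace <- push(iter, ll, g, ls$step, event)
        }
      }
    }
    if (unstable) {
      fails <- fails + 1L
      if (fails >= control$reset_patience) {
        fails <- 0L
        resets <- resets + 1L
        H <- diag(1 / max(1, sqrt(sum(g^2))), p)
        event <- paste0(event, "+reset")
        if (resets >= control$ai_after_resets) {
          ai_out <- .ai_step(td, spec_g, spec_e, index, theta, ll, eval_ll)
          if (!is.null(ai_out)) {
            theta <- ai_out$theta
            kb <- eval_both(theta)
            if (!is.null(kb)) {
              ll <- kb$loglik
              g <- kb$gradient
            }
            event <- paste0(event, "+ai-step")
          }
          resets <- 0L
        }
      }
      trace <- push(iter, ll, g, 0, event)
    }
    converged <- crit(g) < control$grad_tol
    if (control$verbose)
      cat(sprintf("iter %3d  ell %.6f  |g| %.3e  %s\n", iter, ll,
                  sqrt(sum(g^2)), utils::tail(trace$event, 1L)))
  }
  list(theta = theta, loglik = ll, gradient = g, converged = converged,
       n_iter = iter, trace = trace, index = index)
}

# One damped Newton step using the AI matrix: solve (AI + ridge I) delta = g
# with the ridge doubling until the system solves and the step (after
# halving if needed) improves the log-likelihood. Returns NULL if no
# improving step is found.
.ai_step <- function(td, spec_g, spec_e, index, theta, ll, eval_ll) {
  vs <- .implied_variance(theta, spec_g, spec_e, index)
  ai <- tryCatch(.reml_kernel(td, vs, index, want = "ai")$ai,
                 error = function(e) NULL)
  if (is.null(ai) || !all(is.finite(ai))) return(NULL)
  g <- .reml_gradient(td, vs, index)
  p <- length(theta)
  ridge <- 1e-6 * max(mean(abs(diag(ai))), 1e-12)
  for (r in 1:30) {
    delta <- tryCatch(solve(ai + diag(ridge, p), g), error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:30) {
        cand <- theta + step * delta
        if (eval_ll(cand) > ll) return(list(theta = cand))
        step <- step / 2
      }
    }
    ridge <- ridge * 2
  }
  NULL
}
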