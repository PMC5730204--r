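# Empirical Bayes LASSO for oversaturated (p >> n) marker regression.
#
# Hierarchy: beta_j ~ N(0, sigma_j^2) with an exponential prior on
# sigma_j^2 whose rate carries a gamma(a, b) hyperprior; integrating the
# rate out gives the prior density p(sigma_j^2) proportional to
# (b + sigma_j^2)^-(a + 1). The prior variances are estimated by maximising
# the penalised marginal likelihood with greedy add / re-estimate / delete
# actions on one coefficient at a time, in the fast sequential style of
# sparse Bayesian learning: only the active columns enter the posterior,
# and excluded coefficients are exactly zero.

# Per-column contribution to the (penalised) log marginal likelihood as a
# function of the prior variance u = sigma_j^2, given the leave-this-column
# -out statistics s (sparsity) and q (quality). Constants dropped.
.eb_loglik <- function(u, s, q) {
  su <- pmax(1 + u * s, 1e-10)  # guard: s can go non-positive numerically
  0.5 * (-log(su) + q^2 * u / su)
}
.eb_logprior <- function(u, a, b) -(a + 1) * log1p(u / b)

# Stationary point of .eb_loglik + .eb_logprior in u > 0: positive root of
# s^2 (2a+3) u^2 + [s^2 b + 4(a+1) s - (q^2 - s)] u + [2(a+1) - (q^2 - s) b] = 0.
# Returns 0 when no positive root exists (column excluded).
.eb_opt_variance <- function(s, q, a, b) {
  A <- s^2 * (2 * a + 3)
  B <- s^2 * b + 4 * (a + 1) * s - (q^2 - s)
  C <- 2 * (a + 1) - (q^2 - s) * b
  disc <- B^2 - 4 * A * C
  u <- rep(0, length(s))
  ok <- is.finite(disc) & disc >= 0 & A > 0 & s > 0
  u[ok] <- (-B[ok] + sqrt(disc[ok])) / (2 * A[ok])
  u[!is.finite(u) | u < 0] <- 0
  u
}

#' Empirical Bayes LASSO fit
#'
#' Greedy empirical-Bayes shrinkage regression for models with many more
#' candidate columns than observations. Columns are added to, re-estimated
#' in, or deleted from the active set one at a time, choosing at each step
#' the action with the largest improvement of the marginal likelihood
#' penalised by the exponential-gamma prior on the per-coefficient
#' variances; the residual variance is re-estimated after every action.
#' Coefficients of excluded columns are exactly zero.
#'
#' @param y Response vector.
#' @param X Numeric design matrix (e.g. from [build_design()]); `p` may
#'   exceed `n`. Columns and response are centred internally; the intercept
#'   is recovered afterwards.
#' @param a,b Hyperparameters of the gamma(a, b) hyperprior (see
#'   [select_hyperparameters()]).
#' @param tol Convergence: stop when no candidate action improves the
#'   objective by more than `tol`.
#' @param max_actions Iteration cap; non-convergence raises a warning.
#' @return List of class `eb_fit`: `beta` (length-`p`, exact zeros off the
#'   active set), `active` (column indices), `posterior_sd` (per active
#'   column), `t` (`|beta|/posterior sd`, 0 off the active set),
#'   `intercept`, `sigma2` (residual variance), `alpha` (prior precisions),
#'   `n_actions`, `converged`, `a`, `b`.
#' @references Tipping, M. E. and Faul, A. C. (2003) Fast marginal
#'   likelihood maximisation for sparse Bayesian models. AISTATS.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(sample(c(-1, 1), 100 * 30, TRUE), 100, 30)
#' y <- 2 * X[, 5] + rnorm(100)
#' fit <- eb_lasso_fit(y, X)
#' which(fit$beta != 0)
eb_lasso_fit <- function(y, X, a = 1, b = 3e-4, tol = 1e-6, max_actions = NULL) {
  y <- as.numeric(y)
  X <- unclass(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  if (anyNA(y) || anyNA(X) || any(!is.finite(y))) stop("non-finite inputs")
  if (is.null(max_actions)) max_actions <- 10L * p
  # centre and standardise internally so that the prior penalty has a
  # unit-free scale (results are reported on the original scale)
  ybar <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  yc <- (y - ybar) / ysd
  xbar <- colMeans(X); Xc <- sweep(X, 2L, xbar, check.margin = FALSE)
  xsd <- sqrt(colSums(Xc^2) / max(n - 1L, 1L))
  candidate <- xsd > 1e-8              # constant columns can never enter
  xsd[!candidate] <- 1
  Xc <- sweep(Xc, 2L, xsd, "/", check.margin = FALSE)
  cn <- colSums(Xc^2)
  Xty <- crossprod(Xc, yc)[, 1]
  sigma2 <- max(0.1 * stats::var(y), 1e-12)
  active <- integer(0); alpha <- numeric(0)
  V <- matrix(0, p, 0)                 # Xc' Phi, updated on active-set changes
  Sigma <- matrix(0, 0, 0); mu <- numeric(0)
  refresh <- function() {
    k <- length(active)
    if (k == 0L) {
      Sigma <<- matrix(0, 0, 0); mu <<- numeric(0)
      sigma2 <<- max(sum(yc^2) / n, 1e-12)
      return(invisible())
    }
    Phi <- Xc[, active, drop = FALSE]
    H <- crossprod(Phi) / sigma2
    diag(H) <- diag(H) + alpha
    Sigma <<- chol2inv(chol(H))
    Phity <- crossprod(Phi, yc)[, 1]
    mu <<- (Sigma %*% Phity)[, 1] / sigma2
    rss <- sum((yc - Phi %*% mu)^2)
    dof <- n - k + sum(alpha * diag(Sigma))
    sigma2 <<- max(rss / max(dof, 1), 1e-12)
  }
  refresh()
  yty <- sum(yc^2)
  # full penalised objective (profiled over sigma2): used to detect
  # cycling of the greedy actions through the sigma2 re-estimation
  objective <- function() {
    k <- length(active)
    if (k == 0L) return(-0.5 * (n * log(sigma2) + yty / sigma2))
    Phi <- Xc[, active, drop = FALSE]
    H <- crossprod(Phi) / sigma2
    diag(H) <- diag(H) + alpha
    ld <- 2 * sum(log(diag(chol(H))))
    Phity <- crossprod(Phi, yc)[, 1]
    mu_loc <- (chol2inv(chol(H)) %*% Phity)[, 1] / sigma2  # consistent with sigma2
    quad <- (yty - sum(Phity * mu_loc)) / sigma2
    -0.5 * (n * log(sigma2) + ld - sum(log(alpha)) + quad) +
      sum(.eb_logprior(1 / alpha, a, b))
  }
  n_actions <- 0L; converged <- FALSE
  best <- list(obj = objective(), active = active, alpha = alpha,
               sigma2 = sigma2)
  stall <- 0L
  repeat {
    k <- length(active)
    if (k > 0L) {
      VS <- V %*% Sigma
      S <- cn / sigma2 - rowSums(VS * V) / sigma2^2
      Q <- Xty / sigma2 - (V %*% mu)[, 1] / sigma2
    } else {
      S <- cn / sigma2
      Q <- Xty / sigma2
    }
    s <- S; q <- Q
    if (k > 0L) {
      denom <- alpha - S[active]
      denom[abs(denom) < 1e-12] <- 1e-12
      s[active] <- alpha * S[active] / denom
      q[active] <- alpha * Q[active] / denom
    }
    u_new <- .eb_opt_variance(s, q, a, b)
    obj_new <- ifelse(u_new > 0,
                      .eb_loglik(u_new, s, q) + .eb_logprior(u_new, a, b), 0)
    delta <- rep(-Inf, p)
    inact <- which(candidate & !(seq_len(p) %in% active))
    delta[inact] <- obj_new[inact]                       # add (0 if u_new = 0)
    if (k > 0L) {
      u_old <- 1 / alpha
      obj_old <- .eb_loglik(u_old, s[active], q[active]) +
        .eb_logprior(u_old, a, b)
      delta[active] <- obj_new[active] - obj_old         # re-estimate or delete
    }
    j <- which.max(delta)
    if (!is.finite(delta[j]) || delta[j] <= tol) { converged <- TRUE; break }
    if (j %in% active) {
      pos <- match(j, active)
      if (u_new[j] > 0) {
        alpha[pos] <- 1 / u_new[j]
      } else {                                           # delete
        active <- active[-pos]; alpha <- alpha[-pos]
        V <- V[, -pos, drop = FALSE]
      }
    } else {                                             # add
      active <- c(active, j); alpha <- c(alpha, 1 / u_new[j])
      V <- cbind(V, crossprod(Xc, Xc[, j])[, 1])
    }
    refresh()
    n_actions <- n_actions + 1L
    obj <- objective()
    if (obj > best$obj + tol) {
      best <- list(obj = obj, active = active, alpha = alpha, sigma2 = sigma2)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 20L) { converged <- TRUE; break }  # cycling; keep the best
    }
    if (n_actions >= max_actions) break
  }
  if (!identical(active, best$active) || !identical(alpha, best$alpha)) {
    active <- best$active; alpha <- best$alpha; sigma2 <- best$sigma2
    V <- crossprod(Xc, Xc[, active, drop = FALSE])
    refresh()
  }
  if (!converged)
    warning("eb_lasso_fit: no convergence within ", max_actions, " actions")
  beta <- numeric(p); post_sd <- rep(NA_real_, p); tval <- numeric(p)
  if (length(active)) {
    # back-transform to the original y and X scales
    beta[active] <- mu * ysd / xsd[active]
    post_sd[active] <- sqrt(pmax(diag(Sigma), 0)) * ysd / xsd[active]
    tval[active] <- abs(beta[active]) / pmax(post_sd[active], 1e-300)
  }
  names(beta) <- colnames(X)
  list(beta = beta, active = sort(active), posterior_sd = post_sd, t = tval,
       intercept = ybar - sum(xbar * beta), sigma2 = sigma2 * ysd^2,
       alpha = alpha[order(active)], n_actions = n_actions,
       converged = converged, a = a, b = b)
}

#' Default hyperparameter grid
#'
#' `a` over `{0.01, 0.05, 0.1, 0.5, 1}` crossed with `b` over
#' `{1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1}`; the small-`b` points supply
#' the strong-shrinkage regime an oversaturated null model needs (see the
#' package vignette).
#' @return Data frame with columns `a` and `b`.
#' @export
default_hyper_grid <- function() {
  a <- c(0.01, 0.05, 0.1, 0.5, 1)
  b <- c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
  expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE)
}

#' Cross-validated hyperparameter selection
#'
#' k-fold cross-validation of the out-of-fold squared prediction error of
#' [eb_lasso_fit()] over a grid of `(a, b)` values. Ties in the minimum are
#' broken toward the stronger-shrinkage point (larger `(a + 1) / b`, the
#' growth rate of the prior penalty).
#'
#' @param y,X Response and design as in [eb_lasso_fit()].
#' @param grid Data frame with columns `a` and `b`.
#' @param folds Number of folds (default 3).
#' @param seed Integer seed for the fold assignment (local RNG state).
#' @return List with `a`, `b` and the evaluated `grid` (columns `a`, `b`,
#'   `cv_error`).
#' @export
select_hyperparameters <- function(y, X, grid = default_hyper_grid(),
                                   folds = 3L, seed = 1L) {
  y <- as.numeric(y); X <- unclass(X)
  n <- length(y); folds <- as.integer(folds)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (n < folds) stop("fewer observations than folds")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(folds), n))
  err <- vapply(seq_len(nrow(grid)), function(i) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- eb_lasso_fit(y[tr], X[tr, , drop = FALSE],
                          a = grid$a[i], b = grid$b[i])
      pred <- fit$intercept + X[!tr, , drop = FALSE] %*% fit$beta
      se <- se + sum((y[!tr] - pred)^2)
    }
    se / n
  }, 0)
  grid$cv_error <- err
  best <- which(err == min(err))
  if (length(best) > 1L)
    best <- best[which.max((grid$a[best] + 1) / grid$b[best])]
  list(a = grid$a[best], b = grid$b[best], grid = grid)
}
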