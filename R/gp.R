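## Numerically guarded Cholesky: adds escalating jitter (relative to the
## mean diagonal) from 1e-6 up to 1e-4 before giving up.
chol_jitter <- function(K, jitter0 = 1e-8, jitter_max = 1e-4) {
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ## first attempt without jitter so well-conditioned systems are exact
  L <- tryCatch(t(chol(K)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  j <- jitter0
  repeat {
    L <- tryCatch(t(chol(K + diag(j * scale, nrow(K)))),
                  error = function(e) NULL)
    if (!is.null(L)) return(L)
    if (j >= jitter_max) stop("covariance matrix not positive definite after maximum jitter")
    j <- j * 10
  }
}

#' Exact multi-output GP posterior
#'
#' Dense-matrix posterior predictive distribution of the (noisy)
#' observations at query inputs, under the composite kernel times the
#' coregionalization covariance and a (possibly neural-network) mean:
#' `mu* = mu(X*) + K*x (Kxx + s2 I)^-1 (y - mu(X))` and
#' `S* = s2 I + K** - K*x (Kxx + s2 I)^-1 Kx*`.
#'
#' @param X,idx,y training inputs, output indices (0 = dilation,
#'   1 = station; all zero for one output) and observations.
#' @param Xs,idxs query inputs and output indices.
#' @param params a [kernel_params()].
#' @param B a [coreg_matrix()] or `NULL` for one output.
#' @param mean_fn `NULL` (zero mean), a `mean_net`, or a function
#'   `f(X, idx)` returning the mean vector.
#' @param sigma2 observation-noise variance.
#' @param level nominal central-interval level.
#' @return a `gp_posterior`: data.frame with `mean`, `var`, `sd`,
#'   `lower`, `upper`.
#' @export
exact_posterior <- function(X, idx, y, Xs, idxs, params, B = NULL,
                            mean_fn = NULL, sigma2 = 0, level = 0.9) {
  X <- as.matrix(X); Xs <- as.matrix(Xs)
  if (nrow(Xs) == 0L) return(gp_posterior(numeric(0), numeric(0), level))
  mu_x <- eval_mean(mean_fn, X, idx)
  mu_s <- eval_mean(mean_fn, Xs, idxs)
  K <- mo_kernel(params, B, X, idx)
  Ks <- mo_kernel(params, B, X, idx, Xs, idxs)      # n x ns
  kss <- mo_kernel_diag(params, B, Xs, idxs)
  L <- chol_jitter(K + diag(.noise_vec(sigma2, idx, nrow(K)), nrow(K)))
  a <- solve(t(L), solve(L, y - mu_x))
  V <- solve(L, Ks)
  m <- mu_s + drop(t(Ks) %*% a)
  v <- pmax(kss - colSums(V^2), 0) + .noise_vec(sigma2, idxs, length(m))
  gp_posterior(m, v, level)
}

gp_posterior <- function(mean, var, level = 0.9) {
  z <- stats::qnorm(0.5 + level / 2)
  sd <- sqrt(var)
  structure(data.frame(mean = mean, var = var, sd = sd,
                       lower = mean - z * sd, upper = mean + z * sd),
            level = level, class = c("gp_posterior", "data.frame"))
}

eval_mean <- function(mean_fn, X, idx) {
  if (is.null(mean_fn)) return(numeric(nrow(as.matrix(X))))
  if (inherits(mean_fn, "mean_net")) return(mean_net_forward(mean_fn, X, idx))
  mean_fn(X, idx)
}

#' Exact GP log marginal likelihood
#'
#' @inheritParams exact_posterior
#' @return scalar log marginal likelihood of `y`.
#' @export
gp_log_marginal <- function(X, idx, y, params, B = NULL, mean_fn = NULL,
                            sigma2 = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- mo_kernel(params, B, X, idx)
  L <- chol_jitter(K + diag(.noise_vec(sigma2, idx, n), n))
  r <- y - eval_mean(mean_fn, X, idx)
  a <- solve(L, r)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(a^2)
}

## ---- Sparse GP (collapsed variational bound) -------------------------

## Shared factorization for the collapsed bound and its gradients.
## Z/zidx are inducing inputs in the augmented (input, output-index)
## space.  Returns the pieces needed by elbo / predict / gradients.
## Observation-noise variance per stacked point: scalar sigma2 is
## shared; a length-2 sigma2 is indexed by the output index.
.noise_vec <- function(sigma2, idx, n) {
  if (length(sigma2) == 1) rep(sigma2, n) else sigma2[idx + 1L]
}

## sigma2v: per-point noise variances (length n).
.sgpr_core <- function(Kuu, Kuf, kff, r, sigma2v) {
  n <- length(r); m <- nrow(Kuu)
  L <- chol_jitter(Kuu)
  sig <- sqrt(sigma2v)
  A <- sweep(solve(L, Kuf), 2, sig, "/")             # m x n
  AAT <- tcrossprod(A)
  Bmat <- AAT + diag(1, m)
  LB <- t(chol(Bmat))
  rs <- r / sig
  Abar <- drop(A %*% rs)
  cvec <- solve(LB, Abar)
  list(n = n, m = m, L = L, A = A, AAT = AAT, LB = LB,
       r = r, rs = rs, sig = sig, Abar = Abar, cvec = cvec, kff = kff,
       Kuu = Kuu, Kuf = Kuf, sigma2v = sigma2v)
}

.sgpr_factor <- function(X, idx, y, Z, zidx, params, B, mean_fn, sigma2) {
  Kuu <- mo_kernel(params, B, Z, zidx)
  Kuf <- mo_kernel(params, B, Z, zidx, X, idx)       # m x n
  kff <- mo_kernel_diag(params, B, X, idx)
  r <- y - eval_mean(mean_fn, X, idx)
  .sgpr_core(Kuu, Kuf, kff, r, .noise_vec(sigma2, idx, length(r)))
}

.sgpr_elbo_from_factor <- function(f) {
  n <- f$n
  logdet <- 2 * sum(log(diag(f$LB))) + sum(log(f$sigma2v))
  quad <- sum(f$rs^2) - sum(f$cvec^2)
  trace_term <- sum(f$kff / (2 * f$sigma2v)) - 0.5 * sum(diag(f$AAT))
  -0.5 * n * log(2 * pi) - 0.5 * logdet - 0.5 * quad - trace_term
}

#' Collapsed evidence lower bound of sparse GP regression
#'
#' The collapsed (optimal variational distribution) lower bound on the
#' log marginal likelihood for sparse GP regression with inducing
#' inputs `Z`:
#' `log N(y | mu, Qnn + s2 I) - tr(Knn - Qnn) / (2 s2)` with
#' `Qnn = Kfu Kuu^-1 Kuf`.  With `Z = X` the bound equals the exact log
#' marginal likelihood.
#'
#' @inheritParams exact_posterior
#' @param Z,zidx inducing inputs and their output indices.
#' @return scalar lower bound.
#' @export
sgpr_elbo <- function(X, idx, y, Z, zidx, params, B = NULL,
                      mean_fn = NULL, sigma2 = 0.1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(Z) > nrow(X)) stop("more inducing points than observations")
  .sgpr_elbo_from_factor(
    .sgpr_factor(X, idx, y, Z, zidx, params, B, mean_fn, sigma2))
}

#' Sparse GP predictive distribution
#'
#' Predictive mean and variance of the collapsed sparse GP at query
#' points; with `Z = X` it reproduces the exact posterior.  The returned
#' variance includes the observation noise.
#'
#' @inheritParams sgpr_elbo
#' @param Xs,idxs query inputs and output indices.
#' @param level nominal central-interval level.
#' @return a `gp_posterior`.
#' @export
sgpr_predict <- function(X, idx, y, Z, zidx, params, B = NULL,
                         mean_fn = NULL, sigma2 = 0.1, Xs, idxs,
                         level = 0.9) {
  X <- as.matrix(X); Z <- as.matrix(Z); Xs <- as.matrix(Xs)
  if (nrow(Xs) == 0L) return(gp_posterior(numeric(0), numeric(0), level))
  f <- .sgpr_factor(X, idx, y, Z, zidx, params, B, mean_fn, sigma2)
  Kus <- mo_kernel(params, B, Z, zidx, Xs, idxs)
  kss <- mo_kernel_diag(params, B, Xs, idxs)
  tmp1 <- solve(f$L, Kus)
  tmp2 <- solve(f$LB, tmp1)
  mu_s <- eval_mean(mean_fn, Xs, idxs)
  m <- mu_s + drop(crossprod(tmp2, f$cvec))
  v <- pmax(kss - colSums(tmp1^2) + colSums(tmp2^2), 0) +
    .noise_vec(sigma2, idxs, length(m))
  gp_posterior(m, v, level)
}

## Gradient engine for the collapsed bound.  Returns:
##   G_uf (m x n), G_uu (m x m): dELBO/dKuf, dELBO/dKuu
##   g_diag (n): dELBO/dkff_i
##   g_lam (n): dELBO/dsigma2_i (per-point noise derivative; sum within
##     an output, or over all points for shared noise)
##   g_mu (n): dELBO/dmu_i
## Derivation: with Lam = diag(sigma2v), P = Qnn + Lam, alpha = P^-1 r,
##   dELBO/dQ = M = -P^-1/2 + alpha alpha'/2 + Lam^-1/2
##   dELBO/dKfu = 2 M Kfu Kuu^-1 ;  dELBO/dKuu = -Kuu^-1 Kuf M Kfu Kuu^-1
## computed without forming any n x n matrix via Woodbury:
##   P^-1 = Lam^-1/2 (I - A' B^-1 A) Lam^-1/2  with A = L^-1 Kuf Lam^-1/2.
.sgpr_grads <- function(f) {
  s2v <- f$sigma2v; sig <- f$sig
  Kfu <- t(f$Kuf)                                    # n x m
  Binv_Abar <- solve(t(f$LB), solve(f$LB, f$Abar))
  alpha <- (f$rs - drop(crossprod(f$A, Binv_Abar))) / sig
  Kfs <- Kfu / sig                                   # Lam^-1/2 Kfu
  AKfs <- f$A %*% Kfs                                # m x m
  Binv_AKfs <- solve(t(f$LB), solve(f$LB, AKfs))
  PinvKfu <- (Kfs - crossprod(f$A, Binv_AKfs)) / sig # n x m
  aKfu <- drop(crossprod(Kfu, alpha))                # m
  MKfu <- -0.5 * PinvKfu + 0.5 * outer(alpha, aKfu) + (Kfu / s2v) / 2
  Kuu_inv_right <- function(Mx) {                    # Mx %*% Kuu^-1
    t(solve(t(f$L), solve(f$L, t(Mx))))
  }
  G_fu <- 2 * Kuu_inv_right(MKfu)                    # n x m
  KufMKfu <- f$Kuf %*% MKfu                          # m x m, symmetric
  T1 <- solve(t(f$L), solve(f$L, KufMKfu))           # Kuu^-1 S
  G_uu <- -solve(t(f$L), solve(f$L, t(T1)))          # Kuu^-1 S Kuu^-1
  g_diag <- -1 / (2 * s2v)
  BinvA <- solve(t(f$LB), solve(f$LB, f$A))
  diag_Pinv <- (1 - colSums(f$A * BinvA)) / s2v
  Qpp <- s2v * colSums(f$A^2)
  g_lam <- -0.5 * diag_Pinv + 0.5 * alpha^2 +
    (f$kff - Qpp) / (2 * s2v^2)
  list(G_uf = t(G_fu), G_uu = G_uu, g_diag = g_diag,
       g_lam = g_lam, g_mu = alpha)
}
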