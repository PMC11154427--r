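#' Composite kernel hyperparameters
#'
#' Container for the hyperparameters of the composite covariance used
#' throughout the package: the sum of a squared-exponential (Gaussian), a
#' Matern and a linear kernel, each with automatic-relevance-determination
#' (per-input-dimension) scales.  The squared-exponential component models
#' smooth progression, the Matern component accommodates abrupt changes,
#' and the linear component carries the long-term non-decreasing trend of
#' labor progression.
#'
#' @param d input dimension (number of predictors).
#' @param se_var signal variance of the squared-exponential component.
#' @param se_ls lengthscales of the squared-exponential component
#'   (recycled to length `d`).
#' @param mat_var signal variance of the Matern component.
#' @param mat_ls Matern lengthscales (recycled to length `d`).
#' @param mat_nu Matern smoothness, one of 0.5, 1.5, 2.5.
#' @param lin_var per-dimension variances of the linear kernel.
#' @param lin_offset scalar offset subtracted from inputs in the linear
#'   kernel; held fixed during training.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(d, se_var = 1, se_ls = 1,
                          mat_var = 1, mat_ls = 1, mat_nu = 2.5,
                          lin_var = 0.1, lin_offset = 0) {
  stopifnot(d >= 1, mat_nu %in% c(0.5, 1.5, 2.5))
  p <- list(d = as.integer(d),
            se_var = se_var, se_ls = rep_len(se_ls, d),
            mat_var = mat_var, mat_ls = rep_len(mat_ls, d),
            mat_nu = mat_nu,
            lin_var = rep_len(lin_var, d), lin_offset = lin_offset)
  stopifnot(all(unlist(p[c("se_var", "se_ls", "mat_var", "mat_ls")]) > 0),
            all(p$lin_var >= 0))
  structure(p, class = "kernel_params")
}

#' Coregionalization output covariance
#'
#' The 2-output intrinsic coregionalization matrix `B = W W' + diag(kappa)`,
#' which multiplies the base input kernel to give the cross-output
#' covariance.  `B[i, j]` scales the covariance between output `i` and
#' output `j` (0 = dilation, 1 = station in the stacked representation).
#'
#' @param W a 2 x r factor matrix (r = rank, default 1) or a length-2
#'   vector for rank 1.
#' @param kappa length-2 non-negative diagonal inflation.
#' @return an object of class `coreg_matrix` with element `B`.
#' @export
coreg_matrix <- function(W = c(1, 1), kappa = c(0.1, 0.1)) {
  W <- matrix(W, nrow = 2)
  stopifnot(length(kappa) == 2, all(kappa >= 0))
  B <- W %*% t(W) + diag(kappa)
  structure(list(W = W, kappa = kappa, B = B), class = "coreg_matrix")
}

#' @rdname coreg_matrix
#' @param x a `coreg_matrix`.
#' @return `coreg_correlation`: the implied output correlation
#'   `B[1,2] / sqrt(B[1,1] B[2,2])`.
#' @export
coreg_correlation <- function(x) {
  B <- if (inherits(x, "coreg_matrix")) x$B else x
  B[1, 2] / sqrt(B[1, 1] * B[2, 2])
}

## Summed scaled squared distance matrix, via the expansion
## |a - b|^2 = |a|^2 + |b|^2 - 2 a.b (BLAS-backed).
.scaled_sqdist <- function(X1, X2, ls) {
  A <- sweep(X1, 2, ls, "/")
  B <- sweep(X2, 2, ls, "/")
  S <- -2 * tcrossprod(A, B)
  S <- S + rowSums(A^2)
  S <- S + matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE)
  pmax(S, 0)
}

## sum_k over dims of sum_{p,q} W[p,q] (X1[p,k] - X2[q,k])^2, returned
## per dimension; same expansion trick keeps this at one matrix product.
.wsum_sqdiff <- function(W, X1, X2) {
  rs <- rowSums(W); cs <- colSums(W)
  colSums(X1^2 * rs) + colSums(X2^2 * cs) -
    2 * colSums(X1 * (W %*% X2))
}

## per-dimension sum_{p,q} W[p,q] X1[p,k] X2[q,k]
.wsum_cross <- function(W, X1, X2) {
  colSums(X1 * (W %*% X2))
}

.matern_of_t <- function(t, nu) {
  if (nu == 0.5) return(exp(-t))
  if (nu == 1.5) { a <- sqrt(3) * t; return((1 + a) * exp(-a)) }
  a <- sqrt(5) * t
  (1 + a + a^2 / 3) * exp(-a)
}

## d k_mat / d t  divided by nothing (direct derivative in t)
.matern_dt <- function(t, nu) {
  if (nu == 0.5) return(-exp(-t))
  if (nu == 1.5) return(-3 * t * exp(-sqrt(3) * t))
  -(5 / 3) * t * (1 + sqrt(5) * t) * exp(-sqrt(5) * t)
}

#' Evaluate the composite base kernel
#'
#' Cross-covariance matrix of the sum kernel (squared-exponential +
#' Matern + linear) between two input designs.  With `parts = TRUE` the
#' individual component matrices and the intermediate scaled distances are
#' returned as well (used by the analytic gradients).
#'
#' @param params a [kernel_params()] object.
#' @param X1,X2 numeric matrices with `params$d` columns; `X2 = NULL`
#'   means `X1`.
#' @param parts return intermediate quantities.
#' @return an `n1 x n2` covariance matrix, or a list when `parts = TRUE`.
#' @export
base_kernel <- function(params, X1, X2 = NULL, parts = FALSE) {
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  if (ncol(X1) != params$d || ncol(X2) != params$d)
    stop("input dimension mismatch: kernel expects d = ", params$d)
  S_se <- .scaled_sqdist(X1, X2, params$se_ls)
  K_se <- params$se_var * exp(-0.5 * S_se)
  T_mat <- sqrt(pmax(.scaled_sqdist(X1, X2, params$mat_ls), 0))
  K_mat <- params$mat_var * .matern_of_t(T_mat, params$mat_nu)
  Xc1 <- sweep(X1, 2, params$lin_offset)
  Xc2 <- sweep(X2, 2, params$lin_offset)
  K_lin <- (Xc1 * rep(params$lin_var, each = nrow(Xc1))) %*% t(Xc2)
  K <- K_se + K_mat + K_lin
  if (!parts) return(K)
  list(K = K, K_se = K_se, K_mat = K_mat, K_lin = K_lin, T_mat = T_mat)
}

## Diagonal of the base kernel at X.
base_kernel_diag <- function(params, X) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, params$lin_offset)
  params$se_var + params$mat_var +
    drop(Xc^2 %*% params$lin_var)
}

#' Multi-output kernel evaluation
#'
#' Covariance between augmented inputs `(x, i)` and `(x', j)` where `i`,
#' `j` index the output (0 = dilation, 1 = station):
#' `k((x,i),(x',j)) = k_base(x, x') * B[i, j]`.
#'
#' @param params a [kernel_params()] object.
#' @param B a [coreg_matrix()] (or plain matrix); `NULL` for a single
#'   output (treated as `B = 1`).
#' @param X1,X2 input designs.
#' @param idx1,idx2 integer output indices in `{0, 1}` per row.
#' @return covariance matrix.
#' @export
mo_kernel <- function(params, B, X1, idx1, X2 = NULL, idx2 = NULL) {
  if (is.null(X2)) { X2 <- X1; idx2 <- idx1 }
  Kb <- base_kernel(params, X1, X2)
  if (is.null(B)) return(Kb)
  Bm <- if (inherits(B, "coreg_matrix")) B$B else B
  if (any(!idx1 %in% c(0L, 1L)) || any(!idx2 %in% c(0L, 1L)))
    stop("output index must be 0 or 1")
  Kb * Bm[cbind(rep(idx1 + 1L, times = length(idx2)),
                rep(idx2 + 1L, each = length(idx1)))]
}

mo_kernel_diag <- function(params, B, X, idx) {
  kd <- base_kernel_diag(params, X)
  if (is.null(B)) return(kd)
  Bm <- if (inherits(B, "coreg_matrix")) B$B else B
  kd * diag(Bm)[idx + 1L]
}

## Accumulate gradients of sum(Wt * K_base(X1, X2)) with respect to the
## natural kernel hyperparameters.  Returns a named vector in the packing
## order: se_var, se_ls[1..d], mat_var, mat_ls[1..d], lin_var[1..d].
kern_grad_accum <- function(params, X1, X2, Wt, diag_only = FALSE,
                            parts = NULL) {
  X1 <- as.matrix(X1)
  if (!is.null(X2)) X2 <- as.matrix(X2)
  d <- params$d
  g <- numeric(2 * (1 + d) + d)
  names(g) <- c("se_var", paste0("se_ls", seq_len(d)),
                "mat_var", paste0("mat_ls", seq_len(d)),
                paste0("lin_var", seq_len(d)))
  if (diag_only) {
    ## diag contributions: d kdiag/d se_var = 1, d/d mat_var = 1,
    ## d/d lin_var_k = (x_k - c)^2; lengthscale derivatives vanish.
    w <- Wt
    g["se_var"] <- sum(w)
    g["mat_var"] <- sum(w)
    Xc <- sweep(as.matrix(X1), 2, params$lin_offset)
    g[paste0("lin_var", seq_len(d))] <- colSums(w * Xc^2)
    return(g)
  }
  pt <- if (is.null(parts)) base_kernel(params, X1, X2, parts = TRUE)
        else parts
  g["se_var"] <- sum(Wt * pt$K_se) / params$se_var
  g["mat_var"] <- sum(Wt * pt$K_mat) / params$mat_var
  ## Matern: dk/d ls_k = -(dk/dt) * D_k / (ls_k^3 * t), zero where t = 0.
  dK_dt <- params$mat_var * .matern_dt(pt$T_mat, params$mat_nu)
  Tsafe <- pt$T_mat; Tsafe[Tsafe < 1e-12] <- 1
  W_mat <- Wt * dK_dt / Tsafe
  W_mat[pt$T_mat < 1e-12] <- 0
  Xc1 <- sweep(X1, 2, params$lin_offset)
  Xc2 <- sweep(X2, 2, params$lin_offset)
  g[paste0("se_ls", seq_len(d))] <-
    .wsum_sqdiff(Wt * pt$K_se, X1, X2) / params$se_ls^3
  g[paste0("mat_ls", seq_len(d))] <-
    -.wsum_sqdiff(W_mat, X1, X2) / params$mat_ls^3
  g[paste0("lin_var", seq_len(d))] <- .wsum_cross(Wt, Xc1, Xc2)
  g
}
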