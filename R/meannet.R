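#' Feed-forward mean network
#'
#' A small fully connected network (tanh activations, linear output)
#' used as the GP mean function.  For two-output models the trunk is
#' shared and the output index selects both a learned additive embedding
#' on the first hidden layer and an output-specific affine readout
#' (last layer row), so dilation and station share representation but
#' keep separate mean surfaces.
#'
#' @param d input dimension.
#' @param hidden integer vector of hidden-layer widths (may be empty for
#'   an affine mean).
#' @param n_outputs 1 or 2.
#' @param init_scale standard deviation multiplier for the random
#'   initialization (scaled by fan-in).
#' @return an object of class `mean_net` (list of weight matrices `W`,
#'   biases `b`, optional embedding `E`).
#' @export
mean_net <- function(d, hidden = c(32, 32), n_outputs = 1,
                     init_scale = 1) {
  sizes <- c(d, hidden, n_outputs)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1L] * fan_in,
                                  sd = init_scale / sqrt(fan_in)),
                     nrow = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  E <- if (n_outputs == 2 && length(hidden))
    matrix(0, nrow = sizes[2L], ncol = 2) else NULL
  structure(list(W = W, b = b, E = E, sizes = sizes,
                 n_outputs = n_outputs), class = "mean_net")
}

## Forward pass.  X: n x d matrix; idx: output index (0/1) per row.
## cache = TRUE returns activations for backprop.
mean_net_forward <- function(net, X, idx = NULL, cache = FALSE) {
  X <- as.matrix(X)
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  A <- X
  acts[[1L]] <- A
  for (l in seq_len(L)) {
    Zl <- A %*% t(net$W[[l]]) + rep(net$b[[l]], each = nrow(A))
    if (l == 1L && !is.null(net$E) && L > 1L) {
      Zl <- Zl + t(net$E)[idx + 1L, , drop = FALSE]
    }
    A <- if (l < L) tanh(Zl) else Zl
    acts[[l + 1L]] <- A
  }
  mu <- if (net$n_outputs == 2)
    A[cbind(seq_len(nrow(A)), idx + 1L)] else drop(A)
  if (!cache) return(mu)
  list(mu = mu, acts = acts)
}

## Backprop: g is dL/dmu (length n).  Returns gradients with the same
## shapes as the net parameters.
mean_net_backward <- function(net, fw, idx, g) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  n <- length(g)
  if (net$n_outputs == 2) {
    delta <- matrix(0, n, 2)
    delta[cbind(seq_len(n), idx + 1L)] <- g
  } else {
    delta <- matrix(g, ncol = 1)
  }
  for (l in rev(seq_len(L))) {
    A_in <- fw$acts[[l]]
    gW[[l]] <- crossprod(delta, A_in)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      A_out <- fw$acts[[l]]                           # tanh output of layer l-1
      delta <- (delta %*% net$W[[l]]) * (1 - A_out^2)
    }
  }
  gE <- NULL
  if (!is.null(net$E) && L > 1L) {
    gE <- matrix(0, nrow = nrow(net$E), ncol = 2)
    for (j in 0:1) {
      rows <- which(idx == j)
      if (length(rows)) gE[, j + 1L] <- colSums(delta[rows, , drop = FALSE])
    }
  }
  list(W = gW, b = gb, E = gE)
}
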