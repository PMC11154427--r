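test_that("composite kernel matches a pointwise oracle and basic limits", {
  p <- kernel_params(3, se_var = 1.3, se_ls = c(0.5, 1, 2),
                     mat_var = 0.7, mat_ls = c(0.8, 1.2, 0.6),
                     lin_var = c(0.2, 0.1, 0.05), lin_offset = 0.5)
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3)
  K <- base_kernel(p, X)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(K[i, j], oracle_k(p, X[i, ], X[j, ]), tolerance = 1e-12)
  }
  expect_equal(K, t(K))
  ## zero distance: SE component returns its signal variance exactly
  p0 <- kernel_params(2, se_var = 2.5, mat_var = 1e-12, lin_var = 1e-12)
  expect_equal(base_kernel(p0, matrix(c(1, 1), 1))[1, 1], 2.5,
               tolerance = 1e-9)
  ## distance -> infinity: stationary part vanishes
  far <- base_kernel(p0, matrix(c(0, 0), 1), matrix(c(100, 100), 1))
  expect_lt(far[1, 1], 1e-10)
})

test_that("kernel matrices are PSD on random designs for every smoothness", {
  for (nu in c(0.5, 1.5, 2.5)) {
    for (rep in 1:5) {
      set.seed(100 * nu + rep)
      p <- kernel_params(2, se_var = runif(1, 0.5, 2), se_ls = runif(2, 0.3, 2),
                         mat_var = runif(1, 0.2, 1), mat_ls = runif(2, 0.3, 2),
                         mat_nu = nu, lin_var = runif(2, 0, 0.3))
      X <- matrix(rnorm(20), 10, 2)
      ev <- eigen(base_kernel(p, X), symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
      ## multi-output version stays PSD
      B <- coreg_matrix(runif(2, 0.3, 1), runif(2, 0.05, 0.5))
      idx <- rep(0:1, 5)
      ev2 <- eigen(mo_kernel(p, B, X, idx), symmetric = TRUE,
                   only.values = TRUE)$values
      expect_gt(min(ev2), -1e-8)
    }
  }
})

test_that("coregionalization structure scales cross-output covariance", {
  p <- kernel_params(2)
  X <- matrix(rnorm(8), 4, 2)
  Kb <- base_kernel(p, X)
  ## identity B: outputs independent, same-output blocks reduce to base
  Bid <- coreg_matrix(W = matrix(c(0, 0), 2), kappa = c(1, 1))
  K <- mo_kernel(p, Bid, rbind(X, X), rep(0:1, each = 4))
  expect_equal(K[1:4, 5:8], matrix(0, 4, 4))
  expect_equal(K[1:4, 1:4], Kb)
  ## rank-1 w = (1, 1): cross-output covariance equals same-output
  B1 <- coreg_matrix(W = c(1, 1), kappa = c(0, 0))
  K1 <- mo_kernel(p, B1, rbind(X, X), rep(0:1, each = 4))
  expect_equal(K1[1:4, 5:8], K1[1:4, 1:4])
  expect_equal(coreg_correlation(B1), 1)
  expect_error(mo_kernel(p, B1, X, rep(2L, 4)), "output index")
  expect_error(base_kernel(p, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("analytic ELBO gradient matches central finite differences", {
  set.seed(42)
  for (case in list(list(n_out = 2, hidden = c(4, 3)),
                    list(n_out = 2, hidden = integer(0)),
                    list(n_out = 1, hidden = c(5)))) {
    n <- 12; d <- 3
    X <- matrix(runif(n * d), n, d)
    idx <- if (case$n_out == 2) rep(0:1, each = n / 2) else rep(0L, n)
    pinfo <- make_pinfo(d, case$n_out, case$hidden, 2.5)
    theta <- rnorm(pinfo$n_par, 0, 0.5)
    y <- rnorm(n)
    keep <- c(1, 3, 5, 8, 10)
    obj <- make_elbo_objective(X, idx, y, X[keep, , drop = FALSE],
                               idx[keep], pinfo, net_prior_sd = 0.5)
    o <- obj(theta)
    h <- 1e-5
    g_fd <- vapply(seq_len(pinfo$n_par), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (obj(tp, FALSE)$value - obj(tm, FALSE)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(o$grad - g_fd)), 1e-6)
  }
})

test_that("mean network forward pass is deterministic and backprop is exact", {
  set.seed(3)
  net <- mean_net(4, c(6, 5), n_outputs = 2, init_scale = 0.5)
  X <- matrix(rnorm(20), 5, 4)
  idx <- c(0L, 1L, 0L, 1L, 1L)
  mu1 <- mean_net_forward(net, X, idx)
  mu2 <- mean_net_forward(net, X, idx)
  expect_identical(mu1, mu2)
  expect_true(all(is.finite(mu1)))
  ## outputs differ by output index through embedding + readout
  expect_false(isTRUE(all.equal(mean_net_forward(net, X, rep(0L, 5)),
                                mean_net_forward(net, X, rep(1L, 5)))))
})
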