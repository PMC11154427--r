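## Shared fixtures and independent oracles, built in code.

## --- independent dense-matrix oracle for the exact GP posterior -------
## Deliberately written with plain solve() on the full covariance,
## independently of the package's Cholesky code path.
oracle_posterior <- function(K, Ks, kss, y, mu_x, mu_s, sigma2v,
                             sigma2_query) {
  Kn <- K + diag(sigma2v, nrow(K))
  Kinv <- solve(Kn)
  m <- mu_s + drop(t(Ks) %*% Kinv %*% (y - mu_x))
  v <- kss - diag(t(Ks) %*% Kinv %*% Ks) + sigma2_query
  list(mean = m, var = v)
}

## oracle for log marginal likelihood of y ~ N(mu, K + diag(sigma2v))
oracle_lml <- function(K, y, mu, sigma2v) {
  Kn <- K + diag(sigma2v, nrow(K))
  -0.5 * length(y) * log(2 * pi) -
    0.5 * determinant(Kn, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(y - mu) %*% solve(Kn) %*% (y - mu))
}

## oracle for the composite kernel between two single points
oracle_k <- function(p, x1, x2) {
  se <- p$se_var * exp(-0.5 * sum(((x1 - x2) / p$se_ls)^2))
  t <- sqrt(sum(((x1 - x2) / p$mat_ls)^2))
  mat <- p$mat_var * switch(as.character(p$mat_nu),
    "0.5" = exp(-t),
    "1.5" = (1 + sqrt(3) * t) * exp(-sqrt(3) * t),
    "2.5" = (1 + sqrt(5) * t + 5 * t^2 / 3) * exp(-sqrt(5) * t))
  lin <- sum(p$lin_var * (x1 - p$lin_offset) * (x2 - p$lin_offset))
  se + mat + lin
}

## oracle for the collapsed sparse bound, plain dense linear algebra
oracle_sgpr_elbo <- function(Kuu, Kuf, kff, y, mu, sigma2v) {
  Q <- t(Kuf) %*% solve(Kuu) %*% Kuf
  P <- Q + diag(sigma2v, length(y))
  r <- y - mu
  -0.5 * length(y) * log(2 * pi) -
    0.5 * determinant(P, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(r) %*% solve(P) %*% r) -
    0.5 * sum((kff - diag(Q)) / sigma2v)
}

## --- small hand-built deliveries exercising every cleaning rule -------
fixture_delivery <- function() {
  ## absolute hours; delivery at 30, window start at 10
  delivery_record(
    delivery_id = "fix-1",
    exams = data.frame(
      time       = c(5,  12,  14, 14.05, 15,  17,  20,  23),
      dilation   = c(1,   3,   5,  5,     4,  NA,   7,   9),
      effacement = c(10, 40,  50, 50,    55,  70,  NA,  90),
      station    = c(-3, -2,  -2, -2,    -1,   0,   1,   2)),
    contraction_onsets = c(11, 13, 13.5, 16, 18, 19, 22, 22.5),
    induced = TRUE,
    epidural_time = 18.5,
    rom_time = NA_real_,
    delivery_time = 30)
}

## a tiny clean transitions table with known values
fixture_transitions <- function() {
  d <- preprocess_delivery(fixture_delivery())
  build_transitions(d)
}

## --- memoized heavy fixtures shared by acceptance tests ---------------
.acc <- new.env(parent = emptyenv())

acc_memo <- function(name, expr) {
  if (is.null(.acc[[name]])) .acc[[name]] <- force(expr)
  .acc[[name]]
}

## default-condition cohort for the cross-validated model comparison
acc_harness <- function() {
  acc_memo("harness", {
    sim <- simulate_transitions(sim_config(n_deliveries = 200, seed = 21))
    cfg <- train_config(m_inducing = 64, adam_steps = 100,
                        lbfgs_maxit = 60, seed = 7)
    run_evaluation(sim$transitions,
                   models = c("time_only", "me", "dil_only", "joint"),
                   k = 10, seed = 13, train_cfg = cfg)
  })
}

## deliberately heterogeneous cohort for the adaptation pattern
acc_hetero <- function() {
  acc_memo("hetero", {
    sim <- simulate_transitions(
      sim_config(n_deliveries = 80, seed = 11, delivery_bias_sd = 0.6))
    cfg <- train_config(m_inducing = 48, adam_steps = 100,
                        lbfgs_maxit = 50, seed = 5)
    restricted <- run_evaluation(sim$transitions,
                                 models = c("joint", "joint_adapt"),
                                 k = 5, seed = 2, train_cfg = cfg,
                                 folds = 1:2)
    full <- run_evaluation(sim$transitions, models = "joint_adapt",
                           k = 5, seed = 2, train_cfg = cfg,
                           adapt_cfg = adapt_config(unfreeze = "all",
                                                    prior_sd = Inf),
                           folds = 1:2)
    list(restricted = restricted, full = full,
         transitions = sim$transitions, cfg = cfg)
  })
}

abs_err <- function(report, model, output = "dilation") {
  p <- report$predictions
  sel <- p$model == model & p$output == output
  abs(p$pred[sel] - p$obs[sel])
}
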