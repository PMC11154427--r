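test_that("profiled-likelihood fit agrees with lme4 on simulated data", {
  skip_if_not_installed("lme4")
  tr <- acc_memo("cohort-me",
                 simulate_transitions(sim_config(n_deliveries = 80,
                                                 seed = 7)))$transitions
  me <- fit_me(tr)
  lf <- lme4::lmer(
    target_dilation ~ prev_dilation + prev_station + prev_effacement +
      cum_contractions + epidural + (1 | delivery_id),
    data = tr, REML = TRUE)
  expect_equal(unname(me$beta), unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(unname(me$se), unname(coef(summary(lf))[, 2]),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(me$tau2, vc$vcov[1], tolerance = 1e-6)
  expect_equal(me$sigma2, vc$vcov[2], tolerance = 1e-6)
  u <- lme4::ranef(lf)$delivery_id
  expect_equal(unname(me$group_effects[rownames(u)]), u[, 1],
               tolerance = 1e-5)
})

test_that("zero group variance degenerates to ordinary least squares", {
  set.seed(12)
  n <- 400
  df <- data.frame(prev_dilation = runif(n, 2, 9),
                   prev_station = sample(-3:2, n, TRUE),
                   prev_effacement = runif(n, 20, 100),
                   cum_contractions = rpois(n, 40),
                   epidural = rbinom(n, 1, 0.5),
                   delivery_id = rep(sprintf("d%02d", 1:40), each = 10))
  df$target_dilation <- 0.5 + 0.7 * df$prev_dilation + 0.1 * df$prev_station +
    0.01 * df$prev_effacement + 0.002 * df$cum_contractions +
    0.4 * df$epidural + rnorm(n, 0, 0.5)
  me <- fit_me(df, reml = FALSE)
  ols <- lm(target_dilation ~ prev_dilation + prev_station +
              prev_effacement + cum_contractions + epidural, df)
  expect_lt(me$tau2, 0.02)
  expect_equal(unname(me$beta), unname(coef(ols)), tolerance = 0.02)
})

test_that("known coefficients are recovered inside their intervals", {
  beta_true <- c(0.5, 0.7, 0.1, 0.03, 0.001, 0.6)
  hits <- matrix(NA, 10, 6)
  for (rep in 1:10) {
    set.seed(100 + rep)
    ng <- 150; per <- 4; n <- ng * per
    g <- rep(sprintf("g%03d", 1:ng), each = per)
    df <- data.frame(prev_dilation = runif(n, 2, 9),
                     prev_station = sample(-3:2, n, TRUE),
                     prev_effacement = runif(n, 20, 100),
                     cum_contractions = rpois(n, 60),
                     epidural = rbinom(n, 1, 0.5),
                     delivery_id = g)
    u <- rnorm(ng, 0, 0.4)[match(g, unique(g))]
    X <- cbind(1, as.matrix(df[1:5]))
    df$target_dilation <- drop(X %*% beta_true) + u + rnorm(n, 0, 0.7)
    me <- fit_me(df)
    hits[rep, ] <- abs(me$beta - beta_true) <= 1.96 * me$se
  }
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate and deficient designs are flagged", {
  set.seed(30)
  n <- 30
  df <- data.frame(prev_dilation = runif(n, 2, 9),
                   prev_station = sample(-3:2, n, TRUE),
                   prev_effacement = runif(n, 20, 100),
                   cum_contractions = rpois(n, 40),
                   epidural = rbinom(n, 1, 0.5),
                   delivery_id = sprintf("s%02d", seq_len(n)))
  df$target_dilation <- 1 + 0.7 * df$prev_dilation + rnorm(n, 0, 0.5)
  ## single observation per group: identifiability warning
  expect_warning(fit_me(df), "not separably estimable")
  ## collinear columns named in the error
  df2 <- df; df2$delivery_id <- rep(c("a", "b", "c"), 10)
  df2$prev_effacement <- 2 * df2$prev_dilation
  expect_error(fit_me(df2), "collinear")
})

test_that("prediction composes the fixed part, group effects and variances", {
  tr <- acc_memo("cohort-me",
                 simulate_transitions(sim_config(n_deliveries = 80,
                                                 seed = 7)))$transitions
  me <- fit_me(tr)
  ## hand-computed fixed part on a fixture row
  row <- tr[5, ]
  x <- c(1, row$prev_dilation, row$prev_station, row$prev_effacement,
         row$cum_contractions, row$epidural)
  expect_equal(predict_me(me, row)$mean, sum(x * me$beta),
               tolerance = 1e-10)
  ## unknown group: population sd includes the group variance
  p_unk <- predict_me(me, row, group = "no-such-delivery")
  expect_equal(p_unk$sd, sqrt(me$sigma2 + me$tau2))
  p_kn <- predict_me(me, row, group = row$delivery_id)
  expect_lt(p_kn$sd, p_unk$sd)
  ## known-group mean shifts by the estimated group effect
  expect_equal(p_kn$mean - predict_me(me, row)$mean,
               unname(me$group_effects[row$delivery_id]))
  ## predictive sd is constant across elapsed-time gaps
  rows <- tr[1:6, ]; rows$elapsed <- seq(0.5, 8, length.out = 6)
  expect_equal(length(unique(predict_me(me, rows)$sd)), 1L)
  ## summary table carries the coefficient / SE / p-value layout
  s <- me_summary(me)
  expect_equal(nrow(s), 8)
  expect_true(all(c("coefficient", "standard_error", "p_value")
                  %in% names(s)))
})
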