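## Trainer behavior on a small pooled cohort (kept deliberately small;
## the pattern-level experiments live in the acceptance suite).

small_cohort <- function(n = 30, seed = 17) {
  acc_memo(paste0("cohort", n, "-", seed),
           simulate_transitions(sim_config(n_deliveries = n, seed = seed)))
}

fast_cfg <- function(...) {
  args <- list(m_inducing = 24, adam_steps = 40, lbfgs_maxit = 20,
               seed = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

test_that("training is deterministic and the bound improves over milestones", {
  tr <- small_cohort()$transitions
  m1 <- train_prior(tr, fast_cfg(), flavor = "joint")
  m2 <- train_prior(tr, fast_cfg(), flavor = "joint")
  expect_equal(m1$milestones[["lbfgs"]], m2$milestones[["lbfgs"]],
               tolerance = 1e-6)
  expect_identical(m1$theta, m2$theta)
  ## milestones non-decreasing (within optimizer tolerance)
  expect_gte(m1$milestones[["adam"]], m1$milestones[["init"]] - 1e-6)
  expect_gte(m1$milestones[["lbfgs"]], m1$milestones[["adam"]] - 1e-4)
  ## identical predictors give identical predictions
  p1 <- predict(m1, tr[c(1, 1), ])
  expect_equal(p1$mean[p1$row == 1], p1$mean[p1$row == 2])
})

test_that("a zero-step budget returns the initialization unchanged", {
  tr <- small_cohort()$transitions
  m <- train_prior(tr, fast_cfg(adam_steps = 0, lbfgs_maxit = 0),
                   flavor = "dil_only")
  expect_equal(length(m$milestones), 1L)
  m_ref <- train_prior(tr, fast_cfg(adam_steps = 0, lbfgs_maxit = 0),
                       flavor = "dil_only")
  expect_identical(m$theta, m_ref$theta)
})

test_that("flavors expose the documented predictor sets and outputs", {
  tr <- small_cohort()$transitions
  mt <- train_time_only(tr, fast_cfg())
  expect_equal(mt$predictors, "exam_time")
  expect_equal(mt$outputs, "dilation")
  ## the time-only model ignores everything except time
  nd <- tr[1:2, ]
  nd$prev_dilation <- c(0, 9)
  p1 <- predict(mt, nd)
  nd$prev_dilation <- c(9, 0)
  p2 <- predict(mt, nd)
  expect_equal(p1$mean, p2$mean)
  ms <- train_prior(tr, fast_cfg(), flavor = "stat_only")
  expect_equal(ms$outputs, "station")
  expect_error(train_prior(tr, fast_cfg(), flavor = "nope"),
               "unknown flavor")
  expect_error(predict(mt, tr[1:2, setdiff(names(tr), "exam_time")]),
               "exam_time")
  ## single-delivery training set still trains
  one <- tr[tr$delivery_id == tr$delivery_id[1], ]
  expect_s3_class(train_time_only(one, fast_cfg(m_inducing = 2)),
                  "labor_gp")
})

test_that("adaptation is a no-op without data or with everything frozen", {
  tr <- small_cohort()$transitions
  m <- train_prior(tr, fast_cfg(), flavor = "joint")
  te <- tr[tr$delivery_id == tr$delivery_id[1], ]
  m_empty <- adapt_to_delivery(m, te[0, ])
  expect_identical(m_empty$theta, m$theta)
  expect_equal(predict(m_empty, te)$mean, predict(m, te)$mean)
  m_frozen <- adapt_to_delivery(m, te, adapt_config(unfreeze = character(0)))
  expect_equal(predict(m_frozen, te)$mean, predict(m, te)$mean)
  expect_true(m_frozen$adapted)
})

test_that("adaptation corrects a constant per-delivery offset", {
  tr <- small_cohort()$transitions
  m <- train_prior(tr, fast_cfg(), flavor = "joint")
  id <- unique(tr$delivery_id)[1]
  te <- tr[tr$delivery_id == id, ]
  te <- te[order(te$exam_time), ]
  expect_gte(nrow(te), 4)
  ## shift this delivery's dilation observations by a constant
  off <- 1.5
  te$target_dilation <- te$target_dilation + off
  te$prev_dilation <- te$prev_dilation + off
  past <- te[1:(nrow(te) - 1), ]
  last <- te[nrow(te), , drop = FALSE]
  m5b <- adapt_to_delivery(m, past, adapt_config(maxit = 40))
  e5p <- abs(predict(m, last, outputs = "dilation")$mean -
               last$target_dilation)
  e5b <- abs(predict(m5b, last, outputs = "dilation")$mean -
               last$target_dilation)
  expect_lt(e5b, e5p)
})

test_that("predictive sd grows with elapsed time when it is a kernel input", {
  sim <- small_cohort(40, seed = 23)
  cfg <- fast_cfg(include_elapsed = TRUE, adam_steps = 60,
                  lbfgs_maxit = 30)
  m <- train_prior(sim$transitions, cfg, flavor = "joint")
  base <- sim$transitions[3, , drop = FALSE]
  grid <- do.call(rbind, lapply(seq(1, 8, by = 1), function(g) {
    b <- base; b$elapsed <- g; b
  }))
  p <- predict(m, grid, outputs = "dilation")
  expect_gt(p$sd[8], p$sd[1])
  expect_gt(stats::cor(seq(1, 8), p$sd, method = "spearman"), 0.7)
})
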