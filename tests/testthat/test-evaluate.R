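test_that("fold plans partition deliveries with the documented proportions", {
  ids <- sprintf("d%03d", 1:50)
  plan <- make_cv_plan(ids, k = 10, seed = 4)
  expect_setequal(plan$delivery_id, ids)
  expect_true(all(table(plan$fold) == 5))
  tested <- unlist(lapply(1:10, function(f) cv_roles(plan, f)$test))
  expect_setequal(tested, ids)
  expect_equal(anyDuplicated(tested), 0)
  for (f in c(1, 5, 10)) {
    r <- cv_roles(plan, f)
    expect_equal(length(r$train), 40)
    expect_equal(length(r$validation), 5)
    expect_equal(length(r$test), 5)
    expect_equal(length(intersect(r$train, r$test)), 0)
    expect_equal(length(intersect(r$validation, r$test)), 0)
  }
  expect_identical(make_cv_plan(ids, 10, 4), plan)
  expect_error(make_cv_plan(ids[1:5], k = 10), "fewer deliveries")
  ## k = n: each fold tests exactly one delivery
  p1 <- make_cv_plan(ids[1:10], k = 10, seed = 1)
  expect_true(all(table(p1$fold) == 1))
})

test_that("scores follow their definitions and ordering", {
  expect_equal(score(c(1, 2), c(1, 2)), c(rmse = 0, mae = 0))
  expect_equal(score(c(1, 2), c(0, 0)),
               c(rmse = sqrt(2.5), mae = 1.5))
  expect_error(score(numeric(0), numeric(0)), "empty")
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    s <- score(a, b)
    expect_gte(s["rmse"], s["mae"])
  }
})

test_that("paired comparisons behave under identity, shift and symmetry", {
  set.seed(5)
  a <- abs(rnorm(100))
  expect_equal(paired_compare(a, a), 1)
  b <- a + 5
  expect_lt(paired_compare(a, b), 1e-4)
  expect_lt(paired_compare(a, b, method = "wilcoxon"), 1e-4)
  expect_equal(paired_compare(a, b), paired_compare(b, a))
  expect_error(paired_compare(a, b[1:10]), "equal-length")
})

test_that("binned summaries use closed-open integer-hour bins", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- c(0.5, 0.7, 1.0, 1.5, 2.2, 9.9)
  out <- binned_summary(v, g)
  expect_equal(sum(out$n), length(v))
  expect_equal(out$n[1], 2)           # [0,1): 0.5, 0.7
  expect_equal(out$n[2], 2)           # [1,2): 1.0 (closed low), 1.5
  expect_equal(out$n[3], 1)
  expect_equal(out$n[9], 1)           # open-ended last bin
  expect_equal(out$mean[1], 1.5)
  ## hand-computed quartiles on one bin
  out2 <- binned_summary(c(1, 2, 3, 4, 5, 6), rep(0.5, 6))
  expect_equal(out2$q25[1], 2.25)
  expect_equal(out2$q50[1], 3.5)
  expect_equal(out2$q75[1], 4.75)
  expect_equal(out2$n[-1], rep(0L, 8))
  expect_true(all(is.na(out2$mean[-1])))
})

test_that("coverage counts interval hits and respects nesting", {
  obs <- c(0, 1, 2)
  expect_equal(coverage(obs, lower = c(-1, 0, 3), upper = c(1, 2, 4)),
               2 / 3)
  expect_equal(coverage(obs, mean = obs, sd = rep(1, 3), level = 0.9), 1)
  expect_error(coverage(numeric(0), lower = 1, upper = 2), "empty")
  set.seed(8)
  m <- rnorm(200); s <- runif(200, 0.5, 2); o <- rnorm(200, m, s)
  c50 <- coverage(o, mean = m, sd = s, level = 0.5)
  c99 <- coverage(o, mean = m, sd = s, level = 0.99)
  expect_gte(c99, c50)
})

test_that("the harness produces a coherent report on a small cohort", {
  sim <- acc_memo("cohort-me",
                  simulate_transitions(sim_config(n_deliveries = 80,
                                                  seed = 7)))
  cfg <- train_config(m_inducing = 16, adam_steps = 30, lbfgs_maxit = 15,
                      seed = 2)
  rep <- run_evaluation(sim$transitions, models = c("time_only", "me"),
                        k = 5, seed = 3, train_cfg = cfg, folds = 1:2)
  expect_s3_class(rep, "eval_report")
  expect_true(all(rep$per_fold$rmse >= rep$per_fold$mae))
  expect_true(all(rep$coverage$coverage >= 0 & rep$coverage$coverage <= 1))
  ## per-fold metrics cover both models on both folds
  expect_equal(sort(unique(rep$per_fold$model)), c("me", "time_only"))
  expect_equal(sort(unique(rep$per_fold$fold)), c(1, 2))
  ## binned tables conserve the number of test exams
  bt <- rep$binned[["me.dilation"]]$abs_error
  expect_equal(sum(bt$n),
               sum(rep$predictions$model == "me"))
  ## report writer produces the documented artifacts
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(length(js$coverage), nrow(rep$coverage))
})
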