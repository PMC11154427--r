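#' Grouped cross-validation plan
#'
#' Assigns whole deliveries to folds so that no delivery's exams leak
#' across the train/validation/test partition.  For fold `f`, the test
#' set is fold `f`, the validation set is the next fold cyclically, and
#' the remaining folds train — an 80/10/10 split by delivery count at
#' `k = 10`.  Each delivery is tested in exactly one fold.
#'
#' @param delivery_ids character vector (duplicates allowed; the unique
#'   set is partitioned).
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return a `cv_plan` data.frame with columns `delivery_id`, `fold`.
#' @export
make_cv_plan <- function(delivery_ids, k = 10, seed = 1) {
  ids <- unique(as.character(delivery_ids))
  if (length(ids) < k) stop("fewer deliveries (", length(ids),
                            ") than folds (", k, ")")
  shuffled <- with_seed(seed, sample(ids))
  plan <- data.frame(delivery_id = shuffled,
                     fold = rep_len(seq_len(k), length(ids)))
  plan <- plan[order(plan$delivery_id), , drop = FALSE]
  rownames(plan) <- NULL
  structure(plan, k = k, seed = seed, class = c("cv_plan", "data.frame"))
}

#' @rdname make_cv_plan
#' @param plan a `cv_plan`.
#' @param fold fold number.
#' @return `cv_roles`: list of delivery-id vectors `train`, `validation`,
#'   `test`.
#' @export
cv_roles <- function(plan, fold) {
  k <- attr(plan, "k")
  stopifnot(fold >= 1, fold <= k)
  val_fold <- fold %% k + 1
  list(train = plan$delivery_id[!plan$fold %in% c(fold, val_fold)],
       validation = plan$delivery_id[plan$fold == val_fold],
       test = plan$delivery_id[plan$fold == fold])
}

#' Root-mean-square and mean absolute error
#'
#' @param predictions,targets equal-length numeric vectors.
#' @return named vector `c(rmse, mae)`.
#' @export
score <- function(predictions, targets) {
  if (length(predictions) == 0) stop("empty input to score()")
  stopifnot(length(predictions) == length(targets))
  e <- predictions - targets
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Paired comparison of per-sample losses
#'
#' Two-sided paired test of whether two models' per-sample losses
#' differ: a paired t-test by default, Wilcoxon signed-rank as an
#' alternative.  Identical loss vectors give p = 1 (degenerate case).
#'
#' @param errors_a,errors_b per-sample losses, paired by sample.
#' @param method `"t"` or `"wilcoxon"`.
#' @return the two-sided p-value.
#' @export
paired_compare <- function(errors_a, errors_b,
                           method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(errors_a) != length(errors_b))
    stop("paired comparison requires equal-length loss vectors")
  if (length(errors_a) < 2) stop("need at least 2 paired losses")
  d <- errors_a - errors_b
  if (all(abs(d - mean(d)) < 1e-14)) {
    return(if (all(abs(d) < 1e-14)) 1 else 0)
  }
  if (method == "t") {
    stats::t.test(errors_a, errors_b, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(errors_a, errors_b, paired = TRUE,
                       exact = FALSE)$p.value
  }
}

#' Summaries binned by elapsed time since the previous exam
#'
#' Bins are closed-open `[a, b)` with integer-hour edges by default
#' (0-8 h and an open-ended last bin).  Empty bins are reported with
#' count 0 and `NA` statistics.
#'
#' @param values numeric values to summarize (errors or predictive sd).
#' @param elapsed_gaps elapsed hours, same length.
#' @param bin_edges increasing edges in hours.
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `mean`, `q25`,
#'   `q50`, `q75`.
#' @export
binned_summary <- function(values, elapsed_gaps,
                           bin_edges = c(0:8, Inf)) {
  stopifnot(length(values) == length(elapsed_gaps),
            !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1],
                    n = 0L, mean = NA_real_, q25 = NA_real_,
                    q50 = NA_real_, q75 = NA_real_)
  bin <- findInterval(elapsed_gaps, bin_edges, rightmost.closed = FALSE)
  for (b in seq_len(nb)) {
    v <- values[bin == b]
    out$n[b] <- length(v)
    if (length(v)) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out$mean[b] <- mean(v)
      out$q25[b] <- q[1]; out$q50[b] <- q[2]; out$q75[b] <- q[3]
    }
  }
  out
}

#' Empirical central-interval coverage
#'
#' Fraction of observations inside their central predictive interval.
#'
#' @param lower,upper interval bounds per observation (or pass `mean`,
#'   `sd`, `level` to build Gaussian intervals).
#' @param observed observations.
#' @param mean,sd,level alternative Gaussian-interval specification.
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(observed, lower = NULL, upper = NULL,
                     mean = NULL, sd = NULL, level = 0.9) {
  if (length(observed) == 0) stop("empty input to coverage()")
  if (is.null(lower)) {
    stopifnot(!is.null(mean), !is.null(sd), level > 0, level < 1)
    z <- stats::qnorm(0.5 + level / 2)
    lower <- mean - z * sd; upper <- mean + z * sd
  }
  base::mean(observed >= lower & observed <= upper)
}

## ---- full harness ----------------------------------------------------

.model_labels <- c(time_only = "GP(t) dil", me = "ME dil",
                   dil_only = "GP dil", stat_only = "GP stat",
                   joint = "GP dil+stat (5p)",
                   joint_adapt = "GP dil+stat (5b)")

## Predictions of one model on the test transitions; returns rows
## (delivery_id, output, obs, pred, sd, lower, upper, elapsed).
.predict_rows <- function(kind, model, test_tr, adapt_cfg, level) {
  if (kind == "me") {
    pr <- predict_me(model, test_tr)
    z <- stats::qnorm(0.5 + level / 2)
    return(data.frame(delivery_id = test_tr$delivery_id,
                      output = "dilation",
                      obs = test_tr$target_dilation,
                      pred = pr$mean, sd = pr$sd,
                      lower = pr$mean - z * pr$sd,
                      upper = pr$mean + z * pr$sd,
                      elapsed = test_tr$elapsed))
  }
  if (kind == "joint_adapt") {
    out <- list()
    for (id in unique(test_tr$delivery_id)) {
      tr <- test_tr[test_tr$delivery_id == id, , drop = FALSE]
      tr <- tr[order(tr$exam_time), , drop = FALSE]
      for (j in seq_len(nrow(tr))) {
        m5b <- adapt_to_delivery(model, tr[seq_len(j - 1), , drop = FALSE],
                                 adapt_cfg)
        pr <- predict(m5b, tr[j, , drop = FALSE], level = level)
        out[[length(out) + 1L]] <- data.frame(
          delivery_id = id, output = pr$output,
          obs = unlist(tr[j, target_col[pr$output]], use.names = FALSE),
          pred = pr$mean, sd = pr$sd, lower = pr$lower, upper = pr$upper,
          elapsed = tr$elapsed[j])
      }
    }
    return(do.call(rbind, out))
  }
  pr <- predict(model, test_tr, level = level)
  obs <- vapply(seq_len(nrow(pr)), function(i)
    test_tr[[target_col[[pr$output[i]]]]][pr$row[i]], numeric(1))
  data.frame(delivery_id = test_tr$delivery_id[pr$row],
             output = pr$output, obs = obs,
             pred = pr$mean, sd = pr$sd, lower = pr$lower,
             upper = pr$upper, elapsed = test_tr$elapsed[pr$row])
}

#' Run the cross-validated model comparison harness
#'
#' For each fold: trains the requested models on the training
#' deliveries' pooled transitions, predicts the held-out test
#' deliveries, and accumulates per-exam predictions.  Produces RMSE/MAE
#' per fold, paired model comparisons at the exam and fold level,
#' elapsed-time-binned error and uncertainty tables, and interval
#' coverage.
#'
#' @param transitions pooled transitions data.frame.
#' @param models subset of `c("time_only", "me", "dil_only",
#'   "stat_only", "joint", "joint_adapt")`.
#' @param k number of folds.
#' @param seed seed for the fold plan (training seeds derive from it).
#' @param train_cfg a [train_config()].
#' @param adapt_cfg an [adapt_config()] (for `"joint_adapt"`).
#' @param folds optional subset of folds to run (default all).
#' @param level interval level for coverage.
#' @param pairs list of model pairs to compare (defaults below).
#' @return an `eval_report` list.
#' @export
run_evaluation <- function(transitions,
                           models = c("time_only", "me", "dil_only",
                                      "joint"),
                           k = 10, seed = 1,
                           train_cfg = train_config(),
                           adapt_cfg = adapt_config(),
                           folds = NULL, level = 0.9, pairs = NULL) {
  plan <- make_cv_plan(transitions$delivery_id, k = k, seed = seed)
  if (is.null(folds)) folds <- seq_len(k)
  preds <- list()
  for (f in folds) {
    roles <- cv_roles(plan, f)
    train_tr <- transitions[transitions$delivery_id %in% roles$train, ,
                            drop = FALSE]
    test_tr <- transitions[transitions$delivery_id %in% roles$test, ,
                           drop = FALSE]
    if (nrow(test_tr) == 0) next
    fitted <- list()
    need_joint <- any(c("joint", "joint_adapt") %in% models)
    for (kind in setdiff(models, "joint_adapt")) {
      cfg <- train_cfg
      cfg$seed <- substream_seed(seed, f)
      fitted[[kind]] <- if (kind == "me") fit_me(train_tr)
      else train_prior(train_tr, cfg, flavor = kind)
    }
    if (need_joint && is.null(fitted$joint)) {
      cfg <- train_cfg; cfg$seed <- substream_seed(seed, f)
      fitted$joint <- train_prior(train_tr, cfg, flavor = "joint")
    }
    for (kind in models) {
      model <- if (kind == "joint_adapt") fitted$joint else fitted[[kind]]
      rows <- .predict_rows(kind, model, test_tr, adapt_cfg, level)
      rows$fold <- f
      rows$model <- kind
      preds[[length(preds) + 1L]] <- rows
    }
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  ## per-fold metrics
  key <- interaction(predictions$fold, predictions$model,
                     predictions$output, drop = TRUE)
  per_fold <- do.call(rbind, lapply(split(predictions, key), function(s) {
    sc <- score(s$pred, s$obs)
    data.frame(fold = s$fold[1], model = s$model[1], output = s$output[1],
               rmse = sc["rmse"], mae = sc["mae"], n = nrow(s))
  }))
  rownames(per_fold) <- NULL
  skey <- interaction(per_fold$model, per_fold$output, drop = TRUE)
  summary <- do.call(rbind, lapply(split(per_fold, skey), function(s)
    data.frame(model = s$model[1], output = s$output[1],
               rmse_mean = mean(s$rmse), rmse_sd = stats::sd(s$rmse),
               mae_mean = mean(s$mae), mae_sd = stats::sd(s$mae),
               n = sum(s$n))))
  rownames(summary) <- NULL
  if (is.null(pairs)) {
    pairs <- list(c("time_only", "joint", "dilation"),
                  c("time_only", "dil_only", "dilation"),
                  c("me", "dil_only", "dilation"),
                  c("me", "joint", "dilation"),
                  c("dil_only", "joint", "dilation"),
                  c("stat_only", "joint", "station"),
                  c("joint", "joint_adapt", "dilation"),
                  c("joint", "joint_adapt", "station"))
  }
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    a <- predictions[predictions$model == pr[1] &
                       predictions$output == pr[3], , drop = FALSE]
    b <- predictions[predictions$model == pr[2] &
                       predictions$output == pr[3], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0 || nrow(a) != nrow(b)) return(NULL)
    ord <- function(s) s[order(s$fold, s$delivery_id, s$elapsed, s$obs), ]
    a <- ord(a); b <- ord(b)
    fa <- per_fold[per_fold$model == pr[1] & per_fold$output == pr[3], ]
    fb <- per_fold[per_fold$model == pr[2] & per_fold$output == pr[3], ]
    data.frame(model_a = pr[1], model_b = pr[2], output = pr[3],
               rmse_a = sqrt(mean((a$pred - a$obs)^2)),
               rmse_b = sqrt(mean((b$pred - b$obs)^2)),
               mae_a = mean(abs(a$pred - a$obs)),
               mae_b = mean(abs(b$pred - b$obs)),
               p_sq_exam = paired_compare((a$pred - a$obs)^2,
                                          (b$pred - b$obs)^2),
               p_abs_exam = paired_compare(abs(a$pred - a$obs),
                                           abs(b$pred - b$obs)),
               p_rmse_fold = if (nrow(fa) >= 2 && nrow(fa) == nrow(fb))
                 paired_compare(fa$rmse, fb$rmse) else NA_real_)
  }))
  ## binned error / uncertainty and coverage per model x output
  mkey <- interaction(predictions$model, predictions$output, drop = TRUE)
  binned <- lapply(split(predictions, mkey), function(s)
    list(abs_error = binned_summary(abs(s$pred - s$obs), s$elapsed),
         predictive_sd = binned_summary(s$sd, s$elapsed)))
  cov <- do.call(rbind, lapply(split(predictions, mkey), function(s)
    data.frame(model = s$model[1], output = s$output[1],
               level = level,
               coverage = coverage(s$obs, s$lower, s$upper),
               n = nrow(s))))
  rownames(cov) <- NULL
  structure(list(per_fold = per_fold, summary = summary,
                 comparisons = comparisons, binned = binned,
                 coverage = cov, predictions = predictions,
                 plan = plan, level = level, models = models,
                 seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validated labor-progression model comparison\n")
  s <- x$summary
  s$model <- .model_labels[s$model]
  print(s, row.names = FALSE, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("\nPaired comparisons (exam-level):\n")
    print(x$comparisons[c("model_a", "model_b", "output", "rmse_a",
                          "rmse_b", "p_sq_exam", "p_abs_exam")],
          row.names = FALSE, digits = 4)
  }
  cat("\nNote: p-values are unadjusted across the pre-planned contrasts.\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus CSV tables (per-fold metrics, comparisons, binned
#' summaries, coverage).
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_fold, file.path(dir, "per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  utils::write.csv(report$coverage, file.path(dir, "coverage.csv"),
                   row.names = FALSE)
  for (nm in names(report$binned)) {
    utils::write.csv(report$binned[[nm]]$abs_error,
                     file.path(dir, paste0("binned_abs_error_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(report$binned[[nm]]$predictive_sd,
                     file.path(dir, paste0("binned_sd_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summary = report$summary, comparisons = report$comparisons,
         coverage = report$coverage, level = report$level,
         seed = report$seed, models = report$models),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
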