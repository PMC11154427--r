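#' Linear mixed-effects baseline for dilation
#'
#' Fits the random-intercept model
#' `dilation = b0 + b1 prev_dilation + b2 prev_station +
#'  b3 prev_effacement + b4 cum_contractions + b5 epidural +
#'  u(delivery) + e`, with `u ~ N(0, tau2)` per delivery and
#' `e ~ N(0, sigma2)`, by profiling the variance ratio
#' `lambda = tau2 / sigma2`: for fixed `lambda` the generalized
#' least-squares solve is closed-form per group, leaving a 1-D
#' optimization.  REML by default, ML optionally.  Induction is not a
#' fixed effect in the reference formulation; set
#' `include_induction = TRUE` to add it.
#'
#' @param transitions transitions data.frame (see
#'   [build_transitions()]).
#' @param group_ids grouping factor (defaults to
#'   `transitions$delivery_id`).
#' @param reml use REML (default) or ML.
#' @param include_induction add the induction indicator as a fixed
#'   effect.
#' @param response name of the target column.
#' @return an object of class `me_model` with elements `beta`, `se`,
#'   `z`, `p`, `tau2`, `tau2_se`, `sigma2`, `group_effects`, `lambda`.
#' @export
fit_me <- function(transitions, group_ids = transitions$delivery_id,
                   reml = TRUE, include_induction = FALSE,
                   response = "target_dilation") {
  fixed <- c("prev_dilation", "prev_station", "prev_effacement",
             "cum_contractions", "epidural")
  if (include_induction) fixed <- c(fixed, "induced")
  X <- cbind(`(Intercept)` = 1, build_design(transitions, fixed))
  y <- as.numeric(transitions[[response]])
  g <- factor(group_ids)
  if (nlevels(g) < 2) stop("need at least 2 groups to fit a mixed model")
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  gi <- split(seq_len(n), g)
  ng <- lengths(gi)
  if (all(ng == 1))
    warning("every delivery has a single observation: group and residual ",
            "variances are not separably estimable")
  ## sufficient statistics per group
  XtX_g <- lapply(gi, function(ix) crossprod(X[ix, , drop = FALSE]))
  Xs_g <- lapply(gi, function(ix) colSums(X[ix, , drop = FALSE]))
  ys_g <- vapply(gi, function(ix) sum(y[ix]), numeric(1))
  Xty_g <- lapply(gi, function(ix)
    crossprod(X[ix, , drop = FALSE], y[ix]))
  yty <- sum(y^2)
  gls <- function(lambda) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); yVy <- yty
    logdet <- 0
    for (k in seq_along(gi)) {
      w <- lambda / (1 + lambda * ng[k])
      XtVX <- XtVX + XtX_g[[k]] - w * tcrossprod(Xs_g[[k]])
      XtVy <- XtVy + Xty_g[[k]] - w * Xs_g[[k]] * ys_g[k]
      yVy <- yVy - w * ys_g[k]^2
      logdet <- logdet + log1p(lambda * ng[k])
    }
    ch <- chol(XtVX)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    rss <- max(yVy - sum(beta * XtVy), 1e-12)
    list(beta = beta, rss = rss, logdet = logdet, XtVX = XtVX, chol = ch)
  }
  dev <- function(loglambda) {
    f <- gls(exp(loglambda))
    if (reml) {
      s2 <- f$rss / (n - p)
      (n - p) * log(s2) + f$logdet + 2 * sum(log(diag(f$chol)))
    } else {
      s2 <- f$rss / n
      n * log(s2) + f$logdet
    }
  }
  opt <- stats::optimize(dev, interval = c(-12, 8), tol = 1e-9)
  if (dev(-16) <= opt$objective) opt <- list(minimum = -16)  # boundary: tau2 ~ 0
  lambda <- exp(opt$minimum)
  f <- gls(lambda)
  sigma2 <- f$rss / if (reml) n - p else n
  tau2 <- lambda * sigma2
  covb <- sigma2 * chol2inv(f$chol)
  se <- sqrt(diag(covb))
  beta <- drop(f$beta); names(beta) <- colnames(X); names(se) <- colnames(X)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  ## group effects (BLUPs) and their conditional shrinkage
  resid_sum <- ys_g - vapply(Xs_g, function(s) sum(s * beta), numeric(1))
  u <- lambda * resid_sum / (1 + lambda * ng)
  ## SE of the variance components from the numerically observed
  ## information of the (beta-profiled) deviance in (tau2, sigma2)
  dev2 <- function(v) {
    tau2i <- max(v[1], 1e-10); s2i <- max(v[2], 1e-10)
    fi <- gls(tau2i / s2i)
    ld_extra <- if (reml) 2 * sum(log(diag(fi$chol))) - p * log(s2i) else 0
    n * log(s2i) + fi$rss / s2i + fi$logdet + ld_extra
  }
  tau2_se <- tryCatch({
    h <- .num_hessian(dev2, c(tau2, sigma2))
    sqrt(diag(2 * solve(h)))[1]
  }, error = function(e) NA_real_)
  structure(list(beta = beta, se = se, z = z, p = pval,
                 tau2 = tau2, tau2_se = tau2_se, sigma2 = sigma2,
                 lambda = lambda, reml = reml,
                 group_effects = stats::setNames(u, names(gi)),
                 group_sizes = stats::setNames(as.numeric(ng), names(gi)),
                 predictors = fixed, response = response, n = n),
            class = "me_model")
}

.num_hessian <- function(fn, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1e-4) * 1e-4
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Predict from the mixed-effects baseline
#'
#' Known deliveries get the fixed part plus their estimated group
#' effect, with predictive variance `sigma2` plus the conditional
#' variance of the group effect; unknown deliveries get the
#' population-level fixed part with variance `sigma2 + tau2`.
#'
#' @param model a fitted [fit_me()] model.
#' @param newdata transitions data.frame.
#' @param group optional vector of delivery ids (default: the
#'   population-level prediction for every row).
#' @return data.frame with `mean` and `sd`.
#' @export
predict_me <- function(model, newdata, group = NULL) {
  X <- cbind(`(Intercept)` = 1, build_design(newdata, model$predictors))
  mu <- drop(X %*% model$beta)
  sd_pop <- sqrt(model$sigma2 + model$tau2)
  if (is.null(group)) {
    return(data.frame(mean = mu, sd = rep(sd_pop, length(mu))))
  }
  group <- as.character(group)
  known <- group %in% names(model$group_effects)
  mu[known] <- mu[known] + model$group_effects[group[known]]
  sdv <- rep(sd_pop, length(mu))
  ngk <- model$group_sizes[group[known]]
  sdv[known] <- sqrt(model$sigma2 +
                       model$tau2 / (1 + model$lambda * ngk))
  data.frame(mean = mu, sd = sdv)
}

#' Coefficient table of the mixed-effects fit
#'
#' Fixed-effect coefficients with standard errors and Wald p-values,
#' followed by the group (delivery) variance and the residual variance.
#'
#' @param model a fitted [fit_me()] model.
#' @return data.frame with columns `name`, `coefficient`,
#'   `standard_error`, `p_value`.
#' @export
me_summary <- function(model) {
  fx <- data.frame(name = names(model$beta),
                   coefficient = unname(model$beta),
                   standard_error = unname(model$se),
                   p_value = unname(model$p))
  rbind(fx,
        data.frame(name = "Group variance (Delivery ID)",
                   coefficient = model$tau2,
                   standard_error = model$tau2_se, p_value = NA),
        data.frame(name = "Model variance (sigma2)",
                   coefficient = model$sigma2,
                   standard_error = NA, p_value = NA))
}

#' @export
print.me_model <- function(x, ...) {
  cat("Random-intercept mixed-effects model (",
      if (x$reml) "REML" else "ML", "), n = ", x$n, ", groups = ",
      length(x$group_effects), "\n", sep = "")
  print(me_summary(x), row.names = FALSE)
  invisible(x)
}
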