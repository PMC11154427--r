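#' Training configuration
#'
#' Optimization and model-structure settings for the sparse GP trainer.
#' Training uses the hybrid scheme of first-order Adam steps followed by
#' bounded quasi-Newton (L-BFGS-B) refinement of the collapsed bound.
#'
#' @param m_inducing number of inducing points (k-means initialized,
#'   then held fixed).
#' @param hidden hidden-layer widths of the neural mean function.
#' @param mat_nu Matern smoothness (0.5, 1.5 or 2.5).
#' @param adam_steps,adam_lr Adam iteration budget and learning rate.
#' @param lbfgs_maxit maximum L-BFGS-B refinement iterations.
#' @param tol relative convergence tolerance of the refinement stage.
#' @param include_elapsed include the elapsed time since the previous
#'   exam as a kernel input (excluded by default).
#' @param init_scale scale of the random mean-network initialization.
#' @param net_prior_sd standard deviation of the Gaussian prior on the
#'   mean-network parameters (MAP regularization; `Inf` disables it).
#'   Prevents the flexible parametric mean from interpolating small
#'   training pools, which would collapse the noise variance.
#' @param seed seed governing initialization and inducing-point placement.
#' @return a `train_config` list.
#' @export
train_config <- function(m_inducing = 64, hidden = c(32, 32), mat_nu = 2.5,
                         adam_steps = 150, adam_lr = 0.02,
                         lbfgs_maxit = 60, tol = 1e-8,
                         include_elapsed = FALSE, init_scale = 0.3,
                         net_prior_sd = 0.2, seed = 1) {
  stopifnot(m_inducing >= 1, adam_steps >= 0, lbfgs_maxit >= 0, tol > 0,
            net_prior_sd > 0)
  structure(list(m_inducing = m_inducing, hidden = hidden, mat_nu = mat_nu,
                 adam_steps = adam_steps, adam_lr = adam_lr,
                 lbfgs_maxit = lbfgs_maxit, tol = tol,
                 include_elapsed = include_elapsed,
                 init_scale = init_scale, net_prior_sd = net_prior_sd,
                 seed = seed),
            class = "train_config")
}

#' Per-delivery adaptation configuration
#'
#' Controls which parameter groups are unfrozen when the shared prior is
#' fine-tuned on a test delivery's own past exams.  The restrictive
#' default (mean-network output layer, kernel signal variances and the
#' noise variance) guards against the rare catastrophic adapted-model
#' errors that full unfreezing can produce on very small per-delivery
#' samples; `unfreeze = "all"` reproduces the unrestricted behavior.
#'
#' @param maxit L-BFGS-B iteration budget for the fine-tuning.
#' @param unfreeze character vector of parameter groups among
#'   `"kernel_var"`, `"kernel_ls"`, `"coreg"`, `"noise"`, `"net_out"`,
#'   `"net_hidden"`, or the shorthand `"all"`; an empty vector freezes
#'   everything (adaptation becomes a no-op).
#' @param prior_sd standard deviation of the Gaussian trust-region
#'   penalty anchoring the unfrozen raw parameters at their trained
#'   values during fine-tuning; `Inf` removes the anchor (the
#'   unregularized mode, prone to occasional large adapted-model
#'   errors on very small per-delivery samples).
#' @return an `adapt_config` list.
#' @export
adapt_config <- function(maxit = 30,
                         unfreeze = c("net_out", "kernel_var", "noise"),
                         prior_sd = 0.5) {
  if (length(unfreeze) == 1 && identical(unfreeze, "all"))
    unfreeze <- c("kernel_var", "kernel_ls", "coreg", "noise",
                  "net_out", "net_hidden")
  stopifnot(prior_sd > 0)
  structure(list(maxit = maxit, unfreeze = unfreeze, prior_sd = prior_sd),
            class = "adapt_config")
}

## ---- flavors and design matrices -------------------------------------

flavor_predictors <- function(flavor, include_elapsed = FALSE) {
  if (flavor == "time_only") return("exam_time")
  p <- c("prev_dilation", "prev_station", "prev_effacement",
         "cum_contractions", "epidural", "induced")
  if (include_elapsed) p <- c(p, "elapsed")
  p
}

flavor_outputs <- function(flavor) {
  switch(flavor,
         joint = c("dilation", "station"),
         dil_only = "dilation",
         time_only = "dilation",
         stat_only = "station",
         stop("unknown flavor: ", flavor))
}

target_col <- c(dilation = "target_dilation", station = "target_station")

build_design <- function(transitions, predictors) {
  missing <- setdiff(predictors, names(transitions))
  if (length(missing))
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(lapply(transitions[predictors], as.numeric)))
}

## Stack transitions into the augmented (input, output-index)
## representation.  Output index: dilation = 0, station = 1 for joint
## models; single-output models use index 0 throughout.
stack_training <- function(transitions, predictors, outputs) {
  X1 <- build_design(transitions, predictors)
  n_out <- length(outputs)
  X <- X1[rep(seq_len(nrow(X1)), times = n_out), , drop = FALSE]
  idx <- if (n_out == 2) rep(0:1, each = nrow(X1)) else rep(0L, nrow(X1))
  y <- unlist(lapply(outputs, function(o) as.numeric(transitions[[target_col[o]]])),
              use.names = FALSE)
  row_of <- rep(seq_len(nrow(X1)), times = n_out)
  list(X = X, idx = as.integer(idx), y = y, row = row_of)
}

## ---- parameter packing ----------------------------------------------

make_pinfo <- function(d, n_outputs, hidden, mat_nu, lin_offset = 0,
                       rank = 1) {
  sizes <- c(d, hidden, n_outputs)
  slices <- list(); groups <- character(0); pos <- 0L
  add <- function(name, len, group) {
    slices[[name]] <<- pos + seq_len(len)
    groups <<- c(groups, rep(group, len))
    pos <<- pos + len
  }
  add("se_var", 1L, "kernel_var"); add("se_ls", d, "kernel_ls")
  add("mat_var", 1L, "kernel_var"); add("mat_ls", d, "kernel_ls")
  add("lin_var", d, "kernel_var")
  if (n_outputs == 2) {
    add("cW", 2L * rank, "coreg"); add("ckappa", 2L, "coreg")
  }
  ## per-output observation noise for two-output models
  add("sigma2", n_outputs, "noise")
  L <- length(sizes) - 1L
  for (l in seq_len(L)) {
    grp <- if (l == L) "net_out" else "net_hidden"
    add(paste0("net_W", l), sizes[l + 1L] * sizes[l], grp)
    add(paste0("net_b", l), sizes[l + 1L], grp)
  }
  if (n_outputs == 2 && length(hidden))
    add("net_E", sizes[2L] * 2L, "net_hidden")
  list(d = d, n_outputs = n_outputs, hidden = hidden, sizes = sizes,
       mat_nu = mat_nu, lin_offset = lin_offset, rank = rank,
       slices = slices, groups = groups, n_par = pos)
}

pack_theta <- function(pinfo, params, B, sigma2, net) {
  th <- numeric(pinfo$n_par)
  s <- pinfo$slices
  th[s$se_var] <- softplus_inv(params$se_var)
  th[s$se_ls] <- softplus_inv(params$se_ls)
  th[s$mat_var] <- softplus_inv(params$mat_var)
  th[s$mat_ls] <- softplus_inv(params$mat_ls)
  th[s$lin_var] <- softplus_inv(pmax(params$lin_var, 1e-8))
  if (pinfo$n_outputs == 2) {
    th[s$cW] <- as.numeric(B$W)
    th[s$ckappa] <- softplus_inv(pmax(B$kappa, 1e-8))
  }
  th[s$sigma2] <- softplus_inv(rep_len(sigma2, length(s$sigma2)))
  L <- length(pinfo$sizes) - 1L
  for (l in seq_len(L)) {
    th[s[[paste0("net_W", l)]]] <- as.numeric(net$W[[l]])
    th[s[[paste0("net_b", l)]]] <- net$b[[l]]
  }
  if (!is.null(s$net_E)) th[s$net_E] <- as.numeric(net$E)
  th
}

unpack_theta <- function(theta, pinfo) {
  s <- pinfo$slices
  params <- kernel_params(pinfo$d,
                          se_var = softplus(theta[s$se_var]),
                          se_ls = softplus(theta[s$se_ls]),
                          mat_var = softplus(theta[s$mat_var]),
                          mat_ls = softplus(theta[s$mat_ls]),
                          mat_nu = pinfo$mat_nu,
                          lin_var = softplus(theta[s$lin_var]),
                          lin_offset = pinfo$lin_offset)
  B <- NULL
  if (pinfo$n_outputs == 2) {
    B <- coreg_matrix(matrix(theta[s$cW], nrow = 2),
                      softplus(theta[s$ckappa]))
  }
  sigma2 <- softplus(theta[s$sigma2])
  sizes <- pinfo$sizes
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(theta[s[[paste0("net_W", l)]]], nrow = sizes[l + 1L])
    b[[l]] <- theta[s[[paste0("net_b", l)]]]
  }
  E <- if (!is.null(s$net_E)) matrix(theta[s$net_E], ncol = 2) else NULL
  net <- structure(list(W = W, b = b, E = E, sizes = sizes,
                        n_outputs = pinfo$n_outputs),
                   class = "mean_net")
  list(params = params, B = B, sigma2 = sigma2, net = net)
}

## ---- objective with analytic gradient --------------------------------

## Builds fn(theta) -> list(value = ELBO, grad = dELBO/dtheta) for fixed
## stacked data and inducing set.
make_elbo_objective <- function(X, idx, y, Z, zidx, pinfo,
                                net_prior_sd = Inf) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  d <- pinfo$d
  two <- pinfo$n_outputs == 2
  net_idx <- which(pinfo$groups %in% c("net_hidden", "net_out"))
  lam_net <- if (is.finite(net_prior_sd)) 1 / net_prior_sd^2 else 0
  nat_names <- c("se_var", paste0("se_ls", seq_len(d)),
                 "mat_var", paste0("mat_ls", seq_len(d)),
                 paste0("lin_var", seq_len(d)))
  function(theta, want_grad = TRUE) {
    up <- unpack_theta(theta, pinfo)
    params <- up$params; sigma2 <- up$sigma2; net <- up$net
    pt_uu <- base_kernel(params, Z, parts = want_grad)
    pt_uf <- base_kernel(params, Z, X, parts = want_grad)
    Kb_uu <- if (want_grad) pt_uu$K else pt_uu
    Kb_uf <- if (want_grad) pt_uf$K else pt_uf
    kb_ff <- base_kernel_diag(params, X)
    if (two) {
      Bm <- up$B$B
      Kuu <- Kb_uu * blook(Bm, zidx, zidx)
      Kuf <- Kb_uf * blook(Bm, zidx, idx)
      kff <- kb_ff * diag(Bm)[idx + 1L]
    } else {
      Kuu <- Kb_uu; Kuf <- Kb_uf; kff <- kb_ff
    }
    fw <- mean_net_forward(net, X, idx, cache = want_grad)
    mu <- if (want_grad) fw$mu else fw
    r <- y - mu
    core <- tryCatch(.sgpr_core(Kuu, Kuf, kff, r,
                                .noise_vec(sigma2, idx, length(r))),
                     error = function(e) NULL)
    if (is.null(core)) return(list(value = -Inf, grad = NULL))
    value <- .sgpr_elbo_from_factor(core)
    if (lam_net > 0)
      value <- value - 0.5 * lam_net * sum(theta[net_idx]^2)
    if (!want_grad || !is.finite(value))
      return(list(value = value, grad = NULL))
    gr <- .sgpr_grads(core)
    if (two) {
      W_uf <- gr$G_uf * blook(Bm, zidx, idx)
      W_uu <- gr$G_uu * blook(Bm, zidx, zidx)
      w_diag <- gr$g_diag * diag(Bm)[idx + 1L]
    } else {
      W_uf <- gr$G_uf; W_uu <- gr$G_uu; w_diag <- gr$g_diag
    }
    gnat <- kern_grad_accum(params, Z, X, W_uf, parts = pt_uf) +
      kern_grad_accum(params, Z, Z, W_uu, parts = pt_uu) +
      kern_grad_accum(params, X, NULL, w_diag, diag_only = TRUE)
    g <- numeric(pinfo$n_par)
    s <- pinfo$slices
    sp_chain <- function(slice) sigmoid(theta[slice])
    g[s$se_var] <- gnat["se_var"] * sp_chain(s$se_var)
    g[s$se_ls] <- gnat[paste0("se_ls", seq_len(d))] * sp_chain(s$se_ls)
    g[s$mat_var] <- gnat["mat_var"] * sp_chain(s$mat_var)
    g[s$mat_ls] <- gnat[paste0("mat_ls", seq_len(d))] * sp_chain(s$mat_ls)
    g[s$lin_var] <- gnat[paste0("lin_var", seq_len(d))] * sp_chain(s$lin_var)
    if (two) {
      gB <- matrix(0, 2, 2)
      for (i in 0:1) for (j in 0:1) {
        ri <- zidx == i; cj <- idx == j
        gB[i + 1, j + 1] <- gB[i + 1, j + 1] +
          sum(gr$G_uf[ri, cj, drop = FALSE] * Kb_uf[ri, cj, drop = FALSE])
        ci <- zidx == j
        gB[i + 1, j + 1] <- gB[i + 1, j + 1] +
          sum(gr$G_uu[ri, ci, drop = FALSE] * Kb_uu[ri, ci, drop = FALSE])
      }
      for (i in 0:1) {
        sel <- idx == i
        gB[i + 1, i + 1] <- gB[i + 1, i + 1] +
          sum(gr$g_diag[sel] * kb_ff[sel])
      }
      gW <- (gB + t(gB)) %*% up$B$W
      g[s$cW] <- as.numeric(gW)
      g[s$ckappa] <- diag(gB) * sp_chain(s$ckappa)
    }
    if (two) {
      g[s$sigma2] <- c(sum(gr$g_lam[idx == 0L]), sum(gr$g_lam[idx == 1L])) *
        sp_chain(s$sigma2)
    } else {
      g[s$sigma2] <- sum(gr$g_lam) * sp_chain(s$sigma2)
    }
    bp <- mean_net_backward(net, fw, idx, gr$g_mu)
    L <- length(pinfo$sizes) - 1L
    for (l in seq_len(L)) {
      g[s[[paste0("net_W", l)]]] <- as.numeric(bp$W[[l]])
      g[s[[paste0("net_b", l)]]] <- bp$b[[l]]
    }
    if (!is.null(s$net_E)) g[s$net_E] <- as.numeric(bp$E)
    if (lam_net > 0) g[net_idx] <- g[net_idx] - lam_net * theta[net_idx]
    list(value = value, grad = g)
  }
}

## ---- optimizers ------------------------------------------------------

adam_ascend <- function(theta, obj, steps, lr, groups = NULL) {
  if (steps == 0) {
    v0 <- obj(theta, want_grad = FALSE)$value
    return(list(theta = theta, value = v0))
  }
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  val <- NA_real_
  for (t in seq_len(steps)) {
    o <- obj(theta)
    if (!is.finite(o$value)) {
      diag_msg <- if (!is.null(groups)) {
        rng <- vapply(split(theta, groups), function(v)
          paste(signif(range(v), 3), collapse = ".."), character(1))
        paste(names(rng), rng, sep = "=", collapse = "; ")
      } else ""
      stop("non-finite training objective at Adam step ", t,
           "; raw parameter ranges by group: ", diag_msg)
    }
    val <- o$value
    gth <- o$grad
    m <- b1 * m + (1 - b1) * gth
    v <- b2 * v + (1 - b2) * gth^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    theta <- theta + lr * mh / (sqrt(vh) + eps)
  }
  list(theta = theta, value = val)
}

lbfgs_refine <- function(theta, obj, maxit, tol) {
  if (maxit == 0) return(list(theta = theta, value = obj(theta, FALSE)$value))
  memo <- new.env()
  evalo <- function(par) {
    key <- paste0(format(sum(par * seq_along(par)), digits = 17),
                  format(sum(par^2), digits = 17))
    if (!identical(memo$key, key)) {
      memo$o <- obj(par); memo$key <- key
    }
    memo$o
  }
  fn <- function(par) {
    v <- evalo(par)$value
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- function(par) {
    o <- evalo(par)
    if (!is.finite(o$value) || is.null(o$grad)) return(numeric(length(par)))
    -o$grad
  }
  res <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                      lower = -30, upper = 30,
                      control = list(maxit = maxit,
                                     factr = max(tol / 1e-15, 10)))
  list(theta = res$par, value = -res$value)
}

## ---- training --------------------------------------------------------

init_inducing <- function(X1, m, n_outputs) {
  ux <- unique(X1)
  mm <- if (n_outputs == 2) max(1L, floor(m / 2)) else m
  mm <- min(mm, nrow(ux))
  centers <- if (mm >= nrow(ux)) {
    ux
  } else {
    km <- tryCatch(suppressWarnings(
      stats::kmeans(ux, centers = mm, iter.max = 30,
                    algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) ux[sample.int(nrow(ux), mm), , drop = FALSE]
    else km$centers
  }
  if (n_outputs == 2) {
    list(Z = centers[rep(seq_len(nrow(centers)), 2), , drop = FALSE],
         zidx = rep(0:1, each = nrow(centers)))
  } else {
    list(Z = centers, zidx = rep(0L, nrow(centers)))
  }
}

#' Train the shared sparse GP prior over pooled delivery meta-tasks
#'
#' Pools the causal transition samples of the training deliveries and
#' maximizes the collapsed sparse-GP bound over the composite-kernel
#' hyperparameters, the coregionalization matrix, the noise variance and
#' the neural mean parameters, using Adam followed by L-BFGS-B.
#' Predictors and targets are z-scored (the latter per output) on the
#' training pool; all predictions are back-transformed.
#'
#' @param transitions a transitions data frame (see
#'   [build_transitions()]).
#' @param config a [train_config()].
#' @param flavor `"joint"` (dilation + station, the dual-output model),
#'   `"dil_only"`, `"stat_only"` or `"time_only"`.
#' @return a fitted model of class `labor_gp`.
#' @export
train_prior <- function(transitions, config = train_config(),
                        flavor = "joint") {
  outputs <- flavor_outputs(flavor)
  predictors <- flavor_predictors(flavor, config$include_elapsed)
  st <- stack_training(transitions, predictors, outputs)
  n_out <- length(outputs)
  ## normalization on the training pool
  x_mean <- colMeans(st$X); x_sd <- apply(st$X, 2, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
  Xs <- sweep(sweep(st$X, 2, x_mean), 2, x_sd, "/")
  y_mean <- vapply(seq_len(n_out) - 1L,
                   function(i) mean(st$y[st$idx == i]), numeric(1))
  y_sd <- vapply(seq_len(n_out) - 1L,
                 function(i) stats::sd(st$y[st$idx == i]), numeric(1))
  y_sd[!is.finite(y_sd) | y_sd < 1e-12] <- 1
  names(y_mean) <- names(y_sd) <- outputs
  yc <- (st$y - y_mean[st$idx + 1L]) / y_sd[st$idx + 1L]
  vy <- 1
  pinfo <- make_pinfo(length(predictors), n_out, config$hidden,
                      config$mat_nu)
  init <- with_seed(config$seed, {
    net <- mean_net(length(predictors), config$hidden, n_out,
                    init_scale = config$init_scale)
    ind <- init_inducing(Xs[st$idx == 0L, , drop = FALSE],
                         min(config$m_inducing, nrow(Xs)), n_out)
    list(net = net, ind = ind)
  })
  if (n_out == 2) {
    B0 <- coreg_matrix(c(0.6, 0.6), c(0.5, 0.5))
    kv <- 0.5 * vy
  } else {
    B0 <- NULL
    kv <- vy
  }
  params0 <- kernel_params(pinfo$d,
                           se_var = 0.5 * kv, se_ls = 1.5,
                           mat_var = 0.3 * kv, mat_ls = 1.5,
                           mat_nu = config$mat_nu,
                           lin_var = 0.1 * kv / pinfo$d)
  theta <- pack_theta(pinfo, params0, B0, 0.2 * vy, init$net)
  obj <- make_elbo_objective(Xs, st$idx, yc, init$ind$Z, init$ind$zidx,
                             pinfo, net_prior_sd = config$net_prior_sd)
  milestones <- c(init = obj(theta, want_grad = FALSE)$value)
  if (config$adam_steps > 0) {
    ad <- adam_ascend(theta, obj, config$adam_steps, config$adam_lr,
                      groups = pinfo$groups)
    theta <- ad$theta
    milestones <- c(milestones, adam = obj(theta, FALSE)$value)
  }
  if (config$lbfgs_maxit > 0) {
    lb <- lbfgs_refine(theta, obj, config$lbfgs_maxit, config$tol)
    if (lb$value >= milestones[length(milestones)]) theta <- lb$theta
    milestones <- c(milestones, lbfgs = obj(theta, FALSE)$value)
  }
  structure(list(flavor = flavor, outputs = outputs,
                 predictors = predictors, theta = theta, pinfo = pinfo,
                 Z = init$ind$Z, zidx = init$ind$zidx,
                 data = list(X = Xs, idx = st$idx, y = yc),
                 norm = list(x_mean = x_mean, x_sd = x_sd,
                             y_mean = y_mean, y_sd = y_sd),
                 config = config, seed = config$seed,
                 milestones = milestones, adapted = FALSE, extra = NULL),
            class = "labor_gp")
}

#' @rdname train_prior
#' @export
train_time_only <- function(transitions, config = train_config()) {
  train_prior(transitions, config, flavor = "time_only")
}

#' Fine-tune the shared prior on one delivery's own past exams
#'
#' Re-optimizes the unfrozen parameter groups of a trained model by
#' maximizing the exact log marginal likelihood of the delivery's past
#' transition samples, and records those samples as additional
#' conditioning data for subsequent predictions.  With no past samples,
#' or with every group frozen, the model is returned unchanged (the
#' adapted model's predictions coincide with the unadapted ones).
#'
#' @param model a trained `labor_gp`.
#' @param past_transitions transition samples of the delivery observed so
#'   far (strictly before the exam to be predicted).
#' @param config an [adapt_config()].
#' @return an adapted `labor_gp` (field `adapted = TRUE`).
#' @export
adapt_to_delivery <- function(model, past_transitions,
                              config = adapt_config()) {
  out <- model
  out$adapted <- TRUE
  out$adapt_mode <- config
  unfrozen <- which(model$pinfo$groups %in% config$unfreeze)
  if (is.null(past_transitions) || nrow(past_transitions) == 0L ||
      length(unfrozen) == 0L) {
    return(out)
  }
  st <- stack_training(past_transitions, model$predictors, model$outputs)
  Xa <- sweep(sweep(st$X, 2, model$norm$x_mean), 2, model$norm$x_sd, "/")
  ya <- (st$y - model$norm$y_mean[st$idx + 1L]) /
    model$norm$y_sd[st$idx + 1L]
  ## fine-tuning maximizes the exact marginal likelihood of the past
  ## samples (collapsed bound with Z = data), anchored at the trained
  ## parameters by a Gaussian trust-region penalty
  obj_full <- make_elbo_objective(Xa, st$idx, ya, Xa, st$idx, model$pinfo,
                                  net_prior_sd = Inf)
  theta0 <- model$theta
  sub0 <- theta0[unfrozen]
  lam <- if (is.finite(config$prior_sd)) 1 / config$prior_sd^2 else 0
  obj_sub <- function(sub, want_grad = TRUE) {
    th <- theta0; th[unfrozen] <- sub
    o <- obj_full(th, want_grad)
    if (is.finite(o$value) && lam > 0)
      o$value <- o$value - 0.5 * lam * sum((sub - sub0)^2)
    if (want_grad && !is.null(o$grad)) {
      o$grad <- o$grad[unfrozen]
      if (lam > 0) o$grad <- o$grad - lam * (sub - sub0)
    }
    o
  }
  lb <- tryCatch(lbfgs_refine(theta0[unfrozen], obj_sub, config$maxit, 1e-8),
                 error = function(e) NULL)
  theta <- theta0
  if (!is.null(lb)) theta[unfrozen] <- lb$theta
  out$theta <- theta
  out$extra <- list(X = Xa, idx = st$idx, y = ya)
  out
}

#' Predict exam outcomes from a trained model
#'
#' Posterior predictive mean, standard deviation and central interval of
#' the requested outputs at the given transition samples' predictors.
#' For an adapted model the conditioning set is the pooled training data
#' (through the inducing points) plus the delivery's own past exams.
#'
#' @param object a `labor_gp` model.
#' @param newdata transitions data frame with the model's predictor
#'   columns.
#' @param outputs subset of the model's outputs to predict.
#' @param level nominal central-interval level.
#' @param ... unused.
#' @return a data.frame with columns `row`, `output`, `mean`, `sd`,
#'   `var`, `lower`, `upper`, in the original measurement units.
#' @export
predict.labor_gp <- function(object, newdata, outputs = object$outputs,
                             level = 0.9, ...) {
  stopifnot(all(outputs %in% object$outputs))
  Xq <- build_design(newdata, object$predictors)
  Xq <- sweep(sweep(Xq, 2, object$norm$x_mean), 2, object$norm$x_sd, "/")
  up <- unpack_theta(object$theta, object$pinfo)
  X <- object$data$X; idx <- object$data$idx; y <- object$data$y
  if (!is.null(object$extra) && nrow(object$extra$X) > 0) {
    X <- rbind(X, object$extra$X)
    idx <- c(idx, object$extra$idx)
    y <- c(y, object$extra$y)
  }
  res <- lapply(outputs, function(o) {
    oi <- if (length(object$outputs) == 2) match(o, object$outputs) - 1L else 0L
    po <- sgpr_predict(X, idx, y, object$Z, object$zidx,
                       up$params, up$B, up$net, up$sigma2,
                       Xs = Xq, idxs = rep(oi, nrow(Xq)), level = level)
    ym <- object$norm$y_mean[[o]]; ys <- object$norm$y_sd[[o]]
    data.frame(row = seq_len(nrow(Xq)), output = o,
               mean = po$mean * ys + ym,
               sd = po$sd * ys, var = po$var * ys^2,
               lower = po$lower * ys + ym,
               upper = po$upper * ys + ym)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @rdname predict.labor_gp
#' @param model a `labor_gp` model.
#' @param sample one or more transition samples (data frame rows).
#' @export
predict_exam <- function(model, sample, outputs = model$outputs,
                         level = 0.9) {
  predict(model, sample, outputs = outputs, level = level)
}

#' @export
print.labor_gp <- function(x, ...) {
  up <- unpack_theta(x$theta, x$pinfo)
  cat("Sparse multi-output GP labor-progression model\n")
  cat("  flavor:", x$flavor,
      if (isTRUE(x$adapted)) "(adapted)" else "", "\n")
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  inducing points:", nrow(x$Z), " training points:",
      nrow(x$data$X), "\n")
  cat("  noise variance:", signif(up$sigma2, 4), "\n")
  if (!is.null(up$B))
    cat("  output correlation:", signif(coreg_correlation(up$B), 3), "\n")
  cat("  ELBO milestones:", paste(signif(x$milestones, 6), collapse = " -> "),
      "\n")
  invisible(x)
}
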