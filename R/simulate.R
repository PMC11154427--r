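#' Simulator configuration
#'
#' Parameters of the mechanistic labor simulator (regime A).  Defaults
#' describe a nulliparous-style cohort observed over the final hours of
#' the first stage: latent dilation follows a monotone accelerating
#' curve from an admission dilation of 1-3 cm to 10 cm at delivery, with
#' occasional arrest plateaus; fetal station is a monotone transform of
#' a mixture of the shared progression latent and an independent one
#' (yielding a tunable dilation-station correlation); contractions are
#' an inhomogeneous Poisson process whose rate intensifies toward
#' delivery; epidural is triggered by the first crossing of a random
#' dilation threshold; per-delivery examiner bias on dilation creates
#' delivery-level heterogeneity.
#'
#' @param n_deliveries number of deliveries.
#' @param seed master seed; per-delivery substreams are derived
#'   deterministically from `(seed, delivery index)`.
#' @param obs_duration_range range of the unimpeded first-stage
#'   duration (hours) used to calibrate the base dilation speed.
#' @param exam_gap_shape,exam_gap_mean gamma parameters of inter-exam
#'   gaps (hours).
#' @param exam_gap_min minimum generated gap, hours.
#' @param d0_range admission dilation range, cm.
#' @param accel dilation self-acceleration exponent (per cm): the
#'   latent rate is proportional to `exp(accel * (dilation - 10))`.
#' @param epidural_slow multiplicative slowing of the latent rate after
#'   epidural onset.
#' @param induction_slow multiplicative rate factor for induced labors.
#' @param arrest_prob,arrest_len_range probability and length (hours) of
#'   an arrest plateau.
#' @param station_w weight of the shared progression latent in the
#'   station curve (controls dilation-station correlation).
#' @param station_pow exponent shaping late fetal descent.
#' @param eff_pow_range exponent range shaping effacement progression.
#' @param noise_dilation,noise_station,noise_effacement observation noise
#'   standard deviations (cm, station units, percent).
#' @param delivery_bias_sd per-delivery examiner bias s.d. on dilation, cm.
#' @param round_dilation,round_station,round_effacement rounding switches
#'   (integer cm, integer station, 5 percent steps).
#' @param miss_prob probability a recorded field is missing.
#' @param contr_rate0,contr_rate1 contraction rate at onset and its
#'   increase to delivery (events/hour).
#' @param induction_prob probability labor is induced.
#' @param epidural_prob,epidural_dil_mean,epidural_dil_sd epidural
#'   trigger: probability and dilation-threshold distribution (cm).
#' @param rom_prob,rom_dil_mean,rom_dil_sd rupture-of-membranes trigger.
#' @param origin_jitter absolute-time origin drawn uniformly on
#'   `[0, origin_jitter]` hours (exercises t0 re-referencing).
#' @param pre_window_exam_prob probability of an extra exam before the
#'   20-h window (exercises the window filter).
#' @param window analysis window, hours.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_deliveries = 100, seed = 1,
                       obs_duration_range = c(6, 14),
                       exam_gap_shape = 2.5, exam_gap_mean = 1.6,
                       exam_gap_min = 0.25,
                       d0_range = c(1, 3), accel = 0.35,
                       epidural_slow = 0.7, induction_slow = 0.85,
                       arrest_prob = 0.15, arrest_len_range = c(1, 3),
                       station_w = 0.85, station_pow = 1.2,
                       eff_pow_range = c(0.5, 1.1),
                       noise_dilation = 0.2, noise_station = 0.25,
                       noise_effacement = 4, delivery_bias_sd = 0.3,
                       round_dilation = TRUE, round_station = TRUE,
                       round_effacement = TRUE, miss_prob = 0.04,
                       contr_rate0 = 6, contr_rate1 = 14,
                       induction_prob = 0.3,
                       epidural_prob = 0.75, epidural_dil_mean = 4.5,
                       epidural_dil_sd = 1,
                       rom_prob = 0.8, rom_dil_mean = 6, rom_dil_sd = 1.5,
                       origin_jitter = 100, pre_window_exam_prob = 0.1,
                       window = 20) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_deliveries >= 0, all(cfg$obs_duration_range > 0),
            cfg$exam_gap_mean > 0, cfg$exam_gap_shape > 0,
            cfg$contr_rate0 > 0, cfg$contr_rate1 >= 0,
            cfg$noise_dilation >= 0, cfg$noise_station >= 0,
            cfg$noise_effacement >= 0)
  if (cfg$exam_gap_mean >= cfg$window)
    stop("degenerate config: mean exam gap not smaller than the window")
  structure(cfg, class = "sim_config")
}

## One delivery's latent curves.  Dilation follows the self-accelerating
## law dd/dt = c * exp(accel * (d - 10)): slow latent phase, abrupt
## active-phase acceleration toward full dilation, matching the
## clinically described shape of labor curves.  Epidural multiplies the
## rate by `epidural_slow` once dilation crosses a random threshold;
## induction multiplies it by `induction_slow`; an optional arrest
## plateau freezes progression for a random interval.  Delivery occurs
## when dilation reaches 10 cm.  All curves are monotone by
## construction.
.sim_latents <- function(cfg, induced) {
  dt <- 0.05
  d0 <- stats::runif(1, cfg$d0_range[1], cfg$d0_range[2])
  D0 <- stats::runif(1, cfg$obs_duration_range[1], cfg$obs_duration_range[2])
  ## base speed calibrated so the unimpeded curve lasts ~D0 hours
  dgrid <- seq(d0, 10, length.out = 400)
  I <- sum(exp(-cfg$accel * (dgrid - 10))) * (10 - d0) / 400
  cbase <- I / D0
  if (induced) cbase <- cbase * cfg$induction_slow
  epi_thr <- if (stats::runif(1) < cfg$epidural_prob)
    stats::rnorm(1, cfg$epidural_dil_mean, cfg$epidural_dil_sd) else Inf
  rom_thr <- if (stats::runif(1) < cfg$rom_prob)
    stats::rnorm(1, cfg$rom_dil_mean, cfg$rom_dil_sd) else Inf
  arrest <- stats::runif(1) < cfg$arrest_prob
  arrest_at <- stats::runif(1, 4, 7)
  arrest_len <- stats::runif(1, cfg$arrest_len_range[1],
                             cfg$arrest_len_range[2])
  tmax <- 28
  nt <- ceiling(tmax / dt) + 1L
  tg <- (seq_len(nt) - 1L) * dt
  dil <- numeric(nt); dil[1] <- d0
  epi_t <- rom_t <- NA_real_
  arrest_until <- -Inf
  for (i in seq_len(nt - 1L)) {
    d <- dil[i]; tt <- tg[i]
    if (is.na(epi_t) && d >= epi_thr) epi_t <- tt
    if (is.na(rom_t) && d >= rom_thr) rom_t <- tt
    if (arrest && d >= arrest_at) {
      if (arrest_until == -Inf) arrest_until <- tt + arrest_len
      arrest <- FALSE   # trigger once
    }
    rate <- cbase * exp(cfg$accel * (d - 10))
    if (!is.na(epi_t)) rate <- rate * cfg$epidural_slow
    if (tt < arrest_until) rate <- 0
    dil[i + 1L] <- min(d + rate * dt, 10)
    if (dil[i + 1L] >= 10) { nt <- i + 1L; break }
  }
  tg <- tg[seq_len(nt)]; dil <- dil[seq_len(nt)]
  D <- tg[nt]
  u <- (dil - d0) / (10 - d0)
  ## independent monotone latent for station / effacement mixing
  a2 <- stats::runif(1, 0.5, 2)
  r2 <- exp(a2 * (tg - D) / max(D, 1))
  v <- cumsum(r2); v <- (v - v[1]) / max(v[length(v)] - v[1], 1e-9)
  sprog <- cfg$station_w * u + (1 - cfg$station_w) * v
  stat <- -3 + 6 * sprog^cfg$station_pow
  ep <- stats::runif(1, cfg$eff_pow_range[1], cfg$eff_pow_range[2])
  e0 <- stats::runif(1, 20, 60)
  eff <- e0 + (100 - e0) * (0.7 * u + 0.3 * v)^ep
  list(t = tg, dilation = dil, station = stat, effacement = eff,
       progress = u, duration = D, epidural_time = epi_t, rom_time = rom_t)
}

.interp <- function(lat, field, t) {
  stats::approx(lat$t, lat[[field]], xout = t, rule = 2)$y
}

#' Simulate delivery datasets with known ground truth (regime A)
#'
#' @param config a [sim_config()].
#' @return list with `deliveries` (raw [delivery_record()]s, absolute
#'   times) and `truth` (per-delivery latent curves and generative
#'   parameters).
#' @export
simulate_deliveries <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dels <- vector("list", config$n_deliveries)
  truths <- vector("list", config$n_deliveries)
  for (i in seq_len(config$n_deliveries)) {
    res <- with_seed(substream_seed(config$seed, i), {
      .simulate_one(config, i)
    })
    dels[[i]] <- res$delivery
    truths[[i]] <- res$truth
  }
  list(deliveries = dels,
       truth = structure(list(per_delivery = truths, config = config),
                         class = "sim_truth"))
}

.simulate_one <- function(cfg, i) {
  induced <- stats::runif(1) < cfg$induction_prob
  lat <- .sim_latents(cfg, induced)
  D <- lat$duration
  ## exam schedule
  t <- stats::runif(1, 0, 0.3)
  times <- numeric(0)
  while (t < D - 0.05) {
    times <- c(times, t)
    gap <- stats::rgamma(1, shape = cfg$exam_gap_shape,
                         scale = cfg$exam_gap_mean / cfg$exam_gap_shape)
    t <- t + max(gap, cfg$exam_gap_min)
  }
  if (length(times) < 2) times <- c(0.1, D / 2, D - 0.2)
  bias <- stats::rnorm(1, 0, cfg$delivery_bias_sd)
  obs_dil <- .interp(lat, "dilation", times) + bias +
    stats::rnorm(length(times), 0, cfg$noise_dilation)
  obs_sta <- .interp(lat, "station", times) +
    stats::rnorm(length(times), 0, cfg$noise_station)
  obs_eff <- .interp(lat, "effacement", times) +
    stats::rnorm(length(times), 0, cfg$noise_effacement)
  obs_dil <- pmin(pmax(obs_dil, 0), 10)
  obs_sta <- pmin(pmax(obs_sta, -3), 3)
  obs_eff <- pmin(pmax(obs_eff, 0), 100)
  if (cfg$round_dilation) obs_dil <- round(obs_dil)
  if (cfg$round_station) obs_sta <- round(obs_sta)
  if (cfg$round_effacement) obs_eff <- 5 * round(obs_eff / 5)
  nex <- length(times)
  if (cfg$miss_prob > 0 && nex > 2) {
    ## only interior exams can be interpolated; keep ends complete
    interior <- 2:(nex - 1)
    knock <- function(v) {
      hit <- interior[stats::runif(length(interior)) < cfg$miss_prob]
      v[hit] <- NA
      v
    }
    obs_dil <- knock(obs_dil); obs_sta <- knock(obs_sta)
    obs_eff <- knock(obs_eff)
  }
  ## contractions: inhomogeneous Poisson by thinning
  lmax <- cfg$contr_rate0 + cfg$contr_rate1
  cand <- cumsum(stats::rexp(ceiling(lmax * D * 1.5 + 20), rate = lmax))
  cand <- cand[cand <= D]
  lam <- cfg$contr_rate0 + cfg$contr_rate1 * .interp(lat, "progress", cand)
  onsets <- cand[stats::runif(length(cand)) < lam / lmax]
  epi <- lat$epidural_time
  rom <- lat$rom_time
  origin <- stats::runif(1, 0, cfg$origin_jitter)
  exams <- data.frame(time = times + origin, dilation = obs_dil,
                      effacement = obs_eff, station = obs_sta)
  if (stats::runif(1) < cfg$pre_window_exam_prob) {
    exams <- rbind(data.frame(time = origin + D - cfg$window - 1,
                              dilation = 0, effacement = 10, station = -3),
                   exams)
  }
  delivery <- delivery_record(
    delivery_id = sprintf("sim-%04d", i), exams = exams,
    contraction_onsets = onsets + origin, induced = induced,
    epidural_time = if (is.na(epi)) NA_real_ else epi + origin,
    rom_time = if (is.na(rom)) NA_real_ else rom + origin,
    delivery_time = D + origin)
  list(delivery = delivery,
       truth = list(latent = lat, bias = bias, induced = induced,
                    origin = origin, duration = D))
}

#' Simulate, clean and pool transitions in one call
#'
#' @param config a [sim_config()].
#' @return list with `transitions`, cleaned `deliveries` and `truth`.
#' @export
simulate_transitions <- function(config = sim_config()) {
  sim <- simulate_deliveries(config)
  cleaned <- preprocess_deliveries(sim$deliveries, config$window)
  list(transitions = do.call(rbind, lapply(cleaned, build_transitions)),
       deliveries = cleaned, truth = sim$truth)
}

## ---- regime B: sampling from the model's own prior -------------------

#' Draw observations from the GP prior (regime B)
#'
#' Exact multivariate-normal draws of the stacked (dilation, station)
#' function values at given design points under the composite kernel
#' times the coregionalization covariance, plus Gaussian observation
#' noise.  Used for calibration and parameter-recovery experiments where
#' the generative process matches the model's assumptions exactly.
#'
#' @param params a [kernel_params()] (the true hyperparameters).
#' @param B a [coreg_matrix()] or `NULL` for one output.
#' @param sigma2 true noise variance.
#' @param designs a list of design blocks, each a list with elements `X`
#'   (matrix) and `idx` (output indices); blocks are independent draws.
#' @param mean_fn `NULL`, a `mean_net`, or a function `f(X, idx)`.
#' @param seed seed for the draw.
#' @return list of blocks, each with `X`, `idx`, `f` (latent values) and
#'   `y` (noisy observations); attribute `truth` records the generative
#'   parameter set.
#' @export
sample_from_gp_prior <- function(params, B = NULL, sigma2 = 0.05, designs,
                                 mean_fn = NULL, seed = 1) {
  out <- with_seed(seed, lapply(designs, function(d) {
    X <- as.matrix(d$X); idx <- d$idx
    n <- nrow(X)
    K <- mo_kernel(params, B, X, idx)
    L <- chol_jitter(K)
    mu <- eval_mean(mean_fn, X, idx)
    f <- mu + drop(L %*% stats::rnorm(n))
    y <- f + stats::rnorm(n, 0, sqrt(.noise_vec(sigma2, idx, n)))
    list(X = X, idx = idx, f = f, y = y)
  }))
  attr(out, "truth") <- list(params = params, B = B, sigma2 = sigma2)
  out
}
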