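#' Unadjusted sample mean
#'
#' Mean of the observed score among alive respondents at wave `t`, with a
#' normal-theory 95% confidence interval. The reference point against which
#' the adjusted estimators are judged: under selective enrolment and
#' dropout it is badly biased for the population mean.
#'
#' @param sample a `ppcm_sample` frame.
#' @param t wave (0-based).
#' @param level confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n`.
#' @export
naive_sample_mean <- function(sample, t, level = 0.95) {
  stopifnot(inherits(sample, "ppcm_sample"))
  rows <- sample$wave == t & sample$r == 1 & sample$s == 1
  yv <- sample$y[rows]
  if (!length(yv)) stop("no respondents at wave ", t)
  z <- qnorm(1 - (1 - level) / 2)
  se <- if (length(yv) > 1) sd(yv) / sqrt(length(yv)) else Inf
  list(estimate = mean(yv), lower = mean(yv) - z * se,
       upper = mean(yv) + z * se, n = length(yv))
}

#' Cell-adjustment weights
#'
#' Builds longitudinal probability-of-participation weights by cell
#' adjustment: adjustment cells are every unique combination of the
#' categorized auxiliary variables (binary variables as-is, continuous ones
#' cut into tertiles); the weight of cell `j` at wave `t` is the ratio of
#' its surviving population count to its responding sample count. Cells
#' with fewer than `min_cell` respondents are merged into their nearest
#' nonsparse neighbour — the cell with the most similar combination of
#' auxiliary variables, i.e. minimal Hamming distance over the categorized
#' coordinates, ties broken by the larger respondent count and then by cell
#' label. Weights above `trim` are trimmed to `trim`.
#'
#' @param population,sample panel frames sharing the covariates.
#' @param t wave at which respondents are counted.
#' @param binary,continuous covariate names used as-is / tertiled. Noise
#'   covariates should be excluded by the caller.
#' @param min_cell sparse-cell threshold on respondent counts.
#' @param trim weight cap.
#' @param tertile_source `"population"` (default: tertile boundaries are
#'   functionals of the auxiliary variables, known for the whole population)
#'   or `"sample"`.
#' @return object of class `cell_weights`: data.frame of cells with counts,
#'   merge lineage and weights, plus the per-respondent weight lookup.
#' @export
build_cell_weights <- function(population, sample, t = 1L,
                               binary = c("x1", "x2"),
                               continuous = c("x3", "x4"),
                               min_cell = 20L, trim = 30,
                               tertile_source = c("population", "sample")) {
  tertile_source <- match.arg(tertile_source)
  stopifnot(inherits(population, "ppcm_population"),
            inherits(sample, "ppcm_sample"))
  pop0 <- population[population$wave == 0, , drop = FALSE]
  smp0 <- sample[sample$wave == 0, , drop = FALSE]
  pop_alive <- population$s[population$wave == t] == 1
  wS <- panel_wide(sample)
  resp <- rowSums(wS$r[, 1:(t + 1L), drop = FALSE] == 1) == t + 1L
  resp <- resp & wS$s[, t + 1L] == 1

  cat_of <- function(df0, brk) {
    cols <- lapply(binary, function(v) as.character(df0[[v]]))
    cols <- c(cols, lapply(seq_along(continuous), function(k)
      as.character(cut(df0[[continuous[k]]], brk[[k]], labels = FALSE,
                       include.lowest = TRUE))))
    do.call(paste, c(cols, sep = "."))
  }
  brk <- lapply(continuous, function(v) {
    src <- if (tertile_source == "population") pop0[[v]] else smp0[[v]]
    b <- quantile(src, c(0, 1 / 3, 2 / 3, 1))
    b[1] <- -Inf; b[4] <- Inf
    b
  })
  cell_pop <- cat_of(pop0, brk)
  cell_smp <- cat_of(smp0, brk)

  lev <- sort(unique(c(cell_pop, cell_smp)))
  key <- do.call(rbind, strsplit(lev, ".", fixed = TRUE))
  Nj <- as.numeric(table(factor(cell_pop[pop_alive], lev)))
  nj <- as.numeric(table(factor(cell_smp[resp], lev)))

  assign <- seq_along(lev)
  good <- which(nj >= min_cell)
  if (!length(good)) stop("all cells are sparse")
  for (s_ in which(nj < min_cell)) {
    hd <- colSums(t(key[good, , drop = FALSE]) != key[s_, ])
    cand <- good[hd == min(hd)]
    cand <- cand[order(-nj[cand], lev[cand])]
    assign[s_] <- cand[1]
  }
  mN <- tapply(Nj, assign, sum)
  mn <- tapply(nj, assign, sum)
  w_raw <- mN / mn
  w <- pmin(w_raw, trim)
  cell_w <- setNames(as.numeric(w[as.character(assign)]), lev)

  table_ <- data.frame(cell = lev, N_j = Nj, n_j = nj,
                       merged_into = lev[assign],
                       weight = as.numeric(cell_w),
                       stringsAsFactors = FALSE)
  resp_w <- setNames(cell_w[cell_smp[resp]], wS$units[resp])
  structure(list(cells = table_, respondent_weights = resp_w, wave = t,
                 binary = binary, continuous = continuous, breaks = brk,
                 trim = trim, min_cell = min_cell),
            class = "cell_weights")
}

#' @export
print.cell_weights <- function(x, ...) {
  cat(sprintf("cell weights (wave %d): %d cells, %d respondents, weights in [%.2f, %.2f]\n",
              x$wave, nrow(x$cells), length(x$respondent_weights),
              min(x$respondent_weights), max(x$respondent_weights)))
  invisible(x)
}

#' Cell-weighted Horvitz-Thompson estimator
#'
#' Hajek (ratio) form of the weighting estimator: the weighted mean of the
#' observed score over alive respondents at wave `t`, with weights from
#' [build_cell_weights()]. The variance uses the with-replacement
#' approximation for the ratio estimator.
#'
#' @param sample a `ppcm_sample` frame.
#' @param weights a `cell_weights` object built at the same wave from the
#'   same categorization.
#' @param t wave.
#' @param level confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n`.
#' @export
ht_estimate <- function(sample, weights, t = 1L, level = 0.95) {
  stopifnot(inherits(weights, "cell_weights"))
  if (weights$wave != t) stop("weight table was built for wave ", weights$wave)
  rows <- sample$wave == t & sample$r == 1 & sample$s == 1
  ids <- sample$unit_id[rows]
  if (!all(ids %in% names(weights$respondent_weights)))
    stop("weight table does not cover all respondents")
  wi <- weights$respondent_weights[ids]
  yv <- sample$y[rows]
  est <- sum(wi * yv) / sum(wi)
  n <- length(yv)
  v <- sum((wi * (yv - est))^2) / sum(wi)^2 * n / max(n - 1, 1)
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est, lower = est - z * sqrt(v), upper = est + z * sqrt(v),
       n = n)
}

#' General regression (GREG) estimator
#'
#' Combines prediction and weighting: an additive linear working model
#' `m(x)` is fit on alive respondents at wave `t`, population predictions
#' are summed over survivors, and the weighted sum of respondent residuals
#' is added back, so the estimator is consistent if either the outcome
#' model or the participation weights are right. With a perfect working
#' model the residual term vanishes and GREG equals the model-based
#' prediction; with `m = 0` it reduces to the weighted (HT) total over `N`.
#'
#' @inheritParams ht_estimate
#' @param population a `ppcm_population` frame.
#' @param model_covariates covariates entering the linear working model.
#' @export
greg_estimate <- function(population, sample, weights, t = 1L,
                          model_covariates = attr(sample, "covariates"),
                          level = 0.95) {
  stopifnot(inherits(weights, "cell_weights"))
  rows <- sample$wave == t & sample$r == 1 & sample$s == 1
  dat <- sample[rows, , drop = FALSE]
  pop_t <- population[population$wave == t & population$s == 1, , drop = FALSE]
  N_t <- nrow(pop_t)
  if (length(model_covariates) == 0L) {
    # zero working model: the estimator degenerates to the weighted total
    pred_pop <- rep(0, N_t)
    e <- dat$y
  } else {
    f <- stats::as.formula(paste("y ~",
                                 paste(model_covariates, collapse = "+")))
    fit <- lm(f, data = dat)
    pred_pop <- predict(fit, newdata = pop_t)
    e <- dat$y - predict(fit, newdata = dat)
  }
  wi <- weights$respondent_weights[dat$unit_id]
  est <- (sum(pred_pop) + sum(wi * e)) / N_t
  n <- length(e)
  we <- wi * e
  v <- (sum(we^2) - sum(we)^2 / n) * n / max(n - 1, 1) / N_t^2
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est, lower = est - z * sqrt(v), upper = est + z * sqrt(v),
       n = n)
}

#' Parametric model-based PPCM (MB-lm)
#'
#' The PPCM pipeline of [estimate_ppcm()] with conjugate Bayesian linear
#' working models in place of the sum-of-trees models; sensitivity
#' parameters are honoured identically.
#'
#' @inheritParams estimate_ppcm
#' @export
mb_lm_estimate <- function(population, sample, mcmc = mcmc_control(),
                           sens = sensitivity_config(), seed = NULL, ...) {
  estimate_ppcm(population, sample, backend = "linear", mcmc = mcmc,
                sens = sens, seed = seed, ...)
}

#' Multilevel regression and post-stratification (MRP)
#'
#' A hierarchical normal working model for the follow-up score: binary
#' covariates and the baseline outcome enter as fixed effects; each
#' continuous covariate is categorized into sample quartiles and enters as
#' an exchangeable random effect over its bins. The model is sampled with
#' JAGS. Baseline outcomes for population units (never observed) are imputed
#' per posterior draw from the same conjugate baseline model the PPCM
#' pipeline uses, and the post-stratified mean is taken over surviving
#' population units; the interval is the percentile interval over draws.
#'
#' @param population,sample panel frames.
#' @param t follow-up wave whose score is modelled.
#' @param fixed names of binary covariates entering as fixed effects.
#' @param grouped names of continuous covariates entering as random
#'   effects over quartile bins.
#' @param mcmc [mcmc_control()]; `draws` posterior draws are kept.
#' @param seed integer seed.
#' @param level credible level.
#' @return list with `estimate`, `lower`, `upper`, `draws`.
#' @export
mrp_estimate <- function(population, sample, t = 1L,
                         fixed = c("x1", "x2"),
                         grouped = paste0("x", 3:8),
                         mcmc = mcmc_control(), seed = NULL, level = 0.95) {
  stopifnot(inherits(population, "ppcm_population"),
            inherits(sample, "ppcm_sample"))
  mcmc <- do.call(mcmc_control, mcmc)
  if (!is.null(seed)) set.seed(seed)
  smp0 <- sample[sample$wave == 0, , drop = FALSE]
  rows <- sample$wave == t & sample$r == 1 & sample$s == 1
  dat <- sample[rows, , drop = FALSE]
  y0 <- setNames(smp0$y, smp0$unit_id)[dat$unit_id]

  qbrk <- lapply(grouped, function(v) {
    b <- unique(quantile(smp0[[v]], seq(0, 1, 0.25)))
    if (length(b) < 3) b <- range(smp0[[v]]) # degenerate variable
    b[1] <- -Inf; b[length(b)] <- Inf
    b
  })
  bin_of <- function(df) {
    G <- vapply(seq_along(grouped), function(k) {
      g <- cut(df[[grouped[k]]], qbrk[[k]], labels = FALSE,
               include.lowest = TRUE)
      g
    }, integer(nrow(df)))
    G
  }
  G <- bin_of(dat)
  nb <- vapply(qbrk, function(b) length(b) - 1L, integer(1))
  # empty sample bins: merge into the adjacent lower bin
  for (k in seq_along(grouped)) {
    used <- sort(unique(G[, k]))
    if (length(used) < nb[k]) {
      warning("empty bins for ", grouped[k], " merged into adjacent bin")
      G[, k] <- match(G[, k], used)
      nb[k] <- length(used)
    }
  }
  Xf <- as.matrix(cbind(dat[, fixed, drop = FALSE], y0 = y0))

  model <- "
  model {
    for (i in 1:n) {
      for (c in 1:C) { re[i, c] <- u[c, G[i, c]] }
      mu[i] <- b0 + inprod(Xf[i, ], bf[]) + sum(re[i, ])
      y[i] ~ dnorm(mu[i], prec)
    }
    b0 ~ dnorm(0, 1.0E-4)
    for (p in 1:P) { bf[p] ~ dnorm(0, 1.0E-4) }
    for (c in 1:C) {
      for (k in 1:K) { u[c, k] ~ dnorm(0, precu[c]) }
      precu[c] <- pow(sdu[c], -2)
      sdu[c] ~ dunif(0, 10)
    }
    prec <- pow(sdy, -2)
    sdy ~ dunif(0, 100)
  }"
  jd <- list(n = nrow(dat), C = length(grouped), P = ncol(Xf),
             K = max(nb), y = dat$y, Xf = Xf, G = G)
  jm <- rjags::jags.model(textConnection(model), data = jd, n.chains = 1,
                          n.adapt = max(200L, mcmc$burn_in %/% 2L),
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = if (is.null(seed)) 1L else
                                         as.integer(seed)))
  stats::update(jm, mcmc$burn_in, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("b0", "bf", "u"), n.iter = mcmc$draws,
                            progress.bar = "none")[[1]]
  J <- nrow(sm)

  # baseline model for imputing y0 in the population
  covs <- attr(sample, "covariates")
  f0 <- fit_continuous(as.matrix(smp0[, covs, drop = FALSE]), smp0$y,
                       backend = "linear",
                       mcmc = mcmc_control(draws = J))
  pop_t <- population[population$wave == t & population$s == 1, , drop = FALSE]
  pop0 <- population[population$wave == 0, , drop = FALSE]
  pop0 <- pop0[pop0$unit_id %in% pop_t$unit_id, , drop = FALSE]
  Gp <- bin_of(pop_t)
  for (k in seq_along(grouped)) Gp[, k] <- pmin(Gp[, k], nb[k])
  Xp <- as.matrix(pop_t[, fixed, drop = FALSE])

  cn <- colnames(sm)
  b0i <- which(cn == "b0")
  bfi <- grep("^bf\\[", cn)
  ui <- function(c_, k_) which(cn == sprintf("u[%d,%d]", c_, k_))
  est <- numeric(J)
  for (j in seq_len(J)) {
    y0s <- sample_predictive(f0, as.matrix(pop0[, covs, drop = FALSE]), j)
    mu <- sm[j, b0i] +
      drop(cbind(Xp, y0s) %*% sm[j, bfi]) +
      Reduce(`+`, lapply(seq_along(grouped), function(c_)
        sm[j, vapply(seq_len(max(nb)), function(k_) ui(c_, k_), integer(1))][Gp[, c_]]))
    est[j] <- mean(mu)
  }
  a <- (1 - level) / 2
  list(estimate = mean(est),
       lower = unname(quantile(est, a)), upper = unname(quantile(est, 1 - a)),
       draws = est)
}

#' Run the estimator comparison on simulated replicates
#'
#' Generates replicates from a [scenario_spec()] and evaluates the selected
#' estimators on each, returning per-estimator bias, SD, MSE and coverage
#' in the conventional report shape. All estimators see identical replicate
#' data.
#'
#' @param spec a [scenario_spec()].
#' @param reps number of replicates.
#' @param estimators subset of `c("sample", "mb_sp", "mb_lm", "mrp",
#'   "greg", "ht")`.
#' @param seed integer; replicate `i` uses master seed `seed + i`.
#' @param mcmc_sp,mcmc_lm MCMC controls for the trees / linear pipelines.
#' @param sens sensitivity configuration passed to the model-based
#'   estimators.
#' @return data.frame with one row per estimator (class
#'   `comparison_report`).
#' @export
run_comparison <- function(spec, reps, estimators = c("sample", "ht"),
                           seed = 1L,
                           mcmc_sp = mcmc_control(burn_in = 250, draws = 250,
                                                  n_trees = 50),
                           mcmc_lm = mcmc_control(draws = 500),
                           sens = sensitivity_config()) {
  est_names <- match.arg(estimators,
                         c("sample", "mb_sp", "mb_lm", "mrp", "greg", "ht"),
                         several.ok = TRUE)
  res <- lapply(est_names, function(e)
    list(est = numeric(reps), lo = numeric(reps), hi = numeric(reps)))
  names(res) <- est_names
  truths <- numeric(reps)
  for (i in seq_len(reps)) {
    rep_i <- gen_replicate(spec, seed = seed + i)
    truths[i] <- rep_i$truth$mu_U
    cw <- if (any(c("ht", "greg") %in% est_names))
      build_cell_weights(rep_i$population, rep_i$sample, t = 1L) else NULL
    for (e in est_names) {
      r <- switch(e,
        sample = naive_sample_mean(rep_i$sample, t = 1L),
        ht = ht_estimate(rep_i$sample, cw, t = 1L),
        greg = greg_estimate(rep_i$population, rep_i$sample, cw, t = 1L),
        mrp = mrp_estimate(rep_i$population, rep_i$sample, t = 1L,
                           mcmc = mcmc_lm, seed = seed + i),
        mb_lm = {
          p <- mb_lm_estimate(rep_i$population, rep_i$sample,
                              mcmc = mcmc_lm, sens = sens, seed = seed + i)
          list(estimate = p$mean_wave[2], lower = p$ci_wave[2, 1],
               upper = p$ci_wave[2, 2])
        },
        mb_sp = {
          p <- estimate_ppcm(rep_i$population, rep_i$sample,
                             backend = "trees", mcmc = mcmc_sp,
                             sens = sens, seed = seed + i)
          list(estimate = p$mean_wave[2], lower = p$ci_wave[2, 1],
               upper = p$ci_wave[2, 2])
        })
      res[[e]]$est[i] <- r$estimate
      res[[e]]$lo[i] <- r$lower
      res[[e]]$hi[i] <- r$upper
    }
  }
  rows <- lapply(est_names, function(e) {
    m <- compute_metrics(res[[e]]$est, cbind(res[[e]]$lo, res[[e]]$hi),
                         truths)
    data.frame(estimator = e, scenario = spec$scenario, bias = m$bias,
               sd = m$sd, mse = m$mse, cp = m$cp, n_reps = m$n_reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", "data.frame")
  out
}
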