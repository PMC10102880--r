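test_that("wave models have the expected structure and shared J", {
  r <- gen_replicate(scenario_spec(1, N = 1500), seed = 61)
  fits <- fit_wave_models(r$sample, backend = "linear",
                          mcmc = fast_mcmc(40))
  expect_length(fits$y_fits, 2)
  expect_length(fits$r_fits, 1)
  expect_identical(fits$J, 40)
  # wave-1 outcome model consumes the baseline outcome column
  expect_true("y0" %in% fits$y_fits[[2]]$schema)
  expect_false("y0" %in% fits$y_fits[[1]]$schema)
  expect_identical(fits$y_fits[[2]]$schema, fits$r_fits[[1]]$schema)
})

test_that("imputation reproduces the deterministic conditional-mean chain", {
  lw <- linear_world()
  fits <- fit_wave_models(lw$sample, backend = "linear",
                          mcmc = fast_mcmc(20), fit_response = FALSE)
  w <- ppcm:::panel_wide(lw$population)
  n <- length(w$units)
  zero <- matrix(0, n, 1)
  # suppress the innovation noise: the imputation is then the deterministic
  # composition of the fitted conditional means
  imp <- impute_histories(w, fits, zero, zero, j = 5,
                          eps = matrix(0, n, 2), skip_response = TRUE)
  x <- w$X[[1]][, "x1"]
  # the wave-1 regression is exact, so its coefficients are recovered
  # exactly and the chain gives y1hat = 0.5 + 0.8 y0hat - x
  expect_equal(imp$yhat[, 2], 0.5 + 0.8 * imp$yhat[, 1] - x,
               tolerance = 1e-8)
  expect_lt(max(abs(imp$yhat[, 1] - (1 + 2 * x))), 0.2)
})

test_that("forced nonresponse applies the dropout shift everywhere", {
  lw <- linear_world()
  fits <- fit_wave_models(lw$sample, backend = "linear",
                          mcmc = fast_mcmc(20), fit_response = FALSE)
  fits$r_fits[[1]] <- stub_binary_fit(fits$y_fits[[2]]$schema,
                                      intercept = -20, J = 20)
  w <- ppcm:::panel_wide(lw$population)
  n <- length(w$units)
  gam <- matrix(-0.7, n, 1)
  set.seed(62)
  imp <- impute_histories(w, fits, gam, matrix(0, n, 1), j = 3)
  expect_true(all(imp$rstar[, 2] == 0L))
  set.seed(62)
  imp0 <- impute_histories(w, fits, matrix(0, n, 1), matrix(0, n, 1), j = 3)
  expect_equal(imp$yhat[, 2], imp0$yhat[, 2] - 0.7, tolerance = 1e-10)
})

test_that("a constant practice effect shifts predictions additively", {
  lw <- linear_world()
  fits <- fit_wave_models(lw$sample, backend = "linear",
                          mcmc = fast_mcmc(20), fit_response = FALSE)
  w <- ppcm:::panel_wide(lw$population)
  n <- length(w$units)
  eps <- matrix(rnorm(2 * n), n)
  zero <- matrix(0, n, 1)
  a <- impute_histories(w, fits, zero, zero, j = 2, eps = eps,
                        skip_response = TRUE)
  b <- impute_histories(w, fits, zero, matrix(0.3, n, 1), j = 2, eps = eps,
                        skip_response = TRUE)
  expect_equal(b$yhat[, 2], a$yhat[, 2] - 0.3)
  expect_equal(b$ystar[, 2], a$ystar[, 2]) # histories carry no PE removal
})

test_that("with gamma = 0 the response imputation cannot move predictions", {
  r <- gen_replicate(scenario_spec(1, N = 1200), seed = 63)
  fits <- fit_wave_models(r$sample, backend = "linear",
                          mcmc = fast_mcmc(30))
  w <- ppcm:::panel_wide(r$population)
  n <- length(w$units)
  eps <- matrix(rnorm(2 * n), n)
  zero <- matrix(0, n, 1)
  u1 <- matrix(runif(n), n)
  u2 <- matrix(runif(n), n)
  a <- impute_histories(w, fits, zero, zero, j = 9, eps = eps, u = u1)
  b <- impute_histories(w, fits, zero, zero, j = 9, eps = eps, u = u2)
  expect_false(identical(a$rstar, b$rstar))
  expect_identical(a$yhat, b$yhat)
})

test_that("PPCM wave and age aggregations match hand computations", {
  expect_equal(ppcm_wave(c(2, 4, 6), c(1, 1, 0)), 3)
  expect_equal(ppcm_wave(c(2, 4, 6), c(1, 1, 1)), 4)
  expect_error(ppcm_wave(c(1, 2), c(0, 0)), "no survivors")

  units <- sprintf("u%d", 1:3)
  cmap <- age_cohort_map(rep(units, 2), rep(0:1, each = 3),
                         c("a", "a", "b", "a", "a", "b"))
  yhat <- rbind(c(10, 20), c(10, 20), c(7, 9))
  s <- rbind(c(1, 1), c(1, 0), c(1, 1))
  # cohort a: wave means (10, 20), survivor counts (2, 1) -> 40/3
  agg <- ppcm_age(yhat, s, cmap, units, 0:1)
  expect_equal(unname(agg["a"]), (2 * 10 + 1 * 20) / 3)
  expect_equal(unname(agg["b"]), (7 + 9) / 2) # equal counts: plain average
  # single wave reduces to the cohort-restricted wave mean
  agg0 <- ppcm_age(yhat[, 1, drop = FALSE], s[, 1, drop = FALSE], cmap,
                   units, 0)
  expect_equal(unname(agg0["a"]), 10)
  # hand-computed weighted mean with counts (100, 50)
  u2 <- sprintf("v%d", 1:150)
  cm2 <- age_cohort_map(rep(u2, 2), rep(0:1, each = 150), "c")
  yh2 <- cbind(rep(10, 150), rep(20, 150))
  s2 <- cbind(rep(c(1, 0), c(100, 50)), rep(c(1, 0), c(50, 100)))
  expect_equal(unname(ppcm_age(yh2, s2, cm2, u2, 0:1)["c"]),
               (100 * 10 + 50 * 20) / 150)
})

test_that("estimate_ppcm is calibrated on a scenario-1 replicate", {
  r <- gen_replicate(scenario_spec(1, N = 4000), seed = 64)
  p <- estimate_ppcm(r$population, r$sample, backend = "linear",
                     mcmc = mcmc_control(draws = 300), seed = 1)
  post_sd <- sd(p$draws_wave[, 2])
  expect_lt(abs(p$mean_wave[2] - r$truth$mu_U), 3.5 * post_sd)
  expect_lt(p$ci_wave[2, 1], p$ci_wave[2, 2])
})

test_that("J = 1 yields a point posterior with a degenerate interval", {
  r <- gen_replicate(scenario_spec(1, N = 800), seed = 65)
  p <- estimate_ppcm(r$population, r$sample, backend = "linear",
                     mcmc = mcmc_control(draws = 1), seed = 1)
  expect_identical(p$J, 1)
  expect_equal(unname(p$ci_wave[2, 1]), unname(p$ci_wave[2, 2]))
})

test_that("no-missingness limit equals the direct survivor mean", {
  lw <- linear_world(n_pop = 300, n_smp = 300)
  # population identical to the sample's units: saturated, noiseless
  smp <- lw$sample
  popdf <- as.data.frame(smp)
  popdf$y <- NULL; popdf$r <- NULL
  pop <- population_frame(popdf)
  p <- estimate_ppcm(pop, smp, backend = "linear",
                     mcmc = mcmc_control(draws = 50), seed = 2)
  direct <- mean(smp$y[smp$wave == 1])
  expect_lt(abs(p$mean_wave[2] - direct), 0.05)
})

test_that("dead units never contribute to any wave average", {
  lw <- linear_world(n_pop = 200)
  popdf <- as.data.frame(lw$population)
  # poison a unit that dies at wave 1: huge covariate, huge implied y
  popdf$x1[popdf$unit_id == "p0001"] <- 1e6
  popdf$s[popdf$unit_id == "p0001" & popdf$wave == 1] <- 0L
  pop <- population_frame(popdf)
  p <- estimate_ppcm(pop, lw$sample, backend = "linear",
                     mcmc = mcmc_control(draws = 40), seed = 3)
  x <- popdf$x1[popdf$wave == 0 & popdf$unit_id != "p0001"]
  expect_lt(abs(p$mean_wave[2] - mean(0.5 + 0.8 * (1 + 2 * x) - x)), 0.1)
})

test_that("raising the practice-effect bound lowers every posterior draw", {
  r <- gen_replicate(scenario_spec(1, N = 1000), seed = 66)
  p1 <- estimate_ppcm(r$population, r$sample, backend = "linear",
                      mcmc = mcmc_control(draws = 60),
                      sens = sensitivity_config(0, 0.05), seed = 4)
  p2 <- estimate_ppcm(r$population, r$sample, backend = "linear",
                      mcmc = mcmc_control(draws = 60),
                      sens = sensitivity_config(0, 0.15), seed = 4)
  expect_true(all(p2$draws_wave[, 2] <= p1$draws_wave[, 2]))
  expect_identical(p1$draws_wave[, 1], p2$draws_wave[, 1]) # baseline untouched
})

test_that("identical seeds give identical manifests and draws", {
  r <- gen_replicate(scenario_spec(1, N = 600), seed = 67)
  p1 <- estimate_ppcm(r$population, r$sample, backend = "linear",
                      mcmc = mcmc_control(draws = 25), seed = 5)
  p2 <- estimate_ppcm(r$population, r$sample, backend = "linear",
                      mcmc = mcmc_control(draws = 25), seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$manifest$config_hash, p2$manifest$config_hash)
})

test_that("the trees pipeline runs end to end on a small replicate", {
  r <- gen_replicate(scenario_spec(3, N = 1200), seed = 68)
  p <- estimate_ppcm(r$population, r$sample, backend = "trees",
                     mcmc = fast_mcmc(60), seed = 6)
  expect_lt(abs(p$mean_wave[2] - r$truth$mu_U), 0.25)
})
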