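# toy frames for weighting tests: one binary covariate defines two cells
cell_world <- function(npopA = 90, npopB = 10, nrespA = 9, nrespB = 1,
                       yA = 1, yB = 5) {
  pop <- data.frame(unit_id = rep(sprintf("p%03d", 1:(npopA + npopB)),
                                  each = 2),
                    wave = rep(0:1, npopA + npopB), s = 1L,
                    x1 = rep(c(rep(0, npopA), rep(1, npopB)), each = 2))
  nA <- nrespA; nB <- nrespB
  smp <- data.frame(unit_id = rep(sprintf("s%03d", 1:(nA + nB)), each = 2),
                    wave = rep(0:1, nA + nB), s = 1L, r = 1L,
                    x1 = rep(c(rep(0, nA), rep(1, nB)), each = 2))
  smp$y <- as.numeric(rbind(0, rep(c(yA, yB), c(nA, nB))))
  list(population = population_frame(pop), sample = sample_frame(smp))
}

test_that("naive sample mean and its toy cases", {
  cw <- cell_world(nrespA = 2, nrespB = 1, yA = 1.5, yB = 3)
  r <- naive_sample_mean(cw$sample, 1)
  expect_equal(r$estimate, mean(c(1.5, 1.5, 3)))
  smp1 <- cell_world(nrespA = 1, nrespB = 0)$sample
  one <- naive_sample_mean(smp1, 1)
  expect_equal(one$estimate, 1)
  expect_identical(one$lower, -Inf) # degenerate-wide interval flagged
})

test_that("cell weights are population/respondent ratios, trimmed", {
  cw <- cell_world() # N_j = {90, 10}, n_j = {9, 1}
  w <- build_cell_weights(cw$population, cw$sample, t = 1,
                          binary = "x1", continuous = character(0),
                          min_cell = 1)
  expect_equal(sort(unique(w$cells$weight)), 10)
  # trimming: N/n = 45 gets capped at 30
  cw2 <- cell_world(npopA = 90, npopB = 45, nrespA = 9, nrespB = 1)
  w2 <- build_cell_weights(cw2$population, cw2$sample, t = 1,
                           binary = "x1", continuous = character(0),
                           min_cell = 1)
  expect_equal(max(w2$cells$weight), 30)
})

test_that("sparse cells merge into the Hamming-nearest nonsparse cell", {
  # two binary covariates, four cells; cell (1,1) sparse with 5 respondents
  set.seed(71)
  mk <- function(n, x1, x2, id0, sampled, y = 1) {
    df <- data.frame(unit_id = rep(sprintf("%s%04d", id0, 1:n), each = 2),
                     wave = rep(0:1, n), s = 1L,
                     x1 = x1, x2 = x2)
    if (sampled) { df$r <- 1L; df$y <- as.numeric(rbind(0, rep(y, n))) }
    df
  }
  pop <- rbind(mk(100, 0, 0, "a", FALSE), mk(100, 0, 1, "b", FALSE),
               mk(100, 1, 0, "c", FALSE), mk(100, 1, 1, "d", FALSE))
  smp <- rbind(mk(40, 0, 0, "e", TRUE), mk(30, 0, 1, "f", TRUE),
               mk(25, 1, 0, "g", TRUE), mk(5, 1, 1, "h", TRUE))
  w <- build_cell_weights(population_frame(pop), sample_frame(smp), t = 1,
                          binary = c("x1", "x2"),
                          continuous = character(0), min_cell = 20)
  cells <- w$cells
  sparse <- cells[cells$cell == "1.1", ]
  # brute force: Hamming-1 neighbours are 1.0 (n=25) and 0.1 (n=30);
  # the larger respondent count wins
  expect_identical(sparse$merged_into, "0.1")
  merged <- cells[cells$cell == "0.1", ]
  expect_equal(sparse$weight, (100 + 100) / (30 + 5))
  expect_equal(sparse$weight, merged$weight)
})

test_that("HT reduces to the naive mean under equal weights", {
  cw <- cell_world(npopA = 50, npopB = 50, nrespA = 5, nrespB = 5,
                   yA = 2, yB = 8)
  w <- build_cell_weights(cw$population, cw$sample, t = 1, binary = "x1",
                          continuous = character(0), min_cell = 1)
  ht <- ht_estimate(cw$sample, w, 1)
  expect_equal(ht$estimate, naive_sample_mean(cw$sample, 1)$estimate)
})

test_that("HT is the weighted mean on a two-unit toy", {
  cw <- cell_world(npopA = 10, npopB = 30, nrespA = 1, nrespB = 1,
                   yA = 0, yB = 10)
  w <- build_cell_weights(cw$population, cw$sample, t = 1, binary = "x1",
                          continuous = character(0), min_cell = 1)
  # weights 10 and 30: (0*10 + 10*30) / 40
  expect_equal(ht_estimate(cw$sample, w, 1)$estimate, 7.5)
})

test_that("GREG collapses to the model prediction under a perfect model", {
  # y1 = 2 + 3 x exactly, so the linear working model has zero residuals
  set.seed(73)
  mk <- function(n, id0, sampled) {
    x <- runif(n, -1, 1)
    df <- data.frame(unit_id = rep(sprintf("%s%04d", id0, 1:n), each = 2),
                     wave = rep(0:1, n), s = 1L, x1 = rep(x, each = 2))
    if (sampled) { df$r <- 1L; df$y <- as.numeric(rbind(0, 2 + 3 * x)) }
    df
  }
  pop <- population_frame(mk(200, "p", FALSE))
  smp <- sample_frame(mk(60, "s", TRUE))
  w <- build_cell_weights(pop, smp, t = 1, binary = character(0),
                          continuous = "x1", min_cell = 1)
  g <- greg_estimate(pop, smp, w, 1, model_covariates = "x1")
  mb <- mean(2 + 3 * pop$x1[pop$wave == 1])
  expect_lt(abs(g$estimate - mb), 1e-8)
})

test_that("GREG with a zero working model is the weighted total over N", {
  cw <- cell_world(npopA = 10, npopB = 30, nrespA = 1, nrespB = 1,
                   yA = 0, yB = 10)
  w <- build_cell_weights(cw$population, cw$sample, t = 1, binary = "x1",
                          continuous = character(0), min_cell = 1)
  g <- greg_estimate(cw$population, cw$sample, w, 1,
                     model_covariates = character(0))
  expect_equal(g$estimate, (10 * 0 + 30 * 10) / 40)
})

test_that("MRP recovers a fixed-effects truth and respects labels", {
  skip_if_not_installed("rjags")
  r <- gen_replicate(scenario_spec(1, N = 1500), seed = 72)
  m <- mrp_estimate(r$population, r$sample, 1,
                    mcmc = mcmc_control(burn_in = 300, draws = 200),
                    seed = 1)
  expect_lt(abs(m$estimate - r$truth$mu_U), 0.25)
  expect_lt(m$lower, m$upper)
})

test_that("the comparison runner produces the report shape", {
  rep_ <- run_comparison(scenario_spec(1), reps = 3,
                         estimators = c("sample", "ht", "greg"), seed = 5)
  expect_identical(nrow(rep_), 3L)
  expect_identical(rep_$estimator, c("sample", "ht", "greg"))
  expect_true(all(is.finite(rep_$bias)))
  # positive selection bias shows up even at 3 replicates
  expect_gt(rep_$bias[rep_$estimator == "sample"], 0.05)
})
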