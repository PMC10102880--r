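test_that("linear backend recovers a noiseless linear signal", {
  set.seed(51)
  X <- matrix(runif(100, -1, 1), 100, 1, dimnames = list(NULL, "x"))
  f <- fit_continuous(X, 2 * X[, 1], backend = "linear",
                      mcmc = mcmc_control(draws = 200))
  newx <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  preds <- vapply(1:200, function(j) predict_mean(f, newx, j), numeric(1))
  expect_lt(abs(mean(preds) - 2), max(3 * sd(preds), 1e-6))
  expect_lt(sd(preds), 1e-6) # noiseless fit has essentially no uncertainty
})

test_that("trees backend beats the best linear fit on a quadratic", {
  set.seed(52)
  n <- 500
  X <- matrix(runif(2 * n, -1, 1), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1]^2 + rnorm(n, 0, 0.1)
  Xt <- matrix(runif(400, -1, 1), 200, 2, dimnames = list(NULL, c("a", "b")))
  truth <- Xt[, 1]^2
  ft <- fit_continuous(X, y, backend = "trees", mcmc = fast_mcmc(150),
                       seed = 1)
  pt <- rowMeans(vapply(1:150, function(j) predict_mean(ft, Xt, j),
                        numeric(200)))
  # brute-force comparison oracle: least-squares linear fit
  bl <- coef(lm(y ~ X))
  pl <- bl[1] + Xt %*% bl[-1]
  expect_lt(sqrt(mean((pt - truth)^2)), sqrt(mean((pl - truth)^2)))
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(53)
  X <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  f1 <- fit_continuous(X, y, backend = "trees", mcmc = fast_mcmc(30),
                       seed = 7)
  f2 <- fit_continuous(X, y, backend = "trees", mcmc = fast_mcmc(30),
                       seed = 7)
  expect_identical(f1$fit$sigma, f2$fit$sigma)
  expect_identical(predict_mean(f1, X, 30), predict_mean(f2, X, 30))
  l1 <- fit_continuous(X, y, backend = "linear", mcmc = fast_mcmc(30),
                       seed = 7)
  l2 <- fit_continuous(X, y, backend = "linear", mcmc = fast_mcmc(30),
                       seed = 7)
  expect_identical(l1$fit$Beta, l2$fit$Beta)
})

test_that("probit fits recover an intercept-only and a sloped truth", {
  set.seed(54)
  n <- 2000
  X <- matrix(runif(n, -1, 1), n, 1, dimnames = list(NULL, "x"))
  y0 <- rbinom(n, 1, 0.3)
  fb <- fit_binary(X, y0, backend = "trees", mcmc = fast_mcmc(100), seed = 2)
  pp <- rowMeans(vapply(1:100, function(j) predict_prob(fb, X, j),
                        numeric(n)))
  expect_lt(max(abs(pp - 0.3)), 0.15)

  y1 <- rbinom(n, 1, pnorm(1.5 * X[, 1]))
  fl <- fit_binary(X, y1, backend = "linear",
                   mcmc = mcmc_control(burn_in = 200, draws = 300), seed = 3)
  slopes <- fl$fit$Beta[, "x"]
  expect_lt(abs(mean(slopes) - 1.5), 3 * sd(slopes))
  pr <- predict_prob(fl, X, 10)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("probabilities are forced to zero for prior nonrespondents", {
  set.seed(55)
  X <- matrix(runif(50), 50, 1, dimnames = list(NULL, "x"))
  fb <- fit_binary(X, rbinom(50, 1, 0.5), backend = "linear",
                   mcmc = fast_mcmc(20))
  p <- predict_prob(fb, X, 5, force_zero = c(TRUE, rep(FALSE, 49)))
  expect_identical(p[1], 0)
  expect_true(all(p[-1] > 0))
})

test_that("sample_predictive adds exactly N(0, sigma_j^2) noise", {
  set.seed(56)
  X <- matrix(runif(100, -1, 1), 100, 1, dimnames = list(NULL, "x"))
  f <- fit_continuous(X, 1 + X[, 1] + rnorm(100, 0, 0.5),
                      backend = "linear", mcmc = mcmc_control(draws = 50))
  one <- X[rep(1, 4000), , drop = FALSE]
  j <- 17
  draws <- sample_predictive(f, one, j)
  expect_lt(abs(sd(draws) - f$fit$sigma[j]), 0.05)
  expect_lt(abs(mean(draws) - predict_mean(f, one[1, , drop = FALSE], j)),
            0.05)
  # noiseless limit: predictive equals the mean
  f0 <- fit_continuous(X, 2 * X[, 1], backend = "linear",
                       mcmc = mcmc_control(draws = 20))
  expect_equal(sample_predictive(f0, X[1:5, , drop = FALSE], 3),
               predict_mean(f0, X[1:5, , drop = FALSE], 3), tolerance = 1e-5)
})

test_that("backends agree on population predictions under a linear truth", {
  set.seed(57)
  n <- 1000
  X <- matrix(runif(2 * n, -1, 1), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.3)
  ft <- fit_continuous(X, y, backend = "trees",
                       mcmc = mcmc_control(burn_in = 300, draws = 200,
                                           n_trees = 100), seed = 4)
  fl <- fit_continuous(X, y, backend = "linear",
                       mcmc = mcmc_control(draws = 200), seed = 4)
  mt <- mean(rowMeans(vapply(1:200, function(j) predict_mean(ft, X, j),
                             numeric(n))))
  ml <- mean(rowMeans(vapply(1:200, function(j) predict_mean(fl, X, j),
                             numeric(n))))
  expect_lt(abs(mt - ml), 0.05)
})

test_that("degenerate inputs are refused with clear messages", {
  X <- matrix(runif(30), 30, 1, dimnames = list(NULL, "x"))
  expect_error(fit_continuous(X[1:5, , drop = FALSE], rnorm(5)),
               "fewer than 10")
  expect_error(fit_continuous(X, rep(1, 30), backend = "trees"),
               "constant outcome")
  expect_warning(fit_continuous(X, rep(1, 30), backend = "linear",
                                mcmc = fast_mcmc(10)),
                 "degenerate")
  expect_error(fit_binary(X, rep(1, 30), backend = "linear"),
               "single-class")
  f <- fit_continuous(X, rnorm(30), backend = "linear",
                      mcmc = fast_mcmc(10))
  bad <- matrix(1, 2, 2, dimnames = list(NULL, c("x", "zz")))
  expect_error(predict_mean(f, bad, 1), "schema mismatch.*extra: zz")
  expect_error(predict_mean(f, X, 99), "must lie in 1..")
})

test_that("the sparse splitting prior concentrates on active variables", {
  set.seed(58)
  n <- 400
  X <- matrix(runif(5 * n, -1, 1), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 * X[, 3] + rnorm(n, 0, 0.3)
  f <- fit_continuous(X, y, backend = "trees",
                      mcmc = mcmc_control(burn_in = 400, draws = 100,
                                          n_trees = 50), seed = 5)
  vc <- colMeans(f$fit$varcount)
  expect_gt(vc[3], 2.5 * max(vc[-3]))
  # and it is sparser than the same ensemble with uniform splitting
  f0 <- fit_continuous(X, y, backend = "trees",
                       mcmc = mcmc_control(burn_in = 400, draws = 100,
                                           n_trees = 50, dart = FALSE),
                       seed = 5)
  vc0 <- colMeans(f0$fit$varcount)
  expect_gt(vc[3] / sum(vc), vc0[3] / sum(vc0))
})
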