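#' Posterior-draw regression backends
#'
#' The PPCM estimator consumes working models only through a draw-indexed
#' contract: a continuous fit provides, for each posterior draw `j`, a mean
#' function and a residual standard deviation; a binary fit provides a
#' probability function. Two interchangeable backends implement the
#' contract:
#'
#' * `"trees"` — a sum-of-trees (BART) model with the sparse Dirichlet
#'   splitting-rule prior enabled, probit link for binary outcomes;
#' * `"linear"` — a conjugate Bayesian linear regression with flat
#'   (uninformative) priors (posterior: scaled-inverse-chi-squared variance,
#'   normal coefficients), and for binary outcomes a probit regression
#'   sampled by truncated-normal data augmentation.
#'
#' Outcome- and response-model fits never share state: their parameters are
#' a-priori independent and each call is a self-contained posterior.
#'
#' @param features numeric matrix or data.frame of predictors (the recorded
#'   feature schema; prediction inputs must match it by name).
#' @param outcome numeric outcome vector (`fit_continuous`) or 0/1
#'   indicator (`fit_binary`).
#' @param backend `"trees"` or `"linear"`.
#' @param mcmc list of MCMC sizes: `burn_in`, `draws`, `n_trees` (trees
#'   backend only), and optionally `k` (leaf shrinkage), `numcut`. See
#'   [mcmc_control()] for defaults.
#' @param seed integer seed; fits are bit-reproducible given
#'   (seed, backend, mcmc).
#' @return `fit_continuous` returns a `continuous_fit` with `J` posterior
#'   draws; `fit_binary` a `binary_fit`.
#' @examples
#' X <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
#' f <- fit_continuous(X, 2 * X[, 1], backend = "linear",
#'                     mcmc = mcmc_control(draws = 50), seed = 1)
#' predict_mean(f, X[1:5, ], j = 1)
#' @export
fit_continuous <- function(features, outcome, backend = c("trees", "linear"),
                           mcmc = mcmc_control(), seed = NULL) {
  backend <- match.arg(backend)
  X <- as_feature_matrix(features)
  if (nrow(X) != length(outcome)) stop("features/outcome length mismatch")
  if (any(!is.finite(outcome))) stop("outcome must be finite")
  if (nrow(X) < 10) stop("refusing to fit on fewer than 10 rows")
  mcmc <- do.call(mcmc_control, mcmc)
  if (!is.null(seed)) set.seed(seed)
  if (var(outcome) == 0) {
    if (backend == "trees")
      stop("constant outcome: trees backend refuses to fit")
    warning("constant outcome: degenerate linear fit")
  }
  fit <- if (backend == "linear") {
    lin_conjugate(X, outcome, mcmc$draws)
  } else {
    .bart_mcmc(X, outcome, mcmc$n_trees, mcmc$burn_in, mcmc$draws, mcmc$k,
               mcmc$power, mcmc$base, mcmc$nu, mcmc$q, mcmc$numcut,
               mcmc$min_node, mcmc$dart, FALSE, 0)
  }
  structure(list(backend = backend, J = mcmc$draws, schema = colnames(X),
                 fit = fit, mcmc = mcmc),
            class = "continuous_fit")
}

#' @rdname fit_continuous
#' @export
fit_binary <- function(features, outcome, backend = c("trees", "linear"),
                       mcmc = mcmc_control(), seed = NULL) {
  backend <- match.arg(backend)
  X <- as_feature_matrix(features)
  if (nrow(X) != length(outcome)) stop("features/outcome length mismatch")
  if (!all(outcome %in% c(0, 1))) stop("indicator must be 0/1")
  if (length(unique(outcome)) < 2)
    stop("single-class indicator: cannot fit a response model")
  if (nrow(X) < 10) stop("refusing to fit on fewer than 10 rows")
  mcmc <- do.call(mcmc_control, mcmc)
  if (!is.null(seed)) set.seed(seed)
  fit <- if (backend == "linear") {
    probit_gibbs(X, outcome, mcmc$burn_in, mcmc$draws)
  } else {
    off <- qnorm(mean(outcome))
    .bart_mcmc(X, as.numeric(outcome), mcmc$n_trees, mcmc$burn_in,
               mcmc$draws, mcmc$k, mcmc$power, mcmc$base, mcmc$nu, mcmc$q,
               mcmc$numcut, mcmc$min_node, mcmc$dart, TRUE, off)
  }
  structure(list(backend = backend, J = mcmc$draws, schema = colnames(X),
                 fit = fit, mcmc = mcmc),
            class = "binary_fit")
}

#' MCMC and prior controls for the regression backends
#'
#' Defaults mirror common sum-of-trees practice: 1000 burn-in iterations,
#' 1000 retained draws, 200 trees, leaf-prior shrinkage `k = 2`, tree-depth
#' prior (base 0.95, power 2), error-variance prior (nu = 3, q = 0.90),
#' 100 cutpoints per variable, at least 5 observations per leaf, sparse
#' Dirichlet splitting prior on.
#'
#' @param burn_in,draws iterations discarded / retained.
#' @param n_trees number of trees in the ensemble.
#' @param k leaf shrinkage.
#' @param power,base tree-depth prior.
#' @param nu,q error-variance prior calibration.
#' @param numcut cutpoints per variable.
#' @param min_node minimum observations per leaf.
#' @param dart enable the sparse Dirichlet splitting prior.
#' @export
mcmc_control <- function(burn_in = 1000, draws = 1000, n_trees = 200, k = 2,
                         power = 2, base = 0.95, nu = 3, q = 0.90,
                         numcut = 100, min_node = 5, dart = TRUE) {
  list(burn_in = as.integer(burn_in), draws = as.integer(draws),
       n_trees = as.integer(n_trees), k = k, power = power, base = base,
       nu = nu, q = q, numcut = as.integer(numcut),
       min_node = as.integer(min_node), dart = isTRUE(dart))
}

as_feature_matrix <- function(features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("features must be finite")
  X
}

check_schema_match <- function(fit, X) {
  if (!identical(colnames(X), fit$schema)) {
    missing <- setdiff(fit$schema, colnames(X))
    extra <- setdiff(colnames(X), fit$schema)
    stop("feature schema mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  }
}

# flat-prior conjugate normal linear model; draws taken at fit time
lin_conjugate <- function(X, y, J) {
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xd)
  if (qr_$rank < ncol(Xd)) stop("singular design matrix")
  bhat <- qr.coef(qr_, y)
  res <- y - drop(Xd %*% bhat)
  df <- nrow(Xd) - ncol(Xd)
  s2 <- sum(res^2) / max(df, 1)
  XtXinv <- chol2inv(qr.R(qr_))
  Rt <- t(chol(XtXinv))
  p <- ncol(Xd)
  sig2 <- df * s2 / rchisq(J, df)
  Beta <- matrix(bhat, J, p, byrow = TRUE) +
    sqrt(sig2) * t(Rt %*% matrix(rnorm(J * p), p, J))
  colnames(Beta) <- colnames(Xd)
  list(Beta = Beta, sigma = sqrt(sig2))
}

# Albert-Chib probit sampler with flat coefficient prior
probit_gibbs <- function(X, y, burn, J) {
  Xd <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xd); p <- ncol(Xd)
  qr_ <- qr(Xd)
  if (qr_$rank < p) stop("singular design matrix")
  XtXinv <- chol2inv(qr.R(qr_))
  Rt <- t(chol(XtXinv))
  beta <- rep(0, p)
  pos <- y == 1
  Beta <- matrix(NA_real_, J, p)
  for (it in seq_len(burn + J)) {
    eta <- drop(Xd %*% beta)
    pz <- pnorm(-eta)
    u <- runif(n)
    # z | y: truncated normal above/below 0 via inverse CDF
    z <- eta + qnorm(ifelse(pos, pz + u * (1 - pz), u * pz))
    z[!is.finite(z)] <- eta[!is.finite(z)] # extreme-tail guard
    bhat <- drop(XtXinv %*% crossprod(Xd, z))
    beta <- bhat + drop(Rt %*% rnorm(p))
    if (it > burn) Beta[it - burn, ] <- beta
  }
  colnames(Beta) <- colnames(Xd)
  list(Beta = Beta)
}

#' Evaluate one posterior draw of a fitted backend
#'
#' `predict_mean` evaluates draw `j` of the conditional mean function on new
#' rows; `predict_prob` evaluates draw `j` of the response probability, with
#' an optional hard zero for rows whose previous-wave response was 0 (a
#' nonrespondent can never return); `sample_predictive` adds i.i.d. Gaussian
#' noise with that draw's residual SD to the mean, giving one draw from the
#' posterior-predictive distribution row by row.
#'
#' @param fit a `continuous_fit` or `binary_fit`.
#' @param rows new feature rows matching the recorded schema.
#' @param j draw index in `1..J`.
#' @param force_zero logical vector: rows whose probability is structurally
#'   zero (previous-wave nonrespondents).
#' @return numeric vector with one value per row.
#' @export
predict_mean <- function(fit, rows, j) {
  stopifnot(inherits(fit, "continuous_fit"))
  X <- as_feature_matrix(rows)
  check_schema_match(fit, X)
  check_j(fit, j)
  if (fit$backend == "linear") {
    drop(cbind(1, X) %*% fit$fit$Beta[j, ])
  } else {
    f <- fit$fit
    drop(.bart_eval(f$draws[[j]], X, f$ntree)) * f$yscale + f$ymid
  }
}

#' @rdname predict_mean
#' @export
predict_prob <- function(fit, rows, j, force_zero = NULL) {
  stopifnot(inherits(fit, "binary_fit"))
  X <- as_feature_matrix(rows)
  check_schema_match(fit, X)
  check_j(fit, j)
  eta <- if (fit$backend == "linear") {
    drop(cbind(1, X) %*% fit$fit$Beta[j, ])
  } else {
    f <- fit$fit
    drop(.bart_eval(f$draws[[j]], X, f$ntree)) + f$offset
  }
  p <- pnorm(eta)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  if (!is.null(force_zero)) p[force_zero] <- 0
  p
}

#' @rdname predict_mean
#' @export
sample_predictive <- function(fit, rows, j) {
  m <- predict_mean(fit, rows, j)
  m + draw_sigma(fit, j) * rnorm(length(m))
}

draw_sigma <- function(fit, j) {
  stopifnot(inherits(fit, "continuous_fit"))
  check_j(fit, j)
  fit$fit$sigma[j]
}

check_j <- function(fit, j) {
  if (length(j) != 1 || j < 1 || j > fit$J)
    stop("draw index j must lie in 1..", fit$J)
}

#' @export
print.continuous_fit <- function(x, ...) {
  cat(sprintf("continuous fit (%s backend): %d draws, %d features\n",
              x$backend, x$J, length(x$schema)))
  invisible(x)
}

#' @export
print.binary_fit <- function(x, ...) {
  cat(sprintf("binary (probit) fit (%s backend): %d draws, %d features\n",
              x$backend, x$J, length(x$schema)))
  invisible(x)
}
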