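# Fixtures built in code: tiny hand-written panels and a small-N scenario.

# rectangular two-wave panel from per-unit vectors
toy_panel <- function(s0, s1, r0 = NULL, r1 = NULL, y0 = NULL, y1 = NULL,
                      x = NULL) {
  n <- length(s0)
  if (is.null(x)) x <- seq_len(n)
  df <- data.frame(unit_id = rep(sprintf("u%02d", seq_len(n)), each = 2),
                   wave = rep(0:1, n),
                   s = as.integer(rbind(s0, s1)),
                   x1 = rep(x, each = 2))
  if (!is.null(r0)) {
    df$r <- as.integer(rbind(r0, r1))
    df$y <- as.numeric(rbind(y0, y1))
  }
  df
}

# linear two-wave sample + population used for exact-recovery checks:
# y0 = 1 + 2 x + e (e gives the baseline design full rank), and the wave-1
# map y1 = 0.5 + 0.8 y0 - x is exact, so the wave-1 regression is noiseless
linear_world <- function(n_pop = 400, n_smp = 120, seed = 99, sd0 = 0.3) {
  set.seed(seed)
  make <- function(n, sampled) {
    x <- runif(n, -1, 1)
    y0 <- 1 + 2 * x + rnorm(n, 0, sd0)
    y1 <- 0.5 + 0.8 * y0 - x
    df <- data.frame(unit_id = rep(sprintf("%s%04d", if (sampled) "s" else "p",
                                           seq_len(n)), each = 2),
                     wave = rep(0:1, n), s = 1L, x1 = rep(x, each = 2))
    if (sampled) {
      df$r <- 1L
      df$y <- as.numeric(rbind(y0, y1))
    }
    df
  }
  list(population = population_frame(make(n_pop, FALSE)),
       sample = sample_frame(make(n_smp, TRUE)))
}

fast_mcmc <- function(draws = 100, ...) {
  mcmc_control(burn_in = 100, draws = draws, n_trees = 20, ...)
}

# a hand-built linear binary fit with fixed coefficients, for forcing
# response probabilities in white-box tests
stub_binary_fit <- function(schema, intercept, slopes = 0, J = 50) {
  p <- length(schema)
  Beta <- matrix(rep(c(intercept, rep_len(slopes, p)), each = J), J, p + 1)
  colnames(Beta) <- c("(Intercept)", schema)
  structure(list(backend = "linear", J = J, schema = schema,
                 fit = list(Beta = Beta)),
            class = "binary_fit")
}
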