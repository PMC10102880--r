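#' Triangular distribution
#'
#' Exact inverse-CDF sampling for the triangular distribution Tri(lo, mode,
#' hi), used as the sensitivity prior family: a bounded distribution whose
#' three parameters (minimum, mode, maximum) can place prior mass toward one
#' endpoint without requiring an explicit variance. Degenerate
#' `lo = mode = hi` is allowed and gives a point mass.
#'
#' @param p probabilities in \[0, 1\].
#' @param n number of draws.
#' @param lo,mode,hi parameters with `lo <= mode <= hi` (vectors recycle).
#' @return `qtriangular` maps probabilities to quantiles; it is continuous
#'   and non-decreasing in `p`. `rtriangular` draws variates.
#' @examples
#' qtriangular(0.25, 0, 1, 1)  # 0.5: the CDF is x^2 when mode == hi
#' mean(rtriangular(1e4, 0, 0.1, 0.1))  # ~ 2 * 0.1 / 3
#' @export
qtriangular <- function(p, lo, mode, hi) {
  k <- max(length(p), length(lo), length(mode), length(hi))
  p <- rep_len(p, k); lo <- rep_len(lo, k)
  mode <- rep_len(mode, k); hi <- rep_len(hi, k)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(lo > mode | mode > hi))
    stop("triangular parameters must satisfy lo <= mode <= hi")
  rng <- hi - lo
  out <- ifelse(rng == 0, lo, {
    fc <- ifelse(rng == 0, 0.5, (mode - lo) / ifelse(rng == 0, 1, rng))
    ifelse(p <= fc,
           lo + sqrt(pmax(p * rng * (mode - lo), 0)),
           hi - sqrt(pmax((1 - p) * rng * (hi - mode), 0)))
  })
  out
}

#' @rdname qtriangular
#' @export
rtriangular <- function(n, lo, mode, hi) qtriangular(runif(n), lo, mode, hi)

#' Quadratic bound on a sensitivity parameter
#'
#' A covariate-dependent bound `c0 + c1 * a + c2 * a^2` evaluated on a named
#' auxiliary variable (age, by default). Used to let the endpoints of the
#' triangular sensitivity priors vary over units, e.g. practice effects that
#' shrink with age and post-dropout decline that steepens with age.
#'
#' @param c0,c1,c2 finite polynomial coefficients.
#' @param on name of the auxiliary variable the bound is evaluated on.
#' @param range sane evaluation range; values outside trigger a warning
#'   (not an error).
#' @return object of class `poly_bound`.
#' @export
poly_bound <- function(c0, c1 = 0, c2 = 0, on = "age", range = c(18, 110)) {
  stopifnot(is.finite(c0), is.finite(c1), is.finite(c2))
  structure(list(c0 = c0, c1 = c1, c2 = c2, on = on, range = range),
            class = "poly_bound")
}

#' @rdname poly_bound
#' @param bound a `poly_bound` (a plain number is treated as a constant
#'   bound).
#' @param age values of the auxiliary variable.
#' @export
eval_poly_bound <- function(bound, age) {
  if (is.numeric(bound)) return(rep_len(bound, length(age)))
  stopifnot(inherits(bound, "poly_bound"))
  if (any(age < bound$range[1] | age > bound$range[2], na.rm = TRUE))
    warning("evaluating ", bound$on, " bound outside [",
            bound$range[1], ", ", bound$range[2], "]")
  bound$c0 + bound$c1 * age + bound$c2 * age^2
}

#' Sensitivity-parameter configuration
#'
#' Triangular priors for the two sensitivity parameters of the PPCM
#' estimator, per wave `t >= 1`:
#'
#' * `gamma`, the dropout shift: the mean outcome of a nonrespondent
#'   survivor equals the respondent-model prediction *plus* `gamma` (the
#'   signed-shift convention, so post-dropout decline means `gamma < 0`).
#'   Default prior Tri(L, L, 0) with `L <= 0` — mass concentrated toward
#'   the extreme endpoint, mirroring the practice-effect prior. Under
#'   `convention = "published"` positive bounds A are interpreted as the
#'   magnitude of a downward shift and mapped to L = -A internally.
#' * `delta`, the practice effect: the inflation of the observed score at
#'   repeated testing; it is always *subtracted* from predicted observed
#'   scores at waves `t >= 1` and must be nonnegative. Default prior
#'   Tri(0, B, B). No practice effect is assumed at the initial testing.
#'
#' Bounds (`L`, `B`) may be constants or [poly_bound()]s on age, and may be
#' given per wave (a list indexed by wave) or once for all waves. `gamma`
#' may be declared constant across waves within a unit
#' (`gamma_constant = TRUE`): one draw per unit is reused at every wave.
#'
#' @param gamma lower bound L (constant, `poly_bound`, or per-wave list);
#'   `0` gives the ignorable-dropout (MARS) analysis.
#' @param delta upper bound B, likewise; `0` gives no practice-effect
#'   adjustment.
#' @param gamma_constant logical; reuse one gamma draw across waves.
#' @param convention `"signed"` (bounds are the signed shift itself) or
#'   `"published"` (positive gamma bounds denote downward-shift magnitudes).
#' @return object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(gamma = 0, delta = 0, gamma_constant = TRUE,
                               convention = c("signed", "published")) {
  convention <- match.arg(convention)
  structure(list(gamma = gamma, delta = delta,
                 gamma_constant = isTRUE(gamma_constant),
                 convention = convention),
            class = "sensitivity_config")
}

#' @rdname sensitivity_config
#' @param preset one of `"MARS"` (no shift, no practice effect),
#'   `"MNARS+PE"` (age-dependent quadratic bounds for both parameters, the
#'   defaults of the motivating cognitive-aging analysis), or `"2x"` (the
#'   same bounds doubled).
#' @export
sensitivity_preset <- function(preset = c("MARS", "MNARS+PE", "2x")) {
  preset <- match.arg(preset)
  if (preset == "MARS") return(sensitivity_config(0, 0))
  mult <- if (preset == "2x") 2 else 1
  gam <- poly_bound(-8.0 * mult, -0.3 * mult, 3.9e-3 * mult)
  del <- list(poly_bound(4.8 * mult, -0.1 * mult, 5.2e-4 * mult),
              poly_bound(11.0 * mult, -0.3 * mult, 1.9e-3 * mult))
  sensitivity_config(gamma = gam, delta = del, gamma_constant = TRUE)
}

bound_for_wave <- function(bound, t) {
  if (is.list(bound) && !inherits(bound, "poly_bound")) {
    # per-wave list for t = 1, 2, ...; last entry extends to later waves
    bound[[min(t, length(bound))]]
  } else bound
}

#' Draw sensitivity parameters for every unit and wave
#'
#' One fresh set of (gamma, delta) draws per posterior iteration: for each
#' unit and each wave `t >= 1`, gamma ~ Tri(L, L, 0) and delta ~ Tri(0, B, B)
#' with bounds evaluated on the unit's auxiliary value (age) at that wave.
#'
#' @param config a [sensitivity_config()].
#' @param aux data.frame or matrix of per-unit auxiliary values used by
#'   `poly_bound`s, with one row per unit and columns named as the bounds'
#'   `on` fields; may be `NULL` when all bounds are constants. For
#'   time-varying auxiliaries supply a list with one element per wave.
#' @param n_units number of units.
#' @param waves number of follow-up waves (draws are made for t = 1..waves).
#' @return list with `gamma` and `delta`, each an `n_units` x `waves`
#'   matrix; gamma is the signed shift (<= 0), delta >= 0.
#' @export
sample_sensitivity <- function(config, n_units, waves, aux = NULL) {
  stopifnot(inherits(config, "sensitivity_config"))
  eval_bound <- function(bound, t) {
    b <- bound_for_wave(bound, t)
    if (inherits(b, "poly_bound")) {
      a <- aux_col(aux, b$on, t, n_units)
      list(v = eval_poly_bound(b, a), poly = TRUE)
    } else list(v = rep_len(b, n_units), poly = FALSE)
  }
  gam <- del <- matrix(0, n_units, waves)
  for (t in seq_len(waves)) {
    Lb <- eval_bound(config$gamma, t)
    L <- Lb$v
    if (config$convention == "published") L <- -abs(L)
    if (any(L > 0)) {
      # an age-dependent bound may cross zero at the edge of its range;
      # a shift bound above zero is truncated to the null (no shift)
      if (Lb$poly) L <- pmin(L, 0)
      else stop("gamma bound must be <= 0 under the signed convention")
    }
    Bb <- eval_bound(config$delta, t)
    B <- Bb$v
    if (any(B < 0)) {
      if (Bb$poly) B <- pmax(B, 0)
      else stop("delta bound must be >= 0")
    }
    if (t == 1 || !config$gamma_constant)
      gam[, t] <- qtriangular(runif(n_units), L, L, 0)
    else gam[, t] <- gam[, 1]
    del[, t] <- qtriangular(runif(n_units), 0, B, B)
  }
  list(gamma = gam, delta = del)
}

aux_col <- function(aux, nm, t, n_units) {
  if (is.null(aux))
    stop("bound depends on '", nm, "' but no auxiliary table was supplied")
  a <- if (is.list(aux) && !is.data.frame(aux)) aux[[min(t, length(aux))]]
       else aux
  if (!nm %in% colnames(a))
    stop("auxiliary table lacks column '", nm, "'")
  v <- a[, nm]
  if (length(v) != n_units) stop("auxiliary table has wrong number of rows")
  as.numeric(v)
}
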