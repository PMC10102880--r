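#' Longitudinal panel frames
#'
#' A panel frame is a long-format `data.frame` with one row per unit per wave
#' and columns `unit_id`, `wave` (integer, starting at 0), `s` (survival
#' indicator), and the auxiliary covariates. Sample frames additionally carry
#' `r` (response indicator) and `y` (observed score, present exactly when
#' `r = 1` and `s = 1`). Population frames never contain outcomes: the two
#' data sources cannot be linked at the unit level, so predictions are always
#' made for every unit of the population.
#'
#' Both constructors perform a strict schema check (column presence and
#' types, rectangular unit-by-wave grid) and then run [validate_panel()],
#' which checks the substantive invariants: response and survival are
#' monotone (absorbing), everyone responds and is alive at wave 0, response
#' implies being alive, and outcomes are present exactly for alive
#' respondents.
#'
#' @param df a long-format data.frame.
#' @param covariates character vector of covariate column names; defaults to
#'   all columns other than the reserved ones.
#' @param validate logical; run [validate_panel()] and stop on violations.
#' @return a `ppcm_population` / `ppcm_sample` object (a classed data.frame
#'   with attributes `covariates` and `waves`).
#' @examples
#' pop <- population_frame(data.frame(
#'   unit_id = rep(c("a", "b"), each = 2), wave = rep(0:1, 2),
#'   s = c(1, 1, 1, 0), x1 = rnorm(4)))
#' survivors(pop, 1)
#' @export
population_frame <- function(df, covariates = NULL, validate = TRUE) {
  x <- check_schema(df, role = "population", covariates = covariates)
  if (validate) stop_on_violations(validate_panel(x))
  x
}

#' @rdname population_frame
#' @export
sample_frame <- function(df, covariates = NULL, validate = TRUE) {
  x <- check_schema(df, role = "sample", covariates = covariates)
  if (validate) stop_on_violations(validate_panel(x))
  x
}

reserved_cols <- c("unit_id", "wave", "s", "r", "y")

check_schema <- function(df, role, covariates = NULL) {
  df <- as.data.frame(df)
  need <- c("unit_id", "wave", "s", if (role == "sample") "r")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (role == "population" && "y" %in% names(df) && any(!is.na(df$y)))
    stop("population frames must not contain outcome values", call. = FALSE)
  if (role == "sample" && !"y" %in% names(df))
    stop("sample frames require a 'y' column", call. = FALSE)
  if (!is.numeric(df$wave) || any(df$wave != floor(df$wave)) ||
      any(df$wave < 0))
    stop("'wave' must contain non-negative integers", call. = FALSE)
  df$unit_id <- as.character(df$unit_id)
  df$wave <- as.integer(df$wave)
  for (col in intersect(c("s", "r"), names(df))) {
    if (!all(df[[col]] %in% c(0, 1)))
      stop("'", col, "' must be 0/1", call. = FALSE)
    df[[col]] <- as.integer(df[[col]])
  }
  if (is.null(covariates))
    covariates <- setdiff(names(df), reserved_cols)
  bad <- covariates[!vapply(df[covariates], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # rectangular grid check: every unit has exactly the same set of waves
  waves <- sort(unique(df$wave))
  tab <- table(df$unit_id)
  if (length(unique(tab)) != 1L || tab[1] != length(waves) ||
      nrow(unique(df[, c("unit_id", "wave")])) != nrow(df))
    stop(structural_error("unit-by-wave grid is not rectangular"))
  df <- df[order(df$unit_id, df$wave), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            covariates = covariates,
            waves = waves,
            role = if (role == "population") "population" else "sample",
            class = c(paste0("ppcm_", role), "ppcm_panel", "data.frame"))
}

structural_error <- function(msg) {
  structure(class = c("ppcm_structural_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Validate panel invariants
#'
#' Checks the monotone-missingness structure of a panel frame and reports
#' every violated invariant together with the offending unit ids. Nothing is
#' ever repaired silently. A malformed unit-by-wave grid raises a structural
#' error (condition class `ppcm_structural_error`), which is a different
#' failure mode from an invariant violation.
#'
#' Invariants checked: `r` monotone (once a unit misses a wave it never
#' responds again), `s` monotone (death is absorbing), `r = 1` and `s = 1`
#' at wave 0, response implies being alive, and `y` present exactly when
#' `r = 1` and `s = 1` (sample frames only).
#'
#' @param x a `ppcm_population` or `ppcm_sample` frame (or a plain
#'   data.frame with the same columns).
#' @return an object of class `panel_validation`: list with elements `ok`
#'   (logical) and `violations` (data.frame with columns `rule`, `unit_id`).
#' @export
validate_panel <- function(x) {
  if (!inherits(x, "ppcm_panel"))
    x <- check_schema(x, role = if ("r" %in% names(x)) "sample" else "population")
  waves <- attr(x, "waves")
  nT <- length(waves)
  units <- unique(x$unit_id)
  viol <- list()
  add <- function(rule, ids) {
    if (length(ids))
      viol[[length(viol) + 1L]] <<- data.frame(rule = rule,
                                               unit_id = unique(ids),
                                               stringsAsFactors = FALSE)
  }
  # matrices are unit x wave because rows are sorted by (unit_id, wave)
  S <- matrix(x$s, nrow = length(units), ncol = nT, byrow = TRUE)
  non_mono <- function(M) units[apply(M, 1, function(z) any(diff(z) > 0))]
  add("survival not monotone", non_mono(S))
  add("dead at baseline", units[S[, 1] == 0])
  if ("r" %in% names(x)) {
    R <- matrix(x$r, nrow = length(units), ncol = nT, byrow = TRUE)
    add("response not monotone", non_mono(R))
    add("nonresponse at baseline", units[R[, 1] == 0])
    add("response implies alive", units[rowSums(R == 1 & S == 0) > 0])
    if ("y" %in% names(x)) {
      Y <- matrix(x$y, nrow = length(units), ncol = nT, byrow = TRUE)
      add("outcome present iff responding and alive",
          units[rowSums(is.na(Y) != (R == 0 | S == 0)) > 0])
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(), unit_id = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(viol) == 0L, violations = viol),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  if (x$ok) cat("panel validation: pass\n")
  else {
    cat("panel validation: FAIL\n")
    print(x$violations)
  }
  invisible(x)
}

stop_on_violations <- function(v) {
  if (!v$ok)
    stop("panel invariant violation(s): ",
         paste(unique(v$violations$rule), collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

#' Units with complete response history, alive at a wave
#'
#' Returns the rows of the sample frame for units that responded at every
#' wave up to and including `t` and are alive at `t`. These are the fitting
#' data for the wave-`t` working models: the outcome model for wave `t` is
#' fit on full respondents, and the response model for wave `t` is fit on
#' units with full response through `t - 1` that are alive at `t`.
#'
#' @param sample a `ppcm_sample` frame.
#' @param t wave index (0-based).
#' @param through_t if `FALSE`, require full response only through `t - 1`
#'   (the response-model fitting subset).
#' @return a `ppcm_sample` frame restricted to the qualifying units.
#' @export
observed_subset <- function(sample, t, through_t = TRUE) {
  stopifnot(inherits(sample, "ppcm_sample"))
  waves <- attr(sample, "waves")
  if (!t %in% waves) stop("wave ", t, " not present in panel")
  w <- panel_wide(sample)
  upto <- if (through_t) t else max(t - 1L, 0L)
  keep <- rowSums(w$r[, seq_len(upto + 1L), drop = FALSE] == 1) == upto + 1L
  keep <- keep & w$s[, t + 1L] == 1
  if (!any(keep))
    stop("no observed units at wave ", t, call. = FALSE)
  out <- sample[sample$unit_id %in% w$units[keep], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "covariates") <- attr(sample, "covariates")
  attr(out, "waves") <- attr(sample, "waves")
  attr(out, "role") <- attr(sample, "role")
  class(out) <- class(sample)
  out
}

#' Surviving units at a wave
#'
#' @param population a `ppcm_population` (or `ppcm_sample`) frame.
#' @param t wave index (0-based).
#' @return character vector of unit ids with `s = 1` at wave `t`.
#' @export
survivors <- function(population, t) {
  stopifnot(inherits(population, "ppcm_panel"))
  sel <- population$wave == t & population$s == 1
  if (!any(population$wave == t)) stop("wave ", t, " not present in panel")
  unique(population$unit_id[sel])
}

#' Age-cohort map
#'
#' Assigns each unit at each wave to exactly one age-cohort label, the
#' grouping over which the age-aggregated PPCM is computed.
#'
#' @param unit_id,wave,cohort parallel vectors.
#' @return a classed data.frame.
#' @export
age_cohort_map <- function(unit_id, wave, cohort) {
  df <- data.frame(unit_id = as.character(unit_id), wave = as.integer(wave),
                   cohort = as.character(cohort), stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("unit_id", "wave")]))
    stop("a unit maps to more than one cohort within a wave")
  structure(df, class = c("ppcm_cohorts", "data.frame"))
}

# Internal: long -> wide decomposition used by the numerical code.
# Returns unit ids plus unit x wave matrices for s, r, y and a list of
# per-wave covariate matrices.
panel_wide <- function(x) {
  waves <- attr(x, "waves")
  nT <- length(waves)
  units <- unique(x$unit_id) # sorted by construction
  n <- length(units)
  covs <- attr(x, "covariates")
  out <- list(units = units, waves = waves,
              s = matrix(x$s, n, nT, byrow = TRUE))
  if ("r" %in% names(x)) out$r <- matrix(x$r, n, nT, byrow = TRUE)
  if ("y" %in% names(x)) out$y <- matrix(x$y, n, nT, byrow = TRUE)
  out$X <- lapply(seq_len(nT), function(j) {
    m <- as.matrix(x[x$wave == waves[j], covs, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  out$time_constant <- nT == 1L || all(vapply(out$X[-1], function(m)
    isTRUE(all.equal(m, out$X[[1]], check.attributes = FALSE)), logical(1)))
  out
}
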