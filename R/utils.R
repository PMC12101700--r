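`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive per-stage seeds from a single pipeline seed
#'
#' One user-facing seed is split deterministically into independent seeds for
#' each stochastic stage, so that a single integer controls the whole run.
#'
#' @param seed integer master seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
stage_seeds <- function(seed, n = 6L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# stop() with a class so callers can distinguish validation from I/O errors
.fail <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "transmort_error")))
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .fail("transmort_value_error", "'%s' must be a single finite number", name)
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    .fail("transmort_value_error", "'%s' = %g is outside its allowed range", name, x)
  }
  invisible(x)
}

#' Band a metric age into labelled intervals
#'
#' Used when drift effects or reports are wanted per age group while all
#' modelling stays on the metric age scale.
#'
#' @param age numeric ages in years.
#' @param breaks increasing numeric cut points; ages outside are clamped into
#'   the first/last band.
#' @return factor of left-closed bands such as `"[40,50)"`.
#' @export
band_age <- function(age, breaks = seq(20, 80, by = 10)) {
  stopifnot(is.numeric(age), length(breaks) >= 2L, !is.unsorted(breaks))
  age <- pmin(pmax(age, breaks[1L]), breaks[length(breaks)] - 1e-9)
  cut(age, breaks = breaks, right = FALSE, include.lowest = TRUE)
}
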