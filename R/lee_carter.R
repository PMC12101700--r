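#' Fit the Lee-Carter mortality model
#'
#' Fits `log m(x, t) = a_x + b_x * k_t` to one country/sex block of a
#' population rate table by singular value decomposition of the age-centred
#' log-rate matrix (first singular triplet), under the usual identifiability
#' constraints `sum(b) = 1`, `sum(k) = 0`. The period index is modelled as a
#' random walk with drift, the drift being the mean first difference of `k`.
#'
#' @param rates a `population_rates` table (see [as_population_rates()]).
#' @param country country id to fit.
#' @param sex `"F"` or `"M"`.
#' @param years inclusive fitting window, default `c(2008, 2018)`.
#' @param floor_zeros zero rates break the log transform; set `TRUE` to floor
#'   them at half the smallest positive rate in the matrix (with a warning).
#' @return an object of class `lee_carter` with components `a`, `b`, `k`,
#'   `drift`, `ages`, `years`, `sex`, `country_id`, `sigma1` (the retained
#'   singular value).
#' @examples
#' w <- generate_world(world_config(K = 2, seed = 1))
#' fit <- lee_carter(w$population_rates, country = "S1", sex = "F")
#' fit
#' @export
lee_carter <- function(rates, country, sex, years = c(2008, 2018), floor_zeros = FALSE) {
  stopifnot(inherits(rates, "population_rates"), length(years) == 2L, years[1] <= years[2])
  d <- rates[rates$country_id == country & rates$sex == sex &
               rates$year >= years[1] & rates$year <= years[2], ]
  if (!nrow(d)) .fail("transmort_value_error", "no rates for country %s sex %s in %d-%d",
                      country, sex, years[1], years[2])
  ages <- sort(unique(d$age))
  yrs <- years[1]:years[2]
  M <- matrix(NA_real_, length(ages), length(yrs), dimnames = list(ages, yrs))
  M[cbind(match(d$age, ages), match(d$year, yrs))] <- d$rate
  if (anyNA(M)) {
    .fail("transmort_value_error", "missing (age, year) cell(s) in the fitting window: %d of %d",
          sum(is.na(M)), length(M))
  }
  if (any(M == 0)) {
    if (!floor_zeros) {
      .fail("transmort_value_error",
            "zero rate(s) in the fitting window; rerun with floor_zeros = TRUE to floor them at half the smallest positive rate")
    }
    floor_at <- min(M[M > 0]) / 2
    warning(sprintf("flooring %d zero rate(s) at %g before taking logs", sum(M == 0), floor_at))
    M[M == 0] <- floor_at
  }
  L <- log(M)
  a <- rowMeans(L)
  Z <- L - a
  sv <- svd(Z)
  if (sv$d[1] < 1e-12) {
    # rates constant over time: no period signal to attribute
    b <- rep(1 / length(ages), length(ages))
    k <- rep(0, length(yrs))
  } else {
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
    if (sum(u) < 0) { u <- -u; v <- -v }   # sign convention: b sums positive
    b <- u / sum(u)
    k <- sv$d[1] * v * sum(u)
    a <- a + b * mean(k)                   # re-impose sum(k) = 0 exactly
    k <- k - mean(k)
  }
  structure(list(a = stats::setNames(a, ages), b = stats::setNames(b, ages),
                 k = stats::setNames(k, yrs),
                 drift = if (length(yrs) > 1L) mean(diff(k)) else 0,
                 ages = ages, years = yrs, sex = sex, country_id = country,
                 sigma1 = sv$d[1]),
            class = "lee_carter")
}

#' @export
print.lee_carter <- function(x, ...) {
  cat(sprintf("Lee-Carter fit: country %s, sex %s, %d ages x %d years (%d-%d)\n",
              x$country_id, x$sex, length(x$ages), length(x$years),
              min(x$years), max(x$years)))
  cat(sprintf("  drift(k) = %.4f per year; leading singular value %.4g\n", x$drift, x$sigma1))
  invisible(x)
}

#' @export
coef.lee_carter <- function(object, ...) {
  list(a = object$a, b = object$b, k = object$k, drift = object$drift)
}

#' Project rates from a Lee-Carter fit
#'
#' Extends the period index as `k(T + h) = k(T) + h * drift` and returns
#' `exp(a + b * k)` for the projected year(s). `horizon = 0` is allowed
#' internally and reproduces the rank-1 reconstruction of the last fitted
#' year.
#'
#' @param fit a `lee_carter` object.
#' @param horizon positive integer number of years ahead (default 1).
#' @return a `population_rates` table for the projected year(s).
#' @export
project_rates <- function(fit, horizon = 1L) {
  stopifnot(inherits(fit, "lee_carter"))
  if (horizon < 0 || horizon != round(horizon)) {
    .fail("transmort_value_error", "horizon must be a non-negative integer (got %s)", horizon)
  }
  hs <- if (horizon == 0) 0L else seq_len(horizon)
  kT <- fit$k[length(fit$k)]
  out <- do.call(rbind, lapply(hs, function(h) {
    kh <- kT + h * fit$drift
    data.frame(country_id = fit$country_id,
               year = max(fit$years) + h,
               age = fit$ages, sex = fit$sex,
               rate = exp(fit$a + fit$b * kh),
               stringsAsFactors = FALSE)
  }))
  as_population_rates(out)
}

#' @rdname project_rates
#' @param object,... method arguments (`...` passes `horizon`).
#' @export
predict.lee_carter <- function(object, horizon = 1L, ...) project_rates(object, horizon)
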