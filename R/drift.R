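#' Drift model: decompose the ratio of transferred to reference deaths
#'
#' After the transfer, remaining disagreement with a reference table is
#' quantified by the multiplicative drift `delta = D_hat / D_ref` per cell
#' and decomposed over features with a log-link Poisson-deviance GLM. Two
#' mathematically equivalent forms are provided:
#' \itemize{
#'   \item offset form: response `D_hat`, offset `log(D_ref)`;
#'   \item ratio form: response `D_hat / D_ref`, prior weights `D_ref`.
#' }
#' Categorical features use deviation (sum-to-zero) coding, so the
#' exponentiated intercept is the average ratio across cells and each
#' effect is a multiplicative deviation from that average; an exponentiated
#' effect of 1 means the feature does not drive the drift. Non-integer
#' responses are handled as quasi-likelihood (the deviance is minimized by
#' IRLS regardless of integrality); reported standard errors come from the
#' expected information with dispersion fixed at 1 and are nominal.
#'
#' @param pred_deaths predicted (transferred) deaths per cell, `>= 0`.
#' @param ref_deaths reference deaths per cell (`mu_ref * exposure`), `> 0`.
#' @param features data.frame of cell features (character/factor columns are
#'   deviation-coded; numeric columns enter as metric slopes).
#' @return object of class `drift_fit`.
#' @examples
#' cells <- expand.grid(gender = c("F", "M"), band = c("young", "old"))
#' ref <- c(100, 120, 80, 90)
#' fit <- fit_drift_offset(ref * 0.5, ref, cells)   # uniform halving
#' exp(coef(fit))                                   # intercept 0.5, effects 1
#' @name drift_model
NULL

.fit_drift <- function(pred_deaths, ref_deaths, features,
                       form = c("offset", "ratio")) {
  form <- match.arg(form)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  n <- length(pred_deaths)
  stopifnot(length(ref_deaths) == n, nrow(features) == n, n >= 1L)
  if (any(!is.finite(ref_deaths) | ref_deaths <= 0)) {
    .fail("transmort_value_error", "reference deaths must be strictly positive in every cell")
  }
  if (any(!is.finite(pred_deaths) | pred_deaths < 0)) {
    .fail("transmort_value_error", "predicted deaths must be non-negative")
  }
  is_cat <- vapply(features, function(v) is.character(v) || is.factor(v), logical(1))
  for (f in names(features)[is_cat]) features[[f]] <- factor(features[[f]])
  contrasts <- lapply(features[is_cat], function(v) stats::contr.sum(nlevels(v)))
  dat <- cbind(features, .pred = pred_deaths, .ref = ref_deaths)
  rhs <- if (ncol(features)) paste(names(features), collapse = " + ") else "1"
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 200)
  fit <- suppressWarnings(
    if (form == "offset") {
      stats::glm(stats::as.formula(paste(".pred ~", rhs)),
                 family = stats::quasipoisson(link = "log"),
                 offset = log(.ref), data = dat,
                 contrasts = if (length(contrasts)) contrasts else NULL,
                 control = ctrl)
    } else {
      stats::glm(stats::as.formula(paste("I(.pred / .ref) ~", rhs)),
                 family = stats::quasipoisson(link = "log"),
                 weights = .ref, data = dat,
                 contrasts = if (length(contrasts)) contrasts else NULL,
                 control = ctrl)
    }
  )
  if (!fit$converged) {
    .fail("transmort_value_error",
          "drift GLM did not converge in %d IRLS iterations (deviance %.6g)",
          fit$iter, fit$deviance)
  }
  beta <- stats::coef(fit)
  vc <- summary(fit, dispersion = 1)$cov.scaled
  # expand deviation-coded factors to one row per level, incl. the implied last
  rows <- list(data.frame(feature = "(Intercept)", level = NA_character_,
                          estimate = beta[["(Intercept)"]],
                          se = sqrt(vc["(Intercept)", "(Intercept)"]),
                          stringsAsFactors = FALSE))
  for (f in names(features)) {
    if (is_cat[[f]]) {
      lev <- levels(features[[f]])
      nm <- paste0(f, seq_len(length(lev) - 1L))
      est <- beta[nm]
      se <- sqrt(diag(vc)[nm])
      last <- -sum(est)
      se_last <- sqrt(sum(vc[nm, nm, drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, level = lev, estimate = unname(c(est, last)),
        se = unname(c(se, se_last)), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, level = NA_character_, estimate = unname(beta[[f]]),
        se = sqrt(vc[f, f]), stringsAsFactors = FALSE)
    }
  }
  eff <- do.call(rbind, rows)
  eff$exp_estimate <- exp(eff$estimate)
  structure(list(effects = eff, intercept = beta[["(Intercept)"]],
                 method = paste0(form, "_form"), deviance = fit$deviance,
                 glm = fit),
            class = "drift_fit")
}

#' @rdname drift_model
#' @export
fit_drift_offset <- function(pred_deaths, ref_deaths, features) {
  .fit_drift(pred_deaths, ref_deaths, features, "offset")
}

#' @rdname drift_model
#' @export
fit_drift_ratio <- function(pred_deaths, ref_deaths, features) {
  .fit_drift(pred_deaths, ref_deaths, features, "ratio")
}

#' @export
print.drift_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Drift model (%s): average ratio exp(b0) = %.*f, deviance %.4g\n",
              x$method, digits, exp(x$intercept), x$deviance))
  print.data.frame(format(x$effects, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  stats::setNames(object$effects$estimate,
                  ifelse(is.na(object$effects$level), object$effects$feature,
                         paste(object$effects$feature, object$effects$level, sep = ":")))
}

#' @export
summary.drift_fit <- function(object, ...) {
  eff <- object$effects
  eff$exp_lower <- exp(eff$estimate - 1.96 * eff$se)
  eff$exp_upper <- exp(eff$estimate + 1.96 * eff$se)
  structure(list(effects = eff, method = object$method,
                 deviance = object$deviance), class = "summary.drift_fit")
}

#' @export
print.summary.drift_fit <- function(x, ...) {
  cat(sprintf("Drift model (%s), nominal 95%% intervals on the ratio scale:\n", x$method))
  print.data.frame(format(x$effects, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Relative risk of one category versus another
#'
#' From a drift fit's deviation-coded effects, the mortality-ratio of
#' category `a` relative to category `b` of the same feature, as a
#' percentage rounded to the nearest percent: `100 * exp(beta_a - beta_b)`.
#' Effects 33% below and 24% above the average (0.67 vs 1.24), for example,
#' give 54%.
#'
#' @param fit a `drift_fit`.
#' @param feature feature name in the fit.
#' @param category_a,category_b category labels of that feature.
#' @return relative risk in percent (numeric scalar, whole percents).
#' @export
relative_risk <- function(fit, feature, category_a, category_b) {
  stopifnot(inherits(fit, "drift_fit"))
  eff <- fit$effects[fit$effects$feature == feature & !is.na(fit$effects$level), ]
  if (!nrow(eff)) .fail("transmort_value_error", "no categorical feature '%s' in the fit", feature)
  miss <- setdiff(c(category_a, category_b), eff$level)
  if (length(miss)) {
    .fail("transmort_value_error", "unknown category for '%s': %s", feature,
          paste(miss, collapse = ", "))
  }
  ea <- eff$exp_estimate[eff$level == category_a]
  eb <- eff$exp_estimate[eff$level == category_b]
  round(100 * ea / eb)
}

#' Build drift cells from a prediction and a reference table
#'
#' Aggregates a transfer prediction to (age band, gender) cells, attaches the
#' reference deaths `D_ref = mu_ref * exposure` (reference rates matched on
#' integer age, then summed into bands), and returns the table the drift
#' model consumes. Age is banded for effect reporting only; modelling inside
#' the transfer stays on the metric scale.
#'
#' @param pred a `transfer_prediction`.
#' @param reference a `reference_table` with integer ages.
#' @param age_breaks passed to [band_age()].
#' @param extra_features further prediction columns to carry into the cells
#'   (e.g. a portfolio feature absent from the reference table).
#' @return data.frame with `age_band`, `gender`, any extra features,
#'   `exposure`, `d_hat`, `d_ref`.
#' @export
drift_table <- function(pred, reference, age_breaks = seq(20, 80, by = 10),
                        extra_features = character(0)) {
  stopifnot(inherits(pred, "transfer_prediction"), inherits(reference, "reference_table"))
  df <- as.data.frame(pred)
  df$age <- round(df$age)
  hit <- match(paste(df$age, df$gender), paste(reference$age, reference$gender))
  if (anyNA(hit)) {
    .fail("transmort_value_error", "reference table does not cover %d prediction cell(s)",
          sum(is.na(hit)))
  }
  df$d_ref <- reference$rate[hit] * df$exposure
  df$age_band <- band_age(df$age, age_breaks)
  keys <- df[c("age_band", "gender", extra_features)]
  agg <- stats::aggregate(df[c("exposure", "d_hat", "d_ref")], by = keys, FUN = sum)
  agg[do.call(order, agg[c("age_band", "gender", extra_features)]), , drop = FALSE]
}
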