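#' Gradient-boosting settings for the mortality models
#'
#' Both model stages minimize the negative Poisson log-likelihood of death
#' counts with log exposure as offset. Leaf granularity is governed by
#' exposure, not row counts: `min_child_exposure` is translated to the
#' boosting library's hessian floor at the training set's base mortality
#' rate, since the Poisson hessian in a leaf is the sum of predicted deaths.
#'
#' @param n_rounds maximum boosting rounds (default 500).
#' @param learning_rate shrinkage in (0, 1] (default 0.05).
#' @param max_depth tree depth (default 3).
#' @param min_child_exposure minimum life-years of exposure a leaf must
#'   represent, default 1000.
#' @param seed RNG seed for the training stage.
#' @param early_stopping_fraction fraction of rows held out (stratified by
#'   country) to stop boosting when the holdout deviance stalls; 0 disables
#'   early stopping. Default 0.2.
#' @return a `boost_spec` list.
#' @export
boost_spec <- function(n_rounds = 500L, learning_rate = 0.05, max_depth = 3L,
                       min_child_exposure = 1000, seed = 1L,
                       early_stopping_fraction = 0.2) {
  .assert_scalar_num(n_rounds, "n_rounds", lower = 0)
  .assert_scalar_num(learning_rate, "learning_rate", lower = 0, upper = 1, strict_lower = TRUE)
  .assert_scalar_num(max_depth, "max_depth", lower = 1)
  .assert_scalar_num(min_child_exposure, "min_child_exposure", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(early_stopping_fraction, "early_stopping_fraction", lower = 0, upper = 0.499)
  structure(list(n_rounds = as.integer(n_rounds), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_child_exposure = min_child_exposure, seed = as.integer(seed),
                 early_stopping_fraction = early_stopping_fraction),
            class = "boost_spec")
}

# ---- feature encoding -------------------------------------------------------
# categorical columns are mapped to integer level codes; the level maps are
# frozen at fit time and reused at prediction (unseen level -> NA = missing)

.make_encoding <- function(df, features) {
  lapply(stats::setNames(features, features), function(f) {
    if (is.numeric(df[[f]])) NULL else sort(unique(as.character(df[[f]])))
  })
}

.encode_matrix <- function(df, encoding) {
  cols <- lapply(names(encoding), function(f) {
    v <- df[[f]]
    if (is.null(v)) .fail("transmort_value_error", "feature '%s' missing from data", f)
    if (is.null(encoding[[f]])) as.numeric(v) else as.numeric(match(as.character(v), encoding[[f]]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(encoding)
  m
}

.xgb_params <- function(spec, base_rate) {
  list(objective = "count:poisson",
       eta = spec$learning_rate,
       max_depth = spec$max_depth,
       min_child_weight = spec$min_child_exposure * base_rate,
       lambda = 0,
       base_score = 1,       # neutral intercept: the offset carries the level
       nthread = 1)
}

# shared trainer: label = deaths, offset = log(margin_base); returns the
# booster plus its deviance trace and the number of trees actually used
.fit_poisson_boost <- function(X, deaths, margin_base, country, spec, base_rate) {
  dall <- xgboost::xgb.DMatrix(X, label = deaths, base_margin = log(margin_base))
  params <- .xgb_params(spec, base_rate)
  if (spec$n_rounds == 0L) {
    booster <- xgboost::xgb.train(params, dall, nrounds = 0)
    return(list(booster = booster, n_trees = 0L, trace = numeric(0), holdout = NULL))
  }
  set.seed(spec$seed)
  if (spec$early_stopping_fraction > 0 && nrow(X) >= 10L) {
    hold <- unlist(lapply(split(seq_len(nrow(X)), country), function(ix) {
      n <- max(1L, round(length(ix) * spec$early_stopping_fraction))
      sample(ix, n)
    }), use.names = FALSE)
    tr <- setdiff(seq_len(nrow(X)), hold)
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = deaths[tr],
                                base_margin = log(margin_base[tr]))
    dho <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = deaths[hold],
                                base_margin = log(margin_base[hold]))
    fit <- xgboost::xgb.train(params, dtr, nrounds = spec$n_rounds,
                              evals = list(train = dtr, holdout = dho),
                              early_stopping_rounds = 25L, verbose = 0)
    best <- attributes(fit)$best_iteration %||% spec$n_rounds
    # refit on all rows with the selected number of rounds, for final use
    booster <- xgboost::xgb.train(params, dall, nrounds = best,
                                  evals = list(train = dall), verbose = 0)
    log_ <- attributes(booster)$evaluation_log
    list(booster = booster, n_trees = best, trace = log_$train_poisson_nloglik,
         holdout = attributes(fit)$evaluation_log$holdout_poisson_nloglik)
  } else {
    booster <- xgboost::xgb.train(params, dall, nrounds = spec$n_rounds,
                                  evals = list(train = dall), verbose = 0)
    log_ <- attributes(booster)$evaluation_log
    list(booster = booster, n_trees = spec$n_rounds,
         trace = log_$train_poisson_nloglik, holdout = NULL)
  }
}

# tree-only multiplicative factor exp(sum of trees); with base_score = 1 and
# no base_margin on the prediction matrix the margin is exactly the tree sum
.boost_factor <- function(fit, X) {
  if (fit$n_trees == 0L) return(rep(1, nrow(X)))
  d <- xgboost::xgb.DMatrix(X)
  exp(predict(fit$booster, d, outputmargin = TRUE))
}

#' Fit the global mortality model on the pooled portfolio
#'
#' Stage one of the transfer model: a Poisson gradient-boosted ensemble
#' `q(x)` over the features shared by all countries, with log exposure as
#' offset and no country indicator. The fitted rate is
#' `q(x) = base_rate * exp(trees(x))` where `base_rate` is the pooled
#' deaths/exposure ratio, so `n_rounds = 0` yields the pooled base rate
#' everywhere.
#'
#' @param pooled `aggregated_portfolio` with at least two countries.
#' @param global_features feature names; default: the portfolio's declared
#'   global features.
#' @param spec a [boost_spec()].
#' @return object of class `global_boost`.
#' @export
fit_global <- function(pooled, global_features = NULL, spec = boost_spec()) {
  stopifnot(inherits(pooled, "aggregated_portfolio"), inherits(spec, "boost_spec"))
  if (length(unique(pooled$country_id)) < 2L) {
    .fail("transmort_value_error", "global model needs >= 2 countries in the pooled data")
  }
  global_features <- global_features %||% attr(pooled, "global_features")
  if ("country_id" %in% global_features) {
    .fail("transmort_value_error", "the global model must not see a country indicator")
  }
  bad <- global_features[vapply(global_features, function(f) anyNA(pooled[[f]]), logical(1))]
  if (length(bad)) {
    .fail("transmort_value_error", "global feature(s) missing in some country: %s",
          paste(bad, collapse = ", "))
  }
  encoding <- .make_encoding(pooled, global_features)
  X <- .encode_matrix(pooled, encoding)
  base_rate <- sum(pooled$deaths) / sum(pooled$exposure)
  fit <- .fit_poisson_boost(X, pooled$deaths, pooled$exposure * base_rate,
                            pooled$country_id, spec, base_rate)
  structure(list(booster = fit$booster, n_trees = fit$n_trees,
                 base_rate = base_rate, encoding = encoding,
                 features = global_features, trace = fit$trace,
                 holdout_trace = fit$holdout, spec = spec),
            class = "global_boost")
}

#' @export
print.global_boost <- function(x, ...) {
  cat(sprintf("Global Poisson boosting model: %d trees over %d features; base rate %.3e\n",
              x$n_trees, length(x$features), x$base_rate))
  invisible(x)
}

#' Predict mortality rates from the global model
#' @param object a `global_boost`.
#' @param newdata data.frame carrying the global feature columns.
#' @param ... unused.
#' @return strictly positive rate per row (`q(x)`, deaths per life-year).
#' @export
predict.global_boost <- function(object, newdata, ...) {
  X <- .encode_matrix(as.data.frame(newdata), object$encoding)
  object$base_rate * .boost_factor(object, X)
}

#' Fit a country's specialized adjustment model
#'
#' Stage two: boosting continues on one country's data over its global plus
#' local features, with offset `log(q(x) * E)` — the global model's predicted
#' deaths. The ensemble therefore learns the multiplicative correction
#' `h_j(x)`, making the transfer composition `q(x) * h_j(x)` exact by
#' construction; `n_rounds = 0` gives `h_j == 1`. Constant local features are
#' dropped with a warning.
#'
#' @param country_data `aggregated_portfolio` rows of a single country.
#' @param global_model the fitted [fit_global()] model.
#' @param spec a [boost_spec()].
#' @return object of class `specialized_boost`.
#' @export
fit_specialized <- function(country_data, global_model, spec = boost_spec()) {
  stopifnot(inherits(country_data, "aggregated_portfolio"),
            inherits(global_model, "global_boost"), inherits(spec, "boost_spec"))
  cc <- unique(country_data$country_id)
  if (length(cc) != 1L) {
    .fail("transmort_value_error", "specialized model takes exactly one country (got %d)", length(cc))
  }
  fl <- portfolio_features(country_data, country = cc)
  feats <- c(fl$global, fl$local)
  const <- feats[vapply(feats, function(f) length(unique(country_data[[f]])) < 2L, logical(1))]
  if (length(const) && length(const) < length(feats)) {
    warning(sprintf("dropping constant feature(s) for %s: %s", cc, paste(const, collapse = ", ")))
    feats <- setdiff(feats, const)
  }
  encoding <- .make_encoding(country_data, feats)
  X <- .encode_matrix(country_data, encoding)
  q <- predict(global_model, country_data)
  base_rate <- sum(country_data$deaths) / sum(country_data$exposure)
  fit <- .fit_poisson_boost(X, country_data$deaths, q * country_data$exposure,
                            country_data$country_id, spec, base_rate)
  structure(list(country_id = cc, booster = fit$booster, n_trees = fit$n_trees,
                 encoding = encoding, features = feats, trace = fit$trace,
                 holdout_trace = fit$holdout, spec = spec),
            class = "specialized_boost")
}

#' @export
print.specialized_boost <- function(x, ...) {
  cat(sprintf("Specialized model for %s: %d trees over %d features (multiplicative on the global model)\n",
              x$country_id, x$n_trees, length(x$features)))
  invisible(x)
}

#' Predict the multiplicative adjustment of a specialized model
#' @param object a `specialized_boost`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return strictly positive factor `h_j(x)` per row.
#' @export
predict.specialized_boost <- function(object, newdata, ...) {
  X <- .encode_matrix(as.data.frame(newdata), object$encoding)
  .boost_factor(object, X)
}

#' Fit the complete transfer model
#'
#' Convenience wrapper fitting the global model on the pooled portfolio and
#' one specialized model per country, returning them as a single object that
#' [predict_target()] (or `predict()`) applies to a synthetic portfolio.
#'
#' @param pooled pooled `aggregated_portfolio` of all source countries.
#' @param spec a [boost_spec()].
#' @param global_features optional explicit global feature list.
#' @return object of class `transfer_model` with elements `global` and
#'   `specialized` (named list by country).
#' @examples
#' w <- generate_world(world_config(K = 2, seed = 3, cell_exposure = 5e4))
#' tm <- transfer_model(w$portfolio, boost_spec(n_rounds = 20))
#' tm
#' @export
transfer_model <- function(pooled, spec = boost_spec(), global_features = NULL) {
  global <- fit_global(pooled, global_features, spec)
  countries <- sort(unique(pooled$country_id))
  specialized <- lapply(stats::setNames(countries, countries), function(cc) {
    rows <- pooled[pooled$country_id == cc, , drop = FALSE]
    keep <- c(names(rows)[!vapply(rows, anyNA, logical(1))])
    fit_specialized(as_portfolio(as.data.frame(rows)[keep]), global, spec)
  })
  structure(list(global = global, specialized = specialized, spec = spec),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  print(x$global)
  cat(sprintf("Specialized models: %s\n", paste(names(x$specialized), collapse = ", ")))
  invisible(x)
}

#' Transfer predictions on a synthetic portfolio
#'
#' Applies the transfer composition: for every synthetic row, the predicted
#' rate is `mu = q(x_global) * h_origin(x)` and the predicted death count is
#' `mu * exposure`. Summing predicted deaths over rows reproduces the
#' similarity-weighted double sum over origins exactly, because each row
#' belongs to exactly one origin block.
#'
#' @param synth a `synthetic_portfolio`.
#' @param global_model a `global_boost` (or a `transfer_model`, in which case
#'   `specialized` is taken from it).
#' @param specialized named list of `specialized_boost` models covering every
#'   origin present in `synth`.
#' @return object of class `transfer_prediction`: the synthetic rows plus
#'   columns `q`, `h`, `mu_hat`, `d_hat`.
#' @export
predict_target <- function(synth, global_model, specialized = NULL) {
  stopifnot(inherits(synth, "synthetic_portfolio"))
  if (inherits(global_model, "transfer_model")) {
    specialized <- global_model$specialized
    global_model <- global_model$global
  }
  stopifnot(inherits(global_model, "global_boost"))
  origins <- unique(synth$origin_country)
  miss <- setdiff(origins, names(specialized))
  if (length(miss)) {
    .fail("transmort_value_error", "no specialized model for origin(s): %s",
          paste(miss, collapse = ", "))
  }
  df <- as.data.frame(synth)
  df$q <- predict(global_model, df)
  df$h <- NA_real_
  for (cc in origins) {
    ix <- df$origin_country == cc
    df$h[ix] <- predict(specialized[[cc]], df[ix, , drop = FALSE])
  }
  df$mu_hat <- df$q * df$h
  df$d_hat <- df$mu_hat * df$exposure
  structure(df, target_id = attr(synth, "target_id"),
            class = c("transfer_prediction", "data.frame"))
}

#' @export
#' @rdname predict_target
#' @param object,... method interface: `predict(transfer_model, synth)`.
predict.transfer_model <- function(object, synth, ...) {
  predict_target(synth, object$global, object$specialized)
}

#' @export
print.transfer_prediction <- function(x, ...) {
  cat(sprintf("Transfer prediction for '%s': %d rows, %.1f predicted deaths over %s life-years (rate %.3e)\n",
              attr(x, "target_id") %||% "?", nrow(x), sum(x$d_hat),
              format(round(sum(x$exposure)), big.mark = ","),
              sum(x$d_hat) / sum(x$exposure)))
  invisible(x)
}

#' Aggregate a transfer prediction to cell level
#'
#' Sums predicted deaths and exposure by the given keys and reports the cell
#' rate `sum(d_hat) / sum(exposure)`. Metric age is rounded to integer years
#' before grouping when `age` is among the keys.
#'
#' @param pred a `transfer_prediction`.
#' @param by grouping columns, default `c("age", "gender")`.
#' @return data.frame with the keys plus `exposure`, `d_hat`, `mu_hat`.
#' @export
aggregate_prediction <- function(pred, by = c("age", "gender")) {
  stopifnot(inherits(pred, "transfer_prediction"))
  df <- as.data.frame(pred)
  if ("age" %in% by) df$age <- round(df$age)
  keys <- df[by]
  agg <- stats::aggregate(df[c("exposure", "d_hat")], by = keys, FUN = sum)
  agg$mu_hat <- agg$d_hat / agg$exposure
  agg[do.call(order, agg[by]), , drop = FALSE]
}
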