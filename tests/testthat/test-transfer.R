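test_that("the global model recovers a constant rate and degenerates to the base rate at 0 rounds", {
  set.seed(1)
  r <- 0.003
  po <- as_portfolio(data.frame(
    country_id = rep(c("A", "B"), each = 40),
    year = 2020, age = rep(30:49, 4), gender = rep(c("F", "M"), each = 20),
    population_mortality = 0.004,
    deaths = rpois(80, r * 1e8), exposure = 1e8))
  fit <- fit_global(po, spec = boost_spec(n_rounds = 80, learning_rate = 0.1,
                                          early_stopping_fraction = 0, seed = 1))
  expect_lt(max(abs(predict(fit, po) / r - 1)), 0.01)
  fit0 <- fit_global(po, spec = boost_spec(n_rounds = 0))
  expect_equal(predict(fit0, po), rep(sum(po$deaths) / sum(po$exposure), 80))
  expect_error(fit_global(po, c("age", "country_id")), "country indicator")
  expect_error(fit_global(as_portfolio(po[po$country_id == "A", ]), NULL, boost_spec()),
               ">= 2 countries")
})

test_that("the global model recovers the Gompertz age slope on simulated countries", {
  w <- tiny_world(K = 2, seed = 8, ages = 35:64, cell_exposure = 2e5)
  fit <- fit_global(w$portfolio,
                    spec = boost_spec(n_rounds = 300, learning_rate = 0.1,
                                      early_stopping_fraction = 0, seed = 1))
  grid <- data.frame(age = 38:61, gender = "F",
                     population_mortality = 0.002, sum_assured = 36000)
  grid$population_mortality <- w$config$country_frailty[1] *
    w$config$gompertz_alpha * exp(w$config$gompertz_beta * grid$age)
  slope <- coef(lm(log(predict(fit, grid)) ~ grid$age))[2]
  expect_lt(abs(slope / w$config$gompertz_beta - 1), 0.10)
})

test_that("a single-leaf boosting round equals the damped Poisson Newton step", {
  # constant features force a single leaf; with learning rate 1 and no L2
  # penalty the fitted log-factor is sum(D - mu) / (sum(mu) * exp(0.7)),
  # the 0.7 being the standard Poisson step damping
  po <- as_portfolio(data.frame(
    country_id = c("A", "A", "B"), year = 2020, age = 50, gender = "F",
    population_mortality = 0.002, deaths = c(10, 12, 9), exposure = c(5000, 6000, 4500)))
  spec <- boost_spec(n_rounds = 1, learning_rate = 1, max_depth = 1,
                     min_child_exposure = 1, early_stopping_fraction = 0)
  g <- fit_global(po, c("age", "gender", "population_mortality"), spec)
  ca <- as_portfolio(data.frame(
    country_id = "A", year = 2020, age = 50, gender = "F",
    population_mortality = 0.002, deaths = c(20, 24, 18), exposure = c(5000, 6000, 4500)))
  s <- suppressWarnings(fit_specialized(ca, g, spec))
  qe <- predict(g, ca) * ca$exposure
  h_oracle <- exp(sum(ca$deaths - qe) / (sum(qe) * exp(0.7)))
  expect_equal(unique(predict(s, ca)), h_oracle, tolerance = 1e-6)
})

test_that("specialized models learn the multiplicative adjustment", {
  set.seed(3)
  r <- 0.002
  po <- as_portfolio(data.frame(
    country_id = rep(c("A", "B"), each = 40),
    year = 2020, age = rep(30:49, 4), gender = rep(c("F", "M"), each = 20),
    population_mortality = 0.004,
    deaths = rpois(80, r * 1e6), exposure = 1e6))
  g <- fit_global(po, spec = boost_spec(n_rounds = 50, learning_rate = 0.1,
                                        early_stopping_fraction = 0, seed = 1))
  # uniform 2x excess mortality vs the global prediction
  ca <- po[po$country_id == "A", ]
  ca$deaths <- round(2 * predict(g, ca) * ca$exposure)
  s2 <- suppressWarnings(
    fit_specialized(as_portfolio(ca), g,
                    boost_spec(n_rounds = 200, learning_rate = 0.1,
                               early_stopping_fraction = 0, seed = 1)))
  expect_lt(max(abs(predict(s2, ca) / 2 - 1)), 0.05)
  # zero boosting rounds: h == 1 and predictions equal the global model
  s0 <- suppressWarnings(fit_specialized(as_portfolio(ca), g, boost_spec(n_rounds = 0)))
  expect_equal(predict(s0, ca), rep(1, nrow(ca)))
})

test_that("a country drawn exactly from the global rates needs no adjustment", {
  w <- tiny_world(K = 2, seed = 10, cell_exposure = 5e5,
                  country_frailty = c(1, 1), local_effects = c(1, 1, 1))
  g <- fit_global(w$portfolio, spec = boost_spec(n_rounds = 150, learning_rate = 0.1,
                                                 early_stopping_fraction = 0, seed = 2))
  c1 <- w$portfolio[w$portfolio$country_id == "S1", ]
  keep <- names(c1)[!vapply(c1, anyNA, logical(1))]
  s <- fit_specialized(as_portfolio(as.data.frame(c1)[keep]), g,
                       boost_spec(n_rounds = 100, learning_rate = 0.05,
                                  early_stopping_fraction = 0.2, seed = 2))
  h <- predict(s, c1)
  expect_gte(mean(h >= 0.95 & h <= 1.05), 0.95)
})

test_that("training deviance is monotone and fits are seed-deterministic", {
  w <- tiny_world(K = 2, seed = 12)
  spec <- boost_spec(n_rounds = 40, learning_rate = 0.1, early_stopping_fraction = 0, seed = 5)
  f1 <- fit_global(w$portfolio, spec = spec)
  f2 <- fit_global(w$portfolio, spec = spec)
  expect_true(all(diff(f1$trace) <= 1e-10))
  expect_identical(predict(f1, w$portfolio), predict(f2, w$portfolio))
  c1 <- w$portfolio[w$portfolio$country_id == "S1", ]
  keep <- names(c1)[!vapply(c1, anyNA, logical(1))]
  s1 <- fit_specialized(as_portfolio(as.data.frame(c1)[keep]), f1, spec)
  expect_true(all(diff(s1$trace) <= 1e-10))
})

test_that("predict_target composes global and specialized factors row-wise", {
  w <- tiny_world(K = 2, seed = 14)
  sc <- manual_scores(c(S1 = 0.7, S2 = 0.3))
  synth <- synthesize_portfolio(w$portfolio, sc, flat_rates(ages = 40:55),
                                noise_config(seed = 2), 2e6)
  tm <- transfer_model(w$portfolio, boost_spec(n_rounds = 30, seed = 3))
  pred <- predict(tm, synth)
  expect_equal(pred$d_hat, pred$mu_hat * pred$exposure)
  expect_equal(pred$mu_hat, pred$q * pred$h)
  # the row sum equals the per-origin double sum exactly
  expect_equal(sum(pred$d_hat),
               sum(tapply(pred$q * pred$h * pred$exposure, pred$origin_country, sum)))
  # neutral adjustments reduce to the global model
  tm0 <- transfer_model(w$portfolio, boost_spec(n_rounds = 0))
  tm0$specialized <- lapply(tm0$specialized, function(s) s)
  g30 <- transfer_model(w$portfolio, boost_spec(n_rounds = 30, seed = 3))
  pred0 <- predict_target(synth, g30$global, tm0$specialized)
  expect_equal(pred0$mu_hat, predict(g30$global, as.data.frame(synth)))
  # a missing specialized model is a named error
  expect_error(predict_target(synth, tm$global, tm$specialized["S1"]),
               "no specialized model", class = "transmort_value_error")
})

test_that("a single-origin synthetic portfolio reduces the composition to one term", {
  w <- tiny_world(K = 2, seed = 16)
  sc <- manual_scores(c(S1 = 1))
  synth <- synthesize_portfolio(w$portfolio, sc, flat_rates(ages = 40:55),
                                noise_config(seed = 4), 1e6)
  tm <- transfer_model(w$portfolio, boost_spec(n_rounds = 20, seed = 1))
  pred <- predict(tm, synth)
  expect_setequal(unique(pred$origin_country), "S1")
  expect_equal(sum(pred$d_hat), sum(pred$q * pred$h * pred$exposure))
})
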