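# reconstruct the rank-1 structure independently by explicit power iteration,
# for use as an oracle against the SVD-based fitter
power_rank1 <- function(L, iters = 500) {
  a <- rowMeans(L)
  Z <- L - a
  v <- rep(1, ncol(Z)) / sqrt(ncol(Z))
  for (i in seq_len(iters)) {
    u <- Z %*% v; u <- u / sqrt(sum(u^2))
    v <- t(Z) %*% u; v <- v / sqrt(sum(v^2))
  }
  s <- as.numeric(t(u) %*% Z %*% v)
  if (sum(u) < 0) { u <- -u; v <- -v }
  b <- as.numeric(u) / sum(u)
  k <- s * as.numeric(v) * sum(u)
  list(a = a + b * mean(k), b = b, k = k - mean(k))
}

rates_from <- function(a, b, k, country = "X", sex = "F", years = NULL) {
  years <- years %||% (2008 + seq_along(k) - 1)
  ages <- 60 + seq_along(a) - 1
  grid <- expand.grid(age = ages, year = years)
  as_population_rates(data.frame(
    country_id = country, year = grid$year, age = grid$age, sex = sex,
    rate = exp(a[match(grid$age, ages)] + b[match(grid$age, ages)] *
                 k[match(grid$year, years)])))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("an exact rank-1 log-rate surface is recovered to machine precision", {
  a <- log(c(0.002, 0.004, 0.008, 0.016, 0.03))
  b <- c(0.1, 0.15, 0.2, 0.25, 0.3)            # sums to 1
  k <- seq(-2, 2, length.out = 11); k <- k - mean(k)
  fit <- lee_carter(rates_from(a, b, k), "X", "F", years = c(2008, 2018))
  expect_equal(unname(fit$a), a, tolerance = 1e-10)
  expect_equal(unname(fit$b), b, tolerance = 1e-10)
  expect_equal(unname(fit$k), k, tolerance = 1e-10)
  expect_equal(sum(fit$b), 1, tolerance = 1e-12)
  expect_equal(sum(fit$k), 0, tolerance = 1e-10)
})

test_that("rates constant over time give a flat period index and uniform sensitivities", {
  a <- log(c(0.002, 0.005, 0.012))
  fit <- lee_carter(rates_from(a, c(0.2, 0.3, 0.5), rep(0, 11)), "X", "F",
                    years = c(2008, 2018))
  expect_equal(unname(fit$k), rep(0, 11))
  expect_equal(unname(fit$b), rep(1 / 3, 3))
  expect_equal(unname(fit$a), a)
  expect_equal(fit$drift, 0)
})

test_that("noisy rank-1 log-rates match an explicit power-iteration decomposition", {
  set.seed(7)
  a <- log(seq(0.002, 0.03, length.out = 8))
  b <- (1:8) / sum(1:8)
  k <- cumsum(c(0, rnorm(10, -0.3, 0.2))); k <- k - mean(k)
  grid <- rates_from(a, b, k)
  grid$rate <- exp(log(grid$rate) + rnorm(nrow(grid), 0, 0.01))
  fit <- lee_carter(grid, "X", "F", years = c(2008, 2018))
  L <- matrix(log(grid$rate[order(grid$year, grid$age)]), nrow = 8)
  orc <- power_rank1(L)
  expect_lt(max(abs(unname(fit$a) - orc$a)), 1e-8)
  expect_lt(max(abs(unname(fit$b) - orc$b)), 1e-8)
  expect_lt(max(abs(unname(fit$k) - orc$k)), 1e-8)
  expect_lt(max(abs(unname(fit$b) - b)), 0.05)
  expect_lt(max(abs(unname(fit$k) - k)), 0.05)
})

test_that("the fit is invariant to input row order", {
  set.seed(11)
  grid <- rates_from(log(c(0.003, 0.01, 0.02)), c(0.2, 0.3, 0.5),
                     seq(-1, 1, length.out = 11))
  shuffled <- as_population_rates(grid[sample(nrow(grid)), ])
  f1 <- lee_carter(grid, "X", "F", years = c(2008, 2018))
  f2 <- lee_carter(shuffled, "X", "F", years = c(2008, 2018))
  expect_equal(f1[c("a", "b", "k", "drift")], f2[c("a", "b", "k", "drift")])
})

test_that("projection follows the random walk with drift", {
  # k = (-1, 0, 1) over 3 years: drift 1, next k = 2
  a <- log(c(0.004, 0.009)); b <- c(0.4, 0.6)
  fit <- lee_carter(rates_from(a, b, c(-1, 0, 1), years = 2016:2018), "X", "F",
                    years = c(2016, 2018))
  expect_equal(fit$drift, 1, tolerance = 1e-10)
  proj <- project_rates(fit, 1)
  expect_equal(proj$rate, exp(a + b * 2), tolerance = 1e-10)
  expect_equal(unique(proj$year), 2019)
  # zero drift: the projected year equals the last fitted year's reconstruction
  fit0 <- lee_carter(rates_from(a, b, rep(0, 3), years = 2016:2018), "X", "F",
                     years = c(2016, 2018))
  expect_equal(project_rates(fit0, 1)$rate, project_rates(fit0, 0)$rate)
  expect_error(project_rates(fit, -1), "horizon")
})

test_that("a world with steady annual improvement projects within 2% of truth", {
  w <- tiny_world(K = 1, seed = 3, ages = 40:60)
  cfg <- w$config
  fit <- lee_carter(w$population_rates, "S1", "M", years = c(2008, 2018))
  proj <- project_rates(fit, 1)
  truth <- w$population_rates[w$population_rates$country_id == "S1" &
                                w$population_rates$sex == "M" &
                                w$population_rates$year == 2019, ]
  expect_lt(max(abs(proj$rate / truth$rate[match(proj$age, truth$age)] - 1)), 0.02)
})

test_that("zero rates are rejected unless flooring is requested", {
  grid <- rates_from(log(c(0.003, 0.01)), c(0.4, 0.6), rep(0, 3), years = 2016:2018)
  grid$rate[1] <- 0
  expect_error(lee_carter(grid, "X", "F", years = c(2016, 2018)), "floor_zeros")
  expect_warning(fit <- lee_carter(grid, "X", "F", years = c(2016, 2018),
                                   floor_zeros = TRUE), "flooring")
  expect_true(all(is.finite(fit$a)))
  # missing cell is a hard error
  expect_error(lee_carter(as_population_rates(grid[-2, ]), "X", "F",
                          years = c(2016, 2018)), "missing")
})
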