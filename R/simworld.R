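#' Configuration of a synthetic multi-country mortality world
#'
#' Defines a fully known ground truth against which every pipeline stage can
#' be validated. Insured mortality follows a Gompertz baseline
#' `alpha * exp(beta * age)` scaled by a gender multiplier, a per-country
#' frailty, an underwriting selection factor and per-cell local-feature
#' effects; population mortality is the same without selection and local
#' effects; death counts are Poisson given exposure. External indicators are
#' built so that the Manhattan distance between two countries' vectors tracks
#' the difference of their log frailties, plus uninformative noise items. The
#' target country's true insured rates are a mixture of the source countries'
#' rates under `target_mixture`.
#'
#' @param K number of source countries (default 8).
#' @param target_id label of the target country.
#' @param ages integer age range of all schedules.
#' @param years calendar years of the population rate tables.
#' @param portfolio_year year label of the portfolio cells (the last year).
#' @param gompertz_alpha,gompertz_beta baseline hazard level and age slope.
#' @param gender_multiplier male/female rate ratio.
#' @param improvement_rate annual proportional mortality improvement.
#' @param country_frailty length-`K` multiplicative country effects; default
#'   a geometric spread between exp(-0.35) and exp(0.35).
#' @param selection_factor insured/population rate ratio in (0, 1].
#' @param local_levels,local_effects levels and multiplicative effects of
#'   each country's local (country-specific) feature.
#' @param cell_exposure average life-years of exposure per portfolio cell.
#' @param n_signal_items,n_noise_items frailty-informative and pure-noise
#'   indicator items (defaults 7 + 6 = 13 items).
#' @param indicator_noise_sd sd of the noise on signal items, on the log
#'   frailty scale.
#' @param target_mixture length-`K` weights (sum 1) defining the target's
#'   true rates as a mixture of source rates; default equal weights.
#' @param seed RNG seed for world generation.
#' @return a validated `world_config` list.
#' @export
world_config <- function(K = 8L, target_id = "TGT", ages = 30:69,
                         years = 2008:2019, portfolio_year = max(years),
                         gompertz_alpha = 3e-5, gompertz_beta = 0.09,
                         gender_multiplier = 1.5, improvement_rate = 0.01,
                         country_frailty = NULL, selection_factor = 0.7,
                         local_levels = c("L1", "L2", "L3"),
                         local_effects = c(0.85, 1, 1.2),
                         cell_exposure = 2e4,
                         n_signal_items = 7L, n_noise_items = 6L,
                         indicator_noise_sd = 0.1,
                         target_mixture = NULL, seed = 1L) {
  .assert_scalar_num(K, "K", lower = 1)
  .assert_scalar_num(gompertz_alpha, "gompertz_alpha", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(gender_multiplier, "gender_multiplier", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(selection_factor, "selection_factor", lower = 0, upper = 1, strict_lower = TRUE)
  .assert_scalar_num(cell_exposure, "cell_exposure", lower = 0, strict_lower = TRUE)
  country_frailty <- country_frailty %||%
    exp(seq(-0.35, 0.35, length.out = K))
  target_mixture <- target_mixture %||% rep(1 / K, K)
  if (length(country_frailty) != K || any(country_frailty <= 0)) {
    .fail("transmort_value_error", "country_frailty must be %d positive multipliers", K)
  }
  if (length(target_mixture) != K || any(target_mixture < 0) ||
      abs(sum(target_mixture) - 1) > 1e-8) {
    .fail("transmort_value_error", "target_mixture must be %d non-negative weights summing to 1", K)
  }
  if (length(local_levels) != length(local_effects) || any(local_effects <= 0)) {
    .fail("transmort_value_error", "local_effects must be positive, one per local level")
  }
  structure(list(K = as.integer(K), target_id = target_id, ages = as.integer(ages),
                 years = as.integer(years), portfolio_year = as.integer(portfolio_year),
                 gompertz_alpha = gompertz_alpha, gompertz_beta = gompertz_beta,
                 gender_multiplier = gender_multiplier,
                 improvement_rate = improvement_rate,
                 country_frailty = country_frailty,
                 selection_factor = selection_factor,
                 local_levels = local_levels, local_effects = local_effects,
                 cell_exposure = cell_exposure,
                 n_signal_items = as.integer(n_signal_items),
                 n_noise_items = as.integer(n_noise_items),
                 indicator_noise_sd = indicator_noise_sd,
                 target_mixture = target_mixture, seed = as.integer(seed)),
            class = "world_config")
}

.gompertz_rate <- function(cfg, age, male) {
  cfg$gompertz_alpha * exp(cfg$gompertz_beta * age) *
    ifelse(male, cfg$gender_multiplier, 1)
}

#' Generate a synthetic multi-country world
#'
#' @param config a [world_config()].
#' @return object of class `simworld`: list with `portfolio` (pooled sources),
#'   `population_rates` (sources and target), `indicators` (sources and
#'   target), `reference` (the target's true insured age-by-gender rates at
#'   the portfolio year), `truth` (per-cell true rates and frailties),
#'   `target_id` and `config`.
#' @examples
#' w <- generate_world(world_config(K = 3, seed = 42))
#' w$portfolio
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  set.seed(cfg$seed)
  src <- sprintf("S%d", seq_len(cfg$K))
  eff_frailty <- sum(cfg$target_mixture * cfg$country_frailty)
  y0 <- min(cfg$years)

  # population rate tables: frailty x Gompertz, improving over calendar time
  pop_grid <- expand.grid(age = cfg$ages, sex = c("F", "M"), year = cfg$years,
                          country = c(src, cfg$target_id),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  frail_of <- stats::setNames(c(cfg$country_frailty, eff_frailty), c(src, cfg$target_id))
  pop_grid$rate <- frail_of[pop_grid$country] *
    .gompertz_rate(cfg, pop_grid$age, pop_grid$sex == "M") *
    exp(-cfg$improvement_rate * (pop_grid$year - y0))
  population_rates <- as_population_rates(data.frame(
    country_id = pop_grid$country, year = pop_grid$year, age = pop_grid$age,
    sex = pop_grid$sex, rate = pmin(pop_grid$rate, 0.95)))

  # insured portfolio cells per source country, with a country-specific
  # local feature column (NA for every other country's rows)
  t_port <- cfg$portfolio_year
  blocks <- lapply(seq_len(cfg$K), function(j) {
    cells <- expand.grid(age = cfg$ages, gender = c("F", "M"),
                         local = cfg$local_levels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- cfg$selection_factor * cfg$country_frailty[j] *
      .gompertz_rate(cfg, cells$age, cells$gender == "M") *
      cfg$local_effects[match(cells$local, cfg$local_levels)] *
      exp(-cfg$improvement_rate * (t_port - y0))
    E <- cfg$cell_exposure * stats::runif(nrow(cells), 0.6, 1.4)
    popm <- frail_of[src[j]] * .gompertz_rate(cfg, cells$age, cells$gender == "M") *
      exp(-cfg$improvement_rate * (t_port - y0))
    b <- data.frame(country_id = src[j], year = t_port, age = cells$age,
                    gender = cells$gender, population_mortality = popm,
                    sum_assured = round(exp(stats::rnorm(nrow(cells), 10.5, 0.4))),
                    deaths = stats::rpois(nrow(cells), mu * E), exposure = E,
                    stringsAsFactors = FALSE)
    b[[paste0("local_occ_", src[j])]] <- cells$local
    b$true_rate <- mu
    b
  })
  cols <- unique(unlist(lapply(blocks, names)))
  blocks <- lapply(blocks, function(b) { b[setdiff(cols, names(b))] <- NA; b[cols] })
  pooled <- do.call(rbind, blocks)
  truth_rate <- pooled$true_rate
  portfolio <- as_portfolio(pooled[setdiff(cols, "true_rate")])

  # target ground truth: mixture of the sources' exposure-weighted cell rates
  cell_key <- paste(pooled$age, pooled$gender)
  ref_cells <- expand.grid(age = cfg$ages, gender = c("F", "M"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref_cells$rate <- vapply(seq_len(nrow(ref_cells)), function(i) {
    k <- paste(ref_cells$age[i], ref_cells$gender[i])
    per_source <- vapply(seq_len(cfg$K), function(j) {
      ix <- pooled$country_id == src[j] & cell_key == k
      sum(truth_rate[ix] * pooled$exposure[ix]) / sum(pooled$exposure[ix])
    }, numeric(1))
    sum(cfg$target_mixture * per_source)
  }, numeric(1))
  reference <- as_reference_table(ref_cells)

  # indicators: signal items are affine in log frailty (item-specific scale
  # and offset) plus noise; the rest are pure noise
  countries <- c(src, cfg$target_id)
  lf <- log(frail_of[countries])
  items <- list()
  for (q in seq_len(cfg$n_signal_items)) {
    sc <- c(1, 5, 0.5, 20, 2, 0.1, 8)[(q - 1L) %% 7L + 1L]
    items[[sprintf("signal_%02d", q)]] <-
      sc * (lf + stats::rnorm(length(countries), 0, cfg$indicator_noise_sd)) + 3 * sc
  }
  for (q in seq_len(cfg$n_noise_items)) {
    items[[sprintf("noise_%02d", q)]] <- stats::rnorm(length(countries))
  }
  indicators <- as_indicators(data.frame(
    country_id = rep(countries, times = length(items)),
    item_id = rep(names(items), each = length(countries)),
    value = unlist(items, use.names = FALSE), stringsAsFactors = FALSE))

  truth <- list(insured = data.frame(pooled[c("country_id", "age", "gender")],
                                     rate = truth_rate),
                frailty = stats::setNames(cfg$country_frailty, src),
                effective_frailty = eff_frailty)
  structure(list(portfolio = portfolio, population_rates = population_rates,
                 indicators = indicators, reference = reference, truth = truth,
                 target_id = cfg$target_id, config = cfg),
            class = "simworld")
}

#' @export
print.simworld <- function(x, ...) {
  cat(sprintf("Synthetic world: %d source countries + target '%s'; %d portfolio cells, %d indicator items\n",
              x$config$K, x$target_id, nrow(x$portfolio),
              length(unique(x$indicators$item_id))))
  invisible(x)
}

#' Deterministic portfolio fixture with published pooled totals
#'
#' An eight-country aggregated portfolio whose per-country death and exposure
#' totals equal a published pooled-portfolio overview exactly (9,412 deaths
#' over 9,116,634 life-years). Within each country the totals are split over
#' eight age-by-gender cells by a fixed allocation — no randomness, so the
#' totals are bit-stable.
#'
#' @return an `aggregated_portfolio` with countries `"1"`..`"8"`.
#' @export
table1_fixture <- function() {
  deaths <- c(1699, 1291, 494, 1225, 1816, 2132, 458, 297)
  expo <- c(1295299, 1686299, 815795, 1347150, 1825901, 1548157, 498560, 99473)
  start_year <- c(2013, 2010, 2010, 2017, 2016, 2016, 2017, 2015)
  cells <- expand.grid(age = c(35, 45, 55, 65), gender = c("F", "M"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ew <- c(0.09, 0.08, 0.16, 0.14, 0.16, 0.14, 0.13, 0.10)  # exposure split
  dw_raw <- ew * exp(0.085 * (cells$age - 50)) * ifelse(cells$gender == "M", 1.4, 1)
  dw <- dw_raw / sum(dw_raw)
  out <- do.call(rbind, lapply(seq_len(8L), function(j) {
    E <- round(expo[j] * ew, 2)
    E[8L] <- expo[j] - sum(E[-8L])
    D <- floor(deaths[j] * dw)
    D[8L] <- deaths[j] - sum(D[-8L])
    data.frame(country_id = as.character(j), year = start_year[j],
               age = cells$age, gender = cells$gender,
               population_mortality = 4e-5 * exp(0.09 * cells$age) *
                 ifelse(cells$gender == "M", 1.4, 1),
               sum_assured = 40000 + 1000 * j,
               local_class = rep(c("C1", "C2"), 4L),
               deaths = D, exposure = E, stringsAsFactors = FALSE)
  }))
  as_portfolio(out)
}
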