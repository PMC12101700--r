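#' Standardize external indicators to a country-by-item matrix
#'
#' Centres and scales each indicator item to mean 0 and sample standard
#' deviation 1 (denominator `n - 1`) across all countries in the table —
#' sources and target jointly. An item that is constant across countries
#' carries no distance information and is set to all zeros with a warning.
#'
#' @param ind an `external_indicators` table.
#' @return numeric matrix, rows = countries, columns = items.
#' @export
standardize_indicators <- function(ind) {
  stopifnot(inherits(ind, "external_indicators"))
  if (!nrow(ind)) .fail("transmort_value_error", "empty indicator table")
  countries <- sort(unique(ind$country_id))
  items <- sort(unique(ind$item_id))
  Z <- matrix(NA_real_, length(countries), length(items),
              dimnames = list(countries, items))
  Z[cbind(match(ind$country_id, countries), match(ind$item_id, items))] <- ind$value
  mu <- colMeans(Z)
  sd <- apply(Z, 2L, stats::sd)
  const <- sd < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sprintf("constant indicator item(s) set to zero: %s",
                    paste(items[const], collapse = ", ")))
    sd[const] <- 1
  }
  Z <- sweep(sweep(Z, 2L, mu), 2L, sd, "/")
  Z[, const] <- 0
  Z
}

#' Country similarity scores against a target
#'
#' The country similarity index: indicators are standardized jointly over
#' sources and target, the Manhattan (L1) distance `d_j = sum_q |z_jq - z_Mq|`
#' from each source `j` to the target `M` is computed, and mapped to a score
#' `s_j = exp(-d_j)` in `(0, 1]`. Resampling weights are the scores normalized
#' to sum to one.
#'
#' @param ind an `external_indicators` table holding sources and target.
#' @param target_id the target country's id (excluded from the source list).
#' @return object of class `similarity_scores`: a data.frame with columns
#'   `country_id`, `distance`, `score`, `weight`, attribute `target_id`.
#' @examples
#' w <- generate_world(world_config(K = 3, seed = 7))
#' similarity_scores(w$indicators, target_id = w$target_id)
#' @export
similarity_scores <- function(ind, target_id) {
  Z <- standardize_indicators(ind)
  if (!target_id %in% rownames(Z)) {
    .fail("transmort_value_error", "target country '%s' not in the indicator table", target_id)
  }
  src <- setdiff(rownames(Z), target_id)
  if (!length(src)) .fail("transmort_value_error", "no source countries besides the target")
  d <- rowSums(abs(Z[src, , drop = FALSE] -
                     matrix(Z[target_id, ], length(src), ncol(Z), byrow = TRUE)))
  s <- exp(-d)
  out <- data.frame(country_id = src, distance = unname(d), score = unname(s),
                    weight = unname(s / sum(s)), stringsAsFactors = FALSE)
  structure(out[order(-out$score), ], target_id = target_id,
            class = c("similarity_scores", "data.frame"))
}

#' @export
print.similarity_scores <- function(x, digits = 4, ...) {
  cat(sprintf("Similarity to target '%s' (%d sources):\n", attr(x, "target_id"), nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Age-standardized death rate of one country
#'
#' Collapses a full age-by-sex mortality schedule into one scalar per country
#' for use as an indicator item: the rate schedule is averaged with equal
#' weight per (age, sex) cell over the ages shared by both sexes — a uniform
#' standard age structure. Declared convention; the weighting, not the value
#' of any one cell, is what makes countries comparable.
#'
#' @param rates a `population_rates` table.
#' @param country country id.
#' @param year calendar year; default: latest year available for the country.
#' @return the standardized rate (scalar).
#' @export
age_standardized_rate <- function(rates, country, year = NULL) {
  stopifnot(inherits(rates, "population_rates"))
  d <- rates[rates$country_id == country, ]
  if (!nrow(d)) .fail("transmort_value_error", "no rates for country %s", country)
  year <- year %||% max(d$year)
  d <- d[d$year == year, ]
  if (!nrow(d)) .fail("transmort_value_error", "no rates for country %s in %d", country, year)
  ages <- intersect(d$age[d$sex == "F"], d$age[d$sex == "M"])
  mean(d$rate[d$age %in% ages])
}

#' Append an age-standardized mortality item to an indicator table
#'
#' Convenience for building the population-mortality item of the similarity
#' index from a rate table: one [age_standardized_rate()] per country, at the
#' latest year common to all countries in the rate table.
#'
#' @param ind an `external_indicators` table (may be missing the item).
#' @param rates a `population_rates` table covering every indicator country.
#' @param item_id item label, default `"3.1_hmd_asdr"`.
#' @return the indicator table with the item appended, revalidated.
#' @export
add_mortality_indicator <- function(ind, rates, item_id = "3.1_hmd_asdr") {
  stopifnot(inherits(ind, "external_indicators"), inherits(rates, "population_rates"))
  countries <- sort(unique(ind$country_id))
  missing <- setdiff(countries, unique(rates$country_id))
  if (length(missing)) {
    .fail("transmort_value_error", "rate table lacks countries: %s", paste(missing, collapse = ", "))
  }
  year <- min(vapply(countries, function(cc) max(rates$year[rates$country_id == cc]), numeric(1)))
  add <- data.frame(country_id = countries, item_id = item_id,
                    value = vapply(countries, function(cc)
                      age_standardized_rate(rates, cc, year), numeric(1)),
                    stringsAsFactors = FALSE)
  as_indicators(rbind(as.data.frame(ind[ind$item_id != item_id, ]), add))
}
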