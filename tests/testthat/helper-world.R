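# small worlds and hand-built objects shared across tests

tiny_world <- function(K = 2, seed = 1, ages = 40:55, cell_exposure = 5e4, ...) {
  generate_world(world_config(K = K, seed = seed, ages = ages,
                              cell_exposure = cell_exposure, ...))
}

# a similarity_scores object with chosen weights, bypassing the indicator path
manual_scores <- function(weights, target_id = "TGT") {
  s <- weights / max(weights)            # scores on (0, 1], proportional to weights
  structure(data.frame(country_id = names(weights), distance = -log(s),
                       score = s, weight = weights / sum(weights),
                       stringsAsFactors = FALSE),
            target_id = target_id, class = c("similarity_scores", "data.frame"))
}

# flat rate table covering an age range for one country, one year
flat_rates <- function(country = "TGT", year = 2019, ages = 30:69, rate = 0.002) {
  as_population_rates(expand.grid(country_id = country, year = year, age = ages,
                                  sex = c("F", "M"), stringsAsFactors = FALSE) |>
                        transform(rate = rate))
}

# minimal valid portfolio data.frame builder
mini_portfolio <- function(n = 6, countries = c("A", "B"), seed = 1) {
  set.seed(seed)
  df <- expand.grid(country_id = countries, i = seq_len(n / length(countries)),
                    stringsAsFactors = FALSE)
  data.frame(country_id = df$country_id, year = 2020,
             age = sample(30:60, nrow(df), TRUE),
             gender = sample(c("F", "M"), nrow(df), TRUE),
             population_mortality = runif(nrow(df), 1e-3, 5e-3),
             local_grp = sample(c("g1", "g2"), nrow(df), TRUE),
             deaths = rpois(nrow(df), 5), exposure = runif(nrow(df), 1e3, 1e4),
             stringsAsFactors = FALSE)
}
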