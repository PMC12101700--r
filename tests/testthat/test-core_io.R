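test_that("portfolio fixture reproduces the published pooled totals after a disk round trip", {
  po <- table1_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(po, path)
  re <- load_table(path, "portfolio")
  expect_equal(length(unique(re$country_id)), 8L)
  expect_equal(sum(re$deaths), 9412)
  expect_equal(sum(re$exposure), 9116634)
  expect_equal(as.data.frame(re), as.data.frame(po), tolerance = 1e-12)
})

test_that("an empty file with a valid header loads as a zero-row table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("country_id,year,age,gender,population_mortality,deaths,exposure", path)
  po <- load_table(path, "portfolio")
  expect_s3_class(po, "aggregated_portfolio")
  expect_equal(nrow(po), 0L)
})

test_that("validation rejects invariant violations with named rules", {
  base <- mini_portfolio()
  bad <- base; bad$exposure[2] <- 0
  expect_error(as_portfolio(bad), "exposure > 0", class = "transmort_validation_error")
  bad <- base; bad$deaths[1] <- -1
  expect_error(as_portfolio(bad), "deaths", class = "transmort_validation_error")
  bad <- base[setdiff(names(base), "gender")]
  expect_error(as_portfolio(bad), "gender", class = "transmort_schema_error")

  rt <- data.frame(country_id = "X", year = 2020, age = c(50, 50), sex = "F", rate = 0.01)
  expect_error(as_population_rates(rt), "duplicate", class = "transmort_validation_error")
  rt2 <- data.frame(country_id = "X", year = 2020, age = c(50, 52), sex = "F", rate = 0.01)
  expect_error(as_population_rates(rt2), "contiguous", class = "transmort_validation_error")

  ind <- data.frame(country_id = c("A", "A", "B"), item_id = c("i1", "i2", "i1"), value = 1)
  expect_error(as_indicators(ind), "different item set", class = "transmort_validation_error")
  ind2 <- data.frame(country_id = c("A", "B"), item_id = "i1", value = c(1, NA))
  expect_error(as_indicators(ind2), "missing", class = "transmort_validation_error")
})

test_that("every schema round-trips randomized valid tables through CSV", {
  withr::local_seed(42)
  for (rep in 1:3) {
    po <- as_portfolio(mini_portfolio(n = 8, seed = rep))
    rt <- flat_rates(ages = 40:60, rate = runif(1, 1e-3, 1e-2))
    ind <- as_indicators(data.frame(
      country_id = rep(c("A", "B", "C"), each = 4),
      item_id = rep(paste0("i", 1:4), 3), value = rnorm(12)))
    ref <- as_reference_table(data.frame(
      age = rep(40:49, 2), gender = rep(c("F", "M"), each = 10),
      rate = runif(20, 1e-3, 1e-2)))
    for (tb in list(list(po, "portfolio"), list(rt, "population_rates"),
                    list(ind, "indicators"), list(ref, "reference"))) {
      path <- withr::local_tempfile(fileext = ".csv")
      write_table(tb[[1]], path)
      re <- load_table(path, tb[[2]])
      expect_equal(as.data.frame(re), as.data.frame(tb[[1]]), tolerance = 1e-12)
    }
  }
})

test_that("categorical levels containing commas survive quoting", {
  po <- mini_portfolio()
  po$local_grp <- ifelse(po$local_grp == "g1", "white, collar", "blue, collar")
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(as_portfolio(po), path)
  re <- load_table(path, "portfolio")
  expect_setequal(unique(re$local_grp), c("white, collar", "blue, collar"))
})

test_that("prediction tables are written with the declared column order (golden file)", {
  pred <- data.frame(origin_country = c("A", "A", "B"), age = c(40L, 41L, 40L),
                     gender = c("F", "M", "F"), exposure = c(1000, 2000, 1500),
                     mu_hat = c(0.001, 0.002, 0.0015), d_hat = c(1, 4, 2.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(pred, path)
  expect_identical(readLines(path), readLines(test_path("golden_prediction.csv")))
})

test_that("the HMD-style fixed-column layout converts to the long rate schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Year,Age,Female,Male,Total",
               "2018,60,0.005,0.008,0.0065",
               "2018,61,0.006,0.009,0.0075"), path)
  rt <- load_table(path, "population_rates", hmd_layout = TRUE, country_id = "UK")
  expect_equal(nrow(rt), 4L)
  expect_equal(rt$rate[rt$sex == "M" & rt$age == 61], 0.009)
  expect_error(load_table(path, "population_rates", hmd_layout = TRUE),
               "country_id", class = "transmort_schema_error")
})
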