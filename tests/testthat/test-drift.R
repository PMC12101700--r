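drift_cells <- function() {
  cells <- expand.grid(age_band = c("[40,50)", "[50,60)", "[60,70)"),
                       gender = c("F", "M"), stringsAsFactors = FALSE)
  cells$d_ref <- c(120, 150, 300, 180, 220, 400)
  cells
}

test_that("perfect agreement yields zero coefficients; a level shift moves only the intercept", {
  cells <- drift_cells()
  f <- fit_drift_offset(cells$d_ref, cells$d_ref, cells[c("age_band", "gender")])
  expect_equal(unname(coef(f)), rep(0, length(coef(f))), tolerance = 1e-9)
  f5 <- fit_drift_offset(0.5 * cells$d_ref, cells$d_ref, cells[c("age_band", "gender")])
  expect_equal(exp(f5$intercept), 0.5, tolerance = 1e-9)
  expect_equal(f5$effects$exp_estimate[-1], rep(1, nrow(f5$effects) - 1), tolerance = 1e-9)
})

test_that("a saturated two-level gender fit matches the closed form under deviation coding", {
  cells <- data.frame(gender = c("F", "M"))
  f <- fit_drift_offset(c(600, 900), c(1000, 1000), cells)
  expect_equal(exp(f$intercept), sqrt(0.54), tolerance = 1e-9)
  eff <- f$effects[!is.na(f$effects$level), ]
  expect_equal(eff$exp_estimate[eff$level == "F"], sqrt(0.6 / 0.9), tolerance = 1e-9)
  expect_equal(eff$exp_estimate[eff$level == "M"], sqrt(0.9 / 0.6), tolerance = 1e-9)
  # deviation-coded effects sum to zero including the implied last level
  expect_equal(sum(eff$estimate[eff$feature == "gender"]), 0, tolerance = 1e-12)
})

test_that("offset and ratio forms are equivalent on randomized drift scenarios", {
  set.seed(31)
  for (i in 1:5) {
    cells <- drift_cells()
    cells$d_hat <- cells$d_ref * exp(rnorm(6, -0.5, 0.4))
    fo <- fit_drift_offset(cells$d_hat, cells$d_ref, cells[c("age_band", "gender")])
    fr <- fit_drift_ratio(cells$d_hat, cells$d_ref, cells[c("age_band", "gender")])
    expect_lt(max(abs(coef(fo) - coef(fr))), 1e-8)
    expect_equal(fo$effects$se, fr$effects$se, tolerance = 1e-6)
  }
})

test_that("scaling predicted deaths by a constant shifts only the intercept", {
  set.seed(37)
  cells <- drift_cells()
  cells$d_hat <- cells$d_ref * exp(rnorm(6, 0, 0.3))
  f1 <- fit_drift_offset(cells$d_hat, cells$d_ref, cells[c("age_band", "gender")])
  f2 <- fit_drift_offset(3 * cells$d_hat, cells$d_ref, cells[c("age_band", "gender")])
  expect_equal(f2$intercept - f1$intercept, log(3), tolerance = 1e-8)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-8)
})

test_that("metric covariates enter as slopes alongside deviation-coded factors", {
  cells <- expand.grid(age = seq(42, 62, 10), gender = c("F", "M"),
                       stringsAsFactors = FALSE)
  cells$d_ref <- 200
  delta <- 0.6 * exp(0.01 * (cells$age - 52)) * ifelse(cells$gender == "M", 1.1, 1 / 1.1)
  f <- fit_drift_offset(cells$d_ref * delta, cells$d_ref, cells[c("age", "gender")])
  eff <- f$effects[!is.na(f$effects$level) | f$effects$feature == "age", ]
  expect_equal(eff$estimate[eff$feature == "age"], 0.01, tolerance = 1e-6)
  expect_equal(eff$exp_estimate[which(eff$level == "M")], 1.1, tolerance = 1e-6)
})

test_that("drift inputs are validated", {
  cells <- drift_cells()
  expect_error(fit_drift_offset(cells$d_ref, c(0, cells$d_ref[-1]),
                                cells[c("age_band", "gender")]),
               "strictly positive", class = "transmort_value_error")
  expect_error(fit_drift_offset(-1 * cells$d_ref, cells$d_ref,
                                cells[c("age_band", "gender")]),
               "non-negative", class = "transmort_value_error")
})

test_that("relative risk compares exponentiated category effects in percent", {
  # six categories engineered so the extremes sit 33% below and 24% above
  # the average ratio, with the middle levels absorbing the log-sum
  eff <- c(0.67, rep(exp(-(log(0.67) + log(1.24)) / 4), 4), 1.24)
  cells <- data.frame(feature_a = paste0("A", 1:6))
  d_ref <- rep(500, 6)
  f <- fit_drift_offset(d_ref * 0.5 * eff, d_ref, cells)
  got <- f$effects[f$effects$feature == "feature_a", ]
  expect_equal(got$exp_estimate[got$level == "A1"], 0.67, tolerance = 1e-8)
  expect_equal(got$exp_estimate[got$level == "A6"], 1.24, tolerance = 1e-8)
  expect_equal(relative_risk(f, "feature_a", "A1", "A6"), 54)
  expect_equal(relative_risk(f, "feature_a", "A3", "A3"), 100)
  expect_error(relative_risk(f, "feature_a", "A1", "A9"), "unknown category")
  expect_error(relative_risk(f, "nope", "A1", "A2"), "no categorical feature")
  # plain arithmetic case: effects 0.5 vs 2.0
  f2 <- fit_drift_offset(c(0.5, 2) * c(300, 300), c(300, 300),
                         data.frame(g = c("lo", "hi")))
  expect_equal(relative_risk(f2, "g", "lo", "hi"), 25)
})
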