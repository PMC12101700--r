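#' Table schemas
#'
#' Four table kinds flow through the pipeline:
#' \describe{
#'   \item{portfolio}{aggregated insured-portfolio cells: `country_id`, `year`,
#'     global features (always `age`, `gender`, `population_mortality`, plus
#'     any further columns), local features (columns prefixed `local_`),
#'     `deaths`, `exposure`.}
#'   \item{population_rates}{national central death rates: `country_id`,
#'     `year`, `age`, `sex`, `rate`.}
#'   \item{indicators}{external country indicators, long: `country_id`,
#'     `item_id`, `value`.}
#'   \item{reference}{a reference (expected) mortality table for the target:
#'     `age`, `gender`, `rate`.}
#' }
#' Local features are carried as `local_`-prefixed columns so a pooled file
#' can hold every country; a column may be `NA` for all rows of a country that
#' lacks that feature, but never for only some of them.
#'
#' @name schemas
NULL

.PORTFOLIO_FIXED <- c("country_id", "year", "deaths", "exposure")
.PORTFOLIO_CORE_GLOBALS <- c("age", "gender", "population_mortality")

.require_columns <- function(df, cols, schema) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .fail("transmort_schema_error", "%s table is missing column(s): %s",
          schema, paste(missing, collapse = ", "))
  }
}

.check_rows <- function(ok, rule, schema) {
  if (!all(ok)) {
    .fail("transmort_validation_error", "%s table: rule '%s' violated at row(s) %s",
          schema, rule, paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
}

#' Validate an aggregated portfolio table
#'
#' @param df data.frame with the portfolio schema columns.
#' @return the validated table, columns in canonical order, with class
#'   `aggregated_portfolio` and attributes `global_features`/`local_features`.
#' @export
as_portfolio <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .require_columns(df, c(.PORTFOLIO_FIXED, .PORTFOLIO_CORE_GLOBALS), "portfolio")
  local <- sort(grep("^local_", names(df), value = TRUE))
  global <- sort(setdiff(names(df), c(.PORTFOLIO_FIXED, local)))
  global <- c(.PORTFOLIO_CORE_GLOBALS, setdiff(global, .PORTFOLIO_CORE_GLOBALS))
  df <- df[, c("country_id", "year", global, local, "deaths", "exposure"), drop = FALSE]
  df$country_id <- as.character(df$country_id)
  df$gender <- as.character(df$gender)
  if (nrow(df)) {
    .check_rows(is.finite(df$exposure) & df$exposure > 0, "exposure > 0", "portfolio")
    .check_rows(is.finite(df$deaths) & df$deaths >= 0, "deaths >= 0", "portfolio")
    .check_rows(df$gender %in% c("F", "M"), "gender in {F, M}", "portfolio")
    .check_rows(is.finite(df$age), "age is numeric", "portfolio")
    # after aggregating identical feature combinations, the cell rate must be a probability-scale rate
    key <- do.call(paste, c(df[setdiff(names(df), c("deaths", "exposure"))], sep = "\r"))
    dsum <- tapply(df$deaths, key, sum)
    esum <- tapply(df$exposure, key, sum)
    if (any(dsum > esum)) {
      .fail("transmort_validation_error",
            "portfolio table: deaths exceed exposure for %d aggregated cell(s)",
            sum(dsum > esum))
    }
    # a local feature is either present (all non-NA) or absent (all NA) within a country
    for (lc in local) {
      bad <- tapply(is.na(df[[lc]]), df$country_id, function(z) any(z) && !all(z))
      if (any(bad)) {
        .fail("transmort_validation_error",
              "portfolio table: local feature '%s' is partially missing within country %s",
              lc, names(bad)[which(bad)[1L]])
      }
    }
  }
  rownames(df) <- NULL
  structure(df, global_features = global, local_features = local,
            class = c("aggregated_portfolio", "data.frame"))
}

#' @export
print.aggregated_portfolio <- function(x, ...) {
  cat(sprintf("Aggregated portfolio: %d rows, %d countries, %s deaths / %s life-years\n",
              nrow(x), length(unique(x$country_id)),
              format(sum(x$deaths), big.mark = ","),
              format(round(sum(x$exposure)), big.mark = ",")))
  cat("Global features:", paste(attr(x, "global_features"), collapse = ", "), "\n")
  if (length(attr(x, "local_features")))
    cat("Local features:", paste(attr(x, "local_features"), collapse = ", "), "\n")
  invisible(x)
}

#' List the global and local feature columns of a portfolio
#' @param x an `aggregated_portfolio`.
#' @param country optional country id: restrict local features to those the
#'   country actually carries (non-`NA`).
#' @return list with elements `global` and `local`.
#' @export
portfolio_features <- function(x, country = NULL) {
  stopifnot(inherits(x, "aggregated_portfolio"))
  local <- attr(x, "local_features")
  if (!is.null(country)) {
    rows <- x$country_id == country
    local <- local[vapply(local, function(lc) !anyNA(x[[lc]][rows]), logical(1))]
  }
  list(global = attr(x, "global_features"), local = local)
}

#' Validate a population mortality rate table
#' @param df data.frame with columns country_id, year, age, sex, rate.
#' @return validated table of class `population_rates`.
#' @export
as_population_rates <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .require_columns(df, c("country_id", "year", "age", "sex", "rate"), "population_rates")
  df <- df[, c("country_id", "year", "age", "sex", "rate")]
  df$country_id <- as.character(df$country_id)
  df$sex <- as.character(df$sex)
  if (nrow(df)) {
    .check_rows(df$sex %in% c("F", "M"), "sex in {F, M}", "population_rates")
    .check_rows(is.finite(df$rate) & df$rate >= 0, "rate >= 0", "population_rates")
    .check_rows(df$age == round(df$age), "age is an integer", "population_rates")
    key <- paste(df$country_id, df$year, df$age, df$sex)
    if (anyDuplicated(key)) {
      .fail("transmort_validation_error",
            "population_rates table: duplicate (country, year, age, sex) key at row %d",
            anyDuplicated(key))
    }
    by <- split(df$age, paste(df$country_id, df$year, df$sex))
    contiguous <- vapply(by, function(a) all(diff(sort(a)) == 1L), logical(1))
    if (!all(contiguous)) {
      .fail("transmort_validation_error",
            "population_rates table: ages not contiguous within (%s)",
            names(by)[which(!contiguous)[1L]])
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("population_rates", "data.frame"))
}

#' Validate an external indicators table
#' @param df data.frame with columns country_id, item_id, value.
#' @param n_items if given, every country must carry exactly this many items.
#' @return validated table of class `external_indicators`.
#' @export
as_indicators <- function(df, n_items = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .require_columns(df, c("country_id", "item_id", "value"), "indicators")
  df <- df[, c("country_id", "item_id", "value")]
  df$country_id <- as.character(df$country_id)
  df$item_id <- as.character(df$item_id)
  if (nrow(df)) {
    if (anyNA(df$value) || !all(is.finite(df$value))) {
      .fail("transmort_validation_error",
            "indicators table: missing/non-finite values are a hard error (no imputation)")
    }
    items <- split(df$item_id, df$country_id)
    ref <- sort(items[[1L]])
    same <- vapply(items, function(it) identical(sort(it), ref), logical(1))
    if (!all(same)) {
      .fail("transmort_validation_error",
            "indicators table: country %s carries a different item set than %s",
            names(items)[which(!same)[1L]], names(items)[1L])
    }
    if (!is.null(n_items) && length(ref) != n_items) {
      .fail("transmort_validation_error",
            "indicators table: %d items per country, expected %d", length(ref), n_items)
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("external_indicators", "data.frame"))
}

#' Validate a reference mortality table
#' @param df data.frame with columns age, gender, rate.
#' @return validated table of class `reference_table`.
#' @export
as_reference_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  .require_columns(df, c("age", "gender", "rate"), "reference")
  df <- df[, c("age", "gender", "rate")]
  df$gender <- as.character(df$gender)
  if (nrow(df)) {
    .check_rows(df$gender %in% c("F", "M"), "gender in {F, M}", "reference")
    .check_rows(is.finite(df$rate) & df$rate > 0, "rate > 0", "reference")
    key <- paste(df$age, df$gender)
    if (anyDuplicated(key)) {
      .fail("transmort_validation_error",
            "reference table: duplicate (age, gender) key at row %d", anyDuplicated(key))
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("reference_table", "data.frame"))
}

.SCHEMA_VALIDATORS <- list(
  portfolio = as_portfolio,
  population_rates = as_population_rates,
  indicators = as_indicators,
  reference = as_reference_table
)

#' Read and validate a pipeline table from CSV
#'
#' Files are comma-separated UTF-8 with a header row and `.` decimal. Column
#' order in the file is free; validation reorders to the canonical layout.
#'
#' @param path CSV file path.
#' @param schema one of `"portfolio"`, `"population_rates"`, `"indicators"`,
#'   `"reference"`.
#' @param hmd_layout for `population_rates` only: the file is an HMD-style
#'   period-rate export with fixed columns `Year`, `Age`, `Female`, `Male`,
#'   `Total` (one country per file); requires `country_id`.
#' @param country_id country label attached when `hmd_layout = TRUE`.
#' @param ... passed to the schema validator (e.g. `n_items`).
#' @return a validated table of the matching class.
#' @export
load_table <- function(path, schema = c("portfolio", "population_rates", "indicators", "reference"),
                       hmd_layout = FALSE, country_id = NULL, ...) {
  schema <- match.arg(schema)
  if (!file.exists(path)) .fail("transmort_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (hmd_layout) {
    if (schema != "population_rates" || is.null(country_id)) {
      .fail("transmort_schema_error",
            "hmd_layout applies to schema 'population_rates' and needs a country_id")
    }
    .require_columns(df, c("Year", "Age", "Female", "Male"), "HMD rates")
    df <- data.frame(
      country_id = country_id,
      year = rep(as.integer(df$Year), 2L),
      age = rep(as.integer(df$Age), 2L),
      sex = rep(c("F", "M"), each = nrow(df)),
      rate = c(as.numeric(df$Female), as.numeric(df$Male)),
      stringsAsFactors = FALSE
    )
  }
  .SCHEMA_VALIDATORS[[schema]](df, ...)
}

#' Write a pipeline table to CSV
#'
#' Canonical column order, comma-separated UTF-8, `.` decimal, character
#' fields quoted, 15 significant digits so that
#' `load_table(write_table(t))` round-trips up to floating-point
#' representation.
#'
#' @param table a validated table (or any data.frame, e.g. a prediction table).
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_table <- function(table, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) .fail("transmort_io_error", "directory does not exist: %s", dir)
  df <- as.data.frame(table)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .fail("transmort_io_error", "cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
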