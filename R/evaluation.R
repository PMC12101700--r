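#' Agreement metrics between rate vectors
#'
#' Three complementary views of how well a transferred mortality schedule
#' matches a reference one, computed on aligned (age, gender) cell vectors:
#' Spearman rank correlation (ordering), cosine similarity (shape,
#' uncentred), and R-squared on mean-centred vectors (variance alignment;
#' insensitive to a uniform level shift, deliberately — level calibration is
#' out of scope).
#'
#' @param x,y,pred,actual numeric vectors of equal length.
#' @return scalar metric value.
#' @name agreement_metrics
NULL

#' @rdname agreement_metrics
#' @details `spearman_rho()` is the Pearson correlation of mid-ranks
#'   (average ranks on ties).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) .fail("transmort_value_error", "need at least 2 cells")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    .fail("transmort_value_error", "Spearman correlation undefined for a constant vector")
  }
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

#' @rdname agreement_metrics
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) .fail("transmort_value_error", "cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' @rdname agreement_metrics
#' @export
centered_r2 <- function(pred, actual) {
  stopifnot(length(pred) == length(actual))
  if (length(pred) < 2L) .fail("transmort_value_error", "need at least 2 cells")
  a <- actual - mean(actual)
  p <- pred - mean(pred)
  if (all(a == 0)) .fail("transmort_value_error", "centered R-squared undefined for constant actuals")
  1 - sum((a - p)^2) / sum(a^2)
}

#' Agreement report of a transfer prediction against a reference table
#'
#' Aggregates the prediction to (age, gender) cells, aligns them with the
#' reference table on the cells present in both, and computes the three
#' agreement metrics on the aligned rate vectors.
#'
#' @param pred a `transfer_prediction` (or an already aggregated data.frame
#'   with columns `age`, `gender`, `mu_hat`).
#' @param reference a `reference_table`.
#' @return object of class `agreement_report`: list with `spearman`,
#'   `cosine`, `r_squared`, `n_cells`, and the aligned `cells` data.frame.
#' @export
agreement_report <- function(pred, reference) {
  stopifnot(inherits(reference, "reference_table"))
  agg <- if (inherits(pred, "transfer_prediction")) aggregate_prediction(pred) else as.data.frame(pred)
  stopifnot(all(c("age", "gender", "mu_hat") %in% names(agg)))
  key_p <- paste(agg$age, agg$gender)
  key_r <- paste(reference$age, reference$gender)
  common <- intersect(key_p, key_r)
  if (length(common) < 2L) .fail("transmort_value_error", "fewer than 2 aligned (age, gender) cells")
  cells <- data.frame(agg[match(common, key_p), c("age", "gender", "mu_hat")],
                      mu_ref = reference$rate[match(common, key_r)])
  structure(list(spearman = spearman_rho(cells$mu_hat, cells$mu_ref),
                 cosine = cosine_similarity(cells$mu_hat, cells$mu_ref),
                 r_squared = centered_r2(cells$mu_hat, cells$mu_ref),
                 n_cells = nrow(cells), cells = cells),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 4, ...) {
  cat(sprintf("Agreement over %d (age, gender) cells:\n", x$n_cells))
  cat(sprintf("  Spearman correlation %.*f\n  Cosine similarity    %.*f\n  Centered R-squared   %.*f\n",
              digits, x$spearman, digits, x$cosine, digits, x$r_squared))
  invisible(x)
}

#' Bootstrap confidence bands for cell-level transferred rates
#'
#' Percentile bootstrap of the synthetic-portfolio uncertainty: rows are
#' resampled with replacement within each origin block (preserving the
#' similarity quotas), cell rates are recomputed from the fitted row-level
#' predictions, and pointwise percentile bounds are taken over the
#' replicates. Row-level predictions are deterministic given the fitted
#' models, so re-aggregating resampled rows is exactly re-predicting the
#' resampled portfolio.
#'
#' @param pred a `transfer_prediction`.
#' @param B number of bootstrap replicates, default 200.
#' @param seed RNG seed.
#' @param level interval level, default 0.95.
#' @param by grouping keys, default `c("age", "gender")`.
#' @return object of class `bootstrap_band`: data.frame of cells with
#'   `mu_hat` (point), `lower`, `upper`; attributes `B`, `level`, `seed`.
#' @export
bootstrap_band <- function(pred, B = 200L, seed = 1L, level = 0.95,
                           by = c("age", "gender")) {
  stopifnot(inherits(pred, "transfer_prediction"))
  if (B < 2L) .fail("transmort_value_error", "need at least 2 bootstrap replicates")
  df <- as.data.frame(pred)
  if ("age" %in% by) df$age <- round(df$age)
  cell <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  cells <- levels(cell)
  cell_i <- as.integer(cell)
  point <- aggregate_prediction(pred, by = by)
  origin_ix <- split(seq_len(nrow(df)), df$origin_country)
  alpha <- (1 - level) / 2
  set.seed(seed)
  reps <- matrix(NA_real_, length(cells), B)
  for (b in seq_len(B)) {
    ix <- unlist(lapply(origin_ix, function(z) z[sample.int(length(z), length(z), replace = TRUE)]),
                 use.names = FALSE)
    dsum <- tabulate2(cell_i[ix], df$d_hat[ix], length(cells))
    esum <- tabulate2(cell_i[ix], df$exposure[ix], length(cells))
    reps[, b] <- dsum / esum
  }
  # order-statistic quantiles (type 6), the canonical percentile-interval rule
  qs <- t(apply(reps, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, type = 6))
  out <- data.frame(point[by], mu_hat = point$mu_hat,
                    lower = qs[match(do.call(paste, c(point[by], sep = ".")), cells), 1L],
                    upper = qs[match(do.call(paste, c(point[by], sep = ".")), cells), 2L])
  structure(out, B = B, level = level, seed = seed,
            class = c("bootstrap_band", "data.frame"))
}

# weighted tabulate: sum of w by integer bin (empty bins stay 0)
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("Bootstrap %d%% bands over %d cells (B = %d)\n",
              round(100 * attr(x, "level")), nrow(x), attr(x, "B")))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
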