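#' Noise-augmentation configuration
#'
#' Controls the similarity-driven data augmentation applied to resampled
#' rows. The noise standard deviation for rows drawn from source `j` is
#' `sigma_j = 1 - s_j + epsilon`, so near-identical countries contribute
#' almost unperturbed rows while dissimilar ones are corrupted more.
#'
#' @param epsilon small positive constant added to the noise sd (default
#'   `1e-6`), keeping it strictly positive even at similarity 1.
#' @param retention_halfwidth categorical features keep their level when a
#'   `N(0, sigma^2)` draw falls inside `[-h, h]`; default `h = 1`, giving
#'   retention probability about 0.68 at similarity 0 and tending to 1 as
#'   similarity tends to 1.
#' @param seed RNG seed for the synthesis stage.
#' @return a `noise_config` list.
#' @export
noise_config <- function(epsilon = 1e-6, retention_halfwidth = 1, seed = 1L) {
  .assert_scalar_num(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(retention_halfwidth, "retention_halfwidth", lower = 0, strict_lower = TRUE)
  structure(list(epsilon = epsilon, retention_halfwidth = retention_halfwidth,
                 seed = as.integer(seed)), class = "noise_config")
}

#' Per-source exposure quotas
#'
#' Splits the synthetic portfolio's total exposure across sources in
#' proportion to their similarity weights; the last source absorbs the
#' floating-point remainder so the quotas sum to the total exactly.
#'
#' @param scores a `similarity_scores` object (weights sum to 1).
#' @param total_exposure total life-years of the synthetic portfolio
#'   (default 1e8).
#' @return named numeric vector of quotas, one per source.
#' @export
exposure_quotas <- function(scores, total_exposure = 1e8) {
  stopifnot(inherits(scores, "similarity_scores"))
  .assert_scalar_num(total_exposure, "total_exposure", lower = 0, strict_lower = TRUE)
  q <- scores$weight * total_exposure
  q[length(q)] <- total_exposure - sum(q[-length(q)])
  stats::setNames(q, scores$country_id)
}

# summary statistics of a source block needed to put noise on a comparable scale
.augment_stats <- function(rows, metric, categorical) {
  list(
    mean = vapply(metric, function(f) mean(rows[[f]]), numeric(1)),
    sd = vapply(metric, function(f) stats::sd(rows[[f]]), numeric(1)),
    levels = lapply(stats::setNames(categorical, categorical),
                    function(f) sort(unique(rows[[f]][!is.na(rows[[f]])])))
  )
}

#' Augment portfolio rows with similarity-scaled noise
#'
#' Metric features get Gaussian noise of sd `sigma` on their standardized
#' scale (per-feature mean/sd of `reference`), then are mapped back to the
#' original scale; age is clamped to the observed age range. For each
#' categorical feature a draw `z ~ N(0, sigma^2)` decides retention: the level
#' is kept when `|z| <= retention_halfwidth`, otherwise replaced by a uniform
#' draw over the feature's observed levels. `deaths` and `exposure` are never
#' touched. A single-row input is the elementary case.
#'
#' @param rows portfolio rows to perturb (data.frame slice of an
#'   `aggregated_portfolio`).
#' @param sigma noise sd, normally `1 - score + epsilon` for the rows' origin.
#' @param config a [noise_config()]; only `retention_halfwidth` is used here
#'   (seeding is the caller's responsibility).
#' @param reference rows defining feature scales, observed levels and the age
#'   range; defaults to `rows` itself.
#' @return the perturbed rows.
#' @export
augment_rows <- function(rows, sigma, config = noise_config(), reference = rows) {
  stopifnot(sigma >= 0)
  feat_cols <- setdiff(names(rows), c("country_id", "year", "deaths", "exposure", "origin_country"))
  metric <- feat_cols[vapply(feat_cols, function(f) is.numeric(reference[[f]]), logical(1))]
  categorical <- setdiff(feat_cols, metric)
  st <- .augment_stats(reference, metric, categorical)
  n <- nrow(rows)
  for (f in metric) {
    if (anyNA(rows[[f]]) || !is.finite(st$sd[[f]]) || st$sd[[f]] == 0) next
    z <- (rows[[f]] - st$mean[[f]]) / st$sd[[f]] + stats::rnorm(n, 0, sigma)
    rows[[f]] <- st$mean[[f]] + st$sd[[f]] * z
  }
  if ("age" %in% metric) {
    rows$age <- pmin(pmax(rows$age, min(reference$age)), max(reference$age))
  }
  for (f in categorical) {
    lev <- st$levels[[f]]
    if (length(lev) < 1L || anyNA(rows[[f]])) next
    corrupt <- abs(stats::rnorm(n, 0, sigma)) > config$retention_halfwidth
    if (any(corrupt)) {
      rows[[f]][corrupt] <- sample(lev, sum(corrupt), replace = TRUE)
    }
  }
  rows
}

# exposure-weighted resampling with replacement until the quota is met;
# the last row is trimmed (deaths pro rata) so the block hits the quota exactly
.resample_to_quota <- function(rows, quota) {
  p <- rows$exposure / sum(rows$exposure)
  mean_draw <- sum(rows$exposure * p)
  idx <- integer(0)
  total <- 0
  while (total < quota) {
    m <- max(16L, ceiling((quota - total) / mean_draw * 1.25))
    take <- sample.int(nrow(rows), m, replace = TRUE, prob = p)
    idx <- c(idx, take)
    total <- total + sum(rows$exposure[take])
  }
  cum <- cumsum(rows$exposure[idx])
  cut <- which(cum >= quota)[1L]
  idx <- idx[seq_len(cut)]
  out <- rows[idx, , drop = FALSE]
  excess <- cum[cut] - quota
  if (excess > 0) {
    keep <- (out$exposure[cut] - excess) / out$exposure[cut]
    out$deaths[cut] <- out$deaths[cut] * keep
    out$exposure[cut] <- out$exposure[cut] - excess
  }
  out
}

#' Generate the synthetic target-country portfolio
#'
#' For each source country: draw rows with replacement (probability
#' proportional to row exposure) until the source's similarity-proportional
#' exposure quota is met, perturb them with that source's noise level
#' `sigma_j = 1 - s_j + epsilon`, and record the origin. The population
#' mortality feature is then replaced by the target country's rate matched on
#' (rounded age, gender), and the blocks are stacked in similarity order.
#'
#' @param sources pooled `aggregated_portfolio` holding every source country.
#' @param scores a [similarity_scores()] object; its countries must all be
#'   present in `sources`.
#' @param target_rates `population_rates` for the target, covering every
#'   (age, sex) cell the synthetic rows can take (one year; with several
#'   years the latest is used — normally the Lee-Carter projected year).
#' @param config a [noise_config()]; its `seed` drives all randomness here.
#' @param total_exposure total life-years of the synthetic portfolio,
#'   default 1e8.
#' @return a `synthetic_portfolio` (an `aggregated_portfolio` with an
#'   `origin_country` column and attributes `quotas`, `sigmas`, `target_id`).
#' @export
synthesize_portfolio <- function(sources, scores, target_rates,
                                 config = noise_config(), total_exposure = 1e8) {
  stopifnot(inherits(sources, "aggregated_portfolio"),
            inherits(scores, "similarity_scores"),
            inherits(target_rates, "population_rates"),
            inherits(config, "noise_config"))
  missing <- setdiff(scores$country_id, unique(sources$country_id))
  if (length(missing)) {
    .fail("transmort_value_error", "scored countries absent from the portfolio: %s",
          paste(missing, collapse = ", "))
  }
  quotas <- exposure_quotas(scores, total_exposure)
  sigmas <- stats::setNames(1 - scores$score + config$epsilon, scores$country_id)
  yr <- max(target_rates$year)
  tr <- target_rates[target_rates$year == yr, ]
  rate_key <- paste(tr$age, tr$sex)

  set.seed(config$seed)
  blocks <- lapply(scores$country_id, function(cc) {
    rows <- as.data.frame(sources[sources$country_id == cc, , drop = FALSE])
    block <- .resample_to_quota(rows, quotas[[cc]])
    block <- augment_rows(block, sigmas[[cc]], config, reference = rows)
    block$origin_country <- cc
    block
  })
  out <- do.call(rbind, blocks)
  hit <- match(paste(round(out$age), out$gender), rate_key)
  if (anyNA(hit)) {
    miss <- unique(paste(round(out$age), out$gender)[is.na(hit)])
    .fail("transmort_value_error",
          "target rates do not cover (age, sex) cell(s): %s",
          paste(utils::head(miss, 10L), collapse = "; "))
  }
  out$population_mortality <- tr$rate[hit]
  rownames(out) <- NULL
  po <- as_portfolio(out[, setdiff(names(out), "origin_country")])
  po$origin_country <- out$origin_country
  structure(po, quotas = quotas, sigmas = sigmas,
            target_id = attr(scores, "target_id"), scores = scores,
            class = c("synthetic_portfolio", class(po)))
}

#' @export
print.synthetic_portfolio <- function(x, ...) {
  cat(sprintf("Synthetic portfolio for target '%s': %d rows, %s life-years\n",
              attr(x, "target_id"), nrow(x),
              format(round(sum(x$exposure)), big.mark = ",")))
  sh <- tapply(x$exposure, x$origin_country, sum) / sum(x$exposure)
  cat("Origin exposure shares:\n")
  print(round(sh[order(-sh)], 4))
  invisible(x)
}
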