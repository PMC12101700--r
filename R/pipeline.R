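#' Pipeline configuration
#'
#' Collects every input and tuning knob of the end-to-end run. Tables can be
#' given as file paths (CSV, read with [load_table()]) or as already
#' validated in-memory tables. A single `seed` is split deterministically
#' into per-stage seeds.
#'
#' @param portfolio pooled source portfolio (path or `aggregated_portfolio`).
#' @param indicators external indicators incl. the target (path or table).
#' @param target_rates population rates for the target country (path or
#'   table).
#' @param target_id target country id.
#' @param reference optional reference mortality table for evaluation and
#'   drift (path or table).
#' @param total_exposure synthetic portfolio total life-years (default 1e8).
#' @param noise a [noise_config()] (its seed is overridden by the split).
#' @param boost a [boost_spec()] (ditto).
#' @param lc_project project the target rates one year ahead by Lee-Carter
#'   before substitution (default TRUE when the rate table has >= 3 years).
#' @param lc_years Lee-Carter fitting window, default `c(2008, 2018)`
#'   clipped to the years available.
#' @param bootstrap_B bootstrap replicates for the confidence bands.
#' @param drift_age_breaks age bands for the drift model's effect table.
#' @param out_dir directory for artifacts; created if missing.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(portfolio, indicators, target_rates, target_id,
                            reference = NULL, total_exposure = 1e8,
                            noise = noise_config(), boost = boost_spec(),
                            lc_project = NULL, lc_years = c(2008, 2018),
                            bootstrap_B = 200L,
                            drift_age_breaks = seq(20, 80, by = 10),
                            out_dir = tempfile("transmort_run_"), seed = 1L) {
  structure(list(portfolio = portfolio, indicators = indicators,
                 target_rates = target_rates, target_id = target_id,
                 reference = reference, total_exposure = total_exposure,
                 noise = noise, boost = boost, lc_project = lc_project,
                 lc_years = lc_years, bootstrap_B = as.integer(bootstrap_B),
                 drift_age_breaks = drift_age_breaks, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the nested
#' blocks `noise:` and `boost:` map onto [noise_config()] and [boost_spec()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("noise", "boost"))]
  if (!is.null(y$noise)) args$noise <- do.call(noise_config, y$noise)
  if (!is.null(y$boost)) args$boost <- do.call(boost_spec, y$boost)
  do.call(pipeline_config, args)
}

.load_if_path <- function(x, schema, ...) {
  if (is.character(x) && length(x) == 1L) load_table(x, schema, ...) else x
}

#' Run the full transfer pipeline
#'
#' Executes the stages in order — similarity scoring, optional Lee-Carter
#' projection of the target's population rates, synthetic-portfolio
#' generation, global and specialized model fitting, prediction, agreement
#' evaluation, drift decomposition and bootstrap bands — writing every
#' artifact as CSV/JSON under `config$out_dir` together with a manifest
#' (config echo, seeds, file checksums). A failing stage aborts with the
#' stage name; the manifest written so far is persisted.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the manifest list, with the in-memory results
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed, 3L)  # synthesis, boosting, bootstrap
  manifest <- list(package_version = as.character(utils::packageVersion("transmort")),
                   seed = config$seed, stage_seeds = seeds,
                   target_id = config$target_id,
                   total_exposure = config$total_exposure,
                   artifacts = character(0))
  res <- list()
  mpath <- file.path(config$out_dir, "manifest.json")
  emit <- function(name, file) {
    manifest$artifacts[[name]] <<- file
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(c(manifest, list(failed_stage = name)), mpath,
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      .fail("transmort_stage_error", "stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  portfolio <- stage("load", .load_if_path(config$portfolio, "portfolio"))
  indicators <- stage("load", .load_if_path(config$indicators, "indicators"))
  target_rates <- stage("load", .load_if_path(config$target_rates, "population_rates"))
  reference <- if (!is.null(config$reference))
    stage("load", .load_if_path(config$reference, "reference")) else NULL

  res$scores <- stage("similarity", similarity_scores(indicators, config$target_id))
  f <- file.path(config$out_dir, "similarity_scores.csv")
  write_table(as.data.frame(res$scores), f); emit("scores", f)

  tgt_years <- sort(unique(target_rates$year[target_rates$country_id == config$target_id]))
  do_lc <- config$lc_project %||% (length(tgt_years) >= 3L)
  rates_used <- target_rates
  if (do_lc) {
    res$lee_carter <- stage("lee_carter", {
      win <- c(max(config$lc_years[1], min(tgt_years)), min(config$lc_years[2], max(tgt_years)))
      fits <- lapply(c("F", "M"), function(sx)
        lee_carter(target_rates, config$target_id, sx, years = win))
      names(fits) <- c("F", "M")
      fits
    })
    rates_used <- stage("lee_carter", as_population_rates(
      do.call(rbind, lapply(res$lee_carter, function(ft) as.data.frame(project_rates(ft, 1L))))))
    f <- file.path(config$out_dir, "target_rates_projected.csv")
    write_table(rates_used, f); emit("projected_rates", f)
  }

  noise <- config$noise; noise$seed <- seeds[1]
  res$synthetic <- stage("synthesize",
    synthesize_portfolio(portfolio, res$scores,
                         rates_used[rates_used$country_id == config$target_id, ],
                         noise, config$total_exposure))
  f <- file.path(config$out_dir, "synthetic_portfolio.csv")
  write_table(as.data.frame(res$synthetic), f); emit("synthetic", f)

  boost <- config$boost; boost$seed <- seeds[2]
  res$model <- stage("train", transfer_model(portfolio, boost))
  f <- file.path(config$out_dir, "models")
  save_transfer_model(res$model, f); emit("models", f)

  res$prediction <- stage("predict", predict_target(res$synthetic, res$model))
  f <- file.path(config$out_dir, "predictions.csv")
  write_table(as.data.frame(res$prediction), f); emit("predictions", f)
  f <- file.path(config$out_dir, "predicted_cells.csv")
  write_table(aggregate_prediction(res$prediction), f); emit("predicted_cells", f)

  if (!is.null(reference)) {
    res$agreement <- stage("evaluate", agreement_report(res$prediction, reference))
    f <- file.path(config$out_dir, "agreement.json")
    jsonlite::write_json(res$agreement[c("spearman", "cosine", "r_squared", "n_cells")],
                         f, auto_unbox = TRUE, digits = NA)
    emit("agreement", f)

    res$drift <- stage("drift", {
      tab <- drift_table(res$prediction, reference, config$drift_age_breaks)
      fit_drift_offset(tab$d_hat, tab$d_ref, tab[c("age_band", "gender")])
    })
    f <- file.path(config$out_dir, "drift_effects.csv")
    write_table(res$drift$effects, f); emit("drift", f)
  }

  res$bands <- stage("bootstrap",
    bootstrap_band(res$prediction, B = config$bootstrap_B, seed = seeds[3]))
  f <- file.path(config$out_dir, "bootstrap_bands.csv")
  write_table(as.data.frame(res$bands), f); emit("bands", f)

  paths <- unlist(manifest$artifacts)
  paths <- paths[file.exists(paths) & !dir.exists(paths)]
  manifest$checksums <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(invisible(manifest), results = res)
}

#' Save / load a fitted transfer model
#'
#' Boosters are stored as the boosting library's raw byte format inside a
#' single RDS container, with a JSON manifest (features, spec, countries)
#' alongside for inspection.
#'
#' @param model a `transfer_model`.
#' @param dir directory to create/use.
#' @return `save_transfer_model`: invisible `dir`; `load_transfer_model`:
#'   the restored `transfer_model`.
#' @export
save_transfer_model <- function(model, dir) {
  stopifnot(inherits(model, "transfer_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(m) { m$booster_raw <- xgboost::xgb.save.raw(m$booster); m$booster <- NULL; m }
  obj <- model
  obj$global <- strip(obj$global)
  obj$specialized <- lapply(obj$specialized, strip)
  saveRDS(obj, file.path(dir, "transfer_model.rds"))
  jsonlite::write_json(list(countries = names(model$specialized),
                            global_features = model$global$features,
                            n_trees_global = model$global$n_trees,
                            spec = unclass(model$spec)),
                       file.path(dir, "model_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_transfer_model
#' @export
load_transfer_model <- function(dir) {
  obj <- readRDS(file.path(dir, "transfer_model.rds"))
  restore <- function(m) { m$booster <- xgboost::xgb.load.raw(m$booster_raw); m$booster_raw <- NULL; m }
  obj$global <- restore(obj$global)
  obj$specialized <- lapply(obj$specialized, restore)
  obj
}
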