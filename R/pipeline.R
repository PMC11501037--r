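# End-to-end orchestration: one call runs filter -> descriptors ->
# archetypal analysis (+ labels, ternary projection) -> RL fits (+ nested
# model comparison) -> requested simulations -> tracking metrics (+
# composition correlations), and writes every table as delimited text
# with a plain-text run manifest.

#' Build a pipeline configuration
#'
#' @param seed master seed; required, every stochastic stage derives a
#'   child seed from it.
#' @param synthetic list passed to [generate_cohort()] (`n_per_profile`,
#'   `days`, `tracking`), or `NULL` when `trial_log` / `event_log` paths
#'   are given.
#' @param trial_log,event_log input paths for real logs (alternative to
#'   `synthetic`).
#' @param min_trials_per_day inclusion threshold (strict).
#' @param aa list: `k`, `n_restarts`, `tol`.
#' @param fit list passed to [fit_config()] (`n_starts`, `v0`).
#' @param sweep `NULL` or list: `dv_grid`, `n_replicates`.
#' @param attribution `NULL` or character vector of modes.
#' @param cross_context run the sucrose-to-nicotine prediction.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, synthetic = list(), trial_log = NULL,
                       event_log = NULL, min_trials_per_day = 5,
                       aa = list(k = 3, n_restarts = 10, tol = 1e-8),
                       fit = list(n_starts = 20, v0 = 0),
                       sweep = list(dv_grid = c(-1, 0, 1, 2, 3),
                                    n_replicates = 20),
                       attribution = c("own", "random_triplet", "shuffle_chi"),
                       cross_context = TRUE) {
  if (missing(seed) || is.null(seed))
    stop2("a master seed is required; refusing silent nondeterminism")
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 trial_log = trial_log, event_log = event_log,
                 min_trials_per_day = min_trials_per_day, aa = aa, fit = fit,
                 sweep = sweep, attribution = attribution,
                 cross_context = cross_context),
            class = "run_config")
}

#' Run the full decision-profiling pipeline
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return invisible list with every stage's tables: `manifest`,
#'   `descriptors`, `composition`, `archetypes_raw`, `fits`, `sweep`,
#'   `attribution`, `cross_context`, `metrics`, `correlations`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  # -- inputs ---------------------------------------------------------
  gt <- NULL; events <- NULL
  if (!is.null(config$trial_log)) {
    co <- stage("read", read_trial_log(config$trial_log))
    if (!is.null(config$event_log)) events <- read_event_log(config$event_log)
  } else {
    args <- config$synthetic
    gen <- stage("synthetic", do.call(generate_cohort, c(
      args[setdiff(names(args), "seed")], list(seed = derive_seed(seed, 1L)))))
    co <- gen$cohort; events <- gen$events; gt <- gen$manifest
  }
  co <- stage("filter", filter_by_trial_rate(co, config$min_trials_per_day))
  # -- descriptors + archetypes ---------------------------------------
  X <- stage("descriptors", descriptor_matrix(co, scaling = "minmax"))
  model <- stage("archetypes", fit_archetypes(
    X, k = config$aa$k %||% 3, n_restarts = config$aa$n_restarts %||% 10,
    tol = config$aa$tol %||% 1e-8, seed = derive_seed(seed, 2L)))
  comp <- stage("composition", composition_table(model))
  # -- RL fits --------------------------------------------------------
  fits <- stage("fit", fit_cohort(co, fit_config(
    n_starts = config$fit$n_starts %||% 20, v0 = config$fit$v0 %||% 0,
    seed = derive_seed(seed, 3L))))
  cohort_fits <- merge(fits[, c("mouse_id", "alpha", "beta", "chi")],
                       comp[, c("mouse_id", "nearest")], by = "mouse_id")
  names(cohort_fits)[names(cohort_fits) == "nearest"] <- "label"
  cohort_fits$trials_per_day <- vapply(co$records[cohort_fits$mouse_id],
                                       function(r) nrow(r$trials) / r$days_observed,
                                       numeric(1))
  # -- simulations ----------------------------------------------------
  sweep_res <- NULL
  if (!is.null(config$sweep)) {
    by_group <- split(cohort_fits, cohort_fits$label)
    sweep_res <- stage("sweep", delta_v_sweep(
      by_group, dv_grid = config$sweep$dv_grid %||% c(-1, 0, 1, 2, 3),
      n_replicates = config$sweep$n_replicates %||% 20,
      seed = derive_seed(seed, 4L)))
  }
  attr_res <- NULL
  if (length(config$attribution)) {
    attr_res <- lapply(config$attribution, function(md)
      stage(paste0("attribution:", md),
            attribution_study(cohort_fits, md, seed = derive_seed(seed, 5L))))
    names(attr_res) <- config$attribution
  }
  cc_res <- NULL
  if (isTRUE(config$cross_context)) {
    cc <- stage("cross_context", cross_context_prediction(
      cohort_fits, seed = derive_seed(seed, 6L)))
    cc_res <- merge(cc, cohort_fits[, c("mouse_id", "label")], by = "mouse_id")
  }
  # -- tracking -------------------------------------------------------
  metrics <- NULL; corrs <- NULL
  if (!is.null(events)) {
    metrics <- stage("tracking", metrics_table(events))
    corrs <- stage("correlations", correlate_with_composition(
      metrics[, c("mouse_id", "nbd", "ena", "NtoF", "FtoN")], comp))
  }
  out <- list(manifest = gt, descriptors = X, composition = comp,
              archetypes_raw = archetypes_raw(model), model = model,
              fits = fits, cohort_fits = cohort_fits,
              sweep = sweep_res, attribution = attr_res,
              cross_context = cc_res, metrics = metrics,
              correlations = corrs, seed = seed)
  if (!is.null(out_dir)) .write_bundle(out, config, out_dir)
  invisible(out)
}

.write_bundle <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (is.null(df)) return(invisible())
    utils::write.table(as.data.frame(df), file.path(out_dir, name), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$manifest)) w(out$manifest, "ground_truth_manifest.csv")
  w(data.frame(mouse_id = attr(out$descriptors, "mouse_ids"),
               unclass(out$descriptors)[, ]), "descriptors.csv")
  w(out$composition, "composition.csv")
  w(data.frame(archetype = label_archetypes(out$model), out$archetypes_raw),
    "archetypes.csv")
  w(out$fits, "fits.csv")
  if (!is.null(out$sweep)) w(out$sweep$summary, "sweep_summary.csv")
  if (!is.null(out$attribution))
    w(do.call(rbind, lapply(names(out$attribution), function(nm)
      cbind(mode = nm, out$attribution[[nm]]$summary))), "attribution_summary.csv")
  w(out$cross_context, "cross_context.csv")
  w(out$metrics, "tracking_metrics.csv")
  if (!is.null(out$correlations)) w(out$correlations$regression, "regression.csv")
  writeLines(c(
    paste0("master_seed: ", out$seed),
    paste0("package_version: ", as.character(utils::packageVersion("forageRL"))),
    paste0("aa_rss: ", format(out$model$rss, digits = 15)),
    paste0("n_mice: ", nrow(out$composition))
  ), file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}
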