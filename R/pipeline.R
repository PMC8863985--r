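#' Run configuration
#'
#' Layered configuration for [run_pipeline]: built-in defaults, overridden
#' by a YAML config file, overridden by direct arguments. Every run writes
#' a provenance record (config snapshot, package version, seed) next to its
#' outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for all randomness in the run.
#' @param config_file Optional YAML file with the same fields.
#' @param ... Direct overrides: `phantom` (list of [phantom_config]
#'   overrides), `metric`, `weighting`, `subsample`, `exclude_ends`,
#'   `write_volumes`, `log_level`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed, config_file = NULL, ...) {
  defaults <- list(phantom = list(), metric = "r1",
                   weighting = "gaussian", subsample = 10L,
                   exclude_ends = 0L, write_volumes = FALSE,
                   log_level = "info")
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(config_file))
  }
  over <- list(...)
  if (length(over) > 0L) cfg <- utils::modifyList(cfg, over)
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

pipe_log <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full phantom pipeline
#'
#' simulate -> segment -> profile -> model, writing standard artifacts to
#' the output directory: `streamlines.tck`, per-bundle `bundles/<name>.tck`
#' with a segmentation report, `profiles.csv` (long format),
#' `models.json` (mean-bundle fits, the three slope models and their LRT),
#' `truth.json` and `provenance.json`. Identical config + seed produces
#' byte-identical CSV/JSON outputs; inputs are never mutated.
#'
#' @param cfg A [run_config].
#' @return Invisibly, a list with the in-memory results (`phantom`,
#'   `bundles`, `profile_tab`, `mean_dev`, `map`, `slope_models`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  pipe_log(cfg, "info", "simulate: generating phantom (seed %d)", cfg$seed)
  pc <- do.call(phantom_config, c(list(seed = cfg$seed), cfg$phantom))
  ph <- generate_phantom(pc, metrics = cfg$metric)
  write_streamlines(ph$streamlines, file.path(cfg$out_dir, "streamlines.tck"))
  jsonlite::write_json(
    list(labels = ph$truth$labels, beta = as.list(ph$truth$beta),
         nodes = ph$truth$nodes, origin = ph$truth$origin),
    file.path(cfg$out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (isTRUE(cfg$write_volumes)) {
    vdir <- file.path(cfg$out_dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (s in ph$sessions)
      write_volume(s[[cfg$metric]],
                   file.path(vdir, sprintf("%s_%s_%s.nii.gz", s$meta$subject_id,
                                           s$meta$timepoint, cfg$metric)))
    write_mask(ph$ventricle_mask, file.path(vdir, "ventricles.nii.gz"))
  }

  pipe_log(cfg, "info", "segment: %d streamlines, %d bundles",
           length(ph$streamlines), length(ph$atlas$definitions))
  bundles <- segment_all(ph$streamlines, ph$atlas)
  bdir <- file.path(cfg$out_dir, "bundles")
  dir.create(bdir, showWarnings = FALSE)
  report <- lapply(bundles, function(b) {
    if (length(b$member_indices) > 0L)
      write_streamlines(
        streamline_set(bundle_members(b, ph$streamlines)),
        file.path(bdir, paste0(b$name, ".tck")))
    list(n_members = length(b$member_indices),
         n_removed_cleaning = b$n_removed_cleaning)
  })
  jsonlite::write_json(report, file.path(bdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pipe_log(cfg, "info", "profile: metric %s, %s weighting",
           cfg$metric, cfg$weighting)
  tabs <- lapply(ph$sessions, function(s) {
    profs <- lapply(bundles[vapply(bundles, function(b)
      length(b$member_indices) > 0L, logical(1))], function(b)
        compute_profile(b, s[[cfg$metric]], weighting = cfg$weighting,
                        set = ph$streamlines, metric = cfg$metric))
    profile_table(profs, s$meta)
  })
  tab <- do.call(rbind, tabs)
  write_profile_table(tab, path = file.path(cfg$out_dir, "profiles.csv"))

  pipe_log(cfg, "info", "model: mean-bundle and slope models")
  mean_dev <- fit_mean_bundle_development(tab, cfg$metric)
  map <- fit_nodewise_development(tab, cfg$metric,
                                  nodes = seq(cfg$subsample, 100,
                                              cfg$subsample))
  sub <- subsample_every_kth(map, cfg$subsample)
  sm <- fit_slope_models(sub)
  fit_json <- function(f) list(
    beta = as.list(f$beta), se = as.list(f$se), pvalue = as.list(f$pvalue),
    r2_marginal = f$r2_marginal, r2_adjusted = f$r2_adjusted,
    loglik = f$loglik, n_obs = f$n_obs, n_groups = f$n_groups,
    var_random_intercept = f$var_random_intercept,
    var_residual = f$var_residual)
  jsonlite::write_json(
    list(mean_bundle = mean_dev$summary,
         slope_model_newborn = fit_json(sm$model1),
         slope_model_spatial = fit_json(sm$model2),
         slope_model_combined = fit_json(sm$model3),
         lrt_combined_vs_spatial = sm$lrt),
    file.path(cfg$out_dir, "models.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)

  jsonlite::write_json(
    list(tool = "babytract",
         version = as.character(utils::packageVersion("babytract")),
         seed = cfg$seed,
         config = unclass(cfg)[setdiff(names(cfg), c("out_dir"))]),
    file.path(cfg$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(phantom = ph, bundles = bundles, profile_tab = tab,
                 mean_dev = mean_dev, map = map, slope_models = sm))
}
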