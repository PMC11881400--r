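## Configuration-driven experiment workflow: a YAML-round-trippable
## experiment config, report export, and the plumbing behind the thin
## command-line interface shipped in inst/cli/qsarcalib.R.

#' Experiment configuration
#'
#' A plain list validated for the experiment runner; round-trips losslessly
#' through YAML via [write_experiment_config()] / [read_experiment_config()].
#'
#' @param data_source one of `"synthetic"`, `"mtx"`, `"table"`.
#' @param synthetic a [synthetic_config()] (used when `data_source =
#'   "synthetic"`).
#' @param paths named list of input paths for the file-backed sources.
#' @param valid_fold,test_fold fold indices of the split.
#' @param cluster_threshold Tanimoto threshold for leader clustering.
#' @param methods study methods.
#' @param hp_metric grid-search metric.
#' @param n_bins metric bins.
#' @param n_repeats,n_ensemble_repeats,n_members,n_passes repeat settings.
#' @param hmc an [hmc_config()].
#' @param seed master seed.
#' @param outdir output directory.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(data_source = "synthetic",
                              synthetic = synthetic_config(),
                              paths = list(),
                              valid_fold = 3L, test_fold = 4L,
                              cluster_threshold = 0.6,
                              methods = c("mlp", "mlp_p", "hbll"),
                              hp_metric = "bce", n_bins = 10L,
                              n_repeats = 10L, n_ensemble_repeats = 5L,
                              n_members = 50L, n_passes = 100L,
                              hmc = hmc_config(), seed = 1L,
                              outdir = "qsarcalib_run") {
  if (!data_source %in% c("synthetic", "mtx", "table"))
    stop("unknown data_source: ", data_source)
  structure(list(data_source = data_source, synthetic = synthetic,
                 paths = paths, valid_fold = as.integer(valid_fold),
                 test_fold = as.integer(test_fold),
                 cluster_threshold = cluster_threshold,
                 methods = methods, hp_metric = hp_metric,
                 n_bins = as.integer(n_bins),
                 n_repeats = as.integer(n_repeats),
                 n_ensemble_repeats = as.integer(n_ensemble_repeats),
                 n_members = as.integer(n_members),
                 n_passes = as.integer(n_passes),
                 hmc = hmc, seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return invisibly `path`, or the restored config.
#' @export
write_experiment_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$synthetic <- unclass(obj$synthetic)
  obj$hmc <- unclass(obj$hmc)
  obj$hmc$inverse_mass_matrix <- NULL    # always recomputed from the MAP
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, obj$synthetic)
  hmc <- do.call(hmc_config, obj$hmc)
  experiment_config(data_source = obj$data_source, synthetic = syn,
                    paths = obj$paths, valid_fold = obj$valid_fold,
                    test_fold = obj$test_fold,
                    cluster_threshold = obj$cluster_threshold,
                    methods = unlist(obj$methods), hp_metric = obj$hp_metric,
                    n_bins = obj$n_bins, n_repeats = obj$n_repeats,
                    n_ensemble_repeats = obj$n_ensemble_repeats,
                    n_members = obj$n_members, n_passes = obj$n_passes,
                    hmc = hmc, seed = obj$seed, outdir = obj$outdir)
}

#' Export study results
#'
#' Writes the per-repeat table, the aggregate (mean and sd per method and
#' metric), the pairwise t-test matrix, the per-bin reliability data of the
#' last evaluation, a machine-readable JSON manifest of every effective
#' setting and seed, and a short human-readable run log. Errors out before
#' creating anything if the results are empty.
#'
#' @param study a `study_result` from [run_study()].
#' @param outdir output directory (created).
#' @return invisibly, the named vector of files written.
#' @export
write_report <- function(study, outdir) {
  if (!inherits(study, "study_result") || !nrow(study$per_repeat))
    stop("empty study results")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(per_repeat = file.path(outdir, "per_repeat.csv"),
             aggregate = file.path(outdir, "aggregate.csv"),
             ttests = file.path(outdir, "ttests.csv"),
             manifest = file.path(outdir, "manifest.json"),
             log = file.path(outdir, "run.log"))
  data.table::fwrite(study$per_repeat, files["per_repeat"])
  data.table::fwrite(study$aggregate, files["aggregate"])
  if (length(study$ttests)) data.table::fwrite(study$ttests, files["ttests"])
  manifest <- list(schema = "qsarcalib/manifest/1",
                   package_version = as.character(utils::packageVersion("qsarcalib")),
                   methods = study$methods,
                   base_seed = study$base_seed,
                   n_repeats = study$n_repeats,
                   n_ensemble_repeats = study$n_ensemble_repeats,
                   n_members = study$n_members,
                   n_passes = study$n_passes,
                   n_bins = study$n_bins,
                   prior_precision = study$prior_precision,
                   mlp_config = unclass(study$config))
  jsonlite::write_json(manifest, files["manifest"], digits = NA,
                       auto_unbox = TRUE)
  writeLines(c(sprintf("qsarcalib study: %d method(s), base seed %d",
                       length(study$methods), study$base_seed),
               utils::capture.output(print(study))),
             files["log"])
  invisible(files)
}

#' Materialize the dataset described by an experiment config
#'
#' Synthetic sources are generated; file-backed sources are read, leader
#' clustered at the configured threshold and assigned to folds.
#'
#' @param cfg an [experiment_config()].
#' @return a [bioactivity_dataset()] with folds.
#' @export
load_experiment_data <- function(cfg) {
  if (cfg$data_source == "synthetic") {
    return(gen_fingerprint_dataset(cfg$synthetic)$data)
  }
  data <- if (cfg$data_source == "mtx") {
    read_feature_mtx(cfg$paths$mtx, cfg$paths$labels)
  } else {
    load_compound_table(cfg$paths$table, cfg$paths$smiles_column,
                        cfg$paths$label_column,
                        pic50_threshold = cfg$paths$pic50_threshold)
  }
  cl <- leader_cluster(data$features, cfg$cluster_threshold,
                       order_seed = cfg$seed)
  fold <- assign_folds(cl, seed = cfg$seed)
  bioactivity_dataset(data$features, data$labels, cl, fold)
}

#' Run a configured experiment end to end
#'
#' Loads (or generates) the data, builds the split, runs the study and
#' writes the report to `cfg$outdir`.
#'
#' @param cfg an [experiment_config()].
#' @param mlp_cfg baseline [mlp_config()]; default a small regularized
#'   network seeded from `cfg$seed`.
#' @return the `study_result`, invisibly.
#' @export
run_experiment <- function(cfg, mlp_cfg = NULL) {
  data <- load_experiment_data(cfg)
  split <- make_split(cfg$valid_fold, cfg$test_fold)
  if (is.null(mlp_cfg))
    mlp_cfg <- mlp_config(hidden_size = 32L, dropout_rate = 0.2,
                          seed = cfg$seed)
  study <- run_study(data, split, mlp_cfg, methods = cfg$methods,
                     n_repeats = cfg$n_repeats,
                     n_ensemble_repeats = cfg$n_ensemble_repeats,
                     n_members = cfg$n_members, n_passes = cfg$n_passes,
                     hmc = cfg$hmc, n_bins = cfg$n_bins,
                     base_seed = cfg$seed)
  write_report(study, cfg$outdir)
  invisible(study)
}
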