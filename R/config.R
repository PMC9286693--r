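# Experiment orchestration: a serializable config, deterministic seed
# derivation per stage, and an end-to-end run writing tidy outputs plus a
# manifest.

#' Build an experiment configuration
#'
#' All knobs of an end-to-end run in one serializable (YAML) list.  Every
#' stochastic stage derives its seed from `master_seed` via [derive_seed()]
#' with a fixed stage counter, so a config reproduces its results
#' bit-identically.
#'
#' @param n_pairs,disyllabic_count,sem_ones_target,n_sem_clusters synthetic
#'   lexicon parameters (see [generate_synthetic_lexicon()]); or supply
#'   `lexicon_path` to load a TSV lexicon instead.
#' @param lexicon_path optional path to a saved lexicon.
#' @param arch list of [arch_spec()] overrides.
#' @param exposure_ratios list of the two versions' exposure weights.
#' @param epochs,batch_size,lr,corruption_sd,modality_dropout,pretrain_epochs
#'   training parameters.
#' @param offline_sds,positions,offline_repetitions offline test grid.
#' @param online_sds,timesteps,online_repetitions online test grid.
#' @param mechanistic_sds,mechanistic_repetitions mechanistic conditions.
#' @param target_language language of the simulated experiments.
#' @param replications trained replications per version.
#' @param master_seed integer master seed.
#' @param out_dir output directory.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_pairs = 121L,
                              disyllabic_count = c(A = 39L, B = 45L),
                              sem_ones_target = 52.7,
                              n_sem_clusters = 12L,
                              lexicon_path = NULL,
                              arch = list(),
                              exposure_ratios = list(native = c(1, 3),
                                                     nonnative = c(3, 1)),
                              epochs = 5000L, batch_size = 128L, lr = 0.05,
                              corruption_sd = 0.1, modality_dropout = 0.5,
                              pretrain_epochs = 50L,
                              offline_sds = c(0, 0.3, 0.6, 0.9),
                              positions = c("initial", "final"),
                              offline_repetitions = 10L,
                              online_sds = c(0, 0.3, 0.6),
                              timesteps = 0:5,
                              online_repetitions = 10L,
                              mechanistic_sds = c(0, 0.75),
                              mechanistic_repetitions = 5L,
                              target_language = "B",
                              replications = 5L,
                              master_seed = 1L,
                              out_dir = "results") {
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  cfg
}

#' Save / load an experiment config as YAML
#' @param config an `experiment_config`.
#' @param path file path.
#' @return `load_config` returns the config; `save_config` the path,
#'   invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$disyllabic_count <- as.list(x$disyllabic_count)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$disyllabic_count <- unlist(x$disyllabic_count)
  cfg <- do.call(experiment_config, x[names(x) %in%
                                        names(formals(experiment_config))])
  cfg
}

#' Train both model versions of an experiment
#'
#' @param config an `experiment_config`.
#' @param lexicon the lexicon to train on.
#' @return named list (per version) of lists of trained replications.
#' @export
train_versions <- function(config, lexicon) {
  archs <- do.call(arch_spec, config$arch)
  out <- list()
  for (vi in seq_along(config$exposure_ratios)) {
    version <- names(config$exposure_ratios)[vi]
    out[[version]] <- lapply(seq_len(config$replications), function(ri) {
      train_model(lexicon,
                  exposure_ratio = config$exposure_ratios[[vi]],
                  arch = archs,
                  pretrain_epochs = config$pretrain_epochs,
                  seed = derive_seed(config$master_seed, 100L * vi + ri),
                  epochs = config$epochs, batch_size = config$batch_size,
                  lr = config$lr, corruption_sd = config$corruption_sd,
                  modality_dropout = config$modality_dropout)
    })
  }
  out
}

#' Run a full experiment end to end
#'
#' Generates or loads the lexicon, trains the native and non-native
#' versions, runs the offline and online simulations (trained model and
#' Input-based baseline), the mechanistic and RSA analyses and the effect
#' model, and writes all outputs as CSV/TSV plus a manifest (config hash,
#' seed, package version) to `config$out_dir`.
#'
#' @param config an `experiment_config`.
#' @return (invisibly) a list with the in-memory results.
#' @export
run_experiment <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] started")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message("[", name, "] done in ",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s")
    res
  }
  lexicon <- stage("lexicon", {
    if (!is.null(config$lexicon_path)) load_lexicon(config$lexicon_path)
    else generate_synthetic_lexicon(
      n_pairs = config$n_pairs, disyllabic_count = config$disyllabic_count,
      sem_ones_target = config$sem_ones_target,
      n_sem_clusters = config$n_sem_clusters,
      seed = derive_seed(config$master_seed, 1L))
  })
  save_lexicon(lexicon, file.path(config$out_dir, "lexicon.tsv"))
  models <- stage("train", train_versions(config, lexicon))

  offline <- stage("offline", run_offline_experiment(
    models, lexicon, target_language = config$target_language,
    noise_sds = config$offline_sds, positions = config$positions,
    repetitions = config$offline_repetitions,
    seed = derive_seed(config$master_seed, 2L)))
  offline_ib <- stage("offline_input_based", run_offline_experiment(
    models[1L], lexicon, target_language = config$target_language,
    noise_sds = config$offline_sds, positions = config$positions,
    repetitions = config$offline_repetitions,
    seed = derive_seed(config$master_seed, 2L), decoder = "input"))
  displays <- stage("displays", build_displays(lexicon, config$target_language))
  online <- stage("online", run_online_experiment(
    models, lexicon, displays, target_language = config$target_language,
    noise_sds = config$online_sds, timesteps = config$timesteps,
    repetitions = config$online_repetitions,
    seed = derive_seed(config$master_seed, 3L)))
  mech <- stage("mechanistic", run_mechanistic(
    models, lexicon, target_language = config$target_language,
    noise_sds = config$mechanistic_sds, timesteps = setdiff(config$timesteps, 0L),
    repetitions = config$mechanistic_repetitions,
    seed = derive_seed(config$master_seed, 4L)))
  effects <- stage("stats", effect_model_accuracy(offline))

  wr <- function(df, name)
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  wr(offline, "offline_trials.csv")
  wr(summarize_offline(offline), "offline_summary.csv")
  wr(summarize_offline(offline_ib), "offline_input_based_summary.csv")
  wr(online$series, "online_series.csv")
  wr(online$items, "online_items.csv")
  wr(mech$accuracy, "mechanistic_accuracy.csv")
  wr(mech$cumulative_errors, "mechanistic_cumulative_errors.csv")
  wr(mech$ranks, "mechanistic_ranks.csv")
  wr(mech$rsa, "mechanistic_rsa.csv")
  wr(effects, "effect_model.csv")

  cfg_path <- file.path(config$out_dir, "config.yaml")
  save_config(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   master_seed = config$master_seed,
                   package_version =
                     as.character(utils::packageVersion("noisylex")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(lexicon = lexicon, models = models, offline = offline,
                 offline_input_based = offline_ib, online = online,
                 mechanistic = mech, effects = effects, manifest = manifest))
}
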