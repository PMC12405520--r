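pipeline_schema <- function() list(
  sim = names(formals(sim_config)),
  model = c("d_slide", "attn_hidden", "d", "n_tokens", "n_heads", "n_experts",
            "top_k", "boost", "expert_hidden", "token_hidden", "gate_from"),
  train = names(formals(train_config)),
  eval = c("n_times", "by_cancer", "km_split"),
  heatmap = c("alpha", "downsample")
)

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0L) {
    stop_pcm(sprintf("unknown config section(s): %s",
                     paste(unknown, collapse = ", ")), "config_error")
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad) > 0L) {
      stop_pcm(sprintf("unknown key(s) in config section '%s': %s",
                       sec, paste(bad, collapse = ", ")), "config_error")
    }
  }
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

need_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop_pcm(sprintf("'%s' not found: run the '%s' stage before '%s'",
                     path, stage, needed_by), "missing_artifact")
  }
  path
}

#' Run the end-to-end pipeline
#'
#' Wires the stages `simulate -> train -> evaluate -> heatmap` over a single
#' structured configuration with per-stage sections (unknown keys are
#' rejected with a field-level message). Every stage writes its outputs under
#' `out_dir` and appends to a run manifest recording the produced files, the
#' effective configuration and its hash, the package version and the seed;
#' deterministic stages are idempotent for a fixed config and seed.
#'
#' @param config Named list with optional sections `sim`, `model`, `train`,
#'   `eval`, `heatmap`, or the path to a YAML file with the same structure.
#' @param stages Character subset of
#'   `c("simulate", "train", "evaluate", "heatmap")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed from which all stage seeds are derived.
#' @return Invisibly, a list with the effective config and the paths of
#'   produced artifacts.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "train", "evaluate"),
                         out_dir = "pancanmil_run", seed = 0L) {
  stages <- match.arg(stages, c("simulate", "train", "evaluate", "heatmap"),
                      several.ok = TRUE)
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- character()
  manifest_path <- file.path(out_dir, "manifest.tsv")
  bags_dir <- file.path(out_dir, "bags")
  oof_path <- file.path(out_dir, "oof_predictions.tsv")

  if ("simulate" %in% stages) {
    scfg <- do.call(sim_config, config$sim %||% list())
    sim <- simulate_cohort(scfg, seed = derive_seed(seed, 1L))
    write_tsv(sim$manifest, manifest_path)
    dir.create(bags_dir, showWarnings = FALSE)
    for (p in sim$cohort$patients) {
      for (b in p$bags) write_bag(b, file.path(bags_dir, paste0(b$slide_id, ".bag")))
    }
    truth_df <- sim$truth
    truth_df$informative <- NULL
    write_tsv(truth_df, file.path(out_dir, "truth.tsv"))
    produced <- c(produced, manifest_path, bags_dir,
                  file.path(out_dir, "truth.tsv"))
  }

  if ("train" %in% stages) {
    need_artifact(manifest_path, "simulate (or preprocess)", "train")
    need_artifact(bags_dir, "simulate (or preprocess)", "train")
    cohort <- load_cohort_bags(read_manifest(manifest_path), bags_dir)
    margs <- config$model %||% list()
    mcfg <- do.call(model_config,
                    c(list(D = cohort$D, K = cohort$K), margs))
    targs <- config$train %||% list()
    targs$seed <- targs$seed %||% derive_seed(seed, 2L)
    tcfg <- do.call(train_config, targs)
    fit <- fit_survival_model(cohort, mcfg, tcfg)
    for (f in seq_along(fit$models)) {
      save_checkpoint(fit$models[[f]],
                      file.path(out_dir, sprintf("checkpoint_fold%d.rds", f)))
    }
    write_tsv(fit$oof, oof_path)
    write_tsv(fit$logs, file.path(out_dir, "training_logs.tsv"))
    produced <- c(produced, oof_path, file.path(out_dir, "training_logs.tsv"))
  }

  if ("evaluate" %in% stages) {
    need_artifact(oof_path, "train", "evaluate")
    oof <- utils::read.delim(oof_path)
    eargs <- config$eval %||% list()
    report <- do.call(aggregate_cv, c(list(predictions = oof), eargs))
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      overall = list(
        n = report$overall$n, n_events = report$overall$n_events,
        c_index = as.numeric(report$overall$c_index),
        td_auc = as.numeric(report$overall$td_auc),
        logrank_chisq = report$overall$logrank$chisq,
        logrank_p = as.numeric(report$overall$logrank$p)),
      per_cancer = report$per_cancer,
      km = list(low = as.data.frame(report$overall$km_low),
                high = as.data.frame(report$overall$km_high))
    ), report_path, auto_unbox = TRUE, digits = 10)
    write_tsv(tidy(report), file.path(out_dir, "metrics.tsv"))
    produced <- c(produced, report_path, file.path(out_dir, "metrics.tsv"))
  }

  if ("heatmap" %in% stages) {
    ckpt <- file.path(out_dir, "checkpoint_fold1.rds")
    need_artifact(ckpt, "train", "heatmap")
    need_artifact(manifest_path, "simulate (or preprocess)", "heatmap")
    model <- load_checkpoint(ckpt)
    cohort <- load_cohort_bags(read_manifest(manifest_path), bags_dir)
    hargs <- config$heatmap %||% list()
    hm <- attention_heatmap(cohort$patients[[1L]], model,
                            downsample = hargs$downsample %||% 32)
    hm_path <- file.path(out_dir, "heatmap_patient1.tsv")
    utils::write.table(hm$raster, hm_path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    produced <- c(produced, hm_path)
  }

  run_info <- list(
    package_version = as.character(utils::packageVersion("pancanmil")),
    seed = seed, stages = stages, config = config,
    config_hash = rlang::hash(config), produced = produced,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(run_info, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(config = config, produced = produced, out_dir = out_dir))
}
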