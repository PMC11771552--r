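#' Default pipeline configuration
#'
#' A nested key-value configuration covering every stage of the
#' synthetic end-to-end analysis. A single global \code{seed} fans out
#' to fixed per-stage seeds so that, for example, changing the sweep
#' does not perturb the simulated cohort.
#'
#' @param seed global seed.
#' @return nested list with sections \code{sim}, \code{cohort},
#'   \code{features}, \code{model}, \code{train}, \code{sweep},
#'   \code{interpret}.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       sim = list(n_patients = 1131L),
       cohort = list(followup_days = 1095L),
       features = list(seq_len = 128L, p_demo = 0.9, p_survey = 0.8),
       model = list(d_model = 32L, n_heads = 4L, n_layers = 2L, d_ff = 32L,
                    dropout = 0.1, time_scale = 30, demo_hidden = 4L,
                    survey_hidden = 4L),
       train = list(learning_rate = 0.001, epochs = 20L, pos_weight = 3.0,
                    batch_size = 64L, decision_threshold = 0.5,
                    max_overfit_gap = 0.10,
                    split_fractions = c(train = 0.70, validation = 0.05,
                                        test = 0.25)),
       sweep = list(weights = c(1.0, 3.0, 5.0)),
       interpret = list(repeats = 10L, top_k = 5L))
}

validate_config <- function(config) {
  ref <- default_pipeline_config()
  check <- function(cfg, tmpl, path) {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown) > 0) {
      stop("unknown config key(s) ", paste0(path, unknown, collapse = ", "),
           "; valid keys: ", paste0(path, names(tmpl), collapse = ", "))
    }
  }
  check(config, ref, "")
  for (sec in intersect(names(config), names(ref))) {
    if (is.list(ref[[sec]])) check(config[[sec]], ref[[sec]], paste0(sec, "$"))
  }
  merged <- utils::modifyList(default_pipeline_config(), config)
  if (merged$train$pos_weight <= 0) stop("train$pos_weight must be > 0")
  if (merged$train$epochs < 1) stop("train$epochs must be >= 1")
  merged
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11, split = 23, model = 37, train = 41,
               interpret = 53)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% 2147483647)
}

artifact <- function(out_dir, ...) file.path(out_dir, ...)

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run stage '", produced_by,
         "' first")
  }
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the synthetic end-to-end analysis behind named stages:
#' \describe{
#'   \item{simulate}{generate the synthetic cohort tables (CSV).}
#'   \item{phenotype}{assemble timelines and derive chronic-pain labels.}
#'   \item{prepare}{split, fit encoders on the training split, encode
#'     features.}
#'   \item{train}{fit the classifier; write per-epoch history.}
#'   \item{evaluate}{metrics on the train and test splits.}
#'   \item{sweep}{positive-weight sweep.}
#'   \item{interpret}{permutation importance and top attention
#'     connections.}
#'   \item{all}{everything above, in dependency order.}
#' }
#' Re-running a stage with unchanged inputs and config reproduces
#' byte-identical outputs. A manifest with seeds, stage timings and
#' content hashes of produced files is written after every run.
#'
#' @param stage one of the stage names above.
#' @param config nested configuration, see
#'   \code{\link{default_pipeline_config}}; either a list or the path of
#'   a YAML file with the same structure. Partial configs are merged
#'   over the defaults and unknown keys are rejected.
#' @param out_dir directory for all artifacts.
#' @return invisibly, a list with the produced artifact paths.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "phenotype", "prepare",
                                   "train", "evaluate", "sweep", "interpret"),
                         config = list(), out_dir = "pipeline_out") {
  stage <- match.arg(stage)
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "phenotype", "prepare", "train", "evaluate", "sweep",
      "interpret")
  } else {
    stage
  }
  timings <- numeric(0)
  produced <- character(0)
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    produced <- c(produced, run_stage(st, config, out_dir))
    timings[st] <- round(proc.time()[["elapsed"]] - t0, 2)
    message(sprintf("[painattn] stage %-9s done in %6.1fs", st, timings[st]))
  }
  write_manifest(out_dir, config, timings, produced)
  invisible(list(artifacts = produced, timings = timings))
}

run_stage <- function(st, config, out_dir) {
  switch(st,
    simulate = stage_simulate(config, out_dir),
    phenotype = stage_phenotype(config, out_dir),
    prepare = stage_prepare(config, out_dir),
    train = stage_train(config, out_dir),
    evaluate = stage_evaluate(config, out_dir),
    sweep = stage_sweep(config, out_dir),
    interpret = stage_interpret(config, out_dir))
}

stage_simulate <- function(config, out_dir) {
  sim_args <- config$sim
  sim_args$seed <- stage_seed(config$seed, "simulate")
  scfg <- do.call(sim_config, sim_args)
  tables <- generate_cohort(scfg)
  tdir <- artifact(out_dir, "tables")
  write_tables(tables, tdir)
  truth_path <- artifact(out_dir, "synthetic_truth.csv")
  write.csv(attr(tables, "truth"), truth_path, row.names = FALSE)
  c(file.path(tdir, cohort_table_files()), truth_path)
}

pipeline_cohort <- function(config, out_dir) {
  tdir <- artifact(out_dir, "tables")
  require_artifact(file.path(tdir, "persons.csv"), "simulate")
  tables <- read_tables(tdir)
  ccfg <- do.call(cohort_config, config$cohort)
  list(cohort = extract_cohort(tables, ccfg), cohort_config = ccfg)
}

stage_phenotype <- function(config, out_dir) {
  env <- pipeline_cohort(config, out_dir)
  labels <- derive_labels(env$cohort, env$cohort_config)
  path <- artifact(out_dir, "labels.csv")
  write.csv(labels, path, row.names = FALSE)
  path
}

stage_prepare <- function(config, out_dir) {
  labels_path <- require_artifact(artifact(out_dir, "labels.csv"), "phenotype")
  env <- pipeline_cohort(config, out_dir)
  labels_df <- read.csv(labels_path, colClasses = c(patient_id = "character"))
  ids <- vapply(env$cohort, `[[`, character(1), "patient_id")
  y <- as.numeric(labels_df$positive[match(ids, labels_df$patient_id)])
  splits <- split_dataset(y, config$train$split_fractions,
                          seed = stage_seed(config$seed, "split"))
  features <- prepare_features(env$cohort, splits,
                               seq_len = config$features$seq_len,
                               p_demo = config$features$p_demo,
                               p_survey = config$features$p_survey)
  labels_by_split <- lapply(splits, function(idx) y[idx])
  obj <- list(features = features, splits = splits, labels = labels_by_split,
              patient_ids = ids)
  path <- artifact(out_dir, "features.rds")
  saveRDS(obj, path)
  schema_path <- artifact(out_dir, "feature_schema.json")
  write_feature_schema(features, schema_path)
  c(path, schema_path)
}

load_prepared <- function(out_dir) {
  readRDS(require_artifact(artifact(out_dir, "features.rds"), "prepare"))
}

pipeline_model_config <- function(config, prep) {
  margs <- config$model
  margs$vocab_size <- prep$features$vocab$size
  margs$demo_dim <- prep$features$demo_dim
  margs$survey_dim <- prep$features$survey_dim
  margs$seq_len <- config$features$seq_len
  margs$seed <- stage_seed(config$seed, "model")
  do.call(model_config, margs)
}

pipeline_train_config <- function(config) {
  targs <- config$train
  targs$seed <- stage_seed(config$seed, "train")
  do.call(train_config, targs)
}

stage_train <- function(config, out_dir) {
  prep <- load_prepared(out_dir)
  mcfg <- pipeline_model_config(config, prep)
  tcfg <- pipeline_train_config(config)
  fit <- train_model(prep$features, prep$labels, mcfg, tcfg)
  model_path <- artifact(out_dir, "model.rds")
  save_model(fit$params, model_path)
  hist_path <- artifact(out_dir, "history.csv")
  write.csv(fit$history, hist_path, row.names = FALSE)
  c(model_path, hist_path)
}

stage_evaluate <- function(config, out_dir) {
  prep <- load_prepared(out_dir)
  params <- load_model(require_artifact(artifact(out_dir, "model.rds"),
                                        "train"))
  thr <- config$train$decision_threshold
  rows <- lapply(c("train", "test"), function(s) {
    rep <- evaluate_model(params, prep$features$splits[[s]], prep$labels[[s]],
                          thr, split = s)
    data.frame(split = s, n = rep$n, accuracy = rep$accuracy,
               auroc = rep$auroc, precision = rep$precision,
               recall = rep$recall,
               tn = rep$confusion[1, 1], fp = rep$confusion[1, 2],
               fn = rep$confusion[2, 1], tp = rep$confusion[2, 2])
  })
  path <- artifact(out_dir, "metrics.csv")
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  path
}

stage_sweep <- function(config, out_dir) {
  prep <- load_prepared(out_dir)
  mcfg <- pipeline_model_config(config, prep)
  tcfg <- pipeline_train_config(config)
  tab <- pos_weight_sweep(prep$features, prep$labels, mcfg, tcfg,
                          weights = config$sweep$weights)
  path <- artifact(out_dir, "sweep.csv")
  write.csv(tab, path, row.names = FALSE)
  path
}

stage_interpret <- function(config, out_dir) {
  prep <- load_prepared(out_dir)
  params <- load_model(require_artifact(artifact(out_dir, "model.rds"),
                                        "train"))
  test_batch <- prep$features$splits$test
  imp <- permutation_importance(params, test_batch, prep$labels$test,
                                repeats = config$interpret$repeats,
                                seed = stage_seed(config$seed, "interpret"))
  imp_path <- artifact(out_dir, "importance.csv")
  write.csv(as.data.frame(imp), imp_path, row.names = FALSE)

  # attention connections for the first test patient with >= 2 real events
  n_real <- rowSums(test_batch$mask)
  pick <- which(n_real >= 2)[1L]
  conn_path <- artifact(out_dir, "connections.csv")
  if (!is.na(pick)) {
    seqx <- list(tokens = test_batch$tokens[pick, ],
                 timestamps = test_batch$timestamps[pick, ],
                 mask = as.logical(test_batch$mask[pick, ]))
    class(seqx) <- "tokenized_sequence"
    attn <- attention_weights(params, seqx)
    conn <- top_connections(attn, seqx, prep$features$vocab,
                            k = config$interpret$top_k)
    write.csv(as.data.frame(conn), conn_path, row.names = FALSE)
  } else {
    write.csv(data.frame(), conn_path, row.names = FALSE)
  }
  c(imp_path, conn_path)
}

write_manifest <- function(out_dir, config, timings, produced) {
  lines <- c(paste0("seed=", config$seed),
             paste0("stage_seed.", names(stage_seed_table(config$seed)), "=",
                    stage_seed_table(config$seed)),
             paste0("timing.", names(timings), "=", timings, "s"))
  produced <- unique(produced[file.exists(produced)])
  hashes <- tools::md5sum(produced)
  lines <- c(lines, paste0("md5.", basename(produced), "=", hashes))
  writeLines(lines, artifact(out_dir, "run_manifest.txt"))
}

stage_seed_table <- function(seed) {
  stages <- c("simulate", "split", "model", "train", "interpret")
  stats::setNames(vapply(stages, function(s) stage_seed(seed, s), integer(1)),
                  stages)
}
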