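#' End-to-end pipeline configuration
#'
#' One declarative object binding every stage: synthetic-repository
#' generation, preparation (QC, standardization, deduplication), dictionary
#' projection, label extraction and enrichment, model training, evaluation
#' and interpretation. Defaults mirror the reference setting: stacked
#' positive-part representation, one rectifier hidden layer of width 300,
#' dropout 0.2, l1 = l2 = 0.001, WR cutoff k = 10. The global seed
#' propagates to every stochastic stage.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global integer seed.
#' @param grid_shape 3-D array shape of the common grid.
#' @param dict_sizes component counts of the dictionaries, highest first
#'   (the first one generates the synthetic signal).
#' @param n_concepts,n_synonym_pairs,max_depth ontology parameters.
#' @param synth a \code{\link{synth_config}}; its seed is overridden by
#'   \code{seed}.
#' @param qc named list of \code{\link{qc_filter}} thresholds.
#' @param labeling named list: \code{min_count}, \code{max_abs_corr},
#'   optional \code{rules} (a \code{\link{ruleset}}), applied to training
#'   collections only.
#' @param positive use the positive-part representation.
#' @param model named list of \code{\link{model_config}} fields plus
#'   \code{epochs}, \code{batch_size}, \code{learning_rate}.
#' @param eval named list: \code{k}, \code{test_collections}.
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            grid_shape = c(11L, 13L, 11L),
                            dict_sizes = c(64L, 32L, 16L),
                            n_concepts = 20L, n_synonym_pairs = 4L,
                            max_depth = 3L,
                            synth = synth_config(),
                            qc = list(coverage_min = 0.5,
                                      zero_fraction_max = 0.5,
                                      value_cap = 50),
                            labeling = list(min_count = 10L,
                                            max_abs_corr = 0.95,
                                            rules = NULL),
                            positive = TRUE,
                            model = list(n_hidden = 1L, hidden_width = 300L,
                                         activation = "rectifier",
                                         output_mode = "binary",
                                         l1_weight = 0.001, l2_weight = 0.001,
                                         dropout_rate = 0.2, epochs = 100L,
                                         batch_size = 256L,
                                         learning_rate = 1e-3),
                            eval = list(k = 10L,
                                        test_collections = "coll1")) {
  synth$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 dict_sizes = as.integer(dict_sizes),
                 n_concepts = as.integer(n_concepts),
                 n_synonym_pairs = as.integer(n_synonym_pairs),
                 max_depth = as.integer(max_depth),
                 synth = synth, qc = qc, labeling = labeling,
                 positive = positive, model = model, eval = eval),
            class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "prepare", "embed", "label", "train", "evaluate", "interpret")
}

obj_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stage_state_path <- function(config) file.path(config$out_dir, "stage_state.json")

read_stage_state <- function(config) {
  p <- stage_state_path(config)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_stage_state <- function(config, state) {
  jsonlite::write_json(state, stage_state_path(config), auto_unbox = TRUE,
                       pretty = TRUE)
}

log_stage <- function(config, stage, info) {
  entry <- c(list(stage = stage, time = format(Sys.time(), tz = "UTC"),
                  seed = config$seed), info)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(config$out_dir, "log.jsonl"), append = TRUE, sep = "")
  entry
}

stage_inputs <- function(stage, config) {
  d <- config$out_dir
  switch(stage,
    simulate = character(),
    prepare = file.path(d, "repository"),
    embed = c(file.path(d, "kept_ids.json"), file.path(d, "dictionaries")),
    label = file.path(d, "kept_ids.json"),
    train = c(file.path(d, "embeddings.csv"), file.path(d, "labels.csv")),
    evaluate = c(file.path(d, "model.json"), file.path(d, "embeddings.csv"),
                 file.path(d, "labels.csv")),
    interpret = c(file.path(d, "model.json"), file.path(d, "embeddings.csv"))
  )
}

stage_outputs <- function(stage, config) {
  d <- config$out_dir
  switch(stage,
    simulate = c(file.path(d, "repository"), file.path(d, "dictionaries")),
    prepare = c(file.path(d, "qc_report.csv"), file.path(d, "kept_ids.json")),
    embed = file.path(d, "embeddings.csv"),
    label = c(file.path(d, "labels.csv"), file.path(d, "vocabulary.json")),
    train = file.path(d, "model.json"),
    evaluate = file.path(d, "eval.json"),
    interpret = file.path(d, "concept_maps")
  )
}

tree_md5 <- function(paths) {
  files <- as.character(unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      list.files(p, recursive = TRUE, full.names = TRUE)
    } else if (file.exists(p)) p else character()
  })))
  obj_md5(list(files = basename(files),
               md5 = unname(tools::md5sum(sort(files)))))
}

stage_hash <- function(stage, config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  obj_md5(list(stage = stage, config = cfg,
               inputs = tree_md5(stage_inputs(stage, config))))
}

#' Run one pipeline stage
#'
#' Executes the named stage against the artifacts in
#' \code{config$out_dir}, writing its outputs and a structured log entry
#' (inputs, parameters, counts, seed). Stages are re-runnable: a stage
#' whose configuration and input artifacts are unchanged (by content hash)
#' is skipped. Missing upstream artifacts raise an error naming the stage
#' to run first.
#'
#' @param stage one of simulate, prepare, embed, label, train, evaluate,
#'   interpret.
#' @param config a \code{\link{pipeline_config}}.
#' @return The log entry for the stage, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prereq <- stage_inputs(stage, config)
  missing <- prereq[!file.exists(prereq) & !dir.exists(prereq)]
  if (length(missing)) {
    idx <- match(stage, pipeline_stages())
    stop(sprintf("missing upstream artifact(s) %s: run stage '%s' first",
                 paste(basename(missing), collapse = ", "),
                 pipeline_stages()[max(1L, idx - 1L)]), call. = FALSE)
  }
  state <- read_stage_state(config)
  h <- stage_hash(stage, config)
  outs <- stage_outputs(stage, config)
  if (identical(state[[stage]], h) &&
      all(file.exists(outs) | dir.exists(outs))) {
    return(invisible(log_stage(config, stage, list(skipped = TRUE))))
  }
  info <- switch(stage,
    simulate = stage_simulate(config),
    prepare = stage_prepare(config),
    embed = stage_embed(config),
    label = stage_label(config),
    train = stage_train(config),
    evaluate = stage_evaluate(config),
    interpret = stage_interpret(config))
  state[[stage]] <- stage_hash(stage, config)
  # invalidate downstream stages
  idx <- match(stage, pipeline_stages())
  for (s in pipeline_stages()[-seq_len(idx)]) state[[s]] <- NULL
  write_stage_state(config, state)
  invisible(log_stage(config, stage, c(info, list(skipped = FALSE))))
}

#' Run the full pipeline
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return List of per-stage log entries, invisibly.
#' @export
run_pipeline <- function(config) {
  invisible(lapply(pipeline_stages(), run_stage, config = config))
}

write_dictionary_csv <- function(dict, path) {
  utils::write.csv(as.data.frame(dict$components), path, row.names = FALSE)
  invisible(path)
}

read_dictionary_csv <- function(path, grid) {
  component_dictionary(as.matrix(utils::read.csv(path)), grid)
}

pipeline_grid <- function(config) {
  mask_vol <- read_nifti(file.path(config$out_dir, "repository", "mask.nii.gz"))
  volume(array(0, dim(mask_vol$data)), mask_vol$affine,
         array(mask_vol$data != 0, dim(mask_vol$data)))
}

pipeline_dictionaries <- function(config) {
  grid <- pipeline_grid(config)
  lapply(config$dict_sizes, function(K) {
    read_dictionary_csv(
      file.path(config$out_dir, "dictionaries", sprintf("dict_%d.csv", K)),
      grid)
  })
}

stage_simulate <- function(config) {
  grid <- make_grid(config$grid_shape)
  ont <- generate_ontology(config$n_concepts, config$n_synonym_pairs,
                           config$max_depth, seed = config$seed)
  dicts <- lapply(seq_along(config$dict_sizes), function(i) {
    generate_dictionary(config$dict_sizes[i], grid, seed = config$seed + i)
  })
  maps <- generate_repository(ont, dicts, config$synth)
  write_repository(maps, file.path(config$out_dir, "repository"), ont)
  ddir <- file.path(config$out_dir, "dictionaries")
  dir.create(ddir, showWarnings = FALSE)
  for (d in dicts) {
    write_dictionary_csv(d, file.path(ddir, sprintf("dict_%d.csv", d$K)))
  }
  list(n_maps = length(maps), n_concepts = nrow(ont$concepts),
       dict_sizes = config$dict_sizes)
}

prepared_maps <- function(config) {
  maps <- read_repository(file.path(config$out_dir, "repository"))
  kept_ids <- unlist(jsonlite::read_json(
    file.path(config$out_dir, "kept_ids.json"), simplifyVector = TRUE))
  ids <- vapply(maps, `[[`, "", "map_id")
  maps[ids %in% kept_ids]
}

stage_prepare <- function(config) {
  maps <- read_repository(file.path(config$out_dir, "repository"))
  grid <- maps[[1L]]$volume
  maps <- lapply(maps, resample_to_common, target = grid)
  qc <- do.call(qc_filter, c(list(maps = maps), config$qc))
  kept <- deduplicate(qc$kept)
  write_qc_report(qc$report, file.path(config$out_dir, "qc_report.csv"))
  jsonlite::write_json(vapply(kept, `[[`, "", "map_id"),
                       file.path(config$out_dir, "kept_ids.json"))
  list(n_in = length(maps), n_kept = length(kept),
       n_rejected = sum(qc$report$decision == "rejected"),
       n_duplicates = length(qc$kept) - length(kept))
}

stage_embed <- function(config) {
  maps <- prepared_maps(config)
  X <- embed_repository(maps, pipeline_dictionaries(config),
                        positive = config$positive)
  write_embeddings(X, file.path(config$out_dir, "embeddings.csv"))
  list(n_maps = nrow(X), p = ncol(X), positive = config$positive)
}

stage_label <- function(config) {
  maps <- prepared_maps(config)
  ont <- read_ontology(file.path(config$out_dir, "repository",
                                 "ontology.json"))
  vocab <- ont$concepts$id
  rules <- config$labeling$rules
  if (!is.null(rules)) {
    # enrichment rules fire on training collections only
    is_test <- vapply(maps, `[[`, "", "collection_id") %in%
      config$eval$test_collections
    Y_tr <- apply_ruleset(maps[!is_test], ont, vocab, rules)
    Y_te <- extract_exact_labels(maps[is_test], ont, vocab)
    common <- intersect(colnames(Y_tr), colnames(Y_te))
    Y <- rbind(Y_tr[, common, drop = FALSE], Y_te[, common, drop = FALSE])
  } else {
    Y <- extract_exact_labels(maps, ont, vocab)
  }
  Y <- hypernym_close(Y, ont)
  pruned <- prune_vocabulary(Y, config$labeling$min_count,
                             config$labeling$max_abs_corr)
  write_labels(pruned$labels, file.path(config$out_dir, "labels.csv"))
  jsonlite::write_json(pruned$vocabulary,
                       file.path(config$out_dir, "vocabulary.json"))
  list(n_labeled = nrow(pruned$labels),
       n_concepts = length(pruned$vocabulary))
}

pipeline_split <- function(config, Y) {
  maps <- prepared_maps(config)
  leave_collections_out_split(Y, repository_manifest(maps),
                              config$eval$test_collections)
}

stage_train <- function(config) {
  X <- read_embeddings(file.path(config$out_dir, "embeddings.csv"))
  Y <- read_labels(file.path(config$out_dir, "labels.csv"))
  split <- pipeline_split(config, Y)
  ids <- intersect(split$train_ids, rownames(X))
  Ytr <- Y[ids, split$evaluable, drop = FALSE]
  m <- config$model
  cfg <- model_config(input_dim = ncol(X), n_labels = ncol(Ytr),
                      n_hidden = m$n_hidden, hidden_width = m$hidden_width,
                      activation = m$activation, output_mode = m$output_mode,
                      l1_weight = m$l1_weight, l2_weight = m$l2_weight,
                      dropout_rate = m$dropout_rate, seed = config$seed)
  fit <- train_nnod(cfg, X[ids, , drop = FALSE], Ytr, epochs = m$epochs,
                    batch_size = m$batch_size,
                    learning_rate = m$learning_rate)
  write_model(fit, file.path(config$out_dir, "model.json"))
  jsonlite::write_json(split$evaluable,
                       file.path(config$out_dir, "model_vocabulary.json"))
  list(n_train = length(ids), n_labels = ncol(Ytr),
       final_loss = utils::tail(attr(fit, "loss_history"), 1))
}

pipeline_model <- function(config) {
  fit <- read_model(file.path(config$out_dir, "model.json"))
  fit$vocabulary <- unlist(jsonlite::read_json(
    file.path(config$out_dir, "model_vocabulary.json"),
    simplifyVector = TRUE))
  fit
}

stage_evaluate <- function(config) {
  X <- read_embeddings(file.path(config$out_dir, "embeddings.csv"))
  Y <- read_labels(file.path(config$out_dir, "labels.csv"))
  split <- pipeline_split(config, Y)
  fit <- pipeline_model(config)
  ids <- intersect(split$test_ids, rownames(X))
  scores <- predict_scores(fit, X[ids, , drop = FALSE])
  colnames(scores) <- fit$vocabulary
  report <- eval_report(Y[ids, fit$vocabulary, drop = FALSE], scores,
                        k = config$eval$k)
  write_eval_report(report, file.path(config$out_dir, "eval.json"))
  list(n_test = length(ids), macro_auc = report$macro_auc,
       wr_at_k = report$wr_at_k)
}

stage_interpret <- function(config) {
  X <- read_embeddings(file.path(config$out_dir, "embeddings.csv"))
  Y <- read_labels(file.path(config$out_dir, "labels.csv"))
  fit <- pipeline_model(config)
  dicts <- pipeline_dictionaries(config)
  concepts <- utils::head(fit$vocabulary, 3L)
  cmaps <- list()
  for (cid in concepts) {
    cmaps[[length(cmaps) + 1L]] <- threshold_for_display(
      sensitivity_map(fit, X, dicts, cid))
    cmaps[[length(cmaps) + 1L]] <- threshold_for_display(
      encoding_map(X[rownames(Y), , drop = FALSE], Y, dicts, cid))
  }
  write_concept_maps(cmaps, file.path(config$out_dir, "concept_maps"))
  list(n_concept_maps = length(cmaps), concepts = concepts)
}

#' Human-readable pipeline summary
#'
#' Prints the per-label AUC table, macro AUC and WR@k of a completed run
#' and returns the same content as a list (the machine-readable twin).
#'
#' @param config a \code{\link{pipeline_config}} whose evaluate stage has
#'   completed.
#' @return The summary list, invisibly.
#' @export
pipeline_report <- function(config) {
  ep <- file.path(config$out_dir, "eval.json")
  if (!file.exists(ep)) {
    stop("evaluate stage has not run; run_stage('evaluate', config) first",
         call. = FALSE)
  }
  summ <- jsonlite::read_json(ep, simplifyVector = TRUE)
  per_label <- utils::read.csv(sub("\\.json$", ".csv", ep))
  cat(sprintf("Decoding evaluation (%d test maps)\n", summ$n_maps))
  cat(sprintf("  macro AUC = %.3f   WR@%d = %.3f\n",
              summ$macro_auc, summ$k, summ$wr_at_k))
  cat("  per-label AUC:\n")
  for (i in seq_len(nrow(per_label))) {
    cat(sprintf("    %-28s %.3f\n", per_label$concept[i], per_label$auc[i]))
  }
  if (length(summ$excluded_labels)) {
    cat("  excluded labels:\n")
    for (nm in names(summ$excluded_labels)) {
      cat(sprintf("    %-28s %s\n", nm, summ$excluded_labels[[nm]]))
    }
  }
  invisible(list(summary = summ, per_label = per_label))
}
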