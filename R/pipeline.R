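# Stage-wise pipeline: pretrain each scale encoder on its own objective,
# freeze the exported embeddings, then train fusion + pair head. One master
# seed expands to per-stage sub-seeds (see STAGE_OFFSETS), so a run is
# reproducible end to end from a single integer.

run_config_defaults <- function() {
  list(
    paths = list(drugs = NULL, associations = NULL, triples = NULL,
                 pairs = NULL, out_dir = "ddifuse_out"),
    dims = list(d = 32L, rank = NULL, heads = 4L, attr_depth = 2L,
                attr_width = 128L, local_depth = 1L),
    training = list(mode = "binary", strategy = "transformer",
                    attr_epochs = 100L, local_epochs = 60L, kg_epochs = 100L,
                    epochs = 300L, attr_lr = 0.01, local_lr = 0.05,
                    kg_lr = 0.05, lr = 0.01, kg_lambda = 1e-3,
                    kg_negatives = 10L, mask_rate = 0.15, focal_gamma = 2,
                    rare_min_count = 10L, folds = 5L, test_fraction = 0.2,
                    seed = 1L),
    flags = list(fine_tune = FALSE, symmetrize_pairs = TRUE)
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) with sections `paths`, `dims`, `training`, `flags`;
#' absent optional keys take documented defaults. The fully resolved
#' configuration is returned and, when `echo_dir` is given, written beside
#' the outputs as `resolved_config.yaml`.
#'
#' @param path config file path, or NULL for pure defaults.
#' @param overrides named list merged over the file (e.g. from CLI flags).
#' @param echo_dir directory to write the resolved config into.
#' @return list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list(), echo_dir = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- merge_config(cfg, user)
  }
  cfg <- merge_config(cfg, overrides)
  if (is.null(cfg$dims$rank)) cfg$dims$rank <- cfg$dims$d
  if (cfg$dims$d %% cfg$dims$heads != 0L) {
    stop("constraint violated: d (", cfg$dims$d,
         ") must be divisible by heads (", cfg$dims$heads, ")")
  }
  if (!cfg$training$mode %in% c("binary", "event")) {
    stop("training$mode must be 'binary' or 'event'")
  }
  if (!is.null(echo_dir)) {
    dir.create(echo_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(echo_dir, "resolved_config.yaml"))
  }
  structure(cfg, class = c("run_config", "list"))
}

log_line <- function(...) {
  kv <- c(...)
  message(paste(names(kv), unname(kv), sep = "=", collapse = " "))
}

#' Pretrain all three scale encoders and export per-drug embeddings
#'
#' @param drugs drug table (drug_id, smiles).
#' @param assoc association table.
#' @param triples a `triple_set` (should not contain DDI edges: the caller
#'   is responsible for supplying a leakage-free knowledge graph).
#' @param cfg a `run_config`.
#' @return list with scale matrices `a`, `l`, `g` (n_drugs x d, aligned
#'   rownames) and the fitted encoder objects.
#' @export
embed_all_scales <- function(drugs, assoc, triples, cfg) {
  d <- cfg$dims$d
  seed <- cfg$training$seed
  log_line(stage = "pretrain-attr", epochs = cfg$training$attr_epochs)
  mols <- lapply(drugs$smiles, smiles_to_graph)
  at <- pretrain_masking(mols, epochs = cfg$training$attr_epochs,
                         lr = cfg$training$attr_lr,
                         rate = cfg$training$mask_rate,
                         d = cfg$dims$attr_width,
                         K = cfg$dims$attr_depth,
                         seed = sub_seed(seed, STAGE_OFFSETS[["attr_pretrain"]]))
  A <- attr_embeddings(drugs, at$params, d_out = d)
  log_line(stage = "pretrain-attr", final_loss = round(utils::tail(at$loss_history, 1L), 4))

  log_line(stage = "pretrain-local", epochs = cfg$training$local_epochs)
  graph <- hetero_graph(assoc, drugs$drug_id)
  lo <- pretrain_local(graph, epochs = cfg$training$local_epochs,
                       lr = cfg$training$local_lr, d = d,
                       K = cfg$dims$local_depth,
                       seed = sub_seed(seed, STAGE_OFFSETS[["local_pretrain"]]))
  L <- suppressWarnings(encode_local(graph, lo$params))
  log_line(stage = "pretrain-local", final_loss = round(utils::tail(lo$loss_history, 1L), 4))

  log_line(stage = "train-kg", epochs = cfg$training$kg_epochs,
           rank = cfg$dims$rank)
  kg <- train_complex(triples, rank = cfg$dims$rank,
                      epochs = cfg$training$kg_epochs,
                      lr = cfg$training$kg_lr,
                      lambda = cfg$training$kg_lambda,
                      negatives = cfg$training$kg_negatives,
                      seed = sub_seed(seed, STAGE_OFFSETS[["kg_train"]]))
  G <- suppressWarnings(global_embeddings(drugs$drug_id, kg$emb, d))
  log_line(stage = "train-kg", final_loss = round(utils::tail(kg$loss_history, 1L), 4))
  list(a = A, l = L, g = G, attr = at, local = lo, kg = kg)
}

#' Run the full stage-wise pipeline on files
#'
#' Reads the four inputs, pretrains the encoders, splits the pair table
#' (stratified by label), trains fusion + head on the training folds,
#' scores the held-out fold and writes predictions and an evaluation report
#' under `cfg$paths$out_dir`.
#'
#' @param cfg a `run_config` with all input paths set.
#' @return list with the trained model, the evaluation report and the
#'   held-out scores (invisibly).
#' @export
run_pipeline <- function(cfg) {
  p <- cfg$paths
  for (k in c("drugs", "associations", "triples", "pairs")) {
    if (is.null(p[[k]])) stop("config paths$", k, " is required")
    if (!file.exists(p[[k]])) stop("input file not found: ", p[[k]])
  }
  dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE)
  mode <- cfg$training$mode
  drugs <- read_drug_table(p$drugs)
  assoc <- read_association_table(p$associations)
  triples <- read_triples(p$triples)
  pairs <- read_pair_table(p$pairs, mode)
  if (mode == "event") {
    pairs <- filter_rare_events(pairs, cfg$training$rare_min_count)
  }
  sc <- embed_all_scales(drugs, assoc, triples, cfg)
  seed <- cfg$training$seed
  folds <- stratified_kfold(pairs, cfg$training$folds,
                            seed = sub_seed(seed, STAGE_OFFSETS[["split"]]))
  test_idx <- folds[[1L]]$test
  train_pairs <- pairs[folds[[1L]]$train, , drop = FALSE]
  test_pairs <- pairs[test_idx, , drop = FALSE]
  attr(train_pairs, "mode") <- attr(test_pairs, "mode") <- mode
  if (mode == "event") {
    attr(train_pairs, "class_vocab") <- attr(pairs, "class_vocab")
    attr(test_pairs, "class_vocab") <- attr(pairs, "class_vocab")
  }
  plan <- train_plan(mode = mode, epochs = cfg$training$epochs,
                     lr = cfg$training$lr, seed = seed,
                     focal_gamma = cfg$training$focal_gamma,
                     fine_tune_encoders = cfg$flags$fine_tune,
                     folds = cfg$training$folds, heads = cfg$dims$heads,
                     strategy = cfg$training$strategy)
  log_line(stage = "train", mode = mode, strategy = plan$strategy,
           epochs = plan$epochs)
  model <- train_model(train_pairs, sc[c("a", "l", "g")], plan)
  log_line(stage = "train", final_loss = round(utils::tail(model$history$loss, 1L), 4))
  scores <- predict_pairs(model, test_pairs)
  report <- eval_report(test_pairs$label, scores, mode)
  write_predictions(test_pairs, scores,
                    file.path(p$out_dir, "predictions.tsv"))
  rep_json <- report
  rep_json$confusion <- NULL
  jsonlite::write_json(rep_json, file.path(p$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = 6)
  if (!is.null(report$confusion)) {
    utils::write.csv(as.data.frame.matrix(report$confusion),
                     file.path(p$out_dir, "confusion.csv"))
  }
  saveRDS(model, file.path(p$out_dir, "model.rds"))
  log_line(stage = "evaluate",
           metric = if (mode == "binary") "auroc" else "macro_f1",
           value = round(if (mode == "binary") report$auroc else report$macro_f1, 4))
  invisible(list(model = model, report = report, scores = scores,
                 test_pairs = test_pairs, scales = sc))
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  cat("usage: ddifuse <command> [--config FILE] [--seed N] [--out DIR] ...\n",
      "commands:\n",
      "  simulate       write a synthetic dataset (--out DIR, --seed N,\n",
      "                 [--n-drugs N] [--mode binary|event])\n",
      "  pretrain-attr  pretrain the attribute encoder (--drugs TSV --out RDS)\n",
      "  pretrain-local pretrain the local encoder (--associations TSV --drugs TSV --out RDS)\n",
      "  train-kg       train ComplEx embeddings (--triples TSV --out RDS [--rank K])\n",
      "  train          full stagewise run (--config FILE)\n",
      "  predict        score pairs (--model RDS --pairs TSV --out TSV)\n",
      "  evaluate       score predictions (--pred TSV --truth TSV --mode M --out JSON)\n",
      sep = "")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `exec/ddifuse` script; see
#' `cli_usage()` for the subcommands.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
ddi_cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  seed <- as.integer(opt$seed %||% 1L)
  status <- 0L
  switch(cmd,
    simulate = {
      cfg <- synth_config(seed = seed,
                          n_drugs = as.integer(opt$n_drugs %||% 100L))
      simulate_dataset(cfg, opt$out %||% "synthetic",
                       mode = opt$mode %||% "binary")
      log_line(stage = "simulate", out = opt$out %||% "synthetic")
    },
    `pretrain-attr` = {
      drugs <- read_drug_table(opt$drugs)
      mols <- lapply(drugs$smiles, smiles_to_graph)
      fit <- pretrain_masking(mols, epochs = as.integer(opt$epochs %||% 30L),
                              seed = seed)
      saveRDS(fit, opt$out)
    },
    `pretrain-local` = {
      drugs <- read_drug_table(opt$drugs)
      assoc <- read_association_table(opt$associations)
      graph <- hetero_graph(assoc, drugs$drug_id)
      fit <- pretrain_local(graph, epochs = as.integer(opt$epochs %||% 40L),
                            seed = seed)
      saveRDS(fit, opt$out)
    },
    `train-kg` = {
      ts <- read_triples(opt$triples)
      fit <- train_complex(ts, rank = as.integer(opt$rank %||% 32L),
                           epochs = as.integer(opt$epochs %||% 40L),
                           seed = seed)
      saveRDS(fit, opt$out)
    },
    train = {
      cfg <- load_run_config(opt$config,
                             overrides = list(training = list(seed = seed)),
                             echo_dir = opt$out)
      if (!is.null(opt$out)) cfg$paths$out_dir <- opt$out
      run_pipeline(cfg)
    },
    predict = {
      model <- readRDS(opt$model)
      pairs <- read_pair_table(opt$pairs, model$mode)
      if (is.null(model$X_cache)) {
        stop("checkpoint incompatible: no cached embeddings ",
             "(was the model trained with this package version?)")
      }
      scores <- predict_pairs(model, pairs)
      write_predictions(pairs, scores, opt$out)
    },
    evaluate = {
      mode <- opt$mode %||% "binary"
      truth <- read_pair_table(opt$truth, mode)
      pred <- utils::read.delim(opt$pred, colClasses = "character")
      if (mode == "binary") {
        scores <- as.numeric(pred$score)
        rep <- eval_report(truth$label, scores, "binary")
      } else {
        sm <- as.matrix(pred[, -(1:2), drop = FALSE])
        storage.mode(sm) <- "double"
        colnames(sm) <- names(pred)[-(1:2)]
        rep <- eval_report(truth$label, sm, "event")
        utils::write.csv(as.data.frame.matrix(rep$confusion),
                         paste0(opt$out, ".confusion.csv"))
        rep$confusion <- NULL
      }
      jsonlite::write_json(rep, opt$out, auto_unbox = TRUE, digits = 6)
    },
    { cli_usage(); status <- 1L }
  )
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
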