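#' Leave-one-cluster-out finetuning and evaluation
#'
#' Runs the full evaluation protocol: for every schedule iteration one
#' cluster is held out as the test set, `folds` regression models are
#' finetuned on the remaining records (each fold once as validation), the
#' test cluster is predicted with the arithmetic mean of the fold models,
#' and the predictions are scored as both a ranking at the permeability
#' cutoff (ROC-AUC, PR-AUC) and a regression (RMSE).
#'
#' @param records a `permeability_records` tibble (already filtered).
#' @param model a pretrained `peplm_model`.
#' @param vocab the matching `smiles_vocabulary`.
#' @param schedule a `locv_schedule` over `records` rows.
#' @param cutoff classification cutoff on logP.
#' @param lr,dropout,weight_decay,batch_size,max_steps,patience finetuning
#'   hyperparameters, passed to [finetune_regression()].
#' @param seed integer seed.
#' @param verbose print progress lines.
#' @return list of class `locv_eval_report`: `per_cluster` (tibble of
#'   cluster metrics), `aggregate` (means and SDs), `predictions` (tibble
#'   of id, prediction, truth, label, cluster).
#' @export
evaluate_locv <- function(records, model, vocab, schedule, cutoff = -5.5,
                          lr = 5e-6, dropout = 0.15, weight_decay = 0.001,
                          batch_size = 16L, max_steps = 10000L, patience = Inf,
                          seed = 1L, verbose = FALSE) {
  folds <- attr(schedule, "folds")
  if (is.null(folds)) folds <- max(as.integer(sub("fold", "", grep("^fold", schedule$role, value = TRUE))))
  iterations <- sort(unique(schedule$iteration))
  per_cluster <- list()
  pred_rows <- list()
  for (it in iterations) {
    sub <- schedule[schedule$iteration == it, ]
    test_idx <- sub$record[sub$role == "test"]
    models <- vector("list", folds)
    for (f in seq_len(folds)) {
      val_idx <- sub$record[sub$role == paste0("fold", f)]
      tr_idx <- sub$record[sub$role != "test" & sub$role != paste0("fold", f)]
      if (verbose) {
        message(sprintf("iteration %d: finetuning fold %d (%d train / %d val)",
                        it, f, length(tr_idx), length(val_idx)))
      }
      models[[f]] <- finetune_regression(
        model, vocab,
        train = records[tr_idx, ], validation = records[val_idx, ],
        lr = lr, dropout = dropout, weight_decay = weight_decay,
        batch_size = batch_size, max_steps = max_steps, patience = patience,
        seed = seed + 1000L * it + f
      )
    }
    test <- records[test_idx, ]
    preds <- ensemble_predict(models, test, vocab)
    sc <- score_predictions(preds, test, cutoff = cutoff)
    sc$cluster <- sub$test_cluster[1]
    per_cluster[[length(per_cluster) + 1L]] <- sc
    pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
      id = test$id, prediction = preds, truth = test$logP_exp,
      label = test$logP_exp >= cutoff, cluster = sub$test_cluster[1]
    )
    if (verbose) {
      message(sprintf("iteration %d: ROC-AUC %.3f, PR-AUC %.3f, RMSE %.3f",
                      it, sc$roc_auc, sc$pr_auc, sc$rmse))
    }
  }
  per_cluster <- dplyr::bind_rows(per_cluster)
  per_cluster <- dplyr::relocate(per_cluster, "cluster")
  structure(list(per_cluster = per_cluster,
                 aggregate = aggregate_scores(per_cluster),
                 predictions = dplyr::bind_rows(pred_rows),
                 cutoff = cutoff),
            class = "locv_eval_report")
}

#' @export
print.locv_eval_report <- function(x, ...) {
  ag <- x$aggregate
  cat("<locv_eval_report> ", nrow(x$per_cluster), " held-out clusters\n", sep = "")
  cat(sprintf("  ROC-AUC %.3f +/- %.3f   PR-AUC %.3f +/- %.3f   RMSE %.3f +/- %.3f\n",
              ag$roc_auc_mean, ag$roc_auc_sd, ag$pr_auc_mean, ag$pr_auc_sd,
              ag$rmse_mean, ag$rmse_sd))
  invisible(x)
}

#' Desk-scale pipeline configuration
#'
#' Nested parameter blocks for [run_pipeline()]. The defaults run the
#' whole stack (generate, tokenize, pretrain, fixture, split, finetune,
#' evaluate) in minutes on one CPU while exercising every code path:
#' ~2,000 generated molecules of up to 10 residues, a 2-layer/96-hidden
#' encoder, a few hundred pretraining steps, and an 800-record toy
#' permeability panel. Unknown keys are rejected.
#'
#' @param ... named blocks overriding the defaults (partial lists are
#'   merged): `generator`, `tokenizer`, `mlm`, `fixture`, `cluster`,
#'   `finetune`, `seed`.
#' @return nested list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    generator = list(n = 2000L, max_length = 10L),
    tokenizer = list(budget = 581L, max_ngram_chars = 5L),
    mlm = list(layers = 2L, heads = 4L, hidden = 96L, intermediate = 192L,
               steps = 500L, batch_size = 32L, lr = 1e-3,
               validation_fraction = 0.1, eval_interval = 100L),
    fixture = list(n = 800L, noise_sd = 0.3, undetectable_fraction = 0.05,
                   other_assay_fraction = 0.05),
    cluster = list(k_candidates = 2:6, variance_target = 0.99),
    finetune = list(lr = 1e-3, dropout = 0.15, weight_decay = 0.001,
                    batch_size = 16L, max_steps = 200L, patience = 4L,
                    folds = 5L, cutoff = -5.5)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) stop("unknown pipeline config block: ", bad[1])
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]])) {
      unknown <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(unknown) > 0L) {
        stop("unknown key in pipeline config block '", nm, "': ", unknown[1])
      }
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "run_config")
}

#' Save / load a pipeline configuration
#'
#' YAML round trip; loading re-validates the keys, so configs serialize
#' and deserialize losslessly and unknown keys are rejected.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the validated config.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full desk-scale pipeline
#'
#' Executes generate, tokenize, pretrain, make-fixture, split, finetune
#' and evaluate in order, persisting every intermediate under `out_dir`.
#' Each artifact is recorded in a manifest together with the hash of the
#' configuration that produced it; stages whose artifact already exists
#' with a matching hash are skipped, making the pipeline resumable, and a
#' mismatched hash triggers regeneration with a warning.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param library a `residue_library`.
#' @param verbose print stage progress.
#' @return list: `report` (the `locv_eval_report`), `plan`
#'   (`cluster_plan`), `fit` (`mlm_fit`), `paths` of artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("peplm_run_"),
                         library = load_residue_library(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  note <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  fresh <- function(stage, path) {
    file.exists(path) && identical(manifest[[stage]]$config_hash, cfg_hash)
  }
  stamp <- function(stage, path) {
    if (!is.null(manifest[[stage]]) &&
        !identical(manifest[[stage]]$config_hash, cfg_hash)) {
      warning("stage '", stage, "' artifact was built from a different config; regenerated")
    }
    manifest[[stage]] <<- list(artifact = basename(path), config_hash = cfg_hash)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(stage, path, fn) {
    if (fresh(stage, path)) {
      note(stage, "artifact up to date, skipping")
      return(invisible(NULL))
    }
    ok <- FALSE
    on.exit(if (!ok) warning("pipeline aborted in stage '", stage,
                             "'; partial state kept under ", out_dir), add = TRUE)
    fn()
    ok <- TRUE
    stamp(stage, path)
  }
  seed <- config$seed

  corpus_path <- file.path(out_dir, "corpus.txt")
  gen_cfg <- generator_config(max_length = config$generator$max_length)
  run_stage("generate", corpus_path, function() {
    note("generate", "writing %d molecules (seed %d)", config$generator$n, seed)
    generate_corpus(config$generator$n, library, gen_cfg, seed = seed,
                    output = corpus_path)
  })

  vocab_path <- file.path(out_dir, "vocab.txt")
  run_stage("tokenize", vocab_path, function() {
    note("tokenize", "training vocabulary (budget %d)", config$tokenizer$budget)
    v <- train_vocabulary(corpus_path,
                          tokenizer_config(max_ngram_chars = config$tokenizer$max_ngram_chars,
                                           budget = config$tokenizer$budget))
    write_vocabulary(v, vocab_path)
  })
  vocab <- read_vocabulary(vocab_path)

  ckpt_path <- file.path(out_dir, "pretrain.rds")
  fit <- NULL
  run_stage("pretrain", ckpt_path, function() {
    m <- config$mlm
    note("pretrain", "training %d steps (%d layers, hidden %d)",
         m$steps, m$layers, m$hidden)
    mcfg <- model_config(vocab_size = vocab_size(vocab), layers = m$layers,
                         heads = m$heads, hidden = m$hidden,
                         intermediate = m$intermediate, context = 768L)
    fit <<- train_mlm(corpus_path, vocab, mcfg, steps = m$steps,
                      batch_size = m$batch_size, lr = m$lr,
                      validation_fraction = m$validation_fraction,
                      eval_interval = m$eval_interval, seed = seed + 1L,
                      verbose = verbose)
    save_checkpoint(fit$model, vocab, ckpt_path)
    utils::write.csv(fit$report, file.path(out_dir, "pretrain_report.csv"),
                     row.names = FALSE)
  })
  model <- load_checkpoint(ckpt_path, vocab)

  fixture_path <- file.path(out_dir, "fixture.csv")
  run_stage("fixture", fixture_path, function() {
    note("fixture", "planting %d-record permeability panel", config$fixture$n)
    make_toy_permeability_dataset(
      config$fixture$n, library, gen_cfg_fixture(config, gen_cfg),
      noise_sd = config$fixture$noise_sd,
      undetectable_fraction = config$fixture$undetectable_fraction,
      other_assay_fraction = config$fixture$other_assay_fraction,
      seed = seed + 2L, path = fixture_path
    )
  })
  records <- filter_records(read_permeability_table(fixture_path, validate = FALSE))

  clusters_path <- file.path(out_dir, "clusters.csv")
  plan <- NULL
  run_stage("split", clusters_path, function() {
    note("split", "embedding %d records and clustering", nrow(records))
    X <- embed_records(records, model, vocab)
    plan <<- reduce_and_cluster(X, variance_target = config$cluster$variance_target,
                                k_candidates = config$cluster$k_candidates,
                                seed = seed + 3L)
    utils::write.csv(data.frame(id = records$id, cluster = plan$labels),
                     clusters_path, row.names = FALSE)
    utils::write.csv(plan$quality, file.path(out_dir, "cluster_quality.csv"),
                     row.names = FALSE)
  })
  if (is.null(plan)) {
    labels <- utils::read.csv(clusters_path)$cluster
    plan <- structure(list(labels = labels, k = length(unique(labels)),
                           pca_components = NA_integer_, quality = NULL,
                           scores = NULL), class = "cluster_plan")
  }

  report_path <- file.path(out_dir, "report.json")
  ft <- config$finetune
  schedule <- make_locv_schedule(plan, folds = ft$folds, seed = seed + 4L)
  note("finetune", "leave-one-cluster-out over %d clusters x %d folds",
       plan$k, ft$folds)
  report <- evaluate_locv(records, model, vocab, schedule, cutoff = ft$cutoff,
                          lr = ft$lr, dropout = ft$dropout,
                          weight_decay = ft$weight_decay,
                          batch_size = ft$batch_size, max_steps = ft$max_steps,
                          patience = ft$patience, seed = seed + 5L,
                          verbose = verbose)
  utils::write.csv(report$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(per_cluster = report$per_cluster,
                            aggregate = report$aggregate),
                       report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stamp("evaluate", report_path)
  note("evaluate", "ROC-AUC %.3f, PR-AUC %.3f, RMSE %.3f",
       report$aggregate$roc_auc_mean, report$aggregate$pr_auc_mean,
       report$aggregate$rmse_mean)
  list(report = report, plan = plan, fit = fit,
       paths = list(corpus = corpus_path, vocab = vocab_path,
                    checkpoint = ckpt_path, fixture = fixture_path,
                    clusters = clusters_path, report = report_path))
}

# fixture generation uses the corpus generator settings; kept separate so a
# caller can widen the corpus without touching the permeability panel
gen_cfg_fixture <- function(config, gen_cfg) gen_cfg
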