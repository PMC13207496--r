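#' The frozen desk-scale study profile
#'
#' One shared definition of the desk-scale conditions used by the bundled
#' analyses: a ~1,200-image phantom cohort at 64 x 64 with the emulated
#' class imbalance (400 normal / 519 benign / 281 malignant), eight clients
#' under Dirichlet(0.5) label skew with log-normal quantity skew and mild
#' feature skew, a pooled-pixel multinomial logistic classifier, and a
#' frequent-averaging federated protocol: 400 rounds of one local epoch at
#' batch size 64, client learning rate 2 decayed by 0.1 at rounds 280 and
#' 360, weight decay 1e-3. With convex models, one-step-per-round averaging
#' removes the client-drift bias of long local phases, and the weight decay
#' keeps the near-separable objective strongly convex so federated and
#' centralized training converge to the same well-defined optimum; see the
#' methods vignette. The full-scale protocol (100 rounds, 5 epochs, batch
#' 32, Adam at 1e-3) remains available through [fl_config()] defaults.
#'
#' @param seed master seed fanned out to every component.
#' @return list with `dataset`, `partition`, `model`, `fl`, `dp` configs.
#' @export
desk_profile <- function(seed = 1L) {
  list(
    dataset = dataset_spec(400, 519, 281, image_size = 64,
                           seed = derive_seed(seed, "dataset")),
    partition = partition_config(K = 8, alpha = 0.5, quantity_log_sd = 0.3,
                                 seed = derive_seed(seed, "partition")),
    model = model_spec("multinomial_logistic", input_dim = 64, n_classes = 3,
                       pool = 8, seed = derive_seed(seed, "model")),
    fl = fl_config(R = 400, E = 1, B = 64, client_lr = 2,
                   weight_decay = 1e-3, lr_decay_rounds = c(280, 360),
                   allow_small_client = TRUE,
                   seed = derive_seed(seed, "federation")),
    dp = dp_config(enabled = FALSE)
  )
}

#' Experiment configuration for the simulation bench
#'
#' Bundles the sub-configurations of a full run of the pipeline
#' (generate, split, partition, federate, evaluate). Defaults are the
#' frozen [desk_profile()], which keeps the full 3-task x 3-algorithm
#' matrix within minutes on one CPU while preserving the class imbalance
#' of the emulated cohort; the full-scale protocol is reachable by passing
#' the corresponding sub-configs.
#'
#' @param dataset a [dataset_spec()].
#' @param partition a [partition_config()].
#' @param model a [model_spec()].
#' @param fl an [fl_config()].
#' @param dp a [dp_config()].
#' @param tasks character vector of task names.
#' @param seeds integer vector of master seeds (nonempty).
#' @param out_dir output directory for resumable cell records.
#' @return object of class `fldpsim_experiment_config`.
#' @export
experiment_config <- function(dataset = desk_profile()$dataset,
                              partition = desk_profile()$partition,
                              model = desk_profile()$model,
                              fl = desk_profile()$fl,
                              dp = dp_config(enabled = FALSE),
                              tasks = c("screen", "diagnose", "threeclass"),
                              seeds = 1L,
                              out_dir = tempfile("fldpsim_run_")) {
  if (length(seeds) < 1) config_error("seeds", "must be nonempty")
  stopifnot(inherits(dataset, "fldpsim_dataset_spec"),
            inherits(partition, "fldpsim_partition_config"),
            inherits(model, "fldpsim_model_spec"),
            inherits(fl, "fldpsim_fl_config"),
            inherits(dp, "fldpsim_dp_config"))
  structure(list(dataset = dataset, partition = partition, model = model,
                 fl = fl, dp = dp, tasks = tasks,
                 seeds = as.integer(seeds), out_dir = out_dir),
            class = "fldpsim_experiment_config")
}

# JSON round-trips turn all-NA numeric columns into logical; restore the
# schema types so resumed and freshly computed rows compare equal.
normalize_record <- function(df) {
  num_cols <- c("C", "eta", "seed", "accuracy", "macro_precision",
                "macro_recall", "macro_f1", "eps_basic", "eps_sublinear",
                "n_train", "n_test")
  for (cn in intersect(num_cols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df
}

cell_key <- function(task, algorithm, dp, seed) {
  sprintf("%s_%s_dp%d_C%g_eta%g_seed%d", task, algorithm,
          as.integer(dp$enabled), dp$C, dp$eta, seed)
}

# Prepare (or reuse) the per-seed data context: generated samples, split,
# and per-task views restricted to the training and test sets.
prepare_context <- function(config, seed) {
  ds <- config$dataset
  ds$seed <- derive_seed(seed, "dataset")
  samples <- generate_dataset(ds)
  split <- split_dataset(samples, seed = derive_seed(seed, "split"))
  samples <- apply_split(samples, split)
  list(samples = samples, split = split)
}

run_cell <- function(config, ctx, task, algorithm, dp, seed) {
  samples <- ctx$samples
  tags <- vapply(samples, function(s) s$split_tag, character(1))
  view_all <- construct_task(samples, task)
  train_idx <- view_all$index[tags[view_all$index] == "train"]
  test_idx <- view_all$index[tags[view_all$index] == "test"]
  train_samples <- samples[train_idx]
  test_samples <- samples[test_idx]
  view_train <- construct_task(train_samples, task)
  view_test <- construct_task(test_samples, task)

  pc <- config$partition
  pc$seed <- derive_seed(seed, "partition", task)
  manifests <- partition_clients(view_train$sample_ids, view_train$labels, pc)

  spec <- config$model
  spec$n_classes <- length(view_train$class_levels)
  spec$seed <- derive_seed(seed, "model")
  fl <- config$fl
  fl$algorithm <- algorithm
  fl$seed <- derive_seed(seed, "federation", task, algorithm,
                         dp$enabled, dp$C, dp$eta)

  client_data <- build_client_data(train_samples, manifests, view_train, spec)
  test_data <- list(X = featurize(test_samples, spec),
                    y = match(view_test$labels, view_test$class_levels))
  fit <- run_federation(client_data, test_data, spec, fl, dp)
  last <- fit$log[nrow(fit$log), ]
  rep <- evaluate_model(fit$w, spec, test_data$X, test_data$y)
  data.frame(
    task = task, algorithm = algorithm, model = spec$family,
    dp_enabled = dp$enabled, C = dp$C, eta = dp$eta, seed = seed,
    accuracy = rep$accuracy, macro_precision = rep$macro_precision,
    macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1,
    eps_basic = last$eps_basic, eps_sublinear = last$eps_sublinear,
    n_train = sum(vapply(client_data, function(d) nrow(d$X), numeric(1))),
    n_test = length(test_data$y)
  )
}

#' Run the experiment matrix
#'
#' Executes generate, split, partition, federate, evaluate for every
#' (task, algorithm, seed) cell of the configured matrix. Cells are
#' persisted as JSON under `out_dir/cells` and completed cells are skipped
#' on rerun, so the call is resumable and idempotent. All randomness is
#' derived from the per-cell master seed. Failures in individual cells are
#' recorded (column `error`) and the run continues.
#'
#' @param config an [experiment_config()].
#' @param algorithms algorithms to run (default all three).
#' @return long-format results table, one row per completed cell.
#' @export
run_experiment <- function(config,
                           algorithms = c("fedavg", "fedprox", "fedopt")) {
  cells_dir <- file.path(config$out_dir, "cells")
  dir.create(cells_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (seed in config$seeds) {
    ctx <- NULL
    for (task in config$tasks) {
      for (algorithm in algorithms) {
        key <- cell_key(task, algorithm, config$dp, seed)
        path <- file.path(cells_dir, paste0(key, ".json"))
        if (file.exists(path)) {
          rows[[key]] <- normalize_record(
            as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)))
          next
        }
        if (is.null(ctx)) ctx <- prepare_context(config, seed)
        row <- tryCatch(
          run_cell(config, ctx, task, algorithm, config$dp, seed),
          error = function(e) data.frame(
            task = task, algorithm = algorithm, model = config$model$family,
            dp_enabled = config$dp$enabled, C = config$dp$C,
            eta = config$dp$eta, seed = seed, accuracy = NA_real_,
            macro_precision = NA_real_, macro_recall = NA_real_,
            macro_f1 = NA_real_, eps_basic = NA_real_,
            eps_sublinear = NA_real_, n_train = NA_real_, n_test = NA_real_,
            error = conditionMessage(e))
        )
        jsonlite::write_json(row, path, auto_unbox = FALSE, digits = NA,
                             na = "null")
        rows[[key]] <- row
      }
    }
  }
  out <- do.call(rbind, c(lapply(unname(rows), function(r) {
    if (is.null(r$error)) r$error <- NA_character_
    r
  }), list(make.row.names = FALSE)))
  out
}

#' Run the DP ablation grid
#'
#' One federated run per (clipping bound, noise multiplier) pair with DP
#' enabled, FedAvg aggregation only (the scope of the study's DP analysis),
#' over the configured seeds; emits a grid-shaped report alongside the long
#' table. Each row's privacy-ledger fields equal a standalone
#' [build_ledger()] call at that configuration.
#'
#' @param config an [experiment_config()] (its `tasks` should usually be a
#'   single task; the grid runs every configured task).
#' @param C_list clipping bounds.
#' @param eta_list noise multipliers.
#' @return long-format results table with one row per (C, eta, task, seed).
#' @export
run_dp_ablation <- function(config, C_list = c(0.5, 1.0, 1.5, 2.0),
                            eta_list = c(0.5, 1.0, 1.5, 2.0, 3.0)) {
  stopifnot(length(C_list) >= 1, length(eta_list) >= 1)
  rows <- list()
  for (C in C_list) {
    for (eta in eta_list) {
      cfg <- config
      cfg$dp <- dp_config(enabled = TRUE, C = C, eta = eta,
                          delta = config$dp$delta)
      rows[[sprintf("C%g_eta%g", C, eta)]] <-
        run_experiment(cfg, algorithms = "fedavg")
    }
  }
  do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
}

#' Pivot an ablation table into the C x eta grid layout
#' @param table a [run_dp_ablation()] result.
#' @param value metric column to tabulate.
#' @return data frame, clipping bounds as rows and noise multipliers as
#'   columns, seed-averaged.
#' @export
ablation_grid <- function(table, value = "accuracy") {
  agg <- stats::aggregate(table[[value]],
                          by = list(C = table$C, eta = table$eta),
                          FUN = mean)
  grid <- stats::reshape(agg, idvar = "C", timevar = "eta",
                         direction = "wide")
  names(grid) <- sub("^x\\.", "eta_", names(grid))
  grid[order(grid$C), , drop = FALSE]
}

#' Validate a results record against the published schema
#'
#' Checks field presence and types against the JSON schema shipped at
#' `inst/schema/results_record.json`.
#'
#' @param record one-row data frame or named list.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_record <- function(record) {
  schema <- jsonlite::read_json(system.file("schema", "results_record.json",
                                            package = "fldpsim"),
                                simplifyVector = FALSE)
  rec <- as.list(record)
  for (field in names(schema$properties)) {
    required <- field %in% unlist(schema$required)
    if (!field %in% names(rec)) {
      if (required) stop(sprintf("record missing required field '%s'", field))
      next
    }
    type <- schema$properties[[field]]$type
    v <- rec[[field]]
    ok <- switch(type,
      number = is.numeric(v) || all(is.na(v)),
      string = is.character(v) || all(is.na(v)),
      boolean = is.logical(v),
      TRUE)
    if (!ok) stop(sprintf("record field '%s' is not of type %s", field, type))
  }
  invisible(TRUE)
}

render_text_table <- function(df, path) {
  txt <- utils::capture.output(print(df, row.names = FALSE))
  writeLines(txt, path)
}

#' Render the standard report set from a results table
#'
#' Writes (a) a privacy-budget table over the requested noise multipliers,
#' (b) a client-partition summary when manifests are supplied, (c) the
#' communication-cost table over the packaged architectures, (d) per-task
#' metric grids, and (e) the DP-ablation grid when the table contains DP
#' runs — each as CSV plus a rendered text table. Empty subsets are skipped
#' with a notice.
#'
#' @param table long-format results table.
#' @param dir output directory.
#' @param budget_etas noise multipliers for the budget table.
#' @param partition_summary optional [summarize_partition()] data frame.
#' @param K client count for the cost table.
#' @return invisibly, the vector of files written.
#' @export
render_reports <- function(table, dir, budget_etas = c(0.5, 1, 1.5, 2, 3),
                           partition_summary = NULL, K = 8) {
  stopifnot(nrow(table) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    render_text_table(df, file.path(dir, paste0(stem, ".txt")))
    written <<- c(written, csv)
  }
  emit(budget_table(budget_etas), "budget_table")
  if (!is.null(partition_summary)) {
    emit(partition_summary, "partition_summary")
  } else {
    message("render_reports: no partition summary supplied; skipped")
  }
  arch <- architecture_meta()
  arch$comm_cost_mb <- comm_cost_mb(arch$params_millions, K)
  emit(arch, "comm_cost_table")
  for (task in unique(table$task)) {
    sub <- table[table$task == task & !table$dp_enabled, , drop = FALSE]
    if (nrow(sub) == 0) {
      message(sprintf("render_reports: no non-DP results for task '%s'; skipped", task))
      next
    }
    emit(sub[order(sub$algorithm, sub$seed),
             c("task", "algorithm", "model", "seed", "accuracy",
               "macro_precision", "macro_recall", "macro_f1")],
         paste0("metrics_", task))
  }
  dp_sub <- table[table$dp_enabled & !is.na(table$accuracy), , drop = FALSE]
  if (nrow(dp_sub) > 0) {
    emit(ablation_grid(dp_sub), "ablation_grid")
  } else {
    message("render_reports: no DP results; ablation grid skipped")
  }
  invisible(written)
}
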