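# Shared machinery for the desk-scale qualitative studies: builds the
# phantom cohort under the frozen study profile, runs federated /
# centralized / DP training, and returns final test accuracies. Used by
# the acceptance suite and mirrored by scripts/acceptance.R.

study_context <- function(seed, task = "screen") {
  prof <- desk_profile(seed)
  samples <- generate_dataset(prof$dataset)
  split <- split_dataset(samples, seed = derive_seed(seed, "split"))
  samples <- apply_split(samples, split)
  tags <- vapply(samples, function(s) s$split_tag, character(1))
  view <- construct_task(samples, task)
  tr <- view$index[tags[view$index] == "train"]
  te <- view$index[tags[view$index] == "test"]
  view_tr <- construct_task(samples[tr], task)
  view_te <- construct_task(samples[te], task)
  spec <- prof$model
  spec$n_classes <- length(view_tr$class_levels)
  manifests <- partition_clients(view_tr$sample_ids, view_tr$labels,
                                 prof$partition)
  list(
    profile = prof,
    spec = spec,
    client_data = build_client_data(samples[tr], manifests, view_tr, spec),
    test_data = list(X = featurize(samples[te], spec),
                     y = match(view_te$labels, view_te$class_levels))
  )
}

study_fed_accuracy <- function(ctx, algorithm = "fedavg",
                               dp = dp_config(enabled = FALSE)) {
  fl <- ctx$profile$fl
  fl$algorithm <- algorithm
  fit <- run_federation(ctx$client_data, ctx$test_data, ctx$spec, fl, dp)
  evaluate_model(fit$w, ctx$spec, ctx$test_data$X, ctx$test_data$y)$accuracy
}

study_centralized_accuracy <- function(ctx) {
  X <- do.call(rbind, lapply(ctx$client_data, `[[`, "X"))
  y <- unlist(lapply(ctx$client_data, `[[`, "y"))
  w <- train_centralized(X, y, ctx$spec, ctx$profile$fl)
  evaluate_model(w, ctx$spec, ctx$test_data$X, ctx$test_data$y)$accuracy
}

# 5-fold cross-validated accuracy of an L2-regularized logistic reference
# classifier (independent of the package's own model module).
reference_cv_accuracy <- function(X, y, folds = 5, seed = 1) {
  fold <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = length(y))))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fam <- if (length(unique(y)) > 2) "multinomial" else "binomial"
    fit <- glmnet::glmnet(X[tr, ], factor(y[tr]), family = fam, lambda = 1e-3)
    mean(predict(fit, X[!tr, ], type = "class") == y[!tr])
  }, numeric(1))
  mean(acc)
}

STUDY_SEEDS <- 101:105
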