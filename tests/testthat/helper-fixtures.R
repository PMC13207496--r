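# Lightweight label-only sample stubs: construct_task and split_dataset
# only touch sample_id / label, so tests at printed-cohort scale (15,847)
# never materialize pixels.
stub_samples <- function(n_normal, n_benign, n_malignant) {
  labels <- rep(c("normal", "benign", "malignant"),
                c(n_normal, n_benign, n_malignant))
  lapply(seq_along(labels), function(i) {
    list(sample_id = sprintf("s%05d", i), pixels = NULL, label = labels[i],
         split_tag = NA_character_)
  })
}

# Small separable two-class Gaussian-blob problem for optimizer sanity tests.
blob_problem <- function(n_per_class = 100, d = 4, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per_class * d, -sep / 2), ncol = d),
               matrix(stats::rnorm(n_per_class * d, sep / 2), ncol = d))
    y <- rep(1:2, each = n_per_class)
    perm <- sample(length(y))
    list(X = X[perm, ], y = y[perm])
  })
}

# Split blob data evenly across K clients.
blob_clients <- function(prob, K) {
  n <- length(prob$y)
  idx <- split(seq_len(n), rep(seq_len(K), length.out = n))
  lapply(idx, function(i) list(X = prob$X[i, , drop = FALSE], y = prob$y[i]))
}

# Central finite differences of the mean cross-entropy loss.
fd_mean_gradient <- function(w, spec, X, y, h = 1e-6) {
  vapply(seq_along(w), function(j) {
    wp <- w; wm <- w
    wp[j] <- w[j] + h
    wm[j] <- w[j] - h
    (per_sample_gradients(wp, spec, X, y)$loss -
       per_sample_gradients(wm, spec, X, y)$loss) / (2 * h)
  }, numeric(1))
}

# Tiny experiment configuration for orchestration tests: small cohort,
# few rounds, so a full matrix runs in seconds.
tiny_experiment <- function(out_dir, tasks = "screen", seeds = 1L,
                            dp = dp_config(enabled = FALSE)) {
  experiment_config(
    dataset = dataset_spec(40, 40, 40, image_size = 16, seed = 5L),
    partition = partition_config(K = 3, quantity_log_sd = 0, seed = 5L),
    model = model_spec("multinomial_logistic", input_dim = 16, n_classes = 3,
                       pool = 4),
    fl = fl_config(R = 5, E = 1, B = 8, client_lr = 1, weight_decay = 1e-3,
                   lr_decay_rounds = c(4), allow_small_client = TRUE),
    dp = dp, tasks = tasks, seeds = seeds, out_dir = out_dir)
}
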