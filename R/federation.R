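#' Federated-training configuration
#'
#' Defaults follow the benchmark protocol: 100 communication rounds of 5
#' local epochs at batch size 32, full participation, client learning rate
#' 1e-3 decayed by 0.1 at rounds 50 and 80, FedProx proximal weight 0.01,
#' and a server Adam (FedOpt) with beta1 = 0.9, beta2 = 0.99, server
#' learning rate 0.01.
#'
#' @param R communication rounds.
#' @param E local epochs per round.
#' @param B batch size.
#' @param algorithm `"fedavg"`, `"fedprox"` or `"fedopt"`.
#' @param mu FedProx proximal weight (>= 0).
#' @param server_lr FedOpt server learning rate.
#' @param beta1,beta2 FedOpt moment decays in `[0, 1)`.
#' @param adam_eps FedOpt numerical constant.
#' @param client_lr local learning rate.
#' @param weight_decay L2 penalty coefficient added to every local
#'   gradient (`weight_decay * w`); keeps the near-separable desk-scale
#'   objectives strongly convex so training converges to a well-defined
#'   optimum. Data-independent, so it composes with the DP mechanism
#'   without privacy cost.
#' @param lr_decay_rounds rounds at which the local rate is decayed; a
#'   round `r` is decayed once for every entry `<= r`.
#' @param lr_decay_factor multiplicative decay factor.
#' @param local_optimizer `"sgd"` (plain step, always used when DP is on)
#'   or `"adam"` (bias-corrected local Adam, non-private path only).
#' @param weighted_avg use sample-size-weighted aggregation instead of the
#'   plain mean.
#' @param server_bias_correction apply Adam bias correction on the server
#'   (off by default: the server recurrence is used exactly as stated,
#'   without correction terms).
#' @param allow_small_client permit a client smaller than one batch to
#'   train on a single undersized batch.
#' @param seed master seed.
#' @return object of class `fldpsim_fl_config`.
#' @export
fl_config <- function(R = 100, E = 5, B = 32,
                      algorithm = c("fedavg", "fedprox", "fedopt"),
                      mu = 0.01, server_lr = 0.01, beta1 = 0.9, beta2 = 0.99,
                      adam_eps = 1e-8, client_lr = 1e-3, weight_decay = 0,
                      lr_decay_rounds = c(50, 80), lr_decay_factor = 0.1,
                      local_optimizer = c("sgd", "adam"),
                      weighted_avg = FALSE, server_bias_correction = FALSE,
                      allow_small_client = FALSE, seed = 1L) {
  algorithm <- match.arg(algorithm)
  local_optimizer <- match.arg(local_optimizer)
  if (R < 1 || E < 1 || B < 1) config_error("R/E/B", "must all be >= 1")
  if (mu < 0) config_error("mu", "must be nonnegative")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    config_error("beta1/beta2", "must lie in [0, 1)")
  }
  structure(list(R = as.integer(R), E = as.integer(E), B = as.integer(B),
                 algorithm = algorithm, mu = mu, server_lr = server_lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 client_lr = client_lr, weight_decay = weight_decay,
                 lr_decay_rounds = lr_decay_rounds,
                 lr_decay_factor = lr_decay_factor,
                 local_optimizer = local_optimizer,
                 weighted_avg = weighted_avg,
                 server_bias_correction = server_bias_correction,
                 allow_small_client = allow_small_client,
                 seed = as.integer(seed)),
            class = "fldpsim_fl_config")
}

#' Local learning rate at a given round
#'
#' The base rate times `factor^(number of decay rounds <= r)`.
#'
#' @param r round index (1-based).
#' @param base base learning rate.
#' @param decay_rounds decay round indices.
#' @param factor decay factor.
#' @return learning rate for round `r`.
#' @export
lr_at_round <- function(r, base, decay_rounds = c(50, 80), factor = 0.1) {
  base * factor^sum(r >= decay_rounds)
}

#' FedProx gradient adjustment
#'
#' Adds the proximal gradient `mu * (w - w_global)` of the quadratic
#' penalty `mu/2 * ||w - w_global||^2` to a local gradient.
#'
#' @param grad_local local gradient vector.
#' @param w current local parameters.
#' @param w_global global (round-start) parameters.
#' @param mu proximal weight.
#' @return adjusted gradient.
#' @export
fedprox_gradient <- function(grad_local, w, w_global, mu) {
  stopifnot(length(grad_local) == length(w), length(w) == length(w_global))
  grad_local + mu * (w - w_global)
}

#' Local training of one client for one round
#'
#' Runs `E` epochs over `floor(n_k / B)` full batches (the last partial
#' batch is dropped), with the round-indexed decayed learning rate. When DP
#' is enabled every step goes through the private mechanism (per-sample
#' clipping, batch averaging, Gaussian noise) followed by a plain gradient
#' step; otherwise the configured plain optimizer is used. Under FedProx
#' the data-independent proximal gradient `mu * (w - w_global)` is added to
#' every applied gradient. Only weights, never gradients, leave the client.
#'
#' @param w_global round-start global parameters.
#' @param X,y client features and integer labels.
#' @param spec a [model_spec()].
#' @param fl an [fl_config()].
#' @param dp a [dp_config()] (may be disabled).
#' @param round_r current round index (drives the decay schedule).
#' @param client_seed seed for batch shuffling and noise draws.
#' @param client_id identifier carried into the returned update.
#' @return client update: `client_id`, `w_k`, `n_k`, `train_loss` (mean
#'   over the final epoch's batches).
#' @export
local_train <- function(w_global, X, y, spec, fl, dp = dp_config(enabled = FALSE),
                        round_r = 1L, client_seed = 1L, client_id = 1L) {
  X <- check_features(X, spec)
  n_k <- nrow(X)
  n_batches <- floor(n_k / fl$B)
  batch_size <- fl$B
  if (n_batches == 0) {
    if (!fl$allow_small_client) {
      stop(sprintf("client %s has %d samples, fewer than one batch of %d",
                   client_id, n_k, fl$B))
    }
    n_batches <- 1L
    batch_size <- n_k
  }
  lr <- lr_at_round(round_r, fl$client_lr, fl$lr_decay_rounds,
                    fl$lr_decay_factor)
  mu <- if (fl$algorithm == "fedprox") fl$mu else 0
  use_adam <- !dp$enabled && fl$local_optimizer == "adam"
  w <- w_global
  m <- v <- numeric(length(w))
  t_step <- 0
  losses <- numeric(0)
  for (e in seq_len(fl$E)) {
    perm <- withr::with_seed(derive_seed(client_seed, "epoch", e),
                             sample.int(n_k))
    losses <- numeric(0)
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1) * batch_size + 1):(bi * batch_size)]
      if (dp$enabled) {
        step <- dp_local_step(w, X[idx, , drop = FALSE], y[idx], spec, dp, lr,
                              seed = derive_seed(client_seed, "noise", e, bi))
        # proximal pull and weight decay alongside the (noisy) data gradient;
        # both are data-independent and carry no privacy cost
        w <- step$w - lr * (mu * (w - w_global) + fl$weight_decay * w)
        losses <- c(losses, step$loss)
      } else {
        psg <- per_sample_gradients(w, spec, X[idx, , drop = FALSE], y[idx])
        g <- fedprox_gradient(psg$mean_grad, w, w_global, mu) +
          fl$weight_decay * w
        if (use_adam) {
          # local Adam uses the standard bias-corrected defaults (0.9, 0.999);
          # fl$beta1/beta2 belong to the FedOpt server optimizer
          t_step <- t_step + 1
          m <- 0.9 * m + 0.1 * g
          v <- 0.999 * v + 0.001 * g^2
          m_hat <- m / (1 - 0.9^t_step)
          v_hat <- v / (1 - 0.999^t_step)
          w <- w - lr * m_hat / (sqrt(v_hat) + fl$adam_eps)
        } else {
          w <- w - lr * g
        }
        losses <- c(losses, psg$loss)
      }
    }
  }
  list(client_id = client_id, w_k = w, n_k = n_k,
       train_loss = mean(losses))
}

#' FedAvg aggregation
#'
#' The arithmetic mean of client parameter vectors, or the sample-size
#' weighted mean when `weighted = TRUE`.
#'
#' @param updates list of client updates (each with `w_k`, `n_k`).
#' @param weighted use `n_k`-proportional weights.
#' @return aggregated parameter vector.
#' @export
aggregate_fedavg <- function(updates, weighted = FALSE) {
  stopifnot(length(updates) >= 1)
  lens <- vapply(updates, function(u) length(u$w_k), integer(1))
  if (length(unique(lens)) != 1) stop("client parameter lengths differ")
  W <- do.call(rbind, lapply(updates, function(u) u$w_k))
  if (!weighted) {
    colMeans(W)
  } else {
    wts <- vapply(updates, function(u) u$n_k, numeric(1))
    colSums(W * (wts / sum(wts)))
  }
}

#' Initialize server round state
#' @param w0 initial global parameters.
#' @return round state with zeroed server moments.
#' @export
init_round_state <- function(w0) {
  list(round = 0L, w = w0, m = numeric(length(w0)), v = numeric(length(w0)))
}

#' FedOpt server update (server-side Adam on the pseudo-gradient)
#'
#' The pseudo-gradient is `Delta_t = w_t - mean_k(w_k)` (so the update
#' moves the global model toward the clients); moments follow
#' `m_t = beta1 m_{t-1} + (1 - beta1) Delta_t` and
#' `v_t = beta2 v_{t-1} + (1 - beta2) Delta_t^2`, and the new iterate is
#' `w_{t+1} = w_t - server_lr * m_t / (sqrt(v_t) + adam_eps)` elementwise,
#' without bias correction unless configured.
#'
#' @param state round state from [init_round_state()].
#' @param updates list of client updates.
#' @param fl an [fl_config()].
#' @return updated round state.
#' @export
server_update_fedopt <- function(state, updates, fl) {
  w_avg <- aggregate_fedavg(updates, fl$weighted_avg)
  if (length(w_avg) != length(state$w)) stop("parameter length mismatch")
  delta <- state$w - w_avg
  state$m <- fl$beta1 * state$m + (1 - fl$beta1) * delta
  state$v <- fl$beta2 * state$v + (1 - fl$beta2) * delta^2
  m_use <- state$m
  v_use <- state$v
  if (fl$server_bias_correction) {
    t <- state$round + 1L
    m_use <- m_use / (1 - fl$beta1^t)
    v_use <- v_use / (1 - fl$beta2^t)
  }
  state$w <- state$w - fl$server_lr * m_use / (sqrt(v_use) + fl$adam_eps)
  state$round <- state$round + 1L
  state
}

#' Run the full communication-round loop
#'
#' Broadcast, private or plain local training on every client (full
#' participation), then aggregation with the configured algorithm. Per
#' round the global model is evaluated on the shared test set, and when DP
#' is on, the worst-case (largest-client) privacy spend so far is logged.
#' Deterministic given the master seed: each client round uses the derived
#' seed `(master, "client", client_id, round)`.
#'
#' @param client_data list per client of `list(X, y)` training data.
#' @param test_data `list(X, y)` shared global test set (may be `NULL`).
#' @param spec a [model_spec()].
#' @param fl an [fl_config()].
#' @param dp a [dp_config()].
#' @param w0 optional initial parameters (defaults to [init_model()]).
#' @return list with final `w`, per-round `log` data frame (`round`,
#'   `algorithm`, `train_loss`, `test_accuracy`, `macro_f1`, `eps_basic`,
#'   `eps_sublinear`) and the final `state`.
#' @export
run_federation <- function(client_data, test_data, spec, fl,
                           dp = dp_config(enabled = FALSE), w0 = NULL) {
  K <- length(client_data)
  stopifnot(K >= 1)
  if (is.null(w0)) w0 <- init_model(spec)
  state <- init_round_state(w0)
  max_batches <- max(vapply(client_data, function(d) {
    max(1, batches_per_epoch(nrow(check_features(d$X, spec)), fl$B))
  }, numeric(1)))
  log_rows <- vector("list", fl$R)
  for (r in seq_len(fl$R)) {
    updates <- lapply(seq_len(K), function(k) {
      local_train(state$w, client_data[[k]]$X, client_data[[k]]$y, spec, fl,
                  dp, round_r = r,
                  client_seed = derive_seed(fl$seed, "client", k, r),
                  client_id = k)
    })
    if (fl$algorithm == "fedopt") {
      state <- server_update_fedopt(state, updates, fl)
    } else {
      state$w <- aggregate_fedavg(updates, fl$weighted_avg)
      state$round <- r
    }
    acc <- NA_real_; f1 <- NA_real_
    if (!is.null(test_data)) {
      mr <- evaluate_model(state$w, spec, test_data$X, test_data$y)
      acc <- mr$accuracy; f1 <- mr$macro_f1
    }
    eps_b <- NA_real_; eps_s <- NA_real_
    if (dp$enabled) {
      led <- build_ledger(dp, r, fl$E, max_batches)
      eps_b <- led$eps_basic; eps_s <- led$eps_sublinear
    }
    log_rows[[r]] <- data.frame(
      round = r, algorithm = fl$algorithm,
      train_loss = mean(vapply(updates, function(u) u$train_loss, numeric(1))),
      test_accuracy = acc, macro_f1 = f1,
      eps_basic = eps_b, eps_sublinear = eps_s)
  }
  list(w = state$w, log = do.call(rbind, log_rows), state = state)
}

#' Centralized mini-batch training at matched budget
#'
#' The single-client degenerate case of the federated loop: `R` rounds of
#' `E` epochs of mini-batch descent over the pooled training data, using
#' the same schedule and seed derivation, for fair federated-vs-centralized
#' comparisons at equal total epochs.
#'
#' @param X,y pooled training data.
#' @param spec a [model_spec()].
#' @param fl an [fl_config()].
#' @param w0 optional initial parameters.
#' @return final parameter vector.
#' @export
train_centralized <- function(X, y, spec, fl, w0 = NULL) {
  if (is.null(w0)) w0 <- init_model(spec)
  w <- w0
  dp_off <- dp_config(enabled = FALSE)
  for (r in seq_len(fl$R)) {
    upd <- local_train(w, X, y, spec, fl, dp_off, round_r = r,
                       client_seed = derive_seed(fl$seed, "client", 1L, r),
                       client_id = 1L)
    w <- upd$w_k
  }
  w
}

#' Assemble per-client training matrices from manifests
#'
#' Featurizes each client's samples under a task view, applying the
#' client's load-time augmentation spec to raw (unstandardized) pixels
#' when present.
#'
#' @param samples list of image samples (raw pixels in `[0, 1]`).
#' @param manifests list of client manifests.
#' @param task_view a [construct_task()] view over `samples`.
#' @param spec a [model_spec()].
#' @param augment apply per-client augmentation specs.
#' @return list per client of `list(X, y)`.
#' @export
build_client_data <- function(samples, manifests, task_view, spec,
                              augment = TRUE) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  task_label <- stats::setNames(task_view$labels, task_view$sample_ids)
  lapply(manifests, function(m) {
    keep <- m$sample_ids[m$sample_ids %in% task_view$sample_ids]
    subs <- samples[match(keep, ids)]
    if (augment && !is.null(m$augmentation_spec)) {
      subs <- lapply(subs, function(s) {
        s$pixels <- apply_augmentation(s$pixels, m$augmentation_spec)
        s
      })
    }
    list(X = featurize(subs, spec),
         y = match(unname(task_label[keep]), task_view$class_levels))
  })
}
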