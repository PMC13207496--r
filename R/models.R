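#' Desk-scale differentiable classifier specification
#'
#' Two closed-form model families expose exact per-sample gradients through
#' a flat parameter-vector contract, so per-sample clipping needs no
#' automatic differentiation: multinomial logistic regression and a
#' one-hidden-layer tanh network. Images are mean-pooled to a `pool x pool`
#' grid and flattened before the classifier.
#'
#' @param family `"multinomial_logistic"` or `"one_hidden_mlp"`.
#' @param input_dim feature dimension (for pooled images, `pool^2`).
#' @param n_classes number of classes (>= 2).
#' @param hidden_dim hidden width (mlp only).
#' @param init_scale half-width of the symmetric mlp initialization.
#' @param pool pooling grid side used by [featurize()].
#' @param seed initialization seed.
#' @return object of class `fldpsim_model_spec`.
#' @export
model_spec <- function(family = c("multinomial_logistic", "one_hidden_mlp"),
                       input_dim, n_classes, hidden_dim = 16,
                       init_scale = 0.1, pool = 8, seed = 1L) {
  family <- match.arg(family)
  if (input_dim < 1) config_error("input_dim", "must be positive")
  if (n_classes < 2) config_error("n_classes", "must be at least 2")
  if (family == "one_hidden_mlp" && hidden_dim < 1) {
    config_error("hidden_dim", "must be positive")
  }
  structure(list(family = family, input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden_dim = as.integer(hidden_dim),
                 init_scale = init_scale, pool = as.integer(pool),
                 seed = as.integer(seed)),
            class = "fldpsim_model_spec")
}

#' Number of parameters of a model spec
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
n_params <- function(spec) {
  d <- spec$input_dim; K <- spec$n_classes; h <- spec$hidden_dim
  if (spec$family == "multinomial_logistic") d * K + K
  else d * h + h + h * K + K
}

#' Initialize a flat parameter vector
#'
#' Logistic models start at zero (the symmetric optimum of the prior);
#' the mlp uses scaled symmetric uniform draws, deterministic in the spec
#' seed.
#'
#' @param spec a [model_spec()].
#' @return numeric parameter vector of length [n_params()].
#' @export
init_model <- function(spec) {
  p <- n_params(spec)
  if (spec$family == "multinomial_logistic") {
    rep(0, p)
  } else {
    withr::with_seed(derive_seed(spec$seed, "init"),
                     stats::runif(p, -spec$init_scale, spec$init_scale))
  }
}

unpack_params <- function(w, spec) {
  d <- spec$input_dim; K <- spec$n_classes
  if (length(w) != n_params(spec)) {
    stop(sprintf("parameter vector length %d does not match spec (%d)",
                 length(w), n_params(spec)))
  }
  if (spec$family == "multinomial_logistic") {
    list(W = matrix(w[seq_len(d * K)], d, K),
         b = w[d * K + seq_len(K)])
  } else {
    h <- spec$hidden_dim
    i <- 0
    W1 <- matrix(w[i + seq_len(d * h)], d, h); i <- i + d * h
    b1 <- w[i + seq_len(h)]; i <- i + h
    W2 <- matrix(w[i + seq_len(h * K)], h, K); i <- i + h * K
    b2 <- w[i + seq_len(K)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

check_features <- function(X, spec) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != spec$input_dim) {
    stop(sprintf("feature dimension %d does not match input_dim %d",
                 ncol(X), spec$input_dim))
  }
  X
}

#' Class-probability predictions
#'
#' @param w flat parameter vector.
#' @param spec a [model_spec()].
#' @param X feature matrix (rows are samples).
#' @return matrix of per-class probabilities; rows sum to 1.
#' @export
predict_proba <- function(w, spec, X) {
  X <- check_features(X, spec)
  th <- unpack_params(w, spec)
  if (spec$family == "multinomial_logistic") {
    Z <- X %*% th$W + matrix(th$b, nrow(X), spec$n_classes, byrow = TRUE)
  } else {
    H <- tanh(X %*% th$W1 + matrix(th$b1, nrow(X), spec$hidden_dim, byrow = TRUE))
    Z <- H %*% th$W2 + matrix(th$b2, nrow(X), spec$n_classes, byrow = TRUE)
  }
  softmax_rows(Z)
}

# row i of the result is as.vector(outer(A[i,], B[i,])) (column-major),
# matching the parameter layout of unpack_params.
rowwise_outer <- function(A, B) {
  d <- ncol(A); K <- ncol(B)
  A[, rep(seq_len(d), K), drop = FALSE] *
    B[, rep(seq_len(K), each = d), drop = FALSE]
}

#' Exact per-sample gradients and mean cross-entropy loss
#'
#' Closed-form backpropagation for both model families; no numeric
#' differentiation is involved. One gradient row per sample.
#'
#' @param w flat parameter vector.
#' @param spec a [model_spec()].
#' @param X feature matrix.
#' @param y integer class labels in `1..n_classes`.
#' @return list with `grads` (`n x n_params` matrix), `mean_grad`
#'   (full-batch gradient) and `loss` (mean cross-entropy).
#' @export
per_sample_gradients <- function(w, spec, X, y) {
  X <- check_features(X, spec)
  stopifnot(length(y) == nrow(X), all(y >= 1), all(y <= spec$n_classes))
  n <- nrow(X)
  th <- unpack_params(w, spec)
  Y <- matrix(0, n, spec$n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  if (spec$family == "multinomial_logistic") {
    P <- predict_proba(w, spec, X)
    dZ <- P - Y
    G <- cbind(rowwise_outer(X, dZ), dZ)
  } else {
    H <- tanh(X %*% th$W1 + matrix(th$b1, n, spec$hidden_dim, byrow = TRUE))
    Z <- H %*% th$W2 + matrix(th$b2, n, spec$n_classes, byrow = TRUE)
    P <- softmax_rows(Z)
    dZ2 <- P - Y
    dH <- dZ2 %*% t(th$W2)
    dA1 <- dH * (1 - H^2)
    G <- cbind(rowwise_outer(X, dA1), dA1, rowwise_outer(H, dZ2), dZ2)
  }
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  list(grads = G, mean_grad = colMeans(G), loss = loss)
}

#' Mean-pool and flatten image samples into a feature matrix
#'
#' Multi-channel (standardized) images are averaged across channels first,
#' then block-mean-pooled to the spec's `pool x pool` grid and flattened
#' row by row.
#'
#' @param samples list of image samples.
#' @param spec a [model_spec()] whose `input_dim` equals `pool^2`.
#' @return numeric matrix, one row per sample.
#' @export
featurize <- function(samples, spec) {
  t(vapply(samples, function(s) {
    px <- s$pixels
    if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
    pool_image(px, spec$pool)
  }, numeric(spec$pool^2)))
}

# block mean-pooling by group sums over rows then columns
pool_image <- function(px, pool) {
  n <- nrow(px)
  grp <- pmin(ceiling(seq_len(n) / (n / pool)), pool)
  sums <- rowsum(px, grp)                     # pool x n
  sums <- t(rowsum(t(sums), grp))             # pool x pool
  counts <- as.vector(table(grp))
  as.vector(t(sums / outer(counts, counts)))
}

#' Per-round federated communication cost
#'
#' One upload and one download of 32-bit parameters per participating
#' client: `2 * params * 4 bytes * K`, reported in MB (1 MB = 1e6 bytes).
#'
#' @param params_millions parameter count in units of 1e6.
#' @param K number of participating clients.
#' @return megabytes per communication round.
#' @export
comm_cost_mb <- function(params_millions, K) {
  stopifnot(params_millions >= 0, K >= 0)
  2 * params_millions * 1e6 * 4 * K / 1e6
}

#' Packaged architecture metadata (name, parameter count)
#'
#' Parameter counts (in millions) of the seven reference ImageNet
#' architectures used by the communication-cost model; the architectures
#' themselves are metadata only and are never trained here.
#'
#' @return data frame with columns `name`, `params_millions`.
#' @export
architecture_meta <- function() {
  utils::read.csv(system.file("extdata", "architecture_meta.csv",
                              package = "fldpsim"))
}

#' Save / load a model checkpoint (flat binary vector + JSON header)
#' @param w flat parameter vector.
#' @param spec a [model_spec()].
#' @param path output path without extension; writes `path.bin` and
#'   `path.json`.
#' @export
write_checkpoint <- function(w, spec, path) {
  writeBin(as.double(w), paste0(path, ".bin"))
  jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  spec <- do.call(model_spec, jsonlite::read_json(paste0(path, ".json"),
                                                  simplifyVector = TRUE))
  w <- readBin(paste0(path, ".bin"), what = "double", n = n_params(spec))
  list(w = w, spec = spec)
}
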