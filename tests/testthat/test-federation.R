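upd <- function(w, n = 1, id = 1) list(client_id = id, w_k = w, n_k = n)

test_that("FedAvg aggregation: mean, identity, weighted mean", {
  expect_equal(aggregate_fedavg(list(upd(c(0, 2)), upd(c(2, 4)))), c(1, 3))
  expect_equal(aggregate_fedavg(list(upd(c(5, -1)))), c(5, -1))
  expect_equal(aggregate_fedavg(list(upd(c(0, 2), n = 1), upd(c(2, 4), n = 3)),
                                weighted = TRUE), c(1.5, 3.5))
  expect_error(aggregate_fedavg(list(upd(c(1, 2)), upd(c(1, 2, 3)))), "differ")
})

test_that("FedAvg equals a naive elementwise loop on random instances", {
  withr::with_seed(23, {
    for (i in 1:10) {
      K <- sample(2:6, 1); p <- sample(3:40, 1)
      ups <- lapply(seq_len(K), function(k) upd(rnorm(p), n = sample(1:9, 1)))
      naive <- numeric(p)
      for (j in seq_len(p)) {
        for (u in ups) naive[j] <- naive[j] + u$w_k[j]
      }
      naive <- naive / K
      expect_equal(aggregate_fedavg(ups), naive, tolerance = 1e-12)
    }
  })
})

test_that("the proximal gradient vanishes when it should", {
  g <- c(1, -2, 3)
  expect_equal(fedprox_gradient(g, c(1, 1, 1), c(0, 0, 0), 0), g)
  expect_equal(fedprox_gradient(g, c(2, 2, 2), c(2, 2, 2), 5), g)
  expect_equal(fedprox_gradient(g, c(1, 0, 0), c(0, 0, 0), 2), g + c(2, 0, 0))
})

test_that("proximal descent on a quadratic reaches the analytic minimizer", {
  # F(w) = (w - a)^2 / 2 with proximal anchor w_t: minimizer (a + mu w_t) / (1 + mu)
  a <- 3; w_t <- 1; mu <- 0.7
  w <- 0
  for (i in 1:500) {
    w <- w - 0.2 * fedprox_gradient(w - a, w, w_t, mu)
  }
  expect_equal(w, (a + mu * w_t) / (1 + mu), tolerance = 1e-6)
})

test_that("the decayed learning-rate schedule follows the round index", {
  expect_equal(lr_at_round(49, 1e-3), 1e-3)
  expect_equal(lr_at_round(51, 1e-3) / lr_at_round(49, 1e-3), 0.1)
  expect_equal(lr_at_round(80, 1e-3), 1e-5)
  expect_equal(lr_at_round(100, 2, c(50, 80), 0.5), 0.5)
})

test_that("one plain local step unrolls to the batch-gradient update", {
  spec <- model_spec("multinomial_logistic", 4, 2)
  w0 <- withr::with_seed(1, rnorm(n_params(spec), sd = 0.2))
  X <- withr::with_seed(2, matrix(rnorm(6 * 4), 6))
  y <- rep(1:2, 3)
  fl <- fl_config(R = 1, E = 1, B = 6, client_lr = 0.3, algorithm = "fedavg")
  out <- local_train(w0, X, y, spec, fl, round_r = 1, client_seed = 5)
  expect_equal(out$w_k,
               w0 - 0.3 * per_sample_gradients(w0, spec, X, y)$mean_grad,
               tolerance = 1e-12)
  expect_equal(out$n_k, 6)
})

test_that("FedProx with mu = 0 matches FedAvg local training exactly", {
  spec <- model_spec("multinomial_logistic", 4, 2)
  w0 <- withr::with_seed(3, rnorm(n_params(spec), sd = 0.2))
  prob <- blob_problem(30, d = 4, seed = 8)
  fla <- fl_config(R = 1, E = 3, B = 8, client_lr = 0.2, algorithm = "fedavg")
  flp <- fl_config(R = 1, E = 3, B = 8, client_lr = 0.2, algorithm = "fedprox",
                   mu = 0)
  a <- local_train(w0, prob$X, prob$y, spec, fla, client_seed = 4)
  p <- local_train(w0, prob$X, prob$y, spec, flp, client_seed = 4)
  expect_identical(a$w_k, p$w_k)
})

test_that("a huge proximal weight pins the local model to the global one", {
  spec <- model_spec("multinomial_logistic", 4, 2)
  w0 <- withr::with_seed(4, rnorm(n_params(spec), sd = 0.5))
  prob <- blob_problem(30, d = 4, seed = 9)
  fl <- fl_config(R = 1, E = 5, B = 8, client_lr = 1e-7, algorithm = "fedprox",
                  mu = 1e6)
  out <- local_train(w0, prob$X, prob$y, spec, fl, client_seed = 2)
  expect_lt(sqrt(sum((out$w_k - w0)^2)), 1e-4)
})

test_that("clients smaller than one batch error unless explicitly allowed", {
  spec <- model_spec("multinomial_logistic", 4, 2)
  w0 <- rep(0, n_params(spec))
  X <- matrix(rnorm(3 * 4), 3); y <- c(1L, 2L, 1L)
  fl <- fl_config(R = 1, E = 1, B = 8)
  expect_error(local_train(w0, X, y, spec, fl), "fewer than one batch")
  fl2 <- fl_config(R = 1, E = 1, B = 8, allow_small_client = TRUE,
                   client_lr = 0.1)
  expect_equal(local_train(w0, X, y, spec, fl2)$n_k, 3)
})

test_that("FedOpt matches an independently coded Adam recurrence", {
  fl <- fl_config(algorithm = "fedopt", server_lr = 0.01, beta1 = 0.9,
                  beta2 = 0.99, adam_eps = 1e-8)
  p <- 6
  state <- init_round_state(withr::with_seed(6, rnorm(p)))
  # independent recurrence, written step by step
  w_ref <- state$w; m_ref <- rep(0, p); v_ref <- rep(0, p)
  deltas <- withr::with_seed(7, lapply(1:5, function(i) rnorm(p, sd = 0.3)))
  for (t in 1:5) {
    delta <- deltas[[t]]
    ups <- lapply(1:3, function(k) upd(state$w - delta, id = k))
    state <- server_update_fedopt(state, ups, fl)
    m_ref <- 0.9 * m_ref + 0.1 * delta
    v_ref <- 0.99 * v_ref + 0.01 * delta^2
    w_ref <- w_ref - 0.01 * m_ref / (sqrt(v_ref) + 1e-8)
    expect_equal(state$w, w_ref, tolerance = 1e-12)
    expect_equal(state$m, m_ref, tolerance = 1e-12)
    expect_equal(state$v, v_ref, tolerance = 1e-12)
  }
})

test_that("FedOpt fixed point: identical client returns leave the model unchanged", {
  fl <- fl_config(algorithm = "fedopt")
  state <- init_round_state(c(1, 2, 3))
  for (t in 1:3) {
    state <- server_update_fedopt(state, list(upd(c(1, 2, 3)), upd(c(1, 2, 3))), fl)
  }
  expect_equal(state$w, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(state$m, rep(0, 3))
})

test_that("momentum-free FedOpt reduces to the sign-normalized step", {
  fl <- fl_config(algorithm = "fedopt", beta1 = 0, beta2 = 0,
                  server_lr = 0.05, adam_eps = 1e-8)
  state <- init_round_state(c(0, 0))
  delta <- c(0.4, -0.2)
  state <- server_update_fedopt(state, list(upd(state$w - delta)), fl)
  expect_equal(state$w, -0.05 * delta / (abs(delta) + 1e-8), tolerance = 1e-12)
})

test_that("single-client federation reproduces centralized minibatch descent", {
  prob <- blob_problem(60, d = 4, seed = 10)
  spec <- model_spec("multinomial_logistic", 4, 2)
  fl <- fl_config(R = 8, E = 1, B = 16, client_lr = 0.3, seed = 77)
  fed <- run_federation(list(list(X = prob$X, y = prob$y)), NULL, spec, fl)
  cen <- train_centralized(prob$X, prob$y, spec, fl)
  expect_identical(fed$w, cen)
})

test_that("FedProx(mu = 0) and FedAvg coincide end-to-end on a fixed seed", {
  prob <- blob_problem(60, d = 4, seed = 11)
  cd <- blob_clients(prob, 4)
  spec <- model_spec("multinomial_logistic", 4, 2)
  fla <- fl_config(R = 6, E = 2, B = 8, client_lr = 0.3, algorithm = "fedavg",
                   seed = 5)
  flp <- fl_config(R = 6, E = 2, B = 8, client_lr = 0.3, algorithm = "fedprox",
                   mu = 0, seed = 5)
  wa <- run_federation(cd, NULL, spec, fla)$w
  wp <- run_federation(cd, NULL, spec, flp)$w
  expect_identical(wa, wp)
})

test_that("DP with zero noise and a huge bound matches the plain path end-to-end", {
  prob <- blob_problem(60, d = 4, seed = 12)
  cd <- blob_clients(prob, 4)
  spec <- model_spec("multinomial_logistic", 4, 2)
  fl <- fl_config(R = 5, E = 2, B = 8, client_lr = 0.3, seed = 6)
  w_dp <- run_federation(cd, NULL, spec, fl,
                         dp_config(enabled = TRUE, C = 1e9, eta = 0))$w
  w_plain <- run_federation(cd, NULL, spec, fl, dp_config(enabled = FALSE))$w
  expect_equal(w_dp, w_plain, tolerance = 1e-12)
})

test_that("federated training solves a separable task and logs rounds", {
  prob <- blob_problem(200, d = 4, sep = 2, seed = 13)
  test_prob <- blob_problem(100, d = 4, sep = 2, seed = 14)
  cd <- blob_clients(prob, 4)
  spec <- model_spec("multinomial_logistic", 4, 2)
  fl <- fl_config(R = 30, E = 1, B = 16, client_lr = 0.5, seed = 3)
  fit <- run_federation(cd, list(X = test_prob$X, y = test_prob$y), spec, fl)
  expect_equal(nrow(fit$log), 30)
  expect_gte(fit$log$test_accuracy[30], 0.95)
  expect_true(all(is.na(fit$log$eps_basic)))
  # DP on: the log carries the cumulative budget, increasing in rounds
  dp <- dp_config(enabled = TRUE, C = 1.5, eta = 2)
  fit_dp <- run_federation(cd, NULL, spec,
                           fl_config(R = 3, E = 1, B = 16, client_lr = 0.1,
                                     seed = 3), dp)
  expect_true(all(diff(fit_dp$log$eps_basic) > 0))
})

test_that("federation is deterministic in the master seed", {
  prob <- blob_problem(40, d = 3, seed = 15)
  cd <- blob_clients(prob, 2)
  spec <- model_spec("multinomial_logistic", 3, 2)
  fl <- fl_config(R = 4, E = 2, B = 8, client_lr = 0.3, seed = 9)
  expect_identical(run_federation(cd, NULL, spec, fl)$w,
                   run_federation(cd, NULL, spec, fl)$w)
  fl2 <- fl_config(R = 4, E = 2, B = 8, client_lr = 0.3, seed = 10)
  expect_false(identical(run_federation(cd, NULL, spec, fl)$w,
                         run_federation(cd, NULL, spec, fl2)$w))
})
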