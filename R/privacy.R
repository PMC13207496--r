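#' Client-side differential-privacy configuration
#'
#' @param enabled logical; when `FALSE` local training takes plain steps.
#' @param C per-sample l2 clipping bound (> 0).
#' @param eta noise multiplier (>= 0); the Gaussian noise standard
#'   deviation is `eta * C` per coordinate on the batch-averaged gradient.
#' @param delta privacy slack, in (0, 1).
#' @param norm_floor guard on the per-sample norm in the clipping factor,
#'   so the zero gradient maps to zero without division error.
#' @param convention `"batch_mean"` applies noise sd `eta * C` to the
#'   batch-averaged gradient (the accounting and all defaults assume this
#'   form); `"sum_scaled"` exposes the common DP-SGD alternative where the
#'   noise on the average has sd `eta * C / B`, for sensitivity analysis
#'   only.
#' @return object of class `fldpsim_dp_config`.
#' @export
dp_config <- function(enabled = TRUE, C = 1.5, eta = 2.0, delta = 1e-5,
                      norm_floor = 1e-7,
                      convention = c("batch_mean", "sum_scaled")) {
  convention <- match.arg(convention)
  if (C <= 0) config_error("C", "clipping bound must be positive")
  if (eta < 0) config_error("eta", "noise multiplier must be nonnegative")
  if (delta <= 0 || delta >= 1) config_error("delta", "must lie in (0, 1)")
  structure(list(enabled = enabled, C = C, eta = eta, delta = delta,
                 norm_floor = norm_floor, convention = convention),
            class = "fldpsim_dp_config")
}

#' Clip a per-sample gradient to l2 norm at most C
#'
#' Returns `g * min(1, C / max(||g||_2, norm_floor))`: direction is
#' preserved and the output norm never exceeds `C` (up to floating-point
#' rounding). The norm floor guards the zero gradient.
#'
#' @param g numeric gradient vector.
#' @param C clipping bound (> 0).
#' @param norm_floor norm guard.
#' @return clipped vector.
#' @export
clip_per_sample <- function(g, C, norm_floor = 1e-7) {
  stopifnot(C > 0)
  g * min(1, C / max(l2norm(g), norm_floor))
}

#' Batch-average clipped gradients and add calibrated Gaussian noise
#'
#' The mean of the clipped per-sample gradients plus i.i.d. Gaussian noise
#' with per-coordinate standard deviation `eta * C` applied to the batch
#' average (under the default convention; see [dp_config()]).
#'
#' @param clipped_grads matrix of clipped per-sample gradients (rows) or a
#'   list of vectors.
#' @param C clipping bound.
#' @param eta noise multiplier (0 gives the exact mean).
#' @param seed integer seed for the noise draw.
#' @param convention see [dp_config()].
#' @return noisy batch gradient vector.
#' @export
noisy_batch_gradient <- function(clipped_grads, C, eta, seed = 1L,
                                 convention = "batch_mean") {
  if (is.list(clipped_grads)) {
    clipped_grads <- do.call(rbind, clipped_grads)
  }
  stopifnot(nrow(clipped_grads) >= 1, eta >= 0)
  g_bar <- colMeans(clipped_grads)
  if (eta == 0) {
    return(g_bar)
  }
  sd_noise <- if (convention == "batch_mean") eta * C
              else eta * C / nrow(clipped_grads)
  g_bar + withr::with_seed(seed,
                           stats::rnorm(length(g_bar), sd = sd_noise))
}

#' One differentially private local gradient step
#'
#' Per-sample gradients are computed in closed form, individually clipped,
#' batch-averaged with Gaussian noise, and applied as `w - lr * g_hat`.
#' With `eta = 0` and `C` at least the largest per-sample norm this reduces
#' to the plain SGD step.
#'
#' @param w flat parameter vector.
#' @param X,y batch features and integer labels.
#' @param spec a [model_spec()].
#' @param dp a [dp_config()] with `enabled = TRUE`.
#' @param lr learning rate.
#' @param seed integer seed for the noise draw.
#' @return list with updated `w` and the batch `loss`.
#' @export
dp_local_step <- function(w, X, y, spec, dp, lr, seed = 1L) {
  stopifnot(inherits(dp, "fldpsim_dp_config"), dp$enabled)
  psg <- per_sample_gradients(w, spec, X, y)
  clipped <- t(apply(psg$grads, 1, clip_per_sample, C = dp$C,
                     norm_floor = dp$norm_floor))
  if (nrow(psg$grads) == 1) clipped <- matrix(clipped, nrow = 1)
  g_hat <- noisy_batch_gradient(clipped, dp$C, dp$eta, seed, dp$convention)
  list(w = w - lr * g_hat, loss = psg$loss)
}

#' Per-step epsilon of the Gaussian mechanism
#'
#' `sqrt(2 * ln(1.25 / delta)) / eta`. A zero noise multiplier means no
#' privacy: the budget is signaled as `Inf`, not an error.
#'
#' @param eta noise multiplier (>= 0).
#' @param delta per-step privacy slack in (0, 1).
#' @return per-step epsilon (possibly `Inf`).
#' @export
epsilon_step <- function(eta, delta) {
  stopifnot(eta >= 0, delta > 0, delta < 1)
  if (eta == 0) {
    return(Inf)
  }
  sqrt(2 * log(1.25 / delta)) / eta
}

#' Basic (linear) composition over T gradient steps
#' @param eps_step per-step epsilon.
#' @param T_steps number of steps (>= 0).
#' @return `T_steps * eps_step`.
#' @export
compose_basic <- function(eps_step, T_steps) {
  stopifnot(T_steps >= 0)
  T_steps * eps_step
}

#' Sublinear (sqrt-T) composition estimate
#'
#' The advanced-composition-order estimate `sqrt(T) * eps_step`, always at
#' most the basic bound for `T >= 1`.
#'
#' @inheritParams compose_basic
#' @return `sqrt(T_steps) * eps_step`.
#' @export
compose_sublinear <- function(eps_step, T_steps) {
  stopifnot(T_steps >= 0)
  sqrt(T_steps) * eps_step
}

#' Total gradient-step count
#'
#' `R * E * batches_per_epoch`; the companion [batches_per_epoch()] derives
#' the per-epoch batch count from a client size by floor division (partial
#' batches dropped).
#'
#' @param R communication rounds.
#' @param E local epochs per round.
#' @param batches batches per epoch.
#' @return total steps.
#' @export
steps_count <- function(R, E, batches) {
  stopifnot(R >= 1, E >= 1, batches >= 1)
  R * E * batches
}

#' @rdname steps_count
#' @param n_k client sample count.
#' @param B batch size.
#' @export
batches_per_epoch <- function(n_k, B) {
  floor(n_k / B)
}

#' Build a privacy ledger for a training configuration
#'
#' Closed-form accounting over `T = R * E * batches` steps. Two reporting
#' conventions are kept side by side: the exact unrounded values, and a
#' printed-value protocol in which the per-step epsilon is rounded to two
#' decimals before basic composition (this is how a per-step 2.42 composes
#' to 30,250 over 12,500 steps). The per-step slack is set equal to the
#' global `delta`, exactly as the source arithmetic substitutes it; note
#' this conflates per-step and total delta.
#'
#' @param dp a [dp_config()].
#' @param R,E,batches round, epoch and batch counts.
#' @return object of class `fldpsim_privacy_ledger` with fields `T_steps`,
#'   `eps_step`, `eps_step_rounded`, `eps_basic` (exact), `eps_basic_printed`
#'   (rounded protocol), `eps_sublinear`, `delta`.
#' @export
build_ledger <- function(dp, R, E, batches) {
  stopifnot(inherits(dp, "fldpsim_dp_config"))
  T_steps <- steps_count(R, E, batches)
  es <- epsilon_step(dp$eta, dp$delta)
  structure(list(
    eta = dp$eta,
    C = dp$C,
    delta = dp$delta,
    T_steps = T_steps,
    eps_step = es,
    eps_step_rounded = round(es, 2),
    eps_basic = compose_basic(es, T_steps),
    eps_basic_printed = compose_basic(round(es, 2), T_steps),
    eps_sublinear = compose_sublinear(es, T_steps)
  ), class = "fldpsim_privacy_ledger")
}

#' @export
print.fldpsim_privacy_ledger <- function(x, ...) {
  cat(sprintf("privacy ledger: eta=%g C=%g delta=%g T=%d\n",
              x$eta, x$C, x$delta, as.integer(x$T_steps)))
  cat(sprintf("  eps_step      %.4f (rounded %.2f)\n", x$eps_step,
              x$eps_step_rounded))
  cat(sprintf("  eps basic     %.1f (printed protocol %.0f)\n",
              x$eps_basic, x$eps_basic_printed))
  cat(sprintf("  eps sublinear %.1f\n", x$eps_sublinear))
  invisible(x)
}

#' Privacy-budget table over a grid of noise multipliers
#'
#' One row per noise multiplier with basic and sublinear composition
#' bounds, in the layout of the study's budget table.
#'
#' @param etas numeric vector of noise multipliers.
#' @param dp baseline [dp_config()] supplying `C` and `delta`.
#' @param R,E,batches training-length inputs to [steps_count()].
#' @return data frame with columns `eta`, `eps_step`, `eps_basic`,
#'   `eps_basic_printed`, `eps_sublinear`.
#' @export
budget_table <- function(etas, dp = dp_config(), R = 100, E = 5,
                         batches = 25) {
  rows <- lapply(etas, function(e) {
    led <- build_ledger(dp_config(enabled = TRUE, C = dp$C, eta = e,
                                  delta = dp$delta), R, E, batches)
    data.frame(eta = e, eps_step = led$eps_step,
               eps_basic = led$eps_basic,
               eps_basic_printed = led$eps_basic_printed,
               eps_sublinear = led$eps_sublinear)
  })
  do.call(rbind, rows)
}

#' Write a ledger as JSON
#' @param ledger a [build_ledger()] result.
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
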