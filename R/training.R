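# FORCE-style readout training with recursive least squares, plus
# frozen-weight test runs.

#' Initialize an RLS training state
#'
#' @param n_neurons Number of presynaptic rates (readout columns).
#' @param n_outputs Readout rows.
#' @param alpha Initialization scale; `P0 = I / alpha` (acts as an implicit
#'   ridge penalty of strength `alpha`).
#' @param update_every Integration steps between weight updates.
#' @return An object of class `rls_state` with `P`, `W`, `alpha`,
#'   `update_every`.
#' @export
rls_state <- function(n_neurons, n_outputs, alpha = 1, update_every = 2L) {
  stopifnot(n_neurons >= 1, n_outputs >= 1, alpha > 0, update_every >= 1)
  out <- list(P = diag(n_neurons) / alpha,
              W = matrix(0, n_outputs, n_neurons),
              alpha = alpha, update_every = as.integer(update_every))
  class(out) <- "rls_state"
  out
}

#' One recursive-least-squares update
#'
#' Reference (pure R) implementation of the standard RLS step used by the
#' compiled training loop: `k = P r / (1 + r' P r)`, `e = W r - y_target`,
#' `W <- W - e k'`, `P <- P - k (P r)'`. Output weights are unconstrained in
#' sign.
#'
#' @param rls An [rls_state()].
#' @param r Firing-rate vector.
#' @param y_target Target output vector.
#' @return The updated `rls_state` with the pre-update error vector in
#'   element `error`.
#' @export
rls_update <- function(rls, r, y_target) {
  stopifnot(inherits(rls, "rls_state"))
  if (any(!is.finite(r))) stop("non-finite rate vector", call. = FALSE)
  pr <- as.vector(rls$P %*% r)
  k <- pr / (1 + sum(r * pr))
  e <- as.vector(rls$W %*% r) - y_target
  rls$W <- rls$W - outer(e, k)
  rls$P <- rls$P - outer(k, pr)
  if (any(!is.finite(rls$W)) || any(!is.finite(rls$P)))
    stop("training divergence: non-finite RLS update", call. = FALSE)
  rls$error <- e
  rls
}

#' Train the readout with output feedback (FORCE)
#'
#' Runs the network over the assembled training signal with feedback of its
#' own output, applying an RLS update to the readout every `update_every`
#' steps. Training is repeated for `n_iterations` consecutive iterations;
#' the activations are reinitialized (redrawn from the standard normal) at
#' the start of each iteration while `W` and `P` carry over.
#'
#' @param conn A [build_connectivity()] object.
#' @param train_signal An [assemble_signal()] result in train mode.
#' @param n_iterations Training iterations.
#' @param alpha,update_every RLS constants (see [rls_state()]).
#' @return List of class `training_result`: `conn` (with trained `W`),
#'   `err_traces` (per-iteration RMSE traces at each update step) and
#'   `iteration_rmse` (mean RMSE per iteration).
#' @export
train_network <- function(conn, train_signal, n_iterations = 5L,
                          alpha = 1, update_every = 2L) {
  stopifnot(inherits(conn, "connectivity"),
            inherits(train_signal, "assembled_signal"))
  p <- conn$params
  stopifnot(nrow(train_signal$signal) == p$n_outputs)
  code <- transfer_fn(p$transfer)$code
  W <- conn$W
  P <- diag(p$N_tot) / alpha
  err_traces <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(derive_seed(p$seed, 10 + it))
    x0 <- stats::rnorm(p$N_tot)
    res <- cpp_train_rls(conn$J_rec, conn$J_in, conn$J_fb, W, P, x0,
                         train_signal$input_wave, train_signal$signal,
                         p$dt, p$tau, code, as.integer(update_every))
    if (isTRUE(res$diverged))
      stop(sprintf("training divergence in iteration %d at step %d",
                   it, res$divergence_step), call. = FALSE)
    W <- res$W
    P <- res$P
    err_traces[[it]] <- res$err_trace
  }
  conn$W <- W
  out <- list(conn = conn,
              err_traces = err_traces,
              iteration_rmse = vapply(err_traces, mean, numeric(1)))
  class(out) <- "training_result"
  out
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("Trained readout (%d iterations), mean RMSE per iteration: %s\n",
              length(x$err_traces),
              paste(sprintf("%.4f", x$iteration_rmse), collapse = ", ")))
  invisible(x)
}

#' Run a frozen-weight test episode
#'
#' Runs the trained network over the assembled test signal with its own
#' output as feedback and no weight updates. The first stride of the test
#' signal is excluded from evaluation (transient phase); the returned object
#' carries the targets and stride spans for the metrics.
#'
#' @param trained A `training_result` (or a `connectivity` with trained `W`).
#' @param test_signal An [assemble_signal()] result in test mode.
#' @param record Record the full rate/activation matrices.
#' @param init_seed Seed for the initial activation.
#' @return List of class `test_run`: `outputs`, `targets`, `stride_spans`,
#'   `exclude_first = TRUE`, and when `record`ed also `rates` and
#'   `activations`.
#' @export
test_network <- function(trained, test_signal, record = TRUE,
                         init_seed = NULL) {
  conn <- if (inherits(trained, "training_result")) trained$conn else trained
  stopifnot(inherits(conn, "connectivity"),
            inherits(test_signal, "assembled_signal"))
  if (is.null(init_seed))
    init_seed <- derive_seed(conn$params$seed, "init_state")
  res <- run_network(conn, test_signal$input_wave, record = record,
                     init_seed = init_seed)
  out <- list(outputs = res$outputs, targets = test_signal$signal,
              stride_spans = test_signal$stride_spans,
              exclude_first = TRUE,
              rates = res$rates, activations = res$activations)
  class(out) <- "test_run"
  out
}
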