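# Rate dynamics: a single Euler step (reference implementation) and full runs
# through the compiled core.

#' Initialize a network state
#'
#' Activations are drawn from the standard normal; rates and output follow.
#'
#' @param conn A [build_connectivity()] object.
#' @param seed Seed for the initial-state stream; defaults to the stream
#'   derived from the network's master seed.
#' @return A `network_state` list with `x`, `r`, `y` and `t`.
#' @export
init_state <- function(conn, seed = derive_seed(conn$params$seed, "init_state")) {
  stopifnot(inherits(conn, "connectivity"))
  set.seed(seed)
  x <- stats::rnorm(conn$params$N_tot)
  tf <- transfer_fn(conn$params$transfer)
  r <- tf$phi(x)
  out <- list(x = x, r = r, y = as.vector(conn$W %*% r), t = 0)
  class(out) <- "network_state"
  out
}

#' One Euler-forward integration step
#'
#' Reference (pure R) implementation of
#' `x <- x + (dt/tau) * (-x + J_rec phi(x) + J_fb y_fb + J_in u)`;
#' the compiled core used by [run_network()] performs the same update.
#'
#' @param state A `network_state` (see [init_state()]).
#' @param conn A `connectivity` object.
#' @param u Scalar external input value `U(t)`.
#' @param y_fb Feedback vector (length `n_outputs`); defaults to the state's
#'   own output.
#' @return The updated `network_state`.
#' @export
step_network <- function(state, conn, u, y_fb = state$y) {
  p <- conn$params
  tf <- transfer_fn(p$transfer)
  drive <- as.vector(conn$J_rec %*% state$r) +
    as.vector(conn$J_fb %*% y_fb) + conn$J_in * u
  x <- state$x + (p$dt / p$tau) * (-state$x + drive)
  if (any(!is.finite(x)) || max(abs(x)) > 1e6)
    stop("numerical divergence: activation exceeded 1e6 or became non-finite",
         call. = FALSE)
  r <- tf$phi(x)
  out <- list(x = x, r = r, y = as.vector(conn$W %*% r), t = state$t + p$dt)
  class(out) <- "network_state"
  out
}

#' Run the network over an input series
#'
#' Integrates the rate dynamics with Euler forward over the full input series
#' (sampled at `dt`). Feedback is the network's own output `y = W r` unless an
#' external feedback matrix is supplied. The initial activation is drawn from
#' the standard normal unless `x0` is given.
#'
#' @param conn A `connectivity` object.
#' @param input Numeric vector, the external input series `U(t)`.
#' @param feedback Optional external feedback matrix (`n_outputs x length(input)`);
#'   if `NULL` the network feeds back its own output.
#' @param x0 Optional initial activation vector.
#' @param record Logical; record the full rate/activation matrices.
#' @param init_seed Seed used to draw `x0` when it is not supplied.
#' @return List with `outputs` (`n_outputs x T`), `x_final`, and when
#'   `record = TRUE` also `rates` and `activations` (`N_tot x T`).
#' @export
run_network <- function(conn, input, feedback = NULL, x0 = NULL,
                        record = TRUE,
                        init_seed = derive_seed(conn$params$seed, "init_state")) {
  stopifnot(inherits(conn, "connectivity"))
  p <- conn$params
  if (is.null(x0)) {
    set.seed(init_seed)
    x0 <- stats::rnorm(p$N_tot)
  }
  if (!is.null(feedback)) {
    feedback <- as.matrix(feedback)
    stopifnot(nrow(feedback) == p$n_outputs, ncol(feedback) == length(input))
  }
  res <- cpp_run_network(conn$J_rec, conn$J_in, conn$J_fb, conn$W,
                         x0, as.numeric(input), feedback,
                         p$dt, p$tau, transfer_fn(p$transfer)$code,
                         record)
  if (isTRUE(res$diverged))
    stop(sprintf("numerical divergence at step %d (unstable regime)",
                 res$divergence_step), call. = FALSE)
  res$diverged <- NULL
  res$divergence_step <- NULL
  res$x0 <- x0
  res
}

#' Echo-state convergence probe
#'
#' Runs two copies of the same driven network from independent random initial
#' states and reports the ratio of the final to the initial state distance.
#' A driven reservoir whose state has forgotten its initial condition
#' (ratio below `tol`) is operationally stable; a ratio of order one marks
#' chaotic, initial-condition-sensitive dynamics.
#'
#' @param conn A `connectivity` object (readout ignored; feedback is zero
#'   because `W = 0` is used).
#' @param input External input series.
#' @param seed Seed for the two initial states.
#' @return The distance ratio `||x1(T) - x2(T)|| / ||x1(0) - x2(0)||`.
#' @export
esp_distance_ratio <- function(conn, input, seed = 1L) {
  p <- conn$params
  set.seed(seed)
  x1 <- stats::rnorm(p$N_tot)
  x2 <- stats::rnorm(p$N_tot)
  W0 <- matrix(0, p$n_outputs, p$N_tot)
  code <- transfer_fn(p$transfer)$code
  r1 <- cpp_run_network(conn$J_rec, conn$J_in, conn$J_fb, W0, x1,
                        as.numeric(input), NULL, p$dt, p$tau, code, FALSE)
  r2 <- cpp_run_network(conn$J_rec, conn$J_in, conn$J_fb, W0, x2,
                        as.numeric(input), NULL, p$dt, p$tau, code, FALSE)
  if (isTRUE(r1$diverged) || isTRUE(r2$diverged)) return(Inf)
  sqrt(sum((r1$x_final - r2$x_final)^2)) / sqrt(sum((x1 - x2)^2))
}
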