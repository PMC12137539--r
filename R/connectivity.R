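# Realized connectivity: sparse Dale's-law recurrent weights, input weights,
# feedback weights, and the (trainable) readout.

#' Transfer functions
#'
#' Returns the named transfer strategy as a list with elements `phi` (the
#' rate function) and `dphi` (its derivative). Every strategy maps the reals
#' into `[0, 1)`. `"rect_tanh"` is `max(0, tanh(x))`: zero rate for
#' non-positive drive, saturating below 1 for large drive.
#'
#' @param name `"rect_tanh"` or `"sigmoid"`.
#' @return List with functions `phi(x)` and `dphi(x)` and the integer `code`
#'   used by the compiled core.
#' @export
transfer_fn <- function(name = c("rect_tanh", "sigmoid")) {
  name <- match.arg(name)
  switch(name,
    rect_tanh = list(
      name = name, code = 0L,
      phi  = function(x) pmax(0, tanh(x)),
      dphi = function(x) ifelse(x > 0, 1 - tanh(x)^2, 0)
    ),
    sigmoid = list(
      name = name, code = 1L,
      phi  = function(x) 1 / (1 + exp(-x)),
      dphi = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }
    )
  )
}

#' Build a realized network connectivity
#'
#' Draws the recurrent matrix with independent Bernoulli(`p`) masks per
#' population block (self-connections included) and half-normal magnitudes
#' scaled by the pre-truncation standard deviation `sqrt(V0)`; columns of
#' excitatory neurons are nonnegative and columns of inhibitory neurons
#' nonpositive (Dale's law). Input weights are Gaussian with mean 0 and
#' variance `v_in`; feedback weights are uniform on `[-1, 1]`; the readout
#' matrix `W` starts at zero. Column `j` holds the outgoing weights of neuron
#' `j`; neurons `1..N_E` are excitatory, the rest inhibitory.
#'
#' @param params A [network_params()] object.
#' @param seed Seed for the connectivity stream; defaults to the stream
#'   derived from `params$seed`.
#' @return An object of class `connectivity`: list with sparse `J_rec`
#'   (`N_tot x N_tot`, `Matrix::dgCMatrix`), `J_in` (`N_tot`), `J_fb`
#'   (`N_tot x n_outputs`), `W` (`n_outputs x N_tot`) and `params`.
#' @export
#' @examples
#' conn <- build_connectivity(network_params(40, 40, 0.2, 0.2, 1.5, 1.5, seed = 7))
#' all(conn$J_rec[, 1:40] >= 0)
build_connectivity <- function(params, seed = derive_seed(params$seed, "connectivity")) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N_tot
  wm <- weight_moments(params)
  set.seed(seed)
  draw_block <- function(ncol_, V0, sign_) {
    mask <- matrix(stats::rbinom(N * ncol_, 1L, if (sign_ > 0) params$p_E else params$p_I),
                   N, ncol_)
    mag <- abs(matrix(stats::rnorm(N * ncol_, 0, sqrt(V0)), N, ncol_))
    sign_ * mask * mag
  }
  J <- cbind(draw_block(params$N_E, wm$V0_E, +1),
             draw_block(params$N_I, wm$V0_I, -1))
  J_rec <- methods::as(Matrix::Matrix(J, sparse = TRUE), "CsparseMatrix")
  J_in <- stats::rnorm(N, 0, sqrt(params$v_in))
  J_fb <- matrix(stats::runif(N * params$n_outputs, -1, 1), N, params$n_outputs)
  W <- matrix(0, params$n_outputs, N)
  out <- list(J_rec = J_rec, J_in = J_in, J_fb = J_fb, W = W,
              params = params, seed = seed)
  class(out) <- "connectivity"
  out
}

#' @export
print.connectivity <- function(x, ...) {
  nnz <- length(x$J_rec@x)
  cat(sprintf("Realized connectivity: %d neurons (%d E / %d I), %d nonzero recurrent weights (%.1f%%)\n",
              x$params$N_tot, x$params$N_E, x$params$N_I, nnz,
              100 * nnz / x$params$N_tot^2))
  cat(sprintf("  readout: %d outputs, ||W|| = %.3g\n",
              nrow(x$W), sqrt(sum(x$W^2))))
  invisible(x)
}

#' Empirical weight moments of a realized connectivity
#'
#' Full-set (zeros included) mean and variance per population block, the
#' realized imbalance (sum of the mean weights onto a neuron) and the
#' realized nonzero fractions. Used to check the generator against the
#' analytic moments.
#'
#' @param conn A [build_connectivity()] object.
#' @return List with `m_E`, `m_I`, `v_E`, `v_I`, `A_emp`, `p_E_emp`, `p_I_emp`.
#' @export
empirical_weight_moments <- function(conn) {
  stopifnot(inherits(conn, "connectivity"))
  p <- conn$params
  J <- conn$J_rec
  N <- p$N_tot
  blkE <- J[, seq_len(p$N_E), drop = FALSE]
  blkI <- J[, p$N_E + seq_len(p$N_I), drop = FALSE]
  pop_var <- function(x) mean(x^2) - mean(x)^2
  xE <- as.vector(blkE); xI <- as.vector(blkI)
  list(
    m_E = mean(xE), m_I = mean(xI),
    v_E = pop_var(xE), v_I = pop_var(xI),
    A_emp = mean(Matrix::rowSums(J)),
    p_E_emp = mean(xE != 0), p_I_emp = mean(xI != 0)
  )
}

#' Write / read a connectivity as plain text
#'
#' Serializes the realized network to a directory: the sparse recurrent
#' matrix as a triplet CSV (`i`, `j`, `x`), dense weights as CSVs, and all
#' parameters plus the seed as JSON.
#'
#' @param conn A `connectivity` object.
#' @param dir Output directory (created if missing).
#' @return `write_connectivity` returns `dir` invisibly; `read_connectivity`
#'   returns the reconstructed `connectivity` object.
#' @export
write_connectivity <- function(conn, dir) {
  stopifnot(inherits(conn, "connectivity"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trip <- Matrix::summary(conn$J_rec)
  utils::write.csv(as.data.frame(trip), file.path(dir, "J_rec.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(J_in = conn$J_in), file.path(dir, "J_in.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(conn$J_fb), file.path(dir, "J_fb.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(conn$W), file.path(dir, "W.csv"),
                   row.names = FALSE)
  meta <- unclass(conn$params)
  meta$connectivity_seed <- conn$seed
  jsonlite::write_json(meta, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- network_params(meta$N_E, meta$N_I, meta$p_E, meta$p_I,
                           meta$g_E, meta$g_I, tau = meta$tau, dt = meta$dt,
                           v_in = meta$v_in, n_outputs = meta$n_outputs,
                           seed = meta$seed, transfer = meta$transfer)
  trip <- utils::read.csv(file.path(dir, "J_rec.csv"))
  N <- params$N_tot
  J_rec <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                dims = c(N, N))
  out <- list(
    J_rec = methods::as(J_rec, "CsparseMatrix"),
    J_in = utils::read.csv(file.path(dir, "J_in.csv"))$J_in,
    J_fb = as.matrix(utils::read.csv(file.path(dir, "J_fb.csv"))),
    W = as.matrix(utils::read.csv(file.path(dir, "W.csv"))),
    params = params, seed = meta$connectivity_seed
  )
  dimnames(out$J_fb) <- NULL
  dimnames(out$W) <- NULL
  class(out) <- "connectivity"
  out
}
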