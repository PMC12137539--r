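# RLS training: update algebra, ridge equivalence, FORCE protocol.

test_that("rls_update leaves a perfect readout unchanged", {
  rls <- rls_state(5, 2)
  rls$W <- matrix(rnorm(10), 2, 5)
  r <- runif(5)
  y <- as.vector(rls$W %*% r)
  out <- rls_update(rls, r, y)
  expect_equal(out$W, rls$W)
  expect_equal(out$error, c(0, 0))
})

test_that("scalar RLS converges to y/r for constant data", {
  rls <- rls_state(1, 1, alpha = 1e-4)
  for (i in 1:200) rls <- rls_update(rls, 2, 3)
  expect_equal(rls$W[1, 1], 1.5, tolerance = 1e-4)
})

test_that("P stays symmetric positive definite during training", {
  set.seed(7)
  rls <- rls_state(6, 1)
  for (i in 1:100) {
    r <- runif(6)
    rls <- rls_update(rls, r, sum(r) + rnorm(1, sd = 0.01))
    expect_equal(rls$P, t(rls$P), tolerance = 1e-10)
  }
  expect_gt(min(eigen(rls$P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("RLS with every-step updates matches the ridge solution", {
  # classical equivalence on a 10-neuron fixed-rate regression problem:
  # after a full pass, W equals the ridge regression with penalty alpha
  set.seed(11)
  n <- 10L; T_ <- 300L; alpha <- 2
  R <- matrix(runif(n * T_), n, T_)
  w_true <- rnorm(n)
  Y <- matrix(drop(crossprod(R, w_true)) + rnorm(T_, sd = 0.05), 1)
  rls <- rls_state(n, 1, alpha = alpha, update_every = 1L)
  for (t in seq_len(T_)) rls <- rls_update(rls, R[, t], Y[, t])
  ridge <- solve(R %*% t(R) + alpha * diag(n), R %*% t(Y))
  expect_equal(as.vector(rls$W), as.vector(ridge), tolerance = 1e-8)
})

test_that("teacher-student recovery through the compiled trainer", {
  # targets generated as W* r(t) from the frozen network's own rates
  prm <- network_params(30, 30, 0.2, 0.2, 1, 1, n_outputs = 2, seed = 13)
  conn <- build_connectivity(prm)
  conn$J_fb <- matrix(0, 60, 2)   # decouple feedback so rates are shared
  u <- 1 + sin(2 * pi / 0.5 * (1:1200) * prm$dt)
  ref <- run_network(conn, u, record = TRUE, init_seed = 1)
  W_star <- matrix(rnorm(2 * 60, sd = 0.2), 2, 60)
  targets <- W_star %*% ref$rates
  sig <- structure(list(signal = targets, input_wave = u,
                        stride_spans = data.frame(start = c(1, 601),
                                                  end = c(600, 1200),
                                                  activity = c("a", "b"),
                                                  period = 0.5),
                        sample_rate = 200, mode = "train"),
                   class = "assembled_signal")
  trained <- train_network(conn, sig, n_iterations = 5, update_every = 1L)
  run <- run_network(trained$conn, u, record = FALSE, init_seed = 1)
  post <- 201:1200  # skip the initial transient
  rmse <- sqrt(mean((run$outputs[, post] - targets[, post])^2))
  expect_lt(rmse, 1e-2)
})

test_that("zero targets keep the readout at zero", {
  prm <- network_params(20, 20, 0.2, 0.2, 1, 1, n_outputs = 2, seed = 14)
  conn <- build_connectivity(prm)
  sig <- structure(list(signal = matrix(0, 2, 400),
                        input_wave = rep(1, 400),
                        stride_spans = data.frame(start = 1, end = 400,
                                                  activity = "a", period = 2),
                        sample_rate = 200, mode = "train"),
                   class = "assembled_signal")
  trained <- train_network(conn, sig, n_iterations = 2)
  expect_lt(sqrt(sum(trained$conn$W^2)), 1e-6)
})

test_that("training and testing are deterministic given seeds", {
  tg <- synthetic_muscle_targets(seed = 1)
  tr <- assemble_signal(tg, "train")
  te <- assemble_signal(tg, "test", seed = 2)
  prm <- network_params(40, 40, 0.2, 0.2, 1.4, 1.4, seed = 17)
  t1 <- train_network(build_connectivity(prm), tr, n_iterations = 2)
  t2 <- train_network(build_connectivity(prm), tr, n_iterations = 2)
  expect_identical(t1$conn$W, t2$conn$W)
  r1 <- test_network(t1, te)
  r2 <- test_network(t2, te)
  expect_identical(r1$outputs, r2$outputs)
  expect_true(r1$exclude_first)
})

test_that("training divergence carries the iteration index", {
  prm <- network_params(10, 10, 0.3, 0.3, 1, 1, n_outputs = 1, seed = 18)
  conn <- build_connectivity(prm)
  conn$J_in <- rep(1e7, 20)   # guarantees |x| > 1e6 within a step
  sig <- structure(list(signal = matrix(1, 1, 400),
                        input_wave = rep(1, 400),
                        stride_spans = data.frame(start = 1, end = 400,
                                                  activity = "a", period = 2),
                        sample_rate = 200, mode = "train"),
                   class = "assembled_signal")
  expect_error(train_network(conn, sig), "iteration")
})
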