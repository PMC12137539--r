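# Imbalance algebra and parameter handling.

test_that("truncated_gaussian_variance matches the closed form", {
  v <- 1.5^2 / 375
  expect_equal(truncated_gaussian_variance(v, 0.1),
               v / (0.1 * (1 - 0.2 / pi)))
  expect_equal(truncated_gaussian_variance(v, 0.1), 0.0640794,
               tolerance = 1e-5)
  # dense limit
  expect_equal(truncated_gaussian_variance(2, 1), 2 / (1 - 2 / pi))
})

test_that("truncated_gaussian_variance validates inputs", {
  expect_error(truncated_gaussian_variance(-1, 0.1), "positive")
  expect_error(truncated_gaussian_variance(0, 0.1), "positive")
  expect_error(truncated_gaussian_variance(1, 0), "\\(0, 1\\]")
  expect_error(truncated_gaussian_variance(1, 1.2), "\\(0, 1\\]")
})

test_that("sparse half-normal sample moments match the closed forms", {
  # Monte-Carlo oracle: full-set mean and variance of the generator
  v <- 1.5^2 / 375; p <- 0.1; n <- 1e6
  V0 <- truncated_gaussian_variance(v, p)
  set.seed(42)
  w <- rbinom(n, 1, p) * abs(rnorm(n, 0, sqrt(V0)))
  m_expect <- halfnormal_weight_mean(v, p)
  expect_equal(m_expect, sqrt(2 / pi) * sqrt(p * v / (1 - 2 * p / pi)))
  se_mean <- sqrt(v / n)
  expect_lt(abs(mean(w) - m_expect), 4 * se_mean)
  se_var <- sqrt((mean((w - mean(w))^4) - var(w)^2) / n)
  expect_lt(abs(var(w) - v), 4 * se_var)
})

test_that("network_params derives composite quantities", {
  p <- network_params(375, 375, 0.1, 0.1, 1.5, 1.5)
  expect_s3_class(p, "network_params")
  expect_equal(p$v_E, 1.5^2 / 375)
  expect_equal(p$g_tot, sqrt(2 * 1.5^2))
  expect_equal(p$N_tot, 750L)
  expect_equal(p$p_tot, 0.1)
  expect_equal(sqrt(p$v_E * p$N_E + p$v_I * p$N_I), p$g_tot)
})

test_that("network_params rejects invalid anatomy", {
  expect_error(network_params(0, 375, 0.1, 0.1, 1.5, 1.5), "positive integers")
  expect_error(network_params(375, 375, 0, 0.1, 1.5, 1.5), "p_E")
  expect_error(network_params(375, 375, 0.1, 0.1, -1, 1.5), "g_E")
  expect_error(network_params(375, 375, 0.1, 0.1, 1.5, 1.5, dt = 0), "positive")
})

test_that("weight_moments ties A to the population means", {
  p <- network_params(375, 375, 0.1, 0.1, 0.92, 1.91)
  wm <- weight_moments(p)
  expect_gte(wm$m_E, 0)
  expect_lte(wm$m_I, 0)
  expect_equal(wm$A, wm$m_E * p$N_E + wm$m_I * p$N_I)
  expect_equal(wm$A, imbalance_of(p))
})

test_that("symmetric populations have zero imbalance", {
  expect_equal(imbalance_of(network_params(375, 375, 0.1, 0.1, 1.5, 1.5)), 0)
})

test_that("imbalance_of reproduces the printed parameter values", {
  g_tot <- sqrt(2 * 1.5^2)
  A_m5 <- imbalance_of(network_params(375, 375, 0.1, 0.1, 0.92, 1.91))
  A_p10 <- imbalance_of(network_params(375, 375, 0.1, 0.1, 2.12, 0.14))
  expect_lt(abs(A_m5 - (-5)), 0.05)
  expect_lt(abs(A_p10 - 10), 0.05)
})

test_that("by_g solve is exact and round-trips", {
  g_tot <- sqrt(2 * 1.5^2)
  for (A in c(-10, -5, 0, 3, 10)) {
    p <- solve_params_for_imbalance(A, "by_g", g_tot = g_tot,
                                    N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1)
    expect_equal(imbalance_of(p), A, tolerance = 1e-9)
    expect_equal(p$g_tot, g_tot, tolerance = 1e-9)
  }
  # symmetry at A = 0
  p0 <- solve_params_for_imbalance(0, "by_g", g_tot = g_tot,
                                   N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1)
  expect_equal(p0$g_E, g_tot / sqrt(2))
  expect_equal(p0$g_I, g_tot / sqrt(2))
})

test_that("by_g rejects infeasible imbalances", {
  expect_error(
    solve_params_for_imbalance(50, "by_g", g_tot = 2.1213,
                               N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1),
    "infeasible")
  expect_error(
    solve_params_for_imbalance(-15, "by_g", g_tot = 1,
                               N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1),
    "infeasible")
})

test_that("by_N solve hits the nearest-integer imbalance", {
  p <- solve_params_for_imbalance(4, "by_N", N_tot = 750,
                                  p_E = 0.1, p_I = 0.1, g_E = 1.5, g_I = 1.5)
  expect_equal(p$N_tot, 750L)
  expect_equal(attr(p, "achieved_A"), imbalance_of(p))
  # residual bounded by the effect of one neuron moved between populations
  ach <- attr(p, "achieved_A")
  one_step <- abs(imbalance_of(network_params(p$N_E + 1L, p$N_I - 1L,
                                              0.1, 0.1, 1.5, 1.5)) - ach)
  expect_lt(abs(ach - 4), one_step)
  expect_error(
    solve_params_for_imbalance(1e4, "by_N", N_tot = 750,
                               p_E = 0.1, p_I = 0.1, g_E = 1.5, g_I = 1.5),
    "infeasible")
})

test_that("by_p solve round-trips with p_tot held fixed", {
  for (A in c(-4, 0, 4)) {
    p <- solve_params_for_imbalance(A, "by_p", p_tot = 0.1,
                                    N_E = 375, N_I = 375, g_E = 1.5, g_I = 1.5)
    expect_equal(imbalance_of(p), A, tolerance = 1e-9)
    expect_equal(p$p_tot, 0.1, tolerance = 1e-12)
  }
})

test_that("derive_seed is deterministic, stream-distinct and below 2^31", {
  s1 <- derive_seed(7, "connectivity")
  expect_identical(s1, derive_seed(7, "connectivity"))
  streams <- c("connectivity", "init_state", "shuffle", "input", "probe")
  seeds <- vapply(streams, derive_seed, integer(1), master = 7)
  expect_equal(length(unique(seeds)), length(streams))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_error(derive_seed(7, "nope"), "unknown stream")
})
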