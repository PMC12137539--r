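# Outcome parameters: unit properties and hand-counted cases.

toy_spans <- function(n_strides, len) {
  starts <- seq(1, by = len, length.out = n_strides)
  data.frame(start = starts, end = starts + len - 1,
             activity = rep_len(c("a", "b", "c"), n_strides),
             period = 1)
}

test_that("stride success counts hand-made cases exactly", {
  sp <- toy_spans(2, 10)
  y <- matrix(runif(40), 2)
  expect_equal(stride_success(y, y, sp, exclude_first = FALSE)$performance_pct,
               100)
  off <- y + 0.1
  res <- stride_success(off, y, sp, exclude_first = FALSE)
  expect_equal(res$performance_pct, 0)
  expect_equal(res$rmse_matrix, matrix(0.1, 2, 2), tolerance = 1e-12)
  # off by 0.2 on one of four cells -> 75%
  mixed <- y
  mixed[2, 11:20] <- y[2, 11:20] + 0.2
  expect_equal(stride_success(mixed, y, sp,
                              exclude_first = FALSE)$performance_pct, 75)
})

test_that("stride success excludes the first stride and validates input", {
  sp <- toy_spans(3, 10)
  y <- matrix(runif(60), 2, 30)
  bad <- y
  bad[, 1:10] <- 9  # corrupt only the excluded first stride
  expect_equal(stride_success(bad, y, sp)$performance_pct, 100)
  expect_error(stride_success(y[, 1:20], y, sp), "identical dimensions")
  expect_error(stride_success(y[, 1:20], y[, 1:20], sp), "exceed")
})

test_that("performance is invariant to channel and stride permutations", {
  sp <- toy_spans(3, 10)
  set.seed(1)
  y <- matrix(runif(60), 2)
  x <- y + matrix(rnorm(60, sd = 0.05), 2)
  base <- stride_success(x, y, sp, exclude_first = FALSE)$performance_pct
  perm_ch <- stride_success(x[2:1, ], y[2:1, ], sp,
                            exclude_first = FALSE)$performance_pct
  shuf <- c(11:20, 1:10, 21:30)
  perm_st <- stride_success(x[, shuf], y[, shuf], sp,
                            exclude_first = FALSE)$performance_pct
  expect_equal(base, perm_ch)
  expect_equal(base, perm_st)
})

test_that("effective dimensionality handles canonical cases", {
  t_ <- seq(0, 2 * pi, length.out = 200)
  expect_equal(effective_dimensionality(outer(1:3, sin(t_))), 1L)
  two <- rbind(sin(t_), cos(t_))
  expect_equal(effective_dimensionality(two), 2L)
  expect_equal(effective_dimensionality(matrix(5, 4, 100)), 0L)
  set.seed(2)
  iso <- matrix(rnorm(50 * 5000), 50)
  expect_gte(effective_dimensionality(iso), 48L)
  expect_error(effective_dimensionality(matrix(numeric(0), 0, 0)), "empty")
})

test_that("effective dimensionality is bounded and monotone in threshold", {
  set.seed(3)
  m <- matrix(rnorm(8 * 40), 8)
  d99 <- effective_dimensionality(m, 0.99)
  d90 <- effective_dimensionality(m, 0.90)
  expect_lte(d99, min(dim(m)))
  expect_lte(d90, d99)
})

test_that("coactivation index unit properties", {
  y <- runif(50)
  expect_equal(coactivation_index(y, y), 1)
  a <- c(rep(1, 25), rep(0, 25))
  expect_equal(coactivation_index(a, rev(a)), 0)
  expect_equal(coactivation_index(rep(1, 10), rep(0.5, 10)), 2 / 3)
  # symmetry and, under own-max normalization, rescaling invariance
  b <- runif(50)
  expect_equal(coactivation_index(y, b), coactivation_index(b, y))
  expect_equal(coactivation_index(3 * y, b, normalize = TRUE),
               coactivation_index(y, b, normalize = TRUE))
  expect_warning(na <- coactivation_index(rep(0, 5), rep(1, 5)), "all-zero")
  expect_true(is.na(na))
  expect_error(coactivation_index(c(-1, 1), c(1, 1)), "nonnegative")
})

test_that("mean coactivation averages all unordered pairs", {
  a <- c(rep(1, 5), rep(0, 5))
  m <- rbind(a, rev(a), a)
  # normalized pairs: (1,2) disjoint = 0, (1,3) identical = 1, (2,3) = 0
  expect_equal(mean_coactivation(m), 1 / 3)
})

test_that("between-task variance matches hand computation", {
  sp <- toy_spans(3, 101)
  same <- matrix(rep(sin(seq(0, 2 * pi, length.out = 101)), 3), 1)
  expect_equal(between_task_variance(same, sp, exclude_first = FALSE), 0)
  # constant offsets {0, 1, 2} -> population variance 2/3 everywhere
  offs <- matrix(c(rep(0, 101), rep(1, 101), rep(2, 101)), 1)
  expect_equal(between_task_variance(offs, sp, exclude_first = FALSE), 2 / 3)
  # homogeneity: scaling outputs by c scales the variance by c^2
  set.seed(4)
  y <- matrix(runif(3 * 101), 1)
  v1 <- between_task_variance(y, sp, exclude_first = FALSE)
  v2 <- between_task_variance(3 * y, sp, exclude_first = FALSE)
  expect_equal(v2, 9 * v1)
  expect_error(between_task_variance(y, toy_spans(1, 101),
                                     exclude_first = FALSE), "two activities")
})

test_that("pooled skewness conventions", {
  expect_equal(pooled_skewness(rep(3, 10)), 0)
  sym <- c(0.4, 0.5, 0.6)
  expect_equal(pooled_skewness(sym), 0, tolerance = 1e-12)
  expect_gt(pooled_skewness(c(rep(0, 20), 1)), 0)
  expect_lt(pooled_skewness(c(rep(1, 20), 0)), 0)
})

test_that("firing_rate_stats averages the per-time network moments", {
  rates <- rbind(rep(0.2, 5), rep(0.6, 5))
  st <- firing_rate_stats(rates)
  expect_equal(st$rate_mean, 0.4)
  expect_equal(st$rate_var, mean((c(0.2, 0.6) - 0.4)^2))
  expect_equal(firing_rate_stats(matrix(0.3, 4, 6))$rate_var, 0)
  expect_equal(firing_rate_stats(matrix(0.3, 4, 6))$rate_skewness, 0)
  st2 <- firing_rate_stats(rates, activations = rates * 2)
  expect_equal(st2$input_mean, 0.8)
})

test_that("evaluate_network flattens into a well-formed report row", {
  tg <- synthetic_muscle_targets(seed = 1)
  tr <- assemble_signal(tg, "train")
  te <- assemble_signal(tg, "test", seed = 1)
  prm <- network_params(30, 30, 0.2, 0.2, 1.2, 1.2, seed = 19)
  trained <- train_network(build_connectivity(prm), tr, n_iterations = 1)
  rep_ <- evaluate_network(test_network(trained, te))
  expect_s3_class(rep_, "evaluation_report")
  expect_true(rep_$performance_pct >= 0 && rep_$performance_pct <= 100)
  expect_equal(dim(rep_$success_matrix), c(17L, 20L))  # first stride excluded
  expect_lte(rep_$n_output_pc, 8L)
  row <- report_row(rep_, A = 0, instance = 1)
  expect_equal(nrow(row), 1L)
  expect_true(all(c("performance_pct", "n_npc", "cai_mean",
                    "between_task_var", "rate_skewness") %in% names(row)))
})
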