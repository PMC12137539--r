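# Outcome parameters: stride-success performance, effective dimensionality,
# coactivation index, between-task variance, and firing-rate statistics.

#' Per-muscle per-stride success classification
#'
#' RMSE between output and target per channel and stride; a cell is a
#' success when its RMSE is at or below `threshold`. Performance is the
#' percentage of successes over all evaluated cells; the first stride is
#' excluded by default (transient phase).
#'
#' @param outputs,targets `channels x T` matrices, aligned.
#' @param spans Stride spans data frame (`start`, `end`), as produced by
#'   [assemble_signal()].
#' @param threshold Success RMSE threshold.
#' @param exclude_first Exclude the first stride from the matrices.
#' @return List with `success_matrix` and `rmse_matrix`
#'   (`channels x evaluated strides`) and `performance_pct`.
#' @export
#' @examples
#' y <- matrix(runif(40), 2)
#' sp <- data.frame(start = c(1, 11), end = c(10, 20))
#' stride_success(y, y, sp, exclude_first = FALSE)$performance_pct  # 100
stride_success <- function(outputs, targets, spans, threshold = 0.05,
                           exclude_first = TRUE) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets)))
    stop("outputs and targets must have identical dimensions", call. = FALSE)
  if (max(spans$end) > ncol(outputs))
    stop("stride spans exceed the signal length", call. = FALSE)
  idx <- seq_len(nrow(spans))
  if (exclude_first) idx <- idx[-1]
  rmse <- vapply(idx, function(i) {
    cols <- spans$start[i]:spans$end[i]
    sqrt(rowMeans((outputs[, cols, drop = FALSE] -
                     targets[, cols, drop = FALSE])^2))
  }, numeric(nrow(outputs)))
  rmse <- matrix(rmse, nrow = nrow(outputs))
  success <- rmse <= threshold
  list(success_matrix = success, rmse_matrix = rmse,
       performance_pct = 100 * mean(success))
}

#' Effective dimensionality (99%-variance principal components)
#'
#' Smallest number of principal components whose cumulative explained
#' variance reaches `variance_threshold`. The data matrix follows the
#' package convention `variables x time samples` (neurons or channels in
#' rows); PCA treats time samples as observations, mean-centred. Constant
#' data has dimensionality 0.
#'
#' @param data_matrix `variables x samples` matrix.
#' @param variance_threshold Cumulative-variance threshold (inclusive).
#' @return Integer dimensionality.
#' @export
#' @examples
#' effective_dimensionality(outer(1:3, sin(1:100)))  # rank-1 -> 1
effective_dimensionality <- function(data_matrix, variance_threshold = 0.99) {
  data_matrix <- as.matrix(data_matrix)
  if (length(data_matrix) == 0L)
    stop("empty data matrix", call. = FALSE)
  if (ncol(data_matrix) < 2L)
    stop("need at least 2 time samples", call. = FALSE)
  vars <- apply(data_matrix, 1, stats::var)
  if (all(vars == 0)) return(0L)
  pc <- stats::prcomp(t(data_matrix), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= variance_threshold)[1])
}

#' Coactivation index of two nonnegative signals
#'
#' Instantaneous index `2 * min(Y1, Y2) / (Y1 + Y2)`, time-averaged;
#' timepoints where both signals are zero are excluded. The index is defined
#' on signals already normalized to their own maximum over the evaluated
#' window; set `normalize = TRUE` to apply that normalization here (as the
#' pairwise pipeline [mean_coactivation()] does). Identical signals give 1,
#' signals with disjoint support give 0, the constant normalized pair
#' (1, 0.5) gives 2/3.
#'
#' @param y1,y2 Nonnegative signal vectors of equal length.
#' @param normalize Divide each signal by its own maximum first.
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) if either signal is
#'   identically zero.
#' @export
#' @examples
#' coactivation_index(rep(1, 10), rep(0.5, 10))  # 2/3
coactivation_index <- function(y1, y2, normalize = FALSE) {
  stopifnot(length(y1) == length(y2))
  if (any(y1 < 0) || any(y2 < 0))
    stop("coactivation index requires nonnegative signals", call. = FALSE)
  if (max(y1) == 0 || max(y2) == 0) {
    warning("all-zero signal: coactivation index undefined", call. = FALSE)
    return(NA_real_)
  }
  a <- if (normalize) y1 / max(y1) else y1
  b <- if (normalize) y2 / max(y2) else y2
  denom <- a + b
  keep <- denom > 0
  mean(2 * pmin(a[keep], b[keep]) / denom[keep])
}

#' Mean coactivation index over all channel pairs
#'
#' Each channel is normalized to its own maximum over the window; the mean
#' of [coactivation_index()] over all unordered channel pairs is returned.
#'
#' @param outputs `channels x T` nonnegative matrix.
#' @return Mean pairwise coactivation (`NA` pairs dropped).
#' @export
mean_coactivation <- function(outputs) {
  outputs <- as.matrix(outputs)
  n <- nrow(outputs)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, suppressWarnings(
      coactivation_index(outputs[i, ], outputs[j, ], normalize = TRUE)))
  mean(vals, na.rm = TRUE)
}

# resample one stride (channels x n) to 101 points, 0-100% of the cycle
resample_stride <- function(block, n_points = 101L) {
  n <- ncol(block)
  s_in <- seq(0, 1, length.out = n)
  s_out <- seq(0, 1, length.out = n_points)
  t(apply(block, 1, function(ch) stats::approx(s_in, ch, xout = s_out)$y))
}

#' Between-task variance of the output
#'
#' Every stride is time-normalized to 0-100% (101 points) and averaged
#' within its activity; the variance (population convention, divisor `n`)
#' across the per-activity mean cycles is computed per timepoint and channel
#' and averaged to a scalar.
#'
#' @param outputs `channels x T` matrix.
#' @param spans Stride spans with `activity` labels.
#' @param exclude_first Exclude the first stride.
#' @return Scalar between-task variance.
#' @export
between_task_variance <- function(outputs, spans, exclude_first = TRUE) {
  outputs <- as.matrix(outputs)
  idx <- seq_len(nrow(spans))
  if (exclude_first) idx <- idx[-1]
  acts <- unique(spans$activity[idx])
  if (length(acts) < 2L)
    stop("need at least two activities for between-task variance",
         call. = FALSE)
  task_means <- lapply(acts, function(a) {
    rows <- idx[spans$activity[idx] == a]
    cycles <- lapply(rows, function(i)
      resample_stride(outputs[, spans$start[i]:spans$end[i], drop = FALSE]))
    Reduce(`+`, cycles) / length(cycles)
  })
  stack <- simplify2array(task_means)             # channels x 101 x tasks
  m <- apply(stack, c(1, 2), mean)
  pop_var <- apply(stack, c(1, 2), function(v) mean((v - mean(v))^2))
  mean(pop_var)
}

#' Pooled skewness
#'
#' Third standardized moment of the pooled values; 0 by convention when the
#' standard deviation is 0.
#'
#' @param x Numeric vector or matrix (pooled).
#' @return Scalar skewness.
#' @export
pooled_skewness <- function(x) {
  x <- as.numeric(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Firing-rate and input statistics
#'
#' Across-neuron mean and variance at each timepoint, time-averaged, for
#' both the firing rates and the activations (recurrent + external input
#' `x`); skewness is computed on the pooled (neurons x time) distributions.
#'
#' @param rates `neurons x T` firing-rate matrix.
#' @param activations `neurons x T` activation matrix (optional).
#' @return List with `rate_mean`, `rate_var`, `rate_skewness` and, when
#'   activations are given, `input_mean`, `input_var`, `input_skewness`.
#' @export
firing_rate_stats <- function(rates, activations = NULL) {
  rates <- as.matrix(rates)
  per_time <- function(mat) {
    mu <- colMeans(mat)
    v <- colMeans(mat^2) - mu^2
    list(mean = mean(mu), var = mean(v))
  }
  r <- per_time(rates)
  out <- list(rate_mean = r$mean, rate_var = r$var,
              rate_skewness = pooled_skewness(rates))
  if (!is.null(activations)) {
    a <- per_time(as.matrix(activations))
    out$input_mean <- a$mean
    out$input_var <- a$var
    out$input_skewness <- pooled_skewness(activations)
  }
  out
}

#' Full evaluation report for a test run
#'
#' Bundles every outcome parameter computed on a [test_network()] result.
#'
#' @param run A `test_run`.
#' @param threshold Stride-success RMSE threshold.
#' @return List of class `evaluation_report`: `performance_pct`,
#'   `success_matrix`, `rmse_matrix`, `n_npc` (rate dimensionality, `NA`
#'   without recorded rates), `n_output_pc` (target dimensionality),
#'   `cai_mean`, `between_task_var`, `rate_stats`.
#' @export
evaluate_network <- function(run, threshold = 0.05) {
  stopifnot(inherits(run, "test_run"))
  eval_start <- run$stride_spans$start[2]   # first stride excluded
  eval_cols <- eval_start:ncol(run$outputs)
  ss <- stride_success(run$outputs, run$targets, run$stride_spans,
                       threshold, exclude_first = run$exclude_first)
  out_eval <- pmax(run$outputs[, eval_cols, drop = FALSE], 0)
  report <- list(
    performance_pct = ss$performance_pct,
    success_matrix = ss$success_matrix,
    rmse_matrix = ss$rmse_matrix,
    n_npc = if (is.null(run$rates)) NA_integer_ else
      effective_dimensionality(run$rates[, eval_cols, drop = FALSE]),
    n_output_pc = effective_dimensionality(
      run$targets[, eval_cols, drop = FALSE]),
    cai_mean = mean_coactivation(out_eval),
    between_task_var = between_task_variance(run$outputs, run$stride_spans,
                                             exclude_first = run$exclude_first),
    rate_stats = if (is.null(run$rates)) NULL else
      firing_rate_stats(run$rates[, eval_cols, drop = FALSE],
                        if (is.null(run$activations)) NULL else
                          run$activations[, eval_cols, drop = FALSE])
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation: performance %.1f%%, NPCs %s, CAI %.3f, between-task var %.4g\n",
              x$performance_pct,
              if (is.na(x$n_npc)) "NA" else x$n_npc,
              x$cai_mean, x$between_task_var))
  if (!is.null(x$rate_stats))
    cat(sprintf("  rates: mean %.3f, var %.4g, skew %.3f\n",
                x$rate_stats$rate_mean, x$rate_stats$rate_var,
                x$rate_stats$rate_skewness))
  invisible(x)
}

#' Flatten an evaluation report to one data-frame row
#'
#' @param report An `evaluation_report`.
#' @param ... Leading identifier columns (e.g. `A = -5`, `instance = 1`).
#' @return One-row data frame with all scalar metrics.
#' @export
report_row <- function(report, ...) {
  rs <- report$rate_stats
  data.frame(...,
             performance_pct = report$performance_pct,
             n_npc = report$n_npc,
             n_output_pc = report$n_output_pc,
             cai_mean = report$cai_mean,
             between_task_var = report$between_task_var,
             rate_mean = if (is.null(rs)) NA_real_ else rs$rate_mean,
             rate_var = if (is.null(rs)) NA_real_ else rs$rate_var,
             rate_skewness = if (is.null(rs)) NA_real_ else rs$rate_skewness,
             input_mean = if (is.null(rs) || is.null(rs$input_mean)) NA_real_
               else rs$input_mean,
             input_var = if (is.null(rs) || is.null(rs$input_var)) NA_real_
               else rs$input_var)
}
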