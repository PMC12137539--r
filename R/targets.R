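# Periodic multi-channel target signals: bell-shaped motor-primitive
# patterns, synthetic 17-channel locomotor-like targets, and the stride
# assembly / filtering protocol.

activity_periods <- c(slow_walk = 1.30, fast_walk = 1.00, run = 0.72)

#' Construct a stride pattern
#'
#' @param channels `n_channels x n_samples` matrix, values in `[0, 1]`,
#'   spanning exactly one stride.
#' @param period Stride period in seconds.
#' @param activity_id Activity label (or a speed label for primitives).
#' @param sample_rate Samples per second.
#' @return An object of class `stride_pattern`.
#' @export
stride_pattern <- function(channels, period, activity_id,
                           sample_rate = 200) {
  channels <- as.matrix(channels)
  if (any(!is.finite(channels)) || any(channels < 0) || any(channels > 1))
    stop("stride pattern values must be finite and in [0, 1]", call. = FALSE)
  out <- list(channels = channels, period = period,
              activity_id = activity_id, sample_rate = sample_rate)
  class(out) <- "stride_pattern"
  out
}

#' @export
print.stride_pattern <- function(x, ...) {
  cat(sprintf("Stride pattern '%s': %d channels x %d samples, period %.3f s (%g Hz)\n",
              x$activity_id, nrow(x$channels), ncol(x$channels), x$period,
              x$sample_rate))
  invisible(x)
}

# Gaussian bump on the unit circle: center and width as cycle fractions.
circular_bump <- function(s, center, sigma, amplitude = 0.8) {
  d <- abs(s - center)
  d <- pmin(d, 1 - d)
  amplitude * exp(-d^2 / (2 * sigma^2))
}

# speed (m/s) -> stride frequency (Hz); linear artifact map recorded in docs
speed_to_frequency <- function(speed) 0.6 + 0.25 * speed

#' Bell-shaped motor-primitive patterns at a gait speed
#'
#' Five channels, each a Gaussian bump over the stride cycle with centers
#' evenly spaced at 10/30/50/70/90% of the cycle, width 8% of the cycle and
#' peak amplitude 0.8. The stride period follows a linear speed-to-frequency
#' map, `f = 0.6 + 0.25 * speed` Hz.
#'
#' @param speed Gait speed in m/s, within `[0.3, 2.0]`.
#' @param n_primitives Number of bump channels.
#' @param sample_rate Samples per second.
#' @return A [stride_pattern()] with `activity_id = sprintf("speed_%.1f", speed)`.
#' @export
#' @examples
#' p <- primitive_patterns(1.2)
#' which.max(p$channels[1, ]) < which.max(p$channels[2, ])
primitive_patterns <- function(speed, n_primitives = 5L, sample_rate = 200) {
  if (!is.numeric(speed) || length(speed) != 1L || speed < 0.3 || speed > 2.0)
    stop("speed must be a single value in [0.3, 2.0] m/s", call. = FALSE)
  period <- 1 / speed_to_frequency(speed)
  n <- round(period * sample_rate)
  s <- (seq_len(n) - 1) / n
  centers <- (2 * seq_len(n_primitives) - 1) / (2 * n_primitives)
  ch <- t(vapply(centers, function(c0) circular_bump(s, c0, 0.08), numeric(n)))
  stride_pattern(ch, period, sprintf("speed_%.1f", speed), sample_rate)
}

#' Synthetic 17-channel locomotor-like targets
#'
#' Stand-in generator for multi-muscle activation targets: three activities
#' (slow walk, fast walk, run; periods 1.30 / 1.00 / 0.72 s) sharing one
#' nonnegative mixture of the five primitive bumps per channel (each channel
#' uses 4-5 bumps), plus one activity-specific bump (centers at 15/45/75% of
#' the cycle, width 10%) with per-channel amplitudes. Channels are rescaled
#' to peak 0.9 across activities and clipped to `[0, 1]`. Because every
#' channel is a combination of the 5 shared bump profiles and the 3
#' activity-specific profiles, the generated set has at most
#' `n_primitives + activities = 8` principal components.
#'
#' @param n_channels Number of output channels.
#' @param activities Activity labels (subset of slow_walk/fast_walk/run).
#' @param seed RNG seed; same seed gives identical signals.
#' @param sample_rate Samples per second.
#' @return Named list of [stride_pattern()]s, one per activity.
#' @export
#' @examples
#' tg <- synthetic_muscle_targets(seed = 1)
#' range(tg$run$channels)
synthetic_muscle_targets <- function(n_channels = 17L,
                                     activities = names(activity_periods),
                                     seed = 1L, sample_rate = 200) {
  stopifnot(all(activities %in% names(activity_periods)))
  n_prim <- 5L
  set.seed(seed)
  coef <- matrix(stats::runif(n_prim * n_channels, 0.2, 1), n_prim, n_channels)
  # each channel uses 4 or 5 primitives: drop one at random from half of them
  drop_one <- sample(c(TRUE, FALSE), n_channels, replace = TRUE)
  for (j in which(drop_one)) coef[sample.int(n_prim, 1L), j] <- 0
  extra_amp <- matrix(stats::runif(length(activities) * n_channels, 0.2, 0.8),
                      length(activities), n_channels)
  centers <- (2 * seq_len(n_prim) - 1) / (2 * n_prim)
  extra_centers <- c(0.15, 0.45, 0.75)[seq_along(activities)]
  raw <- lapply(seq_along(activities), function(a) {
    period <- activity_periods[[activities[a]]]
    n <- round(period * sample_rate)
    s <- (seq_len(n) - 1) / n
    basis <- vapply(centers, function(c0) circular_bump(s, c0, 0.08), numeric(n))
    extra <- circular_bump(s, extra_centers[a], 0.10, amplitude = 0.5)
    t(basis %*% coef) + outer(extra_amp[a, ], extra)  # channels x samples
  })
  peak <- apply(do.call(cbind, raw), 1, max)
  out <- lapply(seq_along(activities), function(a) {
    ch <- pmin(pmax(raw[[a]] * (0.9 / peak), 0), 1)
    stride_pattern(ch, activity_periods[[activities[a]]], activities[a],
                   sample_rate)
  })
  names(out) <- activities
  out
}

#' Assemble a stride sequence into a continuous target signal
#'
#' Concatenates strides (train mode: each pattern repeated for 5 consecutive
#' strides in the given order, 15 strides for 3 activities; test mode: 21
#' strides, balanced across activities and shuffled by `seed`). Consecutive
#' strides are joined by one interpolated sample (the midpoint of the
#' adjacent values); the whole signal is low-pass filtered at 20 Hz with a
#' 2nd-order bidirectional Butterworth filter and the first and last 50
#' samples are cut. The paired input wave is `U(t) = 1 + sin(omega t)` with
#' `omega = 2 pi / period` switching at stride boundaries; the phase resets
#' at each boundary so every stride starts at `U = 1` rising.
#'
#' @param strides List of [stride_pattern()]s (the available patterns).
#' @param mode `"train"` or `"test"`.
#' @param seed Shuffle seed for the test-stride order.
#' @param n_test_strides Number of strides in test mode.
#' @param strides_per_activity Consecutive repetitions per pattern in train
#'   mode.
#' @param filter_cutoff Low-pass cutoff in Hz (`NA` to skip filtering).
#' @param trim Samples cut from each end after filtering.
#' @return An object of class `assembled_signal`: list with `signal`
#'   (channels x T), `input_wave` (length T), `stride_spans` (data frame
#'   with `start`, `end`, `activity`, `period` in trimmed-sample indices),
#'   `sample_rate`, `mode`.
#' @export
#' @examples
#' tg <- synthetic_muscle_targets(seed = 1)
#' tr <- assemble_signal(tg, "train")
#' nrow(tr$stride_spans)
assemble_signal <- function(strides, mode = c("train", "test"), seed = 1L,
                            n_test_strides = 21L, strides_per_activity = 5L,
                            filter_cutoff = 20, trim = 50L) {
  mode <- match.arg(mode)
  stopifnot(length(strides) >= 1L)
  if (inherits(strides, "stride_pattern")) strides <- list(strides)
  n_act <- length(strides)
  seq_idx <- if (mode == "train") {
    rep(seq_len(n_act), each = strides_per_activity)
  } else {
    base <- rep_len(seq_len(n_act), n_test_strides)
    set.seed(derive_seed(seed, "shuffle"))
    sample(base)
  }
  sr <- strides[[1]]$sample_rate
  n_ch <- nrow(strides[[1]]$channels)
  dt <- 1 / sr

  blocks <- list()
  u_blocks <- list()
  spans <- data.frame(start = integer(0), end = integer(0),
                      activity = character(0), period = numeric(0))
  pos <- 0L
  for (k in seq_along(seq_idx)) {
    p <- strides[[seq_idx[k]]]
    n <- ncol(p$channels)
    u <- 1 + sin(2 * pi / p$period * (seq_len(n) - 1) * dt)
    if (k > 1L) {
      # one-sample gap filled by linear interpolation (midpoint)
      prev <- blocks[[length(blocks)]]
      gap <- (prev[, ncol(prev)] + p$channels[, 1]) / 2
      blocks[[length(blocks) + 1L]] <- matrix(gap, n_ch, 1)
      u_prev <- u_blocks[[length(u_blocks)]]
      u_blocks[[length(u_blocks) + 1L]] <- (u_prev[length(u_prev)] + u[1]) / 2
      pos <- pos + 1L
    }
    blocks[[length(blocks) + 1L]] <- p$channels
    u_blocks[[length(u_blocks) + 1L]] <- u
    spans <- rbind(spans, data.frame(start = pos + 1L, end = pos + n,
                                     activity = as.character(p$activity_id),
                                     period = p$period))
    pos <- pos + n
  }
  signal <- do.call(cbind, blocks)
  input_wave <- unlist(u_blocks, use.names = FALSE)

  if (!is.na(filter_cutoff)) {
    bf <- signal::butter(2, filter_cutoff / (sr / 2), type = "low")
    signal <- t(apply(signal, 1, function(ch) signal::filtfilt(bf, ch)))
  }
  T_full <- ncol(signal)
  if (trim > 0L) {
    keep <- (trim + 1L):(T_full - trim)
    signal <- signal[, keep, drop = FALSE]
    input_wave <- input_wave[keep]
    spans$start <- pmax(spans$start - trim, 1L)
    spans$end <- pmin(spans$end - trim, length(keep))
    spans <- spans[spans$end > spans$start, , drop = FALSE]
    rownames(spans) <- NULL
  }
  out <- list(signal = signal, input_wave = input_wave, stride_spans = spans,
              sample_rate = sr, mode = mode, seed = seed)
  class(out) <- "assembled_signal"
  out
}

#' @export
print.assembled_signal <- function(x, ...) {
  cat(sprintf("Assembled %s signal: %d channels x %d samples (%.2f s), %d strides\n",
              x$mode, nrow(x$signal), ncol(x$signal),
              ncol(x$signal) / x$sample_rate, nrow(x$stride_spans)))
  invisible(x)
}

#' Write / load stride patterns as CSV
#'
#' One CSV per pattern (samples x channels, full double precision) with the
#' metadata (`activity`, `period`, `sample_rate`) in leading `#` comment
#' lines, so a write-then-load round trip is bit-identical.
#'
#' @param patterns List of [stride_pattern()]s (or a single one).
#' @param dir Output directory (created if missing).
#' @param path For the loader: a pattern CSV file or a directory of them.
#' @return `write_stride_patterns` returns the written file paths invisibly;
#'   `load_external_targets` returns a named list of `stride_pattern`s.
#' @export
write_stride_patterns <- function(patterns, dir) {
  if (inherits(patterns, "stride_pattern")) patterns <- list(patterns)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(patterns, function(p) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", p$activity_id),
                                  ".csv"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# activity: %s", p$activity_id),
                 sprintf("# period: %.17g", p$period),
                 sprintf("# sample_rate: %.17g", p$sample_rate),
                 paste(sprintf("ch%02d", seq_len(nrow(p$channels))),
                       collapse = ",")), con)
    utils::write.table(
      matrix(sprintf("%.17g", t(p$channels)), ncol = nrow(p$channels)),
      con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_stride_patterns
#' @export
load_external_targets <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L)
      stop("no pattern CSV files found in ", path, call. = FALSE)
  } else if (file.exists(path)) {
    files <- path
  } else {
    stop("target file or directory not found: ", path, call. = FALSE)
  }
  out <- lapply(files, function(f) {
    lines <- readLines(f)
    meta_lines <- grep("^#", lines, value = TRUE)
    get_meta <- function(key) {
      ln <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
      if (length(ln) != 1L) stop("missing '", key, "' metadata in ", f,
                                 call. = FALSE)
      trimws(sub(paste0("^# ", key, ":"), "", ln))
    }
    dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
    ch <- t(as.matrix(dat))
    dimnames(ch) <- NULL
    if (any(ch < 0 | ch > 1)) {
      warning("target values outside [0, 1] in ", f, "; clipping",
              call. = FALSE)
      ch <- pmin(pmax(ch, 0), 1)
    }
    stride_pattern(ch, as.numeric(get_meta("period")), get_meta("activity"),
                   as.numeric(get_meta("sample_rate")))
  })
  names(out) <- vapply(out, `[[`, character(1), "activity_id")
  out
}
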