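# Experiment orchestration: imbalance sweeps, the speed-generalization
# experiment, and the mean-field comparison. All runs are deterministic
# given (config, master seed) and resumable from the on-disk result tables.

#' Read an experiment configuration
#'
#' Reads a YAML or JSON configuration file into a plain list. YAML support
#' requires the optional `yaml` package.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# per-(cell, instance) master seed, counter-based
instance_seed <- function(master, cell_index, instance) {
  derive_seed(derive_seed(master, 100 + cell_index), 200 + instance)
}

# parameters for one sweep cell; NULL when the cell is infeasible
cell_params <- function(A, mode, total, N_ref = 375L, p_ref = 0.1,
                        g_ref = 1.5, seed = 1L, n_outputs = 17L) {
  tryCatch(switch(mode,
    by_g = solve_params_for_imbalance(A, "by_g", g_tot = total,
                                      N_E = N_ref, N_I = N_ref,
                                      p_E = p_ref, p_I = p_ref,
                                      seed = seed, n_outputs = n_outputs),
    by_N = solve_params_for_imbalance(A, "by_N", N_tot = total,
                                      p_E = p_ref, p_I = p_ref,
                                      g_E = g_ref, g_I = g_ref,
                                      seed = seed, n_outputs = n_outputs),
    by_p = solve_params_for_imbalance(A, "by_p", p_tot = total,
                                      N_E = N_ref, N_I = N_ref,
                                      g_E = g_ref, g_I = g_ref,
                                      seed = seed, n_outputs = n_outputs)
  ), error = function(e) NULL)
}

# build -> train -> test -> evaluate for one instance on given patterns
run_instance <- function(params, patterns, train_seed = 1L,
                         test_seed = params$seed, n_iterations = 5L) {
  conn <- build_connectivity(params)
  train_sig <- assemble_signal(patterns, "train", seed = train_seed)
  test_sig <- assemble_signal(patterns, "test", seed = test_seed)
  trained <- train_network(conn, train_sig, n_iterations = n_iterations)
  run <- test_network(trained, test_sig)
  evaluate_network(run)
}

#' Run an imbalance sweep
#'
#' For every (imbalance, total level, instance) cell: solve the anatomy,
#' build, train on the synthetic targets, test, and evaluate. Per-instance
#' rows are appended to `<out_dir>/sweep_<mode>.csv` as they finish;
#' rerunning with `resume = TRUE` skips rows already on disk. Infeasible or
#' failed cells are recorded with `status != "ok"` and never abort the
#' sweep.
#'
#' @param mode `"by_g"`, `"by_N"` or `"by_p"`.
#' @param A_grid Imbalance values.
#' @param totals Levels of the swept total (`g_tot`, `N_tot` or `p_tot`).
#' @param n_instances Network instances per cell.
#' @param out_dir Output directory.
#' @param master_seed Master seed expanded per (cell, instance).
#' @param N_ref,p_ref,g_ref Fixed reference values for the non-swept totals.
#' @param targets_seed Seed of the synthetic target generator.
#' @param n_iterations Training iterations.
#' @param resume Skip (cell, instance) rows already present on disk.
#' @return List with `results` (per-instance data frame) and `aggregate`
#'   (mean and SD per cell); both are also written as CSV.
#' @export
run_sweep <- function(mode = c("by_g", "by_N", "by_p"),
                      A_grid = seq(-15, 15), totals, n_instances = 20L,
                      out_dir = ".", master_seed = 1L,
                      N_ref = 375L, p_ref = 0.1, g_ref = 1.5,
                      targets_seed = 1L, n_iterations = 5L, resume = TRUE) {
  mode <- match.arg(mode)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0("sweep_", mode, ".csv"))
  done <- if (resume && file.exists(path)) utils::read.csv(path) else NULL
  patterns <- synthetic_muscle_targets(seed = targets_seed)
  grid <- expand.grid(A = A_grid, total = totals)
  for (ci in seq_len(nrow(grid))) {
    A <- grid$A[ci]; total <- grid$total[ci]
    for (inst in seq_len(n_instances)) {
      if (!is.null(done) &&
          any(done$A == A & done$total == total & done$instance == inst))
        next
      seed <- instance_seed(master_seed, ci, inst)
      prm <- cell_params(A, mode, total, N_ref, p_ref, g_ref, seed = seed)
      row <- if (is.null(prm)) {
        data.frame(mode = mode, A = A, total = total, instance = inst,
                   seed = seed, status = "infeasible")
      } else {
        rep <- tryCatch(
          run_instance(prm, patterns, test_seed = seed,
                       n_iterations = n_iterations),
          error = function(e) e)
        if (inherits(rep, "error")) {
          data.frame(mode = mode, A = A, total = total, instance = inst,
                     seed = seed, status = paste("failed:", conditionMessage(rep)))
        } else {
          cbind(report_row(rep, mode = mode, A = A, total = total,
                           instance = inst, seed = seed),
                status = "ok")
        }
      }
      done <- merge_rows(done, row)
      utils::write.csv(done, path, row.names = FALSE)
    }
  }
  agg <- aggregate_sweep(done)
  utils::write.csv(agg, file.path(out_dir, paste0("sweep_", mode,
                                                  "_aggregate.csv")),
                   row.names = FALSE)
  list(results = done, aggregate = agg)
}

# rbind data frames with differing columns (missing ones filled with NA)
merge_rows <- function(df, row) {
  if (is.null(df)) return(row)
  for (nm in setdiff(names(df), names(row))) row[[nm]] <- NA
  for (nm in setdiff(names(row), names(df))) df[[nm]] <- NA
  rbind(df, row[names(df)])
}

#' Aggregate a sweep result table
#'
#' Mean and SD of every scalar metric across instances, per (A, total) cell
#' (rows with `status != "ok"` excluded).
#'
#' @param results Per-instance data frame from [run_sweep()].
#' @return Aggregate data frame.
#' @export
aggregate_sweep <- function(results) {
  ok <- results[results$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) return(data.frame())
  metric_cols <- setdiff(names(ok), c("mode", "A", "total", "instance",
                                      "seed", "status"))
  agg <- do.call(rbind, lapply(split(ok, list(ok$A, ok$total), drop = TRUE),
    function(g) {
      base <- data.frame(mode = g$mode[1], A = g$A[1], total = g$total[1],
                         n = nrow(g))
      for (m in metric_cols) {
        base[[paste0(m, "_mean")]] <- mean(g[[m]])
        base[[paste0(m, "_sd")]] <- stats::sd(g[[m]])
      }
      base
    }))
  rownames(agg) <- NULL
  agg[order(agg$total, agg$A), ]
}

#' Speed-generalization experiment
#'
#' Trains networks on the 5 bell-shaped primitive patterns at the three
#' training speeds (15 training strides: 5 consecutive per speed) and tests
#' each test speed separately with a 21-stride single-speed test signal.
#'
#' @param A_values Imbalances (solved `by_g` at the reference anatomy).
#' @param n_instances Instances per imbalance.
#' @param speeds_train,speeds_test Gait speeds in m/s.
#' @param g_tot,N_ref,p_ref Reference anatomy.
#' @param master_seed Master seed.
#' @param n_iterations Training iterations.
#' @param out_dir Optional directory for the result CSV.
#' @return Data frame with per (A, instance, speed) success percentage and a
#'   `trained` flag.
#' @export
run_generalization <- function(A_values = c(-5, 0, 10), n_instances = 5L,
                               speeds_train = c(0.6, 1.2, 1.6),
                               speeds_test = seq(0.3, 2.0, by = 0.1),
                               g_tot = 2.1213, N_ref = 375L, p_ref = 0.1,
                               master_seed = 1L, n_iterations = 5L,
                               out_dir = NULL) {
  train_patterns <- lapply(speeds_train, function(s)
    primitive_patterns(s, sample_rate = 200))
  rows <- list()
  for (ai in seq_along(A_values)) {
    A <- A_values[ai]
    for (inst in seq_len(n_instances)) {
      seed <- instance_seed(master_seed, ai, inst)
      prm <- solve_params_for_imbalance(A, "by_g", g_tot = g_tot,
                                        N_E = N_ref, N_I = N_ref,
                                        p_E = p_ref, p_I = p_ref,
                                        seed = seed, n_outputs = 5L)
      conn <- build_connectivity(prm)
      train_sig <- assemble_signal(train_patterns, "train", seed = seed)
      trained <- tryCatch(
        train_network(conn, train_sig, n_iterations = n_iterations),
        error = function(e) e)
      for (sp in speeds_test) {
        row <- data.frame(A = A, instance = inst, speed = sp,
                          trained = sp %in% speeds_train,
                          performance_pct = NA_real_, status = "ok")
        if (inherits(trained, "error")) {
          row$status <- paste("failed:", conditionMessage(trained))
        } else {
          pat <- primitive_patterns(sp, sample_rate = 200)
          test_sig <- assemble_signal(list(pat, pat, pat), "test", seed = seed)
          rep <- tryCatch({
            run <- test_network(trained, test_sig, record = FALSE)
            stride_success(run$outputs, run$targets, run$stride_spans,
                           exclude_first = TRUE)$performance_pct
          }, error = function(e) NA_real_)
          row$performance_pct <- rep
          if (is.na(rep)) row$status <- "failed: test divergence"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "generalization.csv"),
                     row.names = FALSE)
  }
  out
}

#' Mean-field vs. simulation comparison
#'
#' For each imbalance: the mean-field prediction (cycle-averaged over the
#' drive) and the simulated time-averaged mean input and mean rate of
#' untrained networks (`W = 0`, so the feedback contributes nothing). The
#' simulation burns one drive cycle and averages over an integer number of
#' subsequent cycles, which removes the bias from partial cycles.
#'
#' @param A_grid Imbalances.
#' @param n_instances Network instances per imbalance.
#' @param N_tot,p,g_tot Anatomy (split symmetrically, solved `by_g`).
#' @param period Drive period in seconds.
#' @param n_cycles Averaged cycles after the burn-in cycle.
#' @param master_seed Master seed; instance seeds are `master_seed + 0:(n-1)`
#'   offsets through the counter scheme.
#' @param out_dir Optional directory for the result CSV.
#' @return Data frame with per-instance simulated statistics and the shared
#'   MFT columns (`mft_mu`, `mft_phi_mean`, plus the E/I current split).
#' @export
run_mft_comparison <- function(A_grid = c(-10, 0), n_instances = 3L,
                               N_tot = 2000L, p = 0.1, g_tot = 2.1213,
                               period = 0.72, n_cycles = 10L,
                               master_seed = 1L, out_dir = NULL) {
  N_half <- as.integer(N_tot / 2)
  dt <- 0.005
  steps_cycle <- round(period / dt)
  tvec <- seq_len(steps_cycle * (n_cycles + 1)) * dt
  input <- 1 + sin(2 * pi / period * tvec)
  avg_cols <- (steps_cycle + 1):length(tvec)
  rows <- list()
  for (A in A_grid) {
    mft <- mft_curves(A, g_tot = g_tot, N_ref = N_half, p_ref = p)
    for (inst in seq_len(n_instances)) {
      seed <- master_seed + inst - 1L
      prm <- solve_params_for_imbalance(A, "by_g", g_tot = g_tot,
                                        N_E = N_half, N_I = N_half,
                                        p_E = p, p_I = p,
                                        seed = seed, n_outputs = 1L)
      conn <- build_connectivity(prm)
      res <- run_network(conn, input, record = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        A = A, instance = inst, seed = seed,
        sim_mean_input = mean(res$activations[, avg_cols]),
        sim_mean_rate = mean(res$rates[, avg_cols]),
        mft_mu = mft$mu, mft_phi_mean = mft$phi_mean,
        mft_E_current = mft$E_current, mft_I_current = mft$I_current)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "mft_comparison.csv"),
                     row.names = FALSE)
  }
  out
}
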