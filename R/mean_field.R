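# Quasi-stationary mean-field theory of the driven two-population rate
# network: Gaussian rate moments, the self-consistent stationary state, the
# variance-gain stability criterion, and the hybrid (analytic + echo-state
# simulation) stability boundary.

.mft_env <- new.env(parent = emptyenv())

gh_nodes <- function(n = 64L) {
  key <- paste0("gh", n)
  if (is.null(.mft_env[[key]])) .mft_env[[key]] <- pracma::gaussHermite(n)
  .mft_env[[key]]
}

gl_nodes <- function(n = 64L) {
  key <- paste0("gl", n)
  if (is.null(.mft_env[[key]])) .mft_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .mft_env[[key]]
}

# E[ f(mu + sqrt(Delta) z) ], z ~ N(0,1), by Gauss-Hermite quadrature.
# Suitable for transfers that are smooth on the whole real line.
gauss_expect <- function(f, mu, Delta, n_nodes = 64L) {
  if (Delta <= 0) return(f(mu))
  gh <- gh_nodes(n_nodes)
  sum(gh$w * f(mu + sqrt(2 * Delta) * gh$x)) / sqrt(pi)
}

# E[ g(x) * 1(x > 0) ], x ~ N(mu, Delta), for g smooth on [0, Inf).
# Rectified transfers have a kink at 0 that ruins Gauss-Hermite convergence,
# so the expectation is taken over the truncated (smooth) domain with
# Gauss-Legendre nodes centred on the Gaussian mass, which restores
# spectral accuracy (< 1e-10 against adaptive quadrature).
gauss_expect_rect <- function(g, mu, Delta, n_nodes = 64L, width = 12) {
  if (Delta <= 0) return(if (mu > 0) g(mu) else 0)
  s <- sqrt(Delta)
  a <- max(0, mu - width * s)
  b <- mu + width * s
  if (b <= 0) return(0)
  gl <- gl_nodes(n_nodes)
  x <- (a + b) / 2 + (b - a) / 2 * gl$x
  (b - a) / 2 * sum(gl$w * g(x) * stats::dnorm(x, mu, s))
}

# dispatch: expectation of the k-th object (phi, phi^2 or dphi^2) under
# N(mu, Delta), exact about the rectification point for rect_tanh
transfer_expect <- function(what = c("phi", "phi_sq", "dphi_sq"),
                            mu, Delta, transfer, n_nodes = 64L) {
  what <- match.arg(what)
  if (transfer == "rect_tanh") {
    g <- switch(what,
                phi = tanh,
                phi_sq = function(x) tanh(x)^2,
                dphi_sq = function(x) (1 - tanh(x)^2)^2)
    gauss_expect_rect(g, mu, Delta, n_nodes)
  } else {
    tf <- transfer_fn(transfer)
    f <- switch(what,
                phi = tf$phi,
                phi_sq = function(x) tf$phi(x)^2,
                dphi_sq = function(x) tf$dphi(x)^2)
    gauss_expect(f, mu, Delta, n_nodes)
  }
}

#' Gaussian firing-rate moments
#'
#' Population mean rate `[phi]` and mean squared rate `[phi^2]` when the
#' activation is Gaussian with mean `mu` and variance `Delta`:
#' `[phi] = E[phi(mu + sqrt(Delta) z)]`, `z ~ N(0,1)`, and likewise for
#' `[phi^2]`. Computed with 64-node Gaussian quadrature; for the rectified
#' transfer the kink at zero is handled exactly by integrating the smooth
#' part over the truncated domain, which keeps the error below `1e-8`.
#'
#' @param mu Activation mean.
#' @param Delta Activation variance (>= 0).
#' @param transfer Transfer function name (see [transfer_fn()]).
#' @param n_nodes Number of quadrature nodes.
#' @return List with `phi_mean` and `phi_sq_mean`.
#' @export
#' @examples
#' gaussian_moments(0, 1)
gaussian_moments <- function(mu, Delta, transfer = "rect_tanh", n_nodes = 64L) {
  if (Delta < 0) stop("Delta must be nonnegative", call. = FALSE)
  list(
    phi_mean = transfer_expect("phi", mu, Delta, transfer, n_nodes),
    phi_sq_mean = transfer_expect("phi_sq", mu, Delta, transfer, n_nodes)
  )
}

# E[ phi'(mu + sqrt(Delta) z)^2 ]
gaussian_dphi_sq <- function(mu, Delta, transfer = "rect_tanh", n_nodes = 64L) {
  transfer_expect("dphi_sq", mu, Delta, transfer, n_nodes)
}

#' Solve the quasi-stationary mean-field state
#'
#' Finds the self-consistent quadruple `(mu, Delta, [phi], [phi^2])`
#' satisfying `mu = A [phi]` and `Delta = g_tot^2 [phi^2] + v_in u^2`, with
#' the rate moments given by [gaussian_moments()]. Solved by damped
#' fixed-point iteration (damping 0.5) with a derivative-free root solve as
#' fallback; the returned state has self-consistency residuals below
#' `1e-10`.
#'
#' @param A Anatomical imbalance (`m_E N_E + m_I N_I`).
#' @param g_tot Total connection strength (`sqrt(v_E N_E + v_I N_I)`).
#' @param v_in Input-weight variance.
#' @param u External input value `U` at which the quasi-stationary solution
#'   is taken.
#' @param transfer Transfer function name.
#' @param init Optional `c(mu, Delta)` starting point (used for warm starts).
#' @param max_iter Maximum fixed-point iterations.
#' @return An object of class `mft_state`: list with `mu`, `Delta`,
#'   `phi_mean`, `phi_sq_mean`, `u`, `residual`.
#' @export
#' @examples
#' solve_stationary(A = 0, g_tot = sqrt(2 * 1.5^2), u = 1)
solve_stationary <- function(A, g_tot, v_in = 1 / 3, u = 1,
                             transfer = "rect_tanh", init = NULL,
                             max_iter = 10000L) {
  stopifnot(g_tot >= 0, v_in >= 0)
  tf <- transfer
  target <- function(mu, Delta) {
    mom <- gaussian_moments(mu, Delta, tf)
    c(A * mom$phi_mean, g_tot^2 * mom$phi_sq_mean + v_in * u^2)
  }
  st <- if (is.null(init)) c(0, v_in * u^2 + 0.5) else init
  damp <- 0.5
  for (i in seq_len(max_iter)) {
    tg <- target(st[1], st[2])
    new <- (1 - damp) * st + damp * tg
    new[2] <- max(new[2], 0)
    if (max(abs(new - st)) < 1e-13) { st <- new; break }
    st <- new
  }
  resid <- max(abs(st - target(st[1], st[2])))
  if (resid > 1e-10) {
    # fallback: derivative-free root solve on the residual map
    f <- function(z) z - target(z[1], max(z[2], 0))
    sol <- tryCatch(pracma::fsolve(f, st, tol = 1e-12), error = function(e) NULL)
    if (!is.null(sol)) {
      cand <- c(sol$x[1], max(sol$x[2], 0))
      r2 <- max(abs(f(cand)))
      if (r2 < resid) { st <- cand; resid <- r2 }
    }
    if (resid > 1e-10)
      stop(sprintf("mean-field solver failed to converge (residual %.2e)", resid),
           call. = FALSE)
  }
  mom <- gaussian_moments(st[1], st[2], tf)
  out <- list(mu = st[1], Delta = st[2],
              phi_mean = mom$phi_mean, phi_sq_mean = mom$phi_sq_mean,
              u = u, residual = resid)
  class(out) <- "mft_state"
  out
}

#' @export
print.mft_state <- function(x, ...) {
  cat(sprintf("MFT state at U = %.3g: mu = %.5f, Delta = %.5f, [phi] = %.5f, [phi^2] = %.5f (resid %.1e)\n",
              x$u, x$mu, x$Delta, x$phi_mean, x$phi_sq_mean, x$residual))
  invisible(x)
}

#' Variance-gain stability of a stationary mean-field state
#'
#' Linearizing around the stationary state, fluctuations are amplified by the
#' variance gain `g_tot^2 * E[phi'(mu + sqrt(Delta) z)^2]`; the state is
#' linearly stable when the gain is below one. Note that in the driven
#' network this analytic criterion is conservative: see
#' [stability_boundary()] for the simulation-backed boundary.
#'
#' @param state An `mft_state` from [solve_stationary()] (or a list of them,
#'   one per evaluated input value).
#' @param g_tot Total connection strength.
#' @param transfer Transfer function name.
#' @return List with `variance_gain` (vector, one value per state) and
#'   `stable` (TRUE iff the gain is below 1 at every evaluated state).
#' @export
stability_margin <- function(state, g_tot, transfer = "rect_tanh") {
  states <- if (inherits(state, "mft_state")) list(state) else state
  gains <- vapply(states, function(s)
    g_tot^2 * gaussian_dphi_sq(s$mu, s$Delta, transfer), numeric(1))
  list(variance_gain = gains, stable = all(gains < 1))
}

# u values of one cycle of U(t) = 1 + sin(omega t) on an n-point grid
cycle_u_grid <- function(n = 32L) 1 + sin(2 * pi * (seq_len(n) - 1) / n)

# solve the quasi-stationary state along a u grid with warm starts
solve_along_cycle <- function(A, g_tot, v_in = 1 / 3, u_values = cycle_u_grid(),
                              transfer = "rect_tanh") {
  states <- vector("list", length(u_values))
  init <- NULL
  ord <- order(u_values, decreasing = TRUE)  # start from the strongest drive
  for (i in ord) {
    states[[i]] <- solve_stationary(A, g_tot, v_in, u_values[i],
                                    transfer = transfer, init = init)
    init <- c(states[[i]]$mu, states[[i]]$Delta)
  }
  states
}

#' Mean-field curves over an imbalance grid
#'
#' For each imbalance, solves the quasi-stationary state over one cycle of
#' the drive `U(t) = 1 + sin(omega t)` (32-point grid) and averages the
#' moments over the cycle (`u_policy = "cycle_average"`), or evaluates at a
#' single fixed `u`. The mean recurrent input is additionally split into its
#' excitatory part `m_E N_E [phi]` and inhibitory part `m_I N_I [phi]`,
#' using the reference anatomy (`N_E = N_I`, common `p`) to map `(A, g_tot)`
#' to the population strengths.
#'
#' @param A_grid Imbalance values.
#' @param g_tot Total connection strength.
#' @param v_in Input-weight variance.
#' @param u_policy `"cycle_average"` (default) or `"fixed"`.
#' @param u Input value when `u_policy = "fixed"`.
#' @param n_u Number of cycle grid points.
#' @param N_ref,p_ref Reference per-population size and connection
#'   probability used for the E/I current split.
#' @param transfer Transfer function name.
#' @return A data frame with one row per imbalance: `A`, `g_tot`, `u_policy`,
#'   `mu`, `Delta`, `phi_mean`, `phi_sq_mean`, `E_current`, `I_current`,
#'   `stable` (analytic variance-gain criterion at every grid `u`).
#' @export
mft_curves <- function(A_grid, g_tot, v_in = 1 / 3,
                       u_policy = c("cycle_average", "fixed"), u = 1,
                       n_u = 32L, N_ref = 375L, p_ref = 0.1,
                       transfer = "rect_tanh") {
  u_policy <- match.arg(u_policy)
  u_values <- if (u_policy == "fixed") u else cycle_u_grid(n_u)
  rows <- lapply(A_grid, function(A) {
    states <- solve_along_cycle(A, g_tot, v_in, u_values, transfer)
    mu <- mean(vapply(states, `[[`, numeric(1), "mu"))
    Delta <- mean(vapply(states, `[[`, numeric(1), "Delta"))
    phim <- mean(vapply(states, `[[`, numeric(1), "phi_mean"))
    phi2m <- mean(vapply(states, `[[`, numeric(1), "phi_sq_mean"))
    sm <- stability_margin(states, g_tot, transfer)
    # E/I split via the reference anatomy
    prm <- solve_params_for_imbalance(A, "by_g", g_tot = g_tot,
                                      N_E = N_ref, N_I = N_ref,
                                      p_E = p_ref, p_I = p_ref)
    wm <- weight_moments(prm)
    data.frame(A = A, g_tot = g_tot, u_policy = u_policy,
               mu = mu, Delta = Delta,
               phi_mean = phim, phi_sq_mean = phi2m,
               E_current = wm$m_E * prm$N_E * phim,
               I_current = wm$m_I * prm$N_I * phim,
               stable = sm$stable)
  })
  do.call(rbind, rows)
}

#' Stability boundary over a (g_tot, A) grid
#'
#' Classifies every grid cell as stable or unstable. Analytically stable
#' cells (variance gain below one at every point of the input cycle) are
#' accepted directly. Because the analytic criterion ignores the stabilizing
#' effect of the time-varying drive it is conservative; cells it flags are
#' re-examined with an echo-state convergence probe on realized networks:
#' two copies of the same driven network started from independent random
#' states must contract their state distance by `esp_tol` within
#' `esp_horizon` seconds, for every probe seed. The returned table carries
#' the analytic gain, the probe result, and the final verdict; the largest
#' `g_tot` stable for all imbalances is in attribute `"max_stable_g_tot"`.
#'
#' @param g_grid Total connection strengths to test.
#' @param A_grid Imbalances to test.
#' @param v_in Input-weight variance.
#' @param n_u Cycle grid size for the analytic criterion.
#' @param N_ref,p_ref Reference anatomy for the probe networks.
#' @param esp_horizon Probe duration in seconds.
#' @param esp_tol Contraction ratio below which the probe counts as
#'   converged.
#' @param esp_seeds Probe seeds (every one must converge).
#' @param omega Drive angular frequency for the probe (defaults to the
#'   running stride, period 0.72 s).
#' @param dt,tau Integration constants for the probe.
#' @param transfer Transfer function name.
#' @return Data frame with columns `g_tot`, `A`, `max_gain`,
#'   `analytic_stable`, `esp_ratio` (NA where no probe was needed) and
#'   `stable`; attribute `"max_stable_g_tot"` holds the largest grid value
#'   stable for every imbalance.
#' @export
stability_boundary <- function(g_grid, A_grid = -15:15, v_in = 1 / 3,
                               n_u = 32L, N_ref = 375L, p_ref = 0.1,
                               esp_horizon = 10, esp_tol = 1e-6,
                               esp_seeds = c(1L, 2L),
                               omega = 2 * pi / 0.72,
                               dt = 0.005, tau = 0.01,
                               transfer = "rect_tanh") {
  u_values <- cycle_u_grid(n_u)
  tvec <- seq_len(round(esp_horizon / dt)) * dt
  probe_input <- 1 + sin(omega * tvec)
  rows <- list()
  for (g_tot in sort(g_grid)) {
    for (A in A_grid) {
      states <- solve_along_cycle(A, g_tot, v_in, u_values, transfer)
      sm <- stability_margin(states, g_tot, transfer)
      esp_ratio <- NA_real_
      stable <- sm$stable
      if (!stable) {
        # the probe needs a realizable network: |A| <= k(N) * g_tot with
        # k the imbalance coefficient, so enlarge the probe populations
        # until the cell's imbalance is reachable
        N_probe <- N_ref
        while (abs(A) > imbalance_coeff(N_probe, p_ref) * g_tot - 1e-12)
          N_probe <- N_probe * 2L
        ratios <- vapply(esp_seeds, function(s) {
          prm <- solve_params_for_imbalance(
            A, "by_g", g_tot = g_tot, N_E = N_probe, N_I = N_probe,
            p_E = p_ref, p_I = p_ref, dt = dt, tau = tau, v_in = v_in,
            n_outputs = 1L, seed = s, transfer = transfer)
          conn <- build_connectivity(prm)
          esp_distance_ratio(conn, probe_input,
                             seed = derive_seed(s, "probe"))
        }, numeric(1))
        esp_ratio <- max(ratios)
        stable <- esp_ratio < esp_tol
      }
      rows[[length(rows) + 1L]] <- data.frame(
        g_tot = g_tot, A = A, max_gain = max(sm$variance_gain),
        analytic_stable = sm$stable, esp_ratio = esp_ratio, stable = stable)
    }
  }
  out <- do.call(rbind, rows)
  by_g <- tapply(out$stable, out$g_tot, all)
  ok <- as.numeric(names(by_g))[by_g]
  attr(out, "max_stable_g_tot") <- if (length(ok)) max(ok) else NA_real_
  out
}

#' Write mean-field curves to CSV
#'
#' @param curves Output of [mft_curves()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mft_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
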