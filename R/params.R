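# Anatomical parameters and the imbalance algebra for two-population
# (excitatory/inhibitory) random rate networks.

#' Pre-truncation Gaussian variance for sparse half-normal weights
#'
#' Non-zero weights are drawn as the absolute value of a centred Gaussian with
#' variance `V0` (negated for inhibitory neurons) and each weight is non-zero
#' with probability `p`. `V0` is chosen so that the variance of the *full* set
#' of weights (zeros included) equals the target `v`, independent of `p`:
#' `V0 = v / (p * (1 - 2 p / pi))`.
#'
#' The full weight set then has mean `sqrt(2/pi) * sqrt(p * v / (1 - 2 p / pi))`
#' (up to sign) and variance `v`.
#'
#' @param v Target full-set weight variance (> 0). Typically `g^2 / N`.
#' @param p Connection probability in (0, 1].
#' @return The pre-truncation Gaussian variance `V0`.
#' @export
#' @examples
#' truncated_gaussian_variance(1.5^2 / 375, 0.1)
truncated_gaussian_variance <- function(v, p) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("`v` must be a single positive number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("`p` must be a single value in (0, 1]", call. = FALSE)
  v / (p * (1 - 2 * p / pi))
}

#' Mean of the full weight set of one population
#'
#' For the sparse half-normal construction, the mean over the full weight set
#' (zeros included) is `p * sqrt(2 V0 / pi)` which simplifies to
#' `sqrt(2/pi) * sqrt(p * v / (1 - 2 p / pi))`.
#'
#' @inheritParams truncated_gaussian_variance
#' @return Full-set mean (nonnegative; negate for the inhibitory population).
#' @export
halfnormal_weight_mean <- function(v, p) {
  if (is.numeric(v) && length(v) == 1L && isTRUE(v == 0)) return(0)
  V0 <- truncated_gaussian_variance(v, p)
  p * sqrt(2 * V0 / pi)
}

#' Network parameters for a two-population Dale's-law reservoir
#'
#' Bundles the anatomical parameters of the excitatory (E) and inhibitory (I)
#' populations together with the integration constants, and derives the
#' composite quantities used throughout: per-population full-set weight
#' variances `v_E = g_E^2 / N_E`, `v_I = g_I^2 / N_I`, total size
#' `N_tot = N_E + N_I`, mean connection probability
#' `p_tot = (N_E p_E + N_I p_I) / N_tot`, and total connection strength
#' `g_tot = sqrt(g_E^2 + g_I^2) = sqrt(v_E N_E + v_I N_I)`.
#'
#' @param N_E,N_I Positive integer neuron counts.
#' @param p_E,p_I Connection probabilities in (0, 1]. Empty populations
#'   (`p = 0`) are rejected.
#' @param g_E,g_I Nonnegative connection-strength scalars.
#' @param tau Neural time constant in seconds.
#' @param dt Euler integration step in seconds.
#' @param v_in Variance of the Gaussian input weights.
#' @param n_outputs Readout dimensionality (number of muscles/channels).
#' @param seed Master RNG seed for a network instance; expanded into
#'   independent streams for connectivity, initial state and test-sequence
#'   shuffling (see [derive_seed()]).
#' @param transfer Transfer function name: `"rect_tanh"` (default) or
#'   `"sigmoid"`. Any transfer must map the reals into `[0, 1)`.
#' @return An object of class `network_params`.
#' @export
#' @examples
#' network_params(375, 375, 0.1, 0.1, 1.5, 1.5)
network_params <- function(N_E, N_I, p_E, p_I, g_E, g_I,
                           tau = 0.01, dt = 0.005, v_in = 1 / 3,
                           n_outputs = 17L, seed = 1L,
                           transfer = "rect_tanh") {
  stopifnot(length(N_E) == 1L, length(N_I) == 1L)
  if (!is.finite(N_E) || !is.finite(N_I) || N_E < 1 || N_I < 1 ||
      N_E != round(N_E) || N_I != round(N_I))
    stop("N_E and N_I must be positive integers", call. = FALSE)
  for (nm in c("p_E", "p_I")) {
    p <- get(nm)
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
      stop(sprintf("%s must be in (0, 1]", nm), call. = FALSE)
  }
  for (nm in c("g_E", "g_I")) {
    g <- get(nm)
    if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0)
      stop(sprintf("%s must be a nonnegative number", nm), call. = FALSE)
  }
  if (tau <= 0 || dt <= 0) stop("tau and dt must be positive", call. = FALSE)
  if (v_in < 0) stop("v_in must be nonnegative", call. = FALSE)
  transfer <- match.arg(transfer, c("rect_tanh", "sigmoid"))
  N_E <- as.integer(N_E); N_I <- as.integer(N_I)
  v_E <- g_E^2 / N_E
  v_I <- g_I^2 / N_I
  out <- list(
    N_E = N_E, N_I = N_I, p_E = p_E, p_I = p_I, g_E = g_E, g_I = g_I,
    tau = tau, dt = dt, v_in = v_in, n_outputs = as.integer(n_outputs),
    seed = as.integer(seed), transfer = transfer,
    v_E = v_E, v_I = v_I,
    N_tot = N_E + N_I,
    p_tot = (N_E * p_E + N_I * p_I) / (N_E + N_I),
    g_tot = sqrt(g_E^2 + g_I^2)
  )
  class(out) <- "network_params"
  out
}

#' @export
print.network_params <- function(x, ...) {
  cat("Two-population reservoir parameters\n")
  cat(sprintf("  E: N = %d, p = %.3g, g = %.4g   I: N = %d, p = %.3g, g = %.4g\n",
              x$N_E, x$p_E, x$g_E, x$N_I, x$p_I, x$g_I))
  cat(sprintf("  N_tot = %d, p_tot = %.3g, g_tot = %.4f, imbalance A = %.4f\n",
              x$N_tot, x$p_tot, x$g_tot, imbalance_of(x)))
  cat(sprintf("  tau = %g s, dt = %g s, v_in = %.4g, transfer = %s, outputs = %d\n",
              x$tau, x$dt, x$v_in, x$transfer, x$n_outputs))
  invisible(x)
}

#' Weight-distribution moments and the anatomical imbalance
#'
#' Computes, for each population, the mean of the full weight set (zeros
#' included), the pre-truncation Gaussian variance `V0`, and the anatomical
#' imbalance `A = m_E * N_E + m_I * N_I`, i.e. the mean summed recurrent
#' weight onto a neuron. Positive `A` means excitation-dominated, negative
#' inhibition-dominated.
#'
#' @param params A [network_params()] object.
#' @return A list with `m_E`, `m_I`, `V0_E`, `V0_I` and `A`.
#' @export
weight_moments <- function(params) {
  stopifnot(inherits(params, "network_params"))
  m_E <- halfnormal_weight_mean(params$v_E, params$p_E)
  m_I <- -halfnormal_weight_mean(params$v_I, params$p_I)
  V0_of <- function(v, p) if (v == 0) 0 else truncated_gaussian_variance(v, p)
  list(
    m_E = m_E, m_I = m_I,
    V0_E = V0_of(params$v_E, params$p_E),
    V0_I = V0_of(params$v_I, params$p_I),
    A = m_E * params$N_E + m_I * params$N_I
  )
}

# population coefficient k such that m * N = k * g for one population
imbalance_coeff <- function(N, p) {
  sqrt(2 / pi) * sqrt(p * N / (1 - 2 * p / pi))
}

#' Anatomical imbalance of a parameter set
#'
#' `A = m_E N_E + m_I N_I`, expressed through the anatomical parameters as
#' `A = sqrt(2/pi) * (g_E sqrt(p_E N_E / (1 - 2 p_E/pi))
#'                  - g_I sqrt(p_I N_I / (1 - 2 p_I/pi)))`.
#'
#' @param params A [network_params()] object.
#' @return The imbalance `A` (scalar).
#' @export
#' @examples
#' imbalance_of(network_params(375, 375, 0.1, 0.1, 1.5, 1.5))  # 0
imbalance_of <- function(params) {
  stopifnot(inherits(params, "network_params"))
  imbalance_coeff(params$N_E, params$p_E) * params$g_E -
    imbalance_coeff(params$N_I, params$p_I) * params$g_I
}

#' Solve anatomical parameters for a target imbalance
#'
#' Finds a parameter set whose imbalance equals `A` while holding the matching
#' total quantity fixed: connection strengths (`by_g`, `g_E^2 + g_I^2 =
#' g_tot^2`, closed form), neuron numbers (`by_N`, `N_E + N_I = N_tot`,
#' nearest-integer split; the achieved imbalance is recorded in attribute
#' `"achieved_A"`), or connection probabilities (`by_p`,
#' `(N_E p_E + N_I p_I)/N_tot = p_tot`, numeric root).
#'
#' @param A Target imbalance.
#' @param mode One of `"by_g"`, `"by_N"`, `"by_p"`.
#' @param g_tot,N_tot,p_tot The fixed total for the chosen mode.
#' @param N_E,N_I Population sizes (fixed in `by_g` and `by_p` modes).
#' @param p_E,p_I Connection probabilities (fixed in `by_g` and `by_N` modes).
#' @param g_E,g_I Connection strengths (fixed in `by_N` and `by_p` modes).
#' @param ... Further arguments passed to [network_params()] (e.g. `seed`,
#'   `n_outputs`, `transfer`).
#' @return A [network_params()] object whose [imbalance_of()] equals `A`
#'   (exactly for `by_g`; to `1e-9` for `by_p`; up to integer rounding for
#'   `by_N`, with the achieved value in `attr(, "achieved_A")`).
#' @export
#' @examples
#' p <- solve_params_for_imbalance(-5, "by_g", g_tot = sqrt(2 * 1.5^2),
#'                                 N_E = 375, N_I = 375, p_E = 0.1, p_I = 0.1)
#' round(c(p$g_E, p$g_I), 2)  # 0.92 1.91
solve_params_for_imbalance <- function(A,
                                       mode = c("by_g", "by_N", "by_p"),
                                       g_tot = NULL, N_tot = NULL, p_tot = NULL,
                                       N_E = NULL, N_I = NULL,
                                       p_E = NULL, p_I = NULL,
                                       g_E = NULL, g_I = NULL, ...) {
  mode <- match.arg(mode)
  switch(mode,
    by_g = {
      stopifnot(!is.null(g_tot), !is.null(N_E), !is.null(N_I),
                !is.null(p_E), !is.null(p_I))
      kE <- imbalance_coeff(N_E, p_E)
      kI <- imbalance_coeff(N_I, p_I)
      # A = kE gE - kI gI,  gE^2 + gI^2 = g_tot^2
      # -> (kE^2 + kI^2) gE^2 - 2 A kE gE + (A^2 - kI^2 g_tot^2) = 0
      a <- kE^2 + kI^2
      b <- -2 * A * kE
      cc <- A^2 - kI^2 * g_tot^2
      disc <- b^2 - 4 * a * cc
      if (disc < 0)
        stop("infeasible imbalance: |A| too large for the given g_tot",
             call. = FALSE)
      gE <- (-b + sqrt(disc)) / (2 * a)   # root with the larger g_E
      gI <- (kE * gE - A) / kI
      if (gE < 0 || gI < 0) {
        gE2 <- (-b - sqrt(disc)) / (2 * a)
        gI2 <- (kE * gE2 - A) / kI
        if (gE2 < 0 || gI2 < 0)
          stop("infeasible imbalance: no nonnegative (g_E, g_I) solution",
               call. = FALSE)
        gE <- gE2; gI <- gI2
      }
      network_params(N_E, N_I, p_E, p_I, gE, gI, ...)
    },
    by_N = {
      stopifnot(!is.null(N_tot), !is.null(p_E), !is.null(p_I),
                !is.null(g_E), !is.null(g_I))
      # With p_E = p_I = p and g_E = g_I = g the imbalance is
      # C (sqrt(N_E) - sqrt(N_I)); solve s - t = A/C with s^2 + t^2 = N_tot.
      if (p_E != p_I || g_E != g_I)
        stop("by_N solving assumes p_E = p_I and g_E = g_I", call. = FALSE)
      C <- sqrt(2 / pi) * g_E * sqrt(p_E / (1 - 2 * p_E / pi))
      a0 <- A / C
      if (a0^2 > 2 * N_tot)
        stop("infeasible imbalance: |A| unreachable for the given N_tot",
             call. = FALSE)
      s <- (a0 + sqrt(2 * N_tot - a0^2)) / 2
      NE <- as.integer(round(s^2))
      NE <- max(1L, min(as.integer(N_tot) - 1L, NE))
      prm <- network_params(NE, as.integer(N_tot) - NE, p_E, p_I, g_E, g_I, ...)
      attr(prm, "achieved_A") <- imbalance_of(prm)
      attr(prm, "target_A") <- A
      prm
    },
    by_p = {
      stopifnot(!is.null(p_tot), !is.null(N_E), !is.null(N_I),
                !is.null(g_E), !is.null(g_I))
      N_tot_ <- N_E + N_I
      pI_of <- function(pE) (N_tot_ * p_tot - N_E * pE) / N_I
      f <- function(pE) {
        imbalance_coeff(N_E, pE) * g_E - imbalance_coeff(N_I, pI_of(pE)) * g_I - A
      }
      eps <- 1e-9
      lo <- max(eps, (N_tot_ * p_tot - N_I) / N_E + eps)
      hi <- min(1, N_tot_ * p_tot / N_E - eps)
      if (lo >= hi || f(lo) * f(hi) > 0)
        stop("infeasible imbalance: no p_E in range achieves A under p_tot",
             call. = FALSE)
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
      pE <- root$root
      if (abs(f(pE)) > 1e-9)
        stop("by_p root residual exceeds 1e-9", call. = FALSE)
      network_params(N_E, N_I, pE, pI_of(pE), g_E, g_I, ...)
    }
  )
}

#' Derive an independent RNG seed from a master seed
#'
#' Deterministic counter-based expansion of one master seed into named
#' streams so that connectivity draws, initial states and test-sequence
#' shuffles are reproducible and independent. All derived seeds stay below
#' 2^31.
#'
#' @param master Master seed (integer).
#' @param stream Stream name (e.g. `"connectivity"`) or a nonnegative integer.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  streams <- c(connectivity = 1, init_state = 2, shuffle = 3,
               input = 4, probe = 5)
  idx <- if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown stream: ", stream)
    streams[[stream]]
  } else as.numeric(stream)
  as.integer((as.numeric(master) * 48271 + idx * 104729) %% 2147483647 + 1)
}
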