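# --- single-node (uncoupled) fixed point -----------------------------------

# Algebraic fixed point of the uncoupled Epileptor.  With all coupling off
# and u1* < 0 the u1 equation closes into a monotone cubic, so the root is
# unique; q1 then solves a second cubic on either the silent (q1 < -0.25)
# or the active branch.  Returns c(u1, u2, v, q1, q2, g) without checking
# stability.
.fp_roots <- function(params, u0) {
  p <- params
  r <- polyroot(c(-(1 + p$I_1 + 4 * u0), 4, 2, 1))
  u1 <- Re(r[abs(Im(r)) < 1e-8])[1]
  u2 <- 1 - 5 * u1^2
  v <- 4 * (u1 - u0)
  g <- p$tau_s * p$tau_12 * p$a_12 * u1
  C <- p$I_2 + 0.002 * g - 0.3 * (v - 3.5)
  r2 <- polyroot(c(C, 1, 0, -1))                    # q1 - q1^3 + C = 0
  re <- Re(r2[abs(Im(r2)) < 1e-8])
  cand <- re[re < -0.25]
  if (length(cand)) {
    q1 <- min(cand); q2 <- 0
  } else {                                          # silent branch gone
    r3 <- polyroot(c(1.5 - C, 5, 0, 1))             # q1^3 + 5 q1 + 1.5 - C = 0
    re3 <- Re(r3[abs(Im(r3)) < 1e-8])
    q1 <- re3[which.min(abs(re3))]
    q2 <- 6 * (q1 + 0.25)
  }
  c(u1 = u1, u2 = u2, v = v, q1 = q1, q2 = q2, g = g)
}

# uncoupled scalar right-hand side (reference implementation; the C++
# integrator must agree with this at zero coupling)
.rhs_single <- function(state, params, u0) {
  p <- params
  u1 <- state[1]; u2 <- state[2]; v <- state[3]
  q1 <- state[4]; q2 <- state[5]; g <- state[6]
  f1 <- if (u1 < 0) u1^3 - 3 * u1^2 else (q1 - 0.6 * (v - 4)^2) * u1
  f2 <- if (q1 < -0.25) 0 else 6 * (q1 + 0.25)
  c((u2 - f1 - v + p$I_1) / p$tau_s,
    (1 - 5 * u1^2 - u2) / p$tau_s,
    (4 * (u1 - u0) - v) / (p$tau_s * p$tau_0),
    (-q2 + q1 - q1^3 + p$I_2 + 0.002 * g - 0.3 * (v - 3.5)) / p$tau_s,
    (-q2 + f2) / (p$tau_s * p$tau_2),
    p$a_12 * u1 - g / (p$tau_s * p$tau_12))
}

.jacobian_single <- function(state, params, u0, eps = 1e-6) {
  J <- matrix(0, 6, 6)
  for (k in 1:6) {
    dp <- dm <- state
    dp[k] <- dp[k] + eps; dm[k] <- dm[k] - eps
    J[, k] <- (.rhs_single(dp, params, u0) - .rhs_single(dm, params, u0)) / (2 * eps)
  }
  J
}

#' Fixed point of the uncoupled Epileptor
#'
#' Solves the healthy-state equilibrium of a single uncoupled Epileptor
#' node analytically (the six equations close into two cubics) and verifies
#' both the residual and linear stability.  In the supercritical regime
#' the equilibrium is unstable and an error is raised.
#'
#' @param params an [epileptor_params()].
#' @param u0 scalar excitability.
#' @return named numeric vector \code{(u1, u2, v, q1, q2, g)}.
#' @export
single_node_fixed_point <- function(params, u0) {
  st <- .fp_roots(params, u0)
  res <- .rhs_single(st, params, u0)
  if (max(abs(res)) > 1e-10)
    stop("fixed-point residual too large: ", format(max(abs(res))))
  ev <- eigen(.jacobian_single(st, params, u0), only.values = TRUE)$values
  if (max(Re(ev)) > 1e-9)
    stop("no stable fixed point at u0 = ", u0,
         " (supercritical regime); check the excitability value")
  st
}

# --- field right-hand side (R reference) ------------------------------------

#' Field-model time derivative
#'
#' Evaluates the right-hand side of the Epileptor neural field for a full
#' state matrix.  The three coupling terms pass the Heaviside-thresholded
#' activity (threshold included: S(theta, theta) = 1) through the
#' discretized kernel.  This R implementation defines the model; the
#' compiled Heun integrator in [simulate_field()] advances the identical
#' equations.
#'
#' @param state numeric matrix (n x 6), columns \code{u1, u2, v, q1, q2, g}.
#' @param params an [epileptor_params()].
#' @param kernel a [build_local_kernel()] result, or NULL for uncoupled
#'   dynamics.
#' @param u0 per-vertex excitability vector (or an \code{excitability_map}).
#' @return matrix (n x 6) of time derivatives (per ms).
#' @export
field_derivatives <- function(state, params, kernel = NULL, u0) {
  if (inherits(u0, "excitability_map")) u0 <- u0$u0
  if (!all(is.finite(state))) stop("non-finite state")
  p <- params
  u1 <- state[, 1]; u2 <- state[, 2]; v <- state[, 3]
  q1 <- state[, 4]; q2 <- state[, 5]; g <- state[, 6]
  if (!is.null(kernel)) {
    W <- kernel$W
    c11 <- as.vector(W %*% (u1 >= p$theta_11))
    c12 <- if (p$theta_12 == p$theta_11) c11 else
      as.vector(W %*% (u1 >= p$theta_12))
    c22 <- as.vector(W %*% (q1 >= p$theta_22))
  } else c11 <- c12 <- c22 <- 0
  f1 <- ifelse(u1 < 0, u1^3 - 3 * u1^2, (q1 - 0.6 * (v - 4)^2) * u1)
  f2 <- ifelse(q1 < -0.25, 0, 6 * (q1 + 0.25))
  cbind((u2 - f1 - v + p$I_1 + p$gamma_11 * c11) / p$tau_s,
        (1 - 5 * u1^2 - u2) / p$tau_s,
        (4 * (u1 - u0) - v) / (p$tau_s * p$tau_0),
        (-q2 + q1 - q1^3 + p$I_2 + 0.002 * g - 0.3 * (v - 3.5) +
           p$gamma_22 * c22) / p$tau_s,
        (-q2 + f2) / (p$tau_s * p$tau_2),
        p$a_12 * u1 + p$gamma_12 * c12 - g / (p$tau_s * p$tau_12))
}

# --- Heun integration --------------------------------------------------------

#' Simulate the Epileptor field on a surface
#'
#' Deterministic Heun (predictor-corrector) integration of the neural
#' field with time step \code{params$dt} (0.2 ms).  Every vertex starts in
#' the stable fixed point of the unconnected Epileptor at the surround
#' excitability, including epileptogenic-zone vertices, which then enter
#' the seizure autonomously.  No input arrives from outside the patch and
#' kernel rows are not renormalized near the boundary.
#'
#' @param surface a [tri_surface()].
#' @param params an [epileptor_params()].
#' @param u0map an [make_excitability_map()] result (or per-vertex vector).
#' @param duration_s simulated time in seconds (1 s = 1000 model ms).
#' @param output_hz requested output sampling rate; the realized rate is
#'   the nearest integer multiple of the time step and is stored as
#'   \code{fs}.
#' @param kernel optional precomputed [build_local_kernel()]; built from
#'   \code{surface} with \code{b = params$b} when missing.  Pass NA to
#'   simulate uncoupled nodes.
#' @param record_u1,record_q1 record additional state variables (u1 is
#'   needed for recruitment maps, q1 for fast-wave estimation).
#' @param stop_vertices optional vertex set: once all of them are
#'   recruited (u1 >= \code{stop_threshold}) the simulation continues for
#'   \code{stop_extra_s} seconds and then halts.
#' @param stop_threshold,stop_extra_s see \code{stop_vertices}.
#' @return object of class \code{simulation_result}: list with \code{t}
#'   (s), \code{s} (time x vertex source activity q1 - u1), optional
#'   \code{u1}, \code{q1}, \code{fs}, \code{params}, \code{u0},
#'   \code{recruitment_threshold} (-0.8).
#' @export
simulate_field <- function(surface, params, u0map, duration_s,
                           output_hz = 256, kernel = NULL,
                           record_u1 = TRUE, record_q1 = FALSE,
                           stop_vertices = NULL, stop_threshold = -0.8,
                           stop_extra_s = 2) {
  stopifnot(duration_s > 0)
  u0 <- if (inherits(u0map, "excitability_map")) u0map$u0 else u0map
  n <- nrow(surface$vertices)
  if (length(u0) != n) stop("u0 map length does not match vertex count")
  if (is.null(kernel)) kernel <- build_local_kernel(surface, b = params$b)
  klist <- if (inherits(kernel, "local_kernel")) {
    W <- kernel$W
    list(p = W@p, i = W@i, x = W@x)
  } else NULL
  st0 <- .fp_roots(params, params$u0_surround)
  state0 <- matrix(rep(st0, each = n), n, 6)
  dt <- params$dt
  n_steps <- ceiling(duration_s * 1000 / dt)
  record_every <- max(1L, round(1000 / (output_hz * dt)))
  fs <- 1000 / (record_every * dt)
  sv <- if (is.null(stop_vertices)) integer(0) else as.integer(stop_vertices) - 1L
  r <- .heun_field_cpp(state0, u0, unclass(params), dt, n_steps, record_every,
                       klist, record_u1, record_q1, sv, stop_threshold,
                       stop_extra_s * 1000)
  nr <- r$n_recorded
  out <- list(t = r$t_ms[seq_len(nr)] / 1000,
              s = r$s[seq_len(nr), , drop = FALSE],
              u1 = if (record_u1) r$u1[seq_len(nr), , drop = FALSE],
              q1 = if (record_q1) r$q1[seq_len(nr), , drop = FALSE],
              fs = fs, params = params, u0 = u0,
              recruitment_threshold = -0.8,
              stopped_early = r$n_steps_done < n_steps)
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d samples x %d vertices, fs = %.1f Hz, %.1f s%s\n",
              nrow(x$s), ncol(x$s), x$fs, max(x$t),
              if (isTRUE(x$stopped_early)) " (stopped early)" else ""))
  invisible(x)
}

#' Per-vertex recruitment times
#'
#' First time each vertex enters the seizing state, defined as u1 crossing
#' the recruitment threshold (-0.8) from below.
#'
#' @param result a [simulate_field()] result with u1 recorded.
#' @param threshold recruitment threshold on u1.
#' @return numeric vector of onset times in seconds; NA for vertices that
#'   are never recruited.
#' @export
recruitment_times <- function(result, threshold = -0.8) {
  if (is.null(result$u1))
    stop("u1 was not recorded; rerun simulate_field(record_u1 = TRUE)")
  idx <- apply(result$u1 >= threshold, 2, function(z) {
    i <- which(z)[1]
    if (is.na(i)) NA_integer_ else i
  })
  ifelse(is.na(idx), NA_real_, result$t[idx])
}
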