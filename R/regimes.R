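# integrate one uncoupled node from a given state; returns recorded traces
.run_single <- function(state0, params, u0, duration_ms, record_every = 50L,
                        record_q1 = FALSE) {
  r <- .heun_field_cpp(matrix(state0, 1, 6), u0, unclass(params), params$dt,
                       ceiling(duration_ms / params$dt), record_every,
                       NULL, TRUE, record_q1, integer(0), -0.8, 0)
  nr <- r$n_recorded
  list(t_ms = r$t_ms[seq_len(nr)], u1 = r$u1[seq_len(nr)],
       s = r$s[seq_len(nr)],
       q1 = if (record_q1) r$q1[seq_len(nr)])
}

#' Excitability regime of the uncoupled Epileptor
#'
#' Classifies a single uncoupled node as \code{"fixed_point"} (converges to
#' the healthy equilibrium) or \code{"oscillatory"} (periodically switches
#' between silent and seizing states) by long integration: the node starts
#' at the algebraic equilibrium with a small perturbation, the first half
#' of the run is discarded as transient, and the late-window peak-to-peak
#' amplitude of u1 is tested against \code{tol}.
#'
#' @param params an [epileptor_params()].
#' @param u0 scalar excitability.
#' @param duration_s integration length in seconds of model time.
#' @param tol oscillation amplitude tolerance.
#' @return \code{"fixed_point"} or \code{"oscillatory"}.
#' @export
classify_excitability_regime <- function(params, u0, duration_s = 60,
                                         tol = 1e-3) {
  st <- .fp_roots(params, u0)
  st[1] <- st[1] + 1e-3
  tr <- .run_single(st, params, u0, duration_s * 1000)
  n <- length(tr$u1)
  late <- tr$u1[(n %/% 2):n]
  if (diff(range(late)) > tol) "oscillatory" else "fixed_point"
}

#' Critical excitability by bisection
#'
#' Locates the excitability threshold above which the uncoupled Epileptor
#' loses its stable healthy state and seizes periodically, by bisecting the
#' regime classifier.
#'
#' @param params an [epileptor_params()].
#' @param bracket interval straddling the transition.
#' @param tol_u0 bisection width at which to stop.
#' @param ... passed to [classify_excitability_regime()].
#' @return the critical u0 (midpoint of the final bracket).
#' @export
find_critical_u0 <- function(params, bracket = c(-2.5, -1.5), tol_u0 = 1e-3,
                             ...) {
  lo <- min(bracket); hi <- max(bracket)
  cl <- function(u) classify_excitability_regime(params, u, ...) == "oscillatory"
  if (cl(lo) || !cl(hi))
    stop("bracket endpoints classify identically; widen the bracket")
  while (hi - lo > tol_u0) {
    mid <- (lo + hi) / 2
    if (cl(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# initial conditions used to probe for a coexisting limit cycle of the
# frozen fast subsystem; fixed list so the classification is deterministic
.fast_ics <- list(c(0.5, 0.9), c(0.0, 0.5), c(1.5, -5), c(0.8, 0),
                  c(0.2, 0.7), c(1.0, -1), c(0.3, 0.8))

#' Monostability vs bistability of the frozen fast subsystem
#'
#' Freezes the slower variables (q1, v, and the g forcing) at their
#' uncoupled fixed-point values and integrates the two-dimensional
#' (u1, u2) fast subsystem from a set of perturbed initial conditions on
#' the oscillatory side.  The subsystem is \code{"bistable"} if a sustained
#' oscillation coexists with the stable equilibrium and
#' \code{"monostable"} otherwise.
#'
#' @param params an [epileptor_params()].
#' @param u0 scalar excitability; must be subcritical (the full fixed
#'   point must be stable).
#' @param duration_s integration length per initial condition (model s).
#' @param tol oscillation amplitude tolerance.
#' @return \code{"monostable"} or \code{"bistable"}.
#' @export
fast_subsystem_bistability <- function(params, u0, duration_s = 30,
                                       tol = 1e-3) {
  st <- single_node_fixed_point(params, u0)   # errors if supercritical
  for (ic in .fast_ics) {
    r <- .heun_fast_subsystem_cpp(ic[1], ic[2], st["q1"], st["v"],
                                  unclass(params), params$dt,
                                  ceiling(duration_s * 1000 / params$dt), 100L)
    n <- r$n_recorded
    late <- r$u1[(n %/% 2):n]
    if (diff(range(late)) > tol) return("bistable")
  }
  "monostable"
}

#' Monostable/bistable boundary by bisection
#'
#' @param params an [epileptor_params()].
#' @param bracket interval with a monostable lower and bistable upper end.
#' @param tol_u0 bisection width at which to stop.
#' @param ... passed to [fast_subsystem_bistability()].
#' @return the boundary u0 (midpoint of the final bracket).
#' @export
find_ms_boundary <- function(params, bracket = c(-3.5, -2.5), tol_u0 = 1e-3,
                             ...) {
  lo <- min(bracket); hi <- max(bracket)
  bi <- function(u) fast_subsystem_bistability(params, u, ...) == "bistable"
  if (bi(lo) || !bi(hi))
    stop("bracket endpoints classify identically; widen the bracket")
  while (hi - lo > tol_u0) {
    mid <- (lo + hi) / 2
    if (bi(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Oscillation frequency at seizure onset of an uncoupled node
#'
#' Integrates a single uncoupled Epileptor at excitability \code{u0}
#' starting from the healthy equilibrium of the surround excitability,
#' detects the seizure onset as the first upward crossing of u1 through
#' the recruitment threshold (-0.8), and returns the power-spectral peak
#' of the source activity s = q1 - u1 over a window following onset,
#' together with the instantaneous rates of the first discharge cycles.
#'
#' @param params an [epileptor_params()].
#' @param u0 excitability of the seizing node.
#' @param window_s spectral window length after onset, in seconds.
#' @param duration_s total integration time.
#' @param output_hz sampling rate of the analyzed trace.
#' @return list with \code{peak_hz} (spectral peak in the window),
#'   \code{onset_s}, \code{initial_rates_hz} (inverse of the first
#'   inter-discharge intervals), \code{freq}, \code{power} (periodogram).
#' @export
onset_oscillation_frequency <- function(params, u0 = -1.8, window_s = 2,
                                        duration_s = 30, output_hz = 1024) {
  st <- .fp_roots(params, params$u0_surround)
  record_every <- max(1L, round(1000 / (output_hz * params$dt)))
  tr <- .run_single(st, params, u0, duration_s * 1000, record_every)
  fs <- 1000 / (record_every * params$dt)
  on <- which(tr$u1 >= -0.8)[1]
  if (is.na(on)) stop("no seizure onset detected at u0 = ", u0)
  w <- on:min(length(tr$s), on + round(window_s * fs))
  x <- tr$s[w] - mean(tr$s[w])
  pg <- spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0.1, spans = 3)
  up <- which(tr$u1[-1] >= 0.5 & tr$u1[-length(tr$u1)] < 0.5)
  spikes <- tr$t_ms[up] / 1000
  spikes <- spikes[spikes >= tr$t_ms[on] / 1000 - 0.1]
  rates <- if (length(spikes) > 1) 1 / diff(spikes) else numeric(0)
  list(peak_hz = pg$freq[which.max(pg$spec)],
       onset_s = tr$t_ms[on] / 1000,
       initial_rates_hz = head(rates, 10),
       freq = pg$freq, power = pg$spec)
}
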