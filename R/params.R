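#' Epileptor field-model parameters
#'
#' Assembles the parameter set of the Epileptor neural field model.  Time is
#' measured in milliseconds throughout; one second of seizure time equals
#' 1000 model time units.  The defaults place the model in the working point
#' used for seizure-spread simulations: a global time constant
#' \code{tau_s = 5.88} ms scaling the whole system, a slow permittivity time
#' constant \code{tau_0 = 20000} giving seizure durations of tens of
#' seconds, and spatial coupling through a Laplacian kernel of decay length
#' \code{b = 1} mm.
#'
#' @details
#' The excitability parameter \code{u0} is not part of this object; it is a
#' per-vertex field supplied via [make_excitability_map()].  Two reference
#' values are carried along for convenience: \code{u0_ez = -1.8}
#' (supercritical, autonomously seizing) and \code{u0_surround = -2.3}
#' (bistable, recruitable).
#'
#' \code{tau_12}, the decay time of the low-pass memory term feeding the
#' intermediate subsystem, is not constrained by the published parameter
#' table.  The default 17 makes the memory term contribute \code{0.002 g* =
#' 0.6 u1*} at equilibrium with a \code{tau_s * tau_12 = 100} ms decay, the
#' scaling used by the original Epileptor's memory integral, and keeps the
#' resting intermediate subsystem well below the coupling threshold
#' \code{theta_22} so that quiescent tissue is not ignited by distant
#' oscillations before the recruiting wavefront arrives.  The critical
#' excitability (u0_crit = -2.056, see [find_critical_u0()]) is insensitive
#' to this choice; the monostable/bistable boundary of the frozen fast
#' subsystem ([find_ms_boundary()]) is not, and lands at -2.97 rather than
#' the published -3.025 (see the methods vignette for the analysis).
#'
#' \code{gamma_11} controls the speed of the slow recruiting wavefront and
#' is intended to be recalibrated per simulation against a target spread
#' velocity with [calibrate_gamma11()]; the default 0.8 yields a spread
#' velocity of roughly 6 mm/s on a flat sheet discretized at 0.8 mm.
#'
#' @param gamma_11 coupling gain of the fast subsystem (slow-front speed).
#' @param tau_12 memory decay parameter of the g-term (see Details).
#' @param dt integration time step in ms.
#' @param ... overrides for any other parameter.
#' @return An object of class \code{epileptor_params} (named list).
#' @export
#' @examples
#' p <- epileptor_params()
#' p$tau_s
epileptor_params <- function(gamma_11 = 0.8, tau_12 = 17, dt = 0.2, ...) {
  p <- list(
    tau_s = 5.88, tau_0 = 20000, tau_2 = 100, tau_12 = tau_12,
    I_1 = 3.1, I_2 = 0.45, a_12 = 3,
    gamma_11 = gamma_11, gamma_12 = 10, gamma_22 = 1,
    theta_11 = -1, theta_12 = -1, theta_22 = -0.5,
    b = 1, dt = dt,
    u0_ez = -1.8, u0_surround = -2.3)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$tau_s > 0, p$tau_0 > 0, p$tau_2 > 0, p$tau_12 > 0,
            p$dt > 0, p$b > 0)
  class(p) <- "epileptor_params"
  p
}

#' @export
print.epileptor_params <- function(x, ...) {
  cat("Epileptor field parameters (time unit: ms)\n")
  nm <- setdiff(names(x), NULL)
  cat(paste0("  ", nm, " = ", unlist(x[nm]), collapse = "\n"), "\n")
  invisible(x)
}
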