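#' Amplitude envelope of an SEEG signal
#'
#' High-pass filters the signal to remove slow drifts (3rd-order
#' Butterworth, 0.2 Hz), rectifies it, and low-pass filters the result
#' (3rd-order Butterworth, 0.6 Hz).  Both filters are applied forward and
#' backward (zero phase), so the envelope is not delayed with respect to
#' the signal.
#'
#' @param x numeric vector or one-column matrix.
#' @param fs sampling rate in Hz; must exceed twice the larger cutoff.
#' @param hp_cutoff,lp_cutoff high-/low-pass cutoffs in Hz.
#' @param order Butterworth order.
#' @return nonnegative numeric vector of the same length.
#' @export
signal_envelope <- function(x, fs, hp_cutoff = 0.2, lp_cutoff = 0.6,
                            order = 3) {
  if (fs <= 2 * max(hp_cutoff, lp_cutoff))
    stop("sampling rate too low for the filter cutoffs")
  hp <- signal::butter(order, hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(order, lp_cutoff / (fs / 2), type = "low")
  x <- as.numeric(x)
  xf <- .filtfilt_padded(hp, x, round(2 * fs / hp_cutoff))
  env <- .filtfilt_padded(lp, abs(xf), round(2 * fs / lp_cutoff))
  pmax(env, 0)
}

# zero-phase filtering with odd-extension padding at both ends, so that
# large offsets or trends do not leak startup transients into the result
# (the cutoffs used here are far below the sampling rate, making the
# unpadded transients several seconds long)
.filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  L <- max(1L, min(n - 1L, as.integer(pad)))
  front <- 2 * x[1] - x[(L + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - L)]
  y <- signal::filtfilt(flt, c(front, x, back))
  y[(L + 1L):(L + n)]
}

#' Detect seizure-onset times on bipolar SEEG channels
#'
#' The onset of a channel is the first time its amplitude envelope rises
#' above \code{fraction} (default 20\%) of the envelope maximum over the
#' provided analysis window.  Onsets are shifted so the earliest detected
#' onset is at zero.  Channels whose envelope never exceeds the threshold
#' (or is all zero) are flagged as undetected rather than zero-filled.
#'
#' @param signals a \code{sensor_signals} object covering the seizure.
#' @param fraction threshold as a fraction of the envelope maximum.
#' @param ... passed to [signal_envelope()].
#' @return object of class \code{onset_result}: data.frame with
#'   \code{channel}, \code{onset_s} (earliest = 0; NA if undetected),
#'   \code{detected}, \code{env_mean}; envelopes are attached as
#'   attribute \code{"envelopes"} (time x channel matrix) along with
#'   \code{"t"} and \code{"fs"}.
#' @export
detect_onsets <- function(signals, fraction = 0.2, ...) {
  sig <- signals$signals
  nch <- ncol(sig)
  env <- matrix(0, nrow(sig), nch, dimnames = list(NULL, signals$names))
  onset <- rep(NA_real_, nch)
  for (k in seq_len(nch)) {
    e <- signal_envelope(sig[, k], signals$fs, ...)
    env[, k] <- e
    mx <- max(e)
    if (mx > 0) {
      i <- which(e >= fraction * mx)[1]
      onset[k] <- signals$t[i]
    }
  }
  detected <- !is.na(onset)
  if (any(detected)) onset <- onset - min(onset[detected])
  out <- data.frame(channel = signals$names, onset_s = onset,
                    detected = detected,
                    env_mean = colMeans(env), stringsAsFactors = FALSE)
  attr(out, "envelopes") <- env
  attr(out, "t") <- signals$t
  attr(out, "fs") <- signals$fs
  class(out) <- c("onset_result", "data.frame")
  out
}

#' Goodness of fit between observed and simulated onset patterns
#'
#' Root-mean-square error and mean absolute error over per-channel onset
#' times, and the Pearson correlation over per-channel envelope means.
#'
#' @param observed_onsets,simulated_onsets numeric vectors (s), equal
#'   length.
#' @param observed_env,simulated_env envelope means per channel (optional;
#'   \code{rho} is NA when omitted or when either vector is constant).
#' @return list with \code{rmse}, \code{mae}, \code{rho}.
#' @export
fit_metrics <- function(observed_onsets, simulated_onsets,
                        observed_env = NULL, simulated_env = NULL) {
  if (length(observed_onsets) != length(simulated_onsets))
    stop("onset vectors must have equal length")
  d <- observed_onsets - simulated_onsets
  rmse <- sqrt(mean(d^2))
  mae <- mean(abs(d))
  rho <- NA_real_
  if (!is.null(observed_env) && !is.null(simulated_env)) {
    if (length(observed_env) != length(simulated_env))
      stop("envelope vectors must have equal length")
    if (sd(observed_env) > 0 && sd(simulated_env) > 0)
      rho <- cor(observed_env, simulated_env)
    else
      warning("constant envelope vector; rho undefined")
  }
  list(rmse = rmse, mae = mae, rho = rho)
}

#' Spectrally flattened spectrogram
#'
#' Short-time power spectrum with 1/f normalization: each frequency bin of
#' the power map is multiplied by its frequency, flattening the 1/f decay
#' of field-potential spectra so that narrow-band ictal rhythms stand out.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap in [0, 1).
#' @return list with \code{t} (window centers, s), \code{f} (Hz),
#'   \code{power} (frequency x time, flattened).
#' @export
flattened_spectrogram <- function(x, fs, window_s = 1, overlap = 0.9) {
  nwin <- round(window_s * fs)
  if (nwin > length(x)) stop("window longer than the signal")
  nov <- floor(overlap * nwin)
  sg <- signal::specgram(x, n = nwin, Fs = fs, overlap = nov)
  pow <- abs(sg$S)^2 * matrix(sg$f, length(sg$f), ncol(sg$S))
  list(t = as.numeric(sg$t), f = as.numeric(sg$f), power = pow)
}
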