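#' Band-pass specification
#'
#' Frequency band and filter order for the BOLD pre-filtering step. The
#' default band 0.04--0.07 Hz selects the low-frequency range conventionally
#' used for resting-state phase synchrony.
#'
#' @param low,high band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Butterworth filter order (applied forward-backward, so the
#'   effective attenuation order doubles).
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low = 0.04, high = 0.07, order = 2L) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low)) {
    abort("Band edges must satisfy 0 < low < high.")
  }
  if (!(order >= 1L && order == round(order))) abort("`order` must be a positive integer.")
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "bandpass_spec")
}

#' Zero-phase band-pass filter of a subject's time series
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) to every ROI column, so the pass band is preserved
#' with (approximately) unit gain and zero phase distortion — essential
#' because downstream instantaneous phases must not inherit filter delay.
#'
#' @param ts a [subject_ts()].
#' @param spec a [bandpass_spec()]; checked against the Nyquist frequency
#'   1 / (2 tr).
#' @return A filtered [subject_ts()] of the same shape.
#' @export
bandpass_filter <- function(ts, spec = bandpass_spec()) {
  stopifnot(inherits(ts, "subject_ts"), inherits(spec, "bandpass_spec"))
  nyq <- 1 / (2 * ts$tr)
  if (spec$high >= nyq) {
    abort(sprintf(
      "Band edge high = %g Hz is at or above the Nyquist frequency %g Hz; check `tr` (= %g s).",
      spec$high, nyq, ts$tr))
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  filtered <- apply(ts$values, 2L, function(x) signal::filtfilt(bf, x))
  out <- ts
  out$values <- matrix(filtered, nrow(ts$values), ncol(ts$values))
  out
}

# Analytic signal via FFT: zero the negative frequencies, double the
# positive ones, keep DC (and Nyquist for even length) untouched.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of each ROI signal
#'
#' Computes the analytic signal of every column via the Hilbert transform and
#' returns its argument. The input is expected to be band-passed already
#' (narrow-band signals give a well-defined instantaneous phase); this is
#' documented, not enforced.
#'
#' @param ts a [subject_ts()] (ideally the output of [bandpass_filter()]).
#' @return A list of class `phase_series` with `phases` (T x N matrix of
#'   radians in (-pi, pi]) and `subject_id`.
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "subject_ts"))
  zero_cols <- which(apply(ts$values, 2L, function(x) all(abs(x) < .Machine$double.eps)))
  if (length(zero_cols) > 0L) {
    abort(sprintf("Phase undefined for all-zero ROI column(s): %s",
                  paste(zero_cols, collapse = ", ")))
  }
  ph <- apply(ts$values, 2L, function(x) Arg(analytic_signal(x)))
  structure(list(phases = matrix(ph, nrow(ts$values), ncol(ts$values)),
                 subject_id = ts$subject_id),
            class = "phase_series")
}

#' Phase-interaction (phase-coherence) connectivity matrix
#'
#' The instantaneous phase coherence between regions i and j at time t is
#' cos(phi_i(t) - phi_j(t)): 1 when in phase, 0 when orthogonal, -1 when in
#' anti-phase. Averaging over time collapses the T instantaneous matrices
#' into the subject's phase-interaction connectome.
#'
#' @param ph a `phase_series` from [instantaneous_phase()].
#' @param trim number of samples dropped from each end of the series before
#'   averaging (Hilbert phases are unreliable near the edges); default 0.
#' @return A [conn_matrix()] with `kind = "phase_interaction"`.
#' @export
phase_interaction_matrix <- function(ph, trim = 0L) {
  stopifnot(inherits(ph, "phase_series"))
  p <- ph$phases
  tt <- nrow(p)
  if (trim < 0L || 2L * trim >= tt - 1L) {
    abort(sprintf("`trim` = %d leaves fewer than 2 of %d samples.", trim, tt))
  }
  if (trim > 0L) p <- p[(trim + 1L):(tt - trim), , drop = FALSE]
  # <P>_ij = mean_t cos(phi_i - phi_j) = (C'C + S'S)/T with C = cos(phi), S = sin(phi)
  cm <- cos(p); sm <- sin(p)
  w <- (crossprod(cm) + crossprod(sm)) / nrow(p)
  w <- pmin(pmax(w, -1), 1)
  diag(w) <- 1
  conn_matrix(w, subject_id = ph$subject_id, kind = "phase_interaction",
              tol = 1e-8)
}

#' Pearson correlation connectivity matrix
#'
#' @param ts a [subject_ts()].
#' @return A [conn_matrix()] with `kind = "pearson"`.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "subject_ts"))
  v <- apply(ts$values, 2L, sd)
  if (any(v == 0)) {
    abort(sprintf("Zero-variance ROI column(s): %s — Pearson correlation undefined.",
                  paste(which(v == 0), collapse = ", ")))
  }
  w <- cor(ts$values)
  dimnames(w) <- NULL
  conn_matrix(w, subject_id = ts$subject_id, kind = "pearson", tol = 1e-8)
}

#' Full phase-interaction pipeline for one subject
#'
#' Convenience composition: band-pass filter, Hilbert phases, time-averaged
#' phase-interaction matrix.
#'
#' @inheritParams bandpass_filter
#' @inheritParams phase_interaction_matrix
#' @return A [conn_matrix()].
#' @export
phase_connectome <- function(ts, spec = bandpass_spec(), trim = 0L) {
  phase_interaction_matrix(instantaneous_phase(bandpass_filter(ts, spec)),
                           trim = trim)
}
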