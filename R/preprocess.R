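#' Detect pulse peaks and troughs
#'
#' Finds the systolic peaks of a (preferably denoised) RF trace with a
#' refractory constraint — consecutive peaks must be at least `min_period`
#' seconds apart, which rejects dicrotic bumps and residual ripple — and
#' places one trough at the minimum between each pair of consecutive peaks.
#'
#' @param trace An [rf_trace()] or numeric vector (then `fs` is used).
#' @param min_period Minimum peak-to-peak interval in seconds (default 0.6,
#'   i.e. 0.6 of a period at a 1 Hz pulse rate — long enough to reject the
#'   dicrotic bump for pulse rates up to ~1.6 Hz). Must exceed `2/fs`.
#' @param fs Sampling rate when `trace` is a bare vector.
#' @param invert Pulse polarity. A rise in blood volume lowers the resonant
#'   frequency, so the pulse event is usually a downward dip; `"auto"`
#'   (default) analyzes the sign-flipped signal when the trace spends most
#'   of its time above its mean (mean below median), `"yes"`/`"no"` force
#'   the choice. "Peaks" then refer to pulse extrema in either polarity.
#' @return A list with integer index vectors `peaks` and `troughs`
#'   (empty for a flat trace) and the logical `inverted`.
#' @examples
#' tr <- generate_rf_trace(pulsation_params(noise_sd = 0, drift_sd = 0),
#'                         equivalent_circuit(), 10)
#' detect_pulses(tr)$peaks
#' @export
detect_pulses <- function(trace, min_period = 0.6, fs = 20,
                          invert = c("auto", "no", "yes")) {
  invert <- match.arg(invert)
  if (inherits(trace, "rf_trace")) {
    x <- trace$values
    fs <- trace$fs
  } else x <- as.numeric(trace)
  if (min_period <= 2 / fs)
    stop("detect_pulses: min_period must exceed 2/fs")
  if (length(x) < 3 || diff(range(x)) == 0)
    return(list(peaks = integer(0), troughs = integer(0), inverted = FALSE))
  inverted <- switch(invert,
                     yes = TRUE,
                     no = FALSE,
                     auto = mean(x) < stats::median(x))
  if (inverted) x <- -x
  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, round(min_period * fs)))
  if (is.null(pk))
    return(list(peaks = integer(0), troughs = integer(0), inverted = inverted))
  peaks <- sort(as.integer(pk[, 2]))
  troughs <- integer(0)
  if (length(peaks) >= 2) {
    troughs <- vapply(seq_len(length(peaks) - 1), function(i) {
      lo <- peaks[i]
      hi <- peaks[i + 1]
      lo + which.min(x[lo:hi]) - 1L
    }, integer(1))
  }
  list(peaks = as.integer(peaks), troughs = as.integer(troughs),
       inverted = inverted)
}

#' Mean pulse amplitude of an RF trace
#'
#' Mean over pulses of the excursion between a systolic peak and the mean of
#' its two flanking troughs — the per-trace pulsation amplitude in MHz whose
#' progressive post-caffeine decline carries the blood-flow information.
#'
#' @inheritParams detect_pulses
#' @return A list with `amplitude` (MHz), `n_pulses` (count used) and
#'   `minute_mark` (copied from the trace when available).
#' @examples
#' tr <- generate_rf_trace(pulsation_params(noise_sd = 0, drift_sd = 0),
#'                         equivalent_circuit(), 30)
#' pulse_amplitude(tr)$amplitude
#' @export
pulse_amplitude <- function(trace, min_period = 0.6, fs = 20) {
  if (inherits(trace, "rf_trace")) {
    x <- trace$values
    fs <- trace$fs
    mm <- trace$minute_mark
  } else {
    x <- as.numeric(trace)
    mm <- NA_real_
  }
  p <- detect_pulses(x, min_period = min_period, fs = fs)
  if (length(p$peaks) < 2 || length(p$troughs) < 1)
    stop("pulse_amplitude: no pulses detected; amplitude undefined")
  if (p$inverted) x <- -x   # measure excursions in pulse-event polarity
  # interior peaks have troughs on both sides
  n <- length(p$peaks)
  if (n >= 3) {
    amps <- vapply(2:(n - 1), function(i) {
      x[p$peaks[i]] - mean(x[p$troughs[c(i - 1, i)]])
    }, numeric(1))
  } else {  # exactly two peaks: a single shared trough
    amps <- x[p$peaks] - x[p$troughs[1]]
  }
  list(amplitude = mean(amps), n_pulses = length(amps), minute_mark = mm)
}

#' Change ratio of amplitude (CRA)
#'
#' Signed percent change of the pulse amplitude relative to the
#' pre-intervention baseline:
#' `CRA = 100 (A_state - A_baseline) / A_baseline`.
#'
#' @param baseline_amplitude Baseline amplitude in MHz (> 0).
#' @param state_amplitude Amplitude(s) in the compared state, MHz.
#' @return CRA in percent (vectorized over `state_amplitude`).
#' @examples
#' cra(2, 1)   # -50
#' @export
cra <- function(baseline_amplitude, state_amplitude) {
  if (length(baseline_amplitude) != 1 || !is.finite(baseline_amplitude) ||
      baseline_amplitude <= 0)
    stop("cra: baseline amplitude must be a single positive value")
  100 * (state_amplitude - baseline_amplitude) / baseline_amplitude
}

#' Amplitude table for a cohort of traces
#'
#' Denoises every trace (hard thresholding by default, which leaves
#' above-threshold signal coefficients untouched and so preserves the pulse
#' amplitude), then measures its mean pulse amplitude.
#'
#' @param traces List of [rf_trace()] objects.
#' @param denoise Apply [wavelet_denoise()] first (default TRUE).
#' @param mode Thresholding mode for the denoising step (default `"hard"`).
#' @param ... Further arguments passed to [wavelet_denoise()].
#' @return A data.frame: `subject_id, state, minute_mark, amplitude_mhz,
#'   n_pulses`.
#' @export
cohort_amplitudes <- function(traces, denoise = TRUE, mode = "hard", ...) {
  rows <- lapply(traces, function(tr) {
    if (denoise) tr <- wavelet_denoise(tr, mode = mode, ...)
    a <- pulse_amplitude(tr)
    data.frame(subject_id = tr$subject_id, state = tr$state,
               minute_mark = tr$minute_mark,
               amplitude_mhz = a$amplitude, n_pulses = a$n_pulses)
  })
  do.call(rbind, rows)
}

#' Per-subject CRA trajectories
#'
#' Joins each subject's state amplitudes against that subject's baseline
#' amplitude and computes the CRA.
#'
#' @param amplitudes Output of [cohort_amplitudes()].
#' @return The input with a `cra_percent` column (NA for baseline rows).
#' @export
cohort_cra <- function(amplitudes) {
  out <- amplitudes
  out$cra_percent <- NA_real_
  for (sid in unique(out$subject_id)) {
    base <- out$amplitude_mhz[out$subject_id == sid & out$state == "baseline"]
    if (length(base) != 1)
      stop("cohort_cra: subject ", sid, " needs exactly one baseline trace")
    sel <- out$subject_id == sid & out$state != "baseline"
    out$cra_percent[sel] <- cra(base, out$amplitude_mhz[sel])
  }
  out
}

#' Estimate the amplitude-decay rate from CRA trajectories
#'
#' Under an exponential amplitude decay `A(m) = A(0) exp(-r m)` the CRA
#' satisfies `log(1 + CRA/100) = -r m`; the rate is recovered by a
#' through-the-origin least-squares fit pooled over subjects.
#'
#' @param minute_mark Minutes since intervention.
#' @param cra_percent CRA values in percent (> -100).
#' @return Estimated decay rate in 1/min.
#' @export
estimate_decay_rate <- function(minute_mark, cra_percent) {
  ok <- is.finite(minute_mark) & is.finite(cra_percent) & cra_percent > -100
  if (sum(ok) < 1) stop("estimate_decay_rate: no usable points")
  y <- log1p(cra_percent[ok] / 100)
  m <- minute_mark[ok]
  -sum(m * y) / sum(m * m)
}

#' Dominant spectral frequency of a trace
#'
#' Frequency of the maximal magnitude-spectrum bin, DC excluded. For the
#' phantom experiments this recovers the pump squeeze rate; for volunteers
#' it sits at the heart rate.
#'
#' @inheritParams detect_pulses
#' @return The dominant frequency in Hz, with the spectral resolution
#'   `fs/N` (Hz per bin) attached as attribute `"resolution"`.
#' @examples
#' tr <- generate_rf_trace(pulsation_params(seed = 1), equivalent_circuit(), 60)
#' dominant_frequency(tr)
#' @export
dominant_frequency <- function(trace, fs = 20) {
  if (inherits(trace, "rf_trace")) {
    x <- trace$values
    fs <- trace$fs
  } else x <- as.numeric(trace)
  n <- length(x)
  if (n < 2) stop("dominant_frequency: need at least 2 samples")
  mags <- Mod(fft(x - mean(x)))
  half <- floor(n / 2)
  mags <- mags[2:(half + 1)]          # exclude DC, keep up to Nyquist
  if (max(mags) <= 1e-12 * n)
    stop("dominant_frequency: trace has no nonzero frequency component")
  k <- which.max(mags)
  structure(k * fs / n, resolution = fs / n)
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation using average ranks for ties. The p-value uses the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom for `n >= 10`, and the exact permutation distribution of rho for
#' smaller samples.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A list with `rho`, `p_value`, `n` and `method`.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  n <- length(x)
  if (n < 3) stop("spearman_rho: need at least 3 observations")
  rho_of <- function(ry) {
    rx <- rank(x)
    suppressWarnings(cor(rx, ry))
  }
  rho <- rho_of(rank(y))
  if (!is.finite(rho)) stop("spearman_rho: correlation undefined (constant input)")
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  } else {
    P <- pracma::perms(seq_len(n))          # n! x n index matrix
    ry <- rank(y)
    M <- t(P)
    M[] <- ry[as.vector(M)]        # columns = permuted rank vectors
    rhos <- suppressWarnings(as.vector(cor(rank(x), M)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12, na.rm = TRUE)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}
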