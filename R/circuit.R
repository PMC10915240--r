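#' Equivalent circuit of the electromagnetic-coupling sensor
#'
#' The sensing element is modelled as a resonant circuit with a fixed no-load
#' inductance `L` and capacitance `C`, plus two tissue-dependent elements:
#' the coupling capacitance `Ccap` (tracks the dielectric constant of the
#' tissue under the sensor) and the induced resistance `Rind` (tracks its
#' conductivity). Pulsatile blood volume perturbs `Ccap` and `Rind`, which
#' moves the circuit's resonant frequency — the measured signal.
#'
#' @param L No-load inductance in henry. Must be > 0.
#' @param C No-load capacitance in farad. Must be > 0.
#' @param Ccap Coupling capacitance in farad. Must be >= 0.
#' @param Rind Induced resistance in ohm. Must be >= 0.
#'
#' @return An object of class `equivalent_circuit` (a named list).
#'
#' @details The defaults place the resonant frequency in the MHz range with
#' pulse-induced excursions on the order of 1e-5 to 1e-4 MHz, matching the
#' operating regime of capacitance-to-digital sensing front ends.
#'
#' @examples
#' circ <- equivalent_circuit()
#' resonant_frequency(circ) / 1e6  # MHz
#' @export
equivalent_circuit <- function(L = 1e-6, C = 1e-9, Ccap = 1e-10, Rind = 1) {
  stopifnot(is.numeric(L), is.numeric(C), is.numeric(Ccap), is.numeric(Rind))
  if (L <= 0) stop("equivalent_circuit: L must be > 0 (got ", L, ")")
  if (C <= 0) stop("equivalent_circuit: C must be > 0 (got ", C, ")")
  if (any(Ccap < 0)) stop("equivalent_circuit: Ccap must be >= 0")
  if (any(Rind < 0)) stop("equivalent_circuit: Rind must be >= 0")
  structure(list(L = L, C = C, Ccap = Ccap, Rind = Rind),
            class = "equivalent_circuit")
}

#' Resonant frequency of the sensing circuit
#'
#' Computes
#' \deqn{f_{osc} = \frac{1}{2\pi}\sqrt{\frac{1}{L(C+C_{cap})} - \frac{R_{ind}^2}{L^2}}}
#' the oscillation frequency of the electromagnetic-coupling equivalent
#' circuit. It is strictly decreasing in both `Ccap` and `Rind`: a rise in
#' tissue dielectric constant or conductivity lowers the measured frequency.
#'
#' @param circuit An [equivalent_circuit()].
#' @param Ccap,Rind Optional numeric vectors overriding the circuit's
#'   `Ccap`/`Rind`, e.g. a time-varying coupling capacitance. Recycled to a
#'   common length.
#'
#' @return Resonant frequency in Hz (vector if the overrides are vectors).
#'
#' @section Errors: If the radicand `1/(L(C+Ccap)) - Rind^2/L^2` is not
#' strictly positive the circuit does not oscillate and an error naming the
#' offending parameter set is raised.
#'
#' @examples
#' resonant_frequency(equivalent_circuit(Ccap = 0, Rind = 0))  # 1/(2*pi*sqrt(LC))
#' @export
resonant_frequency <- function(circuit, Ccap = NULL, Rind = NULL) {
  stopifnot(inherits(circuit, "equivalent_circuit"))
  Ccap <- Ccap %||% circuit$Ccap
  Rind <- Rind %||% circuit$Rind
  if (any(Ccap < 0)) stop("resonant_frequency: Ccap must be >= 0")
  if (any(Rind < 0)) stop("resonant_frequency: Rind must be >= 0")
  radicand <- 1 / (circuit$L * (circuit$C + Ccap)) - Rind^2 / circuit$L^2
  bad <- which(radicand <= 0)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(paste0(
      "resonant_frequency: non-positive radicand (no oscillation) for ",
      "L=%g H, C=%g F, Ccap=%g F, Rind=%g ohm"),
      circuit$L, circuit$C, Ccap[min(i, length(Ccap))],
      Rind[min(i, length(Rind))]))
  }
  sqrt(radicand) / (2 * pi)
}

#' Pulsation-scenario parameters
#'
#' Bundles the parameters of the synthetic vessel-pulsation scenarios: the
#' phantom pump experiments (a silicone tube squeezed at a fixed rate,
#' displaced in depth and laterally) and the two-state volunteer cohort
#' (baseline vs. post-caffeine, where the pulse amplitude decays over the
#' 30 minutes after ingestion).
#'
#' @param drive_rate Pulse frequency in Hz (pump squeeze rate or heart rate).
#' @param pulse_volume Relative peak vessel-volume excursion (dimensionless;
#'   proportional to intravascular pressure).
#' @param dicrotic_ratio Secondary (rebound) wave height as a fraction of the
#'   primary wave, in `[0, 1)`.
#' @param dicrotic_delay Delay of the secondary wave as a fraction of the
#'   pulse period, in `(0, 1)`.
#' @param depth Sensor-to-vessel distance in cm.
#' @param lateral_offset In-plane displacement in cm.
#' @param amplitude_decay_per_min Multiplicative amplitude decay rate (1/min)
#'   applied in the `post_caffeine` state.
#' @param noise_sd Additive white-noise standard deviation, MHz.
#' @param drift_sd Baseline-wander scale: the random-walk drift grows with
#'   standard deviation `drift_sd` MHz per sqrt(second).
#' @param seed Optional random seed for reproducible noise realizations.
#' @param pulse_shape `"halfsine"` (raised half-sine lobes) or `"gaussian"`.
#'
#' @return An object of class `pulsation_params`.
#' @export
pulsation_params <- function(drive_rate = 1, pulse_volume = 1,
                             dicrotic_ratio = 0.3, dicrotic_delay = 0.65,
                             depth = 2, lateral_offset = 0,
                             amplitude_decay_per_min = 0.02,
                             noise_sd = 1e-5, drift_sd = 2e-6,
                             seed = NULL,
                             pulse_shape = c("halfsine", "gaussian")) {
  pulse_shape <- match.arg(pulse_shape)
  if (drive_rate <= 0) stop("pulsation_params: drive_rate must be > 0")
  if (pulse_volume < 0) stop("pulsation_params: pulse_volume must be >= 0")
  if (dicrotic_ratio < 0 || dicrotic_ratio >= 1)
    stop("pulsation_params: dicrotic_ratio must be in [0, 1)")
  if (dicrotic_delay <= 0 || dicrotic_delay >= 1)
    stop("pulsation_params: dicrotic_delay must be in (0, 1)")
  if (noise_sd < 0) stop("pulsation_params: noise_sd must be >= 0")
  if (drift_sd < 0) stop("pulsation_params: drift_sd must be >= 0")
  if (depth < 0) stop("pulsation_params: depth must be >= 0")
  if (lateral_offset < 0) stop("pulsation_params: lateral_offset must be >= 0")
  structure(list(drive_rate = drive_rate, pulse_volume = pulse_volume,
                 dicrotic_ratio = dicrotic_ratio,
                 dicrotic_delay = dicrotic_delay,
                 depth = depth, lateral_offset = lateral_offset,
                 amplitude_decay_per_min = amplitude_decay_per_min,
                 noise_sd = noise_sd, drift_sd = drift_sd, seed = seed,
                 pulse_shape = pulse_shape),
            class = "pulsation_params")
}

# Lobe widths as fractions of the pulse period. The systolic (primary) lobe
# spans 0.6 of the cycle and the dicrotic (secondary) lobe half of that,
# mirroring the broad systolic upstroke/decay and the narrower rebound wave
# of arterial pulses; the broad primary keeps the spectral fundamental
# dominant over the dicrotic-induced second harmonic. With the default
# dicrotic delay of 0.65 the lobes do not overlap, so each period has
# exactly two local maxima with an exact secondary/primary height ratio.
.lobe_width_primary <- 0.6
.lobe_width_secondary <- 0.3

#' Relative vessel-volume waveform
#'
#' Deterministic periodic waveform of relative vessel volume: each period
#' holds a primary lobe of height `pulse_volume` (systolic constriction wave)
#' and a secondary lobe of height `dicrotic_ratio * pulse_volume` delayed by
#' `dicrotic_delay` of the period (rebound / dicrotic wave). The minimum
#' value is 0.
#'
#' @param params A [pulsation_params()].
#' @param t Uniform, increasing time grid in seconds.
#' @return Numeric vector of relative volumes (same length as `t`).
#' @examples
#' p <- pulsation_params(drive_rate = 1)
#' v <- vessel_waveform(p, seq(0, 2, by = 0.05))
#' @export
vessel_waveform <- function(params, t) {
  stopifnot(inherits(params, "pulsation_params"))
  if (length(t) == 0) stop("vessel_waveform: empty time grid")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("vessel_waveform: time grid must be increasing")
  period <- 1 / params$drive_rate
  u <- (t %% period) / period                      # phase in [0, 1)
  lobe <- function(u0, w) {
    # unit-height lobe occupying [0, w] of the phase
    z <- u0 / w
    inside <- u0 >= 0 & u0 <= w
    if (params$pulse_shape == "halfsine") {
      ifelse(inside, sin(pi * pmin(pmax(z, 0), 1)), 0)
    } else {
      ifelse(inside, exp(-0.5 * ((z - 0.5) / 0.18)^2), 0)
    }
  }
  # secondary lobe may wrap across the period boundary
  u2 <- (u - params$dicrotic_delay) %% 1
  params$pulse_volume *
    (lobe(u, .lobe_width_primary) +
       params$dicrotic_ratio * lobe(u2, .lobe_width_secondary))
}

#' RF trace container
#'
#' A uniformly sampled resonant-frequency time series with its sampling rate
#' and scenario labels.
#'
#' @param values RF samples in MHz. All finite, length >= 1.
#' @param fs Sampling rate in Hz (the acquisition firmware downsamples to
#'   20 Hz).
#' @param t0 Start time in seconds.
#' @param subject_id Subject label.
#' @param state State label, e.g. `"baseline"`, `"post_caffeine"`,
#'   `"phantom"`.
#' @param minute_mark Minutes since intervention (NA when not applicable).
#' @return An object of class `rf_trace`.
#' @export
rf_trace <- function(values, fs = 20, t0 = 0, subject_id = "unknown",
                     state = "phantom", minute_mark = NA_real_) {
  if (fs <= 0) stop("rf_trace: fs must be > 0")
  if (length(values) < 1) stop("rf_trace: need at least one sample")
  if (!all(is.finite(values))) stop("rf_trace: all values must be finite")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 subject_id = subject_id, state = state,
                 minute_mark = minute_mark),
            class = "rf_trace")
}

#' @export
print.rf_trace <- function(x, ...) {
  cat(sprintf("<rf_trace> %s/%s%s: %d samples @ %g Hz (%.1f s), mean %.6f MHz\n",
              x$subject_id, x$state,
              if (is.na(x$minute_mark)) "" else sprintf(" t+%gmin", x$minute_mark),
              length(x$values), x$fs, length(x$values) / x$fs,
              mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.rf_trace <- function(x, ...) {
  data.frame(time_s = x$t0 + (seq_along(x$values) - 1) / x$fs,
             rf_mhz = x$values,
             subject_id = x$subject_id, state = x$state,
             minute_mark = x$minute_mark)
}

#' Simulate an RF trace from a pulsating vessel
#'
#' Forward model from vessel state to the measured resonant-frequency trace.
#' The relative volume waveform `v(t)` perturbs the coupling elements as a
#' first-order linear coupling,
#' `Ccap(t) = Ccap (1 + kc a v(t))` and `Rind(t) = Rind (1 + kr a v(t))`,
#' where the attenuation `a = exp(-depth/lambda_d) exp(-lateral_offset/lambda_r)`
#' captures the loss of sensitivity with sensor-to-vessel distance and
#' lateral displacement. The resonant frequency is evaluated per sample,
#' then white Gaussian noise and a slow random-walk drift are added. In the
#' `post_caffeine` state the pulse amplitude is multiplied by
#' `exp(-amplitude_decay_per_min * minute_mark)`.
#'
#' @param params A [pulsation_params()].
#' @param circuit An [equivalent_circuit()].
#' @param duration Trace duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 20).
#' @param state,subject_id,minute_mark Labels stored on the trace.
#' @param kc,kr Phenomenological coupling gains from relative volume to
#'   `Ccap` and `Rind` (defaults 1e-3).
#' @param lambda_d,lambda_r Attenuation length scales in cm for depth and
#'   lateral offset (defaults 3 and 2 cm).
#' @return An [rf_trace()] (values in MHz).
#' @examples
#' tr <- generate_rf_trace(pulsation_params(noise_sd = 0), equivalent_circuit(),
#'                         duration = 10)
#' @export
generate_rf_trace <- function(params, circuit, duration, fs = 20,
                              state = "phantom", subject_id = "phantom",
                              minute_mark = NA_real_,
                              kc = 1e-3, kr = 1e-3,
                              lambda_d = 3, lambda_r = 2) {
  stopifnot(inherits(params, "pulsation_params"),
            inherits(circuit, "equivalent_circuit"))
  if (duration <= 0) stop("generate_rf_trace: duration must be > 0")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- vessel_waveform(params, t)
  if (identical(state, "post_caffeine") && !is.na(minute_mark))
    v <- v * exp(-params$amplitude_decay_per_min * minute_mark)
  a <- exp(-params$depth / lambda_d) * exp(-params$lateral_offset / lambda_r)
  ccap_t <- circuit$Ccap * (1 + kc * a * v)
  rind_t <- circuit$Rind * (1 + kr * a * v)
  f_mhz <- resonant_frequency(circuit, Ccap = ccap_t, Rind = rind_t) / 1e6
  if (params$noise_sd > 0 || params$drift_sd > 0) {
    f_mhz <- with_seed(params$seed, {
      noise <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
      drift <- if (params$drift_sd > 0)
        cumsum(rnorm(n, 0, params$drift_sd / sqrt(fs))) else 0
      f_mhz + noise + drift
    })
  }
  rf_trace(f_mhz, fs = fs, subject_id = subject_id, state = state,
           minute_mark = minute_mark)
}

#' Simulate a two-state volunteer cohort
#'
#' Generates baseline and post-caffeine RF recordings for a cohort of
#' synthetic subjects. Each subject draws an individual heart rate
#' (`drive_rate ~ Normal(1.17, 0.1)` Hz, truncated to `[0.8, 1.6]`, i.e.
#' roughly 50–95 bpm) and pulse strength
#' (`pulse_volume ~ Lognormal(meanlog = log(p0), sdlog = 0.2)` around the
#' base value `p0`). One baseline trace and one post-caffeine trace per
#' requested minute mark are emitted, the latter with the exponentially
#' decayed pulse amplitude.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param minutes Numeric vector of post-caffeine minute marks (possibly
#'   empty).
#' @param circuit An [equivalent_circuit()].
#' @param params_base A [pulsation_params()] giving cohort-level defaults.
#' @param seed Random seed controlling both subject draws and noise.
#' @param minutes_per_state Duration of every trace in minutes (default 1).
#' @param fs Sampling rate in Hz.
#' @return A list of [rf_trace()] objects, ordered subject-major
#'   (baseline first, then the minute marks in the given order).
#' @examples
#' traces <- generate_cohort(2, minutes = c(30), circuit = equivalent_circuit(),
#'                           params_base = pulsation_params(), seed = 1)
#' @export
generate_cohort <- function(n_subjects, minutes, circuit, params_base,
                            seed = 1, minutes_per_state = 1, fs = 20) {
  if (n_subjects < 1) stop("generate_cohort: n_subjects must be >= 1")
  stopifnot(inherits(params_base, "pulsation_params"))
  duration <- minutes_per_state * 60
  with_seed(seed, {
    out <- vector("list", n_subjects * (1 + length(minutes)))
    k <- 0L
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", i)
      p <- params_base
      p$drive_rate <- min(max(rnorm(1, 1.17, 0.1), 0.8), 1.6)
      p$pulse_volume <- rlnorm(1, meanlog = log(params_base$pulse_volume),
                               sdlog = 0.2)
      states <- c(list(list(state = "baseline", minute = NA_real_)),
                  lapply(minutes, function(m)
                    list(state = "post_caffeine", minute = m)))
      for (st in states) {
        p$seed <- sample.int(2147483646L, 1L)
        k <- k + 1L
        out[[k]] <- generate_rf_trace(p, circuit, duration = duration,
                                      fs = fs, state = st$state,
                                      subject_id = sid,
                                      minute_mark = st$minute)
      }
    }
    out
  })
}
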