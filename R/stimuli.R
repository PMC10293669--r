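#' ICMS pulse-train specification
#'
#' Parameterizes a current-controlled, charge-balanced symmetric biphasic
#' pulse train of the kind delivered through an implanted microelectrode
#' array to evoke somatosensory percepts. Both phases carry equal charge
#' magnitude; the leading phase is cathodal by default.
#'
#' The defaults are the stimulation parameters used throughout training:
#' 320 Hz, 200 us per phase, 40 us interphase interval, 650 ms train
#' duration, delivered simultaneously across 10 electrode sites, with a
#' safety limit of 5 nC per phase (reached at 25 uA with a 200 us phase).
#'
#' @param current_amplitude_ua Current amplitude in microamps (>= 0).
#' @param pulse_width_us Duration of each phase in microseconds.
#' @param interphase_interval_us Gap between the two phases, microseconds.
#' @param frequency_hz Pulse rate in hertz.
#' @param train_duration_ms Total train duration in milliseconds.
#' @param n_channels Number of electrode sites pulsed simultaneously.
#' @param cathodal_leading Logical; leading phase is cathodal.
#' @param charge_limit_nc Maximum permitted charge per phase, nC/ph.
#'
#' @return An object of class `pulse_train_spec`.
#' @examples
#' spec <- pulse_train_spec(current_amplitude_ua = 15)
#' charge_per_phase(spec$current_amplitude_ua, spec$pulse_width_us) # 3 nC/ph
#' @export
pulse_train_spec <- function(current_amplitude_ua = 15,
                             pulse_width_us = 200,
                             interphase_interval_us = 40,
                             frequency_hz = 320,
                             train_duration_ms = 650,
                             n_channels = 10,
                             cathodal_leading = TRUE,
                             charge_limit_nc = 5) {
  if (current_amplitude_ua < 0 || pulse_width_us <= 0 ||
      interphase_interval_us < 0 || frequency_hz <= 0 ||
      train_duration_ms <= 0 || n_channels < 1) {
    stop("invalid pulse train parameters: amplitudes/durations must be non-negative, ",
         "widths/frequency/duration/channels positive", call. = FALSE)
  }
  q <- charge_per_phase(current_amplitude_ua, pulse_width_us)
  if (q > charge_limit_nc + 1e-12) {
    stop(sprintf("charge per phase %.3f nC/ph exceeds the %.3f nC/ph limit",
                 q, charge_limit_nc), call. = FALSE)
  }
  period_us <- 1e6 / frequency_hz
  if (period_us < 2 * pulse_width_us + interphase_interval_us) {
    stop("pulse does not fit within the period: need 1/frequency >= ",
         "2*pulse_width + interphase_interval", call. = FALSE)
  }
  structure(
    list(current_amplitude_ua = current_amplitude_ua,
         pulse_width_us = pulse_width_us,
         interphase_interval_us = interphase_interval_us,
         frequency_hz = frequency_hz,
         train_duration_ms = train_duration_ms,
         n_channels = n_channels,
         cathodal_leading = cathodal_leading,
         charge_limit_nc = charge_limit_nc),
    class = "pulse_train_spec"
  )
}

#' @export
print.pulse_train_spec <- function(x, ...) {
  cat(sprintf(
    "ICMS pulse train: %.1f uA, %g us/phase (%.2f nC/ph), %g us IPI, %g Hz, %g ms, %d channels, %s-leading\n",
    x$current_amplitude_ua, x$pulse_width_us,
    charge_per_phase(x$current_amplitude_ua, x$pulse_width_us),
    x$interphase_interval_us, x$frequency_hz, x$train_duration_ms,
    x$n_channels, if (x$cathodal_leading) "cathodal" else "anodal"))
  invisible(x)
}

#' Charge per phase of a biphasic pulse
#'
#' Charge delivered in one phase: current amplitude times phase width,
#' converted to nanocoulombs per phase. 25 uA at 200 us/phase is 5 nC/ph,
#' the top of the 0--25 uA range used during threshold estimation.
#'
#' @param current_amplitude_ua Current amplitude, microamps (vectorized).
#' @param pulse_width_us Phase width, microseconds.
#' @return Charge in nC/ph.
#' @examples
#' charge_per_phase(25, 200) # 5
#' @export
charge_per_phase <- function(current_amplitude_ua, pulse_width_us) {
  if (any(current_amplitude_ua < 0) || any(pulse_width_us < 0)) {
    stop("current amplitude and pulse width must be non-negative", call. = FALSE)
  }
  # uA * us = 1e-6 A * 1e-6 s = 1e-12 C = 1e-3 nC
  current_amplitude_ua * pulse_width_us * 1e-3
}

#' Synthesize the pulse-onset structure of a train
#'
#' Expands a [pulse_train_spec()] into pulse onset times and the per-pulse
#' biphasic phase template. Pulses are spaced uniformly at the period,
#' starting at t = 0; only whole periods emit a pulse, so the count is
#' `floor(train_duration * frequency)`. Each pulse is charge balanced: the
#' signed phase charges sum to zero.
#'
#' @param spec A `pulse_train_spec`.
#' @return A list with `onsets_ms` (numeric vector), `n_pulses`, and
#'   `phases`, a data.frame describing one pulse (phase label, signed
#'   current in uA, start offset and duration in us, signed charge in nC).
#' @examples
#' train <- make_pulse_train(pulse_train_spec())
#' train$n_pulses # 208
#' @export
make_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  n <- floor(spec$train_duration_ms / 1000 * spec$frequency_hz + 1e-9)
  period_ms <- 1000 / spec$frequency_hz
  onsets <- (seq_len(n) - 1) * period_ms
  sgn <- if (spec$cathodal_leading) c(-1, 1) else c(1, -1)
  q <- charge_per_phase(spec$current_amplitude_ua, spec$pulse_width_us)
  phases <- data.frame(
    phase = c("leading", "trailing"),
    current_ua = sgn * spec$current_amplitude_ua,
    start_us = c(0, spec$pulse_width_us + spec$interphase_interval_us),
    duration_us = rep(spec$pulse_width_us, 2),
    charge_nc = sgn * q,
    stringsAsFactors = FALSE
  )
  list(onsets_ms = onsets, n_pulses = n, phases = phases)
}

#' Pure-tone specification for the auditory control stimulus
#'
#' The auditory analogue of the ICMS stimulus: a 6 kHz pure tone with
#' linear onset/offset ramps, whose sinusoidal amplitude is normalized to
#' a 0--100% scale where 0% is silence and 100% is the training tone
#' (~90 dB SPL as produced by the training rig).
#'
#' @param carrier_frequency_hz Carrier frequency, Hz.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param duration_ms Tone duration, ms.
#' @param ramp_duration_ms Linear onset and offset ramp duration, ms.
#' @param amplitude_percent Amplitude on the 0--100% training-tone scale.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(carrier_frequency_hz = 6000,
                      sample_rate_hz = 1e5,
                      duration_ms = 500,
                      ramp_duration_ms = 50,
                      amplitude_percent = 100) {
  if (amplitude_percent < 0 || amplitude_percent > 100) {
    stop("amplitude_percent must lie in [0, 100]", call. = FALSE)
  }
  if (2 * ramp_duration_ms > duration_ms) {
    stop("ramps longer than half the tone duration", call. = FALSE)
  }
  if (carrier_frequency_hz <= 0 || sample_rate_hz <= 0 || duration_ms <= 0 ||
      ramp_duration_ms < 0) {
    stop("tone frequencies and durations must be positive", call. = FALSE)
  }
  structure(
    list(carrier_frequency_hz = carrier_frequency_hz,
         sample_rate_hz = sample_rate_hz,
         duration_ms = duration_ms,
         ramp_duration_ms = ramp_duration_ms,
         amplitude_percent = amplitude_percent),
    class = "tone_spec"
  )
}

#' @export
print.tone_spec <- function(x, ...) {
  cat(sprintf("Pure tone: %g Hz carrier, %g ms (%g ms ramps), %g%% amplitude, fs = %g Hz\n",
              x$carrier_frequency_hz, x$duration_ms, x$ramp_duration_ms,
              x$amplitude_percent, x$sample_rate_hz))
  invisible(x)
}

#' Synthesize a tone waveform
#'
#' Renders a [tone_spec()] as a sample sequence in
#' `[-1, 1] * amplitude_percent / 100`, with linear onset and offset ramps.
#'
#' @param spec A `tone_spec`.
#' @return Numeric waveform of length `round(duration * sample_rate)`.
#' @examples
#' length(synthesize_tone(tone_spec())) # 50000
#' @export
synthesize_tone <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(spec$duration_ms / 1000 * spec$sample_rate_hz)
  t <- (seq_len(n) - 1) / spec$sample_rate_hz
  wave <- sin(2 * pi * spec$carrier_frequency_hz * t)
  ramp_n <- round(spec$ramp_duration_ms / 1000 * spec$sample_rate_hz)
  if (ramp_n > 0) {
    idx <- seq_len(n) - 1
    env <- pmin(1, idx / ramp_n, (n - 1 - idx) / ramp_n)
    env <- pmax(env, 0)
  } else {
    env <- rep(1, n)
  }
  wave * env * spec$amplitude_percent / 100
}

#' Convert percent tone amplitude to dB SPL (reporting convention)
#'
#' One convention for expressing the normalized amplitude scale in dB SPL,
#' anchored at the ~90 dB SPL training tone:
#' `dB = 90 + 20 * log10(percent / 100)`. Provided for reporting only; no
#' computation in the package uses this mapping, and other anchor/scaling
#' conventions exist.
#'
#' @param amplitude_percent Amplitude on the 0--100% scale (vectorized).
#' @return dB SPL under the stated convention (`-Inf` at 0%).
#' @export
amplitude_percent_to_db <- function(amplitude_percent) {
  if (any(amplitude_percent < 0 | amplitude_percent > 100)) {
    stop("amplitude_percent must lie in [0, 100]", call. = FALSE)
  }
  90 + 20 * log10(amplitude_percent / 100)
}

#' Stimulus intensity descriptor
#'
#' A tagged intensity value: charge in nC/ph for ICMS (pulsed across all
#' channels simultaneously) or percent amplitude for the auditory tone.
#'
#' @param modality `"icms"` or `"auditory"`.
#' @param value Intensity: nC/ph (ICMS) or percent amplitude (auditory).
#' @param charge_limit_nc Safety limit applied to ICMS intensities.
#' @return An object of class `stimulus_intensity`.
#' @export
stimulus_intensity <- function(modality = c("icms", "auditory"), value,
                               charge_limit_nc = 5) {
  modality <- match.arg(modality)
  if (value < 0) stop("intensity must be non-negative", call. = FALSE)
  if (modality == "icms" && value > charge_limit_nc + 1e-12) {
    stop("ICMS intensity exceeds the charge limit", call. = FALSE)
  }
  if (modality == "auditory" && value > 100) {
    stop("auditory intensity exceeds 100% amplitude", call. = FALSE)
  }
  structure(list(modality = modality, value = value),
            class = "stimulus_intensity")
}

#' Units string for a modality's intensity scale
#' @param modality `"icms"` or `"auditory"`.
#' @return `"nC/ph"` or `"%amplitude"`.
#' @export
intensity_units <- function(modality = c("icms", "auditory")) {
  modality <- match.arg(modality)
  if (modality == "icms") "nC/ph" else "%amplitude"
}
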