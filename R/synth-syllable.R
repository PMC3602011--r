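#' Specify a synthetic trill syllable
#'
#' A syllable is a windowed frequency sweep: the simplest signal whose
#' 99%-energy bandwidth and spectrogram cross-correlation behave
#' controllably. Real wren syllables are more ornate; see the methods
#' vignette for what this stand-in does and does not emulate.
#'
#' @param f_start,f_end Sweep start and end frequencies, Hz. Must lie in
#'   (0, Nyquist) at synthesis time.
#' @param duration Syllable duration in seconds (> 0).
#' @param sweep_shape `"linear"` (constant Hz/s) or `"exponential"`
#'   (constant octaves/s).
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(f_start, f_end, duration, sweep_shape = "linear") {
  stopifnot(f_start > 0, f_end > 0, duration > 0)
  sweep_shape <- match.arg(sweep_shape, c("linear", "exponential"))
  structure(list(f_start = f_start, f_end = f_end, duration = duration,
                 sweep_shape = sweep_shape),
            class = "syllable_spec")
}

#' Synthesize one syllable
#'
#' Renders the frequency sweep described by `spec` with a raised-cosine
#' (Hann) amplitude envelope. With `jitter_sd > 0` the sweep endpoints and
#' duration are each perturbed multiplicatively by `1 + N(0, jitter_sd)`
#' before rendering; jitter is the single knob controlling downstream
#' trill consistency.
#'
#' @param spec A [syllable_spec()].
#' @param sample_rate Sampling rate, Hz; must be at least twice the
#'   highest (possibly jittered) instantaneous frequency.
#' @param jitter_sd Standard deviation of the multiplicative rendition
#'   jitter (unitless; 0 disables).
#' @return Numeric waveform vector (peak amplitude 1 before enveloping).
#' @export
synth_syllable <- function(spec, sample_rate, jitter_sd = 0) {
  stopifnot(inherits(spec, "syllable_spec"), sample_rate > 0, jitter_sd >= 0)
  f0 <- spec$f_start
  f1 <- spec$f_end
  dur <- spec$duration
  if (jitter_sd > 0) {
    jit <- 1 + stats::rnorm(3, 0, jitter_sd)
    jit <- pmax(jit, 0.2) # guard against degenerate draws
    f0 <- f0 * jit[1]
    f1 <- f1 * jit[2]
    dur <- dur * jit[3]
  }
  nyq <- sample_rate / 2
  if (max(f0, f1) >= nyq)
    stop("syllable frequency ", round(max(f0, f1), 1),
         " Hz at or above Nyquist (", nyq, " Hz)")
  n <- max(2L, round(dur * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  d <- n / sample_rate
  if (spec$sweep_shape == "linear") {
    phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * d))
  } else {
    k <- f1 / f0
    if (abs(k - 1) < 1e-12) {
      phase <- 2 * pi * f0 * t
    } else {
      phase <- 2 * pi * f0 * d * (k^(t / d) - 1) / log(k)
    }
  }
  # raised-cosine onset/offset ramps with a flat sustain, so sweep energy
  # stays near-uniform across the swept band and the 99%-energy bandwidth
  # tracks the sweep span
  ramp <- max(2L, round(0.15 * n))
  env <- rep(1, n)
  up <- 0.5 - 0.5 * cos(pi * (seq_len(ramp) - 1) / (ramp - 1))
  env[seq_len(ramp)] <- up
  env[n + 1 - seq_len(ramp)] <- up
  sin(phase) * env
}

#' Ground truth for one synthetic trill
#'
#' @param male_id,year,trill_id Identifiers carried through to annotations.
#' @param trill_type Syllable-type label (categorical).
#' @param true_rate Target trill rate, syllables/s.
#' @param true_bandwidth Target 99%-energy frequency bandwidth, Hz.
#' @param true_pitch Target pitch (mean syllable high frequency), Hz.
#' @param jitter_sd Rendition jitter controlling consistency (unitless).
#' @param n_syllables Number of syllables (>= 2).
#' @param time_in_song Seconds from song start to trill start.
#' @return An object of class `trill_ground_truth`.
#' @export
trill_ground_truth <- function(male_id, year, trill_id = NA, trill_type = 1L,
                               true_rate, true_bandwidth, true_pitch,
                               jitter_sd = 0, n_syllables = 8L,
                               time_in_song = 0) {
  stopifnot(true_rate > 0, true_bandwidth > 0, true_pitch > true_bandwidth,
            n_syllables >= 2, jitter_sd >= 0, time_in_song >= 0)
  structure(list(male_id = male_id, year = year, trill_id = trill_id,
                 trill_type = trill_type, true_rate = true_rate,
                 true_bandwidth = true_bandwidth, true_pitch = true_pitch,
                 jitter_sd = jitter_sd, n_syllables = as.integer(n_syllables),
                 time_in_song = time_in_song),
            class = "trill_ground_truth")
}

#' Effective measured band of an enveloped linear sweep
#'
#' A linear sweep spends equal time per Hz, so its energy density across
#' the swept span follows the squared amplitude envelope. The onset and
#' offset ramps attenuate the band edges, and symmetric tail trimming of
#' the 99%-energy bandwidth therefore cuts into the ramps. This helper
#' computes, from the envelope alone, which fraction of the span survives
#' trimming, so the generator can widen the sweep to hit a target
#' measured bandwidth.
#'
#' @param ramp_frac Raised-cosine ramp length as a fraction of syllable
#'   duration per side.
#' @param tail Energy fraction trimmed per tail (0.005 for a 99% band).
#' @return List: `v_lo`, `v_hi` (band edges as fractions of the span) and
#'   `effective_fraction` (`v_hi - v_lo`).
#' @keywords internal
sweep_band_calibration <- function(ramp_frac = 0.15, tail = 0.005) {
  v <- seq(0, 1, length.out = 4001)
  env <- rep(1, length(v))
  up <- v < ramp_frac
  env[up] <- 0.5 - 0.5 * cos(pi * v[up] / ramp_frac)
  dn <- v > 1 - ramp_frac
  env[dn] <- 0.5 - 0.5 * cos(pi * (1 - v[dn]) / ramp_frac)
  e <- env^2
  cum <- cumsum(e) / sum(e)
  v_lo <- v[which(cum >= tail)[1]]
  v_hi <- v[which(cum >= 1 - tail)[1]]
  list(v_lo = v_lo, v_hi = v_hi, effective_fraction = v_hi - v_lo)
}

#' Synthesize a trill with syllable annotations
#'
#' Renders `n_syllables` copies of a sweep from `true_pitch -
#' true_bandwidth` to `true_pitch`, spaced so that the realized syllable
#' count divided by the first-onset-to-last-offset span equals
#' `true_rate` exactly (before jitter). Optionally adds white Gaussian
#' background noise at a fixed signal-to-noise ratio.
#'
#' @param gt A [trill_ground_truth()].
#' @param sample_rate Sampling rate in Hz.
#' @param snr_db Signal-to-noise ratio of added white noise in dB;
#'   `Inf` (no noise) leaves the waveform clean.
#' @param duty Fraction of the syllable period spent voicing (0, 1).
#' @param pad_s Leading/trailing silence in seconds.
#' @return A list with `waveform`, `sample_rate`, and `annotations` (one
#'   row per syllable: `begin_s`, `end_s`, `low_hz`, `high_hz`,
#'   `trill_type`, plus ids).
#' @export
synth_trill <- function(gt, sample_rate = 48000, snr_db = 30, duty = 0.55,
                        pad_s = 0.01) {
  stopifnot(inherits(gt, "trill_ground_truth"), duty > 0, duty < 1)
  n <- gt$n_syllables
  rate <- gt$true_rate
  syl_dur <- duty / rate
  # spacing chosen so n / (last offset - first onset) = true_rate
  period <- if (n > 1) (n / rate - syl_dur) / (n - 1) else syl_dur
  if (n > 1 && period < syl_dur)
    stop("infeasible: syllable duration ", signif(syl_dur, 3),
         " s exceeds inter-onset period ", signif(period, 3), " s")
  # widen the sweep so the measured 99%-energy band matches the target:
  # envelope ramps attenuate band-edge energy, so the trimmed band is a
  # known fraction of the swept span
  cal <- sweep_band_calibration()
  span <- gt$true_bandwidth / cal$effective_fraction
  f_high <- gt$true_pitch + (1 - cal$v_hi) * span
  f_low <- f_high - span
  if (f_low <= 0) stop("bandwidth exceeds pitch; sweep would cross 0 Hz")
  spec <- syllable_spec(f_low, f_high, syl_dur)
  onsets <- pad_s + (seq_len(n) - 1) * period
  total_dur <- pad_s * 2 + (n - 1) * period + syl_dur
  wav <- numeric(round(total_dur * sample_rate))
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    syl <- synth_syllable(spec, sample_rate, jitter_sd = gt$jitter_sd)
    i0 <- round(onsets[i] * sample_rate) + 1L
    idx <- i0:(i0 + length(syl) - 1L)
    if (max(idx) > length(wav)) # jitter can lengthen the final syllable
      wav <- c(wav, numeric(max(idx) - length(wav)))
    wav[idx] <- wav[idx] + syl
    ann[[i]] <- data.frame(
      male_id = gt$male_id, year = gt$year, trill_id = gt$trill_id,
      syllable_idx = i,
      begin_s = (i0 - 1L) / sample_rate,
      end_s = (i0 - 1L + length(syl)) / sample_rate,
      low_hz = min(f_low, f_high), high_hz = max(f_low, f_high),
      trill_type = gt$trill_type)
  }
  if (is.finite(snr_db)) {
    sig_rms <- sqrt(mean(wav^2))
    noise_sd <- sig_rms / 10^(snr_db / 20)
    wav <- wav + stats::rnorm(length(wav), 0, noise_sd)
  }
  list(waveform = wav, sample_rate = sample_rate,
       annotations = do.call(rbind, ann))
}
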