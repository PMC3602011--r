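#' Spectrogram parameter presets
#'
#' Two presets are used throughout: a fine-frequency *measurement* preset
#' (Hann window, 4096-point DFT, 111-sample hop, i.e. 11.72 Hz grid at
#' 48 kHz) for bandwidth, pitch and frequency extrema; and a coarser
#' *correlation* preset (Hann, 1024-point DFT, 80% overlap) for syllable
#' cross-correlation. The two tasks use distinct settings deliberately.
#'
#' @param dft_size DFT length in samples.
#' @param hop Hop (frame advance) in samples; `0 < hop <= dft_size`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `spectrogram_params` with the derived grid
#'   (`bin_hz`, Hz per frequency bin; `frame_s`, seconds per frame).
#' @export
spectrogram_params <- function(dft_size, hop, sample_rate) {
  stopifnot(dft_size >= 2, hop > 0, hop <= dft_size, sample_rate > 0)
  structure(list(dft_size = as.integer(dft_size), hop = as.integer(hop),
                 sample_rate = sample_rate,
                 bin_hz = sample_rate / dft_size,
                 frame_s = hop / sample_rate),
            class = "spectrogram_params")
}

#' @rdname spectrogram_params
#' @export
measurement_params <- function(sample_rate = 48000) {
  spectrogram_params(4096L, 111L, sample_rate)
}

#' @rdname spectrogram_params
#' @export
correlation_params <- function(sample_rate = 48000) {
  # 1024-point DFT with 80% overlap -> hop of ~205 samples
  spectrogram_params(1024L, 205L, sample_rate)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier magnitude (not power) of a mono waveform, Hann
#' windowed. Frequency grid spacing is `sample_rate / dft_size`.
#'
#' @param waveform Numeric vector; must be at least `dft_size` samples.
#' @param params A [spectrogram_params()].
#' @return Object of class `trill_spectrogram`: list with `mag`
#'   (frequency x time magnitude matrix), `freq` (bin centre Hz),
#'   `time` (frame centre s), `params`.
#' @export
spectrogram <- function(waveform, params) {
  stopifnot(inherits(params, "spectrogram_params"))
  n <- length(waveform)
  dft <- params$dft_size
  if (n < dft)
    stop("waveform (", n, " samples) shorter than DFT size (", dft, ")")
  hop <- params$hop
  n_frames <- (n - dft) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(dft), starts, `+`)
  frames <- matrix(waveform[idx], nrow = dft) * hann_window(dft)
  spec <- stats::mvfft(frames)
  n_bins <- dft %/% 2L + 1L
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  structure(list(mag = mag,
                 freq = (seq_len(n_bins) - 1L) * params$bin_hz,
                 time = (starts + dft / 2) / params$sample_rate,
                 params = params),
            class = "trill_spectrogram")
}

#' Pooled power spectrum of a selection
#'
#' Mean power (magnitude squared) over Hann-windowed frames on the
#' measurement frequency grid; selections shorter than the DFT are
#' zero-padded to one frame. Pooling uses 50%-overlapping frames (a Welch
#' average; the denser hop of the display spectrogram changes only the
#' estimator's redundancy, not its expectation). Power-spectrum
#' measurements are invariant to uniform gain changes.
#'
#' @inheritParams spectrogram
#' @param hop Frame advance for pooling (default `dft_size / 2`).
#' @return List with `power` (vector) and `freq` (Hz).
#' @export
power_spectrum <- function(waveform, params,
                           hop = params$dft_size %/% 2L) {
  stopifnot(inherits(params, "spectrogram_params"))
  dft <- params$dft_size
  # pad half a frame each side so every sample of the selection receives
  # (near-)uniform total window weight across the pooled frames
  pad <- numeric(dft %/% 2L)
  waveform <- c(pad, waveform, pad)
  if (length(waveform) < dft)
    waveform <- c(waveform, numeric(dft - length(waveform)))
  sp <- spectrogram(waveform,
                    spectrogram_params(dft, hop, params$sample_rate))
  list(power = rowMeans(sp$mag^2), freq = sp$freq)
}

#' Energy bandwidth of a power spectrum
#'
#' Smallest frequency band holding `fraction` of total energy under
#' symmetric tail trimming: at most `(1 - fraction)/2` of the energy lies
#' below `low_hz` and the same above `high_hz`. Band edges are located by
#' linear interpolation of the cumulative energy across bins (each bin
#' treated as uniform over its width), so resolution is about one grid
#' bin.
#'
#' @param power Nonnegative power spectrum values on a uniform grid.
#' @param freq Bin centre frequencies, Hz (uniformly spaced).
#' @param fraction Energy fraction to retain (default 0.99).
#' @return List with `low_hz`, `high_hz`, `bandwidth_hz`.
#' @export
energy_bandwidth <- function(power, freq, fraction = 0.99) {
  stopifnot(length(power) == length(freq), all(power >= -1e-12),
            fraction > 0, fraction < 1)
  power <- pmax(power, 0)
  total <- sum(power)
  if (total <= 0) stop("zero-energy spectrum: bandwidth undefined")
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  edges <- c(freq - df / 2, freq[length(freq)] + df / 2)
  cum <- c(0, cumsum(power))
  tail_e <- (1 - fraction) / 2 * total
  interp_quantile <- function(target) {
    i <- which(cum[-1] > target)[1]
    edges[i] + (target - cum[i]) / power[i] * df
  }
  low <- interp_quantile(tail_e)
  high_target <- total - tail_e
  j <- which(cum[-1] >= high_target)[1]
  high <- edges[j] + (high_target - cum[j]) / power[j] * df
  list(low_hz = low, high_hz = high, bandwidth_hz = high - low)
}

#' Measure every annotated trill in a directory of recordings
#'
#' File-based front end to [measure_trill()] and
#' [measure_consistency()]: reads a tab-delimited selection table (one
#' row per syllable; see [read_selection_table()] for the schema), pulls
#' each trill's samples from its WAV file, and returns the per-trill
#' acoustic measures. Trills sharing a `song_id` are assumed to share a
#' song, whose earliest annotation marks the song start for
#' `time_in_song`.
#'
#' @param wav_dir Directory containing the WAV files named in the
#'   selection table.
#' @param selections Selection table data frame or path.
#' @param sample_rate Expected sampling rate (checked against files).
#' @return Data frame of per-trill measures including `consistency`.
#' @export
measure_selections <- function(wav_dir, selections, sample_rate = 48000) {
  if (is.character(selections))
    selections <- read_selection_table(selections)
  wav_cache <- new.env(parent = emptyenv())
  get_wav <- function(f) {
    if (is.null(wav_cache[[f]])) {
      w <- read_wav(file.path(wav_dir, f))
      if (w$sample_rate != sample_rate)
        stop("unexpected sample rate in ", f, ": ", w$sample_rate)
      wav_cache[[f]] <- w$samples
    }
    wav_cache[[f]]
  }
  song_start <- stats::ave(selections$begin_s, selections$song_id,
                           FUN = min)
  out <- lapply(split(seq_len(nrow(selections)), selections$trill_id),
                function(i) {
                  ann <- selections[i, ]
                  wav <- get_wav(ann$file[1])
                  m <- measure_trill(wav, ann, sample_rate,
                                     song_begin_s = song_start[i][1])
                  m$consistency <- measure_consistency(
                    wav, ann, sample_rate,
                    trill_low_hz = m$low_hz, trill_high_hz = m$high_hz)
                  m$male_id <- if ("male_id" %in% names(ann))
                    ann$male_id[1] else NA
                  m$year <- if ("year" %in% names(ann)) ann$year[1] else NA
                  m
                })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Measure one trill from waveform and annotations
#'
#' Computes the per-trill acoustic summary: trill rate `T` (syllable count
#' divided by the first-onset-to-last-offset span), 99%-energy frequency
#' bandwidth `B` of the pooled whole-trill power spectrum, pitch `P`
#' (mean over syllables of the per-syllable 99%-energy high frequency),
#' trill duration, timing of the trill within the song, and the trill's
#' frequency extrema (min/max of per-syllable 99%-energy bounds, used to
#' bound the consistency cross-correlation).
#'
#' @param waveform Mono waveform containing the trill (whole recording or
#'   trill clip; annotation times index into it).
#' @param annotations Data frame with one row per syllable (`begin_s`,
#'   `end_s` in seconds from waveform start, `trill_type`), ordered or
#'   orderable by onset; syllables must not overlap.
#' @param sample_rate Sampling rate, Hz.
#' @param params Measurement [spectrogram_params()]; defaults to the
#'   4096-point preset.
#' @param song_begin_s Song start time (s) used for `time_in_song`.
#' @param fraction Energy fraction for bandwidth (default 0.99).
#' @return One-row data frame of class `trill_measures`.
#' @export
measure_trill <- function(waveform, annotations, sample_rate = 48000,
                          params = measurement_params(sample_rate),
                          song_begin_s = 0, fraction = 0.99) {
  ann <- annotations[order(annotations$begin_s), , drop = FALSE]
  n <- nrow(ann)
  if (n < 2) stop("need at least 2 annotated syllables, got ", n)
  if (any(ann$end_s <= ann$begin_s)) stop("syllable with non-positive duration")
  if (any(ann$begin_s[-1] < ann$end_s[-n] - 1e-9))
    stop("overlapping or out-of-order syllable annotations")
  clip <- function(b, e) {
    i0 <- max(1L, floor(b * sample_rate) + 1L)
    i1 <- min(length(waveform), ceiling(e * sample_rate))
    waveform[i0:i1]
  }
  span <- ann$end_s[n] - ann$begin_s[1]
  trill_ps <- power_spectrum(clip(ann$begin_s[1], ann$end_s[n]), params)
  bw <- energy_bandwidth(trill_ps$power, trill_ps$freq, fraction)
  syl_bands <- lapply(seq_len(n), function(i) {
    ps <- power_spectrum(clip(ann$begin_s[i], ann$end_s[i]), params)
    energy_bandwidth(ps$power, ps$freq, fraction)
  })
  highs <- vapply(syl_bands, `[[`, numeric(1), "high_hz")
  lows <- vapply(syl_bands, `[[`, numeric(1), "low_hz")
  out <- data.frame(
    trill_id = if ("trill_id" %in% names(ann)) ann$trill_id[1] else NA,
    trill_type = if ("trill_type" %in% names(ann)) ann$trill_type[1] else NA,
    n_syllables = n,
    trill_rate = n / span,
    bandwidth = bw$bandwidth_hz,
    pitch = mean(highs),
    duration = span,
    time_in_song = ann$begin_s[1] - song_begin_s,
    low_hz = min(lows),
    high_hz = max(highs))
  class(out) <- c("trill_measures", class(out))
  out
}
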