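#' Spectrogram cross-correlation between two syllables
#'
#' Peak normalized 2-D cross-correlation over time lags only (sounds are
#' never shifted in frequency, so similarity includes pitch). Before
#' correlating, rows outside `freq_bounds` are zeroed -- callers pass the
#' trill's frequency extrema widened by 200 Hz on each side to suppress
#' background noise -- and, approximating broadband masking, cells below
#' `masking_fraction` of that spectrogram's (bounded) peak magnitude are
#' zeroed. The score is `max_lag <A, B_lag> / (||A|| ||B||)` with
#' Frobenius norms, hence in [0, 1] for nonnegative magnitudes.
#'
#' @param spec_a,spec_b [spectrogram()] objects on identical frequency
#'   grids.
#' @param freq_bounds Length-2 numeric `(low, high)` in Hz, or `NULL` for
#'   no bounding.
#' @param masking_fraction Cells below this fraction of the spectrogram's
#'   peak are zeroed (default 0.5); 0 disables masking.
#' @return Correlation score in [0, 1].
#' @export
syllable_xcorr <- function(spec_a, spec_b, freq_bounds = NULL,
                           masking_fraction = 0.5) {
  stopifnot(inherits(spec_a, "trill_spectrogram"),
            inherits(spec_b, "trill_spectrogram"))
  if (length(spec_a$freq) != length(spec_b$freq) ||
      any(abs(spec_a$freq - spec_b$freq) > 1e-6))
    stop("spectrograms are on different frequency grids")
  a <- prep_spec_mag(spec_a, freq_bounds, masking_fraction)
  b <- prep_spec_mag(spec_b, freq_bounds, masking_fraction)
  na <- ncol(a)
  nb <- ncol(b)
  norm_a <- sqrt(sum(a^2))
  norm_b <- sqrt(sum(b^2))
  if (norm_a == 0 || norm_b == 0) {
    warning("all-zero masked spectrogram; correlation score set to 0")
    return(0)
  }
  best <- 0
  for (lag in -(nb - 1):(na - 1)) {
    ia <- max(1, 1 + lag):min(na, nb + lag)
    ib <- ia - lag
    s <- sum(a[, ia, drop = FALSE] * b[, ib, drop = FALSE])
    if (s > best) best <- s
  }
  min(best / (norm_a * norm_b), 1)
}

prep_spec_mag <- function(sp, freq_bounds, masking_fraction) {
  m <- sp$mag
  if (!is.null(freq_bounds)) {
    keep <- sp$freq >= freq_bounds[1] & sp$freq <= freq_bounds[2]
    m[!keep, ] <- 0
  }
  if (masking_fraction > 0) {
    peak <- max(m)
    m[m < masking_fraction * peak] <- 0
  }
  m
}

#' Trill consistency
#'
#' Mean spectrogram cross-correlation score over all unordered pairs of
#' syllables within one trill: higher consistency means more precise
#' syllable repetition. Pair scores are identical to [syllable_xcorr()];
#' the all-pairs sweep over time lags is batched through row-wise FFTs
#' so that trills with many syllables stay cheap.
#'
#' @param spec_list List of >= 2 syllable [spectrogram()]s (same grid).
#' @inheritParams syllable_xcorr
#' @return Consistency `C` in [0, 1].
#' @export
trill_consistency <- function(spec_list, freq_bounds = NULL,
                              masking_fraction = 0.5) {
  n <- length(spec_list)
  if (n < 2) stop("trill consistency needs at least 2 syllables")
  f0 <- spec_list[[1]]$freq
  for (sp in spec_list[-1]) {
    if (length(sp$freq) != length(f0) || any(abs(sp$freq - f0) > 1e-6))
      stop("spectrograms are on different frequency grids")
  }
  mats <- lapply(spec_list, prep_spec_mag, freq_bounds = freq_bounds,
                 masking_fraction = masking_fraction)
  norms <- vapply(mats, function(m) sqrt(sum(m^2)), numeric(1))
  if (any(norms == 0))
    warning("all-zero masked spectrogram; its pair scores are 0")
  n_frames <- vapply(mats, ncol, integer(1))
  L <- 2L * max(n_frames) # >= na + nb - 1: linear, not circular, correlation
  ffts <- lapply(mats, function(m) {
    pad <- matrix(0, L, nrow(m))
    pad[seq_len(ncol(m)), ] <- t(m)
    stats::mvfft(pad)
  })
  ones <- rep(1 + 0i, ncol(ffts[[1]]))
  scores <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (norms[i] == 0 || norms[j] == 0) {
        scores <- c(scores, 0)
        next
      }
      cross <- drop((ffts[[i]] * Conj(ffts[[j]])) %*% ones)
      xc <- Re(stats::fft(cross, inverse = TRUE)) / L
      scores <- c(scores, min(max(xc) / (norms[i] * norms[j]), 1))
    }
  }
  mean(scores)
}

#' Measure trill consistency from a waveform
#'
#' Extracts each annotated syllable, zero-pads it to twice its length,
#' computes the correlation-preset spectrogram, and returns the mean
#' pairwise cross-correlation bounded at 200 Hz beyond the trill's
#' frequency extrema.
#'
#' @inheritParams measure_trill
#' @param trill_low_hz,trill_high_hz Trill frequency extrema in Hz (e.g.
#'   from [measure_trill()] or the annotations); the correlation band is
#'   `[trill_low_hz - 200, trill_high_hz + 200]`.
#' @param params Correlation-preset [spectrogram_params()].
#' @param bound_pad_hz Widening of the correlation band, Hz (default 200).
#' @param masking_fraction Passed to [syllable_xcorr()].
#' @return Consistency score in [0, 1].
#' @export
measure_consistency <- function(waveform, annotations, sample_rate = 48000,
                                trill_low_hz = NULL, trill_high_hz = NULL,
                                params = correlation_params(sample_rate),
                                bound_pad_hz = 200,
                                masking_fraction = 0.5) {
  ann <- annotations[order(annotations$begin_s), , drop = FALSE]
  if (nrow(ann) < 2) stop("trill consistency needs at least 2 syllables")
  if (is.null(trill_low_hz)) trill_low_hz <- min(ann$low_hz)
  if (is.null(trill_high_hz)) trill_high_hz <- max(ann$high_hz)
  specs <- lapply(seq_len(nrow(ann)), function(i) {
    i0 <- max(1L, floor(ann$begin_s[i] * sample_rate) + 1L)
    i1 <- min(length(waveform), ceiling(ann$end_s[i] * sample_rate))
    syl <- waveform[i0:i1]
    # "data length 50%": analysis frame is half signal, half zero padding
    syl <- c(syl, numeric(length(syl)))
    if (length(syl) < params$dft_size)
      syl <- c(syl, numeric(params$dft_size - length(syl)))
    spectrogram(syl, params)
  })
  trill_consistency(specs,
                    freq_bounds = c(trill_low_hz - bound_pad_hz,
                                    trill_high_hz + bound_pad_hz),
                    masking_fraction = masking_fraction)
}

#' Variance-stabilizing transform for consistency
#'
#' `-log(1 - C)` with natural log; scores at the ceiling are capped at
#' `1 - 1e-6` so the transform stays finite.
#'
#' @param consistency Scores in [0, 1].
#' @return Transformed values (>= 0, finite).
#' @export
consistency_transform <- function(consistency) {
  if (any(!is.finite(consistency)) ||
      any(consistency < 0) || any(consistency > 1))
    stop("consistency scores must lie in [0, 1]")
  -log(1 - pmin(consistency, 1 - 1e-6))
}

#' @rdname consistency_transform
#' @param transformed Values on the transformed scale.
#' @export
consistency_backtransform <- function(transformed) {
  stopifnot(all(transformed >= 0))
  1 - exp(-transformed)
}
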