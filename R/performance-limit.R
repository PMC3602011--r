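#' Upper-bound regression for the vocal performance limit
#'
#' Estimates the performance frontier on the (trill rate, frequency
#' bandwidth) plane: trill rate is partitioned into fixed-width bins, the
#' trill with maximal bandwidth is taken in each occupied bin, and an
#' ordinary least-squares line through those per-bin maxima gives the
#' limit `bandwidth = a * rate + b`. The per-bin maximum keeps its own
#' rate coordinate (rather than the bin midpoint) so that exactly
#' collinear maxima are recovered to machine precision.
#'
#' @param trill_rate,bandwidth Numeric vectors: per-trill rate
#'   (syllables/s) and 99%-energy bandwidth (Hz).
#' @param bin_width Bin width in syllables/s (default 2).
#' @return Object of class `performance_limit`: list with `slope` (Hz per
#'   syll/s), `intercept` (Hz), `n_bins`, `bin_width`, and the per-bin
#'   maxima used (`bin_points`).
#' @export
upper_bound_regression <- function(trill_rate, bandwidth, bin_width = 2) {
  stopifnot(length(trill_rate) == length(bandwidth), bin_width > 0)
  ok <- is.finite(trill_rate) & is.finite(bandwidth)
  trill_rate <- trill_rate[ok]
  bandwidth <- bandwidth[ok]
  if (length(trill_rate) == 0) stop("no finite (rate, bandwidth) points")
  if (stats::var(trill_rate) == 0)
    stop("zero variance in trill rate; cannot bin")
  bin <- floor(trill_rate / bin_width)
  occupied <- split(seq_along(trill_rate), bin)
  if (length(occupied) < 5)
    stop("only ", length(occupied),
         " occupied trill-rate bins; need at least 5")
  max_idx <- vapply(occupied, function(i) i[which.max(bandwidth[i])],
                    integer(1))
  x <- trill_rate[max_idx]
  y <- bandwidth[max_idx]
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_bins = length(occupied), bin_width = bin_width,
                 bin_points = data.frame(trill_rate = x, bandwidth = y)),
            class = "performance_limit")
}

#' @export
print.performance_limit <- function(x, ...) {
  cat("Performance limit: bandwidth =", format(x$slope, digits = 6),
      "* rate +", format(x$intercept, digits = 6), "Hz\n")
  cat("  fitted through maxima of", x$n_bins, "rate bins of width",
      x$bin_width, "syll/s\n")
  invisible(x)
}

#' Simulate a trill cloud under a performance limit
#'
#' Draws (rate, bandwidth) points under the line `bandwidth = slope *
#' rate + intercept`. With the default `"triangular"` shape, orthogonal
#' deviations follow a triangular density with mode 0 (probability decays
#' linearly away from the limit), giving the triangular point cloud
#' expected under a hard performance frontier; `"gaussian"` instead uses
#' a truncated normal deviation (the bundle generator's trait model).
#'
#' @param n Number of trills.
#' @param slope,intercept Limit parameters (Hz per syll/s, Hz).
#' @param rate_range Uniform trill-rate range, syllables/s.
#' @param shape Deviation density shape.
#' @param dev_mean Mean orthogonal deviation (sets the triangular
#'   maximum at `3 * dev_mean`, or the normal mean).
#' @param dev_sd Normal-shape standard deviation.
#' @return Data frame `trill_rate`, `bandwidth`, `deviation`.
#' @export
simulate_trill_cloud <- function(n, slope = -168.5, intercept = 6019,
                                 rate_range = c(2.5, 16),
                                 shape = c("triangular", "gaussian"),
                                 dev_mean = 8.2, dev_sd = 2.5) {
  shape <- match.arg(shape)
  rate <- stats::runif(n, rate_range[1], rate_range[2])
  dev <- if (shape == "triangular") {
    d_max <- 3 * dev_mean
    d_max * (1 - sqrt(stats::runif(n))) # linearly decaying density on [0, d_max]
  } else {
    pmax(stats::rnorm(n, dev_mean, dev_sd), 0)
  }
  bw <- slope * rate + intercept - dev * sqrt(1 + slope^2)
  data.frame(trill_rate = rate, bandwidth = bw, deviation = dev)
}

#' Vocal deviation from the performance limit
#'
#' Signed orthogonal distance from each trill's (rate, bandwidth) point
#' to the performance limit, with bandwidth in Hz and rate in
#' syllables/s: `D = (a*rate + b - bandwidth) / sqrt(1 + a^2)`. Positive
#' below the limit; lower deviation means the trill lies closer to the
#' frontier and is the more physically challenging. Points above the
#' fitted line get negative deviation and are retained.
#'
#' @param trill_rate,bandwidth Numeric vectors (syllables/s, Hz).
#' @param limit A [upper_bound_regression()] fit, or any list with
#'   `slope` and `intercept`.
#' @return Numeric vector of deviations.
#' @export
vocal_deviation <- function(trill_rate, bandwidth, limit) {
  a <- limit$slope
  b <- limit$intercept
  if (!is.finite(a) || !is.finite(b)) stop("invalid performance limit")
  (a * trill_rate + b - bandwidth) / sqrt(1 + a^2)
}
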