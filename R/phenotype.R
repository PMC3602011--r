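#' Body condition as a standardized residual
#'
#' Regresses weight on tarsus length, controlling for capture date
#' (day-of-year) and time of day (decimal hours) as linear covariates,
#' and returns the standardized residual (mean 0, SD 1 over the
#' regression sample). Higher scores mean heavier than expected for
#' skeletal size, date, and hour.
#'
#' @param records Data frame with columns `weight_g`, `tarsus_mm`,
#'   `capture_doy`, `capture_hour`.
#' @return Numeric vector of condition scores, NA where inputs are
#'   incomplete.
#' @export
body_condition <- function(records) {
  need <- c("weight_g", "tarsus_mm", "capture_doy", "capture_hour")
  stopifnot(all(need %in% names(records)))
  cc <- stats::complete.cases(records[, need])
  if (sum(cc) < 10)
    stop("need at least 10 complete records to fit the condition model")
  d <- records[cc, need]
  if (stats::var(d$tarsus_mm) == 0)
    stop("degenerate design: tarsus length is constant")
  fit <- stats::lm(weight_g ~ tarsus_mm + capture_doy + capture_hour,
                   data = d)
  r <- stats::residuals(fit)
  out <- rep(NA_real_, nrow(records))
  s <- stats::sd(r)
  # a perfect fit leaves no condition variation to standardize
  out[cc] <- if (s < 1e-10) 0 else (r - mean(r)) / s
  out
}

#' Aggression metrics from a playback event log
#'
#' Song rate is counted over the entire trial; the proportion of time
#' within 5 m of the speaker and the number of flights across the
#' speaker (2 m ring crossings) are restricted to song-bout windows,
#' since silent periods contain many structural zeros. Transformed
#' versions for analysis (`flights^0.55`, arcsine-square-root of time
#' close) are returned alongside the raw values.
#'
#' @param events Data frame for one trial: columns `event_type` (one of
#'   `trial`, `bout`, `song`, `within_5m`, `crossing`), `t_start`,
#'   `t_end` in seconds.
#' @return One-row data frame: `song_rate` (songs/min), `flights`
#'   (mean crossings per bout), `time_close` (proportion),
#'   `flights_transformed`, `time_close_transformed`.
#' @export
aggression_metrics <- function(events) {
  trial <- events[events$event_type == "trial", ]
  if (nrow(trial) != 1) stop("expected exactly one trial window")
  bouts <- events[events$event_type == "bout", ]
  if (nrow(bouts) == 0) stop("no song-bout windows in log")
  if (any(bouts$t_end <= bouts$t_start)) stop("zero-length song bout")
  trial_min <- (trial$t_end - trial$t_start) / 60
  song_rate <- sum(events$event_type == "song") / trial_min

  overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  pos <- events[events$event_type == "within_5m", , drop = FALSE]
  close_per_bout <- vapply(seq_len(nrow(bouts)), function(b) {
    if (nrow(pos) == 0) return(0)
    sum(overlap(pos$t_start, pos$t_end, bouts$t_start[b], bouts$t_end[b])) /
      (bouts$t_end[b] - bouts$t_start[b])
  }, numeric(1))
  cross <- events[events$event_type == "crossing", , drop = FALSE]
  fl_per_bout <- vapply(seq_len(nrow(bouts)), function(b)
    sum(cross$t_start >= bouts$t_start[b] & cross$t_start < bouts$t_end[b]),
    numeric(1))
  time_close <- mean(close_per_bout)
  flights <- mean(fl_per_bout)
  data.frame(song_rate = song_rate, flights = flights,
             time_close = time_close,
             flights_transformed = flights^0.55,
             time_close_transformed = asin(sqrt(min(max(time_close, 0), 1))))
}

#' Age class from banding history
#'
#' `SY` (second-year, first breeding season) if the bird was banded as a
#' nestling exactly the previous year; `ASY` (after-second-year) if it
#' was banded as an adult in any earlier season; otherwise unknown.
#'
#' @param banding Data frame with columns `band_year` and `stage`
#'   (`"nestling"` or `"adult"`) for one bird.
#' @param observation_year Year the bird is being aged for.
#' @return `"SY"`, `"ASY"`, or `NA_character_`.
#' @export
code_age <- function(banding, observation_year) {
  prior <- banding[banding$band_year < observation_year, , drop = FALSE]
  as_nestling_prev <- any(prior$stage == "nestling" &
                            prior$band_year == observation_year - 1)
  nestling_older <- any(prior$stage == "nestling" &
                          prior$band_year < observation_year - 1)
  as_adult_prior <- any(prior$stage == "adult")
  if (as_nestling_prev && (as_adult_prior || nestling_older))
    stop("contradictory banding history: nestling band in year ",
         observation_year - 1, " alongside earlier records")
  if (as_nestling_prev) return("SY")
  if (as_adult_prior || nestling_older) return("ASY")
  NA_character_
}

#' Derive male-year quality covariates
#'
#' Adds body condition and, when playback logs are supplied, aggression
#' metrics to a male-year phenotype table.
#'
#' @param phenotypes Per-male-year phenotype table (see
#'   [simulate_population()] for the schema).
#' @param playback_events Optional event log covering multiple trials
#'   (column `trial_id` distinguishes them).
#' @return The phenotype table with `condition`, `song_rate`, `flights`,
#'   `time_close` (and transformed) columns appended.
#' @export
derive_quality <- function(phenotypes, playback_events = NULL) {
  out <- phenotypes
  out$condition <- body_condition(phenotypes)
  if (!is.null(playback_events)) {
    per_trial <- lapply(split(playback_events, playback_events$trial_id),
                        function(ev) {
                          cbind(data.frame(male_id = ev$male_id[1],
                                           year = ev$year[1]),
                                aggression_metrics(ev))
                        })
    agg <- do.call(rbind, per_trial)
    out <- merge(out, agg, by = c("male_id", "year"), all.x = TRUE,
                 sort = FALSE)
  }
  out[order(out$male_id, out$year), ]
}
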