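#' Configuration for a full study run
#'
#' @param population A [population_config()] (its seed drives all
#'   randomness in the run).
#' @param measure_audio If `TRUE`, every trill is rendered to audio and
#'   measured through the spectrogram chain; if `FALSE`, the generator's
#'   trait-level values are analyzed directly (fast; identical
#'   statistical structure).
#' @param bin_width Trill-rate bin width (syllables/s) for the
#'   upper-bound regression.
#' @param fdr_q Target false discovery rate for table-wise correction.
#' @param out_dir Output directory for result CSVs (`NULL` for none).
#' @return Object of class `run_config`.
#' @export
run_config <- function(population = population_config(),
                       measure_audio = TRUE, bin_width = 2,
                       fdr_q = 0.05, out_dir = NULL) {
  stopifnot(inherits(population, "population_config"), bin_width > 0,
            fdr_q > 0, fdr_q < 1)
  structure(list(population = population, measure_audio = measure_audio,
                 bin_width = bin_width, fdr_q = fdr_q, out_dir = out_dir),
            class = "run_config")
}

#' Measure every trill of a bundle
#'
#' With `audio = TRUE`, renders each trill from its stored synthesis
#' seed and runs the full acoustic chain (trill rate, 99%-energy
#' bandwidth, pitch, duration, timing, consistency). With `audio =
#' FALSE`, returns the generator's trait-level values in the same
#' schema.
#'
#' @param bundle A `study_bundle`.
#' @param audio Render and measure audio?
#' @return Data frame, one row per trill: ids, `trill_type`,
#'   `trill_rate`, `bandwidth`, `pitch`, `duration`, `time_in_song`,
#'   `consistency`.
#' @export
measure_bundle <- function(bundle, audio = TRUE) {
  stopifnot(inherits(bundle, "study_bundle"))
  tr <- bundle$trills
  base <- tr[, c("trill_id", "male_id", "year", "trill_type")]
  if (!audio) {
    return(cbind(base, tr[, c("trill_rate", "bandwidth", "pitch",
                              "duration", "time_in_song")],
                 consistency = tr$consistency_true))
  }
  snr <- bundle$config$snr_db
  rows <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    syn <- synth_trill_from_row(tr[i, ], snr_db = snr)
    m <- measure_trill(syn$waveform, syn$annotations,
                       sample_rate = syn$sample_rate)
    consistency <- measure_consistency(
      syn$waveform, syn$annotations, sample_rate = syn$sample_rate,
      trill_low_hz = m$low_hz, trill_high_hz = m$high_hz)
    rows[[i]] <- data.frame(
      trill_rate = m$trill_rate, bandwidth = m$bandwidth, pitch = m$pitch,
      duration = m$duration, time_in_song = tr$time_in_song[i],
      consistency = consistency)
  }
  cbind(base, do.call(rbind, rows))
}

# pitch enters models in kHz so fixed-effect columns share a scale
acoustic_covariates <- c("trill_type", "pitch_khz", "duration",
                         "time_in_song")

add_model_columns <- function(measures) {
  measures$pitch_khz <- measures$pitch / 1000
  measures$trill_type <- factor(measures$trill_type)
  measures$year <- factor(measures$year)
  measures
}

focal_row <- function(res, predictor) {
  hit <- grep(paste0("^", predictor), res$terms$term)
  hit <- setdiff(hit, 1L) # never the intercept
  res$terms[hit[1], , drop = FALSE]
}

battery_row <- function(data, response, predictor, covariates,
                        random, family = "gaussian",
                        table_id, family_id, es_kind = "partial_r") {
  vars <- unique(c(response, predictor, covariates,
                   if (!is.null(random)) random))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
            drop = FALSE]
  n_males <- if (!is.null(random)) length(unique(d[[random]]))
  else length(unique(d$male_id))
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  f <- stats::as.formula(paste(
    response, "~", rhs,
    if (!is.null(random)) paste0(" + (1 | ", random, ")") else ""))
  res <- try(fit_mixed(f, d, family = family), silent = TRUE)
  if (inherits(res, "try-error")) {
    return(data.frame(table = table_id, family = family_id,
                      response = response, predictor = predictor,
                      n_males = n_males, n_obs = nrow(d),
                      estimate = NA_real_, se = NA_real_,
                      statistic = NA_real_, df = NA_real_, p = NA_real_,
                      es_kind = es_kind, es = NA_real_,
                      es_low = NA_real_, es_high = NA_real_,
                      note = as.character(res)))
  }
  row <- focal_row(res, predictor)
  df <- row$df
  if (is.na(df)) df <- max(res$n_obs - nrow(res$terms), 1)
  es <- if (es_kind == "cohens_d") {
    lv <- d[[predictor]]
    if (!is.numeric(lv)) lv <- as.integer(factor(lv)) - 1L
    n1 <- length(unique(d$male_id[lv == unique(lv[lv != min(lv)])[1]]))
    n1 <- max(n1, 1)
    n0 <- max(n_males - n1, 1)
    cohens_d(t = row$statistic, n1 = n0, n2 = n1)
  } else {
    effect_partial_r(row$statistic, df)
  }
  data.frame(table = table_id, family = family_id, response = response,
             predictor = predictor, n_males = n_males, n_obs = res$n_obs,
             estimate = row$estimate, se = row$se,
             statistic = row$statistic, df = df, p = row$p,
             es_kind = es_kind, es = es$value,
             es_low = es$ci_low, es_high = es$ci_high, note = "")
}

#' Run the full study analysis
#'
#' Executes simulate -> measure -> performance -> paternity -> phenotype
#' -> statistical battery on one seeded configuration and returns every
#' results table: locus summaries, trill-quality versus male-quality
#' models, mating-success models (polygyny, within-pair success,
#' extra-pair success), paired extra-pair/within-pair comparisons,
#' reproductive-success models, repeatabilities, and the
#' deviation-consistency decomposition, with table-wise FDR flags.
#'
#' @param config A [run_config()].
#' @param bundle Optionally, a pre-simulated `study_bundle` (otherwise
#'   simulated from `config$population`).
#' @return Object of class `study_result`.
#' @export
run_study <- function(config = run_config(), bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (is.null(bundle)) {
    say("simulate: seed ", config$population$seed)
    bundle <- simulate_population(config$population)
  }
  say("simulate: ", nrow(bundle$trills), " trills, ",
      length(unique(bundle$trills$male_id)), " males, ",
      nrow(bundle$offspring), " offspring in ", nrow(bundle$nests),
      " nests")

  measures <- measure_bundle(bundle, audio = config$measure_audio)
  say("measure: ", nrow(measures), " trills measured (audio = ",
      config$measure_audio, ")")

  limit <- upper_bound_regression(measures$trill_rate, measures$bandwidth,
                                  bin_width = config$bin_width)
  measures$deviation <- vocal_deviation(measures$trill_rate,
                                        measures$bandwidth, limit)
  measures$consistency_t <- consistency_transform(measures$consistency)
  measures <- add_model_columns(measures)
  say(sprintf("performance: limit slope %.2f Hz/(syll/s), intercept %.0f Hz (%d bins)",
              limit$slope, limit$intercept, limit$n_bins))

  calls <- call_paternity(bundle$offspring, bundle$adult_genotypes,
                          bundle$offspring_genotypes)
  success <- male_year_success(calls, bundle$nests, bundle$offspring)
  loci <- locus_summaries(bundle$adult_genotypes)
  ep_rate <- mean(calls$status == "EP")
  say(sprintf("paternity: %d/%d offspring EP (%.1f%%), %d unresolved",
              sum(calls$status == "EP"), nrow(calls), 100 * ep_rate,
              sum(calls$status == "unresolved")))

  quality <- derive_quality(bundle$phenotypes, bundle$playback_events)
  my <- merge(quality, success, by = c("male_id", "year"), all = TRUE)
  my$rs_t <- trait_transform("sqrt_plus1", my$annual_rs)
  my$hl_t <- trait_transform("log", my$hl_ratio)
  my$year <- factor(my$year)
  say("phenotype: ", nrow(my), " male-year records")

  trill_df <- merge(measures, my, by = c("male_id", "year"),
                    suffixes = c("", ".my"))

  rep_dev <- repeatability(measures, "deviation", acoustic_covariates,
                           group = "male_id")
  rep_con <- repeatability(measures, "consistency_t", acoustic_covariates,
                           group = "male_id")
  say(sprintf("repeatability: deviation r = %.3f, consistency r = %.3f",
              rep_dev$r, rep_con$r))
  decomp <- within_between_decompose(
    measures, "deviation", "consistency_t",
    group_keys = c("male_id", "trill_type", "year"),
    fixed = c("year", acoustic_covariates), random = "male_id")

  vif_tab <- vif(cbind(pitch = measures$pitch_khz,
                       duration = measures$duration,
                       time_in_song = measures$time_in_song,
                       trill_type = as.integer(measures$trill_type)))

  trill_covars <- c("year", acoustic_covariates)
  qual_meas <- c("tarsus_mm", "wing_mm", "tail_mm", "condition", "age",
                 "hl_t", "bactericidal", "song_rate", "flights",
                 "time_close")
  health <- c("hl_t", "bactericidal")
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  # quality measures against the two trill measures
  for (q in qual_meas) {
    for (resp in c("deviation", "consistency_t")) {
      add(battery_row(trill_df, resp, q, trill_covars, "male_id",
                      table_id = "quality_vs_trills", family_id = "table2",
                      es_kind = if (q == "age") "cohens_d" else "partial_r"))
    }
  }

  # mating success: polygyny, WP proportion, EP success
  succ_vars <- c(polygynous = "polygyny", wp_proportion = "wp_success",
                 ep_success = "ep_success")
  for (s in names(succ_vars)) {
    tbl <- succ_vars[[s]]
    binary_pred <- s != "wp_proportion"
    for (resp in c("deviation", "consistency_t")) {
      add(battery_row(trill_df, resp, s, trill_covars, "male_id",
                      table_id = tbl, family_id = "mating",
                      es_kind = if (binary_pred) "cohens_d"
                      else "partial_r"))
    }
    for (q in qual_meas) {
      if (q == "age") {
        d2 <- my
        d2$age01 <- as.integer(d2$age == "ASY")
        add(battery_row(d2, "age01", s, "year", "male_id",
                        family = "binomial", table_id = tbl,
                        family_id = "mating", es_kind = "partial_r"))
      } else if (q %in% health) {
        add(battery_row(my, q, s, NULL, NULL, table_id = tbl,
                        family_id = "mating",
                        es_kind = if (binary_pred) "cohens_d"
                        else "partial_r"))
      } else {
        add(battery_row(my, q, s, "year", "male_id", table_id = tbl,
                        family_id = "mating",
                        es_kind = if (binary_pred) "cohens_d"
                        else "partial_r"))
      }
    }
  }

  # paired EP males vs the WP males they cuckolded
  paired <- paired_epwp_tables(calls, trill_df, my, trill_covars)
  for (r in paired$rows) add(r)

  # annual reproductive success
  for (resp in c("deviation", "consistency_t")) {
    add(battery_row(trill_df, resp, "annual_rs", trill_covars, "male_id",
                    table_id = "reproductive_success",
                    family_id = "table7", es_kind = "partial_r"))
  }
  rs_preds <- c(qual_meas[qual_meas != "age"], "polygynous",
                "wp_proportion", "ep_success")
  for (q in rs_preds) {
    add(battery_row(my, "rs_t", q, "year", "male_id",
                    table_id = "reproductive_success", family_id = "table7",
                    es_kind = if (is.logical(my[[q]])) "cohens_d"
                    else "partial_r"))
  }

  results <- do.call(rbind, rows)
  ok <- !is.na(results$p)
  fdr <- bh_fdr(results$p[ok], results$family[ok], q = config$fdr_q)
  results$p_adjusted <- NA_real_
  results$significant <- NA
  results$p_adjusted[ok] <- fdr$p_adjusted
  results$significant[ok] <- fdr$significant
  say("stats: ", sum(ok), " tests fit across ",
      length(unique(results$family)), " FDR families")

  out <- structure(list(
    config = config, bundle = bundle, measures = measures, limit = limit,
    locus_summary = loci, paternity_calls = calls, success = success,
    male_years = my, repeatability = list(deviation = rep_dev,
                                          consistency = rep_con),
    decomposition = decomp, vif = vif_tab, results = results,
    ep_rate = ep_rate, log = log_lines,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_result")
  if (!is.null(config$out_dir)) write_study_result(out, config$out_dir)
  out
}

paired_epwp_tables <- function(calls, trill_df, my, trill_covars) {
  ep <- calls[calls$status == "EP" & !is.na(calls$assigned_sire), ]
  pairs <- unique(data.frame(wp = ep$social_father_id,
                             ep = ep$assigned_sire, year = ep$year))
  rows <- list()
  if (nrow(pairs) == 0) return(list(rows = rows, pairs = pairs))
  pairs$pair_id <- sprintf("P%03d", seq_len(nrow(pairs)))
  long <- rbind(
    data.frame(male_id = pairs$wp, year = pairs$year, role = "WP",
               pair_id = pairs$pair_id),
    data.frame(male_id = pairs$ep, year = pairs$year, role = "EP",
               pair_id = pairs$pair_id))
  ptrills <- merge(long, trill_df[, c("male_id", "year", "deviation",
                                      "consistency_t", "trill_type",
                                      "pitch_khz", "duration",
                                      "time_in_song")],
                   by = c("male_id", "year"))
  covars <- acoustic_covariates
  if (length(unique(ptrills$year)) > 1) covars <- c("year", covars)
  for (resp in c("deviation", "consistency_t")) {
    res <- try(paired_role_model(ptrills, resp, covariates = covars),
               silent = TRUE)
    if (inherits(res, "try-error") || !"roleEP" %in% res$terms$term) next
    row <- res$terms[res$terms$term == "roleEP", ]
    df <- if (is.na(row$df)) res$n_obs - nrow(res$terms) else row$df
    es <- cohens_d(t = row$statistic, n = nrow(pairs), paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      table = "paired_epwp", family = "table6", response = resp,
      predictor = "role", n_males = length(unique(ptrills$male_id)),
      n_obs = res$n_obs, estimate = row$estimate, se = row$se,
      statistic = row$statistic, df = df, p = row$p,
      es_kind = "cohens_d", es = es$value, es_low = es$ci_low,
      es_high = es$ci_high, note = "")
  }
  scalar <- c("tarsus_mm", "wing_mm", "tail_mm", "condition", "hl_ratio",
              "bactericidal", "song_rate", "flights", "time_close")
  for (tr in scalar) {
    wp_v <- my[[tr]][match(paste(pairs$wp, pairs$year),
                           paste(my$male_id, my$year))]
    ep_v <- my[[tr]][match(paste(pairs$ep, pairs$year),
                           paste(my$male_id, my$year))]
    ok <- stats::complete.cases(cbind(wp_v, ep_v))
    if (sum(ok) < 3 || stats::sd(ep_v[ok] - wp_v[ok]) == 0) next
    tt <- paired_trait_test(wp_v, ep_v)
    rows[[length(rows) + 1L]] <- data.frame(
      table = "paired_epwp", family = "table6", response = tr,
      predictor = "role",
      n_males = length(unique(c(pairs$wp, pairs$ep))), n_obs = sum(ok),
      estimate = tt$mean_ep - tt$mean_wp, se = NA_real_,
      statistic = tt$t, df = tt$df, p = tt$p, es_kind = "cohens_d",
      es = tt$d$value, es_low = tt$d$ci_low, es_high = tt$d$ci_high,
      note = "")
  }
  list(rows = rows, pairs = pairs)
}

#' Write all result tables of a study run
#'
#' @param result A `study_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  wr(result$locus_summary, "locus_summary.csv")
  r <- result$results
  wr(r[r$table == "quality_vs_trills", ], "quality_vs_trills.csv")
  wr(r[r$table == "polygyny", ], "polygyny_success.csv")
  wr(r[r$table == "wp_success", ], "wp_success.csv")
  wr(r[r$table == "ep_success", ], "ep_success.csv")
  wr(r[r$table == "paired_epwp", ], "paired_epwp.csv")
  wr(r[r$table == "reproductive_success", ], "reproductive_success.csv")
  wr(result$measures, "trill_measures.csv")
  wr(result$paternity_calls, "paternity_calls.csv")
  wr(result$success, "male_year_success.csv")
  writeLines(result$log, file.path(dir, "run_log.txt"))
  writeLines(make_report(result), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable study report
#'
#' Summarizes the fitted performance limit, repeatabilities, the
#' deviation-consistency decomposition, paternity rates, per-male-year
#' least-squares trait summaries against reproductive success, and all
#' significant (FDR-corrected) effects; on simulated bundles it appends
#' ground-truth recovery diagnostics.
#'
#' @param result A `study_result`.
#' @return Character vector of report lines.
#' @export
make_report <- function(result) {
  r <- result$results
  ok <- !is.na(r$p)
  lines <- c(
    "Trill performance and male success: study report",
    strrep("=", 48),
    sprintf("Trills analyzed: %d from %d males", nrow(result$measures),
            length(unique(result$measures$male_id))),
    sprintf("Performance limit: bandwidth = %.2f * rate + %.0f Hz (%d bins)",
            result$limit$slope, result$limit$intercept,
            result$limit$n_bins),
    sprintf("Adjusted repeatability: deviation %.1f%% (p = %.2g), consistency %.1f%% (p = %.2g)",
            100 * result$repeatability$deviation$r,
            result$repeatability$deviation$p,
            100 * result$repeatability$consistency$r,
            result$repeatability$consistency$p),
    sprintf("Deviation ~ consistency: between-male %.2f +/- %.2f, within-male %.2f +/- %.2f",
            result$decomposition$beta_between$estimate,
            result$decomposition$beta_between$se,
            result$decomposition$beta_within$estimate,
            result$decomposition$beta_within$se),
    sprintf("Extra-pair offspring: %.1f%% of %d typed",
            100 * result$ep_rate, nrow(result$paternity_calls)),
    sprintf("Acoustic covariate VIFs all < 5: %s",
            all(result$vif < 5)),
    "")
  if (sum(ok) == 0) {
    lines <- c(lines, "No models were fit.")
    return(lines)
  }
  sig <- r[ok & r$significant, ]
  lines <- c(lines, sprintf("Models fit: %d; FDR-significant: %d",
                            sum(ok), nrow(sig)))
  if (nrow(sig) == 0) {
    lines <- c(lines,
               "No significant song-to-success associations after FDR.")
  } else {
    lines <- c(lines, "Significant after table-wise FDR:",
               sprintf("  [%s] %s ~ %s: est %.3g (p = %.2g, adj %.2g, %s = %.3g)",
                       sig$table, sig$response, sig$predictor,
                       sig$estimate, sig$p, sig$p_adjusted, sig$es_kind,
                       sig$es))
  }
  gt <- result$bundle$ground_truth
  lines <- c(lines, "",
             "Ground-truth recovery (simulated bundle):",
             sprintf("  limit slope %.2f (true %.2f), intercept %.0f (true %.0f)",
                     result$limit$slope, gt$limit["slope"],
                     result$limit$intercept, gt$limit["intercept"]),
             sprintf("  repeatability deviation %.3f (true %.3f), consistency %.3f (true %.3f)",
                     result$repeatability$deviation$r,
                     gt$repeatability["deviation"],
                     result$repeatability$consistency$r,
                     gt$repeatability["consistency"]),
             sprintf("  EP rate %.3f (configured %.3f)", result$ep_rate,
                     result$bundle$config$ep_rate))
  lines
}

#' Least-squares male-year trait means
#'
#' Per-male-year adjusted means of a trill measure, correcting for trill
#' type, pitch, trill duration, and time in song (used for
#' reproductive-success scatter summaries).
#'
#' @param measures Measured trill table (with `deviation`,
#'   `consistency_t`).
#' @param response `"deviation"` or `"consistency_t"`.
#' @return Data frame `male_id`, `year`, `lsmean`.
#' @export
male_year_lsmeans <- function(measures, response = "deviation") {
  f <- stats::as.formula(paste(
    response, "~ 0 + interaction(male_id, year, drop = TRUE) +",
    paste(acoustic_covariates, collapse = " + ")))
  d <- measures
  if (!"pitch_khz" %in% names(d)) d <- add_model_columns(d)
  mm <- stats::lm(f, data = d)
  co <- stats::coef(mm)
  keep <- grep("^interaction", names(co))
  lev <- sub("^interaction\\(male_id, year, drop = TRUE\\)", "",
             names(co)[keep])
  parts <- strsplit(lev, ".", fixed = TRUE)
  covs <- colMeans(stats::model.matrix(mm)[, -keep, drop = FALSE])
  base <- sum(covs * co[-keep], na.rm = TRUE)
  data.frame(male_id = vapply(parts, `[`, character(1), 1),
             year = vapply(parts, `[`, character(1), 2),
             lsmean = unname(co[keep]) + base)
}
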