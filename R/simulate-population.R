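#' Default microsatellite locus panel
#'
#' Seven loci with allele counts, heterozygosities, and null-allele
#' frequencies chosen to resemble a typical wren paternity panel
#' (12--28 alleles per locus, expected heterozygosity 0.52--0.90, null
#' alleles up to about 6%). Allele frequencies follow a truncated
#' geometric series, which reproduces the skewed frequency spectra of
#' real microsatellites.
#'
#' @param n_loci Number of loci (recycled from the 7-locus template).
#' @return List with per-locus `allele_freqs` (lists of probability
#'   vectors summing to 1) and `null_allele_freq`.
#' @export
default_locus_panel <- function(n_loci = 7) {
  n_alleles <- rep_len(c(12L, 10L, 18L, 17L, 28L, 7L, 17L), n_loci)
  null_freq <- rep_len(c(0, 0.059, 0.054, 0, 0, 0.063, 0.001), n_loci)
  # decay tuned per locus so common panels span low to high diversity
  decay <- rep_len(c(0.55, 0.6, 0.85, 0.88, 0.93, 0.62, 0.88), n_loci)
  freqs <- lapply(seq_len(n_loci), function(k) {
    p <- decay[k]^(seq_len(n_alleles[k]) - 1)
    p / sum(p)
  })
  list(allele_freqs = freqs, null_allele_freq = null_freq)
}

#' Configuration for the synthetic study population
#'
#' Bundles every knob of the generator. Defaults emulate the field study
#' the package is designed around: about 60 males recorded over two
#' seasons with 20--100 trills per male-year, a triangular trill-rate by
#' bandwidth cloud under the linear performance limit `bandwidth =
#' -168.5 * rate + 6019` Hz, male-identity repeatability of 0.176 for
#' vocal deviation and 0.295 for (transformed) trill consistency, a
#' 7-locus microsatellite panel, 13.5% extra-pair offspring, and no true
#' song-to-success effects (the null world; set `effect_sizes` to inject
#' effects).
#'
#' @param n_males Number of distinct males.
#' @param years Study years (trills and success measured per male-year).
#' @param prop_both_years Fraction of males recorded in both years.
#' @param trills_per_male Length-2 range of trills per male-year.
#' @param n_types Number of shared syllable types.
#' @param a_true,b_true True performance-limit slope (Hz per syll/s) and
#'   intercept (Hz).
#' @param rate_range Trill-rate range, syllables/s.
#' @param dev_mean Mean vocal deviation (orthogonal-distance units).
#' @param cons_mean Mean trill consistency on the `-log(1 - C)` scale.
#' @param var_between,var_within Named length-2 vectors
#'   (`deviation`, `consistency`) of between-male and within-male trait
#'   variances; consistency variances are on the transformed scale.
#' @param effect_sizes Named list of true male-level effects of
#'   standardized song ability on success, each a named vector with
#'   elements `polygyny`, `wp`, `ep` (log-odds per SD of male ability;
#'   0 = null). Names of the list: `deviation`, `consistency`.
#' @param n_loci Number of microsatellite loci.
#' @param allele_freqs,null_allele_freq Per-locus allele frequency
#'   vectors (each must sum to 1) and null-allele frequencies.
#' @param mutation_rate Per-transmission single-step mutation rate.
#' @param ep_rate Proportion of offspring sired by an extra-pair male.
#' @param polygyny_rate Fraction of male-years with a simultaneous
#'   second nest.
#' @param offspring_per_nest Length-2 range of chicks per nest.
#' @param snr_db Background-noise SNR used when rendering audio.
#' @param deviation_distribution Shape of the deviation cloud under the
#'   limit; `"gaussian"` (truncated) is the implemented choice.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_males = 60,
                              years = c(2009, 2010),
                              prop_both_years = 0.25,
                              trills_per_male = c(20, 100),
                              n_types = 8,
                              a_true = -168.5,
                              b_true = 6019,
                              rate_range = c(2.5, 16),
                              dev_mean = 8.2,
                              cons_mean = 1.7,
                              var_between = c(deviation = 1.1,
                                              consistency = 0.045),
                              var_within = c(deviation = 5.15,
                                             consistency = 0.108),
                              effect_sizes = list(
                                deviation = c(polygyny = 0, wp = 0, ep = 0),
                                consistency = c(polygyny = 0, wp = 0, ep = 0)),
                              n_loci = 7,
                              allele_freqs = NULL,
                              null_allele_freq = NULL,
                              mutation_rate = 0.002,
                              ep_rate = 0.135,
                              polygyny_rate = 0.2,
                              offspring_per_nest = c(3, 7),
                              snr_db = 30,
                              deviation_distribution = "gaussian",
                              seed = 1L) {
  panel <- default_locus_panel(n_loci)
  if (is.null(allele_freqs)) allele_freqs <- panel$allele_freqs
  if (is.null(null_allele_freq)) null_allele_freq <- panel$null_allele_freq
  for (k in seq_along(allele_freqs)) {
    if (abs(sum(allele_freqs[[k]]) - 1) > 1e-8)
      stop("allele frequencies at locus ", k, " do not sum to 1")
  }
  rates <- c(ep_rate, polygyny_rate, mutation_rate, null_allele_freq,
             prop_both_years)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(c(var_between, var_within) < 0)) stop("variances must be >= 0")
  stopifnot(n_males >= 2, length(trills_per_male) == 2,
            trills_per_male[1] >= 1, n_loci == length(allele_freqs),
            n_loci == length(null_allele_freq))
  structure(as.list(environment())[c(
    "n_males", "years", "prop_both_years", "trills_per_male", "n_types",
    "a_true", "b_true", "rate_range", "dev_mean", "cons_mean",
    "var_between", "var_within", "effect_sizes", "n_loci", "allele_freqs",
    "null_allele_freq", "mutation_rate", "ep_rate", "polygyny_rate",
    "offspring_per_nest", "snr_db", "deviation_distribution", "seed")],
    class = "population_config")
}

draw_genotype <- function(freqs, null_freq) {
  # allele 0 encodes the unamplified null allele
  k <- length(freqs)
  p <- c(freqs * (1 - null_freq), null_freq)
  sample(c(seq_len(k), 0L), 2, replace = TRUE, prob = p)
}

observe_genotype <- function(true_alleles) {
  # a null/visible heterozygote types as an apparent homozygote; a
  # null/null homozygote fails to amplify (missing locus)
  vis <- true_alleles[true_alleles != 0L]
  if (length(vis) == 2) sort(vis)
  else if (length(vis) == 1) c(vis, vis)
  else c(NA_integer_, NA_integer_)
}

transmit_allele <- function(true_alleles, n_alleles, mutation_rate) {
  a <- sample(true_alleles, 1)
  if (a != 0L && stats::runif(1) < mutation_rate) {
    step <- if (a == 1L) 1L else if (a == n_alleles) -1L else
      sample(c(-1L, 1L), 1)
    a <- a + step
  }
  a
}

#' Simulate a complete study bundle
#'
#' Generates, from a single seed, every input the analysis pipeline
#' consumes: a per-trill ground-truth table (rates, bandwidths, pitches,
#' deviation, consistency, jitter), per-male-year phenotypes, playback
#' event logs, nest records, and observed microsatellite genotypes for
#' adults and offspring, plus a ground-truth block (true sires, true
#' variance components, true limit, true male-year success) for
#' recovery checks. Audio is rendered lazily: [synth_trill_from_row()]
#' reproduces any trill's waveform bit-identically from its row.
#'
#' @param config A [population_config()].
#' @return Object of class `study_bundle`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  cf <- config
  male_ids <- sprintf("M%03d", seq_len(cf$n_males))
  n_both <- round(cf$prop_both_years * cf$n_males)
  both <- male_ids[seq_len(n_both)]
  rest <- setdiff(male_ids, both)
  year_of <- sample(rep_len(cf$years, length(rest)))
  male_years <- rbind(
    if (length(cf$years) > 1 && n_both > 0)
      expand.grid(male_id = both, year = cf$years,
                  stringsAsFactors = FALSE)
    else NULL,
    data.frame(male_id = rest, year = year_of[seq_along(rest)]))
  male_years <- male_years[order(male_years$male_id, male_years$year), ]
  rownames(male_years) <- NULL

  # latent male song ability (constant across years)
  u_dev <- stats::rnorm(cf$n_males, 0, sqrt(cf$var_between["deviation"]))
  u_cons <- stats::rnorm(cf$n_males, 0, sqrt(cf$var_between["consistency"]))
  names(u_dev) <- names(u_cons) <- male_ids
  z_dev <- (u_dev - mean(u_dev)) / max(stats::sd(u_dev), 1e-9)
  z_cons <- (u_cons - mean(u_cons)) / max(stats::sd(u_cons), 1e-9)

  type_dev <- stats::rnorm(cf$n_types, 0, 0.8)
  type_cons <- stats::rnorm(cf$n_types, 0, 0.12)
  type_pitch <- stats::runif(cf$n_types, 3800, 5800)

  ages <- sample(c("SY", "ASY"), cf$n_males, replace = TRUE,
                 prob = c(0.3, 0.7))
  names(ages) <- male_ids

  trills <- vector("list", nrow(male_years))
  for (i in seq_len(nrow(male_years))) {
    m <- male_years$male_id[i]
    yr <- male_years$year[i]
    n_tr <- sample(seq(cf$trills_per_male[1], cf$trills_per_male[2]), 1)
    repertoire <- sample(seq_len(cf$n_types),
                         min(cf$n_types, sample(4:8, 1)))
    typ <- sample(repertoire, n_tr, replace = TRUE)
    rate <- stats::runif(n_tr, cf$rate_range[1], cf$rate_range[2])
    n_syl <- pmax(3L, pmin(12L, stats::rpois(n_tr, 7)))
    dur <- n_syl / rate
    tis <- stats::runif(n_tr, 0, 3.5)
    pitch <- pmax(3000, stats::rnorm(n_tr, type_pitch[typ], 250))
    z_p <- (pitch - 4800) / 1000
    z_d <- (dur - 1) / 0.5
    z_t <- (tis - 1.75) / 1
    dev <- cf$dev_mean + u_dev[m] + type_dev[typ] -
      0.6 * z_p + 0.3 * z_d - 0.25 * z_t +
      stats::rnorm(n_tr, 0, sqrt(cf$var_within["deviation"]))
    dev <- pmax(dev, 0.3) # the cloud stays under the limit
    cons_t <- cf$cons_mean + u_cons[m] + type_cons[typ] +
      0.08 * z_p - 0.05 * z_d + 0.04 * z_t +
      stats::rnorm(n_tr, 0, sqrt(cf$var_within["consistency"]))
    cons_t <- pmax(cons_t, 0.05)
    bw <- cf$a_true * rate + cf$b_true - dev * sqrt(1 + cf$a_true^2)
    keep_bw <- pmax(bw, 300)
    dev <- (cf$a_true * rate + cf$b_true - keep_bw) / sqrt(1 + cf$a_true^2)
    bw <- keep_bw
    # sweep span is wider than the measured band; keep the sweep above 0 Hz
    pitch <- pmax(pitch, 1.2 * bw + 300)
    consistency <- 1 - exp(-cons_t)
    trills[[i]] <- data.frame(
      trill_id = sprintf("%s_%d_T%03d", m, yr, seq_len(n_tr)),
      male_id = m, year = yr, trill_type = typ,
      trill_rate = rate, bandwidth = bw, pitch = pitch,
      n_syllables = n_syl, duration = dur, time_in_song = tis,
      deviation_true = dev, consistency_true = consistency,
      jitter_sd = pmin(pmax(-log(pmax(consistency, 0.05)) / 5.5, 0), 0.15),
      synth_seed = NA_integer_)
  }
  trills <- do.call(rbind, trills)
  trills$synth_seed <- (cf$seed %% 20000L) * 100000L + seq_len(nrow(trills))

  phen <- simulate_phenotypes(male_years, ages, cf)
  pb <- simulate_playback(male_years, cf)
  pat <- simulate_paternity(male_years, male_ids, z_dev, z_cons, cf)

  truth <- list(
    seed = cf$seed,
    limit = c(slope = cf$a_true, intercept = cf$b_true),
    repeatability = c(
      deviation = unname(cf$var_between["deviation"] /
                           (cf$var_between["deviation"] +
                              cf$var_within["deviation"])),
      consistency = unname(cf$var_between["consistency"] /
                             (cf$var_between["consistency"] +
                                cf$var_within["consistency"]))),
    male_ability = data.frame(male_id = male_ids, u_deviation = u_dev,
                              u_consistency = u_cons, row.names = NULL),
    effect_sizes = cf$effect_sizes,
    true_sires = pat$offspring[, c("offspring_id", "true_sire", "ep")],
    male_year_success = pat$success,
    condition_residual = phen$condition_truth)

  structure(list(config = cf, trills = trills, phenotypes = phen$records,
                 playback_events = pb, nests = pat$nests,
                 offspring = pat$offspring,
                 adult_genotypes = pat$adult_genotypes,
                 offspring_genotypes = pat$offspring_genotypes,
                 ground_truth = truth),
            class = "study_bundle")
}

simulate_phenotypes <- function(male_years, ages, cf) {
  n <- nrow(male_years)
  age <- ages[male_years$male_id]
  tarsus <- stats::rnorm(n, 16.8, 0.45)
  wing <- stats::rnorm(n, ifelse(age == "ASY", 51.2, 49.7), 0.9)
  tail <- stats::rnorm(n, ifelse(age == "ASY", 43.6, 43.0), 1.5)
  date <- round(stats::runif(n, 115, 210))
  hour <- round(stats::runif(n, 5.5, 19), 2)
  cond_e <- stats::rnorm(n, 0, 0.35)
  weight <- -0.5 + 0.62 * tarsus + 0.004 * (date - 160) +
    0.012 * (hour - 12) + cond_e
  # age is only knowable for males banded on-site in an earlier season
  age_known <- stats::runif(n) < 0.65
  recs <- data.frame(
    male_id = male_years$male_id, year = male_years$year,
    tarsus_mm = round(tarsus, 1), wing_mm = round(wing, 1),
    tail_mm = round(tail, 1), weight_g = round(weight, 2),
    capture_doy = date, capture_hour = hour,
    age = ifelse(age_known, age, NA_character_),
    hl_ratio = round(stats::rlnorm(n, log(0.7), 0.5), 3),
    bactericidal = round(stats::rbeta(n, 8, 1.5), 3))
  list(records = recs,
       condition_truth = data.frame(male_id = recs$male_id,
                                    year = recs$year,
                                    residual = cond_e))
}

simulate_playback <- function(male_years, cf) {
  ev <- vector("list", nrow(male_years))
  for (i in seq_len(nrow(male_years))) {
    trial <- sprintf("%s_%d_PB", male_years$male_id[i], male_years$year[i])
    trial_len <- 360
    bouts <- data.frame(t_start = c(30, 150, 270),
                        t_end = c(90, 210, 330))
    songs <- sort(stats::runif(stats::rpois(1, 6 * trial_len / 60),
                               0, trial_len))
    rows <- list(data.frame(trial_id = trial, male_id = male_years$male_id[i],
                            year = male_years$year[i], event_type = "trial",
                            t_start = 0, t_end = trial_len))
    rows$bout <- data.frame(trial_id = trial,
                            male_id = male_years$male_id[i],
                            year = male_years$year[i], event_type = "bout",
                            t_start = bouts$t_start, t_end = bouts$t_end)
    if (length(songs) > 0)
      rows$song <- data.frame(trial_id = trial,
                              male_id = male_years$male_id[i],
                              year = male_years$year[i],
                              event_type = "song",
                              t_start = songs, t_end = songs)
    # within-5m position intervals inside bouts
    close_frac <- stats::rbeta(1, 2, 2.5)
    pos <- lapply(seq_len(nrow(bouts)), function(b) {
      len <- (bouts$t_end[b] - bouts$t_start[b]) * close_frac
      if (len < 0.5) return(NULL)
      start <- stats::runif(1, bouts$t_start[b], bouts$t_end[b] - len)
      data.frame(trial_id = trial, male_id = male_years$male_id[i],
                 year = male_years$year[i], event_type = "within_5m",
                 t_start = start, t_end = start + len)
    })
    rows$pos <- do.call(rbind, pos)
    n_fl <- stats::rpois(1, 1.6 * nrow(bouts))
    if (n_fl > 0) {
      b <- sample(seq_len(nrow(bouts)), n_fl, replace = TRUE)
      t_fl <- stats::runif(n_fl, bouts$t_start[b], bouts$t_end[b])
      rows$fl <- data.frame(trial_id = trial,
                            male_id = male_years$male_id[i],
                            year = male_years$year[i],
                            event_type = "crossing",
                            t_start = t_fl, t_end = t_fl)
    }
    ev[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

simulate_paternity <- function(male_years, male_ids, z_dev, z_cons, cf) {
  n_loci <- cf$n_loci
  n_alleles <- vapply(cf$allele_freqs, length, integer(1))
  # adults: all males plus one female per nest (generated below)
  male_true <- lapply(male_ids, function(m)
    lapply(seq_len(n_loci), function(k)
      draw_genotype(cf$allele_freqs[[k]], cf$null_allele_freq[k])))
  names(male_true) <- male_ids

  es <- cf$effect_sizes
  lin <- function(outcome)
    es$deviation[outcome] * z_dev + es$consistency[outcome] * z_cons

  nests <- list()
  offspring <- list()
  female_true <- list()
  nest_id <- 0L
  for (i in seq_len(nrow(male_years))) {
    m <- male_years$male_id[i]
    yr <- male_years$year[i]
    p_poly <- stats::plogis(stats::qlogis(cf$polygyny_rate) +
                              lin("polygyny")[m])
    n_nests <- 1L + as.integer(stats::runif(1) < p_poly)
    prim_start <- round(stats::runif(1, 120, 170))
    for (j in seq_len(n_nests)) {
      nest_id <- nest_id + 1L
      nid <- sprintf("N%04d", nest_id)
      fem <- sprintf("F%04d", nest_id)
      female_true[[fem]] <- lapply(seq_len(n_loci), function(k)
        draw_genotype(cf$allele_freqs[[k]], cf$null_allele_freq[k]))
      # secondary nests start while the primary is still active
      start <- if (j == 1) prim_start else prim_start +
        round(stats::runif(1, 5, 20))
      nests[[nid]] <- data.frame(
        nest_id = nid, male_id = m, female_id = fem, year = yr,
        start_doy = start, end_doy = start + 30,
        is_secondary = j == 2L, excluded = FALSE)
      n_off <- sample(seq(cf$offspring_per_nest[1],
                          cf$offspring_per_nest[2]), 1)
      p_ep <- stats::plogis(stats::qlogis(cf$ep_rate) - lin("wp")[m])
      others <- setdiff(male_years$male_id[male_years$year == yr], m)
      w_ep <- exp(lin("ep")[others])
      for (o in seq_len(n_off)) {
        is_ep <- length(others) > 0 && stats::runif(1) < p_ep
        sire <- if (is_ep) sample(others, 1, prob = w_ep) else m
        fledged <- stats::runif(1) < 0.92
        offspring[[length(offspring) + 1L]] <- data.frame(
          offspring_id = sprintf("%s_O%d", nid, o), nest_id = nid,
          year = yr, mother_id = fem, social_father_id = m,
          true_sire = sire, ep = is_ep, fledged = fledged)
      }
    }
  }
  nests <- do.call(rbind, nests)
  offspring <- do.call(rbind, offspring)
  rownames(nests) <- rownames(offspring) <- NULL

  off_true <- vector("list", nrow(offspring))
  for (o in seq_len(nrow(offspring))) {
    mom <- female_true[[offspring$mother_id[o]]]
    dad <- male_true[[offspring$true_sire[o]]]
    off_true[[o]] <- lapply(seq_len(n_loci), function(k) c(
      transmit_allele(mom[[k]], n_alleles[k], cf$mutation_rate),
      transmit_allele(dad[[k]], n_alleles[k], cf$mutation_rate)))
  }

  geno_table <- function(ids, true_list, sex, years_of) {
    rows <- lapply(seq_along(ids), function(i) {
      obs <- lapply(true_list[[i]], observe_genotype)
      vals <- unlist(obs)
      df <- as.data.frame(as.list(vals))
      names(df) <- as.vector(t(outer(seq_len(n_loci), 1:2,
                                     function(k, a)
                                       sprintf("locus%d_a%d", k, a))))
      cbind(data.frame(id = ids[i], sex = sex,
                       years = years_of[i]), df)
    })
    do.call(rbind, rows)
  }
  male_years_str <- vapply(male_ids, function(m)
    paste(sort(unique(male_years$year[male_years$male_id == m])),
          collapse = ";"), character(1))
  fem_ids <- names(female_true)
  fem_years <- vapply(fem_ids, function(f)
    as.character(nests$year[nests$female_id == f][1]), character(1))
  adult_geno <- rbind(
    geno_table(male_ids, male_true, "M", male_years_str),
    geno_table(fem_ids, female_true, "F", fem_years))
  off_geno <- geno_table(offspring$offspring_id, off_true, "U",
                         as.character(offspring$year))

  # ground-truth male-year success roll-up
  succ <- lapply(seq_len(nrow(male_years)), function(i) {
    m <- male_years$male_id[i]
    yr <- male_years$year[i]
    soc <- offspring[offspring$social_father_id == m &
                       offspring$year == yr, ]
    ep_off <- offspring[offspring$true_sire == m &
                          offspring$social_father_id != m &
                          offspring$year == yr, ]
    data.frame(
      male_id = m, year = yr,
      wp_proportion = if (nrow(soc)) mean(!soc$ep) else NA_real_,
      ep_success = nrow(ep_off) > 0,
      polygynous = sum(nests$male_id == m & nests$year == yr) > 1,
      annual_rs = sum(!soc$ep & soc$fledged) + sum(ep_off$fledged))
  })
  succ <- do.call(rbind, succ)

  list(nests = nests, offspring = offspring, adult_genotypes = adult_geno,
       offspring_genotypes = off_geno, success = succ)
}

#' Render one trill's audio from its bundle row
#'
#' Deterministically re-synthesizes the waveform and annotations for a
#' single row of `bundle$trills` using the row's stored synthesis seed,
#' so audio needs never be stored: any trill can be regenerated
#' bit-identically on demand.
#'
#' @param row One row of a `study_bundle`'s `trills` table.
#' @param sample_rate Sampling rate, Hz.
#' @param snr_db Background noise SNR (dB); defaults to the bundle's.
#' @return As [synth_trill()].
#' @export
synth_trill_from_row <- function(row, sample_rate = 48000, snr_db = 30) {
  gt <- trill_ground_truth(
    male_id = row$male_id, year = row$year, trill_id = row$trill_id,
    trill_type = row$trill_type, true_rate = row$trill_rate,
    true_bandwidth = row$bandwidth, true_pitch = row$pitch,
    jitter_sd = row$jitter_sd, n_syllables = row$n_syllables,
    time_in_song = row$time_in_song)
  set.seed(row$synth_seed %% .Machine$integer.max)
  synth_trill(gt, sample_rate, snr_db = snr_db)
}

#' Write a study bundle to disk as plain-text files
#'
#' Writes the annotation, phenotype, playback, nest and genotype tables
#' as CSV, ground truth as JSON, and (optionally) per-trill WAV files
#' with tab-delimited selection tables.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @param audio Render WAV files for every trill (slow; default FALSE).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, audio = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  wr(bundle$trills, "trills.csv")
  wr(bundle$phenotypes, "phenotypes.csv")
  wr(bundle$playback_events, "playback_events.csv")
  wr(bundle$nests, "nests.csv")
  wr(bundle$offspring, "offspring.csv")
  wr(bundle$adult_genotypes, "adult_genotypes.csv")
  wr(bundle$offspring_genotypes, "offspring_genotypes.csv")
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (audio) {
    adir <- file.path(dir, "audio")
    dir.create(adir, showWarnings = FALSE)
    ann_all <- vector("list", nrow(bundle$trills))
    for (i in seq_len(nrow(bundle$trills))) {
      row <- bundle$trills[i, ]
      tr <- synth_trill_from_row(row, snr_db = bundle$config$snr_db)
      f <- file.path(adir, paste0(row$trill_id, ".wav"))
      write_wav(tr$waveform, tr$sample_rate, f)
      ann <- tr$annotations
      ann$file <- basename(f)
      ann$song_id <- row$trill_id
      ann_all[[i]] <- ann
    }
    tab <- do.call(rbind, ann_all)
    write_selection_table(
      tab[, c("file", "song_id", "trill_id", "syllable_idx",
              "begin_s", "end_s", "low_hz", "high_hz", "trill_type")],
      file.path(dir, "selections.txt"))
  }
  invisible(dir)
}
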