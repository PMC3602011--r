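test_that("synth_syllable is deterministic and respects Nyquist", {
  sp <- syllable_spec(2000, 4000, 0.05)
  set.seed(1)
  a <- synth_syllable(sp, 48000, jitter_sd = 0)
  b <- synth_syllable(sp, 48000, jitter_sd = 0)
  expect_identical(a, b)
  set.seed(7)
  j1 <- synth_syllable(sp, 48000, jitter_sd = 0.05)
  set.seed(7)
  j2 <- synth_syllable(sp, 48000, jitter_sd = 0.05)
  expect_identical(j1, j2)
  expect_error(synth_syllable(syllable_spec(2000, 30000, 0.05), 48000),
               "Nyquist")
})

test_that("a constant-frequency syllable peaks at its tone frequency", {
  sp <- syllable_spec(2000, 2000, 0.1)
  w <- synth_syllable(sp, 48000)
  spec <- Mod(stats::fft(c(w, numeric(8192 - length(w)))))[1:4096]
  f_peak <- (which.max(spec) - 1) * 48000 / 8192
  expect_lt(abs(f_peak - 2000), 48000 / 8192 + 1e-9)
})

test_that("synth_trill realizes the requested trill rate and timing", {
  gt <- trill_ground_truth("m", 2009, "t", 1, true_rate = 10,
                           true_bandwidth = 2000, true_pitch = 5000,
                           jitter_sd = 0, n_syllables = 10)
  syn <- synth_trill(gt, 48000, snr_db = Inf)
  ann <- syn$annotations
  span <- max(ann$end_s) - min(ann$begin_s)
  expect_lt(abs(span - 1.0), 0.01)
  expect_equal(nrow(ann), 10)
  # jitter-free syllables are identical after alignment
  lens <- round((ann$end_s - ann$begin_s) * 48000)
  syls <- lapply(seq_len(nrow(ann)), function(i) {
    i0 <- round(ann$begin_s[i] * 48000) + 1
    syn$waveform[i0:(i0 + lens[i] - 1)]
  })
  for (i in 2:10) expect_identical(syls[[i]], syls[[1]])
  # infeasible timing: syllable longer than its period
  bad <- trill_ground_truth("m", 2009, "t", 1, true_rate = 10,
                            true_bandwidth = 2000, true_pitch = 5000,
                            n_syllables = 10)
  expect_error(synth_trill(bad, 48000, duty = 1), "duty")
})

test_that("population config validates rates and allele frequencies", {
  expect_error(population_config(ep_rate = 1.5), "rates")
  expect_error(population_config(
    allele_freqs = list(c(0.5, 0.4)),
    null_allele_freq = 0, n_loci = 1), "sum to 1")
  expect_error(population_config(var_within = c(deviation = -1,
                                                consistency = 1)),
               "variances")
})

test_that("same seed gives a bit-identical bundle, files included", {
  cfg <- population_config(n_males = 8, trills_per_male = c(4, 6),
                           seed = 11)
  b1 <- simulate_population(cfg)
  b2 <- simulate_population(cfg)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("simulated clouds honor the performance limit for every trill", {
  b <- small_bundle()
  cf <- b$config
  slack <- cf$a_true * b$trills$trill_rate + cf$b_true - b$trills$bandwidth
  expect_true(all(slack >= -1e-6))
})

test_that("ep_rate = 0 yields zero extra-pair offspring in ground truth", {
  b <- simulate_population(population_config(
    n_males = 8, trills_per_male = c(4, 6), ep_rate = 0, seed = 5))
  expect_equal(sum(b$ground_truth$true_sires$ep), 0)
  expect_true(all(b$offspring$true_sire == b$offspring$social_father_id))
})

test_that("offspring alleles are traceable to their true parents", {
  b <- simulate_population(population_config(
    n_males = 10, trills_per_male = c(4, 6),
    null_allele_freq = rep(0, 7), mutation_rate = 0, seed = 21))
  adults <- b$adult_genotypes
  offs <- b$offspring_genotypes
  for (i in seq_len(nrow(b$offspring))) {
    o <- b$offspring[i, ]
    kid <- offs[offs$id == o$offspring_id, ]
    mom <- adults[adults$id == o$mother_id, ]
    dad <- adults[adults$id == o$true_sire, ]
    for (k in 1:7) {
      ka <- c(kid[[sprintf("locus%d_a1", k)]], kid[[sprintf("locus%d_a2", k)]])
      ma <- c(mom[[sprintf("locus%d_a1", k)]], mom[[sprintf("locus%d_a2", k)]])
      pa <- c(dad[[sprintf("locus%d_a1", k)]], dad[[sprintf("locus%d_a2", k)]])
      # one allele from each parent, in either order
      ok <- (ka[1] %in% ma && ka[2] %in% pa) ||
        (ka[2] %in% ma && ka[1] %in% pa)
      expect_true(ok, label = sprintf("offspring %s locus %d", o$offspring_id, k))
    }
  }
})

test_that("bundle trait structure matches the configured variance ratio", {
  # paternity-free check: recover repeatability from the latent trait table
  rs <- vapply(1:3, function(s) {
    b <- simulate_population(population_config(
      n_males = 60, trills_per_male = c(40, 40),
      var_between = c(deviation = 1, consistency = 0.045),
      var_within = c(deviation = 3, consistency = 0.108), seed = 30 + s))
    m <- measure_bundle(b, audio = FALSE)
    m$deviation <- b$trills$deviation_true
    m$pitch_khz <- m$pitch / 1000
    m$trill_type <- factor(m$trill_type)
    repeatability(m, "deviation",
                  c("trill_type", "pitch_khz", "duration",
                    "time_in_song"), group = "male_id")$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.25), 0.05)
})
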