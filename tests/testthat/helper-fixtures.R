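# shared small fixtures, built once per test session

# a toy genotype row builder: g(1,2, 3,3, ...) -> one-row data frame
toy_geno <- function(..., id = "X", sex = "M", years = "2009") {
  a <- c(...)
  stopifnot(length(a) %% 2 == 0)
  df <- as.data.frame(as.list(as.integer(a)))
  names(df) <- as.vector(t(outer(seq_len(length(a) / 2), 1:2,
                                 function(k, i) sprintf("locus%d_a%d", k, i))))
  cbind(data.frame(id = id, sex = sex, years = years), df)
}

# locus lists directly (alleles as length-2 vectors; NULL = untyped)
loci <- function(...) lapply(list(...), function(g) if (is.null(g)) NULL else as.integer(g))

# one small clean bundle reused across tests
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_population(population_config(
        n_males = 16, trills_per_male = c(6, 10), seed = 401))
    cache
  }
})

# synthesize and fully measure one trill
measured_synth_trill <- function(rate, bandwidth, pitch, jitter = 0,
                                 n_syl = 8, snr_db = 30, seed = 1) {
  set.seed(seed)
  gt <- trill_ground_truth("m1", 2009, "t1", 1, true_rate = rate,
                           true_bandwidth = bandwidth, true_pitch = pitch,
                           jitter_sd = jitter, n_syllables = n_syl)
  syn <- synth_trill(gt, 48000, snr_db = snr_db)
  list(syn = syn,
       measures = measure_trill(syn$waveform, syn$annotations, 48000))
}
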