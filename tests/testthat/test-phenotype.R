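test_that("body condition standardizes residual mass", {
  set.seed(5)
  n <- 1000
  rec <- data.frame(tarsus_mm = rnorm(n, 16.8, 0.5),
                    capture_doy = sample(115:210, n, TRUE),
                    capture_hour = runif(n, 6, 19))
  e <- rnorm(n, 0, 0.3)
  rec$weight_g <- 1 + 0.6 * rec$tarsus_mm + 0.004 * rec$capture_doy +
    0.01 * rec$capture_hour + e
  cond <- body_condition(rec)
  expect_equal(mean(cond), 0, tolerance = 1e-10)
  expect_equal(sd(cond), 1, tolerance = 1e-10)
  expect_gt(cor(cond, e, method = "spearman"), 0.99)
  # an exactly linear weight leaves zero condition for everyone
  rec0 <- rec
  rec0$weight_g <- 1 + 0.6 * rec0$tarsus_mm + 0.004 * rec0$capture_doy
  expect_true(all(body_condition(rec0) == 0))
  rec_bad <- rec
  rec_bad$tarsus_mm <- 17
  expect_error(body_condition(rec_bad), "degenerate")
  expect_error(body_condition(rec[1:5, ]), "at least 10")
})

test_that("aggression metrics follow trial and bout windows", {
  ev <- rbind(
    data.frame(event_type = "trial", t_start = 0, t_end = 360),
    data.frame(event_type = "bout", t_start = c(30, 150, 270),
               t_end = c(90, 210, 330)),
    data.frame(event_type = "song", t_start = seq(10, 340, length.out = 12),
               t_end = seq(10, 340, length.out = 12)),
    data.frame(event_type = "within_5m", t_start = c(30, 150, 270),
               t_end = c(90, 210, 330)))
  m <- aggression_metrics(ev)
  expect_equal(m$song_rate, 2) # 12 songs over 6 minutes
  expect_equal(m$time_close, 1) # close for the entirety of every bout
  expect_equal(m$time_close_transformed, pi / 2)
  expect_equal(m$flights, 0)
  expect_equal(m$flights_transformed, 0)
  bad <- ev
  bad$t_end[2] <- bad$t_start[2]
  expect_error(aggression_metrics(bad), "zero-length")
  expect_error(aggression_metrics(ev[ev$event_type != "bout", ]), "bout")
})

test_that("age coding follows banding history", {
  nestling <- data.frame(band_year = 2008, stage = "nestling")
  expect_equal(code_age(nestling, 2009), "SY")
  expect_equal(code_age(nestling, 2011), "ASY") # nestling two years back
  adult <- data.frame(band_year = 2007, stage = "adult")
  expect_equal(code_age(adult, 2009), "ASY")
  none <- data.frame(band_year = integer(), stage = character())
  expect_true(is.na(code_age(none, 2009)))
  # banded this year only: unknown
  this_yr <- data.frame(band_year = 2009, stage = "adult")
  expect_true(is.na(code_age(this_yr, 2009)))
  contradictory <- data.frame(band_year = c(2008, 2007),
                              stage = c("nestling", "adult"))
  expect_error(code_age(contradictory, 2009), "contradictory")
})

test_that("transform registry is invertible on its domains", {
  cases <- list(sqrt_plus1 = c(0, 3, 8), neg_log_1m = c(0, 0.5, 0.9),
                log = c(0.2, 1, 5), pow_0.55 = c(0, 1, 4),
                arcsine_sqrt = c(0, 0.3, 1))
  for (nm in names(cases)) {
    x <- cases[[nm]]
    expect_equal(trait_untransform(nm, trait_transform(nm, x)), x,
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(trait_transform("sqrt_plus1", c(0, 8)), c(1, 3))
  expect_equal(trait_transform("arcsine_sqrt", 1), pi / 2)
  expect_equal(trait_transform("pow_0.55", 0), 0)
  expect_error(trait_transform("log", -1), "domain")
  expect_error(trait_transform("nope", 1), "unknown transform")
})

test_that("derive_quality merges condition and playback metrics", {
  b <- small_bundle()
  q <- derive_quality(b$phenotypes, b$playback_events)
  expect_true(all(c("condition", "song_rate", "flights", "time_close")
                  %in% names(q)))
  expect_equal(nrow(q), nrow(b$phenotypes))
  expect_equal(mean(q$condition), 0, tolerance = 1e-8)
  # condition recovers the generator's latent residual ordering
  truth <- b$ground_truth$condition_residual
  m <- merge(q, truth, by = c("male_id", "year"))
  expect_gt(cor(m$condition, m$residual, method = "spearman"), 0.7)
})
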