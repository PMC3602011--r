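test_that("fit_mixed collapses to OLS without replication", {
  set.seed(1)
  d <- data.frame(x = rnorm(40), g = factor(1:40))
  d$y <- 1 + 2 * d$x + rnorm(40)
  mm <- suppressWarnings(fit_mixed(y ~ x + (1 | g), d))
  ols <- coef(lm(y ~ x, d))
  expect_lt(max(abs(mm$terms$estimate - ols)), 1e-6)
  expect_error(fit_mixed(y ~ x + (1 | g),
                         transform(d, y = 1)), "constant")
  d$x2 <- d$x
  expect_error(fit_mixed(y ~ x + x2 + (1 | g), d), "aliased.*x2")
})

test_that("mixed-model slope CIs cover the truth at nominal rate", {
  set.seed(99)
  cover <- 0
  for (r in 1:100) {
    g <- rep(1:50, each = 20)
    x <- rnorm(1000)
    y <- 2 * x + rnorm(50, 0, 1)[g] + rnorm(1000, 0, 1)
    d <- data.frame(y = y, x = x, g = factor(g))
    res <- fit_mixed(y ~ x + (1 | g), d)
    row <- res$terms[res$terms$term == "x", ]
    hw <- qt(0.975, row$df) * row$se
    cover <- cover + (abs(row$estimate - 2) <= hw)
  }
  expect_gte(cover, 93)
})

test_that("repeatability recovers variance ratios and edge cases", {
  set.seed(7)
  # zero within-group variance
  d0 <- data.frame(y = rep(rnorm(10), each = 3), g = factor(rep(1:10, each = 3)))
  r0 <- suppressWarnings(repeatability(d0, "y", group = "g"))
  expect_gt(r0$r, 0.999)
  expect_error(repeatability(data.frame(y = rnorm(5), g = 1), "y",
                             group = "g"), "2 groups")
  # known ratio 0.25
  rs <- vapply(1:5, function(s) {
    set.seed(s)
    g <- rep(1:60, each = 40)
    y <- rnorm(60, 0, 1)[g] + rnorm(2400, 0, sqrt(3))
    suppressWarnings(
      repeatability(data.frame(y = y, g = factor(g)), "y", group = "g")$r)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.25), 0.05)
})

test_that("shuffled group labels destroy repeatability", {
  set.seed(12)
  g <- rep(1:30, each = 6)
  y <- rnorm(30, 0, 1)[g] + rnorm(180)
  d <- data.frame(y = y, g = factor(g))
  r_real <- repeatability(d, "y", group = "g")
  expect_gt(r_real$r, 0.2)
  rs <- replicate(50, {
    d$g <- sample(d$g)
    repeatability(d, "y", group = "g")
  }, simplify = FALSE)
  expect_lt(mean(vapply(rs, `[[`, numeric(1), "r")), 0.05)
  # boundary-corrected LRT p is not anticonservative under the null
  expect_lte(mean(vapply(rs, `[[`, numeric(1), "p") < 0.05), 0.1)
})

test_that("within/between decomposition reconstructs and recovers slopes", {
  set.seed(3)
  n_g <- 59
  per <- 60
  g <- rep(seq_len(n_g), each = per)
  xg <- rnorm(n_g, 0, 0.3)
  x <- xg[g] + rnorm(n_g * per, 0, 0.4)
  y <- -5 * xg[g] + -3 * (x - xg[g]) + rnorm(n_g, 0, 1)[g] +
    rnorm(n_g * per, 0, 2)
  d <- data.frame(y = y, x = x, male_id = factor(g),
                  grp = factor(g))
  dec <- within_between_decompose(d, "y", "x", group_keys = "grp")
  expect_lt(max(abs(dec$data$.between + dec$data$.within - d$x)), 1e-12)
  expect_gt(dec$beta_between$ci_high, -5 - 1.2)
  expect_lt(dec$beta_between$ci_low, -5 + 1.2)
  expect_lt(abs(dec$beta_within$estimate - -3), 0.3)
  # covariate constant within groups: within effect undefined, between kept
  d2 <- d
  d2$x <- ave(d$x, d$grp)
  dec2 <- within_between_decompose(d2, "y", "x", group_keys = "grp")
  expect_true(is.na(dec2$beta_within$estimate))
  expect_false(is.na(dec2$beta_between$estimate))
  # all-singleton groups are an error
  d3 <- d[1:30, ]
  d3$grp <- factor(seq_len(30))
  expect_error(within_between_decompose(d3, "y", "x", group_keys = "grp"),
               "singleton")
})

test_that("paired role model detects no effect on identical pairs", {
  set.seed(4)
  base <- data.frame(pair_id = rep(sprintf("p%02d", 1:10), each = 8),
                     trill = rnorm(80))
  d <- rbind(transform(base, role = "WP",
                       male_id = paste0(pair_id, "w")),
             transform(base, role = "EP",
                       male_id = paste0(pair_id, "e")))
  res <- suppressMessages(paired_role_model(d, "trill"))
  expect_lt(abs(res$terms$estimate[res$terms$term == "roleEP"]), 1e-8)
  # duplicated male across pairs is handled by the male random effect
  d2 <- d
  d2$male_id[d2$male_id == "p02e"] <- "p01e"
  expect_s3_class(suppressMessages(paired_role_model(d2, "trill")),
                  "model_result")
  # a pair missing one role is dropped with a warning
  d3 <- d[!(d$pair_id == "p01" & d$role == "EP"), ]
  expect_warning(paired_role_model(d3, "trill"), "missing a role")
})

test_that("paired t-test power tracks the analytic value", {
  n <- 30
  delta <- 0.5
  target <- power.t.test(n = n, delta = delta, sd = 1,
                         type = "paired")$power
  set.seed(21)
  hits <- mean(replicate(400, {
    wp <- rnorm(n)
    ep <- wp + rnorm(n, delta, sqrt(2 - 1)) # paired diff sd 1
    paired_trait_test(wp, ep)$p < 0.05
  }))
  expect_lt(abs(hits - target), 0.05)
})

test_that("effect sizes match closed forms and invert the noncentral t", {
  r0 <- effect_partial_r(0, 50)
  expect_equal(r0$value, 0)
  expect_lt(r0$ci_low, 0)
  expect_gt(r0$ci_high, 0)
  r <- effect_partial_r(2, 100)
  expect_equal(r$value, 2 / sqrt(4 + 100), tolerance = 1e-12)
  expect_equal(r$value, 0.1961, tolerance = 1e-3)
  # the CI endpoints invert pt() at the right probabilities
  ncp_hi <- r$ci_high / sqrt(1 - r$ci_high^2) * sqrt(100)
  expect_equal(pt(2, 100, ncp = ncp_hi), 0.025, tolerance = 1e-6)
  d0 <- cohens_d(mean1 = 5, mean2 = 5, sd1 = 1, sd2 = 1, n1 = 20, n2 = 20)
  expect_equal(d0$value, 0)
  d <- cohens_d(t = 2.5, n1 = 20, n2 = 20)
  expect_equal(d$value, 2.5 * sqrt(0.1), tolerance = 1e-12)
  expect_error(effect_partial_r(1, 0), "positive")
})

test_that("BH-FDR matches stepwise expectations within families", {
  one <- bh_fdr(0.01)
  expect_true(one$significant)
  four <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(four$significant))
  all1 <- bh_fdr(rep(1, 5))
  expect_true(all(!all1$significant))
  expect_true(all(all1$p_adjusted == 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # families adjusted independently
  fam <- bh_fdr(c(0.01, 0.5, 0.01, 0.8), c("a", "a", "b", "b"))
  expect_equal(fam$p_adjusted[1], 0.02)
  expect_equal(fam$p_adjusted[3], 0.02)
  # adjusted p monotone in raw p within family
  set.seed(2)
  p <- runif(30)
  out <- bh_fdr(p)
  expect_true(all(diff(out$p_adjusted[order(out$p)]) >= -1e-12))
})

test_that("VIF flags collinear designs", {
  set.seed(6)
  x <- matrix(rnorm(300), ncol = 3)
  # balanced contrasts: exactly orthogonal after centering
  x_orth <- cbind(rep(c(1, -1), 50), rep(c(1, 1, -1, -1), 25),
                  rep(c(1, -1, -1, 1), 25))
  v <- vif(x_orth)
  expect_true(all(abs(v - 1) < 1e-8))
  near <- cbind(x[, 1], x[, 1] + rnorm(100, 0, 1e-4), x[, 2])
  expect_gt(max(vif(near)), 5)
  exact <- cbind(x[, 1], x[, 1], x[, 2])
  expect_true(is.infinite(max(vif(exact))))
  expect_error(vif(x[, 1, drop = FALSE]), "at least 2")
})
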