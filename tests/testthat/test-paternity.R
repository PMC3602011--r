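test_that("pairwise mismatch follows the null-allele signature", {
  expect_null(pairwise_mismatch(c(1L, 2L), c(2L, 3L)))
  mm <- pairwise_mismatch(c(1L, 1L), c(2L, 2L))
  expect_true(mm$null_consistent)
  mm2 <- pairwise_mismatch(c(1L, 2L), c(3L, 4L))
  expect_false(mm2$null_consistent)
  expect_null(pairwise_mismatch(NULL, c(1L, 2L)))
})

test_that("trio mismatch enumerates parental combinations exhaustively", {
  # compatible: offspring 1/3 from mother 1/2 x father 3/4
  expect_null(trio_mismatch(c(1L, 2L), c(3L, 4L), c(1L, 3L)))
  # offspring homozygous for an allele neither parent carries
  mm <- trio_mismatch(c(1L, 1L), c(2L, 2L), c(3L, 3L))
  expect_false(is.null(mm))
  expect_false(mm$null_consistent)
  # mother homozygote, offspring apparent homozygote for father's allele:
  # explicable if both hide nulls
  mm2 <- trio_mismatch(c(1L, 1L), c(2L, 3L), c(2L, 2L))
  expect_true(mm2$null_consistent)
  # heterozygous parties cannot hide nulls
  mm3 <- trio_mismatch(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  expect_false(mm3$null_consistent)
})

test_that("classification applies the more-than-one-mismatch rule", {
  mom <- loci(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  dad <- loci(c(3, 4), c(3, 4), c(3, 4), c(3, 4))
  kid_wp <- loci(c(1, 3), c(2, 4), c(1, 4), c(2, 3))
  expect_equal(classify_offspring(kid_wp, mom, dad)$status, "WP")
  expect_equal(classify_offspring(kid_wp, mom, dad)$n_trio_mismatches_non_null, 0)
  # exactly one non-null mismatch is tolerated as mutation
  kid_1 <- loci(c(5, 6), c(2, 4), c(1, 4), c(2, 3))
  call1 <- classify_offspring(kid_1, mom, dad)
  expect_equal(call1$status, "WP")
  expect_equal(call1$n_trio_mismatches_non_null, 1)
  # two non-null mismatches force an EP call
  kid_2 <- loci(c(5, 6), c(5, 6), c(1, 4), c(2, 3))
  call2 <- classify_offspring(kid_2, mom, dad)
  expect_equal(call2$status, "EP")
  expect_equal(call2$n_trio_mismatches_non_null, 2)
  # null-consistent mismatches do not count toward the EP rule
  mom_h <- loci(c(1, 1), c(1, 1), c(1, 2), c(1, 2))
  dad_h <- loci(c(2, 3), c(2, 3), c(3, 4), c(3, 4))
  kid_n <- loci(c(2, 2), c(2, 2), c(1, 3), c(2, 4))
  call_n <- classify_offspring(kid_n, mom_h, dad_h)
  expect_equal(call_n$status, "WP")
  expect_equal(call_n$n_trio_mismatches_non_null, 0)
  expect_equal(call_n$n_null_consistent, 2)
  # more than two untyped loci -> unresolved
  kid_m <- loci(c(1, 3), NULL, NULL, NULL)
  expect_equal(classify_offspring(kid_m, mom, dad)$status, "unresolved")
})

test_that("classification is invariant to allele and locus order", {
  mom <- loci(c(1, 2), c(3, 3), c(2, 5))
  dad <- loci(c(3, 4), c(1, 2), c(1, 4))
  kid <- loci(c(6, 6), c(7, 8), c(2, 4))
  base <- classify_offspring(kid, mom, dad)
  flip <- function(g) lapply(g, function(a) if (is.null(a)) a else rev(a))
  expect_equal(classify_offspring(flip(kid), flip(mom), flip(dad))$status,
               base$status)
  perm <- c(3, 1, 2)
  expect_equal(classify_offspring(kid[perm], mom[perm], dad[perm])$status,
               base$status)
})

test_that("EP sire assignment picks unique compatible candidates", {
  mom <- loci(c(1, 2), c(1, 2), c(1, 2))
  kid <- loci(c(1, 5), c(2, 6), c(1, 7))
  good <- loci(c(5, 9), c(6, 9), c(7, 9))
  bad <- loci(c(8, 9), c(8, 9), c(8, 9))
  expect_equal(assign_ep_sire(kid, mom, list(A = good, B = bad)), "A")
  # a single null-consistent mismatch does not disqualify
  mom2 <- loci(c(1, 2), c(1, 2), c(1, 7))
  near <- loci(c(5, 9), c(6, 9), c(9, 9))
  kid2 <- loci(c(1, 5), c(2, 6), c(7, 7))
  expect_equal(assign_ep_sire(kid2, mom2,
                              list(A = near, B = bad)), "A")
  # two fully compatible candidates: ambiguous, no assignment
  expect_identical(assign_ep_sire(kid, mom, list(A = good, B = good)),
                   NA_character_)
  expect_identical(assign_ep_sire(kid, mom, list(B = bad)), NA_character_)
})

test_that("clean simulations are classified without false EP calls", {
  for (s in 1:3) {
    b <- simulate_population(population_config(
      n_males = 14, trills_per_male = c(4, 6),
      null_allele_freq = rep(0, 7), mutation_rate = 0, seed = 500 + s))
    calls <- call_paternity(b$offspring, b$adult_genotypes,
                            b$offspring_genotypes)
    m <- merge(calls, b$ground_truth$true_sires, by = "offspring_id")
    expect_equal(sum(m$status == "EP" & !m$ep), 0)
  }
})

test_that("male-year success roll-up matches simulator bookkeeping", {
  b <- simulate_population(population_config(
    n_males = 18, trills_per_male = c(4, 6),
    null_allele_freq = rep(0, 7), mutation_rate = 0, seed = 77))
  calls <- call_paternity(b$offspring, b$adult_genotypes,
                          b$offspring_genotypes)
  succ <- male_year_success(calls, b$nests, b$offspring)
  truth <- b$ground_truth$male_year_success
  m <- merge(succ, truth, by = c("male_id", "year"),
             suffixes = c("", ".true"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$wp_proportion, m$wp_proportion.true)
  expect_equal(m$polygynous, m$polygynous.true)
  # EP success and annual RS agree wherever the EP sire was assignable
  assigned <- calls$status != "EP" | !is.na(calls$assigned_sire)
  if (all(assigned)) {
    expect_equal(m$ep_success, m$ep_success.true)
    expect_equal(m$annual_rs, m$annual_rs.true)
  } else {
    expect_gte(mean(m$annual_rs == m$annual_rs.true), 0.9)
  }
})

test_that("manual success cases follow the definitions", {
  nests <- data.frame(nest_id = c("n1", "n2"), male_id = "M1",
                      female_id = c("f1", "f2"), year = 2009,
                      start_doy = c(120, 160), end_doy = c(150, 190),
                      is_secondary = c(FALSE, TRUE), excluded = FALSE)
  calls <- data.frame(offspring_id = paste0("o", 1:4),
                      nest_id = "n1", year = 2009, mother_id = "f1",
                      social_father_id = "M1", status = "WP",
                      n_trio_mismatches_non_null = 0,
                      assigned_sire = NA_character_)
  offs <- data.frame(offspring_id = paste0("o", 1:4), fledged = TRUE)
  s <- male_year_success(calls, nests, offs)
  expect_equal(s$wp_proportion, 1.0)
  expect_false(s$ep_success)
  # second nest starts after the primary ends: not simultaneous polygyny
  expect_false(s$polygynous)
  expect_equal(s$annual_rs, 4)
  nests2 <- nests
  nests2$start_doy[2] <- 140 # overlapping -> simultaneous
  expect_true(male_year_success(calls, nests2, offs)$polygynous)
})

test_that("locus summaries report diversity and unbiased heterozygosity", {
  g <- rbind(toy_geno(1, 2, 1, 1, id = "a"),
             toy_geno(1, 2, 1, 1, id = "b"),
             toy_geno(2, 1, 1, 1, id = "c"),
             toy_geno(1, 2, 1, 1, id = "d"))
  ls <- locus_summaries(g)
  expect_equal(ls$h_obs[1], 1.0)
  expect_equal(ls$n_alleles[2], 1)
  expect_equal(ls$h_exp[2], 0)
  expect_equal(ls$h_obs[2], 0)
  # frequencies (0.9, 0.1) at large n approach 0.18
  set.seed(2)
  n <- 500
  a1 <- sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1))
  a2 <- sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1))
  big <- do.call(rbind, lapply(seq_len(n), function(i)
    toy_geno(a1[i], a2[i], id = paste0("x", i))))
  expect_lt(abs(locus_summaries(big)$h_exp - 0.18), 0.03)
})
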