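#' Genotype tables
#'
#' Genotypes are stored one row per individual with two integer allele
#' columns per locus (`locus<k>_a1`, `locus<k>_a2`); `NA` (or 0 in CSV
#' input) marks an untyped locus. Alleles are unordered.
#'
#' @param geno_row One row of a genotype table.
#' @return List of length-2 integer vectors, one per locus (`NULL`
#'   entries for missing loci).
#' @keywords internal
genotype_loci <- function(geno_row) {
  cols <- grep("^locus[0-9]+_a[12]$", names(geno_row), value = TRUE)
  loci <- sort(unique(as.integer(sub("^locus([0-9]+)_a[12]$", "\\1", cols))))
  lapply(loci, function(k) {
    a <- c(geno_row[[sprintf("locus%d_a1", k)]],
           geno_row[[sprintf("locus%d_a2", k)]])
    a <- as.integer(a)
    a[a == 0L] <- NA_integer_
    if (any(is.na(a))) NULL else a
  })
}

#' Pairwise parent-offspring mismatch at one locus
#'
#' A mismatch occurs when parent and offspring share no allele. It is
#' *null-consistent* when both are (apparent) homozygotes for different
#' alleles: each could then carry an unamplified null allele, with the
#' offspring's null inherited from the parent.
#'
#' @param parent,offspring Length-2 integer allele vectors, or `NULL` if
#'   the locus is untyped.
#' @return `NULL` when compatible or untyped; otherwise a list with
#'   `null_consistent` (logical).
#' @export
pairwise_mismatch <- function(parent, offspring) {
  if (is.null(parent) || is.null(offspring)) return(NULL)
  if (length(intersect(parent, offspring)) > 0) return(NULL)
  list(null_consistent =
         parent[1] == parent[2] && offspring[1] == offspring[2])
}

#' Trio-wise mismatch at one locus
#'
#' The trio mismatches when no assignment of one maternal and one
#' paternal allele explains the offspring, checked by exhaustive
#' enumeration over the four parental allele combinations. A trio
#' mismatch is null-consistent if the trio becomes compatible when any
#' apparent homozygote is allowed to hide a null allele (i/null types as
#' i/i; a transmitted null leaves the offspring's visible allele to the
#' other parent).
#'
#' @param mother,father,offspring Length-2 allele vectors or `NULL`.
#' @return `NULL` if compatible or any party untyped; else list with
#'   `null_consistent`.
#' @export
trio_mismatch <- function(mother, father, offspring) {
  if (is.null(mother) || is.null(father) || is.null(offspring))
    return(NULL)
  if (trio_compatible(mother, father, offspring, nulls = FALSE))
    return(NULL)
  list(null_consistent =
         trio_compatible(mother, father, offspring, nulls = TRUE))
}

trio_compatible <- function(mother, father, offspring, nulls = FALSE) {
  expand <- function(g) {
    # an apparent homozygote i/i may really be i/null
    if (nulls && g[1] == g[2]) list(g, c(g[1], 0L)) else list(g)
  }
  offs <- expand(offspring)
  moms <- expand(mother)
  dads <- expand(father)
  for (o in offs) for (mo in moms) for (da in dads) {
    for (i in 1:2) {
      a_m <- o[i]
      a_f <- o[3 - i]
      if ((a_m %in% mo) && (a_f %in% da)) return(TRUE)
    }
  }
  FALSE
}

#' Classify an offspring as within-pair or extra-pair
#'
#' Counts trio-wise mismatches with the social parents that cannot be
#' attributed to null alleles. Zero or one such mismatch is tolerated
#' (single mismatches with a putative parent of either sex are allowed
#' as mutations) and the chick is called within-pair (WP); more than one
#' makes it extra-pair (EP). Trios with more than two untyped loci are
#' unresolved.
#'
#' @param offspring,mother,social_father Rows of a genotype table (or
#'   locus lists from [genotype_loci()]).
#' @return List of class `paternity_call`: `status` (`"WP"`, `"EP"`,
#'   `"unresolved"`), `n_trio_mismatches_non_null`, `n_null_consistent`,
#'   `mismatch_loci`.
#' @export
classify_offspring <- function(offspring, mother, social_father) {
  off <- as_loci(offspring)
  mom <- as_loci(mother)
  dad <- as_loci(social_father)
  n_loci <- length(off)
  missing <- sum(vapply(seq_len(n_loci), function(k)
    is.null(off[[k]]) || is.null(mom[[k]]) || is.null(dad[[k]]),
    logical(1)))
  mm <- lapply(seq_len(n_loci), function(k)
    trio_mismatch(mom[[k]], dad[[k]], off[[k]]))
  non_null <- which(vapply(mm, function(x)
    !is.null(x) && !x$null_consistent, logical(1)))
  null_ok <- which(vapply(mm, function(x)
    !is.null(x) && x$null_consistent, logical(1)))
  status <- if (missing > 2) "unresolved"
  else if (length(non_null) > 1) "EP" else "WP"
  structure(list(status = status,
                 n_trio_mismatches_non_null = length(non_null),
                 n_null_consistent = length(null_ok),
                 mismatch_loci = c(non_null, null_ok),
                 n_missing_loci = missing),
            class = "paternity_call")
}

as_loci <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, function(g) is.null(g) || length(g) == 2, logical(1))))
    return(x)
  genotype_loci(x)
}

#' Assign an extra-pair sire
#'
#' Screens candidate males for compatibility with the mother-offspring
#' pair at every typed locus, allowing at most one null-allele-consistent
#' mismatch for the candidate. A unique qualifying candidate is
#' assigned; with several qualifiers the one with zero mismatches is
#' taken if unique, otherwise no assignment is made (conservative
#' handling of ties).
#'
#' @param offspring,mother Genotype rows or locus lists.
#' @param candidates Named list of candidate genotypes (locus lists or
#'   rows), names are male ids; the social father should be excluded by
#'   the caller.
#' @return Male id or `NA_character_`.
#' @export
assign_ep_sire <- function(offspring, mother, candidates) {
  off <- as_loci(offspring)
  mom <- as_loci(mother)
  eval_candidate <- function(cand) {
    cand <- as_loci(cand)
    non_null <- 0L
    null_ok <- 0L
    for (k in seq_along(off)) {
      m <- trio_mismatch(mom[[k]], cand[[k]], off[[k]])
      if (is.null(m)) next
      if (m$null_consistent) null_ok <- null_ok + 1L
      else non_null <- non_null + 1L
    }
    c(non_null = non_null, null_ok = null_ok)
  }
  scores <- vapply(candidates, eval_candidate, numeric(2))
  qualify <- scores["non_null", ] == 0 & scores["null_ok", ] <= 1
  ids <- names(candidates)[qualify]
  if (length(ids) == 0) return(NA_character_)
  if (length(ids) == 1) return(ids)
  perfect <- names(candidates)[qualify &
                                 colSums(scores) == 0]
  if (length(perfect) == 1) return(perfect)
  NA_character_
}

#' Paternity calls for a full offspring table
#'
#' Runs [classify_offspring()] on every offspring and
#' [assign_ep_sire()] on those called EP, using all genotyped males
#' present in the same year (other than the social father) as
#' candidates.
#'
#' @param offspring Offspring table (`offspring_id`, `mother_id`,
#'   `social_father_id`, `year`).
#' @param adult_genotypes,offspring_genotypes Genotype tables (`id`
#'   column plus locus columns; adults carry a `years` column listing
#'   presence years separated by `;`).
#' @return Data frame: one row per offspring with `status`,
#'   `n_trio_mismatches_non_null`, `assigned_sire`.
#' @export
call_paternity <- function(offspring, adult_genotypes,
                           offspring_genotypes) {
  g_of <- function(tab) {
    loci <- lapply(seq_len(nrow(tab)), function(i) genotype_loci(tab[i, ]))
    names(loci) <- tab$id
    loci
  }
  adults <- g_of(adult_genotypes)
  offs <- g_of(offspring_genotypes)
  adult_years <- strsplit(as.character(adult_genotypes$years), ";")
  names(adult_years) <- adult_genotypes$id
  is_male <- adult_genotypes$sex == "M"
  names(is_male) <- adult_genotypes$id

  out <- vector("list", nrow(offspring))
  for (i in seq_len(nrow(offspring))) {
    o <- offspring[i, ]
    call <- classify_offspring(offs[[o$offspring_id]],
                               adults[[o$mother_id]],
                               adults[[o$social_father_id]])
    sire <- NA_character_
    if (call$status == "EP") {
      yr <- as.character(o$year)
      cand_ids <- names(adults)[is_male[names(adults)] &
                                  vapply(adult_years[names(adults)],
                                         function(y) yr %in% y,
                                         logical(1))]
      cand_ids <- setdiff(cand_ids, o$social_father_id)
      sire <- assign_ep_sire(offs[[o$offspring_id]], adults[[o$mother_id]],
                             adults[cand_ids])
    }
    out[[i]] <- data.frame(
      offspring_id = o$offspring_id, nest_id = o$nest_id, year = o$year,
      mother_id = o$mother_id, social_father_id = o$social_father_id,
      status = call$status,
      n_trio_mismatches_non_null = call$n_trio_mismatches_non_null,
      assigned_sire = sire)
  }
  do.call(rbind, out)
}

#' Male-year mating and reproductive success
#'
#' Rolls paternity calls and nest records up to one row per male-year:
#' the proportion of social offspring sired (pooling all social nests in
#' the year), extra-pair success (sired at least one EP chick that
#' year), simultaneous polygyny (a second nest whose active period
#' overlaps the primary's), and annual reproductive success (fledged WP
#' offspring retained plus fledged EP offspring sired elsewhere).
#' Nests flagged `excluded` are dropped from WP and RS tallies.
#'
#' @param calls Output of [call_paternity()].
#' @param nests Nest table (`nest_id`, `male_id`, `year`, `start_doy`,
#'   `end_doy`, `excluded`).
#' @param offspring Offspring table carrying `fledged`.
#' @return Data frame, one row per male-year, of class
#'   `male_year_success`.
#' @export
male_year_success <- function(calls, nests, offspring) {
  calls <- merge(calls, offspring[, c("offspring_id", "fledged")],
                 by = "offspring_id", sort = FALSE)
  keep_nests <- nests[!nests$excluded, ]
  my <- unique(keep_nests[, c("male_id", "year")])
  out <- lapply(seq_len(nrow(my)), function(i) {
    m <- my$male_id[i]
    yr <- my$year[i]
    mn <- keep_nests[keep_nests$male_id == m & keep_nests$year == yr, ]
    if (nrow(mn) > 1) {
      ov <- mn$start_doy[-1] < mn$end_doy[1] & mn$end_doy[-1] > mn$start_doy[1]
      poly <- any(ov)
    } else poly <- FALSE
    soc <- calls[calls$social_father_id == m & calls$year == yr &
                   calls$nest_id %in% mn$nest_id &
                   calls$status != "unresolved", ]
    ep <- calls[calls$year == yr & calls$status == "EP" &
                  !is.na(calls$assigned_sire) & calls$assigned_sire == m, ]
    wp_kept <- soc[soc$status == "WP", ]
    data.frame(male_id = m, year = yr,
               wp_proportion = if (nrow(soc)) mean(soc$status == "WP")
               else NA_real_,
               ep_success = nrow(ep) > 0,
               polygynous = poly,
               annual_rs = sum(wp_kept$fledged) + sum(ep$fledged))
  })
  res <- do.call(rbind, out)
  class(res) <- c("male_year_success", class(res))
  res
}

#' Per-locus diversity summaries
#'
#' Number of distinct alleles, observed heterozygosity (fraction of
#' typed individuals heterozygous), and unbiased expected
#' heterozygosity `(1 - sum(p_k^2)) * 2n / (2n - 1)`.
#'
#' @param adult_genotypes Adult genotype table.
#' @return Data frame with one row per locus: `locus`, `n_alleles`,
#'   `h_obs`, `h_exp`.
#' @export
locus_summaries <- function(adult_genotypes) {
  cols <- grep("^locus[0-9]+_a1$", names(adult_genotypes), value = TRUE)
  loci <- sort(as.integer(sub("^locus([0-9]+)_a1$", "\\1", cols)))
  out <- lapply(loci, function(k) {
    a1 <- adult_genotypes[[sprintf("locus%d_a1", k)]]
    a2 <- adult_genotypes[[sprintf("locus%d_a2", k)]]
    typed <- !is.na(a1) & !is.na(a2) & a1 != 0 & a2 != 0
    a1 <- a1[typed]
    a2 <- a2[typed]
    n <- length(a1)
    if (n < 2) stop("fewer than 2 typed adults at locus ", k)
    p <- table(c(a1, a2)) / (2 * n)
    h_exp <- (1 - sum(p^2)) * 2 * n / (2 * n - 1)
    data.frame(locus = k, n_alleles = length(p),
               h_obs = mean(a1 != a2), h_exp = h_exp)
  })
  do.call(rbind, out)
}
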