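#' Fit a mixed model with tidy output
#'
#' Thin, contract-enforcing wrapper around [lmerTest::lmer()] (Gaussian,
#' REML, Satterthwaite denominator degrees of freedom) and
#' [lme4::glmer()] (binomial, Laplace). Formulas without a random term
#' fall back to [stats::lm()]/[stats::glm()], and when the estimated
#' group variance is zero the fixed estimates coincide with ordinary
#' least squares on the same design.
#'
#' @param formula Model formula, optionally with `(1 | group)` terms.
#' @param data Data frame; rows with missing values in used variables
#'   are dropped.
#' @param family `"gaussian"` or `"binomial"`.
#' @return Object of class `model_result`: list with `terms` (data frame
#'   of fixed effects: estimate, se, statistic, df, p), `varcomp`
#'   (`between`, `within`), `n_obs`, `n_groups`, and the underlying
#'   `fit`.
#' @export
fit_mixed <- function(formula, data, family = "gaussian") {
  family <- match.arg(family, c("gaussian", "binomial"))
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  resp <- data[[vars[1]]]
  if (length(unique(resp)) < 2)
    stop("response is constant; model variance undefined")
  has_re <- length(lme4::findbars(formula)) > 0

  fixed_formula <- if (has_re) lme4::nobars(formula) else formula
  mm <- stats::model.matrix(fixed_formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  if (!has_re) {
    fit <- if (family == "gaussian") stats::lm(formula, data)
    else stats::glm(formula, data = data, family = stats::binomial())
    sm <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], statistic = sm[, 3],
                        df = if (family == "gaussian")
                          fit$df.residual else NA_real_,
                        p = sm[, 4], row.names = NULL)
    return(structure(list(terms = terms,
                          varcomp = c(between = 0,
                                      within = if (family == "gaussian")
                                        sm[1, 2]^2 * 0 + summary(fit)$sigma^2
                                      else NA_real_),
                          n_obs = nrow(data), n_groups = NA_integer_,
                          family = family, fit = fit),
                     class = "model_result"))
  }

  if (family == "gaussian") {
    # degenerate designs (one observation per group) are allowed so the
    # OLS-collapse contract can be exercised
    fit <- lmerTest::lmer(formula, data = data, REML = TRUE,
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore"))
    sm <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], statistic = sm[, "t value"],
                        df = sm[, "df"], p = sm[, "Pr(>|t|)"],
                        row.names = NULL)
  } else {
    fit <- lme4::glmer(formula, data = data, family = stats::binomial(),
                       control = lme4::glmerControl(
                         check.conv.singular = "ignore"))
    sm <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], statistic = sm[, "z value"],
                        df = NA_real_, p = sm[, "Pr(>|z|)"],
                        row.names = NULL)
  }
  vc <- lme4::VarCorr(fit)
  between <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  within <- if (family == "gaussian") attr(vc, "sc")^2 else NA_real_
  groups <- lme4::ngrps(fit)
  structure(list(terms = terms,
                 varcomp = c(between = between, within = within),
                 n_obs = nrow(data), n_groups = max(groups),
                 family = family, fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("Mixed model (", x$family, "), n =", x$n_obs, "obs")
  if (!is.na(x$n_groups)) cat(",", x$n_groups, "groups")
  cat("\n")
  print(x$terms, digits = 4)
  cat("variance components: between =", signif(x$varcomp["between"], 4),
      " within =", signif(x$varcomp["within"], 4), "\n")
  invisible(x)
}

#' Adjusted repeatability of a trait
#'
#' Fraction of (covariate-adjusted) trait variance attributable to
#' among-group differences, `r = s2_between / (s2_between + s2_within)`,
#' from a Gaussian mixed model with the listed fixed covariates and a
#' random group intercept. Significance is a likelihood-ratio test of
#' the random effect against the fixed-effects-only model, with the
#' chi-square(1) p-value halved for the boundary (variance >= 0)
#' correction.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param covariates Character vector of fixed covariate column names
#'   (may be empty).
#' @param group Grouping column name (e.g. male identity).
#' @return Object of class `repeatability_result`: `r`, `var_between`,
#'   `var_within`, `lrt`, `p`, `n_obs`, `n_groups`.
#' @export
repeatability <- function(data, response, covariates = character(),
                          group = "male_id") {
  if (length(unique(data[[group]])) < 2)
    stop("repeatability needs at least 2 groups")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ")
  else "1"
  f_full <- stats::as.formula(
    paste(response, "~", rhs, "+ (1 |", group, ")"))
  f_null <- stats::as.formula(paste(response, "~", rhs))
  vars <- unique(c(response, covariates, group))
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  full <- lme4::lmer(f_full, data = data, REML = FALSE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
  null <- stats::lm(f_null, data = data)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  reml <- lme4::lmer(f_full, data = data, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(reml)
  s2b <- vc[[1]][1, 1]
  s2w <- attr(vc, "sc")^2
  structure(list(r = s2b / (s2b + s2w), var_between = s2b,
                 var_within = s2w, lrt = lrt, p = p,
                 n_obs = nrow(data),
                 n_groups = length(unique(data[[group]]))),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "Adjusted repeatability r = %.3f (LRT = %.2f, p = %.2g; %d obs, %d groups)\n",
    x$r, x$lrt, x$p, x$n_obs, x$n_groups))
  invisible(x)
}

#' Within/between-group covariate decomposition
#'
#' Splits a covariate into its mean per grouping combination (between
#' effect) and each observation's deviation from that mean (within
#' effect), and fits both in a mixed model for the response. The mean
#' and deviation reconstruct the raw covariate exactly.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param covariate Covariate to decompose.
#' @param group_keys Character vector of columns defining the averaging
#'   groups (e.g. male x trill type x year).
#' @param fixed Additional fixed covariate names.
#' @param random Random intercept grouping column.
#' @return Object of class `decomposition_result`: `beta_between`,
#'   `beta_within` (each a one-row data frame with estimate, se,
#'   statistic, df, p, and confidence limits), plus the fitted
#'   `model_result`.
#' @export
within_between_decompose <- function(data, response, covariate,
                                     group_keys, fixed = character(),
                                     random = "male_id") {
  stopifnot(all(group_keys %in% names(data)))
  key <- interaction(data[group_keys], drop = TRUE)
  mu <- stats::ave(data[[covariate]], key)
  if (max(table(key)) < 2)
    stop("all groups are singletons; within-group effect undefined")
  data$.between <- mu
  data$.within <- data[[covariate]] - mu
  within_degenerate <- max(abs(data$.within)) < 1e-12
  rhs <- c(".between", if (!within_degenerate) ".within", fixed)
  f <- stats::as.formula(paste(
    response, "~", paste(rhs, collapse = " + "),
    "+ (1 |", random, ")"))
  res <- fit_mixed(f, data)
  ci <- function(row) {
    hw <- stats::qt(0.975, row$df) * row$se
    cbind(row, ci_low = row$estimate - hw, ci_high = row$estimate + hw)
  }
  beta_within <- if (within_degenerate) {
    data.frame(term = ".within", estimate = NA_real_, se = NA_real_,
               statistic = NA_real_, df = NA_real_, p = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_)
  } else ci(res$terms[res$terms$term == ".within", ])
  structure(list(
    beta_between = ci(res$terms[res$terms$term == ".between", ]),
    beta_within = beta_within,
    model = res, data = data),
    class = "decomposition_result")
}

#' Paired comparison of extra-pair and cuckolded within-pair males
#'
#' For trill-level traits, fits a mixed model with fixed effects of role
#' (EP vs WP), year, and the acoustic covariates, and crossed random
#' intercepts for male identity and for the pair grouping that links
#' each EP male to the WP male he cuckolded. For one-value-per-male
#' traits, use [paired_trait_test()] instead.
#'
#' @param data Trill-level data with columns `role` (factor `WP`/`EP`),
#'   `pair_id`, `male_id`, the response, and covariates.
#' @param response Response column name.
#' @param covariates Additional fixed covariate names.
#' @return A `model_result`; the `roleEP`-type row is the paired
#'   contrast.
#' @export
paired_role_model <- function(data, response, covariates = character()) {
  stopifnot(all(c("role", "pair_id", "male_id") %in% names(data)))
  data$role <- stats::relevel(factor(data$role), ref = "WP")
  complete_pairs <- names(which(vapply(
    split(data$role, data$pair_id),
    function(r) length(unique(r)) == 2, logical(1))))
  dropped <- setdiff(unique(data$pair_id), complete_pairs)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " pair(s) missing a role")
    data <- data[data$pair_id %in% complete_pairs, , drop = FALSE]
  }
  rhs <- paste(c("role", covariates), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs,
                               "+ (1 | male_id) + (1 | pair_id)"))
  fit_mixed(f, data)
}

#' @rdname paired_role_model
#' @param wp,ep Numeric vectors of per-pair trait values (WP male and EP
#'   male of the same pair, in matching order).
#' @return For `paired_trait_test()`: list with `t`, `df`, `p`,
#'   `mean_wp`, `mean_ep`, `d` (paired Cohen's d with CI).
#' @export
paired_trait_test <- function(wp, ep) {
  stopifnot(length(wp) == length(ep))
  ok <- stats::complete.cases(cbind(wp, ep))
  wp <- wp[ok]
  ep <- ep[ok]
  tt <- stats::t.test(ep, wp, paired = TRUE)
  d <- cohens_d(t = unname(tt$statistic), n = length(wp), paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_wp = mean(wp), mean_ep = mean(ep), d = d)
}
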