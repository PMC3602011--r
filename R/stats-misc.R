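#' Table-wise Benjamini-Hochberg false discovery rate
#'
#' Applies the Benjamini-Hochberg step-up procedure separately within
#' each family of tests (a family is typically one results table, with
#' mating-success tests combined across tables). Adjustment within a
#' family delegates to [stats::p.adjust()].
#'
#' @param p Raw p-values in [0, 1].
#' @param family Family label per p-value (single family if omitted).
#' @param q Target false discovery rate.
#' @return Data frame: `p`, `family`, `p_adjusted`, `significant`.
#' @export
bh_fdr <- function(p, family = NULL, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(family)) family <- rep("all", length(p))
  stopifnot(length(family) == length(p), q > 0, q < 1)
  adj <- stats::ave(p, family,
                    FUN = function(x) stats::p.adjust(x, method = "BH"))
  data.frame(p = p, family = family, p_adjusted = adj,
             significant = adj <= q)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor
#' j on the remaining predictors (with intercept). Perfect collinearity
#' yields `Inf` rather than an error.
#'
#' @param x Numeric design matrix or data frame of predictors (no
#'   intercept column), >= 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 predictors")
  v <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE)
  names(v) <- colnames(x)
  v
}

#' Response-variable transforms
#'
#' The registry of transforms applied to response variables before
#' modelling (predictors are left untransformed): `sqrt_plus1` for
#' reproductive success, `neg_log_1m` for trill consistency, `log` for
#' the heterophile:lymphocyte ratio, `pow_0.55` for flights across the
#' speaker, `arcsine_sqrt` for proportion of time close to the speaker,
#' and `identity`.
#'
#' @param name Transform name.
#' @param x Values in the transform's domain.
#' @return Transformed (or inverse-transformed) values.
#' @export
trait_transform <- function(name, x) {
  f <- transform_registry(name)
  bad <- !f$domain(x)
  if (any(bad, na.rm = TRUE))
    stop("value outside domain of '", name, "' transform: ",
         x[which(bad)[1]])
  f$fun(x)
}

#' @rdname trait_transform
#' @export
trait_untransform <- function(name, x) {
  transform_registry(name)$inv(x)
}

transform_registry <- function(name) {
  reg <- list(
    identity = list(fun = identity, inv = identity,
                    domain = function(x) rep(TRUE, length(x))),
    sqrt_plus1 = list(fun = function(x) sqrt(x + 1),
                      inv = function(y) y^2 - 1,
                      domain = function(x) x >= -1),
    neg_log_1m = list(fun = consistency_transform,
                      inv = consistency_backtransform,
                      domain = function(x) x >= 0 & x <= 1),
    log = list(fun = log, inv = exp, domain = function(x) x > 0),
    pow_0.55 = list(fun = function(x) x^0.55,
                    inv = function(y) y^(1 / 0.55),
                    domain = function(x) x >= 0),
    arcsine_sqrt = list(fun = function(x) asin(sqrt(x)),
                        inv = function(y) sin(y)^2,
                        domain = function(x) x >= 0 & x <= 1))
  if (!name %in% names(reg))
    stop("unknown transform '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}
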