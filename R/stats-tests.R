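#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with the Yates continuity correction (on by
#' default), df = 1, upper-tail p-value. Used to compare the proportion
#' of extra-pair broods (and of extra-pair offspring) between cavity
#' types, years, or plots.
#'
#' @param a,b first row of counts (e.g. extra-pair / within-pair broods
#'   in the natural-cavity plot).
#' @param c,d second row of counts (same split in the nestbox plot).
#' @param continuity apply the Yates correction (default `TRUE`).
#' @return Tibble: `statistic`, `df`, `p_value`, `n`, `method`.
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("2x2 table has a zero margin")
  ht <- suppressWarnings(chisq.test(tab, correct = continuity))
  tibble(
    statistic = unname(ht$statistic), df = 1L,
    p_value = unname(ht$p.value), n = sum(counts),
    method = if (continuity) "pearson_yates" else "pearson"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the first-sample convention
#' `W = R1 - n1(n1+1)/2`. Uses exact enumeration when both samples have
#' at most `exact_max_n` observations and there are no ties, otherwise
#' the normal approximation with tie correction (and optional continuity
#' correction).
#'
#' @param x,y numeric samples.
#' @param continuity continuity correction for the normal approximation
#'   (default `TRUE`).
#' @param exact_max_n per-group size at or below which the exact
#'   distribution is used (default 8).
#' @return Tibble: `statistic` (W), `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE, exact_max_n = 8) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    warn("all values identical across both samples")
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  n1 = length(x), n2 = length(y), method = "degenerate"))
  }
  exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = continuity)
  )
  tibble(
    statistic = unname(ht$statistic), p_value = unname(ht$p.value),
    n1 = length(x), n2 = length(y),
    method = if (exact) "exact" else
      paste0("normal_tie_corrected", if (continuity) "_continuity" else "")
  )
}

#' Z-scale a covariate
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation, applied
#' within the modeling dataset (used to absorb between-year differences
#' in the spatiotemporal covariates).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param name covariate name used in the zero-variance error message.
#' @return Scaled numeric vector.
#' @export
zscale <- function(values, name = deparse(substitute(values))) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2)
    abort(sprintf("cannot z-scale `%s`: zero variance", name))
  (values - mean(values, na.rm = TRUE)) / sd(values, na.rm = TRUE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on the remaining predictors. Perfect collinearity is reported as
#' `Inf`.
#'
#' @param design numeric matrix or data frame of predictors (no
#'   intercept column; at least 2 predictors).
#' @return Tibble `term`, `vif`.
#' @export
compute_vif <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2) abort("need at least 2 predictors")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  vif <- vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    ssr <- sum(stats::residuals(fit)^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - ssr / sst
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = colnames(x), vif = vif)
}

#' Scaled mass index
#'
#' Body-condition index of Peig & Green: each individual's mass is
#' rescaled to the mass it would have at a reference body length,
#' \deqn{SMI_i = m_i (L_0 / L_i)^{b}},
#' where `b` is the standardized-major-axis slope of `ln(mass)` on
#' `ln(length)` (OLS slope divided by Pearson's r) and `L_0` the
#' reference length (default: sample mean).
#'
#' @param mass,tarsus positive numeric vectors (tarsus is the body-length
#'   proxy).
#' @param reference_length `L_0`; default `mean(tarsus)`.
#' @return Numeric SMI vector with attributes `b_sma` and
#'   `reference_length`.
#' @export
scaled_mass_index <- function(mass, tarsus, reference_length = NULL) {
  ok <- !is.na(mass) & !is.na(tarsus)
  if (any(mass[ok] <= 0) || any(tarsus[ok] <= 0))
    abort("mass and tarsus must be positive")
  lm_ <- log(mass[ok]); ll <- log(tarsus[ok])
  if (sd(ll) < 1e-12) {
    # constant length: (L0/L)^b is 1 for any b, so SMI is just the mass
    b <- 0
  } else {
    r <- suppressWarnings(cor(lm_, ll))
    if (!is.finite(r) || abs(r) < 1e-8)
      abort("SMA slope undefined: ln(mass) and ln(tarsus) are uncorrelated")
    b <- sign(r) * sd(lm_) / sd(ll)   # OLS slope / r
  }
  l0 <- reference_length %||% mean(tarsus, na.rm = TRUE)
  out <- mass * (l0 / tarsus)^b
  attr(out, "b_sma") <- b
  attr(out, "reference_length") <- l0
  out
}
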