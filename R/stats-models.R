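#' Binomial GLM with drop-one likelihood-ratio term tests
#'
#' Logit-link binomial regression (Bernoulli responses such as per-brood
#' extra-pair occurrence, or `cbind(successes, failures)` proportion
#' responses such as extra-pair offspring per sampled brood). Per-term
#' p-values come from drop-one likelihood-ratio chi-square tests; Wald
#' standard errors are reported alongside. Aliased (rank-deficient)
#' columns are dropped by the fitter and reported, and apparent complete
#' separation is flagged rather than silenced.
#'
#' @param data model data frame.
#' @param formula model formula (binomial response on the left).
#' @param weights optional prior weights.
#' @return An `epp_glm` object; see [tidy.epp_glm()] / [glance.epp_glm()].
#' @export
glm_binomial <- function(data, formula, weights = NULL) {
  if (is.null(weights)) {
    fit <- stats::glm(formula, family = binomial("logit"), data = data)
  } else {
    data$.prior_w <- weights
    fit <- stats::glm(formula, family = binomial("logit"), data = data,
                      weights = .prior_w)
  }
  aliased <- names(coef(fit))[is.na(coef(fit))]
  separation <- any(abs(coef(fit)) > 10, na.rm = TRUE) || !fit$converged
  if (separation)
    warn("possible separation or non-convergence: estimates unreliable")
  lrt <- drop1(fit, test = "LRT")
  structure(
    list(fit = fit, lrt = lrt, aliased = aliased, separation = separation,
         random_term_dropped = FALSE, n = stats::nobs(fit)),
    class = "epp_glm"
  )
}

#' Binomial GLMM with a single random intercept
#'
#' Logit-link binomial mixed model maximized by adaptive Gauss-Hermite
#' quadrature (`nAGQ` nodes; 1 node is the Laplace approximation). Per-
#' term p-values are drop-one likelihood-ratio chi-square tests on the
#' fixed effects. When the mixed fit fails to converge the random term
#' is discarded and the corresponding [glm_binomial()] fit is returned
#' with `random_term_dropped = TRUE` — never silently.
#'
#' @param data model data frame.
#' @param formula lme4-style formula with exactly one `(1 | group)` term.
#' @param weights optional prior weights.
#' @param nAGQ quadrature nodes (default 10).
#' @return An `epp_glmm` (or, on fallback, `epp_glm`) object.
#' @export
glmm_binomial <- function(data, formula, weights = NULL, nAGQ = 10) {
  bars <- lme4::findbars(formula)
  if (length(bars) != 1) abort("formula must contain exactly one (1 | group) term")
  # drop1() re-evaluates the glmer call in the formula environment, so
  # the data and quadrature settings must be visible there
  env <- new.env(parent = environment(formula) %||% parent.frame())
  assign("data", data, envir = env)
  assign("nAGQ", nAGQ, envir = env)
  if (!is.null(weights)) assign(".prior_w", weights, envir = env)
  environment(formula) <- env
  fit <- tryCatch({
    f <- suppressMessages(suppressWarnings(if (is.null(weights)) {
      lme4::glmer(formula, family = binomial("logit"), data = data,
                  nAGQ = nAGQ)
    } else {
      data$.prior_w <- weights
      lme4::glmer(formula, family = binomial("logit"), data = data,
                  weights = .prior_w, nAGQ = nAGQ)
    }))
    msgs <- f@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs, TRUE)))
      stop("glmer convergence failure")
    if ((f@optinfo$conv$opt %||% 0) != 0) stop("optimizer reported failure")
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fixed <- lme4::nobars(formula)
    out <- glm_binomial(data, fixed, weights)
    out$random_term_dropped <- TRUE
    warn("mixed model did not converge: random term dropped, GLM fitted")
    return(out)
  }
  lrt <- suppressMessages(suppressWarnings(drop1(fit, test = "Chisq")))
  structure(
    list(fit = fit, lrt = lrt, aliased = character(0),
         separation = any(abs(lme4::fixef(fit)) > 10),
         random_term_dropped = FALSE,
         ranef_variance = unname(lme4::VarCorr(fit)[[1]][1]),
         n = stats::nobs(fit), nAGQ = nAGQ),
    class = "epp_glmm"
  )
}

.model_tidy <- function(x) {
  est <- if (inherits(x$fit, "glmerMod")) lme4::fixef(x$fit) else coef(x$fit)
  est <- est[!is.na(est)]
  se <- sqrt(diag(as.matrix(vcov(x$fit))))[names(est)]
  lrt <- x$lrt
  pcol <- grep("^Pr", names(lrt), value = TRUE)
  lrt_p <- setNames(lrt[[pcol]], rownames(lrt))
  wald_p <- 2 * pnorm(-abs(est / se))
  tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    p_lrt = unname(lrt_p[.match_terms(names(est), rownames(lrt))]),
    p_wald = unname(wald_p)
  )
}

# map coefficient names (cavity_typenestbox) back to drop1 term rows
# (cavity_type); interactions and numeric terms match directly
.match_terms <- function(coef_names, term_rows) {
  vapply(coef_names, function(cn) {
    if (cn %in% term_rows) return(cn)
    hit <- term_rows[vapply(term_rows, function(tr) {
      parts <- strsplit(tr, ":", fixed = TRUE)[[1]]
      cps <- strsplit(cn, ":", fixed = TRUE)[[1]]
      length(parts) == length(cps) &&
        all(mapply(function(p, cp) startsWith(cp, p), parts, cps))
    }, logical(1))]
    if (length(hit) == 1) hit else NA_character_
  }, character(1))
}

#' @rdname glm_binomial
#' @param x an `epp_glm` object.
#' @param ... unused.
#' @export
tidy.epp_glm <- function(x, ...) .model_tidy(x)

#' @rdname glmm_binomial
#' @param x an `epp_glmm` object.
#' @param ... unused.
#' @export
tidy.epp_glmm <- function(x, ...) .model_tidy(x)

#' @rdname glm_binomial
#' @export
glance.epp_glm <- function(x, ...) {
  f <- x$fit
  tibble(
    n = x$n, logLik = as.numeric(logLik(f)), AIC = stats::AIC(f),
    deviance = stats::deviance(f),
    dispersion = sum(stats::residuals(f, "pearson")^2) / stats::df.residual(f),
    ranef_variance = NA_real_, converged = f$converged,
    separation = x$separation, random_term_dropped = x$random_term_dropped
  )
}

#' @rdname glmm_binomial
#' @export
glance.epp_glmm <- function(x, ...) {
  f <- x$fit
  tibble(
    n = x$n, logLik = as.numeric(logLik(f)), AIC = stats::AIC(f),
    deviance = stats::deviance(f),
    dispersion = sum(stats::residuals(f, "pearson")^2) / stats::df.residual(f),
    ranef_variance = x$ranef_variance, converged = TRUE,
    separation = x$separation, random_term_dropped = FALSE
  )
}

#' @export
print.epp_glm <- function(x, ...) {
  cat("<epp_glm> binomial GLM", if (x$random_term_dropped)
    "(random term dropped after convergence failure)", "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
print.epp_glmm <- function(x, ...) {
  cat(sprintf("<epp_glmm> binomial GLMM, random-intercept variance %.3f (nAGQ=%d)\n",
              x$ranef_variance, x$nAGQ))
  print(tidy(x))
  invisible(x)
}
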