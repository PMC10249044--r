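test_that("Yates chi-square reproduces the published plot-level statistics", {
  # broods: extra-pair vs within-pair, natural vs nestbox
  expect_equal(round(chi_square_2x2(11, 19, 17, 20)$statistic, 3), 0.267)
  expect_equal(round(chi_square_2x2(12, 20, 16, 10)$statistic, 3), 2.427)
  # offspring: extra-pair vs within-pair
  expect_equal(round(chi_square_2x2(16, 181, 28, 209)$statistic, 3), 1.230)
  expect_equal(round(chi_square_2x2(20, 159, 30, 159)$statistic, 3), 1.352)

  # proportional table without correction is exactly zero
  expect_equal(chi_square_2x2(10, 10, 20, 20, continuity = FALSE)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("chi-square type-I error is near nominal under the null", {
  set.seed(61)
  n1 <- 30; n2 <- 37; p <- 0.4
  sim_null <- function(continuity) {
    mean(replicate(2000, {
      a <- rbinom(1, n1, p); c <- rbinom(1, n2, p)
      if (a %in% c(0, n1) && c %in% c(0, n2)) return(NA)
      chi_square_2x2(a, n1 - a, c, n2 - c,
                     continuity = continuity)$p_value < 0.05
    }), na.rm = TRUE)
  }
  # uncorrected Pearson sits near nominal at these margins
  rate <- sim_null(continuity = FALSE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  # Yates correction is conservative, never anticonservative
  expect_lte(sim_null(continuity = TRUE), rate)
})

test_that("Mann-Whitney exact p equals full enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  set.seed(5)
  for (rep in 1:4) {
    x <- runif(5); y <- runif(5) + 0.2
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
})

test_that("tie-corrected normal variance matches the textbook formula", {
  x <- c(1, 2, 2, 3, 5); y <- c(2, 3, 3, 4, 6)
  got <- mann_whitney_u(x, y, continuity = FALSE)
  n1 <- 5; n2 <- 5; n <- 10
  r <- rank(c(x, y))
  w <- sum(r[1:5]) - n1 * (n1 + 1) / 2
  tie_tab <- table(c(x, y))
  var_w <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (w - n1 * n2 / 2) / sqrt(var_w)
  expect_equal(got$statistic, w)
  expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_match(got$method, "tie_corrected")

  expect_warning(deg <- mann_whitney_u(rep(1, 4), rep(1, 5)), "identical")
  expect_equal(deg$p_value, 1)
})

test_that("z-scaling standardizes and is idempotent", {
  expect_equal(zscale(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  v <- rnorm(40, 50, 7)
  z <- zscale(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscale(z), z, tolerance = 1e-12)
  expect_error(zscale(rep(2, 5), "cov"), "cov")
})

test_that("VIF matches the closed form", {
  set.seed(12)
  x1 <- rnorm(500); x2 <- rnorm(500)
  v <- compute_vif(cbind(a = x1, b = x2))
  expect_true(all(v$vif < 1.05))

  # correlated pair at r = 0.8: VIF = 1 / (1 - 0.64) = 2.78
  x2c <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(500)
  r <- cor(x1, x2c)
  v2 <- compute_vif(cbind(a = x1, b = x2c))
  expect_equal(v2$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-9)

  v3 <- compute_vif(cbind(a = x1, b = x1, c = x2))
  expect_true(any(is.infinite(v3$vif)))
})

test_that("scaled mass index follows the SMA allometry", {
  # identical individuals keep their mass
  smi <- scaled_mass_index(rep(10, 4), rep(20, 4))
  expect_equal(as.numeric(smi), rep(10, 4))

  # hand-computed 4-individual fixture
  mass <- c(9, 10, 11, 12); tarsus <- c(18, 19, 20, 21)
  lm_ <- log(mass); ll <- log(tarsus)
  b <- sign(cor(lm_, ll)) * sd(lm_) / sd(ll)
  l0 <- mean(tarsus)
  expect_equal(as.numeric(scaled_mass_index(mass, tarsus)),
               mass * (l0 / tarsus)^b)
  expect_equal(attr(scaled_mass_index(mass, tarsus), "b_sma"), b)

  # synthetic allometry ln m = 2 ln L + noise: b ~ 2 and SMI decouples
  set.seed(31)
  L <- rnorm(500, 20, 1.5)
  m <- exp(2 * log(L) + rnorm(500, 0, 0.02))
  smi <- scaled_mass_index(m, L)
  expect_equal(attr(smi, "b_sma"), 2, tolerance = 0.1)
  expect_lt(abs(cor(as.numeric(smi), L)), 0.1)
  # varying length but mass unrelated to it: slope undefined
  expect_error(scaled_mass_index(c(10, 10, 10, 10), c(18, 19, 20, 21)),
               "uncorrelated")
})

test_that("logistic GLM recovers simulated coefficients within 3 SE", {
  set.seed(71)
  n <- 500
  x <- rnorm(n)
  eta <- -1 + 0.8 * x
  y <- rbinom(n, 1, plogis(eta))
  fit <- glm_binomial(tibble::tibble(x = x, y = y), y ~ x)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "(Intercept)"] - (-1)) /
              td$std_error[td$term == "(Intercept)"], 3)
  expect_lt(abs(td$estimate[td$term == "x"] - 0.8) /
              td$std_error[td$term == "x"], 3)
  expect_true(all(td$std_error > 0))
})

test_that("null GLM intercept is near zero on a balanced response", {
  set.seed(72)
  y <- rep(c(0, 1), each = 250)
  fit <- glm_binomial(tibble::tibble(y = y), y ~ 1)
  expect_lt(abs(tidy(fit)$estimate[1]), 1e-8)
})

test_that("drop-one LRT matches the uncorrected chi-square asymptotically", {
  set.seed(73)
  n <- 2000
  grp <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, ifelse(grp == 1, 0.45, 0.40))
  fit <- glm_binomial(tibble::tibble(g = grp, y = y), y ~ g)
  p_lrt <- tidy(fit)$p_lrt[2]
  tab <- table(grp, y)
  p_chi <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                          continuity = FALSE)$p_value
  expect_lt(abs(p_lrt - p_chi), 0.01)
})

test_that("LRT p-values are invariant to covariate rescaling", {
  set.seed(74)
  d <- tibble::tibble(x = rnorm(300, 50, 10))
  d$y <- rbinom(300, 1, plogis(0.03 * (d$x - 50)))
  p1 <- tidy(glm_binomial(d, y ~ x))$p_lrt
  d2 <- d; d2$x <- zscale(d$x)
  p2 <- tidy(glm_binomial(d2, y ~ x))$p_lrt
  expect_equal(p1[2], p2[2], tolerance = 1e-8)
})

test_that("GLMM with zero group variance agrees with the GLM", {
  set.seed(81)
  n_g <- 40; per <- 8
  d <- tibble::tibble(
    g = rep(seq_len(n_g), each = per),
    x = rnorm(n_g * per)
  )
  d$y <- rbinom(nrow(d), 1, plogis(-0.5 + 0.6 * d$x))  # no group effect
  mm <- glmm_binomial(d, y ~ x + (1 | g), nAGQ = 10)
  gg <- glm_binomial(d, y ~ x)
  if (!mm$random_term_dropped) {
    expect_lt(mm$ranef_variance, 0.05)
    expect_equal(tidy(mm)$estimate, tidy(gg)$estimate, tolerance = 1e-2)
  } else {
    expect_equal(tidy(mm)$estimate, tidy(gg)$estimate, tolerance = 1e-9)
  }
})

test_that("GLMM recovers simulated fixed effects and variance", {
  set.seed(82)
  ok_sigma <- 0
  for (rep in 1:5) {
    n_g <- 60; per <- 8
    b <- rnorm(n_g, 0, 1)
    d <- tibble::tibble(
      g = rep(seq_len(n_g), each = per),
      x = rnorm(n_g * per)
    )
    d$y <- rbinom(nrow(d), 1, plogis(-0.5 + 0.7 * d$x + b[d$g]))
    fit <- glmm_binomial(d, y ~ x + (1 | g), nAGQ = 10)
    td <- tidy(fit)
    expect_lt(abs(td$estimate[td$term == "x"] - 0.7) /
                td$std_error[td$term == "x"], 3)
    if (fit$ranef_variance > 0.5 && fit$ranef_variance < 2.0)
      ok_sigma <- ok_sigma + 1
  }
  expect_gte(ok_sigma, 4)
})

test_that("GLMM marginal likelihood matches numeric integration", {
  # evaluate the adaptive-quadrature objective at fixed parameters on a
  # 3-group x 3-observation instance and integrate the random effect out
  # numerically by an independent route
  set.seed(83)
  d <- tibble::tibble(
    g = rep(1:3, each = 3),
    x = rnorm(9),
    y = c(1, 0, 1, 0, 0, 1, 1, 1, 0)
  )
  devfun <- lme4::glmer(y ~ x + (1 | g), data = d, family = binomial,
                        nAGQ = 25, devFunOnly = TRUE)
  beta <- c(0.3, 0.5); sigma <- 1.2
  ll_quad <- -devfun(c(sigma, beta)) / 2     # (theta, fixef) parameterization
  X <- model.matrix(~x, d)
  ll_oracle <- oracle_glmm_loglik(d$y, X, d$g, beta, sigma)
  expect_equal(ll_quad, ll_oracle, tolerance = 1e-6)
})
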