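# Independent oracles used across the suite. Each recomputes a quantity
# by a route deliberately different from the package implementation:
# scalar loops, exhaustive enumeration, or numeric integration.

# GCTA relatedness via plain scalar loops over individuals and loci
oracle_grm <- function(dosage, p = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(p)) {
    p <- sapply(seq_len(m), function(k) {
      x <- dosage[, k]
      sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    })
  }
  r <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (l in seq_len(m)) {
      xj <- dosage[j, l]; xk <- dosage[k, l]
      if (is.na(xj) || (j != k && is.na(xk))) next
      w <- 2 * p[l] * (1 - p[l])
      if (w == 0) next
      if (j == k) {
        acc <- acc + (xj^2 - (1 + 2 * p[l]) * xj + 2 * p[l]^2) / w
      } else {
        acc <- acc + (xj - 2 * p[l]) * (xk - 2 * p[l]) / w
      }
      cnt <- cnt + 1
    }
    r[j, k] <- if (cnt == 0) NA_real_ else if (j == k) 1 + acc / cnt else acc / cnt
  }
  dimnames(r) <- list(rownames(dosage), rownames(dosage))
  r
}

# additive relatedness by enumeration of all ancestral paths through
# common ancestors: a_ij = sum over common ancestors A and disjoint path
# pairs of (1/2)^(L1+L2) * (1 + F_A)
oracle_path_relatedness <- function(ped, i, j) {
  idx <- function(id) which(ped$id == id)
  parents <- function(id) {
    r <- ped[idx(id), ]
    stats::na.omit(c(r$mother, r$father))
  }
  # all ancestor chains from x up (including x itself), as id vectors
  chains <- function(id) {
    out <- list(id)
    for (p in parents(id))
      out <- c(out, lapply(chains(p), function(ch) c(id, ch)))
    out
  }
  inbreeding <- function(id) {
    pr <- ped[idx(id), ]
    if (is.na(pr$mother) || is.na(pr$father)) return(0)
    oracle_path_relatedness(ped, pr$mother, pr$father) / 2
  }
  if (i == j) return(1 + inbreeding(i))
  ci <- chains(i); cj <- chains(j)
  total <- 0
  for (a in ci) for (b in cj) {
    # valid path pair: same terminal ancestor, no other shared individual
    if (utils::tail(a, 1) != utils::tail(b, 1)) next
    if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
    anc <- utils::tail(a, 1)
    total <- total +
      (1 / 2)^(length(a) - 1 + length(b) - 1) * (1 + inbreeding(anc))
  }
  total
}

# exact two-sided Mann-Whitney p by enumeration of all labelings
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(ix)
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact expectation of the trio Mendelian-incompatibility rate under the
# per-allele flip error channel, by enumeration over genotype combos
oracle_mendel_error_expectation <- function(p_vec, error_rate) {
  flip_kernel <- function(e) {
    # P(observed | true), rows true 0..2, cols observed 0..2
    k <- matrix(0, 3, 3)
    k[1, ] <- stats::dbinom(0:2, 2, e)
    k[3, ] <- rev(stats::dbinom(0:2, 2, e))
    k[2, ] <- c(e * (1 - e), e^2 + (1 - e)^2, e * (1 - e))
    k
  }
  K <- flip_kernel(error_rate)
  incompat <- function(gm, gf, go) {
    lo <- (gm > 1) + (gf > 1); hi <- (gm > 0) + (gf > 0)
    go < lo | go > hi
  }
  per_locus <- vapply(p_vec, function(p) {
    hw <- stats::dbinom(0:2, 2, p)
    tot <- 0
    for (gm in 0:2) for (gf in 0:2) {
      # offspring distribution given true parents
      po <- sapply(0:2, function(go) {
        pm <- c(1 - gm / 2, gm / 2)   # transmitted-allele law
        pf <- c(1 - gf / 2, gf / 2)
        s <- 0
        for (am in 0:1) for (af in 0:1)
          if (am + af == go) s <- s + pm[am + 1] * pf[af + 1]
        s
      })
      for (go in 0:2) {
        pr_true <- hw[gm + 1] * hw[gf + 1] * po[go + 1]
        if (pr_true == 0) next
        for (om in 0:2) for (of in 0:2) for (oo in 0:2) {
          pr_obs <- K[gm + 1, om + 1] * K[gf + 1, of + 1] * K[go + 1, oo + 1]
          if (incompat(om, of, oo))
            tot <- tot + pr_true * pr_obs
        }
      }
    }
    tot
  }, numeric(1))
  mean(per_locus)
}

# marginal log-likelihood of a Bernoulli random-intercept logit model by
# adaptive numeric integration per group
oracle_glmm_loglik <- function(y, X, group, beta, sigma) {
  eta_fix <- as.vector(X %*% beta)
  ll <- 0
  for (g in unique(group)) {
    ix <- group == g
    f <- function(b) {
      sapply(b, function(bi) {
        eta <- eta_fix[ix] + bi
        prod(stats::plogis(eta)^y[ix] * (1 - stats::plogis(eta))^(1 - y[ix])) *
          stats::dnorm(bi, 0, sigma)
      })
    }
    ll <- ll + log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }
  ll
}

# day-set intersection check for fertile-window overlap
oracle_window_overlap <- function(w1, w2) {
  length(intersect(seq(w1[1], w1[2]), seq(w2[1], w2[2]))) > 0
}

# small deterministic genotype fixture
tiny_genotypes <- function(dosage, ids = NULL, loci = NULL) {
  dosage <- as.matrix(dosage)
  rownames(dosage) <- ids %||% paste0("i", seq_len(nrow(dosage)))
  colnames(dosage) <- loci %||% paste0("L", seq_len(ncol(dosage)))
  genotypes(dosage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
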