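# Sex-linked marker discovery and nestling sexing under avian ZW sex
# determination. Males are ZZ (diploid at Z loci), females ZW carry a
# single Z; diploid genotype callers emit the female's one allele as a
# homozygote, so Z-linked loci show female heterozygosity near zero and
# an elevated between-sex FST (the reduced mean heterozygosity inflates
# the among-group variance component of the Weir-Cockerham estimator).

# vectorized two-population Weir-Cockerham theta per locus
.wc_fst <- function(dosage, pop) {
  stopifnot(length(pop) == nrow(dosage))
  pops <- unique(pop)
  stopifnot(length(pops) == 2)
  stats_for <- function(d) {
    called <- !is.na(d)
    n <- colSums(called)
    p <- colSums(d, na.rm = TRUE) / (2 * pmax(n, 1))
    h <- colSums(d == 1, na.rm = TRUE) / pmax(n, 1)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_for(dosage[pop == pops[1], , drop = FALSE])
  s2 <- stats_for(dosage[pop == pops[2], , drop = FALSE])
  r <- 2
  n_bar <- (s1$n + s2$n) / r
  nc <- (r * n_bar - (s1$n^2 + s2$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (s1$n * s1$p + s2$n * s2$p) / (r * n_bar)
  s2v <- (s1$n * (s1$p - p_bar)^2 + s2$n * (s2$p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (s1$n * s1$h + s2$n * s2$h) / (r * n_bar)
  a <- n_bar / nc *
    (s2v - (p_bar * (1 - p_bar) - (r - 1) / r * s2v - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2v - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  theta <- a / (a + b + cc)
  theta[!is.finite(theta)] <- NA_real_
  list(fst = theta, het1 = s1$h, het2 = s2$h)
}

#' Discover sex-linked loci from known-sex adults
#'
#' Screens for markers behaving like Z-linked SNPs. Two signals are
#' combined: (i) a between-sex difference in observed heterozygosity of
#' at least `het_diff_min`, and (ii) a per-locus exact binomial test of
#' female heterozygote deficit — the observed number of heterozygous
#' females against `Binom(n_F, 2 p_F (1 - p_F))`, the count expected
#' were the locus autosomal — at level `female_het_alpha`. Hemizygosity
#' leaves the allele *frequencies* of the sexes equal, so between-sex
#' FST is uninformative for purely Z-polymorphic markers; it is still
#' computed and reported, and `fst_quantile` (default 0, non-gating)
#' can additionally require FST above that empirical quantile for
#' datasets where Z-W gametologous SNPs create genuine between-sex
#' differentiation. A label-permutation p-value of the heterozygosity
#' difference (sex labels shuffled `n_perm` times) is reported per
#' panel locus.
#'
#' @param adults a [genotypes] object restricted to adults.
#' @param known_sex character vector ("M"/"F") aligned to
#'   `rownames(adults$dosage)`, or a named vector of ids.
#' @param het_diff_min minimum |het_M - het_F| (default 0.05; the
#'   deficit test carries the specificity, this floor only removes
#'   uninformative loci).
#' @param female_het_alpha level of the female het-deficit binomial test
#'   (default 1e-4).
#' @param fst_quantile empirical FST quantile a panel locus must exceed;
#'   0 disables the condition (default).
#' @param n_perm label permutations for the per-locus p-value
#'   (default 999).
#' @return A `sex_marker_panel` tibble: `locus`, `het_m`, `het_f`,
#'   `fst`, `het_deficit_p`, `perm_p`. The full per-locus screen is
#'   kept in the `screen` attribute.
#' @export
find_sex_linked_loci <- function(adults, known_sex, het_diff_min = 0.05,
                                 female_het_alpha = 1e-4,
                                 fst_quantile = 0, n_perm = 999) {
  stopifnot(inherits(adults, "genotypes"))
  d <- adults$dosage
  if (!is.null(names(known_sex))) known_sex <- known_sex[rownames(d)]
  known_sex <- as.character(known_sex)
  stopifnot(length(known_sex) == nrow(d))
  keep <- known_sex %in% c("M", "F")
  d <- d[keep, , drop = FALSE]
  sex <- known_sex[keep]
  if (min(table(sex)) < 5) abort("need at least 5 known-sex adults per sex")

  wc <- .wc_fst(d, sex)
  het_m <- if (unique(sex)[1] == "M") wc$het1 else wc$het2
  het_f <- if (unique(sex)[1] == "M") wc$het2 else wc$het1

  df <- d[sex == "F", , drop = FALSE]
  nf <- colSums(!is.na(df))
  pf <- colSums(df, na.rm = TRUE) / (2 * pmax(nf, 1))
  k_het <- colSums(df == 1, na.rm = TRUE)
  het_deficit_p <- stats::pbinom(k_het, nf, 2 * pf * (1 - pf))

  screen <- tibble(
    locus = colnames(d), het_m = unname(het_m), het_f = unname(het_f),
    fst = unname(wc$fst), het_deficit_p = unname(het_deficit_p)
  )
  poly <- !is.na(screen$fst)
  if (!any(poly)) {
    warn("all loci monomorphic: empty panel")
    panel <- screen[0, ]
    panel$perm_p <- double()
    attr(panel, "screen") <- screen
    class(panel) <- c("sex_marker_panel", class(panel))
    return(panel)
  }
  sel <- poly &
    abs(screen$het_m - screen$het_f) >= het_diff_min &
    screen$het_deficit_p <= female_het_alpha
  if (fst_quantile > 0) {
    cut_fst <- quantile(screen$fst, fst_quantile, na.rm = TRUE, names = FALSE)
    sel <- sel & screen$fst > cut_fst
  }
  panel <- screen[sel, , drop = FALSE]

  if (nrow(panel)) {
    dp <- d[, panel$locus, drop = FALSE]
    obs <- abs(panel$het_m - panel$het_f)
    het_by <- function(lab) {
      h1 <- colMeans(dp[lab == "M", , drop = FALSE] == 1, na.rm = TRUE)
      h2 <- colMeans(dp[lab == "F", , drop = FALSE] == 1, na.rm = TRUE)
      abs(h1 - h2)
    }
    ge <- rep(1L, nrow(panel))   # permutation p includes the observed label
    for (b in seq_len(n_perm)) {
      ge <- ge + as.integer(het_by(sample(sex)) >= obs)
    }
    panel$perm_p <- ge / (n_perm + 1)
  } else {
    panel$perm_p <- double()
  }
  attr(panel, "screen") <- screen
  class(panel) <- c("sex_marker_panel", class(panel))
  panel
}

# per-sex genotype-frequency naive Bayes with add-one smoothing
.nb_train <- function(dosage, sex, loci) {
  d <- dosage[, loci, drop = FALSE]
  lapply(c(M = "M", F = "F"), function(s) {
    ds <- d[sex == s, , drop = FALSE]
    counts <- matrix(
      vapply(0:2, function(gv) colSums(ds == gv, na.rm = TRUE),
             numeric(ncol(ds))),
      ncol = 3
    )
    freq <- (counts + 1) / (rowSums(counts) + 3)   # loci x genotypes
    log(freq)
  })
}

.nb_posterior <- function(model, dosage, loci, prior = c(M = 0.5, F = 0.5)) {
  d <- dosage[, loci, drop = FALSE]
  score <- function(lf) {
    s <- rep(log(1), nrow(d))
    for (k in seq_along(loci)) {
      gk <- d[, k]
      ok <- !is.na(gk)
      s[ok] <- s[ok] + lf[k, gk[ok] + 1]
    }
    s
  }
  lm_ <- score(model$M) + log(prior["M"])
  lf_ <- score(model$F) + log(prior["F"])
  n_used <- rowSums(!is.na(d))
  post_m <- 1 / (1 + exp(lf_ - lm_))
  tibble(
    id = rownames(d),
    sex = dplyr::if_else(n_used == 0, NA_character_,
                         dplyr::if_else(post_m >= 0.5, "M", "F")),
    posterior = dplyr::if_else(n_used == 0, NA_real_, pmax(post_m, 1 - post_m)),
    n_loci_used = n_used
  )
}

#' Assign sex to nestlings from a sex-marker panel
#'
#' Trains a per-sex genotype-frequency naive Bayes classifier (add-one
#' smoothing, equal priors) on known-sex adults at the panel loci, then
#' assigns each nestling the higher-posterior sex. Monte-Carlo
#' cross-validation — `n_mc_splits` random 70/30 train/test splits of the
#' adults — reports the expected assignment accuracy.
#'
#' @param panel a `sex_marker_panel` from [find_sex_linked_loci()] (or a
#'   character vector of locus ids).
#' @param adults a [genotypes] object of known-sex adults.
#' @param known_sex "M"/"F" vector aligned to the adults (or named by id).
#' @param nestlings a [genotypes] object of individuals to sex.
#' @param n_mc_splits number of Monte-Carlo splits (default 100).
#' @param seed integer seed for the split generator.
#' @return A `sex_assignment` list: `assignments` tibble (`id`, `sex`,
#'   `posterior`, `n_loci_used`; `sex` is `NA` when every panel locus is
#'   missing), `cv_accuracy` (mean over splits), `cv_accuracies`, `panel`.
#' @export
assign_sex <- function(panel, adults, known_sex, nestlings,
                       n_mc_splits = 100, seed = 1L) {
  loci <- if (inherits(panel, "sex_marker_panel")) panel$locus else panel
  if (!length(loci)) abort("empty sex-marker panel")
  stopifnot(inherits(adults, "genotypes"), inherits(nestlings, "genotypes"))
  loci <- intersect(loci, colnames(adults$dosage))
  loci <- intersect(loci, colnames(nestlings$dosage))
  if (!length(loci)) abort("no panel loci present in both genotype sets")
  d <- adults$dosage
  if (!is.null(names(known_sex))) known_sex <- known_sex[rownames(d)]
  known_sex <- as.character(known_sex)
  keep <- known_sex %in% c("M", "F")
  d <- d[keep, , drop = FALSE]
  sex <- known_sex[keep]

  model <- .nb_train(d, sex, loci)
  assignments <- .nb_posterior(model, nestlings$dosage, loci)

  set.seed(seed)
  acc <- vapply(seq_len(n_mc_splits), function(b) {
    test <- sample(nrow(d), size = max(1, round(0.3 * nrow(d))))
    m_b <- .nb_train(d[-test, , drop = FALSE], sex[-test], loci)
    pred <- .nb_posterior(m_b, d[test, , drop = FALSE], loci)
    mean(pred$sex == sex[test], na.rm = TRUE)
  }, numeric(1))

  structure(
    list(assignments = assignments, cv_accuracy = mean(acc),
         cv_accuracies = acc, panel = loci),
    class = "sex_assignment"
  )
}

#' @export
print.sex_assignment <- function(x, ...) {
  cat(sprintf(
    "<sex_assignment> %d individuals sexed (%d M / %d F), MC-CV accuracy %.3f over %d panel loci\n",
    sum(!is.na(x$assignments$sex)),
    sum(x$assignments$sex == "M", na.rm = TRUE),
    sum(x$assignments$sex == "F", na.rm = TRUE),
    x$cv_accuracy, length(x$panel)
  ))
  invisible(x)
}
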