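#' Fit the promiscuity model battery
#'
#' Applies the analysis filters and fits, per species, the three model
#' families relating extra-pair paternity to breeding density and
#' synchrony:
#'
#' * **Occurrence models** (nest level, Bernoulli): extra-pair paternity
#'   present in the brood (0/1) on cavity type, laying date, clutch size
#'   and one spatiotemporal covariate at a time — nearest-neighbor
#'   distance (model a), neighbor density (model b), synchronous
#'   neighbor density (model c) — with mother identity as random
#'   intercept, falling back to a GLM on convergence failure.
#' * **Proportion models** (nest level, binomial): extra-pair offspring
#'   over sampled offspring with paternity calls, same predictors and
#'   random term.
#' * **Individual-level models** (Bernoulli, nest random intercept):
#'   extra-pair status on cavity type, year, sex, laying date, clutch
#'   size and body index (scaled mass index), with a cavity x sex
#'   interaction that is dropped when its p-value exceeds 0.05; and
#'   fledging success with extra-pair status as an additional predictor.
#'
#' Filters: first clutches only; proportion models exclude nests whose
#' social father was not sampled and nests where less than half the
#' clutch was sampled; spatiotemporal covariates are z-scaled within the
#' modeling dataset (absorbing between-year differences). Numeric
#' covariates (laying date, clutch size, body index) are z-scaled too so
#' estimates are on comparable scales.
#'
#' @param nests per-nest table (from [call_parentage()]`$nests` joined
#'   with records): needs `nest_id`, `species`, `cavity_type`,
#'   `mother_id`, `first_clutch`, `laying_date`, `clutch_size`,
#'   `father_sampled`, `epp_positive`, `n_offspring_calls`, `n_epo`.
#' @param metrics [spatiotemporal_metrics()] output; the first
#'   `nd_*`/`snd_*` columns (base radius) are used.
#' @param offspring optional per-nestling table for the individual-level
#'   models: `id`, `nest_id`, `epo`, `sex`, `fledged`, `mass`, `tarsus`.
#'   Skipped when `NULL`.
#' @param drop_interaction_p threshold above which the cavity x sex
#'   interaction is removed (default 0.05).
#' @return An `epp_model_report`: tibble with one row per term
#'   (`level`, `response`, `model`, `term`, `estimate`, `std_error`,
#'   `p_lrt`, `fit_note`, `n`), plus a `filters` attribute recording the
#'   rows each filter removed.
#' @export
fit_epp_models <- function(nests, metrics, offspring = NULL,
                             drop_interaction_p = 0.05) {
  metrics <- as_tibble(metrics)
  nests <- as_tibble(nests)
  # metrics take precedence over any like-named columns in the nest table
  dup <- setdiff(intersect(names(nests), names(metrics)), "nest_id")
  nests <- nests %>% select(-dplyr::all_of(dup)) %>%
    left_join(metrics, by = "nest_id")
  nd_col <- grep("^nd_", names(nests), value = TRUE)[1]
  snd_col <- grep("^snd_", names(nests), value = TRUE)[1]
  if (is.na(nd_col)) abort("metrics must contain nd_*/snd_* columns")

  filters <- list()
  n0 <- nrow(nests)
  nests <- nests %>% filter(.data$first_clutch)
  filters$not_first_clutch <- n0 - nrow(nests)
  if (!nrow(nests)) abort("filter `first_clutch` removed every nest")

  scale_covs <- function(d) {
    d %>% mutate(
      nnd_z = zscale(.data$nnd, "nearest neighbor distance"),
      nd_z = zscale(.data[[nd_col]], "neighbor density"),
      snd_z = zscale(.data[[snd_col]], "synchronous neighbor density"),
      laying_z = zscale(.data$laying_date, "laying date"),
      clutch_z = zscale(.data$clutch_size, "clutch size"),
      cavity_type = factor(.data$cavity_type, c("natural", "nestbox"))
    )
  }

  spatio <- c(a = "nnd_z", b = "nd_z", c = "snd_z")
  rows <- list()

  fit_family <- function(d, lhs, level, response, weights = NULL) {
    if (lhs == "epp01" && length(unique(d$epp01)) < 2)
      abort("occurrence response has no variance: cannot fit occurrence models")
    purrr::imap(spatio, function(cov, mdl) {
      f <- as.formula(paste(
        lhs, "~", cov, "+ cavity_type + laying_z + clutch_z + (1 | mother_id)"
      ))
      fit <- glmm_binomial(d, f)
      note <- if (fit$random_term_dropped) "GLM fallback" else "GLMM"
      tidy(fit) %>%
        mutate(level = level, response = response, model = mdl,
               fit_note = note, n = fit$n)
    }) %>% bind_rows()
  }

  # --- occurrence models (all first-clutch nests with paternity info) ---
  # paternity information exists if the father was genotyped or the brood
  # is large enough for sibling evidence
  occ <- nests %>%
    filter(.data$father_sampled | .data$n_genotyped_offspring >= 2) %>%
    mutate(epp01 = as.integer(.data$epp_positive)) %>%
    scale_covs()
  rows$occurrence <- fit_family(occ, "epp01", "nest", "epp_occurrence")

  # --- proportion models ------------------------------------------------
  prop <- nests %>% filter(.data$father_sampled)
  filters$father_unsampled <- nrow(nests) - nrow(prop)
  n1 <- nrow(prop)
  prop <- prop %>%
    filter(.data$n_offspring_calls >= 0.5 * .data$clutch_size)
  filters$under_half_sampled <- n1 - nrow(prop)
  if (nrow(prop) >= 8) {
    prop <- prop %>% scale_covs() %>%
      mutate(n_wpo = .data$n_offspring_calls - .data$n_epo)
    rows$proportion <- purrr::imap(spatio, function(cov, mdl) {
      f <- as.formula(paste(
        "cbind(n_epo, n_wpo) ~", cov,
        "+ cavity_type + laying_z + clutch_z + (1 | mother_id)"
      ))
      fit <- glmm_binomial(prop, f)
      note <- if (fit$random_term_dropped) "GLM fallback" else "GLMM"
      tidy(fit) %>%
        mutate(level = "nest", response = "epo_proportion", model = mdl,
               fit_note = note, n = fit$n)
    }) %>% bind_rows()
  }

  # --- individual level -------------------------------------------------
  if (!is.null(offspring)) {
    ind <- as_tibble(offspring) %>%
      left_join(nests %>% select("nest_id", "cavity_type", "year",
                                 "laying_date", "clutch_size"),
                by = "nest_id") %>%
      filter(!is.na(.data$epo), !is.na(.data$cavity_type))
    if (nrow(ind) >= 20) {
      smi <- scaled_mass_index(ind$mass, ind$tarsus)
      ind <- ind %>% mutate(
        body_z = zscale(as.numeric(smi), "body index"),
        laying_z = zscale(.data$laying_date, "laying date"),
        clutch_z = zscale(.data$clutch_size, "clutch size"),
        cavity_type = factor(.data$cavity_type, c("natural", "nestbox")),
        sex = factor(.data$sex, c("F", "M")),
        year_f = factor(.data$year),
        epo01 = as.integer(.data$epo)
      )
      base <- "cavity_type + sex + laying_z + clutch_z + body_z"
      if (nlevels(droplevels(ind$year_f)) > 1) base <- paste(base, "+ year_f")
      f_int <- as.formula(paste(
        "epo01 ~", base, "+ cavity_type:sex + (1 | nest_id)"))
      fit <- glmm_binomial(ind, f_int)
      td <- tidy(fit)
      int_p <- td$p_lrt[grepl(":", td$term)]
      if (length(int_p) && (is.na(int_p) || int_p > drop_interaction_p)) {
        f_noint <- as.formula(paste("epo01 ~", base, "+ (1 | nest_id)"))
        fit <- glmm_binomial(ind, f_noint)
        td <- tidy(fit)
      }
      rows$individual <- td %>%
        mutate(level = "individual", response = "ep_status", model = "d",
               fit_note = if (fit$random_term_dropped) "GLM fallback" else "GLMM",
               n = fit$n)
      if (length(unique(na.omit(ind$fledged))) > 1) {
        f_fl <- as.formula(paste(
          "fledged ~ epo01 +", base, "+ (1 | nest_id)"))
        fitf <- glmm_binomial(ind, f_fl)
        rows$fledging <- tidy(fitf) %>%
          mutate(level = "individual", response = "fledged", model = "e",
                 fit_note = if (fitf$random_term_dropped) "GLM fallback" else "GLMM",
                 n = fitf$n)
      }
    }
  }

  out <- bind_rows(rows) %>%
    select("level", "response", "model", "term", "estimate",
           std_error = "std_error", "p_lrt", "fit_note", "n")
  attr(out, "filters") <- filters
  structure(out, class = c("epp_model_report", class(out)))
}
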