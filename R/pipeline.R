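#' Run the full inference chain end-to-end
#'
#' QC -> genomic relatedness -> social pedigree -> parentage
#' classification -> sexing -> spatiotemporal metrics -> model battery,
#' on a simulated population (or on externally supplied inputs shaped
#' the same way). Deterministic given the simulation seed.
#'
#' @param sim an `epp_simulation` from [simulate_population()], or a
#'   list with the same components (`genotypes`, `records`, `nestlings`,
#'   `pedigree`).
#' @param call_rate_threshold QC threshold passed to
#'   [filter_call_rate()].
#' @param thresholds an [epp_thresholds()] list.
#' @param radii optional radii override; by default derived from the
#'   observed extra-pair-father link distances via [derive_radii()],
#'   falling back to the species defaults.
#' @param fit_models fit the GLM/GLMM battery (default `TRUE`).
#' @param n_mc_splits Monte-Carlo splits for sexing cross-validation.
#' @return An `epp_run_report` list: `qc` (removal report), `grm`,
#'   `calls`, `summary`, `sexing`, `metrics`, `radii`, `models` (or
#'   `NULL`), and a `ledger` tibble of per-stage record counts.
#' @export
run_pipeline <- function(sim, call_rate_threshold = 0.7,
                         thresholds = epp_thresholds(), radii = NULL,
                         fit_models = TRUE, n_mc_splits = 50) {
  ledger <- list()
  note <- function(stage, n_in, n_out)
    ledger[[length(ledger) + 1L]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out, n_removed = n_in - n_out)

  g0 <- sim$genotypes
  g <- filter_call_rate(g0, call_rate_threshold)
  note("qc_call_rate", nrow(g0$dosage), nrow(g$dosage))

  grm <- grm_gcta(g)
  note("grm", nrow(g$dosage), length(grm$ids))

  ped <- sim$pedigree %||%
    build_pedigree(sim$records, sim$nestlings[, c("id", "nest_id")])

  calls <- call_parentage(grm, ped, sim$records, thresholds = thresholds)
  note("parentage", length(grm$ids), nrow(calls$father_offspring))

  summary <- summarize_epp(calls$nests)

  # sexing: adults of known sex train, nestlings are assigned
  meta <- g$meta
  adults <- subset_genotypes(g, meta$id[meta$stage == "adult"])
  nestl <- subset_genotypes(g, meta$id[meta$stage == "nestling"])
  sexing <- tryCatch({
    panel <- find_sex_linked_loci(
      adults, setNames(adults$meta$sex, adults$meta$id))
    if (nrow(panel) == 0) NULL else
      assign_sex(panel, adults, setNames(adults$meta$sex, adults$meta$id),
                 nestl, n_mc_splits = n_mc_splits,
                 seed = sim$config$seed %||% 1L)
  }, error = function(e) {
    warn(paste("sexing stage skipped:", conditionMessage(e)))
    NULL
  })

  # radii from observed EPF links, species default as fallback
  sp <- species_params(sim$records$species[1])
  link_d <- epf_link_distances(calls$epf_links, ped, sim$records)$distance
  radii <- radii %||% suppressWarnings(
    derive_radii(link_d, sp$multipliers,
                 fallback = sp$base_radius * sp$multipliers))
  metrics <- spatiotemporal_metrics(sim$records, radii = radii)
  note("spatiotemporal", nrow(sim$records), nrow(metrics))

  # cavity-type comparison of each metric (rank-sum tests)
  met_rec <- metrics %>%
    left_join(sim$records %>% select("nest_id", "cavity_type"),
              by = "nest_id")
  spatial_tests <- purrr::map(
    setdiff(names(metrics), "nest_id"),
    function(col) {
      x <- met_rec[[col]][met_rec$cavity_type == "natural"]
      y <- met_rec[[col]][met_rec$cavity_type == "nestbox"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NULL)
      suppressWarnings(mann_whitney_u(x, y)) %>%
        mutate(metric = col,
               median_natural = median(x), median_nestbox = median(y))
    }
  ) %>% bind_rows()

  models <- NULL
  if (fit_models) {
    offspring <- sim$nestlings %>%
      left_join(calls$offspring %>% select("id", "epo"), by = "id")
    models <- fit_epp_models(calls$nests, metrics, offspring)
  }

  structure(
    list(qc = attr(g, "call_rate_report"), grm = grm, calls = calls,
         summary = summary, sexing = sexing, metrics = metrics,
         spatial_tests = spatial_tests, radii = radii, models = models,
         ledger = bind_rows(ledger)),
    class = "epp_run_report"
  )
}

#' @export
print.epp_run_report <- function(x, ...) {
  cat("<epp_run_report>\n")
  print(x$ledger)
  print(x$summary)
  invisible(x)
}

#' Label-encoded fixture of the published field outcome
#'
#' A small per-nest dataset encoding, as labels rather than genotypes,
#' the observed extra-pair-paternity outcome of the two-species,
#' two-plot field study: blue tits with 30 natural-cavity broods (11
#' extra-pair-positive) and 37 nestbox broods (17 positive), 197 and 237
#' nestlings with paternity calls of which 16 and 28 were extra-pair;
#' great tits with 32/26 broods (12/16 positive) and 179/189 nestlings
#' (20/30 extra-pair); per species, 25 cuckolded fathers plus 3
#' half-sibling-evidence nests with unsampled fathers; one
#' brood-parasitism case (blue tit). Encoding outcomes as labels lets
#' the summary and test layers be exercised independently of the
#' genotype layer.
#'
#' @return Tibble shaped like [call_parentage()]`$nests` (columns
#'   `nest_id`, `species`, `cavity_type`, `father_sampled`,
#'   `halfsib_evidence`, `epp_positive`, `n_offspring_calls`, `n_epo`,
#'   `parasitized`).
#' @export
make_field_fixture <- function() {
  cells_def <- list(
    #          species    cavity     broods epp+  offspring epo  halfsib
    list("bluetit", "natural", 30L, 11L, 197L, 16L, 1L),
    list("bluetit", "nestbox", 37L, 17L, 237L, 28L, 2L),
    list("greattit", "natural", 32L, 12L, 179L, 20L, 1L),
    list("greattit", "nestbox", 26L, 16L, 189L, 30L, 2L)
  )
  cells <- purrr::map(cells_def, function(s) {
    names(s) <- c("species", "cavity", "n_broods", "n_epp", "n_off", "n_epo",
                  "n_halfsib")
    n_sampled <- s$n_broods - s$n_halfsib          # father-genotyped nests
    n_cuckold <- s$n_epp - s$n_halfsib             # epp+ via direct calls
    # spread offspring evenly over father-sampled nests, EPO over the
    # cuckolded ones (>= 1 each)
    off_per_nest <- rep(s$n_off %/% n_sampled, n_sampled)
    rem <- s$n_off %% n_sampled
    if (rem) off_per_nest[seq_len(rem)] <- off_per_nest[seq_len(rem)] + 1L
    epo_per_nest <- integer(n_sampled)
    epo_per_nest[seq_len(n_cuckold)] <- 1L
    extra <- s$n_epo - n_cuckold
    k <- 1L
    while (extra > 0L) {  # never let a brood be entirely extra-pair
      if (epo_per_nest[k] < off_per_nest[k] - 1L) {
        epo_per_nest[k] <- epo_per_nest[k] + 1L
        extra <- extra - 1L
      } else k <- k + 1L
      if (k > n_cuckold) k <- 1L
    }
    tibble(
      nest_id = sprintf("%s_%s_%02d", s$species, s$cavity,
                        seq_len(s$n_broods)),
      species = s$species, cavity_type = s$cavity,
      father_sampled = c(rep(TRUE, n_sampled), rep(FALSE, s$n_halfsib)),
      halfsib_evidence = c(rep(FALSE, n_sampled), rep(TRUE, s$n_halfsib)),
      n_offspring_calls = c(off_per_nest, rep(0L, s$n_halfsib)),
      n_epo = c(epo_per_nest, rep(0L, s$n_halfsib))
    )
  }) %>% bind_rows() %>%
    mutate(
      epp_positive = dplyr::if_else(.data$father_sampled, .data$n_epo > 0,
                                    .data$halfsib_evidence),
      parasitized = .data$nest_id == "bluetit_natural_01"
    )
  cells
}

#' Consistency checks on a nest-level call table
#'
#' Verifies the accounting identities of the summary layer: per species,
#' extra-pair-positive broods equal cuckolded-father nests plus
#' half-sibling-evidence nests, and extra-pair offspring never exceed
#' offspring with calls in any nest.
#'
#' @param nests nest-level call tibble.
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
check_epp_consistency <- function(nests) {
  nests <- as_tibble(nests)
  bad <- nests$n_epo > nests$n_offspring_calls
  if (any(bad)) abort("nest with more extra-pair offspring than calls")
  by_sp <- nests %>%
    group_by(.data$species) %>%
    summarise(
      epp_broods = sum(.data$epp_positive),
      cuckolded = sum(.data$father_sampled & .data$n_epo > 0),
      halfsib = sum(!.data$father_sampled & .data$halfsib_evidence),
      .groups = "drop"
    )
  if (!all(by_sp$epp_broods == by_sp$cuckolded + by_sp$halfsib))
    abort("EPP-positive broods != cuckolded fathers + half-sib nests")
  invisible(TRUE)
}

#' Chi-square battery on an EPP summary
#'
#' The four plot-level 2x2 tests: per species, extra-pair vs within-pair
#' broods by cavity type, and extra-pair vs within-pair offspring by
#' cavity type (Yates correction on).
#'
#' @param summary an `epp_summary` from [summarize_epp()].
#' @return Tibble with `species`, `level`, `statistic`, `df`, `p_value`.
#' @export
epp_chisq_battery <- function(summary) {
  purrr::map(split(summary, summary$species), function(s) {
    s <- s[order(s$cavity_type), ]   # natural first
    bind_rows(
      chi_square_2x2(s$n_epp_broods[1], s$n_broods[1] - s$n_epp_broods[1],
                     s$n_epp_broods[2], s$n_broods[2] - s$n_epp_broods[2]) %>%
        mutate(species = s$species[1], level = "broods"),
      chi_square_2x2(s$n_epo[1], s$n_offspring[1] - s$n_epo[1],
                     s$n_epo[2], s$n_offspring[2] - s$n_epo[2]) %>%
        mutate(species = s$species[1], level = "offspring")
    )
  }) %>% bind_rows() %>%
    select("species", "level", "statistic", "df", "p_value", "n")
}
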