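#' Classification thresholds for relatedness bands
#'
#' The genomic relatedness of a father-offspring pair with a social link
#' (expected additive relatedness 0.5) is classified as within-pair above
#' `within_pair_min`, extra-pair below `extra_pair_max`, and ambiguous in
#' between (the band where the two printed cutoffs leave a gap). Within a
#' brood, sibling pairs between `extra_pair_max` and `within_pair_min`
#' are half-siblings; above `within_pair_min`, full siblings. A nestling
#' below `parasite_max` to every genotyped social parent and sibling is a
#' brood-parasitism call. Adult males above `epf_min` to offspring they
#' have no social link to are extra-pair-father candidates. All
#' comparisons are strict inequalities; boundary values fall into the
#' ambiguous/negative class.
#'
#' @param within_pair_min,extra_pair_max,parasite_max,epf_min numeric
#'   cutoffs; defaults 0.35, 0.15, 0.1, 0.35.
#' @return A named list of class `epp_thresholds`.
#' @export
epp_thresholds <- function(within_pair_min = 0.35, extra_pair_max = 0.15,
                           parasite_max = 0.1, epf_min = 0.35) {
  if (!(parasite_max <= extra_pair_max && extra_pair_max < within_pair_min))
    abort("need parasite_max <= extra_pair_max < within_pair_min")
  structure(
    list(within_pair_min = within_pair_min, extra_pair_max = extra_pair_max,
         parasite_max = parasite_max, epf_min = epf_min),
    class = "epp_thresholds"
  )
}

.g_lookup <- function(grm, i, j) grm$r[cbind(match(i, grm$ids), match(j, grm$ids))]

#' Classify social father-offspring pairs
#'
#' Every offspring whose social father is genotyped gets one call:
#' `within_pair` when its genomic relatedness to the father exceeds
#' `within_pair_min`, `extra_pair` below `extra_pair_max`, otherwise
#' `ambiguous` (reported but excluded from extra-pair counts). Offspring
#' whose social father is not genotyped are skipped here; their nests are
#' assessed via sibling evidence (see [classify_sibling_pairs()]).
#'
#' @param grm a `grm` object from [grm_gcta()].
#' @param ped a `social_pedigree`.
#' @param thresholds an [epp_thresholds()] list.
#' @return Tibble `offspring`, `father`, `nest`, `g`, `class`.
#' @export
classify_father_offspring <- function(grm, ped, thresholds = epp_thresholds()) {
  off <- ped %>%
    filter(!is.na(.data$father), .data$id %in% grm$ids,
           .data$father %in% grm$ids)
  g <- .g_lookup(grm, off$id, off$father)
  tibble(
    offspring = off$id, father = off$father, nest = off$natal_nest, g = g,
    class = dplyr::case_when(
      is.na(g) ~ "ambiguous",
      g > thresholds$within_pair_min ~ "within_pair",
      g < thresholds$extra_pair_max ~ "extra_pair",
      TRUE ~ "ambiguous"
    )
  )
}

#' Identify extra-pair fathers
#'
#' Adult males with genomic relatedness above `epf_min` to offspring they
#' have no social-pedigree relationship to (expected relatedness 0) are
#' linked as that offspring's extra-pair father. Candidates whose high
#' relatedness is explained by the pedigree instead — e.g. a full brother
#' of the offspring ringed in a previous cohort (expected relatedness
#' 0.5) — are removed as false positives and reported in the
#' `false_positives` attribute.
#'
#' @param grm a `grm` object.
#' @param ped a `social_pedigree`.
#' @param adult_males character vector of genotyped adult male ids.
#' @param thresholds an [epp_thresholds()] list.
#' @return Tibble `male`, `offspring`, `g` of retained links.
#' @export
find_extra_pair_fathers <- function(grm, ped, adult_males,
                                    thresholds = epp_thresholds()) {
  adult_males <- intersect(adult_males, grm$ids)
  off <- ped %>% filter(!is.na(.data$natal_nest), .data$id %in% grm$ids)
  if (!length(adult_males) || !nrow(off)) {
    out <- tibble(male = character(), offspring = character(), g = double())
    attr(out, "false_positives") <- out
    return(out)
  }
  A <- social_relatedness_matrix(ped, union(adult_males, off$id))
  pairs <- tidyr::expand_grid(male = adult_males, offspring = off$id) %>%
    filter(.data$male != .data$offspring)
  pairs$g <- .g_lookup(grm, pairs$male, pairs$offspring)
  pairs$a <- A[cbind(match(pairs$male, rownames(A)),
                     match(pairs$offspring, rownames(A)))]
  # exclude the social father himself: his pair is classified elsewhere
  fa <- setNames(ped$father, ped$id)
  pairs <- pairs %>%
    filter(!is.na(.data$g), .data$g > thresholds$epf_min,
           .data$male != dplyr::coalesce(fa[.data$offspring], ""))
  fp <- pairs %>% filter(.data$a > 0)
  out <- pairs %>% filter(.data$a == 0) %>% select("male", "offspring", "g")
  attr(out, "false_positives") <- fp %>% select("male", "offspring", "g", "a")
  out
}

#' Classify within-nest sibling pairs
#'
#' Nest-mate pairs (social expectation: full siblings, relatedness 0.5)
#' are called `full` above `within_pair_min`, `half` between
#' `extra_pair_max` and `within_pair_min` (evidence of multiple sires in
#' the brood), and `unrelated_flag` below `extra_pair_max` (which feeds
#' the brood-parasitism check).
#'
#' @inheritParams classify_father_offspring
#' @return Tibble `id1`, `id2`, `nest`, `g`, `class`; empty for
#'   singleton broods.
#' @export
classify_sibling_pairs <- function(grm, ped, thresholds = epp_thresholds()) {
  off <- ped %>% filter(!is.na(.data$natal_nest), .data$id %in% grm$ids)
  by_nest <- split(off$id, off$natal_nest)
  pairs <- purrr::map(names(by_nest), function(nst) {
    ids <- by_nest[[nst]]
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(sort(ids), 2)
    tibble(id1 = cmb[1, ], id2 = cmb[2, ], nest = nst)
  }) %>% bind_rows()
  if (!nrow(pairs))
    return(tibble(id1 = character(), id2 = character(), nest = character(),
                  g = double(), class = character()))
  pairs$g <- .g_lookup(grm, pairs$id1, pairs$id2)
  pairs %>% mutate(class = dplyr::case_when(
    is.na(.data$g) ~ "ambiguous",
    .data$g > thresholds$within_pair_min ~ "full",
    .data$g > thresholds$extra_pair_max ~ "half",
    TRUE ~ "unrelated_flag"
  ))
}

#' Detect brood parasitism
#'
#' A nestling whose genomic relatedness falls below `parasite_max` to
#' *every* genotyped social parent *and* every genotyped nest-mate cannot
#' belong to either attending adult: it was laid by a foreign female.
#' Nestlings with no genotyped relatives at all are unclassifiable and
#' listed in the `unclassifiable` attribute.
#'
#' @inheritParams classify_father_offspring
#' @return Tibble `offspring`, `nest`, `max_g` for parasite calls.
#' @export
detect_brood_parasitism <- function(grm, ped, thresholds = epp_thresholds()) {
  off <- ped %>% filter(!is.na(.data$natal_nest), .data$id %in% grm$ids)
  sib_by_nest <- split(off$id, off$natal_nest)
  res <- purrr::pmap(
    list(off$id, off$mother, off$father, off$natal_nest),
    function(id, mo, fa, nst) {
      rel <- c(
        if (!is.na(mo) && mo %in% grm$ids) mo,
        if (!is.na(fa) && fa %in% grm$ids) fa,
        setdiff(sib_by_nest[[nst]], id)
      )
      if (!length(rel)) return(tibble(offspring = id, nest = nst,
                                      max_g = NA_real_, status = "unclassifiable"))
      gmax <- max(.g_lookup(grm, rep(id, length(rel)), rel), na.rm = TRUE)
      tibble(offspring = id, nest = nst, max_g = gmax,
             status = if (gmax < thresholds$parasite_max) "parasite" else "ok")
    }
  ) %>% bind_rows()
  out <- res %>% filter(.data$status == "parasite") %>%
    select("offspring", "nest", "max_g")
  attr(out, "unclassifiable") <- res %>%
    filter(.data$status == "unclassifiable") %>% select("offspring", "nest")
  out
}

#' Full parentage call set
#'
#' Runs the four classification passes and assembles per-offspring and
#' per-nest tables. A nest whose social father is genotyped is
#' extra-pair-positive when at least one offspring is called extra-pair;
#' a nest with an unsampled father is extra-pair-positive when its brood
#' contains a half-sibling pair (multiple sires). Ambiguous
#' father-offspring calls are excluded from both numerator and
#' denominator of offspring-level rates.
#'
#' @inheritParams classify_father_offspring
#' @param records nest-record tibble (`nest_id`, `species`, `cavity_type`,
#'   `plot`, `year`, `mother_id`, `father_id`, ...).
#' @param adult_males genotyped adult male ids for the extra-pair-father
#'   search; defaults to the genotyped social fathers in `records`.
#' @return A `parentage_calls` list with tibbles `father_offspring`,
#'   `sibling_pairs`, `epf_links`, `parasites`, `offspring`, `nests`.
#' @export
call_parentage <- function(grm, ped, records, adult_males = NULL,
                           thresholds = epp_thresholds()) {
  records <- as_tibble(records)
  if (is.null(adult_males))
    adult_males <- intersect(unique(na.omit(records$father_id)), grm$ids)
  fo <- classify_father_offspring(grm, ped, thresholds)
  sib <- classify_sibling_pairs(grm, ped, thresholds)
  epf <- find_extra_pair_fathers(grm, ped, adult_males, thresholds)
  par <- detect_brood_parasitism(grm, ped, thresholds)

  off <- ped %>% filter(!is.na(.data$natal_nest), .data$id %in% grm$ids) %>%
    select(id = "id", nest = "natal_nest")
  off <- off %>%
    left_join(fo %>% select(id = "offspring", "class"), by = "id") %>%
    mutate(
      parasite = .data$id %in% par$offspring,
      # a brood parasite is not the social pair's offspring at all, so it
      # enters neither the extra-pair numerator nor the denominator
      epo = dplyr::case_when(
        .data$parasite ~ NA,
        .data$class == "extra_pair" ~ TRUE,
        .data$class == "within_pair" ~ FALSE,
        TRUE ~ NA               # ambiguous or father unsampled
      )
    )

  halfsib_nests <- unique(sib$nest[sib$class == "half"])
  nests <- records %>%
    mutate(father_sampled = !is.na(.data$father_id) &
             .data$father_id %in% grm$ids) %>%
    left_join(
      off %>% group_by(.data$nest) %>%
        summarise(
          n_genotyped_offspring = n(),
          n_offspring_calls = sum(!is.na(.data$epo)),
          n_epo = sum(.data$epo, na.rm = TRUE),
          n_ambiguous = sum(is.na(.data$epo)),
          .groups = "drop"
        ),
      by = c(nest_id = "nest")
    ) %>%
    mutate(
      across(c("n_genotyped_offspring", "n_offspring_calls", "n_epo",
               "n_ambiguous"),
             ~ dplyr::coalesce(.x, 0L)),
      halfsib_evidence = .data$nest_id %in% halfsib_nests,
      epp_positive = dplyr::if_else(
        .data$father_sampled, .data$n_epo > 0, .data$halfsib_evidence
      ),
      epo_prop = dplyr::if_else(
        .data$father_sampled & .data$n_offspring_calls > 0,
        .data$n_epo / .data$n_offspring_calls, NA_real_
      )
    )

  structure(
    list(father_offspring = fo, sibling_pairs = sib, epf_links = epf,
         parasites = par, offspring = off, nests = nests),
    class = "parentage_calls"
  )
}

#' @export
print.parentage_calls <- function(x, ...) {
  cat(sprintf(
    "<parentage_calls> %d father-offspring pairs (%d extra-pair), %d EPF links, %d parasites\n",
    nrow(x$father_offspring),
    sum(x$father_offspring$class == "extra_pair"),
    nrow(x$epf_links), nrow(x$parasites)
  ))
  invisible(x)
}

#' Summarize extra-pair paternity by species and cavity type
#'
#' Brood level: nests with at least one extra-pair offspring (or, for
#' unsampled-father nests, half-sibling evidence) over nests with
#' paternity information. Offspring level: extra-pair offspring over
#' offspring with a father-offspring call (unsampled-father nests
#' contribute no offspring to this rate). Percentages are rounded to the
#' nearest integer for report parity.
#'
#' @param nests per-nest call tibble — either `calls$nests` from
#'   [call_parentage()] or a label-encoded fixture from
#'   [make_field_fixture()]. Needs columns `species`, `cavity_type`,
#'   `father_sampled`, `epp_positive`, `n_offspring_calls`, `n_epo`.
#' @return An `epp_summary` tibble, one row per species x cavity type:
#'   brood and offspring counts and integer percentages.
#' @export
summarize_epp <- function(nests) {
  nests <- as_tibble(nests)
  if (!nrow(nests)) {
    warn("empty call set: returning empty summary")
    return(structure(tibble(), class = c("epp_summary", class(tibble()))))
  }
  out <- nests %>%
    group_by(.data$species, .data$cavity_type) %>%
    summarise(
      n_broods = n(),
      n_epp_broods = sum(.data$epp_positive),
      n_offspring = sum(.data$n_offspring_calls[.data$father_sampled]),
      n_epo = sum(.data$n_epo[.data$father_sampled]),
      .groups = "drop"
    ) %>%
    mutate(
      brood_pct = as.integer(round(100 * .data$n_epp_broods / .data$n_broods)),
      offspring_pct = as.integer(round(100 * .data$n_epo / .data$n_offspring))
    )
  structure(out, class = c("epp_summary", class(out)))
}
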