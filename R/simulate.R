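#' Simulation configuration
#'
#' Describes a two-plot, single-species, single- or multi-season breeding
#' population: a natural-cavity plot with uniformly scattered nests and a
#' nestbox plot on a 50 m grid with jitter, separated by a 200 m gap.
#' Defaults mirror the blue-tit study scale: 30 pairs in the natural
#' plot and 37 in the nestbox plot per season, clutches uniform on 8-12
#' eggs laid one per day, laying onset normal around day-of-year 105
#' (SD 5), an offspring-level extra-pair rate of 0.10 with
#' exponential distance decay of sire choice (scale 100 m, same-plot
#' sires only), brood parasitism in 1% of nests, 10% of social fathers
#' ungenotyped, 5000 autosomal plus 20 Z-linked loci with founder minor
#' allele frequencies uniform on [0.05, 0.5], 5% missing genotypes and a
#' 0.5% per-allele error rate.
#'
#' @param species "bluetit" or "greattit" (sets the fertile-window
#'   offset and the default laying-date mean).
#' @param years integer vector of breeding seasons (independent cohorts).
#' @param n_pairs_per_plot length-2 vector `c(natural, nestbox)`.
#' @param natural_extent,nestbox_extent plot side lengths in meters
#'   (natural: uniform placement; nestbox: 50 m grid with jitter).
#' @param plot_gap gap between plot edges (m).
#' @param n_autosomal_loci,n_sexlinked_loci locus counts.
#' @param maf_min lower bound of the uniform founder-frequency law (the
#'   upper bound is 0.5).
#' @param epp_rate probability an offspring is extra-pair.
#' @param sire_decay_scale exponential scale (m) of extra-pair sire
#'   choice.
#' @param parasitism_rate probability a nest receives one parasitic egg.
#' @param unsampled_father_rate probability a nest's social father is
#'   ungenotyped (and unidentified in the field records).
#' @param missing_rate,error_rate per-genotype missingness and per-allele
#'   flip-error probabilities.
#' @param laying_mean,laying_sd laying-onset law (day-of-year).
#' @param clutch_range inclusive integer range of clutch sizes.
#' @param fledge_prob per-nestling fledging probability.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = c("bluetit", "greattit"),
                       years = c(2018L, 2019L),
                       n_pairs_per_plot = c(natural = 30L, nestbox = 37L),
                       natural_extent = 700, nestbox_extent = 390,
                       plot_gap = 200,
                       n_autosomal_loci = 5000L, n_sexlinked_loci = 20L,
                       maf_min = 0.05,
                       epp_rate = 0.10, sire_decay_scale = 100,
                       parasitism_rate = 0.01,
                       unsampled_father_rate = 0.10,
                       missing_rate = 0.05, error_rate = 0.005,
                       laying_mean = NULL, laying_sd = 5,
                       clutch_range = c(8L, 12L),
                       fledge_prob = 0.9,
                       seed = 1L) {
  species <- match.arg(species)
  laying_mean <- laying_mean %||% c(bluetit = 105, greattit = 108)[[species]]
  probs <- c(epp_rate = epp_rate, parasitism_rate = parasitism_rate,
             unsampled_father_rate = unsampled_father_rate,
             missing_rate = missing_rate, error_rate = error_rate,
             fledge_prob = fledge_prob)
  if (any(probs < 0 | probs > 1))
    abort(sprintf("probabilities must be in [0, 1]: %s",
                  paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")))
  if (maf_min <= 0 || maf_min >= 0.5) abort("maf_min must be in (0, 0.5)")
  if (length(n_pairs_per_plot) == 1)
    n_pairs_per_plot <- c(natural = n_pairs_per_plot, nestbox = n_pairs_per_plot)
  if (any(n_pairs_per_plot < 2)) abort("need at least 2 pairs per plot")
  structure(
    list(species = species, years = as.integer(years),
         n_pairs_per_plot = setNames(as.integer(n_pairs_per_plot),
                                     c("natural", "nestbox")),
         natural_extent = natural_extent, nestbox_extent = nestbox_extent,
         plot_gap = plot_gap,
         n_autosomal_loci = as.integer(n_autosomal_loci),
         n_sexlinked_loci = as.integer(n_sexlinked_loci),
         maf_min = maf_min, epp_rate = epp_rate,
         sire_decay_scale = sire_decay_scale,
         parasitism_rate = parasitism_rate,
         unsampled_father_rate = unsampled_father_rate,
         missing_rate = missing_rate, error_rate = error_rate,
         laying_mean = laying_mean, laying_sd = laying_sd,
         clutch_range = as.integer(clutch_range),
         fledge_prob = fledge_prob, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one transmitted allele per parent per locus; dosage/2 is the
# transmission probability for dosages 0, 1, 2
.transmit <- function(dosage_row) rbinom(length(dosage_row), 1L, dosage_row / 2)

# founder draws: autosomes HWE Binom(2, p); Z loci by carrier sex
.founder_autosomal <- function(n, p) {
  matrix(rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

#' Simulate a two-plot breeding population with known truth
#'
#' Generates founder adults in Hardy-Weinberg proportions, places nests
#' in the two plots, draws laying dates and clutch sizes, transmits
#' alleles through Mendelian inheritance (Z-linked loci follow ZW
#' genetics: ZZ males diploid, ZW females hemizygous stored as
#' homozygous), assigns each offspring an extra-pair sire with
#' probability `epp_rate` (chosen among the other males of the same plot
#' with probability proportional to `exp(-d / sire_decay_scale)`),
#' implants one unrelated nestling in parasitized nests, and finally
#' applies per-allele flip error and missingness. Ground truth is
#' returned untouched by error or missingness.
#'
#' @param config a [sim_config()] list.
#' @return An `epp_simulation` list: `genotypes` ([genotypes] object of
#'   all genotyped individuals), `records` (nest tibble), `nestlings`
#'   (per-nestling tibble with fledge status and body measures),
#'   `pedigree` (the field-observed [build_pedigree()] result), and
#'   `truth` (list of `offspring` and `nests` truth tables), plus the
#'   `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_loci <- config$n_autosomal_loci + config$n_sexlinked_loci
  auto_idx <- seq_len(config$n_autosomal_loci)
  z_idx <- config$n_autosomal_loci + seq_len(config$n_sexlinked_loci)
  locus_ids <- c(sprintf("snp%05d", auto_idx),
                 sprintf("zsnp%03d", seq_len(config$n_sexlinked_loci)))
  p <- runif(n_loci, config$maf_min, 0.5)

  all_geno <- list(); all_meta <- list()
  all_nests <- list(); all_nestlings <- list(); all_truth <- list()
  unsampled_fathers <- character()

  for (yr in config$years) {
    # --- nest placement -------------------------------------------------
    n_nat <- config$n_pairs_per_plot[["natural"]]
    n_box <- config$n_pairs_per_plot[["nestbox"]]
    nat_xy <- cbind(runif(n_nat, 0, config$natural_extent),
                    runif(n_nat, 0, config$natural_extent))
    g_side <- ceiling(sqrt(n_box))
    grid <- expand.grid(gx = seq_len(g_side), gy = seq_len(g_side))[seq_len(n_box), ]
    box_xy <- cbind(
      config$natural_extent + config$plot_gap + (grid$gx - 1) * 50 +
        rnorm(n_box, 0, 3),
      (grid$gy - 1) * 50 + rnorm(n_box, 0, 3)
    )
    n_nests <- n_nat + n_box
    nest_ids <- sprintf("%s_%d_n%03d", config$species, yr, seq_len(n_nests))
    cavity <- rep(c("natural", "nestbox"), c(n_nat, n_box))
    xy <- rbind(nat_xy, box_xy)

    # --- founder adults -------------------------------------------------
    mother_ids <- sprintf("%s_%d_F%03d", config$species, yr, seq_len(n_nests))
    father_ids <- sprintf("%s_%d_M%03d", config$species, yr, seq_len(n_nests))
    g_mother <- .founder_autosomal(n_nests, p)
    g_father <- .founder_autosomal(n_nests, p)
    # ZW: female single Z allele stored as homozygote; male ZZ diploid
    f_zallele <- matrix(
      rbinom(n_nests * length(z_idx), 1L, rep(p[z_idx], each = n_nests)),
      nrow = n_nests)
    g_mother[, z_idx] <- 2L * f_zallele
    # fathers already Binom(2, p) at z loci: correct for ZZ

    laying <- round(rnorm(n_nests, config$laying_mean, config$laying_sd))
    clutch <- sample(seq(config$clutch_range[1], config$clutch_range[2]),
                     n_nests, replace = TRUE)

    nests <- tibble(
      nest_id = nest_ids, species = config$species,
      plot = cavity, cavity_type = cavity, year = yr,
      x = xy[, 1], y = xy[, 2],
      laying_date = as.integer(laying), clutch_size = as.integer(clutch),
      mother_id = mother_ids, father_id = father_ids,
      first_clutch = TRUE
    )

    # --- extra-pair sire choice ----------------------------------------
    dmat <- as.matrix(stats::dist(xy))
    same_plot <- outer(cavity, cavity, "==")
    n_off_per_nest <- clutch
    off_nest <- rep(seq_len(n_nests), n_off_per_nest)
    n_off <- length(off_nest)
    is_epo <- runif(n_off) < config$epp_rate
    true_sire_idx <- off_nest   # default: social father
    for (k in which(is_epo)) {
      nst <- off_nest[k]
      cand <- which(same_plot[nst, ] & seq_len(n_nests) != nst)
      if (!length(cand)) abort("no males available as extra-pair sires")
      wgt <- exp(-dmat[nst, cand] / config$sire_decay_scale)
      true_sire_idx[k] <- cand[sample.int(length(cand), 1, prob = wgt)]
    }

    # --- offspring genotypes -------------------------------------------
    off_ids <- sprintf("%s_%d_o%04d", config$species, yr, seq_len(n_off))
    g_off <- matrix(0L, n_off, n_loci)
    off_sex <- sample(c("M", "F"), n_off, replace = TRUE)
    for (k in seq_len(n_off)) {
      mo <- g_mother[off_nest[k], ]
      fa <- g_father[true_sire_idx[k], ]
      gk <- .transmit(mo[auto_idx]) + .transmit(fa[auto_idx])
      # Z: son gets father's Z draw + mother's single Z; daughter gets
      # father's Z only, stored as a homozygote
      fa_z <- .transmit(fa[z_idx])
      if (off_sex[k] == "M") {
        zk <- fa_z + f_zallele[off_nest[k], ]
      } else {
        zk <- 2L * fa_z
      }
      g_off[k, ] <- c(gk, zk)
    }

    # --- brood parasitism ----------------------------------------------
    parasitized <- which(runif(n_nests) < config$parasitism_rate)
    n_par <- length(parasitized)
    par_ids <- character(0)
    if (n_par) {
      par_ids <- sprintf("%s_%d_p%03d", config$species, yr, seq_len(n_par))
      par_sex <- sample(c("M", "F"), n_par, replace = TRUE)
      g_par <- .founder_autosomal(n_par, p)
      pz <- matrix(rbinom(n_par * length(z_idx), 1L, rep(p[z_idx], each = n_par)),
                   nrow = n_par)
      g_par[, z_idx] <- ifelse(matrix(par_sex == "F", n_par, length(z_idx)),
                               2L * pz, g_par[, z_idx, drop = FALSE])
      g_off <- rbind(g_off, g_par)
      off_ids <- c(off_ids, par_ids)
      off_nest <- c(off_nest, parasitized)
      off_sex <- c(off_sex, par_sex)
      is_epo <- c(is_epo, rep(NA, n_par))          # not the pair's offspring
      true_sire_idx <- c(true_sire_idx, rep(NA_integer_, n_par))
    }

    # --- unsampled social fathers --------------------------------------
    hide_father <- runif(n_nests) < config$unsampled_father_rate
    nests$father_id[hide_father] <- NA_character_
    unsampled_fathers <- c(unsampled_fathers, father_ids[hide_father])

    # --- nestling phenotypes -------------------------------------------
    tarsus <- rnorm(length(off_ids), 19.5, 0.6)
    mass <- exp(2 * log(tarsus) + rnorm(length(off_ids), -4.55, 0.05))
    fledged <- rbinom(length(off_ids), 1L, config$fledge_prob)

    nestlings <- tibble(
      id = off_ids, nest_id = nest_ids[off_nest], sex = off_sex,
      fledged = as.integer(fledged),
      mass = round(mass, 2), tarsus = round(tarsus, 2), sampled = TRUE
    )

    truth_off <- tibble(
      id = off_ids, nest_id = nest_ids[off_nest],
      true_sire = ifelse(is.na(true_sire_idx), NA_character_,
                         father_ids[true_sire_idx]),
      social_father = father_ids[off_nest],
      epo = is_epo, parasite = off_ids %in% par_ids,
      sex = off_sex, year = yr
    )

    geno <- rbind(g_mother, g_father, g_off)
    rownames(geno) <- c(mother_ids, father_ids, off_ids)
    meta <- bind_rows(
      tibble(id = mother_ids, stage = "adult", sex = "F",
             plot = cavity, year = yr),
      tibble(id = father_ids, stage = "adult", sex = "M",
             plot = cavity, year = yr),
      tibble(id = off_ids, stage = "nestling", sex = off_sex,
             plot = cavity[off_nest], year = yr)
    )

    all_geno[[as.character(yr)]] <- geno
    all_meta[[as.character(yr)]] <- meta
    all_nests[[as.character(yr)]] <- nests
    all_nestlings[[as.character(yr)]] <- nestlings
    all_truth[[as.character(yr)]] <- truth_off
  }

  geno <- do.call(rbind, all_geno)
  colnames(geno) <- locus_ids
  meta <- bind_rows(all_meta) %>% mutate(species = config$species)
  nests <- bind_rows(all_nests)
  nestlings <- bind_rows(all_nestlings)
  truth_off <- bind_rows(all_truth)

  # --- error and missingness last --------------------------------------
  if (config$error_rate > 0) {
    n_cells <- length(geno)
    flips <- matrix(rbinom(n_cells, 2L, config$error_rate), nrow = nrow(geno))
    het <- geno == 1L
    # homozygotes: each allele flips independently; heterozygotes: one
    # flip moves to either homozygote, two flips stay heterozygous
    new_het <- geno
    one_flip <- het & flips == 1L
    new_het[one_flip] <- 2L * rbinom(sum(one_flip), 1L, 0.5)
    new_hom <- ifelse(geno == 0L, flips, 2L - flips)
    geno <- ifelse(het, new_het, new_hom)
  }
  if (config$missing_rate > 0)
    geno[matrix(runif(length(geno)) < config$missing_rate,
                nrow = nrow(geno))] <- NA_integer_
  storage.mode(geno) <- "integer"

  # ungenotyped fathers leave the matrix; truth keeps their identity
  geno <- geno[setdiff(rownames(geno), unsampled_fathers), , drop = FALSE]
  meta <- meta %>% filter(!.data$id %in% unsampled_fathers)

  truth_nests <- truth_off %>%
    group_by(.data$nest_id) %>%
    summarise(
      n_offspring = sum(!is.na(.data$epo)),
      n_epo = sum(.data$epo, na.rm = TRUE),
      epp_occurrence = any(.data$epo, na.rm = TRUE),
      epo_prop = .data$n_epo / pmax(.data$n_offspring, 1),
      parasitized = any(.data$parasite),
      .groups = "drop"
    )

  ped <- build_pedigree(nests, nestlings %>% select("id", "nest_id"))

  structure(
    list(
      genotypes = genotypes(geno, meta),
      records = nests, nestlings = nestlings, pedigree = ped,
      truth = list(offspring = truth_off, nests = truth_nests),
      config = config
    ),
    class = "epp_simulation"
  )
}

#' @export
print.epp_simulation <- function(x, ...) {
  cat(sprintf(
    "<epp_simulation> %s: %d nests, %d genotyped individuals, %d loci (seed %d)\n",
    x$config$species, nrow(x$records), nrow(x$genotypes$dosage),
    ncol(x$genotypes$dosage), x$config$seed
  ))
  invisible(x)
}

#' Mendelian incompatibility rate per parent-offspring trio
#'
#' For each trio (offspring with both social parents genotyped), the
#' fraction of fully called loci whose dosages are impossible under
#' Mendelian transmission (e.g. parents 0 and 0 with offspring 1). With
#' no genotyping error and no extra-pair paternity the rate is 0;
#' genotyping error raises it predictably, and a cuckolded social father
#' raises it strongly for that trio — which is what makes the statistic a
#' useful simulator oracle.
#'
#' @param g a [genotypes] object.
#' @param ped a `social_pedigree`.
#' @param loci optional locus ids to restrict to. Z-linked loci should be
#'   excluded: the homozygous coding of hemizygous females makes the
#'   diploid transmission rule inapplicable there.
#' @return Tibble `offspring`, `mother`, `father`, `n_loci`,
#'   `n_incompatible`, `rate`; trios with an ungenotyped member are
#'   skipped and counted in the `n_skipped` attribute.
#' @export
mendelian_check <- function(g, ped, loci = NULL) {
  stopifnot(inherits(g, "genotypes"))
  if (!is.null(loci)) g <- subset_genotypes(g, loci = loci)
  ids <- rownames(g$dosage)
  trios <- ped %>%
    filter(!is.na(.data$mother), !is.na(.data$father))
  complete <- trios$id %in% ids & trios$mother %in% ids & trios$father %in% ids
  n_skipped <- sum(!complete)
  if (n_skipped) warn(sprintf("%d trios skipped (ungenotyped member)", n_skipped))
  trios <- trios[complete, ]
  d <- g$dosage
  res <- purrr::pmap(
    list(trios$id, trios$mother, trios$father),
    function(o, m, f) {
      go <- d[o, ]; gm <- d[m, ]; gf <- d[f, ]
      ok <- !is.na(go) & !is.na(gm) & !is.na(gf)
      bad <- .mendel_incompatible(gm[ok], gf[ok], go[ok])
      tibble(offspring = o, mother = m, father = f,
             n_loci = sum(ok), n_incompatible = sum(bad),
             rate = if (sum(ok)) sum(bad) / sum(ok) else NA_real_)
    }
  ) %>% bind_rows()
  attr(res, "n_skipped") <- n_skipped
  res
}

# offspring dosage impossible given parent dosages?
.mendel_incompatible <- function(gm, gf, go) {
  lo <- (gm > 1) + (gf > 1)             # forced minimum of transmitted alleles
  hi <- (gm > 0) + (gf > 0)             # attainable maximum
  go < lo | go > hi
}
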