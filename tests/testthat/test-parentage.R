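# construct a grm object directly from a relatedness matrix
fake_grm <- function(r) {
  structure(list(r = r, n_loci = matrix(1000L, nrow(r), ncol(r),
                                        dimnames = dimnames(r)),
                 ids = rownames(r)),
            class = "grm")
}

# one nest: parents F1 x M1, three nestlings
band_fixture <- function(g_o1, g_o2 = 0.48, g_o3 = 0.52,
                         sib12 = 0.5, sib13 = 0.5, sib23 = 0.5) {
  ids <- c("M1", "F1", "o1", "o2", "o3")
  r <- matrix(0, 5, 5, dimnames = list(ids, ids))
  diag(r) <- 1
  r["M1", "o1"] <- r["o1", "M1"] <- g_o1
  r["M1", "o2"] <- r["o2", "M1"] <- g_o2
  r["M1", "o3"] <- r["o3", "M1"] <- g_o3
  r["F1", "o1"] <- r["o1", "F1"] <- 0.5
  r["F1", "o2"] <- r["o2", "F1"] <- 0.5
  r["F1", "o3"] <- r["o3", "F1"] <- 0.5
  r["o1", "o2"] <- r["o2", "o1"] <- sib12
  r["o1", "o3"] <- r["o3", "o1"] <- sib13
  r["o2", "o3"] <- r["o3", "o2"] <- sib23
  ped <- as_pedigree(tibble::tibble(
    id = ids, mother = c(NA, NA, "F1", "F1", "F1"),
    father = c(NA, NA, "M1", "M1", "M1"),
    natal_nest = c(NA, NA, "n1", "n1", "n1")
  ))
  list(grm = fake_grm(r), ped = ped)
}

test_that("father-offspring bands classify as printed cutoffs dictate", {
  fx <- band_fixture(g_o1 = 0.47)
  cls <- classify_father_offspring(fx$grm, fx$ped)
  expect_equal(cls$class[cls$offspring == "o1"], "within_pair")

  fx <- band_fixture(g_o1 = 0.06)
  cls <- classify_father_offspring(fx$grm, fx$ped)
  expect_equal(cls$class[cls$offspring == "o1"], "extra_pair")

  fx <- band_fixture(g_o1 = 0.25)
  cls <- classify_father_offspring(fx$grm, fx$ped)
  expect_equal(cls$class[cls$offspring == "o1"], "ambiguous")

  # boundary values fall into the ambiguous class (strict inequalities)
  for (gb in c(0.35, 0.15)) {
    fx <- band_fixture(g_o1 = gb)
    cls <- classify_father_offspring(fx$grm, fx$ped)
    expect_equal(cls$class[cls$offspring == "o1"], "ambiguous")
  }
})

test_that("every father-offspring pair gets exactly one class", {
  fx <- band_fixture(g_o1 = 0.06, g_o2 = 0.2)
  cls <- classify_father_offspring(fx$grm, fx$ped)
  expect_equal(nrow(cls), 3)
  expect_equal(sum(table(cls$class)), 3)
  expect_true(all(cls$class %in% c("within_pair", "extra_pair", "ambiguous")))
})

test_that("sibling pairs split into full/half/unrelated bands", {
  fx <- band_fixture(g_o1 = 0.06, sib12 = 0.24, sib13 = 0.52, sib23 = 0.05)
  sib <- classify_sibling_pairs(fx$grm, fx$ped)
  get <- function(a, b) sib$class[sib$id1 == min(a, b) & sib$id2 == max(a, b)]
  expect_equal(get("o1", "o2"), "half")
  expect_equal(get("o1", "o3"), "full")
  expect_equal(get("o2", "o3"), "unrelated_flag")
})

test_that("extra-pair fathers are found and sibling false positives removed", {
  ids <- c("M1", "M2", "F1", "o1")
  r <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(r) <- 1
  r["M2", "o1"] <- r["o1", "M2"] <- 0.41
  r["M1", "o1"] <- r["o1", "M1"] <- 0.05
  r["F1", "o1"] <- r["o1", "F1"] <- 0.5
  ped <- as_pedigree(tibble::tibble(
    id = ids, mother = c(NA, NA, NA, "F1"), father = c(NA, NA, NA, "M1"),
    natal_nest = c(NA, NA, NA, "n1")
  ))
  links <- find_extra_pair_fathers(fake_grm(r), ped, c("M1", "M2"))
  expect_equal(links$male, "M2")
  expect_equal(links$offspring, "o1")

  # same genomic picture, but M2 is o1's full brother ringed earlier:
  # the pedigree explains the relatedness, so the link is a false positive
  ped2 <- as_pedigree(tibble::tibble(
    id = ids, mother = c(NA, "F1", NA, "F1"), father = c(NA, "M1", NA, "M1"),
    natal_nest = c(NA, "n0", NA, "n1")
  ))
  links2 <- find_extra_pair_fathers(fake_grm(r), ped2, c("M1", "M2"))
  expect_equal(nrow(links2), 0)
  fp <- attr(links2, "false_positives")
  expect_equal(fp$male, "M2")
  expect_equal(fp$a, 0.5)
})

test_that("brood parasitism needs low relatedness to parents AND siblings", {
  # o1 unrelated to everyone in the nest
  fx <- band_fixture(g_o1 = 0.02, sib12 = 0.03, sib13 = 0.02)
  r <- fx$grm$r
  r["F1", "o1"] <- r["o1", "F1"] <- 0.01
  calls <- detect_brood_parasitism(fake_grm(r), fx$ped)
  expect_equal(calls$offspring, "o1")

  # an extra-pair offspring (low to father, 0.5 to mother) is NOT a parasite
  fx2 <- band_fixture(g_o1 = 0.02, sib12 = 0.25, sib13 = 0.25)
  calls2 <- detect_brood_parasitism(fx2$grm, fx2$ped)
  expect_equal(nrow(calls2), 0)
})

test_that("raising the within-pair cutoff never decreases the EPO count", {
  set.seed(41)
  cfg <- sim_config(years = 2019L, n_pairs_per_plot = c(8, 8),
                    n_autosomal_loci = 300, n_sexlinked_loci = 0,
                    missing_rate = 0, error_rate = 0, seed = 77)
  sim <- simulate_population(cfg)
  grm <- grm_gcta(sim$genotypes)
  counts <- sapply(c(0.35, 0.45, 0.6), function(wp) {
    th <- epp_thresholds(within_pair_min = wp)
    cls <- classify_father_offspring(grm, sim$pedigree, th)
    sum(cls$class == "extra_pair")
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("classification recovers simulated truth end to end", {
  cfg <- sim_config(years = 2019L, n_pairs_per_plot = c(10, 10),
                    n_autosomal_loci = 3000, n_sexlinked_loci = 0,
                    epp_rate = 0.1, parasitism_rate = 0.05,
                    unsampled_father_rate = 0,
                    missing_rate = 0.02, error_rate = 0, seed = 55)
  sim <- simulate_population(cfg)
  grm <- grm_gcta(filter_call_rate(sim$genotypes))
  calls <- call_parentage(grm, sim$pedigree, sim$records)
  truth <- sim$truth$offspring

  cmp <- dplyr::inner_join(calls$offspring, truth, by = "id",
                           suffix = c("_called", "_true"))
  called <- !is.na(cmp$epo_called) & !cmp$parasite_true
  expect_gt(mean(cmp$epo_called[called] == cmp$epo_true[called]), 0.98)

  # every genotyped true sire is recovered as the EPF, with no spurious links
  links <- calls$epf_links
  true_ep <- truth[!is.na(truth$epo) & truth$epo, ]
  found <- dplyr::inner_join(links, true_ep, by = c(offspring = "id"))
  expect_true(all(found$male == found$true_sire))
  expect_gte(nrow(found) / nrow(true_ep), 0.95)
  expect_equal(nrow(links), nrow(found))   # precision 1

  # parasites recovered exactly
  expect_setequal(calls$parasites$offspring,
                  truth$id[truth$parasite])
})

test_that("summary reproduces the published plot-level percentages", {
  fx <- make_field_fixture()
  s <- summarize_epp(fx)
  get <- function(sp, cv, col) s[[col]][s$species == sp & s$cavity_type == cv]
  expect_equal(get("bluetit", "natural", "brood_pct"), 37L)
  expect_equal(get("bluetit", "nestbox", "brood_pct"), 46L)
  expect_equal(get("greattit", "natural", "brood_pct"), 38L)
  expect_equal(get("greattit", "nestbox", "brood_pct"), 62L)
  expect_equal(get("bluetit", "natural", "offspring_pct"), 8L)
  expect_equal(get("bluetit", "nestbox", "offspring_pct"), 12L)
  expect_equal(get("greattit", "natural", "offspring_pct"), 11L)
  expect_equal(get("greattit", "nestbox", "offspring_pct"), 16L)
  expect_warning(summarize_epp(fx[0, ]), "empty")
})

test_that("EPP-positive broods equal cuckolded fathers plus half-sib nests", {
  fx <- make_field_fixture()
  expect_true(check_epp_consistency(fx))
  by_sp <- dplyr::count(fx, species, wt = epp_positive)
  expect_equal(by_sp$n, c(28, 28))    # 25 + 3 per species
  cuckolded <- dplyr::count(fx[fx$father_sampled & fx$n_epo > 0, ], species)
  expect_equal(cuckolded$n, c(25, 25))
})
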