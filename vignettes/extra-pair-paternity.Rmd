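---
title: "Inferring extra-pair paternity from genomic relatedness: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring extra-pair paternity from genomic relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eppgrm)
```

## The inference problem

A field study of cavity-nesting tits yields two views of parentage. The
*social* view is observational: the female and male attending a nest are
recorded as the mother and father of its nestlings. The *genetic* view
comes from SNP genotypes: pairwise realized relatedness estimated from
thousands of biallelic markers. Where the two disagree — a social father
genomically unrelated to a nestling, or nest-mates related like half
rather than full siblings — the disagreement itself is the biological
signal: extra-pair paternity, multiple sires within a brood, or brood
parasitism. `eppgrm` formalizes that comparison and carries it through
to the population-level statistics that relate promiscuity to breeding
density and synchrony.

## Genomic relatedness

Relatedness is estimated with the GCTA single-component estimator on
allele dosages standardized by allele frequency (see the README for the
exact expressions). Three numerical choices matter:

* **Allele frequencies** are estimated once from the full post-QC sample
  — adults and nestlings, both plots pooled. Family structure inflates
  relatedness estimates slightly relative to an outbred reference
  population, but the classification bands below are wide enough to
  absorb this, and pooling keeps the estimator reproducible from the
  data alone.
* **Missing genotypes** are handled pairwise-complete: each pair is
  averaged over the loci called in both individuals, with the per-pair
  locus count reported. No imputation.
* **Monomorphic and near-monomorphic loci** (`p < 1/(2n)`) are dropped
  before the GRM; their standardization weight `1/(2p(1-p))` would
  otherwise explode.

The call-rate filter removes individuals, then loci, below 70%
non-missing, iterating both passes to a fixed point so the result does
not depend on the order of the two passes.

A note on a degenerate corner of the estimator: for a pair of
genotype-identical individuals homozygous at every locus, at sample
frequency 0.5 the off-diagonal is exactly 2 — the value for duplicates
of a fully inbred genome — not 1. The diagonal term behaves the same
way (`1 + F`). The test suite pins this down against a scalar-loop
oracle.

## The social pedigree and expected relatedness

Field records become a pedigree (nestling to attending adults, recruits
linked across years), and expected additive relatedness is computed by
the tabular method: `a_ii = 1 + a(sire, dam)/2`,
`a_ij = (a(i, sire_j) + a(i, dam_j))/2`, unknown parents contributing
zero. Inbreeding is handled by the same recursion without
special-casing; an independent ancestral-path-counting oracle verifies
it in the tests.

## Threshold bands

Father-offspring pairs with a social link (expected r = 0.5) are
classified by the genomic estimate `G`:

| band | call |
|---|---|
| `G > 0.35` | within-pair paternity |
| `0.15 <= G <= 0.35` | ambiguous (reported, excluded from counts) |
| `G < 0.15` | extra-pair paternity |

Within-brood sibling pairs use the same cutoffs (full siblings above
0.35, half-siblings between 0.15 and 0.35), and a nestling below 0.1 to
*every* genotyped social parent and nest-mate is called brood
parasitism. Unrelated adult males (expected r = 0) above 0.35 to a
nestling are its extra-pair father; candidates whose relatedness the
pedigree already explains (full brothers from a previous cohort) are
removed and reported as false positives.

Design choices worth stating explicitly:

* **The ambiguous band.** Only the two outer cutoffs are principled; no
  rule is invented for the `[0.15, 0.35]` gap. Pairs there are excluded
  from both numerator and denominator of extra-pair rates and always
  reported. At realistic locus counts (thousands) the band is nearly
  empty for true parent-offspring pairs, whose estimates concentrate
  tightly around 0.5 or 0.
* **An extra-pair offspring does not require an identified sire.** The
  offspring call depends only on relatedness to the social father;
  extra-pair-father links are a separate, rarer discovery (the sire must
  himself be genotyped). Conflating the two would systematically
  undercount.
* **Nests with an unsampled social father** cannot yield per-offspring
  calls; brood-level extra-pair occurrence is instead decided by
  half-sibling evidence within the brood. Such nests are excluded from
  offspring-proportion models.
* **Brood parasites are neither extra-pair nor within-pair offspring**:
  they are not the social pair's offspring at all, and enter neither
  count.
* **Ties at the cutoffs** follow the strict inequalities as written;
  boundary values fall into the ambiguous/negative class. With
  continuous estimates this is measure-zero.

## Sexing under ZW sex determination

Males are ZZ, females ZW; a diploid genotype caller emits a female's
single Z allele as a homozygote. Two consequences drive the design:

1. Z-linked loci show a strong *heterozygosity* difference between the
   sexes (female observed heterozygosity near zero).
2. The sexes share allele frequencies at such loci, so between-sex FST
   carries essentially no signal for purely Z-polymorphic markers: in
   the Weir-Cockerham estimator the between-group variance inflation
   from hemizygous sampling and the reduced mean heterozygosity cancel
   almost exactly. We verified this both analytically and by
   simulation; a 95th-percentile FST gate costs most of the panel.

The discovery screen therefore combines the heterozygosity difference
(floor 0.05) with an exact binomial test of female heterozygote deficit
— observed heterozygous females against `Binom(n_F, 2 p_F (1 - p_F))` —
at level `1e-4`. This test retains power even at low minor-allele
frequency, where the raw heterozygosity difference is small, and it is
what keeps the false-discovery rate near zero. FST is still computed and
reported per locus, and an `fst_quantile` gate can be enabled for
datasets in which Z-W gametologous SNPs create genuine between-sex
frequency differentiation (there, females are the constitutively
heterozygous sex and FST is large). A label-permutation p-value of the
heterozygosity difference is reported for each panel locus.

Sex assignment is a per-sex genotype-frequency naive Bayes classifier
with add-one smoothing and equal priors, trained on known-sex adults at
the panel loci; nestlings missing every panel locus stay unsexed.
Accuracy is estimated by Monte-Carlo cross-validation: repeated random
70/30 splits of the adults. With an 11-locus panel and 1% per-allele
genotyping error the cross-validated accuracy is typically 0.95-0.99;
the residual errors are females with a single error-induced
heterozygous call and males homozygous across the whole panel, both of
which scale down with panel size and marker informativeness.

## Spatiotemporal metrics

All metrics are computed per species and year. Nearest-neighbor
distance is the distance to the closest conspecific active nest;
neighbor density counts conspecific nests within a radius; synchronous
neighbor density additionally requires fertile-window overlap with the
focal female.

* **Fertile windows** run from 2 days (blue tit) or 5 days (great tit)
  before laying onset to the penultimate laying day, with one egg laid
  per day, so a laying date `t` and clutch `k` give `[t - offset,
  t + k - 2]`. A clutch of 1 makes the window end before laying begins;
  the formula is retained and the case flagged with a warning rather
  than patched, since it does not arise in real clutches.
* **Overlap is inclusive** of endpoints (days are the data's
  resolution); the exclusive convention is available as a flag.
* **Radii** are derived from the data: the median distance between an
  extra-pair father's own nest and the nest where he sired offspring,
  times multipliers 1, 2, 3 (96/192/288 m for blue tits and 72/144/216
  m for great tits in the populations that motivated the defaults),
  with a configured fallback when a dataset yields no links. Medians of
  even-sized sets are the mean of the middle two.
* **Plots are not boundaries**: neighbors are counted purely by
  distance, which only matters for the largest radius given a 200 m
  plot gap.
* Geographic coordinates are projected to a local spherical
  transverse-Mercator frame centered on the site centroid before
  distances are taken; at within-site scales this agrees with
  great-circle distances to well under 0.1%.

## Statistical battery

Plot-level comparisons use Yates-corrected chi-square tests on 2x2
tables (the correction is the convention that reproduces the reference
statistics for these data) and Mann-Whitney U tests, exact by full
enumeration when both groups have at most 8 untied observations and
normal-approximated with tie correction otherwise.

Nest- and nestling-level models are binomial GLMMs with a logit link
and a single random intercept (mother or nest identity), maximized by
adaptive Gauss-Hermite quadrature with 10 nodes. Because the three
spatiotemporal covariates are moderately correlated, each enters its
own model (a: nearest-neighbor distance, b: neighbor density, c:
synchronous neighbor density) alongside cavity type, laying date and
clutch size. Per-term p-values are drop-one likelihood-ratio chi-square
tests; Wald standard errors are reported alongside. On convergence
failure the random term is dropped and a GLM is fitted, with the
fallback flagged in the output — never silently. Spatiotemporal and
numeric covariates are z-scaled within the modeling dataset, which both
absorbs between-year level differences and puts estimates on comparable
scales. Filters applied before fitting: first clutches only;
proportion models exclude nests with an unsampled social father and
nests with fewer than half the clutch sampled. The nestling-level model
includes a cavity-by-sex interaction that is dropped when its
likelihood-ratio p-value exceeds 0.05; body condition enters as the
scaled mass index (standardized-major-axis slope of log mass on log
tarsus; when tarsus is constant the index reduces to raw mass).
Collinearity is screened with variance inflation factors; dispersion is
reported as the Pearson chi-square over residual degrees of freedom.

## The synthetic-data generator

`simulate_population()` is first-class, tested code, not a fixture. It
emulates the study design the analysis assumes: two plots — a 50 ha
natural-cavity plot with uniformly placed nests and a 15 ha nestbox
plot on a 50 m grid with jitter, separated by a 200 m gap — with 30 and
37 pairs per season, two seasons, clutches uniform on 8-12 eggs laid
one per day, laying onset normal with SD 5 days around day-of-year 105
(blue tit) or 108 (great tit). Founders are drawn in Hardy-Weinberg
proportions at frequencies uniform on [0.05, 0.5]; offspring inherit
one allele per parent per locus; each offspring is extra-pair with
probability 0.10 (close to the offspring-level rates published for
these populations), with the sire drawn among same-plot males with
probability proportional to `exp(-d / 100 m)` and never equal to the
social father; 1% of nests receive one unrelated (parasitic) nestling;
10% of social fathers go ungenotyped; Z-linked loci follow the ZW rules
above; per-allele flip error (0.5%) and missingness (5%) are applied
last. Where the motivating study reports no value (genotyping error,
post-filter locus count) the defaults are stated here and exposed in
`sim_config()`.

What the generator deliberately does not emulate: linkage and linkage
disequilibrium (loci are independent), sequencing-read-level artifacts
(allelic dropout correlated with depth, reference bias), population
structure or immigration, density-dependent extra-pair behavior, and
multi-year adult survival with mate fidelity (seasons are independent
cohorts unless a pedigree with cross-year links is supplied). Passing
tests therefore demonstrate that the inference chain is correct under
its own assumptions — unbiased allele-frequency estimation, Mendelian
transmission, an exponential sire-distance kernel — not that real
DArT-style data meet those assumptions.

## Verification strategy and problem sizes

Every operation with a nontrivial contract is checked against an
independent oracle: the GRM against scalar loops (to 1e-10 on instances
of up to 10 individuals), pedigree relatedness against ancestral-path
counting, the exact Mann-Whitney p against enumeration of all
labelings, the adaptive-quadrature GLMM objective against brute-force
numeric integration (to 1e-6 on a 3-group instance, evaluated at fixed,
non-degenerate parameters — the 9-observation maximum-likelihood fit
itself is boundary-degenerate and unsuitable as a comparison point),
and the simulator's Mendelian-error rate against exact enumeration over
genotype combinations. End-to-end recovery uses 10 replicates per
extra-pair rate in {0.05, 0.10, 0.20} at 5000 error-free loci with 20
nests per replicate, requiring the classified rate inside the 95%
binomial interval of the generating rate in at least 9 of 10 replicates
and exact extra-pair-father precision; sexing uses a 120-pair,
two-season population. These sizes keep the full suite under two
minutes while leaving each check comfortably powered.

## Known limitations

* The ambiguous father-offspring band is reported, not resolved; at low
  locus counts (hundreds) it can hold a nontrivial fraction of pairs.
* Extra-pair sires are only discoverable among genotyped males; link
  recall is bounded by adult sampling completeness, which is why the
  offspring-level extra-pair call deliberately does not depend on it.
* Between-sex FST is uninformative under pure Z-polymorphism (see
  above); the default screen relies on heterozygosity structure, and
  datasets with W-gametologous markers should enable the FST gate.
* The GLMM battery assumes a single random intercept; crossed or nested
  random structures are out of scope, matching the analysis it
  implements.
* Mann-Whitney W values depend on the raw per-nest metric values, so
  they are only reproducible given a dataset, not from summary counts.
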