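# ggplot2 views of the result objects. Band colors follow the
# relatedness-coefficient convention used throughout the classification:
# 1/16, 1/8, 1/4 (half siblings), 1/2 (full siblings / parent-offspring).

.band_colors <- c(`1/16` = "#7b3294", `1/8` = "#e66101",
                  `1/4` = "#0571b0", `1/2` = "#d8b365")

#' Histogram of genomic relatedness with classification bands
#'
#' @param object a `grm` object.
#' @param zoom_min lower relatedness bound of the plotted window
#'   (default 0.03, zooming in on related pairs).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.grm <- function(object, zoom_min = 0.03, ...) {
  d <- grm_tidy(object) %>% filter(.data$relatedness >= zoom_min)
  bands <- tibble(
    label = names(.band_colors),
    center = c(1 / 16, 1 / 8, 1 / 4, 1 / 2)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$relatedness)) +
    ggplot2::geom_vline(
      data = bands, ggplot2::aes(xintercept = .data$center,
                                 colour = .data$label),
      linetype = "dashed") +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::scale_colour_manual(values = .band_colors, name = "expected r") +
    ggplot2::labs(x = "GRM relatedness", y = "pairs")
}

#' Genomic vs social relatedness biplot
#'
#' Concordance between the genomic relatedness matrix and the social
#' pedigree; discrepancies (points far from the diagonal bands) are the
#' extra-pair-paternity signal.
#'
#' @param grm a `grm` object.
#' @param ped a `social_pedigree`.
#' @param thresholds an [epp_thresholds()] list (drawn as horizontal
#'   cutoffs).
#' @return A ggplot.
#' @export
plot_relatedness_bands <- function(grm, ped, thresholds = epp_thresholds()) {
  A <- social_relatedness_matrix(ped, grm$ids)
  d <- grm_tidy(grm)
  d$social <- A[cbind(match(d$id1, grm$ids), match(d$id2, grm$ids))]
  cuts <- tibble(y = c(thresholds$within_pair_min, thresholds$extra_pair_max,
                       thresholds$parasite_max))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$social, y = .data$relatedness)) +
    ggplot2::geom_jitter(width = 0.01, height = 0, alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(data = cuts, ggplot2::aes(yintercept = .data$y),
                        linetype = "dotted") +
    ggplot2::labs(x = "social (pedigree) relatedness",
                  y = "GRM relatedness")
}

#' Extra-pair vs within-pair counts by species and cavity type
#'
#' @param object an `epp_summary` from [summarize_epp()].
#' @param level "broods" or "offspring".
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.epp_summary <- function(object, level = c("broods", "offspring"),
                                 ...) {
  level <- match.arg(level)
  d <- if (level == "broods") {
    object %>% mutate(ep = .data$n_epp_broods,
                      wp = .data$n_broods - .data$n_epp_broods,
                      pct = .data$brood_pct)
  } else {
    object %>% mutate(ep = .data$n_epo,
                      wp = .data$n_offspring - .data$n_epo,
                      pct = .data$offspring_pct)
  }
  d <- d %>%
    tidyr::pivot_longer(c("ep", "wp"), names_to = "status",
                        values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cavity_type, y = .data$count,
                                  fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_manual(
      values = c(ep = "#d95f02", wp = "#7570b3"),
      labels = c(ep = "extra-pair", wp = "within-pair"), name = NULL) +
    ggplot2::labs(x = NULL, y = level)
}
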