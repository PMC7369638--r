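#' Plot the max-AF-difference stratification scan
#'
#' One point per population pair: maximum allele-frequency difference
#' against mean pairwise Fst, with a LOESS trend over pairs passing the
#' sample-size floor. Outlier calls are made by the permutation test, not by
#' distance from the curve.
#'
#' @param strat An `sv_strat` tibble from [max_af_diff_scan()].
#' @return A ggplot object.
#' @export
plot_strat_scan <- function(strat) {
  if (!"fst" %in% names(strat)) {
    abort("plot_strat_scan needs the fst column (supply pairwise Fst to the scan)")
  }
  ggplot2::ggplot(filter(strat, !is.na(.data$fst)),
                  ggplot2::aes(.data$fst, .data$max_diff)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$small_pop), alpha = 0.7) +
    ggplot2::geom_smooth(data = ~ filter(.x, !.data$small_pop),
                         method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "small population") +
    ggplot2::labs(x = "mean pairwise Fst",
                  y = "max allele-frequency difference") +
    ggplot2::theme_minimal()
}

#' Plot per-population copy-number spectra for one variant
#'
#' @param spectra A `cn_spectrum` tibble from [cn_spectrum()].
#' @param variant_id Variant to show.
#' @return A ggplot object.
#' @export
plot_cn_spectrum <- function(spectra, variant_id) {
  d <- filter(spectra, .data$variant_id == !!variant_id)
  if (nrow(d) == 0) abort("variant not present in spectra")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$cn), .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = factor(d$modal_cn[1]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~ population) +
    ggplot2::labs(x = "diploid copy number", y = "samples",
                  title = variant_id) +
    ggplot2::theme_minimal()
}

#' Plot a sample's normalised coverage profile
#'
#' @param profile A `coverage_profile` tibble from [profile_coverage()].
#' @param sample_id Sample to show.
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(profile, sample_id) {
  d <- filter(profile, .data$sample_id == !!sample_id)
  if (nrow(d) == 0) abort("sample not present in profile")
  ggplot2::ggplot(d, ggplot2::aes(.data$start, .data$norm_depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(0.5, 1, 1.5),
                        linetype = c("dotted", "solid", "dotted"),
                        colour = "grey50") +
    ggplot2::facet_wrap(~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position", y = "normalised depth", title = sample_id) +
    ggplot2::theme_minimal()
}
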