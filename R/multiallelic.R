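#' Per-population copy-number spectra
#'
#' Histograms of diploid copy number per population over CNQ-passing calls,
#' with the global modal CN (pooled argmax; ties resolve to the lower CN so
#' duplications register as expansions). Variants with no passing calls are
#' dropped with a warning.
#'
#' @param x An [sv_callset()] with `cn` (and ideally `cnq`) matrices.
#' @param panel Population panel.
#' @param cnq_min Quality threshold (default 13, ~95% confidence).
#' @return Tibble (`variant_id`, `population`, `cn`, `count`, `modal_cn`),
#'   class `cn_spectrum`.
#' @export
cn_spectrum <- function(x, panel, cnq_min = 13) {
  if (is.null(x$cn)) abort("cn_spectrum requires a CN matrix")
  panel <- panel_for(x, panel)
  m <- x$cn
  if (!is.null(x$cnq)) m[is.na(x$cnq) | x$cnq < cnq_min] <- NA_integer_
  has_mcnv <- rowSums(!is.na(m)) > 0
  if (any(!has_mcnv & x$variants$svtype == "mCNV")) {
    warn(sprintf("cn_spectrum: %d variant(s) with no CNQ-passing calls dropped",
                 sum(!has_mcnv & x$variants$svtype == "mCNV")))
  }
  keep <- which(has_mcnv)
  out <- purrr::map_dfr(keep, function(vi) {
    vals <- m[vi, ]
    ok <- !is.na(vals)
    pooled <- table(vals[ok])
    modal <- as.integer(names(pooled)[which.max(pooled)])
    tibble(population = panel$population[ok], cn = as.integer(vals[ok])) |>
      dplyr::count(.data$population, .data$cn, name = "count") |>
      mutate(variant_id = x$variants$id[vi], modal_cn = modal) |>
      select("variant_id", "population", "cn", "count", "modal_cn")
  })
  class(out) <- c("cn_spectrum", class(out))
  out
}

#' Detect regionally restricted runaway copy-number expansions
#'
#' A (variant, population) pair is called when at least `min_frac` of the
#' population's CNQ-passing samples carry a copy number at least
#' `expansion_margin` above the global modal CN, while the equivalent
#' fraction outside the population stays below `min_frac / 2` -- the
#' "mostly low copy number globally, expanded in certain populations"
#' pattern. Expansions of the magnitude reported in human cohorts (up to 18
#' diploid copies against a modal 2) sit comfortably inside these defaults;
#' the rule itself is a package convention, fully configurable.
#'
#' @param spectra A `cn_spectrum` tibble from [cn_spectrum()].
#' @param expansion_margin Copies above modal that count as expanded
#'   (default 2).
#' @param min_frac Minimum expanded fraction within the called population
#'   (default 0.1).
#' @return Tibble (`variant_id`, `population`, `max_cn`, `frac_expanded`,
#'   `modal_cn`, `frac_expanded_outside`), class `runaway_calls`.
#' @export
runaway_scan <- function(spectra, expansion_margin = 2, min_frac = 0.1) {
  sp <- as_tibble(spectra) |>
    mutate(expanded = .data$cn >= .data$modal_cn + expansion_margin)
  per_pop <- sp |>
    group_by(.data$variant_id, .data$population, .data$modal_cn) |>
    summarise(n = sum(.data$count),
              n_exp = sum(.data$count[.data$expanded]),
              max_cn = max(.data$cn),
              .groups = "drop")
  totals <- per_pop |>
    group_by(.data$variant_id) |>
    summarise(n_tot = sum(.data$n), n_exp_tot = sum(.data$n_exp),
              .groups = "drop")
  out <- per_pop |>
    left_join(totals, by = "variant_id") |>
    mutate(
      frac_expanded = .data$n_exp / .data$n,
      frac_expanded_outside = (.data$n_exp_tot - .data$n_exp) /
        pmax(.data$n_tot - .data$n, 1)
    ) |>
    filter(.data$frac_expanded >= min_frac,
           .data$frac_expanded_outside < min_frac / 2) |>
    select("variant_id", "population", "max_cn", "frac_expanded",
           "modal_cn", "frac_expanded_outside")
  class(out) <- c("runaway_calls", class(out))
  out
}

#' Smallest overlapping region consistent across carrier samples
#'
#' Discovery algorithms can report an expansion with slightly different
#' boundaries per sample; the conservative display region is the
#' intersection of all carrier intervals. An empty intersection is an error
#' prompting per-cluster reporting.
#'
#' @param intervals Tibble (`chrom`, `start`, `end`), one row per carrier.
#' @return One-row tibble (`chrom`, `start`, `end`).
#' @export
minimal_consistent_region <- function(intervals) {
  iv <- as_tibble(intervals)
  if (nrow(iv) == 0) abort("no carrier intervals supplied")
  if (length(unique(iv$chrom)) > 1) {
    abort("carrier intervals span multiple chromosomes")
  }
  s <- max(iv$start); e <- min(iv$end)
  if (e <= s) {
    abort("carrier intervals have an empty intersection; report per cluster")
  }
  tibble(chrom = iv$chrom[1], start = s, end = e)
}

#' Flag homozygous expanded haplotypes
#'
#' With phased haplotype copy numbers, equal haplotypes at or above
#' `modal_cn + margin` indicate the same expanded runaway haplotype present
#' twice in one individual; without phase only a high-diploid-CN flag is
#' possible.
#'
#' @param cn Diploid copy number.
#' @param hap_cn Optional length-2 vector of phased haplotype copy numbers;
#'   must sum to `cn`.
#' @param modal_cn Global modal diploid CN at the locus (default 2).
#' @param margin Expansion margin on the haplotype scale (default 2).
#' @return One of `"homozygous_expanded"`, `"not_homozygous_expanded"`,
#'   `"high_cn_phase_unknown"`, `"unremarkable"`.
#' @export
homozygous_expansion_flag <- function(cn, hap_cn = NULL, modal_cn = 2,
                                      margin = 2) {
  if (!is.null(hap_cn)) {
    stopifnot(length(hap_cn) == 2)
    if (sum(hap_cn) != cn) {
      abort("haplotype copy numbers must sum to the diploid CN")
    }
    hap_modal <- modal_cn / 2
    if (hap_cn[1] == hap_cn[2] && hap_cn[1] >= hap_modal + margin) {
      return("homozygous_expanded")
    }
    return("not_homozygous_expanded")
  }
  if (cn >= modal_cn + 2 * margin) "high_cn_phase_unknown" else "unremarkable"
}
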