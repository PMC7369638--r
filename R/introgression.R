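#' Classify archaic genotype states from copy-number calls
#'
#' Compares each archaic genome's diploid copy number at a locus to the
#' reference-diploid expectation (2 unless annotated otherwise): below is
#' DEL, above DUP, equal REF. Calls below the quality threshold are MISSING
#' -- ambiguous archaic genotypes are never guessed.
#'
#' @param archaic Tibble (`variant_id`, `genome`, `cn`, `cnq`).
#' @param variants Variant tibble (or [sv_callset()]); every archaic
#'   `variant_id` must be known.
#' @param cnq_min Quality threshold (default 13, ~95% confidence on the
#'   phred scale).
#' @param ref_cn Reference diploid copy number, a single value or a named
#'   vector by variant id for segmental-duplication loci (default 2).
#' @return Tibble (`variant_id`, `genome`, `state`, `cn`, `cnq`), state in
#'   REF / DEL / DUP / MISSING.
#' @export
classify_archaic <- function(archaic, variants, cnq_min = 13, ref_cn = 2) {
  v <- if (inherits(variants, "sv_callset")) variants$variants else as_tibble(variants)
  archaic <- as_tibble(archaic)
  unknown <- setdiff(archaic$variant_id, v$id)
  if (length(unknown)) {
    abort(paste("classify_archaic: unknown variant id(s):",
                paste(head(unknown, 5), collapse = ", ")))
  }
  ref <- if (length(ref_cn) == 1) rep(ref_cn, nrow(archaic)) else {
    r <- ref_cn[archaic$variant_id]
    r[is.na(r)] <- 2
    r
  }
  archaic |>
    mutate(state = dplyr::case_when(
      is.na(.data$cn) | is.na(.data$cnq) | .data$cnq < cnq_min ~ "MISSING",
      .data$cn < ref ~ "DEL",
      .data$cn > ref ~ "DUP",
      TRUE ~ "REF"
    ))
}

#' Variants exclusive to Africans and archaic genomes
#'
#' The "ancestral" set: variants carried only by African-region populations
#' among modern humans and present (non-reference) in at least one archaic
#' genome -- ancestral variation lost in the out-of-Africa bottleneck.
#'
#' @param freq An `sv_freq` table at region level (from
#'   [population_frequencies()] with `by = "region"`).
#' @param states Tibble from [classify_archaic()].
#' @param african_region African region label (default `"AFRICA"`).
#' @return Character vector of variant ids.
#' @export
ancestral_african_set <- function(freq, states, african_region = "AFRICA") {
  by <- intersect(c("region", "population"), names(freq))[1]
  wide <- tidyr::pivot_wider(freq, id_cols = "variant_id",
                             names_from = dplyr::all_of(by),
                             values_from = "af")
  if (!african_region %in% names(wide)) {
    abort(sprintf("region '%s' absent from frequency table", african_region))
  }
  other <- setdiff(names(wide), c("variant_id", african_region))
  afr_pos <- !is.na(wide[[african_region]]) & wide[[african_region]] > 0
  out_zero <- rowSums(as.matrix(wide[other]) > 0, na.rm = TRUE) == 0
  shared <- states |>
    filter(.data$state %in% c("DEL", "DUP")) |>
    pull(.data$variant_id) |>
    unique()
  wide$variant_id[afr_pos & out_zero & wide$variant_id %in% shared]
}

#' Scan for putatively introgressed archaic-shared variants
#'
#' The candidate filter chain: highly stratified (`Vst > vst_min`), shared
#' with at least one archaic genome in the direction of the variant's
#' non-reference state (a DEL candidate needs an archaic DEL), and absent
#' from African populations (`AF <= african_max`; strictly 0 by default --
#' the tolerance is explicit rather than a manual judgment call). The three
#' filters commute. PBS ranks are attached when supplied.
#'
#' @param freq Region-level `sv_freq` table.
#' @param states Tibble from [classify_archaic()].
#' @param vst_tbl Tibble (`variant_id`, `vst`) from [vst_scan()].
#' @param vst_min Vst threshold (default 0.2).
#' @param african_max Maximum tolerated African allele frequency (default 0).
#' @param african_region African region label.
#' @param pbs_tbl Optional tibble (`variant_id`, `rank`).
#' @return Tibble of candidates sorted by position, class `sv_introgression`:
#'   variant metadata columns when available, per-region `af_*` columns,
#'   `vst`, `sharing_archaic`, `pbs_rank`.
#' @export
introgression_scan <- function(freq, states, vst_tbl, vst_min = 0.2,
                               african_max = 0, african_region = "AFRICA",
                               pbs_tbl = NULL) {
  by <- intersect(c("region", "population"), names(freq))[1]
  wide <- tidyr::pivot_wider(freq, id_cols = c("variant_id", "svtype"),
                             names_from = dplyr::all_of(by),
                             values_from = "af", names_prefix = "af_")
  afr_col <- paste0("af_", african_region)
  if (!afr_col %in% names(wide)) {
    abort(sprintf("region '%s' absent from frequency table", african_region))
  }
  # direction-matched archaic sharing
  dir_of <- c(DEL = "DEL", DUP = "DUP", mCNV = "ANY")
  sharing <- states |>
    filter(.data$state %in% c("DEL", "DUP")) |>
    group_by(.data$variant_id) |>
    summarise(arch_states = list(setNames(.data$state, .data$genome)),
              .groups = "drop")
  wide <- left_join(wide, sharing, by = "variant_id")
  wide$sharing_archaic <- purrr::map2_chr(
    wide$arch_states, dir_of[wide$svtype],
    function(st, want) {
      if (is.null(st) || is.na(want)) return(NA_character_)
      hit <- if (want == "ANY") names(st) else names(st)[st == want]
      if (length(hit)) paste(sort(hit), collapse = ",") else NA_character_
    }
  )
  wide <- left_join(wide, select(as_tibble(vst_tbl), "variant_id", "vst"),
                    by = "variant_id")

  afr_af <- wide[[afr_col]]
  cand <- wide |>
    filter(
      !is.na(.data$vst) & .data$vst > vst_min,
      !is.na(.data$sharing_archaic),
      !is.na(afr_af) & afr_af <= african_max
    ) |>
    select(-"arch_states")
  if (!is.null(pbs_tbl)) {
    cand <- left_join(cand,
                      select(as_tibble(pbs_tbl), "variant_id",
                             pbs_rank = "rank"),
                      by = "variant_id")
  } else {
    cand$pbs_rank <- NA_real_
  }
  class(cand) <- c("sv_introgression", class(cand))
  cand
}

#' Format an introgression candidate report
#'
#' Table-style report: 1-based position string, size, variant class,
#' per-region frequencies to two decimals, PBS rank, and one column per
#' archaic genome (MISSING rendered as an en dash).
#'
#' @param candidates Tibble from [introgression_scan()].
#' @param variants Variant tibble (or [sv_callset()]) supplying coordinates.
#' @param states Tibble from [classify_archaic()] for the per-genome columns.
#' @return A formatted tibble (empty with headers when there are no
#'   candidates).
#' @export
format_candidate_report <- function(candidates, variants, states) {
  v <- if (inherits(variants, "sv_callset")) variants$variants else as_tibble(variants)
  genomes <- sort(unique(states$genome))
  af_cols <- grep("^af_", names(candidates), value = TRUE)
  base <- tibble(position = character(), size = integer(), variant = character())
  if (nrow(candidates) == 0) {
    empty <- bind_cols(base,
                       as_tibble(setNames(rep(list(character()),
                                              length(af_cols) + length(genomes) + 1),
                                          c(af_cols, "pbs_rank", genomes))))
    return(empty)
  }
  meta <- v[match(candidates$variant_id, v$id), ]
  out <- tibble(
    position = sprintf("%s:%d–%d", meta$chrom, meta$start + 1L, meta$end),
    size = meta$size,
    variant = candidates$svtype
  )
  for (col in af_cols) out[[col]] <- sprintf("%.2f", candidates[[col]])
  out$pbs_rank <- ifelse(is.na(candidates$pbs_rank), "–",
                         sprintf("%.1f", 100 * candidates$pbs_rank))
  st <- states |>
    mutate(state = ifelse(.data$state == "MISSING", "–", .data$state))
  for (g in genomes) {
    gs <- filter(st, .data$genome == g)
    out[[g]] <- gs$state[match(candidates$variant_id, gs$variant_id)]
  }
  ord <- order(meta$chrom, meta$start)
  out[ord, ]
}
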