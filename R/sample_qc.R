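#' Normalised rolling-mean coverage profiles
#'
#' Normalises each sample's binned depth by its genome-wide median and takes
#' a centred rolling mean per chromosome. Cell-line aneuploidies show up as
#' chromosomes (or runs of bins) departing from 1.0.
#'
#' @param depth Tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `depth` (as produced by [simulate_coverage()]).
#' @param window Rolling-mean window in bins (1 = per-bin normalised depth).
#' @param min_positions Minimum genome-wide bins per sample.
#' @return Tibble with an added `norm_depth` column, class
#'   `coverage_profile`.
#' @export
profile_coverage <- function(depth, window = 10, min_positions = 1000) {
  depth <- as_tibble(depth)
  counts <- dplyr::count(depth, .data$sample_id)
  if (any(counts$n < min_positions)) {
    abort(sprintf("profile_coverage: samples with fewer than %d genome-wide positions",
                  min_positions))
  }
  out <- depth |>
    group_by(.data$sample_id) |>
    mutate(.norm = .data$depth / median(.data$depth)) |>
    group_by(.data$sample_id, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(norm_depth = as.numeric(
      zoo::rollapply(.data$.norm, window, mean, partial = TRUE)
    )) |>
    ungroup() |>
    select(-".norm")
  class(out) <- c("coverage_profile", class(out))
  out
}

#' Flag aneuploid chromosomes and segments from a coverage profile
#'
#' Reports maximal runs of at least `min_run` consecutive bins beyond the
#' gain/loss thresholds; a chromosome with at least `whole_frac` of its bins
#' beyond a threshold is flagged whole. Mean ratios between the thresholds
#' and 1 +/- 0.4 are classed mosaic.
#'
#' @param profile A `coverage_profile` from [profile_coverage()].
#' @param gain_thresh,loss_thresh Normalised-depth thresholds (defaults 1.35
#'   and 0.65, separating full trisomy/monosomy ratios of 1.5/0.5 from
#'   noise).
#' @param min_run Minimum run length in bins (default 20).
#' @param whole_frac Fraction of bins beyond threshold that promotes a flag
#'   to whole-chromosome (default 0.9).
#' @return Tibble of flags: `sample_id`, `chrom`, `start`, `end`,
#'   `whole_chrom`, `class` (gain / loss / mosaic_gain / mosaic_loss),
#'   `mean_ratio`, `n_bins`.
#' @export
flag_aneuploidies <- function(profile, gain_thresh = 1.35, loss_thresh = 0.65,
                              min_run = 20, whole_frac = 0.9) {
  flags <- profile |>
    group_by(.data$sample_id, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      state <- ifelse(d$norm_depth >= gain_thresh, 1L,
                      ifelse(d$norm_depth <= loss_thresh, -1L, 0L))
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- which(r$values != 0 & r$lengths >= min_run)
      if (!length(hit)) return(tibble())
      purrr::map_dfr(hit, function(h) {
        i <- starts[h]:ends[h]
        ratio <- mean(d$norm_depth[i])
        gain <- r$values[h] == 1L
        tibble(
          start = d$start[starts[h]], end = d$end[ends[h]],
          whole_chrom = length(i) >= whole_frac * nrow(d),
          class = if (gain) {
            if (ratio >= 1.4) "gain" else "mosaic_gain"
          } else {
            if (ratio <= 0.6) "loss" else "mosaic_loss"
          },
          mean_ratio = ratio, n_bins = length(i)
        )
      })
    }) |>
    ungroup()
  if (nrow(flags) == 0) {
    flags <- tibble(sample_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    whole_chrom = logical(), class = character(),
                    mean_ratio = numeric(), n_bins = integer())
  }
  flags
}

#' Build per-sample masks from aneuploidy flags
#'
#' Samples flagged on at least `multi_chrom_exclude` distinct autosomes are
#' excluded entirely (putative cell-line artifacts across multiple
#' chromosomes); other flagged samples receive region masks for the flagged
#' intervals.
#'
#' @param flags Tibble from [flag_aneuploidies()].
#' @param multi_chrom_exclude Number of distinct flagged autosomes that
#'   triggers whole-sample exclusion (default 2).
#' @return List with `masks` (tibble `sample_id`, `chrom`, `start`, `end`)
#'   and `excluded` (character vector of sample ids), class `sample_masks`.
#' @export
build_masks <- function(flags, multi_chrom_exclude = 2) {
  flags <- as_tibble(flags)
  per_sample <- flags |>
    filter(is_autosome(.data$chrom)) |>
    group_by(.data$sample_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop")
  excluded <- per_sample$sample_id[per_sample$n_chrom >= multi_chrom_exclude]
  masks <- flags |>
    filter(!.data$sample_id %in% excluded) |>
    mutate(
      # a whole-chromosome flag masks the entire chromosome, not just the
      # binned span it was detected from
      start = ifelse(.data$whole_chrom, 0, .data$start),
      end = ifelse(.data$whole_chrom, .Machine$integer.max, .data$end)
    ) |>
    select("sample_id", "chrom", "start", "end")
  structure(list(masks = masks, excluded = excluded), class = "sample_masks")
}

#' Apply sample masks to a callset
#'
#' Genotypes of masked samples at variants overlapping a masked interval are
#' set to missing; excluded samples are dropped from the callset. Unmasked
#' genotypes are never altered, so the operation is idempotent.
#'
#' @param x An [sv_callset()].
#' @param masks A `sample_masks` object from [build_masks()].
#' @return The masked [sv_callset()].
#' @export
apply_masks <- function(x, masks) {
  unknown <- setdiff(unique(masks$masks$sample_id), x$samples)
  if (length(unknown)) {
    abort(paste("mask refers to unknown sample(s):",
                paste(head(unknown, 5), collapse = ", ")))
  }
  # excluded samples may already have been dropped by an earlier application
  drop <- intersect(masks$excluded, x$samples)
  if (length(drop)) {
    x <- subset_callset(x, samples = setdiff(x$samples, drop))
  }
  v <- x$variants
  for (r in seq_len(nrow(masks$masks))) {
    m <- masks$masks[r, ]
    si <- match(m$sample_id, x$samples)
    if (is.na(si)) next
    hit <- v$chrom == m$chrom & v$start < m$end & v$end > m$start
    for (field in c("dosage", "gq", "cn", "cnq")) {
      if (!is.null(x[[field]])) x[[field]][hit, si] <- NA_integer_
    }
  }
  x
}

#' Exact one-sided heterozygote-excess test
#'
#' Probability, under the exact Hardy-Weinberg (Levene/Haldane) distribution
#' conditional on the allele counts, of observing at least as many
#' heterozygotes as seen. Small values indicate the shared-heterozygote
#' genotyping artifact that batch filtering targets.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return One-sided p-value in (0, 1].
#' @export
exchet_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) abort("exchet_pvalue: no genotypes")
  na <- 2 * n_hom_alt + n_het        # minor-side allele count (alt)
  # feasible heterozygote counts share the parity of the allele count
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    nalt <- (na - h) / 2
    nref <- n - h - nalt
    lgamma(n + 1) - lgamma(nref + 1) - lgamma(h + 1) - lgamma(nalt + 1) +
      h * log(2) +
      lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hets >= n_het])
}

#' Excess-heterozygosity batch filter
#'
#' Removes variants whose exact heterozygote-excess p-value falls below the
#' per-batch threshold within any library batch, and optionally below
#' `overall` across the whole dataset. Batches with fewer than two genotyped
#' samples are skipped with a warning. Only biallelic (dosage) genotypes are
#' tested; variants without dosages pass through.
#'
#' @param x An [sv_callset()] with dosages.
#' @param panel Population panel; every callset sample needs a batch.
#' @param thresholds Named numeric vector, batch label -> p-value threshold
#'   (a batch present in the data but absent here is an error).
#' @param overall Whole-dataset threshold applied in addition to the
#'   per-batch passes (default `1e-5`; `NULL` disables).
#' @return The filtered [sv_callset()]; attribute `filter_log` is a tibble
#'   (`variant_id`, `batch`, `p`, `action`) of removals.
#' @export
batch_exchet_filter <- function(x, panel, thresholds, overall = 1e-5) {
  panel <- panel_for(x, panel)
  batches <- unique(panel$batch)
  missing_thr <- setdiff(batches, names(thresholds))
  if (length(missing_thr)) {
    abort(paste("no ExcHet threshold for batch(es):",
                paste(missing_thr, collapse = ", ")))
  }
  if (is.null(x$dosage)) abort("batch_exchet_filter requires dosages")

  counts <- function(d) c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                          sum(d == 2, na.rm = TRUE))
  log_rows <- list()
  drop <- rep(FALSE, n_variants(x))
  warned <- character(0)
  for (b in batches) {
    cols <- which(panel$batch == b)
    for (vi in seq_len(n_variants(x))) {
      d <- x$dosage[vi, cols]
      k <- counts(d)
      if (sum(k) < 2) {
        if (!b %in% warned && sum(k) == 1) {
          warn(sprintf("batch '%s' has a single genotyped sample; ExcHet skipped", b))
          warned <- c(warned, b)
        }
        next
      }
      p <- exchet_pvalue(k[1], k[2], k[3])
      if (p < thresholds[[b]]) {
        drop[vi] <- TRUE
        log_rows[[length(log_rows) + 1]] <-
          tibble(variant_id = x$variants$id[vi], batch = b, p = p,
                 action = "removed")
      }
    }
  }
  if (!is.null(overall)) {
    for (vi in seq_len(n_variants(x))) {
      k <- counts(x$dosage[vi, ])
      if (sum(k) < 2) next
      p <- exchet_pvalue(k[1], k[2], k[3])
      if (p < overall) {
        drop[vi] <- TRUE
        log_rows[[length(log_rows) + 1]] <-
          tibble(variant_id = x$variants$id[vi], batch = "_overall_", p = p,
                 action = "removed")
      }
    }
  }
  out <- subset_callset(x, variants = !drop)
  attr(out, "filter_log") <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(variant_id = character(), batch = character(), p = numeric(),
           action = character())
  out
}
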