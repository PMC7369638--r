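#' Reciprocal overlap between genomic intervals
#'
#' The standard SV-matching criterion: the minimum of the two directional
#' overlap fractions, `min(|a n b| / |a|, |a n b| / |b|)`. Intervals on
#' different chromosomes overlap by 0; zero-length intervals are an error.
#' Vectorised over its arguments.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Interval coordinates
#'   (0-based, half-open).
#' @return Numeric vector of overlap fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  la <- end_a - start_a
  lb <- end_b - start_b
  if (any(la <= 0) || any(lb <= 0)) abort("zero-length interval")
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ifelse(chrom_a == chrom_b, pmin(ov / la, ov / lb), 0)
}

#' Merge one sample's copy-number call fragments
#'
#' Joint CNV genotypers can split a single event into several adjacent
#' fragments. High-quality calls (CNQ strictly greater than `cnq_min`) with
#' the same diploid copy number and gaps of at most `max_gap` are chained
#' transitively into one call spanning the constituents; the merged CNQ is
#' the minimum of the constituents. Calls at or below the quality floor are
#' never merged and pass through unchanged.
#'
#' @param calls Tibble of one sample's calls with columns `chrom`, `start`,
#'   `end`, `cn`, `cnq` (and optionally `id`).
#' @param max_gap Maximum gap in bp between chained fragments (default 50000).
#' @param cnq_min Quality floor; only calls with `cnq > cnq_min` are merged
#'   (default 12).
#' @return Tibble of merged calls with an added `n_constituents` column and a
#'   `constituents` list-column of input ids; attribute `merge_records` holds
#'   the merge log.
#' @export
merge_sample_fragments <- function(calls, max_gap = 50000, cnq_min = 12) {
  calls <- as_tibble(calls)
  if (!"id" %in% names(calls)) calls$id <- paste0("call", seq_len(nrow(calls)))
  mergeable <- !is.na(calls$cnq) & calls$cnq > cnq_min
  keep_cols <- c("chrom", "start", "end", "cn", "cnq", "id")

  passthrough <- calls[!mergeable, keep_cols] |>
    mutate(n_constituents = 1L, constituents = purrr::map(.data$id, identity))

  merged <- calls[mergeable, keep_cols] |>
    arrange(.data$chrom, .data$cn, .data$start, .data$end) |>
    group_by(.data$chrom, .data$cn) |>
    mutate(
      # gap to the running (cumulative) end of the previous fragments;
      # transitive chaining: A-B and B-C chained implies A-C chained
      .gap = .data$start - dplyr::lag(cummax(.data$end)),
      .new = is.na(.data$.gap) | .data$.gap > max_gap,
      .chain = cumsum(.data$.new)
    ) |>
    group_by(.data$chrom, .data$cn, .data$.chain) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      cnq = min(.data$cnq),
      id = first(.data$id),
      n_constituents = dplyr::n(),
      constituents = list(.data$id),
      .groups = "drop"
    ) |>
    select(dplyr::all_of(c(keep_cols, "n_constituents", "constituents")))

  out <- bind_rows(merged, passthrough) |>
    arrange(.data$chrom, .data$start, .data$end)
  attr(out, "merge_records") <- out |>
    filter(.data$n_constituents > 1) |>
    mutate(rule = "sample_fragment_50kb")
  out
}

#' Collapse per-sample calls with identical intervals into multi-sample variants
#'
#' The cross-sample merge requires exact interval identity (the 100% overlap
#' rule) and matching svtype; genotypes of collapsed rows are united by taking
#' the per-sample non-missing call. Identical intervals with conflicting
#' svtype are kept separate with a warning.
#'
#' @param x An [sv_callset()] whose variant rows may repeat the same locus.
#' @return An [sv_callset()] with one row per distinct (interval, svtype);
#'   attribute `n_merged_from` reports the input variant count.
#' @export
merge_cross_sample <- function(x) {
  v <- x$variants
  key <- paste(v$chrom, v$start, v$end, v$svtype, sep = "")
  locus <- paste(v$chrom, v$start, v$end, sep = "")
  conflicted <- tapply(v$svtype, locus, function(s) length(unique(s)) > 1)
  if (any(conflicted)) {
    warn(sprintf("merge_cross_sample: %d locus(i) with conflicting svtype kept separate",
                 sum(conflicted)))
  }
  grp <- match(key, unique(key))
  take_first <- !duplicated(grp)

  unite <- function(m) {
    if (is.null(m)) return(NULL)
    out <- matrix(NA_integer_, length(unique(grp)), ncol(m))
    for (g in seq_len(nrow(out))) {
      rows <- which(grp == g)
      sub <- m[rows, , drop = FALSE]
      out[g, ] <- apply(sub, 2, function(col) {
        nz <- col[!is.na(col)]
        if (length(nz)) nz[1] else NA_integer_
      })
    }
    rownames(out) <- v$id[take_first]
    out
  }
  res <- sv_callset(v[take_first, ], x$samples,
                    dosage = unite(x$dosage), gq = unite(x$gq),
                    cn = unite(x$cn), cnq = unite(x$cnq))
  attr(res, "n_merged_from") <- nrow(v)
  res
}

#' Match two callsets by reciprocal overlap and estimate novelty
#'
#' A variant of `A` is "shared" when any variant of `B` reaches reciprocal
#' overlap at least `f_min` at the locus level -- svtype is ignored by
#' default, since a locus can be structurally variable under different class
#' labels across callers; set `type_aware = TRUE` to require matching svtype.
#' Novelty is the fraction of `A` with no such match.
#'
#' @param a,b [sv_callset()] objects (or variant tibbles) on the same
#'   reference coordinates.
#' @param f_min Reciprocal overlap threshold (0.3 for cross-study comparison,
#'   0.5 for within-study merging).
#' @param type_aware Require identical svtype for a match (default `FALSE`).
#' @return List with `matches` (tibble `id_a`, `id_b`, `f`), `novelty`
#'   (fraction of `a` unmatched) and `shared_ids`.
#' @export
match_callsets <- function(a, b, f_min = 0.3, type_aware = FALSE) {
  va <- if (inherits(a, "sv_callset")) a$variants else as_tibble(a)
  vb <- if (inherits(b, "sv_callset")) b$variants else as_tibble(b)
  if (nrow(vb) == 0 || nrow(va) == 0) {
    return(list(matches = tibble(id_a = character(), id_b = character(),
                                 f = numeric()),
                novelty = if (nrow(va)) 1 else NaN,
                shared_ids = character()))
  }
  gra <- GenomicRanges::GRanges(va$chrom, IRanges::IRanges(va$start + 1L, va$end))
  grb <- GenomicRanges::GRanges(vb$chrom, IRanges::IRanges(vb$start + 1L, vb$end))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  f <- reciprocal_overlap(va$chrom[i], va$start[i], va$end[i],
                          vb$chrom[j], vb$start[j], vb$end[j])
  keep <- f >= f_min
  if (type_aware) keep <- keep & va$svtype[i] == vb$svtype[j]
  matches <- tibble(id_a = va$id[i[keep]], id_b = vb$id[j[keep]], f = f[keep])
  shared <- unique(matches$id_a)
  list(matches = matches,
       novelty = 1 - length(shared) / nrow(va),
       shared_ids = shared)
}

#' Collapse adjacent private-variant fragments
#'
#' Complex events can be reported as several adjacent entries; to avoid
#' over-counting, fragments with the same copy number (or svtype for
#' biallelic variants), similar allele frequency (`|dAF| <= af_tol`) and gaps
#' of at most `max_gap` are chained transitively into one counted unit.
#'
#' @param variants Tibble with columns `chrom`, `start`, `end`, `af`, and
#'   `cn` (falls back to `svtype` as the identity key if `cn` is absent).
#' @param max_gap Maximum chaining gap in bp (default 25000).
#' @param af_tol Maximum allele-frequency difference between adjacent chained
#'   fragments (default 0.05).
#' @return Tibble of collapsed units with `n_constituents` and a
#'   `constituents` list-column.
#' @export
collapse_private_fragments <- function(variants, max_gap = 25000, af_tol = 0.05) {
  v <- as_tibble(variants)
  if (!"id" %in% names(v)) v$id <- paste0("frag", seq_len(nrow(v)))
  keycol <- if ("cn" %in% names(v)) "cn" else "svtype"
  v <- arrange(v, .data$chrom, .data$start, .data$end)
  if (nrow(v) == 0) return(mutate(v, n_constituents = integer(), constituents = list()))
  new_chain <- logical(nrow(v))
  new_chain[1] <- TRUE
  if (nrow(v) > 1) {
    run_end <- v$end[1]
    run_af <- v$af[1]
    for (i in 2:nrow(v)) {
      ok <- v$chrom[i] == v$chrom[i - 1] &&
        identical(v[[keycol]][i], v[[keycol]][i - 1]) &&
        abs(v$af[i] - run_af) <= af_tol &&
        (v$start[i] - run_end) <= max_gap
      if (ok) {
        run_end <- max(run_end, v$end[i])
        run_af <- v$af[i]
      } else {
        new_chain[i] <- TRUE
        run_end <- v$end[i]
        run_af <- v$af[i]
      }
    }
  }
  grp <- cumsum(new_chain)
  v |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      !!keycol := first(.data[[keycol]]),
      af = mean(.data$af),
      n_constituents = dplyr::n(),
      constituents = list(.data$id),
      .groups = "drop"
    ) |>
    select(-".grp")
}

#' Allele-frequency concordance between matched callsets
#'
#' Pearson correlation of allele frequencies over variants matched between
#' two callsets; used to assess genotyping concordance across callers or
#' against published catalogues.
#'
#' @param matches Tibble with columns `af_a` and `af_b` (one row per matched
#'   variant pair).
#' @return Pearson `r`.
#' @export
af_correlation <- function(matches) {
  m <- as_tibble(matches)
  ok <- complete.cases(m$af_a, m$af_b)
  if (sum(ok) < 3) abort("af_correlation needs at least 3 matched pairs")
  cor(m$af_a[ok], m$af_b[ok])
}
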