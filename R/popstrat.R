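#' Per-population allele frequencies and missingness
#'
#' Applies GQ masking first, then computes for every variant x group cell
#' the non-reference allele frequency over non-missing genotypes, the
#' missingness, the genotyped sample count and the carrier count. Cells with
#' missingness above `miss_max` have their frequency set to `NA` (recorded,
#' never silently dropped). Sex chromosomes are excluded by default.
#'
#' @param x An [sv_callset()] with dosages.
#' @param panel Population panel covering every callset sample.
#' @param gq_min GQ threshold applied before counting (default 20).
#' @param miss_max Per-group missingness ceiling (default 0.25).
#' @param by Grouping column of the panel: `"population"` (default) or
#'   `"region"`.
#' @param autosomes_only Drop sex-chromosome variants (default `TRUE`).
#' @return Tibble (`variant_id`, `svtype`, group column, `n_samples`,
#'   `n_called`, `missingness`, `af`, `n_carriers`), class `sv_freq`.
#' @export
population_frequencies <- function(x, panel, gq_min = 20, miss_max = 0.25,
                                   by = c("population", "region"),
                                   autosomes_only = TRUE) {
  by <- match.arg(by)
  panel <- panel_for(x, panel)
  if (any(table(panel[[by]]) == 0)) abort("empty group in panel")
  if (!is.null(x$gq)) x <- mask_low_gq(x, gq_min, quiet = TRUE)
  if (autosomes_only) {
    x <- subset_callset(x, variants = is_autosome(x$variants$chrom))
    panel <- panel  # samples unchanged
  }
  if (is.null(x$dosage)) abort("population_frequencies requires dosages")

  groups <- unique(panel[[by]])
  res <- purrr::map_dfr(groups, function(g) {
    cols <- which(panel[[by]] == g)
    d <- x$dosage[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    missing <- 1 - n_called / length(cols)
    af <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
    af[missing > miss_max] <- NA_real_
    tibble(
      variant_id = x$variants$id,
      svtype = x$variants$svtype,
      group = g,
      n_samples = length(cols),
      n_called = as.integer(unname(n_called)),
      missingness = unname(missing),
      af = unname(af),
      n_carriers = as.integer(unname(rowSums(d >= 1, na.rm = TRUE)))
    )
  })
  names(res)[names(res) == "group"] <- by
  class(res) <- c("sv_freq", class(res))
  res
}

#' Hudson's two-population Fst components for one or more sites
#'
#' Returns the per-site numerator and denominator of the Hudson estimator so
#' callers can aggregate as a ratio of averages (the recommended low-bias
#' aggregation): `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `D = p1(1-p2) + p2(1-p1)` with `n1`, `n2` allele counts.
#'
#' @param p1,p2 Allele frequencies in the two populations.
#' @param n1,n2 Allele (not sample) counts; must be at least 2.
#' @return Tibble (`numerator`, `denominator`, `fst`); sites monomorphic in
#'   both populations have `D = 0` and `fst = NA` and must be excluded from
#'   ratio-of-averages aggregation (see [mean_fst()]).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2, na.rm = TRUE) || any(n2 < 2, na.rm = TRUE)) {
    abort("hudson_fst needs allele counts of at least 2")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(numerator = num, denominator = den,
         fst = ifelse(den > 0, num / den, NA_real_))
}

#' Ratio-of-averages mean Fst
#' @param fst_tbl Tibble from [hudson_fst()].
#' @return `sum(N) / sum(D)` over sites with `D > 0`.
#' @export
mean_fst <- function(fst_tbl) {
  ok <- !is.na(fst_tbl$denominator) & fst_tbl$denominator > 0 &
    !is.na(fst_tbl$numerator)
  sum(fst_tbl$numerator[ok]) / sum(fst_tbl$denominator[ok])
}

#' Pairwise Hudson Fst between all population pairs of a frequency table
#'
#' @param freq An `sv_freq` table from [population_frequencies()].
#' @return Tibble (`pop_a`, `pop_b`, `fst`, `n_sites`), ratio-of-averages
#'   per pair.
#' @export
pairwise_fst <- function(freq) {
  by <- intersect(c("population", "region"), names(freq))[1]
  wide_af <- tidyr::pivot_wider(freq, id_cols = "variant_id",
                                names_from = dplyr::all_of(by),
                                values_from = "af")
  wide_n <- tidyr::pivot_wider(freq, id_cols = "variant_id",
                               names_from = dplyr::all_of(by),
                               values_from = "n_called")
  pops <- setdiff(names(wide_af), "variant_id")
  combos <- utils::combn(pops, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(pr) {
    p1 <- wide_af[[pr[1]]]; p2 <- wide_af[[pr[2]]]
    n1 <- 2 * wide_n[[pr[1]]]; n2 <- 2 * wide_n[[pr[2]]]
    ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
    h <- hudson_fst(p1[ok], n1[ok], p2[ok], n2[ok])
    tibble(pop_a = pr[1], pop_b = pr[2], fst = mean_fst(h),
           n_sites = sum(ok))
  })
}

#' Maximum allele-frequency difference scan over population pairs
#'
#' For every population pair, the maximum over variants of the absolute
#' allele-frequency difference (skipping cells recorded `NA`), its argmax
#' variant, and -- when supplied -- the pair's mean SNV Fst for the x-axis of
#' the stratification plot. Pairs involving a population of at most
#' `min_pop_n` samples are flagged for exclusion from trend fitting.
#'
#' @param freq An `sv_freq` table (population level).
#' @param fst Optional tibble (`pop_a`, `pop_b`, `fst`) of mean pairwise SNV
#'   Fst (the conservative null axis); [pairwise_fst()] output also works.
#' @param min_pop_n Sample-size floor (default 10).
#' @return Tibble (`pop_a`, `pop_b`, `fst`, `max_diff`, `variant_id`,
#'   `small_pop`), class `sv_strat`.
#' @export
max_af_diff_scan <- function(freq, fst = NULL, min_pop_n = 10) {
  wide <- tidyr::pivot_wider(freq, id_cols = "variant_id",
                             names_from = "population", values_from = "af")
  sizes <- freq |> distinct(.data$population, .data$n_samples)
  pops <- setdiff(names(wide), "variant_id")
  combos <- utils::combn(pops, 2, simplify = FALSE)
  out <- purrr::map_dfr(combos, function(pr) {
    d <- abs(wide[[pr[1]]] - wide[[pr[2]]])
    if (all(is.na(d))) {
      return(tibble(pop_a = pr[1], pop_b = pr[2], max_diff = NA_real_,
                    variant_id = NA_character_))
    }
    i <- which.max(d)
    tibble(pop_a = pr[1], pop_b = pr[2], max_diff = d[i],
           variant_id = wide$variant_id[i])
  })
  out$small_pop <- sizes$n_samples[match(out$pop_a, sizes$population)] <= min_pop_n |
    sizes$n_samples[match(out$pop_b, sizes$population)] <= min_pop_n
  if (!is.null(fst)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    out$fst <- fst$fst[match(key(out$pop_a, out$pop_b),
                             key(fst$pop_a, fst$pop_b))]
  }
  out <- out[, c("pop_a", "pop_b", intersect("fst", names(out)), "max_diff",
                 "variant_id", "small_pop")]
  class(out) <- c("sv_strat", class(out))
  out
}

# core Vst statistic on clean (non-missing) values; population-variance
# convention (divide by n), size-weighted within-group average
.vst_stat <- function(values, labels) {
  v_t <- mean(values^2) - mean(values)^2
  if (v_t <= 0) return(c(vst = 0, v_t = v_t, v_s = v_t))
  s <- rowsum(values, labels)
  s2 <- rowsum(values^2, labels)
  ng <- as.vector(rowsum(rep(1, length(values)), labels))
  vg <- s2 / ng - (s / ng)^2
  v_s <- sum(ng * vg) / length(values)
  c(vst = (v_t - v_s) / v_t, v_t = v_t, v_s = v_s)
}

#' Vst: between-population copy-number differentiation
#'
#' `Vst = (V_T - V_S) / V_T`, where `V_T` is the variance of all values and
#' `V_S` the size-weighted mean within-population variance (population
#' variance convention, divide by n). Defined as 0 when `V_T = 0`. Applies
#' to diploid copy numbers and equally to biallelic dosages treated as
#' pseudo copy numbers.
#'
#' @param values Numeric per-sample values (CN or dosage); `NA` dropped.
#' @param labels Population label per sample.
#' @return One-row tibble (`vst`, `v_t`, `v_s`, `n`, `n_groups`).
#' @export
vst <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- as.numeric(values[ok]); labels <- as.character(labels[ok])
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("vst needs >= 2 groups with >= 2 non-missing values each")
  }
  st <- .vst_stat(values, labels)
  tibble(vst = unname(st["vst"]), v_t = unname(st["v_t"]),
         v_s = unname(st["v_s"]), n = length(values),
         n_groups = length(tab))
}

#' Label-permutation test for population stratification (pVst)
#'
#' Permutes population labels uniformly `B` times and reports the add-one
#' empirical p-value `(k + 1) / (B + 1)` for the observed Vst, giving a
#' floor of `1 / (B + 1)` (~0.001 at the conventional B = 1000).
#'
#' @param values,labels As in [vst()].
#' @param B Number of permutations (default 1000).
#' @param seed Optional seed for reproducible permutations.
#' @return An object of class `vst_perm` with fields `observed`, `B`, `k`,
#'   `p`, `seed`; see [tidy.vst_perm()].
#' @export
vst_permutation_test <- function(values, labels, B = 1000, seed = NULL) {
  ok <- !is.na(values) & !is.na(labels)
  values <- as.numeric(values[ok]); labels <- as.character(labels[ok])
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("vst_permutation_test needs >= 2 groups with >= 2 values each")
  }
  observed <- unname(.vst_stat(values, labels)["vst"])
  run <- function() {
    n <- length(values)
    idx <- vapply(seq_len(B), function(i) sample.int(n), integer(length(values)))
    vmat <- matrix(values[idx], n, B)
    v_t <- mean(values^2) - mean(values)^2
    if (v_t <= 0) return(rep(0, B))
    s <- rowsum(vmat, labels)
    s2 <- rowsum(vmat^2, labels)
    ng <- as.vector(table(factor(labels, levels = rownames(s))))
    vg <- s2 / ng - (s / ng)^2
    v_s <- colSums(vg * ng) / n
    (v_t - v_s) / v_t
  }
  perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  k <- sum(perm >= observed)
  structure(
    list(observed = observed, B = B, k = k, p = (k + 1) / (B + 1),
         seed = seed, perm = perm),
    class = "vst_perm"
  )
}

#' @export
print.vst_perm <- function(x, ...) {
  cat(sprintf("Vst permutation test: observed Vst = %.4f, B = %d, k = %d, p = %.4g\n",
              x$observed, x$B, x$k, x$p))
  invisible(x)
}

#' Population branch statistic from three pairwise Fst values
#'
#' Branch lengths `T = -log(1 - Fst)`; `PBS = (T_fs + T_fo - T_so) / 2`
#' measures frequency shift specific to the focal branch. Negative Fst is
#' clamped to 0 before the log (only here; raw values are kept elsewhere);
#' `Fst = 1` gives an infinite branch and is an error.
#'
#' @param fst_fs,fst_fo,fst_so Pairwise Fst: focal-sister, focal-outgroup,
#'   sister-outgroup. Vectorised.
#' @return Numeric PBS value(s).
#' @export
pbs <- function(fst_fs, fst_fo, fst_so) {
  if (any(c(fst_fs, fst_fo, fst_so) >= 1, na.rm = TRUE)) {
    abort("pbs: Fst = 1 gives an infinite branch length")
  }
  bl <- function(f) -log(1 - pmax(f, 0))
  (bl(fst_fs) + bl(fst_fo) - bl(fst_so)) / 2
}

#' Per-variant PBS scan against a null distribution
#'
#' Computes per-variant Hudson Fst for the three populations of `triple`,
#' the PBS for the focal population, and each variant's rank within
#' `null_values` (intended: the SNV PBS distribution, a conservative null;
#' when `NULL` the scan's own PBS values are used as a self-null). Variants
#' failing the pooled minor-allele-frequency or missingness filters are
#' excluded; ranks at or above `rank_min` are flagged as departures from
#' neutrality.
#'
#' @param x An [sv_callset()] with dosages.
#' @param panel Population panel.
#' @param triple Character vector `c(focal, sister, outgroup)`; always
#'   explicit, never inferred.
#' @param null_values Numeric null PBS distribution or `NULL` for self-null.
#' @param maf_min Pooled minor-allele-frequency floor (default 0.01).
#' @param miss_max Pooled missingness ceiling (default 0.10).
#' @param gq_min GQ masking threshold (default 20).
#' @param rank_min Rank threshold for the neutrality-departure flag
#'   (default 0.99).
#' @param rank_ties How ties against the null are ranked. `"upper"`
#'   (default) is the plain fraction of null values at or below the PBS;
#'   because negative Fst clamps to zero inside the PBS transform, the
#'   statistic has an atom at exactly 0 and upper ranks are conservative
#'   (inflated) there. `"midrank"` centres ties; `"random"` draws uniformly
#'   within the tie block (the randomized quantile transform), which makes
#'   self-null ranks exactly uniform and is what calibration checks use.
#' @return Tibble (`variant_id`, `fst_fs`, `fst_fo`, `fst_so`, `pbs`,
#'   `rank`, `flagged`), class `sv_pbs`.
#' @export
pbs_scan <- function(x, panel, triple, null_values = NULL,
                     maf_min = 0.01, miss_max = 0.10, gq_min = 20,
                     rank_min = 0.99,
                     rank_ties = c("upper", "midrank", "random")) {
  rank_ties <- match.arg(rank_ties)
  stopifnot(length(triple) == 3)
  panel <- panel_for(x, panel)
  if (!all(triple %in% panel$population)) {
    abort("pbs_scan: triple populations absent from panel")
  }
  keep_samples <- panel$population %in% triple
  x <- subset_callset(x, samples = x$samples[keep_samples])
  panel <- panel[keep_samples, ]
  if (!is.null(x$gq)) x <- mask_low_gq(x, gq_min, quiet = TRUE)
  x <- subset_callset(x, variants = is_autosome(x$variants$chrom) &
                        rowSums(!is.na(x$dosage)) > 0)

  d <- x$dosage
  called <- rowSums(!is.na(d))
  pooled_af <- rowSums(d, na.rm = TRUE) / (2 * pmax(called, 1))
  maf <- pmin(pooled_af, 1 - pooled_af)
  missing <- 1 - called / ncol(d)
  keep <- called > 0 & maf >= maf_min & missing <= miss_max
  d <- d[keep, , drop = FALSE]
  ids <- x$variants$id[keep]
  if (!nrow(d)) {
    return(structure(tibble(variant_id = character(), fst_fs = numeric(),
                            fst_fo = numeric(), fst_so = numeric(),
                            pbs = numeric(), rank = numeric(),
                            flagged = logical()),
                     class = c("sv_pbs", class(tibble()))))
  }

  pf <- function(pop) {
    cols <- which(panel$population == pop)
    dd <- d[, cols, drop = FALSE]
    nc <- rowSums(!is.na(dd))
    list(p = rowSums(dd, na.rm = TRUE) / (2 * pmax(nc, 1)), n = 2 * nc)
  }
  f1 <- pf(triple[1]); f2 <- pf(triple[2]); f3 <- pf(triple[3])
  site_fst <- function(a, b) {
    ok <- a$n >= 2 & b$n >= 2
    out <- rep(NA_real_, length(a$p))
    h <- hudson_fst(a$p[ok], a$n[ok], b$p[ok], b$n[ok])
    out[ok] <- ifelse(is.na(h$fst), 0, h$fst)
    # keep branch lengths finite at locally fixed differences
    pmin(out, 1 - 1e-9)
  }
  fst_fs <- site_fst(f1, f2)
  fst_fo <- site_fst(f1, f3)
  fst_so <- site_fst(f2, f3)
  pbs_val <- pbs(fst_fs, fst_fo, fst_so)
  null_values <- null_values %||% pbs_val[!is.na(pbs_val)]
  rank <- vapply(pbs_val, function(v) {
    if (is.na(v)) return(NA_real_)
    le <- mean(null_values <= v)
    if (rank_ties == "upper") return(le)
    lt <- mean(null_values < v)
    if (rank_ties == "midrank") (le + lt) / 2 else lt + runif(1) * (le - lt)
  }, numeric(1))
  out <- tibble(variant_id = ids, fst_fs = fst_fs, fst_fo = fst_fo,
                fst_so = fst_so, pbs = pbs_val, rank = rank,
                flagged = !is.na(rank) & rank >= rank_min)
  class(out) <- c("sv_pbs", class(out))
  out
}

#' Per-variant Vst scan
#'
#' Computes Vst per variant between groups of the panel, on dosages
#' (biallelic variants, treated as pseudo copy numbers) or on diploid copy
#' numbers (multiallelic variants, CNQ-filtered). Which field is used is an
#' explicit argument, never inferred.
#'
#' @param x An [sv_callset()].
#' @param panel Population panel.
#' @param use `"dosage"` or `"cn"`.
#' @param by Grouping column (default `"region"`).
#' @param gq_min,cnq_min Quality thresholds for the respective field.
#' @return Tibble (`variant_id`, `vst`, `v_t`, `v_s`, `n`).
#' @export
vst_scan <- function(x, panel, use = c("dosage", "cn"), by = "region",
                     gq_min = 20, cnq_min = 13) {
  use <- match.arg(use)
  panel <- panel_for(x, panel)
  labels <- panel[[by]]
  if (use == "dosage") {
    if (!is.null(x$gq)) x <- mask_low_gq(x, gq_min, quiet = TRUE)
    m <- x$dosage
  } else {
    m <- x$cn
    if (!is.null(x$cnq)) m[is.na(x$cnq) | x$cnq < cnq_min] <- NA_integer_
  }
  if (is.null(m)) abort(sprintf("callset has no %s matrix", use))
  purrr::map_dfr(seq_len(nrow(m)), function(vi) {
    vals <- m[vi, ]
    ok <- !is.na(vals)
    tab <- table(labels[ok])
    if (length(tab) < 2 || any(tab < 2)) {
      return(tibble(variant_id = x$variants$id[vi], vst = NA_real_,
                    v_t = NA_real_, v_s = NA_real_, n = sum(ok)))
    }
    st <- .vst_stat(as.numeric(vals[ok]), as.character(labels[ok]))
    tibble(variant_id = x$variants$id[vi], vst = unname(st["vst"]),
           v_t = unname(st["v_t"]), v_s = unname(st["v_s"]), n = sum(ok))
  })
}

#' Private variants of populations or regions
#'
#' A variant is private to a unit when every carrier (dosage >= 1, or
#' non-modal copy number for multiallelic variants) belongs to that unit and
#' there are more than `min_carriers - 1` carriers. At the region level,
#' recently admixed samples (own-region admixture below `admix_min`) are
#' removed first. Adjacent same-type fragments with similar frequencies are
#' collapsed before counting (see [collapse_private_fragments()]).
#'
#' @param x An [sv_callset()] with dosages.
#' @param panel Population panel.
#' @param level `"population"` or `"region"`.
#' @param min_carriers Minimum carrier count (default 3, i.e. n > 2).
#' @param exclude_admixed Drop admixed samples at region level (default
#'   `TRUE`).
#' @param admix_min Own-region admixture fraction below which a sample is
#'   considered admixed (default 0.8).
#' @param gq_min GQ masking threshold.
#' @param collapse Collapse adjacent fragments before counting (default
#'   `TRUE`).
#' @param max_gap,af_tol Collapse parameters (defaults 25000 bp, 0.05).
#' @return Tibble (`variant_id`, `unit`, `n_carriers`, `af`,
#'   `n_constituents`).
#' @export
private_variants <- function(x, panel, level = c("population", "region"),
                             min_carriers = 3, exclude_admixed = TRUE,
                             admix_min = 0.8, gq_min = 20,
                             collapse = TRUE, max_gap = 25000, af_tol = 0.05) {
  level <- match.arg(level)
  panel <- panel_for(x, panel)
  if (level == "region" && exclude_admixed) {
    own_col <- paste0("admixture_", panel$region)
    own <- vapply(seq_len(nrow(panel)), function(i) {
      if (own_col[i] %in% names(panel)) panel[[own_col[i]]][i] else 1
    }, numeric(1))
    keep <- own >= admix_min
    x <- subset_callset(x, samples = x$samples[keep])
    panel <- panel[keep, ]
  }
  if (!is.null(x$gq)) x <- mask_low_gq(x, gq_min, quiet = TRUE)
  x <- subset_callset(x, variants = is_autosome(x$variants$chrom))
  units <- panel[[level]]

  carrier <- matrix(FALSE, n_variants(x), n_samples(x))
  if (!is.null(x$dosage)) carrier <- carrier | (!is.na(x$dosage) & x$dosage >= 1)
  if (!is.null(x$cn)) {
    modal <- apply(x$cn, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_integer_)
      tab <- table(v)
      as.integer(names(tab)[which.max(tab)])  # ties resolve to lower CN
    })
    carrier <- carrier | (!is.na(x$cn) & x$cn != modal)
  }

  per_variant <- purrr::map_dfr(seq_len(n_variants(x)), function(vi) {
    cars <- which(carrier[vi, ])
    u <- unique(units[cars])
    if (length(u) != 1) return(tibble())
    af <- if (!is.null(x$dosage) && !all(is.na(x$dosage[vi, ]))) {
      cols <- which(units == u)
      d <- x$dosage[vi, cols]
      sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
    } else {
      length(cars) / sum(units == u)  # multiallelic: carrier fraction
    }
    tibble(variant_id = x$variants$id[vi], unit = u,
           n_carriers = length(cars), af = af)
  })
  if (nrow(per_variant) == 0) {
    return(tibble(variant_id = character(), unit = character(),
                  n_carriers = integer(), af = numeric(),
                  n_constituents = integer()))
  }
  per_variant <- inner_join(per_variant,
                            select(x$variants, "id", "chrom", "start", "end",
                                   "svtype"),
                            by = c(variant_id = "id"))
  if (collapse) {
    per_variant <- per_variant |>
      group_by(.data$unit) |>
      dplyr::group_modify(function(d, key) {
        col <- collapse_private_fragments(
          rename(d, id = "variant_id"), max_gap = max_gap, af_tol = af_tol
        )
        col |>
          mutate(variant_id = purrr::map_chr(.data$constituents, 1),
                 n_carriers = purrr::map_int(.data$constituents, function(ids) {
                   max(d$n_carriers[match(ids, d$variant_id)])
                 })) |>
          select("variant_id", "n_carriers", "af", "n_constituents")
      }) |>
      ungroup()
  } else {
    per_variant <- mutate(per_variant, n_constituents = 1L) |>
      select("variant_id", "unit", "n_carriers", "af", "n_constituents")
  }
  filter(per_variant, .data$n_carriers >= min_carriers)
}

#' Squared genotype correlation (LD r^2) between two dosage vectors
#'
#' Squared Pearson correlation over jointly non-missing samples; `NA` when
#' either vector is constant.
#'
#' @param dos_a,dos_b Dosage vectors.
#' @return r^2, or `NA` on zero variance.
#' @export
genotype_r2 <- function(dos_a, dos_b) {
  ok <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(ok) < 3) abort("genotype_r2 needs >= 3 jointly non-missing samples")
  a <- dos_a[ok]; b <- dos_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}
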