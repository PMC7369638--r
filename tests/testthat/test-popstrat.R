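mini_freq_callset <- function(dosage, gq = NULL, chrom = "chr1") {
  nv <- nrow(dosage); ns <- ncol(dosage)
  v <- tibble::tibble(
    id = paste0("v", seq_len(nv)), chrom = chrom,
    start = as.integer(seq_len(nv) * 10000L),
    end = as.integer(seq_len(nv) * 10000L + 500L),
    svtype = "DEL", size = 500L
  )
  rownames(dosage) <- v$id
  if (!is.null(gq)) rownames(gq) <- v$id
  sv_callset(v, paste0("s", seq_len(ns)), dosage = dosage, gq = gq)
}

mini_panel <- function(n, pops, regions = NULL) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    population = pops,
    region = regions %||% pops,
    batch = "b", excluded = FALSE
  )
}

test_that("population frequencies count alleles over non-missing calls only", {
  dos <- matrix(c(2L, 1L, 0L, NA), 1, 4)
  cs <- mini_freq_callset(dos)
  fr <- population_frequencies(cs, mini_panel(4, rep("P1", 4)))
  expect_equal(fr$af, 0.5)          # 3 alt alleles / 6 called alleles
  expect_equal(fr$missingness, 0.25)
  expect_equal(fr$n_called, 3L)

  # the whole population missing gives an NA cell, not a silent drop
  cs2 <- mini_freq_callset(matrix(NA_integer_, 1, 4))
  fr2 <- population_frequencies(cs2, mini_panel(4, rep("P1", 4)))
  expect_true(is.na(fr2$af))

  # GQ below threshold is masked before counting
  dos3 <- matrix(1L, 1, 4)
  gq3 <- matrix(c(19L, 60L, 60L, 60L), 1, 4)
  fr3 <- population_frequencies(mini_freq_callset(dos3, gq3),
                                mini_panel(4, rep("P1", 4)))
  expect_equal(fr3$af, 0.5)         # 3 of 4 calls survive, all het
  expect_equal(fr3$missingness, 0.25)

  # missingness above the ceiling blanks the frequency
  dos4 <- matrix(c(1L, 1L, NA, NA), 1, 4)
  fr4 <- population_frequencies(mini_freq_callset(dos4),
                                mini_panel(4, rep("P1", 4)), miss_max = 0.25)
  expect_true(is.na(fr4$af))
  expect_equal(fr4$missingness, 0.5)

  # sex chromosomes are excluded from statistics by default
  csx <- mini_freq_callset(matrix(1L, 1, 4), chrom = "chrX")
  frx <- population_frequencies(csx, mini_panel(4, rep("P1", 4)))
  expect_equal(nrow(frx), 0)
})

test_that("Hudson Fst components match the closed form", {
  h <- hudson_fst(1, 40, 0, 40)
  expect_equal(h$fst, 1)                       # fixation
  h2 <- hudson_fst(0.5, 20, 0.5, 20)
  expect_equal(h2$numerator, -0.25 / 19 * 2, tolerance = 1e-12)
  expect_equal(round(h2$numerator, 5), -0.02632)
  expect_equal(h2$denominator, 0.5)
  expect_error(hudson_fst(0.5, 1, 0.5, 20), "at least 2")
  # monomorphic-in-both sites are excluded from ratio-of-averages
  tbl <- hudson_fst(c(0.3, 0), c(40, 40), c(0.1, 0), c(40, 40))
  expect_equal(mean_fst(tbl), tbl$numerator[1] / tbl$denominator[1])
})

test_that("the max AF difference scan finds the argmax and flags small populations", {
  freq <- tibble::tibble(
    variant_id = rep(c("v1", "v2"), each = 2),
    svtype = "DEL",
    population = rep(c("P1", "P2"), 2),
    n_samples = c(20L, 20L, 20L, 20L),
    n_called = 20L, missingness = 0,
    af = c(0.9, 0.1, 0.5, 0.5), n_carriers = 5L
  )
  res <- max_af_diff_scan(freq, min_pop_n = 10)
  expect_equal(res$max_diff, 0.8)
  expect_equal(res$variant_id, "v1")
  expect_false(res$small_pop)

  # identical frequency vectors give zero
  freq0 <- dplyr::mutate(freq, af = 0.4)
  expect_equal(max_af_diff_scan(freq0)$max_diff, 0)

  # a population at or below the floor is flagged
  freq_small <- dplyr::mutate(freq, n_samples = ifelse(population == "P2", 6L, 20L))
  expect_true(max_af_diff_scan(freq_small, min_pop_n = 10)$small_pop)

  # mean SNV Fst attaches by pair
  fst <- tibble::tibble(pop_a = "P1", pop_b = "P2", fst = 0.12)
  expect_equal(max_af_diff_scan(freq, fst)$fst, 0.12)
})

test_that("Vst matches its definition on the canonical examples", {
  expect_equal(vst(c(2, 2, 2, 2, 4, 4, 4, 4), rep(c("A", "B"), each = 4))$vst, 1)
  expect_equal(vst(c(2, 4, 2, 4, 2, 4, 2, 4), rep(c("A", "B"), each = 4))$vst, 0)
  r <- vst(c(2, 2, 2, 4, 2, 4, 4, 4), rep(c("A", "B"), each = 4))
  expect_equal(r$vst, 0.25)
  expect_equal(r$v_t, 1)
  expect_equal(r$v_s, 0.75)
  # shift invariance
  set.seed(41)
  vals <- sample(0:6, 40, TRUE)
  labs <- rep(c("A", "B"), each = 20)
  expect_equal(vst(vals, labs)$vst, vst(vals + 7, labs)$vst, tolerance = 1e-12)
  expect_error(vst(c(1, 2), c("A", "B")), ">= 2 groups")
})

test_that("the Vst permutation test is seeded, floored and degenerate-safe", {
  expect_equal(vst_permutation_test(rep(2, 20), rep(c("A", "B"), 10), B = 99)$p, 1)
  vals <- c(rep(0, 30), rep(2, 30))
  labs <- rep(c("A", "B"), each = 30)
  pt <- vst_permutation_test(vals, labs, B = 1000, seed = 5)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 1 / 1001)
  pt2 <- vst_permutation_test(vals, labs, B = 1000, seed = 5)
  expect_identical(pt$p, pt2$p)
  expect_identical(pt$perm, pt2$perm)
  td <- tidy(pt)
  expect_equal(td$p.value, pt$p)
  expect_equal(glance(pt)$p.floor, 1 / 1001)
})

test_that("PBS follows the branch-length formula and its symmetries", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.2, 0.2, 0), -log(0.8), tolerance = 1e-12)
  expect_equal(round(pbs(0.2, 0.2, 0), 4), 0.2231)
  expect_equal(pbs(0.3, 0.1, 0.05), pbs(0.1, 0.3, 0.05))  # sister/outgroup swap
  expect_error(pbs(1, 0.2, 0.1), "infinite")
  # strictly increasing in focal-sister Fst
  grid <- seq(0, 0.9, by = 0.1)
  vals <- sapply(grid, function(f) pbs(f, 0.2, 0.1))
  expect_true(all(diff(vals) > 0))
  # negative Fst clamps to zero inside the transform
  expect_equal(pbs(-0.05, 0, 0), 0)
})

test_that("the PBS scan applies MAF and missingness filters and ranks against the null", {
  pops <- tibble::tibble(population = c("F", "S", "O"),
                         region = c("R1", "R1", "R2"), n = 40L)
  cfg <- sim_config(pops, fst = 0.05, n_biallelic = 400, n_multiallelic = 0,
                    missingness = 0, seed = 43)
  co <- simulate_cohort(cfg)
  res <- pbs_scan(co$callset, co$panel, c("F", "S", "O"))
  expect_true(nrow(res) > 100)
  # every retained variant passes the pooled MAF filter (computed after GQ
  # masking inside the scan; the raw-dosage check allows a small margin)
  d <- co$callset$dosage[res$variant_id, ]
  af <- rowSums(d) / (2 * ncol(d))
  expect_true(all(pmin(af, 1 - af) >= 0.008))
  # ranks live in (0, 1] and the flag fires at the 99% threshold
  expect_true(all(res$rank > 0 & res$rank <= 1))
  expect_equal(res$flagged, res$rank >= 0.99)
  expect_equal(glance(res)$n_variants, nrow(res))

  # variants below 1% MAF are excluded
  cs <- co$callset
  rare <- cs$variants$id[which(af < 0.005)[1]]
  expect_false(isTRUE(rare %in% res$variant_id))
  expect_error(pbs_scan(cs, co$panel, c("F", "S", "nope")), "absent")
})

test_that("private variants require >2 carriers confined to one unit", {
  co <- fixture_cohort
  cs <- batch_exchet_filter(co$callset, co$panel, fixture_thresholds)
  priv_pop <- private_variants(cs, co$panel, level = "population")
  inj <- co$truth[co$truth$label == "private", ]
  for (i in seq_len(nrow(inj))) {
    row <- priv_pop[priv_pop$variant_id == inj$variant_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$unit, inj$target[i])
    expect_gt(row$n_carriers, 2)
  }
  # introgressed variants are private to their target region
  priv_reg <- private_variants(cs, co$panel, level = "region")
  intro <- co$truth[co$truth$label == "introgressed", ]
  expect_true(all(intro$variant_id %in% priv_reg$variant_id))

  # constructed: 2 carriers only -> not reported; carriers in 2 units -> not private
  dos <- matrix(0L, 2, 8)
  dos[1, 1:2] <- 1L       # two carriers in P1
  dos[2, c(1, 5)] <- 1L   # carriers split across P1 and P2
  csx <- mini_freq_callset(dos)
  panel <- mini_panel(8, rep(c("P1", "P2"), each = 4))
  expect_equal(nrow(private_variants(csx, panel, level = "population")), 0)
  three <- dos; three[1, 1:3] <- 1L
  csy <- mini_freq_callset(three)
  got <- private_variants(csy, panel, level = "population")
  expect_equal(got$variant_id, "v1")
  expect_equal(got$n_carriers, 3L)

  # invariant under sample order and population renaming
  perm <- sample(seq_len(8))
  csz <- subset_callset(csy, samples = paste0("s", perm))
  got2 <- private_variants(csz, panel, level = "population")
  expect_equal(got2, got)
  panel_renamed <- dplyr::mutate(panel,
                                 population = ifelse(population == "P1", "Zed", "Q"))
  got3 <- private_variants(csy, panel_renamed, level = "population")
  expect_equal(got3$variant_id, got$variant_id)
  expect_equal(got3$unit, "Zed")
})

test_that("admixed samples are excluded from region-level privacy", {
  # one P2 sample is admixed from R1 and carries the otherwise R1-private variant
  dos <- matrix(0L, 1, 8)
  dos[1, c(1, 2, 3, 5)] <- 1L
  cs <- mini_freq_callset(dos)
  panel <- mini_panel(8, rep(c("P1", "P2"), each = 4),
                      regions = rep(c("R1", "R2"), each = 4))
  panel$admixture_R1 <- c(1, 1, 1, 1, 0.4, 0, 0, 0)
  panel$admixture_R2 <- 1 - panel$admixture_R1
  expect_equal(nrow(private_variants(cs, panel, level = "region",
                                     exclude_admixed = FALSE)), 0)
  withadm <- private_variants(cs, panel, level = "region")
  expect_equal(withadm$unit, "R1")
})

test_that("genotype r-squared matches the direct formula", {
  a <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  expect_equal(genotype_r2(a, a), 1)
  expect_equal(genotype_r2(a, 2L - a), 1)   # sign-blind
  set.seed(44)
  b <- sample(0:2, 8, TRUE)
  expect_equal(genotype_r2(a, b), oracle_r2(a, b), tolerance = 1e-12)
  expect_true(is.na(genotype_r2(a, rep(1L, 8))))
  expect_error(genotype_r2(a[1:2], b[1:2]), ">= 3")
})

test_that("pairwise Fst over a structured cohort exceeds that of an unstructured one", {
  pops <- tibble::tibble(population = c("P1", "P2"), region = c("R1", "R2"), n = 50L)
  hi <- simulate_cohort(sim_config(pops, fst = 0.2, n_biallelic = 500,
                                   n_multiallelic = 0, seed = 45))
  lo <- simulate_cohort(sim_config(pops, fst = 0.01, n_biallelic = 500,
                                   n_multiallelic = 0, seed = 45))
  f_hi <- pairwise_fst(population_frequencies(hi$callset, hi$panel))
  f_lo <- pairwise_fst(population_frequencies(lo$callset, lo$panel))
  expect_gt(f_hi$fst, f_lo$fst)
  expect_lt(abs(f_hi$fst - 0.2), 0.05)
})
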