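make_depth <- function(depths_by_chrom, sample_id = "s1", bins = 50) {
  purrr::imap_dfr(depths_by_chrom, function(d, ch) {
    tibble::tibble(sample_id = sample_id, chrom = ch, bin = seq_len(bins),
                   start = (seq_len(bins) - 1L) * 1e6L,
                   end = seq_len(bins) * 1e6L,
                   depth = rep_len(d, bins))
  })
}

flat22 <- function(depth = 30) {
  setNames(as.list(rep(depth, 22)), paste0("chr", 1:22))
}

test_that("coverage profiles normalise by the genome-wide median", {
  prof <- profile_coverage(make_depth(flat22(30)), window = 5)
  expect_true(all(prof$norm_depth == 1))

  d <- flat22(30); d$chr5 <- 45
  prof2 <- profile_coverage(make_depth(d), window = 5)
  expect_equal(unique(prof2$norm_depth[prof2$chrom == "chr5"]), 1.5)
  expect_equal(unique(prof2$norm_depth[prof2$chrom == "chr1"]), 1)

  # window = 1 is the identity: profile equals per-bin normalised depth
  raw <- make_depth(flat22(30))
  raw$depth <- raw$depth * runif(nrow(raw), 0.9, 1.1)
  p1 <- profile_coverage(raw, window = 1)
  expect_equal(p1$norm_depth, p1$depth / median(raw$depth))

  expect_error(profile_coverage(make_depth(flat22(30))[1:100, ]), "1000")
})

test_that("aneuploidy flagging finds whole-chromosome and segmental events", {
  prof <- profile_coverage(make_depth(flat22(30)), window = 5)
  expect_equal(nrow(flag_aneuploidies(prof)), 0)

  d <- flat22(30); d$chr9 <- 45
  f <- flag_aneuploidies(profile_coverage(make_depth(d), window = 5))
  expect_equal(nrow(f), 1)
  expect_equal(f$chrom, "chr9")
  expect_true(f$whole_chrom)
  expect_equal(f$class, "gain")

  # 30% of one chromosome at half depth -> segmental loss over that run only
  raw <- make_depth(flat22(30), bins = 100)
  seg <- raw$chrom == "chr3" & raw$bin >= 41 & raw$bin <= 70
  raw$depth[seg] <- 15
  f2 <- flag_aneuploidies(profile_coverage(raw, window = 1), min_run = 20)
  expect_equal(f2$chrom, "chr3")
  expect_false(f2$whole_chrom)
  expect_equal(f2$class, "loss")
  expect_equal(f2$n_bins, 30)
  expect_equal(f2$start, 40e6)
  expect_equal(f2$end, 70e6)
})

test_that("mask building excludes multi-chromosome artifact samples", {
  flags <- tibble::tibble(
    sample_id = c("a", "a", "a", "b"),
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    start = 0L, end = 50e6, whole_chrom = TRUE,
    class = "gain", mean_ratio = 1.5, n_bins = 50L
  )
  m <- build_masks(flags, multi_chrom_exclude = 2)
  expect_equal(m$excluded, "a")
  expect_equal(m$masks$sample_id, "b")
  m0 <- build_masks(flags[0, ])
  expect_length(m0$excluded, 0)
  expect_equal(nrow(m0$masks), 0)
})

test_that("mask application blanks overlapped calls, drops excluded samples, never touches the rest", {
  cs <- fixture_cohort$callset
  masks <- structure(list(
    masks = tibble::tibble(sample_id = "AfrA_002", chrom = "chr9",
                           start = 0L, end = 250e6),
    excluded = "AfrB_001"
  ), class = "sample_masks")
  out <- apply_masks(cs, masks)
  expect_false("AfrB_001" %in% out$samples)
  chr9 <- out$variants$id[out$variants$chrom == "chr9"]
  expect_true(all(is.na(out$dosage[chr9, "AfrA_002"])))
  expect_true(all(is.na(out$cn[chr9, "AfrA_002"])))
  other <- setdiff(out$variants$id, chr9)
  keep <- setdiff(out$samples, "AfrA_002")
  expect_identical(out$dosage[other, keep], cs$dosage[other, keep])
  # idempotent
  out2 <- apply_masks(out, masks)
  expect_identical(out2$dosage, out$dosage)
  expect_error(
    apply_masks(cs, structure(list(masks = tibble::tibble(
      sample_id = "nobody", chrom = "chr1", start = 0L, end = 1e6),
      excluded = character(0)), class = "sample_masks")),
    "unknown sample"
  )
})

test_that("the exact heterozygote-excess test matches enumeration and is monotone", {
  # frozen from the enumeration oracle: n = 4, all alleles het
  expect_equal(exchet_pvalue(0, 4, 0), 8 / 35, tolerance = 1e-12)
  expect_equal(round(exchet_pvalue(0, 4, 0), 4), 0.2286)
  # zero heterozygotes can never be an excess
  expect_equal(exchet_pvalue(5, 0, 3), 1)
  # 50 shared heterozygotes fall below the strictest filtering threshold
  expect_lt(exchet_pvalue(0, 50, 0), 1e-4)
  expect_error(exchet_pvalue(0, 0, 0), "no genotypes")

  # full agreement with the enumeration oracle for every n <= 5 configuration
  for (n in 2:5) {
    for (na in 0:n) {
      hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
      for (h in hets) {
        naa <- (na - h) / 2
        expect_equal(exchet_pvalue(n - h - naa, h, naa), oracle_exchet(n - h - naa, h, naa),
                     tolerance = 1e-10,
                     label = sprintf("exchet n=%d na=%d het=%d", n, na, h))
      }
    }
  }

  # monotone non-increasing in the heterozygote count at fixed allele counts
  for (n in c(6, 9)) {
    na <- n  # half the alleles alt
    hets <- seq(na %% 2, na, by = 2)
    ps <- sapply(hets, function(h) {
      naa <- (na - h) / 2
      exchet_pvalue(n - h - naa, h, naa)
    })
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("the batch ExcHet filter removes artifacts and spares HWE-conforming variants", {
  pops <- tibble::tibble(population = c("P1", "P2"), region = c("R1", "R2"),
                         n = 60L)
  cfg <- sim_config(
    pops, n_biallelic = 500, n_multiallelic = 0,
    batch_artifact = tibble::tibble(batch = "SangerPCR", n_variants = 10L),
    batches = tibble::tibble(batch = c("SangerPCRfree", "SangerPCR"),
                             n = c(100L, 20L)),
    seed = 21
  )
  co <- simulate_cohort(cfg)
  out <- batch_exchet_filter(co$callset, co$panel, fixture_thresholds)
  removed <- setdiff(co$callset$variants$id, out$variants$id)
  artifacts <- co$truth$variant_id[co$truth$label == "batch_artifact"]
  neutral <- co$truth$variant_id[co$truth$label == "neutral"]
  expect_gte(mean(artifacts %in% removed), 0.95)
  expect_lt(mean(neutral %in% removed), 0.01)
  log <- attr(out, "filter_log")
  expect_true(all(artifacts %in% log$variant_id))

  # a single-sample batch is skipped with a warning, not tested
  panel1 <- co$panel
  panel1$batch[1] <- "Meyer"
  expect_warning(
    batch_exchet_filter(co$callset, panel1,
                        c(fixture_thresholds, Meyer = 1e-3)),
    "single genotyped sample"
  )
  # a batch without a threshold is fatal
  expect_error(batch_exchet_filter(co$callset, panel1, fixture_thresholds),
               "threshold")
})
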