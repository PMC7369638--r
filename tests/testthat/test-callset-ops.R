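test_that("reciprocal overlap matches the base-counting oracle and is symmetric", {
  expect_equal(reciprocal_overlap("c", 100, 200, "c", 100, 200), 1)
  expect_equal(reciprocal_overlap("c", 100, 200, "c", 300, 400), 0)
  expect_equal(reciprocal_overlap("c", 100, 200, "c", 150, 250), 0.5)
  expect_equal(reciprocal_overlap("c1", 100, 200, "c2", 100, 200), 0)
  expect_error(reciprocal_overlap("c", 100, 100, "c", 100, 200), "zero-length")

  set.seed(31)
  for (i in 1:200) {
    s1 <- sample.int(500, 1); e1 <- s1 + sample.int(300, 1)
    s2 <- sample.int(500, 1); e2 <- s2 + sample.int(300, 1)
    f <- reciprocal_overlap("c", s1, e1, "c", s2, e2)
    expect_equal(f, oracle_reciprocal_overlap(s1, e1, s2, e2), tolerance = 1e-12)
    expect_equal(f, reciprocal_overlap("c", s2, e2, "c", s1, e1))
    expect_equal(f == 1, s1 == s2 && e1 == e2)
  }
})

test_that("fragment merging chains same-CN high-quality calls within the gap", {
  calls <- tibble::tibble(
    chrom = "chr1", start = c(0L, 40000L), end = c(10000L, 60000L),
    cn = 3L, cnq = 20L
  )
  m <- merge_sample_fragments(calls)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 60000L)
  expect_equal(m$cn, 3L)
  expect_equal(m$cnq, 20L)
  expect_equal(m$n_constituents, 2L)

  # a 60 kb gap breaks the chain
  far <- calls; far$start[2] <- 70000L; far$end[2] <- 90000L
  expect_equal(nrow(merge_sample_fragments(far)), 2)
  # the quality floor is strict: CNQ = 12 never merges
  low <- calls; low$cnq[2] <- 12L
  expect_equal(nrow(merge_sample_fragments(low)), 2)
  # differing CN never merges
  diffcn <- calls; diffcn$cn[2] <- 2L
  expect_equal(nrow(merge_sample_fragments(diffcn)), 2)
})

test_that("fragment merging is idempotent, order-independent and chains transitively", {
  set.seed(32)
  calls <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 40, TRUE),
    start = as.integer(sample.int(3e5, 40)),
    cn = sample(1:4, 40, TRUE),
    cnq = sample(c(10L, 25L, 40L), 40, TRUE)
  )
  calls$end <- calls$start + as.integer(sample.int(30000, 40))
  m1 <- merge_sample_fragments(calls)
  m2 <- merge_sample_fragments(dplyr::select(m1, -"n_constituents", -"constituents"))
  expect_equal(dplyr::select(m2, "chrom", "start", "end", "cn", "cnq"),
               dplyr::select(m1, "chrom", "start", "end", "cn", "cnq"),
               ignore_attr = TRUE)
  shuffled <- calls[sample.int(nrow(calls)), ]
  m3 <- merge_sample_fragments(shuffled)
  expect_equal(dplyr::select(m3, "chrom", "start", "end", "cn"),
               dplyr::select(m1, "chrom", "start", "end", "cn"),
               ignore_attr = TRUE)
  # merged high-quality intervals are disjoint within a CN class
  hq <- dplyr::filter(m1, cnq > 12) |> dplyr::arrange(chrom, cn, start)
  by_grp <- split(hq, paste(hq$chrom, hq$cn))
  for (g in by_grp) {
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)] + 50000 - 1))
  }
  # A-B and B-C within gap implies one A-C chain
  tri <- tibble::tibble(chrom = "chr1", start = c(0L, 40000L, 80000L),
                        end = c(10000L, 50000L, 90000L), cn = 3L, cnq = 30L)
  expect_equal(nrow(merge_sample_fragments(tri)), 1)
})

test_that("cross-sample merging requires exact interval identity", {
  v <- tibble::tibble(
    id = paste0("v", 1:3),
    chrom = "chr1", start = c(1000L, 1000L, 1001L),
    end = c(5000L, 5000L, 5000L), svtype = "DEL", size = 4000L
  )
  dos <- matrix(c(1L, NA, NA, NA, 1L, NA, NA, NA, 1L), 3, 3, byrow = TRUE,
                dimnames = list(v$id, NULL))
  cs <- sv_callset(v, paste0("s", 1:3), dosage = dos)
  m <- merge_cross_sample(cs)
  expect_equal(nrow(m$variants), 2)  # 1 bp difference keeps variants apart
  merged_id <- m$variants$id[m$variants$start == 1000L]
  expect_equal(unname(m$dosage[merged_id, ]), c(1L, 1L, NA))

  # identical interval with conflicting svtype stays separate, with a warning
  v2 <- v; v2$svtype <- c("DEL", "DUP", "DEL")
  cs2 <- sv_callset(v2, paste0("s", 1:3), dosage = dos)
  expect_warning(m2 <- merge_cross_sample(cs2), "conflicting")
  expect_equal(nrow(m2$variants), 3)
})

test_that("callset matching computes locus-level novelty", {
  mk <- function(starts, svtype = "DEL") {
    n <- length(starts)
    sv_callset(tibble::tibble(
      id = paste0("x", seq_len(n), "_", starts), chrom = "chr1",
      start = as.integer(starts), end = as.integer(starts + 1000L),
      svtype = svtype, size = 1000L
    ), character(0))
  }
  a <- mk(c(0, 10000, 20000, 30000))
  expect_equal(match_callsets(a, a, 0.5)$novelty, 0)
  empty <- mk(integer(0))
  expect_equal(match_callsets(a, empty, 0.3)$novelty, 1)
  # one A variant overlaps B at f = 0.5 -> novelty 3/4 at f_min = 0.3
  b <- mk(500)
  res <- match_callsets(a, b, 0.3)
  expect_equal(res$novelty, 0.75)
  expect_equal(res$matches$f, 0.5)
  # locus-level by default: svtype mismatch still matches
  b_dup <- mk(500, svtype = "DUP")
  expect_equal(match_callsets(a, b_dup, 0.3)$novelty, 0.75)
  expect_equal(match_callsets(a, b_dup, 0.3, type_aware = TRUE)$novelty, 1)
  # novelty is monotone non-decreasing in f_min
  novs <- sapply(c(0.1, 0.3, 0.5, 0.7), function(f) match_callsets(a, b, f)$novelty)
  expect_true(all(diff(novs) >= 0))
})

test_that("private-fragment collapse respects CN, AF tolerance and the 25 kb gap", {
  frags <- tibble::tibble(
    chrom = "chr1", start = c(0L, 20000L), end = c(10000L, 30000L),
    cn = 3L, af = c(0.40, 0.41)
  )
  expect_equal(nrow(collapse_private_fragments(frags)), 1)
  far_af <- frags; far_af$af[2] <- 0.60
  expect_equal(nrow(collapse_private_fragments(far_af)), 2)
  far_gap <- frags; far_gap$start[2] <- 40000L; far_gap$end[2] <- 50000L
  expect_equal(nrow(collapse_private_fragments(far_gap)), 2)
  diff_cn <- frags; diff_cn$cn[2] <- 2L
  expect_equal(nrow(collapse_private_fragments(diff_cn)), 2)
  # idempotent
  once <- collapse_private_fragments(frags)
  twice <- collapse_private_fragments(dplyr::select(once, -"n_constituents",
                                                    -"constituents"))
  expect_equal(twice$start, once$start)
  expect_equal(twice$end, once$end)
})

test_that("allele-frequency concordance equals the textbook Pearson r", {
  id <- tibble::tibble(af_a = c(0.1, 0.5, 0.9), af_b = c(0.1, 0.5, 0.9))
  expect_equal(af_correlation(id), 1)
  anti <- tibble::tibble(af_a = c(0.1, 0.5, 0.9), af_b = 1 - c(0.1, 0.5, 0.9))
  expect_equal(af_correlation(anti), -1)
  set.seed(33)
  tb <- tibble::tibble(af_a = runif(10), af_b = runif(10))
  r_oracle <- with(tb, {
    n <- 10
    (n * sum(af_a * af_b) - sum(af_a) * sum(af_b)) /
      (sqrt(n * sum(af_a^2) - sum(af_a)^2) * sqrt(n * sum(af_b^2) - sum(af_b)^2))
  })
  expect_equal(af_correlation(tb), r_oracle, tolerance = 1e-12)
  expect_error(af_correlation(tb[1:2, ]), "3 matched pairs")
})
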