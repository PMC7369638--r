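# Shared seeded cohort and independent brute-force oracles.

fixture_cohort <- make_fixtures(seed = 42)
fixture_thresholds <- c(SangerPCR = 1e-3, SangerPCRfree = 1e-5)

# -- enumeration oracle for the exact heterozygote-excess test ---------------
# Uniformly enumerate every placement of the alt alleles into the 2n genotype
# slots (combn), pair consecutive slots into genotypes, and count
# heterozygotes; the p-value is the mass at or above the observed count.
oracle_exchet <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  if (na == 0 || na == 2 * n) return(if (n_het == 0) 1 else 0)
  pair <- rep(seq_len(n), each = 2)
  hets <- utils::combn(2 * n, na, FUN = function(idx) {
    sum(tabulate(pair[idx], n) == 1)
  })
  mean(hets >= n_het)
}

# -- naive two-pass Vst oracle ----------------------------------------------
oracle_vst <- function(values, labels) {
  v_t <- sum((values - mean(values))^2) / length(values)
  if (v_t <= 0) return(0)
  groups <- unique(labels)
  v_s <- 0
  for (g in groups) {
    v <- values[labels == g]
    v_s <- v_s + length(v) * (sum((v - mean(v))^2) / length(v))
  }
  v_s <- v_s / length(values)
  (v_t - v_s) / v_t
}

# -- plain-arithmetic Hudson Fst oracle -------------------------------------
oracle_hudson <- function(p1, n1, p2, n2) {
  num <- (p1 - p2) * (p1 - p2) -
    p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

# -- closed-form PBS oracle --------------------------------------------------
oracle_pbs <- function(f_fs, f_fo, f_so) {
  t_fs <- -log(1 - max(f_fs, 0))
  t_fo <- -log(1 - max(f_fo, 0))
  t_so <- -log(1 - max(f_so, 0))
  (t_fs + t_fo - t_so) / 2
}

# -- per-base counting oracle for reciprocal overlap -------------------------
oracle_reciprocal_overlap <- function(s1, e1, s2, e2) {
  a <- seq(s1, e1 - 1)
  b <- seq(s2, e2 - 1)
  ov <- length(intersect(a, b))
  min(ov / length(a), ov / length(b))
}

# -- textbook-formula Pearson r / r^2 oracle ---------------------------------
oracle_r2 <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  (num / den)^2
}

# small hand-written VCF used by the I/O tests
write_mini_vcf <- function(path, records,
                           samples = c("S1", "S2"),
                           format = "GT:GQ") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"c\">",
    "##FORMAT=<ID=CNQ,Number=1,Type=Integer,Description=\"cq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}
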