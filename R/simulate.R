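#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter object consumed by [simulate_cohort()] and friends.
#' The generator emulates the statistical structure the downstream analyses
#' assume: hierarchically structured population allele frequencies
#' (Balding-Nichols), multiallelic copy-number ladders with optional runaway
#' expansions, archaic-shared variants absent from Africa, batch-specific
#' excess-heterozygosity artifacts, and aneuploid coverage profiles. All
#' randomness flows from the single `seed`. None of these parameters is
#' estimated from real data; they are generator conventions (see the package
#' vignette).
#'
#' @param populations Tibble with columns `population`, `region`, `n`.
#' @param fst Balding-Nichols drift parameter `F` in (0, 1); per-population
#'   frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral
#'   frequency p.
#' @param n_biallelic,n_multiallelic Variant counts.
#' @param ancestral_shape1,ancestral_shape2 Beta parameters of the ancestral
#'   allele-frequency distribution (clipped to 0.01-0.99).
#' @param introgression Tibble (`target_region`, `frequency`, `archaic`
#'   (comma-separated genome names), `svtype`) of variants to inject as
#'   archaic-shared and absent from Africa, or `NULL`.
#' @param runaway Tibble (`population`, `hap_cn`, `carrier_frac`,
#'   `n_homozygous`) of runaway expansions to inject, or `NULL`.
#' @param batch_artifact Tibble (`batch`, `n_variants`) of variants forced
#'   heterozygous in every sample of one library batch, or `NULL`.
#' @param private Tibble (`population`, `frequency`) of variants carried by a
#'   single population, or `NULL`.
#' @param admixed Tibble (`population`, `n`, `other_region`, `fraction`) of
#'   samples given recent admixture from another region, or `NULL`.
#' @param batches Tibble (`batch`, `n`) assigning library batches; samples
#'   beyond the assigned counts fall into the first batch.
#' @param archaic_genomes Names of archaic genomes to genotype.
#' @param gq_shape,gq_scale Gamma parameters of the phred GQ model (defaults
#'   put ~5% of calls below GQ 20).
#' @param cnq_shape,cnq_scale Gamma parameters of the phred CNQ model
#'   (defaults put ~5% of calls below CNQ 13).
#' @param missingness Genotype missingness rate.
#' @param mcnv_minor_mean Mean Balding-Nichols ancestral frequency of the
#'   minor ladder allele at multiallelic sites.
#' @param archaic_cnq_degrade Fraction of archaic calls whose CNQ is degraded
#'   below the analysis threshold (exercises the quality-masking path).
#' @param aneuploidy Tibble (`sample_id`, `chrom`, `ratio`, `frac`) of
#'   coverage aberrations (1.5 = trisomy, 0.5 = loss, intermediate = mosaic;
#'   `frac` = affected fraction of the chromosome from its start), or `NULL`.
#' @param bins_per_chrom,n_chrom,base_depth,noise_sd Coverage model: bins per
#'   chromosome, number of autosomes, haploid-genome mean depth and
#'   multiplicative lognormal noise sd.
#' @param seed Integer seed controlling every draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations,
                       fst = 0.1,
                       n_biallelic = 200,
                       n_multiallelic = 20,
                       ancestral_shape1 = 1,
                       ancestral_shape2 = 3,
                       introgression = NULL,
                       runaway = NULL,
                       batch_artifact = NULL,
                       private = NULL,
                       admixed = NULL,
                       batches = NULL,
                       archaic_genomes = c("Neanderthal", "Denisova"),
                       gq_shape = 4, gq_scale = 15,
                       cnq_shape = 4, cnq_scale = 9.75,
                       missingness = 0.02,
                       mcnv_minor_mean = 0.15,
                       archaic_cnq_degrade = 0,
                       aneuploidy = NULL,
                       bins_per_chrom = 50,
                       n_chrom = 22,
                       base_depth = 30,
                       noise_sd = 0.05,
                       seed = 1) {
  populations <- as_tibble(populations)
  stopifnot(all(c("population", "region", "n") %in% names(populations)))
  if (any(fst <= 0) || any(fst >= 1)) abort("fst (drift F) must lie in (0, 1)")
  stopifnot(n_biallelic >= 0, n_multiallelic >= 0, missingness >= 0,
            missingness < 1)
  structure(as.list(environment()), class = "sim_config")
}

clip01 <- function(p, eps = 0.01) pmin(pmax(p, eps), 1 - eps)

# Balding-Nichols draw: per-population frequency around ancestral p with
# drift F; F -> 0 collapses to p.
bn_freq <- function(p_anc, f) {
  a <- p_anc * (1 - f) / f
  b <- (1 - p_anc) * (1 - f) / f
  rbeta(length(p_anc), a, b)
}

rphred <- function(n, shape, scale) pmax(0L, as.integer(round(rgamma(n, shape, scale = scale))))

#' Simulate biallelic structured genotypes
#'
#' Draws ancestral frequencies from the configured Beta distribution,
#' per-population frequencies from the Balding-Nichols model, and
#' Hardy-Weinberg genotypes within populations; applies the GQ quality model
#' and random missingness.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (tibble), `dosage` and `gq` matrices,
#'   `samples`, `sample_pop`, and `true_freq` (long tibble of the generating
#'   per-population frequencies).
#' @export
simulate_biallelic <- function(config) {
  nv <- config$n_biallelic
  pops <- config$populations
  p_anc <- clip01(rbeta(nv, config$ancestral_shape1, config$ancestral_shape2))
  svtype <- sample(c("DEL", "DUP", "INS", "INV"), nv, replace = TRUE,
                   prob = c(0.55, 0.15, 0.2, 0.1))
  chrom <- paste0("chr", sample.int(config$n_chrom, nv, replace = TRUE))
  start <- as.integer(round(runif(nv, 1e6, 2e8)))
  size <- as.integer(pmin(pmax(round(rlnorm(nv, log(500), 1.2)), 50L), 1e6))
  variants <- tibble(
    id = sprintf("bv%04d", seq_len(nv)),
    chrom = chrom, start = start,
    end = ifelse(svtype == "INS", start + 1L, start + size),
    svtype = svtype, size = size
  ) |> mutate(end = as.integer(.data$end))

  samples <- character(0); sample_pop <- character(0)
  dosage <- NULL
  true_freq <- list()
  fvec <- rep_len(config$fst, nrow(pops))
  for (k in seq_len(nrow(pops))) {
    n <- pops$n[k]
    ids <- sprintf("%s_%03d", pops$population[k], seq_len(n))
    p_k <- bn_freq(p_anc, fvec[k])
    d <- matrix(rbinom(nv * n, 2, rep(p_k, n)), nv, n)
    samples <- c(samples, ids)
    sample_pop <- c(sample_pop, rep(pops$population[k], n))
    dosage <- cbind(dosage, d)
    true_freq[[k]] <- tibble(variant_id = variants$id,
                             population = pops$population[k], p = p_k)
  }
  gq <- matrix(rphred(length(dosage), config$gq_shape, config$gq_scale),
               nrow(dosage), ncol(dosage))
  miss <- matrix(runif(length(dosage)) < config$missingness,
                 nrow(dosage), ncol(dosage))
  dosage[miss] <- NA_integer_
  gq[miss] <- NA_integer_
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- rownames(gq) <- variants$id
  colnames(dosage) <- colnames(gq) <- samples
  list(variants = variants, dosage = dosage, gq = gq, samples = samples,
       sample_pop = sample_pop, true_freq = bind_rows(true_freq))
}

#' Simulate multiallelic copy-number ladders
#'
#' Haplotype copy numbers evolve on a ladder: haplotype 1 is fixed at the
#' ancestral single copy, haplotype 2 carries at most one minor ladder allele
#' per variant (copy number 0 or 2) at a Balding-Nichols frequency, so
#' default diploid copy numbers enumerate to \{1, 2, 3\}. Injected runaway
#' variants place a high-copy haplotype (up to 9 copies, diploid 18 when
#' homozygous) segregating in one target population.
#'
#' @param config A [sim_config()].
#' @param samples,sample_pop Sample ids and their populations (from
#'   [simulate_biallelic()]); generated from the config when missing.
#' @return List with `variants`, `cn` and `cnq` matrices, `hap_cn` (list of
#'   the two haplotype matrices), `runaway_ids`, and `true_freq`.
#' @export
simulate_multiallelic <- function(config, samples = NULL, sample_pop = NULL) {
  nv <- config$n_multiallelic
  pops <- config$populations
  if (is.null(samples)) {
    samples <- unlist(purrr::map2(pops$population, pops$n,
                                  ~ sprintf("%s_%03d", .x, seq_len(.y))))
    sample_pop <- rep(pops$population, pops$n)
  }
  ns <- length(samples)
  chrom <- paste0("chr", sample.int(config$n_chrom, nv, replace = TRUE))
  start <- as.integer(round(runif(nv, 1e6, 2e8)))
  size <- as.integer(round(runif(nv, 1e3, 1e5)))
  variants <- tibble(
    id = sprintf("mv%03d", seq_len(nv)),
    chrom = chrom, start = start, end = start + size,
    svtype = "mCNV", size = size
  )
  minor_cn <- sample(c(0L, 2L), nv, replace = TRUE)
  # ancestral minor-allele frequency, structured across populations
  q_anc <- clip01(rbeta(nv, 2, 2 / config$mcnv_minor_mean - 2))
  hap1 <- matrix(1L, nv, ns)
  hap2 <- matrix(1L, nv, ns)
  fvec <- rep_len(config$fst, nrow(pops))
  true_freq <- list()
  for (k in seq_len(nrow(pops))) {
    idx <- which(sample_pop == pops$population[k])
    q_k <- bn_freq(q_anc, fvec[k])
    carry <- matrix(runif(nv * length(idx)) < rep(q_k, length(idx)),
                    nv, length(idx))
    hap2[, idx][carry] <- rep(minor_cn, length(idx))[carry]
    true_freq[[k]] <- tibble(variant_id = variants$id,
                             population = pops$population[k], p = q_k)
  }

  runaway_ids <- character(0)
  if (!is.null(config$runaway) && nrow(config$runaway) > 0 && nv > 0) {
    rw <- as_tibble(config$runaway)
    if (!"hap_cn" %in% names(rw)) rw$hap_cn <- 9L
    if (!"carrier_frac" %in% names(rw)) rw$carrier_frac <- 0.4
    if (!"n_homozygous" %in% names(rw)) rw$n_homozygous <- 1L
    pick <- sample.int(nv, nrow(rw))
    for (r in seq_len(nrow(rw))) {
      vi <- pick[r]
      hap2[vi, ] <- 1L  # clean background for the expansion variant
      idx <- which(sample_pop == rw$population[r])
      if (!length(idx)) abort("runaway target population absent")
      ncar <- max(1L, round(rw$carrier_frac[r] * length(idx)))
      carriers <- idx[seq_len(ncar)]
      hap2[vi, carriers] <- as.integer(rw$hap_cn[r])
      nhom <- min(rw$n_homozygous[r], length(carriers))
      if (nhom > 0) hap1[vi, carriers[seq_len(nhom)]] <- as.integer(rw$hap_cn[r])
      runaway_ids <- c(runaway_ids, variants$id[vi])
    }
  }
  cn <- hap1 + hap2
  cnq <- matrix(rphred(length(cn), config$cnq_shape, config$cnq_scale), nv, ns)
  storage.mode(cn) <- "integer"
  rownames(cn) <- rownames(cnq) <- variants$id
  colnames(cn) <- colnames(cnq) <- samples
  list(variants = variants, cn = cn, cnq = cnq,
       hap_cn = list(hap1 = hap1, hap2 = hap2),
       runaway_ids = runaway_ids, true_freq = bind_rows(true_freq))
}

#' Simulate per-sample binned coverage
#'
#' Diploid baseline with multiplicative lognormal noise; aneuploidy rows
#' scale the affected chromosome (or its leading fraction) by `ratio`
#' (1.5 trisomy, 0.5 loss, intermediate values mosaic).
#'
#' @param config A [sim_config()].
#' @param samples Sample ids; generated from the config when missing.
#' @param aneuploidy Overrides `config$aneuploidy`.
#' @return Tibble `sample_id`, `chrom`, `bin`, `start`, `end`, `depth`.
#' @export
simulate_coverage <- function(config, samples = NULL, aneuploidy = NULL) {
  if (is.null(samples)) {
    pops <- config$populations
    samples <- unlist(purrr::map2(pops$population, pops$n,
                                  ~ sprintf("%s_%03d", .x, seq_len(.y))))
  }
  aneuploidy <- aneuploidy %||% config$aneuploidy
  nb <- config$bins_per_chrom
  if (config$n_chrom * nb < 1000) {
    warn("simulate_coverage: fewer than 1000 genome-wide bins")
  }
  chroms <- paste0("chr", seq_len(config$n_chrom))
  binw <- 1e6L
  grid <- tidyr::expand_grid(chrom = chroms, bin = seq_len(nb)) |>
    mutate(start = (.data$bin - 1L) * binw, end = .data$bin * binw)
  out <- tidyr::expand_grid(sample_id = samples, grid) |>
    mutate(depth = config$base_depth *
             rlnorm(dplyr::n(), -config$noise_sd^2 / 2, config$noise_sd))
  if (!is.null(aneuploidy) && nrow(aneuploidy) > 0) {
    an <- as_tibble(aneuploidy)
    if (!"frac" %in% names(an)) an$frac <- 1
    for (r in seq_len(nrow(an))) {
      hit <- out$sample_id == an$sample_id[r] & out$chrom == an$chrom[r] &
        out$bin <= ceiling(an$frac[r] * nb)
      out$depth[hit] <- out$depth[hit] * an$ratio[r]
    }
  }
  out
}

#' Inject archaic-shared, Africa-absent variants into a cohort
#'
#' For each spec row, one neutral biallelic variant is rewritten so that its
#' frequency is 0 in every African-region population, the configured
#' frequency (Hardy-Weinberg) in the target region, and 0 elsewhere; the
#' named archaic genome(s) become homozygous for the non-reference state with
#' CNQ at or above the analysis threshold. Truth labels are updated.
#'
#' @param cohort A `sv_cohort` from [simulate_cohort()].
#' @param spec Tibble (`target_region`, `frequency`, `archaic`, `svtype`).
#' @param african_region Region label treated as Africa (default `"AFRICA"`).
#' @return The modified `sv_cohort`.
#' @export
inject_introgression <- function(cohort, spec, african_region = "AFRICA") {
  spec <- as_tibble(spec)
  panel <- cohort$panel
  if (!african_region %in% panel$region) {
    abort("cohort has no African-region populations")
  }
  if (!all(spec$target_region %in% panel$region)) {
    abort("introgression target region absent from panel")
  }
  if (!"svtype" %in% names(spec)) spec$svtype <- "DEL"
  cs <- cohort$callset
  neutral <- cohort$truth$variant_id[cohort$truth$label == "neutral" &
                                       cohort$truth$variant_id %in%
                                         cs$variants$id[cs$variants$svtype %in% c("DEL", "DUP")]]
  if (length(neutral) < nrow(spec)) abort("not enough neutral variants to rewrite")
  chosen <- neutral[seq_len(nrow(spec))]
  for (r in seq_len(nrow(spec))) {
    vid <- chosen[r]
    vi <- match(vid, cs$variants$id)
    cs$variants$svtype[vi] <- spec$svtype[r]
    in_target <- panel$region[match(cs$samples, panel$sample_id)] == spec$target_region[r]
    dos <- integer(length(cs$samples))
    if (spec$frequency[r] > 0 && any(in_target)) {
      repeat {
        dos[in_target] <- rbinom(sum(in_target), 2, spec$frequency[r])
        if (sum(dos) > 0) break
      }
    }
    cs$dosage[vi, ] <- dos
    cs$gq[vi, ] <- rphred(length(dos), cohort$config$gq_shape, cohort$config$gq_scale)
    genomes <- strsplit(spec$archaic[r], ",\\s*")[[1]]
    alt_cn <- if (spec$svtype[r] == "DUP") 4L else 0L
    hit <- cohort$archaic$variant_id == vid & cohort$archaic$genome %in% genomes
    cohort$archaic$cn[hit] <- alt_cn
    cohort$archaic$cnq[hit] <- pmax(13L, cohort$archaic$cnq[hit])
    lab <- if (spec$frequency[r] > 0) "introgressed" else "neutral"
    cohort$truth$label[cohort$truth$variant_id == vid] <- lab
    cohort$truth$target[cohort$truth$variant_id == vid] <-
      if (lab == "introgressed") spec$target_region[r] else NA_character_
  }
  cohort$callset <- cs
  cohort
}

#' Generate a full synthetic cohort with ground truth
#'
#' Orchestrates [simulate_biallelic()], [simulate_multiallelic()], archaic
#' genotyping, private-variant and batch-artifact injection,
#' [inject_introgression()] and [simulate_coverage()] under the single
#' config seed. Identical configs produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A `sv_cohort` list: `callset`, `panel`, `archaic` (tibble
#'   `variant_id`, `genome`, `cn`, `cnq`), `coverage`, `truth` (one label per
#'   variant: neutral / introgressed / runaway / batch_artifact / private),
#'   `true_freq`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  pops <- config$populations

  bi <- simulate_biallelic(config)
  mc <- simulate_multiallelic(config, bi$samples, bi$sample_pop)

  truth <- tibble(
    variant_id = c(bi$variants$id, mc$variants$id),
    label = "neutral", target = NA_character_
  )
  truth$label[truth$variant_id %in% mc$runaway_ids] <- "runaway"
  if (length(mc$runaway_ids)) {
    truth$target[match(mc$runaway_ids, truth$variant_id)] <-
      as_tibble(config$runaway)$population
  }

  # private variants: carriers restricted to one population
  if (!is.null(config$private) && nrow(config$private) > 0) {
    pv <- as_tibble(config$private)
    cand <- bi$variants$id[truth$label[seq_len(nrow(bi$variants))] == "neutral"]
    cand <- tail(cand, nrow(pv))
    for (r in seq_len(nrow(pv))) {
      vid <- cand[r]
      vi <- match(vid, bi$variants$id)
      in_pop <- bi$sample_pop == pv$population[r]
      dos <- integer(length(bi$samples))
      repeat {
        dos[in_pop] <- rbinom(sum(in_pop), 2, pv$frequency[r])
        if (sum(dos > 0) > 2) break
      }
      bi$dosage[vi, ] <- dos
      bi$gq[vi, ] <- rphred(length(dos), config$gq_shape, config$gq_scale)
      truth$label[truth$variant_id == vid] <- "private"
      truth$target[truth$variant_id == vid] <- pv$population[r]
    }
  }

  # panel: batches, admixture simplex, exclusion flag
  regions <- unique(pops$region)
  samples <- bi$samples
  batch <- rep("SangerPCRfree", length(samples))
  if (!is.null(config$batches) && nrow(config$batches) > 0) {
    bt <- as_tibble(config$batches)
    pos <- 1L
    for (r in seq_len(nrow(bt))) {
      batch[seq(pos, length.out = bt$n[r])] <- bt$batch[r]
      pos <- pos + bt$n[r]
    }
    if (pos <= length(samples)) batch[pos:length(samples)] <- bt$batch[1]
  }
  adm <- matrix(0, length(samples), length(regions),
                dimnames = list(NULL, paste0("admixture_", regions)))
  own_region <- pops$region[match(bi$sample_pop, pops$population)]
  adm[cbind(seq_along(samples), match(own_region, regions))] <- 1
  if (!is.null(config$admixed) && nrow(config$admixed) > 0) {
    ax <- as_tibble(config$admixed)
    for (r in seq_len(nrow(ax))) {
      idx <- head(which(bi$sample_pop == ax$population[r]), ax$n[r])
      adm[idx, match(own_region[idx], regions)] <- 1 - ax$fraction[r]
      adm[idx, paste0("admixture_", ax$other_region[r])] <- ax$fraction[r]
    }
  }
  panel <- bind_cols(
    tibble(sample_id = samples, population = bi$sample_pop,
           region = own_region, batch = batch),
    as_tibble(adm)
  ) |> mutate(excluded = FALSE) |> validate_panel()

  # batch heterozygosity artifact: every sample of one batch forced het
  if (!is.null(config$batch_artifact) && nrow(config$batch_artifact) > 0) {
    ba <- as_tibble(config$batch_artifact)
    if (!"n_variants" %in% names(ba)) ba$n_variants <- 1L
    cand <- bi$variants$id[truth$label[seq_len(nrow(bi$variants))] == "neutral"]
    pos <- 1L
    for (r in seq_len(nrow(ba))) {
      for (k in seq_len(ba$n_variants[r])) {
        vid <- cand[pos]; pos <- pos + 1L
        vi <- match(vid, bi$variants$id)
        in_batch <- batch == ba$batch[r]
        if (!any(in_batch)) abort("batch_artifact batch has no samples")
        bi$dosage[vi, in_batch] <- 1L
        bi$gq[vi, in_batch] <- 60L
        truth$label[truth$variant_id == vid] <- "batch_artifact"
        truth$target[truth$variant_id == vid] <- ba$batch[r]
      }
    }
  }

  # assemble combined callset (dosage block for biallelic, CN block for mCNV)
  nvb <- nrow(bi$variants); nvm <- nrow(mc$variants); ns <- length(samples)
  full <- function(top, bottom) {
    rbind(
      if (is.null(top)) matrix(NA_integer_, nvb, ns,
                               dimnames = list(bi$variants$id, samples)) else top,
      if (is.null(bottom)) matrix(NA_integer_, nvm, ns,
                                  dimnames = list(mc$variants$id, samples)) else bottom
    )
  }
  callset <- sv_callset(
    bind_rows(bi$variants, mc$variants), samples,
    dosage = full(bi$dosage, NULL), gq = full(bi$gq, NULL),
    cn = full(NULL, mc$cn), cnq = full(NULL, mc$cnq)
  )

  # archaic pseudo-diploid CN calls: reference state everywhere by default
  archaic <- tidyr::expand_grid(variant_id = callset$variants$id,
                                genome = config$archaic_genomes) |>
    mutate(
      cn = 2L,
      cnq = rphred(dplyr::n(), config$cnq_shape, config$cnq_scale)
    )
  if (config$archaic_cnq_degrade > 0) {
    hit <- runif(nrow(archaic)) < config$archaic_cnq_degrade
    archaic$cnq[hit] <- pmin(archaic$cnq[hit], 12L)
  }

  cohort <- structure(
    list(callset = callset, panel = panel, archaic = archaic,
         hap_cn = mc$hap_cn, truth = truth,
         true_freq = bind_rows(bi$true_freq, mc$true_freq),
         config = config, coverage = NULL),
    class = "sv_cohort"
  )

  if (!is.null(config$introgression) && nrow(config$introgression) > 0) {
    afr <- grep("^AFR", unique(pops$region), value = TRUE)
    cohort <- inject_introgression(cohort, config$introgression,
                                   african_region = if (length(afr)) afr[1] else unique(pops$region)[1])
    if (config$archaic_cnq_degrade > 0) {
      inj <- cohort$truth$variant_id[cohort$truth$label == "introgressed"]
      hit <- cohort$archaic$variant_id %in% inj &
        runif(nrow(cohort$archaic)) < config$archaic_cnq_degrade
      cohort$archaic$cnq[hit] <- pmin(cohort$archaic$cnq[hit], 12L)
    }
  }

  cohort$coverage <- simulate_coverage(config, samples)
  cohort
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort> %d variants x %d samples, %d populations, %d archaic genome(s)\n",
              nrow(x$callset$variants), length(x$callset$samples),
              length(unique(x$panel$population)),
              length(unique(x$archaic$genome))))
  print(table(x$truth$label))
  invisible(x)
}

#' Build the small seeded test cohort used across the suite
#'
#' Six populations in four regions (African and Oceanian analogues included),
#' 200 biallelic + 20 multiallelic variants, two archaic genomes, two
#' injected introgression variants, one runaway expansion, one batch
#' artifact, two private variants, three admixed samples, and one trisomy
#' sample (chr9, ratio 1.5).
#'
#' @param seed Integer seed (default 42).
#' @return A `sv_cohort`.
#' @export
make_fixtures <- function(seed = 42) {
  pops <- tibble(
    population = c("AfrA", "AfrB", "EurA", "EasA", "EasB", "OceA"),
    region = c("AFRICA", "AFRICA", "EUROPE", "EASTASIA", "EASTASIA", "OCEANIA"),
    n = 30L
  )
  cfg <- sim_config(
    populations = pops,
    fst = 0.08,
    n_biallelic = 200,
    n_multiallelic = 20,
    introgression = tibble(
      target_region = c("OCEANIA", "EASTASIA"),
      frequency = c(0.63, 0.4),
      archaic = c("Denisova", "Neanderthal"),
      svtype = c("DEL", "DUP")
    ),
    runaway = tibble(population = "EasA", hap_cn = 9L,
                     carrier_frac = 0.4, n_homozygous = 1L),
    batch_artifact = tibble(batch = "SangerPCR", n_variants = 1L),
    private = tibble(population = c("AfrA", "OceA"), frequency = c(0.4, 0.35)),
    admixed = tibble(population = "EurA", n = 3L,
                     other_region = "AFRICA", fraction = 0.3),
    batches = tibble(batch = c("SangerPCRfree", "SangerPCR"), n = c(160L, 20L)),
    aneuploidy = tibble(sample_id = "AfrA_001", chrom = "chr9",
                        ratio = 1.5, frac = 1),
    seed = seed
  )
  simulate_cohort(cfg)
}
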