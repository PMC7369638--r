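#' Pipeline configuration with study-default thresholds
#'
#' Collects every tunable of the pipeline with its conventional default:
#' GQ masking 20, per-population missingness 0.25, fragment-merge CNQ floor
#' 12 and gap 50 kb, analysis CNQ 13, private-collapse gap 25 kb, reciprocal
#' overlap 0.3/0.5, Vst threshold 0.2, 1000 permutations, PBS MAF 1% /
#' missingness 10% / rank 99%.
#'
#' @param out_dir Output directory for reports.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param callset,panel,archaic,coverage Input paths (VCF / TSVs) used when
#'   `simulate = FALSE`.
#' @param simulate Generate the cohort instead of reading inputs.
#' @param gq_min,miss_max,cnq_merge,cnq_analysis,merge_gap,private_gap,f_min,
#'   vst_min,B,maf_min,pbs_miss_max,pbs_rank,af_tol,exchet_overall Analysis
#'   thresholds (defaults as above).
#' @param exchet_thresholds Named per-batch ExcHet p-value thresholds.
#' @param pbs_triple Character vector `c(focal, sister, outgroup)`, or
#'   `NULL` to skip the PBS stage.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("svstrat_run_"),
                            sim = NULL,
                            callset = NULL, panel = NULL, archaic = NULL,
                            coverage = NULL,
                            simulate = !is.null(sim),
                            gq_min = 20, miss_max = 0.25,
                            cnq_merge = 12, cnq_analysis = 13,
                            merge_gap = 50000, private_gap = 25000,
                            f_min = 0.3, vst_min = 0.2, B = 1000,
                            maf_min = 0.01, pbs_miss_max = 0.10,
                            pbs_rank = 0.99, af_tol = 0.05,
                            exchet_overall = 1e-5,
                            exchet_thresholds = c(
                              SangerPCR = 1e-3, SangerPCRfree = 1e-5,
                              SGDPPCR = 0.05, SGDPPCRfree = 1e-5,
                              Meyer = 1e-3
                            ),
                            pbs_triple = NULL,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes QC (coverage flags, masks, ExcHet batch filter), frequency
#' tables, the stratification scan, per-variant Vst, the introgression scan,
#' copy-number spectra with runaway detection, and private-variant discovery
#' over a simulated or file-based cohort, writing one TSV per stage plus a
#' manifest with md5 hashes and the fully resolved configuration. Reruns
#' with the same config and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list of all stage results plus `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)

  if (config$simulate) {
    if (is.null(config$sim)) abort("simulate = TRUE but no sim config given")
    say("simulating cohort (seed %d)", config$sim$seed)
    cohort <- simulate_cohort(config$sim)
    cs <- cohort$callset; panel <- cohort$panel
    archaic <- cohort$archaic; coverage <- cohort$coverage
  } else {
    for (f in c("callset", "panel")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        abort(sprintf("missing required input: %s (%s)", f,
                      config[[f]] %||% "unset"))
      }
    }
    cs <- read_sv_vcf(config$callset)
    panel <- read_panel(config$panel)
    archaic <- if (!is.null(config$archaic))
      readr::read_tsv(config$archaic, show_col_types = FALSE) else NULL
    coverage <- if (!is.null(config$coverage))
      readr::read_tsv(config$coverage, show_col_types = FALSE) else NULL
    cohort <- NULL
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = config$out_dir)

  # --- sample QC ------------------------------------------------------
  if (!is.null(coverage)) {
    say("coverage QC")
    prof <- profile_coverage(coverage)
    flags <- flag_aneuploidies(prof)
    masks <- build_masks(flags)
    cs <- apply_masks(cs, masks)
    panel <- filter(panel, !.data$sample_id %in% masks$excluded)
    res$aneuploidy_flags <- flags
    res$masks <- masks
  }
  say("ExcHet batch filter")
  cs <- batch_exchet_filter(cs, panel, config$exchet_thresholds,
                            overall = config$exchet_overall)
  res$exchet_log <- attr(cs, "filter_log")

  # --- frequencies and stratification --------------------------------
  say("frequency tables")
  freq_pop <- population_frequencies(cs, panel, gq_min = config$gq_min,
                                     miss_max = config$miss_max)
  freq_reg <- population_frequencies(cs, panel, gq_min = config$gq_min,
                                     miss_max = config$miss_max, by = "region")
  say("pairwise Fst + max AF difference scan")
  fst <- pairwise_fst(freq_pop)
  strat <- max_af_diff_scan(freq_pop, fst)
  say("per-variant Vst")
  vst_tbl <- vst_scan(cs, panel, use = "dosage", by = "region",
                      gq_min = config$gq_min)

  pbs_tbl <- NULL
  if (!is.null(config$pbs_triple)) {
    say("PBS scan (%s)", paste(config$pbs_triple, collapse = "; "))
    pbs_tbl <- pbs_scan(cs, panel, config$pbs_triple,
                        maf_min = config$maf_min,
                        miss_max = config$pbs_miss_max,
                        gq_min = config$gq_min,
                        rank_min = config$pbs_rank)
  }

  # --- introgression --------------------------------------------------
  candidates <- NULL
  if (!is.null(archaic)) {
    say("introgression scan")
    archaic <- filter(as_tibble(archaic), .data$variant_id %in% cs$variants$id)
    states <- classify_archaic(archaic, cs, cnq_min = config$cnq_analysis)
    candidates <- introgression_scan(freq_reg, states, vst_tbl,
                                     vst_min = config$vst_min,
                                     pbs_tbl = pbs_tbl)
    res$candidate_report <- format_candidate_report(candidates, cs, states)
    res$ancestral_african <- ancestral_african_set(freq_reg, states)
  }

  # --- multiallelic expansions ---------------------------------------
  runaway <- spectra <- NULL
  if (!is.null(cs$cn)) {
    say("copy-number spectra + runaway scan")
    spectra <- suppressWarnings(cn_spectrum(cs, panel,
                                            cnq_min = config$cnq_analysis))
    runaway <- runaway_scan(spectra)
  }

  say("private variants")
  private_pop <- private_variants(cs, panel, level = "population",
                                  gq_min = config$gq_min,
                                  max_gap = config$private_gap,
                                  af_tol = config$af_tol)
  private_reg <- private_variants(cs, panel, level = "region",
                                  gq_min = config$gq_min,
                                  max_gap = config$private_gap,
                                  af_tol = config$af_tol)

  res <- c(res, list(
    callset = cs, panel = panel, cohort = cohort,
    freq_pop = freq_pop, freq_reg = freq_reg, fst = fst, strat = strat,
    vst = vst_tbl, pbs = pbs_tbl, introgression = candidates,
    spectra = spectra, runaway = runaway,
    private_pop = private_pop, private_reg = private_reg
  ))

  # --- write artifacts ------------------------------------------------
  wr <- function(obj, name) {
    if (is.null(obj)) return(NULL)
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    obj <- as_tibble(as.data.frame(obj, stringsAsFactors = FALSE,
                                   check.names = FALSE))
    for (cl in names(obj)[vapply(obj, is.list, logical(1))]) {
      obj[[cl]] <- purrr::map_chr(obj[[cl]], paste, collapse = ",")
    }
    readr::write_tsv(obj, path)
    path
  }
  paths <- c(
    wr(res$exchet_log, "exchet_log"),
    wr(res$aneuploidy_flags, "aneuploidy_flags"),
    wr(freq_pop, "frequencies_population"),
    wr(freq_reg, "frequencies_region"),
    wr(fst, "pairwise_fst"),
    wr(strat, "stratification_scan"),
    wr(vst_tbl, "vst"),
    wr(pbs_tbl, "pbs"),
    wr(res$candidate_report, "introgression_candidates"),
    wr(spectra, "cn_spectra"),
    wr(runaway, "runaway_calls"),
    wr(private_pop, "private_population"),
    wr(private_reg, "private_region")
  )
  manifest <- tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  cfg_flat <- config[!vapply(config, is.list, logical(1)) |
                       names(config) == "exchet_thresholds"]
  writeLines(
    c(sprintf("svstrat run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      vapply(names(cfg_flat), function(k) {
        sprintf("%s = %s", k, paste(format(cfg_flat[[k]]), collapse = ","))
      }, character(1))),
    file.path(config$out_dir, "run_config.txt")
  )
  res$manifest <- manifest
  invisible(res)
}
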