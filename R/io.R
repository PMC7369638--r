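#' Read a structural-variant VCF into an `sv_callset`
#'
#' Supports the VCF 4.2 dialect used by joint SV genotypers: symbolic ALT
#' alleles (`<DEL>`, `<DUP>`, `<INS>`, `<INV>`, `<CNV>`), INFO fields
#' `SVTYPE`/`END`/`SVLEN`, and FORMAT fields `GT:GQ` (biallelic dosages)
#' and/or `CN:CNQ` (diploid copy numbers). 1-based inclusive VCF coordinates
#' are converted to 0-based half-open on input. Records without `SVTYPE` are
#' rejected with a warning; unparseable genotypes become missing and their
#' count is reported. Per-genotype filter flags (e.g. the FAIL1/FAIL2/FAIL3
#' tags some genotypers emit) are treated generically: a `FT` FORMAT entry
#' other than `PASS`/`.` sets the call to missing.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param quiet Suppress progress messages.
#' @return An [sv_callset()].
#' @export
read_sv_vcf <- function(path, quiet = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records")

  svtype <- vcfR::extract.info(v, "SVTYPE")
  endpos <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  keep <- !is.na(svtype) & svtype != ""
  if (any(!keep)) {
    warn(sprintf("read_sv_vcf: %d record(s) without SVTYPE rejected", sum(!keep)))
  }

  pos <- as.integer(fix$POS)
  start0 <- pos - 1L
  end0 <- ifelse(svtype == "INS", start0 + 1L,
                 ifelse(!is.na(endpos), endpos,
                        start0 + abs(svlen)))
  size <- ifelse(svtype == "INS", abs(svlen), end0 - start0)
  svtype <- ifelse(svtype == "CNV", "mCNV", svtype)

  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("sv", which(is.na(fix$ID) | fix$ID == "."))
  variants <- tibble(
    id = id, chrom = fix$CHROM, start = start0,
    end = as.integer(end0), svtype = svtype, size = as.integer(size)
  )[keep, ]

  samples <- colnames(v@gt)[-1]
  has <- function(el) {
    fmt <- v@gt[, 1]
    any(vapply(strsplit(fmt, ":"), function(f) el %in% f, logical(1)))
  }
  n_bad <- 0L

  grab_int <- function(el) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = FALSE)[keep, , drop = FALSE]
    out <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m),
                                   dimnames = dimnames(m)))
    n_bad <<- n_bad + sum(!is.na(m) & m != "." & is.na(out))
    out
  }

  dosage <- gq <- cn <- cnq <- NULL
  if (length(samples)) {
    if (has("GT")) {
      gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
      gt <- gsub("|", "/", gt, fixed = TRUE)
      dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
      known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
      hit <- gt %in% names(known)
      dos[hit] <- known[gt[hit]]
      n_bad <- n_bad + sum(!is.na(gt) & gt != "./." & gt != "." & !hit)
      dosage <- dos
    }
    if (has("GQ")) gq <- grab_int("GQ")
    if (has("CN")) cn <- grab_int("CN")
    if (has("CNQ")) cnq <- grab_int("CNQ")
    if (has("FT") && !is.null(dosage)) {
      ft <- vcfR::extract.gt(v, element = "FT")[keep, , drop = FALSE]
      flagged <- !is.na(ft) & !ft %in% c("PASS", ".")
      dosage[flagged] <- NA_integer_
      n_bad <- n_bad + sum(flagged)
    }
  }
  if (!quiet && n_bad > 0) {
    message(sprintf("read_sv_vcf: %d unparseable/filtered genotype(s) set to missing", n_bad))
  }

  relabel <- function(m) {
    if (!is.null(m)) rownames(m) <- variants$id
    m
  }
  cs <- sv_callset(variants, samples, dosage = relabel(dosage),
                   gq = relabel(gq), cn = relabel(cn), cnq = relabel(cnq))
  attr(cs, "n_unparseable") <- n_bad
  cs
}

#' Write an `sv_callset` to VCF
#'
#' Inverse of [read_sv_vcf()]: emits VCF 4.2 with symbolic ALT alleles,
#' `SVTYPE`/`END`/`SVLEN` INFO fields, and whichever of `GT:GQ` / `CN:CNQ`
#' the callset carries. Round-tripping through [read_sv_vcf()] reproduces all
#' typed fields, including the missingness pattern.
#'
#' @param x An [sv_callset()].
#' @param path Output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path) {
  v <- x$variants
  alt_of <- c(DEL = "<DEL>", DUP = "<DUP>", INS = "<INS>", INV = "<INV>",
              mCNV = "<CNV>", BND = "<BND>")
  info_type <- ifelse(v$svtype == "mCNV", "CNV", v$svtype)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", info_type, v$end, v$size)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Variant length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Diploid copy number\">",
    "##FORMAT=<ID=CNQ,Number=1,Type=Integer,Description=\"Copy number quality\">",
    paste0("##ALT=<ID=", c("DEL", "DUP", "INS", "INV", "CNV"),
           ",Description=\"Symbolic structural variant\">")
  )

  fmt_parts <- c(
    if (!is.null(x$dosage)) "GT",
    if (!is.null(x$gq)) "GQ",
    if (!is.null(x$cn)) "CN",
    if (!is.null(x$cnq)) "CNQ"
  )
  fmt <- paste(fmt_parts, collapse = ":")

  enc_gt <- function(d) ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  enc_int <- function(m) ifelse(is.na(m), ".", as.character(m))

  cols <- list()
  if (!is.null(x$dosage)) cols$GT <- enc_gt(x$dosage)
  if (!is.null(x$gq)) cols$GQ <- enc_int(x$gq)
  if (!is.null(x$cn)) cols$CN <- enc_int(x$cn)
  if (!is.null(x$cnq)) cols$CNQ <- enc_int(x$cnq)

  nv <- nrow(v); ns <- length(x$samples)
  body <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s", v$chrom, v$start + 1L,
                  v$id, alt_of[v$svtype], info)
  if (ns > 0 && length(cols) > 0) {
    gmat <- matrix("", nv, ns)
    for (i in seq_len(ns)) {
      parts <- lapply(cols, function(m) matrix(m, nv)[, i])
      gmat[, i] <- do.call(paste, c(parts, sep = ":"))
    }
    body <- paste(body, fmt, apply(gmat, 1, paste, collapse = "\t"), sep = "\t")
  }
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", if (ns > 0) c("FORMAT", x$samples)),
                      collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, chrom_line, body), con)
  invisible(path)
}

#' Read a population panel table
#'
#' Tab-separated with header columns `sample_id`, `population`, `region`,
#' `batch`, one `admixture_<REGION>` column per region (a simplex per sample),
#' and optionally `excluded` (logical). Duplicate sample ids and admixture
#' rows not summing to 1 are fatal.
#'
#' @param path Path to the panel TSV.
#' @return A tibble of class `sv_panel`.
#' @export
read_panel <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE)
  validate_panel(p)
}

#' Validate (and normalise) a population panel
#'
#' @param p A data frame with the panel columns described in [read_panel()].
#' @return The panel as a tibble with class `sv_panel`.
#' @export
validate_panel <- function(p) {
  p <- as_tibble(p)
  req <- c("sample_id", "population", "region", "batch")
  if (!all(req %in% names(p))) {
    abort(paste("panel must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(p$sample_id)) abort("duplicate sample_id in panel")
  adm <- grep("^admixture_", names(p), value = TRUE)
  if (length(adm)) {
    fr <- as.matrix(p[adm])
    if (any(fr < 0 | fr > 1)) abort("admixture fractions must lie in [0, 1]")
    s <- rowSums(fr)
    if (any(abs(s - 1) > 1e-6)) {
      abort("admixture fractions must sum to 1 (tolerance 1e-6)")
    }
  }
  if (!"excluded" %in% names(p)) p$excluded <- FALSE
  class(p) <- c("sv_panel", class(p))
  p
}

#' Write a population panel table
#' @param p Panel tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  readr::write_tsv(as_tibble(as.data.frame(p)), path)
  invisible(path)
}

# Panel samples matched to a callset; unknown callset samples are an error,
# never a silent drop.
panel_for <- function(x, panel) {
  missing <- setdiff(x$samples, panel$sample_id)
  if (length(missing)) {
    abort(paste("samples absent from panel:", paste(head(missing, 5), collapse = ", ")))
  }
  panel[match(x$samples, panel$sample_id), ]
}
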