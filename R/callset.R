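#' Structural-variant callset container
#'
#' An `sv_callset` bundles variant metadata with per-sample genotype matrices.
#' Intervals use 0-based, half-open coordinates internally (`start` inclusive,
#' `end` exclusive); VCF I/O converts at the boundary. Insertions are anchored
#' at a single base (`end == start + 1`) and carry their insert length in
#' `size`. Missing calls are `NA` -- never a numeric sentinel -- so statistics
#' cannot silently include them.
#'
#' @param variants Tibble with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (one of DEL, DUP, INS, INV, mCNV, BND) and `size` (bp; insert
#'   length for INS).
#' @param samples Character vector of sample ids.
#' @param dosage,gq Optional integer matrices (variants x samples) of
#'   non-reference allele counts (0/1/2, `NA` missing) and phred-scaled
#'   genotype qualities.
#' @param cn,cnq Optional integer matrices of diploid copy number and
#'   phred-scaled copy-number quality.
#'
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(variants, samples, dosage = NULL, gq = NULL,
                       cn = NULL, cnq = NULL) {
  variants <- as_tibble(variants)
  req <- c("id", "chrom", "start", "end", "svtype", "size")
  if (!all(req %in% names(variants))) {
    abort(paste("variants must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  bad <- variants$svtype != "INS" & variants$end <= variants$start
  if (any(bad)) abort("end must exceed start for non-insertion variants")
  if (any(variants$svtype == "INS" & variants$end != variants$start + 1L)) {
    abort("insertions must be anchored at a single base (end == start + 1)")
  }

  # keep coordinates sorted per chromosome
  ord <- order(variants$chrom, variants$start, variants$end, variants$id)
  variants <- variants[ord, ]

  # matrices may arrive in pre-sort row order; align by rowname when present,
  # otherwise assume caller order and reorder with the variants
  align <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!is.matrix(m)) abort(paste(what, "must be a matrix"))
    if (nrow(m) != nrow(variants) || ncol(m) != length(samples)) {
      abort(paste(what, "dimensions must match variants x samples"))
    }
    if (!is.null(rownames(m))) {
      if (!setequal(rownames(m), variants$id)) {
        abort(paste(what, "rownames must match variant ids"))
      }
      m <- m[variants$id, , drop = FALSE]
    } else {
      m <- m[ord, , drop = FALSE]
      rownames(m) <- variants$id
    }
    colnames(m) <- samples
    storage.mode(m) <- "integer"
    m
  }

  x <- structure(
    list(
      variants = variants,
      samples = as.character(samples),
      dosage = align(dosage, "dosage"),
      gq = align(gq, "gq"),
      cn = align(cn, "cn"),
      cnq = align(cnq, "cnq")
    ),
    class = "sv_callset"
  )
  x
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf(
    "<sv_callset> %d variants x %d samples (%s)\n",
    nrow(x$variants), length(x$samples),
    paste(names(Filter(Negate(is.null), x[c("dosage", "cn")])), collapse = "+")
  ))
  cat("svtype:", paste(sprintf("%s=%d", names(table(x$variants$svtype)),
                               table(x$variants$svtype)), collapse = " "), "\n")
  invisible(x)
}

n_variants <- function(x) nrow(x$variants)
n_samples <- function(x) length(x$samples)

#' Subset a callset by variants and/or samples
#'
#' @param x An `sv_callset`.
#' @param variants Character vector of variant ids or logical/integer index.
#' @param samples Character vector of sample ids or logical/integer index.
#' @return An `sv_callset`.
#' @export
subset_callset <- function(x, variants = NULL, samples = NULL) {
  vi <- seq_len(n_variants(x))
  si <- seq_len(n_samples(x))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, x$variants$id) else vi[variants]
    if (anyNA(vi)) abort("unknown variant id in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples) else si[samples]
    if (anyNA(si)) abort("unknown sample id in subset")
  }
  sub <- function(m) if (is.null(m)) NULL else m[vi, si, drop = FALSE]
  sv_callset(x$variants[vi, ], x$samples[si],
             dosage = sub(x$dosage), gq = sub(x$gq),
             cn = sub(x$cn), cnq = sub(x$cnq))
}

#' Mask low-quality biallelic genotypes
#'
#' Sets dosages with genotype quality below `gq_min` to missing. Masking never
#' rewrites a retained dosage and never un-masks: the operation is idempotent
#' and monotone. The number of newly masked calls is attached as attribute
#' `n_masked` and reported via a message.
#'
#' @param x An `sv_callset` with `dosage` and `gq` matrices.
#' @param gq_min Minimum genotype quality to keep a call (default 20, the
#'   threshold used throughout the stratification analyses).
#' @param quiet Suppress the masked-call message.
#' @return The masked `sv_callset`.
#' @export
mask_low_gq <- function(x, gq_min = 20, quiet = FALSE) {
  if (is.null(x$dosage) || is.null(x$gq)) {
    abort("mask_low_gq requires dosage and gq matrices")
  }
  mask <- !is.na(x$gq) & x$gq < gq_min & !is.na(x$dosage)
  n_masked <- sum(mask)
  x$dosage[mask] <- NA_integer_
  if (!quiet && n_masked > 0) {
    message(sprintf("mask_low_gq: %d genotype(s) set to missing (GQ < %d)",
                    n_masked, gq_min))
  }
  attr(x, "n_masked") <- n_masked
  x
}
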