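#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Vst permutation test
#'
#' @param x A `vst_perm` object from [vst_permutation_test()].
#' @param ... Unused.
#' @return One-row tibble (`observed`, `B`, `k`, `p.value`).
#' @export
tidy.vst_perm <- function(x, ...) {
  tibble(observed = x$observed, B = x$B, k = x$k, p.value = x$p)
}

#' One-row summary of a Vst permutation test
#' @inheritParams tidy.vst_perm
#' @return One-row tibble (`p.value`, `p.floor`, `seed`).
#' @export
glance.vst_perm <- function(x, ...) {
  tibble(p.value = x$p, p.floor = 1 / (x$B + 1),
         seed = x$seed %||% NA_integer_)
}

#' Tidy a PBS scan
#' @param x An `sv_pbs` tibble from [pbs_scan()].
#' @param ... Unused.
#' @return The scan as a plain tibble.
#' @export
tidy.sv_pbs <- function(x, ...) as_tibble(as.data.frame(x))

#' One-row summary of a PBS scan
#' @inheritParams tidy.sv_pbs
#' @return Tibble (`n_variants`, `n_flagged`, `pbs_99`), where `pbs_99` is
#'   the scan's own 99th-percentile PBS.
#' @export
glance.sv_pbs <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_flagged = sum(x$flagged, na.rm = TRUE),
    pbs_99 = stats::quantile(x$pbs, 0.99, na.rm = TRUE, names = FALSE)
  )
}
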