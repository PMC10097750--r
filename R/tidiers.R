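#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression fit
#'
#' @param x A [de_test()] result.
#' @param ... Unused.
#' @return The per-gene results tibble (gene_id, logCPM, logFC, pvalue,
#'   fdr, class).
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$table

#' One-row summary of a differential-expression fit
#'
#' @inheritParams tidy.de_result
#' @return Tibble with contrast, up/down/ns counts, dispersion and alpha.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  cls <- factor(x$table$class, levels = c("up", "down", "ns"))
  tibble::tibble(
    contrast = x$contrast,
    n_genes = nrow(x$table),
    up = sum(cls == "up"), down = sum(cls == "down"), ns = sum(cls == "ns"),
    dispersion = x$dispersion,
    alpha = x$alpha
  )
}
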