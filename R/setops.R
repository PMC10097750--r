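#' Genes classified up or down in a DE result
#'
#' @param fit A [de_test()] result (or its `table`).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene IDs, in table order.
#' @export
de_genes <- function(fit, direction = c("up", "down")) {
  direction <- match.arg(direction)
  tab <- if (inherits(fit, "de_result")) fit$table else fit
  tab$gene_id[tab$class == direction]
}

#' Core set: intersection of several gene lists
#'
#' The "core" construct of a timecourse analysis: genes present in every
#' per-timepoint list (e.g. upregulated at all sampled timepoints).
#' Membership is exact, case-sensitive string identity — systematic gene
#' IDs are case-stable and case-folding could merge distinct IDs.
#'
#' @param sets A list of >= 2 character vectors of gene IDs.
#' @return Character vector: the intersection, ordered as in the first
#'   set.
#' @examples
#' core_set(list(c("a", "b", "c"), c("c", "b"), c("b", "c", "d")))
#' @export
core_set <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  out <- unique(sets[[1]])
  for (s in sets[-1]) out <- out[out %in% s]
  out
}

#' Exclusive-region counts for a Venn diagram
#'
#' @param sets Named list of 2-4 character vectors.
#' @return Tibble `pattern` (membership string, e.g. `"110"`, one digit
#'   per set in input order), `count`. Counts sum to the size of the
#'   union.
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets))
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_counts supports 2-4 sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  patterns <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  all_pat <- apply(as.matrix(expand.grid(rep(list(1:0), k)))[, k:1, drop = FALSE],
                   1, paste, collapse = "")
  all_pat <- setdiff(all_pat, strrep("0", k))
  tibble::tibble(
    pattern = all_pat,
    count = as.integer(table(factor(patterns, levels = all_pat)))
  )
}

#' Percentage of tested genes that are downregulated
#'
#' `100 * down / (up + down + ns)`, rounded half-up to one decimal — the
#' "fraction of the transcriptome repressed" summary of a DE table.
#'
#' @param up,down,ns Non-negative class counts; total must be positive.
#' @return Percentage to one decimal.
#' @examples
#' fraction_down(17, 6436, 159)
#' @export
fraction_down <- function(up, down, ns) {
  stopifnot(up >= 0, down >= 0, ns >= 0)
  total <- up + down + ns
  if (total == 0) stop("zero total gene count", call. = FALSE)
  round_half_up(100 * down / total, 1)
}
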