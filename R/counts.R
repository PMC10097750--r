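#' Build a count table
#'
#' A count table is the package's central input: one row per feature
#' (endogenous gene or spike-in control), a logical `is_spike` column, and
#' one integer column per sample. All downstream functions
#' ([tmm_factors()], [filter_expressed()], [de_test()], ...) take this
#' shape first, so calls chain with the pipe.
#'
#' @param x A data frame with a `feature_id` column and one numeric column
#'   per sample (an `is_spike` column is honoured if already present), or a
#'   matrix with feature row names.
#' @param spike_features Character vector of feature IDs to flag as
#'   spike-in controls. Ignored when `x` already carries `is_spike` and
#'   `spike_features` is `NULL`.
#' @return A tibble with columns `feature_id`, `is_spike`, then samples.
#' @examples
#' m <- matrix(rpois(12, 50), 4, dimnames = list(paste0("g", 1:4), c("s1", "s2", "s3")))
#' as_count_tbl(m, spike_features = "g4")
#' @export
as_count_tbl <- function(x, spike_features = NULL) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    x <- tibble::as_tibble(x, rownames = "feature_id")
  }
  x <- tibble::as_tibble(x)
  if (!"feature_id" %in% names(x)) {
    stop("count table needs a 'feature_id' column", call. = FALSE)
  }
  if (anyDuplicated(x$feature_id)) {
    dup <- x$feature_id[duplicated(x$feature_id)][1]
    stop("duplicated feature ID: ", dup, call. = FALSE)
  }
  if (!is.null(spike_features)) {
    missing <- setdiff(spike_features, x$feature_id)
    if (length(missing) > 0) {
      stop("spike feature(s) absent from count table: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x$is_spike <- x$feature_id %in% spike_features
  } else if (!"is_spike" %in% names(x)) {
    x$is_spike <- FALSE
  }
  smp <- setdiff(names(x), c("feature_id", "is_spike"))
  if (length(smp) == 0) stop("count table has no sample columns", call. = FALSE)
  bad <- smp[!vapply(x[smp], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(x[smp], function(v) any(v < 0 | is.na(v)), logical(1)))) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  dplyr::relocate(x, "feature_id", "is_spike")
}

#' Sample IDs of a count table
#' @param counts A count table (see [as_count_tbl()]).
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(counts) {
  setdiff(names(counts), c("feature_id", "is_spike"))
}

#' Count table as a numeric matrix
#' @inheritParams sample_ids
#' @param spikes One of `"keep"`, `"drop"` (endogenous only) or `"only"`.
#' @return Numeric matrix, features in rows.
#' @export
count_matrix <- function(counts, spikes = c("keep", "drop", "only")) {
  spikes <- match.arg(spikes)
  keep <- switch(spikes,
    keep = rep(TRUE, nrow(counts)),
    drop = !counts$is_spike,
    only = counts$is_spike
  )
  m <- as.matrix(counts[keep, sample_ids(counts), drop = FALSE])
  rownames(m) <- counts$feature_id[keep]
  m
}

#' Round half away from zero
#'
#' Base `round()` is round-half-even, which would turn 56.25 into 56.2;
#' printed report percentages use the conventional half-up rule.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
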