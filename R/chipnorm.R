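#' Spike-in scale factors for ChIP-seq samples
#'
#' `factor_s = spike_reads(reference) / spike_reads(s)`. With
#' `reference = "min"` the sample with the fewest exogenous-genome reads
#' is the reference, so every factor is <= 1 and counts are only ever
#' downscaled — the convention of exogenous-chromatin spike-in
#' normalization. Because a fixed amount of spike chromatin enters each
#' IP, dividing by spike reads makes occupancy comparable across global
#' chromatin changes that per-library scaling would erase.
#'
#' @param spikes Tibble with `sample_id` and `spike_reads` (> 0) columns
#'   (e.g. from [simulate_chip()] or [read_chip_spikes()]).
#' @param reference `"min"` or a sample ID.
#' @return Tibble `sample_id`, `spike_reads`, `spike_factor`.
#' @export
spike_factors <- function(spikes, reference = "min") {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("sample_id", "spike_reads") %in% names(spikes)),
            nrow(spikes) >= 1)
  zero <- spikes$sample_id[spikes$spike_reads <= 0]
  if (length(zero) > 0) {
    stop("zero spike reads in sample(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  ref_reads <- if (identical(reference, "min")) {
    min(spikes$spike_reads)
  } else {
    i <- match(reference, spikes$sample_id)
    if (is.na(i)) stop("reference sample not found: ", reference, call. = FALSE)
    spikes$spike_reads[i]
  }
  dplyr::mutate(spikes[, c("sample_id", "spike_reads")],
                spike_factor = ref_reads / .data$spike_reads)
}

#' Apply spike factors to region counts
#'
#' Each sample's region counts (and totals, if present) are multiplied by
#' its spike factor.
#'
#' @param regions Tibble `region_id` plus one count column per sample.
#' @param factors Output of [spike_factors()] covering every sample.
#' @return `regions` with scaled values.
#' @export
normalize_regions <- function(regions, factors) {
  regions <- tibble::as_tibble(regions)
  smp <- setdiff(names(regions), c("region_id", "chrom", "start", "end"))
  missing <- setdiff(smp, factors$sample_id)
  if (length(missing) > 0) {
    stop("spike factors missing for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  f <- factors$spike_factor[match(smp, factors$sample_id)]
  out <- regions
  for (i in seq_along(smp)) out[[smp[i]]] <- regions[[smp[i]]] * f[i]
  out
}

#' Per-region two-group comparison of normalized counts
#'
#' Two-sided unpaired t-test per region, equal-variance by default (the
#' spreadsheet bar-diagram convention; set `var_equal = FALSE` for
#' Welch). Significance stars: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param regions Normalized region table from [normalize_regions()].
#' @param groups Named list of two character vectors of sample IDs
#'   (`list(a = ..., b = ...)`), each of length >= 2, or a sample sheet
#'   with `sample_id` and `condition` plus `test`/`reference` labels.
#' @param test,reference Condition labels when `groups` is a sample
#'   sheet.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return Tibble `region_id`, `mean_a`, `mean_b`, `t`, `p`, `stars`.
#' @export
compare_groups <- function(regions, groups, test = NULL, reference = NULL,
                           var_equal = TRUE) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(test), !is.null(reference))
    groups <- list(
      a = groups$sample_id[groups$condition == test],
      b = groups$sample_id[groups$condition == reference]
    )
  }
  stopifnot(length(groups) == 2)
  if (any(lengths(groups) < 2)) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  a <- as.matrix(regions[, groups[[1]]])
  b <- as.matrix(regions[, groups[[2]]])
  res <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    va <- a[i, ]; vb <- b[i, ]
    if (stats::sd(c(va, vb)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(va, vb, var.equal = var_equal)
    }
    tibble::tibble(mean_a = mean(va), mean_b = mean(vb),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  dplyr::mutate(
    tibble::tibble(region_id = regions$region_id), res,
    stars = dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*",
                             .default = "")
  )
}
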