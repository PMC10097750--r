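#' Spike-anchored TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values factors using *only* a set of anchor
#' features — by default the spike-in controls. Because the spikes are
#' dosed per cell, anchoring on them makes the effective sizes track total
#' RNA per cell, so a global transcriptional shift shows up as a coherent
#' fold change in every endogenous gene instead of being normalized away.
#'
#' For sample s against reference r, using anchor features nonzero in
#' both, `M_g = log2((x_gs/N_s) / (x_gr/N_r))` and
#' `A_g = 0.5 * log2((x_gs/N_s) * (x_gr/N_r))` with `N` the anchor library
#' size. The top and bottom `trim_m` fraction by M and `trim_a` fraction
#' by A are discarded and the factor is `2^` the precision-weighted mean
#' of the remaining M (binomial delta-method weights). Factors are centred
#' to geometric mean 1.
#'
#' @param counts A count table (see [as_count_tbl()]).
#' @param anchor_features Feature IDs to anchor on; default the table's
#'   spike-in features.
#' @param reference Reference sample ID, or `"auto"`: the sample whose
#'   anchor-count upper-quartile proportion is closest to the mean
#'   (lexicographic sample ID breaks ties).
#' @param trim_m,trim_a Two-sided trim fractions on M and A.
#' @return Tibble with columns `sample_id`, `tmm_factor`,
#'   `anchor_libsize`, `effective_size` (= libsize x factor); the chosen
#'   reference is stored in the `"reference"` attribute.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, depth_per_sample = 5e4))
#' tmm_factors(sim$counts)
#' @export
tmm_factors <- function(counts, anchor_features = NULL, reference = "auto",
                        trim_m = 0.30, trim_a = 0.05) {
  smp <- sample_ids(counts)
  if (is.null(anchor_features)) {
    anchor_features <- counts$feature_id[counts$is_spike]
  }
  if (length(anchor_features) == 0) {
    stop("no anchor features given and no spike-in features flagged",
         call. = FALSE)
  }
  missing <- setdiff(anchor_features, counts$feature_id)
  if (length(missing) > 0) {
    stop("anchor feature(s) absent from counts: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(counts[match(anchor_features, counts$feature_id), smp,
                        drop = FALSE])
  libsize <- colSums(x)
  if (any(libsize == 0)) {
    stop("sample(s) with no nonzero anchor counts: ",
         paste(smp[libsize == 0], collapse = ", "), call. = FALSE)
  }

  if (identical(reference, "auto")) {
    f75 <- apply(x, 2, function(v) stats::quantile(v / sum(v), 0.75))
    ord <- order(abs(f75 - mean(f75)), smp)
    reference <- smp[ord[1]]
  }
  if (!reference %in% smp) {
    stop("reference sample not found: ", reference, call. = FALSE)
  }

  f <- vapply(smp, function(s) {
    tmm_pair(x[, s], x[, reference], libsize[s], libsize[reference],
             trim_m, trim_a, pair = paste(s, "vs", reference))
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # centre to geometric mean 1

  out <- tibble::tibble(
    sample_id = smp,
    tmm_factor = unname(f),
    anchor_libsize = unname(libsize),
    effective_size = unname(libsize * f)
  )
  attr(out, "reference") <- reference
  out
}

# doubly trimmed, precision-weighted mean of M values for one sample pair
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, pair = "") {
  fin <- obs > 0 & ref > 0
  obs <- obs[fin]; ref <- ref[fin]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (length(logR) == 0) {
    stop("no usable anchor features for pair ", pair, call. = FALSE)
  }
  if (max(abs(logR)) < 1e-6) return(1)  # identical profiles
  n <- length(logR)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
    rank(absE) >= loA & rank(absE) <= hiA
  if (sum(keep) < 3) {
    stop("fewer than 3 anchor features survive trimming for pair ", pair,
         call. = FALSE)
  }
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Anchor-batch correction of normalization factors
#'
#' Rescales every non-anchor batch by one multiplicative constant so that
#' its mean factor at the anchor condition matches the anchor batch's mean
#' factor at that condition. Within-batch factor ratios are unchanged;
#' this ties batches together through a condition they share (typically
#' the vegetative T0 reference), the situation that arises when a later
#' batch is sequenced with its own spike-in dosing.
#'
#' @param factors Output of [tmm_factors()].
#' @param sample_sheet Sample sheet with `sample_id`, `batch` and the
#'   condition column.
#' @param anchor_batch Batch label whose factors are left untouched.
#' @param anchor_condition Condition label present in every batch.
#' @param condition_col Sample-sheet column holding condition labels
#'   (default `"timepoint"`).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` mean of the
#'   factors at the anchor condition.
#' @return `factors` with rescaled `tmm_factor` and `effective_size`.
#' @export
batch_correct <- function(factors, sample_sheet, anchor_batch,
                          anchor_condition, condition_col = "timepoint",
                          mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  avg <- if (mean_type == "arithmetic") mean else function(v) exp(mean(log(v)))
  sheet <- tibble::as_tibble(sample_sheet)
  stopifnot(all(c("sample_id", "batch", condition_col) %in% names(sheet)))
  if (!anchor_batch %in% sheet$batch) {
    stop("anchor batch not found: ", anchor_batch, call. = FALSE)
  }
  sheet <- sheet[match(factors$sample_id, sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) {
    stop("sample sheet is missing samples present in the factor table",
         call. = FALSE)
  }
  at_anchor <- sheet[[condition_col]] == anchor_condition
  ref_mean <- avg(factors$tmm_factor[at_anchor & sheet$batch == anchor_batch])
  if (!is.finite(ref_mean)) {
    stop("anchor condition '", anchor_condition, "' absent from batch ",
         anchor_batch, call. = FALSE)
  }
  out <- factors
  for (b in setdiff(unique(sheet$batch), anchor_batch)) {
    in_b <- sheet$batch == b
    if (!any(at_anchor & in_b)) {
      stop("anchor condition '", anchor_condition, "' absent from batch ", b,
           call. = FALSE)
    }
    scale_b <- ref_mean / avg(factors$tmm_factor[at_anchor & in_b])
    out$tmm_factor[in_b] <- out$tmm_factor[in_b] * scale_b
    out$effective_size[in_b] <- out$effective_size[in_b] * scale_b
  }
  out
}

#' Normalize counts to spike-anchored counts per million
#'
#' `value_gs = x_gs * 1e6 / effective_size_s`. With spike-anchored
#' effective sizes this is expression per fixed amount of spike — i.e.
#' per cell — so global shifts are preserved.
#'
#' @param counts A count table.
#' @param factors Output of [tmm_factors()] (possibly batch-corrected),
#'   covering every sample.
#' @param log2 If `TRUE`, return `log2(value + 0.5)`.
#' @param keep_spikes Keep spike rows in the output?
#' @return Tibble in the same wide shape as `counts`, real-valued.
#' @export
normalize_counts <- function(counts, factors, log2 = FALSE,
                             keep_spikes = TRUE) {
  smp <- sample_ids(counts)
  missing <- setdiff(smp, factors$sample_id)
  if (length(missing) > 0) {
    stop("factors missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  es <- factors$effective_size[match(smp, factors$sample_id)]
  out <- counts
  for (i in seq_along(smp)) {
    v <- counts[[smp[i]]] * 1e6 / es[i]
    out[[smp[i]]] <- if (log2) base::log2(v + 0.5) else v
  }
  if (!keep_spikes) out <- out[!out$is_spike, ]
  out
}

#' Per-sample median expression ratio against a reference condition
#'
#' A robust estimate of the global transcription level of each sample
#' relative to the reference: the median, over endogenous genes, of the
#' normalized count ratio against the gene's mean in the reference
#' condition. Under a pure global shift this recovers the global factor.
#'
#' @param counts Count table.
#' @param factors Normalization factors covering all samples.
#' @param sample_sheet Sample sheet with `sample_id` and `condition_col`.
#' @param reference_condition Condition label of the reference group.
#' @param condition_col Sample-sheet column with condition labels.
#' @return Tibble `sample_id`, `condition`, `median_ratio`.
#' @export
global_shift <- function(counts, factors, sample_sheet, reference_condition,
                         condition_col = "condition") {
  sheet <- tibble::as_tibble(sample_sheet)
  norm <- normalize_counts(counts, factors, keep_spikes = FALSE)
  m <- count_matrix(norm, spikes = "drop")
  ref_samples <- sheet$sample_id[sheet[[condition_col]] == reference_condition]
  if (length(ref_samples) == 0) {
    stop("no samples in reference condition ", reference_condition,
         call. = FALSE)
  }
  ref_mean <- rowMeans(m[, ref_samples, drop = FALSE])
  ok <- ref_mean > 0
  med <- apply(m[ok, sheet$sample_id, drop = FALSE], 2,
               function(v) stats::median(v / ref_mean[ok]))
  tibble::tibble(sample_id = sheet$sample_id,
                 condition = sheet[[condition_col]],
                 median_ratio = unname(med))
}
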