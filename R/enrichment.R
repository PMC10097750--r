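#' Terminal (subtelomeric) windows of each chromosome
#'
#' Two windows per chromosome: `[1, window_bp]` and
#' `[L - window_bp + 1, L]`, 1-based inclusive.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths, or a
#'   two-column data frame (chrom, length) as read by
#'   [read_chrom_sizes()].
#' @param window_bp Window width in bp (default 200 kb). Must be smaller
#'   than half of each chromosome; 0 returns an empty window set with a
#'   warning.
#' @param chromosomes Optional subset of chromosome names.
#' @return Tibble `chrom`, `start`, `end`, `arm` (`"left"`/`"right"`).
#' @examples
#' terminal_windows(c(I = 5579133, II = 4539804), chromosomes = "I")
#' @export
terminal_windows <- function(chrom_lengths, window_bp = 200000,
                             chromosomes = NULL) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths[[2]], chrom_lengths[[1]])
  }
  if (!is.null(chromosomes)) {
    unknown <- setdiff(chromosomes, names(chrom_lengths))
    if (length(unknown) > 0) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    chrom_lengths <- chrom_lengths[chromosomes]
  }
  if (window_bp == 0) {
    warning("window_bp = 0: empty window set")
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), arm = character()))
  }
  if (any(window_bp >= chrom_lengths / 2)) {
    stop("window_bp must be < half of every chromosome length", call. = FALSE)
  }
  L <- unname(chrom_lengths)
  tibble::tibble(
    chrom = rep(names(chrom_lengths), each = 2),
    start = as.integer(rbind(1, L - window_bp + 1)),
    end = as.integer(rbind(window_bp, L)),
    arm = rep(c("left", "right"), length(L))
  )
}

#' Flag genes overlapping a window set
#'
#' A gene is subtelomeric iff any of its intervals overlaps any window by
#' at least 1 bp (coordinates 1-based inclusive on both sides). The
#' stricter `"start-in-window"` variant requires the interval start to lie
#' inside a window. Genes on chromosomes absent from the window set are
#' counted non-subtelomeric with a warning.
#'
#' @param loci Gene loci: a tibble with one row per interval, columns
#'   `gene_id`, `chrom`, `start`, `end` (see [read_annotation()]).
#' @param windows Window set from [terminal_windows()].
#' @param rule `"any-overlap"` (default) or `"start-in-window"`.
#' @return Tibble `gene_id`, `subtelomeric`, one row per gene, in first-
#'   appearance order; the subtelomeric count is in attribute `"k"`.
#' @export
assign_windows <- function(loci, windows,
                           rule = c("any-overlap", "start-in-window")) {
  rule <- match.arg(rule)
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(loci)))
  if (any(loci$start > loci$end)) {
    stop("interval with start > end", call. = FALSE)
  }
  off <- setdiff(unique(loci$chrom), unique(windows$chrom))
  if (length(off) > 0) {
    warning("gene intervals on chromosome(s) without windows (counted ",
            "non-subtelomeric): ", paste(off, collapse = ", "))
  }
  hit <- rep(FALSE, nrow(loci))
  on <- loci$chrom %in% windows$chrom
  if (any(on) && nrow(windows) > 0) {
    q <- GenomicRanges::GRanges(
      loci$chrom[on],
      IRanges::IRanges(loci$start[on],
                       if (rule == "any-overlap") loci$end[on]
                       else loci$start[on])
    )
    w <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
    hit[on] <- IRanges::overlapsAny(q, w, minoverlap = 1)
  }
  out <- tibble::tibble(gene_id = loci$gene_id, hit = hit) |>
    dplyr::summarise(subtelomeric = any(.data$hit), .by = "gene_id")
  attr(out, "k") <- sum(out$subtelomeric)
  out
}

#' Chi-square goodness-of-fit enrichment of a gene set
#'
#' One-degree-of-freedom goodness of fit of `k_in` hits out of `n_total`
#' against an expected background fraction, without continuity
#' correction:
#' `chi2 = (k - n p)^2 / (n p) + ((n - k) - n (1 - p))^2 / (n (1 - p))`,
#' the square of the one-proportion z-statistic. The background fraction
#' is a required input (typically the genome-wide fraction of genes
#' inside the windows); it is never defaulted.
#'
#' @param k_in Number of genes of the set inside the windows.
#' @param n_total Size of the set.
#' @param background_fraction Expected fraction under no enrichment, in
#'   (0, 1).
#' @return Tibble `k`, `n`, `fraction` (percentage, one decimal), `chi2`,
#'   `p` (upper tail).
#' @examples
#' enrich_chisq(9, 16, 0.1)
#' @export
enrich_chisq <- function(k_in, n_total, background_fraction) {
  stopifnot(k_in >= 0, n_total >= k_in)
  if (background_fraction <= 0 || background_fraction >= 1) {
    stop("background_fraction must lie in (0, 1)", call. = FALSE)
  }
  e1 <- n_total * background_fraction
  e2 <- n_total * (1 - background_fraction)
  if (min(e1, e2) < 1e-9) stop("degenerate background", call. = FALSE)
  chi2 <- (k_in - e1)^2 / e1 + ((n_total - k_in) - e2)^2 / e2
  tibble::tibble(
    k = k_in, n = n_total,
    fraction = round_half_up(100 * k_in / n_total, 1),
    chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}
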