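#' Filter lowly expressed genes by raw CPM
#'
#' Keeps endogenous genes whose counts-per-million — computed on raw
#' column totals (endogenous + spike), before any spike anchoring —
#' strictly exceed `cpm_threshold` in at least `min_samples` samples.
#' Spike-in features are always retained, since they are needed for
#' normalization regardless of abundance.
#'
#' @param counts Count table.
#' @param cpm_threshold CPM cutoff (strict inequality).
#' @param min_samples Minimum number of samples exceeding the cutoff.
#' @return Filtered count table.
#' @export
filter_expressed <- function(counts, cpm_threshold = 1, min_samples = 3) {
  smp <- sample_ids(counts)
  m <- as.matrix(counts[, smp])
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples | counts$is_spike
  counts[keep, ]
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of a common dispersion phi
#' over endogenous genes, conditioning on each gene's within-group total
#' after counts are adjusted to a common effective size (counts are scaled
#' to the geometric-mean effective size, the adjustment that makes the
#' conditional argument applicable). Groups with a single sample carry no
#' dispersion information and are ignored. The search is bounded on
#' `[1e-6, 10]` and is deterministic.
#'
#' @param counts Count table.
#' @param groups Either a vector of group labels aligned with the sample
#'   columns, or a sample sheet (then `condition_col` names the label
#'   column).
#' @param factors Normalization factors from [tmm_factors()]; `NULL` uses
#'   raw column totals as effective sizes.
#' @param condition_col Sample-sheet column with group labels.
#' @return List with `common_dispersion` and the log-likelihood value,
#'   class `"dispersion_estimate"`.
#' @export
estimate_dispersion <- function(counts, groups, factors = NULL,
                                condition_col = "condition") {
  smp <- sample_ids(counts)
  if (length(smp) < 2) stop("need >= 2 samples", call. = FALSE)
  grp <- resolve_groups(groups, smp, condition_col)
  es <- effective_sizes(counts, factors, smp)
  y <- count_matrix(counts, spikes = "drop")
  if (all(y == 0)) {
    warning("all-zero count matrix; dispersion set to 0")
    return(structure(list(common_dispersion = 0, loglik = 0),
                     class = "dispersion_estimate"))
  }
  y <- sweep(y, 2, exp(mean(log(es))) / es, "*")  # adjust to common size
  groups_use <- names(which(table(grp) >= 2))
  cond_ll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (g in groups_use) {
      yg <- y[, grp == g, drop = FALSE]
      n <- ncol(yg)
      z <- rowSums(yg)
      ll <- ll + sum(rowSums(lgamma(yg + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r))
    }
    ll
  }
  opt <- stats::optimize(cond_ll, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-6)
  structure(list(common_dispersion = exp(opt$maximum), loglik = opt$objective),
            class = "dispersion_estimate")
}

resolve_groups <- function(groups, smp, condition_col) {
  if (is.data.frame(groups)) {
    i <- match(smp, groups$sample_id)
    if (anyNA(i)) stop("sample sheet is missing samples", call. = FALSE)
    as.character(groups[[condition_col]][i])
  } else {
    stopifnot(length(groups) == length(smp))
    as.character(groups)
  }
}

effective_sizes <- function(counts, factors, smp) {
  if (is.null(factors)) {
    colSums(as.matrix(counts[, smp]))
  } else {
    i <- match(smp, factors$sample_id)
    if (anyNA(i)) stop("factors missing for some samples", call. = FALSE)
    factors$effective_size[i]
  }
}

#' Two-group negative-binomial exact test
#'
#' Counts are adjusted to a common effective size, group sums are formed,
#' and conditioning on the pooled total n the p-value sums the
#' probabilities of all splits `(y, n - y)` that are as or less probable
#' than the observed one (two-sided). Conditional on n the split follows a
#' beta-binomial-type law with weights `n_a/phi` and `n_b/phi` that does
#' not depend on the mean; at `phi = 0` it reduces to a binomial with
#' success probability proportional to the group effective sizes. Ties in
#' "as or less probable" use a 1e-12 relative tolerance. The log2 fold
#' change is the size-adjusted group-mean ratio with a 0.125 prior count
#' on each side (display only; it never enters the test).
#'
#' @param ya,yb Per-sample counts in groups a (test) and b (reference).
#' @param es_a,es_b Per-sample effective sizes, positive.
#' @param dispersion Common NB dispersion phi >= 0.
#' @return List with `pvalue` and `logFC` (a vs b).
#' @examples
#' nb_exact_test(c(30, 25), c(10, 12), c(1e6, 1e6), c(1e6, 1e6), 0.1)
#' @export
nb_exact_test <- function(ya, yb, es_a, es_b, dispersion) {
  stopifnot(length(ya) >= 1, length(yb) >= 1,
            length(es_a) == length(ya), length(es_b) == length(yb),
            all(c(es_a, es_b) > 0), dispersion >= 0)
  n0 <- exp(mean(log(c(es_a, es_b))))
  ya_adj <- ya * n0 / es_a
  yb_adj <- yb * n0 / es_b
  za <- round(sum(ya_adj)); zb <- round(sum(yb_adj))
  n <- za + zb
  lfc <- log2((mean(ya_adj) + 0.125) / (mean(yb_adj) + 0.125))
  if (n == 0) return(list(pvalue = 1, logFC = 0))
  p <- split_pvalue(za, n, length(ya), length(yb), dispersion)
  list(pvalue = p, logFC = lfc)
}

# conditional two-sided exact p for observed split (y_obs, n - y_obs)
split_pvalue <- function(y_obs, n, n_a, n_b, phi) {
  y <- 0:n
  if (phi == 0) {
    logf <- stats::dbinom(y, n, n_a / (n_a + n_b), log = TRUE)
  } else {
    ra <- n_a / phi; rb <- n_b / phi
    logf <- lgamma(y + ra) - lgamma(y + 1) - lgamma(ra) +
      lgamma(n - y + rb) - lgamma(n - y + 1) - lgamma(rb)
  }
  f <- exp(logf - max(logf))
  f <- f / sum(f)
  min(1, sum(f[f <= f[y_obs + 1] * (1 + 1e-12)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) m p_(j) / j`, capped at 1 and returned in the
#' input order; a monotone transform of the p-values.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  ord <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * pvalues[ord]))
  q[order(ord)]
}

#' Classify differential-expression results
#'
#' `up` iff FDR < alpha and logFC > 0; `down` iff FDR < alpha and
#' logFC < 0; otherwise `ns`.
#'
#' @param results Tibble with `logFC` and `fdr` columns (e.g. the `table`
#'   of a [de_test()] fit).
#' @param alpha FDR threshold.
#' @return `results` with a `class` column added/replaced.
#' @export
classify_de <- function(results, alpha = 0.05) {
  dplyr::mutate(
    results,
    class = dplyr::case_when(
      .data$fdr < alpha & .data$logFC > 0 ~ "up",
      .data$fdr < alpha & .data$logFC < 0 ~ "down",
      .default = "ns"
    )
  )
}

#' Differential expression between two conditions
#'
#' Runs the two-group NB exact test gene by gene under spike-anchored (or
#' user-supplied) effective sizes, adjusts p-values by Benjamini-Hochberg
#' and classifies at `alpha`. Returns a fit object with [tidy()] and
#' [glance()] methods and an [ggplot2::autoplot()] MA-style plot.
#'
#' @param counts Count table (typically already through
#'   [filter_expressed()]).
#' @param sample_sheet Sample sheet with `sample_id` and `condition_col`.
#' @param test,reference Condition labels to compare (test vs reference).
#' @param factors Normalization factors; `NULL` falls back to raw column
#'   totals (per-library normalization — exactly the anchoring choice the
#'   spike-in design exists to avoid, but useful for contrast
#'   experiments).
#' @param dispersion Common NB dispersion; `NULL` estimates it with
#'   [estimate_dispersion()] on the two groups.
#' @param alpha FDR threshold for classification.
#' @param condition_col Sample-sheet column with condition labels.
#' @return A `de_result` object: list with `table` (gene_id, logCPM,
#'   logFC, pvalue, fdr, class), `dispersion`, `contrast`, `alpha`.
#' @export
de_test <- function(counts, sample_sheet, test, reference, factors = NULL,
                    dispersion = NULL, alpha = 0.05,
                    condition_col = "condition") {
  sheet <- tibble::as_tibble(sample_sheet)
  stopifnot(all(c("sample_id", condition_col) %in% names(sheet)))
  smp_a <- sheet$sample_id[sheet[[condition_col]] == test]
  smp_b <- sheet$sample_id[sheet[[condition_col]] == reference]
  if (length(smp_a) == 0 || length(smp_b) == 0) {
    stop("empty group: ", if (length(smp_a) == 0) test else reference,
         call. = FALSE)
  }
  sub <- counts[, c("feature_id", "is_spike", smp_a, smp_b)]
  es <- effective_sizes(sub, factors, c(smp_a, smp_b))
  if (is.null(dispersion)) {
    grp <- rep(c("a", "b"), c(length(smp_a), length(smp_b)))
    fac <- tibble::tibble(sample_id = c(smp_a, smp_b), effective_size = es)
    dispersion <- estimate_dispersion(sub, grp, fac)$common_dispersion
  }
  y <- count_matrix(sub, spikes = "drop")
  n0 <- exp(mean(log(es)))
  ia <- seq_along(smp_a); ib <- length(smp_a) + seq_along(smp_b)
  res <- vapply(seq_len(nrow(y)), function(g) {
    r <- nb_exact_test(y[g, ia], y[g, ib], es[ia], es[ib], dispersion)
    c(r$pvalue, r$logFC)
  }, numeric(2))
  adj <- sweep(y, 2, n0 / es, "*")
  tab <- tibble::tibble(
    gene_id = rownames(y),
    logCPM = base::log2(rowMeans(adj) * 1e6 / n0 + 0.25),
    logFC = res[2, ],
    pvalue = res[1, ],
    fdr = bh_adjust(res[1, ])
  ) |> classify_de(alpha)
  structure(list(table = tab, dispersion = dispersion,
                 contrast = paste(test, "vs", reference), alpha = alpha,
                 n_samples = c(test = length(smp_a),
                               reference = length(smp_b))),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("Negative-binomial exact test:", x$contrast, "\n")
  cat("  common dispersion:", signif(x$dispersion, 4),
      " alpha:", x$alpha, "\n")
  print(table(x$table$class))
  invisible(x)
}

#' Up/down/ns summary of one or more DE results
#'
#' @param ... `de_result` objects, or a single named list of them.
#' @return Tibble `comparison`, `up`, `down`, `ns` — the shape of a
#'   timecourse DE summary table.
#' @export
de_summary <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "de_result")) fits <- fits[[1]]
  purrr::map_dfr(fits, function(f) {
    cls <- factor(f$table$class, levels = c("up", "down", "ns"))
    tibble::tibble(comparison = f$contrast,
                   up = sum(cls == "up"), down = sum(cls == "down"),
                   ns = sum(cls == "ns"))
  })
}
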