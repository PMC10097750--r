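#' Read a count matrix and spike-feature list
#'
#' Counts: TSV with a feature-ID first column and one integer column per
#' sample. Spikes: one feature ID per line; every listed ID must be
#' present in the matrix and the list must be non-empty (normalization is
#' impossible without anchors).
#'
#' @param path Counts TSV path.
#' @param spike_list_path Spike ID list path.
#' @return A count table (see [as_count_tbl()]).
#' @export
read_counts <- function(path, spike_list_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "feature_id"
  if (anyDuplicated(tab$feature_id)) {
    row <- which(duplicated(tab$feature_id))[1]
    stop("duplicated feature ID '", tab$feature_id[row], "' at data row ",
         row, " of ", path, call. = FALSE)
  }
  smp <- setdiff(names(tab), "feature_id")
  for (s in smp) {
    bad <- which(tab[[s]] != floor(tab[[s]]) | is.na(tab[[s]]))
    if (length(bad) > 0) {
      stop("non-integer count in column '", s, "', data row ", bad[1],
           " of ", path, call. = FALSE)
    }
  }
  spikes <- readLines(spike_list_path)
  spikes <- spikes[nzchar(spikes)]
  if (length(spikes) == 0) {
    stop("empty spike list: ", spike_list_path,
         " (spike-anchored normalization needs anchors)", call. = FALSE)
  }
  as_count_tbl(tab, spike_features = spikes)
}

#' Read a sample sheet
#' @param path TSV with columns sample_id, genotype, timepoint, replicate,
#'   batch, relative_cells (a `condition` column is added if absent).
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "genotype", "timepoint", "replicate", "batch",
            "relative_cells")
  missing <- setdiff(need, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"condition" %in% names(sheet)) {
    sheet$condition <- paste(sheet$genotype, sheet$timepoint, sep = "_")
  }
  sheet
}

#' Read chromosome lengths
#' @param path Two-column TSV (chrom, length), no header.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         show_col_types = FALSE, progress = FALSE)
  stats::setNames(tab$length, tab$chrom)
}

#' Read gene loci from GFF3 or an interval TSV
#'
#' GFF3 (1-based inclusive) is read through `rtracklayer`, keeping `gene`
#' features (all features if none are typed `gene`). The TSV dialect has
#' columns gene_id, chrom, starts, ends, where multi-interval genes carry
#' semicolon-separated coordinate lists.
#'
#' @param path Annotation path; format guessed from the extension unless
#'   `format` is given.
#' @param format `"gff3"` or `"tsv"`.
#' @return Locus tibble: one row per interval, columns `gene_id`,
#'   `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene", na.rm = TRUE)) {
      gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    }
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr)) && !all(is.na(gr$ID))) {
      sub("^gene:", "", gr$ID)
    } else {
      as.character(seq_along(gr))
    }
    return(tibble::tibble(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    ))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1:4] <- c("gene_id", "chrom", "starts", "ends")
  loci <- tab |>
    dplyr::mutate(starts = strsplit(as.character(.data$starts), ";"),
                  ends = strsplit(as.character(.data$ends), ";")) |>
    tidyr::unnest(c("starts", "ends")) |>
    dplyr::mutate(start = as.integer(.data$starts),
                  end = as.integer(.data$ends)) |>
    dplyr::select("gene_id", "chrom", "start", "end",
                  dplyr::any_of(setdiff(names(tab),
                                        c("gene_id", "chrom", "starts", "ends"))))
  bad <- which(loci$start > loci$end)
  if (length(bad) > 0) {
    stop("interval with end < start at data row ", bad[1], " of ", path,
         call. = FALSE)
  }
  loci
}

#' Read ChIP region counts / spike-read tables
#' @param path TSV with region_id (+ optional chrom/start/end) and one
#'   column per sample, or sample_id/spike_reads/total_reads.
#' @return Tibble.
#' @export
read_chip_regions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_chip_regions
#' @export
read_chip_spikes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "spike_reads") %in% names(tab)))
  tab
}

#' Pipeline configuration
#'
#' Collects file paths and parameters for [run_pipeline()]. Values given
#' here override values read from `file` (a flat JSON object with the
#' same keys); overrides are reported in the run log.
#'
#' @param file Optional JSON config file.
#' @param ... Named fields: paths `counts`, `spikes`, `samples`,
#'   `annotation`, `chrom_sizes`, `chip_regions`, `chip_spikes`;
#'   parameters `alpha`, `cpm_threshold`, `min_samples`, `trim_m`,
#'   `trim_a`, `window_bp`, `background_fraction`, `reference`
#'   (timepoint), `anchor_batch`, `anchor_condition`, `chip_test`,
#'   `chip_reference`, `seed`; `outdir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    counts = NULL, spikes = NULL, samples = NULL, annotation = NULL,
    chrom_sizes = NULL, chip_regions = NULL, chip_spikes = NULL,
    alpha = 0.05, cpm_threshold = 1, min_samples = 3,
    trim_m = 0.30, trim_a = 0.05, window_bp = 200000,
    background_fraction = NULL, reference = "T0",
    anchor_batch = NULL, anchor_condition = "T0",
    chip_test = NULL, chip_reference = NULL,
    seed = 1L, outdir = "spikeshift_out"
  )
  cfg <- defaults
  overridden <- character()
  if (!is.null(file)) {
    from_file <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(dots) > 0) {
    cfg[names(dots)] <- dots
    overridden <- names(dots)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  for (p in c("counts", "spikes", "samples")) {
    if (is.null(cfg[[p]])) stop("config needs path '", p, "'", call. = FALSE)
    if (!file.exists(cfg[[p]])) {
      stop("missing file for '", p, "': ", cfg[[p]], call. = FALSE)
    }
  }
  structure(c(cfg, list(.overridden = overridden)), class = "run_config")
}

#' Run the full spike-anchored analysis pipeline
#'
#' filter -> spike-anchored TMM -> optional batch anchoring -> normalized
#' values -> NB exact tests of every non-reference condition against the
#' reference -> classification -> up/down gene sets, core set and Venn
#' counts -> optional subtelomeric enrichment -> optional ChIP branch.
#' All tables are written as TSV under `outdir` together with a
#' machine-readable `summary.json` and a parameter log; outputs are a
#' pure function of (input files, config, seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  logcon <- file(logfile, "w")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) writeLines(paste0("[", Sys.time(), "] ", ...), logcon)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  say("config: ", jsonlite::toJSON(
    config[setdiff(names(config), ".overridden")], auto_unbox = TRUE,
    null = "null"
  ))
  if (length(config$.overridden) > 0) {
    say("overridden by call: ", paste(config$.overridden, collapse = ", "))
  }

  counts <- stage("read", read_counts(config$counts, config$spikes))
  sheet <- stage("read", read_sample_sheet(config$samples))

  counts <- stage("filter", filter_expressed(counts, config$cpm_threshold,
                                             config$min_samples))
  say("filter: ", sum(!counts$is_spike), " genes kept (> ",
      config$cpm_threshold, " CPM in >= ", config$min_samples, " samples)")

  factors <- stage("normalize",
                   tmm_factors(counts, trim_m = config$trim_m,
                               trim_a = config$trim_a))
  say("normalize: reference sample ", attr(factors, "reference"))
  if (!is.null(config$anchor_batch)) {
    factors <- stage("batch_correct",
                     batch_correct(factors, sheet, config$anchor_batch,
                                   config$anchor_condition))
    say("batch_correct: anchored to batch ", config$anchor_batch, " at ",
        config$anchor_condition)
  }
  readr::write_tsv(factors, file.path(config$outdir, "norm_factors.tsv"))
  norm <- normalize_counts(counts, factors)
  readr::write_tsv(norm, file.path(config$outdir, "normalized.tsv"))

  ref_cond <- unique(sheet$condition[sheet$timepoint == config$reference])
  contrasts <- setdiff(unique(sheet$condition), ref_cond)
  fits <- stage("test", lapply(contrasts, function(cc) {
    de_test(counts, sheet, test = cc, reference = ref_cond[1],
            factors = factors, alpha = config$alpha)
  }))
  names(fits) <- contrasts
  for (cc in contrasts) {
    readr::write_tsv(fits[[cc]]$table,
                     file.path(config$outdir, paste0("de_", cc, ".tsv")))
  }
  summary_tab <- de_summary(fits)
  readr::write_tsv(summary_tab, file.path(config$outdir, "de_summary.tsv"))

  up_sets <- lapply(fits, de_genes, direction = "up")
  sets_out <- list()
  if (length(up_sets) >= 2) {
    core <- core_set(up_sets)
    writeLines(core, file.path(config$outdir, "core_up_genes.txt"))
    venn <- venn_counts(up_sets[seq_len(min(4, length(up_sets)))])
    readr::write_tsv(venn, file.path(config$outdir, "venn_up.tsv"))
    sets_out <- list(core_up_size = length(core),
                     venn_up = as.list(stats::setNames(venn$count,
                                                       venn$pattern)))
  }

  enr_out <- NULL
  if (!is.null(config$annotation) && !is.null(config$chrom_sizes)) {
    enr_out <- stage("enrichment", {
      loci <- read_annotation(config$annotation)
      sizes <- read_chrom_sizes(config$chrom_sizes)
      windows <- terminal_windows(sizes, config$window_bp)
      core <- if (length(up_sets) >= 2) core_set(up_sets) else
        unique(unlist(up_sets))
      flags_all <- assign_windows(loci, windows)
      core_flags <- flags_all[flags_all$gene_id %in% core, ]
      readr::write_tsv(core_flags,
                       file.path(config$outdir, "subtelomeric_flags.tsv"))
      k <- sum(core_flags$subtelomeric); n <- nrow(core_flags)
      if (!is.null(config$background_fraction) && n > 0) {
        enr <- enrich_chisq(k, n, config$background_fraction)
      } else {
        say("enrichment: no background_fraction given; reporting counts only")
        enr <- tibble::tibble(
          k = k, n = n,
          fraction = if (n > 0) round_half_up(100 * k / n, 1) else NA_real_,
          chi2 = NA_real_, p = NA_real_
        )
      }
      readr::write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
      as.list(enr)
    })
  }

  chip_out <- NULL
  if (!is.null(config$chip_regions) && !is.null(config$chip_spikes)) {
    chip_out <- stage("chip", {
      regions <- read_chip_regions(config$chip_regions)
      spikes <- read_chip_spikes(config$chip_spikes)
      cf <- spike_factors(spikes)
      normed <- normalize_regions(regions, cf)
      readr::write_tsv(normed,
                       file.path(config$outdir, "chip_normalized.tsv"))
      if (!is.null(config$chip_test) && !is.null(config$chip_reference) &&
          "condition" %in% names(spikes)) {
        cmp <- compare_groups(normed, spikes, test = config$chip_test,
                              reference = config$chip_reference)
        readr::write_tsv(cmp,
                         file.path(config$outdir, "chip_comparison.tsv"))
        list(n_regions = nrow(regions),
             n_significant = sum(cmp$p < 0.05))
      } else {
        list(n_regions = nrow(regions))
      }
    })
  }

  summary <- c(
    list(
      n_genes_tested = sum(!counts$is_spike),
      reference = config$reference,
      alpha = config$alpha,
      seed = config$seed,
      de = lapply(seq_len(nrow(summary_tab)), function(i)
        as.list(summary_tab[i, ]))
    ),
    sets_out,
    if (!is.null(enr_out)) list(enrichment = enr_out),
    if (!is.null(chip_out)) list(chip = chip_out)
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  say("done")
  invisible(summary)
}
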