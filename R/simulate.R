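#' Simulation configuration for spike-anchored RNA-seq counts
#'
#' Describes a study in which total RNA per cell changes between conditions
#' (a *global* shift, invisible to per-library normalization) while
#' spike-in controls are dosed in proportion to cell number. Each
#' condition carries a global factor `global_factor` multiplying every
#' endogenous gene's per-cell abundance; the reference condition must have
#' `global_factor = 1`.
#'
#' The default design mirrors a nitrogen-starvation quiescence timecourse
#' in fission yeast: a vegetative reference (T0) and three starvation
#' timepoints with progressively stronger global repression, three
#' biological replicates each, one batch.
#'
#' @param n_genes Number of endogenous genes.
#' @param n_spikes Number of spike-in species (default 92, the size of the
#'   standard external RNA control mix).
#' @param conditions Data frame with columns `genotype`, `timepoint`,
#'   `global_factor` (in (0, 1]), `n_replicates`, `batch`,
#'   `relative_cells` (> 0).
#' @param baseline_logmean_sd SD of per-gene log baseline abundance
#'   (natural log; ~2 spans the orders of magnitude seen in yeast).
#' @param nb_dispersion Negative-binomial dispersion phi >= 0
#'   (variance mu + phi mu^2); 0 gives Poisson counts.
#' @param depth_per_sample Expected total reads per sample.
#' @param de_fraction Fraction of genes given a condition-specific
#'   relative fold change (on top of the global factor).
#' @param de_logfc_sd SD of those log2 fold changes.
#' @param spike_share Expected spike read fraction in the reference
#'   condition; sets the spike pool size relative to the endogenous pool.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 6000,
                       n_spikes = 92,
                       conditions = default_conditions(),
                       baseline_logmean_sd = 2,
                       nb_dispersion = 0.05,
                       depth_per_sample = 1e6,
                       de_fraction = 0.05,
                       de_logfc_sd = 1,
                       spike_share = 0.05,
                       seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  need <- c("genotype", "timepoint", "global_factor", "n_replicates",
            "batch", "relative_cells")
  if (!all(need %in% names(conditions))) {
    stop("conditions must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(conditions) == 0) stop("no conditions given", call. = FALSE)
  conditions$condition <- paste(conditions$genotype, conditions$timepoint,
                                sep = "_")
  if (anyDuplicated(conditions$condition)) {
    stop("condition labels (genotype x timepoint) must be unique",
         call. = FALSE)
  }
  with(conditions, {
    if (any(global_factor <= 0 | global_factor > 1)) {
      stop("global_factor must lie in (0, 1]", call. = FALSE)
    }
    if (any(relative_cells <= 0)) stop("relative_cells must be > 0", call. = FALSE)
    if (any(n_replicates < 1)) stop("n_replicates must be >= 1", call. = FALSE)
  })
  if (conditions$global_factor[1] != 1) {
    stop("the reference (first) condition must have global_factor = 1",
         call. = FALSE)
  }
  if (n_genes < 1 || n_spikes < 1) stop("need >= 1 gene and spike", call. = FALSE)
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction in [0,1]", call. = FALSE)
  if (spike_share <= 0 || spike_share >= 1) stop("spike_share in (0,1)", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), n_spikes = as.integer(n_spikes),
    conditions = conditions, baseline_logmean_sd = baseline_logmean_sd,
    nb_dispersion = nb_dispersion, depth_per_sample = depth_per_sample,
    de_fraction = de_fraction, de_logfc_sd = de_logfc_sd,
    spike_share = spike_share, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default quiescence-timecourse design
#'
#' Wild-type reference at T0 plus three starvation timepoints with global
#' repression deepening to one fifth of vegetative transcription, three
#' replicates each, one batch, equal cell numbers.
#' @return Condition tibble suitable for [sim_config()].
#' @export
default_conditions <- function() {
  tibble::tibble(
    genotype = "wt",
    timepoint = c("T0", "T1D", "T1W", "T2W"),
    global_factor = c(1, 0.5, 0.2, 0.2),
    n_replicates = 3L,
    batch = "B1",
    relative_cells = 1
  )
}

# deterministic per-sample stream: a fixed affine counter split of the
# master seed, so sample draws do not depend on how many variates earlier
# samples consumed
sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 100003) %% 2147483629)
}

#' Simulate spike-anchored RNA-seq counts
#'
#' Per-cell endogenous abundance of gene g in condition c is
#' `mu_g * f_gc * G_c` (log-normal baseline `mu_g`, relative fold change
#' `f_gc`, global factor `G_c`); per-cell spike abundance is a fixed
#' log2-spaced ladder shared by all samples. Sequencing samples relative
#' proportions: the expected count of feature f is
#' `depth * a_f / sum(a)`, so lowering `G_c` raises the spike read
#' fraction. Counts are negative-binomial around these means (Poisson when
#' `nb_dispersion = 0`).
#'
#' @param config A [sim_config()].
#' @return List with `counts` (count table), `samples` (sample sheet
#'   tibble: sample_id, genotype, timepoint, condition, replicate, batch,
#'   relative_cells) and `truth` (list: `gene_fc` long tibble of true
#'   relative fold changes, `conditions` with true global factors,
#'   `samples` with expected spike read proportion).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, depth_per_sample = 1e4))
#' dplyr::count(sim$counts, is_spike)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cnd <- config$conditions

  set.seed(config$seed)
  mu <- stats::rlnorm(config$n_genes, meanlog = log(10),
                      sdlog = config$baseline_logmean_sd)
  # spike ladder: log2-spaced over ~2^20, scaled so the reference-condition
  # spike read share equals spike_share
  e <- 2^seq(0, 20, length.out = config$n_spikes)
  e <- e * (config$spike_share / (1 - config$spike_share)) * sum(mu) / sum(e)

  n_de <- round(config$de_fraction * config$n_genes)
  fc <- matrix(1, config$n_genes, nrow(cnd),
               dimnames = list(NULL, cnd$condition))
  for (j in seq_len(nrow(cnd))[-1]) {
    if (n_de > 0) {
      idx <- sample.int(config$n_genes, n_de)
      fc[idx, j] <- 2^stats::rnorm(n_de, 0, config$de_logfc_sd)
    }
  }

  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  spike_ids <- sprintf("spike%03d", seq_len(config$n_spikes))

  samples <- tidyr::uncount(cnd, .data$n_replicates, .remove = FALSE,
                            .id = "replicate")
  samples$sample_id <- paste0(samples$condition, "_r", samples$replicate)
  samples <- dplyr::select(samples, "sample_id", "genotype", "timepoint",
                           "condition", "replicate", "batch",
                           "relative_cells")

  phi <- config$nb_dispersion
  depth <- config$depth_per_sample
  mat <- matrix(0L, config$n_genes + config$n_spikes, nrow(samples),
                dimnames = list(c(gene_ids, spike_ids), samples$sample_id))
  spike_prop <- numeric(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    j <- match(samples$condition[s], cnd$condition)
    # relative_cells scales both pools identically and cancels from the
    # proportions; kept explicit to mirror the dosing model
    a <- c(mu * fc[, j] * cnd$global_factor[j], e) * samples$relative_cells[s]
    m <- depth * a / sum(a)
    spike_prop[s] <- sum(e) / (sum(mu * fc[, j]) * cnd$global_factor[j] + sum(e))
    set.seed(sample_seed(config$seed, s))
    mat[, s] <- if (phi == 0) stats::rpois(length(m), m) else
      stats::rnbinom(length(m), mu = m, size = 1 / phi)
  }

  counts <- as_count_tbl(mat, spike_features = spike_ids)
  truth <- list(
    gene_fc = tibble::as_tibble(fc) |>
      dplyr::mutate(gene_id = gene_ids, .before = 1) |>
      tidyr::pivot_longer(-"gene_id", names_to = "condition",
                          values_to = "true_fc"),
    conditions = dplyr::select(cnd, "condition", "global_factor"),
    samples = tibble::tibble(sample_id = samples$sample_id,
                             expected_spike_prop = spike_prop)
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate spike-in ChIP-seq region counts
#'
#' Models an IP in which a fixed amount of exogenous spike-in chromatin is
#' added per sample while target-genome occupancy varies by condition: a
#' condition with occupancy factor `o` contributes target mass
#' proportional to `o`, so its spike read fraction is
#' `sf0 / (sf0 + o * (1 - sf0))` where `sf0` is the spike fraction at
#' occupancy 1. Region counts are negative-binomial around
#' occupancy-weighted propensities.
#'
#' @param n_regions Number of target regions.
#' @param conditions Data frame with columns `condition`, `occupancy`
#'   (> 0) and `n_replicates`.
#' @param spike_fraction Spike read fraction at occupancy 1, in (0, 1).
#' @param depth Expected total reads per sample.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return List with `regions` (region_id + one count column per sample),
#'   `spikes` (sample_id, condition, spike_reads, total_reads) and `truth`
#'   (condition occupancies).
#' @export
simulate_chip <- function(n_regions,
                          conditions,
                          spike_fraction = 0.1,
                          depth = 1e6,
                          dispersion = 0.05,
                          seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("condition", "occupancy", "n_replicates") %in%
                  names(conditions)))
  if (n_regions < 1) stop("need >= 1 region", call. = FALSE)
  if (any(conditions$occupancy <= 0)) {
    stop("occupancy factors must be > 0", call. = FALSE)
  }
  if (spike_fraction <= 0 || spike_fraction >= 1) {
    stop("spike_fraction must lie in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  w <- stats::rlnorm(n_regions, log(10), 1)
  w <- w / sum(w)
  region_ids <- sprintf("region%03d", seq_len(n_regions))

  samples <- tidyr::uncount(conditions, .data$n_replicates, .remove = FALSE,
                            .id = "replicate")
  samples$sample_id <- paste0(samples$condition, "_r", samples$replicate)

  phi <- dispersion
  rdraw <- function(m) if (phi == 0) stats::rpois(length(m), m) else
    stats::rnbinom(length(m), mu = m, size = 1 / phi)

  mat <- matrix(0L, n_regions, nrow(samples),
                dimnames = list(region_ids, samples$sample_id))
  spike_reads <- integer(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    o <- samples$occupancy[s]
    sf <- spike_fraction / (spike_fraction + o * (1 - spike_fraction))
    set.seed(sample_seed(as.integer(seed), s))
    spike_reads[s] <- rdraw(depth * sf)
    mat[, s] <- rdraw(depth * (1 - sf) * w)
  }
  regions <- tibble::as_tibble(mat) |>
    dplyr::mutate(region_id = region_ids, .before = 1)
  spikes <- tibble::tibble(
    sample_id = samples$sample_id,
    condition = samples$condition,
    spike_reads = spike_reads,
    total_reads = spike_reads + colSums(mat)
  )
  list(regions = regions, spikes = spikes,
       truth = dplyr::select(conditions, "condition", "occupancy"))
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Emits everything the pipeline readers consume: counts TSV, spike ID
#' list, sample sheet TSV, a GFF3 gene annotation placing a configurable
#' fraction of genes inside the terminal windows, a chrom.sizes table,
#' and (if a ChIP simulation is supplied) region-count and spike-read
#' TSVs. Files round-trip losslessly through [read_counts()],
#' [read_sample_sheet()] and [read_annotation()].
#'
#' @param sim Result of [simulate_counts()].
#' @param outdir Output directory (created if missing).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param subtel_fraction Fraction of genes placed inside the terminal
#'   `window_bp` windows.
#' @param window_bp Terminal window width used for placement.
#' @param chip Optional result of [simulate_chip()].
#' @param seed Seed for gene placement.
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixtures <- function(sim, outdir,
                           chrom_lengths = c(I = 5579133, II = 4539804,
                                             III = 2452883),
                           subtel_fraction = 0.1,
                           window_bp = 200000,
                           chip = NULL,
                           seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  paths <- list(counts = pth("counts.tsv"), spikes = pth("spikes.txt"),
                samples = pth("samples.tsv"), annotation = pth("genes.gff3"),
                chrom_sizes = pth("chrom.sizes"))
  tryCatch({
    readr::write_tsv(dplyr::select(sim$counts, -"is_spike"), paths$counts)
    writeLines(sim$counts$feature_id[sim$counts$is_spike], paths$spikes)
    readr::write_tsv(sim$samples, paths$samples)
    readr::write_tsv(
      tibble::tibble(chrom = names(chrom_lengths), length = chrom_lengths),
      paths$chrom_sizes, col_names = FALSE
    )
    genes <- sim$counts$feature_id[!sim$counts$is_spike]
    gr <- place_genes(genes, chrom_lengths, subtel_fraction, window_bp, seed)
    rtracklayer::export(gr, paths$annotation, format = "gff3")
    if (!is.null(chip)) {
      paths$chip_regions <- pth("chip_regions.tsv")
      paths$chip_spikes <- pth("chip_spikes.tsv")
      readr::write_tsv(chip$regions, paths$chip_regions)
      readr::write_tsv(chip$spikes, paths$chip_spikes)
    }
  }, error = function(e) {
    stop("failed writing fixtures under ", outdir, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(paths)
}

# random non-overlapping-ish gene placement; a fixed fraction lands inside
# the terminal windows
place_genes <- function(genes, chrom_lengths, subtel_fraction, window_bp,
                        seed) {
  n <- length(genes)
  if (n == 0) {
    return(GenomicRanges::GRanges(seqlengths = chrom_lengths))
  }
  set.seed(as.integer(seed))
  n_sub <- round(subtel_fraction * n)
  is_sub <- seq_len(n) <= n_sub
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- stats::rpois(n, 1500) + 200
  L <- unname(chrom_lengths[chrom])
  start <- integer(n)
  for (i in seq_len(n)) {
    if (is_sub[i]) {
      arm_left <- stats::runif(1) < 0.5
      start[i] <- if (arm_left) sample.int(window_bp - len[i], 1) else
        L[i] - window_bp + sample.int(window_bp - len[i], 1)
    } else {
      start[i] <- window_bp + sample.int(L[i] - 2 * window_bp - len[i], 1)
    }
  }
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(chrom_lengths)),
    ranges = IRanges::IRanges(start = start, width = len),
    type = "gene", ID = genes, Name = genes,
    seqinfo = GenomeInfoDb::Seqinfo(
      seqnames = names(chrom_lengths), seqlengths = unname(chrom_lengths)
    )
  )
}
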