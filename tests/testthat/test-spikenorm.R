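test_that("identical and uniformly scaled spike profiles give unit factors", {
  sp <- cbind(c(10, 20, 40, 80), c(10, 20, 40, 80))
  counts <- toy_counts(sp)
  f <- tmm_factors(counts, reference = "s1")
  expect_equal(f$tmm_factor, c(1, 1))
  expect_equal(f$effective_size[1], f$effective_size[2])

  sp2 <- cbind(c(10, 20, 40, 80), 2 * c(10, 20, 40, 80))
  f2 <- tmm_factors(toy_counts(sp2), reference = "s1")
  expect_equal(f2$tmm_factor, c(1, 1))
  expect_equal(f2$effective_size[2] / f2$effective_size[1], 2)
})

test_that("the 6-feature worked instance matches a direct evaluation", {
  a <- c(10, 20, 40, 80, 160, 320)
  b <- c(30, 60, 120, 240, 480, 10)
  counts <- toy_counts(cbind(a, b))
  f <- tmm_factors(counts, reference = "s1", trim_m = 0.3, trim_a = 0.05)

  # independent arithmetic, spelled out
  na <- sum(a); nb <- sum(b)
  M <- log2((b / nb) / (a / na))
  A <- (log2(b / nb) + log2(a / na)) / 2
  v <- (nb - b) / (nb * b) + (na - a) / (na * a)
  lo_m <- floor(6 * 0.3) + 1; hi_m <- 6 + 1 - lo_m
  lo_a <- floor(6 * 0.05) + 1; hi_a <- 6 + 1 - lo_a
  keep <- rank(M) >= lo_m & rank(M) <= hi_m &
    rank(A) >= lo_a & rank(A) <= hi_a
  f_b <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  centred <- c(1, f_b) / sqrt(f_b)
  expect_equal(f$tmm_factor, centred, tolerance = 1e-12)
})

test_that("spike-restricted factors agree with edgeR on random data", {
  library(edgeR)
  set.seed(9)
  sp <- matrix(rnbinom(92 * 4, mu = 2^runif(92 * 4, 2, 12), size = 5), 92, 4)
  sp[sp == 0] <- 1
  counts <- toy_counts(sp)
  mine <- tmm_factors(counts, reference = "s1")
  theirs <- edgeR::calcNormFactors(sp, lib.size = colSums(sp), method = "TMM",
                                   refColumn = 1, logratioTrim = 0.3,
                                   sumTrim = 0.05)
  expect_equal(mine$tmm_factor, unname(theirs), tolerance = 1e-10)
})

test_that("factors are invariant to endogenous rows and to column scaling", {
  sim <- small_sim(seed = 4, n_genes = 120, depth = 2e4)
  f0 <- tmm_factors(sim$counts, reference = "wt_T0_r1")

  # permute endogenous rows: anchor sufficiency
  genes <- which(!sim$counts$is_spike)
  perm <- sim$counts
  perm[genes, ] <- perm[sample(genes), ]
  f1 <- tmm_factors(perm, reference = "wt_T0_r1")
  expect_equal(f0$tmm_factor, f1$tmm_factor)

  # scaling one whole column (spikes included) leaves its normalized
  # values unchanged up to the precision-weight perturbation: the
  # delta-method weights of the scaled sample shrink relative to the
  # reference half of each pair, so invariance is near-exact, not exact
  scaled <- sim$counts
  scaled$wt_T1W_r2 <- scaled$wt_T1W_r2 * 7
  f2 <- tmm_factors(scaled, reference = "wt_T0_r1")
  n0 <- normalize_counts(sim$counts, f0)
  n2 <- normalize_counts(scaled, f2)
  expect_equal(n0$wt_T1W_r2, n2$wt_T1W_r2, tolerance = 5e-3)
})

test_that("noiseless proportional data recovers total-RNA ratios exactly", {
  mu <- c(100, 50, 20, 10)
  e <- c(40, 20, 10, 5)
  g <- 0.25
  depth <- 1e5
  mk <- function(gf) {
    a <- c(mu * gf, e)
    depth * a / sum(a)  # exact proportions, no sampling noise
  }
  counts <- toy_counts(cbind(mk(1), mk(g))[5:8, , drop = FALSE],
                       gene_mat = cbind(mk(1), mk(g))[1:4, , drop = FALSE])
  f <- tmm_factors(counts, reference = "s1")
  # spikes are fixed per cell, so the effective size is inversely
  # proportional to total RNA per cell
  t1 <- sum(mu) + sum(e); t2 <- sum(mu) * g + sum(e)
  expect_equal(f$effective_size[2] / f$effective_size[1], t1 / t2,
               tolerance = 1e-10)
  # equivalently: normalized endogenous values drop by exactly g
  nrm <- normalize_counts(counts, f, keep_spikes = FALSE)
  expect_equal(nrm$s2 / nrm$s1, rep(g, 4), tolerance = 1e-6)
})

test_that("errors: missing anchors, bad reference, over-trimming", {
  sp <- cbind(c(5, 6, 7), c(5, 6, 7))
  counts <- toy_counts(sp)
  expect_error(tmm_factors(counts, anchor_features = c("nope")), "absent")
  expect_error(tmm_factors(counts, reference = "zzz"), "reference")
  uneven <- toy_counts(cbind(c(10, 220, 43), c(87, 120, 9)))
  expect_error(tmm_factors(uneven, trim_m = 0.45), "fewer than 3")
  zero <- toy_counts(cbind(c(1, 2, 3), c(0, 0, 0)))
  expect_error(tmm_factors(zero), "no nonzero anchor")
})

test_that("batch correction rescales to the anchor batch T0 mean", {
  sheet <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    batch = rep(c("B1", "B2"), each = 4),
    timepoint = rep(c("T0", "T0", "T1W", "T1W"), 2)
  )
  factors <- tibble::tibble(
    sample_id = sheet$sample_id,
    tmm_factor = c(1.1, 1.3, 0.9, 1.0, 0.7, 0.9, 1.2, 1.4),
    anchor_libsize = rep(1000, 8),
    effective_size = 1000 * c(1.1, 1.3, 0.9, 1.0, 0.7, 0.9, 1.2, 1.4)
  )
  out <- batch_correct(factors, sheet, "B1", "T0")
  scale_b2 <- mean(c(1.1, 1.3)) / mean(c(0.7, 0.9))  # = 1.5
  expect_equal(scale_b2, 1.5)
  expect_equal(out$tmm_factor[5:8], factors$tmm_factor[5:8] * 1.5)
  expect_equal(out$tmm_factor[1:4], factors$tmm_factor[1:4])
  # within-batch ratios unchanged
  expect_equal(out$tmm_factor[6] / out$tmm_factor[5],
               factors$tmm_factor[6] / factors$tmm_factor[5])

  # single batch: identity
  one <- batch_correct(factors[1:4, ], sheet[1:4, ], "B1", "T0")
  expect_identical(one, factors[1:4, ])

  # uniform 2x batch: forced rescale by 0.5
  f2 <- factors
  f2$tmm_factor[5:8] <- factors$tmm_factor[1:4] * 2
  out2 <- batch_correct(f2, sheet, "B1", "T0")
  expect_equal(out2$tmm_factor[5:8], factors$tmm_factor[1:4])

  # geometric-mean option and missing-condition error
  outg <- batch_correct(factors, sheet, "B1", "T0", mean_type = "geometric")
  expect_equal(outg$tmm_factor[5],
               0.7 * sqrt(1.1 * 1.3) / sqrt(0.7 * 0.9))
  sheet2 <- sheet; sheet2$timepoint[5:6] <- "T1D"
  expect_error(batch_correct(factors, sheet2, "B1", "T0"), "B2")
})

test_that("normalization recovers a simulated global repression of 0.2", {
  sim <- small_sim(seed = 8, g = 0.2, n_genes = 400, depth = 1e5, phi = 0.05)
  f <- tmm_factors(sim$counts)
  shift <- global_shift(sim$counts, f, sim$samples, "wt_T0")
  med <- median(shift$median_ratio[shift$condition == "wt_T1W"])
  expect_lt(abs(med / 0.2 - 1), 0.1)
})

test_that("all-gene anchoring hides the global shift the spikes reveal", {
  sim <- small_sim(seed = 12, g = 0.2, n_genes = 400, depth = 1e5)
  f_spike <- tmm_factors(sim$counts)
  f_all <- tmm_factors(sim$counts, anchor_features = sim$counts$feature_id)
  s_spike <- global_shift(sim$counts, f_spike, sim$samples, "wt_T0")
  s_all <- global_shift(sim$counts, f_all, sim$samples, "wt_T0")
  med <- function(s) median(s$median_ratio[s$condition == "wt_T1W"])
  expect_lt(abs(med(s_spike) / 0.2 - 1), 0.15)
  expect_gt(med(s_all), 0.85)  # looks like "no change": the false-negative mode
})
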