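---
title: "Spike-anchored analysis of global transcriptome shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-anchored analysis of global transcriptome shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeshift)
library(dplyr)
```

## The measurement problem

Sequencing measures composition, not amount. A library of depth $D$
distributes reads over features in proportion to their share of the RNA
pool, so any normalization that only uses the library itself — total
counts, upper quartiles, or TMM across all genes — is blind to changes in
the *size* of the pool. When fission yeast enter quiescence after
nitrogen removal, transcription per cell collapses to a fraction of the
vegetative level. Under per-library normalization this global repression
is invisible: most fold changes read as zero (false negatives), and the
minority of genes whose relative share rises read as induced even if
their absolute output fell (false positives).

External spike-in controls break the degeneracy when they are dosed **per
cell**. If each sample receives spike molecules in proportion to its cell
number, the spikes contribute a fixed per-cell amount $E$ while the
endogenous pool contributes $G_c \cdot A$ (global factor $G_c$, reference
pool $A$). The expected spike read fraction is then

$$\pi_{\text{spike}}(G_c) \;=\; \frac{E}{G_c A + E},$$

strictly decreasing in $G_c$: global repression *raises* the spike share,
and anchoring normalization on the spikes converts that into a coherent
negative fold change across the transcriptome. Everything in this package
follows from that one identity.

## The count model

`simulate_counts()` generates data under exactly the assumptions the
analysis makes, so parameter recovery is a meaningful test:

* per-cell endogenous abundance of gene $g$ in condition $c$ is
  $\mu_g f_{gc} G_c$, with $\mu_g$ log-normal (`baseline_logmean_sd`,
  default 2 natural-log units — wide enough to span the orders of
  magnitude of a yeast transcriptome) and $f_{gc}$ a gene-specific
  relative fold change (`de_fraction` of genes, log2 effects drawn with
  SD `de_logfc_sd`);
* per-cell spike abundance is a fixed ladder of 92 species, log2-spaced
  over a $2^{20}$ range — reproducing the wide dynamic range of the
  standard external mix without copying proprietary concentrations — and
  scaled so the reference-condition spike share is `spike_share`
  (default 5 %, a typical dosing target);
* sequencing draws counts with NB noise around $D \cdot a_f / \sum a$
  (Poisson when `nb_dispersion = 0`). NB-around-proportions is used
  instead of an explicit multinomial because it matches the downstream
  testing model and is the standard bulk-count approximation;
* `relative_cells` multiplies both pools and cancels from the
  proportions — the algebraic statement of "spikes dosed per cell". It is
  kept explicit because the dosing calibration is the one experimental
  quantity the model cannot invent; it is a free parameter, never a
  guessed molecule count.

One master seed drives gene-level draws; each sample's counts come from a
fixed affine counter split of that seed, so results do not depend on how
many variates earlier samples consumed.

The default design is a quiescence-like timecourse: a vegetative
reference (`global_factor` 1) and three starvation timepoints at 0.5,
0.2, 0.2 with three replicates — a deepening repression of the order
reported for quiescent yeast by absolute quantitation studies, chosen
once as a realistic regime and not tuned thereafter.

**What the simulator does not emulate:** gene length and GC effects,
library-prep composition biases, correlated gene modules, on/off
bimodality, and spike-dosing pipetting error. Passing recovery tests
therefore shows the *inference machinery* is correct under its own
assumptions; it does not certify robustness to every real-data artefact.

## Normalization

`tmm_factors()` is a trimmed mean of M-values restricted to anchor
features (the spikes). Pairwise against a reference sample, using only
anchors nonzero in both (no pseudocount — zeros at the ladder's low end
would otherwise bias the mean): M and A statistics on anchor-library
proportions, two-sided trims of 30 % on M and 5 % on A (the established
TMM defaults; the method is named in the source analyses without
parameters), and a precision-weighted mean using binomial delta-method
variances. Factors are centred to geometric mean 1 so they are comparable
across batches; the effective size is $E_s = N_s f_s$ with $N_s$ the
spike library size. The automatic reference is the sample whose
anchor-count upper-quartile proportion is closest to the mean, with
lexicographic tie-break — deterministic by construction.

Numerical edges: pairs with fewer than three surviving anchors fail
loudly naming the pair; an anchor profile identical to the reference
short-circuits to factor 1; a non-finite weighted mean falls back to
factor 1. One property worth stating precisely: multiplying an entire
column by $c > 0$ leaves that sample's normalized values unchanged only
*up to the precision weights* (the scaled sample's delta-method variances
shrink relative to the reference half of each pair), so the invariance is
near-exact rather than exact; the tests check it at 0.5 % relative
tolerance.

`batch_correct()` handles the situation where a later batch has its own
spike dosing: every non-anchor batch is rescaled by one constant so its
mean factor at a shared condition (typically the vegetative reference)
matches the anchor batch, leaving within-batch ratios untouched. Whether
the historical analyses averaged arithmetically or geometrically, and
whether before or after centring, is not recorded anywhere authoritative;
the arithmetic mean of centred factors is the default and the geometric
mean is an explicit option, with the choice echoed in the run log.

## Differential expression

Filtering keeps genes exceeding 1 CPM in at least 3 samples, computed on
**raw** column totals because filtering precedes normalization in the
stated methods order; spikes are always retained.

The test is a two-group negative-binomial exact test with a common
dispersion. The contrasts of interest are all two-group comparisons
(timepoint vs reference, mutant vs wild type), so a fully specifiable
exact test was chosen over a GLM pipeline: every p-value it produces can
be checked against brute-force enumeration, which the test suite does for
all pooled totals up to 30 at several dispersions. The common dispersion
is the conditional maximum likelihood estimate on counts adjusted to a
common effective size (geometric mean), with a bounded deterministic
search on $[10^{-6}, 10]$; groups with one sample carry no information
and are skipped. The adjustment is a mean rescaling — adequate because
spike-anchored effective sizes within a study are close to each other;
strongly unequal sizes would make the conditional argument approximate.

Conditioning on the pooled total $n$, the split between groups follows a
beta-binomial-type law with weights $n_a/\phi$ and $n_b/\phi$ that is
free of the unknown mean; the two-sided p-value sums all splits as or
less probable than the observed one, with a $10^{-12}$ relative tolerance
on the tie comparison so floating-point noise cannot flip a tail. At
$\phi = 0$ the law reduces to a binomial with success probability
proportional to the group effective sizes. Adjusted group sums are
rounded to integers for enumeration. The reported log2 fold change adds a
0.125 prior count per side — display only, never part of the test — to
avoid infinite estimates on zeros.

Benjamini–Hochberg adjustment is the plain step-up, and classification is
the partition *up* / *down* / *ns* at FDR < 0.05. Under a pure global
shift with spike anchoring, essentially the whole transcriptome is
correctly classified down; the identical pipeline anchored on all genes
classifies almost nothing — the two-sided failure mode the design exists
to avoid. Both behaviours are asserted in the acceptance tests.

## Gene sets and positional enrichment

Set operations are exact, case-sensitive string matching on systematic
gene IDs (case-folding could merge distinct IDs). The "core" set of a
timecourse is the intersection of per-timepoint up-lists, ordered by the
first list; Venn region counts cover 2–4 sets and are checked against a
per-element brute-force tally. Report percentages round half-up to one
decimal (base R's round-half-even would print 56.25 % as 56.2 %).

Subtelomeric windows are the terminal 200 kb of each chromosome arm,
$[1, w]$ and $[L - w + 1, L]$ in 1-based inclusive coordinates. A gene is
subtelomeric iff **any** of its intervals overlaps **any** window by at
least 1 bp — the conservative reading of "within 200 kb of the ends"; a
stricter start-in-window variant is available for sensitivity checks.
Applied to the published coordinates of the 149 genes induced at one day
of starvation (shipped as a plain-text fixture), this rule reproduces the
printed subtelomeric call of every row, and the count of 25/149. The
bundled localization table of the core quiescence genes carries 17 printed
rows against a stated core size of 16; the package reproduces the printed
arithmetic (9 labelled rows over 16) and the discrepancy is inherent to
the printed tables, not resolvable from them.

Enrichment is the 1-df chi-square goodness of fit without continuity
correction (the uncorrected form is the goodness-of-fit default, and the
large published statistics are inconsistent with Yates correction),
algebraically the squared one-proportion z-statistic — an identity the
tests verify numerically. The background fraction is a **required**
argument: the published analyses do not print the background they used,
so defaulting one silently would manufacture agreement; the pipeline
reports counts and fraction without a chi-square when no background is
supplied.

## Spike-in ChIP-seq

With a fixed mass of exogenous chromatin per IP, each sample's scale
factor is `spike_reads(reference) / spike_reads(sample)`; the default
reference is the minimum-spike sample so factors only downscale, the
convention of the exogenous spike-in strategy (an explicit reference
override exists, and the choice is logged, since the historical choice is
not recorded). Normalized between-sample ratios are then invariant to
sequencing depth whenever spike reads scale with depth — the point of the
spike. `simulate_chip()` closes the loop: condition occupancy $o$ sets
the spike fraction to $s_0 / (s_0 + o(1 - s_0))$, and spike-normalized
group means recover the occupancy ratio within 10 % in the acceptance
runs. Group comparison is the equal-variance unpaired t-test (matching
the spreadsheet bar-diagram workflow the quantitation pattern comes
from), Welch behind a flag, with `*`/`**` stars at 0.05 and 0.01;
identical groups return the degenerate $t = 0$, $p = 1$ rather than an
error.

## Problem sizes and determinism

The bundled tests and the acceptance script run the stochastic checks at
2000 genes × 6 samples for the anchoring contrast (depth $10^6$), 1000
genes at depth $2 \times 10^5$ for the 20-seed recovery sweeps, and 30
regions at depth $10^6$ for the ChIP recovery — sizes at which the
Monte-Carlo error of each summary is comfortably inside the asserted
bands while a full run stays in the low tens of seconds. Every stochastic
quantity flows from a single integer seed; printed-table quantities are
deterministic.

## Known limitations

* The common-dispersion model ignores gene-wise dispersion trends; genes
  far more variable than the common $\phi$ will be anti-conservative.
  The exact test also assumes within-group effective sizes are roughly
  equal after adjustment.
* The batch correction assumes the anchor condition is biologically
  identical across batches; if it is not, the rescaling propagates that
  difference to every sample of the batch.
* Spike anchoring inherits the dosing assumption: if spike volume does
  not track cell number (pipetting drift, miscounted cells), the
  "global" signal is confounded with dosing error. The package can flag
  but not repair this.
* The enrichment statistic treats genes as independent Bernoulli draws;
  clustered gene families in subtelomeric regions violate independence
  and inflate significance, which is one reason the background fraction
  must be chosen deliberately.
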