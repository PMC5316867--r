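---
title: "Allele-specific TF binding screens with pwascreen: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific TF binding screens with pwascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwascreen)
```

# The problem

Most disease-associated SNPs from genome-wide association studies fall in
non-coding DNA, where their most plausible mechanism is to create or
destroy a transcription-factor (TF) binding site. A proteome-wide analysis
of disease-associated SNPs (PWAS) probes this directly: for each SNP, two
DNA oligos -- one per allele -- are used as baits in pulldowns from nuclear
extract, the captured proteins are quantified by dimethyl-labelled mass
spectrometry, and proteins with a strong allele-biased heavy/light ratio
are candidate allele-specific binders. Each SNP is assayed in duplicate
with the dimethyl labels swapped between alleles, so a genuine binder
shows *inverted* stored ratios across the two pulldowns while a labelling
artefact shows the same one.

`pwascreen` implements the downstream analysis of such a screen, starting
from protein quantification tables: replicate combination, batch
correction, imputation, ratio-outlier significance, interactor calling,
and a prioritization that weighs each candidate SNP-TF interaction by the
chromatin accessibility of its locus. Companion modules cover exact-test
allelic imbalance at heterozygous SNPs and the "reduced genome"
construction used to map 4C-seq reads. Because the real screens require
large deposited datasets, the package ships a synthetic-data generator
with a ground-truth ledger; every stage is exercised against it.

# The outlier model (Significance A/B)

A pulldown's log2 heavy/light ratios are dominated by background proteins
that bind both alleles equally; allele-specific binders are *outliers* of
that empirical distribution. `significanceOutlierTest()` scores them with
a robust z built from the 15.87/50/84.13 percentiles: with $r_0$ the
median,

$$ z = \begin{cases} (x - r_0) / (P_{84.13} - r_0), & x > r_0 \\
                     (r_0 - x) / (r_0 - P_{15.87}), & x \le r_0
       \end{cases} \qquad p = \operatorname{erfc}(z/\sqrt{2}), $$

a two-sided standard-normal tail. The percentile spreads estimate the
upper and lower standard deviations separately, so a skewed background
does not inflate one tail. Mode B applies the same statistic within
equal-occupancy intensity bins (ratio variance in MS data shrinks with
intensity); mode A is the global version. Defaults: mode B with
`minBinSize = 300`, falling back to mode A (and logging it) when a table
has fewer observed ratios than one full bin -- with one bin the two modes
are identical by construction. Percentiles use linear interpolation
between order statistics (type 7) with ties broken by position, for
determinism across platforms. Degenerate spreads (constant values on one
side of the median) are an error naming the flat side rather than a
division by zero.

# Calling interactors

The screen's working threshold is $p < 0.01$. Two call policies exist:

* **replicates** (default): a protein is called when it is significant at
  `alpha` in *both* label-swap pulldowns of its SNP with sign-consistent
  oriented ratios. This is what the swap design is for: background noise
  must clear the threshold twice, independently, in a consistent
  direction, while a labelling artefact is self-inconsistent. Only
  observed measurements count as evidence; the reported p-value is the
  weaker (larger) of the two.
* **combined**: the literal single-test rule $p < \alpha$ on a combined
  table, retained for data where per-replicate evidence is unavailable.

We made replicate-consistent calling the default after examining its
error structure on synthetic screens: a calibrated single test at
$\alpha = 0.01$ necessarily mislabels about 1% of background proteins,
which swamps a screen with tens of true binders among a thousand
proteins, whereas the dual-consistent rule drives the false-discovery
proportion to a few percent at essentially no cost in recall (the
relevant test cases are in the package's test suite and acceptance
script). Imputed values never vote: a downshifted random draw carries no
directional information, and under the swap convention an imputed pair is
systematically sign-inconsistent, so letting it count would manufacture
spurious alternate-allele calls.

# Batch correction and imputation

Batch effects are removed from the combined log2 fold-change matrix
(proteins x SNPs) with a parametric empirical-Bayes location/scale
adjustment in the ComBat style: per-protein standardization, per-batch
effect estimates, moment-matched normal/inverse-gamma priors, iterative
posterior solution, back-transformation. We wrote the adjuster to
tolerate missing values -- rows with at least two observations in every
batch are adjusted using their observed entries; sparser rows pass
through unchanged and are flagged. On complete matrices it agrees with
the reference implementation in the `sva` package, which serves as an
oracle in the tests. The correction stage runs on the *combined* matrix
because a per-pulldown location shift is already absorbed by the robust
test's median centring; only the Ref/Alt fold changes retain batch
structure worth removing. A single-batch matrix is returned unchanged.

Missing ratios (typically proteins detected in only one channel or below
the detection limit) are imputed per pulldown column from
$\mathcal{N}(\bar{x} - 1.8\,s,\ (0.3\,s)^2)$ of the column's observed
values -- the conventional "replace from a downshifted normal" defaults
(`downshiftFactor = 1.8`, `widthFactor = 0.3`, both exposed). Imputation
completes the fold-change matrix for reporting and ranking and records a
mask so every downstream call carries an `imputed` flag.

# Prioritization by accessibility

TF binding in vivo requires accessible chromatin, so candidate
interactions are ranked by combining binding strength with DNase I
hypersensitivity (DHS) of the SNP locus:

1. per-locus mean DNase I-seq read count across the accessibility
   samples, z-scored across loci (n-1 denominator; raw counts by
   default, with a reads-per-million option behind a flag);
2. absolute log2 Ref/Alt fold change of each interaction, z-scored;
3. the two z-scores are averaged and converted to a one-sided upper-tail
   normal p-value; events with $p < 0.05$ are selected, ranked by p with
   ties broken by descending $|$log2FC$|$, then SNP and protein id.

One interpretive choice matters: the *reference distribution* for the
fold-change z-scores. `fcZscores()` defaults to the vector it is given,
but the pipeline scores calls against the spread of **all quantified
interactions** in the screen. Scoring calls only against each other makes
the statistic self-defeating in clean screens -- if every call is a strong
binder, they centre on one another and none looks exceptional -- whereas
the full-screen reference asks the right question: how extreme is this
fold change relative to everything the screen measured? Per-SNP
z-scoring is available by passing a per-locus reference explicitly. The
upper-tail (one-sided) conversion reflects that $|$log2FC$|$ is
non-negative: only large averages are interesting, and the direction of
preference is carried separately by the fold-change sign. No multiple-
testing correction is applied to this statistic by default; a
Benjamini-Hochberg column is available via `bh = TRUE`.

# Allelic imbalance

Fig-2c/d-style read-outs (ChIP, accessibility, transcription at a
heterozygous SNP) are tested with the exact hypergeometric test on the
2x2 table of assay Ref/Alt counts against a background expectation. The
two-sided p sums the probabilities of all tables with the observed
margins whose point probability does not exceed the observed one (with a
$10^{-7}$ relative guard against floating-point ties between
mathematically equal tables). When no background is supplied, a 50:50
expectation at matched depth is substituted and flagged -- the natural
null for heterozygous genomic DNA; an explicit input/background column
overrides it. The odds ratio is the sample cross-product ratio with the
Haldane-Anscombe 0.5 correction when any cell is zero (flagged).

# The 4C reduced genome

4C-seq reads are short and anchored at restriction sites, so they are
mapped to a "reduced genome": the 30 bases immediately downstream of
every NlaIII site (CATG) on each strand. `digestGenome()` reports every
exact occurrence (palindromic sites once; non-palindromic recognition
sequences are scanned on both strands); `buildReducedGenome()` extracts
the plus-strand flank 3' of the site and the minus-strand flank (reverse
complement of the bases 5' of the site), drops sites within one flank
length of a contig edge, and flags a site unique when neither of its
flanks occurs more than once in the pooled flank multiset. Exact 30-mer
string uniqueness is a deliberate, documented simplification of an
aligner-based mappability evaluation: it is conservative for substitution
errors and makes the filter reproducible without external tools.
Interaction counting tiles contigs with 2.5-kb windows (0-based
half-open; default step = width, so counts conserve reads; a sliding
step is available), counts each read once by its start position,
normalizes to reads per million excluding viewpoint-window reads from
the totals, and reports a log2 between-condition difference with
pseudocount 1 on the normalized counts. The cited interaction caller's
background model is intentionally out of scope; only counts,
normalization and differences are produced.

# What the generator emulates

`simulatePulldownScreen()` reproduces the screen design: 116 SNP loci by
default, two label-swapped pulldowns each, about a thousand quantified
proteins per pulldown, and 27 accessibility samples (15 fetal large
intestine tissues plus 12 CRC cell lines) for `simulateDHSCounts()`.
Choices a user should know, all fixed before the test suite was written:

* **Noise**: replicate log-ratio noise sd 0.3; spiked binders default to
  $|$log2FC$| = 4$ with random sign, both spec-level parameters.
* **Intensities**: log10 intensity ~ Normal(7, 1) -- an arbitrary but
  realistic MS span; only relative binning matters downstream. Spiked
  binders are enriched by one log10 unit (`binderEnrichmentLog10 = 1`):
  a specific binder is, by definition, captured efficiently by its bait.
* **Missingness**: detection-limit censoring -- ratios in the bottom
  intensity quartile are censored with probability 0.1, higher
  intensities never. This is the cleanest missing-not-at-random
  mechanism consistent with ratio-missing proteins in dimethyl data.
* **Batches**: per-batch offsets ~ Normal(0, 0.5) on the oriented
  Ref/Alt scale, expressed relative to the first (reference) batch, one
  label per pulldown pair. Offsets on the oriented scale are the
  component the correction stage can and should remove; a per-replicate
  heavy/light offset would cancel in the swap combination.
* **DHS**: negative-binomial counts, base mean 50, dispersion 0.1,
  10-fold elevation for designated accessible loci.

The generator starts at the protein-quantification table -- no spectra,
peptides or protein inference -- and its background ratios are exactly
normal with intensity-independent variance. Real screens have heavier
tails, correlated proteins (complexes ride along with a direct binder),
and intensity-dependent ratio variance, which is the very reason
Significance B exists but is not simulated; passing tests therefore
demonstrate the machinery's correctness and calibration, not performance
on real extract. Determinism is strict: one seed drives every generator,
stage seeds are derived deterministically from it, and identical
spec + seed reproduces byte-identical tables.

# Problem sizes and numerical choices

The test suite and acceptance script run null calibrations as 20 screens
of 500 proteins, spike recovery as 10 screens of 1,000 proteins with 20
spikes, and end-to-end ranking as 116-locus screens with 1,000 proteins
per pulldown -- sizes matching the study design while keeping a full run
in minutes on one core. The ranking construction places its strongest
spike (effect 6 against 4 for the others) at the only 10x-accessible
locus with censoring disabled, so the expected first rank is a property
of the construction, not of a lucky seed. Other numerical conventions:
z-scores use the n-1 standard deviation and collapse to zero (with a
message) when the spread is zero; the empirical-Bayes iteration converges
at $10^{-4}$ relative change; coordinates are 0-based half-open
everywhere in the 4C module; and all ranking ties break
lexicographically so reruns are byte-identical.

# Limitations

* The headline counts of the original screens (hundreds of binding
  alterations across 116 loci, dozens of prioritized events) depend on
  the deposited mass-spectrometry and sequencing data and are not
  reproducible from synthetic inputs; the package validates properties,
  not those numbers.
* Exact-string flank uniqueness understates mappability relative to an
  aligner that tolerates mismatches.
* The allelic-imbalance module consumes allele counts; extracting them
  from alignments, and any read alignment, peak calling or eQTL fitting,
  are upstream of this package.
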