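#' Screen design for the synthetic pulldown generator
#'
#' A `ScreenSpec` captures the design of a paired-allele DNA-pulldown screen:
#' how many SNP loci are assayed, how many proteins each pulldown quantifies,
#' how many true allele-specific binders are spiked in and at what effect
#' size, the replicate noise level, the missingness regime, the number of
#' DNase I accessibility samples, and the batch layout. Identical spec and
#' seed reproduce byte-identical synthetic data.
#'
#' @slot nLoci number of SNP loci in the screen.
#' @slot nBackgroundProteins number of proteins quantified per pulldown.
#' @slot nSpikedBinders number of true allele-specific binders spiked in.
#' @slot spikeLog2FC true log2 Ref/Alt effect size of spiked binders.
#' @slot noiseSD standard deviation of per-replicate log-ratio noise.
#' @slot missingRateLowIntensity probability that a log-ratio in the bottom
#'   intensity quartile is censored (missing not at random); intensities
#'   above the bottom quartile are never censored.
#' @slot nDHSSamples number of DNase I accessibility samples.
#' @slot batchLabels batch assignment, one label per pulldown pair (locus).
#' @slot seed integer random-number seed.
#' @slot spikeLoci optional locus indices carrying the spiked binders
#'   (recycled/sampled when empty).
#' @slot spikeEffects optional per-spike log2 effect sizes overriding
#'   `spikeLog2FC` (signs are still drawn at random unless supplied signed).
#' @slot binderEnrichmentLog10 log10 intensity enrichment of spiked binders
#'   over the background intensity model (specific binders are enriched by
#'   the pulldown).
#'
#' @seealso [simulatePulldownScreen()], [simulateDHSCounts()]
#' @export
setClass("ScreenSpec",
  representation(
    nLoci = "integer",
    nBackgroundProteins = "integer",
    nSpikedBinders = "integer",
    spikeLog2FC = "numeric",
    noiseSD = "numeric",
    missingRateLowIntensity = "numeric",
    nDHSSamples = "integer",
    batchLabels = "character",
    seed = "integer",
    spikeLoci = "integer",
    spikeEffects = "numeric",
    binderEnrichmentLog10 = "numeric"
  )
)

setValidity("ScreenSpec", function(object) {
  msg <- character()
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (object@nBackgroundProteins < 1L) {
    msg <- c(msg, "nBackgroundProteins must be >= 1")
  }
  if (object@nSpikedBinders < 0L) msg <- c(msg, "nSpikedBinders must be >= 0")
  if (object@nSpikedBinders > object@nBackgroundProteins) {
    msg <- c(msg, "spike count exceeds background protein count")
  }
  if (!is.finite(object@noiseSD) || object@noiseSD <= 0) {
    msg <- c(msg, "noiseSD must be > 0")
  }
  if (object@missingRateLowIntensity < 0 ||
      object@missingRateLowIntensity >= 1) {
    msg <- c(msg, "missingRateLowIntensity must be in [0, 1)")
  }
  if (object@nDHSSamples < 1L) msg <- c(msg, "nDHSSamples must be >= 1")
  if (length(object@batchLabels) != object@nLoci) {
    msg <- c(msg, "batchLabels must have one label per locus")
  }
  if (length(object@spikeLoci) &&
      length(object@spikeLoci) != object@nSpikedBinders) {
    msg <- c(msg, "spikeLoci must be empty or of length nSpikedBinders")
  }
  if (length(object@spikeLoci) &&
      any(object@spikeLoci < 1L | object@spikeLoci > object@nLoci)) {
    msg <- c(msg, "spikeLoci must be locus indices in 1..nLoci")
  }
  if (length(object@spikeEffects) &&
      length(object@spikeEffects) != object@nSpikedBinders) {
    msg <- c(msg, "spikeEffects must be empty or of length nSpikedBinders")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenSpec
#'
#' Defaults reproduce the study design that the generator emulates: 116 CRC
#' risk loci assayed by label-swapped pulldown duplicates, roughly a thousand
#' quantified proteins per pulldown, and 27 DNase I accessibility samples
#' (15 fetal large intestine tissues plus 12 CRC cell lines).
#'
#' @param nLoci,nBackgroundProteins,nSpikedBinders,spikeLog2FC,noiseSD
#'   screen design values; see the class documentation.
#' @param missingRateLowIntensity censoring probability for bottom-quartile
#'   intensities.
#' @param nDHSSamples number of accessibility samples.
#' @param batchLabels one label per locus (a single value is recycled).
#' @param seed integer seed.
#' @param spikeLoci,spikeEffects optional explicit spike placement/effects.
#' @param binderEnrichmentLog10 log10 intensity enrichment of spiked binders.
#' @return A validated [ScreenSpec-class] object.
#' @examples
#' ScreenSpec(nLoci = 3, nBackgroundProteins = 50, nSpikedBinders = 2)
#' @export
ScreenSpec <- function(nLoci = 116L, nBackgroundProteins = 1000L,
                       nSpikedBinders = 0L, spikeLog2FC = 4,
                       noiseSD = 0.3, missingRateLowIntensity = 0.1,
                       nDHSSamples = 27L, batchLabels = "batch1",
                       seed = 1L, spikeLoci = integer(),
                       spikeEffects = numeric(),
                       binderEnrichmentLog10 = 1) {
  nLoci <- .assertCount(nLoci, "nLoci")
  if (length(batchLabels) == 1L) batchLabels <- rep(batchLabels, nLoci)
  new("ScreenSpec",
    nLoci = nLoci,
    nBackgroundProteins = .assertCount(nBackgroundProteins,
                                       "nBackgroundProteins"),
    nSpikedBinders = .assertCount(nSpikedBinders, "nSpikedBinders", min = 0L),
    spikeLog2FC = spikeLog2FC,
    noiseSD = noiseSD,
    missingRateLowIntensity = missingRateLowIntensity,
    nDHSSamples = .assertCount(nDHSSamples, "nDHSSamples"),
    batchLabels = as.character(batchLabels),
    seed = .assertCount(seed, "seed", min = 0L),
    spikeLoci = as.integer(spikeLoci),
    spikeEffects = as.numeric(spikeEffects),
    binderEnrichmentLog10 = binderEnrichmentLog10
  )
}

#' One SNP's paired-allele pulldown experiment
#'
#' A `PulldownPair` holds the two label-swapped replicate quantification
#' tables for one SNP: each table has one row per protein with its
#' heavy/light log2 ratio, summed MS intensity, and the label orientation
#' (`REF_HEAVY` or `ALT_HEAVY`). The stored ratio is always
#' heavy-channel/light-channel, so the `ALT_HEAVY` replicate must be
#' sign-inverted to the Ref/Alt convention before combining; see
#' [combineLabelSwap()].
#'
#' @slot snpId SNP identifier.
#' @slot refAllele,altAllele reference/alternate allele sequence.
#' @slot replicates list of exactly two data frames with columns
#'   `protein_id`, `log2_ratio` (NA when missing), `intensity`,
#'   `orientation`.
#' @export
setClass("PulldownPair",
  representation(
    snpId = "character",
    refAllele = "character",
    altAllele = "character",
    replicates = "list"
  )
)

.validPulldownTable <- function(tab) {
  need <- c("protein_id", "log2_ratio", "intensity", "orientation")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    return("each replicate must be a data frame with columns protein_id, log2_ratio, intensity, orientation")
  }
  if (!all(tab$orientation %in% c("REF_HEAVY", "ALT_HEAVY"))) {
    return("orientation must be REF_HEAVY or ALT_HEAVY")
  }
  if (length(unique(tab$orientation)) != 1L) {
    return("a replicate table must have a single orientation")
  }
  if (any(tab$intensity < 0, na.rm = TRUE)) return("intensities must be >= 0")
  NULL
}

setValidity("PulldownPair", function(object) {
  msg <- character()
  if (length(object@replicates) != 2L) {
    msg <- c(msg, "exactly two replicate tables are required")
  } else {
    for (tab in object@replicates) {
      m <- .validPulldownTable(tab)
      if (!is.null(m)) msg <- c(msg, m)
    }
    if (!length(msg)) {
      ori <- vapply(object@replicates, function(t) t$orientation[1L], "")
      if (ori[1L] == ori[2L]) {
        msg <- c(msg, "replicates must have opposite label orientations")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PulldownPair
#'
#' @param snpId SNP identifier.
#' @param refAllele,altAllele allele sequences (single base or short).
#' @param replicates list of two replicate quantification tables with
#'   opposite label orientations.
#' @return A validated [PulldownPair-class] object.
#' @export
PulldownPair <- function(snpId, refAllele, altAllele, replicates) {
  new("PulldownPair", snpId = as.character(snpId),
      refAllele = as.character(refAllele),
      altAllele = as.character(altAllele),
      replicates = replicates)
}

#' A collection of paired-allele pulldowns with ground truth
#'
#' Container returned by [simulatePulldownScreen()]: the per-locus
#' [PulldownPair-class] objects, the batch label of each pair, the
#' generating [ScreenSpec-class], and -- for synthetic screens -- a
#' ground-truth ledger listing every (locus, protein, true effect).
#'
#' @slot pairs list of [PulldownPair-class] objects, one per locus.
#' @slot batches character vector of batch labels, one per locus.
#' @slot groundTruth data frame with columns `snp_id`, `protein_id`,
#'   `true_log2fc` (0 for background proteins).
#' @slot spec the generating [ScreenSpec-class] (may be `NULL` for screens
#'   read from files).
#' @slot metadata list of generation details (batch offsets, locus ids).
#' @export
setClass("PulldownScreen",
  representation(
    pairs = "list",
    batches = "character",
    groundTruth = "data.frame",
    spec = "ANY",
    metadata = "list"
  )
)

setValidity("PulldownScreen", function(object) {
  msg <- character()
  if (!all(vapply(object@pairs, is, TRUE, "PulldownPair"))) {
    msg <- c(msg, "all elements of pairs must be PulldownPair objects")
  }
  if (length(object@batches) != length(object@pairs)) {
    msg <- c(msg, "one batch label per pulldown pair is required")
  }
  if (length(msg)) msg else TRUE
})

#' Reduced genome for 4C-seq alignment
#'
#' The set of restriction sites kept after in-silico digestion together with
#' their two downstream flanking sequences (one per strand) and an
#' exact-string uniqueness flag. Built by [buildReducedGenome()].
#'
#' @slot sites data frame with `site_id`, `contig`, `position` (0-based
#'   start of the recognition sequence), `enzyme`, `recognition`.
#' @slot flankPlus,flankMinus [Biostrings::DNAStringSet] of downstream
#'   flanks on the plus/minus strand, parallel to `sites`.
#' @slot unique logical; TRUE when neither flank occurs more than once in
#'   the pooled flank multiset.
#' @slot nDropped number of sites dropped for lying within one flank length
#'   of a contig edge.
#' @export
setClass("ReducedGenome",
  representation(
    sites = "data.frame",
    flankPlus = "ANY",
    flankMinus = "ANY",
    unique = "logical",
    nDropped = "integer"
  )
)

setValidity("ReducedGenome", function(object) {
  n <- nrow(object@sites)
  if (length(object@flankPlus) != n || length(object@flankMinus) != n ||
      length(object@unique) != n) {
    return("sites, flanks and uniqueness flags must be parallel")
  }
  TRUE
})
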