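#' @rdname PulldownPair-class
#' @param object,x a `PulldownPair` or `PulldownScreen` object.
#' @export
setGeneric("snpId", function(object) standardGeneric("snpId"))

#' @rdname PulldownPair-class
#' @export
setGeneric("refAllele", function(object) standardGeneric("refAllele"))

#' @rdname PulldownPair-class
#' @export
setGeneric("altAllele", function(object) standardGeneric("altAllele"))

#' @rdname PulldownPair-class
#' @export
setGeneric("replicateTables", function(object) {
  standardGeneric("replicateTables")
})

#' @rdname PulldownScreen-class
#' @param object,x a `PulldownScreen`.
#' @export
setGeneric("pulldownPairs", function(object) standardGeneric("pulldownPairs"))

#' @rdname PulldownScreen-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname PulldownScreen-class
#' @export
setGeneric("screenBatches", function(object) {
  standardGeneric("screenBatches")
})

#' @rdname ReducedGenome-class
#' @param object,x a `ReducedGenome`.
#' @export
setGeneric("reducedSites", function(object) standardGeneric("reducedSites"))

#' @rdname ReducedGenome-class
#' @export
setGeneric("flankPlus", function(object) standardGeneric("flankPlus"))

#' @rdname ReducedGenome-class
#' @export
setGeneric("flankMinus", function(object) standardGeneric("flankMinus"))

#' @rdname ReducedGenome-class
#' @export
setGeneric("isUniqueFlank", function(object) {
  standardGeneric("isUniqueFlank")
})

#' @rdname PulldownPair-class
#' @export
setMethod("snpId", "PulldownPair", function(object) object@snpId)

#' @rdname PulldownPair-class
#' @export
setMethod("refAllele", "PulldownPair", function(object) object@refAllele)

#' @rdname PulldownPair-class
#' @export
setMethod("altAllele", "PulldownPair", function(object) object@altAllele)

#' @rdname PulldownPair-class
#' @export
setMethod("replicateTables", "PulldownPair", function(object) {
  object@replicates
})

#' @rdname PulldownScreen-class
#' @export
setMethod("pulldownPairs", "PulldownScreen", function(object) object@pairs)

#' @rdname PulldownScreen-class
#' @export
setMethod("groundTruth", "PulldownScreen", function(object) {
  object@groundTruth
})

#' @rdname PulldownScreen-class
#' @export
setMethod("screenBatches", "PulldownScreen", function(object) {
  object@batches
})

#' @rdname PulldownScreen-class
#' @export
setMethod("snpId", "PulldownScreen", function(object) {
  vapply(object@pairs, snpId, "")
})

#' @rdname PulldownScreen-class
#' @export
setMethod("length", "PulldownScreen", function(x) length(x@pairs))

#' @rdname ReducedGenome-class
#' @export
setMethod("reducedSites", "ReducedGenome", function(object) object@sites)

#' @rdname ReducedGenome-class
#' @export
setMethod("flankPlus", "ReducedGenome", function(object) object@flankPlus)

#' @rdname ReducedGenome-class
#' @export
setMethod("flankMinus", "ReducedGenome", function(object) object@flankMinus)

#' @rdname ReducedGenome-class
#' @export
setMethod("isUniqueFlank", "ReducedGenome", function(object) object@unique)

#' @rdname ReducedGenome-class
#' @export
setMethod("length", "ReducedGenome", function(x) nrow(x@sites))

setMethod("show", "ScreenSpec", function(object) {
  cat("ScreenSpec:", object@nLoci, "loci x",
      object@nBackgroundProteins, "proteins,",
      object@nSpikedBinders, "spiked binder(s)\n")
  cat("  spike log2FC:", object@spikeLog2FC,
      " noise sd:", object@noiseSD,
      " MNAR rate (bottom quartile):", object@missingRateLowIntensity, "\n")
  cat("  DHS samples:", object@nDHSSamples,
      " batches:", length(unique(object@batchLabels)),
      " seed:", object@seed, "\n")
})

setMethod("show", "PulldownPair", function(object) {
  ori <- vapply(object@replicates, function(t) t$orientation[1L], "")
  cat("PulldownPair", object@snpId,
      sprintf("[%s>%s]", object@refAllele, object@altAllele), "\n")
  for (i in 1:2) {
    cat(sprintf("  replicate %d (%s): %d proteins, %d missing ratios\n",
                i, ori[i], nrow(object@replicates[[i]]),
                sum(is.na(object@replicates[[i]]$log2_ratio))))
  }
})

setMethod("show", "PulldownScreen", function(object) {
  cat("PulldownScreen:", length(object@pairs), "SNP loci,",
      length(unique(object@batches)), "batch(es)\n")
  if (nrow(object@groundTruth)) {
    cat("  ground truth:", sum(object@groundTruth$true_log2fc != 0),
        "spiked binder(s) of", nrow(object@groundTruth), "entries\n")
  }
})

setMethod("show", "ReducedGenome", function(object) {
  cat("ReducedGenome:", nrow(object@sites), "sites kept,",
      object@nDropped, "dropped at contig edges\n")
  cat("  unique flank pairs:", sum(object@unique), "of",
      length(object@unique), "\n")
})
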