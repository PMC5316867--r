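# Prioritization of SNP-TF interactions by DNase I hypersensitivity and
# pulldown fold change: a combined z-statistic converted to a normal
# upper-tail p-value.

.zscore <- function(x, ref = x) {
  s <- sd(ref) # n-1 denominator
  if (!is.finite(s) || s == 0) {
    message("zero spread: all z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(ref)) / s
}

#' Per-locus DNase I hypersensitivity z-scores
#'
#' Averages read counts across the accessibility samples for every locus,
#' then z-score transforms the per-locus means across loci (sd with the
#' n-1 denominator). If all loci share one mean the z-scores are 0.
#'
#' @param profiles a loci x samples count matrix, or a
#'   `SummarizedExperiment` whose first assay is one.
#' @param normalizeDepth when TRUE, counts are first scaled to reads per
#'   million within each sample; the default uses raw counts.
#' @return Named numeric vector of per-locus z-scores.
#' @examples
#' m <- rbind(a = c(0, 0), b = c(10, 10))
#' dhsZscores(m) # +/- 0.7071
#' @export
dhsZscores <- function(profiles, normalizeDepth = FALSE) {
  counts <- if (is(profiles, "SummarizedExperiment")) {
    SummarizedExperiment::assay(profiles)
  } else as.matrix(profiles)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("DHS counts must be non-negative", call. = FALSE)
  }
  if (nrow(counts) < 2L) {
    stop("at least 2 loci are required for a z-score", call. = FALSE)
  }
  if (normalizeDepth) {
    tot <- colSums(counts)
    counts <- sweep(counts, 2L, pmax(tot, 1), "/") * 1e6
  }
  means <- rowMeans(counts)
  setNames(.zscore(means), rownames(counts))
}

#' Fold-change z-scores of SNP-TF interactions
#'
#' z-score transforms absolute log2 fold changes, pooled screen-wide. The
#' sign of the underlying fold change never matters: the absolute value is
#' taken first. A `reference` distribution may be supplied so that a
#' subset of interactions (for example, significant calls) can be scored
#' against the spread of all quantified interactions.
#'
#' @param absLog2fc absolute log2 fold changes to score (absolute value is
#'   taken defensively).
#' @param reference values defining the mean/sd used for the transform;
#'   defaults to `absLog2fc` itself.
#' @return Numeric vector of z-scores.
#' @examples
#' fcZscores(c(1, 3)) # +/- 0.7071
#' @export
fcZscores <- function(absLog2fc, reference = absLog2fc) {
  if (length(reference) < 2L) {
    stop("at least 2 interactions are required for a z-score",
         call. = FALSE)
  }
  .zscore(abs(absLog2fc), abs(reference))
}

#' Combined significance of a SNP-TF interaction
#'
#' Averages the hypersensitivity and fold-change z-scores and converts the
#' average to a one-sided upper-tail standard-normal p-value: large
#' average z (an accessible locus and a strong binding change) gives a
#' small p.
#'
#' @param zDhs,zFc finite numeric vectors (recycled to a common length).
#' @return List with `z_avg` and `p_combined`.
#' @examples
#' combinedSignificance(0, 0)$p_combined  # 0.5
#' combinedSignificance(2, 2)$p_combined  # ~0.02275
#' @export
combinedSignificance <- function(zDhs, zFc) {
  if (!all(is.finite(zDhs)) || !all(is.finite(zFc))) {
    stop("z-scores must be finite", call. = FALSE)
  }
  zAvg <- (zDhs + zFc) / 2
  list(z_avg = zAvg, p_combined = pnorm(zAvg, lower.tail = FALSE))
}

#' Prioritize interactor calls by accessibility and fold change
#'
#' Builds the prioritized-interaction table: each call receives the
#' hypersensitivity z-score of its locus, a fold-change z-score (scored
#' against `fcReference` when given, typically all quantified
#' interactions), their average, and the combined one-sided p-value.
#'
#' @param calls interactor-call data frame (`snp_id`, `protein_id`,
#'   `log2fc_ref_over_alt`, ...).
#' @param dhs count matrix or `SummarizedExperiment` with one row per
#'   locus; row names must cover the called SNPs.
#' @param fcReference optional numeric vector of absolute log2 fold
#'   changes defining the z-scale (default: the calls themselves).
#' @param normalizeDepth passed to [dhsZscores()].
#' @param bh when TRUE, append a Benjamini-Hochberg adjusted column
#'   `p_adj` (no correction is applied to the selection itself).
#' @return Data frame with `abs_log2fc`, `z_fc`, `z_dhs`, `z_avg`,
#'   `p_combined` appended to the calls.
#' @export
prioritizeInteractions <- function(calls, dhs, fcReference = NULL,
                                   normalizeDepth = FALSE, bh = FALSE) {
  zd <- dhsZscores(dhs, normalizeDepth = normalizeDepth)
  if (!nrow(calls)) {
    out <- cbind(calls,
                 data.frame(abs_log2fc = numeric(), z_fc = numeric(),
                            z_dhs = numeric(), z_avg = numeric(),
                            p_combined = numeric()))
    return(out)
  }
  missingLoci <- setdiff(unique(calls$snp_id), names(zd))
  if (length(missingLoci)) {
    stop("no DHS profile for loci: ",
         paste(missingLoci, collapse = ", "), call. = FALSE)
  }
  absfc <- abs(calls$log2fc_ref_over_alt)
  zf <- fcZscores(absfc,
                  reference = if (is.null(fcReference)) absfc
                              else fcReference)
  cs <- combinedSignificance(zd[calls$snp_id], zf)
  out <- cbind(calls,
               data.frame(abs_log2fc = absfc,
                          z_fc = zf,
                          z_dhs = unname(zd[calls$snp_id]),
                          z_avg = unname(cs$z_avg),
                          p_combined = unname(cs$p_combined),
                          stringsAsFactors = FALSE))
  if (bh) out$p_adj <- p.adjust(out$p_combined, method = "BH")
  rownames(out) <- NULL
  out
}

#' Select and rank significant SNP-TF binding events
#'
#' Ranks the prioritized table by ascending combined p-value (ties broken
#' by descending absolute fold change, then `snp_id`, then `protein_id`)
#' and flags rows below the threshold.
#'
#' @param prioritized output of [prioritizeInteractions()].
#' @param threshold selection threshold on `p_combined` (default 0.05).
#' @return The ranked table with columns `rank` and `selected`; the
#'   selected subset is `subset(, selected)`.
#' @export
selectEvents <- function(prioritized, threshold = 0.05) {
  .assertScalarNumber(threshold, "threshold", lower = 0, upper = 1)
  if (!"p_combined" %in% names(prioritized)) {
    stop("prioritized table lacks p_combined", call. = FALSE)
  }
  ord <- order(prioritized$p_combined, -abs(prioritized$abs_log2fc),
               prioritized$snp_id, prioritized$protein_id)
  out <- prioritized[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$p_combined < threshold
  rownames(out) <- NULL
  out
}

#' Restrict calls to annotated transcription factors
#'
#' @param calls interactor-call data frame with a `protein_id` column.
#' @param tfAnnotation character vector of annotated TF / RNA-binding
#'   protein identifiers (one id per line when read from file).
#' @return The filtered calls, with attributes `nKept` and `nDropped`.
#' @export
filterToTFs <- function(calls, tfAnnotation) {
  if (!length(tfAnnotation)) {
    stop("TF annotation must be non-empty", call. = FALSE)
  }
  keep <- calls$protein_id %in% tfAnnotation
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nKept") <- sum(keep)
  attr(out, "nDropped") <- sum(!keep)
  out
}
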