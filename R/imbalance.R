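# Allelic-imbalance testing at heterozygous SNPs: exact 2x2 comparison of
# Ref/Alt read counts against a background expectation.

# Exact two-sided p for a 2x2 table with fixed margins: the sum of
# hypergeometric point probabilities not exceeding that of the observed
# table. A small relative tolerance guards floating-point ties between
# mathematically equal table probabilities.
.exactTwoSided <- function(a, b, c, d, tieTol = 1e-7) {
  m <- a + b      # assay total
  n <- c + d      # background total
  k <- a + c      # ref-column total
  support <- max(0L, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= pObs * (1 + tieTol)]))
}

#' Exact test of allelic imbalance at one site
#'
#' Compares assay Ref/Alt read counts with a background expectation in a
#' 2x2 table using the exact hypergeometric (Fisher) test; the two-sided
#' p-value sums the probabilities of all tables with the same margins
#' whose point probability does not exceed the observed one. When no
#' background counts are supplied, a 50:50 expectation at matched depth is
#' substituted (flagged in the output). The odds ratio is the sample
#' cross-product ratio, with the Haldane-Anscombe 0.5 correction applied
#' to every cell when any cell is zero (flagged).
#'
#' @param refCount,altCount assay read counts (non-negative integers;
#'   their sum must be positive).
#' @param backgroundRef,backgroundAlt expectation counts, e.g. from input
#'   chromatin or genomic DNA; both `NULL` for the 50:50 default.
#' @return List with `odds_ratio`, `p_value`, `preference` (`REF`/`ALT`/
#'   `none`), `haldane` (correction applied) and `background_substituted`.
#' @examples
#' fisherImbalance(10, 10)$p_value             # balanced: 1
#' fisherImbalance(5, 0, 0, 5)$p_value         # 2/choose(10,5) = 0.00794
#' @export
fisherImbalance <- function(refCount, altCount,
                            backgroundRef = NULL, backgroundAlt = NULL) {
  a <- .assertCount(refCount, "refCount", min = 0L)
  b <- .assertCount(altCount, "altCount", min = 0L)
  substituted <- is.null(backgroundRef) && is.null(backgroundAlt)
  if (substituted) {
    depth <- ceiling((a + b) / 2)
    backgroundRef <- depth
    backgroundAlt <- depth
  }
  cc <- .assertCount(backgroundRef, "backgroundRef", min = 0L)
  dd <- .assertCount(backgroundAlt, "backgroundAlt", min = 0L)
  if (a + b == 0L) {
    stop("site is untestable: assay ref + alt counts are zero",
         call. = FALSE)
  }
  if (a + b + cc + dd == 0L) stop("all-zero table", call. = FALSE)
  haldane <- any(c(a, b, cc, dd) == 0L)
  h <- if (haldane) 0.5 else 0
  orHat <- ((a + h) * (dd + h)) / ((b + h) * (cc + h))
  p <- .exactTwoSided(a, b, cc, dd)
  list(
    odds_ratio = orHat,
    p_value = p,
    preference = if (orHat > 1) "REF" else if (orHat < 1) "ALT" else "none",
    haldane = haldane,
    background_substituted = substituted
  )
}

#' Summarize allelic imbalance across sites and assays
#'
#' Runs [fisherImbalance()] for every testable row of a count table and
#' reports untestable rows (zero assay depth) in a skip list with reasons.
#'
#' @param counts data frame with columns `site_id`, `assay`, `ref_count`,
#'   `alt_count` and optional `background_ref`, `background_alt` (`NA`
#'   for the matched-depth 50:50 default).
#' @return List with `results` (one row per tested (site, assay):
#'   odds ratio, p-value, preference, flags) and `skipped` (site, assay,
#'   reason), both deterministic in the input order.
#' @export
summarizeSites <- function(counts) {
  need <- c("site_id", "assay", "ref_count", "alt_count")
  if (!all(need %in% names(counts))) {
    stop("counts must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- list()
  skip <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    if (is.na(row$ref_count) || is.na(row$alt_count) ||
        row$ref_count + row$alt_count <= 0) {
      skip[[length(skip) + 1L]] <- data.frame(
        site_id = row$site_id, assay = row$assay,
        reason = "zero assay depth", stringsAsFactors = FALSE)
      next
    }
    bgR <- if ("background_ref" %in% names(row) && !is.na(row$background_ref))
      row$background_ref else NULL
    bgA <- if ("background_alt" %in% names(row) && !is.na(row$background_alt))
      row$background_alt else NULL
    f <- fisherImbalance(row$ref_count, row$alt_count, bgR, bgA)
    res[[length(res) + 1L]] <- data.frame(
      site_id = row$site_id, assay = row$assay,
      ref_count = row$ref_count, alt_count = row$alt_count,
      odds_ratio = f$odds_ratio, p_value = f$p_value,
      preference = f$preference, haldane = f$haldane,
      background_substituted = f$background_substituted,
      stringsAsFactors = FALSE)
  }
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  list(
    results = if (length(res)) do.call(rbind, res) else
      empty(c("site_id", "assay")),
    skipped = if (length(skip)) do.call(rbind, skip) else
      empty(c("site_id", "assay", "reason"))
  )
}
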