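# Pulldown quantification: label-swap combination, batch correction,
# imputation, ratio-outlier significance, interactor calling.

.orientedValues <- function(tab) {
  ifelse(tab$orientation == "REF_HEAVY", 1, -1) * tab$log2_ratio
}

#' Combine the two label-swapped replicates of a pulldown pair
#'
#' The stored heavy/light log-ratio of the Alt-heavy replicate is
#' sign-inverted to the Ref/Alt convention, then the two oriented
#' log-ratios are averaged per protein. Proteins quantified in only one
#' replicate carry that single oriented value and are flagged. A true
#' binder shows inverted stored ratios across the dimethyl swap, so its
#' oriented values agree; a labelling artefact cancels.
#'
#' @param pair a [PulldownPair-class], or a list of two replicate tables.
#' @return A data frame ordered by `protein_id` with columns `snp_id`,
#'   `protein_id`, `log2fc_ref_over_alt`, `oriented_rep1`, `oriented_rep2`,
#'   `mean_log10_intensity`, `n_replicates`, `single_replicate`. Replicate
#'   1 is always the Ref-heavy pulldown, whatever the storage order.
#' @examples
#' tab <- function(ori, ratio) data.frame(protein_id = "P1",
#'   log2_ratio = ratio, intensity = 1e7, orientation = ori)
#' pr <- PulldownPair("rs1", "G", "A",
#'   list(tab("REF_HEAVY", 1), tab("ALT_HEAVY", 1)))
#' combineLabelSwap(pr)$log2fc_ref_over_alt  # swap symmetry cancels: 0
#' @export
combineLabelSwap <- function(pair) {
  reps <- if (is(pair, "PulldownPair")) {
    validObject(pair)
    replicateTables(pair)
  } else pair
  if (length(reps) != 2L) {
    stop("exactly two replicate tables are required", call. = FALSE)
  }
  ori <- vapply(reps, function(t) t$orientation[1L], "")
  if (ori[1L] == ori[2L]) {
    stop("label-swap bookkeeping fault: both replicates have orientation ",
         ori[1L], call. = FALSE)
  }
  # canonical order: replicate 1 is the Ref-heavy pulldown, so the output
  # does not depend on storage order
  if (ori[1L] != "REF_HEAVY") reps <- rev(reps)
  val <- lapply(reps, function(t) {
    data.frame(protein_id = t$protein_id,
               oriented = .orientedValues(t),
               log10I = log10(pmax(t$intensity, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  merged <- merge(val[[1L]], val[[2L]], by = "protein_id", all = TRUE,
                  suffixes = c("_1", "_2"))
  merged <- merged[order(merged$protein_id), , drop = FALSE]
  o1 <- merged$oriented_1
  o2 <- merged$oriented_2
  nrep <- (!is.na(o1)) + (!is.na(o2))
  comb <- rowMeans(cbind(o1, o2), na.rm = TRUE)
  comb[nrep == 0L] <- NA_real_
  data.frame(
    snp_id = if (is(pair, "PulldownPair")) snpId(pair) else NA_character_,
    protein_id = merged$protein_id,
    log2fc_ref_over_alt = comb,
    oriented_rep1 = o1,
    oriented_rep2 = o2,
    mean_log10_intensity = rowMeans(cbind(merged$log10I_1, merged$log10I_2),
                                    na.rm = TRUE),
    n_replicates = nrep,
    single_replicate = nrep == 1L,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# row variance with NA removal, n-1 denominator
.rowVars <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  out <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  out[n < 2] <- NA_real_
  out
}

#' Remove batch effects from a log-fold-change matrix
#'
#' Parametric empirical-Bayes location/scale adjustment in the ComBat
#' style: each protein row is standardized against its pooled mean and
#' variance, per-batch location and scale effects are estimated, shrunk
#' toward the batch-wide prior (normal prior on locations, inverse-gamma on
#' scales, moment-matched), and the data are back-transformed. The
#' implementation tolerates missing values: moments are computed on
#' observed entries, and rows with fewer than two observed values in any
#' batch are passed through unadjusted and flagged.
#'
#' @param mat numeric matrix, proteins x pulldowns (log2 fold changes).
#' @param batches batch label per column.
#' @param conv convergence tolerance of the empirical-Bayes iteration.
#' @return The corrected matrix, with attributes `passthrough` (logical per
#'   row) and `nBatches`. A single-batch matrix is returned unchanged.
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' m[, 3:4] <- m[, 3:4] + 2                   # additive batch offset
#' cb <- correctBatch(m, c("a", "a", "b", "b"))
#' @export
correctBatch <- function(mat, batches, conv = 1e-4) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("at least 2 pulldowns are required", call. = FALSE)
  if (length(batches) != ncol(mat)) {
    stop("batch vector length does not match the number of pulldowns",
         call. = FALSE)
  }
  batches <- as.character(batches)
  ub <- unique(batches)
  passthrough <- rep(FALSE, nrow(mat))
  if (length(ub) == 1L) {
    attr(mat, "passthrough") <- passthrough
    attr(mat, "nBatches") <- 1L
    return(mat)
  }
  nb <- vapply(ub, function(b) sum(batches == b), 1L)
  N <- ncol(mat)
  obs <- !is.na(mat)
  nObsBatch <- vapply(ub, function(b) {
    rowSums(obs[, batches == b, drop = FALSE])
  }, numeric(nrow(mat)))
  passthrough <- apply(nObsBatch < 2L, 1L, any)
  out <- mat
  idx <- which(!passthrough)
  if (length(idx)) {
    x <- mat[idx, , drop = FALSE]
    batchMeans <- vapply(ub, function(b) {
      rowMeans(x[, batches == b, drop = FALSE], na.rm = TRUE)
    }, numeric(length(idx)))
    alpha <- as.vector(batchMeans %*% (nb / N))
    fit <- batchMeans[, match(batches, ub), drop = FALSE]
    resid <- x - fit
    sigma2 <- rowSums(resid^2, na.rm = TRUE) / rowSums(!is.na(x))
    sigma <- pmax(sqrt(sigma2), 1e-8)
    z <- (x - alpha) / sigma
    for (b in ub) {
      cols <- batches == b
      zb <- z[, cols, drop = FALSE]
      ng <- rowSums(!is.na(zb))
      gammaHat <- rowMeans(zb, na.rm = TRUE)
      deltaHat <- .rowVars(zb)
      gbar <- mean(gammaHat)
      t2 <- var(gammaHat)
      m <- mean(deltaHat)
      s2 <- var(deltaHat)
      if (!is.finite(s2) || s2 < 1e-12 || !is.finite(t2)) {
        # degenerate gene-wide spread: no scale shrinkage possible
        gStar <- if (!is.finite(t2) || t2 < 1e-12) rep(gbar, length(gammaHat))
                 else gammaHat
        dStar <- rep(1, length(gammaHat))
      } else {
        lambda <- (2 * s2 + m^2) / s2
        theta <- (m * s2 + m^3) / s2
        gOld <- gammaHat
        dOld <- deltaHat
        repeat {
          gNew <- (t2 * ng * gammaHat + dOld * gbar) / (t2 * ng + dOld)
          sum2 <- rowSums((zb - gNew)^2, na.rm = TRUE)
          dNew <- (theta + 0.5 * sum2) / (ng / 2 + lambda - 1)
          change <- max(abs(gNew - gOld) / (abs(gOld) + 1e-30),
                        abs(dNew - dOld) / (abs(dOld) + 1e-30))
          gOld <- gNew
          dOld <- dNew
          if (change < conv) break
        }
        gStar <- gOld
        dStar <- pmax(dOld, 1e-12)
      }
      z[, cols] <- (zb - gStar) / sqrt(dStar)
    }
    out[idx, ] <- z * sigma + alpha
  }
  attr(out, "passthrough") <- passthrough
  attr(out, "nBatches") <- length(ub)
  out
}

#' Impute missing log-ratios from a downshifted normal distribution
#'
#' Per pulldown column, missing entries are drawn from
#' Normal(mean - `downshiftFactor` * sd, (`widthFactor` * sd)^2) of that
#' column's observed values: the convention for ratios that are missing
#' because one channel fell below the detection limit. Imputed values are
#' recorded in a mask so downstream calls can be flagged; they carry no
#' directional evidence and are never used by the significance test in
#' [runScreen()].
#'
#' @param mat numeric matrix (proteins x pulldowns) with `NA` for missing.
#' @param widthFactor sd multiplier of the imputation distribution (> 0).
#' @param downshiftFactor downward shift in column-sd units.
#' @param seed optional seed for deterministic imputation.
#' @return list with `matrix` (completed) and `mask` (logical, TRUE where
#'   imputed).
#' @examples
#' m <- matrix(rnorm(30), 10, 3)
#' m[1, 1] <- NA
#' imputeMissing(m, seed = 1)$mask[1, 1]
#' @export
imputeMissing <- function(mat, widthFactor = 0.3, downshiftFactor = 1.8,
                          seed = NULL) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  .assertScalarNumber(widthFactor, "widthFactor", lower = 0,
                      strict_lower = TRUE)
  .assertScalarNumber(downshiftFactor, "downshiftFactor")
  mask <- is.na(mat)
  if (!any(mask)) {
    return(list(matrix = mat, mask = mask))
  }
  withSeed(seed, {
    for (j in seq_len(ncol(mat))) {
      mj <- mask[, j]
      if (!any(mj)) next
      obsv <- mat[!mj, j]
      if (length(obsv) < 3L) {
        stop(sprintf(
          "column %d has %d observed value(s); at least 3 are needed to estimate imputation moments",
          j, length(obsv)), call. = FALSE)
      }
      mu <- mean(obsv)
      s <- sd(obsv)
      mat[mj, j] <- rnorm(sum(mj), mu - downshiftFactor * s,
                          widthFactor * s)
    }
    list(matrix = mat, mask = mask)
  })
}

# Robust percentile z-score outlier p-values on one vector (Significance A).
.significanceA <- function(x) {
  qs <- quantile(x, c(0.1587, 0.5, 0.8413), type = 7, names = FALSE)
  r0 <- qs[2L]
  right <- qs[3L] - r0
  left <- r0 - qs[1L]
  if (right <= 0) {
    stop("degenerate right spread: values above the median are constant",
         call. = FALSE)
  }
  if (left <= 0) {
    stop("degenerate left spread: values below the median are constant",
         call. = FALSE)
  }
  z <- ifelse(x > r0, (x - r0) / right, (r0 - x) / left)
  2 * pnorm(z, lower.tail = FALSE) # erfc(z / sqrt(2))
}

#' Ratio-outlier significance test (Significance A/B)
#'
#' Two-sided outlier p-values for log-ratios, from a robust z-score built
#' on the 15.87/50/84.13 percentiles of the distribution: with r0 the
#' median, the right spread is P84.13 - r0 and the left spread r0 - P15.87;
#' z = (x - r0)/right-spread above the median, (r0 - x)/left-spread below;
#' p = erfc(z/sqrt(2)), the two-sided standard-normal tail. Mode A applies
#' this globally; mode B first sorts proteins by intensity and partitions
#' them into equal-occupancy bins of at least `minBinSize`, computing the
#' mode-A statistic within each bin (ratio spread in MS data depends on
#' intensity). With fewer observed proteins than one full bin, mode B
#' falls back to mode A (flagged in the `fallback` attribute).
#'
#' `NA` log-ratios yield `NA` p-values; all estimation uses observed
#' values only.
#'
#' @param log2fc numeric vector of per-protein log2 ratios.
#' @param logIntensity per-protein log intensities (required for mode B).
#' @param mode `"B"` (intensity-binned, default) or `"A"` (global).
#' @param minBinSize minimum proteins per intensity bin.
#' @return Numeric vector of two-sided p-values in [0, 1], with attributes
#'   `mode` (mode actually used), `nBins` and `fallback`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' p <- significanceOutlierTest(x, mode = "A")
#' p[which.max(abs(x - median(x)))] < 0.01
#' @export
significanceOutlierTest <- function(log2fc, logIntensity = NULL,
                                    mode = c("B", "A"), minBinSize = 300L) {
  mode <- match.arg(mode)
  minBinSize <- .assertCount(minBinSize, "minBinSize")
  n <- length(log2fc)
  p <- rep(NA_real_, n)
  obs <- which(!is.na(log2fc))
  usedMode <- mode
  fallback <- FALSE
  nBins <- 1L
  if (!length(obs)) {
    attr(p, "mode") <- mode
    attr(p, "nBins") <- 0L
    attr(p, "fallback") <- FALSE
    return(p)
  }
  if (mode == "B") {
    if (is.null(logIntensity)) {
      stop("mode B requires per-protein log intensities", call. = FALSE)
    }
    if (length(logIntensity) != n) {
      stop("log2fc and logIntensity lengths differ", call. = FALSE)
    }
    nBins <- length(obs) %/% minBinSize
    if (nBins < 1L) {
      usedMode <- "A"
      fallback <- TRUE
      nBins <- 1L
    }
  }
  if (usedMode == "A") {
    p[obs] <- .significanceA(log2fc[obs])
  } else {
    # equal-occupancy intensity bins; ties broken by position for
    # determinism across platforms
    ord <- obs[order(logIntensity[obs], obs)]
    bounds <- round(seq(0L, length(ord), length.out = nBins + 1L))
    for (b in seq_len(nBins)) {
      sel <- ord[(bounds[b] + 1L):bounds[b + 1L]]
      p[sel] <- .significanceA(log2fc[sel])
    }
  }
  names(p) <- names(log2fc)
  attr(p, "mode") <- usedMode
  attr(p, "nBins") <- if (usedMode == "A") 1L else nBins
  attr(p, "fallback") <- fallback
  p
}

#' Call allele-specific interactors
#'
#' Selects proteins judged allele-specific at each SNP. Two policies:
#'
#' * `"replicates"` (default when per-replicate evidence is present): a
#'   protein is called when its outlier p-value is below `alpha` in *both*
#'   label-swap pulldowns and the two oriented log-ratios agree in sign --
#'   the dimethyl swap design makes a labelling artefact sign-inconsistent.
#'   Only observed (non-imputed) measurements count as evidence. The
#'   reported `p_value` is the weaker of the two (their maximum).
#' * `"combined"`: proteins with `p_value < alpha` in the supplied table
#'   are called, as when only a single combined test is available.
#'
#' @param combined data frame of per-protein results; must contain
#'   `snp_id`, `protein_id`, `log2fc_ref_over_alt` and, depending on
#'   policy, `p_rep1`/`p_rep2`/`oriented_rep1`/`oriented_rep2` or
#'   `p_value`. An `imputed` column is carried through when present.
#' @param alpha significance threshold (default 0.01).
#' @param policy `"replicates"`, `"combined"`, or `"auto"` (default:
#'   replicates when the per-replicate columns exist).
#' @return Data frame of interactor calls ordered by (`snp_id`,
#'   `p_value`), with `allele_preference` (`REF` when the combined log2
#'   Ref/Alt fold change is positive, else `ALT`) and an `imputed` flag.
#' @export
callInteractors <- function(combined, alpha = 0.01,
                            policy = c("auto", "replicates", "combined")) {
  policy <- match.arg(policy)
  .assertScalarNumber(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE)
  repCols <- c("p_rep1", "p_rep2", "oriented_rep1", "oriented_rep2")
  hasRep <- all(repCols %in% names(combined))
  if (policy == "auto") policy <- if (hasRep) "replicates" else "combined"
  if (policy == "replicates" && !hasRep) {
    stop("policy 'replicates' requires per-replicate evidence columns",
         call. = FALSE)
  }
  if (policy == "replicates") {
    ok <- !is.na(combined$p_rep1) & !is.na(combined$p_rep2) &
      combined$p_rep1 < alpha & combined$p_rep2 < alpha &
      sign(combined$oriented_rep1) == sign(combined$oriented_rep2)
    pcall <- pmax(combined$p_rep1, combined$p_rep2)
  } else {
    if (!"p_value" %in% names(combined)) {
      stop("policy 'combined' requires a p_value column", call. = FALSE)
    }
    ok <- !is.na(combined$p_value) & combined$p_value < alpha
    pcall <- combined$p_value
  }
  calls <- data.frame(
    snp_id = combined$snp_id,
    protein_id = combined$protein_id,
    log2fc_ref_over_alt = combined$log2fc_ref_over_alt,
    p_value = pcall,
    allele_preference = ifelse(combined$log2fc_ref_over_alt > 0,
                               "REF", "ALT"),
    imputed = if ("imputed" %in% names(combined)) combined$imputed else
      rep(FALSE, nrow(combined)),
    stringsAsFactors = FALSE
  )[which(ok), , drop = FALSE]
  calls <- calls[order(calls$snp_id, calls$p_value, calls$protein_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}
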