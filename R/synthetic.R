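# Synthetic screen generators. Every input the pipeline consumes can be
# produced here with a known ground truth, so all downstream stages are
# testable without any external download.

.spikeSignedEffects <- function(spec) {
  k <- spec@nSpikedBinders
  if (k == 0L) return(numeric())
  mag <- if (length(spec@spikeEffects)) abs(spec@spikeEffects) else {
    rep(abs(spec@spikeLog2FC), k)
  }
  mag * sample(c(-1, 1), k, replace = TRUE)
}

.lociIds <- function(n) sprintf("snp%03d", seq_len(n))
.proteinIds <- function(n) sprintf("P%05d", seq_len(n))

#' Simulate a paired-allele pulldown screen
#'
#' Generates, for every SNP locus, two label-swapped replicate
#' quantification tables. Background proteins receive a Ref/Alt log-ratio
#' drawn from Normal(0, `noiseSD`); spiked binders at their designated loci
#' receive the spec's log2 effect size with a per-binder random sign,
#' recorded in the ground-truth ledger. Summed MS intensities follow
#' log10-intensity ~ Normal(7, 1), with spiked binders enriched by
#' `binderEnrichmentLog10` log10 units. Ratios in the bottom intensity
#' quartile of each pulldown are censored with probability
#' `missingRateLowIntensity` (missing not at random). Per-batch offsets
#' drawn from Normal(0, 0.5) -- relative to the first batch, which serves
#' as the reference -- are added on the oriented Ref/Alt log-ratio scale
#' of every pulldown pair in the batch.
#'
#' Label-orientation bookkeeping: replicate 1 is Ref-heavy and replicate 2
#' Alt-heavy, and the stored ratio is always heavy/light, so the second
#' replicate must be sign-inverted downstream (see [combineLabelSwap()]).
#'
#' @param spec a [ScreenSpec-class].
#' @return A [PulldownScreen-class]; `groundTruth()` lists every
#'   (locus, protein) with its true signed log2 Ref/Alt effect (0 for
#'   background), and `metadata` records batch offsets and spike placement.
#' @examples
#' sp <- ScreenSpec(nLoci = 2, nBackgroundProteins = 100,
#'                  nSpikedBinders = 1, seed = 7)
#' scr <- simulatePulldownScreen(sp)
#' scr
#' @export
simulatePulldownScreen <- function(spec) {
  stopifnot(is(spec, "ScreenSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    nL <- spec@nLoci
    nP <- spec@nBackgroundProteins
    loci <- .lociIds(nL)
    prot <- .proteinIds(nP)

    spikeLoci <- if (length(spec@spikeLoci)) spec@spikeLoci else {
      if (spec@nSpikedBinders > 0L) {
        sample(nL, spec@nSpikedBinders, replace = spec@nSpikedBinders > nL)
      } else integer()
    }
    # spiked binders are distinct proteins, one designated locus each
    spikeProt <- if (spec@nSpikedBinders > 0L) {
      sample(nP, spec@nSpikedBinders)
    } else integer()
    effects <- .spikeSignedEffects(spec)

    batches <- spec@batchLabels
    ubatch <- unique(batches)
    # offsets are expressed relative to the first (reference) batch, so a
    # single-batch screen carries no batch effect
    offsets <- setNames(c(0, rnorm(length(ubatch) - 1L, 0, 0.5)), ubatch)

    alleles <- c("A", "C", "G", "T")
    truth <- matrix(0, nrow = nP, ncol = nL,
                    dimnames = list(prot, loci))
    if (spec@nSpikedBinders > 0L) {
      for (k in seq_len(spec@nSpikedBinders)) {
        truth[spikeProt[k], spikeLoci[k]] <- effects[k]
      }
    }

    pairs <- vector("list", nL)
    for (i in seq_len(nL)) {
      e <- unname(truth[, i])
      delta <- offsets[[batches[i]]]
      al <- sample(alleles, 2L)
      reps <- vector("list", 2L)
      for (r in 1:2) {
        log10I <- rnorm(nP, 7, 1) +
          ifelse(e != 0, spec@binderEnrichmentLog10, 0)
        intensity <- 10^log10I
        oriented <- unname(e) + delta + rnorm(nP, 0, spec@noiseSD)
        stored <- if (r == 1L) oriented else -oriented
        # detection-limit censoring: bottom intensity quartile only
        miss <- rank(intensity, ties.method = "first") <= nP / 4 &
          runif(nP) < spec@missingRateLowIntensity
        stored[miss] <- NA_real_
        reps[[r]] <- data.frame(
          protein_id = prot,
          log2_ratio = stored,
          intensity = intensity,
          orientation = if (r == 1L) "REF_HEAVY" else "ALT_HEAVY",
          stringsAsFactors = FALSE
        )
      }
      pairs[[i]] <- PulldownPair(loci[i], al[1L], al[2L], reps)
    }

    ledger <- data.frame(
      snp_id = rep(loci, each = nP),
      protein_id = rep(prot, nL),
      true_log2fc = as.vector(truth),
      stringsAsFactors = FALSE
    )

    new("PulldownScreen",
        pairs = pairs,
        batches = batches,
        groundTruth = ledger,
        spec = spec,
        metadata = list(
          batch_offsets = offsets,
          spike_loci = loci[spikeLoci],
          spike_proteins = prot[spikeProt],
          spike_effects = effects
        ))
  })
}

#' Simulate DNase I hypersensitivity read counts
#'
#' Draws negative-binomial read counts for every screen locus across the
#' accessibility samples (by default 27, emulating 15 fetal large intestine
#' tissues plus 12 CRC cell lines). Designated loci receive a
#' `foldChange`-fold elevated mean, mimicking SNPs inside DNase I
#' hypersensitive sites.
#'
#' @param spec a [ScreenSpec-class]; supplies the locus set, sample count
#'   and (via a derived stream) the seed.
#' @param highDhsLoci character locus ids (or integer indices) to elevate;
#'   unknown ids are rejected.
#' @param baseMean negative-binomial mean of a background locus.
#' @param foldChange mean multiplier for `highDhsLoci`.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (loci x samples), rowData column `expected_mean` (the
#'   per-locus ground truth), and the generation parameters in `metadata()`.
#' @examples
#' sp <- ScreenSpec(nLoci = 5, nBackgroundProteins = 10, seed = 3)
#' se <- simulateDHSCounts(sp, highDhsLoci = "snp002")
#' SummarizedExperiment::assay(se)[, 1:4]
#' @export
simulateDHSCounts <- function(spec, highDhsLoci = character(),
                              baseMean = 50, foldChange = 10,
                              dispersion = 0.1) {
  stopifnot(is(spec, "ScreenSpec"))
  .assertScalarNumber(baseMean, "baseMean", lower = 0, strict_lower = TRUE)
  .assertScalarNumber(foldChange, "foldChange", lower = 0,
                      strict_lower = TRUE)
  .assertScalarNumber(dispersion, "dispersion", lower = 0)
  loci <- .lociIds(spec@nLoci)
  if (is.numeric(highDhsLoci)) highDhsLoci <- loci[as.integer(highDhsLoci)]
  unknown <- setdiff(highDhsLoci, loci)
  if (length(unknown)) {
    stop("unknown locus id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mu <- ifelse(loci %in% highDhsLoci, baseMean * foldChange, baseMean)
  withSeed(deriveSeed(spec@seed, "dhs"), {
    counts <- matrix(
      rnbinom(spec@nLoci * spec@nDHSSamples,
              mu = rep(mu, spec@nDHSSamples),
              size = if (dispersion > 0) 1 / dispersion else Inf),
      nrow = spec@nLoci, ncol = spec@nDHSSamples,
      dimnames = list(loci, sprintf("sample%02d", seq_len(spec@nDHSSamples)))
    )
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(expected_mean = mu, row.names = loci),
      metadata = list(baseMean = baseMean, foldChange = foldChange,
                      dispersion = dispersion,
                      highDhsLoci = highDhsLoci)
    )
  })
}

# exhaustive 0-based substring scan, independent of the Biostrings-based
# digestion path; used to record the true site list
.scanSites <- function(seqChar, recognition) {
  n <- nchar(seqChar)
  w <- nchar(recognition)
  if (n < w) return(integer())
  base <- strsplit(seqChar, "", fixed = TRUE)[[1L]]
  pat <- strsplit(recognition, "", fixed = TRUE)[[1L]]
  hit <- rep(TRUE, n - w + 1L)
  for (j in seq_len(w)) {
    hit <- hit & base[seq_len(n - w + 1L) + j - 1L] == pat[j]
  }
  which(hit) - 1L
}

#' Simulate a toy genome with planted restriction sites
#'
#' Random contigs with a recognition sequence (default CATG, the NlaIII
#' site) planted at recorded positions. No suppression of accidental sites
#' is attempted unless `suppressAccidental = TRUE`; in every case the true
#' site list is recomputed by an exhaustive substring scan, so it is exact
#' regardless of chance occurrences.
#'
#' @param nContigs number of contigs.
#' @param length length of each contig in bases (>= 100).
#' @param siteDensity expected planted sites per base (0 plants none).
#' @param seed integer seed.
#' @param recognition recognition sequence to plant.
#' @param suppressAccidental when TRUE, windows containing accidental
#'   (non-planted) occurrences are re-randomized by rejection until none
#'   remain.
#' @return A list with `contigs` (a [Biostrings::DNAStringSet]), `sites`
#'   (data frame `contig`, `position`, 0-based, from the exhaustive scan)
#'   and `planted` (the planted subset).
#' @examples
#' g <- simulateToyGenome(nContigs = 1, length = 500, siteDensity = 0.01,
#'                        seed = 11)
#' head(g$sites)
#' @export
simulateToyGenome <- function(nContigs = 1L, length = 10000L,
                              siteDensity = 0.001, seed = 1L,
                              recognition = "CATG",
                              suppressAccidental = FALSE) {
  nContigs <- .assertCount(nContigs, "nContigs")
  length <- .assertCount(length, "length", min = 100L)
  .assertScalarNumber(siteDensity, "siteDensity", lower = 0)
  w <- nchar(recognition)
  withSeed(seed, {
    contigs <- character(nContigs)
    planted <- list()
    for (ci in seq_len(nContigs)) {
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      nPlant <- round(siteDensity * length)
      pos <- integer()
      if (nPlant > 0) {
        # non-overlapping placements on a coarse grid
        grid <- seq(1L, length - w, by = w)
        pos <- sort(sample(grid, min(nPlant, base::length(grid)))) - 1L
        for (p in pos) s[(p + 1L):(p + w)] <- strsplit(recognition, "")[[1L]]
      }
      if (suppressAccidental) {
        for (iter in 1:200) {
          occ <- .scanSites(paste(s, collapse = ""), recognition)
          occ <- setdiff(occ, pos)
          # keep planted sites intact: skip accidental hits overlapping them
          if (base::length(pos)) {
            keepaway <- unlist(lapply(pos, function(p) (p - w + 1L):(p + w - 1L)))
            occ <- setdiff(occ, keepaway)
          }
          if (!base::length(occ)) break
          for (p in occ) {
            s[(p + 1L):(p + w)] <- sample(c("A", "C", "G", "T"), w,
                                          replace = TRUE)
          }
        }
      }
      contigs[ci] <- paste(s, collapse = "")
      planted[[ci]] <- data.frame(
        contig = rep(sprintf("contig%02d", ci), base::length(pos)),
        position = pos, stringsAsFactors = FALSE
      )
    }
    names(contigs) <- sprintf("contig%02d", seq_len(nContigs))
    sites <- do.call(rbind, lapply(seq_len(nContigs), function(ci) {
      p <- .scanSites(contigs[ci], recognition)
      if (!base::length(p)) {
        return(data.frame(contig = character(), position = integer(),
                          stringsAsFactors = FALSE))
      }
      data.frame(contig = names(contigs)[ci], position = p,
                 stringsAsFactors = FALSE)
    }))
    list(
      contigs = Biostrings::DNAStringSet(contigs),
      sites = sites,
      planted = do.call(rbind, planted)
    )
  })
}

#' Write a synthetic screen to delimited-text files
#'
#' One TSV per pulldown (columns `protein_id`, `log2_ratio`, `intensity`,
#' `orientation`), a TSV of batch labels, and the ground-truth ledger as
#' JSON.
#'
#' @param screen a [PulldownScreen-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
writeScreenTables <- function(screen, dir) {
  stopifnot(is(screen, "PulldownScreen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (pair in pulldownPairs(screen)) {
    for (r in 1:2) {
      f <- file.path(dir, sprintf("%s_rep%d.tsv", snpId(pair), r))
      writeTSV(replicateTables(pair)[[r]], f)
      files <- c(files, f)
    }
  }
  bf <- file.path(dir, "batches.tsv")
  writeTSV(data.frame(
    snp_id = snpId(screen),
    batch = screenBatches(screen),
    ref_allele = vapply(pulldownPairs(screen), refAllele, ""),
    alt_allele = vapply(pulldownPairs(screen), altAllele, "")), bf)
  lf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(groundTruth(screen), lf, digits = NA)
  invisible(c(files, bf, lf))
}

#' Read one pulldown quantification table
#'
#' Expects the TSV layout written by [writeScreenTables()]; missing ratios
#' may be encoded as empty fields or `NA`.
#'
#' @param path path to the TSV.
#' @return A data frame with columns `protein_id`, `log2_ratio`,
#'   `intensity`, `orientation`.
#' @export
readPulldownTable <- function(path) {
  tab <- readTSV(path)
  m <- .validPulldownTable(tab)
  if (!is.null(m)) stop(m, call. = FALSE)
  tab
}
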