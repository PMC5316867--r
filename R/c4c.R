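# 4C-seq reduced-genome utilities: in-silico restriction digestion, flank
# extraction with uniqueness filtering, and windowed interaction counting.

.asDNAStringSet <- function(contigs) {
  if (is(contigs, "DNAStringSet")) return(contigs)
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    return(Biostrings::readDNAStringSet(contigs))
  }
  Biostrings::DNAStringSet(contigs)
}

.isPalindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  identical(rc, recognition)
}

#' In-silico restriction digestion
#'
#' Reports every exact occurrence of a recognition sequence in a set of
#' contigs, in ascending position order (0-based starts). Palindromic
#' recognition sequences such as CATG (NlaIII) or GTAC (CviQI) are
#' reported once per occurrence; a non-palindromic sequence is also
#' scanned on the reverse strand, with minus-strand sites reported at
#' their plus-strand coordinates. Overlapping occurrences are all
#' reported.
#'
#' @param contigs a [Biostrings::DNAStringSet], named character vector of
#'   sequences, or path to a FASTA file.
#' @param recognition recognition sequence (length >= 4, unambiguous
#'   A/C/G/T only).
#' @param enzyme optional enzyme name recorded with each site (defaults
#'   to the recognition sequence).
#' @return Data frame with columns `contig`, `position` (0-based),
#'   `enzyme`, `recognition`.
#' @examples
#' digestGenome(c(chr = "ACATGA"), "CATG")$position  # 1
#' @export
digestGenome <- function(contigs, recognition = "CATG", enzyme = NULL) {
  contigs <- .asDNAStringSet(contigs)
  if (!length(contigs)) stop("empty contig set", call. = FALSE)
  if (is.null(names(contigs))) {
    names(contigs) <- sprintf("contig%02d", seq_along(contigs))
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) {
    stop("recognition sequence must be at least 4 bases", call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", recognition)) {
    stop("recognition sequence must be unambiguous (A/C/G/T only)",
         call. = FALSE)
  }
  pats <- recognition
  if (!.isPalindromic(recognition)) {
    pats <- c(recognition, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(recognition))))
  }
  hits <- lapply(seq_along(contigs), function(i) {
    pos <- sort(unique(unlist(lapply(pats, function(p) {
      BiocGenerics::start(Biostrings::matchPattern(p, contigs[[i]],
                                                   fixed = TRUE)) - 1L
    }))))
    if (!length(pos)) return(NULL)
    data.frame(contig = names(contigs)[i], position = as.integer(pos),
               enzyme = if (is.null(enzyme)) recognition else enzyme,
               recognition = recognition, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(contig = character(), position = integer(),
                      enzyme = character(), recognition = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build the 4C-seq reduced genome
#'
#' For each restriction site, extracts the `flankLen` bases immediately
#' 3' of the recognition sequence on the plus strand, and the `flankLen`
#' bases immediately 3' of the site on the minus strand (the reverse
#' complement of the bases 5' of the site on the plus strand). Sites
#' within one flank length of a contig edge are dropped and counted. A
#' site is flagged unique when neither of its flank strings occurs more
#' than once in the pooled flank multiset -- an exact-string stand-in for
#' an external-aligner mappability evaluation.
#'
#' @param contigs contigs as for [digestGenome()].
#' @param sites data frame from [digestGenome()] on the same contigs.
#' @param flankLen flank length in bases (default 30).
#' @return A [ReducedGenome-class].
#' @export
buildReducedGenome <- function(contigs, sites, flankLen = 30L) {
  contigs <- .asDNAStringSet(contigs)
  if (is.null(names(contigs))) {
    names(contigs) <- sprintf("contig%02d", seq_along(contigs))
  }
  flankLen <- .assertCount(flankLen, "flankLen")
  if (!all(sites$contig %in% names(contigs))) {
    stop("sites reference contigs absent from the sequence set",
         call. = FALSE)
  }
  recLen <- nchar(sites$recognition)
  ctgLen <- Biostrings::width(contigs)[match(sites$contig, names(contigs))]
  keep <- sites$position - flankLen >= 0L &
    sites$position + recLen + flankLen <= ctgLen
  nDropped <- sum(!keep)
  if (nDropped) {
    message(nDropped, " site(s) within ", flankLen,
            " bases of a contig edge dropped")
  }
  kept <- sites[keep, , drop = FALSE]
  recLen <- recLen[keep]
  fp <- Biostrings::DNAStringSet()
  fm <- Biostrings::DNAStringSet()
  if (nrow(kept)) {
    byCtg <- split(seq_len(nrow(kept)), kept$contig)
    fpList <- vector("list", nrow(kept))
    fmList <- vector("list", nrow(kept))
    for (ctg in names(byCtg)) {
      ii <- byCtg[[ctg]]
      subject <- contigs[[ctg]]
      plusRanges <- IRanges::IRanges(
        start = kept$position[ii] + recLen[ii] + 1L, width = flankLen)
      minusRanges <- IRanges::IRanges(
        start = kept$position[ii] - flankLen + 1L, width = flankLen)
      fpCtg <- Biostrings::extractAt(subject, plusRanges)
      fmCtg <- Biostrings::reverseComplement(
        Biostrings::extractAt(subject, minusRanges))
      for (k in seq_along(ii)) {
        fpList[[ii[k]]] <- fpCtg[[k]]
        fmList[[ii[k]]] <- fmCtg[[k]]
      }
    }
    fp <- Biostrings::DNAStringSet(fpList)
    fm <- Biostrings::DNAStringSet(fmList)
  }
  siteId <- sprintf("%s_%d", kept$contig, kept$position)
  pooled <- c(as.character(fp), as.character(fm))
  tab <- table(pooled)
  uni <- if (nrow(kept)) {
    as.vector(tab[as.character(fp)] == 1L & tab[as.character(fm)] == 1L)
  } else logical()
  kept$site_id <- siteId
  kept <- kept[, c("site_id", "contig", "position", "enzyme", "recognition")]
  rownames(kept) <- NULL
  names(fp) <- paste0(siteId, "/plus")
  names(fm) <- paste0(siteId, "/minus")
  new("ReducedGenome", sites = kept, flankPlus = fp, flankMinus = fm,
      unique = uni, nDropped = as.integer(nDropped))
}

#' Export a reduced genome as FASTA (and sites as BED)
#'
#' One FASTA record per kept flank, id `site_id/plus` or `site_id/minus`;
#' flanks round-trip through export/import byte-identically.
#'
#' @param rg a [ReducedGenome-class].
#' @param fastaPath output FASTA path.
#' @param bedPath optional BED path for the site coordinates (0-based
#'   half-open).
#' @param uniqueOnly write only uniquely mappable sites (default TRUE,
#'   matching the reduced-genome filtering).
#' @return Invisibly, the FASTA path.
#' @export
exportReducedGenome <- function(rg, fastaPath, bedPath = NULL,
                                uniqueOnly = TRUE) {
  stopifnot(is(rg, "ReducedGenome"))
  sel <- if (uniqueOnly) which(rg@unique) else seq_len(nrow(rg@sites))
  fp <- rg@flankPlus[sel]
  fm <- rg@flankMinus[sel]
  all <- c(fp, fm)
  if (length(sel)) {
    all <- all[as.vector(rbind(seq_along(sel),
                               seq_along(sel) + length(sel)))]
  }
  Biostrings::writeXStringSet(all, fastaPath)
  if (!is.null(bedPath)) {
    s <- rg@sites[sel, , drop = FALSE]
    writeTSVNoHeader <- function(df, path) {
      write.table(df, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    writeTSVNoHeader(data.frame(
      s$contig, s$position, s$position + nchar(s$recognition), s$site_id),
      bedPath)
  }
  invisible(fastaPath)
}

.asReadStarts <- function(reads) {
  if (is(reads, "GRanges")) {
    return(data.frame(contig = as.character(GenomicRanges::seqnames(reads)),
                      start = BiocGenerics::start(reads) - 1L,
                      stringsAsFactors = FALSE))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    bed <- read.table(reads, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    return(data.frame(contig = bed[[1L]], start = as.integer(bed[[2L]]),
                      stringsAsFactors = FALSE))
  }
  data.frame(contig = as.character(reads$contig),
             start = as.integer(reads$start), stringsAsFactors = FALSE)
}

#' Windowed 4C interaction counting
#'
#' Tiles each contig with fixed-width windows (0-based half-open, default
#' 2.5 kb, stepped by `step`; the default non-overlapping tiling conserves
#' reads) and counts mapped read positions per window and condition. Raw
#' counts are normalized to reads per million using each condition's total
#' mapped reads, excluding reads falling in viewpoint-overlapping windows
#' from the total; with two conditions a log2 difference of normalized
#' counts (pseudocount 1) is reported.
#'
#' @param reads named list of one or two read-position sets (BED-like
#'   data frame with `contig`/`start`/`end`, a `GRanges`, or a BED path).
#'   Each read is counted by its start position.
#' @param contigLengths named integer vector of contig lengths.
#' @param viewpoint optional list/data frame with `contig`, `start`,
#'   `end` (0-based half-open) marking the bait; overlapping windows are
#'   flagged.
#' @param window window width in bases (default 2500).
#' @param step tiling step (default `window`, non-overlapping).
#' @return Data frame with one row per window: `contig`, `start`, `end`,
#'   `viewpoint`, then per condition `count_*` and `rpm_*`, and
#'   `log2_diff` (condition 1 over condition 2) when two conditions are
#'   given.
#' @export
windowInteractions <- function(reads, contigLengths, viewpoint = NULL,
                               window = 2500L, step = window) {
  window <- .assertCount(window, "window")
  step <- .assertCount(step, "step")
  if (!is.list(reads) || is.data.frame(reads)) reads <- list(reads)
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    names(reads) <- paste0("condition", seq_along(reads))
  }
  if (length(reads) < 1L || length(reads) > 2L) {
    stop("one or two read-position sets are required", call. = FALSE)
  }
  if (is.null(names(contigLengths))) {
    stop("contigLengths must be named", call. = FALSE)
  }
  starts <- lapply(names(contigLengths), function(ctg) {
    seq(0L, max(0L, contigLengths[[ctg]] - 1L), by = step)
  })
  win <- data.frame(
    contig = rep(names(contigLengths), lengths(starts)),
    start = unlist(starts),
    stringsAsFactors = FALSE
  )
  win$end <- win$start + window
  winGR <- GenomicRanges::GRanges(
    win$contig, IRanges::IRanges(win$start + 1L, width = window))
  win$viewpoint <- rep(FALSE, nrow(win))
  if (!is.null(viewpoint)) {
    vpGR <- GenomicRanges::GRanges(
      viewpoint$contig,
      IRanges::IRanges(viewpoint$start + 1L,
                       viewpoint$end))
    win$viewpoint <- GenomicRanges::countOverlaps(winGR, vpGR) > 0L
  }
  for (cond in names(reads)) {
    rs <- .asReadStarts(reads[[cond]])
    unknown <- setdiff(unique(rs$contig), names(contigLengths))
    if (length(unknown)) {
      stop("reads on unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!nrow(rs)) {
      stop(sprintf("zero total reads in condition '%s'", cond),
           call. = FALSE)
    }
    ptGR <- GenomicRanges::GRanges(
      rs$contig, IRanges::IRanges(rs$start + 1L, width = 1L))
    cnt <- GenomicRanges::countOverlaps(winGR, ptGR)
    inVP <- GenomicRanges::countOverlaps(
      ptGR, winGR[win$viewpoint]) > 0L
    total <- sum(!inVP)
    if (total == 0L) {
      stop(sprintf(
        "zero mapped reads outside the viewpoint in condition '%s'", cond),
        call. = FALSE)
    }
    win[[paste0("count_", cond)]] <- cnt
    win[[paste0("rpm_", cond)]] <- cnt / total * 1e6
  }
  if (length(reads) == 2L) {
    r1 <- win[[paste0("rpm_", names(reads)[1L])]]
    r2 <- win[[paste0("rpm_", names(reads)[2L])]]
    win$log2_diff <- log2((r1 + 1) / (r2 + 1))
  }
  rownames(win) <- NULL
  win
}
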