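# End-to-end orchestration: synthesize -> quantify -> prioritize -> report,
# plus the 4C chain, with config, logging and fixed seeds.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Quantify a pulldown screen
#'
#' Runs the pulldown-quantification stages over every pair of a screen:
#' label-swap combination, per-pulldown ratio-outlier significance
#' (Significance A/B on observed values), batch correction of the combined
#' log2 fold-change matrix, and imputation of missing fold changes from a
#' downshifted normal distribution. Imputed values complete the
#' fold-change matrix but are never used as significance evidence.
#'
#' @param screen a [PulldownScreen-class].
#' @param mode,minBinSize passed to [significanceOutlierTest()].
#' @param imputeWidth,imputeDownshift passed to [imputeMissing()].
#' @param correctBatches apply [correctBatch()] when more than one batch
#'   label is present.
#' @param seed seed driving the imputation draws.
#' @return List with `table` (one row per locus x protein: combined and
#'   per-replicate evidence, flags), `fcMatrix` (proteins x loci combined
#'   log2 fold changes after correction and imputation), `mask` (imputed
#'   cells) and `log` (mode fallbacks, batch pass-throughs).
#' @export
quantifyScreen <- function(screen, mode = c("B", "A"), minBinSize = 300L,
                           imputeWidth = 0.3, imputeDownshift = 1.8,
                           correctBatches = TRUE, seed = 1L) {
  stopifnot(is(screen, "PulldownScreen"))
  mode <- match.arg(mode)
  pairs <- pulldownPairs(screen)
  loci <- vapply(pairs, snpId, "")
  combined <- .stage("combine", lapply(pairs, combineLabelSwap))
  prot <- sort(unique(unlist(lapply(combined, `[[`, "protein_id"))))
  nP <- length(prot)
  nL <- length(loci)
  mk <- function() matrix(NA_real_, nP, nL, dimnames = list(prot, loci))
  fc <- mk(); o1 <- mk(); o2 <- mk(); p1 <- mk(); p2 <- mk(); mi <- mk()
  nFallback <- 0L
  for (i in seq_len(nL)) {
    cb <- combined[[i]]
    row <- match(cb$protein_id, prot)
    fc[row, i] <- cb$log2fc_ref_over_alt
    o1[row, i] <- cb$oriented_rep1
    o2[row, i] <- cb$oriented_rep2
    mi[row, i] <- cb$mean_log10_intensity
    reps <- replicateTables(pairs[[i]])
    for (tab in reps) {
      pv <- .stage("significance", significanceOutlierTest(
        .orientedValues(tab), log10(pmax(tab$intensity, 1)),
        mode = mode, minBinSize = minBinSize))
      if (isTRUE(attr(pv, "fallback"))) nFallback <- nFallback + 1L
      tgt <- match(tab$protein_id, prot)
      # replicate 1 is the Ref-heavy pulldown by convention
      if (tab$orientation[1L] == "REF_HEAVY") {
        p1[tgt, i] <- pv
      } else {
        p2[tgt, i] <- pv
      }
    }
  }
  passthrough <- logical(nP)
  if (correctBatches && length(unique(screenBatches(screen))) > 1L) {
    fc <- .stage("batch_correction",
                 correctBatch(fc, screenBatches(screen)))
    passthrough <- attr(fc, "passthrough")
  }
  imp <- .stage("imputation", imputeMissing(
    fc, widthFactor = imputeWidth, downshiftFactor = imputeDownshift,
    seed = deriveSeed(seed, "impute")))
  tab <- data.frame(
    snp_id = rep(loci, each = nP),
    protein_id = rep(prot, nL),
    log2fc_ref_over_alt = as.vector(imp$matrix),
    mean_log10_intensity = as.vector(mi),
    oriented_rep1 = as.vector(o1),
    oriented_rep2 = as.vector(o2),
    p_rep1 = as.vector(p1),
    p_rep2 = as.vector(p2),
    imputed = as.vector(imp$mask),
    single_replicate = as.vector(is.na(o1) != is.na(o2)),
    stringsAsFactors = FALSE
  )
  tab$p_value <- pmax(tab$p_rep1, tab$p_rep2)
  list(
    table = tab,
    fcMatrix = imp$matrix,
    mask = imp$mask,
    log = list(mode = mode, minBinSize = minBinSize,
               nModeFallbacks = nFallback,
               nBatchPassthrough = sum(passthrough))
  )
}

#' Run the full PWAS screen pipeline
#'
#' Chains [quantifyScreen()], [callInteractors()],
#' [prioritizeInteractions()] (fold-change z-scores referenced to all
#' quantified interactions) and [selectEvents()], with optional
#' restriction to annotated TFs. Identical inputs and seed reproduce
#' identical outputs.
#'
#' @param screen a [PulldownScreen-class].
#' @param dhs DHS counts (matrix or `SummarizedExperiment`, rows = loci).
#' @param tfAnnotation optional character vector of TF identifiers; when
#'   given, prioritization runs on the TF-restricted calls and both call
#'   counts are reported.
#' @param alphaInteractor interactor-call threshold (default 0.01).
#' @param thresholdPrioritize selection threshold on the combined
#'   z-statistic p-value (default 0.05).
#' @param mode,minBinSize,imputeWidth,imputeDownshift,correctBatches
#'   quantification settings, see [quantifyScreen()].
#' @param policy call policy, see [callInteractors()].
#' @param outDir optional directory; when given, writes
#'   `interactors.tsv`, `ranked.tsv`, `counts.tsv` and `manifest.json`.
#' @param seed integer seed for the stochastic stages (imputation).
#' @return List with `calls`, `ranked` (prioritized table with `rank` and
#'   `selected`), `counts` (summary of call/selection counts), `quant`
#'   (full quantification table) and `manifest`.
#' @export
runScreen <- function(screen, dhs, tfAnnotation = NULL,
                      alphaInteractor = 0.01, thresholdPrioritize = 0.05,
                      mode = c("B", "A"), minBinSize = 300L,
                      imputeWidth = 0.3, imputeDownshift = 1.8,
                      correctBatches = TRUE,
                      policy = c("auto", "replicates", "combined"),
                      outDir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  .assertScalarNumber(alphaInteractor, "alphaInteractor", lower = 0,
                      upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  .assertScalarNumber(thresholdPrioritize, "thresholdPrioritize", lower = 0,
                      upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  quant <- quantifyScreen(screen, mode = mode, minBinSize = minBinSize,
                          imputeWidth = imputeWidth,
                          imputeDownshift = imputeDownshift,
                          correctBatches = correctBatches, seed = seed)
  calls <- .stage("call_interactors",
                  callInteractors(quant$table, alpha = alphaInteractor,
                                  policy = policy))
  nCallsAll <- nrow(calls)
  nCallsTF <- NA_integer_
  used <- calls
  if (!is.null(tfAnnotation)) {
    used <- .stage("tf_filter", filterToTFs(calls, tfAnnotation))
    nCallsTF <- nrow(used)
  }
  fcRef <- abs(quant$fcMatrix[is.finite(quant$fcMatrix)])
  prioritized <- .stage("prioritize", prioritizeInteractions(
    used, dhs, fcReference = fcRef))
  ranked <- .stage("select", selectEvents(prioritized,
                                          threshold = thresholdPrioritize))
  counts <- data.frame(
    metric = c("interactor_calls", "interactor_calls_tf_annotated",
               "selected_events"),
    value = c(nCallsAll, nCallsTF, sum(ranked$selected)),
    stringsAsFactors = FALSE
  )
  manifest <- list(
    package = "pwascreen",
    version = as.character(packageVersion("pwascreen")),
    seed = seed,
    alpha_interactor = alphaInteractor,
    threshold_prioritize = thresholdPrioritize,
    significance_mode = quant$log$mode,
    min_bin_size = minBinSize,
    impute_width = imputeWidth,
    impute_downshift = imputeDownshift,
    call_policy = policy,
    n_loci = length(screen),
    n_mode_fallbacks = quant$log$nModeFallbacks,
    n_batch_passthrough = quant$log$nBatchPassthrough,
    tf_filtered = !is.null(tfAnnotation)
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(calls, file.path(outDir, "interactors.tsv"))
    writeTSV(ranked[, c("rank", "snp_id", "protein_id",
                        "log2fc_ref_over_alt", "z_fc", "z_dhs", "z_avg",
                        "p_combined", "selected")],
             file.path(outDir, "ranked.tsv"))
    writeTSV(counts, file.path(outDir, "counts.tsv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(calls = calls, ranked = ranked, counts = counts, quant = quant,
       manifest = manifest)
}

#' Run the 4C-seq reduced-genome chain
#'
#' Chains [digestGenome()], [buildReducedGenome()] and
#' [windowInteractions()]; any stage error is propagated with the stage
#' name prefixed.
#'
#' @param contigs FASTA path, named character vector, or `DNAStringSet`.
#' @param reads named list of one or two read-position sets (BED paths or
#'   BED-like data frames).
#' @param viewpoint optional bait interval (`contig`, `start`, `end`).
#' @param recognition recognition sequence (default CATG, NlaIII).
#' @param flankLen reduced-genome flank length (default 30).
#' @param window,step window tiling, see [windowInteractions()].
#' @param outDir optional output directory (`reduced_genome.fasta`,
#'   `sites.bed`, `windows.tsv`, `manifest.json`).
#' @param enzyme optional enzyme name.
#' @return List with `sites`, `reducedGenome`, `windows`, `manifest`.
#' @export
run4C <- function(contigs, reads, viewpoint = NULL, recognition = "CATG",
                  flankLen = 30L, window = 2500L, step = window,
                  outDir = NULL, enzyme = NULL) {
  contigSet <- .stage("load_contigs", .asDNAStringSet(contigs))
  if (is.null(names(contigSet))) {
    names(contigSet) <- sprintf("contig%02d", seq_along(contigSet))
  }
  sites <- .stage("digest", digestGenome(contigSet, recognition,
                                         enzyme = enzyme))
  rg <- .stage("reduced_genome",
               buildReducedGenome(contigSet, sites, flankLen = flankLen))
  lens <- setNames(Biostrings::width(contigSet), names(contigSet))
  windows <- .stage("windows", windowInteractions(
    reads, lens, viewpoint = viewpoint, window = window, step = step))
  manifest <- list(
    package = "pwascreen",
    version = as.character(packageVersion("pwascreen")),
    recognition = recognition,
    enzyme = if (is.null(enzyme)) recognition else enzyme,
    flank_length = flankLen,
    window = window,
    step = step,
    n_sites = nrow(sites),
    n_sites_kept = nrow(reducedSites(rg)),
    n_sites_dropped_edge = rg@nDropped,
    n_unique = sum(isUniqueFlank(rg))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    exportReducedGenome(rg, file.path(outDir, "reduced_genome.fasta"),
                        bedPath = file.path(outDir, "sites.bed"))
    writeTSV(windows, file.path(outDir, "windows.tsv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sites = sites, reducedGenome = rg, windows = windows,
       manifest = manifest)
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration with the fields of the run (paths,
#' thresholds, significance mode, imputation parameters, batch labels,
#' seed), filling package defaults for anything omitted and validating
#' thresholds.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    alpha_interactor = 0.01,
    threshold_prioritize = 0.05,
    significance_mode = "B",
    min_bin_size = 300L,
    impute_width = 0.3,
    impute_downshift = 1.8,
    call_policy = "auto",
    seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in c("alpha_interactor", "threshold_prioritize")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop(sprintf("config field '%s' must lie in (0, 1)", nm),
           call. = FALSE)
    }
  }
  for (nm in c("input_dir", "dhs_table", "tf_annotation")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop(sprintf("config input path '%s' (%s) does not exist",
                   cfg[[nm]], nm), call. = FALSE)
    }
  }
  cfg
}

#' Reconstruct a screen from delimited-text tables
#'
#' Reads the per-pulldown TSVs and batch table written by
#' [writeScreenTables()].
#'
#' @param dir directory containing `<snp>_rep1.tsv`, `<snp>_rep2.tsv` and
#'   `batches.tsv`.
#' @return A [PulldownScreen-class] (without ground truth).
#' @export
readScreenTables <- function(dir) {
  bt <- readTSV(file.path(dir, "batches.tsv"))
  pairs <- lapply(seq_len(nrow(bt)), function(i) {
    reps <- lapply(1:2, function(r) {
      readPulldownTable(file.path(dir, sprintf("%s_rep%d.tsv",
                                               bt$snp_id[i], r)))
    })
    PulldownPair(bt$snp_id[i],
                 if ("ref_allele" %in% names(bt)) bt$ref_allele[i] else "N",
                 if ("alt_allele" %in% names(bt)) bt$alt_allele[i] else "N",
                 reps)
  })
  new("PulldownScreen", pairs = pairs, batches = as.character(bt$batch),
      groundTruth = data.frame(), spec = NULL, metadata = list())
}

#' Write / read a DHS count table
#'
#' Loci x samples TSV with locus ids in the first column.
#'
#' @param dhs matrix or `SummarizedExperiment`.
#' @param path TSV path.
#' @return `writeDHSTable` the path, invisibly; `readDHSTable` a count
#'   matrix.
#' @export
writeDHSTable <- function(dhs, path) {
  m <- if (is(dhs, "SummarizedExperiment")) {
    SummarizedExperiment::assay(dhs)
  } else as.matrix(dhs)
  df <- data.frame(locus_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTSV(df, path)
}

#' @rdname writeDHSTable
#' @export
readDHSTable <- function(path) {
  df <- readTSV(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
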