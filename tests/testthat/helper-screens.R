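# small screen constructors shared across test files

makePair <- function(snp = "rs1", o1 = 1, o2 = 1,
                     protein = paste0("P", seq_along(o1)),
                     intensity = 1e7,
                     orientations = c("REF_HEAVY", "ALT_HEAVY")) {
  tab <- function(ratio, ori) {
    data.frame(protein_id = protein, log2_ratio = ratio,
               intensity = intensity, orientation = ori,
               stringsAsFactors = FALSE)
  }
  PulldownPair(snp, "G", "A", list(tab(o1, orientations[1]),
                                   tab(o2, orientations[2])))
}

smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(nLoci = 2L, nBackgroundProteins = 120L,
                   nSpikedBinders = 0L, seed = 42L)
  do.call(ScreenSpec, utils::modifyList(defaults, args))
}
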