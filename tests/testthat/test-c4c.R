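test_that("digestion finds exact recognition-site occurrences", {
  expect_identical(nrow(digestGenome(c(x = "AAAAAA"), "CATG")), 0L)
  d <- digestGenome(c(x = "ACATGA"), "CATG")
  expect_identical(d$position, 1L)
  # overlapping occurrences are all reported
  d2 <- digestGenome(c(x = "ATATATAT"), "ATAT")
  expect_identical(d2$position, c(0L, 2L, 4L))
  expect_error(digestGenome(Biostrings::DNAStringSet(), "CATG"), "empty")
  expect_error(digestGenome(c(x = "ACGT"), "CAT"), "at least 4")
  expect_error(digestGenome(c(x = "ACGT"), "CATN"), "unambiguous")
})

test_that("digestion equals a brute-force scan on a random contig", {
  g <- simulateToyGenome(1, 20000, 0.002, seed = 31)
  seqs <- setNames(as.character(g$contigs), names(g$contigs))
  for (rec in c("CATG", "GTAC")) {
    d <- digestGenome(seqs, rec)
    s <- seqs[[1]]
    brute <- which(vapply(seq_len(nchar(s) - nchar(rec) + 1L),
                          function(i) {
                            substr(s, i, i + nchar(rec) - 1L) == rec
                          }, TRUE)) - 1L
    expect_identical(d$position, as.integer(brute))
  }
})

test_that("palindromic digestion mirrors under reverse complement", {
  g <- simulateToyGenome(1, 5000, 0.003, seed = 32)
  s <- as.character(g$contigs[[1]])
  d <- digestGenome(c(fwd = s), "CATG")
  rc <- as.character(Biostrings::reverseComplement(g$contigs[[1]]))
  dRC <- digestGenome(c(rev = rc), "CATG")
  expect_identical(sort(nchar(s) - 4L - d$position), dRC$position)
})

test_that("non-palindromic recognition sequences are scanned on both strands", {
  # GATC-containing GACGTC is palindromic; use GGTACC? no - take AAGCTT?
  # AAGCTT reverse-complements to itself; use a truly asymmetric one:
  d <- digestGenome(c(x = "TTGATCTT"), "GATC")  # palindromic control
  expect_identical(d$position, 2L)
  d2 <- digestGenome(c(x = "CCCAGGTTTCCTGGTTT"), "CAGG")
  # CAGG at 2 on plus; CCTG at 9 is CAGG on the minus strand
  expect_identical(d2$position, c(2L, 9L))
})

test_that("reduced-genome flanks have the documented geometry", {
  # one site centred in the contig: both flanks length 30, unique
  set.seed(33)
  left <- paste(sample(c("A", "C", "G", "T"), 48, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 48, TRUE), collapse = "")
  ctg <- paste0(left, "CATG", right)
  sites <- digestGenome(c(c1 = ctg), "CATG")
  rg <- buildReducedGenome(c(c1 = ctg), sites[sites$position == 48, ])
  expect_identical(length(rg), 1L)
  expect_identical(as.character(flankPlus(rg)[[1]]), substr(right, 1, 30))
  expect_identical(
    as.character(flankMinus(rg)[[1]]),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(left, 19, 48)))))
  expect_true(isUniqueFlank(rg))
})

test_that("duplicated flank sequences mark both sites non-unique", {
  block <- paste(rep("ACGTGCTAAGCTTGCAATCGGATCCTTAGG", 1), collapse = "")
  stopifnot(nchar(block) == 30)
  pad <- strrep("T", 35)
  ctg <- paste0(pad, "CATG", block, pad, "CATG", block, pad)
  sites <- digestGenome(c(c1 = ctg), "CATG")
  rg <- suppressMessages(buildReducedGenome(c(c1 = ctg), sites))
  dup <- which(as.character(flankPlus(rg)) == block)
  expect_identical(length(dup), 2L)
  expect_false(any(isUniqueFlank(rg)[dup]))
})

test_that("edge sites are dropped and the entry count is conserved", {
  g <- simulateToyGenome(1, 8000, 0.004, seed = 34)
  seqs <- setNames(as.character(g$contigs), names(g$contigs))
  sites <- digestGenome(seqs, "CATG")
  rg <- suppressMessages(buildReducedGenome(seqs, sites))
  nEdge <- sum(sites$position < 30 | sites$position + 4 + 30 > 8000)
  expect_identical(length(rg), nrow(sites) - nEdge)
  expect_identical(rg@nDropped, nEdge)
  expect_true(all(Biostrings::width(flankPlus(rg)) == 30))
  expect_true(all(Biostrings::width(flankMinus(rg)) == 30))
})

test_that("reduced-genome flanks round-trip through FASTA byte-identically", {
  g <- simulateToyGenome(1, 6000, 0.003, seed = 35)
  seqs <- setNames(as.character(g$contigs), names(g$contigs))
  rg <- suppressMessages(
    buildReducedGenome(seqs, digestGenome(seqs, "CATG")))
  fa <- withr::local_tempfile(fileext = ".fasta")
  exportReducedGenome(rg, fa, uniqueOnly = FALSE)
  back <- Biostrings::readDNAStringSet(fa)
  n <- length(rg)
  expect_identical(as.character(back[paste0(rg@sites$site_id, "/plus")]),
                   setNames(as.character(flankPlus(rg)),
                            paste0(rg@sites$site_id, "/plus")))
  expect_identical(as.character(back[paste0(rg@sites$site_id, "/minus")]),
                   setNames(as.character(flankMinus(rg)),
                            paste0(rg@sites$site_id, "/minus")))
  expect_identical(length(back), 2L * n)
})

test_that("non-overlapping windows conserve reads and zero out identical conditions", {
  set.seed(36)
  reads <- data.frame(contig = "c1",
                      start = sample(0:9999, 400, replace = TRUE))
  reads$end <- reads$start + 30
  win <- windowInteractions(list(a = reads, b = reads),
                            c(c1 = 10000L), window = 2500)
  expect_identical(sum(win$count_a), 400L)
  expect_identical(sum(win$count_b), 400L)
  expect_true(all(win$log2_diff == 0))
  expect_true(all(win$end - win$start == 2500))
})

test_that("window counts equal brute-force interval counting", {
  set.seed(37)
  reads <- data.frame(contig = "c1",
                      start = sample(0:4999, 250, replace = TRUE))
  reads$end <- reads$start + 25
  for (step in c(2500L, 1000L)) {
    win <- windowInteractions(list(x = reads), c(c1 = 5000L),
                              window = 2500, step = step)
    brute <- vapply(seq_len(nrow(win)), function(i) {
      sum(reads$start >= win$start[i] & reads$start < win$end[i])
    }, 1L)
    expect_identical(win$count_x, brute)
  }
})

test_that("a single occupied window holds one million reads per million", {
  reads <- data.frame(contig = "c1", start = rep(100L, 12),
                      end = rep(130L, 12))
  win <- windowInteractions(list(only = reads), c(c1 = 5000L),
                            window = 2500)
  expect_equal(win$rpm_only, c(1e6, 0))
})

test_that("viewpoint windows are flagged and excluded from totals", {
  reads <- data.frame(contig = "c1",
                      start = c(rep(100L, 90), rep(3000L, 10)))
  reads$end <- reads$start + 20
  vp <- list(contig = "c1", start = 50L, end = 150L)
  win <- windowInteractions(list(a = reads), c(c1 = 5000L),
                            viewpoint = vp, window = 2500)
  expect_identical(win$viewpoint, c(TRUE, FALSE))
  # totals exclude the 90 viewpoint reads: the far window holds all rpm
  expect_equal(win$rpm_a[2], 1e6)
})

test_that("empty read sets surface a clear normalization error", {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer())
  expect_error(
    windowInteractions(list(a = empty), c(c1 = 1000L)),
    "zero total reads in condition 'a'")
})
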