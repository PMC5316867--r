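test_that("label-swap combination follows the Ref/Alt orientation convention", {
  # forward +1 and reverse +1 (Alt-heavy measured Alt/Ref = 2): cancels
  expect_equal(combineLabelSwap(makePair(o1 = 1, o2 = 1))$log2fc_ref_over_alt,
               0)
  # forward +1, reverse -1: consistent Ref preference
  expect_equal(combineLabelSwap(makePair(o1 = 1, o2 = -1))$log2fc_ref_over_alt,
               1)
})

test_that("combination is invariant to replicate storage order", {
  set.seed(1)
  tabs <- replicateTables(makePair(o1 = rnorm(20), o2 = rnorm(20)))
  a <- combineLabelSwap(tabs)
  b <- combineLabelSwap(rev(tabs))
  expect_equal(a[order(a$protein_id), -1], b[order(b$protein_id), -1])
})

test_that("two replicates with one orientation are a bookkeeping fault", {
  tabs <- replicateTables(makePair(o1 = 1, o2 = 1))
  tabs[[2]]$orientation <- "REF_HEAVY"
  expect_error(combineLabelSwap(tabs), "bookkeeping")
})

test_that("proteins seen in one replicate carry the single oriented value, flagged", {
  t1 <- data.frame(protein_id = c("A", "B"), log2_ratio = c(1, 2),
                   intensity = 1e7, orientation = "REF_HEAVY")
  t2 <- data.frame(protein_id = "A", log2_ratio = -1,
                   intensity = 1e7, orientation = "ALT_HEAVY")
  cb <- combineLabelSwap(list(t1, t2))
  expect_equal(cb$log2fc_ref_over_alt[cb$protein_id == "B"], 2)
  expect_true(cb$single_replicate[cb$protein_id == "B"])
  expect_false(cb$single_replicate[cb$protein_id == "A"])
})

test_that("single-batch matrices pass through batch correction unchanged", {
  m <- matrix(rnorm(50), 10, 5)
  out <- correctBatch(m, rep("b1", 5))
  expect_equal(unclass(out)[, ], m[, ])
  expect_identical(attr(out, "nBatches"), 1L)
})

test_that("a pure location shift between batches is removed", {
  set.seed(2)
  base <- matrix(rnorm(60), 20, 3)
  m <- cbind(base, base + 1.7)
  batches <- rep(c("a", "b"), each = 3)
  out <- correctBatch(m, batches)
  ma <- rowMeans(out[, 1:3])
  mb <- rowMeans(out[, 4:6])
  expect_lt(max(abs(ma - mb)), 1e-8)
})

test_that("batch correction removes most between-batch variance", {
  # variance-decomposition oracle on a noisy two-batch design
  set.seed(3)
  g <- 200
  m <- matrix(rnorm(g * 8, sd = 0.3), g, 8) +
    matrix(rep(c(0, 0.9), each = g * 4), g, 8)
  batches <- rep(c("a", "b"), each = 4)
  bv <- function(x) {
    mean((rowMeans(x[, 1:4]) - rowMeans(x[, 5:8]))^2)
  }
  out <- correctBatch(m, batches)
  expect_lt(bv(out), 0.05 * bv(m))
})

test_that("batch correction agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(4)
  g <- 150
  m <- matrix(rnorm(g * 9), g, 9) +
    outer(rnorm(g), rep(c(0, 1, -0.5), each = 3))
  batches <- rep(c("a", "b", "c"), each = 3)
  mine <- correctBatch(m, batches)
  ref <- suppressMessages(sva::ComBat(m, batch = batches))
  expect_equal(unclass(mine)[, ], ref[, ], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("rows too sparse for a batch are passed through and flagged", {
  set.seed(5)
  m <- matrix(rnorm(40), 10, 4)
  m[1, 3:4] <- NA # fewer than 2 observed in batch b
  out <- correctBatch(m, c("a", "a", "b", "b"))
  expect_true(attr(out, "passthrough")[1])
  expect_equal(out[1, 1:2], m[1, 1:2])
  expect_error(correctBatch(m, c("a", "b")), "length")
})

test_that("imputation is a no-op without missing values and deterministic with them", {
  m <- matrix(rnorm(30), 10, 3)
  res <- imputeMissing(m, seed = 1)
  expect_identical(res$matrix, m)
  expect_false(any(res$mask))
  m[c(1, 5), 2] <- NA
  r1 <- imputeMissing(m, seed = 7)
  r2 <- imputeMissing(m, seed = 7)
  expect_identical(r1$matrix, r2$matrix)
  expect_identical(which(r1$mask), c(11L, 15L))
  m2 <- matrix(c(1, 2, NA, NA, NA), 5, 1)
  expect_error(imputeMissing(m2, seed = 1), "at least 3")
})

test_that("imputed values follow the downshifted normal (law of large numbers)", {
  set.seed(8)
  n <- 20000
  col <- rnorm(n) # mean 0, sd 1
  m <- cbind(c(col, rep(NA_real_, 10000)))
  res <- imputeMissing(m, widthFactor = 0.3, downshiftFactor = 1.8,
                       seed = 9)
  imp <- res$matrix[res$mask]
  mu <- mean(col)
  s <- sd(col)
  sem <- 0.3 * s / sqrt(length(imp))
  expect_lt(abs(mean(imp) - (mu - 1.8 * s)), 3 * sem)
})

test_that("outlier p-values hit the closed-form anchor points", {
  set.seed(10)
  x <- rnorm(501)
  p <- significanceOutlierTest(x, mode = "A")
  qs <- quantile(x, c(0.1587, 0.5, 0.8413), type = 7, names = FALSE)
  # the median scores p = 1
  expect_equal(unname(p[which.min(abs(x - qs[2]))]), 1, tolerance = 1e-2)
  i <- which.min(abs(x - qs[3]))
  # a value at P84.13 sits one robust sigma out: p = erfc(1/sqrt(2))
  expect_equal(unname(p[i]), 2 * pnorm(-1), tolerance = 1e-2)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("outlier p-values are null-calibrated and monotone in |x - median|", {
  set.seed(11)
  x <- rnorm(500)
  p <- significanceOutlierTest(x, mode = "A")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.08)
  r0 <- median(x)
  up <- x > r0
  expect_true(all(diff(p[up][order(x[up])]) <= 1e-12))
  expect_true(all(diff(p[!up][order(-x[!up])]) <= 1e-12))
})

test_that("mode B with a single bin equals mode A exactly", {
  set.seed(12)
  x <- rnorm(250)
  li <- rnorm(250, 7)
  pa <- significanceOutlierTest(x, li, mode = "A")
  pb <- significanceOutlierTest(x, li, mode = "B", minBinSize = 200)
  expect_identical(as.numeric(pa), as.numeric(pb))
  expect_identical(attr(pb, "nBins"), 1L)
})

test_that("mode B bins by intensity and falls back to mode A when too small", {
  set.seed(13)
  n <- 900
  li <- sort(rnorm(n, 7))
  x <- rnorm(n, sd = rep(c(1, 2, 4), each = 300)) # spread grows with intensity
  pb <- significanceOutlierTest(x, li, mode = "B", minBinSize = 300)
  expect_identical(attr(pb, "nBins"), 3L)
  expect_false(attr(pb, "fallback"))
  # within the top bin the wide values are not outliers; globally they are
  pa <- significanceOutlierTest(x, li, mode = "A")
  top <- 601:900
  expect_gt(median(pb[top]), median(pa[top]))
  pf <- significanceOutlierTest(rnorm(100), rnorm(100), mode = "B",
                                minBinSize = 300)
  expect_true(attr(pf, "fallback"))
  expect_identical(attr(pf, "mode"), "A")
})

test_that("degenerate spreads raise errors naming the flat side", {
  expect_error(significanceOutlierTest(c(0, 0, 0, 0, 1), mode = "A"),
               "left")
  expect_error(significanceOutlierTest(c(-1, 0, 0, 0, 0), mode = "A"),
               "right")
})

test_that("NA ratios propagate as NA p-values without affecting the rest", {
  set.seed(14)
  x <- rnorm(400)
  xNA <- c(x, NA, NA)
  p <- significanceOutlierTest(x, mode = "A")
  pNA <- significanceOutlierTest(xNA, mode = "A")
  expect_identical(as.numeric(p), as.numeric(pNA[1:400]))
  expect_true(all(is.na(pNA[401:402])))
})

test_that("interactor calls respect threshold, ordering and preference", {
  tab <- data.frame(
    snp_id = "rs1", protein_id = c("A", "B"),
    log2fc_ref_over_alt = c(-2, 1.5),
    p_value = c(0.005, 0.5)
  )
  calls <- callInteractors(tab, alpha = 0.01, policy = "combined")
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$allele_preference, "ALT")
  expect_identical(nrow(callInteractors(tab[0, ], policy = "combined")), 0L)
})

test_that("replicate policy demands consistent significant evidence in both pulldowns", {
  tab <- data.frame(
    snp_id = "rs1",
    protein_id = c("A", "B", "C", "D"),
    log2fc_ref_over_alt = c(3, 3, 3, 3),
    oriented_rep1 = c(3, 3, 3, NA),
    oriented_rep2 = c(3, -3, 3, 3),
    p_rep1 = c(0.001, 0.001, 0.5, NA),
    p_rep2 = c(0.002, 0.002, 0.001, 0.001),
    imputed = FALSE
  )
  calls <- callInteractors(tab, alpha = 0.01, policy = "replicates")
  expect_identical(calls$protein_id, "A") # B sign-inconsistent, C weak, D single
  expect_equal(calls$p_value, 0.002)
})

test_that("relabelling the alleles flips preferences but not |fc| or p-values", {
  sp <- smallSpec(nLoci = 2L, nBackgroundProteins = 350L,
                  nSpikedBinders = 2L, seed = 15L)
  scr <- simulatePulldownScreen(sp)
  flipPair <- function(pair) {
    reps <- lapply(replicateTables(pair), function(t) {
      t$orientation <- ifelse(t$orientation == "REF_HEAVY",
                              "ALT_HEAVY", "REF_HEAVY")
      t
    })
    PulldownPair(snpId(pair), altAllele(pair), refAllele(pair), rev(reps))
  }
  flipped <- new("PulldownScreen",
                 pairs = lapply(pulldownPairs(scr), flipPair),
                 batches = screenBatches(scr),
                 groundTruth = groundTruth(scr), spec = scr@spec,
                 metadata = scr@metadata)
  a <- callInteractors(quantifyScreen(scr, seed = 1)$table, 0.05)
  b <- callInteractors(quantifyScreen(flipped, seed = 1)$table, 0.05)
  expect_identical(a$protein_id, b$protein_id)
  expect_equal(abs(a$log2fc_ref_over_alt), abs(b$log2fc_ref_over_alt),
               tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_true(all(a$allele_preference != b$allele_preference))
})

test_that("null screens are calibrated: few proteins called at alpha 0.01", {
  frac <- vapply(1:20, function(s) {
    scr <- simulatePulldownScreen(
      ScreenSpec(nLoci = 2L, nBackgroundProteins = 500L,
                 nSpikedBinders = 0L, seed = s))
    calls <- callInteractors(quantifyScreen(scr, seed = s)$table, 0.01)
    nrow(calls) / 1000
  }, 1)
  expect_lte(mean(frac), 0.03)
})

test_that("spiked binders are recovered with high recall and low FDP", {
  res <- t(vapply(1:10, function(s) {
    sp <- ScreenSpec(nLoci = 1L, nBackgroundProteins = 1000L,
                     nSpikedBinders = 20L, spikeLog2FC = 4,
                     noiseSD = 0.3, seed = 100 + s)
    scr <- simulatePulldownScreen(sp)
    calls <- callInteractors(quantifyScreen(scr, seed = s)$table, 0.01)
    gt <- groundTruth(scr)
    truth <- paste(gt$snp_id, gt$protein_id)[gt$true_log2fc != 0]
    called <- paste(calls$snp_id, calls$protein_id)
    tp <- sum(called %in% truth)
    c(recall = tp / 20, fdp = if (length(called)) {
      1 - tp / length(called)
    } else 0)
  }, c(recall = 1, fdp = 1)))
  expect_gte(mean(res[, "recall"]), 0.95)
  expect_lte(mean(res[, "fdp"]), 0.10)
})
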