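constantDepthExperiment <- function(value, nIv = 4, nS = 10) {
  d <- matrix(value, nrow = nIv, ncol = nS)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = (seq_len(nIv) - 1) * 100 + 1, width = 50),
    gene = paste0("G", seq_len(nIv)))
  DepthExperiment(d, gr, sprintf("S%02d", seq_len(nS)))
}

test_that("depth filtering drops low-depth samples and intervals", {
  de <- constantDepthExperiment(100)
  d <- depth(de)
  d[, 1] <- 10                      # uniform 10x sample
  d[2, ] <- c(14, rep(14.9, 9))     # cohort mean below 15x
  de2 <- DepthExperiment(d, SummarizedExperiment::rowRanges(de),
                         colnames(d))
  f <- filterDepth(de2)
  expect_equal(ncol(f), 9)          # the 10x sample is gone
  expect_false("S01" %in% colnames(depth(f)))
  expect_equal(nrow(f), 3)          # the 14.9x interval is gone
  # all cells comfortably above thresholds: identity
  f2 <- filterDepth(constantDepthExperiment(100))
  expect_equal(dim(f2), c(4L, 10L))
  # everything dropped: explicit empty result
  expect_message(filterDepth(constantDepthExperiment(5)), "no data left")
})

test_that("dose rates self-normalize and respond to single-gene events", {
  de <- constantDepthExperiment(100)
  expect_true(all(doseRates(de) == 1))
  # halving one sample's single-interval gene gives dose 0.5 there and
  # leaves every other cell at 1 (hand-computed on the 4 x 10 toy)
  d <- depth(de)
  d[1, 1] <- 50
  de2 <- DepthExperiment(d, SummarizedExperiment::rowRanges(de),
                         colnames(d))
  dose <- doseRates(de2)
  expect_equal(unname(dose[1, 1]), 0.5)
  expect_true(all(dose[-1, ] == 1))
  expect_true(all(dose[1, -1] == 1))
  # doubling a whole sample changes nothing (sample-median invariance)
  d3 <- depth(de2); d3[, 2] <- d3[, 2] * 2
  de3 <- DepthExperiment(d3, SummarizedExperiment::rowRanges(de),
                         colnames(d3))
  expect_equal(doseRates(de3), dose)
  expect_error(doseRates(constantDepthExperiment(100, nS = 2)),
               "3 samples")
})

test_that("scale invariance: rescaling any sample leaves calls unchanged", {
  sim <- simDepthCohort(10, 20, seed = 31,
    spikes = data.frame(sample = 4, firstInterval = 6, nIntervals = 3,
                        dose = 0.5))
  base <- callCnvs(sim$depths)
  d <- depth(sim$depths)
  for (fac in c(0.25, 3)) {
    d2 <- d; d2[, 4] <- d2[, 4] * fac
    de2 <- DepthExperiment(d2, SummarizedExperiment::rowRanges(sim$depths),
                           colnames(d2))
    expect_equal(callCnvs(de2), base, info = paste("factor", fac))
  }
})

test_that("a spiked heterozygous deletion yields one merged call", {
  sim <- simDepthCohort(12, 30, seed = 7,
    spikes = data.frame(sample = 5, firstInterval = 11, nIntervals = 3,
                        dose = 0.5))
  calls <- callCnvs(sim$depths)
  dels <- calls[calls$kind == "deletion", ]
  expect_equal(nrow(dels), 1)
  expect_equal(dels$sample, "S05")
  expect_equal(dels$firstInterval, 11)
  expect_equal(dels$lastInterval, 13)
  expect_lte(dels$doseRate, 0.6)
  expect_lte(dels$z, -2)
})

test_that("all-ones dose matrices and merged outputs are stable", {
  dose <- matrix(1, nrow = 6, ncol = 5,
                 dimnames = list(NULL, paste0("S", 1:5)))
  expect_equal(nrow(callCnvs(dose)), 0)
  sim <- simDepthCohort(12, 30, seed = 7,
    spikes = data.frame(sample = 5, firstInterval = 11, nIntervals = 3,
                        dose = 0.5))
  calls <- callCnvs(sim$depths)
  expect_equal(mergeCnvCalls(calls), calls)  # merging is idempotent
})

test_that("zero-variance intervals with an outlying dose warn and still call", {
  dose <- matrix(1, nrow = 3, ncol = 6,
                 dimnames = list(NULL, paste0("S", 1:6)))
  dose[2, ] <- 0.5  # degenerate: whole interval at deletion dose, sd = 0
  expect_warning(calls <- callCnvs(dose), "zero-variance")
  expect_equal(sort(unique(calls$kind)), "deletion")
  expect_equal(nrow(calls), 6)
})

test_that("deletion pathway is specific on null cohorts", {
  # dose <= 0.60 with z <= -2 sits ~5 sigma below a Poisson-150x diploid
  # baseline, so null cohorts should essentially never produce deletions
  nDel <- vapply(1:20, function(i) {
    sim <- simDepthCohort(20, 50, seed = 5000 + i)
    sum(callCnvs(sim$depths)$kind == "deletion")
  }, numeric(1))
  expect_lt(mean(nDel), 1)
})
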