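## A 10-cell fixture: 7 designed passes, then one violation each of the
## spike-ratio, linearity and aligned-read criteria.
qc_fixture <- function() {
  spikes <- paste0("spike", 1:6)
  genes <- paste0("g", 1:5)
  expected <- setNames(c(1, 2, 4, 8, 16, 32), spikes)
  cells <- paste0("cell", sprintf("%02d", 1:10))
  counts <- matrix(0L, 11, 10, dimnames = list(c(genes, spikes), cells))
  reads <- counts
  for (j in 1:10) {
    counts[genes, j] <- 50L
    reads[genes, j] <- 60000L                    # 300,000 transcript reads
    counts[spikes, j] <- as.integer(expected)    # perfectly linear -> r = 1
    reads[spikes, j] <- 2000L                    # ratio 12,000/300,000 = 0.04
  }
  reads[spikes, 8] <- 6000L                      # ratio 0.12 >= 0.09
  counts[spikes, 9] <- as.integer(rev(expected)) # reversed series -> r = -1
  reads[genes, 10] <- 47000L                     # aligned 247,000 < 250,000
  list(cm = make_cm(counts, reads, spikes), expected = expected)
}

test_that("the three QC criteria admit and reject cells exactly as designed", {
  fx <- qc_fixture()
  qc <- compute_qc(fx$cm, fx$expected)
  expect_equal(sum(qc$pass), 7)
  expect_equal(qc$fail_reason[8], "spike_ratio")
  expect_equal(qc$fail_reason[9], "linearity")
  expect_equal(qc$fail_reason[10], "aligned_reads")
  expect_true(all(qc$fail_reason[1:7] == ""))
  expect_equal(qc$spike_linearity_r[1], 1)
})

test_that("boundary cells fail: ratio at 0.09 and depth one read short", {
  fx <- qc_fixture()
  ## ratio 0.04 with r = 1 and 312,000 aligned reads passes at the defaults
  qc <- compute_qc(fx$cm, fx$expected,
                   max_spike_ratio = 0.09, min_spike_r = 0.8,
                   min_aligned_reads = 250000)
  expect_true(qc$pass[1])
  qc2 <- compute_qc(fx$cm, fx$expected, min_aligned_reads = 312001)
  expect_false(qc2$pass[1])  # aligned 312,000 is below 312,001
})

test_that("raising any threshold never adds a passing cell", {
  fx <- qc_fixture()
  base <- compute_qc(fx$cm, fx$expected, max_spike_ratio = 0.09,
                     min_spike_r = 0.5, min_aligned_reads = 100000)
  for (alt in list(c(0.03, 0.5, 100000), c(0.09, 0.95, 100000),
                   c(0.09, 0.5, 300000))) {
    stricter <- compute_qc(fx$cm, fx$expected, max_spike_ratio = alt[1],
                           min_spike_r = alt[2], min_aligned_reads = alt[3])
    expect_true(all(which(stricter$pass) %in% which(base$pass)))
  }
})

test_that("a cell with zero transcript reads has infinite spike ratio and fails", {
  fx <- qc_fixture()
  fx$cm$reads[paste0("g", 1:5), 1] <- 0L
  fx$cm$aligned_reads <- colSums(fx$cm$reads)
  qc <- compute_qc(fx$cm, fx$expected, min_aligned_reads = 1)
  expect_equal(qc$spike_ratio[1], Inf)
  expect_false(qc$pass[1])
})

test_that("TPM columns are proportions times one million", {
  counts <- matrix(c(10, 30, 60), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "cell1"))
  tpm <- tpm_normalize(counts, is_spikein = rep(FALSE, 3))
  expect_equal(unname(tpm[, 1]), c(1e5, 3e5, 6e5))
  one <- matrix(c(0, 7, 0), ncol = 1, dimnames = list(c("a", "b", "c"), "c1"))
  expect_equal(unname(tpm_normalize(one)[, 1]), c(0, 1e6, 0))
})

test_that("TPM is scale invariant and spike-ins are excluded from the pool", {
  set.seed(1)
  counts <- matrix(rpois(40, 20), 8, 5,
                   dimnames = list(c(paste0("g", 1:6), "spike1", "spike2"),
                                   paste0("c", 1:5)))
  spike <- grepl("^spike", rownames(counts))
  tpm <- tpm_normalize(counts, spike)
  expect_equal(unname(colSums(tpm)), rep(1e6, 5), tolerance = 1e-9)
  expect_false(any(grepl("^spike", rownames(tpm))))
  doubled <- counts; doubled[, 3] <- doubled[, 3] * 2L
  expect_equal(tpm_normalize(doubled, spike)[, 3], tpm[, 3])
})

test_that("zero-count cells normalise to zero columns with a warning", {
  counts <- matrix(c(5, 5, 0, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_warning(tpm <- tpm_normalize(counts, c(FALSE, FALSE)), "zero")
  expect_equal(unname(tpm[, 2]), c(0, 0))
})

test_that("marker summary reports fidelity statistics and detected genes", {
  tpm <- matrix(c(0, 0, 10,
                  5, 5, 5,
                  0, 0, 0), 3, 3, byrow = TRUE,
                dimnames = list(c("roX2", "Lk", "repo"), paste0("c", 1:3)))
  ms <- marker_summary(tpm, c("roX2", "Lk", "repo"))
  expect_equal(ms$markers$mean_tpm, c(10 / 3, 5, 0), tolerance = 1e-12)
  expect_equal(ms$markers$median_tpm, c(0, 5, 0))
  expect_equal(unname(ms$detected_genes), c(1, 1, 2))
  expect_warning(marker_summary(tpm, c("Lk", "nope")), "nope")
})
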