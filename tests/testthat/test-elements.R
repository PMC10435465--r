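test_that("RPKM and RPGC normalization follow their closed forms", {
  tr <- coverage_track("c", rep(10, 4), bin_size = 1000,
                       total_mapped_reads = 1e6, read_length = 50)
  expect_equal(normalize_coverage(tr, "RPKM")$values, rep(10, 4))

  z <- coverage_track("c", rep(0, 10), bin_size = 25,
                      total_mapped_reads = 1000)
  expect_equal(normalize_coverage(z, "RPKM")$values, rep(0, 10))
  expect_equal(normalize_coverage(z, "RPGC")$values, rep(0, 10))

  set.seed(1)
  v <- rpois(200, 8)
  tr2 <- coverage_track("c", v, bin_size = 25, total_mapped_reads = 5e5,
                        read_length = 75)
  got <- normalize_coverage(tr2, "RPGC", genome_size = 2e6)$values
  expect_equal(mean(got), mean(v) * 2e6 / (5e5 * 75))

  bad <- coverage_track("c", v, bin_size = 25, total_mapped_reads = 0)
  expect_error(normalize_coverage(bad, "RPKM"), "positive")
})

test_that("call_peaks finds nothing on a flat track", {
  set.seed(11)
  tr <- coverage_track("c", rpois(4000, 5), bin_size = 25)
  expect_equal(nrow(call_peaks(tr, "narrow", alpha = 0.05)), 0)
})

test_that("the peak-caller false-positive rate on pure noise stays below 2 alpha", {
  set.seed(2024)
  alpha <- 0.05
  any_peak <- vapply(1:100, function(i) {
    tr <- coverage_track("c", rpois(2000, 5), bin_size = 25)
    nrow(call_peaks(tr, "narrow", alpha = alpha)) > 0
  }, logical(1))
  expect_lte(mean(any_peak), 2 * alpha)
})

test_that("call_peaks recovers a single enriched block, per the Poisson-tail oracle", {
  # deterministic track: background exactly at its rate, one 10x 500 bp block
  v <- rep(5, 4000)
  v[2001:2020] <- 50
  tr <- coverage_track("c", v, bin_size = 25)
  peaks <- call_peaks(tr, "narrow", alpha = 0.05)
  expect_equal(nrow(peaks), 1)
  expect_lte(peaks$start, 2000 * 25)
  expect_gte(peaks$end, 2020 * 25)

  # independent oracle: recompute the per-bin Poisson tail and BH decision
  lam_g <- mean(v)
  w <- 401
  half <- (w - 1) %/% 2
  loc <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - half):min(length(v), i + half)])
  }, numeric(1))
  p <- ppois(v - 1, pmax(lam_g, loc), lower.tail = FALSE)
  sig <- which(p.adjust(p, "BH") <= 0.05 & v > pmax(lam_g, loc))
  expect_equal(sig, 2001:2020)
  expect_equal(peaks$start, (min(sig) - 1) * 25)
  expect_equal(peaks$end, max(sig) * 25)
  expect_equal(peaks$summit, (2001 - 0.5) * 25)  # first max-signal bin
  expect_equal(peaks$signal, mean(v[2001:2020]) - lam_g)
})

test_that("block separation controls peak merging, per the brute-force merge oracle", {
  base <- rep(5, 6000)
  mk <- function(gap_bins) {
    v <- base
    v[1001:1020] <- 60
    v[(1021 + gap_bins):(1040 + gap_bins)] <- 60
    coverage_track("c", v, bin_size = 25)
  }
  expect_equal(nrow(call_peaks(mk(1), "narrow")), 1)  # within merge gap
  expect_equal(nrow(call_peaks(mk(5), "narrow")), 2)  # beyond merge gap
})

test_that("replicate consistency and H3K27ac gating filter elements", {
  p <- function(s, e, area = 10) {
    data.frame(chrom = "c", start = s, end = e, name = "p", score = 1,
               strand = ".", summit = (s + e) / 2, signal = 1, area = area,
               replicate_id = 1)
  }
  k27 <- data.frame(chrom = "c", start = 0, end = 1000, area = 5)

  # in both replicates, K27ac underneath -> union span
  els <- consistent_elements(p(100, 200, 10), p(150, 250, 30), k27)
  expect_equal(nrow(els), 1)
  expect_equal(els$start, 100)
  expect_equal(els$end, 250)
  expect_equal(els$signal, (10 + 30) / 2)

  # replicate-1 only -> excluded
  expect_equal(nrow(consistent_elements(p(100, 200), p(500, 600), k27)), 0)

  # no H3K27ac overlap -> excluded
  far_k27 <- data.frame(chrom = "c", start = 5000, end = 6000, area = 5)
  expect_equal(nrow(consistent_elements(p(100, 200), p(150, 250), far_k27)), 0)
})

test_that("GAS motif scanning matches the canonical and non-canonical forms", {
  hits <- scan_gas_motifs("TTCAAAGAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "canonical")
  expect_equal(hits$start, 0)

  hits <- scan_gas_motifs("TTCAAAAGAA", offset = 500)
  expect_equal(hits$kind, "non_canonical")
  expect_equal(hits$start, 500)
  expect_equal(hits$end, 510)

  expect_equal(nrow(scan_gas_motifs("ACGTACGT")), 0)
  expect_equal(nrow(scan_gas_motifs("TTCNNNGAA")), 0)  # N never matches

  # overlapping occurrences are all reported
  hits <- scan_gas_motifs("TTCTTCGAAGAA")
  expect_equal(nrow(hits), 2)
})

test_that("motif scanning is symmetric under reverse complement", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(300)
    fwd <- scan_gas_motifs(s)
    rev <- scan_gas_motifs(reverse_complement(s))
    mapped <- data.frame(start = 300 - rev$end, end = 300 - rev$start,
                         kind = rev$kind)
    mapped <- mapped[order(mapped$start, mapped$kind), ]
    rownames(mapped) <- NULL
    expect_equal(fwd[, c("start", "end", "kind")], mapped)
  }
})

test_that("promoter methylation averages CpGs in the TSS window", {
  gene <- list(chrom = "c", tss = 1000)
  cpg <- data.frame(chrom = "c", pos = c(850, 950, 1100), beta = c(1, 1, 1))
  expect_equal(promoter_methylation(cpg, gene), 1)

  cpg$beta <- c(0.2, 0.4, 0.9)
  expect_equal(promoter_methylation(cpg, gene), 0.5)

  # window is half-open on the right and excludes outside CpGs
  cpg2 <- data.frame(chrom = "c", pos = c(799, 1200), beta = c(1, 1))
  expect_true(is.na(promoter_methylation(cpg2, gene)))
  expect_equal(promoter_methylation(
    data.frame(chrom = "c", pos = 800, beta = 0.3), gene), 0.3)
  expect_error(promoter_methylation(cpg, gene, window = 401), "even")
})
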