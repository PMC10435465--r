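# The generator defaults encode the study conditions: a ~330 kbp locus core
# with 8 genes, 20 STAT5-bound truth elements including a 4-module 10 kbp
# super-enhancer, 12 elements with GAS motifs, and stage/genotype effects.

test_that("the default layout encodes the locus structure", {
  layout <- build_locus_layout(seed = 1)
  expect_equal(nrow(layout$truth$elements), 20)
  se <- layout$truth$se_span
  expect_equal(se$end - se$start, 10000)
  expect_equal(nrow(layout$truth$se_modules), 4)
  expect_equal(sum(layout$truth$elements$gas_canonical > 0 |
                     layout$truth$elements$gas_noncanonical > 0), 12)
  # gene run core spans ~330 kbp within a 400 kbp chromosome
  g <- layout$genes[layout$genes$chrom == "chr5" &
                      !(layout$genes$name %in% c("FillerL", "FillerR")), ]
  expect_lt(max(g$end) - min(g$start), 330000 * 1.1)
  expect_gt(max(g$end) - min(g$start), 330000 * 0.7)
  expect_equal(nrow(layout$ctcf), 4)
})

test_that("embedded GAS motifs are exactly the motifs a genome scan finds", {
  layout <- build_locus_layout(seed = 2)
  truth <- layout$truth$motifs
  for (ch in unique(truth$chrom)) {
    found <- scan_gas_motifs(layout$sequences[[ch]])
    want <- truth[truth$chrom == ch, c("start", "end", "kind")]
    want <- want[order(want$start, want$kind), ]
    rownames(want) <- NULL
    expect_equal(found[, c("start", "end", "kind")], want)
  }
  # chromosomes without configured motifs are scrubbed clean
  expect_equal(nrow(scan_gas_motifs(layout$sequences[["chr9"]])), 0)
})

test_that("a zero-element configuration still yields a valid layout", {
  layout <- build_locus_layout(seed = 1, elements = locus_elements()[0, ])
  expect_equal(nrow(layout$truth$elements), 0)
  expect_null(layout$truth$se_span)
  expect_equal(nrow(scan_gas_motifs(layout$sequences[["chr5"]])), 0)
  tr <- simulate_chip_coverage(layout, "STAT5", 1, seed = 1)
  expect_true(all(tr$values >= 0))
})

test_that("the generator is deterministic under a fixed seed", {
  l1 <- build_locus_layout(seed = 7)
  l2 <- build_locus_layout(seed = 7)
  expect_identical(l1$sequences, l2$sequences)
  expect_identical(simulate_chip_coverage(l1, "STAT5", 1, seed = 3)$values,
                   simulate_chip_coverage(l2, "STAT5", 1, seed = 3)$values)
  s1 <- simulate_counts("dSE-p18", seed = 5)
  s2 <- simulate_counts("dSE-p18", seed = 5)
  expect_identical(s1$counts, s2$counts)
  # replicates draw independent noise
  expect_false(identical(simulate_chip_coverage(l1, "STAT5", 1, seed = 3)$values,
                         simulate_chip_coverage(l1, "STAT5", 2, seed = 3)$values))
})

test_that("expected means follow stage factors and genotype effects", {
  cfg <- scenario_config("Csn1s1-dE1")  # no perturbed genes
  mu_wt <- locusarch:::expected_means(cfg, "WT", "mammary", "L1")
  mu_mut <- locusarch:::expected_means(cfg, "Csn1s1-dE1", "mammary", "L1")
  expect_identical(mu_wt, mu_mut)

  cfg0 <- scenario_config("default")
  mu_v <- locusarch:::expected_means(cfg0, "WT", "mammary", "virgin")
  mu_10 <- locusarch:::expected_means(cfg0, "WT", "mammary", "L10")
  induction <- mu_10[casein_genes()] / mu_v[casein_genes()]
  expect_true(all(induction >= 1e4 & induction <= 1e5))  # 4-5 orders
  # salivary casein expression is 4-5 orders below mammary L1
  mu_sal <- locusarch:::expected_means(cfg0, "WT", "salivary", "adult")
  mu_l1 <- locusarch:::expected_means(cfg0, "WT", "mammary", "L1")
  expect_true(all(mu_l1[casein_genes()] / mu_sal[casein_genes()] > 1e4))
})

test_that("counts approach Poisson noise as dispersion vanishes", {
  cfg <- scenario_config("default", dispersion = 1e-6, depth_sdlog = 0)
  cfg$groups <- data.frame(genotype = "WT", tissue = "mammary", stage = "L1",
                           n = 400, stringsAsFactors = FALSE)
  sim <- simulate_counts(cfg, seed = 1)
  ratio <- var(sim$counts["Bg001", ]) / mean(sim$counts["Bg001", ])
  expect_lt(abs(ratio - 1), 0.25)
  # and with the default dispersion the variance is clearly super-Poisson
  cfg2 <- scenario_config("default", depth_sdlog = 0)
  cfg2$groups <- cfg$groups
  sim2 <- simulate_counts(cfg2, seed = 1)
  ratio2 <- var(sim2$counts["Bg001", ]) / mean(sim2$counts["Bg001", ])
  expect_gt(ratio2, 100)  # ~ 1 + mu * 0.05
})

test_that("methylation emulates promoter activity states", {
  layout <- build_locus_layout(seed = 1)
  meth <- simulate_methylation(layout, seed = 1)
  expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  mam <- meth[meth$tissue == "mammary", ]
  liv <- meth[meth$tissue == "liver", ]
  gene <- function(n) layout$genes[layout$genes$name == n, ]
  expect_gte(promoter_methylation(mam, gene("Fdcsp")), 0.9)
  expect_lte(promoter_methylation(mam, gene("Csn2")), 0.2)
  expect_gte(promoter_methylation(liv, gene("Csn2")), 0.7)
})

test_that("qPCR Ct values follow the closed form and ddct recovers effects", {
  cfg <- scenario_config("Csn2-dP", qpcr_noise_sd = 0)
  ct <- simulate_qpcr(cfg, seed = 1)
  mu <- locusarch:::expected_means(cfg, "WT", "mammary", "L1")
  wt_csn2 <- ct$ct[ct$genotype == "WT" & ct$gene == "Csn2"][1]
  expect_equal(wt_csn2, 38 - log2(mu[["Csn2"]] + 1))
  # effect 0.2 -> ddCt ~ log2(5), relative ~ 0.2
  rel <- ddct(ct, "Csn2", calibrator = "WT")
  mut <- rel$rel_expr[rel$genotype != "WT"]
  expect_equal(unname(mut), rep(0.2, length(mut)), tolerance = 1e-5)
  # Gapdh is constant across genotypes in expectation
  gap <- ct$ct[ct$gene == "Gapdh"]
  expect_equal(max(gap) - min(gap), 0)
})
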