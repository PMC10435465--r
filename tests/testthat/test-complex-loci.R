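mk_genes <- function(n, chrom = "c1", coding = rep(TRUE, n), gap = 2000,
                     width = 3000) {
  ends <- cumsum(rep(width + gap, n))
  starts <- ends - width
  data.frame(chrom = chrom, start = starts, end = ends, strand = "+",
             gene_id = paste0("g", 1:n), name = paste0("g", 1:n),
             biotype = ifelse(coding, "protein_coding", "other"),
             tss = starts, stringsAsFactors = FALSE)
}
no_domains <- function(span = 1e6) data.frame(chrom = "c1", start = 0, end = span)
no_elements <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          signal = numeric())

test_that("induction flags require fold > 2 (strict) and padj < 0.05 in some contrast", {
  genes <- mk_genes(4, coding = c(TRUE, TRUE, TRUE, FALSE))
  de <- function(fold, padj) {
    data.frame(gene = genes$name, fold = fold, padj = padj, tested = TRUE)
  }
  flags <- select_induced_genes(
    list(p6_L1 = de(c(4, 2, 10, 50), c(0.01, 0.01, 0.06, 0.001)),
         p6_L10 = de(c(1, 1, 10, 50), c(0.9, 0.9, 0.06, 0.001))), genes)
  expect_true(flags[["g1"]])    # fold 4, padj 0.01
  expect_false(flags[["g2"]])   # fold exactly 2 is not "more than two-fold"
  expect_false(flags[["g3"]])   # padj 0.06 in both contrasts
  expect_false(flags[["g4"]])   # non-coding genes are never flagged
  expect_error(select_induced_genes(list(only = de(1, 1)), genes), "contrasts")
})

test_that("gene stitching builds maximal flagged coding runs, skipping non-coding genes", {
  genes <- mk_genes(3)
  fl <- stats::setNames(c(TRUE, TRUE, TRUE), genes$name)
  loci <- stitch_genes(genes, fl)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$members, c("g1", "g2", "g3"))
  expect_equal(loci[[1]]$start, genes$start[1])
  expect_equal(loci[[1]]$end, genes$end[3])

  # an unflagged coding gene severs the run
  fl2 <- stats::setNames(c(TRUE, FALSE, TRUE), genes$name)
  loci2 <- stitch_genes(genes, fl2)
  expect_length(loci2, 2)
  expect_equal(lapply(loci2, `[[`, "members"), list("g1", "g3"))

  # a non-coding gene between flagged genes is invisible
  genes3 <- mk_genes(3, coding = c(TRUE, FALSE, TRUE))
  fl3 <- stats::setNames(c(TRUE, FALSE, TRUE), genes3$name)
  loci3 <- stitch_genes(genes3, fl3)
  expect_length(loci3, 1)
  expect_equal(loci3[[1]]$members, c("g1", "g3"))
})

test_that("domain borders discard, split and shrink loci per the four rules", {
  genes <- mk_genes(5)
  fl <- stats::setNames(rep(TRUE, 5), genes$name)
  loci <- stitch_genes(genes, fl)

  # no interior border: unchanged
  out <- apply_domain_constraints(loci, no_domains(), genes)
  expect_length(out, 1)
  expect_equal(out[[1]]$members, genes$name)

  # border between gene 3 and gene 4: keep only the 3-gene fragment, shrunk
  b <- genes$end[3] + 1000
  doms <- data.frame(chrom = "c1", start = c(0, b), end = c(b, 1e6))
  out2 <- apply_domain_constraints(loci, doms, genes)
  expect_length(out2, 1)
  expect_equal(out2[[1]]$members, c("g1", "g2", "g3"))
  expect_equal(out2[[1]]$end, genes$end[3])

  # a 2-gene locus overlapping a border is discarded
  genes2 <- mk_genes(2)
  loci2 <- stitch_genes(genes2, stats::setNames(c(TRUE, TRUE), genes2$name))
  b2 <- genes2$end[1] + 500
  doms2 <- data.frame(chrom = "c1", start = c(0, b2), end = c(b2, 1e6))
  expect_length(apply_domain_constraints(loci2, doms2, genes2), 0)

  # a gene straddling a border is dropped during splitting
  genes7 <- mk_genes(7)
  loci7 <- stitch_genes(genes7, stats::setNames(rep(TRUE, 7), genes7$name))
  b3 <- genes7$start[4] + 100  # inside gene 4
  doms3 <- data.frame(chrom = "c1", start = c(0, b3), end = c(b3, 1e6))
  out3 <- apply_domain_constraints(loci7, doms3, genes7)
  expect_length(out3, 2)
  expect_equal(lapply(out3, `[[`, "members"),
               list(c("g1", "g2", "g3"), c("g5", "g6", "g7")))
})

test_that("loci extend over adjacent intergenic TF sites and retract at borders", {
  genes <- mk_genes(5)  # locus genes g2..g4, neighbors g1 and g5
  fl <- stats::setNames(c(FALSE, TRUE, TRUE, TRUE, FALSE), genes$name)
  loci <- stitch_genes(genes, fl)
  el <- function(s) data.frame(chrom = "c1", start = s, end = s + 200,
                               name = paste0("e", s), signal = 1)

  # element inside the upstream intergenic gap moves the locus start
  e_in <- el(genes$start[2] - 1000)
  out <- extend_with_tf_sites(loci, e_in, genes, no_domains())
  expect_equal(out[[1]]$start, genes$start[2] - 1000)
  expect_equal(nrow(out[[1]]$sites), 1)

  # element beyond the neighboring coding gene is not incorporated
  e_far <- el(genes$start[1] - 1000)
  out2 <- extend_with_tf_sites(loci, e_far, genes, no_domains())
  expect_equal(out2[[1]]$start, genes$start[2])
  expect_equal(nrow(out2[[1]]$sites), 0)

  # extension crossing a border retracts to the last element before it
  e2 <- rbind(el(genes$start[2] - 1900), el(genes$start[2] - 700))
  b <- genes$start[2] - 1000
  doms <- data.frame(chrom = "c1", start = c(0, b), end = c(b, 1e6))
  out3 <- extend_with_tf_sites(loci, e2, genes, doms)
  expect_equal(out3[[1]]$start, genes$start[2] - 700)
  expect_equal(nrow(out3[[1]]$sites), 1)
})

test_that("finalization keeps only loci with at least three genes", {
  genes <- mk_genes(5)
  l2 <- new_locus_for_test(genes, c("g1", "g2"))
  l3 <- new_locus_for_test(genes, c("g3", "g4", "g5"))
  out <- finalize_loci(list(l2, l3))
  expect_length(out, 1)
  expect_equal(out[[1]]$members, c("g3", "g4", "g5"))
})

test_that("the pipeline matches a brute-force reference on randomized genomes", {
  for (seed in 1:200) {
    gnm <- random_genome(seed)
    got <- stitch_genes(gnm$genes, gnm$flags)
    got <- apply_domain_constraints(got, gnm$domains, gnm$genes)
    got <- extend_with_tf_sites(got, gnm$elements, gnm$genes, gnm$domains)
    got <- finalize_loci(got)
    want <- ref_complex_loci(gnm$genes, gnm$flags, gnm$domains, gnm$elements)
    expect_equal(loci_signature(got), loci_signature(want),
                 info = paste("seed", seed))
  }
})

test_that("no output locus strictly contains a domain border; pipeline is idempotent", {
  run <- function(gnm) {
    loci <- stitch_genes(gnm$genes, gnm$flags)
    loci <- apply_domain_constraints(loci, gnm$domains, gnm$genes)
    loci <- extend_with_tf_sites(loci, gnm$elements, gnm$genes, gnm$domains)
    finalize_loci(loci)
  }
  for (seed in 201:260) {
    gnm <- random_genome(seed)
    out <- run(gnm)
    borders <- sort(unique(c(gnm$domains$start, gnm$domains$end)))
    for (l in out) {
      expect_false(any(borders > l$start & borders < l$end),
                   label = paste("border inside locus, seed", seed))
    }
    # idempotence: re-validating and re-finalizing the output changes nothing
    again <- finalize_loci(apply_domain_constraints(out, gnm$domains, gnm$genes))
    expect_equal(loci_signature(again),
                 loci_signature(finalize_loci(out)), info = paste("seed", seed))
  }
})

test_that("removing a border never decreases the number of surviving loci", {
  run_n <- function(gnm) {
    loci <- stitch_genes(gnm$genes, gnm$flags)
    loci <- apply_domain_constraints(loci, gnm$domains, gnm$genes)
    length(finalize_loci(loci))
  }
  for (seed in 301:360) {
    gnm <- random_genome(seed)
    if (nrow(gnm$domains) < 2) next
    n_full <- run_n(gnm)
    # drop one interior border by merging two adjacent domains
    k <- sample(nrow(gnm$domains) - 1, 1)
    merged <- gnm$domains
    merged$end[k] <- merged$end[k + 1]
    merged <- merged[-(k + 1), ]
    gnm2 <- gnm
    gnm2$domains <- merged
    expect_gte(run_n(gnm2), n_full)
  }
})
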