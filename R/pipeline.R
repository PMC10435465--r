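# End-to-end orchestration: simulate -> call elements -> super-enhancers ->
# complex loci -> differential expression, with a machine-readable report and
# truth comparison for recovery testing.

#' Match predicted intervals to truth intervals
#'
#' One-to-one greedy matching (largest overlap first) of pairs whose
#' reciprocal overlap is at least `min_frac` of both interval widths.
#'
#' @param pred,truth interval tables.
#' @param min_frac minimum reciprocal overlap fraction.
#' @return list with `matches` (data.frame of pred/truth row indices),
#'   `precision` (`NA` when there are no predictions) and `recall`.
#' @export
match_intervals <- function(pred, truth, min_frac = 0.5) {
  pairs <- overlap_pairs(pred, truth)
  if (nrow(pairs)) {
    ow <- overlap_width(pred$start[pairs$a], pred$end[pairs$a],
                        truth$start[pairs$b], truth$end[pairs$b])
    keep <- ow >= min_frac * (pred$end[pairs$a] - pred$start[pairs$a]) &
      ow >= min_frac * (truth$end[pairs$b] - truth$start[pairs$b])
    pairs <- pairs[keep, , drop = FALSE]
    ow <- ow[keep]
    pairs <- pairs[order(-ow), , drop = FALSE]
  }
  used_a <- logical(nrow(pred))
  used_b <- logical(nrow(truth))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!used_a[pairs$a[k]] && !used_b[pairs$b[k]]) {
      keep[k] <- TRUE
      used_a[pairs$a[k]] <- TRUE
      used_b[pairs$b[k]] <- TRUE
    }
  }
  matches <- pairs[keep, , drop = FALSE]
  list(matches = matches,
       precision = if (nrow(pred)) nrow(matches) / nrow(pred) else NA_real_,
       recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_)
}

#' Estimate deletion effects for a packaged scenario
#'
#' For each seed: simulate the scenario's WT and mutant count matrices, run
#' [differential_expression()] (mutant over WT) and extract percent
#' reductions and linear fold changes.
#'
#' @param scenario scenario name (not `"default"`).
#' @param seeds integer vector of seeds.
#' @param genes genes to report; defaults to the scenario's perturbed genes,
#'   or all locus genes when the scenario perturbs none.
#' @return data.frame with `seed`, `gene`, `reduction` (percent), `fold`.
#' @export
estimate_genotype_effects <- function(scenario, seeds = 1:10, genes = NULL) {
  config <- scenario_config(scenario)
  if (identical(config$name, "default")) {
    stop("use a deletion scenario, not 'default'", call. = FALSE)
  }
  mutant <- setdiff(config$groups$genotype, "WT")
  if (is.null(genes)) {
    genes <- names(config$effects[[mutant]])
    if (!length(genes)) genes <- c(casein_genes(), "Odam", "Fdcsp")
  }
  rows <- lapply(seeds, function(s) {
    sim <- simulate_counts(config, seed = s)
    wt <- sim$samples$sample[sim$samples$genotype == "WT"]
    mut <- sim$samples$sample[sim$samples$genotype == mutant]
    de <- differential_expression(sim$counts, wt, mut)
    i <- match(genes, de$gene)
    data.frame(seed = s, gene = genes, reduction = 100 * (1 - de$fold[i]),
               fold = de$fold[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

loci_to_intervals <- function(loci) {
  if (!length(loci)) return(empty_intervals())
  data.frame(chrom = vapply(loci, `[[`, character(1), "chrom"),
             start = vapply(loci, `[[`, numeric(1), "start"),
             end = vapply(loci, `[[`, numeric(1), "end"),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on a packaged scenario
#'
#' Simulates the scenario to `outdir`, reads the files back through the
#' package's own readers, then: calls peaks on both STAT5 replicates and
#' broad H3K27ac peaks, derives replicate-consistent H3K27ac-supported
#' elements with GAS-motif annotation, stitches and classifies
#' super-enhancers, identifies complex loci from the p6-to-L1 and p6-to-L10
#' contrasts, summarizes promoter methylation, estimates the casein share of
#' the L1 library, and (for the default scenario) estimates percent
#' reductions for every packaged deletion genotype at this seed. A JSON
#' report and a manifest with file checksums are written; re-running with the
#' same seed reproduces identical checksums.
#'
#' @param outdir output directory.
#' @param seed integer seed for every stage.
#' @param scenario scenario name; the structural stages run on `"default"`.
#' @param alpha peak-calling alpha.
#' @return invisibly, the report list (also at `outdir/report.json`).
#' @export
run_all <- function(outdir, seed = 1, scenario = "default", alpha = 0.05) {
  simres <- simulate_scenario(scenario, outdir, seed)
  report <- list(scenario = scenario, seed = seed,
                 package_version = as.character(utils::packageVersion("locusarch")))

  if (identical(scenario, "default")) {
    genes <- read_gff3_genes(file.path(outdir, "genes.gff3"))
    seqs <- read_fasta(file.path(outdir, "genome.fa"))
    domains <- read_bed6(file.path(outdir, "domains.bed"))
    tracks <- lapply(c(stat5_rep1 = "stat5_rep1.bedgraph",
                       stat5_rep2 = "stat5_rep2.bedgraph",
                       h3k27ac_rep1 = "h3k27ac_rep1.bedgraph",
                       h3k27ac_rep2 = "h3k27ac_rep2.bedgraph"),
                     function(f) read_coverage_bedgraph(file.path(outdir, f)))
    called <- call_elements(tracks$stat5_rep1, tracks$stat5_rep2,
                            tracks$h3k27ac_rep1, tracks$h3k27ac_rep2,
                            alpha = alpha, sequences = seqs)
    elements <- called$elements
    write_bed6(cbind(elements[c("chrom", "start", "end", "name")],
                     score = round(elements$signal, 1)),
               file.path(outdir, "elements_called.bed"))
    if (!is.null(called$motif_hits)) {
      write_tsv_table(called$motif_hits, file.path(outdir, "motif_hits.tsv"))
    }

    se <- classify_superenhancers(stitch_elements(elements, genes))
    se_tab <- se$table[, c("chrom", "start", "end", "name", "n_constituents",
                           "total_signal", "rank", "is_se")]
    write_tsv_table(se_tab, file.path(outdir, "superenhancers.tsv"))

    counts <- simres$sim$counts
    samp <- simres$sim$samples
    pick <- function(stage) samp$sample[samp$stage == stage]
    de_l1 <- differential_expression(counts, pick("p6"), pick("L1"))
    de_l10 <- differential_expression(counts, pick("p6"), pick("L10"))
    loci <- find_complex_loci(genes, list(p6_L1 = de_l1, p6_L10 = de_l10),
                              elements, domains)
    write_tsv_table(loci$table, file.path(outdir, "complex_loci.tsv"))

    meth <- read_tsv_table(file.path(outdir, "methylation.tsv"))
    meth_tab <- do.call(rbind, lapply(c("mammary", "liver"), function(tissue) {
      mm <- meth[meth$tissue == tissue, , drop = FALSE]
      data.frame(gene = genes$name, tissue = tissue,
                 mean_beta = vapply(seq_len(nrow(genes)), function(i) {
                   promoter_methylation(mm, genes[i, ])
                 }, numeric(1)), stringsAsFactors = FALSE)
    }))
    write_tsv_table(meth_tab, file.path(outdir, "promoter_methylation.tsv"))

    frac <- mrna_fraction(counts, casein_genes(), pick("L1"))

    reductions <- lapply(names(scenario_specs()), function(sc) {
      eff <- estimate_genotype_effects(sc, seeds = derive_seed(seed, 17))
      stats::setNames(lapply(seq_len(nrow(eff)), function(i)
        list(reduction = eff$reduction[i], fold = eff$fold[i])), eff$gene)
    })
    names(reductions) <- names(scenario_specs())

    report$n_elements <- nrow(elements)
    report$elements <- elements
    report$superenhancers <- se_tab
    report$complex_loci <- loci$table
    report$locus_members <- lapply(loci$loci, `[[`, "members")
    report$promoter_methylation <- meth_tab
    report$casein_fraction_L1 <- frac$mean
    report$reductions <- reductions
  } else {
    mutant <- setdiff(scenario_config(scenario)$groups$genotype, "WT")
    eff <- estimate_genotype_effects(scenario, seeds = seed)
    report$mutant <- mutant
    report$effects <- eff
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(scenario = scenario, seed = seed,
                   package_version = report$package_version,
                   checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Score a pipeline run against the generator's truth
#'
#' @param report a [run_all()] report (default-scenario run).
#' @param truth the `truth` component of a [build_locus_layout()] result.
#' @param min_frac reciprocal-overlap fraction for element matching.
#' @return list with element `precision`/`recall`, `se_recovered` (top-ranked
#'   region is classified SE and matches the truth SE span) and
#'   `loci_recovered` (every truth member list equals some output locus).
#' @export
compare_to_truth <- function(report, truth, min_frac = 0.5) {
  if (is.null(truth)) stop("missing truth manifest", call. = FALSE)
  elm <- match_intervals(report$elements, truth$elements, min_frac)
  se_tab <- report$superenhancers
  se_ok <- FALSE
  if (!is.null(truth$se_span) && nrow(se_tab)) {
    top <- se_tab[which.max(se_tab$rank), , drop = FALSE]
    ow <- overlap_width(top$start, top$end, truth$se_span$start,
                        truth$se_span$end)
    se_ok <- isTRUE(top$is_se) && top$chrom == truth$se_span$chrom &&
      ow >= min_frac * (top$end - top$start) &&
      ow >= min_frac * (truth$se_span$end - truth$se_span$start)
  }
  loci_ok <- all(vapply(truth$loci, function(members) {
    any(vapply(report$locus_members, function(m)
      identical(sort(unlist(m)), sort(members)), logical(1)))
  }, logical(1)))
  list(element_precision = elm$precision, element_recall = elm$recall,
       element_matches = nrow(elm$matches), se_recovered = se_ok,
       loci_recovered = loci_ok)
}
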