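# Synthetic-locus generator: layout + sequence with embedded GAS motifs,
# replicate ChIP coverage, NB counts, methylation and qPCR Ct tables.
# Everything is deterministic given (scenario, seed).

derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 97 + offset) %% 2147483629)
}

gas_instance <- function(kind) {
  switch(kind, canonical = "TTCTTGGAA", non_canonical = "TTCTAGCGAA",
         stop("unknown GAS kind ", kind))
}

# Truth motif coordinates derived from the element table: canonical copies at
# center-30, center-70, ...; one non-canonical copy at center+15.
truth_motifs <- function(elements) {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    center <- floor((el$start + el$end) / 2)
    if (el$gas_canonical > 0) {
      for (k in seq_len(el$gas_canonical)) {
        s <- center - 30 - 40 * (k - 1)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = el$chrom, start = s, end = s + 9, kind = "canonical",
          element = el$name, stringsAsFactors = FALSE)
      }
    }
    if (el$gas_noncanonical > 0) {
      for (k in seq_len(el$gas_noncanonical)) {
        s <- center + 15 + 40 * (k - 1)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = el$chrom, start = s, end = s + 10, kind = "non_canonical",
          element = el$name, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      kind = character(), element = character()))
  }
  sort_intervals(do.call(rbind, rows))
}

# Remove every GAS occurrence from a sequence except the protected truth
# windows, by mutating one fixed letter (TTC/GAA) of each stray hit.
scrub_gas <- function(seqstr, keep) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  keep_key <- if (nrow(keep)) paste(keep$start, keep$end) else character(0)
  keep_pos <- if (nrow(keep)) {
    unlist(lapply(seq_len(nrow(keep)), function(i) (keep$start[i]):(keep$end[i] - 1)))
  } else integer(0)
  for (iter in 1:60) {
    s <- paste(chars, collapse = "")
    hits <- scan_gas_motifs(s)
    if (nrow(hits)) hits <- hits[!(paste(hits$start, hits$end) %in% keep_key), ]
    if (!nrow(hits)) return(s)
    for (i in seq_len(nrow(hits))) {
      len <- hits$end[i] - hits$start[i]
      pos <- hits$start[i] + c(0, 1, 2, len - 3, len - 2, len - 1)
      pos <- setdiff(pos, keep_pos)
      if (!length(pos)) stop("cannot scrub GAS hit inside a protected window")
      p <- pos[1] + 1
      chars[p] <- if (chars[p] == "C") "A" else "C"
    }
  }
  stop("GAS scrubbing did not converge")
}

#' Build the synthetic locus layout
#'
#' Places the gene models, the 20 STAT5-bound truth elements (with the
#' four-module, 10 kbp super-enhancer), CTCF sites and contact domains, and
#' generates a genome sequence in which the configured GAS motifs are the
#' only GAS occurrences (the background is scrubbed of spurious matches), so
#' that the motif truth set and a genome-wide scan agree exactly.
#'
#' @param seed integer seed for the background sequence.
#' @param domain_variant passed to [locus_domains()].
#' @param elements element table; defaults to [locus_elements()]. An empty
#'   table yields a valid layout with no truth elements.
#' @return a `locus_layout` list: `genes`, `elements`, `ctcf`, `domains`,
#'   `chrom_lengths`, `sequences` (named character) and `truth` (truth
#'   elements, SE span and modules, motif table, expected complex-locus
#'   membership).
#' @export
build_locus_layout <- function(seed = 1, domain_variant = "outside",
                               elements = locus_elements()) {
  genes <- locus_genes()
  lens <- locus_chrom_lengths()
  if (nrow(elements)) {
    check_intervals(elements, "elements")
    if (any(elements$end > lens[elements$chrom])) {
      stop("elements must lie within the locus", call. = FALSE)
    }
  }
  ov <- overlap_pairs(genes, genes)
  if (any(ov$a != ov$b)) stop("gene placements overlap", call. = FALSE)

  set.seed(derive_seed(seed, 1))
  seqs <- vapply(names(lens), function(ch) {
    paste(sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE),
          collapse = "")
  }, character(1))

  motifs <- truth_motifs(elements)
  m5 <- motifs[motifs$chrom == "chr5", , drop = FALSE]
  chars <- strsplit(seqs[["chr5"]], "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(m5))) {
    inst <- strsplit(gas_instance(m5$kind[i]), "", fixed = TRUE)[[1]]
    chars[(m5$start[i] + 1):(m5$end[i])] <- inst
  }
  seqs[["chr5"]] <- scrub_gas(paste(chars, collapse = ""),
                              m5[, c("start", "end"), drop = FALSE])
  seqs[["chr9"]] <- scrub_gas(seqs[["chr9"]], empty_intervals())

  found <- scan_gas_motifs(seqs[["chr5"]])
  want <- m5[order(m5$start, m5$kind), c("start", "end", "kind")]
  got <- found[order(found$start, found$kind), c("start", "end", "kind")]
  rownames(want) <- rownames(got) <- NULL
  if (!isTRUE(all.equal(want, got))) {
    stop("embedded GAS motifs do not match a genome-wide scan", call. = FALSE)
  }

  se_modules <- elements[elements$class == "SE_module", , drop = FALSE]
  se_span <- if (nrow(se_modules)) {
    data.frame(chrom = se_modules$chrom[1], start = min(se_modules$start),
               end = max(se_modules$end), stringsAsFactors = FALSE)
  } else NULL
  locus_members <- c("Csn1s1", "Csn2", "Csn1s2a", "Csn1s2b", "Odam",
                     "Fdcsp", "Prr27", "Csn3")
  truth_loci <- if (domain_variant == "outside") list(locus_members) else {
    list(locus_members[1:6])  # the 270 kbp border severs Prr27/Csn3
  }
  structure(list(genes = genes, elements = elements, ctcf = locus_ctcf_sites(),
                 domains = locus_domains(domain_variant), chrom_lengths = lens,
                 sequences = seqs,
                 truth = list(elements = elements, se_span = se_span,
                              se_modules = se_modules, motifs = motifs,
                              loci = truth_loci)),
            class = "locus_layout")
}

#' Simulate binned ChIP-seq coverage
#'
#' Background bins are Poisson(`lambda_bg`); element bins are Poisson with a
#' multiplicatively enriched rate. STAT5 enrichment is punctate (triangular
#' across each element, apex 15x for SE modules, 12x for local enhancers,
#' 10x for promoter elements); H3K27ac enrichment is broad (6x plateaus over
#' each element extended by 1 kbp, with 500 bp shoulders, and one continuous
#' plateau across the super-enhancer). Replicates share the expected profile
#' and draw independent noise.
#'
#' @param layout a [build_locus_layout()] result.
#' @param mark `"STAT5"` or `"H3K27ac"`.
#' @param replicate_id replicate number (1, 2, ...).
#' @param seed scenario seed; the replicate/mark stream is derived from it.
#' @param bin_size bin width in bp.
#' @param lambda_bg background Poisson rate per bin.
#' @param enrichment_scale scales enrichment above background; 0 gives a
#'   pure-noise null track.
#' @param chrom chromosome to simulate.
#' @return a [coverage_track()].
#' @export
simulate_chip_coverage <- function(layout, mark = c("STAT5", "H3K27ac"),
                                   replicate_id = 1, seed = 1, bin_size = 25,
                                   lambda_bg = 5, enrichment_scale = 1,
                                   chrom = "chr5") {
  mark <- match.arg(mark)
  len <- layout$chrom_lengths[[chrom]]
  n <- ceiling(len / bin_size)
  centers <- (seq_len(n) - 0.5) * bin_size
  prof <- rep(1, n)
  els <- layout$elements[layout$elements$chrom == chrom, , drop = FALSE]
  amps <- c(SE_module = 15, local_enhancer = 12, promoter_element = 10)
  if (nrow(els)) {
    if (mark == "STAT5") {
      for (i in seq_len(nrow(els))) {
        amp <- amps[[els$class[i]]]
        mid <- (els$start[i] + els$end[i]) / 2
        half <- (els$end[i] - els$start[i]) / 2
        tri <- pmax(0, 1 - abs(centers - mid) / half)
        prof <- pmax(prof, 1 + (amp - 1) * tri * enrichment_scale)
      }
    } else {
      blocks <- els[, c("start", "end"), drop = FALSE]
      se <- els[els$class == "SE_module", , drop = FALSE]
      if (nrow(se)) {
        blocks <- rbind(blocks, data.frame(start = min(se$start),
                                           end = max(se$end)))
      }
      for (i in seq_len(nrow(blocks))) {
        lo <- blocks$start[i] - 1000
        hi <- blocks$end[i] + 1000
        ramp <- pmin(1, pmax(0, pmin(centers - (lo - 500), (hi + 500) - centers) / 500))
        prof <- pmax(prof, 1 + 5 * ramp * enrichment_scale)
      }
    }
  }
  set.seed(derive_seed(seed, 100 + 1000 * match(mark, c("STAT5", "H3K27ac")) +
                         replicate_id))
  values <- rpois(n, lambda_bg * prof)
  coverage_track(chrom, values, bin_size)
}

stage_factor_col <- c(virgin = "f_virgin", p6 = "f_p6", L1 = "f_L1",
                      p18 = "f_L1", L10 = "f_L10")

# Expected normalized counts for one group (genotype/tissue/stage), before
# the per-sample depth factor.
expected_means <- function(config, genotype, tissue, stage) {
  prof <- config$profiles
  mu <- if (tissue == "salivary") prof$mu_sal else {
    col <- stage_factor_col[[stage]]
    if (is.null(col)) stop("unknown stage '", stage, "'", call. = FALSE)
    prof$mu_mam_L1 * prof[[col]]
  }
  names(mu) <- prof$gene
  eff <- config$effects[[genotype]]
  if (length(eff)) mu[names(eff)] <- mu[names(eff)] * eff
  mu
}

#' Simulate an RNA-seq count matrix for a scenario
#'
#' Counts are negative binomial with shared dispersion around the expected
#' means of the scenario's groups (gene baseline x stage factor x genotype
#' effect x per-sample depth factor).
#'
#' @param config a [scenario_config()] (or scenario name).
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer-valued matrix),
#'   `samples` (metadata data.frame) and the `config`.
#' @export
simulate_counts <- function(config, seed = 1) {
  if (is.character(config)) config <- scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  g <- config$groups
  samples <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(sample = sprintf("%s_%s_%s_r%d", gsub("[^A-Za-z0-9]", ".",
                                                     g$genotype[i]),
                                g$stage[i], g$tissue[i], seq_len(g$n[i])),
               genotype = g$genotype[i], tissue = g$tissue[i],
               stage = g$stage[i], replicate = seq_len(g$n[i]),
               stringsAsFactors = FALSE)
  }))
  mu <- vapply(seq_len(nrow(samples)), function(j) {
    expected_means(config, samples$genotype[j], samples$tissue[j],
                   samples$stage[j])
  }, numeric(nrow(config$profiles)))
  set.seed(derive_seed(seed, 7))
  depth <- exp(rnorm(nrow(samples), 0, config$depth_sdlog))
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    rnbinom(nrow(mu), mu = mu[, j] * depth[j], size = 1 / config$dispersion)
  }, numeric(nrow(mu)))
  dimnames(counts) <- list(config$profiles$gene, samples$sample)
  list(counts = counts, samples = samples, config = config)
}

#' Simulate a CpG methylation table
#'
#' CpG sites are laid on a fixed grid across each gene's promoter window
#' (400 bp around the TSS); per-site beta values are Beta-distributed around
#' tissue-specific promoter states: active mammary promoters are
#' hypomethylated, the Fdcsp promoter is fully methylated in mammary tissue,
#' and the casein promoters are highly methylated in liver.
#'
#' @param layout a [build_locus_layout()] result.
#' @param seed integer seed.
#' @param n_cpg CpGs per promoter window.
#' @param concentration Beta concentration (larger = tighter around the mean).
#' @return data.frame with `chrom`, `pos`, `tissue`, `gene`, `beta`.
#' @export
simulate_methylation <- function(layout, seed = 1, n_cpg = 12,
                                 concentration = 60) {
  genes <- layout$genes
  target <- function(gene, spec, tissue) {
    if (tissue == "mammary") {
      if (gene == "Fdcsp") 0.95
      else if (gene == "Prr27") 0.75
      else if (spec == "mammary") 0.07
      else if (spec == "dual") 0.15
      else 0.5
    } else {  # liver: the locus is inactive
      if (spec %in% c("mammary", "dual", "salivary")) 0.88 else 0.5
    }
  }
  set.seed(derive_seed(seed, 11))
  rows <- lapply(c("mammary", "liver"), function(tissue) {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      pos <- genes$tss[i] - 190 + (seq_len(n_cpg) - 1) * floor(380 / n_cpg)
      m <- target(genes$name[i], genes$specificity[i], tissue)
      data.frame(chrom = genes$chrom[i], pos = pos, tissue = tissue,
                 gene = genes$name[i],
                 beta = rbeta(n_cpg, m * concentration,
                              (1 - m) * concentration),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow `Ct = 38 - log2(mu + 1) + noise` so that a 2-fold
#' expression change is one cycle; Gapdh is a constant-expression reference
#' across genotypes.
#'
#' @param config a [scenario_config()] (or scenario name).
#' @param seed integer seed.
#' @param targets genes to assay (Gapdh is always added).
#' @return data.frame with `sample`, `genotype`, `gene`, `ct`.
#' @export
simulate_qpcr <- function(config, seed = 1,
                          targets = c(casein_genes(), "Odam", "Fdcsp")) {
  if (is.character(config)) config <- scenario_config(config)
  g <- config$groups
  set.seed(derive_seed(seed, 13))
  rows <- list()
  for (i in seq_len(nrow(g))) {
    mu <- expected_means(config, g$genotype[i], g$tissue[i], g$stage[i])
    mu <- c(mu[targets], Gapdh = 5e5)
    for (r in seq_len(g$n[i])) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = sprintf("%s_r%d", gsub("[^A-Za-z0-9]", ".", g$genotype[i]), r),
        genotype = g$genotype[i], gene = names(mu),
        ct = 38 - log2(mu + 1) + rnorm(length(mu), 0, config$qpcr_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Materialize a scenario on disk
#'
#' Writes everything a downstream run consumes: for the default scenario the
#' genome FASTA, gene GFF3, truth-element/CTCF/domain BED files, per-replicate
#' STAT5 and H3K27ac bedGraphs, the count matrix with sample metadata, the
#' methylation and Ct tables and a JSON truth manifest; for deletion
#' scenarios the counts, metadata, Ct table and truth manifest.
#'
#' @param scenario scenario name (see [list_scenarios()]) or a
#'   [scenario_config()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a list with the written `paths` and the in-memory
#'   objects (`layout`, `sim`, ...).
#' @export
simulate_scenario <- function(scenario, outdir, seed = 1) {
  config <- if (is.character(scenario)) scenario_config(scenario) else scenario
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  pth <- function(f) file.path(outdir, f)

  sim <- simulate_counts(config, seed)
  write_tsv_table(data.frame(gene = rownames(sim$counts), sim$counts,
                             check.names = FALSE), pth("counts.tsv"))
  write_tsv_table(sim$samples, pth("samples.tsv"))
  qpcr <- simulate_qpcr(config, seed)
  write_tsv_table(qpcr, pth("qpcr_ct.tsv"))
  paths <- c(paths, counts = pth("counts.tsv"), samples = pth("samples.tsv"),
             qpcr = pth("qpcr_ct.tsv"))

  truth <- list(scenario = config$name,
                effects = lapply(config$effects, as.list))
  layout <- NULL
  if (identical(config$name, "default")) {
    layout <- build_locus_layout(seed)
    write_fasta(layout$sequences, pth("genome.fa"))
    write_gff3_genes(layout$genes, pth("genes.gff3"))
    write_bed6(layout$elements, pth("elements_truth.bed"))
    write_bed6(layout$ctcf, pth("ctcf.bed"))
    write_bed6(layout$domains, pth("domains.bed"))
    for (mark in c("STAT5", "H3K27ac")) {
      for (rep_id in 1:2) {
        tr <- simulate_chip_coverage(layout, mark, rep_id, seed)
        f <- pth(sprintf("%s_rep%d.bedgraph", tolower(mark), rep_id))
        write_coverage_bedgraph(tr, f)
        paths[[sprintf("%s_rep%d", tolower(mark), rep_id)]] <- f
      }
    }
    meth <- simulate_methylation(layout, seed)
    write_tsv_table(meth, pth("methylation.tsv"))
    paths <- c(paths, genome = pth("genome.fa"), genes = pth("genes.gff3"),
               elements_truth = pth("elements_truth.bed"),
               ctcf = pth("ctcf.bed"), domains = pth("domains.bed"),
               methylation = pth("methylation.tsv"))
    truth$elements <- layout$truth$elements
    truth$se_span <- layout$truth$se_span
    truth$motifs <- layout$truth$motifs
    truth$loci <- layout$truth$loci
  }
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, truth = pth("truth.json"))
  invisible(list(paths = paths, config = config, sim = sim, qpcr = qpcr,
                 layout = layout))
}
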