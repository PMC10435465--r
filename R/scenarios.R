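# Packaged study scenarios: the locus layout, expression baselines and the
# per-genotype deletion effects the generator emulates. These defaults ARE the
# study conditions; they are data, not tuning knobs.

#' Gene models of the synthetic casein locus
#'
#' Eight named locus genes (five caseins, dual-specificity Odam, salivary
#' Fdcsp and Prr27) on a 400 kbp chromosome whose gene run spans ~330 kbp
#' core, two flanking protein-coding filler genes, one non-coding gene inside
#' the locus, plus a second chromosome carrying the Cish control gene and 200
#' constant background genes that anchor library-size normalization.
#'
#' @return data.frame of gene models (0-based half-open, with `tss` and
#'   tissue `specificity`).
#' @export
locus_genes <- function() {
  chr5 <- data.frame(
    name = c("FillerL", "Csn1s1", "Csn2", "Csn1s2a", "Gmnc1", "Csn1s2b",
             "Odam", "Fdcsp", "Prr27", "Csn3", "FillerR"),
    chrom = "chr5",
    start = c(5000, 40000, 70000, 150000, 170000, 185000,
              240000, 260000, 275000, 300000, 380000),
    end = c(15000, 55000, 78000, 165000, 175000, 200000,
            252000, 266000, 281000, 310000, 390000),
    strand = c("+", "+", "-", "+", "+", "+", "+", "-", "+", "+", "+"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "protein_coding", "other", "protein_coding", "protein_coding",
                "protein_coding", "protein_coding", "protein_coding",
                "protein_coding"),
    specificity = c("filler", "mammary", "mammary", "mammary", "filler",
                    "mammary", "dual", "salivary", "salivary", "mammary",
                    "filler"),
    stringsAsFactors = FALSE)
  nbg <- 200
  chr9 <- data.frame(
    name = c("Cish", sprintf("Bg%03d", seq_len(nbg))),
    chrom = "chr9",
    start = 5000 + (0:nbg) * 8000,
    end = 5000 + (0:nbg) * 8000 + 6000,
    strand = rep(c("+", "-"), length.out = nbg + 1),
    biotype = "protein_coding",
    specificity = "filler",
    stringsAsFactors = FALSE)
  g <- rbind(chr5, chr9)
  g$gene_id <- g$name
  g$tss <- ifelse(g$strand == "-", g$end - 1, g$start)
  sort_intervals(g)
}

#' Chromosome lengths of the synthetic genome
#' @return named numeric vector.
#' @export
locus_chrom_lengths <- function() c(chr5 = 400000, chr9 = 1700000)

#' Candidate regulatory elements of the synthetic locus
#'
#' The 20 STAT5-bound elements: the four super-enhancer modules (SE-E1..E4,
#' jointly spanning 10 kbp between Csn1s2b and Odam), gene-local enhancers and
#' STAT5-bound promoter elements. Twelve of the twenty carry GAS motifs
#' (`gas_canonical` / `gas_noncanonical` give the embedded copy numbers).
#' CTCF sites are listed separately by [locus_ctcf_sites()].
#'
#' @return data.frame of elements with class and GAS motif content.
#' @export
locus_elements <- function() {
  e <- read.table(text = "
name start end class gas_canonical gas_noncanonical
Csn1s1-E1 28350 28950 local_enhancer 0 0
Csn1s1-E2 36200 36800 local_enhancer 0 0
Csn1s1-P 39800 40100 promoter_element 1 0
Csn2-P 77850 78150 promoter_element 1 1
Csn2-E1 83700 84300 local_enhancer 1 0
Csn2-E2 102700 103300 local_enhancer 1 0
Csn2-E3 112700 113300 local_enhancer 0 0
Csn1s2a-E1 143000 143600 local_enhancer 0 0
Csn1s2a-P 149850 150150 promoter_element 1 0
Csn1s2b-E1 181000 181600 local_enhancer 1 0
Csn1s2b-P 184850 185150 promoter_element 1 0
SE-E1 215000 216200 SE_module 1 0
SE-E2 217800 219000 SE_module 1 0
SE-E3 220600 221800 SE_module 1 0
SE-E4 223800 225000 SE_module 1 0
Odam-P 239850 240150 promoter_element 0 0
Odam-E1 255000 255600 local_enhancer 0 0
Fdcsp-P 265850 266150 promoter_element 0 0
Csn3-E1 292700 293300 local_enhancer 0 0
Csn3-E2 299100 299700 local_enhancer 2 0
", header = TRUE, stringsAsFactors = FALSE)
  e$chrom <- "chr5"
  sort_intervals(e[, c("chrom", "start", "end", "name", "class",
                       "gas_canonical", "gas_noncanonical")])
}

#' CTCF sites of the synthetic locus
#'
#' Four sites: two bordering the locus and two inside the super-enhancer.
#' They carry no STAT5/H3K27ac signal and are not part of the 20-element
#' truth set.
#'
#' @return data.frame of CTCF site intervals.
#' @export
locus_ctcf_sites <- function() {
  data.frame(chrom = "chr5",
             start = c(33000, 216900, 222100, 366000),
             end = c(33200, 217100, 222300, 366200),
             name = sprintf("CTCF-%d", 1:4), class = "CTCF",
             stringsAsFactors = FALSE)
}

#' Contact domains of the synthetic genome
#'
#' @param variant `"outside"` (default): domain borders flank the locus core
#'   and no border falls inside the gene run. `"bisect"`: a border at 270 kbp
#'   splits the run between Fdcsp and Prr27, exercising the locus-splitting
#'   rules.
#' @return data.frame of ordered, non-overlapping domain intervals.
#' @export
locus_domains <- function(variant = c("outside", "bisect")) {
  variant <- match.arg(variant)
  chr5 <- if (variant == "outside") {
    data.frame(chrom = "chr5", start = c(0, 20000, 370000),
               end = c(20000, 370000, 400000))
  } else {
    data.frame(chrom = "chr5", start = c(0, 20000, 270000, 370000),
               end = c(20000, 270000, 370000, 400000))
  }
  out <- rbind(chr5, data.frame(chrom = "chr9", start = 0, end = 300000))
  out$name <- sprintf("domain_%d", seq_len(nrow(out)))
  sort_intervals(out)
}

# Expected normalized counts (WT) and mammary stage factors relative to L1.
# Caseins are induced 4-5 orders of magnitude from virgin to L10, peak L1
# casein share of the library is ~55%, and salivary expression of the caseins
# sits 4-5 orders below mammary L1. A 200-gene constant background carries
# the remaining ~45% of the library so that median-of-ratios normalization
# has a representative unchanged majority, as in genome-wide data.
expression_profiles <- function() {
  p <- read.table(text = "
gene mu_mam_L1 mu_sal f_virgin f_p6 f_L1 f_L10
Csn1s1 4.0e6 120 2e-4 1e-3 1 10
Csn2 2.5e6 75 2e-4 1e-3 1 10
Csn1s2a 1.6e6 50 2e-4 1e-3 1 10
Csn1s2b 1.4e6 45 2e-4 1e-3 1 10
Csn3 1.5e6 45 2e-4 1e-3 1 10
Odam 1.0e3 1.0e3 0.01 0.2 1 2
Fdcsp 30 5.0e5 0.15 0.15 1 1
Prr27 30 1.0e5 0.15 0.15 1 1
FillerL 1.0e4 1.0e4 1 1 1 1
FillerR 1.0e4 1.0e4 1 1 1 1
Gmnc1 50 50 1 1 1 1
Cish 5.0e4 5.0e4 0.3 0.3 1 1
", header = TRUE, stringsAsFactors = FALSE)
  bg <- data.frame(gene = sprintf("Bg%03d", 1:200), mu_mam_L1 = 4.5e4,
                   mu_sal = 4.5e4, f_virgin = 1, f_p6 = 1, f_L1 = 1,
                   f_L10 = 1, stringsAsFactors = FALSE)
  rbind(p, bg)
}

#' The five casein genes
#' @return character vector of gene names.
#' @export
casein_genes <- function() c("Csn1s1", "Csn2", "Csn1s2a", "Csn1s2b", "Csn3")

# One entry per figure-level deletion experiment. `effects` are multiplicative
# on the expected mean (a 93% reduction is effect 0.07); genes absent from
# `effects` are unchanged. Replicate numbers follow the figure legends.
scenario_specs <- function() {
  list(
    "dSE-p18" = list(tissue = "mammary", stage = "p18", wt_n = 4, mut_n = 4,
                     mutant = "dSE",
                     effects = c(Odam = 0.002, Csn3 = 0.02, Csn1s2b = 0.07,
                                 Csn1s1 = 0.5, Csn2 = 0.7, Csn1s2a = 0.6)),
    "dSE-p6" = list(tissue = "mammary", stage = "p6", wt_n = 3, mut_n = 4,
                    mutant = "dSE",
                    effects = c(Csn1s1 = 0.02, Csn2 = 0.02, Csn1s2a = 0.02,
                                Csn1s2b = 0.02, Csn3 = 0.02, Odam = 0.02)),
    "dSE-salivary" = list(tissue = "salivary", stage = "adult", wt_n = 3,
                          mut_n = 3, mutant = "dSE",
                          effects = c(Odam = 0.001, Fdcsp = 0.01, Csn3 = 0.12)),
    "dOdam" = list(tissue = "mammary", stage = "L1", wt_n = 3, mut_n = 3,
                   mutant = "dOdam", effects = c(Odam = 0, Csn3 = 2.0)),
    "Csn3-dE1" = list(tissue = "mammary", stage = "p18", wt_n = 3, mut_n = 3,
                      mutant = "Csn3-dE1", effects = c(Csn3 = 0.55)),
    "Csn3-dE2-S" = list(tissue = "mammary", stage = "p18", wt_n = 3, mut_n = 3,
                        mutant = "Csn3-dE2-S", effects = c(Csn3 = 0.02)),
    "Csn3-dE2-SN" = list(tissue = "mammary", stage = "p18", wt_n = 3,
                         mut_n = 3, mutant = "Csn3-dE2-SN",
                         effects = c(Csn3 = 0.005)),
    "Csn1s1-dE1" = list(tissue = "mammary", stage = "L1", wt_n = 5, mut_n = 5,
                        mutant = "Csn1s1-dE1", effects = numeric(0)),
    "Csn1s1-dE2" = list(tissue = "mammary", stage = "L1", wt_n = 5, mut_n = 5,
                        mutant = "Csn1s1-dE2", effects = c(Csn1s1 = 0.35)),
    "Csn2-dE1" = list(tissue = "mammary", stage = "L1", wt_n = 4, mut_n = 3,
                      mutant = "Csn2-dE1", effects = numeric(0)),
    "Csn2-dE2/3" = list(tissue = "mammary", stage = "L1", wt_n = 4, mut_n = 4,
                        mutant = "Csn2-dE2/3", effects = numeric(0)),
    "Csn2-dE1/2/3" = list(tissue = "mammary", stage = "L1", wt_n = 4,
                          mut_n = 4, mutant = "Csn2-dE1/2/3",
                          effects = c(Csn2 = 0.5)),
    "Csn2-dP" = list(tissue = "mammary", stage = "L1", wt_n = 4, mut_n = 3,
                     mutant = "Csn2-dP", effects = c(Csn2 = 0.2)),
    "Csn2-dP-E1/2/3" = list(tissue = "mammary", stage = "L1", wt_n = 4,
                            mut_n = 4, mutant = "Csn2-dP-E1/2/3",
                            effects = c(Csn2 = 1e-4)),
    "Csn2-dP-A" = list(tissue = "mammary", stage = "L1", wt_n = 4, mut_n = 3,
                       mutant = "Csn2-dP-A", effects = numeric(0)),
    "Csn2-dP-B" = list(tissue = "mammary", stage = "L1", wt_n = 4, mut_n = 3,
                       mutant = "Csn2-dP-B", effects = c(Csn2 = 0.2))
  )
}

#' List the packaged scenarios
#'
#' `"default"` is the wild-type developmental time course (virgin, p6, L1,
#' L10 mammary) on which the structural stages run; the remaining scenarios
#' are the figure-level enhancer/promoter deletion experiments, each a
#' WT-vs-mutant comparison at the stage, tissue and replicate numbers of the
#' corresponding figure.
#'
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() c("default", names(scenario_specs()))

#' Build a scenario configuration
#'
#' @param name a scenario name from [list_scenarios()].
#' @param dispersion negative-binomial dispersion shared by all genes.
#' @param depth_sdlog log-sd of the per-sample library-depth factor.
#' @param qpcr_noise_sd Gaussian sd on simulated Ct values (cycles).
#' @return a `scenario_config` list: sample groups, per-genotype
#'   multiplicative effects, expression baselines and noise parameters.
#' @export
scenario_config <- function(name, dispersion = 0.05, depth_sdlog = 0.1,
                            qpcr_noise_sd = 0.15) {
  stopifnot(dispersion > 0)
  profiles <- expression_profiles()
  if (identical(name, "default")) {
    groups <- data.frame(genotype = "WT", tissue = "mammary",
                         stage = c("virgin", "p6", "L1", "L10"),
                         n = c(3, 3, 4, 4), stringsAsFactors = FALSE)
    effects <- list(WT = numeric(0))
  } else {
    spec <- scenario_specs()[[name]]
    if (is.null(spec)) {
      stop("unknown scenario '", name, "'; see list_scenarios()", call. = FALSE)
    }
    groups <- data.frame(genotype = c("WT", spec$mutant),
                         tissue = spec$tissue, stage = spec$stage,
                         n = c(spec$wt_n, spec$mut_n), stringsAsFactors = FALSE)
    effects <- list(numeric(0), spec$effects)
    names(effects) <- c("WT", spec$mutant)
  }
  structure(list(name = name, groups = groups, effects = effects,
                 profiles = profiles, dispersion = dispersion,
                 depth_sdlog = depth_sdlog, qpcr_noise_sd = qpcr_noise_sd),
            class = "scenario_config")
}
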