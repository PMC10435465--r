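# Element calling: coverage normalization, Poisson-tail peak calling,
# replicate-consistency + H3K27ac gating, GAS motif scanning and promoter
# methylation summaries.

#' Normalize a coverage track
#'
#' RPKM: bin value / (bin size in kb x mapped reads in millions).
#' RPGC (1x depth): bin value x genome size / (mapped reads x read length).
#'
#' @param track a [coverage_track()] with `total_mapped_reads > 0`.
#' @param mode `"RPKM"` or `"RPGC"`.
#' @param genome_size effective genome size for RPGC; defaults to the track's
#'   own span.
#' @return the track with normalized values.
#' @export
normalize_coverage <- function(track, mode = c("RPKM", "RPGC"),
                               genome_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(track$total_mapped_reads) || track$total_mapped_reads <= 0) {
    stop("total_mapped_reads must be positive", call. = FALSE)
  }
  v <- track$values
  track$values <- if (mode == "RPKM") {
    v / ((track$bin_size / 1000) * (track$total_mapped_reads / 1e6))
  } else {
    if (is.null(genome_size)) genome_size <- length(v) * track$bin_size
    v * genome_size / (track$total_mapped_reads * track$read_length)
  }
  track
}

# Centered running mean with partial windows at the chromosome ends.
running_mean <- function(v, w) {
  n <- length(v)
  half <- (w - 1) %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call enriched regions from a coverage track
#'
#' A transparent bin-wise Poisson enrichment caller (no input control): each
#' bin's count is tested against a background rate, p-values are BH-adjusted
#' across bins, significant bins are merged (narrow: across 1-bin holes;
#' broad: across 10-bin holes at a 10x relaxed alpha) and peaks shorter than
#' two bins are dropped. Narrow mode tests against
#' `max(global mean, local 10 kb mean)`, appropriate for punctate TF binding;
#' broad mode tests against the global mean only, since a treatment-derived
#' local rate inside a histone-mark domain wider than the window would equal
#' the domain's own signal. Tracks shorter than the local window fall back to
#' the global rate.
#'
#' @param track a [coverage_track()] of (integer-valued) bin counts.
#' @param mode `"narrow"` (TF) or `"broad"` (histone marks).
#' @param alpha BH-adjusted significance threshold in (0, 1).
#' @param local_window width (bp) of the local background window.
#' @param replicate_id annotation carried into the output.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `name`, `score`
#'   (-log10 p of the best bin, scaled x10 and capped at 1000), `strand`,
#'   `summit` (midpoint of the max-signal bin), `signal`
#'   (background-subtracted mean enrichment), `area` (background-subtracted
#'   total), `replicate_id`.
#' @export
call_peaks <- function(track, mode = c("narrow", "broad"), alpha = 0.05,
                       local_window = 10000, replicate_id = NA) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  v <- track$values
  n <- length(v)
  bin <- track$bin_size
  lambda_g <- mean(v)
  w <- max(3L, round(local_window / bin))
  if (w %% 2 == 0) w <- w + 1L
  lambda <- if (mode == "narrow" && n > w) {
    pmax(lambda_g, running_mean(v, w))
  } else {
    rep(lambda_g, n)
  }
  p <- ppois(v - 1, lambda, lower.tail = FALSE)  # P(X >= v)
  padj <- p.adjust(p, method = "BH")
  eff_alpha <- if (mode == "broad") min(alpha * 10, 0.5) else alpha
  gap_bins <- if (mode == "broad") 10L else 1L
  sig <- which(padj <= eff_alpha & v > lambda)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character(), summit = numeric(),
                      signal = numeric(), area = numeric(),
                      replicate_id = replicate_id[0])
  if (!length(sig)) return(empty)
  bins <- data.frame(chrom = track$chrom, start = (sig - 1) * bin,
                     end = sig * bin)
  merged <- merge_intervals(bins, gap = gap_bins * bin)
  merged <- merged[merged$end - merged$start >= 2 * bin, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    i0 <- merged$start[i] / bin + 1
    i1 <- merged$end[i] / bin
    vv <- v[i0:i1]
    best <- i0 + which.max(vv) - 1
    data.frame(chrom = track$chrom, start = merged$start[i],
               end = merged$end[i], name = NA_character_,
               score = min(1000, 10 * -log10(max(min(p[i0:i1]), 1e-100))),
               strand = ".", summit = (best - 0.5) * bin,
               signal = mean(vv) - lambda_g,
               area = sum(vv - lambda_g), replicate_id = replicate_id,
               stringsAsFactors = FALSE)
  }))
  out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Replicate-consistent, H3K27ac-supported regulatory elements
#'
#' Keeps only binding observed in both replicates with H3K27ac coverage
#' underneath: each replicate-1 peak is combined with every replicate-2 peak
#' it overlaps (>= 1 bp) into the union span of the pair, pair spans are
#' merged, and only spans overlapping at least one H3K27ac broad peak are
#' emitted. The element signal is the mean over the two replicates of the
#' background-subtracted area of that replicate's supporting peaks.
#'
#' @param peaks_rep1,peaks_rep2 peak tables from [call_peaks()].
#' @param h3k27ac_peaks broad-peak table (replicates may be concatenated).
#' @return data.frame of elements: `chrom`, `start`, `end`, `name`, `signal`,
#'   `h3k27ac_supported`, `n_replicates`.
#' @export
consistent_elements <- function(peaks_rep1, peaks_rep2, h3k27ac_peaks) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), signal = numeric(),
                      h3k27ac_supported = logical(), n_replicates = integer())
  pairs <- overlap_pairs(peaks_rep1, peaks_rep2)
  if (!nrow(pairs)) return(empty)
  spans <- data.frame(
    chrom = peaks_rep1$chrom[pairs$a],
    start = pmin(peaks_rep1$start[pairs$a], peaks_rep2$start[pairs$b]),
    end = pmax(peaks_rep1$end[pairs$a], peaks_rep2$end[pairs$b]))
  els <- merge_intervals(spans, gap = 0)
  k27 <- merge_intervals(h3k27ac_peaks, gap = 0)
  els <- els[overlaps_any(els, k27), , drop = FALSE]
  if (!nrow(els)) return(empty)
  area_sum <- function(peaks) {
    ov <- overlap_pairs(els, peaks)
    s <- numeric(nrow(els))
    if (nrow(ov)) {
      agg <- tapply(peaks$area[ov$b], ov$a, sum)
      s[as.integer(names(agg))] <- agg
    }
    s
  }
  els$name <- sprintf("element_%d", seq_len(nrow(els)))
  els$signal <- (area_sum(peaks_rep1) + area_sum(peaks_rep2)) / 2
  els$h3k27ac_supported <- TRUE
  els$n_replicates <- 2L
  rownames(els) <- NULL
  els
}

#' Scan a sequence for GAS motifs
#'
#' Finds all canonical (`TTCNNNGAA`, 9 bp) and non-canonical (`TTCNNNNGAA`,
#' 10 bp) GAS occurrences, overlaps allowed. `N` in the subject never
#' matches. The scan is forward-strand only: both motif patterns are their
#' own reverse complement, so a reverse-strand scan finds the same sites.
#'
#' @param sequence a DNA string over `A/C/G/T/N`.
#' @param offset base-pair offset added to the reported 0-based coordinates
#'   (use when scanning a sub-sequence).
#' @return data.frame of hits: `start`, `end` (0-based half-open), `kind`,
#'   `seq`.
#' @export
scan_gas_motifs <- function(sequence, offset = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  one <- function(pattern, kind, len) {
    m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) {
      return(data.frame(start = numeric(), end = numeric(),
                        kind = character(), seq = character()))
    }
    st <- as.integer(m)
    data.frame(start = offset + st - 1, end = offset + st - 1 + len,
               kind = kind, seq = substring(s, st, st + len - 1),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("TTC[ACGT]{3}GAA", "canonical", 9L),
               one("TTC[ACGT]{4}GAA", "non_canonical", 10L))
  out <- out[order(out$start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate elements with GAS motif content
#'
#' @param elements element table (e.g. from [consistent_elements()]).
#' @param sequences named character vector of chromosome sequences.
#' @return list with `elements` (input plus `gas_canonical`,
#'   `gas_noncanonical` counts) and `hits` (per-motif table with the host
#'   element).
#' @export
annotate_gas_motifs <- function(elements, sequences) {
  elements$gas_canonical <- 0L
  elements$gas_noncanonical <- 0L
  hits <- list()
  for (i in seq_len(nrow(elements))) {
    ch <- elements$chrom[i]
    if (!ch %in% names(sequences)) {
      stop("chromosome '", ch, "' not present in the supplied sequences",
           call. = FALSE)
    }
    sub <- substring(sequences[[ch]], elements$start[i] + 1, elements$end[i])
    h <- scan_gas_motifs(sub, offset = elements$start[i])
    if (nrow(h)) {
      h$chrom <- ch
      h$element <- elements$name[i]
      hits[[length(hits) + 1]] <- h
      elements$gas_canonical[i] <- sum(h$kind == "canonical")
      elements$gas_noncanonical[i] <- sum(h$kind == "non_canonical")
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(start = numeric(), end = numeric(), kind = character(),
               seq = character(), chrom = character(), element = character())
  }
  list(elements = elements, hits = hits)
}

#' Call regulatory elements from replicate coverage tracks
#'
#' Convenience wrapper chaining [call_peaks()] (narrow on the TF tracks,
#' broad on H3K27ac), [consistent_elements()] and, when a genome sequence is
#' supplied, [annotate_gas_motifs()].
#'
#' @param stat5_rep1,stat5_rep2 TF coverage tracks.
#' @param h3k27ac_rep1,h3k27ac_rep2 histone-mark coverage tracks.
#' @param alpha peak-calling alpha.
#' @param sequences optional named character vector of chromosome sequences.
#' @return list with `elements`, `motif_hits`, and the intermediate peak
#'   tables.
#' @export
call_elements <- function(stat5_rep1, stat5_rep2, h3k27ac_rep1, h3k27ac_rep2,
                          alpha = 0.05, sequences = NULL) {
  p1 <- call_peaks(stat5_rep1, "narrow", alpha, replicate_id = 1L)
  p2 <- call_peaks(stat5_rep2, "narrow", alpha, replicate_id = 2L)
  k1 <- call_peaks(h3k27ac_rep1, "broad", alpha, replicate_id = 1L)
  k2 <- call_peaks(h3k27ac_rep2, "broad", alpha, replicate_id = 2L)
  els <- consistent_elements(p1, p2, rbind(k1, k2))
  hits <- NULL
  if (!is.null(sequences) && nrow(els)) {
    ann <- annotate_gas_motifs(els, sequences)
    els <- ann$elements
    hits <- ann$hits
  }
  list(elements = els, motif_hits = hits, stat5_peaks = list(p1, p2),
       h3k27ac_peaks = list(k1, k2))
}

#' Promoter methylation summary
#'
#' Mean CpG beta over the promoter window `[tss - window/2, tss + window/2)`.
#'
#' @param cpg data.frame with `chrom`, `pos`, `beta` (pre-filtered to one
#'   tissue).
#' @param gene a one-row gene model with `chrom` and `tss`.
#' @param window window width in bp (even, default 400).
#' @return mean beta, or `NA` when the window holds no CpG.
#' @export
promoter_methylation <- function(cpg, gene, window = 400) {
  if (!is.numeric(window) || window <= 0 || window %% 2 != 0) {
    stop("`window` must be a positive even width", call. = FALSE)
  }
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    gene <- as.list(gene)
  }
  half <- window / 2
  sel <- cpg$chrom == gene$chrom & cpg$pos >= gene$tss - half &
    cpg$pos < gene$tss + half
  if (!any(sel)) return(NA_real_)
  mean(cpg$beta[sel])
}
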