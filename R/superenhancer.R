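# ROSE-style stitching and rank-signal super-enhancer classification.

#' Stitch regulatory elements into candidate super-enhancer regions
#'
#' Elements whose center lies within `tss_exclusion` bp of any TSS are
#' removed (promoter-proximal elements do not seed super-enhancers); the
#' remainder are merged whenever their gap is at most `stitch_distance` bp.
#' Defaults are the published ROSE parameters (12.5 kbp stitch, 2.5 kbp TSS
#' exclusion).
#'
#' @param elements element table with `chrom`, `start`, `end`, `name`,
#'   `signal`.
#' @param tss data.frame of TSS positions (`chrom`, `tss`), e.g. a gene
#'   table from [read_gff3_genes()].
#' @param stitch_distance maximum gap merged into one region (bp).
#' @param tss_exclusion half-width of the promoter exclusion zone (bp).
#' @return data.frame of stitched regions: `chrom`, `start`, `end`, `name`,
#'   `n_constituents`, `total_signal`, and `constituents` (list column of
#'   element names).
#' @export
stitch_elements <- function(elements, tss, stitch_distance = 12500,
                            tss_exclusion = 2500) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), n_constituents = integer(),
                      total_signal = numeric())
  empty$constituents <- list()
  if (is.null(elements) || nrow(elements) == 0) return(empty)
  check_intervals(elements, "elements")
  if (is.null(elements$signal)) elements$signal <- 0
  center <- (elements$start + elements$end) / 2
  excl <- vapply(seq_len(nrow(elements)), function(i) {
    any(tss$chrom == elements$chrom[i] &
          abs(tss$tss - center[i]) <= tss_exclusion)
  }, logical(1))
  kept <- elements[!excl, , drop = FALSE]
  if (!nrow(kept)) return(empty)
  regions <- merge_intervals(kept, gap = stitch_distance)
  ov <- overlap_pairs(regions, kept)
  regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  regions$n_constituents <- as.integer(tabulate(ov$a, nrow(regions)))
  sig <- tapply(kept$signal[ov$b], ov$a, sum)
  regions$total_signal <- 0
  regions$total_signal[as.integer(names(sig))] <- sig
  regions$constituents <- lapply(seq_len(nrow(regions)), function(i) {
    kept$name[ov$b[ov$a == i]]
  })
  regions
}

#' Classify super-enhancers by the rank-signal elbow
#'
#' Regions are ranked by ascending total signal; rank and signal are rescaled
#' to the unit square and the cutoff is the rightmost point at which the
#' discrete slope of the curve exceeds 1. Regions above the cutoff are
#' super-enhancers; a perfectly linear (e.g. uniform-signal) curve yields
#' none. Classification is invariant to input order and to uniform positive
#' scaling of the signals.
#'
#' @param regions stitched regions from [stitch_elements()].
#' @return list with `table` (regions plus `rank` and `is_se`, ranked
#'   ascending) and `superenhancers` (the SE subset, strongest last).
#' @export
classify_superenhancers <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    out <- cbind(regions, data.frame(rank = integer(), is_se = logical()))
    return(list(table = out, superenhancers = out))
  }
  ord <- order(regions$total_signal, as.character(regions$chrom),
               regions$start)
  tab <- regions[ord, , drop = FALSE]
  n <- nrow(tab)
  tab$rank <- seq_len(n)
  tab$is_se <- FALSE
  if (n >= 2 && diff(range(tab$total_signal)) > 0) {
    x <- (tab$rank - 1) / (n - 1)
    y <- (tab$total_signal - min(tab$total_signal)) /
      diff(range(tab$total_signal))
    slope <- diff(y) / diff(x)
    steep <- which(slope > 1 + 1e-9)
    if (length(steep)) tab$is_se[seq_len(n) > max(steep)] <- TRUE
  }
  rownames(tab) <- NULL
  list(table = tab, superenhancers = tab[tab$is_se, , drop = FALSE])
}
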