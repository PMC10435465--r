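# Complex mammary loci: stitch runs of hormonally induced protein-coding
# genes, validate against contact-domain borders, extend over adjacent
# intergenic TF sites, and keep loci with at least three genes.
#
# A locus is a list: chrom, start, end, members (gene names in coordinate
# order), sites (incorporated element table), history (applied-rule log).
# Locus spans always derive from member genes plus incorporated sites, so the
# pipeline is idempotent on its own output.

new_locus <- function(chrom, members, genes, history = character(0)) {
  g <- genes[match(members, genes$name), , drop = FALSE]
  list(chrom = chrom, start = min(g$start), end = max(g$end),
       members = members,
       sites = data.frame(chrom = character(), start = numeric(),
                          end = numeric(), name = character()),
       history = history)
}

domain_borders <- function(domains) {
  if (is.null(domains) || nrow(domains) == 0) {
    return(data.frame(chrom = character(), position = numeric(),
                      side = character()))
  }
  check_intervals(domains, "domains")
  out <- rbind(data.frame(chrom = domains$chrom, position = domains$start,
                          side = "start", stringsAsFactors = FALSE),
               data.frame(chrom = domains$chrom, position = domains$end,
                          side = "end", stringsAsFactors = FALSE))
  out[order(out$chrom, out$position), , drop = FALSE]
}

interior_borders <- function(locus, borders) {
  b <- borders[borders$chrom == locus$chrom, , drop = FALSE]
  sort(unique(b$position[b$position > locus$start & b$position < locus$end]))
}

#' Flag hormonally induced genes
#'
#' A gene is flagged when it is induced more than two-fold (strict) with a
#' BH-adjusted p-value below 0.05 in at least one of the supplied contrasts
#' (p6 vs L1 and p6 vs L10 in the packaged scenarios). Non-protein-coding
#' genes are never flagged.
#'
#' @param de_list named list of differential-expression tables (from
#'   [differential_expression()]); at least two contrasts are required.
#' @param genes gene table with `name` and `biotype`.
#' @return named logical vector over `genes$name`.
#' @export
select_induced_genes <- function(de_list, genes) {
  if (!is.list(de_list) || length(de_list) < 2) {
    stop("`de_list` must supply at least two contrasts", call. = FALSE)
  }
  flags <- stats::setNames(rep(FALSE, nrow(genes)), genes$name)
  for (de in de_list) {
    hit <- de$tested & !is.na(de$padj) & de$fold > 2 & de$padj < 0.05
    flags[de$gene[hit & de$gene %in% names(flags)]] <- TRUE
  }
  flags & stats::setNames(genes$biotype == "protein_coding", genes$name)
}

#' Stitch neighboring induced genes into preliminary loci
#'
#' Maximal runs of consecutive flagged protein-coding genes (in
#' protein-coding gene order; non-coding genes are invisible) become loci.
#' Singleton and two-gene runs are kept here and pruned by the later rules.
#'
#' @param genes gene table.
#' @param flags named logical vector from [select_induced_genes()].
#' @return list of loci.
#' @export
stitch_genes <- function(genes, flags) {
  coding <- sort_intervals(genes[genes$biotype == "protein_coding", ,
                                 drop = FALSE])
  loci <- list()
  for (ch in unique(coding$chrom)) {
    g <- coding[coding$chrom == ch, , drop = FALSE]
    fl <- flags[g$name]
    fl[is.na(fl)] <- FALSE
    r <- rle(as.vector(fl))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      members <- g$name[starts[k]:ends[k]]
      loci[[length(loci) + 1]] <- new_locus(
        ch, members, coding,
        history = sprintf("stitched %d consecutive induced coding gene(s)",
                          length(members)))
    }
  }
  loci
}

#' Validate loci against contact-domain borders
#'
#' A locus with no border strictly inside its span passes unchanged. A
#' two-gene locus overlapping a border is discarded. Larger loci are split at
#' each interior border (a gene is assigned to the fragment that contains its
#' full span; a gene itself straddling a border is dropped); fragments with
#' more than two genes are kept, shrunk to their member-gene span.
#'
#' @param loci loci from [stitch_genes()].
#' @param domains contact-domain intervals.
#' @param genes gene table (for member coordinates).
#' @return list of surviving loci.
#' @export
apply_domain_constraints <- function(loci, domains, genes) {
  borders <- domain_borders(domains)
  out <- list()
  for (locus in loci) {
    ib <- interior_borders(locus, borders)
    if (!length(ib)) {
      locus$history <- c(locus$history, "domain check: no interior border")
      out[[length(out) + 1]] <- locus
      next
    }
    if (length(locus$members) <= 2) next  # rule 1: small locus on a border
    cuts <- c(locus$start, ib, locus$end)
    g <- genes[match(locus$members, genes$name), , drop = FALSE]
    seg <- rep(NA_integer_, nrow(g))
    for (j in seq_len(length(cuts) - 1)) {
      inside <- g$start >= cuts[j] & g$end <= cuts[j + 1]
      seg[inside] <- j
    }
    for (j in sort(unique(seg[!is.na(seg)]))) {
      members <- g$name[which(seg == j)]
      if (length(members) <= 2) next  # rule 2: keep > 2 genes
      out[[length(out) + 1]] <- new_locus(
        locus$chrom, members, genes,
        history = c(locus$history,
                    sprintf("split at border(s) %s; kept %d-gene fragment, shrunk to gene span",
                            paste(ib, collapse = ","), length(members))))
    }
  }
  out
}

# Nearest protein-coding gene outside the locus on one side, or NULL.
flank_neighbor <- function(locus, coding, side) {
  g <- coding[coding$chrom == locus$chrom &
                !(coding$name %in% locus$members), , drop = FALSE]
  if (side == "left") {
    g <- g[g$end <= locus$start, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g[which.max(g$end), , drop = FALSE]
  } else {
    g <- g[g$start >= locus$end, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g[which.min(g$start), , drop = FALSE]
  }
}

#' Extend loci over adjacent intergenic TF binding sites
#'
#' Each flank is extended to cover TF (STAT5A) elements lying wholly within
#' the intergenic interval between the terminal member gene and the nearest
#' protein-coding gene outside the locus. If the extension places a
#' contact-domain border inside the span, the flank retracts to the outermost
#' incorporated element on the locus side of that border (or back to the gene
#' edge when none remains).
#'
#' @param loci loci that passed [apply_domain_constraints()].
#' @param elements TF-bound element table.
#' @param genes gene table.
#' @param domains contact-domain intervals.
#' @return list of loci with `sites` and updated spans.
#' @export
extend_with_tf_sites <- function(loci, elements, genes, domains) {
  borders <- domain_borders(domains)
  coding <- sort_intervals(genes[genes$biotype == "protein_coding", ,
                                 drop = FALSE])
  lapply(loci, function(locus) {
    g <- genes[match(locus$members, genes$name), , drop = FALSE]
    base_start <- min(g$start)
    base_end <- max(g$end)
    els <- elements[elements$chrom == locus$chrom, , drop = FALSE]
    bpos <- borders$position[borders$chrom == locus$chrom]
    sites <- list()

    # left flank
    start <- base_start
    nb <- flank_neighbor(locus, coding, "left")
    lo <- if (is.null(nb)) 0 else nb$end
    cand <- els[els$start >= lo & els$end <= base_start, , drop = FALSE]
    if (nrow(cand)) {
      start <- min(cand$start)
      viol <- bpos[bpos > start & bpos <= base_start]
      if (length(viol)) {
        b <- max(viol)
        cand <- cand[cand$start >= b, , drop = FALSE]
        start <- if (nrow(cand)) min(cand$start) else base_start
        locus$history <- c(locus$history,
                           sprintf("left extension retracted at border %s", b))
      }
      if (nrow(cand)) sites[[length(sites) + 1]] <- cand
    }

    # right flank
    end <- base_end
    nb <- flank_neighbor(locus, coding, "right")
    hi <- if (is.null(nb)) Inf else nb$start
    cand <- els[els$start >= base_end & els$end <= hi, , drop = FALSE]
    if (nrow(cand)) {
      end <- max(cand$end)
      viol <- bpos[bpos >= base_end & bpos < end]
      if (length(viol)) {
        b <- min(viol)
        cand <- cand[cand$end <= b, , drop = FALSE]
        end <- if (nrow(cand)) max(cand$end) else base_end
        locus$history <- c(locus$history,
                           sprintf("right extension retracted at border %s", b))
      }
      if (nrow(cand)) sites[[length(sites) + 1]] <- cand
    }

    if (length(sites)) {
      inc <- do.call(rbind, sites)
      locus$sites <- inc[, intersect(c("chrom", "start", "end", "name"),
                                     names(inc)), drop = FALSE]
      locus$history <- c(locus$history,
                         sprintf("incorporated %d intergenic TF site(s)",
                                 nrow(inc)))
    }
    locus$start <- start
    locus$end <- end
    locus
  })
}

#' Finalize complex loci
#'
#' Drops loci with fewer than three member genes and sorts the rest.
#'
#' @param loci list of loci.
#' @return list of final loci.
#' @export
finalize_loci <- function(loci) {
  keep <- Filter(function(l) length(l$members) >= 3, loci)
  ord <- order(vapply(keep, `[[`, character(1), "chrom"),
               vapply(keep, `[[`, numeric(1), "start"))
  lapply(keep[ord], function(l) {
    l$history <- c(l$history, ">=3 member genes: kept")
    l
  })
}

#' Identify complex loci end to end
#'
#' Chains [select_induced_genes()], [stitch_genes()],
#' [apply_domain_constraints()], [extend_with_tf_sites()] and
#' [finalize_loci()].
#'
#' @param genes gene table.
#' @param de_list named list of differential-expression tables.
#' @param elements TF-bound element table (may be empty).
#' @param domains contact-domain intervals.
#' @return list with `loci` (final locus list), `flags` and `table` (one row
#'   per locus: span, members, incorporated sites).
#' @export
find_complex_loci <- function(genes, de_list, elements, domains) {
  flags <- select_induced_genes(de_list, genes)
  loci <- stitch_genes(genes, flags)
  loci <- apply_domain_constraints(loci, domains, genes)
  loci <- extend_with_tf_sites(loci, elements, genes, domains)
  loci <- finalize_loci(loci)
  table <- if (length(loci)) {
    data.frame(chrom = vapply(loci, `[[`, character(1), "chrom"),
               start = vapply(loci, `[[`, numeric(1), "start"),
               end = vapply(loci, `[[`, numeric(1), "end"),
               n_genes = vapply(loci, function(l) length(l$members), integer(1)),
               members = vapply(loci, function(l)
                 paste(l$members, collapse = ","), character(1)),
               n_sites = vapply(loci, function(l) nrow(l$sites), integer(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_genes = integer(), members = character(),
               n_sites = integer())
  }
  list(loci = loci, flags = flags, table = table)
}
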