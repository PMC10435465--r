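# Count normalization, NB differential testing and effect-size estimators.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is the
#' median ratio of its counts to the per-gene geometric mean; factors are
#' rescaled to geometric mean 1. When no gene is nonzero everywhere, falls
#' back to total-count ratios with a warning.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  ok <- rowSums(m > 0) == ncol(m)
  sf <- if (!any(ok)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    colSums(m)
  } else {
    lg <- rowMeans(log(m[ok, , drop = FALSE]))
    apply(m[ok, , drop = FALSE], 2, function(col) exp(median(log(col) - lg)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Negative-binomial differential expression
#'
#' A transparent NB Wald test: counts are normalized by [size_factors()],
#' genes with fewer than `prefilter_total` reads in total are excluded, a
#' pooled method-of-moments dispersion is estimated per gene (floored at
#' 1e-8), and the log-ratio of pseudo-counted group means is tested with a
#' delta-method standard error against a t reference with
#' `n_a + n_b - 2` degrees of freedom. P-values are BH-adjusted across tested
#' genes. Fold change and log2 fold change use a 0.5 pseudo-count on each
#' group mean so that near-silenced genes keep finite estimates.
#'
#' @param counts genes x samples matrix.
#' @param samples_a,samples_b column names (or indices) of the two groups,
#'   each with at least two samples; fold changes are `b` over `a`
#'   (mutant over wild type in the packaged scenarios).
#' @param prefilter_total minimum total raw reads for a gene to be tested.
#' @return data.frame per gene: `gene`, `mean_a`, `mean_b` (normalized group
#'   means), `fold` (linear, b/a), `lfc` (log2), `p`, `padj`, `tested`.
#' @export
differential_expression <- function(counts, samples_a, samples_b,
                                    prefilter_total = 10) {
  m <- as.matrix(counts)
  a <- m[, samples_a, drop = FALSE]
  b <- m[, samples_b, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  sub <- cbind(a, b)
  tested <- rowSums(sub) >= prefilter_total
  sf <- size_factors(sub)
  nm <- sweep(sub, 2, sf, "/")
  ia <- seq_len(na)
  ib <- na + seq_len(nb)
  mu_a <- rowMeans(nm[, ia, drop = FALSE])
  mu_b <- rowMeans(nm[, ib, drop = FALSE])
  v_a <- apply(nm[, ia, drop = FALSE], 1, var)
  v_b <- apply(nm[, ib, drop = FALSE], 1, var)
  mom <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  ta <- mom(v_a, mu_a)
  tb <- mom(v_b, mu_b)
  w_a <- ifelse(is.na(ta), 0, na - 1)
  w_b <- ifelse(is.na(tb), 0, nb - 1)
  phi <- (w_a * ifelse(is.na(ta), 0, ta) + w_b * ifelse(is.na(tb), 0, tb)) /
    pmax(w_a + w_b, 1)
  phi <- pmin(pmax(phi, 1e-8), 10)
  se <- sqrt((1 / na) * (1 / (mu_a + 0.5) + phi) +
               (1 / nb) * (1 / (mu_b + 0.5) + phi))
  lfc_ln <- log(mu_b + 0.5) - log(mu_a + 0.5)
  p <- 2 * pt(-abs(lfc_ln / se), df = na + nb - 2)
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  out <- data.frame(gene = rownames(m), mean_a = mu_a, mean_b = mu_b,
                    fold = (mu_b + 0.5) / (mu_a + 0.5),
                    lfc = log2((mu_b + 0.5) / (mu_a + 0.5)),
                    p = p, padj = padj, tested = tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percent reduction of a gene in the mutant
#'
#' `100 * (1 - mutant mean / WT mean)` on normalized, pseudo-counted group
#' means; negative values indicate an increase.
#'
#' @param de a [differential_expression()] table (group `b` = mutant).
#' @param gene gene name.
#' @return percent reduction, or `NA` for an untested/unknown gene.
#' @export
percent_reduction <- function(de, gene) {
  i <- match(gene, de$gene)
  if (is.na(i) || !de$tested[i]) return(NA_real_)
  100 * (1 - de$fold[i])
}

#' Fraction of the library contributed by a gene set
#'
#' @param counts genes x samples matrix.
#' @param gene_set non-empty character vector of gene names.
#' @param samples columns to use (default all).
#' @return list with `per_sample` fractions and their `mean`.
#' @export
mrna_fraction <- function(counts, gene_set, samples = colnames(counts)) {
  if (!length(gene_set)) stop("`gene_set` must be non-empty", call. = FALSE)
  m <- as.matrix(counts)[, samples, drop = FALSE]
  tot <- colSums(m)
  frac <- colSums(m[intersect(gene_set, rownames(m)), , drop = FALSE]) / tot
  frac[tot == 0] <- NA_real_
  list(per_sample = frac, mean = mean(frac, na.rm = TRUE))
}

#' Comparative-Ct (delta-delta-Ct) quantification
#'
#' `dCt = Ct(target) - Ct(reference)`; `ddCt` subtracts the calibrator-group
#' mean dCt; relative expression is `2^(-ddCt)`. Samples missing either Ct
#' are skipped with a warning.
#'
#' @param ct_table data.frame with `sample`, `genotype`, `gene`, `ct`.
#' @param target target gene name.
#' @param reference reference (housekeeping) gene, default `"Gapdh"`.
#' @param calibrator genotype used as calibrator (e.g. `"WT"`).
#' @return data.frame per sample: `sample`, `genotype`, `dct`, `ddct`,
#'   `rel_expr`.
#' @export
ddct <- function(ct_table, target, reference = "Gapdh", calibrator) {
  t_rows <- ct_table[ct_table$gene == target, , drop = FALSE]
  r_rows <- ct_table[ct_table$gene == reference, , drop = FALSE]
  if (!nrow(r_rows)) stop("reference gene '", reference, "' absent", call. = FALSE)
  i <- match(t_rows$sample, r_rows$sample)
  missing <- is.na(i) | is.na(t_rows$ct) | is.na(r_rows$ct[i])
  if (any(missing)) {
    warning(sum(missing), " sample(s) missing a Ct value; skipped")
    t_rows <- t_rows[!missing, , drop = FALSE]
    i <- i[!missing]
  }
  dct <- t_rows$ct - r_rows$ct[i]
  cal <- t_rows$genotype == calibrator
  if (!any(cal)) stop("no samples in calibrator group '", calibrator, "'",
                      call. = FALSE)
  ddct_v <- dct - mean(dct[cal])
  data.frame(sample = t_rows$sample, genotype = t_rows$genotype, dct = dct,
             ddct = ddct_v, rel_expr = 2^(-ddct_v), stringsAsFactors = FALSE)
}
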