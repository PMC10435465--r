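# Independent brute-force oracles and randomized fixtures used by the
# property-style tests. These deliberately use naive O(n^2)/enumeration
# strategies, coded separately from the package implementations.

# O(n^2) interval merging: repeatedly fuse any two intervals whose gap is
# at most `gap`, until stable.
brute_merge <- function(intervals, gap = 0) {
  xs <- split(intervals, seq_len(nrow(intervals)))
  xs <- lapply(xs, function(r) list(chrom = r$chrom, start = r$start, end = r$end))
  changed <- TRUE
  while (changed && length(xs) > 1) {
    changed <- FALSE
    for (i in seq_along(xs)) {
      for (j in seq_along(xs)) {
        if (i >= j) next
        a <- xs[[i]]; b <- xs[[j]]
        if (a$chrom != b$chrom) next
        sep <- max(a$start, b$start) - min(a$end, b$end)
        if (sep <= gap) {
          xs[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                          end = max(a$end, b$end))
          xs[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  out <- do.call(rbind, lapply(xs, as.data.frame))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_interval_set <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  start <- sample(0:500, n, replace = TRUE)
  data.frame(chrom = sample(c("cA", "cB"), n, replace = TRUE),
             start = start, end = start + sample(1:80, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Exhaustive reciprocal-overlap matcher: enumerate every one-to-one
# assignment on the (small) candidate graph and keep a maximum matching.
brute_match_count <- function(pred, truth, min_frac = 0.5) {
  ok <- function(i, j) {
    if (pred$chrom[i] != truth$chrom[j]) return(FALSE)
    ov <- min(pred$end[i], truth$end[j]) - max(pred$start[i], truth$start[j])
    ov >= min_frac * (pred$end[i] - pred$start[i]) &&
      ov >= min_frac * (truth$end[j] - truth$start[j])
  }
  best <- 0
  recurse <- function(i, used) {
    if (i > nrow(pred)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(i + 1, used)  # leave pred i unmatched
    for (j in seq_len(nrow(truth))) {
      if (!used[j] && ok(i, j)) {
        used[j] <- TRUE
        recurse(i + 1, used)
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nrow(truth)))
  best
}

# Benjamini-Hochberg step-up, written out longhand.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Random small genome for complex-locus property tests: genes laid left to
# right with random gaps, random coding/flag status, borders that may fall
# anywhere (including inside genes), and intergenic-ish elements.
random_genome <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  widths <- sample(500:4000, n, replace = TRUE)
  gaps <- sample(200:6000, n, replace = TRUE)
  ends <- cumsum(widths + gaps)
  starts <- ends - widths
  genes <- data.frame(chrom = "c1", start = starts, end = ends, strand = "+",
                      gene_id = paste0("g", seq_len(n)),
                      name = paste0("g", seq_len(n)),
                      biotype = sample(c("protein_coding", "other"), n,
                                       replace = TRUE, prob = c(0.8, 0.2)),
                      stringsAsFactors = FALSE)
  genes$tss <- genes$start
  flags <- stats::setNames(stats::runif(n) < 0.6, genes$name)
  span <- max(ends) + 5000
  nb <- sample(0:3, 1)
  cuts <- sort(sample(seq(501, span - 500, by = 7), nb))
  dom_edges <- unique(c(0, cuts, span))
  domains <- data.frame(chrom = "c1", start = dom_edges[-length(dom_edges)],
                        end = dom_edges[-1], stringsAsFactors = FALSE)
  ne <- sample(0:4, 1)
  es <- if (ne) sort(sample(seq(100, span - 400, by = 13), ne)) else numeric(0)
  elements <- data.frame(chrom = rep("c1", ne), start = es, end = es + 250,
                         name = if (ne) paste0("e", seq_len(ne)) else character(0),
                         signal = rep(1, ne), stringsAsFactors = FALSE)
  list(genes = genes, flags = flags, domains = domains, elements = elements)
}

# Independent reference for the full complex-locus pipeline (given flags):
# enumerate flagged coding runs with a scan loop, apply the border rules by
# direct segment enumeration, extend flanks, keep >= 3 genes.
ref_complex_loci <- function(genes, flags, domains, elements) {
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  coding <- coding[order(coding$chrom, coding$start), , drop = FALSE]
  result <- list()
  for (ch in unique(coding$chrom)) {
    g <- coding[coding$chrom == ch, , drop = FALSE]
    bs <- sort(unique(c(domains$start[domains$chrom == ch],
                        domains$end[domains$chrom == ch])))
    els <- elements[elements$chrom == ch, , drop = FALSE]
    f <- as.vector(flags[g$name])
    f[is.na(f)] <- FALSE
    i <- 1
    while (i <= nrow(g)) {
      if (!f[i]) { i <- i + 1; next }
      j <- i
      while (j < nrow(g) && f[j + 1]) j <- j + 1
      run <- g[i:j, , drop = FALSE]
      i <- j + 1
      sp <- c(min(run$start), max(run$end))
      inb <- bs[bs > sp[1] & bs < sp[2]]
      frags <- if (!length(inb)) list(run) else if (nrow(run) <= 2) list() else {
        cuts <- c(sp[1], inb, sp[2])
        fr <- list()
        for (k in seq_len(length(cuts) - 1)) {
          sel <- run[run$start >= cuts[k] & run$end <= cuts[k + 1], , drop = FALSE]
          if (nrow(sel) > 2) fr[[length(fr) + 1]] <- sel
        }
        fr
      }
      for (fr in frags) {
        if (nrow(fr) < 3) next
        lo_span <- min(fr$start)
        hi_span <- max(fr$end)
        left_out <- g[g$end <= lo_span & !(g$name %in% fr$name), , drop = FALSE]
        lo <- if (nrow(left_out)) max(left_out$end) else 0
        cl <- els[els$start >= lo & els$end <= lo_span, , drop = FALSE]
        ns <- lo_span
        if (nrow(cl)) {
          ns <- min(cl$start)
          viol <- bs[bs > ns & bs <= lo_span]
          if (length(viol)) {
            cl <- cl[cl$start >= max(viol), , drop = FALSE]
            ns <- if (nrow(cl)) min(cl$start) else lo_span
          }
        }
        right_out <- g[g$start >= hi_span & !(g$name %in% fr$name), , drop = FALSE]
        hi <- if (nrow(right_out)) min(right_out$start) else Inf
        cr <- els[els$start >= hi_span & els$end <= hi, , drop = FALSE]
        ne <- hi_span
        if (nrow(cr)) {
          ne <- max(cr$end)
          viol <- bs[bs >= hi_span & bs < ne]
          if (length(viol)) {
            cr <- cr[cr$end <= min(viol), , drop = FALSE]
            ne <- if (nrow(cr)) max(cr$end) else hi_span
          }
        }
        result[[length(result) + 1]] <-
          list(chrom = ch, start = ns, end = ne, members = fr$name)
      }
    }
  }
  ord <- order(vapply(result, `[[`, character(1), "chrom"),
               vapply(result, `[[`, numeric(1), "start"))
  result[ord]
}

new_locus_for_test <- function(genes, members) {
  locusarch:::new_locus(genes$chrom[1], members, genes)
}

loci_signature <- function(loci) {
  vapply(loci, function(l) {
    paste(l$chrom, l$start, l$end, paste(l$members, collapse = "+"))
  }, character(1))
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
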