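# Readers/writers for the plain-text formats the pipeline touches.
# All coordinates are converted to 0-based half-open at the boundary
# (GFF3 is 1-based closed on disk). Writers emit LF endings and sorted
# records so that identical inputs give byte-identical files.

fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

split_fields <- function(lines, idx, path, min_fields, what) {
  parts <- strsplit(lines, "[ \t]+")
  short <- which(lengths(parts) < min_fields)
  if (length(short)) {
    stop("malformed ", what, " line ", idx[short[1]], " in '", path,
         "': expected at least ", min_fields, " fields", call. = FALSE)
  }
  parts
}

num_field <- function(parts, k, idx, path, what) {
  v <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), k)))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop("malformed ", what, " line ", idx[bad[1]], " in '", path,
         "': field ", k, " is not numeric", call. = FALSE)
  }
  v
}

#' Read a BED6 file
#'
#' 0-based half-open intervals; missing name/score/strand columns default to
#' `"."`, `0`, `"."`. Malformed lines raise an error naming the line.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(cbind(empty_intervals(),
                 data.frame(name = character(), score = numeric(),
                            strand = character())))
  }
  parts <- split_fields(lines[idx], idx, path, 3L, "BED")
  opt <- function(k, default) {
    vapply(parts, function(p) if (length(p) >= k) p[k] else default, character(1))
  }
  score <- suppressWarnings(as.numeric(opt(5, "0")))
  score[is.na(score)] <- 0
  out <- data.frame(chrom = opt(1, ""),
                    start = num_field(parts, 2, idx, path, "BED"),
                    end = num_field(parts, 3, idx, path, "BED"),
                    name = opt(4, "."), score = score, strand = opt(6, "."),
                    stringsAsFactors = FALSE)
  check_intervals(out, paste0("BED file '", path, "'"))
  out
}

#' Write a BED6 file
#'
#' @param x data.frame with at least `chrom`, `start`, `end`; `name`, `score`
#'   and `strand` are filled with defaults when absent.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed6 <- function(x, path) {
  check_intervals(x, "BED")
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$score)) x$score <- 0
  if (is.null(x$strand)) x$strand <- "."
  x <- sort_intervals(x)
  write_lines_lf(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                       x$name, fmt_num(x$score), x$strand, sep = "\t"), path)
}

#' Read a bedGraph coverage file
#'
#' Leading `#key=value` comment lines written by [write_coverage_bedgraph()]
#' (total mapped reads, read length) are recovered when present.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`, `value`, with any recovered
#'   metadata in `attr(, "meta")`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#[A-Za-z_]+=", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#", "", m)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- as.numeric(sub("^[^=]*=", "", kv))
  }
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  parts <- split_fields(lines[idx], idx, path, 4L, "bedGraph")
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    start = num_field(parts, 2, idx, path, "bedGraph"),
                    end = num_field(parts, 3, idx, path, "bedGraph"),
                    value = num_field(parts, 4, idx, path, "bedGraph"),
                    stringsAsFactors = FALSE)
  check_intervals(out, paste0("bedGraph file '", path, "'"))
  attr(out, "meta") <- meta
  out
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as a named character
#' vector, which is what the motif scanner and the generator exchange.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path,
                              width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only `gene` records are consumed. Coordinates are converted from the
#' on-disk 1-based closed convention to internal 0-based half-open, and the
#' TSS is derived from the strand (`start` for `+`, `end - 1` for `-`).
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `name`, `biotype`, `tss`.
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t")
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 line ", idx[bad[1]], " in '", path,
         "': expected 9 tab-separated fields", call. = FALSE)
  }
  type <- vapply(parts, `[`, character(1), 3)
  sel <- which(type == "gene")
  parts <- parts[sel]
  idx <- idx[sel]
  grab_attr <- function(attrs, key) {
    vapply(attrs, function(a) {
      m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
      if (length(m)) sub(paste0("^;?", key, "="), "", m) else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  attrs <- vapply(parts, `[`, character(1), 9)
  strand <- vapply(parts, `[`, character(1), 7)
  start1 <- num_field(parts, 4, idx, path, "GFF3")
  end1 <- num_field(parts, 5, idx, path, "GFF3")
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    start = start1 - 1, end = end1, strand = strand,
                    gene_id = grab_attr(attrs, "ID"),
                    name = grab_attr(attrs, "Name"),
                    biotype = grab_attr(attrs, "biotype"),
                    stringsAsFactors = FALSE)
  out$name[is.na(out$name)] <- out$gene_id[is.na(out$name)]
  out$biotype[is.na(out$biotype)] <- "other"
  out$tss <- ifelse(out$strand == "-", out$end - 1, out$start)
  check_intervals(out, paste0("GFF3 file '", path, "'"))
  sort_intervals(out)
}

#' Write gene models to GFF3
#'
#' @param genes data.frame as returned by [read_gff3_genes()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  check_intervals(genes, "genes")
  genes <- sort_intervals(genes)
  attrs <- paste0("ID=", genes$gene_id, ";Name=", genes$name,
                  ";biotype=", genes$biotype)
  write_lines_lf(c("##gff-version 3",
                   paste(genes$chrom, "locusarch", "gene",
                         fmt_num(genes$start + 1), fmt_num(genes$end), ".",
                         genes$strand, ".", attrs, sep = "\t")), path)
}

#' Read/write a tab-separated table
#'
#' Header row, `#` comments, LF endings; the interchange format for count
#' matrices, metadata, methylation and Ct tables.
#'
#' @param path file path.
#' @return `read_tsv_table`: a data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Binned coverage track
#'
#' A single-chromosome coverage vector in fixed-width bins, plus the library
#' metadata needed for RPKM/RPGC normalization.
#'
#' @param chrom chromosome name.
#' @param values non-negative per-bin values (counts or normalized units).
#' @param bin_size bin width in bp.
#' @param total_mapped_reads library size used for normalization.
#' @param read_length read length in bp (used by RPGC).
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, bin_size,
                           total_mapped_reads = round(sum(values)),
                           read_length = 50) {
  stopifnot(length(chrom) == 1L, nzchar(chrom), is.numeric(values),
            bin_size > 0)
  if (any(values < 0) || anyNA(values)) {
    stop("coverage values must be non-negative", call. = FALSE)
  }
  structure(list(chrom = chrom, bin_size = bin_size,
                 values = as.numeric(values),
                 total_mapped_reads = total_mapped_reads,
                 read_length = read_length),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s, %d bins x %d bp, %s mapped reads\n",
              x$chrom, length(x$values), x$bin_size,
              fmt_num(x$total_mapped_reads)))
  invisible(x)
}

#' Write/read a coverage track as bedGraph
#'
#' One line per bin (no run-length compression) so round trips are
#' byte-stable; library metadata is carried in leading `#key=value` comments.
#'
#' @param track a [coverage_track()].
#' @param path file path.
#' @return the path / the reconstructed track.
#' @export
write_coverage_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  n <- length(track$values)
  starts <- (seq_len(n) - 1) * track$bin_size
  write_lines_lf(c(paste0("#total_mapped_reads=", fmt_num(track$total_mapped_reads)),
                   paste0("#read_length=", fmt_num(track$read_length)),
                   paste(track$chrom, fmt_num(starts),
                         fmt_num(starts + track$bin_size),
                         fmt_num(track$values), sep = "\t")), path)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path) {
  bg <- read_bedgraph(path)
  if (length(unique(bg$chrom)) != 1L) {
    stop("coverage bedGraph '", path, "' must cover one chromosome", call. = FALSE)
  }
  widths <- bg$end - bg$start
  if (length(unique(widths)) != 1L) {
    stop("coverage bedGraph '", path, "' must have uniform bins", call. = FALSE)
  }
  bg <- bg[order(bg$start), , drop = FALSE]
  meta <- attr(bg, "meta")
  coverage_track(bg$chrom[1], bg$value, widths[1],
                 total_mapped_reads = if (!is.null(meta$total_mapped_reads))
                   meta$total_mapped_reads else round(sum(bg$value)),
                 read_length = if (!is.null(meta$read_length))
                   meta$read_length else 50)
}
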