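# Interval algebra on 0-based half-open coordinates (BED convention).
# Strand is carried as annotation only; all overlap/merge logic ignores it.
# Touching intervals (end == start) do NOT overlap.

check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$chrom) || any(!nzchar(as.character(x$chrom)))) {
    stop(what, ": chrom must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x$start) || !is.numeric(x$end) || anyNA(x$start) || anyNA(x$end)) {
    stop(what, ": start/end must be numeric and non-missing", call. = FALSE)
  }
  if (any(x$start < 0) || any(x$end <= x$start)) {
    stop(what, ": intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  invisible(x)
}

sort_intervals <- function(x) {
  x <- x[order(as.character(x$chrom), x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge genomic intervals within a gap
#'
#' Intervals on the same chromosome whose separation is at most `gap` base
#' pairs are merged into one span (overlapping and adjacent intervals merge at
#' `gap = 0`). Output is sorted and pairwise separated by more than `gap`.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). Extra columns are dropped.
#' @param gap single non-negative number of base pairs.
#' @return data.frame of merged intervals, sorted by (`chrom`, `start`).
#' @examples
#' merge_intervals(data.frame(chrom = "c", start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(intervals, gap = 0) {
  if (!is.numeric(gap) || length(gap) != 1L || is.na(gap) || gap < 0) {
    stop("`gap` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(intervals) || nrow(intervals) == 0) return(empty_intervals())
  check_intervals(intervals)
  pieces <- lapply(split(intervals, as.character(intervals$chrom)), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end),
                          min.gapwidth = gap + 1)
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  sort_intervals(do.call(rbind, c(pieces, list(make.row.names = FALSE))))
}

#' Overlap of one interval against a set
#'
#' Half-open overlap test: intervals that merely touch do not overlap.
#'
#' @param query a one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param subjects data.frame of intervals.
#' @return list with `any` (logical) and `hits` (the overlapping subject rows).
#' @export
intersect_any <- function(query, subjects) {
  if (is.data.frame(query)) {
    if (nrow(query) != 1L) stop("`query` must be a single interval", call. = FALSE)
    query <- as.list(query)
  }
  check_intervals(as.data.frame(query[c("chrom", "start", "end")]), "query")
  if (is.null(subjects) || nrow(subjects) == 0) {
    return(list(any = FALSE, hits = subjects))
  }
  check_intervals(subjects, "subjects")
  hit <- subjects$chrom == query$chrom &
    subjects$start < query$end & subjects$end > query$start
  list(any = any(hit), hits = subjects[hit, , drop = FALSE])
}

# All overlapping (a_i, b_j) index pairs across two interval tables.
overlap_pairs <- function(a, b) {
  none <- data.frame(a = integer(), b = integer())
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(none)
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (!length(shared)) return(none)
  pieces <- lapply(shared, function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ia] + 1, a$end[ia]),
      IRanges::IRanges(b$start[ib] + 1, b$end[ib]))
    data.frame(a = ia[S4Vectors::queryHits(ov)],
               b = ib[S4Vectors::subjectHits(ov)])
  })
  out <- do.call(rbind, pieces)
  out[order(out$a, out$b), , drop = FALSE]
}

# For each row of `a`: does it overlap any row of `b`?
overlaps_any <- function(a, b) {
  if (is.null(a) || nrow(a) == 0) return(logical(0))
  seq_len(nrow(a)) %in% overlap_pairs(a, b)$a
}

# Pairwise overlap width (bp) of two single intervals on the same chromosome.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
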