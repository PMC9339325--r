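#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`,
#' anchored on a named scaffold. Format readers ([read_gff3()], [read_bed()])
#' convert at the boundary, so interval arithmetic (flanking, merging,
#' overlap) never has to reason about format conventions.
#'
#' @param scaffold character vector of scaffold identifiers (nonempty).
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand strand per interval: `"+"`, `"-"` or `"."`.
#' @return A data.frame with columns `scaffold`, `start`, `end`, `strand`.
#' @examples
#' gintervals("scf1", c(0, 100), c(50, 200))
#' @export
gintervals <- function(scaffold, start, end, strand = ".") {
  n <- max(length(scaffold), length(start), length(end))
  if (n == 0L) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  scaffold <- rep_len(as.character(scaffold), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(scaffold) | !nzchar(scaffold)))
    stop("scaffold identifiers must be nonempty")
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must not be NA")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end (0-based half-open)")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(scaffold = scaffold, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Merge intervals into a minimal non-overlapping region set
#'
#' Overlapping intervals are combined into maximal runs; touching intervals
#' (`end == start` of the next) are treated as adjacent and merged as well,
#' so abutting flanked gene regions collapse into a single cluster region.
#' The result is sorted by `(scaffold, start)`, strand is dropped (region
#' overlap is strand-agnostic), and the operation is idempotent.
#'
#' @param intervals data.frame as produced by [gintervals()] (strand optional).
#' @param label optional label attached as attribute `"label"`
#'   (e.g. `"query"`, `"universe"`).
#' @return data.frame of pairwise-disjoint intervals with strand `"."`.
#' @examples
#' merge_intervals(gintervals("s", c(90000, 95000), c(111000, 116000)))
#' @export
merge_intervals <- function(intervals, label = NULL) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    out <- gintervals(character(), integer(), integer())
  } else {
    parts <- split(intervals, intervals$scaffold)
    merged <- lapply(names(parts), function(sc) {
      p <- parts[[sc]]
      ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
      red <- IRanges::reduce(ir)  # min.gapwidth = 1 merges touching intervals
      data.frame(scaffold = sc, start = IRanges::start(red) - 1L,
                 end = IRanges::end(red), strand = ".",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$scaffold, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Test whether two intervals overlap
#'
#' Overlap requires at least one shared base on the same scaffold; strand is
#' ignored. Under the half-open convention `[0,10)` and `[10,20)` do not
#' overlap.
#'
#' @param a,b single-row data.frames (or lists) with `scaffold`, `start`, `end`.
#' @return logical.
#' @export
overlaps <- function(a, b) {
  identical(as.character(a$scaffold), as.character(b$scaffold)) &&
    a$start < b$end && b$start < a$end
}

#' Number of intervals in `query` overlapping any interval in `subject`
#'
#' Vectorized companion of [overlaps()]: for each row of `query`, does it
#' share >= 1 bp with some row of `subject` (same scaffold, strand ignored)?
#'
#' @param query,subject interval data.frames.
#' @return logical vector along rows of `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  qr <- IRanges::IRanges(query$start + 1L, query$end)
  hit <- rep(FALSE, nrow(query))
  for (sc in unique(query$scaffold)) {
    qi <- which(query$scaffold == sc)
    si <- which(subject$scaffold == sc)
    if (length(si) == 0L) next
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    hit[qi] <- IRanges::overlapsAny(qr[qi], sr)
  }
  hit
}

#' Expand gene intervals by a flank and merge into cluster regions
#'
#' Each interval is widened by `flank` bp on both sides, clipped to
#' `[0, scaffold_length)`, and the widened set is merged ([merge_intervals]).
#' This is the construction used for both the query regions (the gene family
#' of interest) and the region universe (all genes): clustered genes whose
#' widened windows touch collapse into one region.
#'
#' @param genes interval data.frame of gene spans.
#' @param scaffold_lengths named numeric vector, length of each scaffold in bp.
#' @param flank flank size in bp (default 10000, i.e. 10-kb windows).
#' @param label region-set label attribute.
#' @return merged region set (data.frame).
#' @export
flank_and_merge <- function(genes, scaffold_lengths, flank = 10000,
                            label = NULL) {
  stopifnot(is.data.frame(genes), flank >= 0)
  if (nrow(genes) == 0L)
    return(merge_intervals(genes, label = label))
  if (is.null(names(scaffold_lengths)))
    stop("scaffold_lengths must be a named vector")
  miss <- setdiff(unique(genes$scaffold), names(scaffold_lengths))
  if (length(miss))
    stop("no scaffold length for: ", paste(miss, collapse = ", "))
  len <- scaffold_lengths[genes$scaffold]
  if (any(genes$end > len))
    stop("gene interval extends beyond its scaffold length")
  widened <- gintervals(genes$scaffold,
                        pmax(0, genes$start - flank),
                        pmin(len, genes$end + flank))
  merge_intervals(widened, label = label)
}

#' Total bases covered by an interval set
#' @param intervals interval data.frame.
#' @return numeric, sum of merged widths.
#' @export
covered_bases <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}
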