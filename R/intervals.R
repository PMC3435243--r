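## Interval primitives.  All internal coordinates are 1-based inclusive;
## interval length is end - start + 1.  BED files are the only 0-based
## half-open surface and are converted at the I/O boundary (see formats_io.R).

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end base positions, 1-based inclusive.
#' @return integer-valued length in bases (`end - start + 1`).
#' @export
interval_length <- function(start, end) end - start + 1

## Vectorized intersection length of 1-based inclusive intervals on the same
## chromosome; 0 when disjoint.
intersect_length <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Overlap fraction between two genomic intervals
#'
#' Directional mode (`"of_a"`) returns the fraction of interval `a` covered by
#' `b`; reciprocal mode returns the minimum of the two directional fractions.
#' Intervals on different chromosomes overlap by 0.
#'
#' @param a,b lists or one-row data frames with fields `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param mode `"of_a"` (default) or `"reciprocal"`.
#' @return a number in \[0, 1\].
#' @export
#' @examples
#' a <- list(chrom = "1", start = 1, end = 100000)
#' b <- list(chrom = "1", start = 50001, end = 150000)
#' overlap_fraction(a, b)                # 0.5
#' overlap_fraction(a, b, "reciprocal")  # 0.5
overlap_fraction <- function(a, b, mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  ca <- normalize_chrom(a$chrom)
  cb <- normalize_chrom(b$chrom)
  ov <- ifelse(ca == cb,
               intersect_length(a$start, a$end, b$start, b$end), 0)
  fa <- ov / interval_length(a$start, a$end)
  if (mode == "of_a") return(fa)
  fb <- ov / interval_length(b$start, b$end)
  pmin(fa, fb)
}

## For each row of `query`, the maximum overlap fraction against any row of
## `subject` (optionally restricted to matching `state`).  Fractions are of
## the query interval ("of_a") or reciprocal.  Returns a numeric vector.
max_overlap_fraction <- function(query, subject, mode = "of_a",
                                 match_state = FALSE) {
  out <- numeric(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (match_state) {
    keep <- query$state[qi] == subject$state[si]
    qi <- qi[keep]; si <- si[keep]
  }
  if (!length(qi)) return(out)
  ov <- intersect_length(query$start[qi], query$end[qi],
                         subject$start[si], subject$end[si])
  frac <- ov / interval_length(query$start[qi], query$end[qi])
  if (mode == "reciprocal") {
    frac <- pmin(frac, ov / interval_length(subject$start[si],
                                            subject$end[si]))
  }
  agg <- tapply(frac, qi, max)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

## Fraction of each query interval covered by the UNION of the track records
## (segmental-duplication coverage rule).
union_coverage_fraction <- function(query, track) {
  if (nrow(query) == 0L) return(numeric(0))
  if (nrow(track) == 0L) return(numeric(nrow(query)))
  red <- GenomicRanges::reduce(as_granges(track))
  qgr <- as_granges(query)
  hits <- GenomicRanges::findOverlaps(qgr, red)
  qi <- S4Vectors::queryHits(hits)
  cov <- numeric(nrow(query))
  if (length(qi)) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(qgr)[qi],
      IRanges::ranges(red)[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ov, qi, sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / interval_length(query$start, query$end)
}
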