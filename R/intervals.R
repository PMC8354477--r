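#' Genomic interval helpers
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`
#' on autosome labels `"1".."22"` (a leading `"chr"` prefix is stripped on
#' input). An interval is valid iff `start < end`, so every interval has
#' positive length and two intervals that merely touch (`[0,10)` vs
#' `[10,20)`) do not overlap.
#'
#' @name intervals
NULL

AUTOSOMES <- as.character(1:22)

normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Validate interval columns
#'
#' @param chrom,start,end vectors describing intervals (recycled together).
#' @return invisibly TRUE; stops on the first invalid interval.
#' @keywords internal
check_intervals <- function(chrom, start, end) {
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must not be NA", call. = FALSE)
  bad <- start >= end
  if (any(bad))
    stop(sprintf("invalid interval: start >= end for %d record(s)", sum(bad)),
         call. = FALSE)
  invisible(TRUE)
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap/length(a), overlap/length(b))`; 0 when the intervals sit on
#' different chromosomes or only touch. Symmetric by construction. This is
#' the clustering criterion used to call two deletion (or duplication)
#' events "the same variant" when computing internal control frequencies.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' reciprocal_overlap(list(chrom = "1", start = 100, end = 200),
#'                    list(chrom = "1", start = 150, end = 250))  # 0.5
reciprocal_overlap <- function(a, b) {
  check_intervals(a$chrom, a$start, a$end)
  check_intervals(b$chrom, b$start, b$end)
  if (normalize_chrom(a$chrom) != normalize_chrom(b$chrom)) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Fraction of a target interval covered by a union of regions
#'
#' Regions may overlap each other; coverage is computed on their union
#' (per chromosome) via [IRanges::reduce]. Used by the mask filter: a CNV
#' call more than half covered by telomere/centromere/segmental-duplication
#' sequence is discarded.
#'
#' @param target list with `chrom`, `start`, `end`.
#' @param regions data.frame with columns `chrom`, `start`, `end` (possibly
#'   zero rows).
#' @return fraction in `[0, 1]`.
#' @export
fraction_covered <- function(target, regions) {
  check_intervals(target$chrom, target$start, target$end)
  if (is.null(regions) || nrow(regions) == 0) return(0)
  check_intervals(regions$chrom, regions$start, regions$end)
  keep <- normalize_chrom(regions$chrom) == normalize_chrom(target$chrom)
  if (!any(keep)) return(0)
  # half-open [start, end) -> IRanges closed [start+1, end]
  ir <- IRanges::reduce(IRanges::IRanges(start = regions$start[keep] + 1L,
                                         end = regions$end[keep]))
  tg <- IRanges::IRanges(start = target$start + 1L, end = target$end)
  hit <- IRanges::pintersect(IRanges::findOverlapPairs(ir, tg))
  sum(IRanges::width(hit)) / (target$end - target$start)
}

# Vectorized mask coverage: fraction of each row of `calls` covered by the
# union of `regions`. Same semantics as fraction_covered(), one pass.
mask_coverage <- function(calls, regions) {
  out <- numeric(nrow(calls))
  if (nrow(calls) == 0 || is.null(regions) || nrow(regions) == 0) return(out)
  rch <- normalize_chrom(regions$chrom)
  cch <- normalize_chrom(calls$chrom)
  for (ch in unique(cch)) {
    ci <- which(cch == ch)
    ri <- which(rch == ch)
    if (!length(ri)) next
    red <- IRanges::reduce(IRanges::IRanges(start = regions$start[ri] + 1L,
                                            end = regions$end[ri]))
    tg <- IRanges::IRanges(start = calls$start[ci] + 1L, end = calls$end[ci])
    hits <- IRanges::findOverlaps(tg, red)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        tg[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
      cov <- tapply(ov, S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(cov))
      out[ci[idx]] <- as.numeric(cov) / (calls$end[ci[idx]] - calls$start[ci[idx]])
    }
  }
  out
}
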