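#' CNV quality-control parameters
#'
#' Defaults mirror the standard rare-deletion QC recipe: calls between
#' 5 kb and 20 Mb, at least 10 calling probes, at most half the call
#' covered by telomere/centromere/segmental-duplication masks (strictly
#' more than 50% removes), and internal control frequency strictly below
#' 1%. Reciprocal-overlap clustering at > 50% defines "the same" variant
#' for frequency counting.
#'
#' @param min_size,max_size call length bounds in bases.
#' @param min_probes minimum number of platform calling probes.
#' @param mask_fraction removal threshold on mask coverage (strict `>`).
#' @param maf_threshold internal control frequency kept when strictly below.
#' @param reciprocal_threshold reciprocal overlap defining equivalent calls
#'   (strict `>`).
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_size = 5e3, max_size = 20e6, min_probes = 10,
                      mask_fraction = 0.5, maf_threshold = 0.01,
                      reciprocal_threshold = 0.5) {
  stopifnot(min_size < max_size,
            mask_fraction > 0, mask_fraction < 1,
            maf_threshold > 0, maf_threshold < 1,
            reciprocal_threshold > 0, reciprocal_threshold < 1)
  structure(list(min_size = min_size, max_size = max_size,
                 min_probes = min_probes, mask_fraction = mask_fraction,
                 maf_threshold = maf_threshold,
                 reciprocal_threshold = reciprocal_threshold),
            class = "qc_params")
}

#' Internal control frequency of each CNV call
#'
#' For every call, counts the distinct control individuals carrying a
#' same-type call with reciprocal overlap strictly greater than
#' `reciprocal_threshold`, divided by the number of controls. Deletions
#' and duplications are matched separately; a control's own call matches
#' itself, so a control carrier's call always counts its own individual.
#'
#' @param cnvs `cnv_calls` data.frame.
#' @param n_controls total number of control individuals in the cohort
#'   (not just carriers).
#' @param reciprocal_threshold strict lower bound on reciprocal overlap.
#' @return `cnvs` with `internal_maf` filled in.
#' @export
compute_internal_maf <- function(cnvs, n_controls, reciprocal_threshold = 0.5) {
  if (n_controls <= 0) stop("n_controls must be positive", call. = FALSE)
  if (nrow(cnvs) == 0) return(cnvs)
  maf <- numeric(nrow(cnvs))
  ctrl <- cnvs$phenotype == "control"
  for (ty in unique(cnvs$type)) {
    for (ch in unique(cnvs$chrom[cnvs$type == ty])) {
      qi <- which(cnvs$type == ty & cnvs$chrom == ch)
      si <- qi[ctrl[qi]]
      if (!length(si)) next
      q <- IRanges::IRanges(start = cnvs$start[qi] + 1L, end = cnvs$end[qi])
      s <- IRanges::IRanges(start = cnvs$start[si] + 1L, end = cnvs$end[si])
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      rec <- pmin(ov / IRanges::width(q)[qh], ov / IRanges::width(s)[sh])
      keep <- rec > reciprocal_threshold
      if (!any(keep)) next
      carriers <- tapply(cnvs$sample_id[si][sh[keep]], qh[keep],
                         function(x) length(unique(x)))
      idx <- as.integer(names(carriers))
      maf[qi[idx]] <- as.numeric(carriers) / n_controls
    }
  }
  cnvs$internal_maf <- maf
  cnvs
}

# probe counts per call, from a probe position table (1-based positions)
.count_probes <- function(calls, probes) {
  n <- integer(nrow(calls))
  by_platform <- "platform" %in% names(probes) &&
    "platform" %in% names(calls)
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    pi <- which(probes$chrom == ch)
    if (!length(pi)) next
    pos <- sort(probes$pos[pi])
    # probe at 1-based pos lies inside half-open [start, end) iff
    # start < pos <= end
    n[ci] <- findInterval(calls$end[ci], pos) -
      findInterval(calls$start[ci], pos)
  }
  n
}

#' Apply the CNV quality-control filters
#'
#' Filters are applied in a fixed order -- size, autosome, mask, probes,
#' internal frequency -- and each removed call is attributed to the first
#' filter it fails, so the report's counts reconcile exactly
#' (`input = passed + sum(removed)`). Membership of the passed set does
#' not depend on the order.
#'
#' @param cnvs `cnv_calls` data.frame (with `internal_maf` populated if the
#'   frequency filter is active).
#' @param masks list with data.frames `telomeres`, `centromeres`, `segdups`
#'   (each `chrom`,`start`,`end`) and optionally `probes`.
#' @param params [qc_params].
#' @param deletions_only if TRUE, subset to DEL calls before filtering
#'   (the deletion-focused analysis).
#' @param probes probe table (`chrom`,`pos`); defaults to `masks$probes`.
#'   Ignored for calls that carry their own `probe_count`.
#' @return list with `passed` (`cnv_calls`), `removed` (with `qc_flag`),
#'   and `report` (data.frame of per-filter counts split by phenotype).
#' @export
apply_qc <- function(cnvs, masks, params = qc_params(),
                     deletions_only = FALSE, probes = masks$probes) {
  if (deletions_only) cnvs <- cnvs[cnvs$type == "DEL", , drop = FALSE]
  n_in <- nrow(cnvs)
  flag <- rep("", n_in)
  len <- cnvs$end - cnvs$start
  flag[flag == "" & (len < params$min_size | len > params$max_size)] <- "size"
  flag[flag == "" & !cnvs$chrom %in% AUTOSOMES] <- "non_autosomal"
  mask_regions <- rbind(masks$telomeres[, c("chrom", "start", "end")],
                        masks$centromeres[, c("chrom", "start", "end")],
                        masks$segdups[, c("chrom", "start", "end")])
  cov <- mask_coverage(cnvs, mask_regions)
  flag[flag == "" & cov > params$mask_fraction] <- "mask"
  pc <- cnvs$probe_count
  if (any(is.na(pc))) {
    if (is.null(probes))
      stop("probe filter enabled but no probe_count column and no probe table",
           call. = FALSE)
    pc[is.na(pc)] <- .count_probes(cnvs[is.na(pc), , drop = FALSE], probes)
  }
  flag[flag == "" & pc < params$min_probes] <- "probes"
  maf <- cnvs$internal_maf
  if (any(is.na(maf)))
    stop("internal_maf not computed; run compute_internal_maf() first",
         call. = FALSE)
  flag[flag == "" & maf >= params$maf_threshold] <- "maf"
  cnvs$qc_flag <- flag
  cnvs$probe_count <- pc
  passed <- cnvs[flag == "", , drop = FALSE]
  removed <- cnvs[flag != "", , drop = FALSE]
  report <- qc_report(cnvs)
  list(passed = passed, removed = removed, report = report)
}

#' Tabulate QC outcomes by phenotype
#' @param cnvs `cnv_calls` with `qc_flag` assigned ("" = passed).
#' @return data.frame: one row per filter plus `input` and `passed`,
#'   columns `case`, `control`, `total`.
#' @export
qc_report <- function(cnvs) {
  lab <- c(input = NA, size = "size", non_autosomal = "non_autosomal",
           mask = "mask", probes = "probes", maf = "maf", passed = "")
  rows <- lapply(names(lab), function(k) {
    sel <- if (k == "input") rep(TRUE, nrow(cnvs)) else cnvs$qc_flag == lab[[k]]
    data.frame(filter = k,
               case = sum(sel & cnvs$phenotype == "case"),
               control = sum(sel & cnvs$phenotype == "control"),
               total = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
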