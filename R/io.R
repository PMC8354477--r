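#' Readers and writers for the tabular formats the pipeline touches
#'
#' All tables are TSV with a header; coordinates are converted from the
#' declared input dialect to the internal 0-based half-open convention at
#' load and converted back on write, so load -> write -> load is the
#' identity on accepted records. Masks and regions travel as BED
#' (chrom, start, end \[, name\]; BED is already 0-based half-open).
#' Gene sets travel as GMT.
#'
#' @name delmeta-io
NULL

.dialects <- c("1-based-inclusive", "0-based-half-open")

# start/end columns in external dialect -> internal half-open
.to_internal <- function(start, end, dialect) {
  dialect <- match.arg(dialect, .dialects)
  if (dialect == "1-based-inclusive") list(start = start - 1L, end = end)
  else list(start = start, end = end)
}

.to_external <- function(start, end, dialect) {
  dialect <- match.arg(dialect, .dialects)
  if (dialect == "1-based-inclusive") list(start = start + 1L, end = end)
  else list(start = start, end = end)
}

#' Load a CNV call table
#'
#' Expected columns: `chrom`, `start`, `end`, `type` (DEL/DUP), `sample`,
#' `phenotype` (case/control), `study`; optional `subphenotype`, `probes`.
#' Rows that cannot be represented are rejected (not an error) and returned
#' with a reason, preserving input order.
#'
#' @param path TSV file.
#' @param dialect coordinate convention of the input, one of
#'   `"1-based-inclusive"` (default, typical CNV-call exports) or
#'   `"0-based-half-open"`.
#' @param autosomes_only reject non-autosomal rows (default TRUE; the
#'   analysis is restricted to autosomes).
#' @return list with `calls` (data.frame, class `cnv_calls`) and `rejected`
#'   (data.frame with a `reason` column).
#' @export
load_cnv_table <- function(path, dialect = "1-based-inclusive",
                           autosomes_only = TRUE) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("chrom", "start", "end", "type", "sample", "phenotype", "study")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CNV table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  co <- .to_internal(as.numeric(raw$start), as.numeric(raw$end), dialect)
  chrom <- normalize_chrom(raw$chrom)
  type <- toupper(raw$type)
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(co$start) | is.na(co$end) | co$start >= co$end] <- "invalid interval"
  reason[is.na(reason) & !type %in% c("DEL", "DUP")] <- "unknown type"
  if (autosomes_only)
    reason[is.na(reason) & !chrom %in% AUTOSOMES] <- "non-autosomal"
  reason[is.na(reason) & !tolower(raw$phenotype) %in% c("case", "control")] <-
    "unknown phenotype"
  ok <- is.na(reason)
  calls <- data.frame(
    chrom = chrom[ok], start = co$start[ok], end = co$end[ok],
    type = type[ok], sample_id = as.character(raw$sample)[ok],
    phenotype = tolower(raw$phenotype)[ok],
    subphenotype = if ("subphenotype" %in% names(raw))
      as.character(raw$subphenotype)[ok] else NA_character_,
    study_id = as.character(raw$study)[ok],
    probe_count = if ("probes" %in% names(raw))
      as.integer(raw$probes)[ok] else NA_integer_,
    internal_maf = NA_real_, qc_flag = "",
    stringsAsFactors = FALSE)
  class(calls) <- c("cnv_calls", "data.frame")
  rejected <- cbind(raw[!ok, , drop = FALSE],
                    reason = reason[!ok])
  list(calls = calls, rejected = rejected)
}

#' Write a CNV call table
#'
#' Emits the same column layout [load_cnv_table] consumes, in the requested
#' dialect, with stable column order.
#' @param calls `cnv_calls` data.frame.
#' @param path output TSV path.
#' @inheritParams load_cnv_table
#' @export
write_cnv_table <- function(calls, path, dialect = "1-based-inclusive") {
  co <- .to_external(calls$start, calls$end, dialect)
  out <- data.frame(chrom = calls$chrom, start = co$start, end = co$end,
                    type = calls$type, sample = calls$sample_id,
                    phenotype = calls$phenotype,
                    subphenotype = calls$subphenotype,
                    study = calls$study_id, probes = calls$probe_count,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are deduplicated within a set. Duplicated set names are an
#' error; an empty set is kept with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0))
    warning("empty gene set(s): ",
            paste(nm[lengths(sets) == 0], collapse = ", "), call. = FALSE)
  sets
}

#' Write gene sets to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a BED file of regions (masks, syndrome regions)
#'
#' BED is 0-based half-open, matching the internal convention.
#' @param path BED path (3+ columns, no header).
#' @return data.frame with `chrom`, `start`, `end` and `name` when present.
#' @export
load_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("malformed BED: fewer than 3 columns", call. = FALSE)
  out <- data.frame(chrom = normalize_chrom(raw[[1]]),
                    start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  check_intervals(out$chrom, out$start, out$end)
  out
}

#' Load gene models (BED4-style TSV with header)
#'
#' Columns: `chrom`, `start`, `end`, `gene` plus optional `loeuf`,
#' `oe_lof`, and per-class mutation-rate columns `rate_ptv`,
#' `rate_missense`, `rate_silent`. Coordinates follow `dialect`.
#' @inheritParams load_cnv_table
#' @return data.frame of gene models (class `gene_models`).
#' @export
load_gene_models <- function(path, dialect = "0-based-half-open") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("gene model table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  co <- .to_internal(as.numeric(raw$start), as.numeric(raw$end), dialect)
  check_intervals(raw$chrom, co$start, co$end)
  out <- data.frame(gene_id = as.character(raw$gene),
                    chrom = normalize_chrom(raw$chrom),
                    start = co$start, end = co$end, stringsAsFactors = FALSE)
  for (col in c("loeuf", "oe_lof", "rate_ptv", "rate_missense", "rate_silent"))
    if (col %in% names(raw)) out[[col]] <- as.numeric(raw[[col]])
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Load probe positions
#'
#' TSV with header columns `chrom`, `pos` (1-based probe midpoints) and an
#' optional `platform` column. Positions are sorted per chromosome.
#' @param path TSV path.
#' @return data.frame `chrom`, `pos` (, `platform`), sorted.
#' @export
load_probes <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(raw)))
    stop("probe table needs columns chrom, pos", call. = FALSE)
  out <- data.frame(chrom = normalize_chrom(raw$chrom),
                    pos = as.numeric(raw$pos), stringsAsFactors = FALSE)
  if ("platform" %in% names(raw)) out$platform <- as.character(raw$platform)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Load a de novo variant table
#'
#' Columns: `sample`, `gene`, `consequence`, `maf`, `cohort`; optional
#' `severity` (CADD-like score).
#' @param path TSV path.
#' @return data.frame (class `dnv_records`).
#' @export
load_dnv_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "gene", "consequence", "maf", "cohort")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("DNV table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(sample_id = as.character(raw$sample),
                    gene_id = as.character(raw$gene),
                    consequence_term = tolower(raw$consequence),
                    severity = if ("severity" %in% names(raw))
                      as.numeric(raw$severity) else NA_real_,
                    population_maf = as.numeric(raw$maf),
                    cohort_id = as.character(raw$cohort),
                    stringsAsFactors = FALSE)
  if (any(out$population_maf < 0 | out$population_maf > 1, na.rm = TRUE))
    stop("population MAF outside [0, 1]", call. = FALSE)
  class(out) <- c("dnv_records", "data.frame")
  out
}

#' Load a per-gene mutation-rate table
#'
#' Columns: `gene`, `rate_ptv`, `rate_missense`, `rate_silent`
#' (per-generation probabilities per haploid genome).
#' @param path TSV path.
#' @return data.frame keyed by `gene_id`.
#' @export
load_rate_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "rate_ptv", "rate_missense", "rate_silent")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("rate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(gene_id = as.character(raw$gene),
             rate_ptv = as.numeric(raw$rate_ptv),
             rate_missense = as.numeric(raw$rate_missense),
             rate_silent = as.numeric(raw$rate_silent),
             stringsAsFactors = FALSE)
}

#' Write a generic results table as TSV with stable column order
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
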