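#' Gene-wise and region-wise permutation association testing
#'
#' The unit of evidence is the carrier: an individual carrying at least one
#' QC-passed deletion over a target (gene or region) counts once for that
#' target, and a deletion spanning several genes contributes a carrier to
#' each of them. The test statistic per target is the number of case
#' carriers; significance comes from permuting case/control labels over
#' individuals (each individual's full CNV profile travels with its label),
#' giving a pointwise empirical p-value (EMP1) and a min-p family-wise
#' adjusted one (EMP2).
#'
#' @name cnv-association
NULL

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Carrier incidence and counts per target
#'
#' @param cnvs QC-passed `cnv_calls` (typically deletions).
#' @param targets data.frame with `chrom`, `start`, `end` and an id column
#'   (`gene_id` or `name`); overlap means at least one shared base.
#' @param samples data.frame with `sample_id`, `phenotype` covering the full
#'   cohort (CNV-free individuals included -- they matter for the
#'   permutation margins).
#' @return list of class `overlap_counts`: `counts` (per-target case/control
#'   carriers), `incidence` (sparse targets x individuals 0/1 matrix),
#'   `phenotype` (per individual), `carriers` (per-target sample id lists).
#' @export
gene_overlap_counts <- function(cnvs, targets, samples) {
  if (nrow(targets) == 0) stop("empty target list", call. = FALSE)
  id_col <- if ("gene_id" %in% names(targets)) "gene_id" else "name"
  ids <- as.character(targets[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate target ids", call. = FALSE)
  stopifnot(!anyDuplicated(samples$sample_id))
  sample_idx <- match(cnvs$sample_id, samples$sample_id)
  if (any(is.na(sample_idx)))
    stop("CNV calls from sample(s) absent from the cohort roster",
         call. = FALSE)
  pairs <- vector("list", length(unique(targets$chrom)))
  k <- 0L
  for (ch in unique(targets$chrom)) {
    ti <- which(targets$chrom == ch)
    ci <- which(cnvs$chrom == ch)
    if (!length(ci)) next
    tg <- IRanges::IRanges(start = targets$start[ti] + 1L,
                           end = targets$end[ti])
    cv <- IRanges::IRanges(start = cnvs$start[ci] + 1L, end = cnvs$end[ci])
    hits <- IRanges::findOverlaps(tg, cv)
    if (!length(hits)) next
    k <- k + 1L
    pairs[[k]] <- cbind(target = ti[S4Vectors::queryHits(hits)],
                        indiv = sample_idx[ci[S4Vectors::subjectHits(hits)]])
  }
  pr <- if (k) unique(do.call(rbind, pairs[seq_len(k)])) else
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("target", "indiv")))
  inc <- Matrix::sparseMatrix(i = pr[, "target"], j = pr[, "indiv"], x = 1,
                              dims = c(nrow(targets), nrow(samples)),
                              dimnames = list(ids, samples$sample_id))
  phen <- tolower(samples$phenotype)
  counts <- data.frame(
    target = ids,
    case_carriers = as.integer(inc %*% as.numeric(phen == "case")),
    control_carriers = as.integer(inc %*% as.numeric(phen == "control")),
    stringsAsFactors = FALSE)
  carriers <- lapply(seq_len(nrow(targets)), function(i)
    samples$sample_id[which(inc[i, ] > 0)])
  names(carriers) <- ids
  structure(list(counts = counts, incidence = inc, phenotype = phen,
                 carriers = carriers),
            class = "overlap_counts")
}

#' Label-permutation burden test (EMP1/EMP2)
#'
#' One-sided for case excess. With observed statistic `T_g` (case carriers)
#' and permuted statistics `T*_{g,b}`, `emp1_g = (1 + #\{b: T*_{g,b} >=
#' T_g\}) / (N + 1)`. EMP2 is the min-p (Westfall-Young style) family-wise
#' adjustment: each permutation's best pointwise p across targets is
#' compared against the target's own pointwise p.
#'
#' @param counts an `overlap_counts` object.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed (results are deterministic given the seed).
#' @param strata optional per-individual stratum labels (e.g. study ids);
#'   when given, labels are permuted within strata, preserving each
#'   stratum's case count. Default NULL = unstratified.
#' @param block column multiplication block size (memory/speed knob).
#' @return data.frame of class `permutation_result`: target, case/control
#'   carriers, `emp1`, `emp2`, `n_perm`.
#' @export
permutation_gene_test <- function(counts, n_perm = 10000, seed = NULL,
                                  strata = NULL, block = 512L) {
  stopifnot(inherits(counts, "overlap_counts"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  phen <- counts$phenotype
  n_case <- sum(phen == "case"); n_ctrl <- sum(phen == "control")
  if (n_case == 0 || n_ctrl == 0)
    stop("cohort must contain both cases and controls", call. = FALSE)
  inc <- counts$incidence
  n <- length(phen); g <- nrow(inc)
  if (!is.null(strata)) {
    stopifnot(length(strata) == n)
    strata_idx <- split(seq_len(n), strata)
    strata_k <- vapply(strata_idx, function(i) sum(phen[i] == "case"), 0L)
  }
  obs <- counts$counts$case_carriers
  perm <- matrix(0L, nrow = g, ncol = n_perm)
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      z <- matrix(0, nrow = n, ncol = b)
      for (j in seq_len(b)) {
        if (is.null(strata)) {
          z[sample.int(n, n_case), j] <- 1
        } else {
          for (s in seq_along(strata_idx)) {
            idx <- strata_idx[[s]]
            if (strata_k[s] > 0)
              z[idx[sample.int(length(idx), strata_k[s])], j] <- 1
          }
        }
      }
      perm[, done + seq_len(b)] <- as.matrix(inc %*% z)
      done <- done + b
    }
  })
  emp1 <- (1 + rowSums(perm >= obs)) / (n_perm + 1)
  # pointwise p of every permuted statistic, via per-gene suffix counts
  # over the integer statistic range 0..n_case
  pw_min <- rep(1, n_perm)
  for (i in seq_len(g)) {
    cnt <- tabulate(perm[i, ] + 1L, nbins = n_case + 1L)
    ge <- rev(cumsum(rev(cnt)))            # ge[v+1] = #{b: T*_{i,b} >= v}
    p_i <- (1 + ge[perm[i, ] + 1L]) / (n_perm + 1)
    pw_min <- pmin(pw_min, p_i)
  }
  emp2 <- (1 + vapply(emp1, function(p) sum(pw_min <= p), 0L)) / (n_perm + 1)
  out <- data.frame(target = counts$counts$target,
                    case_carriers = obs,
                    control_carriers = counts$counts$control_carriers,
                    emp1 = emp1, emp2 = pmax(emp1, emp2), n_perm = n_perm,
                    stringsAsFactors = FALSE)
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Region-wise permutation test (syndrome regions)
#'
#' Same machinery as the gene-wise test, run over externally supplied
#' regions (e.g. a DECIPHER-style deletion-syndrome BED).
#'
#' @param cnvs QC-passed `cnv_calls`.
#' @param regions data.frame from [load_bed] (needs a `name` column) or a
#'   BED path.
#' @param samples cohort roster (`sample_id`, `phenotype`).
#' @inheritParams permutation_gene_test
#' @return `permutation_result` data.frame.
#' @export
syndrome_region_test <- function(cnvs, regions, samples, n_perm = 10000,
                                 seed = NULL) {
  if (is.character(regions)) regions <- load_bed(regions)
  if (!"name" %in% names(regions))
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  oc <- gene_overlap_counts(cnvs, regions, samples)
  permutation_gene_test(oc, n_perm = n_perm, seed = seed)
}

#' Merge significant genes into loci
#'
#' Significant genes are joined into one locus when they share at least one
#' supporting case deletion (transitively), reflecting that a single large
#' deletion drives several adjacent genes to significance. Locus span is
#' the union span of its member genes; loci are sorted by position.
#'
#' @param sig_genes `gene_models`-style data.frame of the significant genes.
#' @param cnvs QC-passed case deletions (controls are ignored).
#' @return data.frame: `locus_id`, `chrom`, `start`, `end`, `n_genes`,
#'   `member_genes` (comma-separated).
#' @export
merge_significant_loci <- function(sig_genes, cnvs) {
  if (nrow(sig_genes) == 0)
    return(data.frame(locus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_genes = integer(), member_genes = character(),
                      stringsAsFactors = FALSE))
  case_cnvs <- cnvs[cnvs$phenotype == "case", , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(sig_genes), directed = FALSE)
  for (ch in unique(sig_genes$chrom)) {
    ti <- which(sig_genes$chrom == ch)
    ci <- which(case_cnvs$chrom == ch)
    if (!length(ci) || !length(ti)) next
    tg <- IRanges::IRanges(start = sig_genes$start[ti] + 1L,
                           end = sig_genes$end[ti])
    cv <- IRanges::IRanges(start = case_cnvs$start[ci] + 1L,
                           end = case_cnvs$end[ci])
    hits <- IRanges::findOverlaps(cv, tg)
    if (!length(hits)) next
    by_cnv <- split(ti[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    for (genes in by_cnv) {
      genes <- unique(genes)
      if (length(genes) > 1)
        g <- igraph::add_edges(g, as.vector(rbind(genes[1], genes[-1])))
    }
  }
  comp <- igraph::components(g)$membership
  loci <- lapply(split(seq_len(nrow(sig_genes)), comp), function(idx) {
    data.frame(chrom = sig_genes$chrom[idx[1]],
               start = min(sig_genes$start[idx]),
               end = max(sig_genes$end[idx]),
               n_genes = length(idx),
               member_genes = paste(sort(sig_genes$gene_id[idx]),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out <- out[order(as.integer(out$chrom), out$start), , drop = FALSE]
  out <- cbind(locus_id = sprintf("locus_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted logistic gene-set burden test
#'
#' Regresses case/control status on the number of genes of the set
#' disrupted by at least one of the individual's deletions, adjusting for
#' the individual's averaged CNV size, number of CNV segments, and
#' categorical study membership (one-hot, first study as reference).
#' Individuals without CNVs contribute predictor 0 and size covariate 0.
#'
#' @param cnvs QC-passed `cnv_calls`.
#' @param genes `gene_models` data.frame (universe with coordinates).
#' @param gene_set character vector of gene ids (non-empty).
#' @param samples cohort roster (`sample_id`, `phenotype`, `study_id`).
#' @return one-row data.frame (class `burden_result`): `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n_case`, `n_control`, `status`
#'   (`"ok"` or `"separation"`).
#' @export
geneset_burden_logistic <- function(cnvs, genes, gene_set, samples) {
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  set_genes <- genes[genes$gene_id %in% gene_set, , drop = FALSE]
  phen <- tolower(samples$phenotype)
  y <- as.integer(phen == "case")
  n_genes_hit <- integer(nrow(samples))
  if (nrow(set_genes) > 0 && nrow(cnvs) > 0) {
    oc <- gene_overlap_counts(cnvs, set_genes, samples)
    n_genes_hit <- as.integer(Matrix::colSums(oc$incidence))
  }
  sizes <- tapply((cnvs$end - cnvs$start), cnvs$sample_id, mean)
  nseg <- table(cnvs$sample_id)
  avg_size <- as.numeric(sizes[samples$sample_id])
  n_seg <- as.integer(nseg[samples$sample_id])
  avg_size[is.na(avg_size)] <- 0
  n_seg[is.na(n_seg)] <- 0L
  dat <- data.frame(y = y, hits = n_genes_hit,
                    avg_size = avg_size / 1e6, n_seg = n_seg,
                    study = factor(samples$study_id))
  form <- if (nlevels(dat$study) > 1)
    y ~ hits + avg_size + n_seg + study else y ~ hits + avg_size + n_seg
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  beta <- co["hits", "Estimate"]; se <- co["hits", "Std. Error"]
  if (!is.finite(se) || se > 100) sep <- TRUE
  out <- data.frame(odds_ratio = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p_value = co["hits", "Pr(>|z|)"],
                    n_case = sum(y == 1), n_control = sum(y == 0),
                    status = if (sep) "separation" else "ok",
                    stringsAsFactors = FALSE)
  class(out) <- c("burden_result", "data.frame")
  out
}
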