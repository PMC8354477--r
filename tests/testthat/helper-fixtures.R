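# shared fixture builders (everything generated in code; no stored data)

iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)

make_samples <- function(n_case, n_control, n_studies = 1) {
  n <- n_case + n_control
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    phenotype = rep(c("case", "control"), c(n_case, n_control)),
    subphenotype = NA_character_,
    study_id = paste0("study_", rep_len(seq_len(n_studies), n)),
    stringsAsFactors = FALSE)
}

# quick cnv_calls builder; maf/probes default to passing values
make_cnvs <- function(chrom, start, end, sample_id,
                      phenotype = "case", type = "DEL", study = "study_1",
                      probe_count = 50L, internal_maf = 0) {
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   type = type, sample_id = sample_id,
                   phenotype = phenotype, subphenotype = NA_character_,
                   study_id = study, probe_count = as.integer(probe_count),
                   internal_maf = internal_maf, qc_flag = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

make_genes <- function(chrom, start, end, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- sprintf("G%02d", seq_along(start))
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   start = start, end = end, stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

empty_masks <- function() {
  z <- data.frame(chrom = character(), start = numeric(), end = numeric())
  list(telomeres = z, centromeres = z, segdups = z, probes = NULL)
}

# case-control cohort for the logistic burden test: 40 genes on a 4 Mb
# chromosome, background deletions anywhere, optional case-only excess of
# deletions over the 10-gene target set (so the set predictor is not
# collinear with the segment-count covariate)
build_burden_cohort <- function(seed, effect = 1, n = 2000) {
  set.seed(seed)
  samples <- make_samples(n / 2, n / 2, n_studies = 3)
  genes <- make_genes("1", (0:39) * 100000 + 10000, (0:39) * 100000 + 30000)
  gene_set <- genes$gene_id[1:10]
  rows <- list()
  n_bg <- stats::rpois(n, 1.5)
  for (i in which(n_bg > 0)) {
    st <- round(stats::runif(n_bg[i], 0, 4e6))
    rows[[length(rows) + 1]] <-
      make_cnvs("1", st, st + 30000, samples$sample_id[i],
                samples$phenotype[i], study = samples$study_id[i])
  }
  if (effect > 1) {
    for (i in which(samples$phenotype == "case")) {
      k <- stats::rbinom(1, 10, 0.02 * (effect - 1))
      if (k > 0) {
        gs <- sample.int(10, k)
        rows[[length(rows) + 1]] <-
          make_cnvs("1", genes$start[gs] - 100, genes$end[gs] + 100,
                    samples$sample_id[i], "case",
                    study = samples$study_id[i])
      }
    }
  }
  list(cnvs = do.call(rbind, rows), genes = genes, samples = samples,
       gene_set = gene_set)
}

# exact one-sided permutation p-values by full enumeration of case-label
# assignments (independent oracle for cohorts of <= 8 individuals)
enumerate_exact_p <- function(incidence, phenotype) {
  n <- length(phenotype)
  k <- sum(phenotype == "case")
  inc <- as.matrix(incidence)
  obs <- as.vector(inc %*% (phenotype == "case"))
  combs <- utils::combn(n, k)
  stats <- apply(combs, 2, function(idx) {
    z <- numeric(n); z[idx] <- 1
    as.vector(inc %*% z)
  })
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1)
  vapply(seq_len(nrow(inc)), function(g)
    mean(stats[g, ] >= obs[g]), numeric(1))
}
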