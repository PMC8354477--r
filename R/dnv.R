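#' De novo variant classification and recurrence testing
#'
#' DNVs are classified into three functional groups (protein-truncating,
#' missense, silent), filtered on population frequency, and tested per gene
#' for recurrence against per-gene, per-class mutation-rate expectations
#' (Samocha-style sequence-context rates). The expected count for a class
#' is `lambda = 2 * n_trios * rate` (diploid transmissions).
#'
#' @name dnv-enrichment
NULL

.ptv_terms <- c("stop_gained", "splice_acceptor", "splice_donor", "frameshift",
                "initiator_codon", "start_lost", "conserved_exon_terminus")
.missense_terms <- c("stop_lost", "missense", "inframe_deletion",
                     "inframe_insertion", "coding_sequence", "protein_altering")
.silent_terms <- c("synonymous")

#' Classify a consequence term into PTV / missense / silent
#'
#' Exact mapping over the controlled vocabulary; unknown terms return
#' `"unclassified"` rather than erroring so upstream annotation drift is
#' visible in the output.
#'
#' @param term character vector of lower-cased consequence terms.
#' @return character vector in `{"PTV","missense","silent","unclassified"}`.
#' @export
#' @examples
#' classify_consequence(c("stop_gained", "synonymous", "weird_term"))
classify_consequence <- function(term) {
  if (any(!nzchar(term)) || any(is.na(term)))
    stop("empty consequence term", call. = FALSE)
  term <- tolower(term)
  out <- rep("unclassified", length(term))
  out[term %in% .ptv_terms] <- "PTV"
  out[term %in% .missense_terms] <- "missense"
  out[term %in% .silent_terms] <- "silent"
  out
}

#' Filter DNVs on population frequency
#'
#' Excludes records with population MAF strictly greater than the
#' threshold (a variant at exactly the threshold is kept); variants absent
#' from the reference database carry MAF 0.
#'
#' @param records `dnv_records` data.frame.
#' @param maf_threshold exclusion bound (default 0.01).
#' @return filtered records.
#' @export
filter_dnvs <- function(records, maf_threshold = 0.01) {
  maf <- records$population_maf
  maf[is.na(maf)] <- 0
  records[maf <= maf_threshold, , drop = FALSE]
}

#' Compare per-class DNV rates between two cohorts
#'
#' Exact conditional two-rate Poisson test (binomial conditioning on the
#' total count, exposure = probands per cohort), two-sided, one p-value per
#' variant class.
#'
#' @param counts named list or matrix: per class, counts in cohort 1 and 2.
#'   A matrix must have classes as rows and two columns.
#' @param n_probands length-2 vector of proband counts.
#' @return named numeric vector of two-sided p-values per class.
#' @export
cohort_rate_comparison <- function(counts, n_probands) {
  if (length(n_probands) != 2 || any(n_probands <= 0))
    stop("need positive proband counts for exactly two cohorts", call. = FALSE)
  if (is.list(counts)) counts <- do.call(rbind, counts)
  apply_one <- function(x) {
    if (sum(x) == 0) return(1)
    stats::poisson.test(x, T = n_probands, r = 1)$p.value
  }
  p <- apply(counts, 1, apply_one)
  names(p) <- rownames(counts)
  p
}

#' Gene-wise Poisson recurrence test
#'
#' For each gene, compares the observed DNV count against the mutation-rate
#' expectation `lambda = 2 * n_trios * rate` for two nested classes -- PTV
#' alone and PTV + missense -- taking the upper Poisson tail
#' `P(X >= observed)` and Bonferroni-correcting over the two classes
#' (`p = min(1, 2 * min(tails))`). Genes with observations but no rate are
#' flagged and assigned p = 1.
#'
#' @param observed data.frame with `gene_id`, `n_ptv`, `n_missense` (counts
#'   after MAF filtering; see [dnv_gene_counts]).
#' @param rates rate table (`gene_id`, `rate_ptv`, `rate_missense`).
#' @param n_trios number of parent-offspring trios.
#' @return data.frame: `gene_id`, `n_ptv`, `n_missense`, `n_nsdnv`,
#'   `p_ptv`, `p_ns`, `p_poisson`, `rate_missing`.
#' @export
poisson_recurrence_test <- function(observed, rates, n_trios) {
  stopifnot(n_trios > 0)
  m <- match(observed$gene_id, rates$gene_id)
  lam_ptv <- 2 * n_trios * rates$rate_ptv[m]
  lam_ns <- 2 * n_trios * (rates$rate_ptv[m] + rates$rate_missense[m])
  upper_tail <- function(obs, lam)
    ifelse(obs == 0, 1, stats::ppois(obs - 1, lam, lower.tail = FALSE))
  p_ptv <- upper_tail(observed$n_ptv, lam_ptv)
  n_ns <- observed$n_ptv + observed$n_missense
  p_ns <- upper_tail(n_ns, lam_ns)
  p <- pmin(1, 2 * pmin(p_ptv, p_ns))
  missing_rate <- is.na(m)
  p[missing_rate] <- 1
  data.frame(gene_id = observed$gene_id,
             n_ptv = observed$n_ptv, n_missense = observed$n_missense,
             n_nsdnv = n_ns,
             p_ptv = ifelse(missing_rate, NA_real_, p_ptv),
             p_ns = ifelse(missing_rate, NA_real_, p_ns),
             p_poisson = p, rate_missing = missing_rate,
             stringsAsFactors = FALSE)
}

#' Per-gene, per-class DNV counts
#' @param records filtered `dnv_records`.
#' @return data.frame `gene_id`, `n_ptv`, `n_missense`, `n_silent`.
#' @export
dnv_gene_counts <- function(records) {
  cls <- classify_consequence(records$consequence_term)
  genes <- sort(unique(records$gene_id))
  tab <- table(factor(records$gene_id, levels = genes),
               factor(cls, levels = c("PTV", "missense", "silent")))
  data.frame(gene_id = genes,
             n_ptv = as.integer(tab[, "PTV"]),
             n_missense = as.integer(tab[, "missense"]),
             n_silent = as.integer(tab[, "silent"]),
             stringsAsFactors = FALSE)
}

#' Severity-weighted Monte-Carlo recurrence test (one gene)
#'
#' A simplified severity-score surrogate: the observed statistic is the
#' summed severity over the gene's non-synonymous DNVs; the null draws a
#' Poisson total count at the gene's summed non-synonymous rate, assigns
#' classes multinomially by rate share, and scores them with the per-class
#' weights. Per-variant score calibration is deliberately out of scope;
#' externally computed per-gene p-values can be supplied downstream
#' instead.
#'
#' @param records `dnv_records` of one gene (non-synonymous classes used).
#' @param rate_ptv,rate_missense per-generation class rates for the gene.
#' @param n_trios number of trios.
#' @param weights named numeric, severity weight per class
#'   (default `c(PTV = 2, missense = 1)`; arbitrary units).
#' @param n_sim Monte-Carlo draws (>= 100).
#' @param seed RNG seed.
#' @return scalar p-value `(1 + #\{sim >= obs\}) / (1 + n_sim)`.
#' @export
severity_weighted_test <- function(records, rate_ptv, rate_missense, n_trios,
                                   weights = c(PTV = 2, missense = 1),
                                   n_sim = 10000, seed = NULL) {
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  cls <- classify_consequence(records$consequence_term)
  keep <- cls %in% c("PTV", "missense")
  sev <- records$severity[keep]
  sev[is.na(sev)] <- unname(weights[cls[keep]][is.na(sev)])
  obs <- sum(sev)
  if (obs == 0) return(1)
  lam <- 2 * n_trios * (rate_ptv + rate_missense)
  share_ptv <- rate_ptv / (rate_ptv + rate_missense)
  with_seed(seed, {
    n_draw <- stats::rpois(n_sim, lam)
    k_ptv <- stats::rbinom(n_sim, n_draw, share_ptv)
    s_sim <- k_ptv * weights["PTV"] + (n_draw - k_ptv) * weights["missense"]
    (1 + sum(s_sim >= obs)) / (1 + n_sim)
  })
}

#' Combine the per-gene DNV component tests
#'
#' The reported gene-level DNV p-value is the minimum over the available
#' component tests (rate-based Poisson, severity surrogate, externally
#' supplied), Bonferroni-corrected over the protein-coding gene universe
#' (n = 18,272 by default).
#'
#' @param p_poisson required component.
#' @param p_severity,p_external optional components (NA = absent).
#' @param n_genes Bonferroni divisor.
#' @return data.frame with `p_dnv`, `p_bonferroni`, `no_component`.
#' @export
finalize_dnv_p <- function(p_poisson, p_severity = NA_real_,
                           p_external = NA_real_, n_genes = 18272) {
  comp <- cbind(p_poisson, p_severity, p_external)
  none <- apply(is.na(comp), 1, all)
  p_dnv <- apply(comp, 1, function(x)
    if (all(is.na(x))) 1 else min(x, na.rm = TRUE))
  data.frame(p_dnv = p_dnv,
             p_bonferroni = pmin(1, n_genes * p_dnv),
             no_component = none)
}
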